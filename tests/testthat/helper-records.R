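# Construct minimal single-study records for unit tests.

make_record <- function(variant_id = "rsX", allele_a = "A",
                        allele_b = "B", n_case = NULL, n_control = NULL,
                        case_a = NA, case_b = NA, ctrl_a = NA,
                        ctrl_b = NA,
                        case_AA = NA, case_AB = NA, case_BB = NA,
                        ctrl_AA = NA, ctrl_AB = NA, ctrl_BB = NA,
                        reported = NA, model = "allelic", or = NA,
                        ci_low = NA, ci_high = NA, p = NA,
                        design = "candidate", domain = "susceptibility",
                        drug = NA, pub = "pub1", cohort = pub,
                        maf_global = NA, raw = TRUE, significant = NA,
                        gene = "GENE") {
  if (is.null(n_case))
    n_case <- if (!is.na(case_a)) (case_a + case_b) / 2
              else if (!is.na(case_AA)) case_AA + case_AB + case_BB
              else 100
  if (is.null(n_control))
    n_control <- if (!is.na(ctrl_a)) (ctrl_a + ctrl_b) / 2
                 else if (!is.na(ctrl_AA)) ctrl_AA + ctrl_AB + ctrl_BB
                 else 100
  data.frame(
    pub_id = pub, cohort_id = cohort, variant_id = variant_id,
    gene = gene, chrom = NA, pos = NA, allele_a = allele_a,
    allele_b = allele_b, variant_class = "SNV", design = design,
    domain = domain, drug_class = drug, outcome_scale = NA,
    population = "test", n_case = n_case, n_control = n_control,
    directionality = "case",
    case_AA = case_AA, case_AB = case_AB, case_BB = case_BB,
    ctrl_AA = ctrl_AA, ctrl_AB = ctrl_AB, ctrl_BB = ctrl_BB,
    case_a = case_a, case_b = case_b, ctrl_a = ctrl_a, ctrl_b = ctrl_b,
    case_freq_b = NA, ctrl_freq_b = NA,
    reported_risk_allele = reported, reported_model = model,
    or_value = or, ci_low = ci_low, ci_high = ci_high, p_value = p,
    maf_study = NA, maf_global = maf_global,
    raw_data_available = raw, significant = significant,
    stringsAsFactors = FALSE)
}

make_catalog <- function(...) catalog(rbind(...))
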