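# Synthetic catalog generator with known ground truth: per-variant control
# risk-allele frequency p0 and allelic odds ratio psi; binomial allele
# counts under Hardy-Weinberg at the allele level; configurable
# discordant-risk-allele reporting and missing-raw-data rates.

#' Case risk-allele frequency implied by an allelic odds ratio
#'
#' Solves `odds(p1) = psi * odds(p0)`:
#' `p1 = psi*p0 / (1 + p0*(psi - 1))`.
#'
#' @param p0 control risk-allele frequency in (0,1).
#' @param psi allelic odds ratio > 0.
#' @return the implied case frequency `p1`.
#' @export
case_freq_from_or <- function(p0, psi) {
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must lie strictly in (0,1)")
  if (any(psi <= 0)) stop("psi must be > 0")
  psi * p0 / (1 + p0 * (psi - 1))
}

#' Truth parameters for one synthetic variant
#'
#' @param p0 control risk-allele (allele `b`) frequency in (0,1).
#' @param psi true allelic odds ratio (> 0; 1 = null variant).
#' @param n_case,n_control per-study arm sizes.
#' @param n_studies studies per variant.
#' @param discordance_rate probability that a study's *reported* risk
#'   allele (and reported odds-ratio direction) is flipped; raw counts
#'   are untouched.
#' @param missing_raw_rate probability that a study withholds raw counts
#'   (only the reported statistics survive).
#' @param design_mix fraction of studies labelled `gwas`.
#' @param genotypes also draw HWE genotype counts (enables carrier-unit
#'   paths).
#' @return list of validated parameters.
#' @export
truth_params <- function(p0 = 0.30, psi = 1.5, n_case = 2000,
                         n_control = 2000, n_studies = 5,
                         discordance_rate = 0, missing_raw_rate = 0,
                         design_mix = 0, genotypes = FALSE) {
  stopifnot(p0 > 0, p0 < 1, psi > 0, n_case >= 1, n_control >= 1,
            n_studies >= 1,
            discordance_rate >= 0, discordance_rate <= 1,
            missing_raw_rate >= 0, missing_raw_rate <= 1,
            design_mix >= 0, design_mix <= 1)
  list(p0 = p0, psi = psi, p1 = case_freq_from_or(p0, psi),
       n_case = n_case, n_control = n_control, n_studies = n_studies,
       discordance_rate = discordance_rate,
       missing_raw_rate = missing_raw_rate, design_mix = design_mix,
       genotypes = genotypes)
}

# Deterministic per-(seed, variant, study) substream seed below 2^31, so
# insertion order never changes a study's draw.
.substream_seed <- function(seed, variant_idx, study_idx) {
  (as.numeric(seed) * 2654435761 + variant_idx * 40503 + study_idx * 9973) %%
    2147483647
}

#' Simulate one case-control study record
#'
#' Case risk-allele counts are Binomial(2*n_case, p1) and control counts
#' Binomial(2*n_control, p0); the odds ratio, Woolf interval and allelic
#' chi-square p are self-computed from the drawn counts. With probability
#' `discordance_rate` the *reported* risk allele is flipped while the
#' reported odds-ratio magnitude is kept (the study mislabels the
#' protective allele as risk); with probability `missing_raw_rate` the
#' raw counts are withheld.
#'
#' @param t a [truth_params()].
#' @param variant_id variant label.
#' @param variant_idx,study_idx integer substream indices.
#' @param seed integer master seed.
#' @return single-row catalog records data.frame.
#' @export
simulate_study <- function(t, variant_id, variant_idx, study_idx, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(.substream_seed(seed, variant_idx, study_idx))
  if (t$genotypes) {
    draw_geno <- function(n, p) {
      pr <- c((1 - p)^2, 2 * p * (1 - p), p^2)  # AA, AB, BB under HWE
      as.integer(stats::rmultinom(1, n, pr))
    }
    gcase <- draw_geno(t$n_case, t$p1)
    gctrl <- draw_geno(t$n_control, t$p0)
    case_b <- 2L * gcase[3] + gcase[2]
    ctrl_b <- 2L * gctrl[3] + gctrl[2]
  } else {
    gcase <- gctrl <- rep(NA_integer_, 3)
    case_b <- stats::rbinom(1, 2 * t$n_case, t$p1)
    ctrl_b <- stats::rbinom(1, 2 * t$n_control, t$p0)
  }
  case_a <- 2L * t$n_case - case_b
  ctrl_a <- 2L * t$n_control - ctrl_b
  tab <- allele_table(case_b, case_a, ctrl_b, ctrl_a)
  est <- allelic_odds_ratio(tab)
  p <- allelic_chi2_p(tab)$p
  discordant <- stats::runif(1) < t$discordance_rate
  missing_raw <- stats::runif(1) < t$missing_raw_rate
  design <- if (stats::runif(1) < t$design_mix) "gwas" else "candidate"
  # report allele b as risk when the drawn OR favours b, then flip the
  # whole reported claim if discordant
  rep_allele <- if (est$or >= 1) "B" else "A"
  rep_or <- if (est$or >= 1) est$or else 1 / est$or
  rep_ci <- if (est$or >= 1) c(est$ci_low, est$ci_high)
            else c(1 / est$ci_high, 1 / est$ci_low)
  if (discordant) {
    # the discordant claim attaches the (>1) magnitude to the wrong
    # allele, as when a study labels the protective allele as risk
    rep_allele <- if (rep_allele == "B") "A" else "B"
  }
  pooled_fb <- (case_b + ctrl_b) / (2 * (t$n_case + t$n_control))
  data.frame(
    pub_id = sprintf("%s_s%02d", variant_id, study_idx),
    cohort_id = sprintf("%s_s%02d", variant_id, study_idx),
    variant_id = variant_id, gene = paste0("G_", variant_id),
    chrom = NA, pos = NA, allele_a = "A", allele_b = "B",
    variant_class = "SNV", design = design, domain = "susceptibility",
    drug_class = NA, outcome_scale = NA, population = "synthetic",
    n_case = t$n_case, n_control = t$n_control, directionality = "case",
    case_AA = gcase[1], case_AB = gcase[2], case_BB = gcase[3],
    ctrl_AA = gctrl[1], ctrl_AB = gctrl[2], ctrl_BB = gctrl[3],
    case_a = if (missing_raw) NA_integer_ else case_a,
    case_b = if (missing_raw) NA_integer_ else case_b,
    ctrl_a = if (missing_raw) NA_integer_ else ctrl_a,
    ctrl_b = if (missing_raw) NA_integer_ else ctrl_b,
    case_freq_b = NA, ctrl_freq_b = NA,
    reported_risk_allele = rep_allele, reported_model = "allelic",
    or_value = rep_or, ci_low = rep_ci[1], ci_high = rep_ci[2],
    p_value = p, maf_study = NA,
    maf_global = min(pooled_fb, 1 - pooled_fb),
    raw_data_available = !missing_raw, significant = p < 0.05,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic catalog with a ground-truth table
#'
#' @param params list of [truth_params()], one per variant (names become
#'   variant ids; unnamed entries are labelled `v01`, `v02`, ...).
#' @param seed integer master seed; the same seed and parameters give a
#'   byte-identical catalog.
#' @return list `catalog` (an [catalog()] object) and `truth`
#'   (data.frame `variant_id`, `p0`, `psi`, `p1`).
#' @export
generate_catalog <- function(params, seed = 1) {
  stopifnot(length(params) >= 1)
  ids <- names(params)
  if (is.null(ids) || any(ids == ""))
    ids <- sprintf("v%02d", seq_along(params))
  rows <- list()
  for (vi in seq_along(params)) {
    t <- params[[vi]]
    for (si in seq_len(t$n_studies)) {
      rows[[length(rows) + 1L]] <-
        simulate_study(t, ids[vi], vi, si, seed)
    }
  }
  recs <- do.call(rbind, rows)
  truth <- data.frame(
    variant_id = ids,
    p0 = vapply(params, `[[`, numeric(1), "p0"),
    psi = vapply(params, `[[`, numeric(1), "psi"),
    p1 = vapply(params, `[[`, numeric(1), "p1"),
    stringsAsFactors = FALSE)
  list(catalog = catalog(recs, metadata = list(source = "synthetic",
                                               seed = seed)),
       truth = truth)
}
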