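# Replication engine: group significant records by variant or gene, apply
# the >=2-study replication rule and the MAF filter, classify evidence
# buckets (candidate / gwas / both) and risk-allele consistency.

.domain_family <- function(domain) {
  ifelse(domain %in% c("response", "remission", "resistance"),
         "response", domain)
}

#' Group significant study records by variant or gene
#'
#' Records are first annotated with [annotate_associations()] (unless the
#' annotation columns are already present), non-significant and
#' unassessable records are dropped, and the remainder grouped by
#' `variant_id` (level `"variant"`) or `gene` (level `"gene"`). For the
#' response family the three treatment-outcome domains (response,
#' remission, resistance) are grouped together and only split later by
#' [stratify_response()].
#'
#' Study counting: strata from one publication count once (`pub_id`
#' deduplication) and publications drawn from one participant cohort
#' count once (`cohort_id` deduplication); `n_pubs` is the publication
#' count, `n_countable` the cohort-collapsed count used by the
#' replication rule.
#'
#' @param cat a [catalog()] or an annotated records data.frame.
#' @param level `"variant"` or `"gene"`.
#' @param domain `"susceptibility"` or `"response"` (the response family).
#' @param alpha significance threshold passed to the annotation step.
#' @return list of evidence groups; each has `key`, `level`, `domain`,
#'   `records`, `n_pubs`, `n_countable`, `n_candidate`, `n_gwas`.
#' @export
group_records <- function(cat, level = c("variant", "gene"),
                          domain = c("susceptibility", "response"),
                          alpha = 0.05) {
  level <- match.arg(level)
  domain <- match.arg(domain)
  r <- if (inherits(cat, "evsyn_catalog"))
    annotate_associations(cat, alpha = alpha) else cat
  r <- r[.domain_family(r$domain) == domain &
           r$assoc_basis != "unassessable" & r$is_significant, ,
         drop = FALSE]
  if (nrow(r) == 0) return(list())
  keyvals <- if (level == "variant") r$variant_id else r$gene
  keep <- !is.na(keyvals)
  r <- r[keep, , drop = FALSE]
  keyvals <- keyvals[keep]
  groups <- lapply(split(seq_len(nrow(r)), factor(keyvals,
                                                  unique(keyvals))),
                   function(idx) {
    g <- r[idx, , drop = FALSE]
    reps <- g[!duplicated(g$pub_id), , drop = FALSE]  # one row per pub
    coh <- ifelse(is.na(reps$cohort_id), reps$pub_id, reps$cohort_id)
    list(key = keyvals[idx[1]], level = level, domain = domain,
         records = g,
         n_pubs = nrow(reps),
         n_countable = length(unique(coh)),
         n_candidate = length(unique(reps$pub_id[reps$design ==
                                                   "candidate"])),
         n_gwas = length(unique(reps$pub_id[reps$design == "gwas"])),
         maf_global = g$maf_global[which(!is.na(g$maf_global))[1]])
  })
  unname(groups)
}

#' Keep groups replicated in at least `min_studies` studies
#'
#' @param groups list of evidence groups from [group_records()].
#' @param min_studies minimum countable (cohort-collapsed) study count.
#' @return filtered list of groups.
#' @export
filter_replicated <- function(groups, min_studies = 2) {
  if (min_studies < 1) stop("min_studies must be >= 1")
  Filter(function(g) g$n_countable >= min_studies, groups)
}

#' Split groups by the global minor-allele-frequency filter
#'
#' Groups whose global MAF is strictly below `threshold` are moved to the
#' excluded set; groups without a recorded MAF are kept with a warning.
#'
#' @param groups list of evidence groups.
#' @param threshold exclusion threshold in (0, 0.5].
#' @return list with elements `kept` and `excluded`.
#' @export
filter_maf <- function(groups, threshold = 0.05) {
  if (threshold <= 0 || threshold > 0.5)
    stop("threshold must lie in (0, 0.5]")
  maf <- vapply(groups, function(g)
    if (is.null(g$maf_global) || is.na(g$maf_global)) NA_real_
    else g$maf_global, numeric(1))
  if (any(is.na(maf)))
    warning(sum(is.na(maf)), " group(s) without global MAF kept")
  excl <- !is.na(maf) & maf < threshold
  list(kept = groups[!excl], excluded = groups[excl])
}

#' Classify a group's evidence buckets
#'
#' A replicated group belongs to bucket `candidate` if at least two
#' candidate-design publications support it, `gwas` if at least two GWAS
#' publications do, and `both` if at least one of each design does. A
#' group may hold several buckets (a variant with two candidate studies
#' and one GWAS study is both `candidate` and `both`); headline counts
#' sum bucket sizes, so overlapping groups count in each bucket.
#'
#' @param g one evidence group.
#' @return character vector, subset of `c("candidate","gwas","both")`.
#' @export
classify_evidence <- function(g) {
  b <- character(0)
  if (g$n_candidate >= 2) b <- c(b, "candidate")
  if (g$n_gwas >= 2) b <- c(b, "gwas")
  if (g$n_candidate >= 1 && g$n_gwas >= 1) b <- c(b, "both")
  b
}

#' Assess risk-allele consistency of a group
#'
#' Consistent means every study's harmonized risk allele is the same,
#' defined allele. Any study without a harmonizable direction makes the
#' status `undetermined`, which by default counts toward the inconsistent
#' headline tally (`undetermined_as` = `"inconsistent"`).
#'
#' @param g one evidence group (or any subset of its records).
#' @param records optional records data.frame overriding `g$records`.
#' @return list `status` (`consistent` / `inconsistent` / `undetermined`),
#'   `modal_allele` (the shared allele when consistent), `alleles`
#'   (per-allele study counts).
#' @export
assess_consistency <- function(g, records = NULL) {
  r <- if (!is.null(records)) records else g$records
  al <- r$risk_allele
  tab <- table(al[!is.na(al)])
  if (any(is.na(al)))
    return(list(status = "undetermined", modal_allele = NA_character_,
                alleles = tab))
  if (length(tab) == 1)
    list(status = "consistent", modal_allele = names(tab), alleles = tab)
  else
    list(status = "inconsistent", modal_allele = NA_character_,
         alleles = tab)
}

#' Partition a response-family group into pooling strata
#'
#' Pooling of treatment-outcome evidence never crosses the outcome type
#' (response vs remission vs resistance), the drug class, or the
#' harmonized risk allele; this returns the partition of a group's
#' records by that triple. Susceptibility groups stratify by risk allele
#' only.
#'
#' @param g one evidence group.
#' @return named list of records data.frames; names are
#'   `domain/drug_class/allele` labels (susceptibility: `allele`).
#' @export
stratify_response <- function(g) {
  r <- g$records
  allele <- ifelse(is.na(r$risk_allele), "<none>", r$risk_allele)
  key <- if (g$domain == "response") {
    drug <- ifelse(is.na(r$drug_class), "<na>", r$drug_class)
    paste(r$domain, drug, allele, sep = "/")
  } else {
    allele
  }
  split(r, factor(key, unique(key)))
}

#' Replication summary table (one row per variant-bucket entry)
#'
#' Reproduces the published accounting in which a group supported by both
#' designs appears once per bucket: an entry is (key, bucket) with the
#' bucket-relevant study subset (bucket `candidate` counts candidate
#' studies, `gwas` GWAS studies, `both` all studies). Consistency is
#' assessed per entry over that subset.
#'
#' @param groups replicated, MAF-filtered evidence groups.
#' @return data.frame with columns `key`, `bucket`, `n_studies`,
#'   `consistency`, `modal_allele`, `maf_global`.
#' @export
replication_summary <- function(groups) {
  rows <- list()
  for (g in groups) {
    for (b in classify_evidence(g)) {
      r <- switch(b,
        candidate = g$records[g$records$design == "candidate", ,
                              drop = FALSE],
        gwas = g$records[g$records$design == "gwas", , drop = FALSE],
        both = g$records)
      cons <- assess_consistency(g, records = r)
      rows[[length(rows) + 1L]] <- data.frame(
        key = g$key, bucket = b,
        n_studies = length(unique(r$pub_id)),
        consistency = cons$status,
        modal_allele = if (is.na(cons$modal_allele)) NA_character_
                       else cons$modal_allele,
        maf_global = if (is.null(g$maf_global) || is.na(g$maf_global))
          NA_real_ else g$maf_global,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(key = character(0), bucket = character(0),
                      n_studies = integer(0), consistency = character(0),
                      modal_allele = character(0),
                      maf_global = numeric(0)))
  do.call(rbind, rows)
}

#' Bucket sizes and unique-group count
#'
#' @param summary a [replication_summary()] table.
#' @return list `candidate`, `gwas`, `both`, `bucket_sum`, `n_unique`.
#' @export
bucket_sizes <- function(summary) {
  list(candidate = sum(summary$bucket == "candidate"),
       gwas = sum(summary$bucket == "gwas"),
       both = sum(summary$bucket == "both"),
       bucket_sum = nrow(summary),
       n_unique = length(unique(summary$key)))
}
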