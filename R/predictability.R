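# Diagnostic predictability: 2x2 risk-allele confusion tables per study,
# pooled by summation across concordant studies, yielding sensitivity,
# specificity and positive predictive value; eligibility rules and the
# single-risk-allele shortlist.

#' Confusion table (TP/FN/TN/FP) for risk-allele carriage
#'
#' TP and FN are risk-allele and wild-type counts in cases; TN and FP are
#' wild-type and risk-allele counts in controls. Unit `"allele"` counts
#' alleles (each subject contributes two); `"carrier"` counts subjects
#' with at least one risk allele and requires genotype counts.
#'
#' @param tp,fn,tn,fp non-negative counts.
#' @param unit `"allele"` or `"carrier"`.
#' @return object of class `confusion2x2`.
#' @export
confusion2x2 <- function(tp, fn, tn, fp, unit = "allele") {
  x <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(is.na(x)) || any(x < 0)) stop("counts must be non-negative")
  structure(c(as.list(x),
              list(unit = match.arg(unit, c("allele", "carrier")))),
            class = "confusion2x2")
}

#' Build a study's confusion table for a given risk allele
#'
#' Returns `NULL` (an ineligibility signal, not an error) when the study
#' has no usable raw data for the requested unit or the risk allele does
#' not match the variant's alleles.
#'
#' @param s one catalog record.
#' @param risk_allele the harmonized risk allele to count as "positive".
#' @param unit `"allele"` (default) or `"carrier"`.
#' @return a [confusion2x2()] or `NULL`.
#' @export
confusion_from_study <- function(s, risk_allele, unit = "allele") {
  unit <- match.arg(unit, c("allele", "carrier"))
  if (is.na(risk_allele)) return(NULL)
  risk_is_b <- !is.na(s$allele_b) && risk_allele == s$allele_b
  risk_is_a <- !is.na(s$allele_a) && risk_allele == s$allele_a
  if (!risk_is_a && !risk_is_b) return(NULL)
  if (unit == "carrier") {
    if (!is.na(s$raw_data_available) && !s$raw_data_available) return(NULL)
    if (is.na(s$case_AA)) return(NULL)
    if (risk_is_b) {
      confusion2x2(tp = s$case_AB + s$case_BB, fn = s$case_AA,
                   tn = s$ctrl_AA, fp = s$ctrl_AB + s$ctrl_BB,
                   unit = "carrier")
    } else {
      confusion2x2(tp = s$case_AA + s$case_AB, fn = s$case_BB,
                   tn = s$ctrl_BB, fp = s$ctrl_AA + s$ctrl_AB,
                   unit = "carrier")
    }
  } else {
    ac <- .study_allele_counts(s)
    if (is.null(ac)) return(NULL)
    if (risk_is_b) {
      confusion2x2(tp = ac$case_b, fn = ac$case_a,
                   tn = ac$ctrl_a, fp = ac$ctrl_b)
    } else {
      confusion2x2(tp = ac$case_a, fn = ac$case_b,
                   tn = ac$ctrl_b, fp = ac$ctrl_a)
    }
  }
}

#' Pool confusion tables by element-wise summation
#'
#' @param confusions non-empty list of [confusion2x2()] with one unit.
#' @return the pooled [confusion2x2()].
#' @export
pool_confusions <- function(confusions) {
  if (!length(confusions)) stop("cannot pool an empty set")
  units <- unique(vapply(confusions, `[[`, character(1), "unit"))
  if (length(units) != 1) stop("cannot pool mixed units: ",
                               paste(units, collapse = ", "))
  confusion2x2(tp = sum(vapply(confusions, `[[`, numeric(1), "tp")),
               fn = sum(vapply(confusions, `[[`, numeric(1), "fn")),
               tn = sum(vapply(confusions, `[[`, numeric(1), "tn")),
               fp = sum(vapply(confusions, `[[`, numeric(1), "fp")),
               unit = units)
}

#' Sensitivity, specificity and PPV of a confusion table
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP).
#' Unrounded values are returned; display rounding (2 decimals, half-up)
#' is left to [render_tables()]. A zero denominator yields `NA` for that
#' metric.
#'
#' @param c a [confusion2x2()].
#' @return list `sensitivity`, `specificity`, `ppv`.
#' @export
confusion_metrics <- function(c) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = safe(c$tp, c$tp + c$fn),
       specificity = safe(c$tn, c$tn + c$fp),
       ppv = safe(c$tp, c$tp + c$fp))
}

# round half-up at k decimals (display convention)
round_half_up <- function(x, k = 2) floor(x * 10^k + 0.5) / 10^k

#' Determine eligible pooling strata of an evidence group
#'
#' A stratum (risk allele, plus outcome type and drug class for the
#' response family) is eligible when at least `min_pooled` cohort-distinct
#' studies with available raw data share it. Ineligible strata carry a
#' reason code: `no_raw_data`, `singleton_stratum` (fewer than
#' `min_pooled` countable studies) or `discordant_only` (no defined risk
#' allele).
#'
#' @param g one evidence group from [group_records()].
#' @param min_pooled minimum pooled stratum size (default 2).
#' @return data.frame with columns `stratum`, `risk_allele`, `n_studies`,
#'   `n_raw`, `eligible`, `reason`.
#' @export
eligible_strata <- function(g, min_pooled = 2) {
  strata <- stratify_response(g)
  rows <- lapply(names(strata), function(nm) {
    r <- strata[[nm]]
    allele <- r$risk_allele[1]
    reps <- r[!duplicated(r$pub_id), , drop = FALSE]
    coh <- ifelse(is.na(reps$cohort_id), reps$pub_id, reps$cohort_id)
    raw <- !is.na(reps$raw_data_available) & reps$raw_data_available
    n_raw <- length(unique(coh[raw]))
    if (is.na(allele)) {
      elig <- FALSE; reason <- "discordant_only"
    } else if (n_raw >= min_pooled) {
      elig <- TRUE; reason <- NA_character_
    } else if (length(unique(coh)) < min_pooled) {
      elig <- FALSE; reason <- "singleton_stratum"
    } else {
      elig <- FALSE; reason <- "no_raw_data"
    }
    data.frame(stratum = nm, risk_allele = allele,
               n_studies = length(unique(coh)), n_raw = n_raw,
               eligible = elig, reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pooled predictability per eligible stratum
#'
#' One row per eligible stratum of each group. The pooled metrics are
#' computed from per-study confusion tables whenever the contributing
#' studies carry raw counts (or reconstructable frequencies); strata that
#' are eligible by their availability flags but whose counts are not in
#' the catalog yield `NA` metrics while still being counted as
#' predictability-assessable.
#'
#' @param groups list of evidence groups.
#' @param min_pooled minimum pooled stratum size.
#' @param unit `"allele"` or `"carrier"`.
#' @return data.frame with columns `key`, `stratum`, `risk_allele`,
#'   `n_studies_pooled`, `n_case_total`, `n_ctrl_total`, `sensitivity`,
#'   `specificity`, `ppv`.
#' @export
predictability_table <- function(groups, min_pooled = 2, unit = "allele") {
  rows <- list()
  for (g in groups) {
    es <- eligible_strata(g, min_pooled = min_pooled)
    strata <- stratify_response(g)
    for (i in seq_len(nrow(es))) {
      if (!es$eligible[i]) next
      r <- strata[[es$stratum[i]]]
      raw <- r[!is.na(r$raw_data_available) & r$raw_data_available, ,
               drop = FALSE]
      confs <- Filter(Negate(is.null),
                      lapply(seq_len(nrow(raw)), function(j)
                        confusion_from_study(raw[j, ],
                                             es$risk_allele[i],
                                             unit = unit)))
      if (length(confs)) {
        pooled <- pool_confusions(confs)
        m <- confusion_metrics(pooled)
      } else {
        m <- list(sensitivity = NA_real_, specificity = NA_real_,
                  ppv = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        key = g$key, stratum = es$stratum[i],
        risk_allele = es$risk_allele[i],
        n_studies_pooled = es$n_raw[i],
        n_case_total = sum(raw$n_case, na.rm = TRUE),
        n_ctrl_total = sum(raw$n_control, na.rm = TRUE),
        sensitivity = m$sensitivity, specificity = m$specificity,
        ppv = m$ppv, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(key = character(0), stratum = character(0),
                      risk_allele = character(0),
                      n_studies_pooled = integer(0),
                      n_case_total = integer(0), n_ctrl_total = integer(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      ppv = numeric(0)))
  do.call(rbind, rows)
}

#' Shortlist of replicated single-risk-allele variants with assessable PPV
#'
#' A variant is shortlisted when it is (a) replicated, (b) risk-allele
#' consistent across all its studies, and (c) carries at least one
#' predictability-assessable stratum (for the response family, rule (b)
#' and (c) apply within a single drug-class/outcome stratum, i.e. the
#' assessable stratum's allele is the variant's only risk allele).
#'
#' @param groups replicated, MAF-filtered evidence groups.
#' @param pred a [predictability_table()] over the same groups.
#' @return data.frame `key`, `risk_allele`, `stratum`.
#' @export
shortlist_variants <- function(groups, pred) {
  rows <- list()
  for (g in groups) {
    cons <- assess_consistency(g)
    if (cons$status != "consistent") next
    p <- pred[pred$key == g$key &
                pred$risk_allele == cons$modal_allele, , drop = FALSE]
    if (nrow(p) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      key = g$key, risk_allele = cons$modal_allele,
      stratum = p$stratum[1], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(key = character(0), risk_allele = character(0),
                      stratum = character(0)))
  do.call(rbind, rows)
}
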