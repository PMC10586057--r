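# Allelic association statistics recomputed from raw counts, and
# harmonization of each study's reported risk allele to a common direction.

#' Collapse genotype counts to allele counts
#'
#' For a biallelic variant with genotypes AA/AB/BB, each subject
#' contributes two alleles: count of allele b is `2*BB + AB`, of allele a
#' `2*AA + AB`, per group.
#'
#' @param case_AA,case_AB,case_BB,ctrl_AA,ctrl_AB,ctrl_BB non-negative
#'   integer genotype counts.
#' @return list with `case_a`, `case_b`, `ctrl_a`, `ctrl_b`.
#' @export
alleles_from_genotypes <- function(case_AA, case_AB, case_BB,
                                   ctrl_AA, ctrl_AB, ctrl_BB) {
  gc <- c(case_AA, case_AB, case_BB, ctrl_AA, ctrl_AB, ctrl_BB)
  if (any(is.na(gc)) || any(gc < 0))
    stop("genotype counts must be non-negative and complete")
  if (sum(gc[1:3]) == 0 || sum(gc[4:6]) == 0)
    stop("empty group: each group needs at least one genotyped subject")
  list(case_a = 2L * case_AA + case_AB, case_b = 2L * case_BB + case_AB,
       ctrl_a = 2L * ctrl_AA + ctrl_AB, ctrl_b = 2L * ctrl_BB + ctrl_AB)
}

#' 2x2 allele table
#'
#' Risk-vs-wild allele counts in cases and controls. `unit` records
#' whether counts are alleles (2 per subject) or carriers (subjects).
#'
#' @param case_risk,case_wild,ctrl_risk,ctrl_wild non-negative counts.
#' @param unit `"allele"` or `"carrier"`.
#' @return object of class `allele_table`.
#' @export
allele_table <- function(case_risk, case_wild, ctrl_risk, ctrl_wild,
                         unit = "allele") {
  x <- c(case_risk = case_risk, case_wild = case_wild,
         ctrl_risk = ctrl_risk, ctrl_wild = ctrl_wild)
  if (any(is.na(x)) || any(x < 0)) stop("counts must be non-negative")
  if (sum(x) == 0) stop("at least one margin must be positive")
  structure(c(as.list(x), list(unit = match.arg(unit,
                                                c("allele", "carrier")))),
            class = "allele_table")
}

#' Allelic odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `(case_risk*ctrl_wild)/(case_wild*ctrl_risk)`
#' with a log-scale normal (Woolf) interval, `SE = sqrt(sum 1/cell)`,
#' `z = 1.959964`. When any cell is zero the Haldane-Anscombe correction
#' (+0.5 to every cell) is applied for the estimate and interval only.
#'
#' @param t an [allele_table()].
#' @param zero_cell `"haldane"` (default) or `"error"`.
#' @return list `or`, `ci_low`, `ci_high`.
#' @export
allelic_odds_ratio <- function(t, zero_cell = c("haldane", "error")) {
  zero_cell <- match.arg(zero_cell)
  x <- c(t$case_risk, t$case_wild, t$ctrl_risk, t$ctrl_wild)
  if ((x[1] + x[2]) == 0 || (x[3] + x[4]) == 0)
    stop("undefined estimate: a group has no observations")
  if (any(x == 0)) {
    if (zero_cell == "error") stop("zero cell in allele table")
    x <- x + 0.5
  }
  or <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  z <- 1.959964
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se))
}

#' Allelic chi-square test p-value
#'
#' Pearson chi-square on the 2x2 allele table, 1 df, upper tail. No
#' continuity correction by default (the conventional "allelic P");
#' `correct = TRUE` applies Yates' correction.
#'
#' @param t an [allele_table()].
#' @param correct logical, Yates continuity correction.
#' @return list `statistic`, `p`.
#' @export
allelic_chi2_p <- function(t, correct = FALSE) {
  m <- matrix(c(t$case_risk, t$case_wild, t$ctrl_risk, t$ctrl_wild),
              nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("undefined test: zero margin in allele table")
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Fisher's exact p-value on the allele table
#'
#' Offered as the small-cell alternative to the chi-square test.
#'
#' @param t an [allele_table()].
#' @return two-sided p-value.
#' @export
allelic_fisher_p <- function(t) {
  m <- matrix(c(t$case_risk, t$case_wild, t$ctrl_risk, t$ctrl_wild),
              nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

# Reconstruct allele counts for one study record. Order of preference:
# explicit allele counts, genotype counts, allele-b frequencies
# (round-half-up of freq * 2n). Returns counts of alleles a/b per group or
# NULL when no raw data is available (or the record is flagged
# raw_data_available = FALSE).
.study_allele_counts <- function(s) {
  if (!is.na(s$raw_data_available) && !s$raw_data_available) return(NULL)
  if (!is.na(s$case_a)) {
    return(list(case_a = s$case_a, case_b = s$case_b,
                ctrl_a = s$ctrl_a, ctrl_b = s$ctrl_b, basis = "raw_counts"))
  }
  if (!is.na(s$case_AA)) {
    ac <- alleles_from_genotypes(s$case_AA, s$case_AB, s$case_BB,
                                 s$ctrl_AA, s$ctrl_AB, s$ctrl_BB)
    ac$basis <- "raw_counts"
    return(ac)
  }
  if (!is.na(s$case_freq_b) && !is.na(s$ctrl_freq_b) &&
      !is.na(s$n_case) && !is.na(s$n_control)) {
    rnd <- function(x) floor(x + 0.5)  # round half-up
    cb <- rnd(s$case_freq_b * 2 * s$n_case)
    ub <- rnd(s$ctrl_freq_b * 2 * s$n_control)
    return(list(case_a = 2 * s$n_case - cb, case_b = cb,
                ctrl_a = 2 * s$n_control - ub, ctrl_b = ub,
                basis = "reconstructed_freq"))
  }
  NULL
}

# Map a reported risk label (allele or genotype string such as "TT"/"SS")
# to one of the two alleles; NA when not attributable.
.label_to_allele <- function(label, allele_a, allele_b) {
  if (is.na(label)) return(NA_character_)
  for (al in c(allele_a, allele_b)) {
    if (is.na(al)) next
    if (label == al) return(al)
    # homozygous genotype label: the allele repeated (e.g. "TT", "SS")
    if (nchar(al) >= 1 &&
        label == paste0(al, al)) return(al)
  }
  NA_character_
}

.other_allele <- function(allele, allele_a, allele_b) {
  if (is.na(allele) || is.na(allele_a) || is.na(allele_b))
    return(NA_character_)
  if (allele == allele_a) allele_b else if (allele == allele_b) allele_a
  else NA_character_
}

#' Harmonize a study's risk allele
#'
#' Returns the allele overrepresented in cases, resolving the common
#' inconsistency in which studies report a protective allele (odds ratio
#' below 1). Preference order: raw counts (allele with the higher case
#' frequency), then the reported allele flipped by the direction of the
#' reported odds ratio, then the allele composing a reported risk
#' genotype. A reported allele without any odds ratio is taken at face
#' value. An exact case/control frequency tie yields no risk allele.
#'
#' @param s one catalog record (single-row data.frame or list).
#' @return list `risk_allele` (allele string or `NA`) and `basis` (one of
#'   `raw_counts`, `reported_or_direction`, `reported_genotype`,
#'   `reported_allele`, `unknown`).
#' @export
harmonize_risk_allele <- function(s) {
  ac <- .study_allele_counts(s)
  if (!is.null(ac) && (ac$case_a + ac$case_b) > 0 &&
      (ac$ctrl_a + ac$ctrl_b) > 0) {
    fb_case <- ac$case_b / (ac$case_a + ac$case_b)
    fb_ctrl <- ac$ctrl_b / (ac$ctrl_a + ac$ctrl_b)
    if (fb_case == fb_ctrl)
      return(list(risk_allele = NA_character_, basis = "raw_counts"))
    allele <- if (fb_case > fb_ctrl) s$allele_b else s$allele_a
    return(list(risk_allele = allele, basis = "raw_counts"))
  }
  lab <- s$reported_risk_allele
  if (!is.na(lab)) {
    allele <- .label_to_allele(lab, s$allele_a, s$allele_b)
    is_genotype <- !is.na(allele) && allele != lab
    if (!is.na(allele)) {
      if (!is.na(s$or_value)) {
        if (s$or_value < 1)
          allele <- .other_allele(allele, s$allele_a, s$allele_b)
        basis <- if (is_genotype) "reported_genotype"
                 else "reported_or_direction"
        return(list(risk_allele = allele, basis = basis))
      }
      basis <- if (is_genotype) "reported_genotype" else "reported_allele"
      return(list(risk_allele = allele, basis = basis))
    }
  }
  list(risk_allele = NA_character_, basis = "unknown")
}

#' Select the association result to carry forward for one study
#'
#' Allelic association recomputed from raw data is preferred over the
#' reported (possibly genotypic) statistics whenever raw counts or
#' reconstructable frequencies are available; otherwise the reported odds
#' ratio, interval and p-value are used as published. The significance
#' flag uses the chosen p at alpha (strict `p < alpha`); an explicit
#' curated `significant` flag on the record overrides when the p-value is
#' not numerically available.
#'
#' @param s one catalog record.
#' @param alpha significance threshold (default 0.05, unadjusted).
#' @param test `"chisq"` (default), `"chisq_yates"` or `"fisher"`.
#' @return list `or`, `ci_low`, `ci_high`, `p`, `risk_allele`,
#'   `harmonize_basis`, `basis` (`raw_counts` / `reconstructed_freq` /
#'   `reported` / `unassessable`), `significant`.
#' @export
select_reported_association <- function(s, alpha = 0.05, test = "chisq") {
  harm <- harmonize_risk_allele(s)
  ac <- .study_allele_counts(s)
  if (!is.null(ac)) {
    # orient the table so "risk" rows follow the harmonized allele
    risk_is_b <- !is.na(harm$risk_allele) &&
      !is.na(s$allele_b) && harm$risk_allele == s$allele_b
    t <- if (risk_is_b)
      allele_table(ac$case_b, ac$case_a, ac$ctrl_b, ac$ctrl_a)
    else
      allele_table(ac$case_a, ac$case_b, ac$ctrl_a, ac$ctrl_b)
    est <- allelic_odds_ratio(t)
    p <- switch(test,
      chisq = allelic_chi2_p(t, correct = FALSE)$p,
      chisq_yates = allelic_chi2_p(t, correct = TRUE)$p,
      fisher = allelic_fisher_p(t),
      stop("unknown test: ", test))
    return(list(or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
                p = p, risk_allele = harm$risk_allele,
                harmonize_basis = harm$basis, basis = ac$basis,
                significant = p < alpha))
  }
  if (!is.na(s$p_value) || !is.na(s$or_value) ||
      (!is.na(s$significant))) {
    sig <- if (!is.na(s$p_value)) s$p_value < alpha
           else if (!is.na(s$significant)) s$significant
           else NA
    return(list(or = s$or_value, ci_low = s$ci_low, ci_high = s$ci_high,
                p = s$p_value, risk_allele = harm$risk_allele,
                harmonize_basis = harm$basis, basis = "reported",
                significant = sig))
  }
  list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
       risk_allele = harm$risk_allele, harmonize_basis = harm$basis,
       basis = "unassessable", significant = NA)
}

#' Annotate a catalog with harmonized association results
#'
#' Applies [select_reported_association()] to every record and appends
#' the chosen odds ratio, p-value, harmonized risk allele, basis and
#' significance flag as columns `assoc_or`, `assoc_p`, `risk_allele`,
#' `assoc_basis`, `harmonize_basis`, `is_significant`. Records that are
#' unassessable (no raw data and no reported statistic) are flagged in
#' `assoc_basis` and excluded by the replication engine.
#'
#' @param cat a [catalog()].
#' @inheritParams select_reported_association
#' @return the records data.frame with association columns appended.
#' @export
annotate_associations <- function(cat, alpha = 0.05, test = "chisq") {
  r <- cat$records
  n <- nrow(r)
  out <- data.frame(assoc_or = numeric(n), assoc_p = numeric(n),
                    risk_allele = character(n), assoc_basis = character(n),
                    harmonize_basis = character(n), is_significant = logical(n))
  for (i in seq_len(n)) {
    res <- select_reported_association(r[i, ], alpha = alpha, test = test)
    out$assoc_or[i] <- if (is.null(res$or) || is.na(res$or)) NA_real_ else res$or
    out$assoc_p[i] <- if (is.null(res$p) || is.na(res$p)) NA_real_ else res$p
    out$risk_allele[i] <- res$risk_allele
    out$assoc_basis[i] <- res$basis
    out$harmonize_basis[i] <- res$harmonize_basis
    out$is_significant[i] <- isTRUE(res$significant)
  }
  cbind(r, out)
}
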