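# Functional-annotation summaries: RegulomeDB rank parsing/ordering and
# the aggregate fractions reported for replicated variant sets.

.regulome_levels <- c("1a", "1b", "1c", "1d", "1e", "1f",
                      "2a", "2b", "2c", "3a", "3b", "4", "5", "6", "7")

#' Parse a RegulomeDB rank
#'
#' Ranks are ordinal categories 1a-7 (lower = stronger regulatory
#' evidence); the leading integer is the numeric tier.
#'
#' @param text rank string (e.g. `"2b"`, `"1f"`, `"4"`) or `"na"`/`NA`.
#' @return list `category`, `numeric_part`, `order` (position in the
#'   strict total order; `NA` for missing ranks).
#' @export
parse_regulome_rank <- function(text) {
  if (is.na(text) || identical(tolower(text), "na"))
    return(list(category = NA_character_, numeric_part = NA_integer_,
                order = NA_integer_))
  text <- tolower(trimws(text))
  pos <- match(text, .regulome_levels)
  if (is.na(pos)) stop("unknown RegulomeDB rank: '", text, "'")
  list(category = text,
       numeric_part = as.integer(substr(text, 1, 1)),
       order = pos)
}

#' Summarise a functional-annotation table
#'
#' Aggregates per-variant in-silico annotations over a scope of
#' annotation rows (one row per replicated-variant table entry):
#' deleterious/damaging fractions among missense variants, regulatory
#' tallies from RegulomeDB ranks, splice/miRNA flags, conservation and
#' regulatory-potential exceedances and knockout-mouse / drug-target /
#' brain-expression fractions. Fractions are exact (count/denominator);
#' percent display is left to the caller.
#'
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @param variant_ids optional scope: restrict to these variant ids.
#' @param regulatory_max highest rank category still counted as
#'   "regulatory effect" (default `"5"`; ranks 6/7/na excluded).
#' @param high_threshold numeric tier strictly below which a rank counts
#'   as high-regulatory (default 3).
#' @param conservation_min,reg_potential_min exceedance thresholds
#'   (defaults 0.80 and 0.40, strict `>`), applied to SNV rows.
#' @return list of summary fields (see Details in the vignette).
#' @export
summarize_annotations <- function(annotations, variant_ids = NULL,
                                  regulatory_max = "5",
                                  high_threshold = 3,
                                  conservation_min = 0.80,
                                  reg_potential_min = 0.40) {
  a <- annotations
  if (!is.null(variant_ids)) {
    unknown <- setdiff(variant_ids, a$variant_id)
    if (length(unknown))
      warning("no annotation for: ", paste(unknown, collapse = ", "))
    a <- a[a$variant_id %in% variant_ids, , drop = FALSE]
  }
  n <- nrow(a)
  if (n == 0) {
    return(list(n_variants = 0L, n_missense = 0L,
                frac_sift_deleterious = NA_real_,
                frac_polyphen_damaging = NA_real_,
                n_regulatory = 0L, n_rank_obtained = 0L,
                frac_regulatory = NA_real_, n_high_regulatory = 0L,
                n_splice = 0L, n_mirna = 0L, n_conserved = 0L,
                n_regpot = 0L, frac_ko_mouse = NA_real_,
                frac_drug_target = NA_real_, frac_brain = NA_real_))
  }
  ranks <- lapply(a$regulome_rank, parse_regulome_rank)
  ord <- vapply(ranks, `[[`, integer(1), "order")
  numpart <- vapply(ranks, `[[`, integer(1), "numeric_part")
  max_ord <- match(regulatory_max, .regulome_levels)
  missense <- !is.na(a$missense) & a$missense &
    !is.na(a$variant_class) & a$variant_class == "SNV"
  n_mis <- sum(missense)
  snv <- !is.na(a$variant_class) & a$variant_class == "SNV"
  frac <- function(x) if (sum(!is.na(x)) > 0) sum(x, na.rm = TRUE) /
    sum(!is.na(x)) else NA_real_
  list(
    n_variants = n,
    n_missense = n_mis,
    frac_sift_deleterious = if (n_mis > 0)
      sum(a$sift_class[missense] == "deleterious", na.rm = TRUE) / n_mis
      else NA_real_,
    frac_polyphen_damaging = if (n_mis > 0)
      sum(a$polyphen_class[missense] %in%
            c("probably_damaging", "possibly_damaging"),
          na.rm = TRUE) / n_mis else NA_real_,
    n_regulatory = sum(!is.na(ord) & ord <= max_ord),
    n_rank_obtained = sum(!is.na(ord)),
    frac_regulatory = if (sum(!is.na(ord)) > 0)
      sum(!is.na(ord) & ord <= max_ord) / sum(!is.na(ord)) else NA_real_,
    n_high_regulatory = sum(!is.na(numpart) & numpart < high_threshold),
    n_splice = sum(a$splice_flag, na.rm = TRUE),
    n_mirna = sum(a$mirna_flag, na.rm = TRUE),
    n_conserved = sum(snv & !is.na(a$conservation) &
                        a$conservation > conservation_min),
    n_regpot = sum(snv & !is.na(a$reg_potential) &
                     a$reg_potential > reg_potential_min),
    frac_ko_mouse = frac(a$ko_mouse),
    frac_drug_target = frac(a$drug_target),
    frac_brain = frac(a$brain_expressed))
}

#' Join a shortlist with its functional annotations
#'
#' One row per shortlist variant with the annotation fields rendered in
#' the published style: boolean flags as `"Y"`/`"-"`, missing classes as
#' `"-"`.
#'
#' @param shortlist a [shortlist_variants()] data.frame.
#' @param annotations annotation data.frame.
#' @return data.frame with one row per shortlist variant.
#' @export
shortlist_annotation_join <- function(shortlist, annotations) {
  yn <- function(x) ifelse(is.na(x), "-", ifelse(x, "Y", "-"))
  dash <- function(x) ifelse(is.na(x) | x == "na", "-", x)
  rows <- lapply(seq_len(nrow(shortlist)), function(i) {
    key <- shortlist$key[i]
    a <- annotations[annotations$variant_id == key, , drop = FALSE]
    a <- if (nrow(a)) a[1, ] else annotations[NA_integer_, ]
    data.frame(
      variant_id = key,
      gene = if (nrow(a)) a$gene else NA_character_,
      risk_allele = shortlist$risk_allele[i],
      regulome_rank = dash(a$regulome_rank),
      splice = yn(a$splice_flag), mirna = yn(a$mirna_flag),
      sift = dash(a$sift_class), polyphen = dash(a$polyphen_class),
      reg_potential = a$reg_potential, conservation = a$conservation,
      ko_mouse = yn(a$ko_mouse), drug_target = yn(a$drug_target),
      brain_expression = yn(a$brain_expressed),
      stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(variant_id = character(0), gene = character(0),
                      risk_allele = character(0),
                      regulome_rank = character(0), splice = character(0),
                      mirna = character(0), sift = character(0),
                      polyphen = character(0), reg_potential = numeric(0),
                      conservation = numeric(0), ko_mouse = character(0),
                      drug_target = character(0),
                      brain_expression = character(0)))
  do.call(rbind, rows)
}
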