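# Catalog data model: curated per-study association records and per-variant
# functional annotations, read/written as plain TSV.

.CATALOG_SCHEMA_VERSION <- "1.0"

# column -> storage type ("c" character, "i" integer, "d" double, "l" logical)
.catalog_cols <- c(
  pub_id = "c", cohort_id = "c", variant_id = "c", gene = "c",
  chrom = "c", pos = "i", allele_a = "c", allele_b = "c",
  variant_class = "c", design = "c", domain = "c", drug_class = "c",
  outcome_scale = "c", population = "c",
  n_case = "i", n_control = "i", directionality = "c",
  case_AA = "i", case_AB = "i", case_BB = "i",
  ctrl_AA = "i", ctrl_AB = "i", ctrl_BB = "i",
  case_a = "i", case_b = "i", ctrl_a = "i", ctrl_b = "i",
  case_freq_b = "d", ctrl_freq_b = "d",
  reported_risk_allele = "c", reported_model = "c",
  or_value = "d", ci_low = "d", ci_high = "d", p_value = "d",
  maf_study = "d", maf_global = "d",
  raw_data_available = "l", significant = "l"
)

.annotation_cols <- c(
  variant_id = "c", gene = "c", variant_class = "c", missense = "l",
  sift_class = "c", polyphen_class = "c", regulome_rank = "c",
  splice_flag = "l", mirna_flag = "l",
  conservation = "d", reg_potential = "d",
  ko_mouse = "l", drug_target = "l", brain_expressed = "l"
)

.valid_design <- c("candidate", "gwas")
.valid_domain <- c("susceptibility", "response", "remission", "resistance")
.valid_drug_class <- c("SSRI", "SNRI", "TCA", "atypical", "mixed", "other")
.valid_variant_class <- c("SNV", "indel", "VNTR")
.valid_model <- c("allelic", "genotypic", "unknown")
.valid_sift <- c("deleterious", "tolerated", "na")
.valid_polyphen <- c("probably_damaging", "possibly_damaging", "benign", "na")

#' Construct a validated evidence catalog
#'
#' A catalog bundles per-study association records (one row per published
#' study result, possibly several strata per publication) with optional
#' per-variant functional annotations and provenance metadata.
#'
#' @param records data.frame of study records following the catalog schema
#'   (see [read_catalog()] for the column list). Missing optional columns
#'   are added as `NA`.
#' @param annotations optional data.frame of annotation records.
#' @param metadata named list; `source` and `date` are conventional.
#' @return An object of class `evsyn_catalog`.
#' @export
catalog <- function(records, annotations = NULL, metadata = list()) {
  records <- .coerce_schema(records, .catalog_cols)
  .validate_records(records)
  if (!is.null(annotations)) {
    annotations <- .coerce_schema(annotations, .annotation_cols)
    .validate_annotations(annotations)
  }
  metadata$schema_version <- .CATALOG_SCHEMA_VERSION
  structure(list(records = records, annotations = annotations,
                 metadata = metadata),
            class = "evsyn_catalog")
}

#' @export
print.evsyn_catalog <- function(x, ...) {
  cat(sprintf("<evsyn_catalog> %d study record(s), %d variant(s)",
              nrow(x$records), length(unique(x$records$variant_id))))
  if (!is.null(x$annotations))
    cat(sprintf(", %d annotation row(s)", nrow(x$annotations)))
  cat("\n")
  invisible(x)
}

.coerce_schema <- function(df, schema) {
  stopifnot(is.data.frame(df))
  for (col in names(schema)) {
    if (!col %in% names(df)) df[[col]] <- NA
    df[[col]] <- switch(schema[[col]],
      c = as.character(df[[col]]),
      i = .as_integer_strict(df[[col]], col),
      d = .as_double_strict(df[[col]], col),
      l = .as_logical_strict(df[[col]], col))
  }
  extra <- setdiff(names(df), names(schema))
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  df <- df[, names(schema), drop = FALSE]
  rownames(df) <- NULL
  df
}

.as_integer_strict <- function(x, col) {
  if (is.logical(x) && all(is.na(x))) return(rep(NA_integer_, length(x)))
  if (is.numeric(x)) {
    if (any(!is.na(x) & x != round(x)))
      stop("column ", col, " must be integer-valued")
    return(as.integer(round(x)))
  }
  x <- as.character(x)
  bad <- !is.na(x) & x != "NA" & is.na(suppressWarnings(as.integer(x)))
  if (any(bad))
    stop("cannot parse integer in column ", col, " at row ",
         which(bad)[1], " (value '", x[which(bad)[1]], "')")
  suppressWarnings(as.integer(ifelse(x == "NA", NA, x)))
}

.as_double_strict <- function(x, col) {
  if (is.logical(x) && all(is.na(x))) return(rep(NA_real_, length(x)))
  if (is.numeric(x)) return(as.double(x))
  x <- as.character(x)
  bad <- !is.na(x) & x != "NA" & is.na(suppressWarnings(as.double(x)))
  if (any(bad))
    stop("cannot parse number in column ", col, " at row ",
         which(bad)[1], " (value '", x[which(bad)[1]], "')")
  suppressWarnings(as.double(ifelse(x == "NA", NA, x)))
}

.as_logical_strict <- function(x, col) {
  if (is.logical(x)) return(x)
  x <- toupper(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "YES", "Y", "1")] <- TRUE
  out[x %in% c("FALSE", "F", "NO", "N", "0")] <- FALSE
  bad <- !is.na(x) & x != "NA" & is.na(out)
  if (any(bad))
    stop("cannot parse logical in column ", col, " at row ", which(bad)[1])
  out
}

.check_levels <- function(x, valid, col, pub = NULL) {
  bad <- !is.na(x) & !(x %in% valid)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("invalid value '", x[i], "' in column ", col,
         if (!is.null(pub)) paste0(" (pub_id ", pub[i], ")"),
         "; expected one of: ", paste(valid, collapse = ", "))
  }
}

.validate_records <- function(r) {
  if (nrow(r) == 0) return(invisible(r))
  .fail <- function(i, field, msg)
    stop("record ", i, " (pub_id ", r$pub_id[i], ", variant ",
         r$variant_id[i], "): ", field, " ", msg)
  if (any(is.na(r$pub_id) | r$pub_id == ""))
    stop("pub_id missing at row ", which(is.na(r$pub_id) | r$pub_id == "")[1])
  if (any(is.na(r$variant_id) | r$variant_id == ""))
    stop("variant_id missing at row ",
         which(is.na(r$variant_id) | r$variant_id == "")[1])
  .check_levels(r$design, .valid_design, "design", r$pub_id)
  .check_levels(r$domain, .valid_domain, "domain", r$pub_id)
  .check_levels(r$drug_class, .valid_drug_class, "drug_class", r$pub_id)
  .check_levels(r$variant_class, .valid_variant_class, "variant_class",
                r$pub_id)
  .check_levels(r$reported_model, .valid_model, "reported_model", r$pub_id)
  for (i in seq_len(nrow(r))) {
    if (!is.na(r$allele_a[i]) && !is.na(r$allele_b[i]) &&
        r$allele_a[i] == r$allele_b[i])
      .fail(i, "alleles", "must differ")
    if (!is.na(r$pos[i]) && r$pos[i] <= 0) .fail(i, "pos", "must be > 0")
    for (col in c("n_case", "n_control"))
      if (!is.na(r[[col]][i]) && r[[col]][i] <= 0)
        .fail(i, col, "must be > 0")
    gc_cols <- c("case_AA", "case_AB", "case_BB",
                 "ctrl_AA", "ctrl_AB", "ctrl_BB")
    gc <- unlist(r[i, gc_cols])
    if (any(!is.na(gc))) {
      if (any(is.na(gc))) .fail(i, "genotype_counts", "must be complete")
      if (any(gc < 0)) .fail(i, "genotype_counts", "must be >= 0")
      if (!is.na(r$n_case[i]) && sum(gc[1:3]) != r$n_case[i])
        .fail(i, "genotype_counts", "case triplet must sum to n_case")
      if (!is.na(r$n_control[i]) && sum(gc[4:6]) != r$n_control[i])
        .fail(i, "genotype_counts", "control triplet must sum to n_control")
    }
    ac_cols <- c("case_a", "case_b", "ctrl_a", "ctrl_b")
    ac <- unlist(r[i, ac_cols])
    if (any(!is.na(ac))) {
      if (any(is.na(ac))) .fail(i, "allele_counts", "must be complete")
      if (any(ac < 0)) .fail(i, "allele_counts", "must be >= 0")
      if (!is.na(r$n_case[i]) && ac[1] + ac[2] != 2L * r$n_case[i])
        .fail(i, "allele_counts", "case pair must sum to 2*n_case")
      if (!is.na(r$n_control[i]) && ac[3] + ac[4] != 2L * r$n_control[i])
        .fail(i, "allele_counts", "control pair must sum to 2*n_control")
    }
    for (col in c("case_freq_b", "ctrl_freq_b")) {
      v <- r[[col]][i]
      if (!is.na(v) && (v < 0 || v > 1)) .fail(i, col, "must lie in [0,1]")
    }
    if (!is.na(r$or_value[i]) && r$or_value[i] <= 0)
      .fail(i, "or_value", "must be > 0")
    if (!is.na(r$ci_low[i]) && !is.na(r$ci_high[i]) &&
        !is.na(r$or_value[i]) &&
        !(r$ci_low[i] <= r$or_value[i] && r$or_value[i] <= r$ci_high[i]))
      .fail(i, "ci", "must bracket or_value")
    if (!is.na(r$p_value[i]) && (r$p_value[i] <= 0 || r$p_value[i] > 1))
      .fail(i, "p_value", "must lie in (0,1]")
    for (col in c("maf_study", "maf_global")) {
      v <- r[[col]][i]
      if (!is.na(v) && (v < 0 || v > 0.5)) .fail(i, col, "must lie in [0,0.5]")
    }
  }
  # one VariantKey per variant_id
  key_cols <- c("gene", "chrom", "pos", "allele_a", "allele_b",
                "variant_class")
  keys <- unique(r[, c("variant_id", key_cols)])
  dup <- keys$variant_id[duplicated(keys$variant_id)]
  if (length(dup))
    stop("variant_id ", dup[1], " maps to more than one variant key")
  invisible(r)
}

.validate_annotations <- function(a) {
  if (nrow(a) == 0) return(invisible(a))
  .check_levels(a$sift_class, .valid_sift, "sift_class")
  .check_levels(a$polyphen_class, .valid_polyphen, "polyphen_class")
  ok <- is.na(a$regulome_rank) | a$regulome_rank %in% c("na", .regulome_levels)
  if (any(!ok))
    stop("invalid regulome_rank '", a$regulome_rank[which(!ok)[1]], "'")
  for (col in c("conservation", "reg_potential")) {
    v <- a[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(col, " must lie in [0,1]")
  }
  invisible(a)
}

#' Read an evidence catalog from TSV
#'
#' The file must be tab-separated with a header row carrying the catalog
#' schema columns. Absent optional values are the literal `NA`; zeros are
#' never used for missingness.
#'
#' @param path path to a catalog TSV.
#' @param schema_version expected schema version label.
#' @return A validated [catalog()] object, row order preserved.
#' @export
read_catalog <- function(path, schema_version = .CATALOG_SCHEMA_VERSION) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = "NA", check.names = FALSE)
  missing <- setdiff(names(.catalog_cols), c(names(df), "significant"))
  if (length(missing))
    stop("catalog schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  catalog(df, metadata = list(source = path))
}

#' Write an evidence catalog to TSV
#'
#' Numeric fields are rendered at full precision; absent optionals are the
#' literal `NA`. Output is byte-stable for identical catalogs, so
#' `read_catalog(write_catalog(c))` round-trips field-for-field.
#'
#' @param cat a [catalog()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path) {
  stopifnot(inherits(cat, "evsyn_catalog"))
  df <- cat$records
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE),
        character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read a functional-annotation table from TSV
#'
#' @param path path to an annotation TSV (columns `variant_id`,
#'   `sift_class`, `polyphen_class`, `regulome_rank`, `splice_flag`,
#'   `mirna_flag`, `conservation`, `reg_potential`, `ko_mouse`,
#'   `drug_target`, `brain_expressed`, plus `gene`, `variant_class` and a
#'   `missense` consequence flag).
#' @return A validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = "NA", check.names = FALSE)
  a <- .coerce_schema(df, .annotation_cols)
  .validate_annotations(a)
  a
}

#' Load a bundled fixture catalog
#'
#' Fixture catalogs transcribe the published tables of replicated variants
#' and genes for depression susceptibility and antidepressant response,
#' including the three low-frequency variants excluded by the MAF filter.
#' Annotation fixtures combine published per-variant values with
#' synthetic fill for fields only reported in aggregate (see the package
#' vignette for the transcription rules).
#'
#' @param name one of `"mdd_variants"`, `"mdd_genes"`,
#'   `"response_variants"`, `"response_genes"`, `"annotations_mdd"`,
#'   `"annotations_response"`, `"shortlist_annotations"`.
#' @return A [catalog()] object; for annotation fixtures the `records`
#'   table is empty and the `annotations` slot is populated.
#' @export
load_fixture <- function(name) {
  study_fixtures <- c("mdd_variants", "mdd_genes",
                      "response_variants", "response_genes")
  ann_fixtures <- c("annotations_mdd", "annotations_response",
                    "shortlist_annotations")
  if (!name %in% c(study_fixtures, ann_fixtures))
    stop("unknown fixture: ", name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "evsyn",
                      mustWork = TRUE)
  if (name %in% study_fixtures) {
    read_catalog(path)
  } else {
    ann <- read_annotations(path)
    catalog(utils::read.delim(text = paste(names(.catalog_cols),
                                           collapse = "\t")),
            annotations = ann, metadata = list(source = path))
  }
}

#' Export variant keys as a minimal VCFv4.3 file
#'
#' SNVs with chromosome/position become ordinary data lines; non-SNV
#' variants (VNTRs, multi-site labels) are written with a symbolic ALT and
#' a warning. Variants lacking coordinates are skipped (counted in a
#' warning). INFO keys: `EVC` evidence class, `NST` study count, `RA`
#' harmonized risk allele.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `variant_class` and optionally `evidence`,
#'   `n_studies`, `risk_allele`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.3",
    "##INFO=<ID=EVC,Number=1,Type=String,Description=\"Evidence class\">",
    "##INFO=<ID=NST,Number=1,Type=Integer,Description=\"Number of studies\">",
    "##INFO=<ID=RA,Number=1,Type=String,Description=\"Harmonized risk allele\">",
    "##ALT=<ID=CNV,Description=\"Copy number / repeat polymorphism\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  lines <- character(0)
  n_skipped <- 0L
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (is.na(v$chrom) || is.na(v$pos)) { n_skipped <- n_skipped + 1L; next }
      info <- c(
        if (!is.null(v$evidence) && !is.na(v$evidence))
          paste0("EVC=", v$evidence),
        if (!is.null(v$n_studies) && !is.na(v$n_studies))
          paste0("NST=", v$n_studies),
        if (!is.null(v$risk_allele) && !is.na(v$risk_allele))
          paste0("RA=", v$risk_allele))
      info <- if (length(info)) paste(info, collapse = ";") else "."
      if (!is.na(v$variant_class) && v$variant_class == "SNV") {
        ref <- v$allele_a; alt <- v$allele_b
      } else {
        warning("non-SNV variant ", v$variant_id,
                " written with symbolic ALT")
        ref <- "N"; alt <- "<CNV>"
      }
      lines <- c(lines, paste(v$chrom, v$pos, v$variant_id, ref, alt,
                              ".", ".", info, sep = "\t"))
    }
  }
  if (n_skipped > 0)
    warning(n_skipped, " variant(s) without coordinates skipped")
  writeLines(c(hdr, lines), path)
  invisible(path)
}
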