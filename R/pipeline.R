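# End-to-end pipeline: replication -> MAF filter -> consistency ->
# predictability -> annotation summary -> shortlist, with TSV/JSON
# rendering of the report bundle.

#' Run the full evidence-synthesis pipeline for one domain
#'
#' Orders the analysis as published: annotate associations, group by
#' variant and by gene, apply the replication rule, apply the MAF filter
#' (variant level), classify evidence buckets and risk-allele
#' consistency, determine predictability-eligible strata and pool
#' confusion tables, and intersect consistency with assessability to form
#' the shortlist.
#'
#' @param cat a [catalog()] of study records.
#' @param annotations optional annotation data.frame for the summary.
#' @param domain `"susceptibility"` or `"response"`.
#' @param min_studies replication threshold (default 2).
#' @param maf_threshold MAF exclusion threshold (default 0.05, strict).
#' @param min_pooled minimum pooled stratum size (default 2).
#' @param unit confusion-table unit, `"allele"` or `"carrier"`.
#' @param alpha significance threshold (default 0.05).
#' @return list with `variant_summary`, `gene_summary`, `variant_buckets`,
#'   `gene_buckets`, `maf_excluded`, `consistency_counts`,
#'   `predictability`, `eligibility`, `shortlist`, `annotation_summary`,
#'   `summary` (flat named list mirroring the JSON report).
#' @export
run_pipeline <- function(cat, annotations = NULL,
                         domain = c("susceptibility", "response"),
                         min_studies = 2, maf_threshold = 0.05,
                         min_pooled = 2, unit = "allele", alpha = 0.05) {
  domain <- match.arg(domain)
  recs <- annotate_associations(cat, alpha = alpha)

  vg <- filter_replicated(group_records(recs, "variant", domain),
                          min_studies)
  mf <- filter_maf(vg, maf_threshold)
  vgroups <- mf$kept
  maf_excluded <- vapply(mf$excluded, `[[`, character(1), "key")

  gg <- filter_replicated(group_records(recs, "gene", domain),
                          min_studies)

  vsum <- replication_summary(vgroups)
  gsum <- replication_summary(gg)

  elig <- do.call(rbind, c(lapply(vgroups, function(g)
    cbind(key = g$key, eligible_strata(g, min_pooled),
          stringsAsFactors = FALSE)),
    list(data.frame(key = character(0), stratum = character(0),
                    risk_allele = character(0), n_studies = integer(0),
                    n_raw = integer(0), eligible = logical(0),
                    reason = character(0)))))
  pred <- predictability_table(vgroups, min_pooled = min_pooled,
                               unit = unit)
  sl <- shortlist_variants(vgroups, pred)

  ann_sum <- if (!is.null(annotations))
    summarize_annotations(annotations) else NULL

  cons <- table(factor(vsum$consistency,
                       c("consistent", "inconsistent", "undetermined")))
  ppv <- pred$ppv[!is.na(pred$ppv)]
  summary <- list(
    domain = domain,
    variant_buckets = bucket_sizes(vsum),
    gene_buckets = bucket_sizes(gsum),
    maf_excluded = as.list(maf_excluded),
    n_consistent = unname(cons["consistent"]),
    n_inconsistent = unname(cons["inconsistent"]) +
      unname(cons["undetermined"]),
    n_variants_with_ppv = length(unique(pred$key)),
    ppv_min = if (length(ppv)) min(ppv) else NA,
    ppv_max = if (length(ppv)) max(ppv) else NA,
    n_shortlist = nrow(sl),
    ineligible_reasons = as.list(table(elig$reason[!elig$eligible])))
  list(variant_summary = vsum, gene_summary = gsum,
       variant_buckets = bucket_sizes(vsum),
       gene_buckets = bucket_sizes(gsum),
       maf_excluded = maf_excluded,
       consistency_counts = as.list(cons),
       eligibility = elig, predictability = pred, shortlist = sl,
       annotation_summary = ann_sum, summary = summary,
       groups = vgroups)
}

#' Render pipeline result tables to files
#'
#' Writes the replication, eligibility, predictability and shortlist
#' tables as TSV (or pipe-delimited markdown) with a deterministic column
#' order; metric columns are displayed at 2 decimals (round half-up).
#' The summary is written as JSON.
#'
#' @param results a [run_pipeline()] bundle.
#' @param dir output directory (created if needed).
#' @param style `"tsv"` or `"markdown"`.
#' @return invisible character vector of files written.
#' @export
render_tables <- function(results, dir, style = c("tsv", "markdown")) {
  style <- match.arg(style)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_metrics <- function(df) {
    for (col in intersect(c("sensitivity", "specificity", "ppv"),
                          names(df)))
      df[[col]] <- ifelse(is.na(df[[col]]), NA,
                          sprintf("%.2f", round_half_up(df[[col]], 2)))
    df
  }
  write_one <- function(df, name) {
    ext <- if (style == "tsv") ".tsv" else ".md"
    path <- file.path(dir, paste0(name, ext))
    if (style == "tsv") {
      utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                         row.names = FALSE)
    } else {
      txt <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(df)), collapse = "|"),
                      "|"),
               apply(df, 1, function(row)
                 paste0("| ", paste(ifelse(is.na(row), "NA", row),
                                    collapse = " | "), " |")))
      writeLines(txt, path)
    }
    path
  }
  files <- c(
    write_one(results$variant_summary, "replicated_variants"),
    write_one(results$gene_summary, "replicated_genes"),
    write_one(results$eligibility, "eligibility"),
    write_one(fmt_metrics(results$predictability), "predictability"),
    write_one(results$shortlist, "shortlist"))
  sj <- file.path(dir, "summary.json")
  jsonlite::write_json(results$summary, sj, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, sj))
}
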