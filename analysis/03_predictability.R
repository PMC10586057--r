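#!/usr/bin/env Rscript
# Diagnostic predictability: for each replicated variant, pool 2x2
# risk-allele confusion tables across the studies that agree on the
# harmonized risk allele (and, for treatment outcomes, share outcome
# type and drug class) and report which variants admit a pooled
# sensitivity/specificity/PPV at all. The curated catalogs carry
# raw-data availability flags but not the per-study allele frequencies
# (journal supplement only), so eligibility and stratum sizes are
# computed here while the metric values themselves are demonstrated on
# synthetic counts in analysis/01_simulate.R.
#
# Writes results/{mdd,response}/eligibility.tsv (via 02) and prints the
# eligibility accounting.

suppressMessages(library(evsyn))

for (dom in c("mdd", "response")) {
  cat("==", dom, "==\n")
  fix <- if (dom == "mdd") "mdd_variants" else "response_variants"
  domain <- if (dom == "mdd") "susceptibility" else "response"
  res <- suppressWarnings(run_pipeline(load_fixture(fix),
                                       domain = domain))
  elig <- res$eligibility
  cat(sprintf("variants with >=1 poolable stratum: %d of %d replicated\n",
              res$summary$n_variants_with_ppv,
              length(unique(res$variant_summary$key))))
  reasons <- table(elig$reason[!elig$eligible])
  for (r in names(reasons))
    cat(sprintf("  ineligible strata (%s): %d\n", r, reasons[[r]]))
  two_sided <- names(which(table(elig$key[elig$eligible]) > 1))
  if (length(two_sided))
    cat("variants assessable for two opposite alleles:",
        paste(two_sided, collapse = ", "), "\n")
}
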