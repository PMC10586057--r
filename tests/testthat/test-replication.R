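# Grouping, replication rule, MAF filter, evidence buckets and
# risk-allele consistency.

test_that("grouping collapses publications and cohorts correctly", {
  expect_length(group_records(catalog(make_record()[0, ])), 0)

  mdd <- load_fixture("mdd_variants")
  g <- group_records(mdd, "variant", "susceptibility")
  keys <- vapply(g, `[[`, character(1), "key")
  expect_equal(g[[match("rs6265", keys)]]$n_pubs, 8)
  # two strata of one publication count once
  expect_equal(g[[match("rs1801133", keys)]]$n_pubs, 4)
  # two cohorts inside one publication still count once
  expect_equal(g[[match("rs4291", keys)]]$n_pubs, 3)
  expect_equal(g[[match("rs4291", keys)]]$n_countable, 3)

  # two publications sharing a cohort collapse to one countable study
  resp <- load_fixture("response_variants")
  rg <- group_records(resp, "variant", "response")
  rkeys <- vapply(rg, `[[`, character(1), "key")
  g6295 <- rg[[match("rs6295", rkeys)]]
  expect_equal(g6295$n_pubs, 4)
  expect_equal(g6295$n_countable, 3)
})

test_that("replication rule keeps groups with >= min_studies", {
  one <- make_catalog(make_record(p = 0.01))
  g <- group_records(one)
  expect_length(filter_replicated(g), 0)
  expect_error(filter_replicated(g, min_studies = 0), "min_studies")

  mdd <- load_fixture("mdd_variants")
  g <- filter_replicated(group_records(mdd), min_studies = 3)
  keys <- vapply(g, `[[`, character(1), "key")
  expect_true("5-HTTLPR" %in% keys)
  expect_false("rs1006737" %in% keys)
})

test_that("MAF filter is strict and names the excluded trio", {
  mdd <- load_fixture("mdd_variants")
  g <- filter_replicated(group_records(mdd))
  mf <- filter_maf(g)
  expect_setequal(vapply(mf$excluded, `[[`, character(1), "key"),
                  c("rs120074175", "rs6195", "rs6189+rs6190"))
  # boundary: exactly 0.05 is kept
  g2 <- list(list(key = "x", maf_global = 0.05),
             list(key = "y", maf_global = 0.0499),
             list(key = "z", maf_global = 0.20))
  mf2 <- filter_maf(g2)
  expect_setequal(vapply(mf2$kept, `[[`, character(1), "key"),
                  c("x", "z"))
  expect_error(filter_maf(g2, threshold = 0.7), "threshold")
  expect_warning(filter_maf(list(list(key = "w", maf_global = NA))),
                 "without global MAF")
})

test_that("evidence buckets follow the two-by-design rule", {
  mdd <- load_fixture("mdd_variants")
  g <- filter_maf(filter_replicated(group_records(mdd)))$kept
  keys <- vapply(g, `[[`, character(1), "key")
  expect_setequal(classify_evidence(g[[match("rs2522833", keys)]]),
                  c("candidate", "both"))
  expect_equal(classify_evidence(g[[match("rs2273289", keys)]]), "gwas")
  expect_equal(classify_evidence(g[[match("rs2715147", keys)]]), "both")

  resp <- load_fixture("response_variants")
  rg <- filter_replicated(group_records(resp, domain = "response"))
  rkeys <- vapply(rg, `[[`, character(1), "key")
  expect_equal(classify_evidence(rg[[match("rs6127921", rkeys)]]),
               "both")
  # bucket soundness over all groups
  for (gr in c(g, rg)) {
    b <- classify_evidence(gr)
    if ("both" %in% b)
      expect_true(gr$n_candidate >= 1 && gr$n_gwas >= 1)
    if ("candidate" %in% b && !("both" %in% b))
      expect_equal(gr$n_gwas, 0)
  }
})

test_that("consistency classification matches the harmonized alleles", {
  mdd <- load_fixture("mdd_variants")
  g <- filter_maf(filter_replicated(group_records(mdd)))$kept
  keys <- vapply(g, `[[`, character(1), "key")
  c1 <- assess_consistency(g[[match("rs1801133", keys)]])
  expect_equal(c1$status, "consistent")
  expect_equal(c1$modal_allele, "T")
  c2 <- assess_consistency(g[[match("5-HTTLPR", keys)]])
  expect_equal(c2$status, "inconsistent")
  expect_equal(as.vector(c2$alleles[c("S", "L")]), c(7, 3))
  # order-invariance
  gg <- g[[match("5-HTTLPR", keys)]]
  set.seed(2)
  perm <- gg$records[sample(nrow(gg$records)), ]
  expect_equal(assess_consistency(gg, records = perm)$status,
               c2$status)
  # a record without direction makes the group undetermined
  und <- make_catalog(make_record(pub = "a", p = 0.01),
                      make_record(pub = "b", reported = "B", or = 2,
                                  p = 0.01))
  ug <- group_records(und)
  expect_equal(assess_consistency(ug[[1]])$status, "undetermined")
})

test_that("response stratification partitions by outcome/drug/allele", {
  resp <- load_fixture("response_variants")
  rg <- filter_replicated(group_records(resp, domain = "response"))
  rkeys <- vapply(rg, `[[`, character(1), "key")
  g <- rg[[match("5-HTTLPR", rkeys)]]
  strata <- stratify_response(g)
  expect_true(all(c("response/SSRI/S", "response/SSRI/L",
                    "remission/SSRI/S", "response/TCA/L",
                    "response/atypical/L") %in% names(strata)))
  # partition property: disjoint and covering
  n <- sum(vapply(strata, nrow, integer(1)))
  expect_equal(n, nrow(g$records))
  ids <- unlist(lapply(strata, rownames))
  expect_equal(anyDuplicated(ids), 0)
})

test_that("adding a significant study never removes a replicated variant", {
  set.seed(11)
  params <- replicate(6, truth_params(p0 = 0.3, psi = 2, n_case = 300,
                                      n_control = 300, n_studies = 2),
                      simplify = FALSE)
  gen <- generate_catalog(params, seed = 42)
  base <- vapply(filter_replicated(group_records(gen$catalog)),
                 `[[`, character(1), "key")
  extra <- make_record(pub = "extra", variant_id = "v01",
                       gene = "G_v01", case_a = 100, case_b = 500,
                       ctrl_a = 300, ctrl_b = 300)
  grown <- catalog(rbind(gen$catalog$records, extra))
  after <- vapply(filter_replicated(group_records(grown)),
                  `[[`, character(1), "key")
  expect_true(all(base %in% after))
})

test_that("headline accounting sums bucket sizes with overlap", {
  mdd <- load_fixture("mdd_variants")
  g <- filter_maf(filter_replicated(group_records(mdd)))$kept
  s <- replication_summary(g)
  b <- bucket_sizes(s)
  expect_equal(b$bucket_sum, b$candidate + b$gwas + b$both)
  expect_true(b$n_unique <= b$bucket_sum)
  # the doubly bucketed variant appears once per bucket
  expect_equal(sum(s$key == "rs2522833"), 2)
})
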