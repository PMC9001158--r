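test_that("replicate resolution follows the read-count rule", {
  meta <- tibble::tibble(
    individual = c("a1", "a2", "b1", "b2", "c1"),
    pond = "p",
    replicate_group = c("a", "a", "b", "b", "c"),
    total_reads = c(400000, 100000, 200000, 150000, 80000)
  )
  res <- resolve_replicates(meta)
  res <- res[match(c("a", "b", "c"), res$replicate_group), ]
  expect_equal(res$action, c("keep", "combine", "keep"))
  expect_equal(res$kept_individual, c("a1", NA, "c1"))
})

test_that("combining replicates sums depths and takes the call consensus", {
  gt <- genotype_table(
    tibble::tibble(
      individual = rep(c("r1", "r2"), each = 3),
      locus = rep(c("l1", "l2", "l3"), 2),
      genotype = c("A1A2", "A1A1", "A1A1",
                   "A1A2", "MISSING", "A2A2"),
      depth_a1 = c(5L, 9L, 10L, 4L, 0L, 0L),
      depth_a2 = c(6L, 0L, 0L, 7L, 0L, 12L)
    ),
    meta = tibble::tibble(
      individual = c("r1", "r2"), replicate_group = "g",
      total_reads = c(100000, 120000)
    )
  )
  combined <- combine_replicates(gt)
  expect_equal(individuals(combined), "g")
  cells <- tibble::as_tibble(combined)
  l1 <- cells[cells$locus == "l1", ]
  expect_equal(l1$genotype, "A1A2")        # agreement
  expect_equal(c(l1$depth_a1, l1$depth_a2), c(9L, 13L))
  l2 <- cells[cells$locus == "l2", ]
  expect_equal(l2$genotype, "A1A1")        # missing defers to called
  l3 <- cells[cells$locus == "l3", ]
  expect_equal(l3$genotype, "MISSING")     # conflict
  expect_equal(c(l3$depth_a1, l3$depth_a2), c(0L, 0L))
  expect_equal(sample_meta(combined)$total_reads, 220000)
})

test_that("sample filtering keeps individuals strictly above the threshold", {
  gt <- make_random_table(6, 10, seed = 2)
  meta <- sample_meta(gt)
  meta$total_reads <- c(60000, 40000, 50000, 100000, 10000, 70000)
  sample_meta(gt) <- meta
  kept <- filter_samples(gt, min_reads = 50000)
  expect_setequal(
    individuals(kept),
    meta$individual[meta$total_reads > 50000]
  )
  expect_equal(loci(kept), loci(gt))
  expect_equal(individuals(filter_samples(gt, 0)), individuals(gt))
  top <- filter_samples(gt, min_reads = max(meta$total_reads) - 1)
  expect_equal(individuals(top),
               meta$individual[which.max(meta$total_reads)])
})

test_that("depth masking and MAF removal follow the configured thresholds", {
  gt <- genotype_table(tibble::tibble(
    individual = rep(sprintf("i%02d", 1:20), 2),
    locus = rep(c("low", "rare"), each = 20),
    genotype = c(
      c("A1A2", rep("A1A1", 19)),          # locus "low"
      c("A1A2", rep("A1A1", 19))           # locus "rare": MAF 1/40
    ),
    depth_a1 = c(3L, rep(10L, 19), rep(10L, 20)),
    depth_a2 = c(2L, rep(0L, 19), c(10L, rep(0L, 19)))
  ))
  out <- suppressWarnings(
    filter_snps(gt, filter_config(min_depth = 8, min_maf = 0.05,
                                  max_missing_snp = 1,
                                  max_missing_ind = 1))
  )
  # (3,2) cell masked to MISSING; locus then monomorphic -> dropped by MAF
  expect_false("low" %in% loci(out))
  # MAF 0.025 < 0.05 -> removed
  expect_false("rare" %in% loci(out))
  log <- filter_log(out)
  expect_equal(log$n_removed[log$stage == "depth_mask"], 1L)
  expect_equal(log$n_removed[log$stage == "maf"], 2L)
})

test_that("filter_snps matches an independent brute-force implementation", {
  for (seed in c(1, 2, 3)) {
    gt <- make_random_table(20, 200, seed = seed, missing_p = 0.25)
    cfg <- filter_config(min_depth = 8, min_maf = 0.05,
                         max_missing_snp = 0.4, max_missing_ind = 0.4)
    got <- suppressWarnings(filter_snps(gt, cfg))
    want <- brute_filter_snps(gt, cfg)
    expect_setequal(loci(got), want$loci)
    expect_setequal(individuals(got), want$individuals)
  }
})

test_that("tightening any threshold never enlarges the surviving table", {
  gt <- make_random_table(15, 120, seed = 9, missing_p = 0.3)
  n_surviving <- function(cfg) {
    out <- suppressWarnings(filter_snps(gt, cfg))
    c(loci = length(loci(out)), inds = length(individuals(out)))
  }
  base <- filter_config(max_missing_snp = 0.5, max_missing_ind = 0.5)
  loose <- n_surviving(base)
  for (tweak in list(
    filter_config(min_depth = 12, max_missing_snp = 0.5,
                  max_missing_ind = 0.5),
    filter_config(min_maf = 0.15, max_missing_snp = 0.5,
                  max_missing_ind = 0.5),
    filter_config(max_missing_snp = 0.3, max_missing_ind = 0.5),
    filter_config(max_missing_snp = 0.5, max_missing_ind = 0.3)
  )) {
    tight <- n_surviving(tweak)
    expect_true(all(tight <= loose))
  }
})

test_that("the removal log accounts for every locus and individual", {
  gt <- make_random_table(12, 80, seed = 4, missing_p = 0.3)
  out <- suppressWarnings(filter_snps(gt, filter_config()))
  log <- filter_log(out)
  expect_equal(
    log$n_removed[log$stage == "maf"] + log$n_removed[log$stage == "missing_snp"],
    length(loci(gt)) - length(loci(out))
  )
  expect_equal(
    log$n_removed[log$stage == "missing_ind"],
    length(individuals(gt)) - length(individuals(out))
  )
})
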