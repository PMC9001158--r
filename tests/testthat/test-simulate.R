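test_that("noise-free ponds realise the planted diagnostic structure", {
  spec <- pond_spec(
    pond_id = "p", LL = 10, LR = 10, n_loci = 100,
    fraction_diagnostic = 0.3, missing_rate = 0,
    genotyping_error_rate = 0, seed = 42
  )
  sim <- simulate_pond(spec)
  truth <- sim$truth
  diag_loci <- truth$loci$locus[truth$loci$diagnostic]
  expect_length(diag_loci, 30)
  cells <- tibble::as_tibble(sim$table)
  cells <- cells[cells$locus %in% diag_loci, ]
  ll_ids <- truth$individuals$individual[truth$individuals$genomotype == "LL"]
  lr_ids <- truth$individuals$individual[truth$individuals$genomotype == "LR"]
  expect_true(all(
    cells$genotype[cells$individual %in% ll_ids] %in% c("A1A1", "A2A2")
  ))
  expect_true(all(cells$genotype[cells$individual %in% lr_ids] == "A1A2"))
})

test_that("triploid allele-depth dosage centres on the L-copy fraction", {
  spec <- pond_spec(
    pond_id = "p", LLR = 20, n_loci = 200, fraction_diagnostic = 0.5,
    mean_depth = 30, missing_rate = 0, genotyping_error_rate = 0,
    seed = 7
  )
  sim <- simulate_pond(spec)
  plan <- sim$truth$loci
  cells <- dplyr::inner_join(
    tibble::as_tibble(sim$table),
    plan[plan$diagnostic, c("locus", "L_allele")],
    by = "locus"
  )
  het <- cells[cells$genotype == "A1A2", ]
  rel_L <- ifelse(het$L_allele == "A1", het$depth_a1, het$depth_a2) /
    (het$depth_a1 + het$depth_a2)
  expect_equal(mean(rel_L), 2 / 3, tolerance = 0.02)
})

test_that("simulation is deterministic given the seed", {
  spec <- pond_spec(pond_id = "p", LL = 3, LR = 3, n_loci = 40, seed = 99)
  a <- simulate_pond(spec)
  b <- simulate_pond(spec)
  expect_identical(tibble::as_tibble(a$table), tibble::as_tibble(b$table))
  expect_identical(a$truth, b$truth)
  c <- simulate_pond(pond_spec(pond_id = "p", LL = 3, LR = 3,
                               n_loci = 40, seed = 100))
  expect_false(identical(tibble::as_tibble(a$table),
                         tibble::as_tibble(c$table)))
})

test_that("replicate simulation plants an exact per-cell discordance", {
  base <- simulate_pond(pond_spec(
    pond_id = "p", LL = 2, LR = 2, n_loci = 50,
    missing_rate = 0, genotyping_error_rate = 0, seed = 5
  ))$table

  reps0 <- simulate_replicates(base, 0, seed = 1)
  expect_identical(tibble::as_tibble(reps0$rep1),
                   tibble::as_tibble(reps0$rep2))

  one <- simulate_pond(pond_spec(
    pond_id = "q", LR = 1, n_loci = 100,
    missing_rate = 0, genotyping_error_rate = 0, seed = 6
  ))$table
  reps1 <- simulate_replicates(one, 1, seed = 2)
  expect_true(all(
    tibble::as_tibble(reps1$rep1)$genotype !=
      tibble::as_tibble(reps1$rep2)$genotype
  ))

  big <- simulate_pond(pond_spec(
    pond_id = "r", LL = 20, LR = 20, n_loci = 250,
    missing_rate = 0, genotyping_error_rate = 0, seed = 8
  ))$table  # 10 000 cells
  reps <- simulate_replicates(big, 0.02, seed = 3)
  disc <- mean(
    tibble::as_tibble(reps$rep1)$genotype !=
      tibble::as_tibble(reps$rep2)$genotype
  )
  se <- sqrt(0.02 * 0.98 / 10000)
  expect_lt(abs(disc - 0.02), 3 * se)
})

test_that("DBR read simulation labels PCR duplicates truthfully", {
  none <- simulate_dbr_reads(50, dup_lambda = 0, seed = 1)
  expect_false(any(none$is_pcr_duplicate))
  expect_equal(nrow(none), 50)

  # identical inserts, independent DBRs: not duplicates of each other
  shared <- simulate_dbr_reads(
    2, dup_lambda = 0, seed = 2, n_unique_inserts = 1
  )
  expect_equal(shared$read1_seq[1], shared$read1_seq[2])
  expect_false(shared$dbr[1] == shared$dbr[2])
  expect_false(any(shared$is_pcr_duplicate))

  a <- simulate_dbr_reads(20, dup_lambda = 2, seed = 3)
  b <- simulate_dbr_reads(20, dup_lambda = 2, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("marker simulation writes the diagnostic states by species", {
  calls <- tibble::tibble(
    individual = c("i1", "i2", "i3"),
    call = c("lessonae", "esculentus", "RR")
  )
  sim <- simulate_marker_sequences(calls, seed = 4)
  tpl <- mnd1_templates()
  at <- function(s, p) substr(s, p, p)
  les <- sim$mnd1$sequence[1]
  esc <- sim$mnd1$sequence[2]
  rr <- sim$mnd1$sequence[3]
  for (p in tpl$positions) {
    expect_equal(at(les, p), at(tpl$L, p))
    expect_equal(at(rr, p), at(tpl$R, p))
    expect_false(at(esc, p) %in% c(at(tpl$L, p), at(tpl$R, p)))
    expect_true(at(esc, p) %in% names(Biostrings::IUPAC_CODE_MAP))
  }
  expect_error(
    simulate_marker_sequences(
      tibble::tibble(individual = "x", call = "ridibundus")
    ),
    "unknown call"
  )
})
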