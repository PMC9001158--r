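test_that("error rate counts genotype-level discordance over compared cells", {
  gt <- make_random_table(5, 20, seed = 31, missing_p = 0)
  pairing <- tibble::tibble(id_a = individuals(gt), id_b = individuals(gt))
  expect_equal(as.numeric(snp_error_rate(gt, gt, pairing)), 0)

  # flip exactly one of 100 compared cells
  b <- tibble::as_tibble(gt)
  b$genotype[1] <- if (b$genotype[1] == "A1A1") "A2A2" else "A1A1"
  b$depth_a1[1] <- ifelse(b$genotype[1] == "A2A2", 0L, 10L)
  b$depth_a2[1] <- ifelse(b$genotype[1] == "A2A2", 10L, 0L)
  gtb <- genotype_table(b, sample_meta(gt))
  rate <- snp_error_rate(gt, gtb, pairing)
  expect_equal(as.numeric(rate), 1 / 100)
  expect_equal(attr(rate, "n_compared"), 100L)
})

test_that("error rate is symmetric and errors without comparable cells", {
  gt <- make_random_table(4, 30, seed = 32, missing_p = 0.2)
  reps <- simulate_replicates(gt, 0.1, seed = 1)
  fwd <- snp_error_rate(reps$rep1, reps$rep2, reps$pairing)
  rev <- snp_error_rate(
    reps$rep2, reps$rep1,
    tibble::tibble(id_a = reps$pairing$id_b, id_b = reps$pairing$id_a)
  )
  expect_equal(as.numeric(fwd), as.numeric(rev))

  all_missing <- genotype_table(tibble::tibble(
    individual = "a", locus = "l1", genotype = "MISSING",
    depth_a1 = 0L, depth_a2 = 0L
  ))
  expect_error(
    snp_error_rate(all_missing, all_missing,
                   tibble::tibble(id_a = "a", id_b = "a")),
    "no comparable"
  )
  expect_error(
    snp_error_rate(gt, gt, tibble::tibble(id_a = "nope", id_b = "a")),
    "unknown individual"
  )
})

test_that("planted replicate error is recovered within binomial error", {
  gt <- simulate_pond(pond_spec(
    pond_id = "p", LL = 10, LR = 10, n_loci = 250,
    missing_rate = 0, genotyping_error_rate = 0, seed = 33
  ))$table
  reps <- simulate_replicates(gt, 0.02, seed = 2)
  est <- snp_error_rate(reps$rep1, reps$rep2, reps$pairing)
  n <- attr(est, "n_compared")
  expect_lt(abs(as.numeric(est) - 0.02), 3 * sqrt(0.02 * 0.98 / n))
})

make_sweep_dataset <- function(error, seed) {
  base <- simulate_pond(pond_spec(
    pond_id = "p", LL = 10, LR = 10, n_loci = 200,
    missing_rate = 0.15, genotyping_error_rate = 0, seed = seed
  ))$table
  reps <- simulate_replicates(base, error, seed = seed + 1)
  a <- tibble::as_tibble(reps$rep1)
  b <- tibble::as_tibble(reps$rep2)
  b$individual <- paste0(b$individual, "_rep")
  meta_a <- sample_meta(reps$rep1)
  meta_b <- meta_a
  meta_b$individual <- paste0(meta_b$individual, "_rep")
  combined <- genotype_table(
    dplyr::bind_rows(a, b), dplyr::bind_rows(meta_a, meta_b)
  )
  list(
    table = combined,
    pairing = tibble::tibble(
      id_a = meta_a$individual, id_b = meta_b$individual
    )
  )
}

test_that("the sweep grid produces one record per filter combination", {
  ds <- make_sweep_dataset(0.02, seed = 41)
  records <- run_sweep(list(m3M3 = ds))
  expect_equal(nrow(records), 9L)
  expect_setequal(records$mds, c(0.3, 0.4, 0.5))
  # stricter mds never yields more SNPs at fixed mdi
  for (mdi in c(0.3, 0.4, 0.5)) {
    r <- records[records$mdi == mdi, ]
    r <- r[order(r$mds), ]
    expect_true(all(diff(r$n_snps) >= 0))
  }
  # planted 2% error recovered in every record
  ok <- !is.na(records$error_rate)
  expect_true(all(abs(records$error_rate[ok] - 0.02) < 0.015))
})

test_that("setting selection prefers low error, then size, deterministically", {
  rec <- function(params, n_snps, n_individuals, error_rate) {
    tibble::tibble(
      params = params, mds = 0.3, mdi = 0.3, n_snps = n_snps,
      n_individuals = n_individuals, missing_fraction = 0.1,
      error_rate = error_rate
    )
  }
  single <- rec("only", 100, 10, 0.02)
  expect_equal(select_setting(single)$params, "only")

  two <- dplyr::bind_rows(
    rec("a", 100, 10, 0.01), rec("b", 100, 10, 0.02)
  )
  expect_equal(select_setting(two)$params, "a")

  # a dominated record (fewer SNPs and individuals, higher error) never wins
  three <- dplyr::bind_rows(
    rec("big", 1000, 60, 0.016),
    rec("small_clean", 900, 60, 0.015),
    rec("dominated", 700, 41, 0.025)
  )
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_false(select_setting(three[perm, ])$params == "dominated")
  }
  # order invariance up to tie-breaking: distinct records, same winner
  expect_equal(
    select_setting(three)$params,
    select_setting(three[c(3, 1, 2), ])$params
  )
})
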