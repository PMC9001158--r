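# small helper: a table planted with known diagnostic loci via simulate_pond
plant_pond <- function(..., seed = 61) {
  simulate_pond(pond_spec(
    pond_id = "p", n_loci = 150, fraction_diagnostic = 0.2,
    missing_rate = 0, genotyping_error_rate = 0, seed = seed, ...
  ))
}

test_that("noise-free reference panels recover the planted diagnostic set", {
  sim <- plant_pond(LL = 10, LR = 10)
  truth <- sim$truth
  refs_homo <- truth$individuals$individual[truth$individuals$genomotype == "LL"]
  refs_het <- truth$individuals$individual[truth$individuals$genomotype == "LR"]
  got <- identify_diagnostic_loci(sim$table, refs_homo, refs_het)
  want <- truth$loci[truth$loci$diagnostic, ]
  expect_setequal(got$locus, want$locus)
  m <- match(got$locus, want$locus)
  expect_equal(got$L_allele, want$L_allele[m])
  expect_equal(got$R_allele, want$R_allele[m])
})

test_that("missing-data tolerance admits 3 but rejects 4 missing per panel", {
  sim <- plant_pond(LL = 10, LR = 10, seed = 62)
  truth <- sim$truth
  refs_homo <- truth$individuals$individual[truth$individuals$genomotype == "LL"]
  refs_het <- truth$individuals$individual[truth$individuals$genomotype == "LR"]
  diag_loci <- truth$loci$locus[truth$loci$diagnostic]
  blank <- function(cells, locus, inds) {
    sel <- cells$locus == locus & cells$individual %in% inds
    cells$genotype[sel] <- "MISSING"
    cells$depth_a1[sel] <- 0L
    cells$depth_a2[sel] <- 0L
    cells
  }
  cells <- tibble::as_tibble(sim$table)
  cells <- blank(cells, diag_loci[1], refs_homo[1:3])  # tolerated
  cells <- blank(cells, diag_loci[2], refs_homo[1:4])  # one too many
  tampered <- genotype_table(cells, sample_meta(sim$table))
  got <- identify_diagnostic_loci(tampered, refs_homo, refs_het,
                                  max_missing_per_cluster = 3)
  expect_true(diag_loci[1] %in% got$locus)
  expect_false(diag_loci[2] %in% got$locus)
})

test_that("a homozygous panel split between alleles disqualifies a locus", {
  sim <- plant_pond(LL = 10, LR = 10, seed = 63)
  truth <- sim$truth
  refs_homo <- truth$individuals$individual[truth$individuals$genomotype == "LL"]
  refs_het <- truth$individuals$individual[truth$individuals$genomotype == "LR"]
  diag_loci <- truth$loci$locus[truth$loci$diagnostic]
  cells <- tibble::as_tibble(sim$table)
  sel <- cells$locus == diag_loci[1] & cells$individual == refs_homo[1]
  cells$genotype[sel] <- ifelse(cells$genotype[sel] == "A1A1",
                                "A2A2", "A1A1")
  tmp <- cells$depth_a1[sel]
  cells$depth_a1[sel] <- cells$depth_a2[sel]
  cells$depth_a2[sel] <- tmp
  tampered <- genotype_table(cells, sample_meta(sim$table))
  got <- identify_diagnostic_loci(tampered, refs_homo, refs_het)
  expect_false(diag_loci[1] %in% got$locus)
  expect_error(
    identify_diagnostic_loci(sim$table, refs_homo,
                             c(refs_het, refs_homo[1])),
    "overlap"
  )
})

test_that("cluster orientation is resolved by which panel yields loci", {
  sim <- plant_pond(LL = 10, LR = 10, seed = 64)
  truth <- sim$truth
  ll <- truth$individuals$individual[truth$individuals$genomotype == "LL"]
  lr <- truth$individuals$individual[truth$individuals$genomotype == "LR"]
  d1 <- find_diagnostic_loci(sim$table, ll, lr)
  expect_equal(attr(d1, "homozygous_panel"), "a")
  d2 <- find_diagnostic_loci(sim$table, lr, ll)
  expect_equal(attr(d2, "homozygous_panel"), "b")
  expect_setequal(d1$locus, d2$locus)
  expect_error(
    find_diagnostic_loci(sim$table, ll[1:5], ll[6:10]),
    "neither orientation"
  )
})

test_that("composition profiles partition called diagnostic loci", {
  sim <- plant_pond(LL = 2, LR = 2, LLR = 2, seed = 65)
  truth <- sim$truth
  diag <- truth$loci[truth$loci$diagnostic, c("locus", "L_allele", "R_allele")]
  ll_id <- truth$individuals$individual[truth$individuals$genomotype == "LL"][1]
  p <- composition_profile(sim$table, ll_id, diag)
  expect_equal(p$p_homL, 1)
  expect_equal(p$n_het, 0L)
  expect_equal(nrow(p$het_depths[[1]]), 0)

  profs <- composition_profiles(sim$table, diag)
  expect_equal(profs$p_homL + profs$p_homR + profs$p_het,
               rep(1, nrow(profs)))
  expect_error(
    composition_profile(sim$table, "nobody", diag),
    "unknown individual"
  )
})

test_that("relative L coverage comes from per-locus depths", {
  gt <- genotype_table(tibble::tibble(
    individual = "x",
    locus = c("d1", "d2"),
    genotype = c("A1A2", "A1A2"),
    depth_a1 = c(20L, 3L),
    depth_a2 = c(10L, 2L)
  ))
  diag <- tibble::tibble(
    locus = c("d1", "d2"), L_allele = "A1", R_allele = "A2"
  )
  p <- composition_profile(gt, "x", diag, min_depth = 8)
  hd <- p$het_depths[[1]]
  expect_equal(hd$locus, "d1")              # d2 under the depth floor
  expect_equal(hd$rel_L, 2 / 3, tolerance = 1e-9)
})

test_that("the classification cascade maps pure and hybrid profiles", {
  mk_profile <- function(p_homL, p_homR, p_het, depth_L, total, n = 50) {
    tibble::tibble(
      individual = "x", n_called = 100L,
      p_homL = p_homL, p_homR = p_homR, p_het = p_het,
      n_het = if (length(depth_L)) n else 0L,
      het_depths = list(tibble::tibble(
        locus = sprintf("h%03d", seq_len(if (length(depth_L)) n else 0)),
        depth_L = rep(depth_L, length.out = if (length(depth_L)) n else 0),
        total = rep(total, length.out = if (length(depth_L)) n else 0),
        rel_L = rep(depth_L / total,
                    length.out = if (length(depth_L)) n else 0)
      ))
    )
  }
  expect_equal(
    classify_genotype(mk_profile(1, 0, 0, integer(0), integer(0)))$label,
    "LL"
  )
  expect_equal(
    classify_genotype(mk_profile(0, 1, 0, integer(0), integer(0)))$label,
    "RR"
  )
  # exact binomial fractions: the closed-form high-depth limit
  expect_equal(
    classify_genotype(mk_profile(0.02, 0.02, 0.96, 15L, 30L))$label, "LR"
  )
  expect_equal(
    classify_genotype(mk_profile(0.02, 0.02, 0.96, 20L, 30L))$label, "LLR"
  )
  expect_equal(
    classify_genotype(mk_profile(0.02, 0.02, 0.96, 10L, 30L))$label, "LRR"
  )
  # too few informative loci -> hybrid of unknown ploidy
  few <- mk_profile(0.02, 0.02, 0.96, 15L, 30L, n = 5)
  expect_equal(classify_genotype(few)$label, "E_UNKNOWN_PLOIDY")
  # contamination signature: half fixed L, half diploid-like
  cont <- classify_genotype(mk_profile(0.56, 0.0, 0.44, 15L, 30L))
  expect_equal(cont$label, "UNDETERMINED")
  expect_match(cont$flags, "CONTAMINATION_SUSPECT")
})

test_that("simulated triploids are recovered through the whole chain", {
  sim <- simulate_pond(pond_spec(
    pond_id = "p", LLR = 10, n_loci = 250, fraction_diagnostic = 0.3,
    mean_depth = 30, missing_rate = 0, genotyping_error_rate = 0,
    seed = 66
  ))
  truth <- sim$truth
  diag <- truth$loci[truth$loci$diagnostic,
                     c("locus", "L_allele", "R_allele")]
  calls <- classify_genotypes(sim$table, diag)
  expect_true(all(calls$label == "LLR"))
  expect_true(all(calls$n_het >= 50))
})

test_that("swapping the L/R orientation mirrors the genomotype labels", {
  sim <- simulate_pond(pond_spec(
    pond_id = "p", LL = 4, LR = 4, LLR = 4, LRR = 4, RR = 4,
    n_loci = 250, fraction_diagnostic = 0.3, mean_depth = 30,
    missing_rate = 0, genotyping_error_rate = 0, seed = 67
  ))
  diag <- sim$truth$loci[sim$truth$loci$diagnostic,
                         c("locus", "L_allele", "R_allele")]
  fwd <- classify_genotypes(sim$table, diag)
  rev <- classify_genotypes(sim$table, swap_orientation(diag))
  mirror <- c(LL = "RR", RR = "LL", LLR = "LRR", LRR = "LLR", LR = "LR")
  expect_equal(rev$label, unname(mirror[fwd$label]))
})
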