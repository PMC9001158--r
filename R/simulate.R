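#' Specification of a simulated pond
#'
#' Defines one pond's sample of water frogs by genomotype — LL
#' (*P. lessonae*), LR (diploid *P.* kl. *esculentus*), LLR/LRR (triploid
#' hybrids) and RR (*P. ridibundus* complex) — together with the locus
#' panel and the sequencing noise model. The defaults describe a typical
#' ddRAD study of such a complex: ~1000 biallelic SNPs of which ~16% are
#' L/R-diagnostic, mean per-cell depth 30x with negative-binomial
#' overdispersion, 10% missing cells and a per-call genotyping error of
#' 0.8% (which yields a replicate discordance in the 1.5% range).
#'
#' @param pond_id Pond label, used as a prefix for individual ids.
#' @param LL,LR,LLR,LRR,RR Number of individuals of each genomotype.
#' @param n_loci Number of biallelic loci.
#' @param fraction_diagnostic Fraction of loci planted as L/R-diagnostic
#'   (fixed for one allele in the L genome and the other in the R genome).
#' @param mean_depth,depth_dispersion Mean and dispersion (`size`) of the
#'   negative-binomial per-cell read depth.
#' @param missing_rate Per-cell probability of a missing call.
#' @param genotyping_error_rate Per-cell probability that a call is
#'   flipped to a uniformly chosen different genotype.
#' @param seed Integer seed; all randomness of [simulate_pond()] flows
#'   from it.
#' @return A list of class `pond_spec`.
#' @export
pond_spec <- function(pond_id = "pond1",
                      LL = 0L, LR = 0L, LLR = 0L, LRR = 0L, RR = 0L,
                      n_loci = 1000L,
                      fraction_diagnostic = 0.16,
                      mean_depth = 30,
                      depth_dispersion = 5,
                      missing_rate = 0.1,
                      genotyping_error_rate = 0.008,
                      seed = 1L) {
  counts <- c(LL = LL, LR = LR, LLR = LLR, LRR = LRR, RR = RR)
  if (any(counts < 0)) abort("genomotype counts must be >= 0")
  if (sum(counts) == 0) abort("at least one genomotype count must be > 0")
  if (n_loci < 1) abort("n_loci must be >= 1")
  stopifnot(
    fraction_diagnostic >= 0, fraction_diagnostic <= 1,
    missing_rate >= 0, missing_rate <= 1,
    genotyping_error_rate >= 0, genotyping_error_rate <= 1,
    mean_depth > 0, depth_dispersion > 0
  )
  structure(
    list(
      pond_id = pond_id, counts = counts, n_loci = as.integer(n_loci),
      fraction_diagnostic = fraction_diagnostic,
      mean_depth = mean_depth, depth_dispersion = depth_dispersion,
      missing_rate = missing_rate,
      genotyping_error_rate = genotyping_error_rate,
      seed = as.integer(seed)
    ),
    class = "pond_spec"
  )
}

# genome copy numbers (L, R) per genomotype
genome_copies <- function(genomotype) {
  nL <- c(LL = 2L, LR = 1L, LLR = 2L, LRR = 1L, RR = 0L)
  nR <- c(LL = 0L, LR = 1L, LLR = 1L, LRR = 2L, RR = 2L)
  tibble::tibble(nL = nL[genomotype], nR = nR[genomotype])
}

# negative-binomial depth truncated below at `min`
rdepth_trunc <- function(n, mu, size, min = 1L) {
  d <- stats::rnbinom(n, size = size, mu = mu)
  bad <- which(d < min)
  while (length(bad) > 0) {
    d[bad] <- stats::rnbinom(length(bad), size = size, mu = mu)
    bad <- bad[d[bad] < min]
  }
  d
}

# Binomial(d, p) conditioned on an interior outcome 1..d-1 (needs d >= 2);
# guarantees a heterozygous cell shows both alleles.
rbinom_interior <- function(d, p) {
  x <- stats::rbinom(length(d), d, p)
  bad <- which(x == 0L | x == d)
  while (length(bad) > 0) {
    x[bad] <- stats::rbinom(length(bad), d[bad], p[bad])
    bad <- bad[x[bad] == 0L | x[bad] == d[bad]]
  }
  x
}

# Shared locus panel: diagnostic loci are fixed differentially between the
# L and R genomes; non-diagnostic loci carry ordinary population
# polymorphism, with a 50% chance of a shared allele frequency.
make_locus_plan <- function(n_loci, fraction_diagnostic) {
  n_diag <- round(n_loci * fraction_diagnostic)
  diagnostic <- rep(FALSE, n_loci)
  if (n_diag > 0) {
    diagnostic[sample.int(n_loci, n_diag)] <- TRUE
  }
  L_allele <- ifelse(
    diagnostic,
    sample(c("A1", "A2"), n_loci, replace = TRUE),
    NA_character_
  )
  shared <- stats::runif(n_loci) < 0.5
  p_shared <- stats::runif(n_loci, 0.05, 0.95)
  p_L <- ifelse(shared, p_shared, stats::runif(n_loci, 0.05, 0.95))
  p_R <- ifelse(shared, p_shared, stats::runif(n_loci, 0.05, 0.95))
  # diagnostic loci: frequency of A2 is 0/1, fixed oppositely in L and R
  p_L[diagnostic] <- as.numeric(L_allele[diagnostic] == "A2")
  p_R[diagnostic] <- 1 - p_L[diagnostic]
  tibble::tibble(
    locus = sprintf("loc%04d", seq_len(n_loci)),
    diagnostic = diagnostic,
    L_allele = L_allele,
    R_allele = ifelse(is.na(L_allele), NA_character_,
                      ifelse(L_allele == "A1", "A2", "A1")),
    p_L = p_L, p_R = p_R,
    # hemiclonal lineages: triploids inherit a clonally transmitted
    # parental-genome pair (LL for LLR, RR for LRR), drawn once per plan
    clone_LL_a2 = stats::rbinom(n_loci, 2L, p_L),
    clone_RR_a2 = stats::rbinom(n_loci, 2L, p_R)
  )
}

# core cell-level generator used by simulate_pond / simulate_country;
# assumes an RNG state has already been established by the caller
simulate_cells <- function(individual_truth, plan, mean_depth,
                           depth_dispersion, missing_rate,
                           genotyping_error_rate) {
  cells <- tidyr::expand_grid(
    individual = individual_truth$individual,
    locus = plan$locus
  ) %>%
    dplyr::left_join(individual_truth, by = "individual") %>%
    dplyr::left_join(plan, by = "locus")
  copies <- genome_copies(cells$genomotype)
  kL <- stats::rbinom(nrow(cells), copies$nL, cells$p_L)
  kR <- stats::rbinom(nrow(cells), copies$nR, cells$p_R)
  # triploids carry a clonal parental-genome pair rather than two
  # independently sampled copies (hemiclonal transmission)
  is_llr <- cells$genomotype == "LLR"
  is_lrr <- cells$genomotype == "LRR"
  kL[is_llr] <- cells$clone_LL_a2[is_llr]
  kR[is_lrr] <- cells$clone_RR_a2[is_lrr]
  k <- kL + kR
  ploidy <- copies$nL + copies$nR
  geno <- ifelse(k == 0L, "A1A1", ifelse(k == ploidy, "A2A2", "A1A2"))
  dosage <- k / ploidy

  # genotyping error: flip to a uniformly chosen different called state
  flip <- stats::runif(nrow(cells)) < genotyping_error_rate
  if (any(flip)) {
    geno[flip] <- flip_genotype(geno[flip])
    dosage[flip] <- ifelse(geno[flip] == "A1A2", 0.5,
                           ifelse(geno[flip] == "A2A2", 1, 0))
  }

  het <- geno == "A1A2"
  d <- integer(nrow(cells))
  d[!het] <- rdepth_trunc(sum(!het), mean_depth, depth_dispersion, min = 1L)
  d[het] <- rdepth_trunc(sum(het), mean_depth, depth_dispersion, min = 2L)
  a2 <- integer(nrow(cells))
  a2[geno == "A2A2"] <- d[geno == "A2A2"]
  a2[het] <- rbinom_interior(d[het], dosage[het])

  miss <- stats::runif(nrow(cells)) < missing_rate
  geno[miss] <- "MISSING"
  d[miss] <- 0L
  a2[miss] <- 0L

  tibble::tibble(
    individual = cells$individual,
    locus = cells$locus,
    genotype = geno,
    depth_a1 = d - a2,
    depth_a2 = a2
  )
}

flip_genotype <- function(geno) {
  states <- c("A1A1", "A1A2", "A2A2")
  vapply(geno, function(g) sample(setdiff(states, g), 1L), "",
         USE.NAMES = FALSE)
}

#' Simulate one pond's genotype table
#'
#' Generates a biallelic RAD genotype + allele-depth matrix with the
#' statistical structure the downstream analysis assumes. At diagnostic
#' loci, LL individuals are homozygous for the L allele and RR for the R
#' allele; heterozygous hybrids show an allele-depth **dosage effect**:
#' the L-allele read count at a cell of total depth d is binomial with
#' success probability equal to the L-copy fraction of the genome — 1/2
#' for LR, 2/3 for LLR, 1/3 for LRR. Non-diagnostic loci segregate within
#' and between the parental genomes under Hardy-Weinberg sampling of the
#' per-genome allele frequencies, except that triploids carry a clonally
#' transmitted parental-genome pair (one shared LL diplotype for all LLR,
#' one RR diplotype for all LRR), emulating hemiclonal reproduction — this
#' is what makes triploids form their own cluster in ordination space, as
#' observed in real surveys. Per-cell depth is negative-binomial
#' (truncated at 1 read for called cells, 2 for heterozygotes so both
#' alleles are observed); genotyping errors and missingness are applied
#' i.i.d. per cell. Deterministic given `spec$seed`.
#'
#' @param spec A [pond_spec()].
#' @param plan Optional shared locus plan (from a multi-pond simulation);
#'   by default a fresh plan is drawn from the spec.
#' @return A list with elements `table` (a [genotype_table()]) and `truth`
#'   (list of `individuals` — individual/genomotype — and `loci` — the
#'   locus plan with the planted diagnostic set and L/R orientation).
#' @export
simulate_pond <- function(spec, plan = NULL) {
  stopifnot(inherits(spec, "pond_spec"))
  withr::with_seed(spec$seed, {
    if (is.null(plan)) {
      plan <- make_locus_plan(spec$n_loci, spec$fraction_diagnostic)
    }
    ind_truth <- tibble::tibble(
      genomotype = rep(names(spec$counts), spec$counts)
    )
    ind_truth$individual <- sprintf(
      "%s_%s%02d", spec$pond_id, ind_truth$genomotype,
      stats::ave(seq_len(nrow(ind_truth)), ind_truth$genomotype,
                 FUN = seq_along)
    )
    ind_truth <- ind_truth[c("individual", "genomotype")]
    calls <- simulate_cells(
      ind_truth, plan, spec$mean_depth, spec$depth_dispersion,
      spec$missing_rate, spec$genotyping_error_rate
    )
    meta <- tibble::tibble(
      individual = ind_truth$individual,
      pond = spec$pond_id,
      replicate_group = ind_truth$individual,
      total_reads = round(stats::rlnorm(
        nrow(ind_truth), meanlog = log(480000), sdlog = 0.5
      ))
    )
    list(
      table = genotype_table(calls, meta),
      truth = list(
        individuals = ind_truth,
        loci = plan[c("locus", "diagnostic", "L_allele", "R_allele")]
      )
    )
  })
}

#' Simulate a multi-pond survey with a shared locus panel
#'
#' All ponds share one locus plan (as real ddRAD loci are shared across a
#' study), so individuals from different ponds are comparable and a single
#' diagnostic set serves the whole survey. Also emits a synthetic ancestry
#' (Q) matrix consistent with the planted genomotypes, standing in for the
#' admixture output of an external clustering program: each individual's
#' ancestry is concentrated on its own genomotype cluster (Dirichlet
#' sampling, concentration `q_concentration` on the own cluster, 0.5
#' elsewhere).
#'
#' @param pond_specs A data frame with column `pond_id` and integer
#'   genomotype count columns among `LL`, `LR`, `LLR`, `LRR`, `RR`.
#' @param n_loci,fraction_diagnostic,mean_depth,depth_dispersion,missing_rate,genotyping_error_rate
#'   Shared noise model, as in [pond_spec()].
#' @param seed Integer master seed.
#' @param q_concentration Dirichlet concentration of an individual's own
#'   cluster in the synthetic ancestry matrix.
#' @return A list with `table`, `truth` (as in [simulate_pond()], plus the
#'   pond of each individual via the table's [sample_meta()]) and
#'   `ancestry` (tibble: `individual` plus one `q_*` column per cluster).
#' @export
simulate_country <- function(pond_specs,
                             n_loci = 1000L,
                             fraction_diagnostic = 0.16,
                             mean_depth = 30,
                             depth_dispersion = 5,
                             missing_rate = 0.1,
                             genotyping_error_rate = 0.008,
                             seed = 1L,
                             q_concentration = 30) {
  pond_specs <- tibble::as_tibble(pond_specs)
  stopifnot("pond_id" %in% names(pond_specs))
  for (g in GENOMOTYPE_LEVELS) {
    if (!g %in% names(pond_specs)) pond_specs[[g]] <- 0L
  }
  withr::with_seed(as.integer(seed), {
    plan <- make_locus_plan(n_loci, fraction_diagnostic)
    pond_seeds <- sample.int(.Machine$integer.max, nrow(pond_specs))
    sims <- purrr::map(seq_len(nrow(pond_specs)), function(i) {
      row <- pond_specs[i, ]
      spec <- pond_spec(
        pond_id = row$pond_id,
        LL = row$LL, LR = row$LR, LLR = row$LLR, LRR = row$LRR, RR = row$RR,
        n_loci = n_loci, fraction_diagnostic = fraction_diagnostic,
        mean_depth = mean_depth, depth_dispersion = depth_dispersion,
        missing_rate = missing_rate,
        genotyping_error_rate = genotyping_error_rate,
        seed = pond_seeds[i]
      )
      simulate_pond(spec, plan = plan)
    })
    calls <- dplyr::bind_rows(purrr::map(sims, ~ tibble::as_tibble(.x$table)))
    meta <- dplyr::bind_rows(purrr::map(sims, ~ sample_meta(.x$table)))
    ind_truth <- dplyr::bind_rows(purrr::map(sims, ~ .x$truth$individuals))
    clusters <- intersect(GENOMOTYPE_LEVELS, unique(ind_truth$genomotype))
    alpha <- matrix(0.5, nrow(ind_truth), length(clusters),
                    dimnames = list(NULL, clusters))
    alpha[cbind(seq_len(nrow(ind_truth)),
                match(ind_truth$genomotype, clusters))] <- q_concentration
    gam <- matrix(
      stats::rgamma(length(alpha), shape = alpha),
      nrow = nrow(alpha)
    )
    q <- gam / rowSums(gam)
    colnames(q) <- paste0("q_", clusters)
    ancestry <- dplyr::bind_cols(
      tibble::tibble(individual = ind_truth$individual),
      tibble::as_tibble(q)
    )
    list(
      table = genotype_table(calls, meta),
      truth = list(
        individuals = ind_truth,
        loci = plan[c("locus", "diagnostic", "L_allele", "R_allele")]
      ),
      ancestry = ancestry
    )
  })
}

#' Simulate technical replicates of a genotype table
#'
#' Returns two copies of the table whose non-missing calls differ at each
#' cell independently with probability `per_snp_error` (a flipped call is
#' drawn uniformly from the other two genotype states, with depths
#' redrawn to stay consistent with the new call). This is the generative
#' model under which the replicate-based SNP-calling error rate is the
#' binomial proportion of discordant compared cells.
#'
#' @param table A `genotype_tbl`.
#' @param per_snp_error Per-cell discordance probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `rep1`, `rep2` (genotype tables with the same
#'   individual ids) and `pairing` (tibble `id_a`, `id_b`).
#' @export
simulate_replicates <- function(table, per_snp_error, seed = 1L) {
  stopifnot(per_snp_error >= 0, per_snp_error <= 1)
  withr::with_seed(as.integer(seed), {
    a <- tibble::as_tibble(table)
    b <- a
    eligible <- which(b$genotype != "MISSING")
    flip <- eligible[stats::runif(length(eligible)) < per_snp_error]
    if (length(flip) > 0) {
      new_geno <- flip_genotype(b$genotype[flip])
      d <- pmax(b$depth_a1[flip] + b$depth_a2[flip], 1L)
      a1 <- integer(length(flip))
      hom1 <- new_geno == "A1A1"
      hom2 <- new_geno == "A2A2"
      het <- new_geno == "A1A2"
      a1[hom1] <- d[hom1]
      a1[hom2] <- 0L
      if (any(het)) {
        d[het] <- pmax(d[het], 2L)
        a1[het] <- rbinom_interior(d[het], rep(0.5, sum(het)))
      }
      b$genotype[flip] <- new_geno
      b$depth_a1[flip] <- a1
      b$depth_a2[flip] <- d - a1
    }
    meta <- sample_meta(table)
    list(
      rep1 = genotype_table(a, meta),
      rep2 = genotype_table(b, meta),
      pairing = tibble::tibble(
        id_a = individuals(table), id_b = individuals(table)
      )
    )
  })
}

#' Simulate DBR-tagged read pairs with known PCR duplicates
#'
#' Each template molecule receives a random degenerate-base-region (DBR)
#' tag; PCR copies (count ~ Poisson(`dup_lambda`) beyond the original)
#' share both the template sequence and the DBR. Distinct templates draw
#' independent DBRs even when their insert sequences coincide (set
#' `n_unique_inserts < n_templates` to force such collisions) — this is
#' precisely the situation the DBR exists to disambiguate.
#'
#' @param n_templates Number of independent template molecules.
#' @param dup_lambda Poisson mean of extra PCR copies per template.
#' @param dbr_length DBR tag length in bases.
#' @param seed Integer seed.
#' @param read_length Length of each mate's template sequence.
#' @param n_unique_inserts Number of distinct insert sequences the
#'   templates are drawn from (default: all distinct).
#' @return A `read_pairs` tibble with truth columns `template_id` and
#'   `is_pcr_duplicate` (TRUE for every copy beyond a template's first).
#' @export
simulate_dbr_reads <- function(n_templates, dup_lambda = 1,
                               dbr_length = 8L, seed = 1L,
                               read_length = 60L,
                               n_unique_inserts = n_templates) {
  stopifnot(n_templates >= 1, dbr_length >= 1,
            n_unique_inserts >= 1, n_unique_inserts <= n_templates)
  withr::with_seed(as.integer(seed), {
    rand_dna <- function(n, len) {
      vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
      }, "")
    }
    ins1 <- rand_dna(n_unique_inserts, read_length)
    ins2 <- rand_dna(n_unique_inserts, read_length)
    insert_of <- ((seq_len(n_templates) - 1L) %% n_unique_inserts) + 1L
    dbrs <- rand_dna(n_templates, dbr_length)
    copies <- 1L + stats::rpois(n_templates, dup_lambda)
    template_id <- rep(seq_len(n_templates), copies)
    copy_idx <- unlist(lapply(copies, seq_len))
    n_reads <- length(template_id)
    rand_qual <- function(n, len) {
      vapply(seq_len(n), function(i) {
        intToUtf8(sample(63:73, len, replace = TRUE))  # phred 30..40
      }, "")
    }
    out <- tibble::tibble(
      id = sprintf("tpl%05d_copy%d", template_id, copy_idx),
      read1_seq = ins1[insert_of[template_id]],
      read2_seq = ins2[insert_of[template_id]],
      qual1 = rand_qual(n_reads, read_length),
      qual2 = rand_qual(n_reads, read_length),
      dbr = dbrs[template_id],
      template_id = template_id,
      is_pcr_duplicate = copy_idx > 1L
    )
    class(out) <- c("read_pairs", class(out))
    out
  })
}

#' Simulate MND1 and ND1 marker sequences
#'
#' Emits, per individual, a 33-base MND1 nuclear fragment — the L and R
#' alleles differ at exactly two diagnostic positions, and heterozygous
#' (esculentus) individuals show IUPAC ambiguity codes there, as in
#' direct Sanger sequencing of a heterozygote — and a 336-base ND1
#' mitochondrial haplotype drawn near one of three reference haplogroups
#' (lessonae, ridibundus, bedriagae), carrying 0-`max_private` private
#' substitutions.
#'
#' @param calls A data frame with columns `individual` and `call`, the
#'   latter one of `"lessonae"`, `"esculentus"`, `"RR"`.
#' @param seed Integer seed.
#' @param templates MND1 allele templates, see [mnd1_templates()].
#' @param nd1_refs ND1 reference haplotypes, see [nd1_references()].
#' @param haplogroup_of Named map from call to the ND1 haplogroup the
#'   maternal lineage belongs to. The default sends lessonae and
#'   esculentus to the shared lessonae lineage and RR genotypes to the
#'   bedriagae lineage.
#' @param max_private Maximum number of private ND1 substitutions.
#' @return A list of tibbles `mnd1` (`individual`, `label`, `sequence`)
#'   and `nd1` (`individual`, `haplogroup`, `sequence`).
#' @export
simulate_marker_sequences <- function(calls, seed = 1L,
                                      templates = mnd1_templates(),
                                      nd1_refs = nd1_references(),
                                      haplogroup_of = c(
                                        lessonae = "lessonae",
                                        esculentus = "lessonae",
                                        RR = "bedriagae"
                                      ),
                                      max_private = 2L) {
  calls <- tibble::as_tibble(calls)
  bad <- setdiff(unique(calls$call), c("lessonae", "esculentus", "RR"))
  if (length(bad) > 0) {
    abort(paste0("unknown call label(s): ", paste(bad, collapse = ", ")))
  }
  withr::with_seed(as.integer(seed), {
    pos <- templates$positions
    esc <- templates$L
    for (p in pos) {
      substr(esc, p, p) <- iupac_het(
        substr(templates$L, p, p), substr(templates$R, p, p)
      )
    }
    mnd1_seq <- c(
      lessonae = templates$L, esculentus = esc, RR = templates$R
    )
    mnd1 <- tibble::tibble(
      individual = calls$individual,
      label = calls$call,
      sequence = unname(mnd1_seq[calls$call])
    )
    hg <- unname(haplogroup_of[calls$call])
    ref_seq <- stats::setNames(nd1_refs$sequence, nd1_refs$haplogroup)
    len <- nchar(ref_seq[[1]])
    nd1_seqs <- vapply(seq_len(nrow(calls)), function(i) {
      s <- ref_seq[[hg[i]]]
      k <- sample(0:max_private, 1L)
      if (k > 0) {
        at <- sample.int(len, k)
        for (p in at) {
          substr(s, p, p) <- sample(
            setdiff(c("A", "C", "G", "T"), substr(s, p, p)), 1L
          )
        }
      }
      s
    }, "")
    nd1 <- tibble::tibble(
      individual = calls$individual,
      haplogroup = hg,
      sequence = nd1_seqs
    )
    list(mnd1 = mnd1, nd1 = nd1)
  })
}
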