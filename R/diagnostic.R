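#' Identify L/R-diagnostic loci from reference panels
#'
#' A locus is diagnostic when every called reference of the homozygous
#' panel (the putative *P. lessonae* cluster) is homozygous for the
#' *same* allele, every called reference of the heterozygous panel (the
#' putative diploid hybrid cluster) is heterozygous, and each panel has
#' at most `max_missing_per_cluster` missing calls at the locus (default
#' 3 of 10). The allele fixed in the homozygous panel becomes the L
#' allele; the alternative becomes the R allele.
#'
#' @param table A `genotype_tbl`.
#' @param refs_homo,refs_het Disjoint character vectors of reference
#'   individual ids.
#' @param max_missing_per_cluster Missing calls tolerated per panel.
#' @return A `diagnostic_set` tibble: `locus`, `L_allele`, `R_allele`.
#' @export
identify_diagnostic_loci <- function(table, refs_homo, refs_het,
                                     max_missing_per_cluster = 3L) {
  if (length(refs_homo) == 0 || length(refs_het) == 0) {
    abort("both reference panels must be non-empty")
  }
  overlap <- intersect(refs_homo, refs_het)
  if (length(overlap) > 0) {
    abort(paste0(
      "reference panels overlap: ", paste(overlap, collapse = ", ")
    ))
  }
  calls <- tibble::as_tibble(table)
  homo <- calls[calls$individual %in% refs_homo, , drop = FALSE] %>%
    dplyr::group_by(locus = .data$locus) %>%
    dplyr::summarise(
      n_miss = sum(.data$genotype == "MISSING") +
        (length(.env$refs_homo) - dplyr::n()),
      all_hom_a1 = all(.data$genotype[.data$genotype != "MISSING"] == "A1A1"),
      all_hom_a2 = all(.data$genotype[.data$genotype != "MISSING"] == "A2A2"),
      n_called = sum(.data$genotype != "MISSING"),
      .groups = "drop"
    )
  het <- calls[calls$individual %in% refs_het, , drop = FALSE] %>%
    dplyr::group_by(locus = .data$locus) %>%
    dplyr::summarise(
      n_miss = sum(.data$genotype == "MISSING") +
        (length(.env$refs_het) - dplyr::n()),
      all_het = all(.data$genotype[.data$genotype != "MISSING"] == "A1A2"),
      n_called = sum(.data$genotype != "MISSING"),
      .groups = "drop"
    )
  joined <- dplyr::inner_join(homo, het, by = "locus",
                              suffix = c("_homo", "_het"))
  ok <- joined$n_miss_homo <= max_missing_per_cluster &
    joined$n_miss_het <= max_missing_per_cluster &
    joined$n_called_homo > 0 & joined$n_called_het > 0 &
    (joined$all_hom_a1 | joined$all_hom_a2) &
    joined$all_het
  found <- joined[ok, , drop = FALSE]
  out <- tibble::tibble(
    locus = found$locus,
    L_allele = ifelse(found$all_hom_a1, "A1", "A2"),
    R_allele = ifelse(found$all_hom_a1, "A2", "A1")
  )
  class(out) <- c("diagnostic_set", class(out))
  out
}

#' Discover diagnostic loci with automatic cluster orientation
#'
#' Which of two clusters is the homozygous parental species is not known
#' a priori, so both assignments of the panels to the homozygous /
#' heterozygous roles are attempted; exactly one should yield a
#' substantial number of diagnostic loci (at least `min_diagnostic`),
#' and that orientation defines the L genome. Both succeeding is
#' ambiguous and raises an error demanding manual resolution; neither
#' succeeding means the panels do not contrast a parental species with
#' its hybrid.
#'
#' @param table A `genotype_tbl`.
#' @param refs_a,refs_b Reference panels of the two candidate clusters.
#' @param max_missing_per_cluster Missing calls tolerated per panel.
#' @param min_diagnostic Minimum locus count for an orientation to win.
#' @return A `diagnostic_set`; `attr(x, "homozygous_panel")` records
#'   which panel (`"a"` or `"b"`) turned out to be the parental
#'   (L-genome homozygous) cluster.
#' @export
find_diagnostic_loci <- function(table, refs_a, refs_b,
                                 max_missing_per_cluster = 3L,
                                 min_diagnostic = 10L) {
  d_a <- identify_diagnostic_loci(table, refs_a, refs_b,
                                  max_missing_per_cluster)
  d_b <- identify_diagnostic_loci(table, refs_b, refs_a,
                                  max_missing_per_cluster)
  ok_a <- nrow(d_a) >= min_diagnostic
  ok_b <- nrow(d_b) >= min_diagnostic
  if (ok_a && ok_b) {
    abort(paste0(
      "both cluster orientations yield diagnostic loci (",
      nrow(d_a), " and ", nrow(d_b),
      "); resolve the parental cluster manually"
    ))
  }
  if (!ok_a && !ok_b) {
    abort(paste0(
      "neither orientation yields >= ", min_diagnostic,
      " diagnostic loci (", nrow(d_a), " and ", nrow(d_b), " found)"
    ))
  }
  out <- if (ok_a) d_a else d_b
  attr(out, "homozygous_panel") <- if (ok_a) "a" else "b"
  out
}

#' Swap the L/R orientation of a diagnostic set
#'
#' @param diag_set A `diagnostic_set`.
#' @return The set with L and R alleles exchanged.
#' @export
swap_orientation <- function(diag_set) {
  tmp <- diag_set$L_allele
  diag_set$L_allele <- diag_set$R_allele
  diag_set$R_allele <- tmp
  diag_set
}

#' Genomic composition profile of one individual
#'
#' Over the individual's called diagnostic loci: the fractions of loci
#' homozygous for the L allele (`p_homL`), homozygous for the R allele
#' (`p_homR`) and heterozygous (`p_het`), which sum to 1; and, at each
#' heterozygous diagnostic locus with total depth at least `min_depth`,
#' the relative L-allele coverage `rel_L` = L depth / total depth,
#' together with the underlying read counts (kept for the binomial
#' dosage likelihood).
#'
#' @param table A `genotype_tbl`.
#' @param individual An individual id present in the table.
#' @param diag_set A `diagnostic_set`.
#' @param min_depth Minimum total depth for a heterozygous locus to enter
#'   the dosage data (default 8, the global depth filter).
#' @return A one-row tibble: `individual`, `n_called`, `p_homL`,
#'   `p_homR`, `p_het`, `n_het` and a list-column `het_depths` (tibble
#'   `locus`, `depth_L`, `total`, `rel_L`).
#' @export
composition_profile <- function(table, individual, diag_set,
                                min_depth = 8L) {
  if (!individual %in% individuals(table)) {
    abort(paste0("unknown individual: ", individual))
  }
  cells <- tibble::as_tibble(table)
  cells <- cells[cells$individual == individual, , drop = FALSE]
  cells <- dplyr::inner_join(cells, tibble::as_tibble(diag_set),
                             by = "locus")
  called <- cells[cells$genotype != "MISSING", , drop = FALSE]
  if (nrow(called) == 0) {
    abort(paste0(
      "individual ", individual,
      " has no called diagnostic loci; unclassifiable"
    ))
  }
  hom_l_geno <- ifelse(called$L_allele == "A1", "A1A1", "A2A2")
  hom_r_geno <- ifelse(called$R_allele == "A1", "A1A1", "A2A2")
  is_homL <- called$genotype == hom_l_geno
  is_homR <- called$genotype == hom_r_geno
  is_het <- called$genotype == "A1A2"
  het <- called[is_het, , drop = FALSE]
  depth_L <- ifelse(het$L_allele == "A1", het$depth_a1, het$depth_a2)
  total <- het$depth_a1 + het$depth_a2
  keep <- total >= min_depth
  het_depths <- tibble::tibble(
    locus = het$locus[keep],
    depth_L = depth_L[keep],
    total = total[keep]
  )
  het_depths$rel_L <- het_depths$depth_L / het_depths$total
  tibble::tibble(
    individual = individual,
    n_called = nrow(called),
    p_homL = mean(is_homL),
    p_homR = mean(is_homR),
    p_het = mean(is_het),
    n_het = nrow(het_depths),
    het_depths = list(het_depths)
  )
}

#' Composition profiles for every individual of a table
#'
#' Individuals with no called diagnostic locus are skipped with a
#' warning (they are unclassifiable).
#'
#' @inheritParams composition_profile
#' @return A tibble with one row per profiled individual (see
#'   [composition_profile()]).
#' @export
composition_profiles <- function(table, diag_set, min_depth = 8L) {
  inds <- individuals(table)
  rows <- purrr::map(inds, function(i) {
    tryCatch(
      composition_profile(table, i, diag_set, min_depth),
      error = function(e) NULL
    )
  })
  skipped <- inds[vapply(rows, is.null, TRUE)]
  if (length(skipped) > 0) {
    warn(paste0(
      length(skipped), " individual(s) without called diagnostic loci ",
      "skipped: ", paste(utils::head(skipped, 5), collapse = ", ")
    ))
  }
  dplyr::bind_rows(rows)
}

#' Classification thresholds for genomic composition
#'
#' @param homo_min Minimum homozygous fraction to call a pure species
#'   (LL or RR).
#' @param het_min Minimum heterozygous fraction to attempt a hybrid
#'   ploidy call.
#' @param min_het_loci Minimum number of dosage-informative heterozygous
#'   loci for a ploidy call.
#' @param margin_llr Minimum log-likelihood margin of the winning dosage
#'   model over the runner-up.
#' @param min_depth Minimum total depth for a heterozygous locus to
#'   inform dosage.
#' @param contamination_p Fraction of both `p_homL` and `p_het` above
#'   which an UNDETERMINED profile is flagged as contamination-suspect.
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(homo_min = 0.95, het_min = 0.90,
                            min_het_loci = 10L, margin_llr = 2.0,
                            min_depth = 8L, contamination_p = 0.25) {
  structure(
    list(
      homo_min = homo_min, het_min = het_min,
      min_het_loci = as.integer(min_het_loci),
      margin_llr = margin_llr, min_depth = as.integer(min_depth),
      contamination_p = contamination_p
    ),
    class = "classify_config"
  )
}

# pooled binomial log-likelihood of the heterozygous-locus L-read counts
# under a fixed L-allele fraction p (1/2, 2/3 or 1/3)
dosage_loglik <- function(het_depths, p) {
  sum(stats::dbinom(het_depths$depth_L, het_depths$total, p, log = TRUE))
}

#' Classify a genomic composition profile into a genomotype
#'
#' The decision cascade that operationalises visual inspection of
#' composition plots:
#' 1. a profile nearly fixed for one genome is the corresponding pure
#'    species — `p_homL >= homo_min` gives LL, `p_homR >= homo_min`
#'    gives RR;
#' 2. a predominantly heterozygous profile (`p_het >= het_min`) is a
#'    hybrid whose ploidy comes from the allele-depth dosage effect: the
#'    binomial log-likelihood of the per-locus L-read counts is compared
#'    under L-allele fractions 1/2 (LR), 2/3 (LLR) and 1/3 (LRR); the
#'    best model wins if at least `min_het_loci` loci inform it and it
#'    beats the runner-up by `margin_llr` log-units, else the individual
#'    is a hybrid of unknown ploidy (E_UNKNOWN_PLOIDY);
#' 3. anything else is UNDETERMINED; a profile mixing a large homozygous-L
#'    fraction with a large heterozygous fraction (both above
#'    `contamination_p`) is flagged CONTAMINATION_SUSPECT, the signature
#'    of a cross-contaminated sample.
#'
#' @param profile A one-row profile from [composition_profile()].
#' @param config A [classify_config()].
#' @return A one-row tibble: `individual`, `label`, `p_homL`, `p_homR`,
#'   `p_het`, `n_het`, `loglik_LR`, `loglik_LLR`, `loglik_LRR`, `flags`.
#' @export
classify_genotype <- function(profile, config = classify_config()) {
  stopifnot(nrow(profile) == 1)
  hd <- profile$het_depths[[1]]
  ll <- c(
    LR = dosage_loglik(hd, 1 / 2),
    LLR = dosage_loglik(hd, 2 / 3),
    LRR = dosage_loglik(hd, 1 / 3)
  )
  flags <- character(0)
  label <- if (profile$p_homL >= config$homo_min) {
    "LL"
  } else if (profile$p_homR >= config$homo_min) {
    "RR"
  } else if (profile$p_het >= config$het_min) {
    if (profile$n_het >= config$min_het_loci) {
      ord <- sort(ll, decreasing = TRUE)
      if (ord[1] - ord[2] >= config$margin_llr) {
        names(ord)[1]
      } else {
        "E_UNKNOWN_PLOIDY"
      }
    } else {
      "E_UNKNOWN_PLOIDY"
    }
  } else {
    if (profile$p_homL > config$contamination_p &&
        profile$p_het > config$contamination_p) {
      flags <- c(flags, "CONTAMINATION_SUSPECT")
    }
    "UNDETERMINED"
  }
  tibble::tibble(
    individual = profile$individual,
    label = label,
    p_homL = profile$p_homL,
    p_homR = profile$p_homR,
    p_het = profile$p_het,
    n_het = profile$n_het,
    loglik_LR = unname(ll["LR"]),
    loglik_LLR = unname(ll["LLR"]),
    loglik_LRR = unname(ll["LRR"]),
    flags = paste(flags, collapse = ";")
  )
}

#' Classify every individual of a genotype table
#'
#' Convenience wrapper: profiles each individual against the diagnostic
#' set and runs the classification cascade, attaching pond metadata.
#'
#' @param table A `genotype_tbl`.
#' @param diag_set A `diagnostic_set`.
#' @param config A [classify_config()].
#' @return A tibble of genomotype calls (one row per classifiable
#'   individual) with a `pond` column.
#' @export
classify_genotypes <- function(table, diag_set,
                               config = classify_config()) {
  profiles <- composition_profiles(table, diag_set,
                                   min_depth = config$min_depth)
  calls <- purrr::map_dfr(
    seq_len(nrow(profiles)),
    ~ classify_genotype(profiles[.x, ], config)
  )
  dplyr::left_join(
    calls,
    sample_meta(table)[c("individual", "pond")],
    by = "individual"
  )
}

#' Plot a genomic composition profile
#'
#' Density of the relative L-allele coverage at heterozygous diagnostic
#' loci (with the 1/3, 1/2, 2/3 dosage expectations marked) alongside
#' the homozygous-L/heterozygous/homozygous-R locus fractions.
#'
#' @param profile A one-row profile from [composition_profile()].
#' @return A ggplot: the dosage density when heterozygous loci inform it,
#'   else the homozygosity bars alone.
#' @export
plot_composition <- function(profile) {
  hd <- profile$het_depths[[1]]
  subtitle <- sprintf(
    "hom L %.2f | het %.2f | hom R %.2f (%d diagnostic loci)",
    profile$p_homL, profile$p_het, profile$p_homR, profile$n_called
  )
  if (nrow(hd) < 2) {
    bars <- tibble::tibble(
      class = factor(c("hom L", "het", "hom R"),
                     levels = c("hom L", "het", "hom R")),
      fraction = c(profile$p_homL, profile$p_het, profile$p_homR)
    )
    return(
      ggplot2::ggplot(
        bars, ggplot2::aes(x = .data$class, y = .data$fraction)
      ) +
        ggplot2::geom_col() +
        ggplot2::ylim(0, 1) +
        ggplot2::labs(
          title = profile$individual, subtitle = subtitle, x = NULL,
          y = "fraction of diagnostic loci"
        ) +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(hd, ggplot2::aes(x = .data$rel_L)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(
      xintercept = c(1 / 3, 1 / 2, 2 / 3), linetype = "dashed"
    ) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(
      title = profile$individual, subtitle = subtitle,
      x = "relative L-allele coverage at heterozygous diagnostic loci",
      y = "density"
    ) +
    ggplot2::theme_minimal()
}
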