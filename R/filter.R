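#' Filtering configuration
#'
#' Bundles the quality thresholds of the SNP/sample filtering stage:
#' per-cell minimum summed allele depth (8 reads), minimum minor allele
#' frequency (0.05), the per-SNP (`mds`) and per-individual (`mdi`)
#' maximum missing-data fractions tested over \{30%, 40%, 50%\}, the
#' minimum read counts for inclusion of a sample in the final (50,000)
#' and parameter-test (100,000) datasets, and the read-count threshold
#' above which the best technical replicate is kept rather than the
#' replicates combined (300,000).
#'
#' @param min_depth Minimum summed allele depth for a genotype call.
#' @param min_maf Minimum minor allele frequency.
#' @param max_missing_snp Maximum missing fraction per SNP (mds).
#' @param max_missing_ind Maximum missing fraction per individual (mdi).
#' @param min_reads_final Minimum total reads for the final dataset.
#' @param min_reads_paramtest Minimum total reads for the parameter test.
#' @param replicate_select_threshold Reads above which the best replicate
#'   is selected instead of combining.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 8L,
                          min_maf = 0.05,
                          max_missing_snp = 0.30,
                          max_missing_ind = 0.30,
                          min_reads_final = 50000L,
                          min_reads_paramtest = 100000L,
                          replicate_select_threshold = 300000L) {
  stopifnot(
    min_depth >= 0, min_maf >= 0, min_maf <= 1,
    max_missing_snp >= 0, max_missing_snp <= 1,
    max_missing_ind >= 0, max_missing_ind <= 1,
    min_reads_final >= 0, min_reads_paramtest >= 0,
    replicate_select_threshold >= 0
  )
  structure(
    list(
      min_depth = as.integer(min_depth), min_maf = min_maf,
      max_missing_snp = max_missing_snp,
      max_missing_ind = max_missing_ind,
      min_reads_final = as.integer(min_reads_final),
      min_reads_paramtest = as.integer(min_reads_paramtest),
      replicate_select_threshold = as.integer(replicate_select_threshold)
    ),
    class = "filter_config"
  )
}

#' Resolve technical replicates
#'
#' Per replicate group: when the best replicate has more than
#' `threshold` reads it is kept on its own (ties broken by the first id);
#' otherwise the replicates are combined.
#'
#' @param meta Sample metadata (see [sample_meta()]) with `individual`,
#'   `replicate_group`, `total_reads`.
#' @param threshold Read-count threshold for selection over combination.
#' @return A tibble with one row per replicate group: `replicate_group`,
#'   `action` (`"keep"` or `"combine"`), `kept_individual` (`NA` for
#'   combined groups) and `n_replicates`.
#' @export
resolve_replicates <- function(meta, threshold = 300000L) {
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) == 0) abort("empty sample metadata")
  if (anyNA(meta$total_reads)) {
    abort("total_reads missing for some samples")
  }
  meta %>%
    dplyr::group_by(replicate_group = .data$replicate_group) %>%
    dplyr::summarise(
      n_replicates = dplyr::n(),
      best = .data$individual[order(-.data$total_reads,
                                    seq_along(.data$individual))][1],
      best_reads = max(.data$total_reads),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      action = ifelse(
        .data$best_reads > .env$threshold | .data$n_replicates == 1L,
        "keep", "combine"
      ),
      kept_individual = ifelse(.data$action == "keep", .data$best,
                               NA_character_)
    ) %>%
    dplyr::select(
      "replicate_group", "action", "kept_individual", "n_replicates"
    )
}

#' Apply a replicate resolution to a genotype table
#'
#' "Keep" groups retain the selected replicate only. "Combine" groups are
#' merged into one pseudo-individual named after the replicate group:
#' per-allele depths are summed cell-wise and the genotype is the
#' consensus of the called replicates — agreeing calls stand, a missing
#' call defers to the called one, conflicting calls give MISSING (with
#' zeroed depths). Total reads of combined groups are summed.
#'
#' @param table A `genotype_tbl` whose metadata defines replicate groups.
#' @param resolution Output of [resolve_replicates()]; computed from the
#'   table's metadata by default.
#' @param threshold Passed to [resolve_replicates()] when `resolution` is
#'   not supplied.
#' @return A `genotype_tbl` with one individual per replicate group.
#' @export
combine_replicates <- function(table, resolution = NULL,
                               threshold = 300000L) {
  meta <- sample_meta(table)
  if (is.null(resolution)) {
    resolution <- resolve_replicates(meta, threshold = threshold)
  }
  calls <- tibble::as_tibble(table) %>%
    dplyr::left_join(
      meta[c("individual", "replicate_group")], by = "individual"
    ) %>%
    dplyr::left_join(resolution, by = "replicate_group")

  kept <- calls %>%
    dplyr::filter(.data$action == "keep",
                  .data$individual == .data$kept_individual)
  combined <- calls %>%
    dplyr::filter(.data$action == "combine") %>%
    dplyr::group_by(
      individual = .data$replicate_group, locus = .data$locus
    ) %>%
    dplyr::summarise(
      genotype = consensus_genotype(.data$genotype),
      depth_a1 = sum(.data$depth_a1),
      depth_a2 = sum(.data$depth_a2),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      depth_a1 = ifelse(.data$genotype == "MISSING", 0L, .data$depth_a1),
      depth_a2 = ifelse(.data$genotype == "MISSING", 0L, .data$depth_a2)
    )
  new_calls <- dplyr::bind_rows(
    kept[c("individual", "locus", "genotype", "depth_a1", "depth_a2")],
    combined
  )
  new_meta <- meta %>%
    dplyr::left_join(resolution, by = "replicate_group") %>%
    dplyr::group_by(replicate_group = .data$replicate_group) %>%
    dplyr::summarise(
      individual = ifelse(
        .data$action[1] == "keep", .data$kept_individual[1],
        .data$replicate_group[1]
      ),
      pond = .data$pond[1],
      total_reads = ifelse(
        .data$action[1] == "keep",
        .data$total_reads[match(.data$kept_individual[1], .data$individual)],
        sum(.data$total_reads)
      ),
      .groups = "drop"
    )
  genotype_table(new_calls, new_meta)
}

consensus_genotype <- function(g) {
  called <- unique(g[g != "MISSING"])
  if (length(called) == 1) called else "MISSING"
}

#' Drop low-read samples
#'
#' Keeps individuals whose `total_reads` exceeds `min_reads` (strictly:
#' "more than"); loci are untouched.
#'
#' @param table A `genotype_tbl`.
#' @param min_reads Read-count threshold (default: the 50,000-read final
#'   dataset rule).
#' @return A filtered `genotype_tbl`.
#' @export
filter_samples <- function(table, min_reads = 50000L) {
  meta <- sample_meta(table)
  keep <- meta$individual[!is.na(meta$total_reads) &
                            meta$total_reads > min_reads]
  if (length(keep) == 0) {
    warn("filter_samples removed every individual")
  }
  subset_genotype_table(table, individuals = keep)
}

#' SNP-level quality filtering
#'
#' Applies, in a fixed order, each stage operating on the previous
#' stage's output:
#' 1. *depth masking*: calls whose summed allele depth is below
#'    `min_depth` become MISSING (depths zeroed);
#' 2. *minor allele frequency*: loci with MAF below `min_maf` — computed
#'    allele-wise over non-missing calls — are removed;
#' 3. *per-SNP missingness*: loci with a missing fraction above
#'    `max_missing_snp` are removed;
#' 4. *per-individual missingness*: individuals with a missing fraction
#'    above `max_missing_ind`, over the retained loci, are removed.
#'
#' @param table A `genotype_tbl`.
#' @param config A [filter_config()].
#' @return The filtered `genotype_tbl`, with a per-stage removal log in
#'   `attr(x, "filter_log")` (also via [filter_log()]).
#' @export
filter_snps <- function(table, config = filter_config()) {
  calls <- tibble::as_tibble(table)
  meta <- sample_meta(table)
  n_loci0 <- length(unique(calls$locus))
  n_ind0 <- length(unique(calls$individual))

  # (1) depth mask
  low <- calls$genotype != "MISSING" &
    (calls$depth_a1 + calls$depth_a2) < config$min_depth
  n_masked <- sum(low)
  calls$genotype[low] <- "MISSING"
  calls$depth_a1[low] <- 0L
  calls$depth_a2[low] <- 0L

  # (2) MAF over called genotypes (allele counting)
  by_locus <- calls %>%
    dplyr::group_by(locus = .data$locus) %>%
    dplyr::summarise(
      n_called = sum(.data$genotype != "MISSING"),
      a2 = sum((.data$genotype == "A1A2") + 2L * (.data$genotype == "A2A2")),
      miss_frac = mean(.data$genotype == "MISSING"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      p2 = ifelse(.data$n_called > 0, .data$a2 / (2 * .data$n_called), 0),
      maf = pmin(.data$p2, 1 - .data$p2)
    )
  keep_maf <- by_locus$locus[by_locus$n_called > 0 &
                               by_locus$maf >= config$min_maf]
  n_maf_removed <- n_loci0 - length(keep_maf)
  calls <- calls[calls$locus %in% keep_maf, , drop = FALSE]

  # (3) per-SNP missingness
  keep_mds <- by_locus$locus[
    by_locus$locus %in% keep_maf &
      by_locus$miss_frac <= config$max_missing_snp
  ]
  n_mds_removed <- length(keep_maf) - length(keep_mds)
  calls <- calls[calls$locus %in% keep_mds, , drop = FALSE]

  # (4) per-individual missingness over retained loci
  if (nrow(calls) > 0) {
    by_ind <- calls %>%
      dplyr::group_by(individual = .data$individual) %>%
      dplyr::summarise(
        miss_frac = mean(.data$genotype == "MISSING"), .groups = "drop"
      )
    keep_ind <- by_ind$individual[by_ind$miss_frac <= config$max_missing_ind]
  } else {
    keep_ind <- character(0)
  }
  n_ind_removed <- n_ind0 - length(keep_ind)
  calls <- calls[calls$individual %in% keep_ind, , drop = FALSE]

  if (nrow(calls) == 0) {
    warn("filter_snps produced an empty table")
  }
  out <- genotype_table(calls, meta[meta$individual %in% keep_ind, ])
  attr(out, "filter_log") <- tibble::tibble(
    stage = c("depth_mask", "maf", "missing_snp", "missing_ind"),
    unit = c("cells", "loci", "loci", "individuals"),
    n_removed = c(n_masked, n_maf_removed, n_mds_removed, n_ind_removed),
    n_in = c(nrow(table), n_loci0, length(keep_maf), n_ind0),
    n_out = c(
      nrow(table) - 0L,  # cells are masked, not dropped
      length(keep_maf), length(keep_mds), length(keep_ind)
    )
  )
  out
}

#' @rdname filter_snps
#' @param x A table returned by `filter_snps()`.
#' @export
filter_log <- function(x) {
  attr(x, "filter_log")
}
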