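#' SNP-calling error rate from technical replicates
#'
#' Over every (replicate pair, locus) cell where *both* replicates carry a
#' non-missing call, the error rate is the fraction of discordant calls.
#' Discordance is counted at the genotype level (any allele differs).
#'
#' @param table_a,table_b Genotype tables sharing a locus set.
#' @param pairing A data frame with columns `id_a`, `id_b` mapping each
#'   individual of `table_a` to its replicate in `table_b`.
#' @return The discordance proportion, with attributes `n_compared` and
#'   `n_discordant`.
#' @export
snp_error_rate <- function(table_a, table_b, pairing) {
  pairing <- tibble::as_tibble(pairing)
  if (!all(c("id_a", "id_b") %in% names(pairing))) {
    abort("pairing needs columns id_a and id_b")
  }
  unknown_a <- setdiff(pairing$id_a, individuals(table_a))
  unknown_b <- setdiff(pairing$id_b, individuals(table_b))
  if (length(unknown_a) + length(unknown_b) > 0) {
    abort(paste0(
      "pairing refers to unknown individual(s): ",
      paste(c(unknown_a, unknown_b), collapse = ", ")
    ))
  }
  shared_loci <- intersect(loci(table_a), loci(table_b))
  a <- tibble::as_tibble(table_a) %>%
    dplyr::filter(.data$locus %in% shared_loci) %>%
    dplyr::inner_join(pairing, by = c(individual = "id_a"))
  b <- tibble::as_tibble(table_b)[
    , c("individual", "locus", "genotype")
  ]
  names(b) <- c("id_b", "locus", "genotype_b")
  joined <- dplyr::inner_join(a, b, by = c("id_b", "locus"))
  comparable <- joined$genotype != "MISSING" & joined$genotype_b != "MISSING"
  n_compared <- sum(comparable)
  if (n_compared == 0) {
    abort("no comparable cells between the replicate tables")
  }
  n_disc <- sum(joined$genotype[comparable] != joined$genotype_b[comparable])
  structure(
    n_disc / n_compared,
    n_compared = n_compared, n_discordant = n_disc
  )
}

#' Evaluate assembly-parameter datasets across a filter grid
#'
#' For every input dataset (one per upstream assembly setting, e.g. a
#' Stacks m/M/n combination, each consisting of a replicate genotype
#' table and its pairing) and every (mds, mdi) missing-data combination,
#' applies [filter_snps()] and computes the replicate
#' [snp_error_rate()], recording dataset size and missingness.
#'
#' @param datasets A named list; each element a list with `table` (a
#'   `genotype_tbl` containing both members of every replicate pair) and
#'   `pairing` (`id_a`, `id_b`).
#' @param mds_grid,mdi_grid Per-SNP / per-individual maximum missing-data
#'   fractions to test.
#' @param config Base [filter_config()]; its `max_missing_snp` /
#'   `max_missing_ind` are overridden by the grid.
#' @return A tibble of sweep records: `params`, `mds`, `mdi`, `n_snps`,
#'   `n_individuals`, `missing_fraction`, `error_rate`.
#' @export
run_sweep <- function(datasets,
                      mds_grid = c(0.3, 0.4, 0.5),
                      mdi_grid = c(0.3, 0.4, 0.5),
                      config = filter_config()) {
  if (length(datasets) == 0) abort("empty dataset map")
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    abort("datasets must be a named list (one name per parameter setting)")
  }
  grid <- tidyr::expand_grid(
    params = names(datasets), mds = mds_grid, mdi = mdi_grid
  )
  purrr::pmap_dfr(grid, function(params, mds, mdi) {
    ds <- datasets[[params]]
    cfg <- config
    cfg$max_missing_snp <- mds
    cfg$max_missing_ind <- mdi
    filtered <- suppressWarnings(filter_snps(ds$table, cfg))
    kept <- individuals(filtered)
    pairing <- ds$pairing[
      ds$pairing$id_a %in% kept & ds$pairing$id_b %in% kept, ,
      drop = FALSE
    ]
    err <- if (nrow(pairing) == 0 || length(loci(filtered)) == 0) {
      NA_real_
    } else {
      tryCatch(
        as.numeric(snp_error_rate(filtered, filtered, pairing)),
        error = function(e) NA_real_
      )
    }
    tibble::tibble(
      params = params, mds = mds, mdi = mdi,
      n_snps = length(loci(filtered)),
      n_individuals = length(kept),
      missing_fraction = if (nrow(filtered) > 0) {
        mean(filtered$genotype == "MISSING")
      } else NA_real_,
      error_rate = err
    )
  })
}

#' Select the final assembly/filter setting
#'
#' A deterministic stand-in for the judgement call "maximise individuals
#' and loci while keeping the error rate low": records with an error rate
#' above the `error_quantile`-quantile of the observed error rates are
#' discarded, then the record with the most individuals, then most SNPs,
#' is chosen; remaining ties go to the lowest error rate and finally to
#' input order.
#'
#' @param records A sweep-record tibble from [run_sweep()].
#' @param error_quantile Quantile (0-1) of observed error rates used as
#'   the admissibility gate.
#' @return The selected single-row record.
#' @export
select_setting <- function(records, error_quantile = 0.25) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) abort("no sweep records")
  records$.order <- seq_len(nrow(records))
  usable <- records[!is.na(records$error_rate), , drop = FALSE]
  if (nrow(usable) == 0) abort("no sweep records with a defined error rate")
  gate <- stats::quantile(usable$error_rate, error_quantile, names = FALSE)
  pool <- usable[usable$error_rate <= gate, , drop = FALSE]
  pool <- pool[order(
    -pool$n_individuals, -pool$n_snps, pool$error_rate, pool$.order
  ), , drop = FALSE]
  out <- pool[1, , drop = FALSE]
  out$.order <- NULL
  out
}
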