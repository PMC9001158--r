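#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

GENOTYPE_LEVELS <- c("A1A1", "A1A2", "A2A2", "MISSING")
GENOMOTYPE_LEVELS <- c("LL", "LR", "LLR", "LRR", "RR")

#' Build a genotype table
#'
#' The central container of the pipeline: one row per (individual, locus)
#' cell of a biallelic SNP matrix, holding the genotype call and the
#' per-allele read depths, plus per-individual sample metadata. Alleles
#' `A1`/`A2` are the raw REF/ALT of the source VCF; they acquire an L/R
#' (i.e. *P. lessonae* / *P. ridibundus*) orientation only later, through a
#' [diagnostic set][find_diagnostic_loci].
#'
#' Invariants enforced by the constructor:
#' * one row per (individual, locus) pair;
#' * `genotype` is one of `"A1A1"`, `"A1A2"`, `"A2A2"`, `"MISSING"`;
#' * a `MISSING` cell has both depths 0;
#' * a heterozygous cell has depth >= 1 for both alleles.
#'
#' @param calls A data frame with columns `individual`, `locus`,
#'   `genotype`, `depth_a1`, `depth_a2`.
#' @param meta Optional per-individual metadata: columns `individual`,
#'   `pond`, `replicate_group`, `total_reads`. Missing columns are filled
#'   with defaults (pond `NA`, replicate_group = individual, total_reads
#'   `NA`).
#' @return A tibble of class `genotype_tbl` with a `sample_meta` attribute.
#' @examples
#' gt <- genotype_table(tibble::tibble(
#'   individual = "frog1", locus = "L1",
#'   genotype = "A1A2", depth_a1 = 12L, depth_a2 = 9L
#' ))
#' sample_meta(gt)
#' @export
genotype_table <- function(calls, meta = NULL) {
  calls <- tibble::as_tibble(calls)
  required <- c("individual", "locus", "genotype", "depth_a1", "depth_a2")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`calls` lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  calls <- calls[required]
  calls$individual <- as.character(calls$individual)
  calls$locus <- as.character(calls$locus)
  calls$genotype <- as.character(calls$genotype)
  calls$depth_a1 <- as.integer(calls$depth_a1)
  calls$depth_a2 <- as.integer(calls$depth_a2)
  meta <- complete_sample_meta(meta, unique(calls$individual))
  out <- tibble::new_tibble(calls, class = "genotype_tbl")
  attr(out, "sample_meta") <- meta
  validate_genotype_table(out)
  out
}

complete_sample_meta <- function(meta, individuals) {
  if (is.null(meta)) {
    meta <- tibble::tibble(individual = individuals)
  } else {
    meta <- tibble::as_tibble(meta)
    if (!"individual" %in% names(meta)) {
      abort("`meta` must have an `individual` column")
    }
    meta$individual <- as.character(meta$individual)
    extra <- setdiff(individuals, meta$individual)
    if (length(extra) > 0) {
      meta <- dplyr::bind_rows(meta, tibble::tibble(individual = extra))
    }
    meta <- meta[match(
      union(individuals, meta$individual), meta$individual
    ), , drop = FALSE]
  }
  if (!"pond" %in% names(meta)) meta$pond <- NA_character_
  if (!"replicate_group" %in% names(meta)) {
    meta$replicate_group <- meta$individual
  }
  meta$replicate_group <- ifelse(
    is.na(meta$replicate_group), meta$individual, meta$replicate_group
  )
  if (!"total_reads" %in% names(meta)) meta$total_reads <- NA_real_
  meta[c("individual", "pond", "replicate_group", "total_reads")]
}

validate_genotype_table <- function(x) {
  bad_geno <- setdiff(unique(x$genotype), GENOTYPE_LEVELS)
  if (length(bad_geno) > 0) {
    abort(paste0(
      "invalid genotype code(s): ", paste(bad_geno, collapse = ", ")
    ))
  }
  if (anyDuplicated(paste(x$individual, x$locus, sep = "\r"))) {
    abort("duplicated (individual, locus) cells in genotype table")
  }
  if (any(x$depth_a1 < 0 | x$depth_a2 < 0, na.rm = TRUE)) {
    abort("negative read depths")
  }
  miss <- x$genotype == "MISSING"
  if (any(x$depth_a1[miss] != 0 | x$depth_a2[miss] != 0)) {
    abort("MISSING cells must have zero depths")
  }
  het <- x$genotype == "A1A2"
  if (any(x$depth_a1[het] < 1 | x$depth_a2[het] < 1)) {
    abort("heterozygous cells must have depth >= 1 for both alleles")
  }
  invisible(x)
}

#' Access or replace the sample metadata of a genotype table
#'
#' @param x A `genotype_tbl`.
#' @param value A metadata data frame (see [genotype_table()]).
#' @return A tibble with columns `individual`, `pond`, `replicate_group`,
#'   `total_reads`.
#' @export
sample_meta <- function(x) {
  attr(x, "sample_meta")
}

#' @rdname sample_meta
#' @export
`sample_meta<-` <- function(x, value) {
  attr(x, "sample_meta") <- complete_sample_meta(value, individuals(x))
  x
}

# dplyr verbs drop custom attributes; rebuild the class after manipulation.
as_genotype_table <- function(calls, meta) {
  genotype_table(calls, meta)
}

#' Individuals and loci of a genotype table
#'
#' Order follows first appearance in the table (for VCF input, the VCF
#' sample and record order).
#'
#' @param x A `genotype_tbl`.
#' @return A character vector.
#' @export
individuals <- function(x) unique(x$individual)

#' @rdname individuals
#' @export
loci <- function(x) unique(x$locus)

#' @export
print.genotype_tbl <- function(x, ...) {
  n_ind <- length(individuals(x))
  n_loc <- length(loci(x))
  miss <- mean(x$genotype == "MISSING")
  cat(sprintf(
    "# Genotype table: %d individuals x %d loci (%.1f%% missing)\n",
    n_ind, n_loc, 100 * miss
  ))
  NextMethod()
}

#' Dosage matrix of a genotype table
#'
#' Encodes each call as the count of allele `A2` (0, 1 or 2; `NA` for
#' missing), the conventional input encoding for genotype PCA.
#'
#' @param table A `genotype_tbl`.
#' @return A numeric matrix, individuals in rows, loci in columns.
#' @export
genotype_matrix <- function(table) {
  inds <- individuals(table)
  locs <- loci(table)
  code <- c(A1A1 = 0, A1A2 = 1, A2A2 = 2, MISSING = NA_real_)
  m <- matrix(
    NA_real_, nrow = length(inds), ncol = length(locs),
    dimnames = list(inds, locs)
  )
  m[cbind(
    match(table$individual, inds),
    match(table$locus, locs)
  )] <- code[table$genotype]
  m
}

#' Per-individual missingness
#'
#' @param table A `genotype_tbl`.
#' @return A tibble with columns `individual` and `missingness` (the
#'   fraction of loci with a MISSING call).
#' @export
individual_missingness <- function(table) {
  table %>%
    tibble::as_tibble() %>%
    dplyr::group_by(individual = .data$individual) %>%
    dplyr::summarise(
      missingness = mean(.data$genotype == "MISSING"),
      .groups = "drop"
    )
}

# Restrict a table to a subset of individuals and/or loci, preserving order.
subset_genotype_table <- function(table, individuals = NULL, loci = NULL) {
  calls <- tibble::as_tibble(table)
  if (!is.null(individuals)) {
    calls <- calls[calls$individual %in% individuals, , drop = FALSE]
  }
  if (!is.null(loci)) {
    calls <- calls[calls$locus %in% loci, , drop = FALSE]
  }
  meta <- sample_meta(table)
  genotype_table(calls, meta[meta$individual %in% calls$individual, ])
}
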