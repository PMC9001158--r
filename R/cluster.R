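#' Principal component analysis of a genotype table
#'
#' Genotypes are encoded as counts of allele A2 (0/1/2); missing cells
#' are mean-imputed per locus, the matrix is centred, and the covariance
#' is eigendecomposed (via [stats::prcomp()]). Loci that are missing in
#' every individual carry no information and are dropped with a warning.
#' Scores are deterministic up to component sign.
#'
#' @param table A `genotype_tbl` with at least 2 individuals and 2 loci.
#' @param n_components Number of components to retain (default: all).
#' @return An object of class `rad_pca`: list with `scores` (tibble,
#'   `individual` + `PC1..PCk`), `variance_explained`, `sdev`, `n_loci`.
#' @export
pca_genotypes <- function(table, n_components = NULL) {
  m <- genotype_matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("PCA needs at least 2 individuals and 2 loci")
  }
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    warn(paste0(
      sum(all_missing), " all-missing locus/loci dropped before PCA"
    ))
    m <- m[, !all_missing, drop = FALSE]
  }
  col_means <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m))
  if (length(idx) > 0) {
    m[idx] <- col_means[((idx - 1) %/% nrow(m)) + 1]
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(
    if (is.null(n_components)) ncol(fit$x) else n_components,
    ncol(fit$x)
  )
  var_exp <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(individual = rownames(m)), scores
  )
  structure(
    list(
      scores = scores,
      variance_explained = var_exp[seq_len(k)],
      sdev = fit$sdev,
      n_loci = ncol(m)
    ),
    class = "rad_pca"
  )
}

#' @export
print.rad_pca <- function(x, ...) {
  cat(sprintf(
    "# PCA of %d individuals x %d loci; PC1 %.1f%%, PC2 %.1f%% variance\n",
    nrow(x$scores), x$n_loci,
    100 * x$variance_explained[1],
    100 * if (length(x$variance_explained) > 1) x$variance_explained[2] else 0
  ))
  print(x$scores, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genotype PCA
#'
#' `tidy()` returns per-individual scores in long form; `glance()` a
#' one-row per-component summary of the variance explained.
#'
#' @param x A `rad_pca`.
#' @param ... Unused.
#' @method tidy rad_pca
#' @export
tidy.rad_pca <- function(x, ...) {
  tidyr::pivot_longer(
    x$scores, -"individual",
    names_to = "component", values_to = "score"
  )
}

#' @rdname tidy.rad_pca
#' @method glance rad_pca
#' @export
glance.rad_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$variance_explained)),
    variance_explained = x$variance_explained
  )
}

#' Plot a genotype PCA
#'
#' @param object A `rad_pca`.
#' @param colour_by Optional data frame (`individual`, `label`) used to
#'   colour points, e.g. genomotype calls or cluster assignments.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rad_pca
#' @export
autoplot.rad_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  mapping <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  if (!is.null(colour_by)) {
    df <- dplyr::left_join(df, tibble::as_tibble(colour_by),
                           by = "individual")
    mapping <- ggplot2::aes(
      x = .data$PC1, y = .data$PC2, colour = .data$label
    )
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Assign individuals to clusters from an ancestry matrix
#'
#' Applies the admixture-threshold rule: an individual belongs to its
#' argmax cluster iff that cluster's ancestry coefficient strictly
#' exceeds `threshold` (default q > 0.8); otherwise it is UNASSIGNED.
#' The ancestry matrix is an external input (e.g. from sNMF/ADMIXTURE);
#' rows must sum to 1 within `tol`.
#'
#' @param ancestry A data frame: `individual` plus one numeric column per
#'   cluster (any names; `q_*` columns are typical).
#' @param threshold Assignment threshold in (0.5, 1].
#' @param tol Tolerance on row sums.
#' @return A tibble: `individual`, `cluster` (`"UNASSIGNED"` below
#'   threshold), `q_max`.
#' @export
assign_from_q <- function(ancestry, threshold = 0.8, tol = 1e-6) {
  stopifnot(threshold > 0.5, threshold <= 1)
  ancestry <- tibble::as_tibble(ancestry)
  qcols <- setdiff(names(ancestry), "individual")
  q <- as.matrix(ancestry[qcols])
  if (any(q < -tol | q > 1 + tol)) {
    abort("ancestry coefficients must lie in [0, 1]")
  }
  sums <- rowSums(q)
  if (any(abs(sums - 1) > tol)) {
    abort(paste0(
      "ancestry rows do not sum to 1 (max deviation ",
      format(max(abs(sums - 1))), ")"
    ))
  }
  best <- max.col(q, ties.method = "first")
  q_max <- q[cbind(seq_len(nrow(q)), best)]
  tibble::tibble(
    individual = ancestry$individual,
    cluster = ifelse(q_max > threshold, qcols[best], "UNASSIGNED"),
    q_max = q_max
  )
}

#' Select reference individuals for diagnostic-locus discovery
#'
#' From one cluster, picks the `n` individuals that are centrally located
#' in ordination space — smallest Euclidean distance to the cluster
#' centroid in the first two components — and well genotyped:
#' individuals with missingness above `max_missing` are ineligible, and
#' distance ties break by lower missingness, then id.
#'
#' @param ordination A `rad_pca`.
#' @param assignments Tibble `individual`, `cluster` (from
#'   [assign_from_q()] or any clustering).
#' @param cluster The cluster to draw references from.
#' @param n Number of references (default 10).
#' @param missingness Tibble `individual`, `missingness`; see
#'   [individual_missingness()].
#' @param max_missing Maximum tolerated missingness for a reference.
#' @return Character vector of `n` individual ids, ordered from most to
#'   least central.
#' @export
select_references <- function(ordination, assignments, cluster, n = 10L,
                              missingness = NULL, max_missing = 0.2) {
  stopifnot(inherits(ordination, "rad_pca"))
  assignments <- tibble::as_tibble(assignments)
  members <- assignments$individual[assignments$cluster == cluster]
  if (length(members) < n) {
    abort(sprintf(
      "cluster '%s' has %d members; %d references requested",
      cluster, length(members), n
    ))
  }
  sc <- ordination$scores
  sc <- sc[sc$individual %in% members, , drop = FALSE]
  if (is.null(missingness)) {
    missingness <- tibble::tibble(
      individual = sc$individual, missingness = 0
    )
  }
  sc <- dplyr::left_join(sc, tibble::as_tibble(missingness),
                         by = "individual")
  sc$missingness[is.na(sc$missingness)] <- 0
  centroid <- c(mean(sc$PC1), mean(sc$PC2))
  sc$dist <- sqrt((sc$PC1 - centroid[1])^2 + (sc$PC2 - centroid[2])^2)
  eligible <- sc[sc$missingness <= max_missing, , drop = FALSE]
  if (nrow(eligible) < n) {
    abort(sprintf(
      paste0(
        "only %d of %d cluster members pass the missingness cap %.2f; ",
        "%d references requested (short by %d)"
      ),
      nrow(eligible), nrow(sc), max_missing, n, n - nrow(eligible)
    ))
  }
  eligible <- eligible[order(
    eligible$dist, eligible$missingness, eligible$individual
  ), , drop = FALSE]
  eligible$individual[seq_len(n)]
}
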