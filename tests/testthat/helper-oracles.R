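# bare call columns, without container attributes, for round-trip equality
bare_calls <- function(x) {
  tibble::tibble(
    individual = x$individual, locus = x$locus, genotype = x$genotype,
    depth_a1 = x$depth_a1, depth_a2 = x$depth_a2
  )
}

# Brute-force reference implementations and random-table builders used by
# the oracle-equivalence tests. Deliberately written in plain loops over
# wide matrices, independent of the package's dplyr pipelines.

make_random_table <- function(n_ind = 10, n_loc = 50, seed = 1,
                              missing_p = 0.15) {
  withr::with_seed(seed, {
    inds <- sprintf("ind%02d", seq_len(n_ind))
    locs <- sprintf("loc%03d", seq_len(n_loc))
    grid <- expand.grid(individual = inds, locus = locs,
                        stringsAsFactors = FALSE)
    geno <- sample(
      c("A1A1", "A1A2", "A2A2", "MISSING"), nrow(grid), replace = TRUE,
      prob = c((1 - missing_p) * c(0.4, 0.3, 0.3), missing_p)
    )
    d1 <- integer(nrow(grid))
    d2 <- integer(nrow(grid))
    hom1 <- geno == "A1A1"
    hom2 <- geno == "A2A2"
    het <- geno == "A1A2"
    d1[hom1] <- sample(0:25, sum(hom1), replace = TRUE)
    d2[hom2] <- sample(0:25, sum(hom2), replace = TRUE)
    d1[het] <- sample(1:15, sum(het), replace = TRUE)
    d2[het] <- sample(1:15, sum(het), replace = TRUE)
    meta <- data.frame(
      individual = inds,
      pond = "p1",
      replicate_group = inds,
      total_reads = sample(10000:600000, n_ind)
    )
    genotype_table(
      data.frame(
        individual = grid$individual, locus = grid$locus,
        genotype = geno, depth_a1 = d1, depth_a2 = d2
      ),
      meta = meta
    )
  })
}

# independent filter_snps: wide-matrix loops, same staged definition
brute_filter_snps <- function(table, cfg) {
  inds <- individuals(table)
  locs <- loci(table)
  G <- matrix("MISSING", length(inds), length(locs),
              dimnames = list(inds, locs))
  D <- matrix(0L, length(inds), length(locs), dimnames = list(inds, locs))
  for (r in seq_len(nrow(table))) {
    i <- table$individual[r]; l <- table$locus[r]
    G[i, l] <- table$genotype[r]
    D[i, l] <- table$depth_a1[r] + table$depth_a2[r]
  }
  # stage 1: depth mask
  for (i in inds) for (l in locs) {
    if (G[i, l] != "MISSING" && D[i, l] < cfg$min_depth) G[i, l] <- "MISSING"
  }
  # stage 2: MAF
  keep_loc <- character(0)
  for (l in locs) {
    g <- G[, l]
    called <- g[g != "MISSING"]
    if (length(called) == 0) next
    a2 <- sum(called == "A1A2") + 2 * sum(called == "A2A2")
    p <- a2 / (2 * length(called))
    if (min(p, 1 - p) >= cfg$min_maf) keep_loc <- c(keep_loc, l)
  }
  # stage 3: per-SNP missingness
  keep_loc2 <- character(0)
  for (l in keep_loc) {
    if (mean(G[, l] == "MISSING") <= cfg$max_missing_snp) {
      keep_loc2 <- c(keep_loc2, l)
    }
  }
  # stage 4: per-individual missingness over retained loci
  keep_ind <- character(0)
  for (i in inds) {
    if (length(keep_loc2) == 0) break
    if (mean(G[i, keep_loc2] == "MISSING") <= cfg$max_missing_ind) {
      keep_ind <- c(keep_ind, i)
    }
  }
  list(loci = keep_loc2, individuals = keep_ind)
}

# independent select_references: full ranking by explicit loops
brute_select_references <- function(ordination, assignments, cluster, n,
                                    missingness, max_missing = 0.2) {
  members <- assignments$individual[assignments$cluster == cluster]
  sc <- as.data.frame(ordination$scores)
  sc <- sc[sc$individual %in% members, ]
  miss <- setNames(missingness$missingness, missingness$individual)
  sc$miss <- ifelse(is.na(miss[sc$individual]), 0, miss[sc$individual])
  cx <- mean(sc$PC1); cy <- mean(sc$PC2)
  sc$d <- sqrt((sc$PC1 - cx)^2 + (sc$PC2 - cy)^2)
  sc <- sc[sc$miss <= max_missing, ]
  sc <- sc[order(sc$d, sc$miss, sc$individual), ]
  head(sc$individual, n)
}

# independent dedup: explicit group map keyed on (prefix1, prefix2, dbr)
brute_dedup <- function(pairs, key_length) {
  keys <- paste(
    substr(pairs$read1_seq, 1, key_length),
    substr(pairs$read2_seq, 1, key_length),
    pairs$dbr
  )
  mq <- vapply(seq_len(nrow(pairs)), function(r) {
    mean(utf8ToInt(paste0(pairs$qual1[r], pairs$qual2[r]))) - 33
  }, 0)
  keep <- integer(0)
  for (k in unique(keys)) {
    rows <- which(keys == k)
    best <- rows[which.max(mq[rows])]  # which.max = first max: input order
    keep <- c(keep, best)
  }
  sort(keep)
}
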