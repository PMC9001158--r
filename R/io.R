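#' Read a genotype table from a VCF file
#'
#' Expects biallelic SNP records with a per-sample genotype (`GT`) and
#' allelic-depth (`AD`) field, the layout produced by RAD genotypers.
#' Multi-allelic records are rejected: the downstream diagnostic-locus and
#' dosage machinery is defined for biallelic loci only. Records without an
#' `AD` field are imported with both depths 0 and flagged, because genomic
#' composition analysis (not plain genotype classification) needs depths.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @return A [genotype_table()]. Individuals appear in VCF sample order;
#'   loci use the `ID` column when present, else `CHROM_POS`. Loci imported
#'   without depth information are listed in the `no_depth_loci` attribute.
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      abort(paste0("malformed VCF '", path, "': ", conditionMessage(e)))
    }
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    abort(paste0(
      "multi-allelic site(s) not supported: record(s) ",
      paste(which(multi), collapse = ", "),
      " (CHROM:POS ",
      paste(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), collapse = ", "),
      ")"
    ))
  }
  ids <- fix[, "ID"]
  locus_ids <- ifelse(
    is.na(ids) | ids == ".",
    paste0(fix[, "CHROM"], "_", fix[, "POS"]),
    ids
  )
  if (anyDuplicated(locus_ids)) {
    locus_ids <- make.unique(locus_ids, sep = "_dup")
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  rownames(gt) <- locus_ids
  ad_raw <- tryCatch(
    vcfR::extract.gt(vcf, element = "AD"),
    error = function(e) NULL
  )
  geno_from_gt <- function(g) {
    g <- gsub("\\|", "/", g)
    dplyr::case_when(
      is.na(g) | g %in% c("./.", ".") ~ "MISSING",
      g == "0/0" ~ "A1A1",
      g %in% c("0/1", "1/0") ~ "A1A2",
      g == "1/1" ~ "A2A2",
      TRUE ~ NA_character_
    )
  }
  long <- tidyr::expand_grid(individual = samples, locus = locus_ids)
  idx <- cbind(match(long$locus, locus_ids), match(long$individual, samples))
  long$genotype <- geno_from_gt(gt[idx])
  if (anyNA(long$genotype)) {
    bad <- unique(gt[idx][is.na(long$genotype)])
    abort(paste0(
      "unsupported genotype encoding(s) in VCF: ",
      paste(bad, collapse = ", ")
    ))
  }
  if (is.null(ad_raw)) {
    long$depth_a1 <- 0L
    long$depth_a2 <- 0L
    no_depth <- locus_ids
  } else {
    ad <- ad_raw[idx]
    parts <- strsplit(ifelse(is.na(ad), "0,0", ad), ",", fixed = TRUE)
    long$depth_a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    long$depth_a2 <- suppressWarnings(as.integer(vapply(
      parts, function(p) if (length(p) >= 2) p[2] else "0", ""
    )))
    long$depth_a1[is.na(long$depth_a1)] <- 0L
    long$depth_a2[is.na(long$depth_a2)] <- 0L
    per_locus_depth <- tapply(long$depth_a1 + long$depth_a2, long$locus, sum)
    no_depth <- names(per_locus_depth)[per_locus_depth == 0]
  }
  # depth fields must respect the table invariants even for sloppy input
  miss <- long$genotype == "MISSING"
  long$depth_a1[miss] <- 0L
  long$depth_a2[miss] <- 0L
  het_bad <- long$genotype == "A1A2" & (long$depth_a1 < 1 | long$depth_a2 < 1)
  if (any(het_bad)) {
    # depthless het imports (e.g. AD absent) keep the call; give each allele
    # a placeholder single read so the invariant holds, flagged via no_depth
    long$depth_a1[het_bad] <- pmax(long$depth_a1[het_bad], 1L)
    long$depth_a2[het_bad] <- pmax(long$depth_a2[het_bad], 1L)
  }
  out <- genotype_table(long)
  attr(out, "no_depth_loci") <- as.character(no_depth)
  if (length(no_depth) > 0) {
    warn(paste0(
      length(no_depth), " locus/loci imported without read depths ",
      "(depths set to 0; see attr(x, 'no_depth_loci'))"
    ))
  }
  out
}

#' Write a genotype table to a minimal VCF
#'
#' Emits one biallelic record per locus with `GT:AD` per-sample fields,
#' placeholder REF/ALT alleles (`A`/`T`) and `CHROM = locus`, `POS = 1`
#' (RAD loci are anonymous tags with no genomic coordinates).
#'
#' @param table A `genotype_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(table, path) {
  inds <- individuals(table)
  locs <- loci(table)
  gt_code <- c(A1A1 = "0/0", A1A2 = "0/1", A2A2 = "1/1", MISSING = "./.")
  cells <- tibble::as_tibble(table)
  cells$field <- paste0(
    gt_code[cells$genotype], ":", cells$depth_a1, ",", cells$depth_a2
  )
  m <- matrix(
    "./.:0,0", nrow = length(locs), ncol = length(inds),
    dimnames = list(locs, inds)
  )
  m[cbind(match(cells$locus, locs), match(cells$individual, inds))] <- cells$field
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=raddose",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", inds
    ), collapse = "\t")
  )
  body <- vapply(seq_along(locs), function(i) {
    paste(c(
      locs[i], "1", locs[i], "A", "T", ".", "PASS", ".", "GT:AD",
      m[i, ]
    ), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write the project's genotype TSV dialect
#'
#' A flat 5-column dialect: `individual`, `locus`, `allele1_depth`,
#' `allele2_depth`, `genotype`, one row per cell. `read_genotype_tsv()`
#' inverts `write_genotype_tsv()` exactly on the call matrix; sample
#' metadata is not part of the dialect and can be supplied via `meta`.
#'
#' @param table A `genotype_tbl`.
#' @param path File path.
#' @param meta Optional sample metadata passed to [genotype_table()].
#' @return `write_genotype_tsv()` returns `path` invisibly;
#'   `read_genotype_tsv()` returns a `genotype_tbl`.
#' @export
write_genotype_tsv <- function(table, path) {
  out <- tibble::as_tibble(table)[
    , c("individual", "locus", "depth_a1", "depth_a2", "genotype")
  ]
  names(out) <- c(
    "individual", "locus", "allele1_depth", "allele2_depth", "genotype"
  )
  utils::write.table(
    out, path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path, meta = NULL) {
  raw <- utils::read.table(
    path, sep = "\t", header = TRUE, colClasses = c(
      individual = "character", locus = "character",
      allele1_depth = "integer", allele2_depth = "integer",
      genotype = "character"
    )
  )
  expected <- c(
    "individual", "locus", "allele1_depth", "allele2_depth", "genotype"
  )
  if (!identical(names(raw), expected)) {
    abort(paste0(
      "unexpected TSV header in '", path, "': expected ",
      paste(expected, collapse = ", ")
    ))
  }
  genotype_table(
    tibble::tibble(
      individual = raw$individual, locus = raw$locus,
      genotype = raw$genotype,
      depth_a1 = raw$allele1_depth, depth_a2 = raw$allele2_depth
    ),
    meta = meta
  )
}

#' Read a FASTA file as a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    id = names(set),
    sequence = unname(as.character(set))
  )
}

#' Write sequences to FASTA
#'
#' @param seqs A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs$sequence)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read paired FASTQ files into a read-pair table
#'
#' The degenerate base region (DBR) — a random-sequence adapter tag used to
#' distinguish PCR duplicates from independent template molecules — is cut
#' out of the read named by `dbr_spec` and reported in its own column; the
#' remaining bases form the template sequence.
#'
#' @param path1,path2 Paths to the R1 and R2 FASTQ files (phred+33).
#' @param dbr_spec A list with elements `read` (1 or 2), `offset` (0-based
#'   position of the DBR within the read) and `length`. Use
#'   `dbr_spec(read, offset, length)` to build one, or `NULL` for no DBR.
#' @return A tibble of class `read_pairs` with columns `id`, `read1_seq`,
#'   `read2_seq`, `qual1`, `qual2`, `dbr`.
#' @export
read_fastq_pairs <- function(path1, path2, dbr_spec = NULL) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    abort(sprintf(
      "unpaired FASTQ input: %d records in '%s' vs %d in '%s'",
      length(r1), path1, length(r2), path2
    ))
  }
  pairs <- tibble::tibble(
    id = sub(" .*$", "", names(r1)),
    read1_seq = unname(as.character(r1)),
    read2_seq = unname(as.character(r2)),
    qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
    qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)),
    dbr = ""
  )
  id2 <- sub(" .*$", "", names(r2))
  if (!all(pairs$id == id2)) {
    abort("FASTQ record ids of the two files do not pair up")
  }
  if (!is.null(dbr_spec)) {
    pairs <- extract_dbr(pairs, dbr_spec)
  }
  class(pairs) <- c("read_pairs", class(pairs))
  pairs
}

#' @rdname read_fastq_pairs
#' @param read Which mate carries the DBR (1 or 2).
#' @param offset 0-based offset of the DBR within that read.
#' @param length DBR length in bases.
#' @export
dbr_spec <- function(read = 2L, offset = 0L, length = 8L) {
  stopifnot(read %in% c(1L, 2L), offset >= 0, length >= 1)
  list(read = as.integer(read), offset = as.integer(offset),
       length = as.integer(length))
}

extract_dbr <- function(pairs, spec) {
  col <- if (spec$read == 1L) "read1_seq" else "read2_seq"
  qcol <- if (spec$read == 1L) "qual1" else "qual2"
  seqs <- pairs[[col]]
  from <- spec$offset + 1L
  to <- spec$offset + spec$length
  if (any(nchar(seqs) < to)) {
    abort("DBR region extends beyond read length for some records")
  }
  pairs$dbr <- substr(seqs, from, to)
  drop_region <- function(x) {
    paste0(substr(x, 1L, from - 1L), substr(x, to + 1L, nchar(x)))
  }
  pairs[[col]] <- drop_region(seqs)
  pairs[[qcol]] <- drop_region(pairs[[qcol]])
  bad <- grepl("[^ACGTNacgtn]", pairs$dbr) |
    grepl("[^ACGTNacgtn]", pairs$read1_seq) |
    grepl("[^ACGTNacgtn]", pairs$read2_seq)
  if (any(bad)) {
    abort(paste0(
      "non-IUPAC characters in read(s): ",
      paste(utils::head(pairs$id[bad], 5), collapse = ", ")
    ))
  }
  pairs
}

#' Write a read-pair table back to paired FASTQ
#'
#' The DBR is re-attached at the position given by `dbr_spec` so the files
#' round-trip through [read_fastq_pairs()].
#'
#' @param pairs A `read_pairs` tibble.
#' @param path1,path2 Output paths for R1 and R2.
#' @param dbr_spec Where to re-insert the DBR; `NULL` leaves it off.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2, dbr_spec = NULL) {
  r1 <- pairs$read1_seq
  r2 <- pairs$read2_seq
  q1 <- pairs$qual1
  q2 <- pairs$qual2
  if (!is.null(dbr_spec)) {
    ins <- function(x, tag) {
      paste0(
        substr(x, 1L, dbr_spec$offset),
        tag,
        substr(x, dbr_spec$offset + 1L, nchar(x))
      )
    }
    qual_tag <- strrep("I", dbr_spec$length)
    if (dbr_spec$read == 1L) {
      r1 <- ins(r1, pairs$dbr); q1 <- ins(q1, qual_tag)
    } else {
      r2 <- ins(r2, pairs$dbr); q2 <- ins(q2, qual_tag)
    }
  }
  fq <- function(path, ids, seqs, quals) {
    writeLines(
      as.vector(rbind(paste0("@", ids), seqs, "+", quals)),
      path
    )
  }
  fq(path1, pairs$id, r1, q1)
  fq(path2, pairs$id, r2, q2)
  invisible(c(path1, path2))
}
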