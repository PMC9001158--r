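#' MND1 allele templates
#'
#' The rapid species call uses a 33-bp fragment of the nuclear MND1
#' (meiotic nuclear division 1) gene, in which the L and R alleles differ
#' by exactly two nucleotide substitutions; a heterozygote sequenced
#' directly shows IUPAC ambiguity codes at both positions. The templates
#' shipped here are *synthetic* stand-ins with that exact structure (the
#' field-validated templates are a configurable input; any pair of
#' 33-base alleles differing at two sites works).
#'
#' @param L,R Optional replacement allele sequences of equal length
#'   differing at exactly two positions.
#' @return A list: `L`, `R` (33-base strings) and `positions` (the two
#'   diagnostic positions, derived by comparison).
#' @export
mnd1_templates <- function(L = NULL, R = NULL) {
  if (is.null(L)) L <- "ATGGTCAAGCTTGACGAATCGGTACCATGGACT"
  if (is.null(R)) R <- "ATGGTCAAGTTTGACGAATCGGTAACATGGACT"
  if (nchar(L) != nchar(R)) abort("allele templates differ in length")
  lb <- strsplit(L, "")[[1]]
  rb <- strsplit(R, "")[[1]]
  positions <- which(lb != rb)
  if (length(positions) != 2) {
    abort(paste0(
      "allele templates must differ at exactly 2 positions (found ",
      length(positions), ")"
    ))
  }
  list(L = L, R = R, positions = positions)
}

# IUPAC ambiguity code for a two-base heterozygote
iupac_het <- function(b1, b2) {
  target <- paste(sort(c(b1, b2)), collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  code <- names(map)[vapply(map, function(x) {
    paste(sort(strsplit(x, "")[[1]]), collapse = "") == target
  }, TRUE)]
  if (length(code) != 1) abort(paste0("no IUPAC code for ", b1, "/", b2))
  code
}

# does IUPAC code `code` represent exactly the pair {b1, b2}?
is_het_code <- function(code, b1, b2) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) return(FALSE)
  bases <- sort(strsplit(map[[code]], "")[[1]])
  identical(bases, sort(c(b1, b2)))
}

#' Species call from an MND1 sequence
#'
#' Reads the two diagnostic positions of the 33-bp fragment: both in the
#' L state is *P. lessonae*; both in the R state is an RR genotype
#' (*P. ridibundus* complex); both showing the L/R two-base IUPAC
#' ambiguity code is the heterozygous hybrid *P.* kl. *esculentus*. Any
#' other combination — one position ambiguous, discordant states, or an
#' unreadable base — is UNIDENTIFIED. Note the marker's inherent
#' limitation: an RR individual heterozygous by descent, or a triploid,
#' is not distinguished beyond these three states, and the call does not
#' resolve ploidy.
#'
#' @param sequence A putative 33-base MND1 sequence (IUPAC alphabet).
#' @param templates From [mnd1_templates()].
#' @param max_mismatch Maximum tolerated mismatches against both
#'   templates at non-diagnostic positions before the sequence is
#'   declared unalignable (error).
#' @return One of `"LESSONAE"`, `"ESCULENTUS"`, `"RR_GENOTYPE"`,
#'   `"UNIDENTIFIED"`.
#' @export
call_mnd1 <- function(sequence, templates = mnd1_templates(),
                      max_mismatch = 3L) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != nchar(templates$L)) {
    abort(sprintf(
      "sequence length %d does not match the %d-base template",
      nchar(sequence), nchar(templates$L)
    ))
  }
  sb <- strsplit(sequence, "")[[1]]
  lb <- strsplit(templates$L, "")[[1]]
  pos <- templates$positions
  backbone <- setdiff(seq_along(lb), pos)
  mismatches <- sum(sb[backbone] != lb[backbone])
  if (mismatches > max_mismatch) {
    abort(sprintf(
      "sequence does not align to the MND1 template (%d backbone mismatches)",
      mismatches
    ))
  }
  rb <- strsplit(templates$R, "")[[1]]
  state_at <- function(p) {
    if (sb[p] == lb[p]) return("L")
    if (sb[p] == rb[p]) return("R")
    if (is_het_code(sb[p], lb[p], rb[p])) return("H")
    "X"
  }
  states <- vapply(pos, state_at, "")
  if (all(states == "L")) return("LESSONAE")
  if (all(states == "R")) return("RR_GENOTYPE")
  if (all(states == "H")) return("ESCULENTUS")
  "UNIDENTIFIED"
}

#' Call MND1 species for a table of sequences
#'
#' @param seqs A data frame with columns `individual` (or `id`) and
#'   `sequence`.
#' @inheritParams call_mnd1
#' @return A tibble `individual`, `label`. Unalignable sequences get
#'   `"UNIDENTIFIED"` rather than aborting the batch.
#' @export
call_mnd1_all <- function(seqs, templates = mnd1_templates(),
                          max_mismatch = 3L) {
  seqs <- tibble::as_tibble(seqs)
  if (!"individual" %in% names(seqs) && "id" %in% names(seqs)) {
    seqs$individual <- seqs$id
  }
  tibble::tibble(
    individual = seqs$individual,
    label = vapply(seqs$sequence, function(s) {
      tryCatch(
        call_mnd1(s, templates, max_mismatch),
        error = function(e) "UNIDENTIFIED"
      )
    }, "", USE.NAMES = FALSE)
  )
}

#' Synthetic ND1 reference haplotypes
#'
#' Three 336-base mitochondrial ND1 (NADH dehydrogenase subunit 1)
#' reference haplotypes, one per haplogroup of interest: the shared
#' *P. lessonae* / *P.* kl. *esculentus* maternal lineage, *P.
#' ridibundus*, and the invasive *P.* cf. *bedriagae*. These are
#' deterministic synthetic stand-ins with realistic between-group
#' divergence (~7%); real GenBank references can be supplied instead
#' wherever a `references` argument is accepted.
#'
#' @param length Fragment length.
#' @param n_diff Substitutions distinguishing each non-lessonae
#'   reference from the lessonae backbone.
#' @return A tibble `haplogroup`, `sequence`.
#' @export
nd1_references <- function(length = 336L, n_diff = 24L) {
  withr::with_seed(1139L, {
    base <- paste(
      sample(c("A", "C", "G", "T"), length, replace = TRUE),
      collapse = ""
    )
    mutate_at <- function(s, at) {
      for (p in at) {
        substr(s, p, p) <- sample(
          setdiff(c("A", "C", "G", "T"), substr(s, p, p)), 1L
        )
      }
      s
    }
    pos_rid <- sample.int(length, n_diff)
    pos_bed <- sample.int(length, n_diff)
    tibble::tibble(
      haplogroup = c("lessonae", "ridibundus", "bedriagae"),
      sequence = c(
        base,
        mutate_at(base, pos_rid),
        mutate_at(base, pos_bed)
      )
    )
  })
}

#' Assign an ND1 sequence to a mitochondrial haplogroup
#'
#' Nearest-reference assignment by Hamming distance over the aligned
#' fragment; a tie between references is unresolvable and returns
#' UNIDENTIFIED with the tie flagged.
#'
#' @param sequence An ND1 sequence, same aligned length as the
#'   references.
#' @param references A data frame `haplogroup`, `sequence` (default the
#'   synthetic [nd1_references()]).
#' @return A one-row tibble: `haplogroup`, `distance`, `tie`.
#' @export
assign_nd1_haplogroup <- function(sequence, references = nd1_references()) {
  references <- tibble::as_tibble(references)
  lens <- nchar(references$sequence)
  if (length(unique(c(lens, nchar(sequence)))) != 1) {
    abort(sprintf(
      "sequence length %d does not match reference length(s) %s",
      nchar(sequence), paste(unique(lens), collapse = ", ")
    ))
  }
  sb <- strsplit(toupper(sequence), "")[[1]]
  d <- vapply(references$sequence, function(r) {
    sum(sb != strsplit(toupper(r), "")[[1]])
  }, 0L, USE.NAMES = FALSE)
  best <- which(d == min(d))
  if (length(best) > 1) {
    return(tibble::tibble(
      haplogroup = "UNIDENTIFIED", distance = as.integer(min(d)), tie = TRUE
    ))
  }
  tibble::tibble(
    haplogroup = references$haplogroup[best],
    distance = as.integer(d[best]),
    tie = FALSE
  )
}

#' Concordance between two species-identification methods
#'
#' Cross-tabulates two call sets over their shared individuals.
#' `n_matched` counts the diagonal and `n_mismatched` the off-diagonal,
#' both restricted to individuals *identified by both* methods (the
#' UNIDENTIFIED label is excluded from the rate's denominator, since a
#' method that abstains is not wrong).
#'
#' @param calls_a,calls_b Data frames `individual`, `label`.
#' @param unidentified The label(s) treated as "no identification".
#' @return A list: `table` (confusion tibble, method A labels in rows),
#'   `n_matched`, `n_mismatched`, `rate` = matched / (matched +
#'   mismatched).
#' @export
marker_concordance <- function(calls_a, calls_b,
                               unidentified = "UNIDENTIFIED") {
  calls_a <- tibble::as_tibble(calls_a)
  calls_b <- tibble::as_tibble(calls_b)
  shared <- intersect(calls_a$individual, calls_b$individual)
  if (length(shared) == 0) {
    abort("the two call sets share no individual ids")
  }
  joined <- dplyr::inner_join(
    calls_a[c("individual", "label")],
    calls_b[c("individual", "label")],
    by = "individual", suffix = c("_a", "_b")
  )
  tab <- joined %>%
    dplyr::count(label_a = .data$label_a, label_b = .data$label_b) %>%
    tidyr::pivot_wider(
      names_from = "label_b", values_from = "n", values_fill = 0L
    )
  both_identified <- !(joined$label_a %in% unidentified) &
    !(joined$label_b %in% unidentified)
  n_matched <- sum(joined$label_a[both_identified] ==
                     joined$label_b[both_identified])
  n_mismatched <- sum(both_identified) - n_matched
  if (n_matched + n_mismatched == 0) {
    abort("no individuals identified by both methods; rate undefined")
  }
  list(
    table = tab,
    n_matched = n_matched,
    n_mismatched = n_mismatched,
    rate = n_matched / (n_matched + n_mismatched)
  )
}

#' Expand a published confusion table into individual-level call pairs
#'
#' Printed method-comparison tables report counts per (method A label,
#' method B label) cell; this helper materialises them as two call
#' tibbles with synthetic individual ids so they can be fed to
#' [marker_concordance()].
#'
#' @param counts A data frame `label_a`, `label_b`, `n`.
#' @return A list of tibbles `calls_a`, `calls_b`.
#' @export
expand_confusion_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("label_a", "label_b", "n") %in% names(counts)))
  idx <- rep(seq_len(nrow(counts)), counts$n)
  ids <- sprintf("ind%04d", seq_along(idx))
  list(
    calls_a = tibble::tibble(
      individual = ids, label = counts$label_a[idx]
    ),
    calls_b = tibble::tibble(
      individual = ids, label = counts$label_b[idx]
    )
  )
}
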