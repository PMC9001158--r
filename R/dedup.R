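#' Remove PCR duplicates using the degenerate base region
#'
#' Read pairs are grouped by the triple (first `key_length` bases of read
#' 1, first `key_length` bases of read 2, DBR tag). Pairs sharing all
#' three are PCR copies of one template molecule; pairs with identical
#' inserts but different DBR tags are independent templates and are both
#' kept — distinguishing these two cases is what the DBR is for. Within
#' each group the pair with the highest mean base quality is retained
#' (ties broken by input order); output preserves the input order of the
#' kept pairs. A sequence-prefix key (rather than the full read) makes the
#' grouping robust to 3' quality decay.
#'
#' @param pairs A `read_pairs` tibble (see [read_fastq_pairs()] /
#'   [simulate_dbr_reads()]).
#' @param key_length Number of leading bases of each mate used in the
#'   duplicate key.
#' @return A list with `kept` (the deduplicated `read_pairs` tibble) and
#'   `report` (tibble: `n_input`, `n_kept`, `n_removed`,
#'   `duplicate_rate`).
#' @export
remove_pcr_duplicates <- function(pairs, key_length = 30L) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) {
    report <- tibble::tibble(
      n_input = 0L, n_kept = 0L, n_removed = 0L, duplicate_rate = 0
    )
    out <- pairs
    class(out) <- c("read_pairs", class(out))
    return(list(kept = out, report = report))
  }
  if (length(unique(nchar(pairs$dbr))) > 1) {
    abort("inconsistent DBR lengths across read pairs")
  }
  if (any(key_length > nchar(pairs$read1_seq)) ||
      any(key_length > nchar(pairs$read2_seq))) {
    abort("key_length exceeds read length")
  }
  key <- paste(
    substr(pairs$read1_seq, 1L, key_length),
    substr(pairs$read2_seq, 1L, key_length),
    pairs$dbr,
    sep = "|"
  )
  mq <- mean_base_quality(pairs$qual1, pairs$qual2)
  # representative = highest mean quality, earliest input position on ties
  ord <- order(key, -mq, seq_len(nrow(pairs)))
  keep_sorted <- !duplicated(key[ord])
  keep <- sort(ord[keep_sorted])
  kept <- pairs[keep, , drop = FALSE]
  class(kept) <- c("read_pairs", class(kept))
  n_input <- nrow(pairs)
  n_kept <- length(keep)
  report <- tibble::tibble(
    n_input = n_input,
    n_kept = n_kept,
    n_removed = n_input - n_kept,
    duplicate_rate = (n_input - n_kept) / n_input
  )
  list(kept = kept, report = report)
}

# mean phred score over both mates (phred+33)
mean_base_quality <- function(qual1, qual2) {
  vapply(paste0(qual1, qual2), function(q) {
    mean(utf8ToInt(q)) - 33
  }, 0, USE.NAMES = FALSE)
}
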