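#' Classify a pond's breeding system from its genomotype calls
#'
#' Water frog populations persist under distinct breeding systems that
#' are recognisable from the set of genomotypes present:
#' * **L_E** — the classic lessonae-esculentus system: LL and LR
#'   co-occur, the hybrid backcrossing with the parental species;
#' * **MODIFIED_L_E** — LLR triploids alongside LL (and usually LR), the
#'   triploids depending on the diploid hybrids;
#' * **E_E_CANDIDATE** — triploids (LLR or LRR) with LR but *no* LL
#'   detected: the all-hybrid pattern. "Candidate" because absence of LL
#'   in a finite sample may be a sampling artifact;
#' * **UNDETERMINED** — a single genomotype, or a combination the rules
#'   do not cover.
#'
#' Rules are applied in order: (1) triploid present, LL absent, LR
#' present gives E_E_CANDIDATE; (2) LLR and LL present gives
#' MODIFIED_L_E; (3) LL and LR present gives L_E; (4) a single observed
#' label gives UNDETERMINED ("single-taxon sample"). Hybrids of unknown
#' ploidy (E_UNKNOWN_PLOIDY) count as LR-or-LLR presence for rule (3)
#' only. RR genotypes set an RR_PRESENT note whatever the system.
#'
#' @param calls A data frame of genomotype calls for *one* pond, with a
#'   `label` column (and optionally `pond`).
#' @return A one-row tibble: `pond`, per-label counts, `system`, `notes`.
#' @export
classify_pond <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) abort("classify_pond needs at least one call")
  pond <- if ("pond" %in% names(calls)) {
    unique(calls$pond)[1]
  } else {
    NA_character_
  }
  labels <- calls$label
  has <- function(l) any(labels == l)
  triploid <- has("LLR") || has("LRR")
  lr_like <- has("LR") || has("E_UNKNOWN_PLOIDY")  # rule (3) only
  observed <- unique(labels)

  system <- if (triploid && !has("LL") && has("LR")) {
    "E_E_CANDIDATE"
  } else if (has("LLR") && has("LL")) {
    "MODIFIED_L_E"
  } else if (has("LL") && lr_like) {
    "L_E"
  } else {
    "UNDETERMINED"
  }
  notes <- character(0)
  if (system == "UNDETERMINED" && length(observed) == 1) {
    notes <- c(notes, "single-taxon sample")
  }
  if (has("RR")) notes <- c(notes, "RR_PRESENT")

  count_of <- function(l) sum(labels == l)
  tibble::tibble(
    pond = pond,
    n_LL = count_of("LL"), n_LR = count_of("LR"),
    n_LLR = count_of("LLR"), n_LRR = count_of("LRR"),
    n_RR = count_of("RR"),
    n_E_unknown = count_of("E_UNKNOWN_PLOIDY"),
    n_undetermined = count_of("UNDETERMINED"),
    system = system,
    notes = paste(notes, collapse = ";")
  )
}

#' Classify the breeding system of every pond
#'
#' @param calls Genomotype calls with `pond` and `label` columns (as from
#'   [classify_genotypes()]).
#' @return A tibble with one row per pond (see [classify_pond()]).
#' @export
classify_ponds <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (!"pond" %in% names(calls)) {
    abort("calls need a `pond` column")
  }
  calls %>%
    dplyr::group_split(.data$pond) %>%
    purrr::map_dfr(classify_pond) %>%
    dplyr::arrange(.data$pond)
}
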