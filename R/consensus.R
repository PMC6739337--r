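# Per-indication TopX consensus predictions. For each approved drug of an
# indication, the TopX most signature-similar compounds are collected; a
# candidate's consensus count is the number of approved drugs whose TopX
# lists contain it, and its percent occurrence normalizes that count by the
# number of approved drugs (the maximum number of times the candidate could
# have been predicted).

#' Construct / validate a consensus table
#'
#' A long-format table of prediction entries, one row per
#' (indication, compound, TopX). Usually produced by
#' [build_consensus_table()]; the constructor also lets tests and worked
#' examples inject a hand-built table directly.
#'
#' @param entries data.frame with columns `indication_id`, `compound_id`,
#'   `topx`, `consensus_count`, and optionally `percent_occurrence` and
#'   `already_approved`.
#' @param provenance optional list (config snapshot, seed) carried as an
#'   attribute.
#' @return data.frame of class `consensus_table`.
#' @export
consensus_table <- function(entries, provenance = NULL) {
  need <- c("indication_id", "compound_id", "topx", "consensus_count")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("consensus table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  entries$indication_id <- norm_id(entries$indication_id)
  entries$compound_id <- norm_id(entries$compound_id)
  entries$topx <- as.integer(entries$topx)
  entries$consensus_count <- as.integer(entries$consensus_count)
  if (any(entries$consensus_count < 0)) {
    stop("consensus counts must be nonnegative", call. = FALSE)
  }
  if (is.null(entries$percent_occurrence)) entries$percent_occurrence <- NA_real_
  if (is.null(entries$already_approved)) entries$already_approved <- FALSE
  key <- paste(entries$indication_id, entries$compound_id, entries$topx, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (indication, compound, topx) entry in consensus table",
         call. = FALSE)
  }
  entries <- entries[order(entries$topx, entries$indication_id,
                           entries$compound_id), , drop = FALSE]
  rownames(entries) <- NULL
  attr(entries, "provenance") <- provenance
  class(entries) <- c("consensus_table", "data.frame")
  entries
}

#' Consensus predictions for one indication at one TopX cutoff
#'
#' Takes the TopX signature neighbours of each approved drug and tabulates
#' how many approved drugs nominate each candidate. Candidates that are
#' themselves approved for the indication are retained but flagged
#' `already_approved` (recovering an approved drug is the platform's own
#' benchmark signal). Psychoactives never act as queries -- they cannot
#' appear in approved sets -- but always remain eligible candidates.
#'
#' @param indication a single row of an [indication_table()] (or a list
#'   with `mesh_id` and `approved`).
#' @param matrix an [interaction_matrix()].
#' @param topx list length X.
#' @param distm optional precomputed [rmsd_matrix()] (internal fast path).
#' @return data.frame of prediction entries for this indication.
#' @export
predict_indication <- function(indication, matrix, topx, distm = NULL) {
  if (is.data.frame(indication)) {
    stopifnot(nrow(indication) == 1)
    mesh_id <- indication$mesh_id
    approved <- indication$approved[[1]]
  } else {
    mesh_id <- indication$mesh_id
    approved <- indication$approved
  }
  mesh_id <- norm_id(mesh_id)
  approved <- norm_id(approved)
  if (length(approved) == 0) {
    stop(sprintf("indication '%s' unusable for prediction: no approved compounds",
                 mesh_id), call. = FALSE)
  }
  miss <- setdiff(approved, rownames(matrix))
  if (length(miss)) {
    stop(sprintf("approved compound '%s' absent from interaction matrix", miss[1]),
         call. = FALSE)
  }
  hits <- character(0)
  for (d in approved) {
    nb <- rank_neighbors(d, matrix, top = topx,
                         dist_row = if (!is.null(distm)) distm[d, ] else NULL)
    hits <- c(hits, nb$compound_id)
  }
  tab <- table(hits)
  out <- data.frame(
    indication_id = mesh_id,
    compound_id = names(tab),
    topx = as.integer(topx),
    consensus_count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out$percent_occurrence <- 100 * out$consensus_count / length(approved)
  out$already_approved <- out$compound_id %in% approved
  out[order(out$compound_id), , drop = FALSE]
}

#' Build the full consensus table over indications and TopX cutoffs
#'
#' @param indications an [indication_table()]; indications without usable
#'   approved drugs are skipped with a warning, not fatal.
#' @param matrix an [interaction_matrix()].
#' @param config an [analysis_config()]; its `topx_values` define the
#'   cutoffs.
#' @return a [consensus_table()] covering every usable indication at every
#'   TopX. Deterministic given its inputs (no randomness is involved).
#' @export
build_consensus_table <- function(indications, matrix, config = analysis_config()) {
  usable <- indications[indications$usable, , drop = FALSE]
  skipped <- indications$mesh_id[!indications$usable]
  if (length(skipped)) {
    warning("skipping indication(s) with no approved compounds: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (nrow(usable) == 0) stop("no usable indication", call. = FALSE)
  distm <- rmsd_matrix(matrix)
  blocks <- list()
  for (x in sort(config$topx_values)) {
    for (i in seq_len(nrow(usable))) {
      blocks[[length(blocks) + 1L]] <-
        predict_indication(usable[i, ], matrix, x, distm = distm)
    }
  }
  consensus_table(do.call(rbind, blocks),
                  provenance = list(config = unclass(config)))
}

# Subset a consensus table to one TopX level, erroring when absent.
table_at_topx <- function(table, topx) {
  out <- table[table$topx == as.integer(topx), , drop = FALSE]
  if (nrow(out) == 0) stop("consensus table has no entries at TopX = ", topx,
                           call. = FALSE)
  out
}
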