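# Indication-indication association network. Two indications are
# associated when at least two distinct psychoactive compounds are
# predicted above a per-TopX minimum consensus threshold for BOTH
# indications; the association count is the number of such shared
# qualifying psychoactives. Thresholds (study design: >=2 at Top10, >=3 at
# Top25, >=4 at Top40, >=6 at Top100) are applied per endpoint: a shared
# compound must clear the threshold in each indication independently.

#' Build the thresholded indication-indication association edge list
#'
#' @param table a [consensus_table()].
#' @param compounds a [compound_table()] (only psychoactive-flagged
#'   compounds ever contribute).
#' @param topx TopX level; must have a threshold defined.
#' @param config an [analysis_config()] supplying the TopX-to-threshold
#'   map, or a named vector of thresholds.
#' @param indications optional [indication_table()]; when supplied with
#'   `mental_health_only = TRUE` (default), only mental-health indication
#'   pairs are considered.
#' @param mental_health_only restrict pairs to mental-health indications.
#' @return data.frame with one row per edge: `indication_a`,
#'   `indication_b` (canonically sorted within and across rows), `topx`,
#'   `threshold`, `association_count`, and `shared_compounds`
#'   (semicolon-joined `id:count_a|count_b`). Pairs sharing fewer than two
#'   qualifying psychoactives are never emitted.
#' @export
build_associations <- function(table, compounds, topx, config = analysis_config(),
                               indications = NULL, mental_health_only = TRUE) {
  thresholds <- if (inherits(config, "analysis_config")) {
    config$association_thresholds
  } else config
  tau <- thresholds[as.character(as.integer(topx))]
  if (is.na(tau)) stop("no association threshold defined for TopX = ", topx,
                       call. = FALSE)
  tau <- as.integer(tau)
  tab <- table_at_topx(table, topx)
  psy_ids <- compounds$compound_id[compounds$is_psychoactive]
  tab <- tab[tab$compound_id %in% psy_ids & tab$consensus_count >= tau, ,
             drop = FALSE]
  ind_ids <- sort(unique(tab$indication_id))
  if (!is.null(indications) && mental_health_only) {
    mh <- indications$mesh_id[indications$is_mental_health]
    ind_ids <- intersect(ind_ids, mh)
  }
  qual <- split(tab$compound_id, tab$indication_id)
  cc <- split(stats::setNames(tab$consensus_count, tab$compound_id),
              tab$indication_id)
  rows <- list()
  if (length(ind_ids) >= 2) {
    for (i in seq_len(length(ind_ids) - 1)) {
      for (j in seq(i + 1, length(ind_ids))) {
        a <- ind_ids[i]; b <- ind_ids[j]
        shared <- sort(intersect(qual[[a]], qual[[b]]))
        if (length(shared) >= 2) {
          rows[[length(rows) + 1L]] <- data.frame(
            indication_a = a, indication_b = b,
            topx = as.integer(topx), threshold = tau,
            association_count = length(shared),
            shared_compounds = paste(sprintf("%s:%d|%d", shared,
                                             cc[[a]][shared], cc[[b]][shared]),
                                     collapse = ";"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(indication_a = character(), indication_b = character(),
                      topx = integer(), threshold = integer(),
                      association_count = integer(),
                      shared_compounds = character(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$indication_a, out$indication_b), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("association_edges", "data.frame")
  out
}
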