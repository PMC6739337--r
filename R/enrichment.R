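# The two headline enrichment statistics. Both are consensus-weighted
# percentages:
#   normalized indication rank -- per indication, the share of its total
#     consensus mass contributed by psychoactive candidates;
#   normalized compound rank   -- per compound, the share of its total
#     consensus mass that falls on mental-health indications.
# Entities with zero total consensus mass are omitted, not reported as 0.

new_rank_distribution <- function(values, kind, topx, class_filter = NULL) {
  structure(values,
            kind = kind, topx = as.integer(topx), class_filter = class_filter,
            class = c("rank_distribution", "data.frame"))
}

#' Normalized indication rank
#'
#' For each indication at the given TopX: 100 * (consensus mass of
#' psychoactive candidates) / (consensus mass of all candidates). Consensus
#' mass means the sum of consensus counts, so a compound nominated by seven
#' approved drugs weighs seven times one nominated once.
#'
#' @param table a [consensus_table()].
#' @param compounds a [compound_table()] supplying psychoactive flags and
#'   chemical classes.
#' @param topx TopX level to evaluate.
#' @param class_filter optional chemical class: restrict the numerator to
#'   psychoactives of that class.
#' @return data.frame `(indication_id, value)`, values in [0, 100], class
#'   `rank_distribution`. Indications with zero total consensus are dropped
#'   with a warning.
#' @export
indication_rank <- function(table, compounds, topx, class_filter = NULL) {
  tab <- table_at_topx(table, topx)
  flag <- compounds$is_psychoactive[match(tab$compound_id, compounds$compound_id)]
  flag[is.na(flag)] <- FALSE
  if (!is.null(class_filter)) {
    cls <- compounds$chem_class[match(tab$compound_id, compounds$compound_id)]
    flag <- flag & !is.na(cls) & cls == class_filter
  }
  tot <- tapply(tab$consensus_count, tab$indication_id, sum)
  psy <- tapply(tab$consensus_count * flag, tab$indication_id, sum)
  keep <- tot > 0
  if (any(!keep)) {
    warning("omitting indication(s) with zero total consensus: ",
            paste(names(tot)[!keep], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(indication_id = names(tot)[keep],
                    value = 100 * as.numeric(psy[keep]) / as.numeric(tot[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new_rank_distribution(out, "indication_rank", topx, class_filter)
}

#' Normalized compound rank
#'
#' For each predicted compound at the given TopX: 100 * (its consensus mass
#' on mental-health indications) / (its consensus mass on all indications).
#' Expresses a compound's preference for mental-health indications.
#'
#' @param table a [consensus_table()].
#' @param indications an [indication_table()] supplying the mental-health
#'   flags (epilepsy-tree indications are conventionally flagged
#'   mental-health in that table, pooling them with the MeSH F03 set).
#' @param topx TopX level to evaluate.
#' @return data.frame `(compound_id, value)`, class `rank_distribution`;
#'   compounds never predicted are absent.
#' @export
compound_rank <- function(table, indications, topx) {
  tab <- table_at_topx(table, topx)
  mh <- indications$is_mental_health[match(tab$indication_id, indications$mesh_id)]
  if (anyNA(mh)) {
    stop("consensus table references indication(s) missing from the indication table: ",
         paste(unique(tab$indication_id[is.na(mh)]), collapse = ", "), call. = FALSE)
  }
  tot <- tapply(tab$consensus_count, tab$compound_id, sum)
  mhm <- tapply(tab$consensus_count * mh, tab$compound_id, sum)
  keep <- tot > 0
  out <- data.frame(compound_id = names(tot)[keep],
                    value = 100 * as.numeric(mhm[keep]) / as.numeric(tot[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new_rank_distribution(out, "compound_rank", topx)
}

#' Normalized compound rank per psychoactive chemical class
#'
#' Splits the compound-rank distribution by chemical class (amphetamine,
#' cathinone, phenethylamine, tryptamine, cannabinoid, other). Classes with
#' no predicted members yield empty distributions.
#'
#' @inheritParams compound_rank
#' @param compounds a [compound_table()] with `chem_class` filled.
#' @return named list of `rank_distribution` data.frames, one per class.
#' @export
class_breakdown <- function(table, compounds, indications, topx) {
  cr <- compound_rank(table, indications, topx)
  cls <- compounds$chem_class[match(cr$compound_id, compounds$compound_id)]
  classes <- setdiff(CHEM_CLASSES, "none")
  out <- lapply(classes, function(k) {
    sub <- cr[!is.na(cls) & cls == k, , drop = FALSE]
    rownames(sub) <- NULL
    new_rank_distribution(sub, "compound_rank", topx, class_filter = k)
  })
  names(out) <- classes
  out
}
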