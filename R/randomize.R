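# Monte-Carlo randomized controls. Both controls relabel the consensus
# table rather than re-running prediction: consensus counts ride along
# unchanged, only identities shuffle.
#
#   compound shuffle  -- per replicate, per indication, the indication's
#     distinct predicted compounds are replaced by an injective uniform
#     draw from the full compound library; a compound predicted multiple
#     times (its whole consensus count) is replaced consistently, i.e. its
#     entire mass transfers to the one replacement.
#   indication shuffle -- per replicate, the mental-health labels are
#     permuted across indications (label counts preserved) and compound
#     ranks recomputed.
#
# Per-replicate values are retained alongside replicate-averaged values so
# downstream tests can consume either view.

new_null_distribution <- function(control_kind, rank_kind, topx, per_replicate,
                                  n_replicates, seed) {
  mv <- stats::aggregate(value ~ entity_id, data = per_replicate, FUN = mean)
  mv <- mv[order(mv$entity_id), , drop = FALSE]
  rownames(mv) <- NULL
  structure(
    list(control_kind = control_kind,
         rank_kind = rank_kind,
         topx = as.integer(topx),
         per_replicate = per_replicate,
         mean_values = mv,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %s / %s, Top%d, %d replicates, mean %.2f%%\n",
              x$control_kind, x$rank_kind, x$topx, x$n_replicates,
              mean(x$mean_values$value)))
  invisible(x)
}

#' Compound-randomization control
#'
#' @param table a [consensus_table()].
#' @param compounds a [compound_table()] spanning the full compound library
#'   (replacements are drawn from it); must cover every compound in the
#'   table.
#' @param topx TopX level.
#' @param n_reps number of replicates (study design: 1000).
#' @param seed integer seed.
#' @param kind which rank statistic to recompute on the relabelled table:
#'   `"indication_rank"` (default) or `"compound_rank"`.
#' @param indications an [indication_table()]; required for
#'   `kind = "compound_rank"` (mental-health flags).
#' @return a `null_distribution` with per-replicate values and
#'   replicate-averaged `mean_values` per entity (per indication for
#'   indication ranks; per replacement compound, averaged over the
#'   replicates in which it was drawn, for compound ranks).
#' @export
shuffle_compounds <- function(table, compounds, topx, n_reps = 1000, seed = 1,
                              kind = c("indication_rank", "compound_rank"),
                              indications = NULL) {
  kind <- match.arg(kind)
  tab <- table_at_topx(table, topx)
  lib <- compounds$compound_id
  if (!all(tab$compound_id %in% lib)) {
    stop("compound library does not span all predicted compounds", call. = FALSE)
  }
  psy <- compounds$is_psychoactive
  by_ind <- split(tab[c("compound_id", "consensus_count")], tab$indication_id)
  ks <- vapply(by_ind, nrow, 1L)
  if (max(ks) > length(lib)) {
    stop("library smaller than an indication's distinct-prediction count; ",
         "injective replacement impossible", call. = FALSE)
  }
  ind_ids <- names(by_ind)
  if (kind == "compound_rank") {
    if (is.null(indications)) {
      stop("indications table required for kind = 'compound_rank'", call. = FALSE)
    }
    mh <- indications$is_mental_health[match(ind_ids, indications$mesh_id)]
    if (anyNA(mh)) stop("indication table does not cover the consensus table",
                        call. = FALSE)
  }
  cc_list <- lapply(by_ind, function(b) as.numeric(b$consensus_count))
  nL <- length(lib)
  reps <- with_rng(seed, lapply(seq_len(n_reps), function(r) {
    draws <- lapply(ks, function(k) sample.int(nL, k))
    if (kind == "indication_rank") {
      vals <- vapply(seq_along(ind_ids), function(i) {
        cc <- cc_list[[i]]
        100 * sum(cc[psy[draws[[i]]]]) / sum(cc)
      }, numeric(1))
      data.frame(replicate = r, entity_id = ind_ids, value = vals,
                 stringsAsFactors = FALSE)
    } else {
      idx <- unlist(draws, use.names = FALSE)
      cc <- unlist(cc_list, use.names = FALSE)
      is_mh <- rep(mh, ks)
      tot <- tapply(cc, idx, sum)
      mhm <- tapply(cc * is_mh, idx, sum)
      data.frame(replicate = r,
                 entity_id = lib[as.integer(names(tot))],
                 value = 100 * as.numeric(mhm) / as.numeric(tot),
                 stringsAsFactors = FALSE)
    }
  }))
  new_null_distribution("compound_shuffle", kind, topx, do.call(rbind, reps),
                        n_reps, seed)
}

#' Indication-label randomization control
#'
#' @param indications an [indication_table()] covering the consensus table;
#'   must contain at least one mental-health and one other indication among
#'   those predicted (an all-identical label set makes the permutation
#'   vacuous and is an error).
#' @param table a [consensus_table()].
#' @param topx TopX level.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return a `null_distribution` of compound ranks under permuted
#'   mental-health labels.
#' @export
shuffle_indications <- function(indications, table, topx, n_reps = 1000, seed = 1) {
  tab <- table_at_topx(table, topx)
  ind_ids <- sort(unique(tab$indication_id))
  mh <- indications$is_mental_health[match(ind_ids, indications$mesh_id)]
  if (anyNA(mh)) stop("indication table does not cover the consensus table",
                      call. = FALSE)
  if (all(mh) || all(!mh)) {
    stop("mental-health labels all identical; permutation control is vacuous",
         call. = FALSE)
  }
  cmp_ids <- sort(unique(tab$compound_id))
  M <- matrix(0, nrow = length(cmp_ids), ncol = length(ind_ids),
              dimnames = list(cmp_ids, ind_ids))
  M[cbind(match(tab$compound_id, cmp_ids), match(tab$indication_id, ind_ids))] <-
    tab$consensus_count
  tot <- rowSums(M)
  reps <- with_rng(seed, lapply(seq_len(n_reps), function(r) {
    lab <- sample(mh)
    data.frame(replicate = r, entity_id = cmp_ids,
               value = 100 * as.numeric(M %*% lab) / tot,
               stringsAsFactors = FALSE)
  }))
  new_null_distribution("indication_shuffle", "compound_rank", topx,
                        do.call(rbind, reps), n_reps, seed)
}

#' Pool a null distribution's values
#'
#' @param null a `null_distribution`.
#' @param pooled if `TRUE`, return every per-replicate value; otherwise the
#'   replicate-averaged per-entity values.
#' @return named numeric vector of rank values (names are entity ids;
#'   pooled values repeat entities across replicates).
#' @export
null_values <- function(null, pooled = FALSE) {
  if (pooled) {
    stats::setNames(null$per_replicate$value, null$per_replicate$entity_id)
  } else {
    stats::setNames(null$mean_values$value, null$mean_values$entity_id)
  }
}
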