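# Interaction-signature comparison. Two compounds are compared by the root
# mean squared deviation (RMSD) of their proteome-wide interaction
# signatures over the full protein panel -- no per-protein weighting and no
# protein-class special-casing. Smaller RMSD means more similar.

#' Root mean squared deviation between two interaction signatures
#'
#' `sqrt(mean((a - b)^2))` over the protein panel. Symmetric, zero iff the
#' vectors are identical.
#'
#' @param sig_a,sig_b numeric vectors of equal length (one interaction
#'   score per protein).
#' @return nonnegative scalar.
#' @examples
#' rmsd(c(0, 0), c(3, 4)) # sqrt(12.5)
#' @export
rmsd <- function(sig_a, sig_b) {
  if (length(sig_a) != length(sig_b)) {
    stop("signature length mismatch: ", length(sig_a), " vs ", length(sig_b),
         call. = FALSE)
  }
  if (length(sig_a) < 1) stop("signatures must be non-empty", call. = FALSE)
  if (anyNA(sig_a) || anyNA(sig_b)) stop("signatures contain missing values", call. = FALSE)
  sqrt(mean((sig_a - sig_b)^2))
}

# All-pairs RMSD matrix: euclidean distance / sqrt(n_proteins).
rmsd_matrix <- function(matrix) {
  d <- as.matrix(stats::dist(unclass(matrix), method = "euclidean"))
  d / sqrt(ncol(matrix))
}

#' Rank all compounds by signature similarity to a query
#'
#' Every other compound in the matrix, sorted by ascending RMSD to the
#' query's signature. Ties are broken by (case-folded) compound id so the
#' ordering is deterministic across platforms. The query itself is excluded
#' (its distance-0 self-match carries no information).
#'
#' @param query_id compound id present in `matrix`.
#' @param matrix an [interaction_matrix()].
#' @param top optional integer: truncate to the `top` nearest neighbours.
#' @param dist_row optional precomputed named vector of RMSDs from the query
#'   to all compounds (internal fast path).
#' @return data.frame `(query_id, compound_id, rmsd, rank)` with 1-based
#'   ranks; scores nondecreasing with rank.
#' @export
rank_neighbors <- function(query_id, matrix, top = NULL, dist_row = NULL) {
  query_id <- norm_id(query_id)
  if (is.null(dist_row)) {
    i <- match(query_id, rownames(matrix))
    if (is.na(i)) stop("unknown query compound: ", query_id, call. = FALSE)
    delta <- sweep(unclass(matrix), 2, unclass(matrix)[i, ], "-")
    dist_row <- sqrt(rowMeans(delta^2))
  } else if (!query_id %in% names(dist_row)) {
    stop("unknown query compound: ", query_id, call. = FALSE)
  }
  dist_row <- dist_row[names(dist_row) != query_id]
  ord <- order(dist_row, names(dist_row), method = "radix")
  out <- data.frame(
    query_id = query_id,
    compound_id = names(dist_row)[ord],
    rmsd = unname(dist_row[ord]),
    stringsAsFactors = FALSE
  )
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
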