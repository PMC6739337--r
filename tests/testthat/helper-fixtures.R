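# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small labelled interaction matrix with reproducible random scores.
random_matrix <- function(n_compounds, n_proteins, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_compounds * n_proteins), n_compounds, n_proteins,
              dimnames = list(sprintf("c%02d", seq_len(n_compounds)),
                              sprintf("p%02d", seq_len(n_proteins))))
  interaction_matrix(m)
}

# Independent brute-force neighbour ranking: double loop over compounds,
# explicit RMSD formula, sort by (distance, id).
brute_force_neighbors <- function(query_id, mat) {
  others <- setdiff(rownames(mat), query_id)
  d <- vapply(others, function(j) {
    sqrt(mean((mat[query_id, ] - mat[j, ])^2))
  }, numeric(1))
  ord <- order(d, others, method = "radix")
  data.frame(compound_id = others[ord], rmsd = unname(d[ord]),
             rank = seq_along(others), stringsAsFactors = FALSE)
}

# Config evaluating a single TopX level.
config_top <- function(x, tau = 2L, ...) {
  analysis_config(topx_values = x,
                  association_thresholds = stats::setNames(tau, x), ...)
}

# Hand-built consensus table from a compact spec:
# rows list(indication, compound, count), all at one TopX.
toy_table <- function(rows, topx = 10L) {
  consensus_table(data.frame(
    indication_id = vapply(rows, `[[`, "", 1),
    compound_id = vapply(rows, `[[`, "", 2),
    topx = topx,
    consensus_count = vapply(rows, function(r) as.integer(r[[3]]), 1L),
    stringsAsFactors = FALSE
  ))
}

# One-sided KS statistic computed independently of the package (used as
# the oracle's own D+; kept deliberately naive).
oracle_dplus <- function(obs, nul) {
  xs <- sort(unique(c(obs, nul)))
  max(stats::ecdf(nul)(xs) - stats::ecdf(obs)(xs), 0)
}

# Exact permutation tail probability of D+ by full enumeration.
oracle_ks_exact_p <- function(obs, nul) {
  m <- length(obs); n <- length(nul)
  pool <- c(obs, nul)
  d0 <- oracle_dplus(obs, nul)
  cmb <- utils::combn(m + n, m)
  ds <- apply(cmb, 2, function(ix) oracle_dplus(pool[ix], pool[-ix]))
  mean(ds >= d0 - 1e-12)
}
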