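# Significance tests comparing observed rank distributions against the
# randomized controls. The alternative hypothesis in both tests is that the
# observed values are stochastically greater than the null (hence one
# tailed): the direction in which a genuine psychoactive preference for
# mental-health indications would show.

new_test_result <- function(test_name, statistic, p_value, alternative,
                            n_observed, n_null) {
  structure(
    list(test_name = test_name,
         statistic = as.numeric(statistic),
         p_value = as.numeric(p_value),
         alternative = alternative,
         n_observed = as.integer(n_observed),
         n_null = as.integer(n_null)),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n_obs = %d, n_null = %d)\n  alternative: %s\n",
              x$test_name, x$statistic, x$p_value, x$n_observed, x$n_null,
              x$alternative))
  invisible(x)
}

#' One-tailed two-sample Kolmogorov-Smirnov test
#'
#' Statistic `D+ = sup_x [ECDF_null(x) - ECDF_observed(x)]`: large when the
#' observed sample sits above the null sample. The p-value is the one-sided
#' asymptotic bound `exp(-2 m n D+^2 / (m + n))`.
#'
#' @param observed,null_sample numeric samples (rank values in percent);
#'   both nonempty.
#' @return a `rank_test` result.
#' @examples
#' ks_one_tailed(c(10, 20, 30), c(1, 2, 3)) # D+ = 1, p = exp(-3)
#' @export
ks_one_tailed <- function(observed, null_sample) {
  observed <- as.numeric(observed)
  null_sample <- as.numeric(null_sample)
  if (length(observed) == 0 || length(null_sample) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (anyNA(observed) || anyNA(null_sample)) {
    stop("samples contain missing values", call. = FALSE)
  }
  m <- length(observed)
  n <- length(null_sample)
  xs <- sort(unique(c(observed, null_sample)))
  d_plus <- max(stats::ecdf(null_sample)(xs) - stats::ecdf(observed)(xs), 0)
  p <- min(1, exp(-2 * m * n * d_plus^2 / (m + n)))
  new_test_result("ks_one_tailed", d_plus, p,
                  "observed stochastically greater than null", m, n)
}

#' One-tailed paired t-test
#'
#' Tests whether the mean of the entity-wise differences
#' `observed - null` is greater than zero. When both inputs are named,
#' entities are aligned by name (order-independent); unnamed inputs must
#' already be aligned and of equal length.
#'
#' @param observed,null_sample numeric vectors, optionally named by entity
#'   id; at least 2 aligned pairs with nonzero difference variance.
#' @return a `rank_test` result.
#' @export
paired_t_one_tailed <- function(observed, null_sample) {
  if (!is.null(names(observed)) && !is.null(names(null_sample))) {
    common <- intersect(names(observed), names(null_sample))
    if (length(common) < 2) {
      stop("fewer than 2 common entities after alignment", call. = FALSE)
    }
    observed <- observed[common]
    null_sample <- null_sample[common]
  } else if (length(observed) != length(null_sample)) {
    stop("length mismatch after alignment: ", length(observed), " vs ",
         length(null_sample), call. = FALSE)
  }
  if (length(observed) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- as.numeric(observed) - as.numeric(null_sample)
  if (stats::sd(d) == 0) {
    stop("zero-variance differences; paired t-test degenerate", call. = FALSE)
  }
  tt <- stats::t.test(as.numeric(observed), as.numeric(null_sample),
                      paired = TRUE, alternative = "greater")
  new_test_result("paired_t_one_tailed", unname(tt$statistic), tt$p.value,
                  "mean of observed - null differences greater than zero",
                  length(observed), length(null_sample))
}
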