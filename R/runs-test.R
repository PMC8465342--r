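#' Wald-Wolfowitz runs test on a residual series
#'
#' Tests the randomness of the sign sequence of (weighted) residuals: too
#' few runs mean clustered residuals (systematic model misfit), too many
#' mean negative correlation; both reject. Exact zeros are excluded from
#' the sign sequence. Above `exact_below` observations the normal
#' approximation is used, `z = (R - mu) / sigma` with
#' `mu = 2 n1 n2 / n + 1` and
#' `sigma^2 = 2 n1 n2 (2 n1 n2 - n) / (n^2 (n - 1))`; below it the exact
#' runs distribution is enumerated and a two-sided probability-mass p-value
#' computed.
#'
#' @param residuals numeric series (weighted residuals of a fit).
#' @param alpha significance level; the series *passes* (is consistent
#'   with randomness) when `p >= alpha`.
#' @param exact_below use the exact distribution when fewer than this many
#'   non-zero residuals (default 20).
#' @return list with `pass` (logical), `p`, `runs`, `n_pos`, `n_neg`, `z`
#'   (`NA` for the exact branch).
#' @examples
#' runs_test(rep(c(1, -1), 25))   # strictly alternating: too many runs
#' runs_test(c(rep(1, 10), rep(-1, 10)))  # two runs: clustered
#' @export
runs_test <- function(residuals, alpha = 0.05, exact_below = 20) {
  s <- sign(residuals[residuals != 0])
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  n <- n1 + n2
  if (n < 10)
    stop("runs test needs at least 10 non-zero residuals", call. = FALSE)
  r <- length(rle(s)$lengths)
  if (n1 == 0 || n2 == 0)
    return(list(pass = FALSE, p = .Machine$double.xmin, runs = r,
                n_pos = n1, n_neg = n2, z = NA_real_))
  if (n < exact_below) {
    pmf <- runs_pmf(n1, n2)
    p <- sum(pmf[pmf <= pmf[r - 1] * (1 + 1e-12)])
    z <- NA_real_
  } else {
    mu <- 2 * n1 * n2 / n + 1
    sig2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    z <- (r - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  p <- max(p, .Machine$double.xmin)
  list(pass = p >= alpha, p = p, runs = r, n_pos = n1, n_neg = n2, z = z)
}

#' Exact distribution of the number of runs
#'
#' Probability mass of `R = 2, ..., n1 + n2` runs in a random arrangement
#' of `n1` symbols of one kind and `n2` of the other.
#'
#' @param n1,n2 counts of the two symbols (both >= 1).
#' @return numeric vector of probabilities for r = 2, ..., n1 + n2 runs
#'   (element r - 1 is the probability of exactly r runs).
#' @export
runs_pmf <- function(n1, n2) {
  rmax <- n1 + n2
  denom <- lchoose(n1 + n2, n1)
  p <- numeric(rmax - 1)
  for (r in 2:rmax) {
    k <- r %/% 2
    p[r - 1] <- if (r %% 2 == 0) {
      2 * exp(lchoose(n1 - 1, k - 1) + lchoose(n2 - 1, k - 1) - denom)
    } else {
      exp(lchoose(n1 - 1, k) + lchoose(n2 - 1, k - 1) - denom) +
        exp(lchoose(n1 - 1, k - 1) + lchoose(n2 - 1, k) - denom)
    }
  }
  p
}
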