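# MCMC convergence diagnostics on a chains x iterations x parameters draws
# array: Gelman-Rubin potential scale reduction and Geweke window z-scores.

.as_draws_array <- function(draws) {
  if (inherits(draws, "diet_posterior")) draws <- draws$draws
  if (is.matrix(draws)) draws <- array(draws, c(1L, dim(draws)),
                                       dimnames = c(list(NULL), dimnames(draws)))
  stopifnot(is.array(draws), length(dim(draws)) == 3L)
  draws
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For each parameter, compares the between-chain variance of the chain
#' means with the mean within-chain variance:
#' `rhat = sqrt(((n-1)/n * W + B/n) / W)` for chains of length `n`, where
#' `W` is the mean within-chain variance and `B = n * var(chain means)`.
#' Values near 1 indicate the chains sample the same distribution. A chain
#' set with zero within-chain variance (stuck chains) gets an `Inf`
#' sentinel so it is always flagged.
#'
#' @param draws a chains x iterations x parameters array (or a
#'   `diet_posterior`).
#' @return named numeric vector of rhat values, one per parameter.
#' @export
gelman_rubin <- function(draws) {
  x <- .as_draws_array(draws)
  m <- dim(x)[1L]; n <- dim(x)[2L]
  if (m < 2L) stop("Gelman-Rubin needs at least 2 chains")
  r <- vapply(seq_len(dim(x)[3L]), function(p) {
    ch <- x[, , p, drop = FALSE][, , 1L]
    w <- mean(apply(ch, 1L, var))
    b <- n * var(rowMeans(ch))
    if (!is.finite(w) || w == 0) return(Inf)
    sqrt(((n - 1) / n * w + b / n) / w)
  }, numeric(1), USE.NAMES = FALSE)
  names(r) <- dimnames(x)[[3L]]
  r
}

# spectral density at frequency zero, AR-fit estimator
.spectrum0 <- function(x) {
  v <- var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE), silent = TRUE)
  if (inherits(fit, "try-error")) return(v)
  if (!length(fit$ar)) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence z-scores
#'
#' Compares the mean of an early window of each chain with the mean of a
#' late window; under stationarity the standardized difference is
#' approximately standard normal. Variances are spectral-density estimates
#' at frequency zero (AR-model fit), so autocorrelation is accounted for.
#' `|z| < 2` is the conventional pass.
#'
#' @inheritParams gelman_rubin
#' @param first,last fractions of the chain used for the early and late
#'   windows (defaults 0.1 and 0.5).
#' @return matrix of z-scores, chains x parameters; `NA` where a window is
#'   degenerate (zero spectral variance).
#' @export
geweke <- function(draws, first = 0.1, last = 0.5) {
  stopifnot(first > 0, last > 0, first + last <= 1)
  x <- .as_draws_array(draws)
  m <- dim(x)[1L]; n <- dim(x)[2L]; np <- dim(x)[3L]
  n1 <- max(2L, floor(first * n)); n2 <- max(2L, floor(last * n))
  if (n1 + n2 > n) stop("chain too short for the requested windows")
  z <- matrix(NA_real_, m, np,
              dimnames = list(NULL, dimnames(x)[[3L]]))
  for (c in seq_len(m)) for (p in seq_len(np)) {
    xs <- x[c, , p]
    a <- xs[seq_len(n1)]; b <- xs[seq.int(n - n2 + 1L, n)]
    sv <- .spectrum0(a) / n1 + .spectrum0(b) / n2
    if (sv > 0) z[c, p] <- (mean(a) - mean(b)) / sqrt(sv)
  }
  z
}

#' Summarise convergence of a fitted posterior
#'
#' @param draws draws array or `diet_posterior`.
#' @param rhat_threshold maximum admissible rhat (default 1.05).
#' @param geweke_threshold maximum admissible |z| (default 2).
#' @param geweke_pass_fraction fraction of chain/parameter z-scores that
#'   must fall below the threshold (default 0.9; with many parameters a few
#'   |z| slightly above 2 are expected by chance).
#' @return object of class `convergence_report`: `rhat`, `geweke_z`,
#'   `passed`, and the thresholds used.
#' @export
convergence_report <- function(draws, rhat_threshold = 1.05,
                               geweke_threshold = 2,
                               geweke_pass_fraction = 0.9) {
  rhat <- gelman_rubin(draws)
  gz <- geweke(draws)
  frac_ok <- mean(abs(gz) < geweke_threshold, na.rm = TRUE)
  passed <- all(is.finite(rhat)) && all(rhat < rhat_threshold) &&
    !anyNA(gz) && frac_ok >= geweke_pass_fraction
  structure(list(rhat = rhat, geweke_z = gz, passed = passed,
                 rhat_threshold = rhat_threshold,
                 geweke_threshold = geweke_threshold,
                 geweke_pass_fraction = geweke_pass_fraction),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: %s (max rhat %.4f, %.0f%% of |geweke z| < %g)\n",
              if (x$passed) "PASSED" else "FAILED",
              max(x$rhat), 100 * mean(abs(x$geweke_z) < x$geweke_threshold,
                                      na.rm = TRUE),
              x$geweke_threshold))
  invisible(x)
}
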