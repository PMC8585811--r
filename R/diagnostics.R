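#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free PSRF over parallel chains:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \; W + B/n}{W}}}
#' with `W` the mean within-chain variance and `B` the between-chain variance
#' of the chain means (times n). Values near 1 indicate the chains have mixed.
#'
#' @param chains Numeric matrix, iterations x chains (>= 2 chains, >= 10
#'   iterations each), or a list of equal-length numeric vectors.
#' @return The PSRF (a single number); `NaN` with a warning when the
#'   within-chain variance is zero.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2L) stop("Gelman-Rubin needs at least 2 chains", call. = FALSE)
  if (n < 10L) stop("chains too short (need >= 10 draws)", call. = FALSE)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) {
    warning("zero within-chain variance; rhat undefined", call. = FALSE)
    return(NaN)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window of a chain with the mean of a late
#' window: \deqn{z = \frac{\bar x_{first} - \bar x_{last}}
#' {\sqrt{\widehat{se}^2_{first} + \widehat{se}^2_{last}}}}
#' with standard errors from the spectral density at frequency zero
#' (AR-model estimate), so autocorrelation is accounted for. For a stationary
#' chain z is approximately standard normal.
#'
#' @param x Numeric vector, one chain.
#' @param first,last Fractions of the chain used for the early and late
#'   windows (defaults 0.1 and 0.5); must not overlap.
#' @return The z-score; `NaN` with a warning for constant windows.
#' @export
geweke <- function(x, first = 0.1, last = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  if (first + last > 1) stop("first and last windows overlap", call. = FALSE)
  n1 <- floor(first * n); n2 <- floor(last * n)
  if (n1 < 5L || n2 < 5L) stop("chain too short for Geweke windows", call. = FALSE)
  w1 <- x[seq_len(n1)]
  w2 <- x[seq.int(n - n2 + 1L, n)]
  s1 <- spectrum0_ar(w1); s2 <- spectrum0_ar(w2)
  denom <- sqrt(s1 / n1 + s2 / n2)
  if (!is.finite(denom) || denom == 0) {
    warning("degenerate (constant) chain window; Geweke z undefined", call. = FALSE)
    return(NaN)
  }
  (mean(w1) - mean(w2)) / denom
}

# spectral density at frequency zero via an AIC-selected AR fit
spectrum0_ar <- function(x) {
  if (stats::var(x) == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(length(x) - 1L, 10 * log10(length(x)))),
    error = function(e) NULL
  )
  if (is.null(fit)) return(stats::var(x))
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Tidy the convergence diagnostics of a fit
#'
#' @param fit A `diet_fit`.
#' @return A tibble with one row per parameter: `parameter`, `rhat`, and the
#'   worst absolute Geweke z across chains.
#' @export
diagnostics_table <- function(fit) {
  stopifnot(inherits(fit, "diet_fit"))
  gw <- fit$diagnostics$geweke |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(max_abs_geweke_z = max(abs(.data$z)), .groups = "drop")
  dplyr::left_join(fit$diagnostics$rhat, gw, by = "parameter")
}
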