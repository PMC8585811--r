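#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mixing model
#'
#' One row per diet proportion (and residual multiplier, if sampled) with the
#' posterior median, 95% credible interval and convergence diagnostics —
#' broom-style.
#'
#' @param x A `diet_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate` (posterior median), `conf.low`,
#'   `conf.high`, `rhat`.
#' @export
tidy.diet_fit <- function(x, ...) {
  smry <- summarize_posterior(x)
  out <- tibble::tibble(
    term = paste0("p[", smry$source, "]"),
    estimate = smry$median,
    conf.low = smry$ci_lower,
    conf.high = smry$ci_upper
  )
  if (!is.null(x$xi_draws)) {
    xi <- purrr::map_dfr(seq_len(dim(x$xi_draws)[3]), function(j) {
      d <- as.vector(x$xi_draws[, , j])
      q <- stats::quantile(d, c(0.5, 0.025, 0.975), names = FALSE)
      tibble::tibble(term = paste0("xi[", dimnames(x$xi_draws)[[3]][j], "]"),
                     estimate = q[1], conf.low = q[2], conf.high = q[3])
    })
    out <- dplyr::bind_rows(out, xi)
  }
  dplyr::left_join(out, x$diagnostics$rhat,
                   by = c(term = "parameter")) |>
    dplyr::rename(rhat = "rhat")
}

#' Glance at a fitted mixing model
#'
#' @param x A `diet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_sources`, `n_consumers`, `n_chains`,
#'   `n_draws`, `max_rhat`, `converged`, `seed`.
#' @export
glance.diet_fit <- function(x, ...) {
  tibble::tibble(
    n_sources = length(x$sources),
    n_consumers = x$n_consumers,
    n_chains = dim(x$p_draws)[1],
    n_draws = dim(x$p_draws)[1] * dim(x$p_draws)[2],
    max_rhat = max(x$diagnostics$rhat$rhat, na.rm = TRUE),
    converged = x$diagnostics$pass,
    seed = x$config$seed
  )
}

#' Tidy a screening result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return The pairwise comparison tibble with the aggregation group of each
#'   pair's members attached.
#' @export
tidy.screen_result <- function(x, ...) {
  x$pairwise |>
    dplyr::left_join(x$plan, by = c(group_a = "source")) |>
    dplyr::rename(group_a_merged = "group") |>
    dplyr::left_join(x$plan, by = c(group_b = "source")) |>
    dplyr::rename(group_b_merged = "group")
}

#' Glance at a screening result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return One-row tibble: global pseudo-F, p, group counts before and after
#'   aggregation, NMDS stress.
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    pseudo_f = x$global$pseudo_f,
    p_value = x$global$p_value,
    df_among = x$global$df_among,
    n_sources = nrow(x$plan),
    n_groups = length(unique(x$plan$group)),
    stress = if (!is.null(x$nmds)) x$nmds$stress else NA_real_
  )
}
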