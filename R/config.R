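#' Run configuration
#'
#' Bundles every tunable of a pipeline run: MCMC settings, error-model choice,
#' Dirichlet prior, permutation-test settings and the calibration-coefficient
#' exclusion threshold. Defaults follow common mixing-model practice: an
#' uninformative Dirichlet(1, ..., 1) prior, multiplicative process x residual
#' error, 999 permutations with Bonferroni adjustment, and a CC exclusion
#' threshold of 3.
#'
#' @param n_chains Number of MCMC chains (>= 3 recommended; >= 2 required).
#' @param n_iter Iterations per chain (post adaptation, pre thinning).
#' @param n_burn Burn-in iterations discarded per chain; must be < `n_iter`.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; recorded in all outputs.
#' @param error_model `"process_x_residual"` (per-tracer multiplicative
#'   residual factor xi sampled) or `"process_only"` (xi fixed at 1).
#' @param prior_alpha Dirichlet concentration; scalar (recycled over sources)
#'   or length-K vector, all > 0.
#' @param n_permutations Permutations for PERMANOVA tests.
#' @param distance_metric `"bray_curtis"` or `"euclidean"`; `NULL` picks the
#'   suite default (Bray-Curtis for FA compositions, Euclidean for SI pairs).
#' @param p_adjust Multiple-testing method for pairwise comparisons
#'   (default `"bonferroni"`; any [stats::p.adjust()] method).
#' @param fa_cc_exclusion_threshold Drop FA tracers whose CC exceeds this.
#' @param alpha Significance level used when building the aggregation plan.
#' @return A `run_config` list.
#' @export
run_config <- function(n_chains = 3L,
                       n_iter = 100000L,
                       n_burn = 50000L,
                       thin = 50L,
                       seed = 1L,
                       error_model = c("process_x_residual", "process_only"),
                       prior_alpha = 1,
                       n_permutations = 999L,
                       distance_metric = NULL,
                       p_adjust = "bonferroni",
                       fa_cc_exclusion_threshold = 3,
                       alpha = 0.05) {
  error_model <- match.arg(error_model)
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  n_burn <- as.integer(n_burn); thin <- as.integer(thin)
  if (n_chains < 2L) stop("need at least 2 chains", call. = FALSE)
  if (n_iter <= n_burn) stop("n_iter must exceed n_burn", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  if (any(prior_alpha <= 0)) stop("prior_alpha must be positive", call. = FALSE)
  if (!is.null(distance_metric)) {
    distance_metric <- match.arg(distance_metric, c("bray_curtis", "euclidean"))
  }
  structure(
    list(
      n_chains = n_chains, n_iter = n_iter, n_burn = n_burn, thin = thin,
      seed = as.integer(seed), error_model = error_model,
      prior_alpha = prior_alpha, n_permutations = as.integer(n_permutations),
      distance_metric = distance_metric, p_adjust = p_adjust,
      fa_cc_exclusion_threshold = fa_cc_exclusion_threshold, alpha = alpha
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Flat keys map one-to-one onto [run_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# short deterministic run identifier from config + seed
run_id <- function(config) {
  key <- paste(unlist(config), collapse = "|")
  # 31-bit polynomial rolling hash; stable across sessions
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147483647
  sprintf("run-%08x", as.integer(h))
}
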