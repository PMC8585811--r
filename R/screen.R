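#' Pairwise distance matrix for tracer replicates
#'
#' Computes the distance matrix used by the distinguishability tests.
#' Defaults follow compositional practice: Bray-Curtis for FA profiles (data
#' on the simplex), Euclidean for low-dimensional SI data.
#'
#' @param samples Data frame with a `source` (or `group`) column plus numeric
#'   tracer columns, one row per replicate.
#' @param metric `"bray_curtis"` or `"euclidean"`; `NULL` picks by column
#'   content via `suite`, falling back to Euclidean.
#' @param suite Optional [tracer_suite()]; used to pick columns and default
#'   metric.
#' @return A `dist` object with attributes `groups` (factor of group labels)
#'   and `metric`.
#' @export
tracer_distance <- function(samples, metric = NULL, suite = NULL) {
  samples <- tibble::as_tibble(samples)
  gcol <- intersect(c("source", "group"), names(samples))[1]
  if (is.na(gcol)) stop_schema("samples need a 'source' or 'group' column")
  tracers <- if (!is.null(suite)) suite$tracers else setdiff(names(samples), c("source", "group", "id"))
  vals <- as.matrix(samples[tracers])
  if (anyNA(vals) || !is.numeric(vals)) stop("NaN or non-numeric tracer values", call. = FALSE)
  if (nrow(vals) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(metric)) {
    metric <- if (!is.null(suite) && is_fa(suite)) "bray_curtis" else "euclidean"
  }
  metric <- match.arg(metric, c("bray_curtis", "euclidean"))
  d <- vegan::vegdist(vals, method = if (metric == "bray_curtis") "bray" else "euclidean")
  attr(d, "groups") <- factor(samples[[gcol]], levels = unique(samples[[gcol]]))
  attr(d, "metric") <- metric
  d
}

# sums of squares from a distance matrix via the Huygens decomposition
permanova_ss <- function(dmat2, groups) {
  n <- nrow(dmat2)
  ss_total <- sum(dmat2[upper.tri(dmat2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- dmat2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

permanova_f <- function(dmat2, groups) {
  g <- nlevels(groups)
  n <- nrow(dmat2)
  ss <- permanova_ss(dmat2, groups)
  (ss["among"] / (g - 1)) / (ss["within"] / (n - g))
}

#' Permutational multivariate analysis of variance
#'
#' Distance-based one-way PERMANOVA: partitions the total sum of squared
#' distances (Huygens decomposition, \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / N})
#' into among- and within-group components and forms the pseudo-F
#' \deqn{F = \frac{SS_{among}/(g-1)}{SS_{within}/(N-g)}.}
#' The p-value is permutational with the observed statistic counted among the
#' permutations: \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}.
#'
#' @param d A `dist` from [tracer_distance()] (or any `dist`).
#' @param groups Group labels, one per sample; taken from `attr(d, "groups")`
#'   when omitted. Every group needs at least 2 members.
#' @param n_permutations Number of random label permutations (default 999).
#' @param seed Integer seed making the permutation stream reproducible.
#' @return A one-row tibble: `df_among`, `df_within`, `ss_among`, `ss_within`,
#'   `pseudo_f`, `p_value`, `n_permutations`.
#' @export
permanova <- function(d, groups = NULL, n_permutations = 999L, seed = 1L) {
  if (is.null(groups)) groups <- attr(d, "groups")
  groups <- droplevels(as.factor(groups))
  dmat2 <- as.matrix(d)^2
  n <- nrow(dmat2)
  if (length(groups) != n) stop_schema("group labels do not match distance matrix size")
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 members (within-group SS undefined otherwise)",
         call. = FALSE)
  }
  f_obs <- permanova_f(dmat2, groups)
  exceed <- 0L
  if (n_permutations > 0L) {
    perm_f <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        permanova_f(dmat2, groups[sample.int(n)])
      }, numeric(1))
    })
    # ties and Inf compare with >=; NaN (degenerate permutations) never exceed
    exceed <- sum(perm_f >= f_obs, na.rm = TRUE)
  }
  ss <- permanova_ss(dmat2, groups)
  tibble::tibble(
    df_among = nlevels(groups) - 1L,
    df_within = n - nlevels(groups),
    ss_among = unname(ss["among"]),
    ss_within = unname(ss["within"]),
    pseudo_f = unname(f_obs),
    p_value = (1 + exceed) / (1 + n_permutations),
    n_permutations = as.integer(n_permutations)
  )
}

#' Pairwise PERMANOVA comparisons
#'
#' Runs [permanova()] on the sub-matrix of every pair of groups and adjusts
#' the raw p-values across pairs (Bonferroni by default, matching the
#' pairwise multilevel comparison convention; adjusted p capped at 1).
#'
#' @inheritParams permanova
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return A tibble with one row per pair: `group_a`, `group_b`, `pseudo_f`,
#'   `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups = NULL, n_permutations = 999L,
                               p_adjust = "bonferroni", seed = 1L) {
  if (is.null(groups)) groups <- attr(d, "groups")
  groups <- droplevels(as.factor(groups))
  dmat <- as.matrix(d)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    idx <- which(groups %in% c(a, b))
    sub <- stats::as.dist(dmat[idx, idx])
    res <- permanova(sub, droplevels(groups[idx]), n_permutations,
                     seed = seed + i)
    tibble::tibble(group_a = a, group_b = b,
                   pseudo_f = res$pseudo_f, p_value = res$p_value)
  })
  rows$p_adjusted <- pmin(stats::p.adjust(rows$p_value, method = p_adjust), 1)
  rows
}

#' Non-metric multidimensional scaling of sources
#'
#' Rank-based ordination minimizing Kruskal stress, used to inspect group
#' separation visually before the formal tests. Best configuration over
#' `n_starts` random starts.
#'
#' @inheritParams permanova
#' @param k Embedding dimension (default 2).
#' @param n_starts Random starts (default 20).
#' @return A list of class `nmds_result`: `coordinates` (tibble with `group`
#'   and axis columns, centered), `stress` (Kruskal stress-1, in \[0,1\]),
#'   `converged`.
#' @export
nmds_screen <- function(d, k = 2, n_starts = 20, seed = 1L) {
  dmat <- as.matrix(d)
  if (all(dmat == 0)) stop("degenerate all-zero distance matrix", call. = FALSE)
  if (nrow(dmat) < 4L) stop("NMDS needs at least 4 samples", call. = FALSE)
  groups <- attr(d, "groups")
  fit <- withr::with_seed(seed, {
    withCallingHandlers(
      vegan::metaMDS(stats::as.dist(dmat), k = k, trymax = n_starts,
                     trace = 0, autotransform = FALSE, wascores = FALSE),
      # near-zero stress just means the configuration embeds exactly
      warning = function(w) {
        if (grepl("stress is .nearly. zero", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  coords <- scale(fit$points, center = TRUE, scale = FALSE)
  tb <- tibble::as_tibble(coords, .name_repair = ~ paste0("axis", seq_len(k)))
  if (!is.null(groups)) tb <- dplyr::bind_cols(tibble::tibble(group = as.character(groups)), tb)
  structure(
    list(coordinates = tb, stress = fit$stress, converged = fit$converged > 0),
    class = "nmds_result"
  )
}

#' Build a source-aggregation plan from pairwise tests
#'
#' Sources whose pairwise comparison is non-significant (adjusted p >= alpha)
#' are linked; connected components of that non-difference graph become
#' combined groups, so mutually indistinguishable sets merge and intransitive
#' triples resolve deterministically. Combined labels abbreviate and
#' concatenate member names (e.g. "Pa_Ea" for *P. antarcticum* +
#' *E. antarctica*).
#'
#' @param pairwise Tibble from [pairwise_permanova()].
#' @param alpha Significance level (default 0.05); pairs with adjusted
#'   p >= `alpha` are treated as indistinguishable.
#' @return A tibble of class `aggregation_plan`: `source`, `group` (combined
#'   label). Every source appears exactly once.
#' @export
build_aggregation_plan <- function(pairwise, alpha = 0.05) {
  sources <- unique(c(pairwise$group_a, pairwise$group_b))
  comp <- stats::setNames(seq_along(sources), sources)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  link <- pairwise$p_adjusted >= alpha
  for (r in which(link)) {
    a <- find(match(pairwise$group_a[r], sources))
    b <- find(match(pairwise$group_b[r], sources))
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_along(sources), find, integer(1))
  label_of <- function(members) {
    if (length(members) == 1L) return(members)
    paste(abbreviate_source(members), collapse = "_")
  }
  labels <- vapply(split(sources, roots), label_of, character(1))
  out <- tibble::tibble(
    source = sources,
    group = unname(labels[as.character(roots)])
  )
  class(out) <- c("aggregation_plan", class(out))
  out
}

# "P. antarcticum" -> "Pa", "E. superba" -> "Es", single-word names -> first 2 chars
abbreviate_source <- function(x) {
  vapply(x, function(nm) {
    parts <- strsplit(gsub("\\.", "", nm), "[ _]+")[[1]]
    if (length(parts) >= 2) {
      paste0(toupper(substr(parts[1], 1, 1)), tolower(substr(parts[2], 1, 1)))
    } else {
      paste0(toupper(substr(nm, 1, 1)), tolower(substr(nm, 2, 2)))
    }
  }, character(1))
}

#' Combine sources according to an aggregation plan
#'
#' Merges each planned group by pooling the member samples: n-weighted pooled
#' mean, and pooled SD that includes the spread between member means,
#' \deqn{s^2 = \frac{\sum_k [(n_k-1) s_k^2 + n_k (m_k - \bar m)^2]}{(\sum_k n_k) - 1}.}
#' Sample sizes are summed; concentrations, if present, are n-weighted means.
#'
#' @param src A `source_tbl`.
#' @param plan An `aggregation_plan` (or tibble with `source`,`group`).
#' @return A new `source_tbl` with one entry per combined group.
#' @export
combine_sources <- function(src, plan) {
  suite <- attr(src, "suite")
  sources <- attr(src, "sources")
  unknown <- setdiff(plan$source, sources)
  if (length(unknown)) stop_schema("plan references unknown source(s): ",
                                   paste(unknown, collapse = ", "))
  if (!setequal(plan$source, sources) || anyDuplicated(plan$source)) {
    stop_schema("plan must partition the source set")
  }
  merged <- src |>
    dplyr::left_join(plan, by = "source") |>
    dplyr::group_by(.data$group, .data$tracer) |>
    dplyr::summarise(
      new_mean = sum(.data$n * .data$mean) / sum(.data$n),
      sd = sqrt(pmax(0,
        (sum((.data$n - 1) * .data$sd^2 + .data$n * (.data$mean - new_mean)^2)) /
          (sum(.data$n) - 1))),
      conc = if ("conc" %in% names(src)) sum(.data$n * .data$conc) / sum(.data$n) else NA_real_,
      n = sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::rename(source = "group", mean = "new_mean")
  if (!"conc" %in% names(src)) merged$conc <- NULL
  group_order <- unique(plan$group[match(sources, plan$source)])
  merged <- merged[order(match(merged$source, group_order),
                         match(merged$tracer, suite$tracers)), ]
  if (is_fa(suite)) {
    # pooled FA means of simplex profiles stay on the simplex (convexity)
    merged <- merged |>
      dplyr::group_by(.data$source) |>
      dplyr::mutate(mean = .data$mean / sum(.data$mean)) |>
      dplyr::ungroup()
  }
  source_table(merged, suite, .allow_single = TRUE)
}

#' Screen sources for distinguishability
#'
#' One-stop screening: global PERMANOVA, pairwise comparisons, NMDS
#' coordinates, and the resulting aggregation plan.
#'
#' @param replicates Replicate-level source data (see
#'   [read_source_replicates()]).
#' @param suite A [tracer_suite()].
#' @param config A [run_config()]; supplies metric, permutation count,
#'   adjustment method, alpha and seed.
#' @return A list of class `screen_result`: `global` (one-row tibble),
#'   `pairwise`, `nmds`, `plan`.
#' @export
screen_sources <- function(replicates, suite, config = run_config()) {
  d <- tracer_distance(replicates, metric = config$distance_metric, suite = suite)
  glob <- permanova(d, n_permutations = config$n_permutations, seed = config$seed)
  pw <- pairwise_permanova(d, n_permutations = config$n_permutations,
                           p_adjust = config$p_adjust, seed = config$seed)
  nm <- tryCatch(nmds_screen(d, seed = config$seed),
                 error = function(e) NULL)
  plan <- build_aggregation_plan(pw, alpha = config$alpha)
  structure(list(global = glob, pairwise = pw, nmds = nm, plan = plan),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat(sprintf("  global pseudo-F(%d) = %.2f, p = %.3f\n",
              x$global$df_among, x$global$pseudo_f, x$global$p_value))
  n_merged <- length(unique(x$plan$group))
  cat(sprintf("  %d sources -> %d groups after aggregation\n",
              nrow(x$plan), n_merged))
  invisible(x)
}
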