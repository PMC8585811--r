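#' Default fatty-acid tracer names
#'
#' Twelve dietary and extended-dietary fatty acids commonly retained for
#' marine-mammal diet work after calibration-coefficient screening.
#'
#' @return Character vector of 12 FA names.
#' @export
default_fa_names <- function() {
  c("14:0", "16:0", "16:1n-7", "18:1n-9", "18:1n-7", "18:2n-6",
    "18:4n-3", "20:1n-9", "20:5n-3", "22:1n-11", "22:5n-3", "22:6n-3")
}

#' Define a simulation scenario
#'
#' A scenario holds everything needed to generate one synthetic predator
#' group: the tracer suite, the source layout, the true diet composition
#' `true_p` (the simulation truth used only by the generator and by recovery
#' tests), the trophic-modifier truth and the error truth.
#'
#' Defaults echo a pack-ice-seal study design: SI scenarios carry 2 isotope
#' tracers and 4 sources; FA scenarios carry 12 FA tracers and 4-5 sources;
#' a dominant source contributes 60-90% of the diet.
#'
#' @param name Scenario label.
#' @param kind `"SI"` or `"FA"`.
#' @param k Number of sources.
#' @param true_p True diet proportions (length `k`, summing to 1).
#' @param n_consumers Number of consumers to generate.
#' @param source_sd Per-tracer source scatter: SD in per mil for SI, logistic
#'   jitter scale for FA replicates.
#' @param n_replicates Replicate prey samples per source (for screening).
#' @param confound_pair Integer pair of source indices given identical means,
#'   to exercise aggregation (`NULL` for none).
#' @param xi True per-tracer residual multipliers (default 1).
#' @param seed Integer seed.
#' @return A `scenario` list.
#' @export
scenario <- function(name, kind = c("SI", "FA"), k = 4,
                     true_p = NULL, n_consumers = 21,
                     source_sd = if (kind[1] == "SI") 0.5 else 0.15,
                     n_replicates = 10, confound_pair = NULL,
                     xi = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(true_p)) {
    true_p <- c(0.85, rep(0.15 / (k - 1), k - 1))
  }
  if (length(true_p) != k || abs(sum(true_p) - 1) > 1e-9 || any(true_p < 0)) {
    stop("true_p must be a length-k simplex vector", call. = FALSE)
  }
  if (!is.null(confound_pair) && (length(confound_pair) != 2 ||
                                  any(confound_pair > k))) {
    stop("confound_pair must index two sources", call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, k = k, true_p = true_p,
         n_consumers = n_consumers, source_sd = source_sd,
         n_replicates = n_replicates, confound_pair = confound_pair,
         xi = xi, seed = as.integer(seed)),
    class = "scenario"
  )
}

#' Generate stable-isotope sources
#'
#' Draws K prey sources with distinct (d13C, d15N) means spread over a
#' realistic Antarctic food-web envelope (d13C around -27 to -21 per mil,
#' d15N around 3 to 12 per mil, spanning krill to fish trophic levels) and
#' Gaussian replicate scatter. A `confound_pair` in the scenario gets
#' identical means, emulating isotopically indistinguishable prey.
#'
#' @param scn An SI [scenario()].
#' @return A list: `source` (a `source_tbl` with means/SDs/n summarized from
#'   the replicates), `replicates` (tibble for screening), `suite`.
#' @export
make_si_sources <- function(scn) {
  stopifnot(inherits(scn, "scenario"), scn$kind == "SI")
  suite <- tracer_suite("SI", c("d13C", "d15N"))
  withr::with_seed(scn$seed, {
    k <- scn$k
    # spread sources over the envelope in both tracers, shuffling the d15N
    # levels so the source polygon has area (collinear means would collapse
    # the 2-tracer mixing space to one dimension)
    mu_c <- seq(-26.5, -21.5, length.out = k) + stats::rnorm(k, 0, 0.3)
    lev_n <- seq(3.5, 11.5, length.out = k)
    perm <- sample.int(k)
    while (k > 2 && (all(diff(perm) > 0) || all(diff(perm) < 0))) {
      perm <- sample.int(k)
    }
    mu_n <- lev_n[perm] + stats::rnorm(k, 0, 0.3)
    if (!is.null(scn$confound_pair)) {
      a <- scn$confound_pair[1]; b <- scn$confound_pair[2]
      mu_c[b] <- mu_c[a]; mu_n[b] <- mu_n[a]
    }
    names_k <- paste0("source", seq_len(k))
    reps <- purrr::map_dfr(seq_len(k), function(i) {
      tibble::tibble(
        source = names_k[i],
        d13C = stats::rnorm(scn$n_replicates, mu_c[i], scn$source_sd),
        d15N = stats::rnorm(scn$n_replicates, mu_n[i], scn$source_sd)
      )
    })
    src <- summarize_replicates(reps, suite)
    list(source = src, replicates = reps, suite = suite)
  })
}

#' Generate fatty-acid sources
#'
#' Draws K simplex mean profiles from a Dirichlet distribution and replicate
#' profiles by logistic-normal jitter around each mean (perturb log
#' proportions with Gaussian noise, then renormalize), so replicates stay on
#' the simplex.
#'
#' @param scn An FA [scenario()].
#' @param fa_names Tracer names (default [default_fa_names()]).
#' @param concentration Dirichlet concentration for the mean profiles
#'   (larger = more even profiles).
#' @return As [make_si_sources()].
#' @export
make_fa_sources <- function(scn, fa_names = default_fa_names(),
                            concentration = 6) {
  stopifnot(inherits(scn, "scenario"), scn$kind == "FA")
  j <- length(fa_names)
  if (j < 3L) stop("FA scenarios need at least 3 tracers", call. = FALSE)
  suite <- tracer_suite("FA", fa_names)
  withr::with_seed(scn$seed, {
    k <- scn$k
    mu <- t(vapply(seq_len(k), function(i) rdirichlet1(rep(concentration, j)),
                   numeric(j)))
    if (!is.null(scn$confound_pair)) {
      mu[scn$confound_pair[2], ] <- mu[scn$confound_pair[1], ]
    }
    names_k <- paste0("source", seq_len(k))
    reps <- purrr::map_dfr(seq_len(k), function(i) {
      prof <- t(vapply(seq_len(scn$n_replicates), function(r) {
        z <- log(mu[i, ]) + stats::rnorm(j, 0, scn$source_sd)
        exp(z) / sum(exp(z))
      }, numeric(j)))
      out <- tibble::as_tibble(as.data.frame(prof))
      names(out) <- fa_names
      dplyr::bind_cols(tibble::tibble(source = names_k[i]), out)
    })
    src <- summarize_replicates(reps, suite, normalize_means = TRUE)
    list(source = src, replicates = reps, suite = suite)
  })
}

summarize_replicates <- function(reps, suite, normalize_means = FALSE) {
  long <- reps |>
    tidyr::pivot_longer(dplyr::all_of(suite$tracers),
                        names_to = "tracer", values_to = "value") |>
    dplyr::group_by(.data$source, .data$tracer) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  if (normalize_means) {
    long <- long |>
      dplyr::group_by(.data$source) |>
      dplyr::mutate(mean = .data$mean / sum(.data$mean)) |>
      dplyr::ungroup()
  }
  long$source <- factor(long$source, levels = unique(reps$source))
  long <- dplyr::arrange(long, .data$source, match(.data$tracer, suite$tracers))
  long$source <- as.character(long$source)
  source_table(long, suite)
}

# one Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate consumers from the mixing model
#'
#' Draws consumer tracer values from exactly the likelihood the mixing model
#' fits: \eqn{x_{ij} \sim N(\mu_j(p^*), \omega_j^2(p^*, \xi^*))} using the
#' same [mixture_mean()]/[mixture_variance()] implementation (no duplicated
#' formulas to drift apart). FA consumers are renormalized back onto the
#' simplex after the Gaussian draw; any negative draws are truncated at zero
#' first and the truncation count is reported as an attribute.
#'
#' @param scn A [scenario()].
#' @param src A model-ready `source_tbl` (CC-transferred for FA).
#' @param modifier A [trophic_modifier()].
#' @return A `consumer_tbl` with `scn$n_consumers` rows; attributes `true_p`,
#'   `truncated` (count of zero-truncated FA cells).
#' @export
generate_consumers <- function(scn, src, modifier) {
  suite <- attr(src, "suite")
  mu <- mixture_mean(scn$true_p, src, modifier)
  J <- length(mu)
  xi <- rep(scn$xi, length.out = J)
  v <- mixture_variance(scn$true_p, src, modifier, xi = xi)
  withr::with_seed(scn$seed + 1L, {
    X <- matrix(stats::rnorm(scn$n_consumers * J, mean = rep(mu, each = scn$n_consumers),
                             sd = rep(sqrt(v), each = scn$n_consumers)),
                nrow = scn$n_consumers, ncol = J)
    truncated <- 0L
    if (is_fa(suite)) {
      truncated <- sum(X < 0)
      X[X < 0] <- 0
      if (any(rowSums(X) <= 0)) {
        stop("infeasible FA scenario: a consumer lost all mass to truncation",
             call. = FALSE)
      }
      X <- X / rowSums(X)
    }
    df <- tibble::as_tibble(as.data.frame(X))
    names(df) <- suite$tracers
    df$id <- sprintf("%s_%02d", scn$name, seq_len(scn$n_consumers))
    out <- suppressWarnings(consumer_table(df, suite))
    attr(out, "true_p") <- scn$true_p
    attr(out, "truncated") <- truncated
    out
  })
}

#' Write a complete synthetic study bundle
#'
#' Generates and writes a runnable input set emulating a three-predator
#' pack-ice-seal study: three consumer groups (n = 21, 18 and 13), each with
#' an FA variant (12 tracers, 4-5 sources, CC table including one coefficient
#' above 3 to exercise exclusion) and an SI variant (2 tracers, 4-5 sources,
#' one deliberately confounded source pair in the first group, discrimination
#' table 2.2 +/- 0.7 and 3.5 +/- 0.6 per mil). Dominant-source truths follow
#' krill/fish-dominated diets (0.84/0.91, 0.66/0.72, 0.66/0.63).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return Invisibly, a tibble manifest of the files written, with the truth
#'   attached as attribute `truths`.
#' @export
make_study_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- study_scenarios(seed)
  files <- list()
  truths <- list()
  for (g in groups) {
    made <- if (g$scn$kind == "SI") make_si_sources(g$scn) else make_fa_sources(g$scn)
    src <- made$source
    if (g$scn$kind == "FA") {
      cc <- g$cc
      readr::write_csv(tibble::tibble(tracer = names(cc), cc = unname(cc)),
                       file.path(dir, paste0(g$tag, "_cc.csv")))
      files[[paste0(g$tag, "_cc")]] <- file.path(dir, paste0(g$tag, "_cc.csv"))
      sel <- select_fa_tracers(names(cc), cc, threshold = 3)
      kept <- sel$tracer[sel$keep]
      suite_kept <- tracer_suite("FA", kept)
      src_kept <- restrict_sources(src, suite_kept)
      trans <- apply_calibration_coefficients(src_kept, cc[kept])
      cons <- generate_consumers(g$scn, trans$source, trans$modifier)
      src_out <- src   # raw (pre-CC) sources ship in the bundle
      reps_out <- made$replicates
    } else {
      tdf <- tibble::tibble(tracer = c("d13C", "d15N"),
                            delta_mean = c(2.2, 3.5), delta_sd = c(0.7, 0.6))
      readr::write_csv(tdf, file.path(dir, paste0(g$tag, "_discrimination.csv")))
      files[[paste0(g$tag, "_tdf")]] <- file.path(dir, paste0(g$tag, "_discrimination.csv"))
      att <- attach_discrimination(src, tdf)
      cons <- generate_consumers(g$scn, att$source, att$modifier)
      src_out <- src
      reps_out <- made$replicates
    }
    cpath <- file.path(dir, paste0(g$tag, "_consumers.csv"))
    spath <- file.path(dir, paste0(g$tag, "_sources.csv"))
    rpath <- file.path(dir, paste0(g$tag, "_source_replicates.csv"))
    write_consumer_table(cons, cpath)
    write_source_table(src_out, spath)
    readr::write_csv(reps_out, rpath)
    files[[paste0(g$tag, "_consumers")]] <- cpath
    files[[paste0(g$tag, "_sources")]] <- spath
    files[[paste0(g$tag, "_replicates")]] <- rpath
    truths[[g$tag]] <- g$scn$true_p
  }
  manifest <- tibble::tibble(key = names(files), path = unlist(files))
  attr(manifest, "truths") <- truths
  invisible(manifest)
}

#' Restrict a source table to a tracer subset
#'
#' Keeps only the tracers of `suite_kept`; FA mean profiles are renormalized
#' to the reduced simplex.
#'
#' @param src A `source_tbl`.
#' @param suite_kept A [tracer_suite()] whose tracers are a subset of the
#'   current ones.
#' @return A `source_tbl` on the reduced suite.
#' @export
restrict_sources <- function(src, suite_kept) {
  suite <- attr(src, "suite")
  sub <- src[src$tracer %in% suite_kept$tracers, ]
  if (is_fa(suite_kept)) {
    sub <- sub |>
      dplyr::group_by(.data$source) |>
      dplyr::mutate(mean = .data$mean / sum(.data$mean)) |>
      dplyr::ungroup()
  }
  source_table(sub, suite_kept)
}

# the three predator-group scenarios the bundle and the recovery tests share:
# dominant-source truths follow krill- and fish-dominated diets
study_scenarios <- function(seed = 1L) {
  fa_cc <- function(s) {
    withr::with_seed(s, {
      cc <- exp(stats::rnorm(12, 0, 0.3))
      cc <- pmin(pmax(cc, 0.4), 2.5)
      cc[11] <- 3.5   # one coefficient above the exclusion threshold
      stats::setNames(cc, default_fa_names())
    })
  }
  list(
    list(tag = "groupA_fa",
         scn = scenario("groupA_fa", "FA", k = 4,
                        true_p = c(0.84, 0.012, 0.109, 0.039),
                        n_consumers = 21, seed = seed + 11L),
         cc = fa_cc(seed + 101L)),
    list(tag = "groupA_si",
         scn = scenario("groupA_si", "SI", k = 4,
                        true_p = c(0.91, 0.041, 0.025, 0.024),
                        n_consumers = 21, confound_pair = c(3L, 4L),
                        seed = seed + 12L)),
    list(tag = "groupB_fa",
         scn = scenario("groupB_fa", "FA", k = 5,
                        true_p = c(0.076, 0.008, 0.657, 0.017, 0.242),
                        n_consumers = 18, seed = seed + 13L),
         cc = fa_cc(seed + 102L)),
    list(tag = "groupB_si",
         scn = scenario("groupB_si", "SI", k = 3,
                        true_p = c(0.04, 0.72, 0.24),
                        n_consumers = 18, seed = seed + 14L)),
    list(tag = "groupC_fa",
         scn = scenario("groupC_fa", "FA", k = 5,
                        true_p = c(0.194, 0.663, 0.111, 0.027, 0.005),
                        n_consumers = 13, seed = seed + 15L),
         cc = fa_cc(seed + 103L)),
    list(tag = "groupC_si",
         scn = scenario("groupC_si", "SI", k = 5,
                        true_p = c(0.063, 0.632, 0.077, 0.083, 0.145),
                        n_consumers = 13, seed = seed + 16L))
  )
}
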