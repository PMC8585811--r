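#' Delta notation from isotope ratios
#'
#' Converts heavy/light isotope abundance ratios to delta notation in per mil:
#' \deqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000}
#' with the international standards V-PDB for carbon and atmospheric N2 for
#' nitrogen as the reference ratio.
#'
#' @param r_sample,r_standard Strictly positive ratios of the heavier to the
#'   lighter isotope; vectors are recycled elementwise.
#' @return Delta values in per mil.
#' @examples
#' delta_from_ratio(0.0112372, 0.0112372) # 0 permil: sample equals standard
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("isotope ratios must be finite and strictly positive", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Whole-whisker mean isotope value
#'
#' Whiskers are analysed in consecutive 2 mm sections; diet estimation uses
#' one mean isotope value per individual, the unweighted arithmetic mean over
#' all sections.
#'
#' @param sections A data frame with one row per section: an `id` column
#'   identifying the individual plus one numeric column per tracer.
#' @param tracers Character vector of tracer column names
#'   (default `c("d13C", "d15N")`).
#' @return A tibble with one row per individual: `id` plus the per-tracer
#'   means.
#' @export
mean_consumer_isotope <- function(sections, tracers = c("d13C", "d15N")) {
  sections <- tibble::as_tibble(sections)
  if (nrow(sections) == 0L) stop("no whisker sections supplied", call. = FALSE)
  miss <- setdiff(c("id", tracers), names(sections))
  if (length(miss)) stop_schema("sections are missing column(s): ",
                                paste(miss, collapse = ", "))
  sections |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(tracers), mean), .groups = "drop")
}

#' Normalize a fatty-acid profile to proportions of total FA
#'
#' Converts raw FA amounts (concentrations, peak areas, percentages) to
#' proportions of the total, the scale on which all FA work in this package
#' happens. Idempotent on already-normalized input.
#'
#' @param raw_amounts Nonnegative numeric vector (or matrix with one profile
#'   per row) with at least one positive entry per profile.
#' @return Object of the same shape with each profile summing to 1.
#' @examples
#' normalize_fa_profile(c(2, 3, 5))
#' @export
normalize_fa_profile <- function(raw_amounts) {
  if (is.matrix(raw_amounts)) {
    if (any(raw_amounts < 0) || anyNA(raw_amounts)) {
      stop("FA amounts must be nonnegative and complete", call. = FALSE)
    }
    rs <- rowSums(raw_amounts)
    if (any(rs <= 0)) stop("all-zero FA profile cannot be normalized", call. = FALSE)
    return(raw_amounts / rs)
  }
  if (any(raw_amounts < 0) || anyNA(raw_amounts)) {
    stop("FA amounts must be nonnegative and complete", call. = FALSE)
  }
  s <- sum(raw_amounts)
  if (s <= 0) stop("all-zero FA profile cannot be normalized", call. = FALSE)
  raw_amounts / s
}

#' Select fatty-acid tracers for diet estimation
#'
#' Starting from the dietary and extended-dietary candidate FAs, drops those
#' whose calibration coefficient exceeds `threshold` (default 3): a high CC
#' indicates predator metabolism or preferential accrual dominates over diet,
#' so the tracer carries little dietary signal.
#'
#' @param candidates Character vector of candidate FA names.
#' @param cc Named numeric vector (or tibble with `tracer`,`cc` columns) of
#'   calibration coefficients covering every candidate.
#' @param threshold Exclusion threshold (default 3; a candidate is kept when
#'   CC <= threshold).
#' @param exclude Optional character vector of candidates to drop regardless
#'   (reason `user_excluded`).
#' @return A tibble of class `tracer_selection` with columns `tracer`, `cc`,
#'   `keep`, `reason` (one of `kept`, `cc_above_threshold`, `user_excluded`).
#' @export
select_fa_tracers <- function(candidates, cc, threshold = 3, exclude = character()) {
  if (is.data.frame(cc)) cc <- stats::setNames(cc$cc, cc$tracer)
  miss <- setdiff(candidates, names(cc))
  if (length(miss)) stop_schema("no calibration coefficient for: ",
                                paste(miss, collapse = ", "))
  cc <- cc[candidates]
  reason <- dplyr::case_when(
    candidates %in% exclude ~ "user_excluded",
    cc > threshold ~ "cc_above_threshold",
    TRUE ~ "kept"
  )
  out <- tibble::tibble(tracer = candidates, cc = unname(cc),
                        keep = reason == "kept", reason = reason)
  if (sum(out$keep) < 2L) {
    stop("fewer than 2 tracers survive selection; relax the threshold or the candidate set",
         call. = FALSE)
  }
  class(out) <- c("tracer_selection", class(out))
  out
}

#' Transfer prey FA profiles into predator space
#'
#' Multiplies each source mean profile by the per-FA calibration coefficients
#' and renormalizes to the simplex:
#' \deqn{\mu'_{kj} = \mu_{kj} CC_j / \sum_l \mu_{kl} CC_l.}
#' Because a Gaussian-likelihood mixing model treats trophic modification as
#' additive, this multiplicative step happens before fitting and the returned
#' modifier carries zero additive discrimination.
#'
#' SDs are, by default, scaled by the same per-source linear factor
#' \eqn{CC_j / \sum_l \mu_{kl} CC_l} applied to the means (a first-order
#' treatment holding the renormalization denominator at its mean), which keeps
#' per-tracer coefficients of variation stable; `scale_sd = FALSE` leaves SDs
#' untouched.
#'
#' @param src An FA `source_tbl`.
#' @param cc Named numeric vector (or `tracer`,`cc` tibble) of positive
#'   calibration coefficients, one per suite tracer.
#' @param scale_sd Scale SDs by the same factor as means (default `TRUE`).
#' @return A list with `source` (the transformed `source_tbl`, rows re-summing
#'   to 1) and `modifier` (a [trophic_modifier()] with the CCs recorded and
#'   discrimination fixed at zero).
#' @export
apply_calibration_coefficients <- function(src, cc, scale_sd = TRUE) {
  suite <- attr(src, "suite")
  if (!is_fa(suite)) stop("calibration coefficients apply to FA suites only", call. = FALSE)
  if (is.data.frame(cc)) cc <- stats::setNames(cc$cc, cc$tracer)
  if (is.null(names(cc))) names(cc) <- suite$tracers
  miss <- setdiff(suite$tracers, names(cc))
  if (length(miss)) stop_schema("no calibration coefficient for: ",
                                paste(miss, collapse = ", "))
  cc <- cc[suite$tracers]
  if (any(!is.finite(cc)) || any(cc <= 0)) {
    stop("calibration coefficients must be positive", call. = FALSE)
  }
  m <- source_matrices(src)
  raw <- sweep(m$mean, 2, cc, `*`)
  denom <- rowSums(raw)               # sum_l mu_kl * CC_l, per source
  mean_new <- raw / denom
  factor_kj <- sweep(matrix(1 / denom, nrow = nrow(raw), ncol = ncol(raw)), 2, cc, `*`)
  sd_new <- if (scale_sd) m$sd * factor_kj else m$sd
  long <- tibble::tibble(
    source = rep(m$sources, each = length(suite$tracers)),
    tracer = rep(suite$tracers, times = length(m$sources)),
    mean = as.vector(t(mean_new)),
    sd = as.vector(t(sd_new)),
    n = rep(m$n, each = length(suite$tracers))
  )
  if (!is.null(m$conc)) long$conc <- as.vector(t(m$conc))
  list(
    source = source_table(long, suite),
    modifier = trophic_modifier(suite, cc = cc)
  )
}

#' Attach trophic discrimination to stable-isotope sources
#'
#' Records the additive trophic discrimination factor (mean and SD per
#' tracer) alongside the sources so the mixing model can use it in the
#' likelihood: the discrimination mean shifts each source mean and its SD
#' enters the mixture variance, so discrimination uncertainty propagates into
#' the posterior rather than being pre-added to source means.
#'
#' @param src An SI `source_tbl`.
#' @param delta_mean,delta_sd Numeric vectors (one value per suite tracer) or
#'   a tibble with `tracer`,`delta_mean`,`delta_sd` columns passed as
#'   `delta_mean`.
#' @return A list with `source` (unchanged) and `modifier` (a
#'   [trophic_modifier()]).
#' @export
attach_discrimination <- function(src, delta_mean, delta_sd = NULL) {
  suite <- attr(src, "suite")
  if (is_fa(suite)) stop("additive discrimination applies to SI suites only", call. = FALSE)
  if (is.data.frame(delta_mean)) {
    tab <- delta_mean
    miss <- setdiff(suite$tracers, tab$tracer)
    if (length(miss)) stop_schema("no discrimination for tracer(s): ",
                                  paste(miss, collapse = ", "))
    idx <- match(suite$tracers, tab$tracer)
    delta_sd <- tab$delta_sd[idx]
    delta_mean <- tab$delta_mean[idx]
  }
  list(
    source = src,
    modifier = trophic_modifier(suite, delta_mean = delta_mean, delta_sd = delta_sd)
  )
}
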