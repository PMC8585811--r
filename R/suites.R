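#' Define a tracer suite
#'
#' A tracer suite names the biotracers a dataset carries and fixes their
#' semantics: fatty-acid (FA) suites hold proportions of total FA that sum to
#' one per individual, stable-isotope (SI) suites hold delta values in per mil
#' (permil) relative to the international standards (V-PDB for carbon,
#' atmospheric N2 for nitrogen).
#'
#' @param kind `"FA"` or `"SI"`.
#' @param tracers Character vector of tracer names, e.g. FA names such as
#'   `"20:5n-3"`, or `"d13C"`/`"d15N"` for isotopes. Must be unique; FA suites
#'   need at least 2 tracers, SI suites 1 or 2.
#' @return A `tracer_suite` object (a list with `kind`, `tracers`, `units`).
#' @examples
#' tracer_suite("SI", c("d13C", "d15N"))
#' tracer_suite("FA", c("16:0", "18:1n-9", "22:6n-3"))
#' @export
tracer_suite <- function(kind = c("FA", "SI"), tracers) {
  kind <- match.arg(kind)
  tracers <- as.character(tracers)
  if (length(tracers) == 0L) stop("tracer suite needs at least one tracer name", call. = FALSE)
  if (anyDuplicated(tracers)) stop("tracer names must be unique", call. = FALSE)
  if (any(!nzchar(tracers))) stop("tracer names must be non-empty", call. = FALSE)
  if (kind == "FA" && length(tracers) < 2L) {
    stop("FA suites need at least 2 tracers", call. = FALSE)
  }
  if (kind == "SI" && length(tracers) > 2L) {
    stop("SI suites carry at most 2 tracers (d13C, d15N)", call. = FALSE)
  }
  structure(
    list(
      kind = kind,
      tracers = tracers,
      units = if (kind == "FA") "proportion of total FA" else "‰"
    ),
    class = "tracer_suite"
  )
}

#' @export
print.tracer_suite <- function(x, ...) {
  cat("<tracer_suite> ", x$kind, " (", x$units, "): ",
      paste(x$tracers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_tracers <- function(suite) length(suite$tracers)

is_fa <- function(suite) identical(suite$kind, "FA")

stop_schema <- function(...) stop(paste0(...), call. = FALSE)

#' Build a consumer table
#'
#' Validates per-individual tracer observations into the tibble the rest of
#' the pipeline consumes: one row per individual, an `id` column, one numeric
#' column per tracer. FA rows are renormalized to sum to one; row sums that
#' deviate from 1 by more than `tol_warn` trigger a warning (percent tables
#' commonly lose trace FAs), zero-sum rows are rejected. SI values must be
#' finite per-mil numbers.
#'
#' @param data A data frame with an `id` column (created if absent) and one
#'   column per tracer in `suite`.
#' @param suite A [tracer_suite()].
#' @param tol_warn Row-sum deviation above which renormalization warns.
#' @return A tibble of class `consumer_tbl` with attribute `suite`.
#' @export
consumer_table <- function(data, suite, tol_warn = 1e-3) {
  stopifnot(inherits(suite, "tracer_suite"))
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(suite$tracers, names(data))
  if (length(missing_cols)) {
    stop_schema("consumer table is missing tracer column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(data) == 0L) stop_schema("consumer table has no rows")
  if (!"id" %in% names(data)) data$id <- paste0("ind", seq_len(nrow(data)))
  vals <- as.matrix(data[suite$tracers])
  if (!is.numeric(vals)) stop_schema("non-numeric values in tracer columns")
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop_schema("missing or non-finite value at row ", bad[1],
                ", tracer '", suite$tracers[bad[2]], "'")
  }
  if (is_fa(suite)) {
    if (any(vals < 0)) stop_schema("FA proportions must be nonnegative")
    rs <- rowSums(vals)
    if (any(rs <= 0)) stop_schema("FA row(s) sum to zero; cannot normalize")
    # percent input: header-free heuristic is not used; caller converts.
    if (any(abs(rs - 1) > tol_warn)) {
      warning("renormalizing ", sum(abs(rs - 1) > tol_warn),
              " FA row(s) with |sum - 1| > ", tol_warn, call. = FALSE)
    }
    vals <- vals / rs
    data[suite$tracers] <- vals
  }
  out <- data[c("id", suite$tracers)]
  attr(out, "suite") <- suite
  class(out) <- c("consumer_tbl", class(out))
  out
}

#' Build a source summary table
#'
#' Validates per-source tracer summaries (mean, SD, sample size, optional
#' concentration) into the long tibble used by the mixing model: columns
#' `source`, `tracer`, `mean`, `sd`, `n`, and optionally `conc`.
#'
#' @param data Data frame in long form with columns `source`, `tracer`,
#'   `mean`, `sd`, `n` and optionally `conc`.
#' @param suite A [tracer_suite()].
#' @param .allow_single Permit a single source (used internally when an
#'   aggregation plan collapses everything into one group).
#' @return A tibble of class `source_tbl` with attribute `suite`; source order
#'   follows first appearance.
#' @export
source_table <- function(data, suite, .allow_single = FALSE) {
  stopifnot(inherits(suite, "tracer_suite"))
  data <- tibble::as_tibble(data)
  need <- c("source", "tracer", "mean", "sd", "n")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_schema("source table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  sources <- unique(data$source)
  if (length(sources) < 2L && !.allow_single) {
    stop_schema("need at least 2 sources (K >= 2)")
  }
  if (any(!is.finite(data$mean))) stop_schema("non-finite source mean")
  if (any(!is.finite(data$sd)) || any(data$sd < 0)) {
    stop_schema("source SDs must be finite and nonnegative")
  }
  if (any(data$n < 1)) stop_schema("source sample sizes must be >= 1")
  # every source must carry every tracer exactly once
  tab <- table(data$source, data$tracer)
  if (!setequal(colnames(tab), suite$tracers) || any(tab != 1L)) {
    stop_schema("each source needs exactly one row per suite tracer")
  }
  if ("conc" %in% names(data) && any(!is.na(data$conc) & data$conc <= 0)) {
    stop_schema("concentrations must be positive")
  }
  keep <- intersect(c("source", "tracer", "mean", "sd", "n", "conc"), names(data))
  out <- data[keep]
  out$tracer <- factor(out$tracer, levels = suite$tracers)
  out <- dplyr::arrange(out, match(.data$source, sources), .data$tracer)
  out$tracer <- as.character(out$tracer)
  if (is_fa(suite)) {
    sums <- tapply(out$mean, factor(out$source, levels = sources), sum)
    if (any(abs(sums - 1) > 1e-6)) {
      stop_schema("FA source mean profiles must sum to 1 (max deviation ",
                  format(max(abs(sums - 1))), ")")
    }
  }
  attr(out, "suite") <- suite
  attr(out, "sources") <- sources
  class(out) <- c("source_tbl", class(out))
  out
}

# K x J matrices from a source_tbl, in suite tracer order
source_matrices <- function(src) {
  suite <- attr(src, "suite")
  sources <- attr(src, "sources")
  J <- n_tracers(suite)
  K <- length(sources)
  shape <- function(col) {
    m <- matrix(col, nrow = K, ncol = J, byrow = TRUE,
                dimnames = list(sources, suite$tracers))
    m
  }
  ord <- order(match(src$source, sources), match(src$tracer, suite$tracers))
  src <- src[ord, ]
  list(
    mean = shape(src$mean),
    sd = shape(src$sd),
    n = src$n[!duplicated(src$source)],
    conc = if ("conc" %in% names(src) && !anyNA(src$conc)) shape(src$conc) else NULL,
    sources = sources,
    suite = suite
  )
}

#' Build a trophic modifier
#'
#' Holds the trophic transfer parameters linking prey tissue to predator
#' tissue: for SI suites an additive trophic discrimination factor per tracer
#' (mean and SD, in per mil); for FA suites a multiplicative calibration
#' coefficient (CC) per tracer. Exactly one of the two parameterizations is
#' active, matching the suite kind.
#'
#' @param suite A [tracer_suite()].
#' @param delta_mean,delta_sd Numeric vectors (length = number of tracers),
#'   SI only. `delta_sd` must be nonnegative.
#' @param cc Positive numeric vector of calibration coefficients, FA only.
#' @return A `trophic_modifier` object.
#' @examples
#' si <- tracer_suite("SI", c("d13C", "d15N"))
#' trophic_modifier(si, delta_mean = c(2.2, 3.5), delta_sd = c(0.7, 0.6))
#' @export
trophic_modifier <- function(suite, delta_mean = NULL, delta_sd = NULL, cc = NULL) {
  stopifnot(inherits(suite, "tracer_suite"))
  J <- n_tracers(suite)
  if (is_fa(suite)) {
    if (is.null(cc) || !is.null(delta_mean) || !is.null(delta_sd)) {
      stop_schema("FA suites take calibration coefficients (cc), not discrimination")
    }
    if (length(cc) != J) stop_schema("cc length must match number of tracers (", J, ")")
    if (any(!is.finite(cc)) || any(cc <= 0)) stop_schema("calibration coefficients must be positive")
    names(cc) <- suite$tracers
    # after CC transfer the FA path carries zero additive discrimination
    delta_mean <- stats::setNames(rep(0, J), suite$tracers)
    delta_sd <- delta_mean
  } else {
    if (!is.null(cc)) stop_schema("SI suites take additive discrimination, not cc")
    if (is.null(delta_mean)) delta_mean <- rep(0, J)
    if (is.null(delta_sd)) delta_sd <- rep(0, J)
    if (length(delta_mean) != J || length(delta_sd) != J) {
      stop_schema("discrimination vectors must match number of tracers (", J, ")")
    }
    if (any(!is.finite(delta_mean))) stop_schema("non-finite discrimination mean")
    if (any(!is.finite(delta_sd)) || any(delta_sd < 0)) {
      stop_schema("discrimination SDs must be finite and nonnegative")
    }
    names(delta_mean) <- names(delta_sd) <- suite$tracers
  }
  structure(
    list(suite = suite, delta_mean = delta_mean, delta_sd = delta_sd, cc = cc),
    class = "trophic_modifier"
  )
}

#' @export
print.trophic_modifier <- function(x, ...) {
  cat("<trophic_modifier> ", x$suite$kind, "\n", sep = "")
  if (is_fa(x$suite)) {
    cat("  CC: ", paste(sprintf("%s=%.3g", names(x$cc), x$cc), collapse = ", "), "\n")
  } else {
    cat("  Delta: ", paste(sprintf("%s=%.2f±%.2f", names(x$delta_mean),
                                   x$delta_mean, x$delta_sd), collapse = ", "), "\n")
  }
  invisible(x)
}
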