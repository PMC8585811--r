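#' Read a consumer tracer table
#'
#' Reads a comma-separated file with a header row naming the tracers and one
#' row per individual (optional `id` column). Percent-scaled FA columns are
#' accepted when the header flags them with a trailing `%` (e.g. `16:0%`);
#' values are divided by 100 and the flag is stripped, so all proportions are
#' stored as fractions internally.
#'
#' @param path Path to a CSV file. Lines starting with `#` are metadata
#'   comments and are skipped.
#' @param suite A [tracer_suite()] naming the expected tracer columns.
#' @return A validated `consumer_tbl` (see [consumer_table()]).
#' @export
read_consumer_table <- function(path, suite) {
  df <- read_csv_strict(path)
  if (nrow(df) == 0L) stop_schema("consumer file '", path, "' has no data rows")
  pct <- endsWith(names(df), "%")
  if (any(pct)) {
    for (j in which(pct)) df[[j]] <- df[[j]] / 100
    names(df)[pct] <- sub("%$", "", names(df)[pct])
  }
  consumer_table(df, suite)
}

#' Write a consumer tracer table
#'
#' @param data A `consumer_tbl`.
#' @param path Destination CSV path.
#' @param config Optional `run_config`; its seed and run id are embedded as a
#'   `#`-comment header.
#' @return `path`, invisibly.
#' @export
write_consumer_table <- function(data, path, config = NULL) {
  write_csv_stamped(tibble::as_tibble(as.data.frame(data)), path, config)
}

#' Read a source summary table
#'
#' Reads the wide mixing-model dialect: one row per source with columns
#' `source`, `n`, `Mean_<tracer>`, `SD_<tracer>` and optionally
#' `Conc_<tracer>`.
#'
#' @inheritParams read_consumer_table
#' @return A validated `source_tbl` (see [source_table()]).
#' @export
read_source_table <- function(path, suite) {
  df <- read_csv_strict(path)
  if (!"source" %in% names(df)) stop_schema("source file needs a 'source' column")
  if (anyDuplicated(df$source)) stop_schema("duplicate source name in '", path, "'")
  if (!"n" %in% names(df)) stop_schema("source file needs an 'n' column")
  need_mean <- paste0("Mean_", suite$tracers)
  need_sd <- paste0("SD_", suite$tracers)
  miss <- setdiff(c(need_mean, need_sd), names(df))
  if (length(miss)) {
    stop_schema("source file is missing column(s): ", paste(miss, collapse = ", "))
  }
  conc_cols <- paste0("Conc_", suite$tracers)
  has_conc <- all(conc_cols %in% names(df))
  long <- tibble::tibble(
    source = rep(df$source, each = n_tracers(suite)),
    tracer = rep(suite$tracers, times = nrow(df)),
    mean = as.vector(t(as.matrix(df[need_mean]))),
    sd = as.vector(t(as.matrix(df[need_sd]))),
    n = rep(df$n, each = n_tracers(suite))
  )
  if (has_conc) long$conc <- as.vector(t(as.matrix(df[conc_cols])))
  source_table(long, suite)
}

#' Write a source summary table
#'
#' Writes the wide `Mean_*`/`SD_*`/`Conc_*` dialect read by
#' [read_source_table()].
#'
#' @param src A `source_tbl`.
#' @inheritParams write_consumer_table
#' @return `path`, invisibly.
#' @export
write_source_table <- function(src, path, config = NULL) {
  suite <- attr(src, "suite")
  m <- source_matrices(src)
  wide <- tibble::tibble(source = m$sources, n = m$n)
  for (j in seq_along(suite$tracers)) {
    wide[[paste0("Mean_", suite$tracers[j])]] <- m$mean[, j]
  }
  for (j in seq_along(suite$tracers)) {
    wide[[paste0("SD_", suite$tracers[j])]] <- m$sd[, j]
  }
  if (!is.null(m$conc)) {
    for (j in seq_along(suite$tracers)) {
      wide[[paste0("Conc_", suite$tracers[j])]] <- m$conc[, j]
    }
  }
  write_csv_stamped(wide, path, config)
}

#' Read a replicate-level source table
#'
#' Replicate-level prey measurements (one row per prey individual, columns
#' `source` plus tracers) are required for distinguishability screening;
#' summaries alone do not support permutation tests.
#'
#' @inheritParams read_consumer_table
#' @return A tibble with `source` plus one column per tracer.
#' @export
read_source_replicates <- function(path, suite) {
  df <- read_csv_strict(path)
  if (!"source" %in% names(df)) stop_schema("replicate file needs a 'source' column")
  miss <- setdiff(suite$tracers, names(df))
  if (length(miss)) stop_schema("replicate file is missing tracer column(s): ",
                                paste(miss, collapse = ", "))
  vals <- as.matrix(df[suite$tracers])
  if (anyNA(vals) || !is.numeric(vals)) stop_schema("non-numeric or missing replicate values")
  tibble::as_tibble(df[c("source", suite$tracers)])
}

#' Read a calibration-coefficient table
#'
#' @param path CSV with columns `tracer,cc`.
#' @return A tibble with columns `tracer`, `cc`.
#' @export
read_cc_table <- function(path) {
  df <- read_csv_strict(path)
  miss <- setdiff(c("tracer", "cc"), names(df))
  if (length(miss)) stop_schema("CC file needs columns tracer,cc")
  if (any(!is.finite(df$cc)) || any(df$cc <= 0)) stop_schema("CCs must be positive")
  tibble::as_tibble(df[c("tracer", "cc")])
}

#' Read a trophic discrimination table
#'
#' @param path CSV with columns `tracer,delta_mean,delta_sd`.
#' @return A tibble with columns `tracer`, `delta_mean`, `delta_sd`.
#' @export
read_discrimination_table <- function(path) {
  df <- read_csv_strict(path)
  miss <- setdiff(c("tracer", "delta_mean", "delta_sd"), names(df))
  if (length(miss)) stop_schema("discrimination file needs columns tracer,delta_mean,delta_sd")
  if (any(df$delta_sd < 0)) stop_schema("discrimination SDs must be nonnegative")
  tibble::as_tibble(df[c("tracer", "delta_mean", "delta_sd")])
}

#' Write a posterior report
#'
#' Writes two files: `<path>` with the per-source summary (median, 95%
#' equal-tailed credible interval, min-max range of draws, posterior mean) and
#' `<path base>_draws.csv` with the raw draws in long form
#' (`chain,iteration,parameter,value`). Both embed the seed and run id and
#' round-trip through [read_posterior_draws()].
#'
#' @param fit A `diet_fit` from [fit_mixing_model()].
#' @param path Destination CSV path for the summary table.
#' @return Invisibly, a list with the two paths written.
#' @export
write_posterior_report <- function(fit, path) {
  stopifnot(inherits(fit, "diet_fit"))
  smry <- summarize_posterior(fit)
  write_csv_stamped(smry, path, fit$config)
  draws_path <- sub("(\\.[A-Za-z]+)?$", "_draws.csv", path)
  long <- posterior_long(fit)
  write_csv_stamped(long, draws_path, fit$config)
  invisible(list(summary = path, draws = draws_path))
}

#' Read a raw-draw file back into a long tibble
#'
#' @param path Path written by [write_posterior_report()] (`*_draws.csv`).
#' @return A tibble with columns `chain`, `iteration`, `parameter`, `value`.
#' @export
read_posterior_draws <- function(path) {
  read_csv_strict(path)
}

posterior_long <- function(fit) {
  dn <- dimnames(fit$p_draws)[[3]]
  p_long <- purrr::map_dfr(seq_len(dim(fit$p_draws)[1]), function(ch) {
    m <- fit$p_draws[ch, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = length(dn))
    tibble::tibble(
      chain = ch,
      iteration = rep(seq_len(nrow(m)), times = ncol(m)),
      parameter = rep(paste0("p[", dn, "]"), each = nrow(m)),
      value = as.vector(m)
    )
  })
  if (!is.null(fit$xi_draws)) {
    xn <- dimnames(fit$xi_draws)[[3]]
    xi_long <- purrr::map_dfr(seq_len(dim(fit$xi_draws)[1]), function(ch) {
      m <- fit$xi_draws[ch, , , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, ncol = length(xn))
      tibble::tibble(
        chain = ch,
        iteration = rep(seq_len(nrow(m)), times = ncol(m)),
        parameter = rep(paste0("xi[", xn, "]"), each = nrow(m)),
        value = as.vector(m)
      )
    })
    p_long <- dplyr::bind_rows(p_long, xi_long)
  }
  p_long
}

# ---- internals ----

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  out <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE, name_repair = "minimal"),
    error = function(e) stop_schema("cannot parse '", path, "': ", conditionMessage(e))
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop_schema("parse error in '", path, "' at row ", probs$row[1],
                ", column ", probs$col[1], ": expected ", probs$expected[1])
  }
  if (ncol(out) == 0L || nrow(out) == 0L && ncol(out) <= 1L) {
    stop_schema("file '", path, "' is empty or has no usable header")
  }
  out
}

write_csv_stamped <- function(df, path, config = NULL) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con), add = TRUE)
  if (!is.null(config)) {
    writeLines(sprintf("# seed=%d run=%s", config$seed, run_id(config)), con)
  }
  utils::write.csv(as.data.frame(df), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
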