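#' Run the stable-isotope diet-estimation pipeline
#'
#' Orchestrates the full SI analysis for one predator group: read inputs,
#' screen sources for distinguishability (when replicate-level prey data are
#' available; skipped with a warning otherwise), aggregate indistinguishable
#' sources, attach trophic discrimination, fit the mixing model, check
#' convergence, and write the posterior report plus a run manifest.
#'
#' @param consumer_file CSV of consumer isotope values (`id`, `d13C`, `d15N`).
#' @param source_file CSV of source summaries (wide `Mean_*`/`SD_*` dialect).
#' @param discrimination_file CSV `tracer,delta_mean,delta_sd`.
#' @param replicate_file Optional CSV of replicate-level prey values for
#'   screening; `NULL` skips screening.
#' @param out_dir Output directory for reports (`NULL` writes nothing).
#' @param config A [run_config()].
#' @param force Report summaries even when convergence diagnostics fail
#'   (default `FALSE`: the summary is still returned, flagged, but a failed
#'   fit refuses to write report files).
#' @param tracers SI tracer names (default `c("d13C","d15N")`).
#' @return A list of class `pipeline_result`: `fit`, `summary`, `screen`
#'   (NULL if skipped), `source` (post-aggregation), `manifest`.
#' @export
run_si_pipeline <- function(consumer_file, source_file, discrimination_file,
                            replicate_file = NULL, out_dir = NULL,
                            config = run_config(), force = FALSE,
                            tracers = c("d13C", "d15N")) {
  suite <- tracer_suite("SI", tracers)
  t0 <- Sys.time()
  cons <- read_consumer_table(consumer_file, suite)
  src <- read_source_table(source_file, suite)
  tdf <- read_discrimination_table(discrimination_file)
  scr <- NULL
  if (!is.null(replicate_file)) {
    reps <- read_source_replicates(replicate_file, suite)
    scr <- screen_sources(reps, suite, config)
    src <- combine_sources(src, scr$plan)
  } else {
    warning("no replicate-level source data; distinguishability screening skipped",
            call. = FALSE)
  }
  att <- attach_discrimination(src, tdf)
  fit <- fit_mixing_model(cons, att$source, att$modifier, config)
  finish_pipeline(fit, scr, att$source, out_dir, config, force,
                  inputs = c(consumer_file, source_file, discrimination_file,
                             replicate_file),
                  t0 = t0)
}

#' Run the fatty-acid diet-estimation pipeline
#'
#' As [run_si_pipeline()], with the FA-specific preprocessing in front:
#' tracers whose calibration coefficient exceeds the configured threshold are
#' dropped (reason recorded in the manifest), prey profiles are multiplied by
#' the surviving CCs and renormalized into predator space, and additive
#' discrimination is set to zero from there on.
#'
#' @inheritParams run_si_pipeline
#' @param cc_file CSV `tracer,cc` of calibration coefficients.
#' @param tracers Candidate FA names (default [default_fa_names()]).
#' @return A `pipeline_result`; its `selection` element records per-tracer
#'   keep/drop reasons.
#' @export
run_fa_pipeline <- function(consumer_file, source_file, cc_file,
                            replicate_file = NULL, out_dir = NULL,
                            config = run_config(), force = FALSE,
                            tracers = default_fa_names()) {
  cc_tab <- read_cc_table(cc_file)
  sel <- select_fa_tracers(tracers, cc_tab,
                           threshold = config$fa_cc_exclusion_threshold)
  kept <- sel$tracer[sel$keep]
  suite_full <- tracer_suite("FA", tracers)
  suite <- tracer_suite("FA", kept)
  t0 <- Sys.time()
  # the consumer file may carry any superset of the kept tracers; reading with
  # the kept suite renormalizes each row onto the reduced simplex
  cons <- suppressWarnings(read_consumer_table(consumer_file, suite))
  src_full <- read_source_table(source_file, suite_full)
  src <- restrict_sources(src_full, suite)
  scr <- NULL
  if (!is.null(replicate_file)) {
    reps_full <- read_source_replicates(replicate_file, suite_full)
    reps <- dplyr::bind_cols(
      reps_full["source"],
      normalize_fa_profile(as.matrix(reps_full[kept])) |> tibble::as_tibble()
    )
    scr <- screen_sources(reps, suite, config)
    src <- combine_sources(src, scr$plan)
  } else {
    warning("no replicate-level source data; distinguishability screening skipped",
            call. = FALSE)
  }
  cc <- stats::setNames(cc_tab$cc, cc_tab$tracer)[kept]
  trans <- apply_calibration_coefficients(src, cc)
  fit <- fit_mixing_model(cons, trans$source, trans$modifier, config)
  out <- finish_pipeline(fit, scr, trans$source, out_dir, config, force,
                         inputs = c(consumer_file, source_file, cc_file,
                                    replicate_file),
                         t0 = t0)
  out$selection <- sel
  out
}

finish_pipeline <- function(fit, scr, src, out_dir, config, force, inputs, t0) {
  smry <- summarize_posterior(fit)
  manifest <- tibble::tibble(
    key = c("run_id", "seed", "inputs", "converged", "elapsed_s"),
    value = c(run_id(config), as.character(config$seed),
              paste(inputs, collapse = ";"),
              as.character(fit$diagnostics$pass),
              sprintf("%.2f", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  )
  outputs <- NULL
  if (!is.null(out_dir)) {
    if (!fit$diagnostics$pass && !force) {
      warning("convergence diagnostics failed; refusing to write report files ",
              "(use force = TRUE to override)", call. = FALSE)
    } else {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- write_posterior_report(fit, file.path(out_dir, "posterior_summary.csv"))
      write_csv_stamped(diagnostics_table(fit),
                        file.path(out_dir, "diagnostics.csv"), config)
      if (!is.null(scr)) {
        write_csv_stamped(scr$pairwise, file.path(out_dir, "pairwise_permanova.csv"),
                          config)
        yaml::write_yaml(split(scr$plan$source, scr$plan$group),
                         file.path(out_dir, "aggregation_plan.yaml"))
        if (!is.null(scr$nmds)) {
          write_csv_stamped(scr$nmds$coordinates,
                            file.path(out_dir, "nmds_coordinates.csv"), config)
        }
      }
      outputs <- unlist(paths)
    }
  }
  structure(
    list(fit = fit, summary = smry, screen = scr, source = src,
         manifest = manifest, outputs = outputs),
    class = "pipeline_result"
  )
}

restrict_consumers <- function(cons, suite_kept) {
  suite <- attr(cons, "suite")
  sub <- tibble::as_tibble(cons)[c("id", suite_kept$tracers)]
  if (is_fa(suite_kept)) {
    vals <- as.matrix(sub[suite_kept$tracers])
    sub[suite_kept$tracers] <- vals / rowSums(vals)
  }
  consumer_table(sub, suite_kept)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$screen)) print(x$screen)
  print(x$fit)
  invisible(x)
}
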