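#' Pipeline configuration
#'
#' Collects the analysis settings; the defaults reproduce the standard SSS
#' analysis: envelopes resampled to 100 Hz, band-passed 3.5-5.5 Hz, PLV over
#' 5 s windows with 2 s overlap, mixture EM capped at 140 iterations, and
#' 10,000 Monte-Carlo simulations for confidence intervals.
#'
#' @param input_manifest Path to a manifest CSV, or a data frame, with
#'   columns `participant_id` and `path` (WAV audio or envelope CSV per
#'   participant) plus any covariate columns (`sex`, `age`, `edu_years`,
#'   `music_years`, `music_level`, `cohort`, ...). Multiple rows per
#'   participant are allowed; their PLVs are averaged.
#' @param stimulus_path Path to the stimulus WAV or envelope CSV, or an
#'   [envelope_series].
#' @param band_hz Envelope pass band, Hz.
#' @param window_s,overlap_s PLV window length and overlap, seconds.
#' @param resample_hz Envelope analysis rate, Hz.
#' @param gmm_max_iter,gmm_seed Mixture EM settings.
#' @param mc_sims Monte-Carlo simulations for KS confidence intervals.
#' @param max_silence_s Exclusion threshold for silent gaps, seconds.
#' @param output_dir Directory for CSV/JSON artifacts (`NULL` = no files).
#' @return A `run_config` list.
#' @export
run_config <- function(input_manifest = NULL, stimulus_path = NULL,
                       band_hz = c(3.5, 5.5), window_s = 5, overlap_s = 2,
                       resample_hz = 100, gmm_max_iter = 140, gmm_seed = 1,
                       mc_sims = 10000, max_silence_s = 4,
                       output_dir = NULL) {
  if (window_s <= 0 || overlap_s < 0 || resample_hz <= 0) {
    stop("durations and rates must be positive")
  }
  structure(
    list(input_manifest = input_manifest, stimulus_path = stimulus_path,
         band_hz = band_hz, window_s = window_s, overlap_s = overlap_s,
         resample_hz = resample_hz, gmm_max_iter = gmm_max_iter,
         gmm_seed = gmm_seed, mc_sims = mc_sims,
         max_silence_s = max_silence_s, output_dir = output_dir),
    class = "run_config"
  )
}

#' Load a stimulus or production input as a broadband envelope
#'
#' WAV audio is pre-filtered and its Hilbert envelope extracted; a
#' two-column CSV (`time_s`, `amplitude`) is read as an envelope directly;
#' an [envelope_series] is returned as is.
#'
#' @param path_or_env File path, [audio_signal] or [envelope_series].
#' @param id Identifier for the returned envelope.
#' @return An [envelope_series].
#' @export
load_envelope_input <- function(path_or_env, id = NULL) {
  if (inherits(path_or_env, "envelope_series")) return(path_or_env)
  if (inherits(path_or_env, "audio_signal")) {
    return(extract_envelope(prefilter(path_or_env)))
  }
  stopifnot(is.character(path_or_env), length(path_or_env) == 1)
  if (grepl("\\.wav$", path_or_env, ignore.case = TRUE)) {
    sig <- read_wav(path_or_env, participant_id = id)
    extract_envelope(prefilter(sig))
  } else {
    read_envelope_csv(path_or_env, source_id = id)
  }
}

#' Phase-locking value of one participant against a stimulus
#'
#' Convenience wrapper over the synchrony pipeline: both envelopes are
#' resampled and band-passed, phases extracted, series trimmed to their
#' common length, and the windowed PLV computed.
#'
#' @param stim_env,prod_env Broadband [envelope_series] of the heard and
#'   produced signals.
#' @param config A [run_config].
#' @return A `plv_result`.
#' @export
participant_plv <- function(stim_env, prod_env, config = run_config()) {
  b1 <- resample_and_band(stim_env, config$resample_hz, config$band_hz)
  b2 <- resample_and_band(prod_env, config$resample_hz, config$band_hz)
  th1 <- extract_phase(b1)
  th2 <- extract_phase(b2)
  n <- min(length(th1), length(th2))
  pair <- phase_pair(th1[seq_len(n)], th2[seq_len(n)], config$resample_hz)
  compute_plv(pair, config$window_s, config$overlap_s)
}

#' Run the full SSS analysis pipeline
#'
#' Executes, per manifest row: input loading, quality control (WAV inputs),
#' envelope extraction, and the windowed PLV against the stimulus. Failing
#' or excluded participants are logged with a reason and the pipeline
#' continues. The included PLVs are then fitted with 1-3 component Gaussian
#' mixtures (AIC selection), classified into high/low synchronizers when the
#' two-component model wins, and passed with the manifest covariates to the
#' statistical battery. All artifacts are written under
#' `config$output_dir` when set.
#'
#' @param config A [run_config] with `input_manifest` and `stimulus_path`.
#' @return A `run_report` list: `n_input`, `n_analyzed`, `n_excluded`,
#'   `exclusions`, `plv_table`, `mixture`, `classification`, `stats`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- config$input_manifest
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (!is.data.frame(manifest) || nrow(manifest) == 0) {
    stop("empty or missing input manifest")
  }
  if (!all(c("participant_id", "path") %in% names(manifest))) {
    stop("manifest needs columns participant_id and path")
  }
  if (is.null(config$stimulus_path)) stop("stimulus_path is required")

  stim_env <- load_envelope_input(config$stimulus_path, "stimulus")
  stim_band <- resample_and_band(stim_env, config$resample_hz, config$band_hz)
  th1 <- extract_phase(stim_band)

  plv_rows <- list()
  exclusions <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    res <- tryCatch({
      is_wav <- grepl("\\.wav$", row$path, ignore.case = TRUE)
      if (is_wav) {
        sig <- read_wav(row$path, participant_id = row$participant_id)
        qc <- quality_check(sig, max_silence_s = config$max_silence_s)
        if (!qc$included) {
          list(excluded = paste(qc$reasons, collapse = ";"))
        } else {
          env <- extract_envelope(prefilter(sig))
          list(plv = participant_plv(stim_env, env, config))
        }
      } else {
        env <- read_envelope_csv(row$path, source_id = row$participant_id)
        sig <- audio_signal(env$values + 1e-12, env$sample_rate_hz,
                            row$participant_id)
        qc <- quality_check(sig, max_silence_s = config$max_silence_s)
        if (!qc$included) {
          list(excluded = paste(qc$reasons, collapse = ";"))
        } else {
          list(plv = participant_plv(stim_env, env, config))
        }
      }
    }, error = function(e) list(excluded = paste0("error: ", conditionMessage(e))))

    if (!is.null(res$excluded)) {
      exclusions[[length(exclusions) + 1]] <- data.frame(
        participant_id = row$participant_id, reason = res$excluded,
        stringsAsFactors = FALSE)
    } else {
      plv_rows[[length(plv_rows) + 1]] <- data.frame(
        participant_id = row$participant_id,
        plv = res$plv$plv_mean, n_windows = res$plv$n_windows,
        stringsAsFactors = FALSE)
    }
  }
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(participant_id = character(0), reason = character(0))
  plv_table <- if (length(plv_rows)) do.call(rbind, plv_rows) else
    stop("no participant passed quality control")
  # average PLVs over repeated runs of the same participant
  plv_table <- stats::aggregate(cbind(plv, n_windows) ~ participant_id,
                                plv_table, mean)

  fit <- select_k_by_aic(plv_table$plv, 1:3, max_iter = config$gmm_max_iter,
                         seed = config$gmm_seed)
  cls <- NULL
  stats_out <- NULL
  if (fit$k == 2) {
    cls <- classify(fit, plv_table$plv)
    plv_table$label <- cls$labels
    covars <- manifest[!duplicated(manifest$participant_id),
                       setdiff(names(manifest), c("path")), drop = FALSE]
    cohort_tab <- merge(plv_table, covars, by = "participant_id")
    stats_out <- run_group_comparisons(cohort_tab, mc_sims = config$mc_sims,
                                       seed = config$gmm_seed)
  }

  report <- structure(
    list(n_input = length(unique(manifest$participant_id)),
         n_analyzed = nrow(plv_table),
         n_excluded = nrow(exclusions),
         exclusions = exclusions,
         plv_table = plv_table,
         mixture = fit,
         classification = cls,
         stats = stats_out,
         provenance = list(
           band_hz = config$band_hz, window_s = config$window_s,
           overlap_s = config$overlap_s, resample_hz = config$resample_hz,
           gmm_max_iter = config$gmm_max_iter, gmm_seed = config$gmm_seed,
           mc_sims = config$mc_sims,
           package_version = as.character(utils::packageVersion("speechsync")))),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d input, %d analyzed, %d excluded\n",
              x$n_input, x$n_analyzed, x$n_excluded))
  print(x$mixture)
  if (!is.null(x$classification)) print(x$classification)
  invisible(x)
}

write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$plv_table, file.path(dir, "plv.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  fit <- report$mixture
  jsonlite::write_json(
    list(k = fit$k, weights = fit$weights, means = fit$means,
         sds = sqrt(fit$variances), aic = fit$aic, converged = fit$converged,
         aic_by_k = as.list(attr(fit, "aic_by_k"))),
    file.path(dir, "mixture.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$stats)) {
    utils::write.csv(report$stats$summary, file.path(dir, "stats.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Reported reference values for deposit-based replication
#'
#' The cohort-level quantities reported by the study whose deposited PLVs
#' [replicate_from_deposit()] re-analyzes, with the comparison tolerance per
#' quantity (mixture-derived quantities to +/- 0.01 of their two-decimal
#' printed values; KS statistics to +/- 0.005; counts exact; the Bayes
#' factor to 10%).
#'
#' @return Data frame with columns `scope`, `quantity`, `value`, `tol`.
#' @export
reference_values <- function() {
  rbind(
    data.frame(scope = "english",
               quantity = c("n_high", "n_low", "mean_high", "mean_low",
                            "sd_high", "sd_low", "weight_high", "weight_low",
                            "ks_d"),
               value = c(25, 36, 0.77, 0.48, 0.045, 0.106, 0.38, 0.62, 0.59),
               tol = c(0, 0, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.005)),
    data.frame(scope = "swedish",
               quantity = c("n_high", "n_low", "mean_high", "mean_low",
                            "sd_high", "sd_low", "weight_high", "weight_low",
                            "ks_d"),
               value = c(34, 26, 0.69, 0.38, 0.071, 0.096, 0.57, 0.43, 0.58),
               tol = c(0, 0, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.005)),
    data.frame(scope = "combined",
               quantity = c("n_high", "n_low", "mean_high", "mean_low",
                            "weight_high", "weight_low", "ks_d"),
               value = c(47, 74, 0.75, 0.48, 0.35, 0.65, 0.58),
               tol = c(0, 0, 0.01, 0.01, 0.01, 0.01, 0.005)),
    data.frame(scope = "between",
               quantity = c("ks_d", "bf01"),
               value = c(0.16, 4.8),
               tol = c(0.005, 0.48))
  )
}

#' Re-analyze deposited per-participant PLVs
#'
#' Skips the audio stages and runs the mixture/classification and
#' distributional statistics directly on a deposited PLV table, comparing
#' each recomputed quantity against the reported reference values. Rows
#' with PLVs outside `[0, 1]` are rejected with a reason.
#'
#' @param plv_csv Path to a CSV with columns `participant_id`, `cohort`,
#'   `plv` (or a data frame).
#' @param reference Reference table as from [reference_values()].
#' @param gmm_seed,mc_sims Analysis settings.
#' @return A list: per-scope fits and classifications, `stats`,
#'   `comparison` (quantity, reference, estimate, tolerance, pass),
#'   `rejected`.
#' @export
replicate_from_deposit <- function(plv_csv, reference = reference_values(),
                                   gmm_seed = 1, mc_sims = 10000) {
  d <- if (is.data.frame(plv_csv)) plv_csv else utils::read.csv(plv_csv)
  need <- c("participant_id", "cohort", "plv")
  if (!all(need %in% names(d))) {
    stop("deposit CSV needs columns: ", paste(need, collapse = ", "))
  }
  bad <- !is.finite(d$plv) | d$plv < 0 | d$plv > 1
  rejected <- d[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "plv outside [0, 1]"
  d <- d[!bad, , drop = FALSE]
  if (nrow(d) == 0) stop("no valid PLV rows in deposit")

  cohorts <- unique(d$cohort)
  scopes <- stats::setNames(as.list(cohorts), cohorts)
  if (length(cohorts) > 1) scopes$combined <- cohorts
  out <- list()
  est_rows <- list()
  for (nm in names(scopes)) {
    x <- d$plv[d$cohort %in% scopes[[nm]]]
    fit <- select_k_by_aic(x, 1:3, seed = gmm_seed)
    ks <- ks_one_sample(x, n_sim = mc_sims, seed = gmm_seed)
    scope_out <- list(fit = fit, ks = ks, n = length(x))
    if (fit$k == 2) {
      cls <- classify(fit, x)
      scope_out$classification <- cls
      est_rows[[length(est_rows) + 1]] <- data.frame(
        scope = nm,
        quantity = c("n_high", "n_low", "mean_high", "mean_low",
                     "sd_high", "sd_low", "weight_high", "weight_low", "ks_d"),
        estimate = c(cls$n_high, cls$n_low, fit$means[2], fit$means[1],
                     sqrt(fit$variances[2]), sqrt(fit$variances[1]),
                     fit$weights[2], fit$weights[1], ks$d_stat))
    } else {
      est_rows[[length(est_rows) + 1]] <- data.frame(
        scope = nm, quantity = "ks_d", estimate = ks$d_stat)
    }
    out[[nm]] <- scope_out
  }
  if (length(cohorts) == 2) {
    x <- d$plv[d$cohort == cohorts[1]]
    y <- d$plv[d$cohort == cohorts[2]]
    ks2 <- ks_two_sample(x, y, n_sim = mc_sims, seed = gmm_seed)
    bf <- bayes_factor_ttest(x, y)
    out$between <- list(ks = ks2, bf = bf)
    est_rows[[length(est_rows) + 1]] <- data.frame(
      scope = "between", quantity = c("ks_d", "bf01"),
      estimate = c(ks2$d_stat, bf$bf01))
  } else {
    message("single-cohort deposit: between-cohort comparisons skipped")
  }
  estimates <- do.call(rbind, est_rows)
  comparison <- merge(reference, estimates, by = c("scope", "quantity"))
  comparison$pass <- abs(comparison$estimate - comparison$value) <=
    comparison$tol
  out$comparison <- comparison[order(comparison$scope, comparison$quantity), ]
  out$rejected <- rejected
  out
}
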