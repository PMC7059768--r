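# Configuration-driven orchestration of the simulation / reconstruction
# study: simulate -> decompose -> select -> invert -> evaluate.
#
# The raw arm (`decomposition = "none"`) inverts the noisy EEG
# directly; the MEMD arm decomposes the reduced-montage EEG, keeps the
# highest-entropy IMFs and inverts the rebuilt signal.  Spatial error
# is the 1-Wasserstein distance between time-ROI power distributions of
# the estimate and the ground truth.

#' Pipeline configuration
#'
#' @param scenario `"one"`, `"three"` or `"five"` (synthetic study), or
#'   `NULL` when `input` is given.
#' @param montage 8, 16, 32 or `"full"`; or a character vector of 10-10
#'   labels.
#' @param snr_db broadband SNR of the simulated recording in dB.
#' @param decomposition `"memd"`, `"emd"` (channel-wise), or `"none"`
#'   for the raw arm.
#' @param selection either a single integer k (keep the k
#'   highest-entropy IMFs) or an integer vector of explicit IMF indices
#'   (e.g. `c(2, 4, 6)`).  The default (`NULL`) is scenario-aware:
#'   k = number of simulated sources + 1, so that every source rhythm
#'   can be captured even when one mode splits across two IMFs or a
#'   noise mode ranks high; for recorded input the default is 3.
#' @param inversion `"msp"` or `"mn"`.
#' @param memd_estimate how the MEMD arm forms its source estimate:
#'   `"mix"` (default) inverts each selected IMF separately and sums
#'   the resulting brain maps, which lets the inverse solver adapt its
#'   covariance weights to one oscillatory mode at a time; `"rebuild"`
#'   inverts the rebuilt (summed) signal once.
#' @param rois list of `c(t_min, t_max)` windows (s); default: 250 ms
#'   before and after each simulated source's activity center.
#' @param seeds integer vector of noise seeds; one pipeline cell is run
#'   per seed.
#' @param fs,t_end,sigma sampling rate (Hz), segment end (s) and source
#'   window width (s) of the simulation.
#' @param n_vertices,head_seed fixture head-model size and seed.
#' @param V,max_imfs decomposition settings (see [memd_config()]).
#' @param n_patches,smoothing_mm MSP prior settings (see
#'   [build_patches()]).
#' @param mn_regularization minimum-norm regularization weight.
#' @param input optional path to a recorded EEG (delimited or EDF); then
#'   `leadfield_prefix` must point to a head model written by
#'   [write_headmodel()], and Wasserstein evaluation is skipped unless
#'   ground-truth activity is supplied separately.
#' @param leadfield_prefix head-model file prefix for `input` mode.
#' @param output_dir if non-`NULL`, the Wm table and manifest are
#'   written there as delimited text / YAML.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "three", montage = 8, snr_db = 10,
                            decomposition = c("memd", "emd", "none"),
                            selection = NULL,
                            inversion = c("msp", "mn"),
                            memd_estimate = c("mix", "rebuild"),
                            rois = NULL, seeds = 1L,
                            fs = 200, t_end = 6, sigma = 0.12,
                            n_vertices = 500L, head_seed = 7L,
                            V = NULL, max_imfs = 12L,
                            n_patches = 128L, smoothing_mm = 10,
                            mn_regularization = 0.1,
                            input = NULL, leadfield_prefix = NULL,
                            output_dir = NULL) {
  decomposition <- match.arg(decomposition)
  inversion <- match.arg(inversion)
  memd_estimate <- match.arg(memd_estimate)
  montage_labels_ <- if (is.character(montage) && length(montage) > 1L)
    montage else montage_labels(montage)
  if (!is.null(input) && is.null(leadfield_prefix))
    stop("input mode needs a leadfield_prefix head model")
  if (is.null(selection)) {
    selection <- if (is.null(input))
      switch(scenario, one = 2L, three = 4L, five = 6L, 3L)
    else 3L
  }
  structure(list(scenario = scenario, montage = montage_labels_,
                 montage_size = length(montage_labels_),
                 snr_db = snr_db, decomposition = decomposition,
                 selection = selection, inversion = inversion,
                 memd_estimate = memd_estimate,
                 rois = rois, seeds = as.integer(seeds), fs = fs,
                 t_end = t_end, sigma = sigma,
                 n_vertices = as.integer(n_vertices),
                 head_seed = as.integer(head_seed), V = V,
                 max_imfs = as.integer(max_imfs),
                 n_patches = as.integer(n_patches),
                 smoothing_mm = smoothing_mm,
                 mn_regularization = mn_regularization,
                 input = input, leadfield_prefix = leadfield_prefix,
                 output_dir = output_dir),
            class = "pipeline_config")
}

.method_name <- function(config) {
  pre <- switch(config$decomposition, none = "raw", config$decomposition)
  paste0(pre, "-", config$inversion)
}

# decomposition + entropy selection for one reduced recording; returns
# a list of signals to invert (one per selected IMF in the "mix" MEMD
# mode, a single rebuilt/raw signal otherwise) whose source estimates
# are summed
.preprocess_signal <- function(y, config) {
  dec <- config$decomposition
  if (dec == "none") return(list(y))
  if (dec == "memd") {
    d <- memd(y, config = memd_config(V = config$V,
                                      max_imfs = config$max_imfs))
    M <- length(d$imfs)
    if (M == 0L) return(list(y))
    keep <- if (length(config$selection) > 1L) {
      keep <- intersect(as.integer(config$selection), seq_len(M))
      if (!length(keep)) stop("explicit IMF selection is out of range")
      keep
    } else rank_and_select(d, k = min(as.integer(config$selection), M))$selected
    if (identical(config$memd_estimate, "mix")) {
      return(lapply(keep, function(i)
        eeg_signal(d$imfs[[i]], fs = d$fs, t0 = y$t0, labels = y$labels)))
    }
    out <- rebuild(d, keep)
    out$t0 <- y$t0
    return(list(out))
  }
  # channel-wise EMD: per-channel entropy ranking (no mode alignment,
  # so only the rebuilt signal is meaningful)
  data <- y$data
  out <- matrix(0, nrow(data), ncol(data))
  for (ch in seq_len(nrow(data))) {
    dch <- emd(data[ch, ], fs = y$fs, max_imfs = config$max_imfs)
    M <- length(dch$imfs)
    if (M == 0L) next
    sel <- if (length(config$selection) > 1L)
      intersect(as.integer(config$selection), seq_len(M))
    else rank_and_select(dch, k = min(as.integer(config$selection), M))$selected
    if (!length(sel)) next
    out[ch, ] <- Reduce(`+`, dch$imfs[sel])
  }
  list(eeg_signal(out, fs = y$fs, t0 = y$t0, labels = y$labels))
}

.invert_signal <- function(y, head, config, priors = NULL) {
  if (config$inversion == "msp")
    invert_msp(y, head, priors = priors)
  else
    invert_mn(y, head, regularization = config$mn_regularization)
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the reconstruction pipeline
#'
#' Executes the configured chain for every noise seed and evaluates the
#' spatial accuracy against the simulated ground truth.  With
#' `decomposition = "none"` this is the raw arm: the inverse solver
#' sees the noisy recording unchanged.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_manifest`: `wm` (data frame with
#'   columns scenario, method, montage, snr_db, seed, roi_center, wm),
#'   `config`, `config_hash`, `timing` (per-stage seconds), `version`,
#'   and `estimates` (the last seed's `source_estimate`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- Sys.time()
  timing <- c()
  tick <- function(name, t0) {
    timing[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  }

  t0 <- Sys.time()
  if (!is.null(config$input)) {
    head_full <- read_headmodel(config$leadfield_prefix)
    y_clean <- load_eeg(config$input)
    scenario <- NULL
  } else {
    head_full <- synth_headmodel(config$n_vertices,
                                 montage_labels("full"),
                                 seed = config$head_seed)
    scenario <- make_scenario(config$scenario, head_full, fs = config$fs,
                              t_end = config$t_end, sigma = config$sigma)
    y_clean <- forward_project(head_full, scenario)
  }
  tick("setup", t0)

  rois <- config$rois
  if (is.null(rois) && !is.null(scenario))
    rois <- lapply(scenario$specs$c, function(cc) c(cc - 0.25, cc + 0.25))

  gt_pd <- NULL
  if (!is.null(scenario))
    gt_pd <- lapply(rois, function(r)
      roi_power(scenario, r, head_full$vertex_coords))

  priors <- NULL
  rows <- list()
  est <- NULL
  for (seed in config$seeds) {
    t0 <- Sys.time()
    y <- if (!is.null(scenario)) add_noise(y_clean, config$snr_db, seed)
         else y_clean
    red <- reduce_montage(y, head_full, config$montage)
    tick("simulate", t0)

    t0 <- Sys.time()
    yin <- .preprocess_signal(red$signal, config)
    tick("decompose", t0)

    t0 <- Sys.time()
    if (is.null(priors) && config$inversion == "msp")
      priors <- build_patches(red$head,
                              n_patches = min(config$n_patches,
                                              ncol(red$head$leadfield)),
                              smoothing_mm = config$smoothing_mm)
    ests <- lapply(yin, .invert_signal, head = red$head, config = config,
                   priors = priors)
    est <- ests[[1L]]
    if (length(ests) > 1L) {
      # mixed brain map: sum of the per-IMF conditional means
      est$xhat <- Reduce(`+`, lapply(ests, `[[`, "xhat"))
      est$free_energy <- sum(vapply(ests, `[[`, numeric(1L), "free_energy"))
      est$free_energy_trace <- numeric(0)
      est$hyperparameters <- lapply(ests, `[[`, "hyperparameters")
      est$converged <- all(vapply(ests, `[[`, logical(1L), "converged"))
    }
    tick("invert", t0)

    if (!is.null(gt_pd)) {
      t0 <- Sys.time()
      for (k in seq_along(rois)) {
        est_pd <- roi_power(est, rois[[k]], head_full$vertex_coords)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = config$scenario, method = .method_name(config),
          montage = config$montage_size, snr_db = config$snr_db,
          seed = seed, roi_center = mean(rois[[k]]),
          wm = wasserstein(est_pd, gt_pd[[k]]))
      }
      tick("evaluate", t0)
    }
  }
  timing[["total"]] <- round(as.numeric(Sys.time() - t_all, units = "secs"), 3)

  manifest <- structure(
    list(wm = if (length(rows)) do.call(rbind, rows) else NULL,
         config = config, config_hash = .config_hash(config),
         timing = unlist(timing),
         version = as.character(utils::packageVersion("memdeeg")),
         estimates = est),
    class = "pipeline_manifest")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(manifest$wm))
      utils::write.table(manifest$wm,
                         file.path(config$output_dir, "wm_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(config_hash = manifest$config_hash,
                          version = manifest$version,
                          timing = as.list(manifest$timing),
                          seeds = config$seeds),
                     file.path(config$output_dir, "manifest.yaml"))
  }
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("<pipeline_manifest>", .method_name(x$config), "|",
      x$config$montage_size, "channels |", length(x$config$seeds),
      "seed(s) | hash", substr(x$config_hash, 1L, 8L), "\n")
  if (!is.null(x$wm)) {
    agg <- stats::aggregate(wm ~ method + montage, x$wm, mean)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}

#' Sweep montages and methods over shared noise seeds
#'
#' Runs the pipeline for every (montage, method) cell with the same
#' seeds, so that Wm values are paired across arms, and binds the Wm
#' tables.  `methods` names the preprocessing arm: `"raw"`, `"memd"`
#' or `"emd"`.
#'
#' @param montages vector of montage sizes, e.g. `c(8, 16, 32)`.
#' @param methods preprocessing arms to compare.
#' @param seeds shared noise seeds.
#' @param ... further arguments to [pipeline_config()].
#' @return data frame of Wm values across all cells.
#' @export
run_study <- function(montages = c(8, 16, 32), methods = c("raw", "memd"),
                      seeds = 1:20, ...) {
  out <- list()
  for (mo in montages) {
    for (me in methods) {
      cfg <- pipeline_config(montage = mo,
                             decomposition = if (me == "raw") "none" else me,
                             seeds = seeds, ...)
      out[[length(out) + 1L]] <- run_pipeline(cfg)$wm
    }
  }
  do.call(rbind, out)
}

#' Paired accuracy comparison of two pipeline arms
#'
#' Averages Wm over the ROIs of each seed, then compares the two
#' methods at one montage size with a paired two-sided t-test.
#'
#' @param wm_table data frame from [run_study()] / `run_pipeline()$wm`.
#' @param montage montage size to compare at.
#' @param method_a,method_b method names as they appear in the table
#'   (defaults: raw-msp vs memd-msp).
#' @param n_comparisons Bonferroni family size.
#' @return list with per-seed means `wm_a`/`wm_b`, their grand means,
#'   `reduction_pct` (of a relative to b), and `test` (a
#'   [compare_conditions()] result).
#' @export
study_comparison <- function(wm_table, montage,
                             method_a = "raw-msp", method_b = "memd-msp",
                             n_comparisons = 1L) {
  sub <- wm_table[wm_table$montage == montage, ]
  per_seed <- function(meth) {
    s <- sub[sub$method == meth, ]
    if (!nrow(s)) stop("no rows for method ", meth)
    agg <- stats::aggregate(wm ~ seed, s, mean)
    agg[order(agg$seed), "wm"]
  }
  wa <- per_seed(method_a)
  wb <- per_seed(method_b)
  list(wm_a = wa, wm_b = wb, mean_a = mean(wa), mean_b = mean(wb),
       reduction_pct = percent_reduction(mean(wa), mean(wb)),
       test = compare_conditions(wa, wb, n_comparisons = n_comparisons))
}

#' Load an EEG recording
#'
#' @param path file path.
#' @param format `"auto"` (by extension/signature), `"delimited"` or
#'   `"edf"`.
#' @return an `eeg_signal`.
#' @export
load_eeg <- function(path, format = c("auto", "delimited", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  }
  if (format == "edf") read_edf(path) else read_eeg(path)
}
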