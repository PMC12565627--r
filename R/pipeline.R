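#' Run the full profiling pipeline on a synthetic scenario or a manifest
#'
#' Orchestrates quantification -> histogram profiling -> peak statistics ->
#' mitochondrial CDF segmentation -> SA-beta-Gal scoring, writing every
#' tabular result as CSV plus a diagnostics JSON and a plain-text run log
#' that records all parameters and every excluded datum (zero-intensity
#' pixels, shape-test exclusions, undefined selectivity indices). Figures
#' are views of the CSVs, never sole outputs.
#'
#' @param config list or JSON file path. Recognised fields: \code{seed},
#'   \code{out_dir}, \code{scenario} (overrides passed to
#'   \code{scenario_spec}), \code{manifest} (CSV path; when present the
#'   lysosomal arm quantifies real images instead of synthetic
#'   populations), \code{n_bins}, \code{smooth_window}, \code{prominence_frac},
#'   \code{min_distance_frac}, \code{cdf_grid_size}, \code{cdf_smooth_window},
#'   \code{donor_ref}, \code{inducer_ref}, \code{min_peaks},
#'   \code{redistribution_threshold}, \code{fdr_level}, \code{render}
#'   (logical, default FALSE).
#' @return invisibly, a run report list: \code{peaks}, \code{lmm},
#'   \code{diagnostics}, \code{shape_tests}, \code{mito}, \code{redistribution},
#'   \code{scores}, \code{flow}, \code{paths}.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(list(
    seed = 1L, out_dir = tempfile("senoscope_run"), scenario = list(),
    manifest = NULL, n_bins = NULL, smooth_window = NULL,
    prominence_frac = NULL, min_distance_frac = NULL,
    cdf_grid_size = 1000L, cdf_smooth_window = NULL,
    donor_ref = "YD", inducer_ref = "C10", min_peaks = 2L,
    redistribution_threshold = 5, fdr_level = 0.05, render = FALSE
  ), config)
  if (!is.null(cfg$manifest) && !file.exists(cfg$manifest)) {
    stop("manifest not found: ", cfg$manifest, call. = FALSE)
  }
  spec <- do.call(scenario_spec, c(list(seed = cfg$seed), cfg$scenario))
  n_bins <- cfg$n_bins %||% spec$profile_n_bins
  smooth_window <- cfg$smooth_window %||% spec$profile_smooth_window
  prom_frac <- cfg$prominence_frac %||% spec$profile_prominence_frac
  dist_frac <- cfg$min_distance_frac %||% spec$profile_min_distance_frac
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("senoscope run, seed %d", cfg$seed),
                 sprintf("profiling: n_bins=%d smooth_window=%d prominence_frac=%g min_distance_frac=%g",
                         n_bins, smooth_window, prom_frac, dist_frac))

  ## ---- lysosomal arm: per-condition event populations -> profiles -> peaks
  if (!is.null(cfg$manifest)) {
    cells_tbl <- quantify_cells(cfg$manifest)
    conds <- unique(cells_tbl[, c("donor", "inducer")])
    pops <- lapply(seq_len(nrow(conds)), function(i) {
      sel <- cells_tbl$donor == conds$donor[i] &
        cells_tbl$inducer == conds$inducer[i]
      list(donor = conds$donor[i], inducer = conds$inducer[i],
           cells = cells_tbl$densities[sel], truth = NULL)
    })
    utils::write.csv(cells_tbl[, c("cell_id", "donor", "inducer", "area_um2",
                                   "mean_density", "n_pixels")],
                     file.path(cfg$out_dir, "cells.csv"), row.names = FALSE)
  } else {
    combos <- expand.grid(donor = names(spec$donors),
                          inducer = names(spec$inducers),
                          stringsAsFactors = FALSE)
    pops <- lapply(seq_len(nrow(combos)), function(i) {
      g <- generate_intensity_population(spec, combos$donor[i],
                                         combos$inducer[i])
      list(donor = combos$donor[i], inducer = combos$inducer[i],
           cells = g$cells, truth = g$truth)
    })
  }
  peak_rows <- list()
  profile_rows <- list()
  truth_rows <- list()
  for (p in pops) {
    curve <- paste(p$donor, p$inducer, sep = "_")
    prof <- build_profile(p$cells, n_bins = n_bins)
    pk <- detect_peaks(prof,
                       prominence = prom_frac * max(moving_average(
                         prof$mean_counts, smooth_window)),
                       min_distance = max(1L, round(dist_frac * n_bins)),
                       smooth_window = smooth_window, curve_id = curve)
    pk$donor <- rep(p$donor, nrow(pk))
    pk$inducer <- rep(p$inducer, nrow(pk))
    peak_rows[[curve]] <- pk
    nb <- length(prof$mean_counts)
    profile_rows[[curve]] <- data.frame(
      curve_id = curve, bin_left = prof$bin_edges[-(nb + 1L)],
      bin_right = prof$bin_edges[-1L], mean_count = prof$mean_counts,
      stringsAsFactors = FALSE)
    log_lines <- c(log_lines, sprintf(
      "curve %s: %d cells, %d zero-intensity events excluded, %d peaks",
      curve, prof$n_cells, prof$n_zero_excluded, nrow(pk)))
    if (!is.null(p$truth)) {
      truth_rows[[curve]] <- data.frame(
        curve_id = curve, peak_id = seq_along(p$truth$modes_log10),
        true_log10_mode = p$truth$modes_log10, stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, peak_rows)
  rownames(peaks) <- NULL
  utils::write.csv(peaks, file.path(cfg$out_dir, "peaks.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, profile_rows),
                   file.path(cfg$out_dir, "profiles.csv"), row.names = FALSE)
  if (length(truth_rows)) {
    utils::write.csv(do.call(rbind, truth_rows),
                     file.path(cfg$out_dir, "peak_truth.csv"),
                     row.names = FALSE)
  }

  ## ---- peak statistics
  obs <- data.frame(log10_xpeak = peaks$log10_position, donor = peaks$donor,
                    inducer = peaks$inducer, peak_id = peaks$peak_id,
                    curve_id = peaks$curve_id, stringsAsFactors = FALSE)
  lmm <- fit_peak_lmm(obs, donor_ref = cfg$donor_ref,
                      inducer_ref = cfg$inducer_ref)
  utils::write.csv(lmm$fixed_effects,
                   file.path(cfg$out_dir, "lmm_coefficients.csv"),
                   row.names = FALSE)
  sw <- residual_normality(lmm)
  lev <- variance_homogeneity(obs$log10_xpeak, obs$donor)
  diagnostics <- list(shapiro_W = sw$W, shapiro_p = sw$p,
                      levene_F = lev$F, levene_p = lev$p,
                      random_intercept_variance = lmm$random_intercept_variance)
  jsonlite::write_json(diagnostics, file.path(cfg$out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  by_inducer <- split(peaks, peaks$inducer)
  shape_in <- lapply(by_inducer, function(d) {
    lapply(split(d$log10_position, d$donor), as.numeric)
  })
  shape_tests <- shape_compare(shape_in, min_peaks = cfg$min_peaks)
  utils::write.csv(shape_tests, file.path(cfg$out_dir, "shape_tests.csv"),
                   row.names = FALSE)
  for (i in which(!shape_tests$included)) {
    log_lines <- c(log_lines, sprintf("shape test excluded inducer %s (%s)",
                                      shape_tests$inducer[i],
                                      shape_tests$exclusion_reason[i]))
  }

  ## ---- mitochondrial arm: one CDF per donor, C10 as redistribution reference
  mito_rows <- list()
  redis_rows <- list()
  for (dn in names(spec$donors)) {
    frac_by_ind <- list()
    for (ind in names(spec$inducers)) {
      g <- generate_mito_population(
        spec, seed = child_seed(spec$seed, paste("mito", dn, ind)))
      cdf <- build_cdf(g$values, grid_size = cfg$cdf_grid_size)
      cdf <- find_inflexions(cdf, smooth_window = cfg$cdf_smooth_window)
      fr <- segment_fractions(cdf)
      th <- c(cdf$thetas, NA_real_, NA_real_)[1:2]
      frac_by_ind[[ind]] <- fr
      mito_rows[[paste(dn, ind)]] <- data.frame(
        donor = dn, inducer = ind, theta1 = th[1L], theta2 = th[2L],
        dpsi1 = fr[1L], dpsi2 = fr[2L], dpsi3 = fr[3L],
        n_cells = cdf$n, stringsAsFactors = FALSE)
    }
    ref <- frac_by_ind[["C10"]]
    for (ind in setdiff(names(spec$inducers), "C10")) {
      if (anyNA(ref) || anyNA(frac_by_ind[[ind]])) next
      rd <- redistribution(ref, frac_by_ind[[ind]],
                           threshold = cfg$redistribution_threshold)
      redis_rows[[paste(dn, ind)]] <- data.frame(
        donor = dn, reference = "C10", treatment = ind,
        delta1 = rd$deltas[1L], delta2 = rd$deltas[2L], delta3 = rd$deltas[3L],
        sig1 = rd$significant[1L], sig2 = rd$significant[2L],
        sig3 = rd$significant[3L], stringsAsFactors = FALSE)
    }
  }
  mito <- do.call(rbind, mito_rows); rownames(mito) <- NULL
  redis <- do.call(rbind, redis_rows); rownames(redis) <- NULL
  utils::write.csv(mito, file.path(cfg$out_dir, "mito_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(redis, file.path(cfg$out_dir, "redistribution.csv"),
                   row.names = FALSE)

  ## ---- SA-beta-Gal scoring + flow summaries
  ct <- generate_count_tables(spec)
  scores <- score_conditions(ct$counts, control = "control")
  utils::write.csv(scores, file.path(cfg$out_dir, "scores.csv"),
                   row.names = FALSE)
  for (i in which(!scores$SI_defined)) {
    log_lines <- c(log_lines, sprintf("undefined SI for condition %s",
                                      scores$condition[i]))
  }
  flow <- do.call(rbind, lapply(split(ct$flow$intensity, ct$flow$condition),
                                function(v) {
                                  fs <- flow_summary(v)
                                  data.frame(mfi = fs$mfi, iqr = fs$iqr,
                                             n = fs$n)
                                }))
  flow <- data.frame(condition = rownames(flow), flow,
                     row.names = NULL, stringsAsFactors = FALSE)
  utils::write.csv(flow, file.path(cfg$out_dir, "flow_summary.csv"),
                   row.names = FALSE)

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  report <- list(peaks = peaks, lmm = lmm, diagnostics = diagnostics,
                 shape_tests = shape_tests, mito = mito,
                 redistribution = redis, scores = scores, flow = flow,
                 profiles = do.call(rbind, profile_rows),
                 truth = if (length(truth_rows)) do.call(rbind, truth_rows),
                 out_dir = cfg$out_dir,
                 paths = file.path(cfg$out_dir,
                                   c("peaks.csv", "profiles.csv",
                                     "lmm_coefficients.csv", "diagnostics.json",
                                     "shape_tests.csv", "mito_fractions.csv",
                                     "redistribution.csv", "scores.csv",
                                     "flow_summary.csv", "run_log.txt")))
  if (isTRUE(cfg$render)) render_figures(report, cfg$out_dir)
  invisible(report)
}

#' Render the figure analogues of a pipeline run
#'
#' Log-log profile panels per donor with axis limits frozen across all
#' conditions (direct comparability), CDF-style stacked fraction bars per
#' donor-inducer pair, and peak-position box summaries by donor and by
#' inducer. Every plotted number also exists in a CSV written by
#' \code{run_pipeline}.
#'
#' @param report a run report from \code{run_pipeline}.
#' @param out_dir directory for the PNG files (default: the run's).
#' @return invisibly, the written file paths.
#' @export
render_figures <- function(report, out_dir = report$out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  prof <- report$profiles
  if (!is.null(prof) && nrow(prof)) {
    prof <- prof[prof$mean_count > 0, ]
    prof$donor <- sub("_.*", "", prof$curve_id)
    prof$inducer <- sub(".*_", "", prof$curve_id)
    # pooled, frozen axis limits
    xl <- range(prof$bin_left); yl <- range(prof$mean_count)
    gp <- ggplot2::ggplot(prof, ggplot2::aes(x = bin_left, y = mean_count,
                                             colour = inducer)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::scale_x_log10(limits = xl) +
      ggplot2::scale_y_log10(limits = yl) +
      ggplot2::facet_wrap(~donor) +
      ggplot2::labs(x = "intensity density (a.u./um^2)",
                    y = "mean counts per bin per cell") +
      ggplot2::theme_minimal()
    p <- file.path(out_dir, "profiles.png")
    suppressWarnings(ggplot2::ggsave(p, gp, width = 9, height = 3.5, dpi = 120))
    paths <- c(paths, p)
  }
  if (!is.null(report$mito) && nrow(report$mito)) {
    m <- report$mito
    long <- data.frame(
      donor = rep(m$donor, 3), inducer = rep(m$inducer, 3),
      segment = rep(c("depolarised", "mid", "hyperpolarised"),
                    each = nrow(m)),
      percent = c(m$dpsi1, m$dpsi2, m$dpsi3))
    long$segment <- factor(long$segment,
                           levels = c("depolarised", "mid", "hyperpolarised"))
    gp <- ggplot2::ggplot(long, ggplot2::aes(x = inducer, y = percent,
                                             fill = segment)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~donor) +
      ggplot2::labs(y = "% of cells") +
      ggplot2::theme_minimal()
    p <- file.path(out_dir, "mito_fractions.png")
    suppressWarnings(ggplot2::ggsave(p, gp, width = 9, height = 3.5, dpi = 120))
    paths <- c(paths, p)
  }
  if (!is.null(report$peaks) && nrow(report$peaks)) {
    pk <- report$peaks
    gp <- ggplot2::ggplot(pk, ggplot2::aes(x = donor, y = log10_position)) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::labs(y = "log10 peak position") +
      ggplot2::theme_minimal()
    p <- file.path(out_dir, "peaks_by_donor.png")
    suppressWarnings(ggplot2::ggsave(p, gp, width = 5, height = 3.5, dpi = 120))
    gp2 <- ggplot2::ggplot(pk, ggplot2::aes(x = inducer, y = log10_position,
                                            colour = donor)) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::labs(y = "log10 peak position") +
      ggplot2::theme_minimal()
    p2 <- file.path(out_dir, "peaks_by_inducer.png")
    suppressWarnings(ggplot2::ggsave(p2, gp2, width = 7, height = 3.5,
                                     dpi = 120))
    paths <- c(paths, p, p2)
  }
  invisible(paths)
}
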