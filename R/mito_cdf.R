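#' Empirical CDF of per-cell intensity densities on a log10 grid
#'
#' Summarises per-cell mean mitochondrial intensity densities (X, a.u. per
#' square micrometre) as a cumulative conversion curve alpha(u), u =
#' log10(X), scaled to percent of cells (0-100). The exact empirical CDF is
#' retained alongside the gridded curve so that segment fractions can be
#' evaluated free of grid bias.
#'
#' @param values positive per-cell densities (>= 10 required).
#' @param grid_size number of uniform grid points in u (default 1000).
#' @param u_range optional length-2 grid range in u; default spans the data.
#' @return A \code{cdf_profile}: \code{u_grid}, \code{alpha} (percent,
#'   nondecreasing), \code{u_data} (sorted log10 values), \code{n},
#'   \code{thetas}/\code{fractions} unset until segmentation.
#' @export
build_cdf <- function(values, grid_size = 1000L, u_range = NULL) {
  values <- values[!is.na(values)]
  pos <- values[values > 0]
  if (length(pos) < 10L) {
    stop("degenerate input: fewer than 10 positive values", call. = FALSE)
  }
  u <- sort(log10(pos))
  if (is.null(u_range)) u_range <- range(u)
  u_grid <- seq(u_range[1L], u_range[2L], length.out = grid_size)
  alpha <- 100 * stats::ecdf(u)(u_grid)
  structure(list(u_grid = u_grid, alpha = alpha, u_data = u,
                 n = length(u), thetas = NULL, fractions = NULL),
            class = "cdf_profile")
}

#' @export
print.cdf_profile <- function(x, ...) {
  cat("<cdf_profile> n = ", x$n, ", u in [",
      signif(min(x$u_grid), 4), ", ", signif(max(x$u_grid), 4), "]",
      if (!is.null(x$thetas)) paste0(", thetas = ",
                                     paste(signif(x$thetas, 4), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Data-driven inflexion points of a CDF
#'
#' The derivative d(alpha)/du -- the population density on the log10 axis --
#' is estimated by central finite differences on the grid, smoothed by a
#' moving average, and its local maxima are the inflexion points theta. When
#' more than two maxima pass the prominence floor, the two most prominent
#' become theta_1 < theta_2; with exactly one, theta_2 is unset and the
#' downstream partition degrades to two segments; with none (monotone or
#' flat density) the profile is flagged single-population.
#'
#' @param cdf a \code{cdf_profile}.
#' @param smooth_window moving-average window in grid points (default 5% of
#'   the grid, minimum 3): at a few hundred cells the finite-difference
#'   derivative of an empirical CDF is Poisson-noisy, and narrower windows
#'   let noise bumps through the prominence floor.
#' @param min_prominence_frac prominence floor as a fraction of the maximum
#'   smoothed derivative (default 0.25); keeps sampling noise on a flat
#'   density from minting spurious thresholds.
#' @param max_thetas maximum number of thresholds retained (default 2).
#' @return the profile with \code{thetas} (ascending, possibly length 0-2),
#'   \code{single_population} flag and \code{derivative} attached.
#' @export
find_inflexions <- function(cdf, smooth_window = NULL,
                            min_prominence_frac = 0.25, max_thetas = 2L) {
  g <- cdf$u_grid
  n <- length(g)
  if (is.null(smooth_window)) smooth_window <- max(3L, round(0.05 * n))
  du <- g[2L] - g[1L]
  d <- c(NA, (cdf$alpha[3:n] - cdf$alpha[1:(n - 2L)]) / (2 * du), NA)
  d[1L] <- d[2L]; d[n] <- d[n - 1L]
  ds <- moving_average(d, smooth_window)
  pk <- find_peaks_core(ds, prominence_min = min_prominence_frac * max(ds),
                        min_distance = smooth_window)
  idx <- pk$index
  if (length(idx) > max_thetas) {
    keep <- order(-pk$prominence)[seq_len(max_thetas)]
    idx <- sort(idx[keep])
  }
  cdf$thetas <- g[idx]
  cdf$single_population <- length(idx) == 0L
  cdf$derivative <- ds
  cdf
}

#' Segment fractions of a CDF at two thresholds
#'
#' Partitions the distribution into consecutive segments [min, theta_1],
#' [theta_1, theta_2], [theta_2, max] and reports the percent of cells in
#' each: dpsi_1 = alpha(theta_1), dpsi_2 = alpha(theta_2) - alpha(theta_1),
#' dpsi_3 = 100 - alpha(theta_2). Fractions are evaluated from the exact
#' empirical CDF (not the gridded curve) and sum to 100 for every curve.
#' With \code{theta2 = NULL} (single inflexion fallback) two segments are
#' returned and \code{dpsi3} is \code{NA}.
#'
#' @param cdf a \code{cdf_profile}.
#' @param theta1,theta2 thresholds in u, \code{theta1 < theta2}; defaults to
#'   the profile's detected \code{thetas}.
#' @return named numeric \code{c(dpsi1, dpsi2, dpsi3)} in percent.
#' @export
segment_fractions <- function(cdf, theta1 = NULL, theta2 = NULL) {
  if (is.null(theta1) && !is.null(cdf$thetas) && length(cdf$thetas) >= 1L) {
    theta1 <- cdf$thetas[1L]
    if (length(cdf$thetas) >= 2L) theta2 <- cdf$thetas[2L]
  }
  if (is.null(theta1)) {
    if (isTRUE(cdf$single_population)) {
      return(c(dpsi1 = 100, dpsi2 = 0, dpsi3 = 0))
    }
    stop("no thresholds available: run find_inflexions or supply theta1",
         call. = FALSE)
  }
  u <- cdf$u_data; n <- cdf$n
  if (is.null(theta2)) {
    d1 <- 100 * sum(u <= theta1) / n
    return(c(dpsi1 = d1, dpsi2 = 100 - d1, dpsi3 = NA_real_))
  }
  if (!(theta1 < theta2)) {
    stop("thresholds must satisfy theta1 < theta2", call. = FALSE)
  }
  n1 <- sum(u <= theta1)
  n12 <- sum(u <= theta2)
  d1 <- 100 * n1 / n
  d2 <- 100 * (n12 - n1) / n
  c(dpsi1 = d1, dpsi2 = d2, dpsi3 = 100 - d1 - d2)
}

#' Classify cells into membrane-potential subpopulations
#'
#' Labels each cell by the segment its log10 density falls in: depolarised
#' (u <= theta_1), mid (theta_1 < u <= theta_2), hyperpolarised (u >
#' theta_2). Percentages match \code{segment_fractions} exactly because both
#' use the same cut semantics on the same data.
#'
#' @param values positive per-cell densities (linear scale).
#' @param theta1,theta2 thresholds in u = log10(X).
#' @return list with \code{labels} (factor) and \code{percent} (named, sums
#'   to 100).
#' @export
classify_population <- function(values, theta1, theta2) {
  u <- log10(values)
  lab <- ifelse(u <= theta1, "depolarised",
                ifelse(u <= theta2, "mid", "hyperpolarised"))
  lab <- factor(lab, levels = c("depolarised", "mid", "hyperpolarised"))
  counts <- table(lab)
  n <- length(u)
  pct <- 100 * counts[c("depolarised", "mid")] / n
  percent <- c(pct, hyperpolarised = 100 - sum(pct))
  names(percent) <- c("depolarised", "mid", "hyperpolarised")
  list(labels = lab, percent = percent)
}

#' Condition-to-condition redistribution of segment fractions
#'
#' Signed per-segment changes in percentage points between a reference and a
#' treatment triple. Deltas sum to zero (each triple sums to 100); a change
#' with absolute value less than or equal to the threshold (default 5
#' percentage points) is reported as not significant.
#'
#' @param reference,treatment numeric triples summing to 100.
#' @param threshold significance threshold in percentage points.
#' @return list with \code{deltas}, \code{significant} (logical per
#'   segment), \code{threshold}.
#' @export
redistribution <- function(reference, treatment, threshold = 5) {
  for (tr in list(reference, treatment)) {
    if (length(tr) != 3L || any(is.na(tr)) || any(tr < 0) ||
        abs(sum(tr) - 100) > 1e-6) {
      stop("fraction triples must be non-negative and sum to 100",
           call. = FALSE)
    }
  }
  deltas <- as.numeric(treatment) - as.numeric(reference)
  names(deltas) <- c("dpsi1", "dpsi2", "dpsi3")
  list(deltas = deltas,
       significant = abs(deltas) > threshold,
       threshold = threshold)
}
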