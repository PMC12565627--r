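#' Default synthetic study scenario
#'
#' Bundles every constant the generators need, with defaults emulating the
#' study design: three donor populations (young donor YD as reference, old
#' donor OD shifted +0.3 log10 units, replicatively senescent RS +0.5),
#' six induction conditions relative to the 10% serum control (C10), one to
#' three lognormal mixture components per curve whose log-modes climb by the
#' peak-order slope, a per-curve random intercept, bimodal mitochondrial
#' densities, and field-count/flow tables with known S%, survival and MFI.
#'
#' Donor/inducer offsets are calibration constants of the scenario (chosen
#' so age and induction shift peaks towards higher log10 positions at a
#' detectable desk scale), not biological claims. SA-beta-Gal percentages
#' default to the magnitudes reported for young/old/replicatively exhausted
#' fibroblast populations.
#'
#' @param seed integer seed; fans out deterministically to per-stream child
#'   seeds so modules can be regenerated independently.
#' @param ... overrides for any listed field.
#' @return A \code{scenario_spec} list.
#' @export
scenario_spec <- function(seed = 1L, ...) {
  spec <- list(
    seed = as.integer(seed),
    donors = c(YD = 0, OD = 0.3, RS = 0.5),
    inducers = c(C10 = 0, C1 = 0.10, Doxo = 0.12, Cis = 0.18, Eto = 0.08,
                 Bleo = 0.22),
    base_log10 = 0.6,
    peak_slope = 0.4,
    curve_intercept_sd = 0.1,
    residual_sd = 0.05,
    component_log_sd = 0.15,
    n_components = 2L,
    n_cells = 200L,
    events_per_cell = 500L,
    # desk-scale profiling settings (see methods vignette)
    profile_n_bins = 3000L,
    profile_smooth_window = 51L,
    profile_prominence_frac = 0.05,
    profile_min_distance_frac = 0.01,
    # mitochondrial arm
    mito_modes_u = c(1.0, 2.5),
    mito_weights = c(0.3, 0.7),
    mito_log_sd = 0.25,
    mito_n_cells = 500L,
    # SA-beta-Gal / flow arm
    s_percent = c(YD = 2.5, OD = 9.1, RS = 16.3),
    v_rel = c(YD = 95, OD = 85, RS = 70),
    fields_per_condition = 5L,
    cells_per_field = 200L,
    flow_mfi = c(C10 = 100, C1 = 175, Doxo = 250, Eto = 250, Cis = 350,
                 Bleo = 380),
    flow_log_sd = 0.6,
    flow_events = 200L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(spec))
  if (length(bad)) {
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  spec[names(over)] <- over
  if (abs(sum(spec$mito_weights) - 1) > 1e-9) {
    stop("mito_weights must sum to 1", call. = FALSE)
  }
  if (spec$n_components < 1L || spec$n_components > 3L) {
    stop("n_components must be between 1 and 3", call. = FALSE)
  }
  structure(spec, class = "scenario_spec")
}

#' Deterministic child seed for a named random stream
#'
#' Mixes the parent seed and a stream label through repeated Lehmer steps
#' modulo 2^31 - 1 so that related parents and labels land far apart in seed
#' space (nearby integer seeds give correlated early Mersenne-Twister
#' output; see also the burn-in in \code{seed_rng}).
#'
#' @param seed integer parent seed.
#' @param stream character stream label.
#' @return integer in [1, 2^31 - 2].
#' @export
child_seed <- function(seed, stream) {
  M <- 2147483647
  cp <- utf8ToInt(stream)
  x <- as.numeric(seed) %% M
  x <- (x * 48271 + sum(cp * seq_along(cp) * 131)) %% M
  x <- (x * 48271 + 11) %% M
  x <- (x * 48271) %% M
  as.integer(x %% 2147483645 + 1)
}

# Seed the session RNG and discard one full Mersenne-Twister block so the
# stream no longer reflects seeding artefacts (first outputs of nearby seeds
# are correlated before the first twist).
seed_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(stats::runif(701))
}

#' Generate peak-position observations with known fixed effects
#'
#' Draws curve-level data directly from the linear model the mixed model
#' estimates: position = base + donor offset + inducer offset +
#' slope * peak_id + curve intercept + residual. Curves cycle through all
#' donor-inducer combinations; the number of peaks per curve cycles through
#' 1..3.
#'
#' @param spec a \code{scenario_spec}.
#' @param n_curves number of curves (default 60).
#' @param seed optional override of the spec-derived stream seed.
#' @return data.frame of observations with attribute \code{truth} (named
#'   true fixed effects as the fitted model names them, plus variance
#'   components).
#' @export
generate_peak_observations <- function(spec = scenario_spec(), n_curves = 60L,
                                       seed = NULL) {
  seed_rng(seed %||% child_seed(spec$seed, "peak_obs"))
  combos <- expand.grid(donor = names(spec$donors),
                        inducer = names(spec$inducers),
                        stringsAsFactors = FALSE)
  idx <- rep_len(seq_len(nrow(combos)), n_curves)
  # random peak counts: keeps peaks-per-curve unconfounded with the
  # condition grid (a cyclic assignment would alias it with donor)
  n_peaks <- sample(1:3, n_curves, replace = TRUE)
  rows <- lapply(seq_len(n_curves), function(ci) {
    donor <- combos$donor[idx[ci]]
    inducer <- combos$inducer[idx[ci]]
    b <- stats::rnorm(1, 0, spec$curve_intercept_sd)
    pid <- seq_len(n_peaks[ci])
    data.frame(
      curve_id = sprintf("curve%03d", ci),
      donor = donor, inducer = inducer, peak_id = pid,
      log10_xpeak = spec$base_log10 + spec$donors[donor] +
        spec$inducers[inducer] + spec$peak_slope * pid + b +
        stats::rnorm(length(pid), 0, spec$residual_sd),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  truth <- c(
    "(Intercept)" = unname(spec$base_log10),
    stats::setNames(unname(spec$donors[-1L]),
                    paste0("donor", names(spec$donors)[-1L])),
    stats::setNames(unname(spec$inducers[-1L]),
                    paste0("inducer", names(spec$inducers)[-1L])),
    peak_id = unname(spec$peak_slope)
  )
  attr(out, "truth") <- list(fixed = truth,
                             curve_intercept_sd = spec$curve_intercept_sd,
                             residual_sd = spec$residual_sd)
  out
}

#' Generate a per-cell lysosomal intensity population for one condition
#'
#' Each cell contributes \code{events_per_cell} events drawn from the
#' condition's lognormal mixture: component log-modes are base + donor +
#' inducer offsets + slope * k for component k, shifted by one curve-level
#' random intercept shared by all cells of the condition. The realised
#' (intercept-shifted) modes are the ground truth a peak detector should
#' recover from this curve.
#'
#' @param spec a \code{scenario_spec}.
#' @param donor,inducer condition labels present in the spec.
#' @param n_cells,events_per_cell overrides of the spec values.
#' @param seed optional override of the spec-derived stream seed.
#' @return list with \code{cells} (list of per-cell event vectors, linear
#'   a.u. per square micrometre) and \code{truth} (\code{modes_log10}
#'   ascending, \code{curve_intercept}, \code{component_log_sd}).
#' @export
generate_intensity_population <- function(spec = scenario_spec(),
                                          donor = "YD", inducer = "C10",
                                          n_cells = spec$n_cells,
                                          events_per_cell = spec$events_per_cell,
                                          seed = NULL) {
  if (!donor %in% names(spec$donors)) stop("unknown donor: ", donor, call. = FALSE)
  if (!inducer %in% names(spec$inducers)) {
    stop("unknown inducer: ", inducer, call. = FALSE)
  }
  seed_rng(seed %||% child_seed(spec$seed, paste("lyso", donor, inducer)))
  m <- spec$n_components
  mu <- spec$base_log10 + spec$donors[donor] + spec$inducers[inducer] +
    spec$peak_slope * seq_len(m)
  b <- stats::rnorm(1, 0, spec$curve_intercept_sd)
  mu <- unname(mu) + b
  cells <- lapply(seq_len(n_cells), function(i) {
    comp <- sample.int(m, events_per_cell, replace = TRUE)
    10^stats::rnorm(events_per_cell, mu[comp], spec$component_log_sd)
  })
  list(cells = cells,
       truth = list(modes_log10 = mu, curve_intercept = b,
                    component_log_sd = spec$component_log_sd))
}

#' Generate a bimodal mitochondrial per-cell density population
#'
#' Per-cell mean densities from a two-component lognormal mixture, with the
#' analytic mixture CDF attached so recovered segment fractions can be
#' compared to truth at any threshold.
#'
#' @param spec a \code{scenario_spec}.
#' @param n_cells override of \code{spec$mito_n_cells}.
#' @param seed optional override of the spec-derived stream seed.
#' @return list with \code{values} (linear densities), \code{truth}:
#'   \code{weights}, \code{modes_u}, \code{log_sd}, \code{alpha} (function
#'   u -> percent of cells below), \code{planned_thetas} (the component
#'   modes, the density maxima an inflexion search should find) and
#'   \code{fractions_at} (function returning the analytic triple for any
#'   theta pair).
#' @export
generate_mito_population <- function(spec = scenario_spec(),
                                     n_cells = spec$mito_n_cells,
                                     seed = NULL) {
  w <- spec$mito_weights
  if (length(w) != 2L) stop("mito scenario needs exactly 2 components",
                            call. = FALSE)
  seed_rng(seed %||% child_seed(spec$seed, "mito"))
  comp <- sample.int(2L, n_cells, replace = TRUE, prob = w)
  u <- stats::rnorm(n_cells, spec$mito_modes_u[comp], spec$mito_log_sd)
  alpha <- function(q) {
    100 * (w[1] * stats::pnorm(q, spec$mito_modes_u[1], spec$mito_log_sd) +
             w[2] * stats::pnorm(q, spec$mito_modes_u[2], spec$mito_log_sd))
  }
  fractions_at <- function(theta1, theta2) {
    a1 <- alpha(theta1); a2 <- alpha(theta2)
    c(dpsi1 = a1, dpsi2 = a2 - a1, dpsi3 = 100 - a2)
  }
  list(values = 10^u,
       truth = list(weights = w, modes_u = spec$mito_modes_u,
                    log_sd = spec$mito_log_sd, alpha = alpha,
                    planned_thetas = spec$mito_modes_u,
                    fractions_at = fractions_at))
}

#' Generate SA-beta-Gal field counts and flow-cytometry events
#'
#' Field totals are Poisson around the per-field cell load (scaled by the
#' condition's true relative survival), positives binomial around the true
#' S%, and flow events lognormal with the condition MFI as median.
#'
#' @param spec a \code{scenario_spec}.
#' @param seed optional override of the spec-derived stream seed.
#' @return list with \code{counts} (condition, field_id, n_positive,
#'   n_total; conditions are the donors plus a \code{control}), \code{flow}
#'   (condition, intensity), and \code{truth} (s_percent, v_rel, mfi).
#' @export
generate_count_tables <- function(spec = scenario_spec(), seed = NULL) {
  seed_rng(seed %||% child_seed(spec$seed, "counts"))
  nf <- spec$fields_per_condition
  cpf <- spec$cells_per_field
  conds <- names(spec$s_percent)
  ctrl <- data.frame(condition = "control", field_id = seq_len(nf),
                     n_total = stats::rpois(nf, cpf), stringsAsFactors = FALSE)
  ctrl$n_positive <- stats::rbinom(nf, ctrl$n_total, 0.01)
  rows <- lapply(conds, function(cn) {
    tot <- stats::rpois(nf, cpf * spec$v_rel[cn] / 100)
    data.frame(condition = cn, field_id = seq_len(nf),
               n_total = tot,
               n_positive = stats::rbinom(nf, tot, spec$s_percent[cn] / 100),
               stringsAsFactors = FALSE)
  })
  counts <- rbind(ctrl, do.call(rbind, rows))
  counts <- counts[, c("condition", "field_id", "n_positive", "n_total")]
  flow <- do.call(rbind, lapply(names(spec$flow_mfi), function(cn) {
    data.frame(condition = cn,
               intensity = stats::rlnorm(spec$flow_events,
                                         log(spec$flow_mfi[cn]),
                                         spec$flow_log_sd),
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, flow = flow,
       truth = list(s_percent = spec$s_percent, v_rel = spec$v_rel,
                    mfi = spec$flow_mfi))
}

#' Paint a synthetic masked cell field to disk
#'
#' Places non-overlapping elliptical cells of known pixel area on a zero
#' background, fills each with intensities drawn from the condition's
#' lognormal mixture, and writes the 16-bit TIFF image, one PNG mask per
#' cell, a sidecar metadata JSON with the pixel size, and a manifest CSV --
#' the complete on-disk input set of the quantification stage, with exact
#' ground truth.
#'
#' @param spec a \code{scenario_spec}.
#' @param dir output directory (created if needed).
#' @param donor,inducer condition labels.
#' @param image_size c(rows, cols) in pixels.
#' @param n_cells number of ellipses (>= 1).
#' @param pixel_size_um isotropic pixel size written to the sidecar.
#' @param seed optional override of the spec-derived stream seed.
#' @return list with \code{image_path}, \code{manifest_path},
#'   \code{manifest}, and \code{truth} (per-cell pixel areas, mean
#'   intensities and integrated intensities).
#' @export
generate_cell_field <- function(spec = scenario_spec(), dir = tempfile("field"),
                                donor = "YD", inducer = "C10",
                                image_size = c(128L, 128L), n_cells = 4L,
                                pixel_size_um = 0.5, seed = NULL) {
  if (n_cells < 1L) stop("n_cells must be at least 1", call. = FALSE)
  seed_rng(seed %||% child_seed(spec$seed, paste("field", donor, inducer)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nr <- image_size[1L]; nc <- image_size[2L]
  img <- matrix(0, nr, nc)
  occupied <- matrix(FALSE, nr, nc)
  masks <- vector("list", n_cells)
  attempts <- 0L
  placed <- 0L
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  m <- spec$n_components
  mu <- unname(spec$base_log10 + spec$donors[donor] + spec$inducers[inducer] +
                 spec$peak_slope * seq_len(m))
  while (placed < n_cells) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_cells) {
      stop("placement capacity exceeded: cells do not fit without overlap",
           call. = FALSE)
    }
    a <- stats::runif(1, nr / 16, nr / 8)  # semi-axes in pixels
    b <- stats::runif(1, nc / 16, nc / 8)
    cy <- stats::runif(1, a + 1, nr - a - 1)
    cx <- stats::runif(1, b + 1, nc - b - 1)
    ell <- ((rowg - cy) / a)^2 + ((colg - cx) / b)^2 <= 1
    if (!any(ell) || any(ell & occupied)) next
    placed <- placed + 1L
    occupied <- occupied | ell
    masks[[placed]] <- ell
    npx <- sum(ell)
    comp <- sample.int(m, npx, replace = TRUE)
    img[ell] <- 10^stats::rnorm(npx, mu[comp], spec$component_log_sd)
  }
  img16 <- pmin(round(img), 65535)
  image_path <- file.path(dir, "field.tiff")
  tiff::writeTIFF(img16 / 65535, image_path, bits.per.sample = 16,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_x_um = pixel_size_um,
                            pixel_size_y_um = pixel_size_um),
                       paste0(image_path, ".json"), auto_unbox = TRUE)
  mask_paths <- vapply(seq_len(n_cells), function(i) {
    p <- file.path(dir, sprintf("mask_%02d.png", i))
    png::writePNG(masks[[i]] * 1.0, p)
    p
  }, character(1))
  manifest <- data.frame(image_path = image_path, mask_path = mask_paths,
                         donor = donor, inducer = inducer,
                         cell_id = sprintf("%s_%s_%02d", donor, inducer,
                                           seq_len(n_cells)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  areas_px <- vapply(masks, sum, numeric(1))
  integrated <- vapply(masks, function(mk) sum(img16[mk]), numeric(1))
  list(image_path = image_path, manifest_path = manifest_path,
       manifest = manifest,
       truth = list(areas_px = areas_px,
                    areas_um2 = areas_px * pixel_size_um^2,
                    integrated_intensity = integrated,
                    pixel_size_um = pixel_size_um))
}
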