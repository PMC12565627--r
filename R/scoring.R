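#' SA-beta-Gal positive fraction across visual fields
#'
#' Per-field percentages of stained cells, summarised as mean and standard
#' error across fields. Fields are the replication unit, so the SE is taken
#' across field-level percentages rather than from a pooled binomial.
#' Zero-total fields are excluded with a warning.
#'
#' @param n_positive,n_total integer vectors, one entry per field
#'   (0 <= positive <= total).
#' @return list with \code{s_percent} (mean), \code{se}, \code{per_field},
#'   \code{n_fields}.
#' @export
positive_fraction <- function(n_positive, n_total) {
  if (length(n_positive) != length(n_total)) {
    stop("n_positive and n_total must have equal length", call. = FALSE)
  }
  if (any(n_positive < 0) || any(n_total < 0) || any(n_positive > n_total)) {
    stop("counts must satisfy 0 <= n_positive <= n_total", call. = FALSE)
  }
  keep <- n_total > 0
  if (!any(keep)) stop("all fields have zero total cells", call. = FALSE)
  if (!all(keep)) {
    warning(sum(!keep), " zero-total field(s) excluded", call. = FALSE)
  }
  pf <- 100 * n_positive[keep] / n_total[keep]
  se <- if (length(pf) > 1L) stats::sd(pf) / sqrt(length(pf)) else NA_real_
  list(s_percent = mean(pf), se = se, per_field = pf, n_fields = length(pf))
}

#' Relative survival versus control
#'
#' Each treated field's total cell count divided by the mean total of the
#' control fields, times 100, averaged across treated fields. Values above
#' 100 (proliferation under treatment) are legal everywhere except in the
#' selectivity index.
#'
#' @param treated_totals,control_totals integer vectors of field totals.
#' @return list with \code{v_rel_percent} and \code{per_field}.
#' @export
relative_survival <- function(treated_totals, control_totals) {
  cm <- mean(control_totals)
  if (!is.finite(cm) || cm <= 0) {
    stop("control mean total must be positive", call. = FALSE)
  }
  per_field <- 100 * treated_totals / cm
  list(v_rel_percent = mean(per_field), per_field = per_field)
}

#' Selectivity index of senescence induction
#'
#' SI = S% / (100 - V%rel): the yield of induced senescent cells per unit of
#' cell loss. Ranks inducers by how selectively they push cells into
#' senescence rather than death. Undefined when relative survival reaches
#' 100% (no cell loss); that case returns an undefined result with a reason
#' rather than an error.
#'
#' @param s_percent SA-beta-Gal positive percentage (0-100).
#' @param v_rel_percent relative survival percentage (>= 0).
#' @return list with \code{si}, \code{defined}, \code{reason}.
#' @export
selectivity_index <- function(s_percent, v_rel_percent) {
  if (s_percent < 0 || s_percent > 100) {
    stop("s_percent must lie in [0, 100]", call. = FALSE)
  }
  if (v_rel_percent < 0) stop("v_rel_percent must be >= 0", call. = FALSE)
  if (v_rel_percent >= 100 * (1 - 1e-12)) {
    return(list(si = NA_real_, defined = FALSE,
                reason = "relative survival >= 100%: no net cell loss"))
  }
  list(si = s_percent / (100 - v_rel_percent), defined = TRUE, reason = NA_character_)
}

#' Flow-cytometry event summary
#'
#' Median fluorescence intensity and interquartile range of a per-event
#' intensity population. Quartiles use linear interpolation (R quantile
#' type 7), declared in the output.
#'
#' @param events numeric vector of per-event intensities (>= 10 events).
#' @return list with \code{mfi}, \code{iqr}, \code{n},
#'   \code{quartile_type}.
#' @export
flow_summary <- function(events) {
  events <- events[!is.na(events)]
  if (length(events) < 10L) {
    stop("at least 10 events are required", call. = FALSE)
  }
  q <- stats::quantile(events, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(mfi = q[2L], iqr = q[3L] - q[1L], n = length(events), quartile_type = 7L)
}

#' Score all conditions of a field-count table
#'
#' Applies \code{positive_fraction}, \code{relative_survival} and
#' \code{selectivity_index} per condition against a named control.
#'
#' @param counts data.frame with columns \code{condition}, \code{field_id},
#'   \code{n_positive}, \code{n_total}.
#' @param control name of the control condition used for relative survival.
#' @return data.frame: \code{condition}, \code{S_percent}, \code{S_SE},
#'   \code{V_rel}, \code{SI}, \code{SI_defined}.
#' @export
score_conditions <- function(counts, control) {
  need <- c("condition", "field_id", "n_positive", "n_total")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("counts lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!control %in% counts$condition) {
    stop("control condition '", control, "' absent from counts", call. = FALSE)
  }
  ctrl_totals <- counts$n_total[counts$condition == control]
  conds <- unique(counts$condition)
  rows <- lapply(conds, function(cn) {
    sub <- counts[counts$condition == cn, ]
    pf <- positive_fraction(sub$n_positive, sub$n_total)
    rs <- relative_survival(sub$n_total, ctrl_totals)
    si <- selectivity_index(pf$s_percent, rs$v_rel_percent)
    data.frame(condition = cn, S_percent = pf$s_percent, S_SE = pf$se,
               V_rel = rs$v_rel_percent, SI = si$si, SI_defined = si$defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
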