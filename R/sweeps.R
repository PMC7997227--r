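#' Specification of a one-dimensional sweep
#'
#' Describes which axis to sweep (diagnostic threshold, standard
#' measurement uncertainty, or total population sample size), the grid of
#' values, which measures to evaluate and the output mode. Grids must be
#' strictly increasing with at least two points; sample-size grids are
#' integers >= 4 (so each population can keep at least two subjects).
#'
#' @param axis \code{"threshold"}, \code{"measurement_uncertainty"} or
#'   \code{"sample_size"}.
#' @param grid Strictly increasing numeric vector (integers for
#'   \code{"sample_size"}), length >= 2.
#' @param measures Character vector of measure identifiers; defaults to all
#'   eleven.
#' @param output \code{"absolute"} (standard uncertainties),
#'   \code{"relative"} (uncertainty / value) or \code{"ci"} (confidence
#'   bounds).
#' @return An object of class \code{sweep_spec}.
#' @examples
#' sweep_spec("threshold", seq(1.1, 2.5, length.out = 15), "DOR")
#' @export
sweep_spec <- function(axis = c("threshold", "measurement_uncertainty",
                                "sample_size"),
                       grid, measures = dam_ids(),
                       output = c("absolute", "relative", "ci")) {
  axis <- match.arg(axis)
  output <- match.arg(output)
  measures <- match_dam_id(measures)
  if (!is.numeric(grid) || length(grid) < 2 || any(!is.finite(grid)) ||
      any(diff(grid) <= 0))
    stop("`grid` must be a strictly increasing numeric vector, length >= 2",
         call. = FALSE)
  if (axis == "sample_size" && (any(grid != round(grid)) || any(grid < 4)))
    stop("sample-size grid values must be integers >= 4", call. = FALSE)
  if (axis == "measurement_uncertainty" && any(grid < 0))
    stop("measurement-uncertainty grid values must be non-negative",
         call. = FALSE)
  structure(list(axis = axis, grid = grid, measures = measures,
                 output = output), class = "sweep_spec")
}

# one rectangular row of the sweep schema from a propagate() breakdown
breakdown_row <- function(axis, value, b) {
  rel <- relative_uncertainty(b)
  data.frame(
    axis = axis, axis_value = value, measure = b$measure,
    value = b$value, u_meas = b$u_meas, u_samp = b$u_samp, u_c = b$u_c,
    v_eff = b$v_eff,
    rel_meas = unname(rel["rel_meas"]), rel_samp = unname(rel["rel_samp"]),
    rel_c = unname(rel["rel_c"]),
    ci_lo = unname(b$ci["lower"]), ci_hi = unname(b$ci["upper"]),
    flag = b$flag, stringsAsFactors = FALSE, row.names = NULL)
}

sweep_rows <- function(axis, scenarios, values, measures) {
  rows <- vector("list", length(values) * length(measures))
  k <- 0L
  for (i in seq_along(values)) {
    for (m in measures) {
      k <- k + 1L
      rows[[k]] <- breakdown_row(axis, values[i],
                                 propagate(m, scenarios[[i]]))
    }
  }
  do.call(rbind, rows)
}

#' Sweep the uncertainty budget along the diagnostic threshold
#'
#' Evaluates \code{\link{propagate}} for every requested measure at every
#' threshold in the grid, with all other scenario parameters fixed. Grid
#' points where a measure is unbounded or undefined are flagged, not
#' dropped, so the result is always rectangular. Each grid point is an
#' independent evaluation identical to the single-point calculator.
#'
#' @param s A \code{\link{scenario}} (its own threshold is ignored).
#' @param spec A \code{\link{sweep_spec}} with \code{axis = "threshold"}.
#' @return An object of class \code{sweep_result}: a data frame with
#'   columns \code{axis}, \code{axis_value}, \code{measure}, \code{value},
#'   \code{u_meas}, \code{u_samp}, \code{u_c}, \code{v_eff},
#'   \code{rel_meas}, \code{rel_samp}, \code{rel_c}, \code{ci_lo},
#'   \code{ci_hi}, \code{flag}, and the spec as an attribute.
#' @examples
#' sw <- sweep_threshold(glucose_example(),
#'                       sweep_spec("threshold", seq(1.1, 2.5, 0.1), "DOR"))
#' @export
sweep_threshold <- function(s, spec) {
  stopifnot(inherits(s, "scenario"), inherits(spec, "sweep_spec"))
  if (spec$axis != "threshold")
    stop("spec axis must be \"threshold\"", call. = FALSE)
  scenarios <- lapply(spec$grid, function(d)
    scenario(s$non_diseased, s$diseased, s$measurement, d, s$confidence))
  out <- sweep_rows("threshold", scenarios, spec$grid, spec$measures)
  structure(out, spec = spec, class = c("sweep_result", "data.frame"))
}

#' Sweep the uncertainty budget along the measurement uncertainty
#'
#' As \code{\link{sweep_threshold}}, but varying the standard measurement
#' uncertainty \code{u_m} with the threshold fixed.
#'
#' @param s A \code{\link{scenario}} (its own \code{u_m} is ignored).
#' @param spec A \code{\link{sweep_spec}} with
#'   \code{axis = "measurement_uncertainty"}.
#' @return A \code{sweep_result}; see \code{\link{sweep_threshold}}.
#' @export
sweep_measurement_uncertainty <- function(s, spec) {
  stopifnot(inherits(s, "scenario"), inherits(spec, "sweep_spec"))
  if (spec$axis != "measurement_uncertainty")
    stop("spec axis must be \"measurement_uncertainty\"", call. = FALSE)
  scenarios <- lapply(spec$grid, function(um)
    scenario(s$non_diseased, s$diseased,
             measurement_model(um, s$measurement$n_u),
             s$threshold, s$confidence))
  out <- sweep_rows("measurement_uncertainty", scenarios, spec$grid,
                    spec$measures)
  structure(out, spec = spec, class = c("sweep_result", "data.frame"))
}

#' Sweep the uncertainty budget along the total sample size
#'
#' For each total size \code{n} in the grid the two population sizes are
#' set to \code{n_D = round(r n)} and \code{n_ND = n - n_D}, each floored
#' at 2, and the whole uncertainty chain recomputed. Grid points where
#' either population would fall below 2 subjects are flagged undefined.
#'
#' @param s A \code{\link{scenario}} supplying means, SDs, measurement
#'   model, threshold and confidence level.
#' @param r Prevalence rate in (0, 1) used to split each total size.
#' @param spec A \code{\link{sweep_spec}} with \code{axis = "sample_size"}.
#' @return A \code{sweep_result}; see \code{\link{sweep_threshold}}.
#' @export
sweep_sample_size <- function(s, r, spec) {
  stopifnot(inherits(s, "scenario"), inherits(spec, "sweep_spec"))
  if (spec$axis != "sample_size")
    stop("spec axis must be \"sample_size\"", call. = FALSE)
  if (!is.numeric(r) || r <= 0 || r >= 1)
    stop("`r` must be in (0, 1)", call. = FALSE)
  split_n <- function(n) {
    n_d <- max(2L, as.integer(round(r * n)))
    n_nd <- n - n_d
    if (n_nd < 2L) return(NULL)
    c(n_d = n_d, n_nd = n_nd)
  }
  rows <- list(); k <- 0L
  for (n in spec$grid) {
    ns <- split_n(n)
    for (m in spec$measures) {
      k <- k + 1L
      if (is.null(ns)) {
        rows[[k]] <- data.frame(
          axis = "sample_size", axis_value = n, measure = m,
          value = NA_real_, u_meas = NA_real_, u_samp = NA_real_,
          u_c = NA_real_, v_eff = NA_real_, rel_meas = NA_real_,
          rel_samp = NA_real_, rel_c = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, flag = "undefined",
          stringsAsFactors = FALSE, row.names = NULL)
      } else {
        sc <- scenario(
          population_sample(s$non_diseased$mean, s$non_diseased$sd,
                            ns["n_nd"]),
          population_sample(s$diseased$mean, s$diseased$sd, ns["n_d"]),
          s$measurement, s$threshold, s$confidence)
        rows[[k]] <- breakdown_row("sample_size", n, propagate(m, sc))
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, spec = spec, class = c("sweep_result", "data.frame"))
}

#' The three single-point calculator tables
#'
#' Evaluates the full uncertainty chain once for every measure at the
#' scenario's own settings and lays the results out as the three standard
#' tables: absolute standard uncertainties (measurement, sampling,
#' combined), relative standard uncertainties in percent, and point
#' estimates with confidence-interval bounds.
#'
#' @param s A \code{\link{scenario}}.
#' @return List with data frames \code{absolute}, \code{relative} (percent)
#'   and \code{ci}, each with one row per measure and a \code{flag} column.
#' @examples
#' calculator_tables(glucose_example())$relative
#' @export
calculator_tables <- function(s) {
  stopifnot(inherits(s, "scenario"))
  rows <- lapply(dam_ids(), function(m)
    breakdown_row("point", s$threshold, propagate(m, s)))
  full <- do.call(rbind, rows)
  list(
    absolute = full[, c("measure", "value", "u_meas", "u_samp", "u_c",
                        "flag")],
    relative = transform(
      full[, c("measure", "value", "flag")],
      rel_meas_pct = 100 * full$rel_meas,
      rel_samp_pct = 100 * full$rel_samp,
      rel_c_pct = 100 * full$rel_c)[
        , c("measure", "value", "rel_meas_pct", "rel_samp_pct",
            "rel_c_pct", "flag")],
    ci = full[, c("measure", "value", "v_eff", "ci_lo", "ci_hi", "flag")])
}
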