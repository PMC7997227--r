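#' Component uncertainties of the inputs
#'
#' Standard sampling uncertainties of a sample mean and SD, their combined
#' versions including measurement uncertainty, and the Agresti-Coull
#' standard uncertainty of the prevalence rate:
#' \itemize{
#'   \item \code{sampling_u_mean}: \eqn{u_s(m_P) = s_P / \sqrt{n_P}}
#'   \item \code{sampling_u_sd}: \eqn{u_s(s_P) = s_P / \sqrt{2 (n_P - 1)}}
#'   \item \code{combined_u_mean}: \eqn{u_c(m_P) = \sqrt{s_P^2/n_P + u_m^2}}
#'   \item \code{combined_u_sd}: \eqn{u_c(s_P) = \sqrt{s_P^2/(2(n_P-1)) + u_m^2}}
#'   \item \code{prevalence_u}:
#'     \eqn{u_s(r) = \sqrt{(2+n_{\bar D})(2+n_D)/(4+n_{\bar D}+n_D)^3}},
#'     the add-two-successes/add-two-failures adjusted Wald standard error.
#' }
#'
#' @param s A \code{\link{population_sample}}.
#' @param m A \code{\link{measurement_model}}.
#' @param n_nd,n_d Non-negative counts of non-diseased and diseased
#'   subjects; their sum must be positive.
#' @return A single non-negative number.
#' @examples
#' sampling_u_mean(population_sample(0, 1, 2488))
#' prevalence_u(2488, 179)
#' @name input_uncertainties
NULL

#' @rdname input_uncertainties
#' @export
sampling_u_mean <- function(s) {
  stopifnot(inherits(s, "population_sample"))
  s$sd / sqrt(s$n)
}

#' @rdname input_uncertainties
#' @export
sampling_u_sd <- function(s) {
  stopifnot(inherits(s, "population_sample"))
  s$sd / sqrt(2 * (s$n - 1))
}

#' @rdname input_uncertainties
#' @export
combined_u_mean <- function(s, m) {
  stopifnot(inherits(s, "population_sample"),
            inherits(m, "measurement_model"))
  sqrt(s$sd^2 / s$n + m$u_m^2)
}

#' @rdname input_uncertainties
#' @export
combined_u_sd <- function(s, m) {
  stopifnot(inherits(s, "population_sample"),
            inherits(m, "measurement_model"))
  sqrt(s$sd^2 / (2 * (s$n - 1)) + m$u_m^2)
}

#' @rdname input_uncertainties
#' @export
prevalence_u <- function(n_nd, n_d) {
  stopifnot(is.numeric(n_nd), is.numeric(n_d), n_nd >= 0, n_d >= 0)
  if (n_nd + n_d < 1)
    stop("at least one subject is required", call. = FALSE)
  sqrt((2 + n_nd) * (2 + n_d) / (4 + n_nd + n_d)^3)
}

# ---------------------------------------------------------------------------
# Gradients

# partials of (Se, Sp) wrt (m_D, s_D, m_ND, s_ND); rows Se, Sp
se_sp_gradient <- function(s) {
  zD <- (s$threshold - s$diseased$mean) / s$diseased$sd
  zN <- (s$threshold - s$non_diseased$mean) / s$non_diseased$sd
  phiD <- stats::dnorm(zD)
  phiN <- stats::dnorm(zN)
  rbind(
    Se = c(m_d  = phiD / s$diseased$sd,
           s_d  = phiD * zD / s$diseased$sd,
           m_nd = 0, s_nd = 0),
    Sp = c(m_d = 0, s_d = 0,
           m_nd = -phiN / s$non_diseased$sd,
           s_nd = -phiN * zN / s$non_diseased$sd))
}

# partials of measure wrt (se, sp, r); complements supplied for accuracy
measure_partials <- function(id, se, sp, r, se_c = 1 - se,
                             sp_c = 1 - sp) {
  switch(id,
    Se  = c(1, 0, 0),
    Sp  = c(0, 1, 0),
    PPV = {
      A <- r * se; B <- (1 - r) * sp_c
      c(r * B, (1 - r) * A, se * B + A * sp_c) / (A + B)^2
    },
    NPV = {
      C <- (1 - r) * sp; E <- r * se_c
      c(r * C, (1 - r) * E, -(sp * E + C * se_c)) / (C + E)^2
    },
    ODA = c(r, 1 - r, se - sp),
    DOR = c(sp / (se_c^2 * sp_c), se / (se_c * sp_c^2), 0),
    LRpos = c(1 / sp_c, se / sp_c^2, 0),
    LRneg = c(-1 / sp, -se_c / sp^2, 0),
    J   = c(1, 1, 0),
    ED  = {
      e <- sqrt(se_c^2 + sp_c^2)
      c(-se_c / e, -sp_c / e, 0)
    },
    CZ  = c(sp, se, 0))
}

#' Analytic gradient of a measure with respect to the scenario inputs
#'
#' Partial derivatives of a diagnostic accuracy measure with respect to the
#' five input parameters (diseased mean and SD, non-diseased mean and SD,
#' prevalence rate), obtained by the chain rule through sensitivity and
#' specificity. The normal-density derivatives of Se and Sp are exact;
#' the algebraic layer on top of (Se, Sp, r) is differentiated in closed
#' form. Prevalence-invariant measures have an exactly zero prevalence
#' component.
#'
#' @param id One measure identifier from \code{\link{dam_ids}}.
#' @param s A \code{\link{scenario}}.
#' @return Named numeric vector with components \code{m_d}, \code{s_d},
#'   \code{m_nd}, \code{s_nd}, \code{r}.
#' @seealso \code{\link{numeric_gradient}} for the finite-difference
#'   cross-check.
#' @examples
#' dam_gradient("Se", glucose_example())
#' @export
dam_gradient <- function(id, s) {
  id <- match.arg(id, dam_ids())
  stopifnot(inherits(s, "scenario"))
  t <- se_sp_at(s)
  x <- eval_measure(id, t$se, t$sp, s$prevalence, t$se_c, t$sp_c)
  if (!is.finite(x))
    stop("measure ", id, " is ", dam_flag(x),
         " at this scenario; gradient does not exist", call. = FALSE)
  dss <- se_sp_gradient(s)
  dm <- measure_partials(id, t$se, t$sp, s$prevalence, t$se_c, t$sp_c)
  g <- c(dm[1] * dss["Se", ] + dm[2] * dss["Sp", ], r = dm[3])
  names(g) <- c("m_d", "s_d", "m_nd", "s_nd", "r")
  if (any(!is.finite(g)))
    stop("gradient of ", id, " is not finite at this scenario",
         call. = FALSE)
  g
}

#' Central finite-difference gradient of a measure
#'
#' Independent numerical check of \code{\link{dam_gradient}}: each of the
#' five inputs is perturbed by a central difference with relative step
#' \code{h * max(|theta|, 1)} and the measure re-evaluated through the same
#' closed forms.
#'
#' @inheritParams dam_gradient
#' @param h Relative step size; default \code{1e-6}.
#' @return Named numeric vector as in \code{\link{dam_gradient}}.
#' @export
numeric_gradient <- function(id, s, h = 1e-6) {
  id <- match.arg(id, dam_ids())
  stopifnot(inherits(s, "scenario"))
  f <- function(m_d, s_d, m_nd, s_nd, r) {
    z_d <- (s$threshold - m_d) / s_d
    z_n <- (s$threshold - m_nd) / s_nd
    eval_measure(id,
                 se = stats::pnorm(z_d, lower.tail = FALSE),
                 sp = stats::pnorm(z_n), r = r,
                 se_c = stats::pnorm(z_d),
                 sp_c = stats::pnorm(z_n, lower.tail = FALSE))
  }
  theta <- c(m_d = s$diseased$mean, s_d = s$diseased$sd,
             m_nd = s$non_diseased$mean, s_nd = s$non_diseased$sd,
             r = s$prevalence)
  vapply(seq_along(theta), function(i) {
    step <- h * max(abs(theta[i]), 1)
    up <- theta; up[i] <- up[i] + step
    dn <- theta; dn[i] <- dn[i] - step
    (do.call(f, as.list(up)) - do.call(f, as.list(dn))) / (2 * step)
  }, numeric(1)) -> g
  names(g) <- names(theta)
  g
}

# ---------------------------------------------------------------------------
# Welch-Satterthwaite, expanded uncertainty, confidence intervals

#' Welch-Satterthwaite effective degrees of freedom
#'
#' \eqn{\nu_{eff} = u_c^4 / \sum_i u_i^4/\nu_i} for independent uncertainty
#' components \eqn{(u_i, \nu_i)} combined in quadrature. The result always
#' lies between the smallest component df and the sum of all dfs; it is
#' generally non-integer and is used as-is in Student-t quantiles.
#'
#' @param u Numeric vector of non-negative component standard uncertainties.
#' @param v Numeric vector of component degrees of freedom, each >= 1.
#' @return Effective degrees of freedom (scalar, possibly non-integer).
#' @examples
#' effective_dof(c(0.3, 0.4), c(10, 20))
#' @export
effective_dof <- function(u, v) {
  stopifnot(length(u) == length(v), all(u >= 0), all(v >= 1))
  if (all(u == 0))
    stop("all uncertainty components are zero; degrees of freedom undefined",
         call. = FALSE)
  uc2 <- sum(u^2)
  uc2^2 / sum(u^4 / v)
}

#' Expanded combined uncertainty at a confidence level
#'
#' Student-t scaled offsets \eqn{(t_{(1-p)/2, \nu} u_c, t_{(1+p)/2, \nu} u_c)}
#' around a result whose standard combined uncertainty is \code{u_c} with
#' \code{v_eff} effective degrees of freedom. The pair is symmetric.
#'
#' @param u_c Standard combined uncertainty, non-negative.
#' @param v_eff Effective degrees of freedom, >= 1 (non-integer accepted).
#' @param p Confidence level in (0, 1).
#' @return Numeric vector \code{c(lower, upper)} of offsets (lower <= 0).
#' @examples
#' expanded_uncertainty(1, 10, 0.95)
#' @export
expanded_uncertainty <- function(u_c, v_eff, p) {
  stopifnot(u_c >= 0, v_eff >= 1)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("`p` must be a single number in (0, 1)", call. = FALSE)
  half <- stats::qt((1 + p) / 2, df = v_eff) * u_c
  c(lower = -half, upper = half)
}

#' Confidence interval of a measure, clipped to its admissible range
#'
#' Adds the expanded-uncertainty offsets to the point estimate and clips
#' the bounds to the measure's range ([0, 1] for the probability-type
#' measures, [0, Inf) for DOR, the likelihood ratios and ED, [-1, 1] for
#' Youden's index). Each clipped bound is flagged.
#'
#' @param x Point estimate of the measure.
#' @param u_c Standard combined uncertainty.
#' @param v_eff Effective degrees of freedom.
#' @param p Confidence level in (0, 1).
#' @param id Measure identifier (determines the admissible range).
#' @return List with elements \code{ci} (length-2 numeric) and
#'   \code{clipped} (length-2 logical).
#' @examples
#' confidence_interval(0.988, 0.0037, 100, 0.95, "Sp")
#' @export
confidence_interval <- function(x, u_c, v_eff, p, id) {
  id <- match.arg(id, dam_ids())
  off <- expanded_uncertainty(u_c, v_eff, p)
  raw <- x + off
  b <- dam_bounds(id)
  ci <- pmin(pmax(raw, b[, "lower"]), b[, "upper"])
  list(ci = stats::setNames(ci, c("lower", "upper")),
       clipped = stats::setNames(ci != raw, c("lower", "upper")))
}

# ---------------------------------------------------------------------------
# Propagation

# component table for one measure at one scenario: value u, df v, and
# whether the component belongs to the sampling or the measurement budget
uncertainty_components <- function(id, s) {
  g <- dam_gradient(id, s)
  nd <- s$non_diseased; dis <- s$diseased; mm <- s$measurement
  u_samp <- c(sampling_u_mean(dis), sampling_u_sd(dis),
              sampling_u_mean(nd), sampling_u_sd(nd))
  df_samp <- c(dis$n - 1, dis$n - 1, nd$n - 1, nd$n - 1)
  comp <- data.frame(
    input  = c(rep(c("m_d", "s_d", "m_nd", "s_nd"), 2), "r"),
    budget = c(rep("sampling", 4), rep("measurement", 4), "sampling"),
    u = c(abs(g[1:4]) * u_samp,
          abs(g[1:4]) * mm$u_m,
          abs(g["r"]) * prevalence_u(nd$n, dis$n)),
    df = c(df_samp, rep(mm$n_u - 1, 4), dis$n + nd$n - 1),
    stringsAsFactors = FALSE, row.names = NULL)
  comp
}

#' First-order uncertainty propagation to one measure
#'
#' Propagates the input uncertainties to a diagnostic accuracy measure by
#' the first-order (delta-method) rule \eqn{u_i(x) = |\partial x/\partial
#' \theta_i| u(\theta_i)} and combines them in quadrature. The nine
#' components are split into two budgets:
#' \itemize{
#'   \item sampling: the four location/scale inputs with their sampling
#'     uncertainties plus the prevalence rate with its Agresti-Coull
#'     uncertainty;
#'   \item measurement: the four location/scale inputs, each with
#'     standard measurement uncertainty \code{u_m}.
#' }
#' So \eqn{u_c^2 = u_{meas}^2 + u_{samp}^2} by construction. Effective
#' degrees of freedom come from Welch-Satterthwaite over all components
#' (sampling components of each population carry \eqn{n_P - 1} df, the
#' measurement components \eqn{n_u - 1}, the prevalence component
#' \eqn{n_D + n_{\bar D} - 1}); the expanded uncertainty and the clipped
#' confidence interval at the scenario's confidence level complete the
#' breakdown.
#'
#' If the measure is unbounded or undefined at the scenario the breakdown
#' is returned with \code{flag} set accordingly and NA uncertainty fields,
#' so grids of results stay rectangular.
#'
#' @param id One measure identifier from \code{\link{dam_ids}}.
#' @param s A \code{\link{scenario}}.
#' @return An object of class \code{dam_uncertainty}: a list with elements
#'   \code{measure}, \code{value}, \code{u_meas}, \code{u_samp}, \code{u_c},
#'   \code{v_eff}, \code{expanded}, \code{ci}, \code{ci_clipped},
#'   \code{flag} and \code{components} (the per-component table).
#' @examples
#' propagate("Se", glucose_example())
#' @export
propagate <- function(id, s) {
  id <- match.arg(id, dam_ids())
  stopifnot(inherits(s, "scenario"))
  t <- se_sp_at(s)
  x <- eval_measure(id, t$se, t$sp, s$prevalence, t$se_c, t$sp_c)
  if (!is.finite(x)) {
    return(structure(list(
      measure = id, value = x, u_meas = NA_real_, u_samp = NA_real_,
      u_c = NA_real_, v_eff = NA_real_,
      expanded = c(lower = NA_real_, upper = NA_real_),
      ci = c(lower = NA_real_, upper = NA_real_),
      ci_clipped = c(lower = NA, upper = NA),
      flag = dam_flag(x), components = NULL),
      class = "dam_uncertainty"))
  }
  # the gradient can overflow even at a finite measure value (extreme
  # tails, e.g. DOR with 1 - Se near the double-precision floor); such
  # cells are flagged, not raised, so grids stay rectangular
  comp <- tryCatch(uncertainty_components(id, s), error = function(e) NULL)
  if (is.null(comp) || any(!is.finite(comp$u))) {
    return(structure(list(
      measure = id, value = x, u_meas = NA_real_, u_samp = NA_real_,
      u_c = NA_real_, v_eff = NA_real_,
      expanded = c(lower = NA_real_, upper = NA_real_),
      ci = c(lower = NA_real_, upper = NA_real_),
      ci_clipped = c(lower = NA, upper = NA),
      flag = "undefined", components = NULL),
      class = "dam_uncertainty"))
  }
  u_samp <- sqrt(sum(comp$u[comp$budget == "sampling"]^2))
  u_meas <- sqrt(sum(comp$u[comp$budget == "measurement"]^2))
  u_c <- sqrt(sum(comp$u^2))
  if (u_c == 0) {
    v_eff <- Inf
    expanded <- c(lower = 0, upper = 0)
    ci <- list(ci = c(lower = x, upper = x),
               clipped = c(lower = FALSE, upper = FALSE))
  } else {
    v_eff <- effective_dof(comp$u, comp$df)
    expanded <- expanded_uncertainty(u_c, v_eff, s$confidence)
    ci <- confidence_interval(x, u_c, v_eff, s$confidence, id)
  }
  structure(list(
    measure = id, value = x, u_meas = u_meas, u_samp = u_samp,
    u_c = u_c, v_eff = v_eff, expanded = expanded,
    ci = ci$ci, ci_clipped = ci$clipped,
    flag = "ok", components = comp),
    class = "dam_uncertainty")
}

#' @export
print.dam_uncertainty <- function(x, ...) {
  cat(sprintf("%s = %.6g  [%s]\n", x$measure, x$value, x$flag))
  if (x$flag == "ok") {
    cat(sprintf("  u_meas = %.4g, u_samp = %.4g, u_c = %.4g (v_eff = %.4g)\n",
                x$u_meas, x$u_samp, x$u_c, x$v_eff))
    cat(sprintf("  CI: [%.6g, %.6g]%s\n", x$ci[1], x$ci[2],
                if (any(x$ci_clipped)) "  (clipped)" else ""))
  }
  invisible(x)
}

#' Relative standard uncertainties of a propagated measure
#'
#' Divides the measurement, sampling and combined standard uncertainties by
#' the point estimate. Returned as fractions; multiply by 100 for percent.
#' For |value| below 1e-12 the ratios are NA with flag
#' \code{"undefined-relative"} rather than infinities.
#'
#' @param b A \code{dam_uncertainty} object from \code{\link{propagate}}.
#' @return Named numeric vector \code{c(rel_meas, rel_samp, rel_c)} with a
#'   \code{"flag"} attribute.
#' @export
relative_uncertainty <- function(b) {
  stopifnot(inherits(b, "dam_uncertainty"))
  if (b$flag != "ok" || !is.finite(b$value) || abs(b$value) < 1e-12) {
    out <- c(rel_meas = NA_real_, rel_samp = NA_real_, rel_c = NA_real_)
    attr(out, "flag") <- if (b$flag != "ok") b$flag else "undefined-relative"
    return(out)
  }
  out <- c(rel_meas = b$u_meas, rel_samp = b$u_samp, rel_c = b$u_c) /
    abs(b$value)
  attr(out, "flag") <- "ok"
  out
}
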