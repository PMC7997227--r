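#' Monte-Carlo configuration
#'
#' Settings for the stochastic validation routines. Two modes exist:
#' \code{"parameter_perturbation"} perturbs the five summary parameters
#' directly with their component standard uncertainties (the target of the
#' first-order analytic propagation), while \code{"full_bootstrap"}
#' regenerates raw measurement data and re-estimates the summaries, so the
#' whole estimation chain is exercised.
#'
#' @param n_draws Number of Monte-Carlo draws, at least 1000.
#' @param seed Integer seed (always explicit).
#' @param mode \code{"parameter_perturbation"} or \code{"full_bootstrap"}.
#' @return An object of class \code{mc_config}.
#' @export
mc_config <- function(n_draws = 10000L, seed,
                      mode = c("parameter_perturbation", "full_bootstrap")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_draws) || n_draws < 1000)
    stop("`n_draws` must be at least 1000", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("an explicit integer `seed` is required", call. = FALSE)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 mode = mode), class = "mc_config")
}

#' Monte-Carlo propagation of input uncertainties to one measure
#'
#' Independent stochastic oracle for the analytic propagation: each input
#' parameter is drawn from a normal centred at its scenario value with its
#' combined component standard uncertainty (sampling plus measurement for
#' the means and SDs; Agresti-Coull for the prevalence), the measure is
#' recomputed per draw, and the sample SD of the resulting values estimates
#' the combined standard uncertainty. Perturbed SDs drawn non-positive are
#' redrawn (rejection) and the rejection count reported; perturbed
#' prevalences are clipped to (1e-6, 1 - 1e-6). Draws where the measure is
#' undefined or unbounded are dropped from the SD and counted; if they
#' exceed 1\% of all draws a warning is raised and the estimate flagged.
#'
#' In \code{"full_bootstrap"} mode each draw instead simulates raw samples
#' via \code{\link{simulate_samples}}, re-estimates the summary statistics
#' and recomputes the measure, so the sampling variability enters through
#' the estimators themselves rather than through the closed-form component
#' uncertainties.
#'
#' @param id One measure identifier from \code{\link{dam_ids}}.
#' @param s A \code{\link{scenario}}.
#' @param cfg An \code{\link{mc_config}}.
#' @return List with elements \code{sd} (Monte-Carlo estimate of the
#'   combined standard uncertainty), \code{mc_se} (its Monte-Carlo standard
#'   error, approximately \code{sd / sqrt(2 (n - 1))}), \code{n_undefined},
#'   \code{n_rejected_sd} and \code{flagged}.
#' @examples
#' mc_propagate("Se", glucose_example(), mc_config(2000, seed = 1))
#' @export
mc_propagate <- function(id, s, cfg) {
  id <- match.arg(id, dam_ids())
  stopifnot(inherits(s, "scenario"), inherits(cfg, "mc_config"))
  x0 <- all_measures(s)
  x0 <- x0$value[x0$measure == id]
  if (!is.finite(x0))
    stop("measure ", id, " is not finite at this scenario", call. = FALSE)
  nd <- s$non_diseased; dis <- s$diseased; mm <- s$measurement
  n <- cfg$n_draws
  eps <- 1e-6
  with_preserved_seed(cfg$seed, {
    if (cfg$mode == "parameter_perturbation") {
      u_md  <- combined_u_mean(dis, mm)
      u_sd  <- combined_u_sd(dis, mm)
      u_mnd <- combined_u_mean(nd, mm)
      u_snd <- combined_u_sd(nd, mm)
      u_r   <- prevalence_u(nd$n, dis$n)
      m_d  <- stats::rnorm(n, dis$mean, u_md)
      m_nd <- stats::rnorm(n, nd$mean, u_mnd)
      s_d  <- draw_positive(n, dis$sd, u_sd)
      s_nd <- draw_positive(n, nd$sd, u_snd)
      r    <- pmin(pmax(stats::rnorm(n, s$prevalence, u_r), eps), 1 - eps)
      rejected <- attr(s_d, "rejected") + attr(s_nd, "rejected")
    } else {
      draws <- replicate(n, {
        raw <- simulate_samples_impl(s)
        c(mean(raw$diseased), stats::sd(raw$diseased),
          mean(raw$non_diseased), stats::sd(raw$non_diseased))
      })
      m_d <- draws[1, ]; s_d <- draws[2, ]
      m_nd <- draws[3, ]; s_nd <- draws[4, ]
      r <- rep(s$prevalence, n)
      rejected <- 0L
    }
    z_d <- (s$threshold - m_d) / s_d
    z_n <- (s$threshold - m_nd) / s_nd
    vals <- eval_measure(id,
                         se = stats::pnorm(z_d, lower.tail = FALSE),
                         sp = stats::pnorm(z_n), r = r,
                         se_c = stats::pnorm(z_d),
                         sp_c = stats::pnorm(z_n, lower.tail = FALSE))
    ok <- is.finite(vals)
    n_undef <- sum(!ok)
    flagged <- n_undef > 0.01 * n
    if (flagged)
      warning(sprintf("%d/%d Monte-Carlo draws gave an undefined %s; ",
                      n_undef, n, id),
              "the SD estimate is flagged", call. = FALSE)
    sd_hat <- stats::sd(vals[ok])
    list(sd = sd_hat,
         mc_se = sd_hat / sqrt(2 * (sum(ok) - 1)),
         n_undefined = n_undef,
         n_rejected_sd = as.integer(rejected),
         flagged = flagged)
  })
}

# rejection sampling for a perturbed SD constrained positive
draw_positive <- function(n, centre, u) {
  if (u == 0) {
    out <- rep(centre, n)
    attr(out, "rejected") <- 0L
    return(out)
  }
  out <- stats::rnorm(n, centre, u)
  rejected <- 0L
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    rejected <- rejected + length(bad)
    out[bad] <- stats::rnorm(length(bad), centre, u)
    bad <- bad[out[bad] <= 0]
  }
  attr(out, "rejected") <- rejected
  out
}

#' Simulate raw measurement data for a scenario
#'
#' Draws \code{n_D} measurand values from the diseased normal and
#' \code{n_ND} from the non-diseased normal, then adds independent
#' \code{Normal(0, u_m)} measurement error to every value. A measurement
#' strictly above the threshold is test-positive when tabulated.
#'
#' @param s A \code{\link{scenario}}.
#' @param seed Integer seed; same seed, same data.
#' @return List with numeric vectors \code{diseased} and
#'   \code{non_diseased}.
#' @examples
#' raw <- simulate_samples(glucose_example(), seed = 1)
#' @export
simulate_samples <- function(s, seed) {
  stopifnot(inherits(s, "scenario"))
  with_preserved_seed(seed, simulate_samples_impl(s))
}

simulate_samples_impl <- function(s) {
  u_m <- s$measurement$u_m
  d_true  <- stats::rnorm(s$diseased$n, s$diseased$mean, s$diseased$sd)
  nd_true <- stats::rnorm(s$non_diseased$n, s$non_diseased$mean,
                          s$non_diseased$sd)
  list(diseased = d_true + stats::rnorm(s$diseased$n, 0, u_m),
       non_diseased = nd_true + stats::rnorm(s$non_diseased$n, 0, u_m))
}

#' Tabulate simulated measurements against the threshold
#'
#' Convenience glue from raw simulated data to a
#' \code{\link{contingency_table}}: a measurement strictly above the
#' threshold is test-positive, a value at or below it test-negative.
#'
#' @param raw List as returned by \code{\link{simulate_samples}}.
#' @param d Diagnostic threshold.
#' @return A \code{\link{contingency_table}}.
#' @export
tabulate_samples <- function(raw, d) {
  stopifnot(is.list(raw), all(c("diseased", "non_diseased") %in% names(raw)))
  contingency_table(
    tn = sum(raw$non_diseased <= d),
    fp = sum(raw$non_diseased > d),
    fn = sum(raw$diseased <= d),
    tp = sum(raw$diseased > d))
}

#' Empirical coverage of the propagated confidence intervals
#'
#' Parametric-bootstrap check of the nominal level: raw samples are
#' repeatedly simulated from the scenario, the summary statistics
#' re-estimated, the confidence interval recomputed through the full
#' analytic chain, and the fraction of intervals covering the generating
#' (true) measure value reported together with its binomial standard
#' error.
#'
#' @param s A \code{\link{scenario}} (the generating truth).
#' @param id One measure identifier.
#' @param reps Number of bootstrap replicates, at least 200.
#' @param seed Integer seed.
#' @return List with elements \code{coverage}, \code{se} (binomial standard
#'   error), \code{reps} and \code{nominal}.
#' @export
mc_ci_coverage <- function(s, id, reps, seed) {
  id <- match.arg(id, dam_ids())
  stopifnot(inherits(s, "scenario"))
  if (!is.numeric(reps) || reps < 200)
    stop("`reps` must be at least 200", call. = FALSE)
  truth <- all_measures(s)
  truth <- truth$value[truth$measure == id]
  with_preserved_seed(seed, {
    hits <- vapply(seq_len(reps), function(i) {
      raw <- simulate_samples_impl(s)
      est <- scenario(
        non_diseased = population_sample(mean(raw$non_diseased),
                                         stats::sd(raw$non_diseased),
                                         s$non_diseased$n),
        diseased = population_sample(mean(raw$diseased),
                                     stats::sd(raw$diseased),
                                     s$diseased$n),
        measurement = s$measurement,
        threshold = s$threshold,
        confidence = s$confidence)
      b <- propagate(id, est)
      if (b$flag != "ok") return(NA)
      b$ci[1] <= truth && truth <= b$ci[2]
    }, logical(1))
    hits <- hits[!is.na(hits)]
    cov <- mean(hits)
    list(coverage = cov,
         se = sqrt(cov * (1 - cov) / length(hits)),
         reps = length(hits),
         nominal = s$confidence)
  })
}
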