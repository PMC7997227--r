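#' Summary statistics of a measurand in one population sample
#'
#' A population sample is described by the mean, standard deviation and size
#' of the (possibly log-transformed, standardized) measurand observed in it.
#' These three numbers are all the diagnostic model needs: the measurand is
#' assumed normally distributed within the population, so the sample mean and
#' SD act as plug-in estimates of the population parameters.
#'
#' @param mean Sample mean of the measurand, in measurand units.
#' @param sd Sample standard deviation, same units; must be positive.
#' @param n Sample size; integer, at least 2 (the sampling uncertainty of the
#'   SD divides by \code{n - 1}).
#'
#' @return An object of class \code{population_sample}.
#' @examples
#' population_sample(mean = 2.99, sd = 0.75, n = 179)
#' @export
population_sample <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("`sd` must be a single positive finite number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 ||
      n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n)),
            class = "population_sample")
}

#' Standard measurement uncertainty of the test
#'
#' The measurement procedure's standard uncertainty \code{u_m} (a standard
#' deviation, in measurand units) and the number of measurements \code{n_u}
#' from which it was estimated. \code{n_u} supplies the degrees of freedom
#' attached to every measurement-uncertainty component during propagation.
#' Bias, if relevant, is folded into \code{u_m} by the caller.
#'
#' @param u_m Standard measurement uncertainty, measurand units; non-negative.
#' @param n_u Number of measurements behind the estimate of \code{u_m};
#'   integer, at least 2.
#'
#' @return An object of class \code{measurement_model}.
#' @examples
#' measurement_model(u_m = 0.046, n_u = 80)
#' @export
measurement_model <- function(u_m, n_u) {
  if (!is.numeric(u_m) || length(u_m) != 1L || !is.finite(u_m) || u_m < 0)
    stop("`u_m` must be a single non-negative finite number", call. = FALSE)
  if (!is.numeric(n_u) || length(n_u) != 1L || !is.finite(n_u) || n_u < 2 ||
      n_u != round(n_u))
    stop("`n_u` must be a single integer >= 2", call. = FALSE)
  structure(list(u_m = as.numeric(u_m), n_u = as.integer(n_u)),
            class = "measurement_model")
}

#' Full description of a screening scenario
#'
#' Binds together everything a diagnostic-accuracy analysis needs: the two
#' population samples, the measurement model, the diagnostic threshold and
#' the confidence level. A measurement strictly above the threshold is
#' classified test-positive; a measurement at or below it is test-negative.
#' The prevalence rate is taken from the two sample sizes,
#' \code{r = n_D / (n_D + n_ND)}.
#'
#' @param non_diseased,diseased \code{\link{population_sample}} objects for
#'   the non-diseased and diseased populations.
#' @param measurement A \code{\link{measurement_model}}.
#' @param threshold Diagnostic threshold \code{d}, measurand units; finite.
#' @param confidence Confidence level \code{p} in (0, 1) for expanded
#'   uncertainties and confidence intervals. Default 0.95.
#'
#' @return An object of class \code{scenario} with an additional
#'   \code{prevalence} element.
#' @examples
#' scenario(
#'   non_diseased = population_sample(0, 1, 2488),
#'   diseased     = population_sample(2.99, 0.75, 179),
#'   measurement  = measurement_model(0.046, 80),
#'   threshold    = 2.26
#' )
#' @export
scenario <- function(non_diseased, diseased, measurement, threshold,
                     confidence = 0.95) {
  stopifnot(inherits(non_diseased, "population_sample"),
            inherits(diseased, "population_sample"),
            inherits(measurement, "measurement_model"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold))
    stop("`threshold` must be a single finite number", call. = FALSE)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1)
    stop("`confidence` must be a single number in (0, 1)", call. = FALSE)
  r <- diseased$n / (diseased$n + non_diseased$n)
  stopifnot(r > 0, r < 1)
  structure(list(non_diseased = non_diseased, diseased = diseased,
                 measurement = measurement,
                 threshold = as.numeric(threshold),
                 confidence = as.numeric(confidence),
                 prevalence = r),
            class = "scenario")
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("Population sample: mean = %g, sd = %g, n = %d\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' @export
print.measurement_model <- function(x, ...) {
  cat(sprintf("Measurement model: u_m = %g (from n_u = %d measurements)\n",
              x$u_m, x$n_u))
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat("Diagnostic scenario\n")
  cat(sprintf("  non-diseased: mean = %g, sd = %g, n = %d\n",
              x$non_diseased$mean, x$non_diseased$sd, x$non_diseased$n))
  cat(sprintf("  diseased:     mean = %g, sd = %g, n = %d\n",
              x$diseased$mean, x$diseased$sd, x$diseased$n))
  cat(sprintf("  u_m = %g (n_u = %d), threshold d = %g, confidence p = %g\n",
              x$measurement$u_m, x$measurement$n_u, x$threshold,
              x$confidence))
  cat(sprintf("  prevalence r = %.6g\n", x$prevalence))
  invisible(x)
}

#' A 2 x 2 diagnostic contingency table
#'
#' Counts of true negatives, false positives, false negatives and true
#' positives from applying a dichotomized test to samples classified by a
#' gold-standard method.
#'
#' @param tn,fp,fn,tp Non-negative integer counts.
#' @return An object of class \code{contingency_table}.
#' @examples
#' contingency_table(tn = 90, fp = 10, fn = 20, tp = 80)
#' @export
contingency_table <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("all counts must be non-negative integers", call. = FALSE)
  structure(lapply(counts, as.integer), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), nrow = 2, byrow = TRUE,
              dimnames = list(c("test negative", "test positive"),
                              c("non-diseased", "diseased")))
  print(m)
  invisible(x)
}
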