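#' Identifiers of the eleven diagnostic accuracy measures
#'
#' Returns the canonical ordering used throughout the package: sensitivity
#' (Se), specificity (Sp), positive and negative predictive value (PPV,
#' NPV), overall diagnostic accuracy (ODA), diagnostic odds ratio (DOR),
#' likelihood ratios for a positive and a negative result (LRpos, LRneg),
#' Youden's index (J), Euclidean distance of (Se, Sp) from the perfect
#' point (ED) and concordance probability (CZ).
#'
#' @return Character vector of length 11.
#' @export
dam_ids <- function() {
  c("Se", "Sp", "PPV", "NPV", "ODA", "DOR", "LRpos", "LRneg",
    "J", "ED", "CZ")
}

#' Which measures depend on prevalence
#'
#' PPV, NPV and ODA are prevalence-dependent; the other eight measures are
#' prevalence-invariant (their partial derivative with respect to the
#' prevalence rate is exactly zero).
#'
#' @param id Character vector of measure identifiers (see \code{\link{dam_ids}}).
#' @return Logical vector, \code{TRUE} where the measure depends on prevalence.
#' @export
dam_prevalence_dependent <- function(id) {
  id <- match_dam_id(id)
  id %in% c("PPV", "NPV", "ODA")
}

# admissible range per measure, used to clip confidence intervals
dam_bounds <- function(id) {
  id <- match_dam_id(id)
  lower <- ifelse(id == "J", -1, 0)
  upper <- ifelse(id %in% c("DOR", "LRpos", "LRneg", "ED"), Inf, 1)
  cbind(lower = lower, upper = upper)
}

match_dam_id <- function(id) {
  out <- match.arg(id, dam_ids(), several.ok = TRUE)
  if (length(out) != length(id))
    stop("unknown measure identifier", call. = FALSE)
  out
}

#' Sensitivity of a binormal test at a threshold
#'
#' Probability that a diseased subject measures above the diagnostic
#' threshold, \eqn{Se = P(X > d)} with \eqn{X \sim N(\mu_D, \sigma_D)}.
#' Evaluated through the upper-tail normal probability so that far-tail
#' values (|z| > 6) keep full relative precision.
#'
#' @param d Diagnostic threshold, measurand units.
#' @param diseased A \code{\link{population_sample}} for the diseased
#'   population.
#' @return Probability in [0, 1]. Vectorized over \code{d}.
#' @examples
#' sensitivity(2.26, population_sample(2.99, 0.75, 179))
#' @export
sensitivity <- function(d, diseased) {
  stopifnot(inherits(diseased, "population_sample"))
  if (any(!is.finite(d) & !is.infinite(d)))
    stop("`d` must be numeric (finite or infinite)", call. = FALSE)
  stats::pnorm((d - diseased$mean) / diseased$sd, lower.tail = FALSE)
}

#' Specificity of a binormal test at a threshold
#'
#' Probability that a non-diseased subject measures at or below the
#' diagnostic threshold, \eqn{Sp = P(X \le d)} with
#' \eqn{X \sim N(\mu_{\bar D}, \sigma_{\bar D})}.
#'
#' @param d Diagnostic threshold, measurand units.
#' @param non_diseased A \code{\link{population_sample}} for the
#'   non-diseased population.
#' @return Probability in [0, 1]. Vectorized over \code{d}.
#' @examples
#' specificity(2.26, population_sample(0, 1, 2488))
#' @export
specificity <- function(d, non_diseased) {
  stopifnot(inherits(non_diseased, "population_sample"))
  if (any(!is.finite(d) & !is.infinite(d)))
    stop("`d` must be numeric (finite or infinite)", call. = FALSE)
  stats::pnorm((d - non_diseased$mean) / non_diseased$sd)
}

#' One diagnostic accuracy measure from (Se, Sp, r)
#'
#' Evaluates any of the eleven measures from sensitivity, specificity and
#' (where needed) the prevalence rate:
#' \itemize{
#'   \item \code{PPV = r Se / (r Se + (1-r)(1-Sp))}
#'   \item \code{NPV = (1-r) Sp / ((1-r) Sp + r (1-Se))}
#'   \item \code{ODA = r Se + (1-r) Sp}
#'   \item \code{DOR = Se Sp / ((1-Se)(1-Sp))}
#'   \item \code{LR+ = Se / (1-Sp)}, \code{LR- = (1-Se) / Sp}
#'   \item \code{J = Se + Sp - 1}, \code{ED = sqrt((1-Se)^2 + (1-Sp)^2)},
#'         \code{CZ = Se Sp}
#' }
#' Degenerate cases (e.g. \code{DOR} at \code{Sp = 1}) return \code{Inf}
#' rather than raising, so tabulations over a grid stay rectangular; use
#' \code{\link{dam_flag}} to label such cells.
#'
#' @param id One measure identifier from \code{\link{dam_ids}}.
#' @param se,sp Sensitivity and specificity, each in [0, 1].
#' @param r Prevalence rate in (0, 1); required only for PPV, NPV and ODA.
#' @return A single numeric value (possibly \code{Inf} or \code{NaN} in
#'   degenerate cases).
#' @examples
#' measure_value("DOR", se = 0.8348, sp = 0.98809)
#' measure_value("PPV", se = 0.8, sp = 0.9, r = 0.1)
#' @export
measure_value <- function(id, se, sp, r = NA_real_) {
  id <- match.arg(id, dam_ids())
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1)
  if (id %in% c("PPV", "NPV", "ODA") && (is.na(r) || r <= 0 || r >= 1))
    stop("`r` in (0, 1) is required for ", id, call. = FALSE)
  eval_measure(id, se, sp, r)
}

# vectorized, complement-aware evaluation: se_c = 1 - Se and sp_c = 1 - Sp
# can be supplied directly (from accurate tail probabilities) so that
# far-tail values do not lose precision to the literal subtraction
eval_measure <- function(id, se, sp, r = NA_real_,
                         se_c = 1 - se, sp_c = 1 - sp) {
  switch(id,
    Se  = se,
    Sp  = sp,
    PPV = r * se / (r * se + (1 - r) * sp_c),
    NPV = (1 - r) * sp / ((1 - r) * sp + r * se_c),
    ODA = r * se + (1 - r) * sp,
    DOR = se * sp / (se_c * sp_c),
    LRpos = se / sp_c,
    LRneg = se_c / sp,
    J   = se - sp_c,
    ED  = sqrt(se_c^2 + sp_c^2),
    CZ  = se * sp)
}

# accurate tail probabilities of the binormal model at threshold d
se_sp_at <- function(s) {
  z_d <- (s$threshold - s$diseased$mean) / s$diseased$sd
  z_n <- (s$threshold - s$non_diseased$mean) / s$non_diseased$sd
  list(se = stats::pnorm(z_d, lower.tail = FALSE),
       se_c = stats::pnorm(z_d),
       sp = stats::pnorm(z_n),
       sp_c = stats::pnorm(z_n, lower.tail = FALSE))
}

#' Flag degenerate measure values
#'
#' Classifies a computed measure value as \code{"ok"}, \code{"unbounded"}
#' (infinite, e.g. DOR when Sp = 1) or \code{"undefined"} (0/0 forms).
#'
#' @param x Numeric vector of measure values.
#' @return Character vector of flags, same length as \code{x}.
#' @export
dam_flag <- function(x) {
  ifelse(is.nan(x) | is.na(x), "undefined",
         ifelse(is.infinite(x), "unbounded", "ok"))
}

#' All eleven measures for a scenario
#'
#' Computes sensitivity and specificity at the scenario's threshold under
#' the binormal model, takes the prevalence from the two sample sizes, and
#' evaluates every measure. The sample mean and SD are used as plug-in
#' values for the population parameters; the measurement uncertainty
#' \code{u_m} does not broaden the measurand distributions here -- it enters
#' only the uncertainty layer (see \code{\link{propagate}}).
#'
#' @param s A \code{\link{scenario}}.
#' @return A data frame with columns \code{measure}, \code{value} and
#'   \code{flag}, one row per measure in \code{\link{dam_ids}} order.
#' @examples
#' all_measures(glucose_example())
#' @export
all_measures <- function(s) {
  stopifnot(inherits(s, "scenario"))
  t <- se_sp_at(s)
  vals <- vapply(dam_ids(), eval_measure, numeric(1),
                 se = t$se, sp = t$sp, r = s$prevalence,
                 se_c = t$se_c, sp_c = t$sp_c)
  data.frame(measure = dam_ids(), value = unname(vals),
             flag = dam_flag(unname(vals)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Diagnostic accuracy measures from a contingency table
#'
#' Natural-frequency computation of the eleven measures from observed
#' counts, e.g. \code{Se = TP / (FN + TP)} and
#' \code{DOR = TN TP / (FN FP)}. Measures whose required marginal is zero
#' are flagged \code{"undefined"}; measures with a zero denominator but
#' positive numerator are \code{Inf} and flagged \code{"unbounded"}.
#'
#' @param t A \code{\link{contingency_table}}.
#' @return A list with elements \code{measures} (data frame as in
#'   \code{\link{all_measures}}) and \code{prevalence}
#'   (\code{(FN + TP) / total}).
#' @examples
#' dams_from_counts(contingency_table(tn = 90, fp = 10, fn = 20, tp = 80))
#' @export
dams_from_counts <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  # doubles: products like tn*tp overflow 32-bit integers
  tn <- as.numeric(t$tn); fp <- as.numeric(t$fp)
  fn <- as.numeric(t$fn); tp <- as.numeric(t$tp)
  total <- tn + fp + fn + tp
  if (total == 0) stop("empty contingency table", call. = FALSE)
  nd  <- fn + tp   # diseased margin
  nnd <- tn + fp   # non-diseased margin
  frac <- function(num, den) if (den == 0) NaN else num / den
  se <- frac(tp, nd)
  sp <- frac(tn, nnd)
  vals <- c(
    Se  = se,
    Sp  = sp,
    PPV = frac(tp, fp + tp),
    NPV = frac(tn, tn + fn),
    ODA = (tn + tp) / total,
    DOR = if (nd == 0 || nnd == 0) NaN else
          if (fn * fp == 0) (if (tn * tp == 0) NaN else Inf) else
          (tn * tp) / (fn * fp),
    LRpos = if (nd == 0 || nnd == 0) NaN else
            if (fp == 0) (if (tp == 0) NaN else Inf) else
            (tp * nnd) / (fp * nd),
    LRneg = if (nd == 0 || nnd == 0) NaN else
            if (tn == 0) (if (fn == 0) NaN else Inf) else
            (fn * nnd) / (tn * nd),
    J   = if (nd == 0 || nnd == 0) NaN else
          (tn * tp - fn * fp) / (nnd * nd),
    ED  = if (nd == 0 || nnd == 0) NaN else
          sqrt((fn / nd)^2 + (fp / nnd)^2),
    CZ  = if (nd == 0 || nnd == 0) NaN else (tn * tp) / (nnd * nd))
  list(
    measures = data.frame(measure = dam_ids(), value = unname(vals),
                          flag = dam_flag(unname(vals)),
                          stringsAsFactors = FALSE, row.names = NULL),
    prevalence = nd / total)
}
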