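#' Built-in glucose screening example
#'
#' The package's reference scenario: standardized log-transformed 2-h
#' post-load glucose in a Malaysian adult survey population, with 179
#' diabetic and 2488 non-diabetic subjects. All quantities are in units of
#' the non-diseased sample's log-glucose standard deviation, so the
#' non-diseased sample has mean 0 and SD 1; the diabetic sample has mean
#' 2.99 and SD 0.75. The standardized standard measurement uncertainty is
#' 0.046 (estimated from 80 measurements) and the diagnostic threshold is
#' the standardized ADA 2-h OGTT cutoff, 2.26. Confidence level 0.95.
#'
#' @return A \code{\link{scenario}}.
#' @examples
#' glucose_example()
#' @export
glucose_example <- function() {
  scenario(
    non_diseased = population_sample(mean = 0, sd = 1, n = 2488),
    diseased     = population_sample(mean = 2.99, sd = 0.75, n = 179),
    measurement  = measurement_model(u_m = 0.046, n_u = 80),
    threshold    = 2.26,
    confidence   = 0.95)
}

#' Random non-degenerate scenario for property tests
#'
#' Draws a reproducible scenario with a clear separation between the two
#' populations: the standardized separation |mu_D - mu_ND| / sigma_ND is
#' uniform on [0.5, 5], the SD ratio sigma_D / sigma_ND on [0.3, 3], both
#' sample sizes log-uniform on [30, 5000], u_m / sigma_ND uniform on
#' [0, 0.15] (with n_u between 20 and 200), and the threshold uniform
#' between the two means. These ranges mirror realistic screening-test
#' settings and keep every measure finite.
#'
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param confidence Confidence level of the generated scenario.
#' @return A \code{\link{scenario}}.
#' @examples
#' random_scenario(1)
#' @export
random_scenario <- function(seed, confidence = 0.95) {
  with_preserved_seed(seed, {
    s_nd <- 1
    m_nd <- stats::runif(1, -1, 1)
    sep  <- stats::runif(1, 0.5, 5)
    m_d  <- m_nd + sep * s_nd
    s_d  <- s_nd * stats::runif(1, 0.3, 3)
    n_nd <- as.integer(round(exp(stats::runif(1, log(30), log(5000)))))
    n_d  <- as.integer(round(exp(stats::runif(1, log(30), log(5000)))))
    u_m  <- stats::runif(1, 0, 0.15) * s_nd
    n_u  <- as.integer(round(stats::runif(1, 20, 200)))
    d    <- stats::runif(1, m_nd + 0.05 * sep, m_d - 0.05 * sep)
    scenario(
      non_diseased = population_sample(m_nd, s_nd, n_nd),
      diseased     = population_sample(m_d, s_d, n_d),
      measurement  = measurement_model(u_m, n_u),
      threshold    = d,
      confidence   = confidence)
  })
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
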