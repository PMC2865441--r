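#' Population configuration for synthetic case generation
#'
#' Describes the marginal distributions of the ocular-hypertension risk
#' factors used to simulate a case cohort: each continuous factor is a
#' (possibly truncated) normal, `diabetes` is Bernoulli, and `gender` is
#' categorical. The factors correspond to the baseline glaucoma risk
#' factors used by 5-year risk calculators: age (years), intraocular
#' pressure `iop` (mmHg), cup-disc ratio `cdr`, pattern standard deviation
#' `psd` (dB), and central corneal thickness `cct` (micrometres).
#'
#' @param continuous Named list over `age`, `iop`, `cdr`, `psd`, `cct`;
#'   each element a list with `mean`, `sd` and optional truncation bounds
#'   `lower`, `upper` (eligibility-criteria truncation). Omitted bounds
#'   default to `-Inf`/`Inf` (`cdr` is additionally clamped to `[0, 1]` by
#'   its bounds defaulting to 0 and 1).
#' @param binary Named list of success probabilities; must contain
#'   `diabetes`.
#' @param categorical Named list of named probability vectors; must contain
#'   `gender` with levels `female` and `male`.
#' @param n_cases Number of cases to generate.
#' @param seed Optional integer seed; identical configurations (including
#'   the seed) yield byte-identical case tables.
#'
#' @return An object of class `population_config`.
#' @export
population_config <- function(continuous, binary, categorical, n_cases,
                              seed = NULL) {
  needed <- c("age", "iop", "cdr", "psd", "cct")
  if (!all(needed %in% names(continuous)))
    stopf("continuous factors missing: %s",
          paste(setdiff(needed, names(continuous)), collapse = ", "))
  continuous <- lapply(continuous[needed], function(f) {
    f$lower <- if (is.null(f$lower)) -Inf else f$lower
    f$upper <- if (is.null(f$upper)) Inf else f$upper
    f
  })
  # cdr is a ratio by definition
  continuous$cdr$lower <- max(continuous$cdr$lower, 0)
  continuous$cdr$upper <- min(continuous$cdr$upper, 1)
  for (nm in needed) {
    f <- continuous[[nm]]
    if (!is.finite(f$mean) || !is.finite(f$sd) || f$sd < 0)
      stopf("factor %s: mean must be finite and sd >= 0", nm)
    if (f$lower >= f$upper)
      stopf("factor %s: bounds must satisfy lower < upper", nm)
  }
  if (is.null(binary$diabetes) || binary$diabetes < 0 || binary$diabetes > 1)
    stopf("binary$diabetes must be a probability in [0, 1]")
  g <- categorical$gender
  if (is.null(g) || !all(c("female", "male") %in% names(g)) ||
      abs(sum(g) - 1) > 1e-8 || any(g < 0))
    stopf("categorical$gender must give probabilities for female and male summing to 1")
  if (!is.numeric(n_cases) || n_cases < 0 || n_cases != round(n_cases))
    stopf("n_cases must be a non-negative integer")
  structure(list(continuous = continuous, binary = binary,
                 categorical = categorical, n_cases = as.integer(n_cases),
                 seed = seed),
            class = "population_config")
}

# Rejection-resampled truncated-normal draws (never clipped: clipping would
# pile mass on the bounds and distort the shape).
rtruncnorm_reject <- function(n, mean, sd, lower, upper, factor_name,
                              max_attempts = 10000L) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  attempt <- 1L
  while (length(bad)) {
    if (attempt >= max_attempts)
      stopf("factor %s: could not draw a value inside [%s, %s] after %d attempts",
            factor_name, format(lower), format(upper), max_attempts)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    attempt <- attempt + 1L
  }
  x
}

#' Simulate a synthetic case cohort
#'
#' Draws `n_cases` ocular-hypertension cases from the marginal
#' distributions in `config`. Continuous factors are truncated-normal via
#' rejection resampling; `diabetes` is Bernoulli; `gender` categorical.
#' Factors are drawn independently (no correlation structure).
#'
#' @param config A [population_config()].
#' @return A `data.frame` with columns `case_id`, `age`, `iop`, `cdr`,
#'   `psd`, `cct`, `diabetes` (0/1 integer), `gender`.
#' @export
simulate_cases <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_cases
  with_seed(config$seed, {
    cols <- lapply(names(config$continuous), function(nm) {
      f <- config$continuous[[nm]]
      rtruncnorm_reject(n, f$mean, f$sd, f$lower, f$upper, nm)
    })
    names(cols) <- names(config$continuous)
    diabetes <- as.integer(stats::runif(n) < config$binary$diabetes)
    g <- config$categorical$gender
    gender <- names(g)[1L + as.integer(stats::runif(n) >= g[[1]])]
    out <- data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                      cols, diabetes = diabetes, gender = gender,
                      stringsAsFactors = FALSE)
    if (n == 0L)
      out <- data.frame(case_id = character(), age = numeric(),
                        iop = numeric(), cdr = numeric(), psd = numeric(),
                        cct = numeric(), diabetes = integer(),
                        gender = character(), stringsAsFactors = FALSE)
    out
  })
}

#' Summarize a risk distribution with a moment-matched log-normal
#'
#' Computes the sample mean and variance of per-case disease risks and the
#' parameters of the log-normal distribution with exactly those first two
#' moments: `sigma^2 = log(1 + var/mean^2)`, `mu = log(mean) - sigma^2/2`.
#' This is the parametric overlay used to characterise the right-skewed
#' risk distribution of a simulated cohort.
#'
#' @param risks Numeric vector of risks, all strictly in (0, 1), length >= 2.
#' @return A list of class `distribution_summary` with `mean`, `variance`,
#'   `lognormal_mu`, `lognormal_sigma`, `n`.
#' @export
summarize_risk_distribution <- function(risks) {
  if (length(risks) < 2) stopf("need at least 2 risks to summarize")
  assert_prob(risks, "risks")
  m <- mean(risks)
  v <- stats::var(risks) * (length(risks) - 1) / length(risks)
  s2 <- log(1 + v / m^2)
  structure(list(mean = m, variance = v,
                 lognormal_mu = log(m) - s2 / 2,
                 lognormal_sigma = sqrt(s2),
                 n = length(risks)),
            class = "distribution_summary")
}
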