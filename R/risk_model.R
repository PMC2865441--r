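#' Risk-model configuration
#'
#' A pluggable linear-predictor model converting case risk factors into a
#' probability of developing disease over a stated horizon. The published
#' 5-year glaucoma risk calculators have this structure (a weighted sum of
#' risk factors passed through a link); their exact coefficients are not
#' built in — they are supplied here.
#'
#' Two link families are supported:
#' \describe{
#'   \item{`logistic`}{`risk = 1 / (1 + exp(-lp))`.}
#'   \item{`cloglog_survival`}{`risk = 1 - S0^exp(lp)` with baseline
#'     survival `S0` in (0, 1), the proportional-hazards form used by
#'     survival-based calculators.}
#' }
#'
#' @param coefficients Named numeric vector; names must be `Case` fields
#'   (`age`, `iop`, `cdr`, `psd`, `cct`, `diabetes`). `gender` carries no
#'   coefficient.
#' @param intercept Intercept added to the weighted sum.
#' @param link `"logistic"` or `"cloglog_survival"`.
#' @param baseline_survival Baseline survival `S0`, required for the
#'   `cloglog_survival` link; must be strictly in (0, 1).
#' @param risk_horizon Informational horizon in years (default 5).
#' @return An object of class `risk_model_config`.
#' @export
risk_model_config <- function(coefficients, intercept = 0,
                              link = c("logistic", "cloglog_survival"),
                              baseline_survival = NULL, risk_horizon = 5) {
  link <- match.arg(link)
  allowed <- c("age", "iop", "cdr", "psd", "cct", "diabetes")
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad))
    stopf("coefficients refer to unknown case fields: %s",
          paste(bad, collapse = ", "))
  if (!is.numeric(intercept) || !is.finite(intercept))
    stopf("intercept must be finite")
  if (link == "cloglog_survival") {
    if (is.null(baseline_survival) || baseline_survival <= 0 ||
        baseline_survival >= 1)
      stopf("cloglog_survival link requires baseline_survival strictly in (0, 1)")
  }
  structure(list(coefficients = coefficients, intercept = intercept,
                 link = link, baseline_survival = baseline_survival,
                 risk_horizon = risk_horizon),
            class = "risk_model_config")
}

#' Linear predictor for one or more cases
#'
#' `intercept + sum(coefficient * factor value)` per case.
#'
#' @param cases A case `data.frame` (see [simulate_cases()]).
#' @param config A [risk_model_config()].
#' @return Numeric vector, one value per case row.
#' @export
linear_predictor <- function(cases, config) {
  stopifnot(inherits(config, "risk_model_config"))
  lp <- rep(config$intercept, nrow(cases))
  for (nm in names(config$coefficients)) {
    if (!nm %in% names(cases))
      stopf("case table lacks factor '%s' required by the risk model", nm)
    v <- as.numeric(cases[[nm]])
    if (anyNA(v) || any(!is.finite(v))) {
      i <- which(is.na(v) | !is.finite(v))[1]
      id <- if ("case_id" %in% names(cases)) cases$case_id[i] else i
      stopf("missing or non-finite value for factor '%s' in case %s", nm, id)
    }
    lp <- lp + config$coefficients[[nm]] * v
  }
  lp
}

#' Map a linear predictor to a risk probability
#'
#' Applies the configured link; both links are strictly increasing and map
#' the real line onto (0, 1).
#'
#' @param lp Numeric vector of linear-predictor values.
#' @param config A [risk_model_config()].
#' @return Risks strictly in (0, 1).
#' @export
risk_from_linear_predictor <- function(lp, config) {
  stopifnot(inherits(config, "risk_model_config"))
  if (any(!is.finite(lp))) stopf("linear predictor must be finite")
  r <- switch(config$link,
    logistic = logistic(lp),
    cloglog_survival = 1 - config$baseline_survival^exp(lp))
  pmin(pmax(r, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Compute per-case disease risks
#'
#' Composition of [linear_predictor()] and [risk_from_linear_predictor()],
#' order-preserving with the case table.
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of risks, one per case.
#' @export
compute_risks <- function(cases, config) {
  if (nrow(cases) == 0L) return(numeric())
  risk_from_linear_predictor(linear_predictor(cases, config), config)
}
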