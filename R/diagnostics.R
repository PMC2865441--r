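#' Nagelkerke pseudo-R-squared
#'
#' Rescales the Cox–Snell likelihood-ratio R² so that its maximum is 1:
#' `R2_CS = 1 - exp((2/n) * (ll_null - ll_full))`, then
#' `R2 = R2_CS / (1 - exp((2/n) * ll_null))`.
#'
#' @param fit Any list with `loglik_full`, `loglik_null` and `n`
#'   (e.g. an `ordinal_fit`).
#' @return A value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  if (is.null(fit$n) || fit$n == 0) stopf("n must be positive")
  r2_cs <- 1 - exp((2 / fit$n) * (fit$loglik_null - fit$loglik_full))
  r2_max <- 1 - exp((2 / fit$n) * fit$loglik_null)
  min(max(r2_cs / r2_max, 0), 1)
}

#' Concordance index for ordinal responses against risk
#'
#' Over all case pairs whose collapsed response categories differ, the
#' fraction in which the case with the higher category also has the
#' strictly higher risk; risk ties count 0.5. For binary responses this is
#' the area under the ROC curve.
#'
#' @param risks Numeric vector of case risks.
#' @param responses3 Collapsed responses (levels No, Unsure, Yes).
#' @return A value in `[0, 1]`, or `NA` when fewer than two response
#'   categories are present.
#' @export
concordance_index <- function(risks, responses3) {
  y <- resp3_int(responses3)
  if (length(risks) != length(y)) stopf("risks and responses differ in length")
  present <- sort(unique(y))
  if (length(present) < 2) return(NA_real_)
  conc <- 0; tot <- 0
  for (i in seq_len(length(present) - 1)) {
    for (j in seq(i + 1, length(present))) {
      rl <- risks[y == present[i]]
      rh <- risks[y == present[j]]
      d <- outer(rh, rl, "-")
      conc <- conc + sum(d > 0) + 0.5 * sum(d == 0)
      tot <- tot + length(d)
    }
  }
  conc / tot
}
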