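# Core estimator: per-physician proportional-odds fit of collapsed
# recommendations against case risk, and the closed-form treatment
# threshold r* = -(alpha_U + alpha_Y) / (2 beta), the risk at which
# P(Yes | r) = P(No | r).
#
# Internal parameterization of the cumulative-logit model (note the
# direction): logit P(t >= j | r) = alpha_j + beta * r for j in
# {Unsure, Yes}. Fitters that model P(t <= j) return negated parameters;
# everything in this package is converted to the P(t >= j) form before the
# threshold formula is applied.

resp3_int <- function(responses3) {
  y <- as.character(responses3)
  bad <- setdiff(unique(y), response_levels3)
  if (length(bad))
    stopf("unknown collapsed response level(s): %s", paste(bad, collapse = ", "))
  match(y, response_levels3)
}

# Negative log-likelihood and gradient. theta = (alpha_U, gamma, beta)
# with alpha_Y = alpha_U - exp(gamma), which enforces alpha_U > alpha_Y.
ord_nll_theta <- function(theta, r, y) {
  ord_nll_natural(c(theta[1], theta[1] - exp(theta[2]), theta[3]), r, y)
}

ord_nll_natural <- function(par, r, y) {
  a <- par[1] + par[3] * r   # logit P(t >= Unsure)
  b <- par[2] + par[3] * r   # logit P(t >= Yes)
  ll <- numeric(length(y))
  i1 <- y == 1L; i2 <- y == 2L; i3 <- y == 3L
  ll[i1] <- stats::plogis(a[i1], lower.tail = FALSE, log.p = TRUE)
  mid <- stats::plogis(a[i2]) - stats::plogis(b[i2])
  ll[i2] <- log(pmax(mid, .Machine$double.xmin))
  ll[i3] <- stats::plogis(b[i3], log.p = TRUE)
  -sum(ll)
}

# Gradient of the *negative* log-likelihood wrt the natural parameters
# (alpha_U, alpha_Y, beta).
ord_grad_natural <- function(par, r, y) {
  a <- par[1] + par[3] * r
  b <- par[2] + par[3] * r
  pa <- stats::plogis(a); pb <- stats::plogis(b)
  da <- numeric(length(y)); db <- numeric(length(y))
  i1 <- y == 1L; i2 <- y == 2L; i3 <- y == 3L
  da[i1] <- -pa[i1]
  mid <- pmax(pa[i2] - pb[i2], .Machine$double.xmin)
  da[i2] <- pa[i2] * (1 - pa[i2]) / mid
  db[i2] <- -pb[i2] * (1 - pb[i2]) / mid
  db[i3] <- 1 - pb[i3]
  -c(sum(da), sum(db), sum((da + db) * r))
}

ord_grad_theta <- function(theta, r, y) {
  g <- ord_grad_natural(c(theta[1], theta[1] - exp(theta[2]), theta[3]), r, y)
  c(g[1] + g[2], -exp(theta[2]) * g[2], g[3])
}

# Intercept-only maximum log-likelihood: category frequencies.
null_loglik3 <- function(y) {
  n <- tabulate(y, nbins = 3L)
  sum(n[n > 0] * log(n[n > 0] / length(y)))
}

# Complete separation of the collapsed categories along risk: every
# present lower category sits strictly below every present higher one.
empirically_separated <- function(r, y) {
  present <- sort(unique(y))
  if (length(present) < 2) return(FALSE)
  for (k in seq_len(length(present) - 1)) {
    if (max(r[y == present[k]]) >= min(r[y == present[k + 1]])) return(FALSE)
  }
  TRUE
}

#' Fit the per-physician proportional-odds model
#'
#' Maximizes the likelihood of the cumulative-logit model
#' `logit P(t >= j | r) = alpha_j + beta * r` (j in Unsure, Yes) over one
#' physician's collapsed recommendations. The cutpoint ordering
#' `alpha_U > alpha_Y` is enforced by optimizing over
#' `(alpha_U, gamma, beta)` with `alpha_Y = alpha_U - exp(gamma)`
#' (quasi-Newton with analytic gradients, then Newton polish to gradient
#' norm `grad_tol`; up to 3 jittered restarts on non-convergence).
#'
#' @param risks Numeric vector of case risks (finite).
#' @param responses3 Collapsed responses (levels No, Unsure, Yes), same
#'   length as `risks`; all three categories should be present — vectors
#'   with an absent No or Yes belong to the degenerate/binary routes of
#'   [estimate_threshold()].
#' @param beta_bound Divergence bound: fits with `|beta|` above this are
#'   flagged as separated (default `1e4` per unit risk).
#' @param grad_tol Gradient-norm convergence tolerance (default `1e-8`).
#' @return Object of class `ordinal_fit`: `alpha_U`, `alpha_Y`, `beta`,
#'   standard errors `se` (from the inverse observed information), `vcov`,
#'   `loglik_full`, `loglik_null`, `n`, `converged`, `separation`.
#' @export
fit_ordinal_model <- function(risks, responses3, beta_bound = 1e4,
                              grad_tol = 1e-8) {
  y <- resp3_int(responses3)
  r <- as.numeric(risks)
  if (length(r) != length(y)) stopf("risks and responses differ in length")
  if (length(y) < 3) stopf("need at least 3 observations to fit")
  if (any(!is.finite(r))) stopf("risks must be finite")
  sep_emp <- empirically_separated(r, y)

  pU <- mean(y >= 2L); pY <- mean(y == 3L)
  aU0 <- stats::qlogis(min(max(pU, 1e-3), 1 - 1e-3))
  aY0 <- stats::qlogis(min(max(pY, 1e-3), 1 - 1e-3))
  if (aU0 - aY0 < 1e-3) aY0 <- aU0 - 1e-3
  start <- c(aU0, log(aU0 - aY0), 0)

  best <- NULL
  for (attempt in 1:3) {
    th <- if (attempt == 1) start else
      start + stats::rnorm(3, 0, c(0.5, 0.2, 0.5 / max(stats::sd(r), 1e-8)))
    opt <- try(stats::optim(th, ord_nll_theta, ord_grad_theta, r = r, y = y,
                            method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-15)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    theta <- opt$par
    # Newton polish on the gradient in theta-space
    for (it in 1:50) {
      g <- ord_grad_theta(theta, r, y)
      if (max(abs(g)) <= grad_tol) break
      H <- try(stats::optimHess(theta, ord_nll_theta, ord_grad_theta,
                                r = r, y = y), silent = TRUE)
      if (inherits(H, "try-error")) break
      step <- try(solve(H, g), silent = TRUE)
      if (inherits(step, "try-error") || any(!is.finite(step))) break
      f0 <- ord_nll_theta(theta, r, y)
      lam <- 1
      repeat {
        cand <- theta - lam * step
        if (is.finite(ord_nll_theta(cand, r, y)) &&
            ord_nll_theta(cand, r, y) <= f0 + 1e-12) break
        lam <- lam / 2
        if (lam < 1e-10) { cand <- theta; break }
      }
      if (identical(cand, theta)) break
      theta <- cand
    }
    g <- ord_grad_theta(theta, r, y)
    val <- ord_nll_theta(theta, r, y)
    conv <- max(abs(g)) <= max(grad_tol, 1e-8 * (1 + abs(val)))
    cand <- list(theta = theta, value = val, converged = conv)
    if (is.null(best) || val < best$value - 1e-10 ||
        (conv && !best$converged)) best <- cand
    if (conv && !sep_emp) break
  }
  if (is.null(best)) stopf("ordinal likelihood optimization failed")

  theta <- best$theta
  par <- c(theta[1], theta[1] - exp(theta[2]), theta[3])
  separation <- sep_emp || abs(par[3]) > beta_bound
  se <- c(alpha_U = NA_real_, alpha_Y = NA_real_, beta = NA_real_)
  vc <- NULL
  if (!separation) {
    H <- try(stats::optimHess(par, ord_nll_natural, ord_grad_natural,
                              r = r, y = y), silent = TRUE)
    if (!inherits(H, "try-error")) {
      vc <- try(solve(H), silent = TRUE)
      if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
        dimnames(vc) <- list(names(se), names(se))
        se[] <- sqrt(diag(vc))
      } else vc <- NULL
    }
  }
  structure(list(alpha_U = par[1], alpha_Y = par[2], beta = par[3],
                 se = se, vcov = vc,
                 loglik_full = -best$value, loglik_null = null_loglik3(y),
                 n = length(y), converged = best$converged,
                 separation = separation),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("Proportional-odds fit (logit P(t >= j) = alpha_j + beta * r)\n")
  cat(sprintf("  alpha_U = %.4f, alpha_Y = %.4f, beta = %.4f\n",
              x$alpha_U, x$alpha_Y, x$beta))
  cat(sprintf("  n = %d, logLik = %.3f (null %.3f), converged: %s, separation: %s\n",
              x$n, x$loglik_full, x$loglik_null, x$converged, x$separation))
  invisible(x)
}

#' Closed-form treatment threshold from a fitted model
#'
#' Under the fitted model, `P(No | r) = 1 - P(t >= Unsure | r)` and
#' `P(Yes | r) = P(t >= Yes | r)`; these are equal at the unique risk
#' `r* = -(alpha_U + alpha_Y) / (2 * beta)` — the point of maximal
#' uncertainty, defined as the physician's treatment threshold.
#'
#' @param fit An `ordinal_fit` (or any list with `alpha_U`, `alpha_Y`,
#'   `beta`).
#' @return The threshold risk. If `beta <= 0` the value is returned with a
#'   warning: recommendations then decrease with risk and the
#'   interpretation is inverted.
#' @export
threshold_from_fit <- function(fit) {
  if (is.null(fit$alpha_U) || is.null(fit$alpha_Y) || is.null(fit$beta))
    stopf("fit must provide alpha_U, alpha_Y and beta")
  if (fit$beta == 0) stopf("threshold undefined when beta = 0")
  if (fit$beta < 0)
    warning("beta < 0: recommendations decrease with risk; threshold interpretation inverted")
  -(fit$alpha_U + fit$alpha_Y) / (2 * fit$beta)
}

new_threshold_estimate <- function(physician_id, threshold, method,
                                   r2 = NA_real_, concordance = NA_real_,
                                   warnings = character(), fit = NULL) {
  structure(list(physician_id = physician_id, threshold = threshold,
                 method = method, r2_nagelkerke = r2,
                 concordance = concordance, warnings = warnings, fit = fit),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("Threshold estimate for %s: %s (method: %s)\n",
              x$physician_id,
              if (is.na(x$threshold)) "undefined" else sprintf("%.4f", x$threshold),
              x$method))
  if (!is.na(x$r2_nagelkerke))
    cat(sprintf("  Nagelkerke R2 = %.3f, concordance = %.3f\n",
                x$r2_nagelkerke, x$concordance))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Binary logistic fallback for physicians who are never unsure
#'
#' When only No and Yes occur, the three-level model degenerates to binary
#' logistic regression `logit P(Yes | r) = alpha + beta * r`; the
#' threshold is the P = 0.5 point `-alpha / beta`, which is again the risk
#' where Yes and No recommendations are equally likely.
#'
#' @param risks Numeric vector of case risks.
#' @param responses3 Collapsed responses using only No and Yes.
#' @param physician_id Identifier carried into the result.
#' @return A `threshold_estimate` with `method = "binary"` (or
#'   `"separation_midpoint"` under complete separation).
#' @export
fit_binary_threshold <- function(risks, responses3, physician_id = NA_character_) {
  y <- resp3_int(responses3)
  if (any(y == 2L)) stopf("binary route requires responses without Unsure")
  if (length(unique(y)) < 2) stopf("need both No and Yes responses")
  r <- as.numeric(risks)
  warnings <- character()
  if (empirically_separated(r, y)) {
    thr <- (max(r[y == 1L]) + min(r[y == 3L])) / 2
    return(new_threshold_estimate(physician_id, thr, "separation_midpoint",
                                  warnings = "complete separation; midpoint of empirical gap"))
  }
  yy <- as.integer(y == 3L)
  fit <- suppressWarnings(stats::glm(yy ~ r, family = stats::binomial()))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || abs(b) < 1e-8) {
    warnings <- c(warnings, "slope near zero; threshold unstable")
    thr <- if (is.finite(b) && b != 0) -a / b else NA_real_
  } else {
    if (b < 0) warnings <- c(warnings,
      "beta < 0: recommendations decrease with risk; interpretation inverted")
    thr <- -a / b
  }
  if (abs(b) > 1e4) {
    thr <- (max(r[y == 1L]) + min(r[y == 3L])) / 2
    return(new_threshold_estimate(physician_id, thr, "separation_midpoint",
                                  warnings = "quasi-separation; midpoint of empirical gap"))
  }
  ll_full <- as.numeric(stats::logLik(fit))
  ll_null <- as.numeric(stats::logLik(
    suppressWarnings(stats::glm(yy ~ 1, family = stats::binomial()))))
  r2 <- nagelkerke_r2(list(loglik_full = ll_full, loglik_null = ll_null,
                           n = length(yy)))
  new_threshold_estimate(physician_id, thr, "binary", r2 = r2,
                         concordance = concordance_index(r, responses3),
                         warnings = warnings, fit = fit)
}

#' Assigned thresholds for never-treat / always-treat physicians
#'
#' A physician who never answers Yes gives no information about where
#' above the presented risks their threshold lies; following the
#' assignment rule, it is set to the average of the highest presented risk
#' and 100%. Symmetrically, a physician who never answers No is assigned
#' the average of the lowest presented risk and 0%. A physician who only
#' answers Unsure has an undefined threshold.
#'
#' @param responses3 Collapsed responses missing Yes and/or No.
#' @param risks Case risks presented to the physician.
#' @param physician_id Identifier carried into the result.
#' @return A `threshold_estimate` with method `never_treat`,
#'   `always_treat` or `undefined`; diagnostics are absent.
#' @export
degenerate_threshold <- function(responses3, risks, physician_id = NA_character_) {
  y <- resp3_int(responses3)
  if (!length(y)) stopf("empty response vector")
  has <- c(No = any(y == 1L), Unsure = any(y == 2L), Yes = any(y == 3L))
  if (has[["Yes"]] && has[["No"]])
    stopf("responses contain both No and Yes; not a degenerate pattern")
  if (!has[["Yes"]] && !has[["No"]])
    return(new_threshold_estimate(physician_id, NA_real_, "undefined",
                                  warnings = "all responses Unsure; no balance point identifiable"))
  if (!has[["Yes"]])
    new_threshold_estimate(physician_id, (max(risks) + 1) / 2, "never_treat",
                           warnings = "no Yes responses; threshold assigned above highest presented risk")
  else
    new_threshold_estimate(physician_id, min(risks) / 2, "always_treat",
                           warnings = "no No responses; threshold assigned below lowest presented risk")
}

#' Estimate one physician's treatment threshold
#'
#' The dispatcher for a single physician's records: collapses the 7-point
#' responses to No/Unsure/Yes, joins them to case risks by `case_id`, and
#' routes to the appropriate estimator — the assignment rules when Yes or
#' No never occurs, binary logistic regression when Unsure never occurs,
#' and the full proportional-odds fit otherwise. Under complete separation
#' the threshold is the midpoint between the largest risk drawing a
#' sub-Yes response and the smallest risk drawing a Yes.
#'
#' @param responses `data.frame` with columns `case_id` and `response`
#'   (7-point labels) for one physician; an optional `physician_id` column
#'   must be constant.
#' @param risks Named numeric vector of risks (names are case ids) or a
#'   `data.frame` with columns `case_id` and `risk`.
#' @return A `threshold_estimate`.
#' @export
estimate_threshold <- function(responses, risks) {
  if (is.data.frame(risks)) {
    stopifnot(all(c("case_id", "risk") %in% names(risks)))
    risks <- stats::setNames(risks$risk, risks$case_id)
  }
  pid <- if ("physician_id" %in% names(responses)) {
    u <- unique(responses$physician_id)
    if (length(u) != 1) stopf("estimate_threshold expects one physician's records")
    u
  } else NA_character_
  missing_ids <- setdiff(responses$case_id, names(risks))
  if (length(missing_ids))
    stopf("no risk available for case id(s): %s",
          paste(utils::head(missing_ids, 5), collapse = ", "))
  r <- unname(risks[responses$case_id])
  y3 <- collapse_scale(responses$response)
  y <- as.integer(y3)

  has <- c(any(y == 1L), any(y == 2L), any(y == 3L))
  if (!has[3] || !has[1]) return(degenerate_threshold(y3, r, pid))
  if (!has[2]) return(fit_binary_threshold(r, y3, pid))

  fit <- fit_ordinal_model(r, y3)
  if (fit$separation || !fit$converged) {
    sub_yes <- r[y < 3L]; yes <- r[y == 3L]
    if (max(sub_yes) < min(yes)) {
      return(new_threshold_estimate(pid, (max(sub_yes) + min(yes)) / 2,
                                    "separation_midpoint", fit = fit,
                                    warnings = "complete separation; midpoint of empirical gap"))
    }
    warn <- if (fit$separation) "separation flagged but Yes responses overlap lower categories in risk"
            else "optimizer did not reach gradient tolerance"
  } else warn <- character()
  thr <- withCallingHandlers(
    threshold_from_fit(fit),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  new_threshold_estimate(pid, thr, "ordinal",
                         r2 = nagelkerke_r2(fit),
                         concordance = concordance_index(r, y3),
                         warnings = warn, fit = fit)
}
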