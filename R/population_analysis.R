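#' Screen physicians for risk-based decision making
#'
#' Physicians who report treating solely on an intraocular-pressure cutoff
#' are not using overall disease risk as the basis for their
#' recommendations and are excluded from threshold estimation. Reported
#' always-treat / never-treat dispositions are carried through (such
#' physicians remain included; their thresholds come from the assignment
#' rules).
#'
#' @param answers `data.frame` with columns `physician_id`,
#'   `always_treats`, `never_treats`, `iop_only_rule` (logicals).
#' @return `data.frame` with `physician_id`, `included` and `reason`
#'   (`NA` for included physicians).
#' @export
screen_physicians <- function(answers) {
  need <- c("physician_id", "always_treats", "never_treats", "iop_only_rule")
  if (!all(need %in% names(answers)))
    stopf("answers must have columns: %s", paste(need, collapse = ", "))
  for (col in need[-1]) {
    if (anyNA(answers[[col]]))
      stopf("screening answer '%s' missing for physician %s", col,
            answers$physician_id[which(is.na(answers[[col]]))[1]])
  }
  excluded <- as.logical(answers$iop_only_rule)
  data.frame(
    physician_id = answers$physician_id,
    included = !excluded,
    reason = ifelse(excluded,
                    "treats solely on an intraocular-pressure cutoff",
                    NA_character_),
    stringsAsFactors = FALSE)
}

#' Estimate thresholds for every included physician
#'
#' Runs [estimate_threshold()] for each included physician, in the order
#' physicians first appear in the response table.
#'
#' @param responses `data.frame` with `physician_id`, `case_id`,
#'   `response` (7-point labels).
#' @param risks Named risk vector or `data.frame(case_id, risk)`.
#' @param include Optional inclusion: a `data.frame` from
#'   [screen_physicians()] or a character vector of included ids; `NULL`
#'   includes everyone.
#' @return `data.frame` with one row per included physician:
#'   `physician_id`, `threshold`, `method`, `r2_nagelkerke`, `concordance`,
#'   `warnings` (collapsed with `"; "`).
#' @export
estimate_all_thresholds <- function(responses, risks, include = NULL) {
  ids <- unique(responses$physician_id)
  if (is.data.frame(include)) include <- include$physician_id[include$included]
  if (!is.null(include)) {
    absent <- setdiff(include, ids)
    if (length(absent))
      stopf("included physician(s) with no responses: %s",
            paste(absent, collapse = ", "))
    ids <- ids[ids %in% include]
  }
  rows <- lapply(ids, function(id) {
    est <- estimate_threshold(responses[responses$physician_id == id,
                                        c("physician_id", "case_id", "response")],
                              risks)
    data.frame(physician_id = id, threshold = est$threshold,
               method = est$method, r2_nagelkerke = est$r2_nagelkerke,
               concordance = est$concordance,
               warnings = paste(est$warnings, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Maximum-likelihood beta fit of a threshold distribution
#'
#' Fits a two-parameter beta distribution to per-physician thresholds by
#' maximum likelihood, with standard errors from the inverse observed
#' information at the optimum. Boundary values (0 or 1, as can arise from
#' the assignment rules) are nudged inward by `nudge` with a warning.
#'
#' @param thresholds Numeric vector of thresholds in `[0, 1]`, `n >= 5`.
#' @param nudge Inward nudge applied to boundary values (default `1e-6`).
#' @return Object of class `beta_fit`: `shape1`, `shape2`, `se1`, `se2`,
#'   `vcov`, `loglik`, `n`.
#' @export
fit_beta_mle <- function(thresholds, nudge = 1e-6) {
  x <- as.numeric(thresholds)
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    stopf("thresholds must be finite values in [0, 1]")
  if (length(x) < 5) stopf("need at least 5 thresholds for a beta fit")
  if (any(x <= 0 | x >= 1)) {
    warning("boundary threshold value(s) nudged inward by ", nudge)
    x <- pmin(pmax(x, nudge), 1 - nudge)
  }
  m <- mean(x); v <- stats::var(x)
  # method-of-moments start
  k <- max(m * (1 - m) / max(v, 1e-12) - 1, 0.1)
  start <- list(shape1 = max(m * k, 0.05), shape2 = max((1 - m) * k, 0.05))
  fit <- try(suppressWarnings(
    MASS::fitdistr(x, "beta", start = start,
                   lower = c(1e-8, 1e-8), method = "L-BFGS-B")),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    # log-parameterized fallback with jittered restarts
    nll <- function(p) -sum(stats::dbeta(x, exp(p[1]), exp(p[2]), log = TRUE))
    best <- NULL
    for (s in list(log(unlist(start)), c(0, 0), c(1, 1))) {
      o <- try(stats::optim(s, nll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14)),
               silent = TRUE)
      if (!inherits(o, "try-error") &&
          (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stopf("beta maximum-likelihood fit failed to converge")
    est <- exp(best$par)
    H <- stats::optimHess(est, function(p)
      -sum(stats::dbeta(x, p[1], p[2], log = TRUE)))
    vc <- solve(H)
    se <- sqrt(diag(vc))
    ll <- -best$value
  } else {
    est <- unname(fit$estimate)
    vc <- fit$vcov
    se <- unname(fit$sd)
    ll <- as.numeric(fit$loglik)
  }
  if (any(est <= 0) || any(!is.finite(se)) || any(se <= 0))
    stopf("beta maximum-likelihood fit did not yield positive shapes and standard errors")
  structure(list(shape1 = est[1], shape2 = est[2],
                 se1 = se[1], se2 = se[2], vcov = vc,
                 loglik = ll, n = length(x)),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("Beta MLE: shape1 = %.3f (SE %.3f), shape2 = %.3f (SE %.3f), n = %d\n",
              x$shape1, x$se1, x$shape2, x$se2, x$n))
  invisible(x)
}

#' Summarize the population threshold distribution
#'
#' Mean threshold, a histogram of configurable bin width on `[0, 1]`, the
#' modal bin, and a tally of estimation methods. Physicians with an
#' undefined threshold are counted but excluded from the mean and
#' histogram.
#'
#' @param estimates `data.frame` from [estimate_all_thresholds()].
#' @param bin_width Histogram bin width (default 0.05, which resolves a
#'   10–20% modal range).
#' @param n_excluded Number of physicians excluded at screening (carried
#'   into the summary).
#' @return Object of class `population_summary`.
#' @export
summarize_population <- function(estimates, bin_width = 0.05, n_excluded = 0) {
  thr <- estimates$threshold[!is.na(estimates$threshold)]
  if (!length(thr)) stopf("no numeric thresholds to summarize")
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  # histogram lives on [0,1]; balance points estimated beyond the unit
  # interval are shown in the edge bins
  h <- graphics::hist(pmin(pmax(thr, 0), 1), breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  modal <- which.max(h$counts)
  structure(list(
    mean_threshold = mean(thr),
    histogram = list(edges = edges, counts = h$counts),
    modal_interval = c(edges[modal], edges[modal + 1]),
    n_included = nrow(estimates),
    n_excluded = n_excluded,
    method_counts = table(estimates$method)),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population of %d physicians (%d excluded at screening)\n",
              x$n_included, x$n_excluded))
  cat(sprintf("  mean threshold: %.3f; modal interval: [%.2f, %.2f)\n",
              x$mean_threshold, x$modal_interval[1], x$modal_interval[2]))
  cat("  methods:", paste(sprintf("%s=%d", names(x$method_counts),
                                  x$method_counts), collapse = ", "), "\n")
  invisible(x)
}
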