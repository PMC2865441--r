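# Shared fixtures and independent oracles, all built in code.

make_pop_config <- function(n_cases = 50, seed = 1) {
  population_config(
    continuous = list(
      age = list(mean = 55, sd = 9.5, lower = 40, upper = 80),
      iop = list(mean = 24.9, sd = 2.7, lower = 22, upper = 32),
      cdr = list(mean = 0.39, sd = 0.19, lower = 0, upper = 0.8),
      psd = list(mean = 1.91, sd = 0.2, lower = 0.5, upper = 3),
      cct = list(mean = 573, sd = 38, lower = 450, upper = 700)),
    binary = list(diabetes = 0.12),
    categorical = list(gender = c(female = 0.43, male = 0.57)),
    n_cases = n_cases, seed = seed)
}

make_risk_config <- function() {
  risk_model_config(
    coefficients = c(age = 0.02, iop = 0.08, cdr = 1.5, psd = 0.3,
                     cct = -0.006, diabetes = -0.2),
    intercept = -2.76, link = "logistic")
}

# Population config whose derived risks span most of (0, 1): used for
# recovery studies where case risks must cover the threshold support.
make_wide_risk_setup <- function(n_cases, seed) {
  pop <- make_pop_config(n_cases, seed)
  pop$continuous$iop <- list(mean = 27, sd = 5, lower = 20, upper = 40)
  cfg <- risk_model_config(coefficients = c(iop = 0.35), intercept = -10.4,
                           link = "logistic")
  cases <- simulate_cases(pop)
  list(cases = cases, risks = compute_risks(cases, cfg))
}

# Plain bisection root of P(Yes | r) - P(No | r) for given coefficients;
# independent of the closed-form path under test.
bisect_balance <- function(alpha_U, alpha_Y, beta, lo = -5, hi = 5,
                           tol = 1e-12) {
  f <- function(r) plogis(alpha_Y + beta * r) - (1 - plogis(alpha_U + beta * r))
  stopifnot(f(lo) * f(hi) < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Draw collapsed 3-level responses from the cumulative-logit model with
# logit P(t >= Unsure) = aU + b r, logit P(t >= Yes) = aY + b r.
draw_responses3 <- function(risks, alpha_U, alpha_Y, beta) {
  pU <- plogis(alpha_U + beta * risks)
  pY <- plogis(alpha_Y + beta * risks)
  u <- runif(length(risks))
  c("No", "Unsure", "Yes")[1L + (u < pU) + (u < pY)]
}

# Independent proportional-odds log-likelihood (category probabilities
# assembled directly, no code shared with the fitting path).
indep_ord_loglik <- function(par, r, y3) {
  pU <- plogis(par[1] + par[3] * r)
  pY <- plogis(par[2] + par[3] * r)
  p <- cbind(1 - pU, pU - pY, pY)
  idx <- match(y3, c("No", "Unsure", "Yes"))
  sum(log(pmax(p[cbind(seq_along(idx), idx)], 1e-300)))
}

# Brute-force maximum of the same likelihood: coarse grid then
# Nelder-Mead polish from the best grid points.
indep_ord_mle <- function(r, y3) {
  grid <- expand.grid(aU = seq(-6, 6, by = 1), gap = seq(0.25, 8, by = 0.75),
                      b = seq(-60, 60, by = 5))
  vals <- apply(grid, 1, function(g)
    indep_ord_loglik(c(g[1], g[1] - g[2], g[3]), r, y3))
  best <- NULL
  for (i in order(vals, decreasing = TRUE)[1:5]) {
    g <- as.numeric(grid[i, ])
    o <- optim(c(g[1], g[1] - g[2], g[3]),
               function(p) if (p[1] <= p[2]) 1e10 else -indep_ord_loglik(p, r, y3),
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(par = best$par, loglik = -best$value)
}

# Exhaustive pairwise concordance, naive double loop.
naive_concordance <- function(risks, y3) {
  ord <- match(y3, c("No", "Unsure", "Yes"))
  num <- 0; den <- 0
  for (i in seq_along(risks)) for (j in seq_along(risks)) {
    if (i < j && ord[i] != ord[j]) {
      hi <- which.max(c(ord[i], ord[j]))
      rh <- risks[c(i, j)][hi]; rl <- risks[c(i, j)][-hi]
      num <- num + (rh > rl) + 0.5 * (rh == rl)
      den <- den + 1
    }
  }
  num / den
}

case_ids_for <- function(risks) sprintf("case_%03d", seq_along(risks))

named_risks <- function(risks) setNames(risks, case_ids_for(risks))

responses_df <- function(risks, response7, physician_id = "md_x") {
  data.frame(physician_id = physician_id, case_id = case_ids_for(risks),
             response = response7, stringsAsFactors = FALSE)
}
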