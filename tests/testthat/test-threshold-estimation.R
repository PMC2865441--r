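test_that("closed-form threshold matches arithmetic and the bisection oracle", {
  # symmetric intercepts balance at zero
  expect_equal(threshold_from_fit(list(alpha_U = 2, alpha_Y = -2, beta = 10)), 0)

  # worked example with the balance verified explicitly
  thr <- threshold_from_fit(list(alpha_U = -1, alpha_Y = -6, beta = 25))
  expect_equal(thr, 0.14)
  expect_equal(plogis(-6 + 25 * thr), 1 - plogis(-1 + 25 * thr))
  expect_equal(plogis(-6 + 25 * thr), plogis(-2.5))

  expect_equal(threshold_from_fit(list(alpha_U = -0.5, alpha_Y = -4, beta = 20)),
               bisect_balance(-0.5, -4, 20), tolerance = 1e-9)

  # oracle equivalence over random coefficient triples with r* in (0,1)
  set.seed(31)
  for (rep in 1:100) {
    rstar <- runif(1, 0.05, 0.95); beta <- runif(1, 5, 60)
    gap <- runif(1, 0.5, 5)
    aU <- -beta * rstar + gap; aY <- -beta * rstar - gap
    cf <- threshold_from_fit(list(alpha_U = aU, alpha_Y = aY, beta = beta))
    expect_lt(abs(cf - bisect_balance(aU, aY, beta)), 1e-9)
    # balance identity at the closed-form root
    expect_lt(abs(plogis(aY + beta * cf) - (1 - plogis(aU + beta * cf))), 1e-9)
  }

  expect_error(threshold_from_fit(list(alpha_U = 1, alpha_Y = -1, beta = 0)),
               "beta")
  expect_warning(threshold_from_fit(list(alpha_U = 1, alpha_Y = -1, beta = -5)),
                 "inverted")
})

test_that("the proportional-odds fit recovers generating parameters", {
  set.seed(32)
  r <- runif(2000)
  y3 <- draw_responses3(r, alpha_U = -1, alpha_Y = -6, beta = 25)
  fit <- fit_ordinal_model(r, y3)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_lt(abs(fit$alpha_U - (-1)), 3 * fit$se[["alpha_U"]])
  expect_lt(abs(fit$alpha_Y - (-6)), 3 * fit$se[["alpha_Y"]])
  expect_lt(abs(fit$beta - 25), 3 * fit$se[["beta"]])
  expect_gte(fit$loglik_full, fit$loglik_null - 1e-8)
  expect_gte(fit$alpha_U, fit$alpha_Y)
})

test_that("fitted parameters agree with an independent cumulative-link fitter", {
  # MASS::polr models P(t <= j) = logis(zeta_j - beta x); the package's
  # canonical form is logit P(t >= j) = alpha_j + beta r, so alpha_U =
  # -zeta_1, alpha_Y = -zeta_2 and the slopes coincide. A sign slip here
  # would invert every threshold.
  set.seed(33)
  r <- runif(600)
  y3 <- draw_responses3(r, alpha_U = -0.8, alpha_Y = -4.5, beta = 18)
  fit <- fit_ordinal_model(r, y3)
  pf <- MASS::polr(factor(y3, levels = c("No", "Unsure", "Yes"), ordered = TRUE) ~ r)
  expect_equal(fit$alpha_U, unname(-pf$zeta[1]), tolerance = 1e-3)
  expect_equal(fit$alpha_Y, unname(-pf$zeta[2]), tolerance = 1e-3)
  expect_equal(fit$beta, unname(coef(pf)), tolerance = 1e-3)
  # the package's Newton polish must do at least as well as the reference
  expect_gte(fit$loglik_full, as.numeric(logLik(pf)) - 1e-6)
})

test_that("responses unrelated to risk give a null fit", {
  set.seed(34)
  r <- runif(600)
  y3 <- sample(c("No", "Unsure", "Yes"), 600, replace = TRUE,
               prob = c(0.4, 0.3, 0.3))
  fit <- fit_ordinal_model(r, y3)
  expect_lt(fit$loglik_full - fit$loglik_null, 3)
  expect_lt(abs(fit$beta), 3 * fit$se[["beta"]])
  expect_lt(nagelkerke_r2(fit), 0.02)
})

test_that("complete separation along risk is detected", {
  r <- c(0.05, 0.1, 0.15, 0.3, 0.35, 0.5, 0.55, 0.6)
  y3 <- c("No", "No", "No", "Unsure", "Unsure", "Yes", "Yes", "Yes")
  fit <- fit_ordinal_model(r, y3)
  expect_true(fit$separation)
})

test_that("binary fallback equals the logistic-regression 0.5 point", {
  expect_equal(-(-3) / 30, 0.1)  # the definition: threshold = -alpha/beta

  set.seed(35)
  r <- runif(2000)
  p <- plogis(-3 + 30 * r)
  y3 <- ifelse(runif(2000) < p, "Yes", "No")
  est <- fit_binary_threshold(r, y3, "md_b")
  expect_equal(est$method, "binary")
  expect_lt(abs(est$threshold - 0.1), 0.01)
  expect_false(is.na(est$r2_nagelkerke))
  expect_false(is.na(est$concordance))

  # uninformative data: equal Yes/No at every risk
  r2 <- rep(seq(0.1, 0.5, by = 0.1), each = 2)
  y2 <- rep(c("Yes", "No"), 5)
  est2 <- fit_binary_threshold(r2, y2)
  expect_true(any(grepl("unstable", est2$warnings)))
})

test_that("degenerate response patterns follow the assignment rules", {
  risks <- c(0.1, 0.42, 0.3)
  never <- degenerate_threshold(c("No", "Unsure", "No"), risks)
  expect_equal(never$threshold, (0.42 + 1) / 2)
  expect_equal(never$method, "never_treat")

  always <- degenerate_threshold(c("Yes", "Unsure", "Yes"), c(0.02, 0.3, 0.5))
  expect_equal(always$threshold, 0.01)
  expect_equal(always$method, "always_treat")

  unsure <- degenerate_threshold(rep("Unsure", 5), runif(5))
  expect_equal(unsure$method, "undefined")
  expect_true(is.na(unsure$threshold))

  expect_error(degenerate_threshold(character(), numeric()), "empty")
  expect_error(degenerate_threshold(c("No", "Yes"), c(0.1, 0.2)), "degenerate")
})

test_that("the dispatcher routes by observed response pattern", {
  set.seed(36)
  risks <- runif(500, 0.01, 0.6)
  nr <- named_risks(risks)

  # well-mixed three-level data -> ordinal, with recovery of r* = 0.20
  panel <- data.frame(physician_id = "md_a", threshold = 0.20,
                      discrimination = 40)
  attr(panel, "spacing") <- default_spacing()
  resp <- simulate_responses(panel, risks, seed = 37)
  est <- estimate_threshold(resp, nr)
  expect_equal(est$method, "ordinal")
  expect_lt(abs(est$threshold - 0.20), 0.02)
  expect_false(is.na(est$r2_nagelkerke))

  # only firm answers -> binary
  p <- plogis(40 * (risks - 0.2))
  firm <- ifelse(runif(500) < p, "DefinitelyYes", "DefinitelyNo")
  est_b <- estimate_threshold(responses_df(risks, firm), nr)
  expect_equal(est_b$method, "binary")

  # never a Yes -> assignment rule
  est_n <- estimate_threshold(responses_df(risks,
    sample(c("DefinitelyNo", "PossiblyNo", "Unsure"), 500, TRUE)), nr)
  expect_equal(est_n$method, "never_treat")
  expect_equal(est_n$threshold, (max(risks) + 1) / 2)

  # separation -> empirical-gap midpoint
  r_sep <- c(0.1, 0.15, 0.2, 0.3, 0.32, 0.45, 0.5)
  y_sep <- c("DefinitelyNo", "ProbablyNo", "PossiblyNo", "Unsure",
             "PossiblyYes", "ProbablyYes", "DefinitelyYes")
  est_s <- estimate_threshold(responses_df(r_sep, y_sep), named_risks(r_sep))
  expect_equal(est_s$method, "separation_midpoint")
  expect_equal(est_s$threshold, (0.32 + 0.45) / 2)

  # unjoinable case ids are listed
  bad <- responses_df(risks, resp$response)
  bad$case_id[1] <- "case_zzz"
  expect_error(estimate_threshold(bad, nr), "case_zzz")
})

test_that("threshold estimation is affine-equivariant and unit-invariant", {
  set.seed(38)
  r <- runif(800, 0.01, 0.6)
  y3 <- draw_responses3(r, alpha_U = 0.5 - 30 * 0.18, alpha_Y = -0.5 - 30 * 0.18,
                        beta = 30)
  f0 <- fit_ordinal_model(r, y3)
  t0 <- threshold_from_fit(f0)

  a <- 2.5; b <- 0.04
  f1 <- fit_ordinal_model(a * r + b, y3)
  expect_lt(abs(threshold_from_fit(f1) - (a * t0 + b)), 1e-6)

  # percent-scale risks give 100x the proportion-scale threshold
  f2 <- fit_ordinal_model(100 * r, y3)
  expect_lt(abs(threshold_from_fit(f2) - 100 * t0), 1e-4)
})

test_that("balance identity holds at every converged fit", {
  set.seed(39)
  for (rep in 1:10) {
    r <- runif(400, 0.01, 0.7)
    rstar <- runif(1, 0.1, 0.4); beta <- runif(1, 10, 50)
    y3 <- draw_responses3(r, -beta * rstar + 1.2, -beta * rstar - 1.2, beta)
    if (length(unique(y3)) < 3) next
    fit <- fit_ordinal_model(r, y3)
    if (!fit$converged || fit$separation) next
    thr <- threshold_from_fit(fit)
    p_yes <- plogis(fit$alpha_Y + fit$beta * thr)
    p_no <- 1 - plogis(fit$alpha_U + fit$beta * thr)
    expect_lt(abs(p_yes - p_no), 1e-9)
  }
})

test_that("Nagelkerke R2 matches a brute-force maximization of the likelihood", {
  expect_equal(nagelkerke_r2(list(loglik_full = -10, loglik_null = -10, n = 20)), 0)

  # fixed 6-observation fixtures with overlapping categories (finite MLE)
  fixtures <- list(
    list(r = c(0.10, 0.30, 0.15, 0.40, 0.20, 0.45),
         y = c("No", "No", "Unsure", "Unsure", "Yes", "Yes")),
    list(r = c(0.05, 0.25, 0.12, 0.33, 0.18, 0.28),
         y = c("No", "Yes", "Unsure", "Yes", "No", "Unsure")),
    list(r = c(0.20, 0.10, 0.35, 0.30, 0.25, 0.15),
         y = c("Unsure", "No", "Yes", "Unsure", "Yes", "No")))
  for (fx in fixtures) {
    r <- fx$r; y3 <- fx$y
    fit <- fit_ordinal_model(r, y3)
    oracle <- indep_ord_mle(r, y3)
    expect_lt(abs(fit$loglik_full - oracle$loglik), 1e-6)
    n_j <- table(factor(y3, levels = c("No", "Unsure", "Yes")))
    ll0 <- sum(n_j[n_j > 0] * log(n_j[n_j > 0] / 6))
    r2_oracle <- (1 - exp((2 / 6) * (ll0 - oracle$loglik))) /
      (1 - exp((2 / 6) * ll0))
    expect_lt(abs(nagelkerke_r2(fit) - r2_oracle), 1e-6)
  }

  # informative data outscores permuted labels on the same cases
  set.seed(41)
  r <- runif(300, 0.01, 0.6)
  y3 <- draw_responses3(r, -0.5 - 35 * 0.2, 0.5 - 35 * 0.2 - 1, 35)
  f_real <- fit_ordinal_model(r, y3)
  f_perm <- fit_ordinal_model(r, sample(y3))
  expect_gt(nagelkerke_r2(f_real), nagelkerke_r2(f_perm))
})

test_that("concordance matches exhaustive pair enumeration", {
  expect_equal(concordance_index(c(0.1, 0.2, 0.3), c("No", "Yes", "Unsure")),
               2 / 3)
  expect_equal(concordance_index(c(0.1, 0.2, 0.3, 0.4),
                                 c("No", "Unsure", "Yes", "Yes")), 1)
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    r <- round(runif(n, 0.05, 0.5), 2)  # rounding produces occasional ties
    y3 <- sample(c("No", "Unsure", "Yes"), n, replace = TRUE)
    if (length(unique(y3)) < 2) next
    expect_equal(concordance_index(r, y3), naive_concordance(r, y3))
  }
  # permuted responses at n=1000 sit near one half
  r <- runif(1000)
  y3 <- sample(c("No", "Unsure", "Yes"), 1000, replace = TRUE)
  expect_lt(abs(concordance_index(r, y3) - 0.5), 0.05)
  expect_true(is.na(concordance_index(runif(5), rep("Yes", 5))))
})
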