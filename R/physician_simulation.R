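#' The 7-point and collapsed 3-point recommendation scales
#'
#' Physicians express how likely they would be to recommend treatment on a
#' 7-point ordinal scale; analysis collapses it to No < Unsure < Yes.
#'
#' @format Character vectors of ordered level labels.
#' @export
response_levels7 <- c("DefinitelyNo", "ProbablyNo", "PossiblyNo", "Unsure",
                      "PossiblyYes", "ProbablyYes", "DefinitelyYes")

#' @rdname response_levels7
#' @export
response_levels3 <- c("No", "Unsure", "Yes")

# 7 -> 3 mapping: the two firm "No" levels collapse to No, the middle three
# hedged levels to Unsure, the two firm "Yes" levels to Yes.
collapse_map <- c(DefinitelyNo = "No", ProbablyNo = "No",
                  PossiblyNo = "Unsure", Unsure = "Unsure",
                  PossiblyYes = "Unsure",
                  ProbablyYes = "Yes", DefinitelyYes = "Yes")

#' Collapse 7-point recommendations to the 3-point analysis scale
#'
#' Maps each response to the nearest of No/Unsure/Yes while keeping an
#' explicit Unsure category: DefinitelyNo and ProbablyNo become No;
#' PossiblyNo, Unsure and PossiblyYes become Unsure; ProbablyYes and
#' DefinitelyYes become Yes. The mapping is total and order-preserving.
#'
#' @param response Character vector (or factor) of 7-point level labels.
#' @return Ordered factor with levels No < Unsure < Yes.
#' @export
collapse_scale <- function(response) {
  response <- as.character(response)
  bad <- setdiff(unique(response), names(collapse_map))
  if (length(bad))
    stopf("unknown response level(s): %s", paste(bad, collapse = ", "))
  factor(unname(collapse_map[response]), levels = response_levels3,
         ordered = TRUE)
}

#' Default cutpoint spacing for the response generator
#'
#' Six strictly decreasing offsets `s2..s7` placing the boundaries of the
#' seven response regions around the latent threshold. The inner-boundary
#' symmetry `s3 = -s6` guarantees that on the collapsed scale the risk at
#' which Yes and No are equally likely equals the physician's latent
#' threshold exactly.
#'
#' @return Numeric vector of length 6.
#' @export
default_spacing <- function() c(3, 1.5, 0.5, -0.5, -1.5, -3)

#' Simulate a panel of physicians
#'
#' Latent treatment thresholds are i.i.d. Beta(`shape1`, `shape2`) —
#' mirroring the beta-distributed population of thresholds — and each
#' physician's discrimination (the slope of the cumulative logit in risk)
#' is uniform on `discrimination_range`.
#'
#' @param n_physicians Panel size.
#' @param shape1,shape2 Beta shape parameters of the threshold population.
#' @param discrimination_range Length-2 positive range `(lo, hi)`.
#' @param spacing Cutpoint offsets `s2..s7`, strictly decreasing with
#'   `s3 = -s6`; see [default_spacing()].
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `physician_id`, `threshold`,
#'   `discrimination`; the spacing is attached as attribute `"spacing"`.
#' @export
simulate_physician_panel <- function(n_physicians, shape1 = 2.56,
                                     shape2 = 9.14,
                                     discrimination_range = c(20, 60),
                                     spacing = default_spacing(),
                                     seed = NULL) {
  if (shape1 <= 0 || shape2 <= 0) stopf("beta shapes must be positive")
  lo <- discrimination_range[1]; hi <- discrimination_range[2]
  if (!(0 < lo && lo <= hi)) stopf("discrimination range must satisfy 0 < lo <= hi")
  validate_spacing(spacing)
  with_seed(seed, {
    panel <- data.frame(
      physician_id = sprintf("md_%04d", seq_len(n_physicians)),
      threshold = stats::rbeta(n_physicians, shape1, shape2),
      discrimination = stats::runif(n_physicians, lo, hi),
      stringsAsFactors = FALSE)
    attr(panel, "spacing") <- spacing
    panel
  })
}

validate_spacing <- function(spacing) {
  if (length(spacing) != 6 || any(diff(spacing) >= 0))
    stopf("spacing must be 6 strictly decreasing offsets s2..s7")
  if (abs(spacing[2] + spacing[5]) > 1e-12)
    stopf("spacing must satisfy s3 = -s6 so the collapsed threshold equals the latent threshold")
  invisible(spacing)
}

# Cumulative P(t >= j | r), j = 2..7, for one physician.
cumulative_probs7 <- function(risk, threshold, discrimination, spacing) {
  cp <- vapply(spacing, function(s)
    logistic(discrimination * (risk - threshold) + s), numeric(length(risk)))
  matrix(cp, nrow = length(risk))
}

#' Simulate 7-point recommendations from a physician panel
#'
#' For each (physician, case) pair a level is drawn from the 7-category
#' proportional-odds model with cumulative logits
#' `logit P(t >= j | r) = beta * (r - r*) + s_j` for `j = 2..7`, i.e.
#' cutpoints `kappa_j = -beta * r* + s_j` so the latent threshold `r*` is
#' the risk at which, after collapsing, Yes and No are equally likely.
#'
#' @param panel Output of [simulate_physician_panel()] (or a compatible
#'   `data.frame` with a `"spacing"` attribute).
#' @param risks Numeric vector of case risks in (0, 1).
#' @param case_ids Optional case identifiers (default `case_001`, ...).
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `physician_id`, `case_id`, `response`
#'   (7-point level labels), one row per (physician, case).
#' @export
simulate_responses <- function(panel, risks, case_ids = NULL, seed = NULL) {
  if (nrow(panel) == 0L) stopf("panel must contain at least one physician")
  assert_prob(risks, "risks")
  spacing <- attr(panel, "spacing")
  if (is.null(spacing)) spacing <- default_spacing()
  validate_spacing(spacing)
  if (is.null(case_ids)) case_ids <- sprintf("case_%03d", seq_along(risks))
  with_seed(seed, {
    out <- vector("list", nrow(panel))
    for (i in seq_len(nrow(panel))) {
      cp <- cumulative_probs7(risks, panel$threshold[i],
                              panel$discrimination[i], spacing)
      u <- stats::runif(length(risks))
      level <- 1L + rowSums(cp > u)   # P(t>=j) decreasing in j
      out[[i]] <- data.frame(physician_id = panel$physician_id[i],
                             case_id = case_ids,
                             response = response_levels7[level],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
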