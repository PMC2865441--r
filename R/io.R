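# Delimited-text I/O with header validation. Risks are serialized as
# proportions with 6 decimals; a percent flag converts at the boundary
# only (the estimator itself is unit-agnostic).

case_columns <- c("case_id", "age", "iop", "cdr", "psd", "cct",
                  "diabetes", "gender")

#' Read and validate a case table
#'
#' @param path CSV file with header
#'   `case_id,age,iop,cdr,psd,cct,diabetes,gender`; `diabetes` coded 0/1.
#' @return Validated case `data.frame`.
#' @export
read_case_table <- function(path) {
  if (!file.exists(path)) stopf("case table not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(case_columns, names(d))
  if (length(missing))
    stopf("case table %s lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  d <- d[case_columns]
  for (col in c("age", "iop", "cdr", "psd", "cct")) {
    v <- d[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stopf("non-numeric or missing %s at row %d", col,
            which(is.na(suppressWarnings(as.numeric(v))) | !is.finite(suppressWarnings(as.numeric(v))))[1])
  }
  bad <- which(d$cdr < 0 | d$cdr > 1)
  if (length(bad)) stopf("cdr outside [0, 1] at row %d", bad[1])
  bad <- which(d$age <= 0 | d$iop <= 0 | d$psd <= 0 | d$cct <= 0)
  if (length(bad)) stopf("non-positive risk factor at row %d", bad[1])
  if (!all(d$diabetes %in% c(0L, 1L)))
    stopf("diabetes must be coded 0/1 (row %d)",
          which(!d$diabetes %in% c(0L, 1L))[1])
  if (anyDuplicated(d$case_id))
    stopf("duplicate case_id: %s", d$case_id[anyDuplicated(d$case_id)])
  d$diabetes <- as.integer(d$diabetes)
  d
}

#' Write a case table
#' @param cases Case `data.frame`.
#' @param path Output CSV path.
#' @export
write_case_table <- function(cases, path) {
  out <- cases[case_columns]
  for (col in c("age", "iop", "cdr", "psd", "cct"))
    out[[col]] <- sprintf("%.6f", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a response table
#'
#' @param path CSV with header `physician_id,case_id,response` using the
#'   seven canonical level strings of [response_levels7].
#' @return Validated response `data.frame`.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stopf("response table not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("physician_id", "case_id", "response")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stopf("response table %s lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  d <- d[need]
  bad <- setdiff(unique(d$response), response_levels7)
  if (length(bad))
    stopf("unknown response level(s): %s", paste(bad, collapse = ", "))
  key <- paste(d$physician_id, d$case_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stopf("duplicate (physician_id, case_id) pair: (%s, %s)",
          d$physician_id[i], d$case_id[i])
  }
  d
}

#' Write a response table
#' @param responses Response `data.frame`.
#' @param path Output CSV path.
#' @export
write_response_table <- function(responses, path) {
  utils::write.csv(responses[c("physician_id", "case_id", "response")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a risk table
#'
#' @param path CSV with columns `case_id` and `risk` (additional columns
#'   are allowed and ignored).
#' @param percent If `TRUE`, the file stores percentages; values are
#'   converted to proportions on read.
#' @return `data.frame` with `case_id` and `risk` as proportions.
#' @export
read_risk_table <- function(path, percent = FALSE) {
  if (!file.exists(path)) stopf("risk table not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "risk") %in% names(d)))
    stopf("risk table %s needs columns case_id and risk", path)
  if (percent) d$risk <- d$risk / 100
  assert_prob(d$risk, "risk")
  d[c("case_id", "risk")]
}

#' Write a risk column appended to a case table
#'
#' @param cases Case `data.frame`.
#' @param risks Risk vector (proportions), one per case.
#' @param path Output CSV path.
#' @param percent Write percentages instead of proportions.
#' @export
write_risk_table <- function(cases, risks, path, percent = FALSE) {
  out <- cases[case_columns]
  for (col in c("age", "iop", "cdr", "psd", "cct"))
    out[[col]] <- sprintf("%.6f", out[[col]])
  out$risk <- sprintf("%.6f", if (percent) 100 * risks else risks)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

yaml_block <- function(conf, path, name) {
  if (is.character(conf)) {
    p <- if (file.exists(conf)) conf else file.path(dirname(path), conf)
    if (!file.exists(p)) stopf("%s config file not found: %s", name, conf)
    yaml::read_yaml(p)
  } else conf
}

#' Read a population configuration from YAML
#' @param path YAML file with keys `n_cases`, `continuous`, `binary`,
#'   `categorical` and optional `seed`.
#' @return A [population_config()].
#' @export
read_population_config <- function(path) {
  y <- yaml::read_yaml(path)
  population_config(continuous = y$continuous, binary = y$binary,
                    categorical = lapply(y$categorical, unlist),
                    n_cases = y$n_cases, seed = y$seed)
}

#' Read a risk-model configuration from YAML
#' @param path YAML file with keys `coefficients`, `intercept`, `link`,
#'   optional `baseline_survival` and `risk_horizon`.
#' @return A [risk_model_config()].
#' @export
read_risk_config <- function(path) {
  y <- yaml::read_yaml(path)
  risk_model_config(coefficients = unlist(y$coefficients),
                    intercept = y$intercept %||% 0,
                    link = y$link %||% "logistic",
                    baseline_survival = y$baseline_survival,
                    risk_horizon = y$risk_horizon %||% 5)
}

#' Read a physician-panel configuration from YAML
#' @param path YAML file with keys `n_physicians`, `threshold_shape1`,
#'   `threshold_shape2`, `discrimination_range`, optional `spacing`.
#' @return A plain list consumed by [simulate_physician_panel()].
#' @export
read_panel_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(n_physicians = y$n_physicians,
       shape1 = y$threshold_shape1 %||% 2.56,
       shape2 = y$threshold_shape2 %||% 9.14,
       discrimination_range = unlist(y$discrimination_range %||% c(20, 60)),
       spacing = unlist(y$spacing %||% default_spacing()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
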