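#' One-tailed Student's t-test between two groups
#'
#' Classical pooled-variance (equal-variance) Student's t-test with a
#' one-tailed alternative, significant at P < 0.01.  When the pooled
#' variance is zero and the means are equal, the one-tailed p-value is 0.5
#' by convention (the null is exactly on the boundary).
#'
#' @param a,b numeric vectors (n >= 2 each) or `group_sample` lists with
#'   fields `values`, `condition`, `unit`.
#' @param alternative `"a_greater"` or `"b_greater"`: the directed
#'   alternative hypothesis.
#' @param welch use the Welch (unequal-variance) statistic instead of the
#'   pooled one, default `FALSE`.
#' @param alpha significance level, default 0.01.
#' @return a `test_result` list: `t_statistic`, `df`, `p_one_tailed`,
#'   `significant`, `direction`.
#' @export
one_tailed_t_test <- function(a, b, alternative = c("a_greater", "b_greater"),
                              welch = FALSE, alpha = 0.01) {
  alternative <- match.arg(alternative)
  ga <- as_group_sample(a); gb <- as_group_sample(b)
  if (!is.null(ga$unit) && !is.null(gb$unit) && !identical(ga$unit, gb$unit))
    abort_invalid("mismatched units: ", ga$unit, " vs ", gb$unit)
  x <- ga$values; y <- gb$values
  if (length(x) < 2L || length(y) < 2L)
    abort_invalid("both groups need n >= 2")

  nx <- length(x); ny <- length(y)
  if (welch) {
    vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
    se <- sqrt(vx + vy)
    df <- if (se == 0) nx + ny - 2 else (vx + vy)^2 /
      (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  delta <- mean(x) - mean(y)
  tstat <- if (se == 0) {
    if (delta == 0) 0 else sign(delta) * Inf
  } else delta / se
  # p for the stated direction
  p <- if (alternative == "a_greater") pt(tstat, df, lower.tail = FALSE)
       else pt(tstat, df, lower.tail = TRUE)
  if (se == 0 && delta == 0) p <- 0.5
  structure(
    list(t_statistic = tstat, df = df, p_one_tailed = p,
         significant = p < alpha, alpha = alpha,
         direction = if (alternative == "a_greater") "A_greater" else "B_greater"),
    class = "test_result")
}

as_group_sample <- function(x) {
  if (is.list(x) && !is.null(x$values)) x else list(values = as.numeric(x),
                                                    condition = NA, unit = NULL)
}

#' Bundle replicate values for one experimental condition
#'
#' @param condition condition label.
#' @param values numeric replicate values.
#' @param unit `"kPa"` or `"s"`.
#' @return a `group_sample` list.
#' @export
group_sample <- function(condition, values, unit = c("s", "kPa")) {
  unit <- match.arg(unit)
  if (length(values) < 2L) abort_invalid("a group sample needs n >= 2")
  structure(list(condition = condition, values = as.numeric(values),
                 unit = unit), class = "group_sample")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("One-tailed Student's t: t = %.4g (df %.4g), p = %.4g (%s)\n",
              x$t_statistic, x$df, x$p_one_tailed,
              if (x$significant) paste0("significant at P < ", x$alpha)
              else "not significant"))
  invisible(x)
}

#' Compare conditions against a baseline
#'
#' Tabulates per-condition summaries (pressure estimates and/or extrusion
#' times), differences from the baseline condition, and one-tailed
#' Student's t-tests wherever replicate-level samples exist on both sides;
#' single point estimates are compared by difference only, with the test
#' column marked not applicable.
#'
#' @param results named list (condition -> entry); each entry may contain a
#'   `pressure_estimate` (field `pressure`) and/or a `group_sample` of
#'   replicate values (field `times` or `samples`).  A bare
#'   `pressure_estimate` or `group_sample` is also accepted.
#' @param baseline name of the baseline condition (must be present).
#' @param alternative direction of the test applied to baseline vs other:
#'   `"baseline_greater"` tests baseline > other (pressures under
#'   inhibition), `"other_greater"` tests other > baseline (delayed
#'   extrusion times), default `"other_greater"`.
#' @param alpha significance level, default 0.01.
#' @return a `condition_comparison`: data frame with one row per condition
#'   (`condition`, `pressure_kPa`, `mean_time_s`, `n`, `diff_from_baseline`,
#'   `t_statistic`, `p_one_tailed`, `significant`, `test`).
#' @export
compare_conditions <- function(results, baseline,
                               alternative = c("other_greater",
                                               "baseline_greater"),
                               alpha = 0.01) {
  alternative <- match.arg(alternative)
  if (!baseline %in% names(results))
    abort_invalid("baseline condition '", baseline, "' not in results")
  entries <- lapply(results, normalise_entry)
  base <- entries[[baseline]]

  rows <- lapply(names(entries), function(cond) {
    e <- entries[[cond]]
    est <- if (!is.null(e$pressure)) e$pressure$pressure_kPa else NA_real_
    smp <- e$sample
    mean_t <- if (!is.null(smp)) mean(smp$values) else NA_real_
    n <- if (!is.null(smp)) length(smp$values) else
      if (!is.null(e$pressure)) 1L else 0L
    base_val <- if (!is.null(base$sample)) mean(base$sample$values)
      else if (!is.null(base$pressure)) base$pressure$pressure_kPa else NA_real_
    this_val <- if (!is.null(smp)) mean_t else est
    diff <- if (cond == baseline) 0 else this_val - base_val

    tt <- NULL
    if (cond != baseline && !is.null(smp) && !is.null(base$sample))
      tt <- one_tailed_t_test(
        smp, base$sample,
        alternative = if (alternative == "other_greater") "a_greater"
                      else "b_greater",
        alpha = alpha)
    data.frame(
      condition = cond,
      pressure_kPa = est,
      mean_time_s = mean_t,
      n = n,
      diff_from_baseline = diff,
      t_statistic = if (is.null(tt)) NA_real_ else tt$t_statistic,
      p_one_tailed = if (is.null(tt)) NA_real_ else tt$p_one_tailed,
      significant = if (is.null(tt)) NA else tt$significant,
      test = if (is.null(tt)) {
        if (cond == baseline) "baseline" else "not applicable"
      } else "one-tailed Student's t")
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- baseline
  attr(out, "alpha") <- alpha
  class(out) <- c("condition_comparison", "data.frame")
  out
}

normalise_entry <- function(e) {
  if (inherits(e, "pressure_estimate")) return(list(pressure = e, sample = NULL))
  if (inherits(e, "group_sample")) return(list(pressure = NULL, sample = e))
  if (is.numeric(e)) return(list(pressure = NULL,
                                 sample = list(values = e, unit = NULL)))
  smp <- e$times %||% e$samples %||% e$sample
  if (is.numeric(smp)) smp <- list(values = smp, unit = NULL)
  list(pressure = e$pressure, sample = smp)
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison (baseline: ", attr(x, "baseline"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a comparison report as CSV and JSON
#'
#' @param comparison a `condition_comparison`.
#' @param stem output path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @export
write_comparison <- function(comparison, stem) {
  write.csv(as.data.frame(comparison), paste0(stem, ".csv"),
            row.names = FALSE)
  jsonlite::write_json(as.data.frame(comparison), paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(stem)
}
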