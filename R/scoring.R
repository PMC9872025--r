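#' Two-standard-deviation standardization
#'
#' Centers a numeric vector and divides by twice its sample standard deviation
#' (n-1 denominator), so the output has mean 0 and SD 0.5. Dividing by 2 SD
#' puts coefficients of binary predictors on a scale comparable to
#' standardized continuous ones. The returned scaling record allows exact
#' back-transformation with [unstandardize()].
#'
#' @param values Numeric vector with at least two non-missing values and
#'   non-zero variance.
#' @param name Optional label stored in the scaling record.
#' @return List with `values` (standardized vector), `center` (mean) and
#'   `scale` (2 x sample SD).
#' @export
#' @examples
#' standardize_2sd(c(-1, 1))$values  # -0.3536, +0.3536
standardize_2sd <- function(values, name = NULL) {
  ok <- !is.na(values)
  if (sum(ok) < 2) abort(sprintf("need >= 2 non-missing values%s",
                                 if (is.null(name)) "" else paste0(" for ", name)))
  s <- sd(values, na.rm = TRUE)
  if (s == 0) abort(sprintf("degenerate scale: zero variance%s",
                            if (is.null(name)) "" else paste0(" in ", name)))
  ctr <- mean(values, na.rm = TRUE)
  list(values = (values - ctr) / (2 * s), center = ctr, scale = 2 * s, name = name)
}

#' @rdname standardize_2sd
#' @param std Standardized values.
#' @param record A scaling record (list with `center` and `scale`).
#' @return `unstandardize()`: values on the original scale.
#' @export
unstandardize <- function(std, record) {
  record$center + record$scale * std
}

outcome_fields <- c("cmj", "line_drill", "yoyo_ir1")

#' Pooled z-scores and the composite fitness score
#'
#' Standardizes each fitness outcome against the pooled mean and sample SD
#' over all non-missing observations (all sexes, age groups and occasions),
#' reverses the line-drill z-score (lower times are better), and sums the
#' three z-scores into the overall physical fitness score. A row missing any
#' of the three outcomes gets a missing composite. Pooling across the whole
#' sample is what makes the composite comparable across sex and age cells
#' (younger/female cells sit below zero, older male cells above).
#'
#' When `scaling` is supplied (from a previous call, via
#' `attr(scored, "scaling")`), the stored pooled means/SDs are reused so new
#' data are scored against the fitted reference rather than re-standardized.
#'
#' @param table Observation table.
#' @param scaling Optional list of per-outcome `center`/`sd` records to reuse.
#' @return The table augmented with `z_cmj`, `z_line_drill_rev`, `z_yoyo`,
#'   `fitness_score`, with a `scaling` attribute recording pooled means/SDs.
#' @export
score_fitness <- function(table, scaling = NULL) {
  if (is.null(scaling)) {
    scaling <- lapply(setNames(outcome_fields, outcome_fields), function(f) {
      x <- table[[f]]
      if (sum(!is.na(x)) < 2) abort(sprintf("need >= 2 non-missing values in %s", f))
      s <- sd(x, na.rm = TRUE)
      if (s == 0) abort(sprintf("degenerate scale: zero variance in %s", f))
      list(center = mean(x, na.rm = TRUE), sd = s)
    })
  }
  z <- function(f) (table[[f]] - scaling[[f]]$center) / scaling[[f]]$sd
  out <- table
  out$z_cmj <- z("cmj")
  out$z_line_drill_rev <- -z("line_drill")
  out$z_yoyo <- z("yoyo_ir1")
  out$fitness_score <- out$z_cmj + out$z_line_drill_rev + out$z_yoyo
  attr(out, "scaling") <- scaling
  attr(out, "provenance") <- attr(table, "provenance")
  out
}
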