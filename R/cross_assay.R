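# Cross-assay comparison: ordinary least-squares regression of one
# mutation-frequency endpoint on another (e.g. duplex-sequencing MF vs a
# transgenic reporter mutant frequency measured in the same animals).

#' Least-squares regression of paired frequencies
#'
#' @param x,y Equal-length paired frequency vectors (n >= 3, `x` must vary).
#' @param scope Label recorded in the result (`"per-animal"` or
#'   `"per-dose"`).
#' @return A `regression_result`: `slope`, `intercept`, `r_squared`, `n`,
#'   `scope`.
#' @export
#' @examples
#' regress(1:5, 2 * (1:5)) # slope 2, R^2 = 1
regress <- function(x, y, scope = "per-animal") {
  if (length(x) != length(y)) stop_fmt("x and y must have equal length")
  if (length(x) < 3L) stop_fmt("need at least 3 paired points")
  if (stats::sd(x) == 0) stop_fmt("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
      n = length(x),
      scope = scope
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s regression (n = %d): slope %.4g, intercept %.4g, R^2 = %.4f\n",
              x$scope, x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Compare two assays measured on the same animals
#'
#' Pairs two per-sample frequency tables by `sample_id` (per-animal mode) or
#' averages within dose first (per-dose mode), then regresses assay `b` on
#' assay `a`.
#'
#' @param a,b `data.frame`s with columns `sample_id` and `frequency`.
#' @param metadata Sample metadata (needed for `by = "dose"`).
#' @param by `"animal"` or `"dose"`.
#' @return A `regression_result`.
#' @export
compare_assays <- function(a, b, metadata = NULL, by = c("animal", "dose")) {
  by <- match.arg(by)
  merged <- merge(a, b, by = "sample_id", suffixes = c("_a", "_b"))
  if (nrow(merged) < 3L) stop_fmt("fewer than 3 paired samples")
  if (by == "dose") {
    if (is.null(metadata)) stop_fmt("per-dose pairing requires metadata")
    merged$dose <- metadata$dose[match(merged$sample_id, metadata$sample_id)]
    xa <- tapply(merged$frequency_a, merged$dose, mean)
    xb <- tapply(merged$frequency_b, merged$dose, mean)
    return(regress(as.numeric(xa), as.numeric(xb), scope = "per-dose"))
  }
  regress(merged$frequency_a, merged$frequency_b, scope = "per-animal")
}
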