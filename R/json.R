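#' Serialize models and reports to JSON
#'
#' Full-double-precision JSON for the package's model and report objects:
#' linear models as `{terms, intercept, coefficients, stats, fitted_on}`,
#' polynomial models with an additional `quadratic` block, networks as
#' `{spec, weights, scaling}`, and validation reports with their
#' `conventions` block.
#'
#' @param x A `qsar_mlr`, `qsar_mnlr`, `qsar_ann`, `gt_report` or
#'   `crossval_report` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return A JSON string (invisibly the path when writing to file).
#' @export
model_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "qsar_mlr")) {
    list(type = "linear", terms = x$terms, intercept = x$intercept,
         coefficients = as.list(x$coefficients), stats = x$stats,
         fitted_on = x$fitted_on)
  } else if (inherits(x, "qsar_mnlr")) {
    list(type = "polynomial", terms = x$base_terms, intercept = x$intercept,
         coefficients = as.list(x$linear_coefficients),
         quadratic = as.list(x$quadratic_coefficients),
         stats = x$stats, condition_number = x$condition_number,
         fitted_on = x$fitted_on)
  } else if (inherits(x, "qsar_ann")) {
    list(type = "feedforward", spec = unclass(x$spec), terms = x$terms,
         weights = if (identical(x$backend, "nnet")) x$fit$wts
                   else c(t(x$w_hidden), x$w_output),
         scaling = x$scaling, stats = x$stats, fitted_on = x$fitted_on)
  } else if (inherits(x, c("gt_report", "crossval_report"))) {
    unclass(x)
  } else {
    stop("no JSON serialization for class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    invisible(path)
  }
}
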