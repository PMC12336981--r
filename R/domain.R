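#' Warning leverage threshold
#'
#' The conventional cut-off `h* = 3 (p + 1) / n` for hat-matrix leverage,
#' with `p` descriptors and `n` reference compounds. For the study model
#' (p = 6 descriptors, n = 31 modeling compounds) `h* = 21/31 = 0.677`.
#'
#' @param p Number of descriptors.
#' @param n Number of compounds defining the reference design.
#' @return The warning leverage.
#' @examples
#' warning_leverage(6, 31) # 0.677
#' @export
warning_leverage <- function(p, n) {
  stopifnot(p >= 0)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  3 * (p + 1) / n
}

#' Hat-matrix leverages and applicability domain
#'
#' Computes `h_i = x_i (X'X)^{-1} x_i'` with `X` the intercept-augmented
#' descriptor matrix of the reference (training) records; query records are
#' evaluated against the same `X'X`, so their leverages may exceed 1. A
#' compound is flagged in-domain when its leverage is below the warning
#' leverage `h* = 3(p+1)/n_reference`.
#'
#' The intercept column is included because both the trace identity
#' (sum of reference leverages = p + 1) and the study's printed h*
#' (which counts p + 1 parameters) presuppose it.
#'
#' @param training_records Reference compound records; the design must be
#'   full rank.
#' @param query_records Optional further records (test compounds,
#'   candidates) to evaluate against the reference design.
#' @param terms Descriptor labels. Default [qsar_terms()].
#' @return An object of class `leverage_report`: a data frame `compounds`
#'   with `compound_id`, `leverage`, `set` (`"train"`/`"query"`) and
#'   `in_domain`, plus `h_star`, `p` and `n` (reference size).
#' @examples
#' ds <- load_study_dataset()
#' lev <- leverages(ds$modeling)   # study convention: all 31 as reference
#' max(lev$compounds$leverage) < lev$h_star
#' @export
leverages <- function(training_records, query_records = NULL,
                      terms = qsar_terms()) {
  X <- cbind(1, design_matrix(training_records, terms))
  if (qr(X)$rank < ncol(X)) {
    stop("singular reference design: X'X is not invertible", call. = FALSE)
  }
  XtX_inv <- solve(crossprod(X))
  h_train <- rowSums((X %*% XtX_inv) * X)

  out <- data.frame(compound_id = record_ids(training_records),
                    leverage = h_train, set = "train",
                    stringsAsFactors = FALSE)
  if (!is.null(query_records) && nrow(query_records) > 0L) {
    Q <- cbind(1, design_matrix(query_records, terms))
    out <- rbind(out, data.frame(compound_id = record_ids(query_records),
                                 leverage = rowSums((Q %*% XtX_inv) * Q),
                                 set = "query", stringsAsFactors = FALSE))
  }
  h_star <- warning_leverage(length(terms), nrow(training_records))
  out$in_domain <- out$leverage < h_star

  structure(list(compounds = out, h_star = h_star,
                 p = length(terms), n = nrow(training_records)),
            class = "leverage_report")
}

#' Williams-plot data
#'
#' Pairs each compound's leverage with its standardized residual
#' (residual divided by the training RMSE), the conventional axes of a
#' Williams plot, together with the domain boundaries: the warning leverage
#' `h*` on the leverage axis and +/-3 on the residual axis. A compound is
#' in-domain when its leverage is below `h*` and its standardized residual
#' within +/-3.
#'
#' @param report A [leverages()] report.
#' @param residuals Named numeric vector of raw residuals
#'   (observed - predicted), names matching the report's compound ids.
#'   Compounds without residuals are dropped from the plot data.
#' @param residual_scale Positive scale for standardization, normally the
#'   RMSE of the training fit.
#' @return An object of class `williams_data`: data frame `points`
#'   (`compound_id`, `leverage`, `std_residual`, `set`, `in_domain`) and
#'   `boundaries` (`h_star`, `residual_limit = 3`).
#' @export
williams_data <- function(report, residuals, residual_scale) {
  stopifnot(inherits(report, "leverage_report"))
  if (!is.numeric(residual_scale) || residual_scale <= 0) {
    stop("residual_scale must be positive", call. = FALSE)
  }
  if (is.null(names(residuals))) {
    stop("residuals must be named by compound id", call. = FALSE)
  }
  pts <- report$compounds[report$compounds$compound_id %in% names(residuals), ]
  if (nrow(pts) == 0L) stop("no residuals match report compounds", call. = FALSE)
  pts$std_residual <- as.numeric(residuals[pts$compound_id]) / residual_scale
  pts$in_domain <- pts$leverage < report$h_star & abs(pts$std_residual) <= 3
  pts <- pts[, c("compound_id", "leverage", "std_residual", "set", "in_domain")]

  structure(list(points = pts,
                 boundaries = list(h_star = report$h_star, residual_limit = 3)),
            class = "williams_data")
}

#' Export Williams-plot data as CSV
#'
#' Writes `id,leverage,std_residual,set` rows for external plotting.
#'
#' @param wd A [williams_data()] object.
#' @param path Output file path.
#' @export
write_williams_csv <- function(wd, path) {
  stopifnot(inherits(wd, "williams_data"))
  out <- wd$points[, c("compound_id", "leverage", "std_residual", "set")]
  names(out)[1] <- "id"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.leverage_report <- function(x, ...) {
  cat(sprintf("Leverage report: p=%d, n=%d, h*=%.3f\n", x$p, x$n, x$h_star))
  cat(sprintf("  %d/%d compounds in domain (max leverage %.3f)\n",
              sum(x$compounds$in_domain), nrow(x$compounds),
              max(x$compounds$leverage)))
  invisible(x)
}
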