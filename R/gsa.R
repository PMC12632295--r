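#' Standardised-regression global sensitivity analysis
#'
#' Ordinary least squares of the response (typically the DGFC score) on the
#' sampled model parameters, each predictor scaled to unit sample standard
#' deviation so that coefficient magnitudes are comparable measures of
#' importance. A parameter is flagged significant when its 95% confidence
#' interval excludes zero.
#'
#' @param X data.frame or matrix of sampled parameter values (patients in
#'   rows); fixed (zero-variance) columns are dropped.
#' @param y numeric response vector.
#' @return An object of class `gsa_result`: data.frame with columns
#'   `parameter`, `slope`, `ci_lo`, `ci_hi`, `significant`, ordered by
#'   decreasing `|slope|`, with the fitted model in attribute `fit`.
#' @export
gsa_regression <- function(X, y) {
  X <- as.data.frame(X)
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  sds <- vapply(X, stats::sd, numeric(1))
  X <- X[, sds > 0, drop = FALSE]
  sds <- sds[sds > 0]
  if (nrow(X) <= ncol(X) + 1)
    stop("gsa_regression: need more observations than predictors")
  Z <- as.data.frame(scale(X, center = FALSE, scale = sds))
  fit <- stats::lm(y ~ ., data = cbind(y = y, Z))
  if (fit$rank < ncol(Z) + 1)
    stop("gsa_regression: rank-deficient predictor matrix")
  co <- stats::coef(fit)[-1]
  ci <- stats::confint(fit, level = 0.95)[-1, , drop = FALSE]
  out <- data.frame(parameter = names(co), slope = unname(co),
                    ci_lo = unname(ci[, 1]), ci_hi = unname(ci[, 2]))
  out$significant <- out$ci_lo > 0 | out$ci_hi < 0
  out <- out[order(-abs(out$slope)), ]
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  attr(out, "intercept") <- unname(stats::coef(fit)[1])
  attr(out, "sigma") <- stats::sigma(fit)
  class(out) <- c("gsa_result", "data.frame")
  out
}

#' Partial-regression (added-variable) decomposition
#'
#' For predictor `j`: residuals of `y` regressed on all other predictors,
#' paired with residuals of `X_j` regressed on the same; the slope of the
#' residual-on-residual fit equals the full-model coefficient of `X_j`
#' (Frisch-Waugh-Lovell).
#'
#' @param X data.frame or matrix of predictors.
#' @param y response vector.
#' @param j column name or index of the predictor of interest.
#' @return A list with `residual_y`, `residual_x`, `slope` and the
#'   full-model coefficient `full_coef`.
#' @export
partial_regression <- function(X, y, j) {
  X <- as.data.frame(X)
  if (is.character(j)) j <- match(j, names(X))
  if (is.na(j) || j < 1 || j > ncol(X))
    stop("partial_regression: unknown predictor")
  others <- as.matrix(X[, -j, drop = FALSE])
  xj <- X[[j]]
  ry <- stats::residuals(stats::lm(y ~ others))
  rx <- stats::residuals(stats::lm(xj ~ others))
  slope <- unname(stats::coef(stats::lm(ry ~ rx))[2])
  full <- unname(stats::coef(stats::lm(y ~ ., data = X))[j + 1])
  list(residual_y = unname(ry), residual_x = unname(rx),
       slope = slope, full_coef = full)
}

#' Split patients into good and poor responders
#'
#' Good responders score DGFC above the upper threshold, poor responders
#' below the lower one; patients in between are excluded. Reports group
#' means of the self-renewal sensitivity `psi` and proliferation rate `ms`
#' and independent two-sample t-tests for each.
#'
#' @param patients data.frame containing at least `psi` and `ms` columns.
#' @param dgfc_scores numeric DGFC vector aligned with `patients`.
#' @param good_above,poor_below DGFC thresholds.
#' @return A list with `good` and `poor` row indices, per-group `means`
#'   (`psi`, `ms`), and `tests` (t-test p-values), or with `skipped = TRUE`
#'   and a warning when a group is empty.
#' @export
responder_split <- function(patients, dgfc_scores, good_above = 1.2,
                            poor_below = 1.1) {
  stopifnot(nrow(patients) == length(dgfc_scores))
  good <- which(!is.na(dgfc_scores) & dgfc_scores > good_above)
  poor <- which(!is.na(dgfc_scores) & dgfc_scores < poor_below)
  if (!length(good) || !length(poor)) {
    warning("responder_split: empty responder group; comparison skipped")
    return(list(good = good, poor = poor, skipped = TRUE))
  }
  means <- data.frame(
    group = c("good", "poor"),
    psi = c(mean(patients$psi[good]), mean(patients$psi[poor])),
    ms = c(mean(patients$ms[good]), mean(patients$ms[poor]))
  )
  tests <- c(
    psi = if (length(good) > 1 && length(poor) > 1)
      stats::t.test(patients$psi[good], patients$psi[poor])$p.value
      else NA_real_,
    ms = if (length(good) > 1 && length(poor) > 1)
      stats::t.test(patients$ms[good], patients$ms[poor])$p.value
      else NA_real_
  )
  list(good = good, poor = poor, means = means, tests = tests,
       skipped = FALSE)
}

#' Write a GSA coefficient table to CSV
#'
#' @param gsa a [gsa_regression()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gsa_csv <- function(gsa, path) {
  utils::write.csv(as.data.frame(gsa), path, row.names = FALSE)
  invisible(path)
}
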