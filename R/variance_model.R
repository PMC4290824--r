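#' Per-sgRNA sample moments within a condition
#'
#' Computes the sample mean \eqn{\hat\mu} and unbiased sample variance
#' \eqn{\hat\sigma^2} of each sgRNA's normalized counts across the
#' replicates of one condition.  These moment pairs feed the
#' mean-variance regression of [fit_mean_variance()].
#'
#' @param table A normalized [count_table].
#' @param samples Character vector of sample names (>= 2) to treat as
#'   replicates.
#' @return A data frame with columns `sgrna`, `mean`, `var`.
#' @export
sample_moments <- function(table, samples) {
  missing <- setdiff(samples, table$sample_names)
  if (length(missing))
    stop("moments: sample(s) not in table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(samples) < 2)
    stop("moments: variance needs at least 2 replicates; with a single ",
         "sample, pool both conditions before fitting the model",
         call. = FALSE)
  x <- table$counts[, samples, drop = FALSE]
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (length(samples) - 1)
  data.frame(sgrna = table$sgrna_ids, mean = m, var = v,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the empirical mean-variance model
#'
#' Screens (like RNA-seq libraries) are overdispersed: the replicate
#' variance of a count exceeds its mean.  The model pools information
#' across sgRNAs by assuming the variance is a smooth function of the
#' mean,
#' \deqn{\sigma^2 = \mu + k\,\mu^b, \qquad k \ge 0,\; b \ge 0,}
#' and estimates \eqn{(k, b)} by ordinary least squares of
#' \eqn{\log(\hat\sigma^2 - \hat\mu)} on \eqn{\log\hat\mu}.  Moment pairs
#' with \eqn{\hat\mu = 0} or \eqn{\hat\sigma^2 \le \hat\mu} have no
#' defined log and are excluded; their number is recorded.
#'
#' @param moments Data frame from [sample_moments()].
#' @return An object of class `mean_var_model`: list with `k`, `b`,
#'   `n_points` (sgRNAs used in the regression), `n_dropped`, and `r2`
#'   (coefficient of determination in log space).
#' @export
fit_mean_variance <- function(moments) {
  use <- moments$mean > 0 & moments$var > moments$mean
  if (sum(use) < 2)
    stop("mean-variance fit: fewer than 2 sgRNAs with variance exceeding ",
         "mean; no overdispersion to model - fall back to a Poisson model ",
         "(k = 0)", call. = FALSE)
  x <- log(moments$mean[use])
  y <- log(moments$var[use] - moments$mean[use])
  fit <- stats::lm.fit(cbind(1, x), y)
  k <- exp(fit$coefficients[[1]])
  b <- fit$coefficients[[2]]
  if (b < 0) {
    warning("mean-variance fit: negative exponent b = ",
            signif(b, 3), " clamped to 0", call. = FALSE)
    b <- 0
  }
  r2 <- if (stats::var(y) > 0) 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
        else NA_real_
  structure(list(k = k, b = b, n_points = sum(use),
                 n_dropped = sum(!use), r2 = r2),
            class = "mean_var_model")
}

#' A Poisson (no-overdispersion) mean-variance model
#'
#' Convenience constructor for the `k = 0` limit of the mean-variance
#' law, used as a fallback when the regression has no usable points.
#'
#' @return A `mean_var_model` with `k = 0`, `b = 0`.
#' @export
poisson_model <- function() {
  structure(list(k = 0, b = 0, n_points = 0L, n_dropped = NA_integer_,
                 r2 = NA_real_),
            class = "mean_var_model")
}

#' @export
print.mean_var_model <- function(x, ...) {
  cat(sprintf("mean-variance model: sigma^2 = mu + %.4g * mu^%.4g\n",
              x$k, x$b))
  cat(sprintf("  fitted on %d sgRNAs (%s dropped), log-space R^2 = %s\n",
              x$n_points, format(x$n_dropped), format(signif(x$r2, 3))))
  invisible(x)
}

#' Predict the variance of a count from its mean
#'
#' Evaluates the fitted law \eqn{\sigma^2 = \mu + k \mu^b}.  For `k = 0`
#' this is the Poisson limit \eqn{\sigma^2 = \mu}.
#'
#' @param model A `mean_var_model`.
#' @param mean Non-negative mean count(s).
#' @return Predicted variance(s), same length as `mean`.
#' @export
predict_variance <- function(model, mean) {
  if (any(mean < 0))
    stop("predict_variance: negative mean", call. = FALSE)
  mean + model$k * mean^model$b
}

#' Method-of-moments negative binomial parameters
#'
#' Converts a (mean, variance) pair with \eqn{\sigma^2 > \mu} into the
#' NB(r, p) parameterization
#' \deqn{p = 1 - \mu/\sigma^2, \qquad r = \mu^2 / (\sigma^2 - \mu),}
#' where `r` may be non-integral (gamma-extended NB).  Under this
#' convention the NB mean is \eqn{r p / (1 - p)} and equals \eqn{\mu};
#' in terms of [stats::pnbinom()], `size = r` and `prob = 1 - p`.
#'
#' @param mean Mean \eqn{\mu > 0} (vectorized).
#' @param var Variance \eqn{\sigma^2 > \mu} (vectorized).
#' @return A data frame with columns `r`, `p`, `mean`, `var`.
#' @export
nb_params <- function(mean, var) {
  if (any(mean <= 0))
    stop("nb_params: mean must be positive", call. = FALSE)
  if (any(var <= mean))
    stop("nb_params: variance must exceed mean (overdispersion); ",
         "inflate the variance before converting", call. = FALSE)
  data.frame(r = mean^2 / (var - mean), p = 1 - mean / var,
             mean = mean, var = var)
}
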