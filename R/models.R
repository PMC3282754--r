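## Locally weighted degree-1 (plane) regression predictions.
## For each query point, the span*N nearest training pixels (at least 3)
## receive tri-cube distance weights and a weighted least-squares plane in
## (x, y) is evaluated at the query. Returns a length(query) x length(spans)
## matrix of predictions; all spans share one neighbour ordering per query.
predict_local <- function(train_xy, train_y, query_xy, spans) {
  ntr <- nrow(train_xy)
  nq <- nrow(query_xy)
  qs <- pmin(pmax(3L, ceiling(spans * ntr)), ntr)
  out <- matrix(NA_real_, nq, length(spans))
  for (m in seq_len(nq)) {
    dx <- train_xy[, 1] - query_xy[m, 1]
    dy <- train_xy[, 2] - query_xy[m, 2]
    d <- sqrt(dx * dx + dy * dy)
    o <- order(d)
    for (si in seq_along(spans)) {
      idx <- o[seq_len(qs[si])]
      dmax <- d[idx[qs[si]]]
      w <- if (dmax > 0) (1 - pmin(d[idx] / dmax, 1)^3)^3 else rep(1, length(idx))
      X <- cbind(1, train_xy[idx, 1], train_xy[idx, 2])
      fit <- tryCatch(stats::lm.wfit(X, train_y[idx], w),
                      error = function(e) NULL)
      pred <- if (!is.null(fit) && !anyNA(fit$coefficients)) {
        sum(fit$coefficients * c(1, query_xy[m, 1], query_xy[m, 2]))
      } else {                       # collinear neighbourhood: weighted mean
        sum(w * train_y[idx]) / sum(w)
      }
      out[m, si] <- pred
    }
  }
  out
}

## Valid-pixel coordinates (pixel centres) and rates of a map.
map_pixels <- function(map) {
  v <- which(map$valid)
  n <- map$geometry$n
  i <- ((v - 1) %% n) + 1
  j <- ((v - 1) %/% n) + 1
  list(xy = cbind(map$geometry$centers[i], map$geometry$centers[j]),
       y = map$rate[v], idx = v)
}

#' Percent of variance explained by predictions
#'
#' `100 * (1 - var(residuals) / var(observed))`: the share of pixel-to-pixel
#' firing-rate variance captured by a regression fit. Invariant to adding a
#' constant to, or rescaling, the rates.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return PVE in percent (at most 100; can be negative for fits worse than
#'   the mean).
#' @export
percent_variance_explained <- function(observed, predicted) {
  resid <- observed - predicted
  100 * (1 - stats::var(resid) / stats::var(observed))
}

#' Locally weighted spatial regression of firing rate on position
#'
#' Fits, for every valid pixel, a weighted least-squares plane in (x, y)
#' over its `span * N` nearest valid pixels with tri-cube distance weights,
#' and evaluates it at that pixel. The span is the smoothing parameter: the
#' fraction of pixels in each local neighbourhood. Reports the SD of
#' residuals, the SD of the observed rates, and the percent of firing-rate
#' variance explained.
#'
#' @param map A [rate_map()].
#' @param span Neighbourhood fraction in `(0, 1]`.
#' @return An object of class `spatial_regression` with `span`, `fitted`,
#'   `residuals`, `pixels` (linear indices), `sigma_resid`, `sigma_total`,
#'   `pve`.
#' @export
fit_spatial_regression <- function(map, span) {
  if (!is.finite(span) || span <= 0 || span > 1) {
    pf_error("pf_error_invalid", "span must be in (0, 1]")
  }
  px <- map_pixels(map)
  if (length(px$y) < 3) pf_error("pf_error_empty", "need at least 3 valid pixels")
  pred <- predict_local(px$xy, px$y, px$xy, span)[, 1]
  resid <- px$y - pred
  structure(list(span = span, fitted = pred, residuals = resid,
                 pixels = px$idx,
                 sigma_resid = stats::sd(resid),
                 sigma_total = stats::sd(px$y),
                 pve = percent_variance_explained(px$y, pred)),
            class = "spatial_regression")
}

#' @export
print.spatial_regression <- function(x, ...) {
  cat(sprintf("<spatial_regression> span %.2f, pve %.1f%% (sd resid %.3f / total %.3f Hz)\n",
              x$span, x$pve, x$sigma_resid, x$sigma_total))
  invisible(x)
}

#' Select the smoothing span by 10-fold cross-validation
#'
#' Valid pixels are randomly partitioned into `k` folds; for every
#' candidate span each fold is predicted from a local fit on the remaining
#' folds, and the span minimising the mean held-out squared error is
#' returned (ties to the smaller span).
#'
#' @param map A [rate_map()].
#' @param span_grid Candidate spans (default
#'   `c(0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1)`).
#' @param k Number of folds (default 10).
#' @param seed Optional RNG seed for the fold assignment.
#' @return List with `span` (the selected value) and `cv_error` (named mean
#'   squared errors per span).
#' @export
select_span_cv <- function(map, span_grid = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1),
                           k = 10, seed = NULL) {
  if (!length(span_grid)) pf_error("pf_error_invalid", "span_grid is empty")
  span_grid <- sort(span_grid)
  px <- map_pixels(map)
  N <- length(px$y)
  if (N < k) pf_error("pf_error_invalid", "fewer valid pixels than folds")
  folds <- with_seed(seed, sample(rep_len(seq_len(k), N)))
  sse <- numeric(length(span_grid))
  for (f in seq_len(k)) {
    test <- folds == f
    pred <- predict_local(px$xy[!test, , drop = FALSE], px$y[!test],
                          px$xy[test, , drop = FALSE], span_grid)
    sse <- sse + colSums((px$y[test] - pred)^2)
  }
  cv <- sse / N
  list(span = span_grid[which.min(cv)],
       cv_error = stats::setNames(cv, span_grid))
}

#' Logistic regression of remapping by IRLS
#'
#' Fits `logit P(remap) = a0 + a1*isi_peak + a2*group + a3*session2 +
#' a4*session3` by maximum likelihood using iteratively reweighted least
#' squares with step-halving (so the deviance never increases), declaring
#' convergence when the largest coefficient change falls below `tol`. The
#' reduced model (e.g. group and session only) is obtained by passing a
#' subset of `terms`. Perfect separation is flagged as non-convergence.
#'
#' @param data Data frame with a 0/1 column `remap` and the predictor
#'   columns named in `terms`.
#' @param terms Predictor columns to include (default all four).
#' @param max_iter,tol IRLS controls.
#' @return An object of class `remap_logistic` with `coefficients`, `se`,
#'   `z`, `p`, `deviance`, `deviance_trace`, `converged`, `fitted`, `n`.
#' @export
fit_remap_logistic <- function(data,
                               terms = c("isi_peak", "group", "session2", "session3"),
                               max_iter = 100, tol = 1e-8) {
  y <- as.numeric(data$remap)
  if (anyNA(y) || !all(y %in% c(0, 1))) pf_error("pf_error_invalid", "remap must be 0/1")
  if (length(unique(y)) < 2) {
    pf_error("pf_error_single_class", "all outcomes identical: need both classes")
  }
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms)) {
    pf_error("pf_error_missing_column",
             paste("missing predictor columns:", paste(missing_terms, collapse = ", ")))
  }
  X <- cbind("(Intercept)" = 1, as.matrix(data[terms]))
  p <- ncol(X)
  dev_fn <- function(beta) {
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  beta <- rep(0, p)
  dev <- dev_fn(beta)
  trace <- dev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_prop <- tryCatch(solve(XtW %*% X, XtW %*% z),
                          error = function(e) NULL)
    if (is.null(beta_prop)) break
    step <- drop(beta_prop) - beta
    tfac <- 1
    repeat {
      cand <- beta + tfac * step
      dc <- dev_fn(cand)
      if (dc <= dev + 1e-10 || tfac < 1e-4) break
      tfac <- tfac / 2
    }
    if (dc > dev + 1e-10) break       # cannot decrease deviance further
    delta <- max(abs(cand - beta))
    beta <- cand
    dev <- dc
    trace <- c(trace, dev)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  vcov <- tryCatch(solve(t(X * w) %*% X), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  diagnostic <- NULL
  if (!converged) {
    diagnostic <- if (max(abs(eta)) > 25)
      "possible complete separation: fitted probabilities pinned at 0/1" else
      "IRLS did not converge"
    warning(diagnostic, call. = FALSE)
  }
  coefs <- stats::setNames(beta, colnames(X))
  structure(list(coefficients = coefs, se = stats::setNames(se, colnames(X)),
                 z = coefs / se, p = 2 * stats::pnorm(-abs(coefs / se)),
                 deviance = dev, deviance_trace = trace,
                 converged = converged, diagnostic = diagnostic,
                 fitted = mu, n = length(y), terms = terms),
            class = "remap_logistic")
}

#' @export
print.remap_logistic <- function(x, ...) {
  cat(sprintf("<remap_logistic> n = %d, deviance = %.2f, converged = %s\n",
              x$n, x$deviance, x$converged))
  print(round(cbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p), 4))
  invisible(x)
}
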