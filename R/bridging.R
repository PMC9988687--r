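#' Fit per-feature bridge regressions between platforms
#'
#' For every source-platform feature j, fits the ordinary least squares
#' regression `X_src[, j] ~ X_tgt` over paired samples: each microarray
#' log2 intensity is expressed in terms of all included target-platform
#' delta-Ct values. All J regressions share the identical target design, so
#' the fits are computed from one QR decomposition. Unregularized OLS is
#' used deliberately — it is the estimator whose coefficients are
#' substituted into the classifier — and a rank-deficient design is an
#' error naming the collinear features rather than a silent fallback.
#'
#' Samples with any missing value among the used columns are dropped with a
#' warning before fitting.
#'
#' @param x_src Numeric matrix, samples x J source features (column names
#'   required).
#' @param x_tgt Numeric matrix over the same samples, samples x K target
#'   features (column names required), `K >= 1`.
#' @param min_samples Minimum complete samples required; default `K + 2`
#'   (one residual degree of freedom). `K + 1` gives a saturated but
#'   identifiable fit, used by the leave-one-out inner folds.
#' @return An object of class `BridgeRegressionSet`: list with
#'   `coefficients` ((K+1) x J matrix, intercept row first), `se`
#'   (matching standard errors; `NA` when saturated), `r_squared` (J),
#'   `sigma` (J residual SDs), `features` (target ids), `source_features`,
#'   `n_used`, `df_residual`, `dropped_samples`.
#' @export
fit_bridge <- function(x_src, x_tgt, min_samples = ncol(x_tgt) + 2) {
  x_src <- as.matrix(x_src); x_tgt <- as.matrix(x_tgt)
  if (is.null(colnames(x_src)) || is.null(colnames(x_tgt)))
    stop("`x_src` and `x_tgt` must have feature (column) names")
  if (nrow(x_src) != nrow(x_tgt))
    stop("`x_src` and `x_tgt` must cover the same samples")
  K <- ncol(x_tgt)
  complete <- stats::complete.cases(x_src) & stats::complete.cases(x_tgt)
  dropped <- rownames(x_src)[!complete]
  if (length(dropped))
    warning("dropping ", length(dropped), " sample(s) with missing values: ",
            paste(dropped, collapse = ", "))
  x_src <- x_src[complete, , drop = FALSE]
  x_tgt <- x_tgt[complete, , drop = FALSE]
  n <- nrow(x_tgt)
  if (n < max(min_samples, K + 1))
    stop("too few complete samples (", n, ") for ", K,
         " target features; need >= ", max(min_samples, K + 1))
  X <- cbind(`(Intercept)` = 1, x_tgt)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq.int(qr_x$rank + 1, ncol(X))]]
    stop("rank-deficient bridge design; collinear feature(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, x_src)                      # (K+1) x J
  fitted <- X %*% beta
  resid <- x_src - fitted
  rss <- colSums(resid^2)
  tss <- colSums(sweep(x_src, 2, colMeans(x_src))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, ifelse(rss <= 1e-24, 1, NA_real_))
  df_res <- n - ncol(X)
  xtx_inv_diag <- diag(chol2inv(chol(crossprod(X))))
  if (df_res > 0) {
    sigma <- sqrt(rss / df_res)
    se <- sqrt(outer(xtx_inv_diag, sigma^2))
    dimnames(se) <- dimnames(beta)
  } else {
    sigma <- rep(NA_real_, ncol(x_src))
    se <- beta * NA_real_
  }
  structure(list(coefficients = beta, se = se,
                 r_squared = stats::setNames(pmin(pmax(r2, 0), 1), colnames(x_src)),
                 sigma = stats::setNames(sigma, colnames(x_src)),
                 features = colnames(x_tgt),
                 source_features = colnames(x_src),
                 n_used = n, df_residual = df_res,
                 dropped_samples = dropped),
            class = "BridgeRegressionSet")
}

#' @export
print.BridgeRegressionSet <- function(x, ...) {
  cat("BridgeRegressionSet:", length(x$source_features), "source features on",
      length(x$features), "target features;", x$n_used, "samples\n")
  cat("R^2 range:", paste(round(range(x$r_squared), 3), collapse = " - "), "\n")
  invisible(x)
}

#' Confidence intervals for bridge regression coefficients
#'
#' @param br A [fit_bridge()] result with positive residual df.
#' @param level Confidence level; default 0.95.
#' @return List with matrices `lower` and `upper`, each (K+1) x J.
#' @export
bridge_confint <- function(br, level = 0.95) {
  stopifnot(inherits(br, "BridgeRegressionSet"))
  if (br$df_residual <= 0) stop("saturated fit: no residual df for intervals")
  tq <- qt(1 - (1 - level) / 2, br$df_residual)
  list(lower = br$coefficients - tq * br$se,
       upper = br$coefficients + tq * br$se)
}

#' Reweight a classifier onto the target platform
#'
#' Substitutes the bridge regressions into the original model: writing the
#' original classifier as `w0 + sum_j w_j * x_j` over source features and
#' each source feature as `b0_j + sum_k b_jk * t_k` over target features,
#' the bridged classifier on target features is
#' `(w0 + sum_j w_j b0_j) + sum_k (sum_j w_j b_jk) * t_k`.
#' The substitution is linear in the original weights.
#'
#' @param original A `LinearClassifier` over source features (any
#'   representation; its weighted features must all have a bridge
#'   regression).
#' @param br A [fit_bridge()] result whose source features cover
#'   `original`'s weighted features.
#' @return A `LinearClassifier` in the `"raw-dct"` representation over the
#'   bridge's target features.
#' @export
reweight <- function(original, br) {
  stopifnot(inherits(original, "LinearClassifier"),
            inherits(br, "BridgeRegressionSet"))
  w <- original$weights
  missing <- setdiff(names(w), br$source_features)
  if (length(missing))
    stop("no bridge regression for weighted source feature(s): ",
         paste(missing, collapse = ", "))
  B <- br$coefficients[, names(w), drop = FALSE]
  new_intercept <- original$intercept + sum(w * B["(Intercept)", ])
  new_w <- drop(B[br$features, , drop = FALSE] %*% w)
  linear_classifier(new_intercept, stats::setNames(new_w, br$features), "raw-dct")
}

#' Convert a normalized delta-Ct classifier to the raw representation
#'
#' With per-feature normalization `z_k = (x_k - mu_k) / sigma_k`, the model
#' `c + sum_k w_k z_k` equals `(c - sum_k w_k mu_k / sigma_k) +
#' sum_k (w_k / sigma_k) x_k` on raw values.
#'
#' @param model A `LinearClassifier` with representation `"normalized-dct"`.
#' @return The equivalent `"raw-dct"` `LinearClassifier`.
#' @export
to_raw <- function(model) {
  stopifnot(inherits(model, "LinearClassifier"))
  if (model$representation != "normalized-dct")
    stop("`to_raw` expects a normalized-dct model")
  w <- model$weights
  mu <- model$norm$mean[names(w)]
  sigma <- model$norm$sd[names(w)]
  linear_classifier(model$intercept - sum(w * mu / sigma), w / sigma, "raw-dct")
}

#' Convert a raw delta-Ct classifier to the normalized representation
#'
#' Exact inverse of [to_raw()] for the supplied normalization parameters.
#'
#' @param model A `LinearClassifier` with representation `"raw-dct"`.
#' @param norm List with named numeric vectors `mean` and `sd` covering the
#'   weighted features, `sd > 0`.
#' @return The equivalent `"normalized-dct"` `LinearClassifier`.
#' @export
to_normalized <- function(model, norm) {
  stopifnot(inherits(model, "LinearClassifier"))
  if (model$representation != "raw-dct")
    stop("`to_normalized` expects a raw-dct model")
  w <- model$weights
  mu <- norm$mean[names(w)]
  sigma <- norm$sd[names(w)]
  if (any(is.na(mu)) || any(is.na(sigma)))
    stop("`norm` must cover all weighted features")
  linear_classifier(model$intercept + sum(w * mu), w * sigma,
                    "normalized-dct",
                    norm = list(mean = mu, sd = sigma))
}

#' Mean/SD-normalize a feature table
#'
#' @param x Samples x features numeric matrix.
#' @param norm List with named `mean` and `sd` vectors.
#' @return Matrix of z-scored features (columns restricted to `norm`'s).
#' @export
apply_norm <- function(x, norm) {
  feats <- names(norm$mean)
  missing <- setdiff(feats, colnames(x))
  if (length(missing))
    stop("features absent from table: ", paste(missing, collapse = ", "))
  sweep(sweep(x[, feats, drop = FALSE], 2, norm$mean), 2, norm$sd, `/`)
}

#' Score samples with a linear classifier
#'
#' `score_s = intercept + sum_k w_k x_sk`. The feature table must be on the
#' scale of the model's representation (log2 intensities, raw delta-Ct, or
#' z-scored delta-Ct). Higher scores indicate the positive (Kawasaki
#' disease) class.
#'
#' @param model A `LinearClassifier`.
#' @param features Samples x features numeric matrix containing all
#'   weighted features; missing values among weighted features are an
#'   error naming the offending samples and features.
#' @return Named numeric vector of per-sample scores with attribute
#'   `representation`.
#' @export
score <- function(model, features) {
  stopifnot(inherits(model, "LinearClassifier"))
  features <- as.matrix(features)
  w <- model$weights
  absent <- setdiff(names(w), colnames(features))
  if (length(absent))
    stop("weighted feature(s) absent from table: ",
         paste(absent, collapse = ", "))
  X <- features[, names(w), drop = FALSE]
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop("missing weighted feature value(s): ",
         paste(sprintf("sample '%s' feature '%s'",
                       rownames(X)[bad[, 1]], colnames(X)[bad[, 2]]),
               collapse = "; "))
  }
  s <- drop(X %*% w) + model$intercept
  structure(stats::setNames(s, rownames(features)),
            representation = model$representation)
}
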