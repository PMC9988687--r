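test_that("self-regression recovers the identity map with R^2 = 1", {
  set.seed(1)
  X <- matrix(rnorm(60, 9), 20, 3,
              dimnames = list(NULL, c("g1", "g2", "g3")))
  br <- fit_bridge(X, X)
  expect_equal(unname(br$coefficients["(Intercept)", ]), rep(0, 3),
               tolerance = 1e-10)
  expect_equal(unname(br$coefficients[-1, ]), diag(3), tolerance = 1e-10)
  expect_equal(unname(br$r_squared), rep(1, 3))
})

test_that("noiseless affine targets are inverted exactly", {
  toy <- make_affine_pair(n = 25, J = 4, seed = 2)
  br <- fit_bridge(toy$x_src, toy$x_tgt)
  expect_equal(unname(br$r_squared), rep(1, 4), tolerance = 1e-12)
  slopes <- diag(br$coefficients[-1, ])
  expect_equal(unname(slopes), unname(1 / toy$b), tolerance = 1e-8)
  off <- br$coefficients[-1, ]; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-8)
})

test_that("bridge coefficient intervals cover generative values", {
  # one source feature regressed on 6 targets; 40 replicates here, the
  # full 200-replicate calibration runs in the acceptance suite
  hits <- 0; total <- 0
  for (r in 1:40) {
    set.seed(1000 + r)
    n <- 60; K <- 6
    X <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, paste0("t", 1:K)))
    beta <- runif(K, -1, 1); b0 <- 0.5
    y <- matrix(b0 + X %*% beta + rnorm(n, sd = 0.7),
                dimnames = list(NULL, "src"))
    br <- fit_bridge(y, X)
    ci <- bridge_confint(br)
    inside <- ci$lower[-1, 1] <= beta & beta <= ci$upper[-1, 1]
    hits <- hits + sum(inside); total <- total + K
  }
  expect_gt(hits / total, 0.88)
})

test_that("rank-deficient designs fail loudly, small n fails", {
  set.seed(3)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  Xd <- cbind(X, d = X[, "a"] * 2)
  y <- matrix(rnorm(10), dimnames = list(NULL, "s"))
  expect_error(fit_bridge(y, Xd), "collinear")
  expect_error(fit_bridge(y[1:4, , drop = FALSE], X[1:4, ]), "too few")
  # samples with missing target features are dropped with a warning
  Xm <- X; Xm[2, "b"] <- NA
  rownames(Xm) <- rownames(y) <- sprintf("s%02d", 1:10)
  expect_warning(br <- fit_bridge(y, Xm), "s02")
  expect_equal(br$n_used, 9)
})

test_that("reweighting substitutes regressions into the original model", {
  J <- 4
  ids <- paste0("g", 1:J)
  # identity regressions leave the model unchanged
  br <- structure(list(
    coefficients = rbind(`(Intercept)` = rep(0, J),
                         matrix(diag(J), J, J, dimnames = list(ids, ids))),
    features = ids, source_features = ids, n_used = 10, df_residual = 5),
    class = "BridgeRegressionSet")
  colnames(br$coefficients) <- ids
  orig <- linear_classifier(1.5, setNames(c(1, -2, 0.5, 0), ids),
                            "microarray-log2")
  rw <- reweight(orig, br)
  expect_equal(rw$intercept, orig$intercept)
  expect_equal(rw$weights, orig$weights, ignore_attr = TRUE)
  expect_equal(rw$representation, "raw-dct")
  # a weighted source feature without a regression is an error
  orig2 <- linear_classifier(0, c(setNames(1, "g1"), missing_gene = 2),
                             "microarray-log2")
  expect_error(reweight(orig2, br), "missing_gene")
})

test_that("bridged scores equal original scores under the noiseless oracle", {
  toy <- make_affine_pair(n = 30, J = 5, seed = 4)
  br <- fit_bridge(toy$x_src, toy$x_tgt)
  bridged <- reweight(toy$model, br)
  expect_equal(as.numeric(score(bridged, toy$x_tgt)),
               as.numeric(score(toy$model, toy$x_src)), tolerance = 1e-9)
})

test_that("reweighting is linear in the original weights", {
  toy <- make_affine_pair(n = 30, J = 5, seed = 5)
  set.seed(6)
  noisy_tgt <- toy$x_tgt + matrix(rnorm(length(toy$x_tgt), sd = 0.3),
                                  nrow(toy$x_tgt))
  br <- fit_bridge(toy$x_src, noisy_tgt)
  ids <- colnames(toy$x_src)
  w1 <- setNames(runif(5, -1, 1), ids); w2 <- setNames(runif(5, -1, 1), ids)
  m1 <- linear_classifier(1, w1, "microarray-log2")
  m2 <- linear_classifier(2, w2, "microarray-log2")
  m12 <- linear_classifier(3, w1 + w2, "microarray-log2")
  r1 <- reweight(m1, br); r2 <- reweight(m2, br); r12 <- reweight(m12, br)
  expect_equal(r12$weights, r1$weights + r2$weights, tolerance = 1e-10)
  expect_equal(r12$intercept, r1$intercept + r2$intercept, tolerance = 1e-10)
})

test_that("normalized-to-raw conversion reproduces the published model", {
  B <- kids_gep_model("normalized")
  C <- kids_gep_model("raw")
  raw <- to_raw(B)
  expect_equal(round(raw$weights[names(C$weights)], 3), C$weights)
  # the published raw intercept was computed from full-precision inputs;
  # from the 3-dp printed inputs it reproduces within rounding propagation
  expect_lt(abs(raw$intercept - C$intercept), 0.002)
  expect_equal(raw$representation, "raw-dct")
})

test_that("representation conversions invert each other", {
  B <- kids_gep_model("normalized")
  back <- to_normalized(to_raw(B), B$norm)
  expect_equal(back$intercept, B$intercept, tolerance = 1e-10)
  expect_equal(back$weights, B$weights, tolerance = 1e-10)
  # published raw model converted with the published mean/SD recovers the
  # normalized weights at printed precision
  C <- kids_gep_model("raw")
  normed <- to_normalized(C, kids_gep_model("normalized")$norm)
  # the printed raw weights carry their own 3-dp rounding, so recovery of
  # the normalized weights is exact only to within that propagated error
  expect_lt(max(abs(normed$weights - B$weights[names(normed$weights)])), 1.5e-3)
  expect_lt(abs(normed$intercept - B$intercept), 0.005)
  # identity when mu = 0, sigma = 1
  m <- linear_classifier(2, c(g = 3), "normalized-dct",
                         norm = list(mean = c(g = 0), sd = c(g = 1)))
  expect_equal(to_raw(m)$weights, m$weights)
  expect_equal(to_raw(m)$intercept, m$intercept)
  # one-feature model, hand-computed: w/sigma = 4, c - w*mu/sigma = -11
  m1 <- linear_classifier(1, c(g = 2), "normalized-dct",
                          norm = list(mean = c(g = 3), sd = c(g = 0.5)))
  expect_equal(unname(to_raw(m1)$weights), 4)
  expect_equal(to_raw(m1)$intercept, -11)
})

test_that("scoring matches the linear form and both representations agree", {
  m <- linear_classifier(1, c(x = 2), "raw-dct")
  expect_equal(as.numeric(score(m, matrix(3, 1, 1, dimnames = list("s", "x")))), 7)
  zeroes <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "x"))
  expect_equal(as.numeric(score(m, zeroes)), c(1, 1))     # intercept only
  set.seed(7)
  for (i in 1:10) {
    K <- sample(2:6, 1)
    ids <- paste0("f", 1:K)
    norm <- list(mean = setNames(rnorm(K), ids),
                 sd = setNames(runif(K, 0.3, 3), ids))
    mn <- linear_classifier(rnorm(1), setNames(rnorm(K), ids),
                            "normalized-dct", norm = norm)
    X <- matrix(rnorm(8 * K, sd = 3), 8, K, dimnames = list(NULL, ids))
    expect_equal(as.numeric(score(mn, apply_norm(X, norm))),
                 as.numeric(score(to_raw(mn), X)), tolerance = 1e-9)
  }
  expect_error(score(m, matrix(1, 1, 1, dimnames = list("s", "y"))), "absent")
  Xna <- matrix(NA_real_, 1, 1, dimnames = list("s", "x"))
  expect_error(score(m, Xna), "s.*x")
})
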