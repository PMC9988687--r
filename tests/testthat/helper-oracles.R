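# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (loops, enumeration, brute-force pair counting) and do
# not share code paths with the package.

# Brute-force pair-counting AUC: P(score_pos > score_neg) + 0.5 P(tie)
pair_auc <- function(scores, labels, positive = "KD") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  sum(cmp) / (length(pos) * length(neg))
}

# Naive per-gene reference screen (loops + stats::aov for the DE p-value)
naive_reference_screen <- function(values, condition, expr_window = c(11, 15),
                                   de_alpha = 0.05, z_threshold = 3.5,
                                   max_outliers = 3) {
  g <- factor(condition)
  res <- data.frame(gene = colnames(values), pass = NA, variance = NA)
  for (i in seq_len(ncol(values))) {
    x <- values[, i]
    m <- mean(x); v <- var(x)
    p <- if (v == 0) 1 else {
      fit <- summary(stats::aov(x ~ g))[[1]]
      pv <- fit[["Pr(>F)"]][1]
      if (is.na(pv)) 1 else pv
    }
    med <- median(x); mad0 <- median(abs(x - med))
    n_out <- if (mad0 == 0) 0L else sum(abs(0.6745 * (x - med) / mad0) > z_threshold)
    res$pass[i] <- (m >= expr_window[1] && m <= expr_window[2]) &&
      (p >= de_alpha) && (n_out <= max_outliers)
    res$variance[i] <- v
  }
  surv <- res[res$pass, , drop = FALSE]
  surv <- surv[order(surv$variance, surv$gene), , drop = FALSE]
  list(pass = setNames(res$pass, res$gene), ranking = surv$gene)
}

# Exact two-sided rank-sum p-value by full enumeration of rank assignments
wilcox_enum_p <- function(x, y) {
  n <- length(x) + length(y)
  ranks <- rank(c(x, y))
  obs <- sum(ranks[seq_along(x)])
  all_sums <- apply(utils::combn(n, length(x)), 2, function(idx) sum(idx))
  mu <- length(x) * (n + 1) / 2
  mean(abs(all_sums - mu) >= abs(obs - mu) - 1e-9)
}

# Noiseless paired-platform toy: target features are an exact per-gene
# affine transform of the source features, plus a random original model.
make_affine_pair <- function(n = 30, J = 5, seed = 1,
                             a = NULL, b = NULL) {
  set.seed(seed)
  if (is.null(a)) a <- runif(J, -6, -1)
  if (is.null(b)) b <- runif(J, 0.5, 2)
  src_ids <- sprintf("SRC%02d", seq_len(J))
  tgt_ids <- sprintf("TGT%02d", seq_len(J))
  L <- matrix(rnorm(n * J, mean = 9, sd = 1.5), n, J,
              dimnames = list(sprintf("P%03d", seq_len(n)), src_ids))
  x_tgt <- sweep(sweep(L, 2, b, `*`), 2, a, `+`)
  colnames(x_tgt) <- tgt_ids
  w <- setNames(round(runif(J, -1, 1), 2), src_ids)
  model <- linear_classifier(2.5, w, "microarray-log2")
  list(x_src = L, x_tgt = x_tgt, a = setNames(a, tgt_ids),
       b = setNames(b, tgt_ids), model = model)
}

# Synthetic expression cohort for the reference screen: 2 planted stable
# genes among `n_noise` variable / differentially expressed genes.
make_screen_cohort <- function(seed, n_noise = 50, n_per_group = 20,
                               groups = c("KD", "DV", "DB")) {
  set.seed(seed)
  n <- n_per_group * length(groups)
  cond <- rep(groups, each = n_per_group)
  planted <- cbind(REFA = rnorm(n, 12.1, 0.15), REFB = rnorm(n, 13.4, 0.15))
  noise <- sapply(seq_len(n_noise), function(i) {
    mu <- runif(1, 8, 16)
    sdv <- runif(1, 0.3, 1.5)
    x <- rnorm(n, mu, sdv)
    if (runif(1) < 0.6)   # differentially expressed across conditions
      x <- x + rep(rnorm(length(groups), 0, runif(1, 1, 3)), each = n_per_group)
    x
  })
  colnames(noise) <- sprintf("G%03d", seq_len(n_noise))
  values <- cbind(planted, noise)
  rownames(values) <- sprintf("S%03d", seq_len(n))
  expression_matrix(values, setNames(cond, rownames(values)))
}
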