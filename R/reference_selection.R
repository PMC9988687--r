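#' Configuration for the reference-gene screen
#'
#' Holds the constants of the three-criterion reference-gene screen:
#' moderate-to-high mean expression, no differential expression across
#' disease conditions, and few between-sample outliers, with survivors
#' ranked by increasing variance.
#'
#' @param expr_window Inclusive (low, high) bounds on mean log2 expression;
#'   default `c(11, 15)`.
#' @param de_alpha Genes with a differential-expression p-value below this
#'   are excluded; default 0.05.
#' @param z_threshold Robust-Z magnitude above which a sample counts as an
#'   outlier; default 3.5.
#' @param max_outliers Genes with more than this many outliers are excluded
#'   ("more than three"); default 3.
#' @param two_sided Count outliers on `|z|` (both tails, default) or on
#'   `z` alone (the screening formula as printed is one-sided).
#' @param moderated Use limma's empirical-Bayes moderated F-test for the DE
#'   criterion instead of the ordinary one-way F-test (requires limma).
#' @return A `ReferenceScreenConfig` list.
#' @export
reference_screen_config <- function(expr_window = c(11, 15), de_alpha = 0.05,
                                    z_threshold = 3.5, max_outliers = 3,
                                    two_sided = TRUE, moderated = FALSE) {
  stopifnot(length(expr_window) == 2, expr_window[1] < expr_window[2],
            de_alpha > 0, de_alpha < 1, z_threshold > 0, max_outliers >= 0)
  structure(list(expr_window = expr_window, de_alpha = de_alpha,
                 z_threshold = z_threshold, max_outliers = max_outliers,
                 two_sided = two_sided, moderated = moderated),
            class = "ReferenceScreenConfig")
}

#' Robust Z scores
#'
#' `z_i = 0.6745 * (x_i - median(x)) / MAD(x)`, where MAD is the unscaled
#' median of absolute deviations from the median. The 0.6745 factor makes z
#' comparable to an ordinary Z score under normality. A degenerate vector
#' (MAD = 0, e.g. a constant gene) gets all-zero scores and a `degenerate`
#' attribute: a constant gene is maximally stable and is never excluded by
#' the outlier criterion.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector of robust Z scores, with attribute `degenerate`.
#' @export
robust_z <- function(x) {
  if (length(x) < 2 || !all(is.finite(x)))
    stop("`x` must be a finite numeric vector of length >= 2")
  med <- median(x)
  mad0 <- median(abs(x - med))
  if (mad0 == 0)
    return(structure(rep(0, length(x)), degenerate = TRUE))
  structure(0.6745 * (x - med) / mad0, degenerate = FALSE)
}

#' Count outliers among robust Z scores
#'
#' @param z Robust Z scores (finite).
#' @param z_threshold Outlier cutoff; default 3.5.
#' @param two_sided Count `|z| > threshold` (default) or `z > threshold`.
#' @return Integer outlier count.
#' @export
count_outliers <- function(z, z_threshold = 3.5, two_sided = TRUE) {
  if (!all(is.finite(z))) stop("`z` must be finite")
  if (two_sided) sum(abs(z) > z_threshold) else sum(z > z_threshold)
}

#' Per-gene differential-expression screen across conditions
#'
#' One-way fixed-effects F-test of any expression difference across the
#' condition groups, vectorized over genes. With `moderated = TRUE` the
#' limma empirical-Bayes moderated F statistic is used instead; at the
#' sample sizes this screen is meant for, moderation is immaterial, and the
#' ordinary F-test keeps the exclusion filter free of any one ecosystem's
#' implementation. A gene with identical values in every sample has no
#' between-group variance and is reported as p = 1 (never excluded by this
#' criterion).
#'
#' @param expr An [expression_matrix()]; at least 2 condition groups, each
#'   with at least 2 samples.
#' @param moderated Use limma's moderated F-test.
#' @return Named numeric vector of per-gene p-values.
#' @export
de_screen <- function(expr, moderated = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  f <- factor(expr$condition)
  if (nlevels(f) < 2) stop("need >= 2 condition groups")
  sizes <- table(f)
  if (any(sizes < 2))
    stop("condition group(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  Y <- expr$values
  if (moderated) {
    if (!requireNamespace("limma", quietly = TRUE))
      stop("`moderated = TRUE` requires the limma package")
    design <- stats::model.matrix(~f)
    fit <- limma::eBayes(limma::lmFit(t(Y), design))
    tt <- limma::topTable(fit, coef = 2:ncol(design), number = Inf,
                          sort.by = "none")
    p <- stats::setNames(tt$P.Value, rownames(tt))
    p[apply(Y, 2, var) == 0] <- 1
    return(p)
  }
  n <- nrow(Y); k <- nlevels(f)
  grand <- colMeans(Y)
  group_means <- rowsum(Y, f) / as.vector(sizes)
  ssb <- colSums(group_means^2 * as.vector(sizes)) - n * grand^2
  sst <- colSums(Y^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  p[ssb <= .Machine$double.eps * pmax(sst, 1)] <- 1     # no between-group signal
  p[ssw == 0 & ssb > 0] <- 0                            # perfect separation
  stats::setNames(p, colnames(Y))
}

#' Screen an expression matrix for candidate reference genes
#'
#' Applies the three criteria of [reference_screen_config()] and ranks the
#' survivors by increasing between-sample variance (ties broken by gene id,
#' for determinism). The full per-criterion audit trail is retained for
#' failing genes.
#'
#' @param expr An [expression_matrix()].
#' @param cfg A [reference_screen_config()].
#' @return A data.frame of class `ReferenceCandidateReport` with columns
#'   `gene`, `mean`, `variance`, `de_p`, `n_outliers`, `pass_window`,
#'   `pass_de`, `pass_outlier`, `pass`, `rank` (NA for failures), ordered by
#'   rank then gene id.
#' @export
screen_references <- function(expr, cfg = reference_screen_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(cfg, "ReferenceScreenConfig"))
  Y <- expr$values
  gene_mean <- colMeans(Y)
  gene_var <- apply(Y, 2, var)
  de_p <- de_screen(expr, moderated = cfg$moderated)
  n_out <- vapply(colnames(Y), function(g)
    count_outliers(robust_z(Y[, g]), cfg$z_threshold, cfg$two_sided),
    integer(1))
  rep_df <- data.frame(
    gene = colnames(Y),
    mean = gene_mean,
    variance = gene_var,
    de_p = de_p[colnames(Y)],
    n_outliers = n_out,
    stringsAsFactors = FALSE, row.names = NULL)
  rep_df$pass_window <- rep_df$mean >= cfg$expr_window[1] &
    rep_df$mean <= cfg$expr_window[2]
  rep_df$pass_de <- rep_df$de_p >= cfg$de_alpha
  rep_df$pass_outlier <- rep_df$n_outliers <= cfg$max_outliers
  rep_df$pass <- rep_df$pass_window & rep_df$pass_de & rep_df$pass_outlier
  ord <- order(!rep_df$pass, rep_df$variance, rep_df$gene)
  rep_df <- rep_df[ord, , drop = FALSE]
  rep_df$rank <- NA_integer_
  rep_df$rank[rep_df$pass] <- seq_len(sum(rep_df$pass))
  rownames(rep_df) <- NULL
  if (!any(rep_df$pass))
    warning("no gene survives the reference screen; empty ranking")
  class(rep_df) <- c("ReferenceCandidateReport", "data.frame")
  rep_df
}
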