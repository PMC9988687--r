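#' Configuration for the synthetic paired-platform cohort generator
#'
#' Describes a febrile-illness cohort measured on both platforms: per
#' condition, gene-wise latent log2 expression is multivariate normal with
#' compound-symmetric co-regulation; the microarray observes the latent
#' value plus noise; the qRT-PCR observes a gene-specific affine transform
#' of the latent value (as delta-Ct, via stably generated reference-gene
#' Cts) plus noise. Two failure modes of the real assay are modeled: one
#' target whose Ct is undetermined in a fraction of samples (the unstable
#' construct), and one intronless-gene target whose delta-Ct is inflated in
#' low-RIN samples (genomic-DNA contamination).
#'
#' Defaults emulate the published bridging cohort: 107 samples across five
#' conditions, latent SDs and delta-Ct means seeded from the published
#' per-gene normalization parameters, and condition effects scaled so the
#' original classifier's analytic AUC for KD vs the rest is about 0.96
#' (the cross-validated regime reported for the bridged assay). These
#' defaults are illustrative of the study conditions, not inferential.
#'
#' @param n_per_condition Named integer vector of samples per condition;
#'   `"KD"` is the positive class.
#' @param effect_size Condition shift for KD in units of per-gene latent SD
#'   (signed per gene by the original model's weight sign).
#' @param condition_scale Named multipliers of `effect_size` per condition.
#' @param rho Compound-symmetric latent correlation between classifier
#'   genes (co-regulation).
#' @param array_noise_sd Microarray measurement noise SD (log2 units).
#' @param ct_noise_sd qRT-PCR delta-Ct noise SD (cycles).
#' @param slope Per-gene affine slope of delta-Ct on latent log2 expression
#'   (scalar recycled or named vector).
#' @param ref_ct_mean,ref_ct_sd Reference-gene Ct means and SD (stable).
#' @param dropout_gene,dropout_prob,dropout_mechanism Unstable target, its
#'   undetermined probability, and mechanism: `"mcar"` (missing completely
#'   at random, default) or `"censor"` (left-censoring at `max_cycles`,
#'   low abundance being the suspected cause in the real assay).
#' @param contamination_gene,contamination_slope Intronless target and the
#'   delta-Ct inflation per RIN unit below 8 (0 switches it off).
#' @param rin List: `p_high`, `high_mean`, `high_sd`, `low_mean`, `low_sd`,
#'   `p_unquantifiable` — a mixture populating both RIN strata.
#' @param max_cycles qRT-PCR cycle count.
#' @param seed Default seed used by [generate_cohort()].
#' @return A `SyntheticCohortConfig` list (includes the derived per-gene
#'   table `genes`: probe, gene, latent mean/sd, signed effect, affine
#'   intercept `a` and slope `b`).
#' @export
synthetic_cohort_config <- function(
    n_per_condition = c(KD = 27, DB = 15, DV = 25, U = 24, HC = 16),
    effect_size = 0.92,
    condition_scale = c(KD = 1, DB = 0.45, U = 0.3, DV = 0, HC = 0),
    rho = 0.3,
    array_noise_sd = 0.15,
    ct_noise_sd = 0.25,
    slope = 1,
    ref_ct_mean = c(AURKAIP1 = 20.0, SSU72 = 20.4),
    ref_ct_sd = 0.12,
    dropout_gene = "DDIAS", dropout_prob = 0.3,
    dropout_mechanism = c("mcar", "censor"),
    contamination_gene = "LINC02035", contamination_slope = 0.6,
    rin = list(p_high = 0.75, high_mean = 9.2, high_sd = 0.35,
               low_mean = 7.0, low_sd = 0.8, p_unquantifiable = 0.03),
    max_cycles = 40, seed = 1L) {
  dropout_mechanism <- match.arg(dropout_mechanism)
  stopifnot(all(n_per_condition >= 1), "KD" %in% names(n_per_condition),
            rho > -1, rho < 1, array_noise_sd >= 0, ct_noise_sd >= 0,
            dropout_prob >= 0, dropout_prob <= 1, contamination_slope >= 0)
  missing_scale <- setdiff(names(n_per_condition), names(condition_scale))
  if (length(missing_scale))
    stop("no condition_scale for condition(s): ",
         paste(missing_scale, collapse = ", "))
  genes <- .default_gene_table()
  b <- if (length(slope) == 1) stats::setNames(rep(slope, nrow(genes)), genes$gene)
       else slope[genes$gene]
  if (any(is.na(b)) || any(b == 0)) stop("per-gene slopes must be non-zero")
  genes$b <- unname(b)
  # affine intercept chosen so baseline delta-Ct means sit at the published
  # per-gene normalization means
  genes$a <- genes$dct_mean - genes$b * genes$mean
  genes$effect <- sign(genes$w_original) * effect_size * genes$sd
  structure(list(n_per_condition = n_per_condition, effect_size = effect_size,
                 condition_scale = condition_scale, rho = rho,
                 array_noise_sd = array_noise_sd, ct_noise_sd = ct_noise_sd,
                 genes = genes, ref_ct_mean = ref_ct_mean,
                 ref_ct_sd = ref_ct_sd,
                 dropout_gene = dropout_gene, dropout_prob = dropout_prob,
                 dropout_mechanism = dropout_mechanism,
                 contamination_gene = contamination_gene,
                 contamination_slope = contamination_slope,
                 rin = rin, max_cycles = max_cycles, seed = seed),
            class = "SyntheticCohortConfig")
}

# Latent gene table: published per-gene delta-Ct normalization means/SDs
# anchor the target-platform scale; baseline microarray means are plausible
# whole-blood log2 intensities. DDIAS (absent from the published normalized
# model) gets low-abundance parameters consistent with its unstable assay
# behavior.
.default_gene_table <- function() {
  map <- utils::read.table(system.file("extdata", "kids_gep_probe_map.tsv",
                                       package = "gepbridge", mustWork = TRUE),
                           sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  B <- read_classifier(system.file("extdata", "kids_gep_normalized.json",
                                   package = "gepbridge", mustWork = TRUE))
  A <- read_classifier(system.file("extdata", "kids_gep_original.json",
                                   package = "gepbridge", mustWork = TRUE))
  genes <- data.frame(probe = map$probe, gene = map$gene,
                      stringsAsFactors = FALSE)
  genes$w_original <- unname(A$weights[genes$probe])
  genes$dct_mean <- unname(B$norm$mean[genes$gene])
  genes$sd <- unname(B$norm$sd[genes$gene])
  genes$dct_mean[genes$gene == "DDIAS"] <- -6.5
  genes$sd[genes$gene == "DDIAS"] <- 1.4
  base_means <- c(CACNA1E = 7.6, DDIAS = 6.9, KLHL2 = 10.8, PYROXD2 = 7.9,
                  SMOX = 9.4, ZNF185 = 9.8, LINC02035 = 8.2, CLIC3 = 8.9,
                  S100P = 11.6, IFI27 = 10.9, TIGIT = 8.4, CD163 = 10.2,
                  RTN1 = 9.0)
  genes$mean <- unname(base_means[genes$gene])
  genes
}

.latent_sigma <- function(cfg) {
  sds <- cfg$genes$sd
  G <- length(sds)
  C <- matrix(cfg$rho, G, G); diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("latent correlation matrix is not positive semi-definite")
  diag(sds) %*% C %*% diag(sds)
}

#' Generate a synthetic paired-platform cohort
#'
#' Draws a cohort under a [synthetic_cohort_config()]: a microarray
#' [expression_matrix()] (columns named by probe id), a qRT-PCR
#' [ct_table()] (columns named by gene symbol, reference targets included,
#' per-sample RIN), and a `SyntheticTruth` oracle carrying the latent
#' expression, the true affine platform map, the noise-free classifier
#' scores, the class-conditional score distributions and the generator's
#' closed-form AUC. All randomness flows from `seed`.
#'
#' @param cfg A `SyntheticCohortConfig`.
#' @param seed Integer seed; default `cfg$seed`.
#' @return List with elements `expression`, `ct`, `truth`.
#' @export
generate_cohort <- function(cfg = synthetic_cohort_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "SyntheticCohortConfig"))
  set.seed(seed)
  genes <- cfg$genes
  G <- nrow(genes)
  conds <- rep(names(cfg$n_per_condition), cfg$n_per_condition)
  n <- length(conds)
  ids <- sprintf("S%03d", seq_len(n))
  Sigma <- .latent_sigma(cfg)
  mean_matrix <- outer(rep(1, n), genes$mean) +
    outer(cfg$condition_scale[conds], genes$effect)
  L <- mean_matrix + MASS::mvrnorm(n, mu = rep(0, G), Sigma = Sigma)
  dimnames(L) <- list(ids, genes$gene)

  X <- L + matrix(rnorm(n * G, sd = cfg$array_noise_sd), n, G)
  colnames(X) <- genes$probe; rownames(X) <- ids

  # RIN mixture: both strata populated, a few unquantifiable
  high <- runif(n) < cfg$rin$p_high
  rin <- ifelse(high,
                pmin(10, rnorm(n, cfg$rin$high_mean, cfg$rin$high_sd)),
                pmax(1, rnorm(n, cfg$rin$low_mean, cfg$rin$low_sd)))
  rin[!high] <- pmin(rin[!high], 8)    # low stratum stays at or below cutoff
  rin[high] <- pmax(rin[high], 8.05)
  rin[runif(n) < cfg$rin$p_unquantifiable] <- NA
  rin <- stats::setNames(rin, ids)

  ref_ct <- sapply(names(cfg$ref_ct_mean), function(r)
    rnorm(n, cfg$ref_ct_mean[r], cfg$ref_ct_sd))
  rownames(ref_ct) <- ids
  anchor <- 0.5 * rowSums(ref_ct)

  dct_true <- sweep(sweep(L, 2, genes$b, `*`), 2, genes$a, `+`)
  dct_noisy <- dct_true + matrix(rnorm(n * G, sd = cfg$ct_noise_sd), n, G)
  colnames(dct_noisy) <- genes$gene
  if (cfg$contamination_slope > 0 && cfg$contamination_gene %in% genes$gene) {
    rin_eff <- ifelse(is.na(rin), cfg$rin$low_mean, rin)
    dct_noisy[, cfg$contamination_gene] <-
      dct_noisy[, cfg$contamination_gene] +
      cfg$contamination_slope * pmax(0, 8 - rin_eff)
  }
  ct_vals <- anchor - dct_noisy
  if (cfg$dropout_prob > 0 && cfg$dropout_gene %in% genes$gene) {
    if (cfg$dropout_mechanism == "mcar") {
      drop_i <- runif(n) < cfg$dropout_prob
    } else {
      cutoff <- quantile(ct_vals[, cfg$dropout_gene], 1 - cfg$dropout_prob,
                         type = 7)
      drop_i <- ct_vals[, cfg$dropout_gene] > cutoff
    }
    ct_vals[drop_i, cfg$dropout_gene] <- NA
  }
  ct_all <- cbind(ct_vals, ref_ct)
  ct <- ct_table(ct_all, rin = rin, max_cycles = cfg$max_cycles)

  expr <- expression_matrix(X, stats::setNames(conds, ids))

  original <- kids_gep_model("original")
  w <- original$weights[genes$probe]
  score_var <- drop(t(w) %*% Sigma %*% w) + cfg$array_noise_sd^2 * sum(w^2)
  cond_names <- names(cfg$n_per_condition)
  score_means <- vapply(cond_names, function(cc)
    original$intercept +
      sum(w * (genes$mean + cfg$condition_scale[cc] * genes$effect)),
    numeric(1))
  non_kd <- setdiff(cond_names, "KD")
  pi_c <- cfg$n_per_condition[non_kd] / sum(cfg$n_per_condition[non_kd])
  analytic_auc <- sum(pi_c * pnorm((score_means["KD"] - score_means[non_kd]) /
                                     sqrt(2 * score_var)))
  truth <- structure(list(
    latent = L, affine = list(a = stats::setNames(genes$a, genes$gene),
                              b = stats::setNames(genes$b, genes$gene)),
    true_scores = stats::setNames(
      original$intercept + drop(L %*% w), ids),
    score_means = score_means, score_var = score_var,
    analytic_auc = unname(analytic_auc),
    condition = stats::setNames(conds, ids),
    config = cfg, seed = seed), class = "SyntheticTruth")
  list(expression = expr, ct = ct, truth = truth)
}

#' Generate a toy transcriptome with probe-matching scenarios
#'
#' Builds a small set of spliced transcript models realizing the
#' probe-design scenarios that matter for cross-platform quantification:
#' a single-isoform gene whose microarray probe and qRT-PCR amplicon match
#' the identical transcript set; a two-isoform exon-skipping gene whose
#' probes match platform-exclusive isoforms (the discordant case); and an
#' intronless gene whose amplicon cannot span a junction (the genomic-DNA
#' contamination risk). Per-sample TPM tables include isoform switching for
#' the skipping gene, and every sample's TPM sums to 1e6.
#'
#' @param n_samples Number of samples in the TPM table.
#' @param seed Integer seed.
#' @return List with `transcripts` (list of [transcript_model()]),
#'   `tpm` (transcripts x samples), `probes` (data.frame: probe_id, gene,
#'   platform, sequence, spans_junction, intronless).
#' @export
generate_transcriptome <- function(n_samples = 24, seed = 1L) {
  set.seed(seed)
  rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
  substr_at <- function(s, start, len) substr(s, start, start + len - 1)

  # GENEA: one isoform, three exons
  a_ex <- vapply(c(120, 150, 130), rand_seq, character(1))
  A1 <- transcript_model("GENEA-1", "GENEA", paste(a_ex, collapse = ""))
  # GENEB: B1 = e1+e2+e3, B2 = e1+e3 (exon 2 skipped)
  b_ex <- vapply(c(140, 110, 160), rand_seq, character(1))
  B1 <- transcript_model("GENEB-1", "GENEB", paste(b_ex, collapse = ""))
  B2 <- transcript_model("GENEB-2", "GENEB", paste(b_ex[c(1, 3)], collapse = ""))
  # GENEC: intronless, single exon
  C1 <- transcript_model("GENEC-1", "GENEC", rand_seq(400))

  probes <- rbind(
    data.frame(probe_id = "ARR_GENEA", gene = "GENEA", platform = "microarray",
               sequence = substr_at(a_ex[3], 31, 50), spans_junction = FALSE,
               intronless = FALSE, stringsAsFactors = FALSE),
    data.frame(probe_id = "PCR_GENEA", gene = "GENEA", platform = "qrt-pcr",
               # amplicon across the exon1/exon2 junction of the only isoform
               sequence = substr_at(paste(a_ex, collapse = ""), 120 - 40, 90),
               spans_junction = TRUE, intronless = FALSE),
    data.frame(probe_id = "ARR_GENEB", gene = "GENEB", platform = "microarray",
               sequence = substr_at(b_ex[2], 21, 50), spans_junction = FALSE,
               intronless = FALSE),
    data.frame(probe_id = "PCR_GENEB", gene = "GENEB", platform = "qrt-pcr",
               # amplicon across the e1/e3 junction: matches only the skipped
               # isoform B2 (platform-exclusive match sets)
               sequence = substr_at(paste(b_ex[c(1, 3)], collapse = ""),
                                    140 - 40, 90),
               spans_junction = TRUE, intronless = FALSE),
    data.frame(probe_id = "ARR_GENEC", gene = "GENEC", platform = "microarray",
               sequence = substr_at(C1$sequence, 51, 50),
               spans_junction = FALSE, intronless = TRUE),
    data.frame(probe_id = "PCR_GENEC", gene = "GENEC", platform = "qrt-pcr",
               sequence = substr_at(C1$sequence, 201, 90),
               spans_junction = FALSE, intronless = TRUE))

  ids <- sprintf("T%02d", seq_len(n_samples))
  gene_level <- rbind(GENEA = 2^rnorm(n_samples, 6, 0.7),
                      GENEB = 2^rnorm(n_samples, 7, 0.7),
                      GENEC = 2^rnorm(n_samples, 5, 0.7))
  p_b1 <- runif(n_samples, 0.1, 0.9)   # isoform switching across samples
  raw <- rbind(`GENEA-1` = gene_level["GENEA", ],
               `GENEB-1` = gene_level["GENEB", ] * p_b1,
               `GENEB-2` = gene_level["GENEB", ] * (1 - p_b1),
               `GENEC-1` = gene_level["GENEC", ])
  tpm <- sweep(raw, 2, colSums(raw), `/`) * 1e6
  colnames(tpm) <- ids
  list(transcripts = list(A1, B1, B2, C1), tpm = tpm, probes = probes)
}
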