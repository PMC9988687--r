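#' Construct a spliced transcript model
#'
#' A transcript is its ordered, non-overlapping exon intervals (1-based,
#' closed, GTF convention; optional — probe matching works on spliced
#' sequence alone) plus the spliced sequence itself. Genomic alignment is
#' deliberately not modeled: exact matching against spliced transcript
#' sequences is equivalent for abundance-aggregation purposes, and
#' splice-junction-spanning probes match the spliced sequence naturally.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param sequence Spliced sequence (character, A/C/G/T/N).
#' @param strand `"+"` or `"-"`.
#' @param exons Optional data.frame with columns `start`, `end` (1-based,
#'   closed, ordered, non-overlapping); total length must equal
#'   `nchar(sequence)`.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, sequence, strand = "+",
                             exons = NULL) {
  stopifnot(strand %in% c("+", "-"))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over {A,C,G,T,N}")
  if (!is.null(exons)) {
    stopifnot(all(c("start", "end") %in% colnames(exons)))
    exons <- exons[order(exons$start), , drop = FALSE]
    if (any(exons$end < exons$start)) stop("exon end < start")
    if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
      stop("exons must be non-overlapping and ordered")
    if (sum(exons$end - exons$start + 1) != nchar(sequence))
      stop("spliced sequence length must equal total exon length")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 strand = strand, exons = exons, sequence = sequence),
            class = "TranscriptModel")
}

.transcript_seqs <- function(transcripts) {
  if (inherits(transcripts, "TranscriptModel")) transcripts <- list(transcripts)
  seqs <- vapply(transcripts, function(t) t$sequence, character(1))
  names(seqs) <- vapply(transcripts, function(t) t$transcript_id, character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Match a probe (or amplicon) sequence against transcript models
#'
#' Reports the transcripts whose spliced sequence contains the probe in
#' sense orientation, or its reverse complement (antisense). `N` bases in
#' the probe act as wildcards; no mismatches are allowed unless
#' `max_mismatch > 0`.
#'
#' @param probe_seq Probe or amplicon sequence, length >= 15 nt, over
#'   A/C/G/T/N with at most 20% N.
#' @param transcripts List of [transcript_model()]s.
#' @param probe_id Identifier carried into the result.
#' @param platform `"microarray"` or `"qrt-pcr"` tag.
#' @param max_mismatch Allowed Hamming mismatches; default 0 (exact).
#' @return An object of class `ProbeMatch`: list with `probe_id`,
#'   `platform`, `matches` (data.frame `transcript_id`, `orientation`).
#' @export
match_probe <- function(probe_seq, transcripts, probe_id = "probe",
                        platform = c("microarray", "qrt-pcr"),
                        max_mismatch = 0) {
  platform <- match.arg(platform)
  probe_seq <- toupper(probe_seq)
  if (nchar(probe_seq) < 15) stop("probe must be >= 15 nt")
  if (grepl("[^ACGTN]", probe_seq)) stop("probe must be over {A,C,G,T,N}")
  n_frac <- lengths(regmatches(probe_seq, gregexpr("N", probe_seq))) / nchar(probe_seq)
  if (n_frac > 0.2) stop("probe rejected: more than 20% N")
  seqs <- .transcript_seqs(transcripts)
  probe <- Biostrings::DNAString(probe_seq)
  fixed <- c(pattern = FALSE, subject = TRUE)  # N in probe is a wildcard
  sense <- Biostrings::vcountPattern(probe, seqs, max.mismatch = max_mismatch,
                                     fixed = fixed) > 0
  anti <- Biostrings::vcountPattern(Biostrings::reverseComplement(probe), seqs,
                                    max.mismatch = max_mismatch,
                                    fixed = fixed) > 0
  matches <- rbind(
    if (any(sense)) data.frame(transcript_id = names(seqs)[sense],
                               orientation = "sense", stringsAsFactors = FALSE),
    if (any(anti)) data.frame(transcript_id = names(seqs)[anti],
                              orientation = "antisense", stringsAsFactors = FALSE))
  if (is.null(matches))
    matches <- data.frame(transcript_id = character(), orientation = character(),
                          stringsAsFactors = FALSE)
  structure(list(probe_id = probe_id, platform = platform, matches = matches),
            class = "ProbeMatch")
}

#' @export
print.ProbeMatch <- function(x, ...) {
  cat("ProbeMatch '", x$probe_id, "' [", x$platform, "]: ",
      nrow(x$matches), " transcript match(es)\n", sep = "")
  invisible(x)
}

#' Aggregate TPM over the transcripts a probe matches
#'
#' Per sample, sums TPM over the matched transcripts of one orientation.
#' Both orientations are searched at match time; aggregation keeps the
#' majority orientation of the probe's matches, so a probe is quantified on
#' a consistent strand.
#'
#' @param match A [match_probe()] result.
#' @param tpm Transcripts x samples TPM matrix (row names = transcript ids,
#'   non-negative).
#' @return Named numeric vector of per-sample aggregated TPM (zeros with a
#'   warning when the match set is empty).
#' @export
aggregate_probe_tpm <- function(match, tpm) {
  stopifnot(inherits(match, "ProbeMatch"), is.matrix(tpm))
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (!nrow(match$matches)) {
    warning("empty match set for probe '", match$probe_id, "'; zero abundance")
    return(stats::setNames(rep(0, ncol(tpm)), colnames(tpm)))
  }
  tab <- table(match$matches$orientation)
  keep_orient <- names(tab)[which.max(tab)]
  tx <- unique(match$matches$transcript_id[match$matches$orientation == keep_orient])
  absent <- setdiff(tx, rownames(tpm))
  if (length(absent))
    stop("matched transcript(s) absent from TPM table: ",
         paste(absent, collapse = ", "))
  colSums(tpm[tx, , drop = FALSE])
}

#' Cross-platform probe concordance
#'
#' Simple linear regression of one probe's per-sample aggregate abundance
#' on the other's; returns the coefficient of determination and the slope's
#' p-value. Raw TPM by default; `scale = "log2"` regresses on
#' `log2(TPM + 1)`.
#'
#' @param agg_a,agg_b Per-sample aggregated abundances (same samples,
#'   length >= 3).
#' @param scale `"raw"` (default) or `"log2"`.
#' @return List with `r_squared`, `p_value`, `slope`, `n` (`r_squared` NA
#'   when either vector has zero variance).
#' @export
platform_concordance <- function(agg_a, agg_b, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (length(agg_a) != length(agg_b)) stop("aggregates must cover the same samples")
  if (length(agg_a) < 3) stop("need >= 3 samples")
  if (scale == "log2") { agg_a <- log2(agg_a + 1); agg_b <- log2(agg_b + 1) }
  if (var(agg_a) == 0 || var(agg_b) == 0)
    return(list(r_squared = NA_real_, p_value = NA_real_, slope = NA_real_,
                n = length(agg_a)))
  fit <- lm(agg_a ~ agg_b)
  sm <- suppressWarnings(summary(fit))   # a perfect fit is a legitimate input
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["agg_b", "Pr(>|t|)"],
       slope = unname(coef(fit)["agg_b"]),
       n = length(agg_a))
}
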