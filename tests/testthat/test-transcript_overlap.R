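rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

toy_pair <- function(seed = 30) {
  # T1 splices e1+e2; T2 retains the intron between them
  set.seed(seed)
  e1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  e2 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  intron <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  list(spliced = transcript_model("T1", "G", paste0(e1, e2)),
       retained = transcript_model("T2", "G", paste0(e1, intron, e2)),
       e1 = e1, e2 = e2)
}

test_that("probe matching: exonic, junction-spanning and antisense cases", {
  tp <- toy_pair()
  txs <- list(tp$spliced, tp$retained)
  exonic <- substr(tp$e1, 11, 40)                 # inside a shared exon
  m1 <- match_probe(exonic, txs, "exonic")
  expect_setequal(m1$matches$transcript_id, c("T1", "T2"))
  expect_true(all(m1$matches$orientation == "sense"))
  junction <- paste0(substr(tp$e1, 41, 60), substr(tp$e2, 1, 20))
  m2 <- match_probe(junction, txs, "junction")
  expect_equal(m2$matches$transcript_id, "T1")    # intron-retainer excluded
  m3 <- match_probe(rc(junction), txs, "junction-rc")
  expect_equal(m3$matches$transcript_id, "T1")
  expect_equal(m3$matches$orientation, "antisense")
})

test_that("probe validation: length, alphabet and N fraction", {
  t1 <- transcript_model("T", "G", strrep("ACGT", 30))
  expect_error(match_probe("ACGTACGTACGT", list(t1)), ">= 15")
  expect_error(match_probe(strrep("X", 20), list(t1)), "A,C,G,T,N")
  expect_error(match_probe(paste0(strrep("N", 6), strrep("A", 14)), list(t1)),
               "20%")
  # N under the cap acts as a wildcard
  m <- match_probe(paste0("NCGT", strrep("ACGT", 4)), list(t1))
  expect_true("T" %in% m$matches$transcript_id[m$matches$orientation == "sense"])
})

test_that("transcript model invariants hold", {
  expect_error(transcript_model("T", "G", "ACGTX"), "A,C,G,T,N")
  expect_error(transcript_model("T", "G", "ACGTACGT",
                                exons = data.frame(start = 1, end = 4)),
               "length")
  tm <- transcript_model("T", "G", "ACGTACGT",
                         exons = data.frame(start = c(1, 11), end = c(4, 14)))
  expect_equal(nrow(tm$exons), 2)
  expect_error(transcript_model("T", "G", "ACGTACGT",
                                exons = data.frame(start = c(1, 3),
                                                   end = c(4, 6))),
               "non-overlapping")
})

test_that("TPM aggregation is additive over matched transcripts", {
  tpm <- rbind(T1 = c(3, 1), T2 = c(2, 5), T3 = c(7, 7))
  colnames(tpm) <- c("s1", "s2")
  one <- structure(list(probe_id = "p", platform = "qrt-pcr",
                        matches = data.frame(transcript_id = "T1",
                                             orientation = "sense")),
                   class = "ProbeMatch")
  expect_equal(aggregate_probe_tpm(one, tpm), c(s1 = 3, s2 = 1))
  both <- one; both$matches <- data.frame(transcript_id = c("T1", "T2"),
                                          orientation = "sense")
  expect_equal(aggregate_probe_tpm(both, tpm), c(s1 = 5, s2 = 6))
  third <- one; third$matches <- data.frame(transcript_id = "T3",
                                            orientation = "sense")
  all3 <- one; all3$matches <- data.frame(transcript_id = c("T1", "T2", "T3"),
                                          orientation = "sense")
  expect_equal(aggregate_probe_tpm(both, tpm) + aggregate_probe_tpm(third, tpm),
               aggregate_probe_tpm(all3, tpm))   # partition additivity
  empty <- one; empty$matches <- empty$matches[0, ]
  expect_warning(z <- aggregate_probe_tpm(empty, tpm), "empty")
  expect_equal(z, c(s1 = 0, s2 = 0))
  # aggregation keeps the majority orientation only
  mixed <- one
  mixed$matches <- data.frame(transcript_id = c("T1", "T2", "T3"),
                              orientation = c("sense", "sense", "antisense"))
  expect_equal(aggregate_probe_tpm(mixed, tpm), c(s1 = 5, s2 = 6))
})

test_that("concordance: identity, affine, degenerate and null inputs", {
  a <- c(1, 4, 2, 8, 5)
  expect_equal(platform_concordance(a, a)$r_squared, 1)
  expect_equal(platform_concordance(2 * a + 1, a)$r_squared, 1)
  expect_true(is.na(platform_concordance(rep(3, 5), a)$r_squared))
  set.seed(31)
  r2 <- platform_concordance(rnorm(1000), rnorm(1000))$r_squared
  expect_lt(r2, 0.02)
  expect_error(platform_concordance(a, a[1:3]), "same samples")
})

test_that("matched probe pairs concord; platform-exclusive isoforms do not", {
  tx <- generate_transcriptome(n_samples = 24, seed = 32)
  agg <- function(probe_id) {
    p <- tx$probes[tx$probes$probe_id == probe_id, ]
    m <- match_probe(p$sequence, tx$transcripts, probe_id,
                     platform = p$platform)
    aggregate_probe_tpm(m, tx$tpm)
  }
  # single-isoform gene: identical match sets, perfect concordance
  expect_equal(platform_concordance(agg("ARR_GENEA"), agg("PCR_GENEA"))$r_squared, 1)
  # exon-skipping gene: the platforms quantify different isoforms
  r2b <- platform_concordance(agg("ARR_GENEB"), agg("PCR_GENEB"))$r_squared
  expect_lt(r2b, 1 - 1e-6)
  # dropping a sample-varying transcript from a matched set lowers R^2
  mA <- match_probe(tx$probes$sequence[tx$probes$probe_id == "ARR_GENEB"],
                    tx$transcripts, "ARR_GENEB")
  full_gene <- colSums(tx$tpm[c("GENEB-1", "GENEB-2"), ])
  only_b1 <- aggregate_probe_tpm(mA, tx$tpm)
  r2_full <- platform_concordance(full_gene, full_gene)$r_squared
  r2_drop <- platform_concordance(only_b1, full_gene)$r_squared
  expect_lt(r2_drop, r2_full)
})
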