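test_that("expression matrix round-trips through delimited files", {
  vals <- matrix(c(10.5, 11.25, 12, 9.875, 13.5, 8.125), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("GENE1", "GENE2")))
  em <- expression_matrix(vals, c(s1 = "KD", s2 = "DV", s3 = "HC"),
                          site = c(s1 = "A", s2 = "A", s3 = "B"))
  f <- tempfile(fileext = ".tsv"); fm <- tempfile(fileext = ".tsv")
  write_expression(em, f, fm)
  back <- read_expression(f, fm)
  expect_equal(back$values, em$values)
  expect_equal(back$condition, em$condition)
  expect_equal(back$site, em$site)
  # a second write of the re-read object is byte-identical
  f2 <- tempfile(); fm2 <- tempfile()
  write_expression(back, f2, fm2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("expression reader rejects bad cells and labels with coordinates", {
  f <- tempfile(); fm <- tempfile()
  writeLines(c("sample\tG1\tG2", "s1\t1.5\tNA", "s2\t2\t3"), f)
  writeLines(c("sample\tcondition", "s1\tKD", "s2\tDV"), fm)
  expect_error(read_expression(f, fm), "s1.*G2")
  writeLines(c("sample\tG1\tG2", "s1\t1.5\tx7", "s2\t2\t3"), f)
  expect_error(read_expression(f, fm), "non-numeric")
  # missing condition label names the sample
  writeLines(c("sample\tG1\tG2", "s1\t1.5\t2.5", "s2\t2\t3"), f)
  writeLines(c("sample\tcondition", "s1\tKD"), fm)
  expect_error(read_expression(f, fm), "s2")
})

test_that("constructors enforce identifier and finiteness invariants", {
  vals <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("g1", "g2")))
  expect_error(expression_matrix(vals, c("KD", "DV")), "duplicated sample")
  vals2 <- matrix(c(1, 2, Inf, 4), 2,
                  dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(expression_matrix(vals2, c("KD", "DV")), "non-finite")
})

test_that("Ct reader flags undetermined values and enforces cycle bounds", {
  f <- tempfile()
  writeLines(c("sample\tT1\tT2\tRIN", "s1\t25.0\tUndetermined\t9.1",
               "s2\t30\t22\t"), f)
  ct <- read_ct(f)
  expect_equal(ct$ct["s1", "T1"], 25.0)
  expect_true(ct$undetermined["s1", "T2"])
  expect_true(is.na(ct$ct["s1", "T2"]))
  expect_equal(unname(ct$rin), c(9.1, NA))
  writeLines(c("sample\tT1", "s1\t41.0"), f)
  expect_error(read_ct(f, max_cycles = 40), "max_cycles")
  writeLines(c("sample\tT1", "s1\t-3"), f)
  expect_error(read_ct(f), "negative|zero")
  # configurable undetermined token
  writeLines(c("sample\tT1", "s1\tUndet"), f)
  ct2 <- read_ct(f, undetermined_tokens = "Undet")
  expect_true(ct2$undetermined["s1", "T1"])
})

test_that("Ct round-trip preserves values, flags and RIN", {
  m <- matrix(c(25, NA, 30.125, 22), 2,
              dimnames = list(c("s1", "s2"), c("T1", "T2")))
  ct <- ct_table(m, rin = c(s1 = 9.1, s2 = NA))
  f <- tempfile()
  write_ct(ct, f)
  back <- read_ct(f)
  expect_equal(back$ct, ct$ct)
  expect_equal(back$undetermined, ct$undetermined)
  expect_equal(back$rin, ct$rin)
})

test_that("packaged classifier fixtures load with the published values", {
  A <- kids_gep_model("original")
  expect_length(A$weights, 13)
  expect_identical(A$intercept, 0)   # printed without an intercept
  expect_equal(unname(A$weights["ILMN_1664047"]), 0.955)
  B <- kids_gep_model("normalized")
  expect_equal(B$intercept, 21.720)
  expect_equal(unname(B$weights["CACNA1E"]), 0.746)
  expect_equal(unname(B$norm$mean["CACNA1E"]), -4.763)
  expect_equal(unname(B$norm$sd["CACNA1E"]), 1.751)
  expect_length(B$weights, 12)
  expect_false("DDIAS" %in% names(B$weights))
  C <- kids_gep_model("raw")
  expect_equal(C$intercept, 23.972)
  expect_equal(unname(C$weights["CACNA1E"]), 0.426)
})

test_that("classifier validation rejects inconsistent norm parameters", {
  w <- c(g1 = 1, g2 = -0.5)
  expect_error(linear_classifier(0, w, "normalized-dct"), "norm")
  expect_error(
    linear_classifier(0, w, "normalized-dct",
                      norm = list(mean = c(g1 = 0, g2 = 0),
                                  sd = c(g1 = 1, g2 = 0))),
    "> 0")
  expect_error(
    linear_classifier(0, w, "normalized-dct",
                      norm = list(mean = c(g1 = 0), sd = c(g1 = 1))),
    "exactly")
  # JSON round-trip
  m <- linear_classifier(1.5, w, "normalized-dct",
                         norm = list(mean = c(g1 = -2, g2 = 3),
                                     sd = c(g1 = 1.2, g2 = 0.8)))
  f <- tempfile(fileext = ".json")
  write_classifier(m, f)
  back <- read_classifier(f)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$weights, m$weights)
  expect_equal(back$norm$mean, m$norm$mean)
  expect_equal(back$norm$sd, m$norm$sd)
  f2 <- tempfile()
  writeLines('{"intercept": 0, "representation": "normalized-dct",
    "weights": {"g1": 1}, "norm": {"g1": {"mean": 0, "sd": 0}}}', f2)
  expect_error(read_classifier(f2), "> 0")
})

test_that("cohort pairing is exact-id and reports unpaired samples", {
  vals <- matrix(rnorm(6), 3, dimnames = list(c("s1", "s2", "s3"), c("g1", "g2")))
  em <- expression_matrix(vals, setNames(c("KD", "DV", "HC"), rownames(vals)))
  ctm <- matrix(c(20, 21, 22, 23), 2,
                dimnames = list(c("s2", "s9"), c("T1", "T2")))
  cp <- cohort_pair(em, ct_table(ctm))
  expect_equal(cp$pairing, "s2")
  expect_setequal(cp$unpaired_expression, c("s1", "s3"))
  expect_equal(cp$unpaired_ct, "s9")
})
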