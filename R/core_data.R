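REPRESENTATIONS <- c("microarray-log2", "normalized-dct", "raw-dct")

#' Construct an expression matrix
#'
#' Container for a samples-by-genes table of log2 intensities with a
#' condition label per sample and an optional site label, as produced by a
#' source (microarray) platform.
#'
#' @param values Numeric matrix, samples in rows, genes in columns; both
#'   dimensions named, all values finite.
#' @param condition Character or factor of condition labels, one per sample,
#'   named by sample id or in row order.
#' @param site Optional character of site labels, same conventions.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, condition, site = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x genes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample (row) and gene (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated gene identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  condition <- .align_sample_labels(condition, rownames(values), "condition")
  missing_cond <- rownames(values)[is.na(condition) | condition == ""]
  if (length(missing_cond))
    stop("samples without a condition label: ", paste(missing_cond, collapse = ", "))
  if (!is.null(site)) site <- .align_sample_labels(site, rownames(values), "site")
  structure(list(values = values, condition = condition, site = site),
            class = "ExpressionMatrix")
}

.align_sample_labels <- function(x, sample_ids, what) {
  x <- as.character(x) |> stats::setNames(names(x))
  if (!is.null(names(x))) {
    missing <- setdiff(sample_ids, names(x))
    if (length(missing))
      stop("no ", what, " label for sample(s): ", paste(missing, collapse = ", "))
    x <- x[sample_ids]
  } else if (length(x) != length(sample_ids)) {
    stop("`", what, "` must have one entry per sample")
  }
  stats::setNames(x, sample_ids)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "samples x", ncol(x$values), "genes\n")
  cat("conditions:", paste(sprintf("%s(%d)", names(table(x$condition)),
                                   table(x$condition)), collapse = " "), "\n")
  invisible(x)
}

#' Construct a Ct table
#'
#' Samples-by-targets cycle-threshold values from a qRT-PCR assay.
#' Undetermined reactions (no threshold crossing within `max_cycles`) carry
#' no numeric value and are stored as `NA` with an explicit flag. Each
#' sample optionally carries an RNA integrity number (RIN); `NA` RIN means
#' unquantifiable.
#'
#' @param ct Numeric matrix, samples in rows, targets in columns; `NA` marks
#'   an undetermined Ct.
#' @param rin Optional numeric vector of per-sample RIN values in \[1, 10\];
#'   `NA` = unquantifiable. Missing entirely = all unquantifiable.
#' @param max_cycles Maximum thermal cycles of the assay; finite Ct values
#'   must lie in (0, `max_cycles`\].
#' @return An object of class `CtTable`.
#' @export
ct_table <- function(ct, rin = NULL, max_cycles = 40) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (samples x targets)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have sample (row) and target (column) names")
  if (anyDuplicated(rownames(ct)) || anyDuplicated(colnames(ct)))
    stop("duplicated sample or target identifiers in Ct table")
  finite <- ct[!is.na(ct)]
  if (any(finite <= 0))
    stop("negative or zero Ct values are not valid cycle thresholds")
  if (any(finite > max_cycles))
    stop("Ct values exceed max_cycles = ", max_cycles, ": ",
         paste(utils::head(signif(finite[finite > max_cycles], 4), 5), collapse = ", "))
  if (is.null(rin)) {
    rin <- stats::setNames(rep(NA_real_, nrow(ct)), rownames(ct))
  } else {
    rin <- stats::setNames(as.numeric(rin), names(rin))
    if (is.null(names(rin))) {
      if (length(rin) != nrow(ct)) stop("`rin` must have one entry per sample")
      names(rin) <- rownames(ct)
    } else {
      rin <- rin[rownames(ct)]
      names(rin) <- rownames(ct)
    }
    bad <- !is.na(rin) & (rin < 1 | rin > 10)
    if (any(bad))
      stop("RIN outside [1, 10] for sample(s): ",
           paste(rownames(ct)[bad], collapse = ", "))
  }
  structure(list(ct = ct, undetermined = is.na(ct), rin = rin,
                 max_cycles = max_cycles),
            class = "CtTable")
}

#' @export
print.CtTable <- function(x, ...) {
  cat("CtTable:", nrow(x$ct), "samples x", ncol(x$ct), "targets;",
      sum(x$undetermined), "undetermined Ct value(s);",
      sum(!is.na(x$rin)), "sample(s) with quantified RIN\n")
  invisible(x)
}

#' Construct a linear classifier
#'
#' An intercept plus per-feature weights, tagged with the feature
#' representation it applies to: source-platform log2 intensities
#' (`"microarray-log2"`), mean/SD-normalized delta-Ct values
#' (`"normalized-dct"`), or raw delta-Ct values (`"raw-dct"`). The
#' normalized representation additionally carries the per-feature mean and
#' SD used for normalization.
#'
#' @param intercept Scalar intercept.
#' @param weights Named numeric vector of feature weights.
#' @param representation One of `"microarray-log2"`, `"normalized-dct"`,
#'   `"raw-dct"`.
#' @param norm For `"normalized-dct"` only: list with named numeric vectors
#'   `mean` and `sd` covering exactly the weighted features, all `sd > 0`.
#' @return An object of class `LinearClassifier`.
#' @export
linear_classifier <- function(intercept, weights, representation, norm = NULL) {
  representation <- match.arg(representation, REPRESENTATIONS)
  if (!is.numeric(weights) || is.null(names(weights)) || anyDuplicated(names(weights)))
    stop("`weights` must be a named numeric vector with unique feature ids")
  if (!all(is.finite(weights)) || !is.finite(intercept))
    stop("classifier intercept and weights must be finite")
  if (representation == "normalized-dct") {
    if (is.null(norm))
      stop("normalized-dct representation requires `norm` (per-feature mean/sd)")
    if (!setequal(names(norm$mean), names(weights)) ||
        !setequal(names(norm$sd), names(weights)))
      stop("`norm` must cover exactly the weighted features")
    norm$mean <- norm$mean[names(weights)]
    norm$sd <- norm$sd[names(weights)]
    if (any(!is.finite(norm$sd)) || any(norm$sd <= 0))
      stop("all normalization SDs must be finite and > 0")
  } else if (!is.null(norm)) {
    stop("`norm` is only meaningful for the normalized-dct representation")
  }
  structure(list(intercept = as.numeric(intercept),
                 weights = weights,
                 representation = representation,
                 norm = norm),
            class = "LinearClassifier")
}

#' @export
print.LinearClassifier <- function(x, digits = 3, ...) {
  cat("LinearClassifier [", x$representation, "], ",
      length(x$weights), " features\n", sep = "")
  cat("intercept:", round(x$intercept, digits), "\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' Pair samples measured on both platforms
#'
#' Pairs an [expression_matrix()] with a [ct_table()] by exact sample-id
#' match. Samples present on only one platform are reported in the result,
#' never silently dropped.
#'
#' @param expression An `ExpressionMatrix`.
#' @param ct A `CtTable`.
#' @return An object of class `CohortPair` with elements `expression`, `ct`,
#'   `pairing` (shared sample ids, in expression-row order),
#'   `unpaired_expression`, `unpaired_ct`.
#' @export
cohort_pair <- function(expression, ct) {
  stopifnot(inherits(expression, "ExpressionMatrix"), inherits(ct, "CtTable"))
  shared <- intersect(rownames(expression$values), rownames(ct$ct))
  if (!length(shared)) stop("no shared sample identifiers between platforms")
  structure(list(expression = expression, ct = ct, pairing = shared,
                 unpaired_expression = setdiff(rownames(expression$values), shared),
                 unpaired_ct = setdiff(rownames(ct$ct), shared)),
            class = "CohortPair")
}

#' @export
print.CohortPair <- function(x, ...) {
  cat("CohortPair:", length(x$pairing), "paired samples;",
      length(x$unpaired_expression), "expression-only;",
      length(x$unpaired_ct), "Ct-only\n")
  invisible(x)
}

# ---- readers / writers -----------------------------------------------------

.read_table_strict <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = character())
  if (anyDuplicated(df[[1]]))
    stop("duplicated sample identifiers in ", path)
  if (anyDuplicated(colnames(df)))
    stop("duplicated column identifiers in ", path)
  df
}

.numeric_cells <- function(df, path, allow_na_tokens = character()) {
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  flagged <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    raw <- trimws(m[, j])
    is_token <- raw %in% allow_na_tokens | is.na(raw)
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is_token & is.na(val)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("non-numeric cell in ", path, " at (sample '", rownames(m)[i],
           "', column '", colnames(m)[j], "'): \"", raw[i], "\"")
    }
    out[, j] <- ifelse(is_token, NA_real_, val)
    flagged[, j] <- is_token
  }
  list(values = out, flagged = flagged)
}

#' Read an expression matrix from delimited files
#'
#' Expects a delimited table with a leading sample-id column and one column
#' per gene, plus a metadata sidecar with columns `sample`, `condition` and
#' optionally `site`.
#'
#' @param path Path to the values table.
#' @param meta_path Path to the metadata sidecar.
#' @param sep Field separator (tab by default; use `","` for CSV).
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, meta_path, sep = "\t") {
  df <- .read_table_strict(path, sep)
  parsed <- .numeric_cells(df, path)      # no NA tokens allowed: any NA is an error
  meta <- utils::read.table(meta_path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% colnames(meta)))
    stop("metadata sidecar must have columns `sample` and `condition`")
  condition <- stats::setNames(as.character(meta$condition), meta$sample)
  site <- if ("site" %in% colnames(meta))
    stats::setNames(as.character(meta$site), meta$sample)
  expression_matrix(parsed$values, condition, site)
}

#' Write an expression matrix (and sidecar) to delimited files
#' @param x An `ExpressionMatrix`.
#' @inheritParams read_expression
#' @export
write_expression <- function(x, path, meta_path, sep = "\t") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(sample = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = rownames(x$values), condition = x$condition,
                     stringsAsFactors = FALSE)
  if (!is.null(x$site)) meta$site <- x$site
  utils::write.table(meta, meta_path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a Ct table from a delimited file
#'
#' Undetermined Ct values are encoded by any of `undetermined_tokens`
#' (instrument-export dialects vary). An optional `RIN` column carries the
#' per-sample RNA integrity number; absent or empty means unquantifiable.
#'
#' @param path Path to the delimited table (leading sample-id column).
#' @param undetermined_tokens Character values parsed as undetermined.
#' @param max_cycles Assay cycle count; Ct values above it are rejected.
#' @param sep Field separator.
#' @return A `CtTable`.
#' @export
read_ct <- function(path, undetermined_tokens = c("Undetermined", "NA", ""),
                    max_cycles = 40, sep = "\t") {
  df <- .read_table_strict(path, sep)
  has_rin <- "RIN" %in% colnames(df)
  parsed <- .numeric_cells(df, path, allow_na_tokens = undetermined_tokens)
  vals <- parsed$values
  rin <- NULL
  if (has_rin) {
    rin <- vals[, "RIN"]
    vals <- vals[, setdiff(colnames(vals), "RIN"), drop = FALSE]
  }
  ct_table(vals, rin = rin, max_cycles = max_cycles)
}

#' Write a Ct table to a delimited file
#' @param x A `CtTable`.
#' @param path Output path.
#' @param undetermined_token Token written for undetermined cells.
#' @param sep Field separator.
#' @export
write_ct <- function(x, path, undetermined_token = "Undetermined", sep = "\t") {
  stopifnot(inherits(x, "CtTable"))
  chr <- matrix(as.character(x$ct), nrow(x$ct), dimnames = dimnames(x$ct))
  chr[x$undetermined] <- undetermined_token
  df <- data.frame(sample = rownames(x$ct), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (any(!is.na(x$rin))) df$RIN <- ifelse(is.na(x$rin), "", x$rin)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a linear classifier from a JSON weights file
#'
#' Schema: `{intercept, representation, weights: {id: w}, norm: {id: {mean,
#' sd}}}`; `norm` is required iff `representation` is `"normalized-dct"`.
#'
#' @param path Path to the JSON file.
#' @return A `LinearClassifier`.
#' @export
read_classifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$weights) || is.null(j$representation))
    stop("classifier JSON must provide `weights` and `representation`")
  weights <- unlist(j$weights)
  norm <- NULL
  if (!is.null(j$norm) && length(j$norm)) {
    norm <- list(
      mean = vapply(j$norm, function(g) as.numeric(g[["mean"]]), numeric(1)),
      sd = vapply(j$norm, function(g) as.numeric(g[["sd"]]), numeric(1)))
  }
  linear_classifier(intercept = if (is.null(j$intercept)) 0 else j$intercept,
                    weights = weights,
                    representation = j$representation,
                    norm = norm)
}

#' Write a linear classifier to JSON
#' @param x A `LinearClassifier`.
#' @param path Output path.
#' @export
write_classifier <- function(x, path) {
  stopifnot(inherits(x, "LinearClassifier"))
  out <- list(intercept = x$intercept, representation = x$representation,
              weights = as.list(x$weights))
  if (!is.null(x$norm))
    out$norm <- stats::setNames(
      lapply(names(x$weights), function(g)
        list(mean = unname(x$norm$mean[g]), sd = unname(x$norm$sd[g]))),
      names(x$weights))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}

#' Published KiDs-GEP classifier models
#'
#' Loads the packaged weight files for the Kawasaki disease classifier in
#' its three published representations: the original 13-probe microarray
#' model, the bridged model on mean/SD-normalized delta-Ct values, and the
#' same bridged model on raw delta-Ct values.
#'
#' @param representation `"original"` (microarray log2), `"normalized"` or
#'   `"raw"` (delta-Ct).
#' @return A `LinearClassifier`.
#' @export
kids_gep_model <- function(representation = c("original", "normalized", "raw")) {
  representation <- match.arg(representation)
  f <- switch(representation, original = "kids_gep_original.json",
              normalized = "kids_gep_normalized.json", raw = "kids_gep_raw.json")
  read_classifier(system.file("extdata", f, package = "gepbridge", mustWork = TRUE))
}

#' Probe-to-gene map of the published assay
#'
#' The correspondence between the original classifier's microarray probes
#' and the qRT-PCR target genes, in published row order.
#'
#' @return A data.frame with columns `probe` and `gene`.
#' @export
kids_gep_probe_map <- function() {
  utils::read.table(system.file("extdata", "kids_gep_probe_map.tsv",
                                package = "gepbridge", mustWork = TRUE),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
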