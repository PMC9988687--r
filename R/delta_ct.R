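#' Compute delta-Ct values relative to two reference genes
#'
#' `dCt_target = 0.5 * (Ct_ref1 + Ct_ref2) - Ct_target` per sample. Higher
#' expression means lower Ct, hence higher delta-Ct. Amplification
#' efficiencies are assumed constant within a gene (they may differ between
#' genes), so no efficiency correction is applied; `efficiency` provides a
#' hook for per-gene scaling should an assay require it.
#'
#' Samples in which either reference Ct is undetermined are dropped with a
#' warning: delta-Ct is undefined without both anchors, and partial
#' imputation would silently distort a bridge. An undetermined target Ct
#' yields a missing delta-Ct for that (sample, target) only.
#'
#' @param ct A [ct_table()].
#' @param ref1,ref2 Distinct reference target ids present in `ct`.
#' @param efficiency Optional named per-gene scale applied to delta-Ct
#'   (default none).
#' @return An object of class `DeltaCtMatrix`: list with `delta_ct`
#'   (samples x classifier targets, `NA` = missing), `ref_ids`,
#'   `dropped_samples`.
#' @export
compute_delta_ct <- function(ct, ref1, ref2, efficiency = NULL) {
  stopifnot(inherits(ct, "CtTable"))
  if (ref1 == ref2) stop("`ref1` and `ref2` must differ")
  absent <- setdiff(c(ref1, ref2), colnames(ct$ct))
  if (length(absent))
    stop("reference target(s) absent from Ct table: ",
         paste(absent, collapse = ", "))
  ref_ok <- !is.na(ct$ct[, ref1]) & !is.na(ct$ct[, ref2])
  dropped <- rownames(ct$ct)[!ref_ok]
  if (length(dropped))
    warning("dropping ", length(dropped),
            " sample(s) with undetermined reference Ct: ",
            paste(dropped, collapse = ", "))
  if (!any(ref_ok))
    stop("all samples dropped: no sample has both reference Cts determined")
  m <- ct$ct[ref_ok, , drop = FALSE]
  targets <- setdiff(colnames(m), c(ref1, ref2))
  anchor <- 0.5 * (m[, ref1] + m[, ref2])
  dct <- anchor - m[, targets, drop = FALSE]
  if (!is.null(efficiency)) {
    eff <- efficiency[colnames(dct)]
    eff[is.na(eff)] <- 1
    dct <- sweep(dct, 2, eff, `*`)
  }
  structure(list(delta_ct = dct, ref_ids = c(ref1, ref2),
                 dropped_samples = dropped),
            class = "DeltaCtMatrix")
}

#' @export
print.DeltaCtMatrix <- function(x, ...) {
  cat("DeltaCtMatrix:", nrow(x$delta_ct), "samples x", ncol(x$delta_ct),
      "targets (refs", paste(x$ref_ids, collapse = ", "), "removed);",
      sum(is.na(x$delta_ct)), "missing value(s)\n")
  invisible(x)
}

#' Flag unstable assay targets by missingness
#'
#' A target whose delta-Ct is missing (undetermined Ct) in more than
#' `max_missing_frac` of samples is marked excluded from downstream
#' bridging, mirroring the removal of an unreliable qRT-PCR construct from
#' the explanatory terms of the bridge model.
#'
#' @param dct A [compute_delta_ct()] result.
#' @param max_missing_frac Missing-fraction threshold; default 0.05.
#' @return A data.frame of class `FeatureStability` with columns `target`,
#'   `missing_frac`, `included`.
#' @export
assess_stability <- function(dct, max_missing_frac = 0.05) {
  stopifnot(inherits(dct, "DeltaCtMatrix"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- colMeans(is.na(dct$delta_ct))
  out <- data.frame(target = colnames(dct$delta_ct),
                    missing_frac = unname(frac),
                    included = unname(frac <= max_missing_frac),
                    stringsAsFactors = FALSE)
  excl <- out$target[!out$included]
  if (length(excl))
    message("excluding unstable target(s): ", paste(excl, collapse = ", "))
  class(out) <- c("FeatureStability", "data.frame")
  out
}
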