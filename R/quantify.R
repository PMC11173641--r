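# Global-sample-intensity normalization and group summarization.
#
# Normalization rescales every quantification value by its sample's
# overall intensity and the grand mean intensity:
#   q'_ij = q_ij / S_j * mean_k(S_k),   S_j = sum over detected i of q_ij.
# Missing values stay missing; no imputation is performed at any point.

#' Global-sample-intensity normalization
#'
#' Divides each quantification value by the overall (summed) intensity of
#' its sample and multiplies by the mean overall intensity across all
#' samples, so that every corrected column total equals the mean of the
#' original column totals. Within-sample ratios and rank order of
#' detected values are preserved exactly, and the operation is
#' idempotent.
#'
#' @param x a `protein_table` or a proteins x samples numeric matrix with
#'   `NA` for missing values.
#' @param ... unused.
#' @return Object of the same class with corrected abundances; a
#'   `protein_table` gets its `normalized` flag set.
#' @export
normalize_global_intensity <- function(x, ...) UseMethod("normalize_global_intensity")

#' @rdname normalize_global_intensity
#' @export
normalize_global_intensity.matrix <- function(x, ...) {
  n_det <- colSums(detection(x))
  if (any(n_det == 0)) {
    abort_validation(sprintf(
      "sample(s) with no detected values cannot be normalized: %s",
      paste(colnames(x)[n_det == 0] %||% which(n_det == 0), collapse = ", ")))
  }
  totals <- colSums(x, na.rm = TRUE)
  sweep(x, 2, mean(totals) / totals, `*`)
}

#' @rdname normalize_global_intensity
#' @export
normalize_global_intensity.protein_table <- function(x, ...) {
  x$abundance <- normalize_global_intensity(x$abundance)
  x$normalized <- TRUE
  add_provenance(x, "normalize_global_intensity")
}

#' Mean abundance per sample group
#'
#' Collapses replicate columns to their group mean, taken over detected
#' replicates only; a protein missing in all replicates of a group is
#' missing for that group.
#'
#' @param x a `protein_table` or abundance matrix.
#' @param design required when `x` is a matrix.
#' @param scope design columns defining the groups (default sampling
#'   time, `profile:phase`).
#' @return proteins x groups numeric matrix, groups in design order.
#' @export
summarize_by_group <- function(x, design = NULL, scope = c("profile", "phase")) {
  if (inherits(x, "protein_table")) {
    design <- x$design
    x <- x$abundance
  }
  if (is.null(design)) abort_validation("a design is required to group samples")
  grp <- group_ids(design, scope)
  groups <- unique(grp)
  means <- vapply(groups, function(g) {
    m <- rowMeans(x[, grp == g, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }, numeric(nrow(x)))
  matrix(means, nrow = nrow(x), dimnames = list(rownames(x), groups))
}
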