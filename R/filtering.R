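# Identification-quality and replicate-presence filters, pairwise
# exclusivity ("excluded proteins"), and presence sets for intersection
# analysis. All rules are record-wise predicates on detection patterns;
# abundances are never modified.

new_filter_report <- function(n_input, removed) {
  structure(list(
    n_input = n_input,
    n_removed_confidence = length(removed$confidence %||% character()),
    n_removed_score = length(removed$score %||% character()),
    n_removed_peptides = length(removed$peptides %||% character()),
    n_removed_presence = length(removed$presence %||% character()),
    n_output = n_input - sum(lengths(removed)),
    removed_accessions = removed
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d out\n", x$n_input, x$n_output))
  cat(sprintf("  removed: confidence %d, score %d, peptides %d, presence %d\n",
              x$n_removed_confidence, x$n_removed_score,
              x$n_removed_peptides, x$n_removed_presence))
  invisible(x)
}

#' Filter on identification quality
#'
#' Retains protein groups with high protein-level FDR confidence
#' (FDR < 0.01 category) and adequate search-engine evidence. Under the
#' default `combine = "or"` a record is removed when it fails any single
#' gate: confidence below `confidence`, score below `min_score`, or fewer
#' than `min_peptides` peptides. `combine = "and"` instead removes on the
#' joint low-score-and-low-peptide condition (confidence is always
#' required). Each removed record is attributed to the first rule that
#' removes it, in the order confidence, score, peptides.
#'
#' @param table a `protein_table`.
#' @param min_score minimum protein score retained (default 2).
#' @param min_peptides minimum peptide count retained (default 3, i.e.
#'   records with a peptide number of 2 or fewer are removed).
#' @param confidence required FDR confidence level (default `"high"`).
#' @param combine `"or"` (remove on either evidence gate, default) or
#'   `"and"` (remove only when both score and peptide gates fail).
#' @return list with elements `table` (filtered) and `report`
#'   (a `filter_report`).
#' @export
filter_identification <- function(table, min_score = 2, min_peptides = 3,
                                  confidence = "high",
                                  combine = c("or", "and")) {
  combine <- match.arg(combine)
  rec <- table$records
  fail_conf <- rec$fdr_confidence != confidence
  fail_score <- rec$score < min_score
  fail_pept <- rec$num_peptides < min_peptides
  if (combine == "or") {
    removed <- list(
      confidence = rec$accession[fail_conf],
      score = rec$accession[!fail_conf & fail_score],
      peptides = rec$accession[!fail_conf & !fail_score & fail_pept])
  } else {
    joint <- fail_score & fail_pept
    removed <- list(
      confidence = rec$accession[fail_conf],
      score = rec$accession[!fail_conf & joint],
      peptides = character())
  }
  keep <- !rec$accession %in% unlist(removed)
  out <- subset_records(table, keep)
  out <- add_provenance(out, sprintf(
    "filter_identification(min_score=%g, min_peptides=%d, confidence=%s, combine=%s)",
    min_score, min_peptides, confidence, combine))
  list(table = out, report = new_filter_report(nrow(rec), removed))
}

# Fraction of a group's replicates in which each protein is detected:
# proteins x groups matrix.
detection_fraction <- function(table, scope = c("profile", "phase")) {
  det <- detection(table)
  grp <- group_ids(table$design, scope)
  groups <- unique(grp)
  if (!length(groups) || !ncol(det)) {
    abort_validation("design defines no sample groups for the given scope")
  }
  frac <- vapply(groups, function(g) {
    cols <- grp == g
    rowMeans(det[, cols, drop = FALSE])
  }, numeric(nrow(det)))
  if (!is.matrix(frac)) frac <- matrix(frac, nrow = nrow(det))
  dimnames(frac) <- list(rownames(det), groups)
  frac
}

#' Filter on replicate presence
#'
#' Retains proteins identified in at least `min_frac` of the replicates
#' of at least one sample group (by default the sampling-time groups
#' `profile:phase`). The comparison is inclusive, so 2 detections out of
#' 4 replicates pass at the default 50% threshold.
#'
#' @param table a `protein_table`.
#' @param min_frac minimum detected fraction within a group, in (0, 1].
#' @param scope design columns defining the sample groups.
#' @return list with elements `table` and `report`.
#' @export
filter_replicate_presence <- function(table, min_frac = 0.5,
                                      scope = c("profile", "phase")) {
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1) {
    abort_validation("min_frac must lie in (0, 1]")
  }
  frac <- detection_fraction(table, scope)
  keep <- apply(frac >= min_frac, 1, any)
  removed <- list(confidence = character(), score = character(),
                  peptides = character(),
                  presence = table$records$accession[!keep])
  out <- subset_records(table, keep)
  out <- add_provenance(out, sprintf(
    "filter_replicate_presence(min_frac=%g, scope=%s)",
    min_frac, paste(scope, collapse = ",")))
  list(table = out, report = new_filter_report(nrow(frac), removed))
}

resolve_group <- function(table, group, scope) {
  grp <- group_ids(table$design, scope)
  if (!group %in% grp) {
    abort_validation(sprintf("group '%s' not found; available: %s",
                             group, paste(unique(grp), collapse = ", ")))
  }
  which(grp == group)
}

#' Exclusive proteins of a pairwise comparison
#'
#' In a pairwise comparison of two sample groups, a protein is exclusive
#' to group A when it is identified in at least `min_frac` of A's
#' replicates and not detected in any replicate of B (and symmetrically
#' for B). Such proteins are excluded from shared totals in pairwise
#' comparisons.
#'
#' @param table a `protein_table`.
#' @param group_a,group_b group labels in `scope` terms, e.g. `"FW:UL"`
#'   for scope `c("profile", "phase")`.
#' @param scope design columns defining the groups.
#' @param min_frac presence threshold within the owning group.
#' @return list with character vectors `exclusive_a` and `exclusive_b`.
#' @export
exclusive_proteins <- function(table, group_a, group_b,
                               scope = c("profile", "phase"),
                               min_frac = 0.5) {
  ia <- resolve_group(table, group_a, scope)
  ib <- resolve_group(table, group_b, scope)
  if (length(intersect(ia, ib))) {
    abort_validation(sprintf("groups '%s' and '%s' share samples", group_a, group_b))
  }
  det <- detection(table)
  frac_a <- rowMeans(det[, ia, drop = FALSE])
  frac_b <- rowMeans(det[, ib, drop = FALSE])
  any_a <- frac_a > 0
  any_b <- frac_b > 0
  acc <- table$records$accession
  list(exclusive_a = acc[frac_a >= min_frac & !any_b],
       exclusive_b = acc[frac_b >= min_frac & !any_a])
}

#' Presence sets per sample group
#'
#' One accession set per group: the proteins detected in at least
#' `min_frac` of that group's replicates (or in any replicate when
#' `rule = "any"`). These sets feed the intersection analysis.
#'
#' @param table a `protein_table`.
#' @param scope design columns defining the groups.
#' @param min_frac presence threshold.
#' @param rule `"replicate_fraction"` (default) or `"any"`.
#' @return Named list of character vectors, one per group, in design
#'   order.
#' @export
presence_sets <- function(table, scope = c("profile", "phase"),
                          min_frac = 0.5,
                          rule = c("replicate_fraction", "any")) {
  rule <- match.arg(rule)
  frac <- detection_fraction(table, scope)
  thr <- if (rule == "any") .Machine$double.xmin else min_frac
  sets <- lapply(colnames(frac), function(g) {
    rownames(frac)[frac[, g] >= thr]
  })
  names(sets) <- colnames(frac)
  sets
}
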