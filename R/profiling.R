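# Qualitative metaproteomics: taxon frequency profiles and GO-term
# frequency profiles per sampling time. Frequencies are based on
# identification counts only, so they are invariant under abundance
# normalization.

# Accessions in scope for a group label (or all records when scope=NULL).
scope_members <- function(table, scope, min_frac, rule) {
  if (is.null(scope)) {
    return(list(global = table$records$accession))
  }
  presence_sets(table, scope = scope, min_frac = min_frac, rule = rule)
}

#' Taxon frequency profile
#'
#' Counts, per sampling-time group (or globally when `scope = NULL`),
#' the proteins attributed to each taxon at the requested rank, and
#' expresses each count as a percentage of the total proteins in that
#' group. Proteins with no parsed organism fall in an `unassigned` bin,
#' so frequencies always sum to 100. Within a group a protein counts as
#' present under the same replicate-fraction rule as the presence filter.
#'
#' @param table a `protein_table` with parsed taxonomy.
#' @param rank `"genus"`, `"species"` or `"family"`.
#' @param scope design columns defining the groups, or `NULL` for a
#'   single global profile.
#' @param min_frac presence threshold within a group.
#' @param rule detection rule, `"replicate_fraction"` or `"any"`.
#' @param main_threshold optional percentage; when given, an extra
#'   logical column `main` marks taxa above it (e.g. the main `>1%`
#'   genera).
#' @return data.frame of class `taxon_profile` with columns `scope`,
#'   `rank`, `taxon`, `count`, `frequency` (percent), sorted by
#'   descending frequency (ties alphabetical) within each scope.
#' @export
taxon_frequency <- function(table, rank = c("genus", "species", "family"),
                            scope = c("profile", "phase"), min_frac = 0.5,
                            rule = c("replicate_fraction", "any"),
                            main_threshold = NULL) {
  rank <- match.arg(rank)
  rule <- match.arg(rule)
  sets <- scope_members(table, scope, min_frac, rule)
  taxon <- table$records[[rank]]
  taxon[is.na(taxon)] <- "unassigned"
  names(taxon) <- table$records$accession
  out <- lapply(names(sets), function(g) {
    members <- sets[[g]]
    if (!length(members)) {
      return(data.frame(scope = character(), rank = character(),
                        taxon = character(), count = integer(),
                        frequency = numeric(), stringsAsFactors = FALSE))
    }
    tab <- base::table(taxon[members])
    df <- data.frame(scope = g, rank = rank, taxon = names(tab),
                     count = as.integer(tab),
                     frequency = 100 * as.integer(tab) / length(members),
                     stringsAsFactors = FALSE)
    df[order(-df$frequency, df$taxon), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(main_threshold)) res$main <- res$frequency > main_threshold
  structure(res, class = c("taxon_profile", "data.frame"))
}

#' GO-term frequency profile
#'
#' Counts, per group, the distinct proteins annotated with each GO term
#' of one aspect, and expresses each count as a percentage of the
#' proteins annotated in that aspect within the group. A protein may
#' carry several terms, so frequencies do not sum to 100. Unannotated
#' proteins are reported via the `n_unannotated` column.
#'
#' @param table a `protein_table`.
#' @param annotations data.frame (`accession`, `go_id`, `aspect`) as
#'   from [read_go_annotations()].
#' @param aspect one GO aspect.
#' @param scope design columns defining the groups, or `NULL` for
#'   global.
#' @param min_frac presence threshold within a group.
#' @param rule detection rule.
#' @return data.frame of class `go_profile` with columns `scope`,
#'   `aspect`, `term`, `count`, `frequency`, `n_annotated`,
#'   `n_unannotated`, sorted by descending frequency within scope.
#' @export
go_frequency <- function(table, annotations,
                         aspect = c("biological_process",
                                    "molecular_function",
                                    "cellular_component"),
                         scope = c("profile", "phase"), min_frac = 0.5,
                         rule = c("replicate_fraction", "any")) {
  if (length(aspect) == 1 && !aspect %in% GO_ASPECTS) {
    abort_validation(sprintf("unknown GO aspect '%s'; allowed: %s",
                             aspect, paste(GO_ASPECTS, collapse = ", ")))
  }
  aspect <- match.arg(aspect)
  rule <- match.arg(rule)
  ann <- unique(annotations[annotations$aspect == aspect,
                            c("accession", "go_id")])
  sets <- scope_members(table, scope, min_frac, rule)
  out <- lapply(names(sets), function(g) {
    members <- sets[[g]]
    ann_g <- ann[ann$accession %in% members, , drop = FALSE]
    n_annotated <- length(unique(ann_g$accession))
    n_unannotated <- length(members) - n_annotated
    if (!n_annotated) {
      return(data.frame(scope = character(), aspect = character(),
                        term = character(), count = integer(),
                        frequency = numeric(), n_annotated = integer(),
                        n_unannotated = integer(), stringsAsFactors = FALSE))
    }
    tab <- base::table(ann_g$go_id)
    df <- data.frame(scope = g, aspect = aspect, term = names(tab),
                     count = as.integer(tab),
                     frequency = 100 * as.integer(tab) / n_annotated,
                     n_annotated = n_annotated,
                     n_unannotated = n_unannotated,
                     stringsAsFactors = FALSE)
    df[order(-df$frequency, df$term), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # per-scope unannotated counts survive even when a scope has no
  # annotated protein at all (and hence no rows above)
  unann <- vapply(names(sets), function(g) {
    length(setdiff(sets[[g]], ann$accession))
  }, integer(1))
  structure(res, class = c("go_profile", "data.frame"),
            n_unannotated_by_scope = unann)
}

#' Export an accession list
#'
#' Writes one accession per line in sorted order, e.g. for submission of
#' a protein cluster to an external interaction-network service.
#'
#' @param x a `protein_table` or a character vector of accessions.
#' @param path output file.
#' @param subset optional accessions to restrict a `protein_table` to.
#' @return `path`, invisibly.
#' @export
export_accession_list <- function(x, path, subset = NULL) {
  acc <- if (inherits(x, "protein_table")) x$records$accession else as.character(x)
  if (!is.null(subset)) acc <- intersect(acc, subset)
  writeLines(sort(acc), path)
  invisible(path)
}
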