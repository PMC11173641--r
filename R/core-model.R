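# Domain model: protein-group tables, study designs, annotation tables.
#
# A protein_table binds a record data.frame (identification metadata and
# parsed taxonomy), a proteins x samples abundance matrix (NA = not
# detected), a study design, and a provenance trail of applied operations.

PHASE_LEVELS <- c("FL", "DL", "EL", "UL")
GO_ASPECTS <- c("molecular_function", "biological_process", "cellular_component")
CONFIDENCE_LEVELS <- c("high", "medium", "low")

#' Default dialect for reading protein-group exports
#'
#' A dialect names the columns of a Proteome Discoverer-style protein-group
#' TSV export and fixes the missing-value convention. `abundance_pattern`
#' is a regular expression whose first capture group yields the sample id.
#' When `confidence_is_numeric` is `TRUE` the confidence column is read as
#' a protein-level FDR q-value and mapped to the categorical levels
#' (`high` below 0.01, `medium` below 0.05, `low` otherwise).
#'
#' @param accession,description,score,peptides,confidence column names.
#' @param abundance_pattern regex with one capture group for the sample id.
#' @param zero_is_missing treat zero abundances as not detected.
#' @param confidence_is_numeric interpret the confidence column as a
#'   numeric protein FDR instead of categorical levels.
#' @param family_lookup named character vector mapping genus to family;
#'   defaults to the bundled Acetobacteraceae membership list.
#' @return A list of class `acetoprot_dialect`.
#' @export
default_dialect <- function(accession = "Accession",
                            description = "Description",
                            score = "Score",
                            peptides = "Peptides",
                            confidence = "Confidence",
                            abundance_pattern = "^Abundance: (.+)$",
                            zero_is_missing = TRUE,
                            confidence_is_numeric = FALSE,
                            family_lookup = NULL) {
  structure(list(
    accession = accession, description = description, score = score,
    peptides = peptides, confidence = confidence,
    abundance_pattern = abundance_pattern,
    zero_is_missing = isTRUE(zero_is_missing),
    confidence_is_numeric = isTRUE(confidence_is_numeric),
    family_lookup = family_lookup %||% genus_family_lookup()
  ), class = "acetoprot_dialect")
}

#' Read a dialect/configuration file
#'
#' Reads a YAML configuration with (optionally nested) keys matching the
#' arguments of [default_dialect()]; a `columns:` section may hold the
#' column names, and `family_lookup_path` may point at a two-column
#' (genus, family) TSV.
#'
#' @param path YAML file.
#' @return An `acetoprot_dialect`.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("dialect file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cols <- cfg$columns %||% list()
  lookup <- NULL
  if (!is.null(cfg$family_lookup_path)) {
    lookup <- genus_family_lookup(cfg$family_lookup_path)
  }
  default_dialect(
    accession = cols$accession %||% cfg$accession %||% "Accession",
    description = cols$description %||% cfg$description %||% "Description",
    score = cols$score %||% cfg$score %||% "Score",
    peptides = cols$peptides %||% cfg$peptides %||% "Peptides",
    confidence = cols$confidence %||% cfg$confidence %||% "Confidence",
    abundance_pattern = cfg$abundance_pattern %||% "^Abundance: (.+)$",
    zero_is_missing = cfg$zero_is_missing %||% TRUE,
    confidence_is_numeric = cfg$confidence_is_numeric %||% FALSE,
    family_lookup = lookup
  )
}

#' Genus-to-family lookup table
#'
#' Loads a two-column TSV (`genus`, `family`). The bundled default covers
#' the Acetobacteraceae genera recurrently identified in vinegar
#' microbiota (acetic acid bacteria and the acidophilic clade).
#'
#' @param path optional TSV path; defaults to the bundled table.
#' @return Named character vector: `lookup[genus] == family`.
#' @export
genus_family_lookup <- function(path = NULL) {
  path <- path %||% system.file("extdata", "genus_family.tsv", package = "acetoprot")
  if (!file.exists(path)) abort_io(sprintf("family lookup not found: %s", path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$family, tab$genus)
}

#' Parse the organism out of a UniProt-style description
#'
#' UniProt FASTA headers (and hence search-engine description fields)
#' carry the source organism as `OS=<Genus> <species> ...` followed by
#' further `XX=` tags. The genus is the first organism token and the
#' species is the `Genus species` binomial; infraspecific qualifiers
#' (`subsp.`, strain suffixes) are dropped. Descriptions without an
#' organism field yield `NA` taxa, which downstream profiling counts in
#' an `unassigned` bin. The function is total: it never errors.
#'
#' @param description character vector of description fields.
#' @param family_lookup named genus-to-family vector
#'   (default [genus_family_lookup()]).
#' @return data.frame with columns `genus`, `species`, `family`
#'   (NA where unknown), one row per description.
#' @examples
#' parse_organism("Alcohol dehydrogenase OS=Komagataeibacter europaeus OX=33995")
#' @export
parse_organism <- function(description, family_lookup = NULL) {
  family_lookup <- family_lookup %||% genus_family_lookup()
  description <- as.character(description)
  n <- length(description)
  genus <- species <- rep(NA_character_, n)
  has_os <- !is.na(description) & grepl("OS=", description, fixed = TRUE)
  if (any(has_os)) {
    os <- sub(".*OS=", "", description[has_os])
    os <- sub("\\s+[A-Z]{2}=.*$", "", os)
    os <- trimws(os)
    toks <- strsplit(os, "\\s+")
    g <- vapply(toks, function(t) if (length(t) >= 1) t[[1]] else NA_character_, "")
    s2 <- vapply(toks, function(t) if (length(t) >= 2) t[[2]] else NA_character_, "")
    ok <- !is.na(g) & grepl("^[A-Z][A-Za-z-]+$", g)
    g[!ok] <- NA_character_
    # species epithets are lowercase; reject qualifiers like "(strain" tokens
    sp_ok <- ok & !is.na(s2) & grepl("^[a-z][a-z.-]*$", s2) &
      !s2 %in% c("subsp.", "str.", "var.", "pv.")
    genus[has_os] <- g
    species[has_os] <- ifelse(sp_ok, paste(g, s2), NA_character_)
  }
  family <- unname(family_lookup[genus])
  data.frame(genus = genus, species = species, family = family,
             stringsAsFactors = FALSE)
}

# --- study design --------------------------------------------------------

#' Construct and validate a study design
#'
#' @param samples data.frame with columns `sample_id`, `profile`, `phase`,
#'   `replicate`.
#' @param extra_phases additional phase labels allowed besides
#'   FL, DL, EL, UL.
#' @return data.frame of class `study_design`.
#' @export
study_design <- function(samples, extra_phases = character()) {
  req <- c("sample_id", "profile", "phase", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    abort_format(sprintf("design is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  samples <- as.data.frame(samples)[req]
  samples$sample_id <- as.character(samples$sample_id)
  samples$profile <- as.character(samples$profile)
  samples$phase <- as.character(samples$phase)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id)) {
    abort_integrity(sprintf(
      "duplicated sample_id in design: %s",
      paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", ")))
  }
  allowed <- c(PHASE_LEVELS, extra_phases)
  bad <- setdiff(unique(samples$phase), allowed)
  if (length(bad)) {
    abort_validation(sprintf(
      "unknown phase label(s) %s; allowed: %s",
      paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1)) {
    abort_validation("replicate must be a positive integer")
  }
  structure(samples, class = c("study_design", "data.frame"))
}

#' Read a study design TSV
#'
#' Expects a tab-separated file with header
#' `sample_id  profile  phase  replicate`.
#'
#' @inheritParams study_design
#' @param path TSV file.
#' @return A `study_design`.
#' @export
read_design <- function(path, extra_phases = character()) {
  if (!file.exists(path)) abort_io(sprintf("design file not found: %s", path))
  study_design(read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
               extra_phases = extra_phases)
}

# Group label per sample for a grouping scope such as c("profile","phase").
group_ids <- function(design, scope = c("profile", "phase")) {
  bad <- setdiff(scope, names(design))
  if (length(bad)) abort_validation(sprintf("unknown scope column(s): %s", paste(bad, collapse = ", ")))
  do.call(paste, c(unname(as.list(as.data.frame(design)[scope])), sep = ":"))
}

# --- GO annotations ------------------------------------------------------

#' Read a GO annotation table
#'
#' Tab-separated with header `accession  go_id  aspect`; aspect must be
#' one of `molecular_function`, `biological_process`,
#' `cellular_component`.
#'
#' @param path TSV file.
#' @return data.frame with those three character columns, duplicates
#'   removed.
#' @export
read_go_annotations <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("annotation file not found: %s", path))
  ann <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("accession", "go_id", "aspect")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    abort_format(sprintf("annotation table is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(ann$aspect), GO_ASPECTS)
  if (length(bad)) {
    abort_validation(sprintf("unknown GO aspect(s): %s; allowed: %s",
                             paste(bad, collapse = ", "),
                             paste(GO_ASPECTS, collapse = ", ")))
  }
  unique(ann[req])
}

# --- protein_table -------------------------------------------------------

#' Construct a protein table
#'
#' @param records data.frame with columns `accession`, `description`,
#'   `score`, `num_peptides`, `fdr_confidence` and (optionally) `genus`,
#'   `species`, `family`; taxonomy is parsed from `description` when
#'   absent.
#' @param abundance numeric matrix, proteins x samples, `NA` for not
#'   detected; rownames are accessions, colnames sample ids.
#' @param design a `study_design` covering exactly the abundance columns,
#'   or `NULL` for an unbound placeholder design.
#' @param provenance character vector of operations applied so far.
#' @param dialect dialect used for taxonomy lookup.
#' @return Object of class `protein_table`.
#' @export
protein_table <- function(records, abundance, design = NULL,
                          provenance = character(),
                          dialect = default_dialect()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req <- c("accession", "description", "score", "num_peptides", "fdr_confidence")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    abort_format(sprintf("records are missing column(s): %s", paste(miss, collapse = ", ")))
  }
  records$accession <- as.character(records$accession)
  if (any(!nzchar(records$accession) | is.na(records$accession))) {
    abort_integrity("empty accession in protein table")
  }
  if (anyDuplicated(records$accession)) {
    abort_integrity(sprintf(
      "duplicated accession(s): %s",
      paste(unique(records$accession[duplicated(records$accession)]), collapse = ", ")))
  }
  if (any(records$score < 0, na.rm = TRUE)) abort_integrity("negative protein score")
  if (any(records$num_peptides < 0, na.rm = TRUE)) abort_integrity("negative peptide count")
  bad_conf <- setdiff(unique(records$fdr_confidence), CONFIDENCE_LEVELS)
  if (length(bad_conf)) {
    abort_validation(sprintf("unknown FDR confidence level(s): %s",
                             paste(bad_conf, collapse = ", ")))
  }
  if (!all(c("genus", "species", "family") %in% names(records))) {
    records <- cbind(records,
                     parse_organism(records$description, dialect$family_lookup))
  }
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (nrow(abundance) != nrow(records)) {
    abort_integrity("abundance matrix and records disagree on protein count")
  }
  rownames(abundance) <- records$accession
  if (is.null(design)) {
    design <- study_design(data.frame(
      sample_id = colnames(abundance), profile = "unspecified",
      phase = "UL", replicate = seq_len(ncol(abundance)),
      stringsAsFactors = FALSE))
  }
  if (!setequal(colnames(abundance), design$sample_id)) {
    abort_integrity("abundance columns do not match the design sample set")
  }
  abundance <- abundance[, design$sample_id, drop = FALSE]
  if (any(abundance < 0, na.rm = TRUE)) abort_integrity("negative abundance value")
  structure(list(records = records, abundance = abundance, design = design,
                 provenance = provenance, normalized = FALSE),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat(sprintf("protein_table: %d proteins x %d samples (%s)\n",
              nrow(x$records), ncol(x$abundance),
              if (x$normalized) "normalized" else "raw"))
  grp <- group_ids(x$design)
  cat("groups:", paste(sprintf("%s[n=%d]", names(table(grp)), table(grp)),
                       collapse = " "), "\n")
  if (length(x$provenance)) {
    cat("provenance:\n")
    for (p in x$provenance) cat("  -", p, "\n")
  }
  invisible(x)
}

#' @export
dim.protein_table <- function(x) dim(x$abundance)

# Logical detection matrix: present and strictly positive.
detection <- function(table) {
  ab <- if (inherits(table, "protein_table")) table$abundance else table
  !is.na(ab) & ab > 0
}

# Record an operation in the provenance trail.
add_provenance <- function(table, what) {
  table$provenance <- c(table$provenance, what)
  table
}

# Subset a protein_table by a logical/row index, keeping everything in sync.
subset_records <- function(table, keep) {
  table$records <- table$records[keep, , drop = FALSE]
  rownames(table$records) <- NULL
  table$abundance <- table$abundance[keep, , drop = FALSE]
  table
}

#' Attach a study design to a table
#'
#' @param table a `protein_table`.
#' @param design a `study_design` whose sample set equals the table's
#'   abundance columns.
#' @return The table with the design bound (columns reordered to design
#'   order).
#' @export
bind_design <- function(table, design) {
  if (!setequal(colnames(table$abundance), design$sample_id)) {
    abort_integrity("design sample set does not match the table's samples")
  }
  table$design <- design
  table$abundance <- table$abundance[, design$sample_id, drop = FALSE]
  table
}

# --- table I/O -----------------------------------------------------------

#' Read a protein-group table
#'
#' Reads a tab-separated search-engine export. Column names are taken
#' from the dialect; every column whose name matches the dialect's
#' `abundance_pattern` becomes a sample, its id given by the pattern's
#' first capture group. Blank cells (and zeros, when the dialect says so)
#' become missing. Lines starting with `#` (the provenance trailer
#' written by [write_table()]) are skipped.
#'
#' @param path TSV file.
#' @param dialect an `acetoprot_dialect` ([default_dialect()]).
#' @param design optional `study_design` to bind; when `NULL` a
#'   placeholder single-group design is synthesized and should be
#'   replaced via [bind_design()] before any grouped analysis.
#' @return A `protein_table`.
#' @export
read_protein_table <- function(path, dialect = default_dialect(), design = NULL) {
  if (!file.exists(path)) abort_io(sprintf("protein table not found: %s", path))
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#", quote = "")
  mandatory <- c(accession = dialect$accession, description = dialect$description,
                 score = dialect$score, peptides = dialect$peptides,
                 confidence = dialect$confidence)
  miss <- mandatory[!mandatory %in% names(raw)]
  if (length(miss)) {
    abort_format(sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")))
  }
  ab_match <- regmatches(names(raw), regexec(dialect$abundance_pattern, names(raw)))
  is_ab <- lengths(ab_match) >= 2
  sample_ids <- vapply(ab_match[is_ab], `[[`, "", 2L)
  ab <- as.matrix(raw[, is_ab, drop = FALSE])
  storage.mode(ab) <- "double"
  colnames(ab) <- sample_ids
  if (dialect$zero_is_missing) ab[!is.na(ab) & ab == 0] <- NA_real_
  conf <- raw[[dialect$confidence]]
  if (dialect$confidence_is_numeric) {
    confn <- as.numeric(conf)
    conf <- ifelse(confn < 0.01, "high", ifelse(confn < 0.05, "medium", "low"))
  } else {
    conf <- tolower(as.character(conf))
  }
  records <- data.frame(
    accession = as.character(raw[[dialect$accession]]),
    description = as.character(raw[[dialect$description]]),
    score = as.numeric(raw[[dialect$score]]),
    num_peptides = as.integer(raw[[dialect$peptides]]),
    fdr_confidence = conf,
    stringsAsFactors = FALSE)
  protein_table(records, ab, design = design, dialect = dialect,
                provenance = sprintf("read_protein_table(%s)", basename(path)))
}

#' Write a protein table as TSV
#'
#' Writes the dialect's mandatory columns plus one `Abundance: <sample>`
#' column per sample; missing abundances become empty cells. The
#' provenance trail is written as leading `#provenance:` comment lines so
#' that `write_table` then [read_protein_table()] round-trips the data.
#'
#' @param table a `protein_table`.
#' @param path output file.
#' @param dialect dialect giving the output column names.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, dialect = default_dialect()) {
  out <- data.frame(
    table$records$accession, table$records$description,
    table$records$score, table$records$num_peptides,
    # write the categorical level capitalized, PD-style
    paste0(toupper(substring(table$records$fdr_confidence, 1, 1)),
           substring(table$records$fdr_confidence, 2)),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c(dialect$accession, dialect$description, dialect$score,
                  dialect$peptides, dialect$confidence)
  ab <- table$abundance
  abd <- as.data.frame(ab)
  names(abd) <- paste0("Abundance: ", colnames(ab))
  out <- cbind(out, abd)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in table$provenance) writeLines(paste0("#provenance: ", p), con)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""))
  invisible(path)
}

#' Write a study design TSV
#'
#' @param design a `study_design`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
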