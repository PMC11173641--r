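# End-to-end pipeline and command-line entry point. run_all() chains
# filter -> normalize -> summarize -> profiles -> diffquant -> intersect,
# writes every result with a provenance trailer, and emits a
# machine-readable run manifest. All outputs are sorted by accession (or
# the stated key), so results do not depend on input row order.

#' Validate a pipeline configuration
#'
#' @param config list (or YAML path) with input paths (`table`,
#'   `design`, optional `annotations`, `dialect`) or a `simulate`
#'   section (`seed`, plus [sim_config()] overrides), an `out_dir`, and
#'   thresholds: `min_score`, `min_peptides`, `confidence`, `combine`,
#'   `min_replicate_frac`, `main_threshold`, `k_clusters`, `alpha`,
#'   `scope`, `pi0_method`.
#' @return The completed configuration list, with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_io(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    table = NULL, design = NULL, annotations = NULL, dialect = NULL,
    simulate = NULL, out_dir = "acetoprot_out",
    min_score = 2, min_peptides = 3, confidence = "high", combine = "or",
    min_replicate_frac = 0.5, main_threshold = 1, k_clusters = 3,
    alpha = 0.05, scope = c("profile", "phase"), pi0_method = "smoother")
  config <- modifyList(defaults, config)
  config$scope <- unlist(config$scope)
  if (config$min_replicate_frac <= 0 || config$min_replicate_frac > 1) {
    abort_validation("min_replicate_frac must lie in (0, 1]")
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    abort_validation("alpha must lie in (0, 1)")
  }
  if (config$min_score < 0 || config$min_peptides < 0) {
    abort_validation("min_score and min_peptides must be non-negative")
  }
  if (config$k_clusters < 1) abort_validation("k_clusters must be >= 1")
  if (is.null(config$table) && is.null(config$simulate)) {
    abort_validation("config needs either a 'table' path or a 'simulate' section")
  }
  if (!is.null(config$table) && is.null(config$design)) {
    abort_validation("a 'design' path is required with a 'table' input")
  }
  config
}

write_tsv_provenance <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in provenance) writeLines(paste0("#provenance: ", p), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""))
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes, in order: identification filtering, replicate-presence
#' filtering, global-intensity normalization, per-sampling-time
#' summarization, taxon and GO profiling, z-scoring + Pearson-distance
#' complete-linkage clustering, per-protein ANOVA + Tukey HSD with
#' q-value correction, and intersection analysis, writing every result
#' under `out_dir`. The run is fully deterministic: for fixed inputs
#' (and, when simulating, a fixed seed) repeated runs produce
#' byte-identical outputs, and outputs are invariant to input row order.
#'
#' @param config a [pipeline_config()] list or YAML path.
#' @return Invisibly, the output directory path.
#' @export
run_all <- function(config = list()) {
  cfg <- pipeline_config(config)
  out_dir <- cfg$out_dir
  dialect <- if (is.null(cfg$dialect)) default_dialect() else read_dialect(cfg$dialect)

  # --- inputs ---
  truth <- NULL
  if (!is.null(cfg$table)) {
    design <- read_design(cfg$design)
    table <- read_protein_table(cfg$table, dialect = dialect, design = design)
  } else {
    sim_args <- cfg$simulate
    seed <- sim_args$seed %||% 1
    sim_args$seed <- NULL
    sim <- simulate_proteins(do.call(sim_config, sim_args), seed = seed)
    table <- sim$table
    truth <- sim$truth
  }
  ann <- if (!is.null(cfg$annotations)) read_go_annotations(cfg$annotations)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # row order independence: canonical accession order throughout
  ord <- order(table$records$accession)
  table <- subset_records(table, ord)

  # --- filtering ---
  f1 <- filter_identification(table, min_score = cfg$min_score,
                              min_peptides = cfg$min_peptides,
                              confidence = cfg$confidence,
                              combine = cfg$combine)
  f2 <- filter_replicate_presence(f1$table, min_frac = cfg$min_replicate_frac,
                                  scope = cfg$scope)
  filtered <- f2$table
  report <- list(identification = unclass(f1$report),
                 replicate_presence = unclass(f2$report))
  jsonlite::write_json(report, file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_table(filtered, file.path(out_dir, "filtered.tsv"), dialect = dialect)

  # --- profiling (identification counts; unaffected by normalization) ---
  for (rank in c("genus", "species")) {
    prof <- taxon_frequency(filtered, rank = rank, scope = cfg$scope,
                            min_frac = cfg$min_replicate_frac,
                            main_threshold = cfg$main_threshold)
    write_tsv_provenance(prof, file.path(out_dir, paste0("taxon_", rank, ".tsv")),
                         filtered$provenance)
  }
  if (!is.null(ann)) {
    for (aspect in GO_ASPECTS) {
      gp <- go_frequency(filtered, ann, aspect = aspect, scope = cfg$scope,
                         min_frac = cfg$min_replicate_frac)
      write_tsv_provenance(gp, file.path(out_dir, paste0("go_", aspect, ".tsv")),
                           filtered$provenance)
    }
  }

  # --- quantification ---
  normalized <- normalize_global_intensity(filtered)
  write_table(normalized, file.path(out_dir, "normalized.tsv"), dialect = dialect)
  means <- summarize_by_group(normalized, scope = cfg$scope)
  write_tsv_provenance(
    data.frame(accession = rownames(means), means, check.names = FALSE),
    file.path(out_dir, "group_means.tsv"), normalized$provenance)

  # --- clustering (rows with enough group means for Pearson distance) ---
  clusters <- NULL
  clusterable <- rowSums(!is.na(means)) >= 3
  zs <- if (sum(clusterable) >= 2) {
    suppressWarnings(zscore_rows(means[clusterable, , drop = FALSE]))
  }
  if (!is.null(zs) && nrow(zs) >= 2) {
    dend <- cluster_complete(pearson_distance(zs))
    k <- min(cfg$k_clusters, nrow(zs))
    clusters <- cut_clusters(dend, k)
    write_newick(dend, file.path(out_dir, "dendrogram.nwk"))
    write_heatmap_matrix(zs, dend, file.path(out_dir, "heatmap_matrix.tsv"))
    for (ci in sort(unique(clusters))) {
      export_accession_list(names(clusters)[clusters == ci],
                            file.path(out_dir, sprintf("accessions_cluster_%d.txt", ci)))
    }
  }

  # --- differential quantification ---
  dq <- anova_tukey(normalized, scope = cfg$scope, pi0_method = cfg$pi0_method)
  write_diffquant(dq, file.path(out_dir, "diffquant.tsv"), clusters = clusters)

  # --- intersection analysis ---
  sets <- presence_sets(filtered, scope = cfg$scope,
                        min_frac = cfg$min_replicate_frac)
  inter <- intersections(sets)
  write_tsv_provenance(inter, file.path(out_dir, "intersections.tsv"),
                       filtered$provenance)

  if (!is.null(truth)) {
    write_tsv_provenance(truth, file.path(out_dir, "truth.tsv"),
                         table$provenance)
  }

  manifest <- list(
    package = "acetoprot",
    version = as.character(utils::packageVersion("acetoprot")),
    stages = c("filter_identification", "filter_replicate_presence",
               "normalize_global_intensity", "summarize_by_group",
               "profiling", "clustering", "anova_tukey", "intersections"),
    parameters = cfg[c("min_score", "min_peptides", "confidence", "combine",
                       "min_replicate_frac", "main_threshold", "k_clusters",
                       "alpha", "scope", "pi0_method")],
    n_input = f1$report$n_input,
    n_retained = nrow(filtered$records),
    n_tested = nrow(dq$stats),
    n_significant = sum(dq$stats$q < cfg$alpha, na.rm = TRUE),
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# --- command-line interface ---------------------------------------------

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) abort_validation(sprintf("unexpected argument '%s'", a))
    key <- gsub("-", "_", substring(a, 3))
    if (i < length(args) && !startsWith(args[[i + 1]], "--")) {
      val <- args[[i + 1]]
      num <- suppressWarnings(as.numeric(val))
      flags[[key]] <- if (!is.na(num)) num else val
      i <- i + 2
    } else {
      flags[[key]] <- TRUE
      i <- i + 1
    }
  }
  flags
}

cli_read_inputs <- function(flags) {
  if (is.null(flags$table) || is.null(flags$design)) {
    abort_validation("--table and --design are required")
  }
  dialect <- if (is.null(flags$dialect)) default_dialect() else read_dialect(flags$dialect)
  design <- read_design(flags$design)
  read_protein_table(flags$table, dialect = dialect, design = design)
}

#' Command-line entry point
#'
#' Implements the `acetoprot` command with subcommands `simulate`,
#' `filter`, `normalize`, `summarize`, `profile-taxa`, `profile-go`,
#' `diffquant`, `intersect` and `run-all`, each a thin wrapper over the
#' package functions. Intended to be called from the bundled script
#' (`system.file("scripts", "acetoprot.R", package = "acetoprot")`).
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status: 0 on success, 2 for validation errors,
#'   3 for integrity errors, 4 for I/O errors, 1 otherwise.
#' @export
acetoprot_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (!length(args)) {
      abort_validation(paste(
        "usage: acetoprot <simulate|filter|normalize|summarize|profile-taxa|",
        "profile-go|diffquant|intersect|run-all> [--flags]"))
    }
    cmd <- args[[1]]
    flags <- parse_cli_flags(args[-1])
    scope <- if (!is.null(flags$scope)) strsplit(flags$scope, ",")[[1]] else c("profile", "phase")
    switch(cmd,
      "simulate" = {
        cfg <- if (!is.null(flags$config)) read_sim_config(flags$config) else sim_config()
        sim <- simulate_proteins(cfg, seed = as.integer(flags$seed %||% 1))
        write_table(sim$table, flags$out %||% "table.tsv")
        write_design(sim$table$design, flags$design_out %||% "design.tsv")
        write_tsv_provenance(sim$truth, flags$truth %||% "truth.tsv",
                             sim$table$provenance)
      },
      "filter" = {
        table <- cli_read_inputs(flags)
        f1 <- filter_identification(table,
                                    min_score = flags$min_score %||% 2,
                                    min_peptides = flags$min_peptides %||% 3,
                                    confidence = flags$confidence %||% "high")
        f2 <- filter_replicate_presence(f1$table,
                                        min_frac = flags$min_replicate_frac %||% 0.5,
                                        scope = scope)
        write_table(f2$table, flags$out %||% "filtered.tsv")
        jsonlite::write_json(
          list(identification = unclass(f1$report),
               replicate_presence = unclass(f2$report)),
          flags$report %||% "filter_report.json",
          auto_unbox = TRUE, pretty = TRUE, digits = NA)
      },
      "normalize" = {
        table <- cli_read_inputs(flags)
        write_table(normalize_global_intensity(table), flags$out %||% "normalized.tsv")
      },
      "summarize" = {
        table <- cli_read_inputs(flags)
        means <- summarize_by_group(table, scope = scope)
        write_tsv_provenance(
          data.frame(accession = rownames(means), means, check.names = FALSE),
          flags$out %||% "group_means.tsv", table$provenance)
      },
      "profile-taxa" = {
        table <- cli_read_inputs(flags)
        prof <- taxon_frequency(table, rank = flags$rank %||% "genus",
                                scope = scope,
                                main_threshold = flags$main_threshold)
        write_tsv_provenance(prof, flags$out %||% "taxon_profile.tsv",
                             table$provenance)
      },
      "profile-go" = {
        if (is.null(flags$annotations)) abort_validation("--annotations is required")
        table <- cli_read_inputs(flags)
        ann <- read_go_annotations(flags$annotations)
        gp <- go_frequency(table, ann,
                           aspect = flags$aspect %||% "biological_process",
                           scope = scope)
        write_tsv_provenance(gp, flags$out %||% "go_profile.tsv", table$provenance)
      },
      "diffquant" = {
        table <- cli_read_inputs(flags)
        table <- normalize_global_intensity(table)
        means <- summarize_by_group(table, scope = scope)
        clusterable <- rowSums(!is.na(means)) >= 3
        clusters <- NULL
        if (sum(clusterable) >= 2) {
          zs <- suppressWarnings(zscore_rows(means[clusterable, , drop = FALSE]))
          dend <- cluster_complete(pearson_distance(zs))
          clusters <- cut_clusters(dend, min(flags$clusters %||% 3, nrow(zs)))
          write_newick(dend, file.path(dirname(flags$out %||% "."), "dendrogram.nwk"))
        }
        dq <- anova_tukey(table, scope = scope)
        write_diffquant(dq, flags$out %||% "diffquant.tsv", clusters = clusters)
      },
      "intersect" = {
        table <- cli_read_inputs(flags)
        sets <- presence_sets(table, scope = scope,
                              min_frac = flags$min_replicate_frac %||% 0.5)
        write_tsv_provenance(intersections(sets),
                             flags$out %||% "intersections.tsv", table$provenance)
      },
      "run-all" = {
        cfg <- if (!is.null(flags$config)) flags$config else {
          c(flags[intersect(names(flags),
                            c("table", "design", "annotations", "dialect",
                              "out_dir", "min_score", "min_peptides",
                              "min_replicate_frac", "k_clusters", "alpha"))],
            if (is.null(flags$table)) list(simulate = list(seed = as.integer(flags$seed %||% 1))))
        }
        run_all(cfg)
      },
      abort_validation(sprintf("unknown subcommand '%s'", cmd))
    )
    0L
  }
  tryCatch(run(),
    acetoprot_validation_error = function(e) { message("validation error: ", conditionMessage(e)); 2L },
    acetoprot_integrity_error = function(e) { message("integrity error: ", conditionMessage(e)); 3L },
    acetoprot_io_error = function(e) { message("i/o error: ", conditionMessage(e)); 4L },
    error = function(e) { message("error: ", conditionMessage(e)); 1L })
}
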