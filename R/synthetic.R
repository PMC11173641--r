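# Synthetic protein-group tables with planted ground truth. The
# generator emulates the statistical structure of label-free LC-MS/MS
# protein-group exports from a semicontinuous acetification profile:
# a handful of Acetobacteraceae taxa dominated by one species,
# log-normal abundances, phase-specific multiplicative effects for a
# planted differential fraction organized in quantification-pattern
# clusters, intensity-dependent (MNAR) missingness, and a planted
# fraction of low-quality identifications.

default_taxa <- function() {
  # genus weights 0.90 / 0.05 / 0.03 / 0.02, one dominant species at 0.75
  data.frame(
    genus = c("Komagataeibacter", "Komagataeibacter", "Komagataeibacter",
              "Acetobacter", "Gluconacetobacter", "Gluconobacter"),
    species = c("Komagataeibacter europaeus", "Komagataeibacter intermedius",
                "Komagataeibacter xylinus", "Acetobacter pasteurianus",
                "Gluconacetobacter entanii", "Gluconobacter oxydans"),
    weight = c(0.75, 0.08, 0.07, 0.05, 0.03, 0.02),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the study conditions a simulated protein-group table
#' emulates. Defaults follow a three-phase semicontinuous acetification
#' design (FL, DL, UL) with 3 biological replicates per sampling time,
#' a multi-genus Acetobacteraceae community dominated by one species,
#' log-normal abundances, planted differential clusters (one per phase,
#' each up-regulated in its phase), logistic intensity-dependent
#' missingness, and a planted fraction of low-quality identifications.
#'
#' @param n_proteins number of protein groups.
#' @param taxa data.frame (`genus`, `species`, `weight`); weights must
#'   sum to 1.
#' @param profile profile label used in sample ids.
#' @param phases sampling-time phase labels.
#' @param replicates replicates per phase (scalar or one per phase).
#' @param meanlog_mean,meanlog_sd between-protein distribution of the
#'   log-scale baseline abundance (natural log).
#' @param sdlog replicate-to-replicate log-scale noise.
#' @param differential_fraction fraction of proteins with a planted
#'   phase effect.
#' @param effect_size multiplicative up-shift of a differential protein
#'   in its cluster's phase.
#' @param n_clusters number of planted quantification-pattern clusters
#'   (assigned to phases cyclically).
#' @param missingness `"mnar"` (logistic in log-abundance, default),
#'   `"mcar"`, or `"none"`.
#' @param detect_mid,detect_scale logistic detection-curve midpoint and
#'   scale on the natural-log abundance axis.
#' @param mcar_rate missing rate when `missingness = "mcar"`.
#' @param low_quality_fraction fraction of records planted to fail the
#'   identification filter (low confidence, score below 2, or a peptide
#'   number of at most 2).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 300,
                       taxa = default_taxa(),
                       profile = "SY",
                       phases = c("FL", "DL", "UL"),
                       replicates = 3,
                       meanlog_mean = 15, meanlog_sd = 2,
                       sdlog = 0.25,
                       differential_fraction = 0.15,
                       effect_size = 2,
                       n_clusters = 3,
                       missingness = c("mnar", "mcar", "none"),
                       detect_mid = 12, detect_scale = 1,
                       mcar_rate = 0.1,
                       low_quality_fraction = 0.1) {
  missingness <- match.arg(missingness)
  if (abs(sum(taxa$weight) - 1) > 1e-9) {
    abort_validation("taxa weights must sum to 1")
  }
  if (any(taxa$weight < 0)) abort_validation("taxa weights must be non-negative")
  if (n_proteins < 1) abort_validation("n_proteins must be positive")
  if (length(replicates) == 1) replicates <- rep(replicates, length(phases))
  if (length(replicates) != length(phases) || any(replicates < 2)) {
    abort_validation("need >= 2 replicates for each phase")
  }
  if (differential_fraction < 0 || differential_fraction > 1 ||
      low_quality_fraction < 0 || low_quality_fraction > 1) {
    abort_validation("fractions must lie in [0, 1]")
  }
  structure(list(
    n_proteins = n_proteins, taxa = taxa, profile = profile,
    phases = phases, replicates = replicates,
    meanlog_mean = meanlog_mean, meanlog_sd = meanlog_sd, sdlog = sdlog,
    differential_fraction = differential_fraction,
    effect_size = effect_size, n_clusters = n_clusters,
    missingness = missingness, detect_mid = detect_mid,
    detect_scale = detect_scale, mcar_rate = mcar_rate,
    low_quality_fraction = low_quality_fraction), class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()]; `taxa` may be a list of
#' `{genus, species, weight}` records.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("sim config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  for (nm in c("phases", "replicates")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  if (!is.null(cfg$taxa)) {
    cfg$taxa <- do.call(rbind, lapply(cfg$taxa, function(t) {
      data.frame(genus = t$genus, species = t$species, weight = t$weight,
                 stringsAsFactors = FALSE)
    }))
  }
  do.call(sim_config, cfg)
}

#' Simulate a protein-group table with ground truth
#'
#' Draws a protein-group table under the configured study conditions and
#' returns it together with the planted ground truth needed to score
#' every pipeline stage: taxon assignment, true phase multipliers,
#' differential flag and planted cluster, and whether each record was
#' planted to fail the identification filter.
#'
#' @param config a [sim_config()].
#' @param seed integer random seed; a fixed seed gives byte-identical
#'   output.
#' @return list with `table` (a `protein_table`) and `truth`
#'   (data.frame, one row per protein).
#' @export
simulate_proteins <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_proteins
  phases <- config$phases
  acc <- sprintf("P%05d", seq_len(n))

  # design
  design <- study_design(do.call(rbind, lapply(seq_along(phases), function(p) {
    data.frame(sample_id = sprintf("%s_%s_%d", config$profile, phases[p],
                                   seq_len(config$replicates[p])),
               profile = config$profile, phase = phases[p],
               replicate = seq_len(config$replicates[p]),
               stringsAsFactors = FALSE)
  })))

  # taxonomy
  ti <- sample.int(nrow(config$taxa), n, replace = TRUE,
                   prob = config$taxa$weight)
  genus <- config$taxa$genus[ti]
  species <- config$taxa$species[ti]

  # differential structure: clusters assigned to phases cyclically
  n_diff <- round(config$differential_fraction * n)
  differential <- c(rep(TRUE, n_diff), rep(FALSE, n - n_diff))
  cluster <- integer(n)
  if (n_diff > 0) {
    cluster[seq_len(n_diff)] <- rep_len(seq_len(config$n_clusters), n_diff)
  }
  up_phase <- ifelse(cluster > 0,
                     phases[(cluster - 1) %% length(phases) + 1], NA)
  log_mult <- matrix(0, n, length(phases), dimnames = list(acc, phases))
  for (p in seq_along(phases)) {
    log_mult[, p] <- ifelse(!is.na(up_phase) & up_phase == phases[p],
                            log(config$effect_size), 0)
  }

  # abundances
  baseline <- rnorm(n, config$meanlog_mean, config$meanlog_sd)
  phase_of <- match(design$phase, phases)
  loga <- matrix(rnorm(n * nrow(design),
                       mean = baseline + log_mult[, phase_of],
                       sd = config$sdlog),
                 nrow = n, dimnames = list(acc, design$sample_id))
  ab <- exp(loga)

  # missingness
  if (config$missingness == "mnar") {
    p_det <- plogis((loga - config$detect_mid) / config$detect_scale)
    ab[runif(length(ab)) > p_det] <- NA_real_
  } else if (config$missingness == "mcar") {
    ab[runif(length(ab)) < config$mcar_rate] <- NA_real_
  }

  # identification quality
  n_low <- round(config$low_quality_fraction * n)
  low_quality <- rep(FALSE, n)
  if (n_low > 0) low_quality[sample.int(n, n_low)] <- TRUE
  score <- 2 + rexp(n, rate = 1 / 8)
  peptides <- 3L + rpois(n, 6)
  confidence <- rep("high", n)
  defect <- sample.int(3, n, replace = TRUE)
  score[low_quality & defect == 1] <- runif(sum(low_quality & defect == 1), 0, 1.9)
  peptides[low_quality & defect == 2] <- sample(1:2, sum(low_quality & defect == 2),
                                                replace = TRUE)
  confidence[low_quality & defect == 3] <-
    sample(c("medium", "low"), sum(low_quality & defect == 3), replace = TRUE)

  records <- data.frame(
    accession = acc,
    description = sprintf("Simulated protein %d OS=%s OX=0", seq_len(n), species),
    score = score, num_peptides = peptides, fdr_confidence = confidence,
    stringsAsFactors = FALSE)
  table <- protein_table(records, ab, design = design,
                         provenance = sprintf("simulate_proteins(seed=%d)", seed))

  truth <- data.frame(
    accession = acc, genus = genus, species = species,
    baseline_meanlog = baseline, differential = differential,
    cluster = cluster, up_phase = up_phase, low_quality = low_quality,
    pass_identification = !low_quality, stringsAsFactors = FALSE)
  for (p in phases) truth[[paste0("mult_", p)]] <- exp(log_mult[, p])

  list(table = table, truth = truth)
}

#' Score pipeline output against planted ground truth
#'
#' Compares pipeline results with the ground truth of
#' [simulate_proteins()]: maximum absolute deviation (percentage
#' points) of recovered taxon frequencies from the planted per-table
#' multinomial count frequencies; sensitivity and observed false
#' discovery proportion of the differential-protein calls at
#' `q < q_threshold`; and the adjusted Rand index between planted and
#' recovered cluster assignments.
#'
#' @param truth ground-truth data.frame from [simulate_proteins()].
#' @param taxon_profile optional `taxon_profile` (global scope, genus
#'   rank) to score.
#' @param taxon_accessions accessions the profile was computed over
#'   (defaults to all of `truth`); the planted frequencies are the
#'   multinomial count frequencies over this set.
#' @param diffquant optional `diffquant_result` to score.
#' @param clusters optional named cluster assignment (from
#'   [cut_clusters()]) to score against planted clusters.
#' @param q_threshold significance threshold on q-values.
#' @return list of class `recovery_report` with any of
#'   `taxon_max_abs_dev`, `sensitivity`, `fdp`, `ari`.
#' @export
recovery_report <- function(truth, taxon_profile = NULL,
                            taxon_accessions = NULL, diffquant = NULL,
                            clusters = NULL, q_threshold = 0.05) {
  out <- list()
  if (!is.null(taxon_profile)) {
    scored <- taxon_profile[taxon_profile$taxon != "unassigned", , drop = FALSE]
    if (any(!scored$taxon %in% truth$genus)) {
      abort_integrity("taxon profile contains taxa absent from the ground truth")
    }
    taxon_accessions <- taxon_accessions %||% truth$accession
    if (any(!taxon_accessions %in% truth$accession)) {
      abort_integrity("profiled accessions absent from the ground truth")
    }
    planted <- base::table(truth$genus[truth$accession %in% taxon_accessions])
    all_g <- union(names(planted), scored$taxon)
    planted_freq <- setNames(rep(0, length(all_g)), all_g)
    planted_freq[names(planted)] <- 100 * as.numeric(planted) / sum(planted)
    obs <- setNames(rep(0, length(all_g)), all_g)
    obs[scored$taxon] <- scored$frequency
    out$taxon_max_abs_dev <- max(abs(obs - planted_freq))
  }
  if (!is.null(diffquant)) {
    st <- diffquant$stats
    if (any(!st$accession %in% truth$accession)) {
      abort_integrity("diffquant result contains unknown accessions")
    }
    is_diff <- truth$differential[match(st$accession, truth$accession)]
    called <- st$q < q_threshold
    n_called <- sum(called)
    out$sensitivity <- if (any(is_diff)) sum(called & is_diff) / sum(is_diff) else NA_real_
    out$fdp <- if (n_called > 0) sum(called & !is_diff) / n_called else 0
    out$n_called <- n_called
  }
  if (!is.null(clusters)) {
    idx <- match(names(clusters), truth$accession)
    if (anyNA(idx)) abort_integrity("cluster assignment contains unknown accessions")
    planted <- truth$cluster[idx]
    keep <- planted > 0
    out$ari <- mclust::adjustedRandIndex(planted[keep], clusters[keep])
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report:\n")
  for (nm in names(x)) cat(sprintf("  %s: %.4g\n", nm, x[[nm]]))
  invisible(x)
}
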