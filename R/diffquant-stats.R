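# Per-protein differential quantification: one-way ANOVA across sample
# groups on normalized replicate-level abundances, Tukey HSD post-hoc
# comparisons (Tukey-Kramer standard errors for unequal group sizes),
# and q-value multiple-testing correction. Intensities are log-
# transformed before model fitting by default: label-free LC-MS/MS
# abundances are approximately log-normal, and the linear model's
# equal-variance normal-error assumptions hold on the log scale.

#' Per-protein one-way ANOVA with Tukey HSD
#'
#' For every protein with at least `min_groups` groups each holding at
#' least `min_reps` detected replicates, fits a one-way ANOVA of
#' (normalized) abundance on the sampling-time group and computes all
#' pairwise Tukey HSD comparisons via the studentized-range
#' distribution. Proteins failing the testability requirement are
#' reported in `untestable`, not tested. p-values are corrected across
#' proteins with [qvalues()].
#'
#' By default the model is fitted to natural-log intensities, the
#' standard variance-stabilizing choice for label-free quantification
#' (Tukey mean differences are then log fold changes);
#' `log_transform = FALSE` fits the raw scale.
#'
#' @param x a `protein_table` (normalized) or abundance matrix.
#' @param design required when `x` is a matrix.
#' @param scope design columns defining the groups.
#' @param min_reps minimum detected replicates per group (default 2).
#' @param min_groups minimum number of qualifying groups (default 2).
#' @param log_transform fit log-scale intensities (default `TRUE`).
#' @param pi0_method passed to [qvalues()].
#' @return Object of class `diffquant_result`: list with `stats`
#'   (data.frame accession, df1, df2, F, p, q), `tukey` (data.frame
#'   accession, pair, diff, p_adj) and `untestable` (accessions).
#' @export
anova_tukey <- function(x, design = NULL, scope = c("profile", "phase"),
                        min_reps = 2, min_groups = 2, log_transform = TRUE,
                        pi0_method = c("smoother", "fixed")) {
  pi0_method <- match.arg(pi0_method)
  if (inherits(x, "protein_table")) {
    design <- x$design
    x <- x$abundance
  }
  if (is.null(design)) abort_validation("a design is required to group samples")
  grp <- group_ids(design, scope)
  acc <- rownames(x) %||% as.character(seq_len(nrow(x)))
  stats_rows <- vector("list", nrow(x))
  tukey_rows <- vector("list", nrow(x))
  untestable <- character()
  for (i in seq_len(nrow(x))) {
    y <- x[i, ]
    ok <- !is.na(y) & y > 0
    g_tab <- base::table(grp[ok])
    g_use <- names(g_tab)[g_tab >= min_reps]
    use <- ok & grp %in% g_use
    if (length(g_use) < min_groups) {
      untestable <- c(untestable, acc[i])
      next
    }
    dat <- data.frame(y = if (log_transform) log(y[use]) else y[use],
                      g = factor(grp[use]))
    fit <- aov(y ~ g, data = dat)
    an <- anova(fit)
    tk <- suppressWarnings(TukeyHSD(fit))$g
    stats_rows[[i]] <- data.frame(
      accession = acc[i], df1 = an$Df[1], df2 = an$Df[2],
      F = an$`F value`[1], p = an$`Pr(>F)`[1], stringsAsFactors = FALSE)
    tukey_rows[[i]] <- data.frame(
      accession = acc[i], pair = rownames(tk), diff = tk[, "diff"],
      p_adj = tk[, "p adj"], stringsAsFactors = FALSE, row.names = NULL)
  }
  st <- do.call(rbind, stats_rows)
  if (is.null(st)) {
    return(structure(list(
      stats = data.frame(accession = character(), df1 = integer(),
                         df2 = integer(), F = numeric(), p = numeric(),
                         q = numeric(), stringsAsFactors = FALSE),
      tukey = data.frame(accession = character(), pair = character(),
                         diff = numeric(), p_adj = numeric(),
                         stringsAsFactors = FALSE),
      untestable = untestable), class = "diffquant_result"))
  }
  rownames(st) <- NULL
  st$q <- qvalues(st$p, pi0_method = pi0_method)
  structure(list(stats = st, tukey = do.call(rbind, tukey_rows),
                 untestable = untestable),
            class = "diffquant_result")
}

#' @export
print.diffquant_result <- function(x, ...) {
  cat(sprintf("diffquant_result: %d proteins tested, %d untestable\n",
              nrow(x$stats), length(x$untestable)))
  if (nrow(x$stats)) {
    cat(sprintf("  q < 0.05: %d proteins\n", sum(x$stats$q < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}

#' q-value multiple-testing correction
#'
#' Storey's q-values: the proportion of true nulls pi0 is estimated by
#' the smoother method (a cubic smoothing spline through
#' pi0(lambda) = mean(p > lambda) / (1 - lambda) over
#' lambda = 0.05, 0.10, ..., 0.95, evaluated at the largest lambda),
#' and q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j), clipped
#' at 1. With fewer than 100 tests the pi0 estimate is unstable, so pi0
#' is fixed at 1 and the result equals Benjamini-Hochberg adjusted
#' p-values; `pi0_method = "fixed"` forces that behaviour at any m.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param pi0_method `"smoother"` (default) or `"fixed"` (pi0 = 1).
#' @param lambda grid for the smoother estimate.
#' @return Numeric vector of q-values, monotone in p-value rank.
#' @export
qvalues <- function(p, pi0_method = c("smoother", "fixed"),
                    lambda = seq(0.05, 0.95, by = 0.05)) {
  pi0_method <- match.arg(pi0_method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (!m) return(numeric())
  if (pi0_method == "fixed" || m < 100) {
    pi0 <- 1
  } else {
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- smooth.spline(lambda, pi0_lambda, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
    pi0 <- min(pi0, 1)
    if (pi0 <= 0) {
      warning("pi0 estimate <= 0; falling back to pi0 = 1")
      pi0 <- 1
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))[ro]
  attr(q, "pi0") <- pi0
  q
}

#' Exact-combination intersection analysis
#'
#' UpSet-style intersection counts: every element of the union is
#' attributed to exactly one membership combination (the full set of
#' groups containing it), unlike cumulative Venn overlaps. Combination
#' counts therefore sum to the union size.
#'
#' @param sets named list of character vectors (e.g. from
#'   [presence_sets()]).
#' @return data.frame of class `intersection_summary` with columns
#'   `combination` (group names joined by `&`), `degree`, `count`,
#'   sorted by descending count then combination.
#' @export
intersections <- function(sets) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort_validation("intersections requires a non-empty named list of sets")
  }
  elements <- sort(unique(unlist(sets)))
  if (!length(elements)) {
    return(structure(data.frame(combination = character(), degree = integer(),
                                count = integer(), stringsAsFactors = FALSE),
                     class = c("intersection_summary", "data.frame"),
                     n_union = 0L))
  }
  member <- vapply(sets, function(s) elements %in% s,
                   logical(length(elements)))
  member <- matrix(member, nrow = length(elements),
                   dimnames = list(elements, names(sets)))
  combo <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  tab <- base::table(combo)
  res <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  res <- res[order(-res$count, res$combination), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("intersection_summary", "data.frame"),
            n_union = length(elements))
}

#' Write a differential-quantification result as TSV
#'
#' Writes the per-protein statistics with Tukey comparisons spread to
#' wide columns (`diff <pair>`, `p_adj <pair>`), sorted by accession.
#'
#' @param result a `diffquant_result`.
#' @param path output file.
#' @param clusters optional named cluster assignment to join in.
#' @return `path`, invisibly.
#' @export
write_diffquant <- function(result, path, clusters = NULL) {
  st <- result$stats[order(result$stats$accession), , drop = FALSE]
  if (!is.null(clusters)) {
    st$cluster <- unname(clusters[st$accession])
  }
  if (nrow(result$tukey)) {
    for (pr in sort(unique(result$tukey$pair))) {
      sub <- result$tukey[result$tukey$pair == pr, ]
      st[[paste0("diff ", pr)]] <- sub$diff[match(st$accession, sub$accession)]
      st[[paste0("p_adj ", pr)]] <- sub$p_adj[match(st$accession, sub$accession)]
    }
  }
  write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
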