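# Fixture builders and independent brute-force oracles shared across the
# suite. Oracles deliberately use naive per-element loops so they stay
# independent of the vectorized implementation paths they check.

make_design <- function(profile = "SY", phases = c("FL", "DL", "UL"),
                        reps = 3) {
  if (length(reps) == 1) reps <- rep(reps, length(phases))
  study_design(do.call(rbind, Map(function(ph, r) {
    data.frame(sample_id = sprintf("%s_%s_%d", profile, ph, seq_len(r)),
               profile = profile, phase = ph, replicate = seq_len(r),
               stringsAsFactors = FALSE)
  }, phases, reps)))
}

make_table <- function(abundance, design,
                       score = NULL, peptides = NULL, confidence = NULL,
                       description = NULL) {
  n <- nrow(abundance)
  acc <- rownames(abundance) %||% sprintf("P%03d", seq_len(n))
  rownames(abundance) <- acc
  protein_table(
    data.frame(
      accession = acc,
      description = description %||%
        rep("Test protein OS=Komagataeibacter europaeus OX=33995", n),
      score = score %||% rep(10, n),
      num_peptides = peptides %||% rep(5L, n),
      fdr_confidence = confidence %||% rep("high", n),
      stringsAsFactors = FALSE),
    abundance, design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random table with mixed identification quality and missingness
random_table <- function(n_proteins, design, p_missing = 0.25) {
  m <- length(design$sample_id)
  ab <- matrix(runif(n_proteins * m, 1, 100), n_proteins,
               dimnames = list(sprintf("P%03d", seq_len(n_proteins)),
                               design$sample_id))
  ab[runif(n_proteins * m) < p_missing] <- NA_real_
  make_table(ab, design,
             score = runif(n_proteins, 0, 10),
             peptides = sample(1:10, n_proteins, replace = TRUE),
             confidence = sample(c("high", "medium", "low"), n_proteins,
                                 replace = TRUE, prob = c(0.7, 0.2, 0.1)))
}

# --- naive filtering oracles (per-protein loops) ------------------------

oracle_identification <- function(table, min_score = 2, min_peptides = 3) {
  keep <- character()
  for (i in seq_len(nrow(table$records))) {
    r <- table$records[i, ]
    if (r$fdr_confidence == "high" && r$score >= min_score &&
        r$num_peptides >= min_peptides) {
      keep <- c(keep, r$accession)
    }
  }
  keep
}

oracle_group_samples <- function(design, scope = c("profile", "phase")) {
  lab <- apply(as.data.frame(design)[scope], 1, paste, collapse = ":")
  split(design$sample_id, lab)
}

oracle_detected <- function(table, acc, sample) {
  v <- table$abundance[acc, sample]
  !is.na(v) && v > 0
}

oracle_presence_retained <- function(table, min_frac = 0.5,
                                     scope = c("profile", "phase")) {
  groups <- oracle_group_samples(table$design, scope)
  keep <- character()
  for (acc in table$records$accession) {
    for (g in groups) {
      n_det <- 0
      for (s in g) if (oracle_detected(table, acc, s)) n_det <- n_det + 1
      if (n_det / length(g) >= min_frac) {
        keep <- c(keep, acc)
        break
      }
    }
  }
  keep
}

oracle_presence_sets <- function(table, min_frac = 0.5,
                                 scope = c("profile", "phase")) {
  groups <- oracle_group_samples(table$design, scope)
  lapply(groups, function(g) {
    out <- character()
    for (acc in table$records$accession) {
      n_det <- sum(vapply(g, function(s) oracle_detected(table, acc, s), TRUE))
      if (n_det / length(g) >= min_frac) out <- c(out, acc)
    }
    out
  })
}

oracle_exclusive <- function(table, samples_a, samples_b, min_frac = 0.5) {
  ex_a <- ex_b <- character()
  for (acc in table$records$accession) {
    da <- sum(vapply(samples_a, function(s) oracle_detected(table, acc, s), TRUE))
    db <- sum(vapply(samples_b, function(s) oracle_detected(table, acc, s), TRUE))
    if (da / length(samples_a) >= min_frac && db == 0) ex_a <- c(ex_a, acc)
    if (db / length(samples_b) >= min_frac && da == 0) ex_b <- c(ex_b, acc)
  }
  list(exclusive_a = ex_a, exclusive_b = ex_b)
}

# --- naive complete-linkage oracle --------------------------------------
# Recomputes every inter-cluster distance as the max over the ORIGINAL
# distance matrix (no Lance-Williams update), with the shared tie-break:
# smallest (lexicographic) pair of smallest member indices.

oracle_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- vector("list", n)
  assign_of <- function(cl) {
    a <- integer(n)
    ord <- order(vapply(cl, min, 0))
    for (ci in seq_along(ord)) a[cl[[ord[ci]]]] <- ci
    a
  }
  partitions[[n]] <- assign_of(clusters)
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf; best_key <- c(Inf, Inf)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d <- max(D[clusters[[a]], clusters[[b]]])
        key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        if (d < best_d ||
            (d == best_d && (key[1] < best_key[1] ||
                             (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best <- c(a, b); best_d <- d; best_key <- key
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    partitions[[length(clusters)]] <- assign_of(clusters)
  }
  list(heights = heights, partitions = partitions)
}

# --- textbook one-way ANOVA + Tukey-Kramer oracle -----------------------

oracle_anova_tukey <- function(groups) {
  y <- unlist(groups)
  idx <- rep(seq_along(groups), lengths(groups))
  ni <- unname(lengths(groups))
  k <- length(groups)
  N <- sum(ni)
  mi <- unname(vapply(groups, mean, 0))
  gm <- mean(y)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((y - mi[idx])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  Fv <- msb / msw
  p <- stats::pf(Fv, k - 1, N - k, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  tukey <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(msw / 2 * (1 / ni[i] + 1 / ni[j]))
    qstat <- abs(mi[j] - mi[i]) / se
    c(diff = mi[j] - mi[i],
      p_adj = stats::ptukey(qstat, k, N - k, lower.tail = FALSE))
  })
  list(F = Fv, p = p, df1 = k - 1, df2 = N - k, tukey = t(tukey))
}
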