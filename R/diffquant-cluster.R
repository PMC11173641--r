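# Quantitative pattern analysis: z-score scaling of per-sampling-time
# mean quantification values, 1 - Pearson correlation distances, and
# complete-linkage agglomerative clustering with a deterministic
# tie-break. The agglomeration is implemented here (rather than wrapping
# stats::hclust) so that the tie-break rule is explicit and testable;
# stats::hclust serves as an independent cross-check in the test suite.

#' Row-wise z-score transformation
#'
#' Scales and centers each row to mean 0 and unit standard deviation
#' (denominator n - 1), the usual preparation of mean quantification
#' values for correlation-based clustering. Rows with fewer than two
#' non-missing values or zero variance cannot be scaled; they are
#' dropped, reported in the `dropped` attribute, and flagged with a
#' warning.
#'
#' @param x numeric matrix (proteins x groups), `NA` allowed.
#' @return The scaled matrix with attribute `dropped` (character vector
#'   of dropped row names).
#' @export
zscore_rows <- function(x) {
  x <- as.matrix(x)
  n_ok <- rowSums(!is.na(x))
  sds <- apply(x, 1, sd, na.rm = TRUE)
  bad <- n_ok < 2 | is.na(sds) | sds == 0
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with < 2 values or zero variance", sum(bad)))
  }
  out <- x[!bad, , drop = FALSE]
  out <- (out - rowMeans(out, na.rm = TRUE)) / apply(out, 1, sd, na.rm = TRUE)
  attr(out, "dropped") <- rownames(x)[bad] %||% character()
  out
}

#' Pearson correlation distance between rows
#'
#' d(i, j) = 1 - r(i, j) with r the Pearson correlation over
#' pairwise-complete columns, giving distances in \[0, 2\] (0 for
#' identical profiles, 2 for perfectly anti-correlated ones).
#'
#' @param x numeric matrix (proteins x groups); every row pair must
#'   share at least 2 columns with finite values in both rows.
#' @return A `stats::dist` object over the rows of `x`.
#' @export
pearson_distance <- function(x) {
  x <- as.matrix(x)
  obs <- !is.na(x)
  shared <- tcrossprod(obs * 1)
  diag(shared) <- NA
  if (any(shared < 2, na.rm = TRUE)) {
    idx <- which(shared < 2, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pairs <- apply(idx, 1, function(ij) {
      paste(rownames(x)[ij] %||% ij, collapse = " / ")
    })
    abort_validation(sprintf(
      "row pair(s) share fewer than 2 columns: %s",
      paste(utils::head(pairs, 5), collapse = "; ")))
  }
  r <- suppressWarnings(cor(t(x), use = "pairwise.complete.obs"))
  if (anyNA(r)) abort_validation("undefined correlation (constant row over shared columns)")
  d <- 1 - r
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  as.dist(d)
}

# Internal: complete-linkage agglomeration over a full distance matrix.
# Tie-break: among cluster pairs at the minimal linkage distance, merge
# the pair whose (smallest member, other cluster's smallest member)
# index pair is lexicographically smallest.
complete_linkage_engine <- function(D, labels) {
  n <- nrow(D)
  members <- as.list(seq_len(n))    # original observation indices
  minmem <- seq_len(n)              # smallest member per active cluster
  node <- -seq_len(n)               # hclust coding: -obs or +merge step
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    best_key <- c(Inf, Inf)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        dij <- D[i, j]
        key <- sort(c(minmem[i], minmem[j]))
        better <- dij < best_d ||
          (dij == best_d && (key[1] < best_key[1] ||
                             (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) {
          best <- c(i, j); best_d <- dij; best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    # hclust convention: singletons (negative) before merged nodes, else
    # ascending
    ni <- node[i]; nj <- node[j]
    pair <- sort(c(ni, nj))
    merge[step, ] <- pair
    height[step] <- best_d
    # complete linkage update into slot i
    newd <- pmax(D[i, ], D[j, ])
    D[i, ] <- newd
    D[, i] <- newd
    D[i, i] <- 0
    members[[i]] <- c(members[[i]], members[[j]])
    minmem[i] <- min(minmem[i], minmem[j])
    node[i] <- step
    active[j] <- FALSE
  }
  list(merge = merge, height = height)
}

# Leaf order for plotting, built by walking the merge tree (left subtree
# before right), as stats::hclust does.
merge_order <- function(merge) {
  n <- nrow(merge) + 1
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerates the observations of a distance matrix by repeatedly
#' merging the two clusters with the smallest maximum inter-point
#' distance (complete linkage, whose merge heights are non-decreasing).
#' Ties are broken deterministically by the lexicographically smallest
#' pair of smallest member indices. The result converts to a standard
#' `hclust` object via [as.hclust()].
#'
#' @param d a `stats::dist` object or symmetric distance matrix.
#' @return Object of class `protein_dendrogram` with elements `merge`,
#'   `height`, `order`, `labels`.
#' @export
cluster_complete <- function(d) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12)) {
    abort_validation("distance matrix must be symmetric")
  }
  n <- nrow(D)
  if (n < 2) abort_validation("need at least 2 observations to cluster")
  labels <- rownames(D) %||% as.character(seq_len(n))
  eng <- complete_linkage_engine(D, labels)
  structure(list(merge = eng$merge, height = eng$height,
                 order = merge_order(eng$merge), labels = labels,
                 method = "complete", dist.method = "pearson"),
            class = "protein_dendrogram")
}

#' @export
as.hclust.protein_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = x$dist.method),
            class = "hclust")
}

#' @export
print.protein_dendrogram <- function(x, ...) {
  cat(sprintf("protein_dendrogram: %d leaves, complete linkage, max height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k - 1 merges of the agglomeration, yielding a
#' k-cluster partition. Clusters are numbered 1..k in order of their
#' smallest member index (the numbering `stats::cutree` uses).
#'
#' @param dendrogram a `protein_dendrogram`.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return Named integer vector of cluster assignments.
#' @export
cut_clusters <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k)) {
    abort_validation(sprintf("k must be an integer in [1, %d]", n))
  }
  assign <- seq_len(n)
  if (k < n) {
    node_cluster <- integer(n - 1)       # cluster id carried by merge node
    for (step in seq_len(n - k)) {
      m <- dendrogram$merge[step, ]
      ids <- vapply(1:2, function(t) {
        if (m[t] < 0) assign[-m[t]] else node_cluster[m[t]]
      }, integer(1))
      keep <- min(ids)
      assign[assign %in% ids] <- keep
      node_cluster[step] <- keep
    }
  }
  # renumber 1..k by smallest member index
  out <- match(assign, sort(unique(assign)))
  names(out) <- dendrogram$labels
  out
}

#' Write a dendrogram as Newick text
#'
#' @param dendrogram a `protein_dendrogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(as.hclust(dendrogram))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write the heat-map matrix in dendrogram leaf order
#'
#' Exports the (z-scored) matrix underlying a heat map with rows ordered
#' exactly as the dendrogram leaves, so no downstream reordering occurs.
#'
#' @param x numeric matrix whose rownames are the dendrogram labels.
#' @param dendrogram a `protein_dendrogram` over the rows of `x`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_heatmap_matrix <- function(x, dendrogram, path) {
  ord <- dendrogram$labels[dendrogram$order]
  if (!all(ord %in% rownames(x))) {
    abort_integrity("dendrogram labels are not all rows of the matrix")
  }
  out <- data.frame(accession = ord, x[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heat map of clustered quantification patterns
#'
#' Convenience wrapper around `pheatmap` using this package's dendrogram
#' for the row tree (columns stay in design order).
#'
#' @param x z-scored matrix.
#' @param dendrogram a `protein_dendrogram` over the rows of `x`.
#' @param ... passed to `pheatmap::pheatmap`.
#' @return The pheatmap object, invisibly.
#' @export
plot_heatmap <- function(x, dendrogram, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    abort_validation("plot_heatmap requires the pheatmap package")
  }
  ph <- pheatmap::pheatmap(x, cluster_rows = as.hclust(dendrogram),
                           cluster_cols = FALSE, ...)
  invisible(ph)
}
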