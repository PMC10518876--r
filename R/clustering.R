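# Community-state typing: silhouette-guided complete-linkage clustering of a
# beta-diversity matrix, singleton exclusion, dominant-taxon labelling.

#' Complete-linkage hierarchical clustering of a distance matrix
#' @param dm dist object or symmetric matrix
#' @return an [stats::hclust] tree (merge heights non-decreasing)
#' @export
complete_linkage <- function(dm) {
  d <- stats::as.dist(dm)
  if (anyNA(d) || any(!is.finite(d))) stop("distances contain NA/Inf")
  if (attr(d, "Size") < 2) stop("need at least 2 samples")
  stats::hclust(d, method = "complete")
}

#' Cut a dendrogram into k clusters
#' @param tree hclust tree
#' @param k number of clusters (1..n)
#' @return named integer vector sample_id -> cluster id (1..k)
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  stats::cutree(tree, k = k)
}

#' Silhouette widths from a distance matrix
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) where a(i) is the mean distance of
#' sample i to its own cluster (excluding itself) and b(i) the smallest mean
#' distance to another cluster.  Members of singleton clusters get s(i) = 0.
#'
#' @param dm dist or symmetric matrix
#' @param clusters integer cluster vector aligned with the matrix
#' @return numeric vector of widths in [-1, 1]
#' @export
silhouette_widths <- function(dm, clusters) {
  m <- as.matrix(dm)
  n <- nrow(m)
  stopifnot(length(clusters) == n)
  cl <- as.integer(factor(clusters))
  k <- max(cl)
  sizes <- tabulate(cl, k)
  # mean distance from every sample to every cluster, n x k
  sums <- m %*% outer(cl, seq_len(k), "==")
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cl[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1)
    b <- min((sums[i, -ci] / sizes[-ci]))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Select the number of clusters by mean silhouette width
#'
#' For each k in `k_range`, cuts the complete-linkage tree of `dm` and
#' computes the mean silhouette width directly from the distance matrix
#' (with `space = "pcoa"`, from Euclidean distances over the positive PCoA
#' axes instead).  The selected k maximises the mean width; ties go to the
#' smallest k.
#'
#' @param dm dist object
#' @param k_range candidate cluster numbers (default 2..20, capped at n-1)
#' @param space `"distance"` (default) or `"pcoa"`
#' @return list: `k` (selected), `mean_silhouette` (named by k), `tree`
#' @export
silhouette_k_selection <- function(dm, k_range = 2:20,
                                   space = c("distance", "pcoa")) {
  space <- match.arg(space)
  n <- attr(stats::as.dist(dm), "Size")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("empty k_range after capping at n-1")
  d_eval <- if (space == "pcoa") stats::dist(pcoa(dm)$coordinates) else dm
  if (stats::sd(as.vector(stats::as.dist(dm))) == 0)
    stop("degenerate distance matrix: all distances equal")
  tree <- complete_linkage(dm)
  ms <- vapply(k_range, function(k) {
    mean(silhouette_widths(d_eval, cut_tree(tree, k)))
  }, numeric(1))
  names(ms) <- k_range
  list(k = k_range[which.max(ms)], mean_silhouette = ms, tree = tree)
}

#' Cluster assignment with singleton exclusion bookkeeping
#'
#' @param clusters named integer vector sample -> cluster
#' @param excluded character vector of excluded sample ids
#' @param k_selected selected k (after exclusion this is the cluster count)
#' @param mean_silhouette_by_k optional named vector from k selection
#' @return `cluster_assignment` object
#' @export
cluster_assignment <- function(clusters, excluded = character(),
                               k_selected = length(unique(clusters)),
                               mean_silhouette_by_k = NULL) {
  ids <- sort(unique(as.integer(clusters)))
  if (!identical(ids, seq_along(ids)))
    stop("cluster ids must be contiguous 1..k")
  structure(list(clusters = clusters, excluded = excluded,
                 k_selected = k_selected,
                 mean_silhouette_by_k = mean_silhouette_by_k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples in %d clusters (%d excluded)\n",
              length(x$clusters), length(unique(x$clusters)),
              length(x$excluded)))
  invisible(x)
}

#' Exclude singleton clusters
#'
#' Clusters of size 1 are moved to the excluded list and the remaining
#' cluster ids renumbered contiguously (preserving their original order).
#'
#' @param clusters named integer vector sample -> cluster, or a
#'   `cluster_assignment`
#' @param mean_silhouette_by_k optional k-selection curve carried through
#' @return `cluster_assignment` with singletons excluded
#' @export
exclude_singletons <- function(clusters, mean_silhouette_by_k = NULL) {
  if (inherits(clusters, "cluster_assignment")) {
    mean_silhouette_by_k <- mean_silhouette_by_k %||% clusters$mean_silhouette_by_k
    clusters <- clusters$clusters
  }
  sizes <- table(clusters)
  singleton_ids <- as.integer(names(sizes)[sizes == 1])
  excluded <- names(clusters)[clusters %in% singleton_ids]
  keep <- clusters[!(clusters %in% singleton_ids)]
  if (!length(keep)) stop("all clusters are singletons; nothing left")
  remap <- match(keep, sort(unique(keep)))
  names(remap) <- names(keep)
  cluster_assignment(remap, excluded = excluded,
                     k_selected = length(unique(remap)),
                     mean_silhouette_by_k = mean_silhouette_by_k)
}

#' Dominant-taxon labels for clusters
#'
#' A cluster is labelled with the taxon exceeding `abundance_cut` relative
#' abundance in more than `prevalence_cut` of its member samples (both
#' strict inequalities).  If several taxa qualify, the one with the highest
#' mean abundance wins; if none, the cluster is `"mixed"`.
#'
#' @param assignment `cluster_assignment` (or named cluster vector)
#' @param proportions relative-abundance matrix (samples x taxa, rows sum
#'   to 1), typically genus-level
#' @param abundance_cut relative-abundance threshold (default 0.35)
#' @param prevalence_cut within-cluster prevalence threshold (default 0.70)
#' @return data.frame: cluster_id, label, support (fraction of member
#'   samples above the abundance cut for the labelling taxon), mean_abundance
#' @export
dominant_taxon_labels <- function(assignment, proportions,
                                  abundance_cut = 0.35, prevalence_cut = 0.70) {
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$clusters else assignment
  if (!all(names(cl) %in% rownames(proportions)))
    stop("proportions missing rows for some assigned samples")
  p <- proportions[names(cl), , drop = FALSE]
  res <- lapply(sort(unique(cl)), function(k) {
    sub <- p[cl == k, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty cluster ", k)
    prev <- colMeans(sub > abundance_cut)
    qual <- which(prev > prevalence_cut)
    if (length(qual) == 0) {
      best <- which.max(colMeans(sub))
      data.frame(cluster_id = k, label = "mixed",
                 support = prev[best], mean_abundance = colMeans(sub)[best])
    } else {
      means <- colMeans(sub[, qual, drop = FALSE])
      best <- qual[which.max(means)]
      data.frame(cluster_id = k, label = colnames(sub)[best],
                 support = prev[best], mean_abundance = max(means))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-cluster summary table
#'
#' @param assignment `cluster_assignment`
#' @param labels data.frame from [dominant_taxon_labels()]
#' @param proportions relative-abundance matrix (samples x taxa)
#' @param shannon named per-sample Shannon index (optional)
#' @param qpcr data.frame sample_id, copies (optional)
#' @param n_top number of top taxa to report per cluster
#' @return data.frame: cluster_id, n, label, top taxa with mean abundances,
#'   median_shannon, median_copies
#' @export
cluster_summary <- function(assignment, labels, proportions,
                            shannon = NULL, qpcr = NULL, n_top = 4) {
  cl <- assignment$clusters
  res <- lapply(sort(unique(cl)), function(k) {
    ids <- names(cl)[cl == k]
    sub <- proportions[ids, , drop = FALSE]
    mu <- sort(colMeans(sub), decreasing = TRUE)
    top <- utils::head(mu, n_top)
    data.frame(
      cluster_id = k,
      n = length(ids),
      label = labels$label[labels$cluster_id == k],
      top_taxa = paste(sprintf("%s=%.3f", names(top), top), collapse = ";"),
      median_shannon = if (is.null(shannon)) NA_real_ else
        stats::median(shannon[ids]),
      median_copies = if (is.null(qpcr)) NA_real_ else
        stats::median(qpcr$copies[match(ids, qpcr$sample_id)], na.rm = TRUE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a cluster assignment (TSV) and its labels/k-curve (JSON)
#' @param assignment `cluster_assignment`
#' @param labels data.frame from [dominant_taxon_labels()] (optional)
#' @param path_tsv sample-to-cluster TSV path
#' @param path_json labels + k-selection JSON path (optional)
#' @param config optional config list recorded in the header comment
#' @export
write_cluster_assignment <- function(assignment, labels = NULL, path_tsv,
                                     path_json = NULL, config = NULL) {
  con <- file(path_tsv, "w"); on.exit(close(con))
  writeLines(reproducibility_header(config), con)
  utils::write.table(
    data.frame(sample_id = names(assignment$clusters),
               cluster_id = unname(assignment$clusters)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(k_selected = assignment$k_selected,
           excluded_samples = assignment$excluded,
           mean_silhouette_by_k = as.list(assignment$mean_silhouette_by_k),
           labels = labels),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_tsv)
}
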