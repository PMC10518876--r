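# Alpha diversity, rarefaction, compositional transforms, dissimilarity
# matrices and principal coordinate analysis.

#' Shannon diversity index
#'
#' H = -sum p_i log p_i over the nonzero proportions of a count vector.
#' Natural-log units by default, matching the usual convention for 16S
#' alpha diversity.
#'
#' @param counts non-negative count vector with positive sum
#' @param base logarithm base (default `exp(1)`)
#' @return non-negative scalar, at most log(richness)
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero count vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Shannon index for every sample of a feature table
#' @inheritParams shannon_index
#' @param ft feature table
#' @return named numeric vector
#' @export
shannon_samples <- function(ft, base = exp(1)) {
  apply(unclass(ft), 1, shannon_index, base = base)
}

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to a common depth.  One draw per sample; deterministic
#' under `seed`.  Samples whose library size is below `depth` are dropped
#' with a warning.
#'
#' @param ft feature table
#' @param depth target depth (positive integer); default is the minimum
#'   library size so no sample is dropped
#' @param seed integer seed
#' @return rarefied feature table; every library size equals `depth`
#' @export
rarefy_counts <- function(ft, depth = min(library_sizes(ft)), seed = 1L) {
  if (depth <= 0 || depth != round(depth)) stop("depth must be a positive integer")
  ls <- library_sizes(ft)
  drop <- names(ls)[ls < depth]
  if (length(drop)) {
    warning(length(drop), " sample(s) below depth ", depth, " dropped")
    ft <- ft[!(rownames(ft) %in% drop), , drop = FALSE]
    if (nrow(ft) == 0) stop("no samples at or above rarefaction depth")
  }
  m <- unclass(ft)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- suppressWarnings(vegan::rrarefy(m, depth))  # shallow samples already dropped
  feature_table(out)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i) on counts.  Typically applied
#' to a rarefied table so library sizes are even.
#'
#' @param ft feature table with positive library sizes
#' @return a [stats::dist] object with `method = "bray_curtis"`
#' @export
bray_curtis_matrix <- function(ft) {
  ls <- library_sizes(ft)
  if (any(ls == 0))
    stop("zero-sum sample(s): ", paste(names(ls)[ls == 0], collapse = ", "))
  d <- vegan::vegdist(unclass(ft), method = "bray")
  attr(d, "method") <- "bray_curtis"
  d
}

as_dist_matrix <- function(m, metric) {
  d <- stats::as.dist(m)
  attr(d, "method") <- metric
  d
}

#' Centred log-ratio (CLR) transform
#'
#' Adds a pseudocount to every cell, takes natural logs and centres each
#' sample (row) to mean zero.  The pseudocount handles the zeros inherent
#' to sparse ASV tables; +1 on counts by default.
#'
#' @param ft feature table
#' @param pseudocount positive value added to every count (default 1)
#' @return real matrix, each row summing to 0
#' @export
clr_transform <- function(ft, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  m <- unclass(ft) + pseudocount
  if (any(m <= 0)) stop("pseudocount must make all entries positive")
  lm <- log(m)
  sweep(lm, 1, rowMeans(lm))
}

#' Aitchison distance matrix
#'
#' Euclidean distance between CLR-transformed samples, computed on
#' unrarefied counts (CLR is scale-invariant for zero-free compositions).
#'
#' @inheritParams clr_transform
#' @return a [stats::dist] object with `method = "aitchison"`
#' @export
aitchison_matrix <- function(ft, pseudocount = 1) {
  d <- stats::dist(clr_transform(ft, pseudocount))
  attr(d, "method") <- "aitchison"
  d
}

# Gower-centred eigendecomposition of a squared distance matrix; shared by
# pcoa() and permdisp().
gower_eigen <- function(dm) {
  m <- as.matrix(dm)
  n <- nrow(m)
  a <- -0.5 * m^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  rownames(e$vectors) <- rownames(m)
  e
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower-centres -D^2/2, eigendecomposes, and scales eigenvectors by the
#' square root of their eigenvalues.  Axes with negative eigenvalues (which
#' arise for non-Euclidean dissimilarities such as Bray-Curtis) are excluded
#' from the coordinates but their eigenvalues are reported uncorrected.
#'
#' @param dm distance matrix ([stats::dist] or symmetric matrix)
#' @param n_axes number of axes to return (default: all positive axes)
#' @return object of class `cst_pcoa`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, non-increasing), `proportion_explained`
#'   (positive eigenvalues over their sum), `sample_ids`
#' @export
pcoa <- function(dm, n_axes = NULL) {
  e <- gower_eigen(dm)
  ev <- e$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  if (is.null(n_axes)) n_axes <- length(pos)
  if (n_axes > length(pos)) {
    warning("n_axes exceeds number of positive eigenvalues; truncated to ",
            length(pos))
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), n_axes)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 proportion_explained = ev[pos] / sum(ev[pos]),
                 sample_ids = rownames(e$vectors)),
            class = "cst_pcoa")
}

#' @export
print.cst_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes; axis 1-2 explain %.1f%% + %.1f%%\n",
              length(x$sample_ids), ncol(x$coordinates),
              100 * x$proportion_explained[1],
              100 * (x$proportion_explained[2] %||% NA)))
  invisible(x)
}

#' Write a distance matrix as a square TSV
#' @param dm dist object
#' @param path output path
#' @param config optional config list recorded in the header comment
#' @export
write_distance_matrix <- function(dm, path, config = NULL) {
  m <- as.matrix(dm)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(reproducibility_header(config), con)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square-TSV distance matrix
#' @param path TSV path
#' @param metric metric name stored on the result
#' @return dist object
#' @export
read_distance_matrix <- function(path, metric = "unknown") {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  as_dist_matrix(m, metric)
}
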