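# Shared in-code fixtures.  Everything is generated; nothing binary.

tiny_ft <- function() {
  feature_table(matrix(c(5, 3, 2,
                         1, 0, 9,
                         4, 4, 4), nrow = 3, byrow = TRUE,
                       dimnames = list(c("s1", "s2", "s3"),
                                       c("t1", "t2", "t3"))))
}

random_ft <- function(n = 6, p = 8, seed = 1, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda = 10), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("t", seq_len(p))))
  m[1, ] <- m[1, ] + 1  # avoid all-zero rows
  feature_table(m)
}

# two tight, well-separated blobs as a distance matrix
blob_dist <- function(n_per = 5, within = 0.01, between = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  m <- matrix(between, n, n)
  m[1:n_per, 1:n_per] <- within
  m[(n_per + 1):n, (n_per + 1):n] <- within
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  stats::as.dist(m)
}

# Euclidean distances of labelled 2-D points
points_dist <- function(xy, ids = paste0("s", seq_len(nrow(xy)))) {
  rownames(xy) <- ids
  stats::dist(xy)
}

# memoised small simulated cohort shared across test files
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_config(n_subjects = 30, seed = 7))
    cache
  }
})

# metadata frame with planted screening violations, detached from simulation
screen_metadata <- function(n = 100, seed = 3) {
  set.seed(seed)
  md <- data.frame(
    sample_id = paste0("s", 1:n),
    subject_id = paste0("u", 1:n),
    timepoint_class = "PRE",
    collection_order = 1L,
    arm = sample(c("active", "placebo"), n, TRUE),
    cont_ok = rnorm(n),
    cont_missing = replace(rnorm(n), 1:20, NA),      # 20% missing
    cont_some_na = replace(rnorm(n), 1:14, NA),      # 14% missing
    bin_ok = sample(c("a", "b"), n, TRUE, prob = c(0.6, 0.4)),
    bin_rare = c(rep("a", 95), rep("b", 5)),         # 5% minority
    disc_rare_level = c(rep("x", 60), rep("y", 38), rep("z", 2)))
  sample_metadata(md, c(cont_ok = "continuous", cont_missing = "continuous",
                        cont_some_na = "continuous", bin_ok = "binary",
                        bin_rare = "binary", disc_rare_level = "discrete"))
}

# brute-force distinct two-group assignments of n items with sizes (n1, n2)
two_group_assignments <- function(n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  lapply(seq_len(ncol(combos)), function(i) {
    g <- rep("B", n)
    g[combos[, i]] <- "A"
    g
  })
}
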