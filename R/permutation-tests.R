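# Permutation-based community statistics (PERMANOVA, ANOSIM, PERMDISP) and
# the classical tests used alongside them.  All permutation p-values follow
# the (1 + b) / (1 + m) convention; an "exhaustive" mode enumerates every
# distinct relabelling for small designs.

new_perm_result <- function(statistic_name, observed, r_squared = NA_real_,
                            p_value, n_permutations, seed = NA_integer_,
                            extra = list()) {
  structure(c(list(statistic_name = statistic_name, observed = observed,
                   r_squared = r_squared, p_value = p_value,
                   n_permutations = n_permutations, seed = seed), extra),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("%s = %.4f%s, p = %.4g (%s permutations)\n",
              x$statistic_name, x$observed,
              if (is.na(x$r_squared)) "" else sprintf(", R2 = %.4f", x$r_squared),
              x$p_value,
              if (is.na(x$n_permutations)) "exhaustive" else x$n_permutations))
  invisible(x)
}

# all n! permutations of 1..n as an n! x n matrix (n <= 8 intended)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# shared permutation driver: stat_fun(group_vector) -> scalar
permute_p <- function(groups, stat_fun, n_permutations, seed, exhaustive,
                      tol = 1e-10) {
  obs <- stat_fun(groups)
  n <- length(groups)
  if (exhaustive) {
    perms <- all_permutations(n)
    stats_all <- apply(perms, 1, function(idx) stat_fun(groups[idx]))
    p <- mean(stats_all >= obs - tol)
    list(observed = obs, p = p, n_perm = NA_integer_)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      if (stat_fun(groups[sample.int(n)]) >= obs - tol) ge <- ge + 1L
    }
    list(observed = obs, p = (1 + ge) / (1 + n_permutations),
         n_perm = n_permutations)
  }
}

check_groups <- function(dm, groups, min_per_group = 1) {
  n <- attr(stats::as.dist(dm), "Size")
  if (length(groups) != n) stop("groups length must match distance matrix")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < min_per_group))
    stop("every group needs at least ", min_per_group, " sample(s)")
  g
}

#' PERMANOVA (one factor)
#'
#' Partitions the total sum of squared dissimilarities (SS_T = sum of
#' squared pairwise distances / N) into among- and within-group components
#' and forms the pseudo-F statistic
#' F = (SS_A / (a - 1)) / (SS_W / (N - a)); R^2 = SS_A / SS_T.  The p-value
#' is obtained by permuting group labels, or by exhaustive enumeration of
#' all relabellings when `exhaustive = TRUE`.
#'
#' @param dm distance matrix (dist or symmetric matrix)
#' @param groups categorical labels, one per sample
#' @param n_permutations number of random permutations (default 999)
#' @param seed integer seed for the permutations
#' @param exhaustive enumerate all permutations instead (small n only)
#' @return `perm_test_result` with fields observed (pseudo-F), r_squared,
#'   p_value, n_permutations, seed
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = 1L,
                      exhaustive = FALSE) {
  g <- check_groups(dm, groups)
  m2 <- as.matrix(stats::as.dist(dm))^2
  n <- nrow(m2)
  a <- nlevels(g)
  if (a == n) stop("each sample its own group: no residual df")
  if (any(table(g) == n)) stop("a group contains every sample")
  ss_total <- sum(m2[upper.tri(m2)]) / n
  stat_fun <- function(gg) {
    gg <- as.integer(factor(gg))
    ng <- tabulate(gg, a)
    s <- rowsum(m2, gg)                 # a x n: row sums per group
    tt <- rowsum(t(s), gg)              # a x a block sums
    ss_w <- sum(diag(tt) / (2 * ng))    # diagonal blocks counted twice
    ss_a <- ss_total - ss_w
    (ss_a / (a - 1)) / (ss_w / (n - a))
  }
  pr <- permute_p(as.character(g), stat_fun, n_permutations, seed, exhaustive)
  # recover R^2 from observed F
  f <- pr$observed
  ss_w <- ss_total / (1 + f * (a - 1) / (n - a))
  new_perm_result("pseudo-F", f, r_squared = 1 - ss_w / ss_total,
                  p_value = pr$p, n_permutations = pr$n_perm, seed = seed)
}

#' ANOSIM
#'
#' R = (mean between-group rank - mean within-group rank) / (M / 2) with
#' M = n(n-1)/2 pairwise dissimilarities ranked with average ties.
#' R lies in [-1, 1]; the p-value is by label permutation (or exhaustive
#' enumeration).
#'
#' @inheritParams permanova
#' @return `perm_test_result` with observed = R
#' @export
anosim <- function(dm, groups, n_permutations = 999, seed = 1L,
                   exhaustive = FALSE) {
  g <- check_groups(dm, groups)
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  r <- rank(as.vector(d))  # average ranks for ties
  m_pairs <- n * (n - 1) / 2
  # index pairs in dist order (column-major lower triangle)
  pair_i <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  pair_j <- rep(seq_len(n - 1), times = (n - 1):1)
  stat_fun <- function(gg) {
    within <- gg[pair_i] == gg[pair_j]
    (mean(r[!within]) - mean(r[within])) / (m_pairs / 2)
  }
  pr <- permute_p(as.character(g), stat_fun, n_permutations, seed, exhaustive)
  new_perm_result("ANOSIM R", pr$observed, p_value = pr$p,
                  n_permutations = pr$n_perm, seed = seed)
}

#' PERMDISP: homogeneity of multivariate dispersion
#'
#' Embeds the distance matrix by principal coordinates (keeping negative
#' axes), computes each sample's distance to its group centroid as
#' sqrt(max(0, d+^2 - d-^2)) — the real and imaginary parts combined — and
#' tests the group effect with a one-way ANOVA F on those distances.  The
#' permutation p-value permutes the least-squares residuals of the
#' distances-to-centroid model.
#'
#' @inheritParams permanova
#' @return `perm_test_result` with observed = F; `extra$distances` holds the
#'   per-sample distances to centroid
#' @export
permdisp <- function(dm, groups, n_permutations = 999, seed = 1L,
                     exhaustive = FALSE) {
  g <- check_groups(dm, groups, min_per_group = 2)
  e <- gower_eigen(dm)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  xp <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  xn <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  z <- numeric(length(g))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    cp <- colMeans(xp[idx, , drop = FALSE])
    dp2 <- rowSums(sweep(xp[idx, , drop = FALSE], 2, cp)^2)
    dn2 <- if (ncol(xn)) {
      cn <- colMeans(xn[idx, , drop = FALSE])
      rowSums(sweep(xn[idx, , drop = FALSE], 2, cn)^2)
    } else 0
    z[idx] <- sqrt(pmax(0, dp2 - dn2))
  }
  f_stat <- function(vals) {
    fit <- stats::anova(stats::lm(vals ~ g))
    fit$`F value`[1]
  }
  obs <- f_stat(z)
  resid <- z - stats::ave(z, g)
  tol <- 1e-10
  if (exhaustive) {
    perms <- all_permutations(length(z))
    fs <- apply(perms, 1, function(idx) f_stat(resid[idx]))
    p <- mean(fs >= obs - tol)
    n_perm <- NA_integer_
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      if (f_stat(resid[sample.int(length(z))]) >= obs - tol) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  new_perm_result("PERMDISP F", obs, p_value = p,
                  n_permutations = n_perm, seed = seed,
                  extra = list(distances = stats::setNames(z, labels(stats::as.dist(dm)))))
}

#' Brown-Forsythe (median-centred Levene) test for equality of spread
#'
#' One-way ANOVA on absolute deviations from group medians (or means with
#' `center = "mean"`).
#'
#' @param values numeric vector
#' @param groups group labels (>= 2 groups, each >= 2 values)
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"`
#' @return list: statistic (F), df, p_value
#' @export
levene_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 values each")
  ctr <- if (center == "median") stats::ave(values, g, FUN = stats::median)
         else stats::ave(values, g, FUN = mean)
  z <- abs(values - ctr)
  if (all(stats::ave(z, g, FUN = stats::var) == 0)) {
    if (stats::var(stats::ave(z, g, FUN = mean)) > 0) {
      warning("zero within-group deviation everywhere; p reported as 0 limit")
      return(list(statistic = Inf, df = c(nlevels(g) - 1,
                                          length(z) - nlevels(g)), p_value = 0))
    }
    return(list(statistic = 0, df = c(nlevels(g) - 1,
                                      length(z) - nlevels(g)), p_value = 1))
  }
  fit <- stats::anova(stats::lm(z ~ g))
  list(statistic = fit$`F value`[1],
       df = fit$Df,
       p_value = fit$`Pr(>F)`[1])
}

#' Chi-squared test for a 2x2 table with Yates continuity correction
#'
#' chi^2 = N (|ad - bc| - N/2)^2 / (R1 R2 C1 C2), df = 1.  The correction is
#' the default convention for 2x2 contingency comparisons of mover/stayer
#' counts.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   marginals
#' @param correct apply the continuity correction (default TRUE)
#' @return list: statistic, p_value, df = 1
#' @export
chisq_yates_2x2 <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in 2x2 table")
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), p_value = res$p.value, df = 1)
}

#' Pearson chi-squared test for an r x c table (no correction)
#' @param tab r x c matrix of non-negative counts, r,c >= 2, no zero
#'   row/column margins
#' @return list: statistic, p_value, df = (r-1)(c-1)
#' @export
chisq_rxc <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row/column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter))
}

#' Bonferroni-corrected significance threshold
#' @param alpha family-wise error rate (default 0.05)
#' @param m number of tests (>= 1)
#' @return alpha / m
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (any(m < 1)) stop("m must be >= 1")
  alpha / m
}

#' Spearman correlation of each taxon's relative abundance with 16S load
#'
#' Correlates per-taxon relative abundance against log10 qPCR copies across
#' samples; Benjamini-Hochberg adjusted q-values.  Constant taxa are
#' skipped (rho undefined).
#'
#' @param ft feature table
#' @param qpcr data.frame sample_id, copies
#' @param min_overlap minimum number of overlapping samples (default 10)
#' @return data.frame: taxon, rho, p_value, q_value
#' @export
spearman_load_correlation <- function(ft, qpcr, min_overlap = 10) {
  common <- intersect(rownames(ft), qpcr$sample_id)
  if (length(common) < min_overlap)
    stop("fewer than ", min_overlap, " overlapping samples")
  p <- relative_abundance(ft[common, , drop = FALSE])
  x <- log10(qpcr$copies[match(common, qpcr$sample_id)])
  res <- lapply(colnames(p), function(tx) {
    y <- p[, tx]
    if (stats::sd(y) == 0) return(NULL)
    ct <- suppressWarnings(stats::cor.test(y, x, method = "spearman"))
    data.frame(taxon = tx, rho = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no variable taxa")
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
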