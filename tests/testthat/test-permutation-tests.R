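test_that("PERMANOVA partitions sums of squares and matches vegan's adonis2", {
  set.seed(10)
  xy <- rbind(matrix(rnorm(16, 0), 8, 2), matrix(rnorm(16, 2), 8, 2))
  rownames(xy) <- paste0("s", 1:16)
  d <- stats::dist(xy)
  g <- rep(c("A", "B"), each = 8)
  res <- permanova(d, g, n_permutations = 199, seed = 5)
  ref <- vegan::adonis2(d ~ g, permutations = 199)
  expect_equal(res$observed, ref$F[1], tolerance = 1e-8)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-8)
  expect_gte(res$r_squared, 0)
  expect_lte(res$r_squared, 1)
  # p-value convention (1 + b) / (1 + m)
  expect_true(res$p_value >= 1 / 200 && res$p_value <= 1)
  # reproducible under seed
  expect_equal(permanova(d, g, 199, seed = 5)$p_value, res$p_value)

  # R^2 -> 1 when within-group distances vanish
  m <- matrix(1, 6, 6); m[1:3, 1:3] <- 0; m[4:6, 4:6] <- 0; diag(m) <- 0
  r1 <- permanova(stats::as.dist(m), rep(c("A", "B"), each = 3),
                  n_permutations = 99, seed = 1)
  expect_equal(r1$r_squared, 1, tolerance = 1e-10)

  expect_error(permanova(d, rep("A", 16), 99), "2 groups")
})

test_that("PERMANOVA exhaustive p equals the 2+2 closed case and enumeration oracle", {
  # two tight pairs far apart: 3 distinct relabellings, observed maximal
  m <- matrix(10, 4, 4); m[1:2, 1:2] <- 0.1; m[3:4, 3:4] <- 0.1; diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- c("A", "A", "B", "B")
  res <- permanova(m, g, exhaustive = TRUE)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  # general oracle: brute-force assignments scored by vegan's adonis2 F
  for (sizes in list(c(3, 3), c(3, 5), c(4, 4))) {
    set.seed(sum(sizes))
    n <- sum(sizes)
    xy <- matrix(rnorm(2 * n), n, 2)
    rownames(xy) <- paste0("s", 1:n)
    d <- stats::dist(xy)
    g <- rep(c("A", "B"), sizes)
    mine <- permanova(d, g, exhaustive = TRUE)
    fs <- vapply(two_group_assignments(sizes[1], sizes[2]), function(gg)
      vegan::adonis2(d ~ gg, permutations = 2)$F[1], numeric(1))
    oracle_p <- mean(fs >= fs[1] - 1e-10)
    expect_equal(mine$p_value, oracle_p, tolerance = 1e-12)
  }
})

test_that("ANOSIM matches rank arithmetic, vegan, and exhaustive enumeration", {
  # perfect separation: R = 1
  sep <- blob_dist(n_per = 4)
  r <- anosim(sep, rep(c("A", "B"), each = 4), n_permutations = 99, seed = 2)
  expect_equal(r$observed, 1, tolerance = 1e-12)

  # hand-computed 4-sample example with tied ranks
  m <- matrix(c(0, 1, 3, 3,
                1, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4, dimnames = list(paste0("s", 1:4), NULL))
  # dists: within {1, 2}, between {3, 3, 3, 3}; ranks: 1, 2, then 4.5 x4
  # r_w = 1.5, r_b = 4.5, R = (4.5 - 1.5) / (6 / 2) = 1
  rh <- anosim(stats::as.dist(m), c("A", "A", "B", "B"), 99, seed = 1)
  expect_equal(rh$observed, 1, tolerance = 1e-12)
  ref <- vegan::anosim(stats::as.dist(m), factor(c("A", "A", "B", "B")),
                       permutations = 2)
  expect_equal(rh$observed, unname(ref$statistic), tolerance = 1e-10)

  # exhaustive enumeration against a vegan-scored oracle
  set.seed(77)
  xy <- matrix(rnorm(14), 7, 2)
  rownames(xy) <- paste0("s", 1:7)
  d <- stats::dist(xy)
  g <- rep(c("A", "B"), c(3, 4))
  mine <- anosim(d, g, exhaustive = TRUE)
  rs <- vapply(two_group_assignments(3, 4), function(gg)
    unname(vegan::anosim(d, factor(gg), permutations = 2)$statistic),
    numeric(1))
  expect_equal(mine$observed, rs[1], tolerance = 1e-10)
  expect_equal(mine$p_value, mean(rs >= rs[1] - 1e-10), tolerance = 1e-12)
})

test_that("PERMDISP distances equal coordinate geometry and detect dispersion", {
  # Euclidean-embeddable: distances-to-centroid from raw coordinates
  set.seed(12)
  xy <- rbind(matrix(rnorm(20, sd = 1), 10, 2), matrix(rnorm(20, sd = 1), 10, 2))
  rownames(xy) <- paste0("s", 1:20)
  g <- rep(c("A", "B"), each = 10)
  res <- permdisp(stats::dist(xy), g, n_permutations = 99, seed = 3)
  direct <- unlist(lapply(split(seq_len(20), g), function(idx) {
    ctr <- colMeans(xy[idx, ])
    sqrt(rowSums(sweep(xy[idx, ], 2, ctr)^2))
  }))
  expect_equal(sort(unname(res$distances)), sort(unname(direct)),
               tolerance = 1e-8)

  # mirror-image groups: identical dispersion, F ~ 0
  mir <- rbind(xy[1:10, ], xy[1:10, ] + 100)
  rownames(mir) <- paste0("m", 1:20)
  rm <- permdisp(stats::dist(mir), g, n_permutations = 199, seed = 4)
  expect_lt(rm$observed, 1e-10)
  expect_gt(rm$p_value, 0.9)

  # one tight, one diffuse group
  set.seed(13)
  tight <- matrix(rnorm(20, sd = 0.01), 10, 2)
  diffuse <- matrix(rnorm(20, sd = 0.9), 10, 2)
  both <- rbind(tight, diffuse)
  rownames(both) <- paste0("t", 1:20)
  rd <- permdisp(stats::dist(both), g, n_permutations = 999, seed = 5)
  expect_lte(rd$p_value, 0.01)

  # cross-check observed F against vegan's betadisper on a bray matrix
  ft <- small_cohort()$dataset$feature_table[1:20, ]
  class(ft) <- c("feature_table", "matrix", "array")
  d <- bray_curtis_matrix(rarefy_counts(ft, 1268, seed = 1))
  bd <- vegan::betadisper(d, g, type = "centroid", bias.adjust = FALSE)
  refF <- stats::anova(bd)$`F value`[1]
  expect_equal(permdisp(d, g, n_permutations = 49, seed = 1)$observed, refF,
               tolerance = 1e-6)

  expect_error(permdisp(stats::dist(xy), c(rep("A", 19), "B"), 99), "at least 2")
})

test_that("Brown-Forsythe test matches hand ANOVA and car::leveneTest", {
  # identical deviation patterns: F = 0, p = 1
  r0 <- levene_test(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # hand example: deviations {5,5,0} vs {1,1,0}
  vals <- c(0, 10, 5, 4, 6, 5)
  g <- rep(c("a", "b"), each = 3)
  r1 <- levene_test(vals, g)
  ref <- car::leveneTest(vals, factor(g), center = stats::median)
  expect_equal(r1$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r1$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # scale invariance of p
  expect_equal(levene_test(vals * 7, g)$p_value, r1$p_value, tolerance = 1e-12)
  # mean-centred flag matches classic Levene
  refm <- car::leveneTest(vals, factor(g), center = mean)
  expect_equal(levene_test(vals, g, center = "mean")$statistic,
               refm$`F value`[1], tolerance = 1e-10)
  expect_error(levene_test(c(1, 2), c("a", "b")), ">= 2 groups")
})

test_that("2x2 chi-squared applies the Yates correction by default", {
  tab <- matrix(c(24, 8, 4, 6), 2, 2)
  res <- chisq_yates_2x2(tab)
  # closed form: N(|ad - bc| - N/2)^2 / (R1 R2 C1 C2)
  n <- sum(tab)
  expected <- n * (abs(24 * 6 - 4 * 8) - n / 2)^2 / (28 * 14 * 32 * 10)
  expect_equal(res$statistic, expected, tolerance = 1e-10)
  expect_equal(res$p_value, stats::pchisq(expected, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(res$p_value, 3), 0.096)
  # without correction the same table gives 4.2
  expect_equal(chisq_yates_2x2(tab, correct = FALSE)$statistic, 4.2,
               tolerance = 1e-10)
  # independence: statistic 0, p 1
  r0 <- chisq_yates_2x2(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # the correction is conservative on random tables
  for (seed in 1:10) {
    set.seed(seed)
    t2 <- matrix(rpois(4, 10) + 1, 2, 2)
    expect_gte(chisq_yates_2x2(t2)$p_value,
               chisq_yates_2x2(t2, correct = FALSE)$p_value)
  }
  expect_error(chisq_yates_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("r x c chi-squared matches the textbook formula", {
  expect_equal(chisq_rxc(matrix(5, 3, 3))$statistic, 0)
  tab <- matrix(c(10, 20, 30, 25, 15, 5), 2, 3, byrow = TRUE)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_counts)^2 / exp_counts)
  res <- chisq_rxc(tab)
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(chisq_rxc(tab[2:1, ])$statistic, res$statistic)
  expect_error(chisq_rxc(matrix(c(1, 1), 1, 2)), "at least 2x2")
})

test_that("Bonferroni threshold is alpha / m", {
  expect_equal(round(bonferroni_threshold(0.05, 30), 5), 0.00167)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  ms <- bonferroni_threshold(0.05, 1:20)
  expect_true(all(diff(ms) < 0))
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("Spearman load correlations find planted monotone taxa", {
  set.seed(21)
  n <- 40
  copies <- 10^runif(n, 3, 6)
  other <- matrix(50, n, 8)  # constant background so proportions track counts
  # planted taxon: relative abundance decreasing in load
  planted <- round(1000 * rank(-copies) / n)
  m <- cbind(planted = planted, other)
  colnames(m) <- c("planted", paste0("t", 1:8))
  rownames(m) <- paste0("s", 1:n)
  ft <- feature_table(m)
  qp <- data.frame(sample_id = rownames(m), copies = copies)
  res <- spearman_load_correlation(ft, qp)
  expect_equal(res$rho[res$taxon == "planted"], -1, tolerance = 1e-10)
  # rank invariance under a monotone transform of copies
  qp2 <- qp; qp2$copies <- qp$copies^2
  res2 <- spearman_load_correlation(ft, qp2)
  expect_equal(res$rho, res2$rho, tolerance = 1e-10)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_error(spearman_load_correlation(ft[1:5, ], qp), "overlapping")
})

test_that("metadata screen applies the three inclusion rules", {
  md <- screen_metadata()
  scr <- metadata_screen(md)
  expect_true(all(c("cont_ok", "cont_some_na", "bin_ok", "disc_rare_level")
                  %in% scr$kept$variable))
  expect_equal(scr$excluded$reason[scr$excluded$variable == "cont_missing"],
               "missingness")
  expect_equal(scr$excluded$reason[scr$excluded$variable == "bin_rare"],
               "insufficient binary variation")
  # rare discrete level omitted, variable kept
  kept_row <- scr$kept[scr$kept$variable == "disc_rare_level", ]
  expect_equal(kept_row$omitted_levels, "z")
  expect_error(metadata_screen(data.frame(sample_id = "a")), "covariate types")
})

test_that("pairwise association matrix flags the planted pair", {
  sim <- small_cohort()
  md <- sim$dataset$metadata
  assoc <- metadata_association_matrix(md)
  hit <- assoc[(assoc$var1 == "site" & assoc$var2 == "il6") |
                 (assoc$var1 == "il6" & assoc$var2 == "site"), ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$flagged)
  expect_equal(hit$test, "anova")
  # no self-pairs
  expect_false(any(assoc$var1 == assoc$var2))
})
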