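mk_md <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], subject_id = r[[2]], timepoint_class = r[[3]],
               collection_order = r[[4]], arm = r[[5]])))
  sample_metadata(df)
}

traj_of <- function(clusters, md) build_trajectories(clusters, md)

test_that("trajectories use the first ILI sample and tolerate exclusions", {
  md <- mk_md(list(list("p1", "u1", "PRE", 1L, "active"),
                   list("i1", "u1", "ILI", 2L, "active"),
                   list("i2", "u1", "ILI", 3L, "active"),
                   list("q1", "u1", "POST", 4L, "active")))
  cl <- c(p1 = 1, i1 = 2, i2 = 3, q1 = 1)
  tr <- traj_of(cl, md)
  expect_length(tr, 1)
  expect_equal(classify_movement(tr$u1)$category, "2")  # first ILI (cluster 2)

  # PRE-only subject is unclassifiable downstream
  md2 <- mk_md(list(list("p2", "u2", "PRE", 1L, "placebo")))
  tr2 <- traj_of(c(p2 = 1), md2)
  expect_equal(classify_movement(tr2$u2)$category, "UNCLASSIFIABLE")

  # samples without an assignment (e.g. excluded singletons) are dropped
  expect_warning(tr3 <- build_trajectories(c(p1 = 1, i1 = 2, q1 = 1), md),
                 "without cluster assignment")
  expect_equal(nrow(tr3$u1$points), 3)
})

test_that("the four movement categories follow the PRE/ILI/POST definitions", {
  mk_traj <- function(pre, ili, post, arm = "placebo") {
    structure(list(subject_id = "u", points = data.frame(
      timepoint_class = c("PRE", if (!is.na(ili)) "ILI", "POST"),
      sample_id = c("a", if (!is.na(ili)) "b", "c"),
      cluster_id = c(pre, if (!is.na(ili)) ili, post)),
      ili_status = !is.na(ili), arm = arm), class = "trajectory")
  }
  expect_equal(classify_movement(mk_traj(5, 5, 5))$category, "1")
  expect_false(classify_movement(mk_traj(5, 5, 5))$moved)
  expect_equal(classify_movement(mk_traj(1, 7, 1))$category, "2")
  expect_equal(classify_movement(mk_traj(3, 2, 4))$category, "3")
  expect_true(classify_movement(mk_traj(3, 2, 4))$moved)
  expect_equal(classify_movement(mk_traj(3, 2, 2))$category, "3")  # stays moved
  expect_equal(classify_movement(mk_traj(9, 9, 3))$category, "4")
  # non-ILI subjects: moved flag only
  no_ili <- classify_movement(mk_traj(2, NA, 3))
  expect_true(is.na(no_ili$category))
  expect_true(no_ili$moved)
  expect_false(classify_movement(mk_traj(2, NA, 2))$moved)
})

test_that("category counts partition classifiable ILI subjects and survive relabelling", {
  sim <- small_cohort()
  truth <- sim$truth
  cl <- setNames(as.integer(factor(truth$true_archetype)), truth$sample_id)
  tr <- build_trajectories(cl, sim$dataset$metadata)
  cats <- classify_movements(tr)
  ili <- cats[cats$ili_status, ]
  n_class <- sum(ili$category != "UNCLASSIFIABLE")
  expect_equal(sum(table(ili$category[ili$category != "UNCLASSIFIABLE"])),
               n_class)
  # classifier recovers the planted categories exactly
  per_subj <- unique(truth[, c("subject_id", "true_category", "true_moved")])
  merged <- merge(cats[cats$category != "UNCLASSIFIABLE" | is.na(cats$category), ],
                  per_subj, by = "subject_id")
  ok <- !is.na(merged$moved)
  expect_true(all(merged$moved[ok] == merged$true_moved[ok]))
  ili_ok <- ok & merged$ili_status
  expect_true(all(merged$category[ili_ok] == merged$true_category[ili_ok]))

  # moved fraction invariant under cluster relabelling
  perm <- sample(max(cl))
  cl2 <- setNames(perm[cl], names(cl))
  cats2 <- classify_movements(build_trajectories(cl2, sim$dataset$metadata))
  expect_equal(cats2$moved, cats$moved)
})

test_that("movement frequency test reproduces printed-count arithmetic", {
  # placebo-ILI: 24 moved / 4 stayed; active-ILI: 8 moved / 6 stayed
  cats <- data.frame(
    subject_id = paste0("u", 1:42),
    arm = rep(c("placebo", "active"), c(28, 14)),
    ili_status = TRUE,
    category = c(rep("3", 24), rep("1", 4), rep("3", 8), rep("1", 6)),
    moved = c(rep(TRUE, 24), rep(FALSE, 4), rep(TRUE, 8), rep(FALSE, 6)))
  res <- movement_frequency_test(cats, "arm")
  expect_equal(res$pooled_percent_moved, 100 * 32 / 42, tolerance = 1e-10)
  expect_equal(unname(res$percent_moved["placebo"]), 100 * 24 / 28)
  expect_equal(round(res$test$p_value, 3), 0.096)

  # all movers in both groups: independence, p = 1
  allm <- cats; allm$moved <- TRUE
  allm$moved[c(1, 29)] <- FALSE  # keep both margins positive
  expect_gt(movement_frequency_test(allm, "arm")$test$p_value, 0.9)
  expect_error(movement_frequency_test(cats[cats$arm == "placebo", ], "arm"),
               "2 non-empty groups")
})

test_that("transition counts conserve consecutive pairs", {
  md <- mk_md(list(list("a", "u1", "PRE", 1L, "active"),
                   list("b", "u1", "ILI", 2L, "active"),
                   list("c", "u1", "POST", 4L, "active"),
                   list("d", "u2", "PRE", 1L, "placebo"),
                   list("e", "u2", "POST", 4L, "placebo")))
  cl <- c(a = 3, b = 2, c = 4, d = 1, e = 1)
  tr <- traj_of(cl, md)
  tc <- transition_counts(tr)
  expect_equal(tc["3", "2"], 1)
  expect_equal(tc["2", "4"], 1)
  expect_equal(tc["1", "1"], 1)
  expect_equal(sum(tc), sum(vapply(tr, function(t) nrow(t$points) - 1L,
                                   integer(1))))
  by_pair <- transition_counts(tr, by_pair = TRUE)
  expect_setequal(names(by_pair), c("PRE->ILI", "ILI->POST", "PRE->POST"))
  expect_equal(sum(Reduce(`+`, by_pair)), sum(tc))
})

test_that("within-subject distances summarise trajectory spread", {
  md <- mk_md(list(list("a", "u1", "PRE", 1L, "active"),
                   list("b", "u1", "POST", 4L, "active"),
                   list("c", "u2", "PRE", 1L, "active")))
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- m["b", "a"] <- 0.6
  m["a", "c"] <- m["c", "a"] <- 0.9
  m["b", "c"] <- m["c", "b"] <- 0.9
  tr <- traj_of(c(a = 1, b = 2, c = 1), md)
  res <- within_subject_distance(tr, stats::as.dist(m))
  # two-sample subject: mean equals the single pairwise distance
  expect_equal(res$per_subject$mean_distance[res$per_subject$subject_id == "u1"],
               0.6)
  # single-sample subject skipped
  expect_false("u2" %in% res$per_subject$subject_id)

  # identical samples give zero
  m2 <- m; m2["a", "b"] <- m2["b", "a"] <- 0
  expect_equal(within_subject_distance(tr, stats::as.dist(m2))$per_subject$
                 mean_distance[1], 0)
})

test_that("permanent movers show larger within-subject distances on synthetic data", {
  sim <- small_cohort()
  truth <- sim$truth
  cl <- setNames(as.integer(factor(truth$true_archetype)), truth$sample_id)
  md <- sim$dataset$metadata
  tr <- build_trajectories(cl, md)
  cats <- classify_movements(tr)
  rare <- rarefy_counts(sim$dataset$feature_table, 1268, seed = 2)
  dm <- bray_curtis_matrix(rare)
  res <- within_subject_distance(tr, dm, cats)
  per <- res$per_subject[!is.na(res$per_subject$category), ]
  stay <- per$mean_distance[per$category == "1"]
  move <- per$mean_distance[per$category %in% c("3", "4")]
  if (length(stay) >= 2 && length(move) >= 2)
    expect_gt(mean(move), mean(stay))
})
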