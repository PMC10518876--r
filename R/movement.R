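# Longitudinal cluster-movement analysis: per-subject trajectories across
# PRE / ILI / POST timepoints, the four-category movement classification,
# frequency comparisons and transition-count networks.

#' Build per-subject cluster trajectories
#'
#' One trajectory per subject, ordered by collection_order.  Samples not in
#' the cluster assignment (e.g. excluded singleton-cluster members or
#' QC-removed samples) are dropped with a warning; subjects left with no
#' usable sample are omitted.  When a subject has several ILI samples the
#' first (by collection_order) is the one used for classification.
#'
#' @param assignment `cluster_assignment` (or named cluster vector)
#' @param md validated [sample_metadata()]
#' @return list of `trajectory` objects: subject_id, points (data.frame
#'   timepoint_class, sample_id, cluster_id), ili_status, arm
#' @export
build_trajectories <- function(assignment, md) {
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$clusters else assignment
  missing <- setdiff(md$sample_id, names(cl))
  if (length(missing))
    warning(length(missing),
            " sample(s) without cluster assignment dropped from trajectories")
  md <- md[md$sample_id %in% names(cl), , drop = FALSE]
  out <- list()
  for (s in unique(md$subject_id)) {
    sub <- md[md$subject_id == s, , drop = FALSE]
    sub <- sub[order(sub$collection_order), , drop = FALSE]
    if (nrow(sub) == 0) next
    pts <- data.frame(timepoint_class = sub$timepoint_class,
                      sample_id = sub$sample_id,
                      cluster_id = unname(cl[sub$sample_id]))
    out[[s]] <- structure(list(subject_id = s, points = pts,
                               ili_status = any(pts$timepoint_class == "ILI"),
                               arm = sub$arm[1]),
                          class = "trajectory")
  }
  dropped <- setdiff(unique(md$subject_id), names(out))
  if (length(dropped))
    warning("subject(s) with no usable samples omitted: ",
            paste(dropped, collapse = ", "))
  out
}

traj_cluster <- function(traj, tp) {
  p <- traj$points
  hit <- which(p$timepoint_class == tp)
  if (!length(hit)) return(NA_integer_)
  p$cluster_id[hit[1]]  # first ILI sample is the classifying one
}

#' Classify a trajectory into a movement category
#'
#' For subjects who experienced ILI (requires PRE, ILI and POST samples):
#' * category 1 — same cluster at PRE, ILI and POST (no movement);
#' * category 2 — moved at ILI, returned to the PRE cluster at POST;
#' * category 3 — moved at ILI, did not return to the PRE cluster;
#' * category 4 — stayed at ILI, moved only at POST.
#' Subjects without ILI (requires PRE and POST) get `moved` = whether the
#' POST cluster differs from PRE, with category NA (the four categories are
#' defined relative to an ILI sample).  Subjects missing a required
#' timepoint are UNCLASSIFIABLE.
#'
#' @param traj a `trajectory`
#' @return data.frame row: subject_id, arm, ili_status, category
#'   ("1".."4", NA for non-ILI, "UNCLASSIFIABLE"), moved (logical, NA when
#'   unclassifiable)
#' @export
classify_movement <- function(traj) {
  pre <- traj_cluster(traj, "PRE")
  post <- traj_cluster(traj, "POST")
  ili <- traj_cluster(traj, "ILI")
  row <- data.frame(subject_id = traj$subject_id, arm = traj$arm,
                    ili_status = traj$ili_status,
                    category = NA_character_, moved = NA)
  if (traj$ili_status) {
    if (is.na(pre) || is.na(ili) || is.na(post)) {
      row$category <- "UNCLASSIFIABLE"
      return(row)
    }
    if (ili == pre && post == pre) row$category <- "1"
    else if (ili != pre && post == pre) row$category <- "2"
    else if (ili != pre && post != pre) row$category <- "3"
    else row$category <- "4"
    row$moved <- row$category %in% c("2", "3", "4")
  } else {
    if (is.na(pre) || is.na(post)) {
      row$category <- "UNCLASSIFIABLE"
      return(row)
    }
    row$moved <- post != pre
  }
  row
}

#' Classify every trajectory
#' @param trajectories list from [build_trajectories()]
#' @return data.frame with one row per subject
#' @export
classify_movements <- function(trajectories) {
  out <- do.call(rbind, lapply(trajectories, classify_movement))
  rownames(out) <- NULL
  out
}

#' Compare mover frequency between two groups
#'
#' Builds the 2x2 moved/stayed table by group over classifiable subjects
#' and tests it with the Yates-corrected chi-squared.
#'
#' @param categories data.frame from [classify_movements()]
#' @param grouping `"ili_status"` or `"arm"`; for `"arm"` only ILI subjects
#'   are compared (movement categories are defined around an ILI episode)
#' @return list: table (2x2 moved/stayed by group), percent_moved (named by
#'   group), pooled_percent_moved, test (chisq_yates_2x2 result)
#' @export
movement_frequency_test <- function(categories,
                                    grouping = c("ili_status", "arm")) {
  grouping <- match.arg(grouping)
  cc <- categories[!is.na(categories$moved), , drop = FALSE]
  if (grouping == "arm") cc <- cc[cc$ili_status, , drop = FALSE]
  g <- factor(cc[[grouping]])
  if (nlevels(g) != 2) stop("need exactly 2 non-empty groups")
  tab <- table(moved = factor(cc$moved, levels = c(TRUE, FALSE)), group = g)
  if (any(colSums(tab) == 0)) stop("empty group")
  pct <- 100 * tab["TRUE", ] / colSums(tab)
  list(table = tab,
       percent_moved = pct,
       pooled_percent_moved = 100 * sum(tab["TRUE", ]) / sum(tab),
       test = chisq_yates_2x2(t(tab)))
}

#' Cluster-to-cluster transition counts
#'
#' counts[i, j] is the number of consecutive-sample moves from cluster i to
#' cluster j across all trajectories (diagonal = stays).  By default both
#' consecutive pairs (PRE to ILI, ILI to POST, or PRE to POST when no ILI
#' sample exists) are pooled; `by_pair = TRUE` returns one matrix per
#' consecutive timepoint-class pair.
#'
#' @param trajectories list from [build_trajectories()]
#' @param by_pair split counts by timepoint-class pair (default FALSE)
#' @return square matrix of counts (or a named list of them)
#' @export
transition_counts <- function(trajectories, by_pair = FALSE) {
  ks <- sort(unique(unlist(lapply(trajectories,
                                  function(t) t$points$cluster_id))))
  empty <- matrix(0L, length(ks), length(ks), dimnames = list(ks, ks))
  add <- function(mats, key, from, to) {
    if (is.null(mats[[key]])) mats[[key]] <- empty
    mats[[key]][as.character(from), as.character(to)] <-
      mats[[key]][as.character(from), as.character(to)] + 1L
    mats
  }
  mats <- list()
  for (tr in trajectories) {
    p <- tr$points
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1)) {
      key <- if (by_pair)
        paste(p$timepoint_class[i], p$timepoint_class[i + 1], sep = "->")
      else "all"
      mats <- add(mats, key, p$cluster_id[i], p$cluster_id[i + 1])
    }
  }
  if (by_pair) mats else mats[["all"]] %||% empty
}

#' Mean within-subject dissimilarity, grouped by movement category
#'
#' For each subject with at least two samples, the mean of all pairwise
#' distances among that subject's samples; summarised by movement category.
#'
#' @param trajectories list from [build_trajectories()]
#' @param dm distance matrix covering the trajectory samples
#' @param categories data.frame from [classify_movements()]
#' @return list: per_subject (data.frame subject_id, mean_distance,
#'   category), by_category (data.frame category, n, mean)
#' @export
within_subject_distance <- function(trajectories, dm, categories = NULL) {
  m <- as.matrix(dm)
  rows <- list()
  for (tr in trajectories) {
    ids <- tr$points$sample_id
    ids <- ids[ids %in% rownames(m)]
    if (length(ids) < 2) next
    sub <- m[ids, ids]
    rows[[tr$subject_id]] <- data.frame(
      subject_id = tr$subject_id,
      mean_distance = mean(sub[upper.tri(sub)]))
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  if (!is.null(categories)) {
    per$category <- categories$category[match(per$subject_id,
                                              categories$subject_id)]
    agg <- stats::aggregate(mean_distance ~ category, data = per,
                            FUN = function(x) c(n = length(x), mean = mean(x)))
    by_cat <- data.frame(category = agg$category,
                         n = agg$mean_distance[, "n"],
                         mean = agg$mean_distance[, "mean"])
  } else by_cat <- NULL
  list(per_subject = per, by_category = by_cat)
}

#' Write movement categories and a transition matrix to TSV
#' @param categories data.frame from [classify_movements()]
#' @param counts matrix from [transition_counts()]
#' @param path_categories output TSV for categories
#' @param path_transitions output TSV for the transition matrix (optional)
#' @param config optional config list recorded in the header comment
#' @export
write_movement <- function(categories, counts = NULL, path_categories,
                           path_transitions = NULL, config = NULL) {
  con <- file(path_categories, "w"); on.exit(close(con))
  writeLines(reproducibility_header(config), con)
  utils::write.table(categories, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_transitions) && !is.null(counts)) {
    con2 <- file(path_transitions, "w")
    writeLines(reproducibility_header(config), con2)
    utils::write.table(data.frame(from_cluster = rownames(counts), counts,
                                  check.names = FALSE),
                       con2, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con2)
  }
  invisible(path_categories)
}
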