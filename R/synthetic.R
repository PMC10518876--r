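# Synthetic longitudinal cohort generator.  Emulates the post-denoising
# state of a nasal 16S dataset: nine compositional archetypes (eight with a
# dominant taxon, one mixed/diverse), per-subject PRE / ILI / POST
# trajectories with ILI-triggered cluster transitions, an arm-level
# stabilisation effect, log-normal library sizes and qPCR loads, and exact
# ground-truth labels for recovery testing.

#' Construct an archetype specification
#'
#' @param name archetype name
#' @param mean_composition named proportion vector over the taxon panel
#'   (sums to 1)
#' @param concentration Dirichlet precision; larger = less sample-to-sample
#'   compositional noise
#' @param dominant_taxon genus label, or NA for a mixed archetype (if set,
#'   its total mean proportion must exceed 0.35)
#' @return `archetype_spec` object
#' @export
archetype_spec <- function(name, mean_composition, concentration,
                           dominant_taxon = NA_character_) {
  stopifnot(abs(sum(mean_composition) - 1) < 1e-8, concentration > 0)
  if (!is.na(dominant_taxon)) {
    genus <- sub("_ASV[0-9]+$", "", names(mean_composition))
    if (sum(mean_composition[genus == dominant_taxon]) <= 0.35)
      stop("dominant taxon mean proportion must exceed 0.35")
  }
  structure(list(name = name, mean_composition = mean_composition,
                 concentration = concentration,
                 dominant_taxon = dominant_taxon),
            class = "archetype_spec")
}

archetype_shannon <- function(arch) {
  p <- arch$mean_composition
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Default panel of nine nasal community archetypes
#'
#' Builds eight dominant-taxon archetypes — three Corynebacterium (each
#' dominated by a distinct ASV), three Moraxella (likewise), one
#' Staphylococcus, one Dolosigranulum — plus one mixed high-diversity
#' archetype whose largest mean proportion stays below 0.2 and whose
#' expected Shannon index exceeds every dominant archetype's.  The taxon
#' panel holds multiple ASVs per dominant genus and filler ASVs from genera
#' commonly observed in nasal swabs.
#'
#' @param n_taxa panel size (>= 20; default 60)
#' @param concentration Dirichlet precision shared by all archetypes
#'   (default 150)
#' @param seed integer seed (the panel is deterministic under it)
#' @return named list of nine [archetype_spec()] objects
#' @export
make_default_archetypes <- function(n_taxa = 60, concentration = 150,
                                    seed = 1L) {
  if (n_taxa < 20) stop("n_taxa must be at least 20")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  named <- c(paste0("Corynebacterium_ASV", 1:4),
             paste0("Moraxella_ASV", 1:5),
             "Staphylococcus_ASV1", "Dolosigranulum_ASV1")
  filler_genera <- c("Haemophilus", "Streptococcus", "Pseudomonas",
                     "Lactobacillus", "Anaerococcus", "Peptoniphilus",
                     "Finegoldia", "Cutibacterium", "Micrococcus",
                     "Acinetobacter", "Prevotella", "Veillonella")
  n_fill <- n_taxa - length(named)
  g <- rep_len(filler_genera, n_fill)
  idx <- stats::ave(seq_along(g), g, FUN = seq_along)
  fillers <- paste0(g, "_ASV", idx)
  panel <- c(named, fillers)

  base_background <- function(dominant_id, mass) {
    # concentrate the non-dominant mass on a handful of taxa so dominant
    # archetypes stay low-diversity
    others <- setdiff(panel, dominant_id)
    w <- 0.55 ^ seq_along(others)
    w <- w[order(sample.int(length(others)))]  # random permutation of decay
    stats::setNames(c(mass * w / sum(w)), others)
  }
  make_dom <- function(name, dominant_id, dominant_genus) {
    p_dom <- stats::runif(1, 0.5, 0.8)
    comp <- stats::setNames(numeric(length(panel)), panel)
    comp[dominant_id] <- p_dom
    bg <- base_background(dominant_id, 1 - p_dom)
    comp[names(bg)] <- bg
    archetype_spec(name, comp, concentration, dominant_genus)
  }
  archetypes <- list(
    coryne_1 = make_dom("coryne_1", "Corynebacterium_ASV1", "Corynebacterium"),
    coryne_2 = make_dom("coryne_2", "Corynebacterium_ASV2", "Corynebacterium"),
    coryne_3 = make_dom("coryne_3", "Corynebacterium_ASV3", "Corynebacterium"),
    moraxella_1 = make_dom("moraxella_1", "Moraxella_ASV1", "Moraxella"),
    moraxella_2 = make_dom("moraxella_2", "Moraxella_ASV2", "Moraxella"),
    moraxella_3 = make_dom("moraxella_3", "Moraxella_ASV3", "Moraxella"),
    staph = make_dom("staph", "Staphylococcus_ASV1", "Staphylococcus"),
    dolosigranulum = make_dom("dolosigranulum", "Dolosigranulum_ASV1",
                              "Dolosigranulum"))
  # mixed archetype: broad composition, max mean proportion < 0.2
  w <- stats::rgamma(length(panel), shape = 2)
  w <- pmin(w, stats::quantile(w, 0.9))
  comp <- stats::setNames(w / sum(w), panel)
  archetypes$mixed <- archetype_spec("mixed", comp, concentration,
                                     NA_character_)
  if (max(comp) >= 0.2) stop("internal: mixed archetype too concentrated")
  stopifnot(archetype_shannon(archetypes$mixed) >
              max(vapply(archetypes[1:8], archetype_shannon, numeric(1))))
  archetypes
}

#' Taxonomy map for an archetype panel
#'
#' ASV ids follow the `<Genus>_ASV<k>` convention; the genus is recovered
#' by stripping the ASV suffix.
#' @param archetypes list of archetype specs sharing a panel
#' @return data.frame asv_id, genus
#' @export
panel_taxonomy <- function(archetypes) {
  panel <- names(archetypes[[1]]$mean_composition)
  data.frame(asv_id = panel, genus = sub("_ASV[0-9]+$", "", panel))
}

#' Draw one Dirichlet-multinomial sample from an archetype
#'
#' Composition is drawn from Dirichlet(concentration * mean_composition),
#' then `depth` reads from the resulting multinomial.  Uses the current R
#' random number generator state.
#'
#' @param arch [archetype_spec()]
#' @param depth library size (positive integer)
#' @return integer count vector summing to `depth`, named by taxon
#' @export
simulate_sample <- function(arch, depth) {
  stopifnot(depth >= 1, depth == round(depth))
  alpha <- arch$concentration * arch$mean_composition
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  p <- g / sum(g)
  stats::setNames(as.integer(stats::rmultinom(1, depth, p)),
                  names(arch$mean_composition))
}

#' Cohort simulation configuration
#'
#' Defaults encode the study conditions of a probiotic trial in long-term
#' care: 150 subjects, 34% ILI attack proportion, mover probabilities of
#' 0.487 for non-ILI subjects and 0.857 / 0.571 for ILI subjects on placebo
#' / active arms, 12.5% of ILI movers returning to their pre-ILI cluster,
#' post-season dropout of 23/150, log-normal library sizes (median ~20k,
#' floor 1268) and log-normal qPCR loads with ~4% of samples below 1e3
#' copies.
#'
#' @param n_subjects number of subjects (>= 1)
#' @param p_ili probability a subject experiences ILI
#' @param p_move_healthy probability a non-ILI subject's POST cluster
#'   differs from PRE
#' @param p_move_ili_active,p_move_ili_placebo movement probabilities for
#'   ILI subjects by arm
#' @param p_return_given_move probability an ILI mover is category 2
#'   (returns to the PRE cluster at POST)
#' @param p_cat4_given_move probability an ILI mover is category 4 (moves
#'   only at POST); category 3 takes the remaining probability
#' @param p_second_ili probability an ILI subject has a second ILI sample
#' @param p_post_dropout probability the POST sample is missing
#' @param prop_active fraction of subjects in the active (probiotic) arm
#' @param depth_log_mean,depth_log_sd log-normal library-size parameters
#' @param depth_floor minimum library size
#' @param qpcr_log_mean,qpcr_log_sd log-normal 16S copy-number parameters
#' @param seed integer seed
#' @return validated `cohort_config` list
#' @export
cohort_config <- function(n_subjects = 150,
                          p_ili = 0.34,
                          p_move_healthy = 0.487,
                          p_move_ili_active = 0.571,
                          p_move_ili_placebo = 0.857,
                          p_return_given_move = 0.125,
                          p_cat4_given_move = 0.25,
                          p_second_ili = 7 / 51,
                          p_post_dropout = 23 / 150,
                          prop_active = 73 / 150,
                          depth_log_mean = log(20000),
                          depth_log_sd = 0.5,
                          depth_floor = 1268,
                          qpcr_log_mean = log(3e4),
                          qpcr_log_sd = 2,
                          seed = 1L) {
  cfg <- as.list(environment())
  probs <- cfg[grep("^p_|^prop_", names(cfg))]
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop("probabilities must lie in [0, 1]")
  if (cfg$p_return_given_move + cfg$p_cat4_given_move > 1)
    stop("p_return_given_move + p_cat4_given_move must not exceed 1")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(cfg, class = "cohort_config")
}

#' Simulate a longitudinal cohort with ground truth
#'
#' Each subject receives a PRE sample, one ILI sample if they experience
#' ILI (occasionally two; the second shares the first's archetype), and a
#' POST sample unless they drop out.  Movement is planted by drawing the
#' true category first and then archetypes consistent with it, so the
#' ground truth is exact; the archetype a mover transitions into is drawn
#' uniformly from the other archetypes.  Metadata includes per-subject
#' covariates with one deliberately associated pair (collection site and a
#' site-shifted inflammatory marker) plus variables engineered to trip each
#' screening rule.
#'
#' @param cfg [cohort_config()]
#' @param archetypes list of archetype specs (default
#'   [make_default_archetypes()] under the config seed)
#' @return list: `dataset` (a [study_dataset()]) and `truth` (data.frame,
#'   one row per sample: sample_id, subject_id, timepoint_class,
#'   true_archetype, ili_status, arm, true_category, true_moved)
#' @export
simulate_cohort <- function(cfg = cohort_config(),
                            archetypes = make_default_archetypes(seed = cfg$seed)) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  arch_names <- names(archetypes)
  n_arch <- length(archetypes)
  n <- cfg$n_subjects
  n_active <- round(cfg$prop_active * n)
  arm <- sample(c(rep("active", n_active), rep("placebo", n - n_active)))

  other <- function(a) sample(setdiff(arch_names, a), 1)
  counts <- list(); md_rows <- list(); truth_rows <- list(); qpcr_rows <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("subj%03d", i)
    pre_arch <- sample(arch_names, 1)
    ili <- stats::runif(1) < cfg$p_ili
    p_move <- if (!ili) cfg$p_move_healthy
              else if (arm[i] == "active") cfg$p_move_ili_active
              else cfg$p_move_ili_placebo
    moved <- stats::runif(1) < p_move
    if (ili) {
      if (!moved) {
        cat <- "1"; ili_arch <- pre_arch; post_arch <- pre_arch
      } else {
        u <- stats::runif(1)
        if (u < cfg$p_return_given_move) {
          cat <- "2"; ili_arch <- other(pre_arch); post_arch <- pre_arch
        } else if (u < cfg$p_return_given_move + cfg$p_cat4_given_move) {
          cat <- "4"; ili_arch <- pre_arch; post_arch <- other(pre_arch)
        } else {
          cat <- "3"; ili_arch <- other(pre_arch); post_arch <- other(pre_arch)
        }
      }
    } else {
      cat <- NA_character_
      ili_arch <- NA_character_
      post_arch <- if (moved) other(pre_arch) else pre_arch
    }
    second_ili <- ili && stats::runif(1) < cfg$p_second_ili
    has_post <- stats::runif(1) >= cfg$p_post_dropout

    plan <- data.frame(timepoint_class = "PRE", arch = pre_arch,
                       collection_order = 1L)
    if (ili) {
      plan <- rbind(plan, data.frame(timepoint_class = "ILI", arch = ili_arch,
                                     collection_order = 2L))
      if (second_ili)
        plan <- rbind(plan, data.frame(timepoint_class = "ILI",
                                       arch = ili_arch, collection_order = 3L))
    }
    if (has_post)
      plan <- rbind(plan, data.frame(timepoint_class = "POST",
                                     arch = post_arch, collection_order = 4L))
    for (r in seq_len(nrow(plan))) {
      smp <- sprintf("%s_t%d", sid, plan$collection_order[r])
      depth <- max(cfg$depth_floor,
                   round(stats::rlnorm(1, cfg$depth_log_mean, cfg$depth_log_sd)))
      counts[[smp]] <- simulate_sample(archetypes[[plan$arch[r]]], depth)
      md_rows[[smp]] <- data.frame(sample_id = smp, subject_id = sid,
                                   timepoint_class = plan$timepoint_class[r],
                                   collection_order = plan$collection_order[r],
                                   arm = arm[i])
      qpcr_rows[[smp]] <- data.frame(sample_id = smp,
                                     copies = stats::rlnorm(1, cfg$qpcr_log_mean,
                                                            cfg$qpcr_log_sd))
      truth_rows[[smp]] <- data.frame(sample_id = smp, subject_id = sid,
                                      timepoint_class = plan$timepoint_class[r],
                                      true_archetype = plan$arch[r],
                                      ili_status = ili, arm = arm[i],
                                      true_category = cat, true_moved = moved)
    }
  }
  ft <- feature_table(do.call(rbind, counts))
  md <- do.call(rbind, md_rows)
  truth <- do.call(rbind, truth_rows)
  qpcr <- do.call(rbind, qpcr_rows)
  rownames(md) <- rownames(truth) <- rownames(qpcr) <- NULL

  # per-subject covariates, replicated across samples
  subjects <- unique(md$subject_id)
  ns <- length(subjects)
  site <- sample(c("home_A", "home_B", "home_C"), ns, replace = TRUE,
                 prob = c(0.45, 0.35, 0.20))
  il6 <- stats::rnorm(ns, mean = c(home_A = 2, home_B = 4, home_C = 7)[site],
                      sd = 1.5)                      # planted association with site
  age <- round(stats::rnorm(ns, 86, 7))
  sex <- sample(c("F", "M"), ns, replace = TRUE, prob = c(0.7, 0.3))
  barthel <- pmin(20, pmax(0, round(stats::rnorm(ns, 7, 5))))
  rare_condition <- sample(c("no", "yes"), ns, replace = TRUE,
                           prob = c(0.97, 0.03))     # trips the binary-variation rule
  tnf <- stats::rnorm(ns, 5, 2)
  tnf[sample.int(ns, round(0.2 * ns))] <- NA         # trips the missingness rule
  room_type <- sample(c("single", "shared", "ward"), ns, replace = TRUE,
                      prob = c(0.55, 0.43, 0.02))    # "ward" trips the rare-level rule
  cov <- data.frame(subject_id = subjects, site = site, il6 = il6, age = age,
                    sex = sex, barthel = barthel, rare_condition = rare_condition,
                    tnf = tnf, room_type = room_type)
  md <- merge(md, cov, by = "subject_id", sort = FALSE)
  md <- md[match(rownames(ft), md$sample_id), ]
  rownames(md) <- NULL
  md <- sample_metadata(md, c(site = "discrete", il6 = "continuous",
                              age = "continuous", sex = "binary",
                              barthel = "continuous",
                              rare_condition = "binary", tnf = "continuous",
                              room_type = "discrete"))
  ds <- study_dataset(ft, panel_taxonomy(archetypes), md, qpcr)
  list(dataset = ds, truth = truth)
}

#' Write / read a ground-truth table
#' @param truth data.frame from [simulate_cohort()]
#' @param path TSV path
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(reproducibility_header(NULL), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          na.strings = c("NA", ""))
  df$true_category <- as.character(df$true_category)
  df
}
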