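# Metadata inclusion rules and pairwise association screening.  Covariates
# are screened before being tested against community composition so that
# sparse, near-constant or heavily missing variables do not generate
# spurious associations.

#' Screen metadata covariates for inclusion
#'
#' Applies three rules to each declared covariate:
#' 1. missingness: excluded if more than `max_missing` of values are NA;
#' 2. binary variables: excluded if the minority level carries less than
#'    `min_binary_variation` of the observations;
#' 3. non-binary discrete variables: levels accounting for at most
#'    `min_level_share` of observations are omitted (the level, not the
#'    variable).
#' Continuous variables are always included, subject only to rule 1.
#'
#' @param md validated [sample_metadata()] with a `covariate_types` attribute
#' @param max_missing missingness ceiling (default 0.15)
#' @param min_binary_variation minimum minority share for binaries (default 0.10)
#' @param min_level_share minimum share per discrete level (default 0.03,
#'   strict: a level is kept only if its share is > the threshold)
#' @return `metadata_screen_report`: data.frames `kept` (variable, type,
#'   omitted_levels), `excluded` (variable, reason)
#' @export
metadata_screen <- function(md, max_missing = 0.15,
                            min_binary_variation = 0.10,
                            min_level_share = 0.03) {
  types <- attr(md, "covariate_types")
  if (is.null(types)) stop("metadata has no declared covariate types")
  kept <- list(); excluded <- list()
  for (v in names(types)) {
    x <- md[[v]]
    ty <- types[[v]]
    if (mean(is.na(x)) > max_missing) {
      excluded[[v]] <- data.frame(variable = v, reason = "missingness")
      next
    }
    omitted <- character()
    if (ty == "binary") {
      tab <- table(x[!is.na(x)])
      if (length(tab) < 2 || min(tab) / sum(tab) < min_binary_variation) {
        excluded[[v]] <- data.frame(variable = v,
                                    reason = "insufficient binary variation")
        next
      }
    } else if (ty == "discrete") {
      tab <- table(x[!is.na(x)])
      share <- tab / sum(tab)
      omitted <- names(share)[share <= min_level_share]
      if (length(omitted) == length(share)) {
        excluded[[v]] <- data.frame(variable = v, reason = "rare level")
        next
      }
    }
    kept[[v]] <- data.frame(variable = v, type = ty,
                            omitted_levels = paste(omitted, collapse = ";"))
  }
  structure(list(kept = if (length(kept)) do.call(rbind, kept) else
                   data.frame(variable = character(), type = character(),
                              omitted_levels = character()),
                 excluded = if (length(excluded)) do.call(rbind, excluded) else
                   data.frame(variable = character(), reason = character())),
            class = "metadata_screen_report")
}

#' @export
print.metadata_screen_report <- function(x, ...) {
  cat(sprintf("metadata screen: %d kept, %d excluded\n",
              nrow(x$kept), nrow(x$excluded)))
  invisible(x)
}

#' Pairwise association tests between screened covariates
#'
#' For every pair of kept covariates: categorical x categorical by Pearson
#' chi-squared, categorical x continuous by one-way ANOVA, continuous x
#' continuous by Pearson correlation test.  Pairs with p < `alpha` are
#' flagged as associated.  Constant variables are skipped with a warning;
#' discrete levels omitted by the screen are dropped before testing.
#'
#' @param md validated metadata
#' @param screen a `metadata_screen_report` (default: computed from `md`)
#' @param alpha flagging threshold (default 0.05)
#' @return data.frame: var1, var2, test, p_value, flagged
#' @export
metadata_association_matrix <- function(md, screen = metadata_screen(md),
                                        alpha = 0.05) {
  types <- attr(md, "covariate_types")
  vars <- screen$kept$variable
  omit <- stats::setNames(strsplit(screen$kept$omitted_levels, ";"),
                          screen$kept$variable)
  get_var <- function(v) {
    x <- md[[v]]
    if (types[[v]] != "continuous") {
      x <- as.character(x)
      x[x %in% omit[[v]]] <- NA
      factor(x)
    } else as.numeric(x)
  }
  res <- list()
  if (length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
      v1 <- vars[i]; v2 <- vars[j]
      x <- get_var(v1); y <- get_var(v2)
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      if (is.factor(x)) x <- droplevels(x)
      if (is.factor(y)) y <- droplevels(y)
      constant <- function(z) if (is.factor(z)) nlevels(z) < 2 else
        stats::sd(z) == 0
      if (length(x) < 3 || constant(x) || constant(y)) {
        warning("skipping constant/degenerate pair ", v1, " vs ", v2)
        next
      }
      if (is.factor(x) && is.factor(y)) {
        test <- "chi-squared"
        p <- suppressWarnings(stats::chisq.test(table(x, y), correct = FALSE)$p.value)
      } else if (!is.factor(x) && !is.factor(y)) {
        test <- "correlation"
        p <- stats::cor.test(x, y)$p.value
      } else {
        test <- "anova"
        if (is.factor(y)) { tmp <- x; x <- y; y <- tmp }
        p <- stats::anova(stats::lm(y ~ x))$`Pr(>F)`[1]
      }
      res[[length(res) + 1]] <- data.frame(var1 = v1, var2 = v2, test = test,
                                           p_value = p, flagged = p < alpha)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(var1 = character(), var2 = character(), test = character(),
               p_value = numeric(), flagged = logical())
  rownames(out) <- NULL
  out
}

#' Per-variable PERMANOVA association table
#'
#' Runs a one-factor PERMANOVA of the community distance matrix against
#' every kept covariate — continuous covariates are discretised into
#' quartile bins for the one-factor design — and reports statistic, R^2 and
#' p, the community-association analogue of a per-variable screen.
#'
#' @param dm distance matrix
#' @param md validated metadata (rows aligned to `dm` labels)
#' @param screen `metadata_screen_report`
#' @param n_permutations permutations per variable
#' @param seed integer seed
#' @return data.frame: variable, metric, statistic, r_squared, p_value,
#'   n_permutations, seed
#' @export
permanova_screen <- function(dm, md, screen = metadata_screen(md),
                             n_permutations = 999, seed = 1L) {
  ids <- labels(stats::as.dist(dm))
  md <- md[match(ids, md$sample_id), , drop = FALSE]
  types <- attr(md, "covariate_types")
  res <- list()
  for (v in screen$kept$variable) {
    x <- md[[v]]
    if (types[[v]] == "continuous") {
      x <- cut(as.numeric(x), breaks = unique(stats::quantile(as.numeric(x),
               probs = seq(0, 1, 0.25), na.rm = TRUE)), include.lowest = TRUE)
    }
    x <- factor(x)
    ok <- !is.na(x)
    if (sum(ok) < 4 || nlevels(droplevels(x[ok])) < 2) next
    sub <- as.matrix(dm)[ok, ok]
    pt <- permanova(sub, droplevels(x[ok]), n_permutations = n_permutations,
                    seed = seed)
    res[[v]] <- data.frame(variable = v, metric = attr(dm, "method") %||% "unknown",
                           statistic = pt$observed, r_squared = pt$r_squared,
                           p_value = pt$p_value, n_permutations = n_permutations,
                           seed = seed)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
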