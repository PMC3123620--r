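#' Principal component analysis of signature expression
#'
#' Samples are projected onto the principal components of the
#' signature-restricted expression matrix, with features centered and
#' scaled to unit variance beforehand. Zero-variance features are dropped
#' with a warning; features with missing wells are mean-imputed across
#' samples for the projection only (values in the Ct matrix itself are
#' untouched). Loading signs are fixed by making each component's
#' largest-magnitude loading positive, so reports are reproducible.
#'
#' @param m Ct matrix.
#' @param signature a `mirna_signature` or character vector of features;
#'   `NULL` uses every feature.
#' @return object of class `ct_pca`: `scores` (samples x components),
#'   `loadings` (features x components), `var_explained` (fractions,
#'   non-increasing, summing to 1 over all components), `features_used`,
#'   `dropped`.
#' @export
ct_pca <- function(m, signature = NULL) {
  feats <- if (is.null(signature)) rownames(m)
           else signature_features(signature)
  absent <- setdiff(feats, rownames(m))
  if (length(absent) > 0L) {
    stop("signature feature(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  }
  X <- t(m[feats, , drop = FALSE])           # samples x features
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples")
  # mean-impute missing wells per feature (projection only)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2L, stats::sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, !drop, drop = FALSE]
  }
  if (ncol(X) < 1L) stop("no features with nonzero variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(scores = pc$x,
                 loadings = pc$rotation,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 features_used = colnames(X),
                 dropped = feats[feats %in% setdiff(feats, colnames(X))]),
            class = "ct_pca")
}

#' @export
print.ct_pca <- function(x, ...) {
  cat("PCA of", length(x$features_used), "features x",
      nrow(x$scores), "samples\n")
  ve <- utils::head(x$var_explained, 3L)
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve),
            collapse = ", "), "\n")
  invisible(x)
}

# classic one-way ANOVA F-test p-value for one feature
oneway_f_p <- function(x, g) {
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]
  g <- droplevels(factor(g[ok]))
  if (nlevels(g) < 2L || length(x) - nlevels(g) < 1L) return(NA_real_)
  fit <- stats::lm(x ~ g)
  av <- stats::anova(fit)
  av[["Pr(>F)"]][1L]
}

#' Unsupervised subgroup-discovery sweep over significance thresholds
#'
#' Emulates gradually lowering a p-value threshold over all miRNAs until
#' subgroups among the malignant samples emerge. For each threshold in
#' descending order: (1) a per-feature one-way F-test p across the levels
#' of `grouping_variable` (the statistic is pluggable); (2) features with
#' p strictly below the threshold are kept; (3) PCA on the kept features;
#' (4) k-means (g centers, `nstart` restarts, seeded) on the top
#' `n_components` score dimensions; (5) concordance with the known
#' grouping by majority vote per cluster (within-cluster ties counted
#' fully misplaced). The reported solution is the largest threshold whose
#' misplacement is minimal; the full trace (and per-threshold detail) is
#' returned so stricter, smaller feature sets can be inspected.
#'
#' @param m Ct matrix (normalized).
#' @param a sample annotation; only malignant samples enter the sweep.
#' @param grouping_variable annotation column defining known subgroups
#'   (default `"gleason_score"`); needs >= 2 levels.
#' @param thresholds descending p-value thresholds to sweep.
#' @param n_components score dimensions used for clustering.
#' @param seed seed for the k-means step (set before every call, so the
#'   sweep is deterministic given data and thresholds).
#' @param statistic optional `function(values, groups) -> p` replacing
#'   the F-test.
#' @param nstart k-means restarts.
#' @return object of class `subgroup_sweep`: `best_threshold`,
#'   `selected_features`, `assignment` (sample -> cluster at the best
#'   threshold), `cluster_level` (majority grouping level per cluster),
#'   `misplaced` (count at best), `p_values`, `trace` (threshold,
#'   n_features, misplaced), `details` (per-threshold feature sets and
#'   assignments).
#' @export
subgroup_sweep <- function(m, a, grouping_variable = "gleason_score",
                           thresholds = c(0.05, 0.04, 0.03, 0.02, 0.017,
                                          0.01, 0.005, 0.001, 1e-4, 1e-5),
                           n_components = 2, seed = 1,
                           statistic = NULL, nstart = 50) {
  a <- validate_sample_annotation(a)
  mal <- a[a$tissue_class == "malignant", , drop = FALSE]
  if (is.null(mal[[grouping_variable]])) {
    stop("grouping variable '", grouping_variable, "' not in annotation")
  }
  keep <- !is.na(mal[[grouping_variable]])
  if (any(!keep)) {
    message(sum(!keep), " malignant sample(s) without a ",
            grouping_variable, " value dropped from the sweep")
  }
  mal <- mal[keep, , drop = FALSE]
  g <- factor(mal[[grouping_variable]])
  if (nlevels(g) < 2L) {
    stop("grouping variable needs at least 2 levels among malignant samples")
  }
  X <- m[, mal$sample_id, drop = FALSE]
  stat_fun <- if (is.null(statistic)) oneway_f_p else statistic
  p <- apply(X, 1L, stat_fun, g = g)

  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  trace <- data.frame(threshold = thresholds,
                      n_features = NA_integer_,
                      misplaced = NA_integer_)
  details <- vector("list", length(thresholds))
  n_groups <- nlevels(g)
  for (t_i in seq_along(thresholds)) {
    thr <- thresholds[t_i]
    feats <- rownames(X)[!is.na(p) & p < thr]
    trace$n_features[t_i] <- length(feats)
    if (length(feats) < 2L) {
      warning("threshold ", format(thr),
              " leaves fewer than 2 features; skipped")
      next
    }
    pc <- suppressWarnings(ct_pca(X, feats))
    ncomp <- min(n_components, ncol(pc$scores))
    sc <- pc$scores[, seq_len(ncomp), drop = FALSE]
    if (nrow(sc) <= n_groups) next
    set.seed(seed)
    km <- stats::kmeans(sc, centers = n_groups, nstart = nstart)
    cl <- km$cluster
    misplaced <- 0L
    cluster_level <- character(n_groups)
    for (cc in seq_len(n_groups)) {
      lv <- g[cl == cc]
      tab <- table(lv)
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) {          # tie: count the cluster fully misplaced
        cluster_level[cc] <- NA_character_
        misplaced <- misplaced + length(lv)
      } else {
        cluster_level[cc] <- top
        misplaced <- misplaced + sum(lv != top)
      }
    }
    trace$misplaced[t_i] <- misplaced
    details[[t_i]] <- list(threshold = thr, features = feats,
                           assignment = stats::setNames(cl, mal$sample_id),
                           cluster_level = cluster_level,
                           misplaced = misplaced)
  }
  usable <- !is.na(trace$misplaced)
  if (!any(usable)) stop("no threshold produced a usable clustering")
  best_mis <- min(trace$misplaced[usable])
  best_i <- which(usable & trace$misplaced == best_mis)[1L]  # largest thr
  best <- details[[best_i]]
  structure(list(best_threshold = best$threshold,
                 selected_features = best$features,
                 assignment = best$assignment,
                 cluster_level = best$cluster_level,
                 misplaced = best$misplaced,
                 n_samples = nrow(mal),
                 p_values = p,
                 trace = trace,
                 details = details[usable],
                 grouping_variable = grouping_variable),
            class = "subgroup_sweep")
}

#' @export
print.subgroup_sweep <- function(x, ...) {
  cat("Subgroup sweep on", x$grouping_variable, ":",
      length(x$selected_features), "features at p <",
      format(x$best_threshold), "->", x$misplaced, "of",
      x$n_samples, "samples misplaced\n")
  invisible(x)
}
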