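#' Paired Student's t-test per feature
#'
#' For each miRNA, forms the within-case differences
#' `d = Ct(malignant) - Ct(normal)` over complete pairs (pairs with a
#' missing well in either member are dropped per feature) and tests
#' `mean(d) = 0` with the one-sample t statistic `t = mean(d) / (sd(d) /
#' sqrt(n))`, two-sided p from the Student t distribution on `n - 1`
#' degrees of freedom.
#'
#' Direction encodes expression, not Ct: because Ct falls as template
#' abundance rises, `direction = "+"` (up in malignant) corresponds to
#' `mean_delta_ct < 0` and `"-"` to `mean_delta_ct > 0`.
#'
#' Degenerate features are flagged rather than thrown: fewer than 2 usable
#' pairs, or all differences exactly zero, yields `p_t = NA`
#' (`untestable`); identical nonzero differences (`sd = 0`) yield `p_t =
#' 0` with `degenerate = TRUE`.
#'
#' @param m normalized Ct matrix.
#' @param a sample annotation; pairs are taken from [complete_pairs()].
#' @return data.frame (class `de_result`) with one row per feature:
#'   `feature_id`, `n_pairs_used`, `mean_delta_ct`, `direction`, `t_stat`,
#'   `df`, `p_t`, `p_adj` (Benjamini-Hochberg over testable features),
#'   `degenerate`, `untestable`.
#' @export
paired_t <- function(m, a) {
  pr <- complete_pairs(a)
  if (nrow(pr) < 2L) stop("need at least 2 complete normal/malignant pairs")
  D <- m[, pr$malignant, drop = FALSE] - m[, pr$normal, drop = FALSE]
  n <- rowSums(!is.na(D))
  mean_d <- ifelse(n > 0L, rowMeans(D, na.rm = TRUE), NA_real_)
  ss <- rowSums((D - mean_d)^2, na.rm = TRUE)
  sd_d <- ifelse(n > 1L, sqrt(ss / pmax(n - 1L, 1L)), NA_real_)

  t_stat <- rep(NA_real_, nrow(m))
  p <- rep(NA_real_, nrow(m))
  untestable <- n < 2L
  testable <- !untestable
  zero_sd <- testable & sd_d == 0
  all_zero <- zero_sd & mean_d == 0
  untestable <- untestable | all_zero
  degenerate <- zero_sd & !all_zero

  reg <- testable & !zero_sd
  t_stat[reg] <- mean_d[reg] / (sd_d[reg] / sqrt(n[reg]))
  p[reg] <- 2 * stats::pt(abs(t_stat[reg]), n[reg] - 1L, lower.tail = FALSE)
  t_stat[degenerate] <- sign(mean_d[degenerate]) * Inf
  p[degenerate] <- 0

  res <- data.frame(
    feature_id = rownames(m),
    n_pairs_used = n,
    mean_delta_ct = ifelse(n > 0L, mean_d, NA_real_),
    direction = ifelse(is.na(mean_d) | mean_d == 0, NA_character_,
                       ifelse(mean_d < 0, "+", "-")),
    t_stat = t_stat,
    df = ifelse(n >= 1L, n - 1L, NA_integer_),
    p_t = p,
    degenerate = degenerate,
    untestable = untestable,
    stringsAsFactors = FALSE
  )
  res$p_adj <- bh_adjust(res$p_t)
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Paired Wilcoxon signed-rank test per feature
#'
#' Two-sided signed-rank p per miRNA on the same within-case differences
#' as [paired_t()]. Zero differences are dropped before ranking. The exact
#' null distribution is used for n <= 25 without ties in the absolute
#' differences; otherwise a normal approximation with continuity and tie
#' corrections is used.
#'
#' @inheritParams paired_t
#' @return data.frame: `feature_id`, `n_pairs_used` (nonzero differences
#'   actually ranked), `p_wilcoxon`.
#' @export
paired_wilcoxon <- function(m, a) {
  pr <- complete_pairs(a)
  if (nrow(pr) < 2L) stop("need at least 2 complete normal/malignant pairs")
  D <- m[, pr$malignant, drop = FALSE] - m[, pr$normal, drop = FALSE]
  res <- t(apply(D, 1L, function(d) {
    d <- d[!is.na(d)]
    if (length(d) < 2L) return(c(n = length(d), p = NA_real_))
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) return(c(n = 0, p = NA_real_))
    c(n = n, p = signed_rank_p(d))
  }))
  out <- data.frame(feature_id = rownames(m),
                    n_pairs_used = as.integer(res[, "n"]),
                    p_wilcoxon = res[, "p"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# two-sided signed-rank p for nonzero differences d
signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !ties) {
    p <- if (W > mu) {
      2 * stats::psignrank(W - 1, n, lower.tail = FALSE)
    } else if (W < mu) {
      2 * stats::psignrank(W, n)
    } else 1
    return(min(1, p))
  }
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(NA_real_)
  z <- W - mu
  z <- z - sign(z) * 0.5          # continuity correction
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over the testable (non-`NA`)
#' p-values; `NA`s pass through and do not count toward the number of
#' tests.
#'
#' @param p p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Select an expression signature by significance threshold
#'
#' Keeps features with raw paired-t p strictly below `alpha`, ordered by
#' ascending p with lexicographic feature-id tie-break, so signatures at
#' nested thresholds are nested sets.
#'
#' @param results a `de_result` from [paired_t()].
#' @param alpha selection threshold (strict inequality, as in "p < 1e-4").
#' @return object of class `mirna_signature`: list with `feature_ids`,
#'   `alpha`, and the members' `p` values.
#' @export
select_signature <- function(results, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  keep <- !is.na(results$p_t) & results$p_t < alpha
  sub <- results[keep, , drop = FALSE]
  ord <- order(sub$p_t, sub$feature_id)
  sig <- structure(list(
    feature_ids = sub$feature_id[ord],
    alpha = alpha,
    p = stats::setNames(sub$p_t[ord], sub$feature_id[ord])
  ), class = "mirna_signature")
  if (length(sig$feature_ids) == 0L) {
    message("empty signature at alpha = ", format(alpha))
  }
  sig
}

#' @export
print.mirna_signature <- function(x, ...) {
  cat("miRNA signature:", length(x$feature_ids),
      "features at p <", format(x$alpha), "\n")
  if (length(x$feature_ids) > 0L) {
    show <- utils::head(x$feature_ids, 10L)
    cat(" ", paste(show, collapse = ", "),
        if (length(x$feature_ids) > 10L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
length.mirna_signature <- function(x) length(x$feature_ids)

# accept either a signature object or a plain character vector of features
signature_features <- function(signature) {
  if (inherits(signature, "mirna_signature")) return(signature$feature_ids)
  if (is.character(signature)) return(signature)
  stop("signature must be a 'mirna_signature' or a character vector")
}

#' Concordance of paired t and Wilcoxon selections
#'
#' Per-feature flags for which test calls the feature differentially
#' expressed at `alpha`, plus overlap counts: a reconciliation of the
#' parametric and nonparametric views of the same paired design.
#'
#' @param results_t `de_result` from [paired_t()].
#' @param results_w data.frame from [paired_wilcoxon()].
#' @param alpha significance threshold applied to both tests.
#' @return list with `table` (feature_id, p_t, p_wilcoxon, sig_t, sig_w),
#'   `n_t`, `n_w`, `n_both`, and `overlap_frac` = shared calls / size of
#'   the smaller selection (NA when either selection is empty).
#' @export
compare_tests <- function(results_t, results_w, alpha = 1e-4) {
  tab <- merge(results_t[, c("feature_id", "p_t")],
               results_w[, c("feature_id", "p_wilcoxon")],
               by = "feature_id", sort = FALSE)
  tab$sig_t <- !is.na(tab$p_t) & tab$p_t < alpha
  tab$sig_w <- !is.na(tab$p_wilcoxon) & tab$p_wilcoxon < alpha
  n_t <- sum(tab$sig_t)
  n_w <- sum(tab$sig_w)
  n_both <- sum(tab$sig_t & tab$sig_w)
  list(table = tab, alpha = alpha, n_t = n_t, n_w = n_w, n_both = n_both,
       overlap_frac = if (min(n_t, n_w) > 0L) n_both / min(n_t, n_w)
                      else NA_real_)
}
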