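#' Cross-validation configuration
#'
#' Defaults match the generalization test of a 19-pair cohort: in each of
#' 15 repetitions, 14 pairs (28 samples) are drawn for signature
#' re-selection at p < 1e-4 and the remaining 10 samples are clustered on
#' that signature into 3 clusters (one cluster absorbing the typical
#' outlier) and scored by majority vote.
#'
#' @param n_repeats number of repetitions.
#' @param n_train_pairs pairs drawn (intact) for training each repeat.
#' @param alpha signature-selection threshold (strict).
#' @param k_clusters clusters to cut among the held-out samples.
#' @param seed RNG seed driving a per-repeat seed sequence.
#' @param permute_labels permute tissue-class labels before each repeat
#'   (the null control).
#' @param permutation one of `"pairwise"` (swap normal/malignant within
#'   each case with probability 1/2, preserving the paired design) or
#'   `"free"` (unrestricted shuffle of labels across samples; cases that
#'   end up without one label of each kind drop out of the paired test).
#' @return object of class `cv_config`.
#' @export
cv_config <- function(n_repeats = 15, n_train_pairs = 14, alpha = 1e-4,
                      k_clusters = 3, seed = NULL, permute_labels = FALSE,
                      permutation = c("pairwise", "free")) {
  if (!is.numeric(n_repeats) || n_repeats < 1 || n_repeats != round(n_repeats)) {
    stop("invalid 'n_repeats'")
  }
  if (!is.numeric(n_train_pairs) || n_train_pairs < 2 ||
      n_train_pairs != round(n_train_pairs)) {
    stop("invalid 'n_train_pairs'")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("invalid 'alpha'")
  if (!is.numeric(k_clusters) || k_clusters < 1 ||
      k_clusters != round(k_clusters)) {
    stop("invalid 'k_clusters'")
  }
  structure(list(n_repeats = as.integer(n_repeats),
                 n_train_pairs = as.integer(n_train_pairs),
                 alpha = alpha, k_clusters = as.integer(k_clusters),
                 seed = seed, permute_labels = isTRUE(permute_labels),
                 permutation = match.arg(permutation)),
            class = "cv_config")
}

#' Cross-validated generalization test of a signature pipeline
#'
#' Each repetition: (1) draw `n_train_pairs` cases uniformly without
#' replacement, keeping pairs intact; (2) run the paired t-test on the
#' training samples only; (3) select the signature at `alpha`; (4)
#' cluster only the held-out samples on that signature (Euclidean
#' distance, average linkage, cut at `k_clusters`); (5) score by majority
#' vote. Held-out samples never touch signature selection. A repetition
#' whose signature is empty is recorded as failed and excluded from the
#' error-rate mean (but still counts in selection-frequency
#' denominators).
#'
#' @param m normalized Ct matrix.
#' @param a sample annotation.
#' @param cfg a [cv_config()].
#' @return object of class `cv_report`: per-repeat records (`train_cases`,
#'   `held_samples`, `signature`, `n_misplaced`, `error_rate`, `failed`),
#'   misplaced-count `histogram`, `average_error_rate` (fraction) and
#'   `average_error_rate_pct`, `selection_frequency` table, `n_failed`,
#'   and the configuration.
#' @export
run_cv <- function(m, a, cfg = cv_config()) {
  stopifnot(inherits(cfg, "cv_config"))
  a <- validate_sample_annotation(a)
  pairs_all <- complete_pairs(a)
  if (nrow(pairs_all) < cfg$n_train_pairs + 1L) {
    stop("need at least n_train_pairs + 1 complete pairs (have ",
         nrow(pairs_all), ")")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  repeat_seeds <- sample.int(.Machine$integer.max, cfg$n_repeats)

  held_size <- 2L * (nrow(pairs_all) - cfg$n_train_pairs)
  repeats <- vector("list", cfg$n_repeats)
  for (i in seq_len(cfg$n_repeats)) {
    set.seed(repeat_seeds[i])
    a_i <- a
    if (cfg$permute_labels) {
      a_i <- permute_tissue_labels(a_i, pairs_all, mode = cfg$permutation)
    }
    pairs_i <- complete_pairs(a_i)
    train_cases <- sample(pairs_all$case_id, cfg$n_train_pairs)
    train_pairs <- pairs_i[pairs_i$case_id %in% train_cases, , drop = FALSE]
    held_cases <- setdiff(pairs_all$case_id, train_cases)
    held_samples <- a_i$sample_id[a_i$case_id %in% held_cases]

    rec <- list(seed = repeat_seeds[i], train_cases = train_cases,
                held_samples = held_samples, signature = character(0),
                n_misplaced = NA_integer_, error_rate = NA_real_,
                failed = FALSE, fail_reason = NA_character_)
    if (nrow(train_pairs) < 2L) {
      rec$failed <- TRUE
      rec$fail_reason <- "fewer than 2 usable training pairs"
      repeats[[i]] <- rec
      next
    }
    a_train <- a_i[a_i$case_id %in% train_pairs$case_id, , drop = FALSE]
    de <- paired_t(m[, a_train$sample_id, drop = FALSE], a_train)
    sig <- suppressMessages(select_signature(de, cfg$alpha))
    rec$signature <- sig$feature_ids
    if (length(sig) == 0L) {
      rec$failed <- TRUE
      rec$fail_reason <- "empty signature"
      repeats[[i]] <- rec
      next
    }
    k <- min(cfg$k_clusters, length(held_samples))
    sc <- tryCatch({
      d <- suppressMessages(
        distance_matrix(m[, held_samples, drop = FALSE], sig))
      asg <- cut_tree(average_linkage(d), k)
      suppressMessages(score_assignment(asg, a_i))
    }, error = function(e) e)
    if (inherits(sc, "error")) {
      rec$failed <- TRUE
      rec$fail_reason <- conditionMessage(sc)
    } else {
      rec$n_misplaced <- sc$n_misplaced
      rec$error_rate <- sc$error_rate
    }
    repeats[[i]] <- rec
  }

  ok <- !vapply(repeats, `[[`, logical(1L), "failed")
  counts <- vapply(repeats[ok], `[[`, integer(1L), "n_misplaced")
  histogram <- table(factor(counts, levels = 0:held_size))
  avg <- if (any(ok)) {
    mean(vapply(repeats[ok], `[[`, numeric(1L), "error_rate"))
  } else NA_real_

  all_feats <- sort(unique(unlist(lapply(repeats, `[[`, "signature"))))
  times <- vapply(all_feats, function(f) {
    sum(vapply(repeats, function(r) f %in% r$signature, logical(1L)))
  }, integer(1L))
  freq <- data.frame(feature_id = all_feats,
                     times_selected = times,
                     frequency = if (length(times)) times / cfg$n_repeats
                                 else numeric(0),
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$times_selected, freq$feature_id), , drop = FALSE]
  rownames(freq) <- NULL

  structure(list(repeats = repeats, histogram = histogram,
                 held_out_size = held_size,
                 average_error_rate = avg,
                 average_error_rate_pct = 100 * avg,
                 selection_frequency = freq,
                 n_failed = sum(!ok), config = cfg),
            class = "cv_report")
}

# permute normal/malignant labels for the null control
permute_tissue_labels <- function(a, pairs, mode = "pairwise") {
  if (mode == "pairwise") {
    flip <- stats::runif(nrow(pairs)) < 0.5
    for (j in which(flip)) {
      idx <- match(c(pairs$normal[j], pairs$malignant[j]), a$sample_id)
      a$tissue_class[idx] <- rev(a$tissue_class[idx])
    }
  } else {
    a$tissue_class <- sample(a$tissue_class)
    if (!is.null(a$in_paired_analysis)) a$in_paired_analysis <- NULL
  }
  a
}

#' Permuted-label null run of the cross-validation
#'
#' Runs [run_cv()] with tissue-class labels randomly permuted before each
#' repetition. With no true class signal, signatures collapse toward the
#' type-I expectation `n_features * alpha` and most repetitions fail
#' empty.
#'
#' @inheritParams run_cv
#' @return a `cv_report`.
#' @export
run_permutation_null <- function(m, a, cfg = cv_config()) {
  cfg$permute_labels <- TRUE
  run_cv(m, a, cfg)
}

#' Summarize a misclassification distribution
#'
#' Aggregates per-repetition misplaced-sample counts into a histogram,
#' the average error rate (mean of `count / held_out_size`, as a
#' percentage), and the complementary accuracy.
#'
#' @param counts misplaced-sample count per repetition.
#' @param held_out_size number of samples clustered per repetition.
#' @return list: `histogram`, `n_repeats`, `average_error_rate_pct`,
#'   `accuracy_pct`.
#' @export
summarize_misclassification <- function(counts, held_out_size) {
  if (!is.numeric(counts) || any(counts != round(counts)) || anyNA(counts)) {
    stop("counts must be non-missing integers")
  }
  if (any(counts < 0 | counts > held_out_size)) {
    stop("misplaced count out of range [0, ", held_out_size, "]")
  }
  err <- 100 * mean(counts / held_out_size)
  list(histogram = table(factor(counts, levels = 0:held_out_size)),
       n_repeats = length(counts),
       average_error_rate_pct = err,
       accuracy_pct = 100 - err)
}

#' Per-feature selection frequency across CV repetitions
#'
#' @param report a `cv_report` from [run_cv()].
#' @return data.frame: `feature_id`, `times_selected`, `frequency`
#'   (count / total repetitions).
#' @export
selection_frequency <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  if (report$n_failed >= report$config$n_repeats) {
    stop("no successful repetitions in the report")
  }
  report$selection_frequency
}

#' @export
print.cv_report <- function(x, ...) {
  n_ok <- x$config$n_repeats - x$n_failed
  cat("Cross-validation:", x$config$n_repeats, "repetitions (",
      x$n_failed, "failed ),", x$config$n_train_pairs,
      "training pairs, alpha =", format(x$config$alpha), "\n")
  if (n_ok > 0L) {
    cat("  average error rate:",
        sprintf("%.1f%%", x$average_error_rate_pct),
        "over", x$held_out_size, "held-out samples per repeat\n")
    cat("  misplaced-count histogram:\n")
    print(x$histogram[x$histogram > 0])
  }
  invisible(x)
}
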