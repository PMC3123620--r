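#' Run the full signature pipeline end to end
#'
#' Composes the whole analysis: ingest (or simulate) -> sample exclusion
#' -> quantile normalization -> paired t and Wilcoxon tests with BH
#' correction -> signature selection at two thresholds -> full-cohort
#' clustering at `k_full` with misplacement scoring -> cross-validated
#' generalization test -> permuted-label null -> PCA of the stringent
#' signature -> optional Gleason subgroup sweep. Every stochastic step is
#' seeded from `seed`, so a rerun with the same inputs and seed is
#' byte-identical, and each stage logs the counts it produces.
#'
#' @param ct Ct matrix, or path to a delimited Ct table.
#' @param annotation sample annotation data.frame, or path.
#' @param sim_config alternatively, a [simulation_config()]; the cohort is
#'   then generated (its `seed` is derived from `seed` if unset).
#' @param exclude sample ids to exclude before analysis.
#' @param normalize apply quantile normalization (TRUE unless the input
#'   is already normalized).
#' @param alphas two selection thresholds, permissive then stringent.
#' @param k_full clusters for the full-cohort evaluation.
#' @param cv a [cv_config()]; its seed is derived from `seed` if unset.
#' @param subgroup run the Gleason subgroup sweep when the annotation has
#'   >= 2 Gleason levels among malignant samples.
#' @param subgroup_thresholds thresholds for [subgroup_sweep()].
#' @param out_dir optional directory for artifacts (normalized matrix,
#'   DE table, signatures, CV tables, JSON summary).
#' @param seed global seed.
#' @param verbose narrate stages via `message()`.
#' @return object of class `mirct_pipeline`: all stage results plus a
#'   flat `summary` list (the JSON payload).
#' @export
run_pipeline <- function(ct = NULL, annotation = NULL, sim_config = NULL,
                         exclude = character(), normalize = TRUE,
                         alphas = c(1e-4, 1e-5), k_full = 2,
                         cv = cv_config(), subgroup = TRUE,
                         subgroup_thresholds = c(0.05, 0.04, 0.03, 0.02,
                                                 0.017, 0.01, 0.005, 0.001,
                                                 1e-4, 1e-5),
                         out_dir = NULL, seed = 1, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stopifnot(length(alphas) == 2L, all(alphas > 0), all(alphas < 1))
  set.seed(seed)
  derived <- sample.int(.Machine$integer.max, 3L)

  truth <- NULL
  if (!is.null(sim_config)) {
    if (is.null(sim_config$seed)) sim_config$seed <- derived[1L]
    ds <- generate_paired_dataset(sim_config)
    ct <- ds$ct
    annotation <- ds$annotation
    truth <- ds
    say("simulated cohort: ", nrow(ct), " miRNAs x ", ncol(ct), " samples")
  } else {
    if (is.character(ct)) ct <- read_ct_table(ct)
    if (is.character(annotation)) annotation <- read_sample_annotation(annotation)
    validate_ct_matrix(ct)
    annotation <- validate_sample_annotation(annotation)
    say("ingested cohort: ", nrow(ct), " miRNAs x ", ncol(ct), " samples")
  }

  ex <- exclude_samples(ct, annotation, exclude)
  ct <- ex$ct
  annotation <- ex$annotation
  pairs <- complete_pairs(annotation)
  say(length(exclude), " sample(s) excluded; ", nrow(pairs),
      " complete pairs enter the paired analyses")

  norm_report <- NULL
  if (normalize) {
    qn <- quantile_normalize(ct)
    ct <- qn$ct
    norm_report <- qn$report
    say("quantile normalization applied (",
        sum(norm_report$n_missing), " missing wells untouched)")
  }

  de <- paired_t(ct, annotation)
  wil <- paired_wilcoxon(ct, annotation)
  de$p_wilcoxon <- wil$p_wilcoxon[match(de$feature_id, wil$feature_id)]
  comparison <- compare_tests(de, wil, alpha = alphas[1L])
  sig_loose <- suppressMessages(select_signature(de, alphas[1L]))
  sig_strict <- suppressMessages(select_signature(de, alphas[2L]))
  say("differential expression: ", length(sig_loose), " miRNAs at p < ",
      format(alphas[1L]), ", ", length(sig_strict), " at p < ",
      format(alphas[2L]), "; Wilcoxon agrees on ", comparison$n_both,
      " of the ", comparison$n_t, " t-test calls")

  cohort_scores <- lapply(list(loose = sig_loose, strict = sig_strict),
                          function(sig) {
    if (length(sig) == 0L) return(NULL)
    asg <- cut_tree(average_linkage(distance_matrix(ct, sig)),
                    min(k_full, ncol(ct)))
    suppressMessages(score_assignment(asg, annotation))
  })
  for (nm in names(cohort_scores)) {
    sc <- cohort_scores[[nm]]
    if (!is.null(sc)) {
      say("full-cohort clustering (", nm, " signature, k = ", k_full, "): ",
          sc$n_misplaced, " of ", sc$n, " samples misplaced")
    }
  }

  if (is.null(cv$seed)) cv$seed <- derived[2L]
  cv_report <- run_cv(ct, annotation, cv)
  say("cross-validation: average error rate ",
      sprintf("%.1f%%", cv_report$average_error_rate_pct), " over ",
      cv$n_repeats, " repetitions (", cv_report$n_failed, " failed)")
  cv_null <- cv
  cv_null$permute_labels <- TRUE
  null_report <- run_cv(ct, annotation, cv_null)
  say("permuted-label null: ", null_report$n_failed, " of ",
      cv$n_repeats, " repetitions produced no signature")

  pca_res <- if (length(sig_strict) >= 2L) ct_pca(ct, sig_strict) else NULL

  sweep_res <- NULL
  gl <- annotation$gleason_score[annotation$tissue_class == "malignant"]
  if (subgroup && length(unique(gl[!is.na(gl)])) >= 2L) {
    sweep_res <- suppressMessages(
      subgroup_sweep(ct, annotation, thresholds = subgroup_thresholds,
                     seed = derived[3L]))
    say("subgroup sweep: ", length(sweep_res$selected_features),
        " miRNAs at p < ", format(sweep_res$best_threshold), " -> ",
        sweep_res$misplaced, " of ", sweep_res$n_samples,
        " malignant samples misplaced vs Gleason score")
  }

  summary <- list(
    n_features = nrow(ct),
    n_samples = ncol(ct),
    n_pairs = nrow(pairs),
    alpha_loose = alphas[1L],
    alpha_strict = alphas[2L],
    signature_size_loose = length(sig_loose),
    signature_size_strict = length(sig_strict),
    wilcoxon_significant = comparison$n_w,
    tests_overlap = comparison$n_both,
    full_cohort_misplaced_loose =
      if (is.null(cohort_scores$loose)) NA_integer_
      else cohort_scores$loose$n_misplaced,
    full_cohort_misplaced_strict =
      if (is.null(cohort_scores$strict)) NA_integer_
      else cohort_scores$strict$n_misplaced,
    cv_average_error_rate_pct = cv_report$average_error_rate_pct,
    cv_failed_repeats = cv_report$n_failed,
    null_failed_repeats = null_report$n_failed,
    pca_var_explained_pc1 =
      if (is.null(pca_res)) NA_real_ else pca_res$var_explained[1L],
    pca_var_explained_pc2 =
      if (is.null(pca_res) || length(pca_res$var_explained) < 2L) NA_real_
      else pca_res$var_explained[2L],
    subgroup_threshold =
      if (is.null(sweep_res)) NA_real_ else sweep_res$best_threshold,
    subgroup_misplaced =
      if (is.null(sweep_res)) NA_integer_ else sweep_res$misplaced,
    seed = seed
  )

  result <- structure(list(
    ct = ct, annotation = annotation, truth = truth,
    normalization = norm_report, de = de, comparison = comparison,
    signature_loose = sig_loose, signature_strict = sig_strict,
    cohort_scores = cohort_scores, cv = cv_report, null = null_report,
    pca = pca_res, subgroups = sweep_res, summary = summary
  ), class = "mirct_pipeline")

  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_table(result$ct, file.path(out_dir, "ct_normalized.csv"))
  write_sample_annotation(result$annotation,
                          file.path(out_dir, "annotation.csv"))
  utils::write.table(result$de, file.path(out_dir, "de_results.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE, na = "")
  writeLines(result$signature_loose$feature_ids,
             file.path(out_dir, "signature_loose.txt"))
  writeLines(result$signature_strict$feature_ids,
             file.path(out_dir, "signature_strict.txt"))
  reps <- result$cv$repeats
  cvdf <- data.frame(
    repeat_idx = seq_along(reps),
    n_signature = vapply(reps, function(r) length(r$signature), integer(1L)),
    n_misplaced = vapply(reps, `[[`, integer(1L), "n_misplaced"),
    failed = vapply(reps, `[[`, logical(1L), "failed")
  )
  utils::write.table(cvdf, file.path(out_dir, "cv_repeats.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE, na = "")
  utils::write.table(result$cv$selection_frequency,
                     file.path(out_dir, "selection_frequency.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.mirct_pipeline <- function(x, ...) {
  s <- x$summary
  cat("mirct pipeline run (seed ", s$seed, ")\n", sep = "")
  cat("  cohort: ", s$n_features, " miRNAs x ", s$n_samples, " samples, ",
      s$n_pairs, " pairs\n", sep = "")
  cat("  signatures: ", s$signature_size_loose, " miRNAs at p < ",
      format(s$alpha_loose), ", ", s$signature_size_strict, " at p < ",
      format(s$alpha_strict), "\n", sep = "")
  cat("  CV average error rate: ",
      sprintf("%.1f%%", s$cv_average_error_rate_pct), "\n", sep = "")
  invisible(x)
}
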