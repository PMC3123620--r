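# build a Ct matrix realizing the given per-feature difference rows:
# normal = 25, malignant = 25 + d
ct_from_diffs <- function(D) {
  n_cases <- ncol(D)
  a <- make_paired_annotation(n_cases)
  m <- matrix(25, nrow(D), 2 * n_cases,
              dimnames = list(paste0("f", seq_len(nrow(D))), a$sample_id))
  m[, a$tissue_class == "malignant"] <- 25 + D
  list(ct = m, annotation = a)
}

test_that("paired t matches the closed form on differences {1,2,3}", {
  d <- ct_from_diffs(matrix(c(1, 2, 3), nrow = 1))
  res <- paired_t(d$ct, d$annotation)
  expect_equal(res$t_stat, 3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_t, 0.0741799, tolerance = 1e-6)
  expect_equal(res$mean_delta_ct, 2)
  expect_equal(res$direction, "-")          # higher Ct = lower expression
})

test_that("swapping class labels negates t, keeps p, flips direction", {
  set.seed(20)
  d <- random_ct_matrix(10, 6)
  a_swapped <- d$annotation
  a_swapped$tissue_class <- ifelse(a_swapped$tissue_class == "normal",
                                   "malignant", "normal")
  r1 <- paired_t(d$ct, d$annotation)
  r2 <- paired_t(d$ct, a_swapped)
  expect_equal(r2$t_stat, -r1$t_stat)
  expect_equal(r2$p_t, r1$p_t)
  expect_equal(r2$direction, ifelse(r1$direction == "+", "-", "+"))
})

test_that("degenerate difference vectors are flagged, not thrown", {
  D <- rbind(c(0, 0, 0),    # all zero: untestable
             c(2, 2, 2),    # sd 0, nonzero: p = 0, degenerate
             c(1, NA, NA))  # < 2 usable pairs: untestable
  d <- ct_from_diffs(D)
  m <- d$ct
  m[3, c("s02M", "s03M")] <- NA
  res <- paired_t(m, d$annotation)
  expect_true(res$untestable[1])
  expect_true(is.na(res$p_t[1]))
  expect_true(res$degenerate[2])
  expect_equal(res$p_t[2], 0)
  expect_equal(res$t_stat[2], Inf)
  expect_true(res$untestable[3])
})

test_that("paired t equals the one-sample t.test oracle on 100 random instances", {
  set.seed(21)
  for (rep in 1:100) {
    n_cases <- sample(3:12, 1)
    d <- random_ct_matrix(1, n_cases)
    res <- paired_t(d$ct, d$annotation)
    nrm <- d$ct[1, d$annotation$tissue_class == "normal"]
    mal <- d$ct[1, d$annotation$tissue_class == "malignant"]
    ref <- t.test(mal, nrm, paired = TRUE)
    expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_t, ref$p.value, tolerance = 1e-12)
    expect_equal(res$mean_delta_ct, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("per-feature missing pairs are dropped before testing", {
  set.seed(22)
  d <- random_ct_matrix(1, 8)
  d$ct[1, "s03M"] <- NA
  res <- paired_t(d$ct, d$annotation)
  expect_equal(res$n_pairs_used, 7)
  nrm <- d$ct[1, d$annotation$tissue_class == "normal"]
  mal <- d$ct[1, d$annotation$tissue_class == "malignant"]
  ref <- t.test(mal[-3], nrm[-3], paired = TRUE)
  expect_equal(res$p_t, ref$p.value, tolerance = 1e-12)
})

test_that("signed-rank p is exact for the hand-enumerable cases", {
  d3 <- ct_from_diffs(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(paired_wilcoxon(d3$ct, d3$annotation)$p_wilcoxon, 0.25)
  d6 <- ct_from_diffs(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1))
  expect_equal(paired_wilcoxon(d6$ct, d6$annotation)$p_wilcoxon, 2 / 64)
  # sign symmetry
  dneg <- ct_from_diffs(matrix(-c(1, 2, 3), nrow = 1))
  expect_equal(paired_wilcoxon(dneg$ct, dneg$annotation)$p_wilcoxon, 0.25)
})

test_that("signed-rank p matches enumeration and wilcox.test on 100 random instances", {
  set.seed(23)
  for (rep in 1:100) {
    n_cases <- sample(4:10, 1)
    diffs <- rnorm(n_cases)             # continuous: tie-free a.s.
    d <- ct_from_diffs(matrix(diffs, nrow = 1))
    p <- paired_wilcoxon(d$ct, d$annotation)$p_wilcoxon
    expect_equal(p, oracle_signed_rank_p(diffs), tolerance = 1e-12)
    ref <- wilcox.test(diffs, exact = TRUE)
    expect_equal(p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("zero differences are dropped before ranking", {
  d <- ct_from_diffs(matrix(c(0, 1, 2, 3), nrow = 1))
  res <- paired_wilcoxon(d$ct, d$annotation)
  expect_equal(res$n_pairs_used, 3)
  expect_equal(res$p_wilcoxon, 0.25)
})

test_that("BH adjustment follows the step-up formula and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(24)
  for (rep in 1:100) {
    p <- runif(sample(2:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in p
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  # NA pass-through: m counts only testable p-values
  expect_equal(bh_adjust(c(0.01, NA, 0.02)),
               c(oracle_bh(c(0.01, 0.02))[1], NA, oracle_bh(c(0.01, 0.02))[2]))
})

test_that("signatures are strict-threshold, ordered, and nested across alphas", {
  res <- data.frame(
    feature_id = c("b", "a", "c", "d"),
    p_t = c(2e-5, 2e-5, 5e-6, 0.5),
    stringsAsFactors = FALSE
  )
  sig4 <- select_signature(res, 1e-4)
  expect_equal(sig4$feature_ids, c("c", "a", "b"))   # p then id tie-break
  sig5 <- select_signature(res, 1e-5)
  expect_equal(sig5$feature_ids, "c")
  expect_true(all(sig5$feature_ids %in% sig4$feature_ids))
  expect_message(sig0 <- select_signature(res, 0), "empty")
  expect_length(sig0$feature_ids, 0)
  # boundary is strict: p == alpha is excluded
  expect_false("a" %in% select_signature(res, 2e-5)$feature_ids)
})

test_that("planted up-regulation yields '+' calls under the Ct-decrease encoding", {
  cfg <- simulation_config(n_cases = 6, n_features = 30, n_de = 4,
                           effect_ct = 2, effect_sign_fraction_up = 1,
                           case_sd = 0, noise_sd = 0, array_offset_sd = 0,
                           missing_rate = 0, seed = 25)
  ds <- generate_paired_dataset(cfg)
  res <- paired_t(ds$ct, ds$annotation)
  calls <- res$direction[match(ds$truth_de$feature_id, res$feature_id)]
  expect_true(all(calls == "+"))
})

test_that("test-comparison overlap counts behave at the extremes", {
  rt <- data.frame(feature_id = letters[1:4], p_t = c(1e-6, 1e-6, 0.5, 0.6))
  rw <- data.frame(feature_id = letters[1:4],
                   p_wilcoxon = c(1e-6, 1e-6, 0.5, 0.6))
  cmp <- compare_tests(rt, rw, alpha = 1e-4)
  expect_equal(cmp$overlap_frac, 1)
  expect_equal(cmp$n_both, 2)
  rw2 <- data.frame(feature_id = letters[1:4],
                    p_wilcoxon = c(0.5, 0.6, 1e-6, 1e-6))
  cmp2 <- compare_tests(rt, rw2, alpha = 1e-4)
  expect_equal(cmp2$n_both, 0)
  expect_equal(cmp2$overlap_frac, 0)
})

test_that("type-I error of the paired t is controlled on null data", {
  tot <- 0L
  n_tests <- 0L
  for (s in 1:30) {
    ds <- generate_null_dataset(
      simulation_config(n_features = 200, seed = 2000 + s))
    ct <- quantile_normalize(ds$ct)$ct
    de <- paired_t(ct, ds$annotation)
    tot <- tot + sum(de$p_t < 0.01, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(de$p_t))
  }
  rate <- tot / n_tests
  # binomial tolerance around alpha = 0.01
  expect_lt(abs(rate - 0.01), 4 * sqrt(0.01 * 0.99 / n_tests) + 2e-3)
})
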