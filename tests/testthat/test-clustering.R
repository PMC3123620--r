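test_that("Euclidean distances on a signature match hand values and a brute force", {
  m <- rbind(f1 = c(a = 0, b = 3), f2 = c(a = 0, b = 4))
  # validate_ct_matrix wants > 0 values; shift preserves distances
  m <- m + 10
  d <- distance_matrix(m, c("f1", "f2"))
  expect_equal(as.vector(d), 5)
  expect_equal(as.vector(distance_matrix(cbind(m, c = m[, "a"]),
                                         c("f1", "f2")))[2], 0)
  set.seed(30)
  mm <- matrix(runif(24, 20, 35), nrow = 4,
               dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  d <- as.matrix(distance_matrix(mm, rownames(mm)))
  for (i in 1:6) for (j in 1:6) {
    expect_equal(d[i, j], sqrt(sum((mm[, i] - mm[, j])^2)), tolerance = 1e-12)
  }
  expect_error(distance_matrix(mm, c("f1", "zzz")), "zzz")
})

test_that("missing wells rescale distances by sqrt(n_total / n_used)", {
  m <- rbind(f1 = c(a = 21, b = 24), f2 = c(a = 22, b = 26),
             f3 = c(a = 23, b = NA))
  d <- as.vector(distance_matrix(m, rownames(m)))
  expect_equal(d, sqrt((9 + 16) * 3 / 2), tolerance = 1e-12)
})

test_that("UPGMA reproduces the hand dendrogram for 1-D points {0, 1, 10}", {
  dm <- as.matrix(dist(c(0, 1, 10)))
  hc <- average_linkage(dm)
  expect_equal(hc$height, c(1, 9.5))      # mean(10, 9) = 9.5
  cl <- cut_tree(hc, 2)$cluster
  expect_equal(cutree_partition(cl), canonical_partition(list(c(1, 2), 3)))
})

test_that("two samples merge at exactly their distance", {
  dm <- matrix(c(0, 4.2, 4.2, 0), 2)
  hc <- average_linkage(dm)
  expect_equal(hc$height, 4.2)
})

test_that("UPGMA equals an exhaustive naive oracle on 100 random instances", {
  set.seed(31)
  for (rep in 1:100) {
    n <- 7
    pts <- matrix(runif(n * 3), n)
    dm <- as.matrix(dist(pts))
    hc <- average_linkage(dm)
    orc <- oracle_upgma(dm)
    expect_equal(hc$height, orc$heights, tolerance = 1e-10)
    # merge heights are monotone non-decreasing
    expect_true(all(diff(hc$height) >= -1e-12))
    # cuts at every k agree with the oracle's partial partitions
    for (k in 2:(n - 1)) {
      ours <- cutree_partition(cut_tree(hc, k)$cluster)
      theirs <- canonical_partition(orc$partitions[[n - k]])
      expect_equal(ours, theirs)
    }
  }
})

test_that("cutting a tree gives the degenerate partitions at k = 1 and k = n", {
  set.seed(32)
  dm <- as.matrix(dist(matrix(runif(12), 6)))
  hc <- average_linkage(dm)
  expect_equal(unname(cut_tree(hc, 1)$cluster), rep(1L, 6))
  expect_length(unique(cut_tree(hc, 6)$cluster), 6L)
  expect_error(cut_tree(hc, 0), "k must be")
  expect_error(cut_tree(hc, 7), "k must be")
})

test_that("partitions only refine as k grows", {
  set.seed(33)
  for (rep in 1:20) {
    dm <- as.matrix(dist(matrix(runif(16), 8)))
    hc <- average_linkage(dm)
    for (k in 2:8) {
      coarse <- cut_tree(hc, k - 1)$cluster
      fine <- cut_tree(hc, k)$cluster
      # every fine cluster sits inside exactly one coarse cluster
      expect_true(all(tapply(coarse, fine,
                             function(x) length(unique(x))) == 1L))
    }
  }
})

test_that("UPGMA on an ultrametric input reconstructs the generating tree", {
  set.seed(34)
  base <- hclust(dist(matrix(runif(20), 10)), method = "average")
  dm <- as.matrix(cophenetic(base))
  hc <- average_linkage(dm)
  expect_equal(hc$height, base$height, tolerance = 1e-10)
  expect_equal(as.matrix(cophenetic(hc)), dm, tolerance = 1e-10)
})

test_that("invalid distance input is rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(average_linkage(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(average_linkage(neg), "non-negative")
})

test_that("majority scoring counts minority members as misplaced", {
  cl <- c(A1 = 1, A2 = 1, A3 = 1, B1 = 2, B2 = 2)
  a <- data.frame(sample_id = names(cl),
                  case_id = paste0("c", 1:5),
                  tissue_class = c("malignant", "malignant", "normal",
                                   "normal", "normal"))
  sc <- score_assignment(cl, a)
  expect_equal(sc$n_misplaced, 1L)
  expect_equal(sc$misplaced_ids, "A3")
  expect_equal(sc$error_rate, 0.2)
  # a 10-sample clustering with 1 misplaced scores a 10% error rate
  cl10 <- setNames(rep(1:2, each = 5), paste0("x", 1:10))
  a10 <- data.frame(sample_id = names(cl10), case_id = paste0("c", 1:10),
                    tissue_class = c(rep("malignant", 4), "normal",
                                     rep("normal", 5)))
  sc10 <- score_assignment(cl10, a10)
  expect_equal(sc10$n_misplaced, 1L)
  expect_equal(sc10$error_rate, 0.1)
})

test_that("perfect separation scores zero misplaced and errors stay below half", {
  cl <- setNames(rep(1:2, each = 4), paste0("s", 1:8))
  a <- data.frame(sample_id = names(cl), case_id = paste0("c", 1:8),
                  tissue_class = rep(c("malignant", "normal"), each = 4))
  expect_equal(score_assignment(cl, a)$n_misplaced, 0L)
  set.seed(35)
  for (rep in 1:20) {
    n <- 10
    cl <- setNames(sample(1:3, n, replace = TRUE), paste0("s", 1:n))
    a <- data.frame(sample_id = names(cl), case_id = paste0("c", 1:n),
                    tissue_class = sample(rep(c("malignant", "normal"), 5)))
    sc <- suppressMessages(score_assignment(cl, a))
    # per-cluster majority rule caps the balanced-class error at 1/2
    expect_lte(sc$error_rate, 0.5)
  }
})

test_that("within-cluster ties are scored against the global majority, deterministically", {
  cl <- c(s1 = 1, s2 = 1, s3 = 2, s4 = 2, s5 = 2)
  a <- data.frame(sample_id = names(cl), case_id = paste0("c", 1:5),
                  tissue_class = c("malignant", "normal", "normal",
                                   "normal", "malignant"))
  expect_message(sc <- score_assignment(cl, a), "tie")
  # global majority is normal (3/5): tied cluster 1 counts its malignant member
  expect_equal(sc$cluster_class[["1"]], "normal")
  expect_true("s1" %in% sc$misplaced_ids)
  expect_error(score_assignment(cl, a[-1, ]), "s1")
})
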