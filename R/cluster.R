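#' Euclidean distances between samples on a signature
#'
#' Distances are computed over the signature-restricted expression
#' vectors. When a pair of samples has missing wells among the signature
#' features, the distance uses the mutually non-missing features and is
#' rescaled by `sqrt(n_total / n_used)` so magnitudes stay comparable
#' (the scaling [stats::dist()] applies).
#'
#' A sample pair with no mutually non-missing signature feature has no
#' defined distance; such entries are set to the largest finite distance
#' in the matrix (the uninformative sample becomes a maximal outlier), so
#' clustering stays well defined. If no pair has a defined distance the
#' signature carries no information and an error is raised.
#'
#' @param m Ct matrix.
#' @param signature a `mirna_signature` or character vector of feature
#'   ids; all must be present in `m`.
#' @return a `dist` object over samples.
#' @export
distance_matrix <- function(m, signature) {
  feats <- signature_features(signature)
  if (length(feats) == 0L) stop("signature is empty")
  absent <- setdiff(feats, rownames(m))
  if (length(absent) > 0L) {
    stop("signature feature(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  }
  d <- stats::dist(t(m[feats, , drop = FALSE]), method = "euclidean")
  if (anyNA(d)) {
    finite <- d[is.finite(d)]
    if (length(finite) == 0L) {
      stop("no sample pair shares a non-missing signature feature")
    }
    message("sample pair(s) without shared signature features; ",
            "distance set to the maximum observed")
    d[!is.finite(d)] <- max(finite)
  }
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is
#' the unweighted mean of all cross-cluster pairwise distances (UPGMA,
#' not the weighted WPGMA recurrence). Merge heights are monotone
#' non-decreasing on any metric input.
#'
#' @param d a `dist` object or symmetric non-negative distance matrix.
#' @return an [stats::hclust] tree.
#' @export
average_linkage <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d)))) {
      stop("distance matrix must be symmetric")
    }
    if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) stop("d must be a 'dist' or a symmetric matrix")
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  if (attr(d, "Size") < 2L) stop("need at least 2 samples to cluster")
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges of the tree, yielding exactly `k`
#' clusters.
#'
#' @param tree an [stats::hclust] tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (named sample -> cluster index) and `k`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1L || k > n) {
    stop("k must be an integer in [1, ", n, "]")
  }
  structure(list(cluster = stats::cutree(tree, k = k), k = as.integer(k)),
            class = "cluster_assignment")
}

#' Score a cluster assignment against tissue classes
#'
#' Each cluster is labeled with its majority tissue class; members of the
#' minority class are counted misplaced. A within-cluster tie (equal
#' normal and malignant counts) is resolved conservatively: members whose
#' class differs from the global majority class of the scored samples are
#' all counted misplaced, and the tie is reported.
#'
#' @param assignment a `cluster_assignment` from [cut_tree()] (or any
#'   named sample -> cluster vector).
#' @param a sample annotation covering every assigned sample.
#' @return object of class `assignment_score`: `cluster_class` (majority
#'   class per cluster), `misplaced_ids`, `n_misplaced`, `n`,
#'   `error_rate`, `tied_clusters`.
#' @export
score_assignment <- function(assignment, a) {
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$cluster
        else assignment
  a <- validate_sample_annotation(a)
  cls <- a$tissue_class[match(names(cl), a$sample_id)]
  if (anyNA(cls)) {
    stop("unannotated sample(s): ",
         paste(names(cl)[is.na(cls)], collapse = ", "))
  }
  counts <- table(factor(cls, levels = c("malignant", "normal")))
  global_major <- names(counts)[which.max(counts)]   # lexicographic on tie

  clusters <- sort(unique(cl))
  cluster_class <- character(length(clusters))
  names(cluster_class) <- clusters
  tied <- integer(0)
  misplaced <- character(0)
  for (g in clusters) {
    members <- names(cl)[cl == g]
    mc <- cls[cl == g]
    n_mal <- sum(mc == "malignant")
    n_nor <- sum(mc == "normal")
    if (n_mal == n_nor) {
      tied <- c(tied, g)
      major <- global_major
    } else {
      major <- if (n_mal > n_nor) "malignant" else "normal"
    }
    cluster_class[as.character(g)] <- major
    misplaced <- c(misplaced, members[mc != major])
  }
  if (length(tied) > 0L) {
    message("majority tie in cluster(s) ", paste(tied, collapse = ", "),
            "; scored against the global majority class")
  }
  structure(list(cluster_class = cluster_class,
                 misplaced_ids = misplaced,
                 n_misplaced = length(misplaced),
                 n = length(cl),
                 error_rate = length(misplaced) / length(cl),
                 tied_clusters = tied),
            class = "assignment_score")
}

#' @export
print.assignment_score <- function(x, ...) {
  cat("Cluster scoring:", x$n_misplaced, "of", x$n, "samples misplaced (",
      sprintf("%.1f%%", 100 * x$error_rate), ")\n")
  if (x$n_misplaced > 0L) {
    cat("  misplaced:", paste(x$misplaced_ids, collapse = ", "), "\n")
  }
  invisible(x)
}
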