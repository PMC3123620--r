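# Independent brute-force oracles and fixture builders used across tests.
# Each oracle is deliberately naive and shares no code with the package.

# annotation for columns named s01N, s01M, s02N, ...
make_paired_annotation <- function(n_cases) {
  data.frame(
    sample_id = as.vector(rbind(paste0("s", sprintf("%02d", 1:n_cases), "N"),
                                paste0("s", sprintf("%02d", 1:n_cases), "M"))),
    case_id = rep(sprintf("case%02d", 1:n_cases), each = 2),
    tissue_class = rep(c("normal", "malignant"), n_cases),
    stringsAsFactors = FALSE
  )
}

# small random Ct matrix with paired sample names
random_ct_matrix <- function(n_features, n_cases, missing_rate = 0) {
  a <- make_paired_annotation(n_cases)
  m <- matrix(runif(n_features * 2 * n_cases, 20, 35),
              nrow = n_features,
              dimnames = list(sprintf("miR-%04d", seq_len(n_features)),
                              a$sample_id))
  if (missing_rate > 0) {
    m[matrix(runif(length(m)) < missing_rate, nrow(m))] <- NA_real_
  }
  list(ct = m, annotation = a)
}

# naive UPGMA: full recomputation of cross-cluster means at every step
oracle_upgma <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bh <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- mean(dm[clusters[[i]], clusters[[j]]])
        if (h < bh) {
          bh <- h
          best <- c(j, i)
        }
      }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    heights <- c(heights, bh)
    partitions[[length(partitions) + 1L]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition: sorted member sets, ordered by smallest member
canonical_partition <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, min, numeric(1L)))]
}

cutree_partition <- function(cl) {
  canonical_partition(unname(split(seq_along(cl), cl)))
}

# exact two-sided signed-rank p by enumeration of all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  mu <- n * (n + 1) / 4
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# hand application of the BH step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
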