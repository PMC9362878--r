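# Small programmatic fixtures and brute-force oracles shared across tests.
# Oracles are deliberately naive (loops, set arithmetic) and independent of
# the package's vectorised implementations.

tiny_assign <- function() {
  cell_assignments(
    cell_ids = paste0("c", 1:6),
    labels = cbind(c(0L, 0L, 0L, 1L, 1L, 1L),
                   c(0L, 0L, 1L, 1L, 2L, 2L)),
    resolutions = c(0.1, 0.2)
  )
}

random_assign <- function(n, k_per_col, seed) {
  set.seed(seed)
  lab <- vapply(k_per_col, function(k) sample.int(k, n, replace = TRUE) - 1L,
                integer(n))
  cell_assignments(sprintf("c%06d", seq_len(n)), lab,
                   seq(0.1, by = 0.1, length.out = length(k_per_col)))
}

blob_embedding <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  emb <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2L,
          centers[i, ], "+")
  }))
  rownames(emb) <- sprintf("c%04d", seq_len(nrow(emb)))
  emb
}

small_expr <- function(values, cells = NULL, genes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- cells %||% paste0("c", seq_len(nrow(m)))
  colnames(m) <- genes %||% paste0("g", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) brute-force kNN by full pairwise distances, ties by index
oracle_knn <- function(emb, k) {
  n <- nrow(emb)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(emb) - emb[i, ])^2))
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k)))
}

# Jaccard weight between two cells' neighbour sets via explicit set ops
oracle_jaccard <- function(knn_idx, u, v) {
  a <- knn_idx[u, ]; b <- knn_idx[v, ]
  length(intersect(a, b)) / length(union(a, b))
}

# per-cell tally of (source label, target label) pairs between two columns
oracle_flow_tally <- function(assign, j) {
  counts <- new.env()
  for (i in seq_along(assign$cell_ids)) {
    key <- paste(assign$labels[i, j], assign$labels[i, j + 1L], sep = "|")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  out <- sort(vapply(ls(counts), function(k) counts[[k]], integer(1L)))
  out
}

# textbook per-cell silhouette with explicit loops
oracle_silhouette <- function(emb, labels) {
  n <- nrow(emb)
  d <- as.matrix(dist(emb))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1L)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  vapply(sort(unique(labels)), function(cl) mean(s[labels == cl]),
         numeric(1L))
}

# textbook Calinski-Harabasz / Davies-Bouldin with explicit loops
oracle_ch_db <- function(emb, labels) {
  cls <- sort(unique(labels))
  k <- length(cls); n <- nrow(emb)
  grand <- colMeans(emb)
  cent <- t(vapply(cls, function(cl) colMeans(emb[labels == cl, ,
                                                  drop = FALSE]),
                   numeric(ncol(emb))))
  B <- 0; W <- 0
  for (ci in seq_len(k)) {
    members <- which(labels == cls[ci])
    B <- B + length(members) * sum((cent[ci, ] - grand)^2)
    for (i in members) W <- W + sum((emb[i, ] - cent[ci, ])^2)
  }
  ch <- (B / (k - 1)) / (W / (n - k))
  s <- vapply(seq_len(k), function(ci) {
    members <- which(labels == cls[ci])
    mean(vapply(members, function(i) sqrt(sum((emb[i, ] - cent[ci, ])^2)),
                numeric(1L)))
  }, numeric(1L))
  db <- mean(vapply(seq_len(k), function(ci) {
    max(vapply(setdiff(seq_len(k), ci), function(cj) {
      (s[ci] + s[cj]) / sqrt(sum((cent[ci, ] - cent[cj, ])^2))
    }, numeric(1L)))
  }, numeric(1L)))
  list(ch = ch, db = db)
}

# double-summation GEP per the defining ratio, explicit loops
oracle_gep <- function(expr, cells, genes) {
  num <- vapply(genes, function(gn) {
    tot <- 0
    for (cl in cells) tot <- tot + expr[cl, gn]
    tot
  }, numeric(1L))
  den <- sum(num)
  if (den == 0) rep(NA_real_, 3L) else num / den
}

# adjusted Rand index between two labelings (closed form on the
# contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
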