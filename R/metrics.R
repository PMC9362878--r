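#' Per-cluster mean silhouette width
#'
#' For each cell, s(i) = (b(i) - a(i)) / max(a(i), b(i)), where a(i) is the
#' mean Euclidean distance to the other members of the cell's own cluster
#' (excluding itself) and b(i) is the smallest mean distance to any other
#' cluster. Cells in singleton clusters get s(i) = 0, and 0/0 (all distances
#' zero) is defined as 0. The per-cluster value is the mean of s(i) over the
#' cluster's members and lies in \[-1, 1\]. Low values indicate samples near
#' the decision boundary of neighbouring clusters.
#'
#' Distances are computed in the supplied embedding (the same space as kNN
#' construction), via a full pairwise distance matrix — exact, O(n^2).
#'
#' @param emb Cells x components numeric matrix.
#' @param labels Integer (or factor) cluster label per row of `emb`; at
#'   least 2 distinct clusters are required.
#' @return A `cluster_metric_table` data.frame: `cluster`, `metric`
#'   (`"silhouette"`), `raw`.
#' @export
silhouette_per_cluster <- function(emb, labels) {
  emb <- as.matrix(emb)
  labels <- as.vector(labels)
  if (length(labels) != nrow(emb)) stop("labels length must match embedding")
  f <- factor(labels)
  if (nlevels(f) < 2L) stop("silhouette is undefined for a single cluster")
  d <- as.matrix(stats::dist(emb))
  sizes <- tabulate(f)
  # mean distance from every cell to every cluster: n x k
  grp_sum <- t(rowsum(d, f))               # cells x clusters, sums
  idx <- as.integer(f)
  n <- nrow(emb)
  a_sum <- grp_sum[cbind(seq_len(n), idx)]
  a <- ifelse(sizes[idx] > 1L, a_sum / (sizes[idx] - 1L), NA_real_)
  mean_to <- sweep(grp_sum, 2L, sizes, "/")
  mean_to[cbind(seq_len(n), idx)] <- Inf    # exclude own cluster from b
  b <- apply(mean_to, 1L, min)
  s <- numeric(n)
  ok <- !is.na(a) & pmax(a, b) > 0
  s[ok] <- (b[ok] - a[ok]) / pmax(a[ok], b[ok])
  # singleton clusters (a undefined) and all-zero distances stay at 0
  out <- data.frame(
    cluster = as.integer(levels(f)),
    metric = "silhouette",
    raw = as.numeric(tapply(s, f, mean)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("cluster_metric_table", class(out))
  out
}

#' Normalise a cluster metric for node painting
#'
#' `affine` (the default used for silhouette) maps \[-1, 1\] linearly onto
#' \[0, 1\] via (raw + 1) / 2, a bijection that preserves comparability
#' across graphs. `minmax` rescales over the rows present; constant input
#' maps to 0.5.
#'
#' @param table A `cluster_metric_table` (any data.frame with a `raw`
#'   column).
#' @param mode `"affine"` or `"minmax"`.
#' @return The table with a `normalized` column in \[0, 1\].
#' @export
normalize_metric <- function(table, mode = c("affine", "minmax")) {
  mode <- match.arg(mode)
  if (!"raw" %in% colnames(table)) stop("metric table lacks a 'raw' column")
  table$normalized <- switch(mode,
    affine = (table$raw + 1) / 2,
    minmax = minmax_norm(table$raw)
  )
  table
}

#' Column-level Calinski-Harabasz and Davies-Bouldin indices
#'
#' Both are whole-partition quality indices computed from their standard
#' definitions in the supplied embedding and attached to every cluster of
#' the column (they do not decompose per cluster). Calinski-Harabasz is
#' the ratio of between- to within-cluster dispersion,
#' `(B / (k - 1)) / (W / (n - k))` (higher is better); Davies-Bouldin is the
#' mean over clusters of the worst pairwise `(s_i + s_j) / d_ij` similarity,
#' with `s_i` the mean member-to-centroid distance and `d_ij` the centroid
#' distance (lower is better).
#'
#' @inheritParams silhouette_per_cluster
#' @return A `cluster_metric_table` with metrics `"calinski_harabasz"` and
#'   `"davies_bouldin"`, each value repeated for every cluster of the column.
#' @export
other_metrics <- function(emb, labels) {
  emb <- as.matrix(emb)
  f <- factor(as.vector(labels))
  k <- nlevels(f)
  if (k < 2L) stop("cluster indices are undefined for a single cluster")
  n <- nrow(emb)
  centroids <- rowsum(emb, f) / tabulate(f)
  grand <- colMeans(emb)
  sizes <- tabulate(f)
  B <- sum(sizes * rowSums(sweep(centroids, 2L, grand)^2))
  W <- sum(rowSums((emb - centroids[as.integer(f), , drop = FALSE])^2))
  ch <- (B / (k - 1)) / (W / (n - k))
  s_i <- as.numeric(tapply(
    sqrt(rowSums((emb - centroids[as.integer(f), , drop = FALSE])^2)),
    f, mean))
  dc <- as.matrix(stats::dist(centroids))
  rat <- outer(s_i, s_i, "+") / dc
  diag(rat) <- -Inf
  db <- mean(apply(rat, 1L, max))
  out <- data.frame(
    cluster = rep(as.integer(levels(f)), 2L),
    metric = rep(c("calinski_harabasz", "davies_bouldin"), each = k),
    raw = c(rep(ch, k), rep(db, k)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("cluster_metric_table", class(out))
  out
}

#' Top differentially expressed genes of a cluster versus its column
#'
#' One-vs-rest Wilcoxon rank-sum test per gene, using the normal
#' approximation with tie correction (no continuity correction). Genes are
#' ranked by ascending p-value, ties broken by descending mean difference
#' (cluster minus rest). Benjamini-Hochberg FDR over all genes is reported
#' alongside the raw p-values; the tags are descriptive, not inferential.
#'
#' @param expr Cells x genes expression matrix.
#' @param cells Cell ids of the cluster.
#' @param rest_cells Cell ids of the same-column complement; must be
#'   non-empty.
#' @param k Number of top genes to return (default 5); `k >= n_genes`
#'   returns all genes, totally ranked.
#' @return data.frame `gene`, `p`, `fdr`, `mean_diff`, `direction`
#'   (+1 up in the cluster, -1 down, 0 no difference), `z`; top `k` rows of
#'   the full deterministic ranking.
#' @export
top_de_genes <- function(expr, cells, rest_cells, k = 5L) {
  if (length(cells) == 0L) stop("cluster has no cells")
  if (length(rest_cells) == 0L) {
    stop("rest set is empty (single-cluster column): one-vs-rest test ",
         "is undefined")
  }
  if (k < 1L) stop("k must be >= 1")
  x <- as.matrix(expr[c(cells, rest_cells), , drop = FALSE])
  n1 <- length(cells); n2 <- length(rest_cells); n <- n1 + n2
  stat <- apply(x, 2L, function(v) {
    r <- rank(v)
    R1 <- sum(r[seq_len(n1)])
    u <- R1 - n1 * (n1 + 1) / 2
    ties <- table(v)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(c(z = 0, p = 1))
    z <- (u - n1 * n2 / 2) / sqrt(sig2)
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  mean_diff <- colMeans(x[seq_len(n1), , drop = FALSE]) -
    colMeans(x[-seq_len(n1), , drop = FALSE])
  res <- data.frame(
    gene = colnames(x), p = stat["p", ], fdr = stats::p.adjust(stat["p", ],
                                                               "BH"),
    mean_diff = mean_diff, direction = sign(mean_diff), z = stat["z", ],
    stringsAsFactors = FALSE, row.names = NULL
  )
  res <- res[order(res$p, -res$mean_diff, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, k)
}

#' Attach silhouette and partition-quality metrics to every graph node
#'
#' Runs [silhouette_per_cluster()] (affine-normalised) and [other_metrics()]
#' (min-max-normalised over the whole graph) for every resolution column and
#' merges the results into the graph's node annotation table. Columns with a
#' single cluster get `NA` metrics.
#'
#' @param g A `sankey_graph`.
#' @param emb Cells x components embedding aligned with the graph's cells.
#' @return The graph with `node_annotations` columns `silhouette`,
#'   `silhouette_norm`, `calinski_harabasz`, `davies_bouldin`, plus min-max
#'   normalised variants of the latter two.
#' @export
annotate_metrics <- function(g, emb) {
  stopifnot(inherits(g, "sankey_graph"))
  emb <- as.matrix(emb)[g$cell_ids, , drop = FALSE]
  ann <- g$node_annotations
  for (col in c("silhouette", "calinski_harabasz", "davies_bouldin")) {
    ann[[col]] <- NA_real_
  }
  for (j in seq_along(g$res_labels)) {
    rl <- g$res_labels[j]
    sel <- g$nodes$res_label == rl
    labels <- integer(g$n_cells)
    for (id in g$nodes$node_id[sel]) {
      labels[match(g$members[[id]], g$cell_ids)] <-
        g$nodes$label[g$nodes$node_id == id]
    }
    if (length(unique(labels)) < 2L) next
    sil <- silhouette_per_cluster(emb, labels)
    oth <- other_metrics(emb, labels)
    key <- node_id_of(rl, sil$cluster)
    ann$silhouette[match(key, ann$node_id)] <- sil$raw
    for (m in unique(oth$metric)) {
      sub <- oth[oth$metric == m, , drop = FALSE]
      ann[[m]][match(node_id_of(rl, sub$cluster), ann$node_id)] <- sub$raw
    }
  }
  ann$silhouette_norm <- (ann$silhouette + 1) / 2
  for (m in c("calinski_harabasz", "davies_bouldin")) {
    ok <- !is.na(ann[[m]])
    ann[[paste0(m, "_norm")]] <- NA_real_
    if (any(ok)) ann[[paste0(m, "_norm")]][ok] <- minmax_norm(ann[[m]][ok])
  }
  g$node_annotations <- ann
  g
}

#' Attach top marker-gene tags to every graph node
#'
#' For each node, runs [top_de_genes()] against the same-column complement
#' and stores the top `k` gene ids (semicolon-joined, for hover text) in the
#' node annotation table. Single-cluster columns get `NA`.
#'
#' @param g A `sankey_graph`.
#' @param expr Cells x genes expression matrix.
#' @param k Number of marker genes per node (default 5).
#' @return The graph with a `top_genes` annotation column.
#' @export
annotate_top_genes <- function(g, expr, k = 5L) {
  stopifnot(inherits(g, "sankey_graph"))
  tags <- rep(NA_character_, nrow(g$nodes))
  for (i in seq_len(nrow(g$nodes))) {
    id <- g$nodes$node_id[i]
    same_col <- g$nodes$node_id[g$nodes$res_label == g$nodes$res_label[i]]
    rest <- setdiff(unlist(g$members[same_col]), g$members[[id]])
    if (length(rest) == 0L) next
    de <- top_de_genes(expr, g$members[[id]], rest, k = k)
    tags[i] <- paste(de$gene, collapse = ";")
  }
  g$node_annotations$top_genes <- tags
  g
}

#' Merge an external per-cluster annotation table into the graph
#'
#' Rows are keyed by (resolution, cluster) and matched to node ids
#' `"<resolution>_<cluster>"`; resolutions are matched numerically against
#' the graph's grid. Typical use: externally computed enrichment scores and
#' term titles. Numeric columns become paintable node overlays (min-max
#' normalised variants are added by [export_viz_spec()] consumers via
#' [normalize_metric()]).
#'
#' @param g A `sankey_graph`.
#' @param table A data.frame from [read_annotations()] (columns
#'   `resolution`, `cluster`, plus named fields).
#' @param mode `"strict"` errors on any key that resolves to no node;
#'   `"permissive"` skips such rows with a `message()`.
#' @return The graph with the table's fields merged into
#'   `node_annotations`.
#' @export
ingest_annotations <- function(g, table, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "sankey_graph"))
  res_num <- suppressWarnings(as.numeric(table$resolution))
  jmatch <- vapply(res_num, function(r) {
    hit <- which(abs(g$resolutions - r) < 1e-9)
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1L))
  keys <- ifelse(is.na(jmatch), NA_character_,
                 node_id_of(g$res_labels[jmatch], table$cluster))
  ok <- !is.na(keys) & keys %in% g$nodes$node_id
  if (any(!ok)) {
    bad <- paste0(table$resolution[!ok], "_", table$cluster[!ok])
    if (mode == "strict") {
      stop("annotation key(s) do not resolve to graph nodes: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    message("ingest_annotations: skipped ", sum(!ok), " of ", nrow(table),
            " row(s) with unresolvable keys")
  }
  fields <- setdiff(colnames(table), c("resolution", "cluster"))
  for (fld in fields) {
    if (!fld %in% colnames(g$node_annotations)) {
      g$node_annotations[[fld]] <- if (is.numeric(table[[fld]]))
        NA_real_ else NA_character_
    }
    g$node_annotations[[fld]][match(keys[ok],
                                    g$node_annotations$node_id)] <-
      table[[fld]][ok]
  }
  g
}
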