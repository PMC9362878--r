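test_that("silhouette approaches 1 for well-separated blobs, 0 degenerate", {
  emb <- blob_embedding(30, rbind(c(0, 0), c(100, 100)), sd = 0.5, seed = 8)
  labels <- rep(0:1, each = 30)
  tab <- silhouette_per_cluster(emb, labels)
  expect_true(all(tab$raw >= 0.99))

  # all coincident points: a = b = 0 handled as s = 0
  flat <- matrix(0, 10, 2)
  rownames(flat) <- paste0("c", 1:10)
  tab0 <- silhouette_per_cluster(flat, rep(0:1, 5))
  expect_equal(tab0$raw, c(0, 0))

  expect_error(silhouette_per_cluster(emb, rep(0, 60)), "single cluster")
})

test_that("silhouette matches the quadratic oracle within 1e-10", {
  set.seed(15)
  emb <- matrix(rnorm(150 * 4), 150)
  rownames(emb) <- paste0("c", 1:150)
  labels <- sample(0:3, 150, replace = TRUE)
  got <- silhouette_per_cluster(emb, labels)
  expect_equal(got$raw, oracle_silhouette(emb, labels), tolerance = 1e-10)
  expect_true(all(got$raw >= -1 & got$raw <= 1))

  # independent cross-check against the cluster package
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(labels, dist(emb))
  ref <- summary(sil)$clus.avg.widths
  expect_equal(got$raw, as.numeric(ref), tolerance = 1e-10)
})

test_that("silhouette handles singleton clusters by convention s = 0", {
  emb <- rbind(c(0, 0), c(0.1, 0), c(9, 9))
  rownames(emb) <- paste0("c", 1:3)
  tab <- silhouette_per_cluster(emb, c(0, 0, 1))
  expect_equal(tab$raw[tab$cluster == 1], 0)
})

test_that("metric normalisation: affine endpoints and minmax degenerate", {
  t1 <- data.frame(cluster = 0:1, metric = "silhouette", raw = c(-1, 1))
  n1 <- normalize_metric(t1, "affine")
  expect_equal(n1$normalized, c(0, 1))
  t2 <- data.frame(cluster = 0:1, metric = "m", raw = c(0.2, 0.6))
  expect_equal(normalize_metric(t2, "minmax")$normalized, c(0, 1))
  t3 <- data.frame(cluster = 0:1, metric = "m", raw = c(0.4, 0.4))
  expect_equal(normalize_metric(t3, "minmax")$normalized, c(0.5, 0.5))
})

test_that("CH/DB match the textbook formulas and order separability", {
  set.seed(16)
  emb <- matrix(rnorm(100 * 3), 100)
  rownames(emb) <- paste0("c", 1:100)
  labels <- sample(0:2, 100, replace = TRUE)
  got <- other_metrics(emb, labels)
  want <- oracle_ch_db(emb, labels)
  expect_equal(unique(got$raw[got$metric == "calinski_harabasz"]),
               want$ch, tolerance = 1e-10)
  expect_equal(unique(got$raw[got$metric == "davies_bouldin"]),
               want$db, tolerance = 1e-10)

  # separated blobs score a higher CH than a random split of one blob
  sep <- blob_embedding(40, rbind(c(0, 0), c(30, 30)), sd = 1, seed = 17)
  ch_sep <- other_metrics(sep, rep(0:1, each = 40))
  one <- blob_embedding(80, rbind(c(0, 0)), sd = 1, seed = 18)
  ch_rand <- other_metrics(one, rep(0:1, 40))
  expect_gt(unique(ch_sep$raw[ch_sep$metric == "calinski_harabasz"]),
            unique(ch_rand$raw[ch_rand$metric == "calinski_harabasz"]))

  expect_error(other_metrics(emb, rep(0, 100)), "single cluster")
})

test_that("metrics are invariant to cell and label permutation", {
  set.seed(19)
  emb <- matrix(rnorm(80 * 3), 80)
  rownames(emb) <- paste0("c", 1:80)
  labels <- sample(0:2, 80, replace = TRUE)
  base_s <- silhouette_per_cluster(emb, labels)
  base_o <- other_metrics(emb, labels)
  perm <- sample(80)
  perm_s <- silhouette_per_cluster(emb[perm, ], labels[perm])
  expect_equal(perm_s$raw, base_s$raw, tolerance = 1e-12)
  # relabel 0->2, 1->0, 2->1: values follow the member sets
  relab <- c(2L, 0L, 1L)[labels + 1L]
  rel_s <- silhouette_per_cluster(emb, relab)
  expect_equal(rel_s$raw[match(c(2, 0, 1), rel_s$cluster)], base_s$raw,
               tolerance = 1e-12)
  rel_o <- other_metrics(emb, relab)
  expect_equal(sort(unique(rel_o$raw)), sort(unique(base_o$raw)),
               tolerance = 1e-12)
})

test_that("rank-sum marker test matches wilcox.test and ranks separators", {
  set.seed(20)
  ids <- paste0("c", 1:80)
  inside <- ids[1:40]; outside <- ids[41:80]
  x <- small_expr(cbind(c(rexp(40) + 3, rep(0, 40)),
                        rnorm(80, 5, 1), rnorm(80, 5, 1)),
                  cells = ids, genes = c("sep", "n1", "n2"))
  de <- top_de_genes(x, inside, outside, k = 3)
  expect_equal(de$gene[1], "sep")
  expect_equal(de$direction[1], 1)

  # p-values equal the normal approximation with tie correction
  for (gn in colnames(x)) {
    ref <- stats::wilcox.test(x[inside, gn], x[outside, gn],
                              exact = FALSE, correct = FALSE)$p.value
    expect_equal(de$p[de$gene == gn], ref, tolerance = 1e-12)
  }
})

test_that("rank-sum statistic equals an exhaustive rank computation", {
  set.seed(22)
  ids <- paste0("c", 1:20)
  x <- small_expr(matrix(sample(0:5, 20 * 4, replace = TRUE), 20),
                  cells = ids)
  de <- top_de_genes(x, ids[1:8], ids[9:20], k = 10)
  for (gn in colnames(x)) {
    v <- x[c(ids[1:8], ids[9:20]), gn]
    r <- rank(v)
    u <- sum(r[1:8]) - 8 * 9 / 2
    ref <- stats::wilcox.test(v[1:8], v[9:20], exact = FALSE,
                              correct = FALSE)
    expect_equal(unname(ref$statistic), u)
    expect_equal(de$p[de$gene == gn], ref$p.value, tolerance = 1e-12)
  }
  # k >= n_genes returns all genes, totally and deterministically ranked
  expect_equal(nrow(de), 4L)
  expect_identical(de, top_de_genes(x, ids[1:8], ids[9:20], k = 10))

  # permuting cell order leaves the ranking unchanged
  perm <- sample(ids)
  de2 <- top_de_genes(x[perm, ], ids[1:8], ids[9:20], k = 10)
  expect_equal(de2$gene, de$gene)

  expect_error(top_de_genes(x, ids, character(0)), "rest")
})

test_that("annotation ingest merges keys, strict errors, permissive skips", {
  g <- build_graph(tiny_assign())
  tab <- data.frame(resolution = c(0.1, 0.2), cluster = c(0, 2),
                    score = c(42, 7), term = c("alpha", "beta"))
  g2 <- ingest_annotations(g, tab)
  ann <- g2$node_annotations
  expect_equal(ann$score[ann$node_id == "0.1_0"], 42)
  expect_equal(ann$term[ann$node_id == "0.2_2"], "beta")

  bad <- rbind(tab, data.frame(resolution = 0.9, cluster = 5,
                               score = 1, term = "ghost"))
  expect_error(ingest_annotations(g, bad, mode = "strict"), "0.9_5")
  expect_message(g3 <- ingest_annotations(g, bad, mode = "permissive"),
                 "skipped 1 of 3")
  expect_equal(g3$node_annotations$score[ann$node_id == "0.1_0"], 42)
})

test_that("graph-level metric annotation paints every multi-cluster column", {
  fx <- synth_generate(pbmc_like_preset(), seed = 6)
  sub <- fx$assignments$cell_ids[seq(1, 2700, by = 6)]
  a <- cell_assignments(sub,
                        fx$assignments$labels[sub, , drop = FALSE],
                        fx$assignments$resolutions)
  g <- annotate_metrics(build_graph(a), fx$embedding[sub, ])
  ann <- g$node_annotations
  expect_true(all(!is.na(ann$silhouette)))
  expect_true(all(ann$silhouette_norm >= 0 & ann$silhouette_norm <= 1))
  expect_true(all(ann$calinski_harabasz_norm >= 0 &
                    ann$calinski_harabasz_norm <= 1))
})
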