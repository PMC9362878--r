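make_flow_graph <- function() {
  # 6 cells, two columns; cluster {c1..c3} stays together, {c4..c6} splits
  a <- cell_assignments(paste0("c", 1:6),
                        cbind(c(0L, 0L, 0L, 1L, 1L, 1L),
                              c(0L, 0L, 0L, 1L, 1L, 2L)), c(0.1, 0.2))
  build_graph(a)
}

test_that("flow mean expression is the arithmetic mean over member cells", {
  g <- make_flow_graph()
  x <- small_expr(cbind(c(1, 3, 5, 0, 0, 0), rep(0, 6)),
                  cells = paste0("c", 1:6), genes = c("gA", "gB"))
  m <- flow_mean_expression(g, x, "gA")
  expect_equal(unname(m["0.1_0->0.2_0"]), 3)    # mean(1, 3, 5)
  expect_equal(unname(m["0.1_1->0.2_1"]), 0)
  expect_equal(unname(flow_mean_expression(g, x, "gB")),
               rep(0, nrow(g$flows)))
  expect_error(flow_mean_expression(g, x, "gAA"), "gA")
})

test_that("GEP matches the defining double sum and its forced cases", {
  g <- make_flow_graph()
  # only gene 1 expressed -> (1, 0, 0); equal sums -> (1/3, 1/3, 1/3)
  x <- small_expr(cbind(c(2, 1, 1, 2, 2, 2), c(0, 0, 0, 2, 2, 2),
                        c(0, 0, 0, 2, 2, 2)),
                  cells = paste0("c", 1:6), genes = c("r", "g", "b"))
  gep <- compute_gep(g, x, c("r", "g", "b"))
  row1 <- gep[gep$flow_id == "0.1_0->0.2_0", ]
  expect_equal(unlist(row1[, c("gep1", "gep2", "gep3")]),
               c(gep1 = 1, gep2 = 0, gep3 = 0))
  row2 <- gep[gep$flow_id == "0.1_1->0.2_1", ]
  expect_equal(unname(unlist(row2[, c("gep1", "gep2", "gep3")])),
               rep(1 / 3, 3))

  # random 50-cell flow equals the brute-force double sum within 1e-12
  set.seed(14)
  a <- cell_assignments(sprintf("c%03d", 1:50),
                        cbind(rep(0L, 50), rep(0L, 50)), c(0.1, 0.2))
  gg <- build_graph(a)
  xr <- small_expr(matrix(runif(50 * 3, 0, 4), 50),
                   cells = sprintf("c%03d", 1:50),
                   genes = c("r", "g", "b"))
  got <- compute_gep(gg, xr, c("r", "g", "b"))
  want <- oracle_gep(xr, sprintf("c%03d", 1:50), c("r", "g", "b"))
  expect_equal(unname(unlist(got[1, c("gep1", "gep2", "gep3")])),
               unname(want), tolerance = 1e-12)

  expect_error(compute_gep(g, x, c("r", "g")), "exactly 3")
})

test_that("defined GEP triples sum to 1; zero flows are undefined", {
  g <- make_flow_graph()
  x <- small_expr(cbind(c(1, 2, 0, 0, 0, 0), c(0, 1, 1, 0, 0, 0),
                        c(0.5, 0, 0, 0, 0, 0)),
                  cells = paste0("c", 1:6), genes = c("r", "g", "b"))
  gep <- compute_gep(g, x, c("r", "g", "b"))
  def <- gep[gep$defined, ]
  expect_true(all(abs(rowSums(def[, c("gep1", "gep2", "gep3")]) - 1)
                  < 1e-9))
  # flows over c4..c6 carry no geneset expression at all
  expect_false(any(gep$defined[gep$flow_id %in%
                                 c("0.1_1->0.2_1", "0.1_1->0.2_2")]))
})

test_that("GEP is invariant to cell order and to common rescaling", {
  set.seed(91)
  ids <- sprintf("c%03d", 1:40)
  a <- cell_assignments(ids, cbind(rep(0:1, 20), rep(0:1, 20)),
                        c(0.1, 0.2))
  g <- build_graph(a)
  x <- small_expr(matrix(rexp(40 * 3), 40), cells = ids,
                  genes = c("r", "g", "b"))
  base <- compute_gep(g, x, c("r", "g", "b"))
  perm <- sample(ids)
  gp <- build_graph(cell_assignments(perm,
                                     a$labels[perm, , drop = FALSE],
                                     a$resolutions))
  shuffled <- compute_gep(gp, x[perm, ], c("r", "g", "b"))
  expect_equal(shuffled[match(base$flow_id, shuffled$flow_id),
                        c("gep1", "gep2", "gep3")],
               base[, c("gep1", "gep2", "gep3")],
               ignore_attr = TRUE)
  scaled <- compute_gep(g, x * 7.3, c("r", "g", "b"))
  expect_equal(scaled[, c("gep1", "gep2", "gep3")],
               base[, c("gep1", "gep2", "gep3")], tolerance = 1e-12)
})

test_that("hex mapping rounds half away from zero, uppercase, neutral NA", {
  expect_equal(gep_to_hex(c(1, 0, 0)), "#FF0000")
  expect_equal(gep_to_hex(c(0, 0, 1)), "#0000FF")
  expect_equal(gep_to_hex(c(1, 1, 1) / 3), "#555555")   # round(85.0) = 85
  # 0.5 * 255 = 127.5 rounds away from zero to 128
  expect_equal(gep_to_hex(c(0.5, 0.5, 0)), "#808000")
  expect_equal(gep_to_hex(c(NA, NA, NA)), "#BEBEBE")
  expect_equal(gep_to_hex(c(NA, NA, NA), neutral = "#aaaaaa"), "#AAAAAA")
})

test_that("expression painting normalises min-max with midpoint fallback", {
  g <- make_flow_graph()
  x <- small_expr(cbind(c(0, 0, 0, 5, 5, 5), rep(2, 6)),
                  cells = paste0("c", 1:6), genes = c("gA", "gB"))
  gpaint <- paint_flows_expression(g, x, "gA")
  ov <- gpaint$overlays[["expr:gA"]]
  expect_equal(sort(unique(ov$norm)), c(0, 1))
  expect_equal(ov$value,
               unname(flow_mean_expression(g, x, "gA")[ov$flow_id]))

  const <- paint_flows_expression(g, x, "gB")
  expect_true(all(const$overlays[["expr:gB"]]$norm == 0.5))

  expect_error(paint_flows_expression(g, x, "gA", colormap = "nope"),
               "unknown colormap")
})

test_that("ternary dataset applies the 2 * log2(m) size rule", {
  a <- cell_assignments(paste0("c", 1:5),
                        cbind(c(0L, 0L, 0L, 0L, 1L),
                              c(0L, 0L, 0L, 0L, 1L)), c(0.1, 0.2))
  g <- build_graph(a)
  x <- small_expr(cbind(rep(1, 5), rep(0.5, 5), rep(0.25, 5)),
                  cells = paste0("c", 1:5), genes = c("r", "g", "b"))
  td <- ternary_dataset(g, x, c("r", "g", "b"))
  expect_equal(td$size[td$count == 4], 4)        # 2 * log2(4)
  expect_equal(td$size[td$count == 1], 0)        # 2 * log2(1)
  # one point per flow with nonzero geneset expression
  expect_equal(nrow(td),
               sum(compute_gep(g, x, c("r", "g", "b"))$defined))
})
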