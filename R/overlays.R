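#' Mean expression of one gene over each flow's member cells
#'
#' The value painted on a flow for single-gene overlays: the arithmetic mean
#' of the gene's expression over the cells shared between the flow's source
#' and target clusters.
#'
#' @param g A `sankey_graph`.
#' @param expr Cells x genes expression matrix (aligned cell ids).
#' @param gene A gene id present in `expr`.
#' @param flows Optional character vector of flow ids; default all flows.
#' @return Named numeric vector of means, one per flow.
#' @export
flow_mean_expression <- function(g, expr, gene, flows = NULL) {
  stopifnot(inherits(g, "sankey_graph"))
  check_genes(expr, gene)
  if (is.null(flows)) flows <- g$flows$flow_id
  v <- expr[, gene]
  names(v) <- rownames(expr)
  vapply(g$flow_members[flows], function(cells) mean(v[cells]),
         numeric(1L))
}

check_genes <- function(expr, genes) {
  if (anyDuplicated(genes)) stop("duplicate gene ids in geneset")
  missing <- setdiff(genes, colnames(expr))
  if (length(missing) > 0L) {
    near <- unlist(lapply(missing, function(gn) {
      utils::head(agrep(gn, colnames(expr), max.distance = 0.25,
                        ignore.case = TRUE, value = TRUE), 3L)
    }))
    stop("gene(s) not in expression matrix: ",
         paste(missing, collapse = ", "),
         if (length(near) > 0L) paste0(" (did you mean: ",
                                       paste(unique(near), collapse = ", "),
                                       "?)"))
  }
  invisible(genes)
}

#' Per-flow gene expression percentage (GEP) for a 3-gene set
#'
#' For an ordered geneset of n = 3 genes and a flow of m cells, the GEP of
#' gene i is the gene's summed expression over the flow's cells divided by
#' the summed expression of all three genes over those cells:
#' \deqn{GEP_i = \frac{\sum_{j=1}^{m} E_{i,j}}{\sum_{j=1}^{m}\sum_{k=1}^{n} E_{k,j}}.}
#' The three fractions lie in \[0, 1\] and sum to 1; they are barycentric
#' co-expression coordinates for the ternary chart. When the denominator is
#' zero (no expression of any geneset gene in the flow) the triple is
#' undefined and `defined` is `FALSE`.
#'
#' @param g A `sankey_graph`.
#' @param expr Cells x genes expression matrix.
#' @param genes Ordered character vector of exactly 3 gene ids
#'   (first -> red, second -> green, third -> blue channel).
#' @param flows Optional flow id subset; default all flows.
#' @return data.frame with columns `flow_id`, `gep1`, `gep2`, `gep3`
#'   (NA when undefined), `total` (the denominator) and `defined`.
#' @export
compute_gep <- function(g, expr, genes, flows = NULL) {
  stopifnot(inherits(g, "sankey_graph"))
  if (length(genes) != 3L) stop("co-expression geneset must contain ",
                                "exactly 3 genes")
  check_genes(expr, genes)
  if (is.null(flows)) flows <- g$flows$flow_id
  sub <- as.matrix(expr[, genes, drop = FALSE])
  rownames(sub) <- rownames(expr)
  sums <- t(vapply(g$flow_members[flows], function(cells) {
    colSums(sub[cells, , drop = FALSE])
  }, numeric(3L)))
  total <- rowSums(sums)
  gep <- sums / total
  gep[total == 0, ] <- NA_real_
  out <- data.frame(
    flow_id = flows, gep1 = gep[, 1L], gep2 = gep[, 2L], gep3 = gep[, 3L],
    total = total, defined = total > 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "genes") <- genes
  out
}

#' Map GEP triples to RGB hex colours
#'
#' Each fraction becomes one colour channel in geneset order (first gene ->
#' red, second -> green, third -> blue): channel = round(255 * GEP), rounding
#' half away from zero. Undefined triples map to a neutral colour.
#'
#' @param gep A data.frame from [compute_gep()], or a numeric vector of 3
#'   fractions, or a 3-column numeric matrix.
#' @param neutral Hex colour for undefined triples; default `"#BEBEBE"`.
#' @return Character vector of uppercase `"#RRGGBB"` strings.
#' @export
gep_to_hex <- function(gep, neutral = "#BEBEBE") {
  if (is.data.frame(gep)) {
    m <- as.matrix(gep[, c("gep1", "gep2", "gep3")])
  } else if (is.matrix(gep)) {
    m <- gep
  } else {
    m <- matrix(gep, nrow = 1L)
  }
  if (ncol(m) != 3L) stop("GEP input must have 3 components")
  ch <- floor(255 * m + 0.5)          # round half away from zero (values >= 0)
  hex <- sprintf("#%02X%02X%02X", ch[, 1L], ch[, 2L], ch[, 3L])
  hex[!stats::complete.cases(m)] <- toupper(neutral)
  hex
}

resolve_colormap <- function(colormap, n = 256L) {
  pals <- grDevices::hcl.pals()
  hit <- pals[match(tolower(colormap), tolower(pals))]
  if (is.na(hit)) {
    stop("unknown colormap '", colormap, "'; available palettes include: ",
         paste(utils::head(pals, 8L), collapse = ", "), ", ...")
  }
  grDevices::hcl.colors(n, palette = hit)
}

value_to_hex <- function(norm, colormap) {
  pal <- resolve_colormap(colormap)
  idx <- pmin(length(pal), pmax(1L, 1L + floor(norm * (length(pal) - 1L) + 0.5)))
  toupper(pal[idx])
}

#' Paint flows by single-gene mean expression
#'
#' Computes each flow's mean expression of `gene`, min-max normalises over
#' all flows (global scale, matching a single scale bar) or within each
#' column gap (`per_column`), and maps the normalised value through a named
#' colormap. If all values in a scaling group are equal, they map to the
#' colormap midpoint. Both the raw mean and the hex colour are stored on the
#' graph under `overlays[["expr:<gene>"]]`.
#'
#' @param g A `sankey_graph`.
#' @param expr Cells x genes expression matrix.
#' @param gene Gene id to paint.
#' @param colormap Palette name (case-insensitive, e.g. `"viridis"`);
#'   resolved via [grDevices::hcl.colors()].
#' @param scale `"global"` (default) or `"per_column"`.
#' @return The graph with the overlay attached.
#' @export
paint_flows_expression <- function(g, expr, gene, colormap = "viridis",
                                   scale = c("global", "per_column")) {
  scale <- match.arg(scale)
  resolve_colormap(colormap)   # fail fast on unknown name
  raw <- flow_mean_expression(g, expr, gene)
  norm <- rep(NA_real_, length(raw))
  if (scale == "global") {
    norm <- minmax_norm(raw)
  } else {
    src_col <- match(g$nodes$res_label[match(g$flows$source,
                                             g$nodes$node_id)],
                     g$res_labels)
    for (j in unique(src_col)) {
      sel <- src_col == j
      norm[sel] <- minmax_norm(raw[sel])
    }
  }
  g$overlays[[paste0("expr:", gene)]] <- list(
    type = "expression", gene = gene, colormap = colormap, scale = scale,
    flow_id = g$flows$flow_id,
    value = unname(raw), norm = unname(norm),
    hex = value_to_hex(norm, colormap),
    range = c(min(raw), max(raw))
  )
  g
}

minmax_norm <- function(x) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Paint flows by 3-gene GEP co-expression
#'
#' Attaches the GEP triple of every flow and its direct RGB rendering
#' ([gep_to_hex()]) as an overlay named `"gep:<g1>+<g2>+<g3>"`.
#'
#' @inheritParams compute_gep
#' @param neutral Colour for flows with no geneset expression.
#' @return The graph with the overlay attached.
#' @export
paint_flows_gep <- function(g, expr, genes, neutral = "#BEBEBE") {
  gep <- compute_gep(g, expr, genes)
  g$overlays[[paste0("gep:", paste(genes, collapse = "+"))]] <- list(
    type = "gep", genes = genes,
    flow_id = gep$flow_id,
    gep = unname(as.matrix(gep[, c("gep1", "gep2", "gep3")])),
    defined = gep$defined,
    hex = gep_to_hex(gep, neutral)
  )
  g
}

#' Ternary chart dataset of per-flow co-expression
#'
#' One scatter point per flow with a defined GEP triple. The barycentric
#' coordinates are the three GEP fractions; the point size is twice the
#' log2 of the flow's cell count (so a 4-cell flow has size 4). Single-cell
#' flows have true size 0 and are intended to be rendered at a small floor;
#' the raw value is stored.
#'
#' @inheritParams compute_gep
#' @return data.frame with `flow_id`, `source`, `target`, `count`, the
#'   three `gep*` coordinates, `size` (= 2 * log2(count)) and `hex`; the
#'   geneset is carried in `attr(, "genes")`.
#' @export
ternary_dataset <- function(g, expr, genes) {
  gep <- compute_gep(g, expr, genes)
  keep <- gep$defined
  fl <- g$flows[match(gep$flow_id[keep], g$flows$flow_id), , drop = FALSE]
  out <- data.frame(
    flow_id = fl$flow_id, source = fl$source, target = fl$target,
    count = fl$count,
    gep1 = gep$gep1[keep], gep2 = gep$gep2[keep], gep3 = gep$gep3[keep],
    size = 2 * log2(fl$count),
    hex = gep_to_hex(gep[keep, , drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "genes") <- genes
  out
}
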