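#' Layered barycenter layout for a cluster-flow graph
#'
#' Assigns deterministic positions: x is the column index scaled to \[0, 1\];
#' within-column vertical order starts from the size order (ascending label)
#' and is refined by barycenter sweeps — alternating left-to-right and
#' right-to-left passes in which each node is re-ordered by the
#' flow-count-weighted mean position of its neighbours in the fixed adjacent
#' column. Ties are broken by node label. Node heights are proportional to
#' size, with a configurable total gap fraction per column. A sweep result is
#' only kept if it does not increase the total edge crossing count, so the
#' final layout is never worse than the naive size-order layout.
#'
#' @param g A `sankey_graph`.
#' @param iterations Number of sweep rounds (one round = one pass each way);
#'   default 4.
#' @param gap Fraction of the unit column height distributed as gaps between
#'   nodes; default 0.05.
#' @return The graph with `layout` set: data.frame `node_id`, `x`, `y`
#'   (centre), `y0`, `y1`, `height`, `order` (0-based within-column rank,
#'   top to bottom).
#' @export
layout_graph <- function(g, iterations = 4L, gap = 0.05) {
  stopifnot(inherits(g, "sankey_graph"))
  cols <- lapply(g$res_labels, function(rl) {
    nd <- g$nodes[g$nodes$res_label == rl, , drop = FALSE]
    nd$node_id[order(nd$label)]
  })
  nc <- length(cols)
  orders <- cols   # each element: node_ids in vertical order, top first

  pos_of <- function(ids) stats::setNames(seq_along(ids), ids)
  label_of <- stats::setNames(g$nodes$label, g$nodes$node_id)

  reorder_col <- function(ids, nbr_pos, edges, end_col) {
    # edges: flows between this column and the fixed neighbour column;
    # end_col: "source" if this column holds the flow sources
    me <- if (end_col == "source") edges$source else edges$target
    other <- if (end_col == "source") edges$target else edges$source
    bc <- vapply(ids, function(id) {
      sel <- me == id
      if (!any(sel)) return(NA_real_)
      sum(edges$count[sel] * nbr_pos[other[sel]]) / sum(edges$count[sel])
    }, numeric(1L))
    # nodes without neighbours keep their current rank as barycenter
    bc[is.na(bc)] <- seq_along(ids)[is.na(bc)]
    ids[order(bc, label_of[ids])]
  }

  best <- orders
  best_cross <- total_crossings(g, best)
  for (r in seq_len(max(0L, as.integer(iterations)))) {
    for (j in seq_len(nc - 1L) + 1L) {        # left-to-right: fix j-1
      edges <- g$flows[g$flows$source %in% orders[[j - 1L]], , drop = FALSE]
      orders[[j]] <- reorder_col(orders[[j]], pos_of(orders[[j - 1L]]),
                                 edges, "target")
    }
    for (j in rev(seq_len(nc - 1L))) {        # right-to-left: fix j+1
      edges <- g$flows[g$flows$target %in% orders[[j + 1L]], , drop = FALSE]
      orders[[j]] <- reorder_col(orders[[j]], pos_of(orders[[j + 1L]]),
                                 edges, "source")
    }
    cr <- total_crossings(g, orders)
    if (cr <= best_cross) { best <- orders; best_cross <- cr }
  }
  orders <- best

  rows <- list()
  for (j in seq_len(nc)) {
    ids <- orders[[j]]
    sizes <- g$nodes$size[match(ids, g$nodes$node_id)]
    h <- sizes / g$n_cells * (1 - gap)
    gap_each <- if (length(ids) > 1L) gap / (length(ids) - 1L) else 0
    y1 <- cumsum(h) + (seq_along(ids) - 1L) * gap_each   # bottom edges, top-down
    y0 <- y1 - h
    rows[[j]] <- data.frame(
      node_id = ids,
      x = if (nc > 1L) (j - 1L) / (nc - 1L) else 0,
      y = (y0 + y1) / 2, y0 = y0, y1 = y1, height = h,
      order = seq_along(ids) - 1L,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  layout <- do.call(rbind, rows)
  g$layout <- layout[match(g$nodes$node_id, layout$node_id), , drop = FALSE]
  rownames(g$layout) <- NULL
  g
}

#' Count edge crossings of a layout
#'
#' Two flows between the same pair of adjacent columns cross when their
#' source order and target order disagree. Counts distinct crossing pairs
#' over all column gaps, under the graph's current layout order (or the
#' size/label order if no layout has been computed).
#'
#' @param g A `sankey_graph`.
#' @return Integer crossing count.
#' @export
count_crossings <- function(g) {
  stopifnot(inherits(g, "sankey_graph"))
  if (is.null(g$layout)) {
    orders <- lapply(g$res_labels, function(rl) {
      nd <- g$nodes[g$nodes$res_label == rl, , drop = FALSE]
      nd$node_id[order(nd$label)]
    })
  } else {
    orders <- lapply(g$res_labels, function(rl) {
      ly <- g$layout[g$nodes$res_label == rl, , drop = FALSE]
      ly$node_id[order(ly$order)]
    })
  }
  total_crossings(g, orders)
}

total_crossings <- function(g, orders) {
  total <- 0L
  for (j in seq_len(length(orders) - 1L)) {
    sp <- stats::setNames(seq_along(orders[[j]]), orders[[j]])
    tp <- stats::setNames(seq_along(orders[[j + 1L]]), orders[[j + 1L]])
    e <- g$flows[g$flows$source %in% orders[[j]], , drop = FALSE]
    if (nrow(e) < 2L) next
    s <- sp[e$source]; t <- tp[e$target]
    for (a in seq_len(nrow(e) - 1L)) {
      b <- (a + 1L):nrow(e)
      total <- total + sum((s[a] - s[b]) * (t[a] - t[b]) < 0)
    }
  }
  as.integer(total)
}
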