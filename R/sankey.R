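#' Relabel clusters by descending size within each resolution column
#'
#' Cluster labels follow the convention that lower numbers denote larger
#' clusters: per column, label 0 is the largest cluster, label 1 the next,
#' and so on. The partition itself is unchanged. Size ties are broken by the
#' original label order, so the operation is deterministic and idempotent.
#'
#' @param assign A [cell_assignments] object.
#' @return A relabelled [cell_assignments] object carrying, per column, the
#'   original-to-new label map in `attr(, "relabel_maps")`.
#' @export
relabel_by_size <- function(assign) {
  stopifnot(inherits(assign, "cell_assignments"))
  lab <- assign$labels
  maps <- vector("list", ncol(lab))
  names(maps) <- assign$res_labels
  for (j in seq_len(ncol(lab))) {
    f <- factor(lab[, j])
    sizes <- tabulate(f)
    old <- as.integer(levels(f))
    # rank by descending size, ties by ascending original label
    new <- integer(length(old))
    new[order(-sizes, old)] <- seq_along(old) - 1L
    lab[, j] <- new[as.integer(f)]
    maps[[j]] <- stats::setNames(new, old)
  }
  out <- cell_assignments(assign$cell_ids, lab, assign$resolutions,
                          assign$res_labels)
  attr(out, "relabel_maps") <- maps
  out
}

node_id_of <- function(res_label, label) paste0(res_label, "_", label)

#' Build the per-resolution cluster nodes of the flow graph
#'
#' One node per (resolution, observed cluster label). Node identifiers are
#' `"<resolution>_<label>"`, with the resolution rendered exactly as in the
#' input header. Member sets partition the cells within each column.
#'
#' @param assign A size-ordered [cell_assignments] object (see
#'   [relabel_by_size()]).
#' @return List with `nodes` (data.frame: `node_id`, `resolution`,
#'   `res_label`, `label`, `size`) and `members` (named list of cell id
#'   vectors keyed by `node_id`).
#' @export
build_nodes <- function(assign) {
  stopifnot(inherits(assign, "cell_assignments"))
  rows <- list(); members <- list()
  for (j in seq_along(assign$resolutions)) {
    f <- factor(assign$labels[, j])
    sp <- split(assign$cell_ids, f)
    labs <- as.integer(levels(f))
    ids <- node_id_of(assign$res_labels[j], labs)
    rows[[j]] <- data.frame(
      node_id = ids, resolution = assign$resolutions[j],
      res_label = assign$res_labels[j], label = labs,
      size = lengths(sp), stringsAsFactors = FALSE, row.names = NULL
    )
    members[ids] <- sp
  }
  nodes <- do.call(rbind, rows)
  rownames(nodes) <- NULL
  list(nodes = nodes, members = members)
}

#' Flows between two adjacent resolution columns
#'
#' A flow from cluster `a` at resolution `j` to cluster `b` at the next grid
#' resolution is the set of cells assigned to both; its count is the
#' corresponding entry of the source-label x target-label contingency table.
#' Zero-count pairs produce no flow. `forward_prop` is count / source size,
#' `backward_prop` is count / target size.
#'
#' @param assign A [cell_assignments] object.
#' @param j Index of the source column; the target is column `j + 1`.
#' @return List with `flows` (data.frame: `flow_id`, `source`, `target`,
#'   `count`, `forward_prop`, `backward_prop`) and `members` (named list of
#'   shared cell id vectors keyed by `flow_id`).
#' @export
compute_flows <- function(assign, j) {
  stopifnot(inherits(assign, "cell_assignments"))
  if (j < 1L || j >= length(assign$resolutions)) {
    stop("j must index a column with a successor")
  }
  src <- assign$labels[, j]
  tgt <- assign$labels[, j + 1L]
  key <- paste(src, tgt, sep = "\r")
  sp <- split(assign$cell_ids, key)
  parts <- strsplit(names(sp), "\r", fixed = TRUE)
  a <- as.integer(vapply(parts, `[[`, "", 1L))
  b <- as.integer(vapply(parts, `[[`, "", 2L))
  src_sizes <- table(src)
  tgt_sizes <- table(tgt)
  source_id <- node_id_of(assign$res_labels[j], a)
  target_id <- node_id_of(assign$res_labels[j + 1L], b)
  flow_id <- paste(source_id, target_id, sep = "->")
  count <- lengths(sp)
  flows <- data.frame(
    flow_id = flow_id, source = source_id, target = target_id,
    count = as.integer(count),
    forward_prop = as.numeric(count / as.integer(src_sizes[as.character(a)])),
    backward_prop = as.numeric(count / as.integer(tgt_sizes[as.character(b)])),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ord <- order(a, b)
  flows <- flows[ord, , drop = FALSE]
  rownames(flows) <- NULL
  members <- stats::setNames(sp, flow_id)[flows$flow_id]
  list(flows = flows, members = members)
}

#' Build the multi-resolution cluster-flow graph
#'
#' The central data structure: a directed acyclic graph whose columns are
#' resolution values in ascending order, whose nodes are the clusters found
#' at each resolution (scaled by cell count, labels ordered by descending
#' size), and whose edges ("flows") carry the cells shared between clusters
#' at consecutive resolutions. No flow-proportion threshold is applied at
#' build time; the structure is lossless and filtering is a render-time
#' option.
#'
#' @param assign A [cell_assignments] object with at least 2 resolutions.
#'   Labels are size-ordered internally (idempotent if already ordered).
#' @return An object of class `sankey_graph`: list with `nodes`, `flows`
#'   (data.frames as in [build_nodes()] / [compute_flows()]), `members`,
#'   `flow_members`, `resolutions`, `res_labels`, `cell_ids`, `n_cells`,
#'   `layout` (`NULL` until [layout_graph()]), `overlays` and
#'   `node_annotations`.
#' @export
build_graph <- function(assign) {
  stopifnot(inherits(assign, "cell_assignments"))
  if (length(assign$resolutions) < 2L) {
    stop("at least 2 resolutions are required to define flows")
  }
  assign <- relabel_by_size(assign)
  nd <- build_nodes(assign)
  fl <- lapply(seq_len(length(assign$resolutions) - 1L),
               function(j) compute_flows(assign, j))
  flows <- do.call(rbind, lapply(fl, `[[`, "flows"))
  rownames(flows) <- NULL
  flow_members <- do.call(c, lapply(fl, `[[`, "members"))
  g <- structure(
    list(
      nodes = nd$nodes, flows = flows,
      members = nd$members, flow_members = flow_members,
      resolutions = assign$resolutions, res_labels = assign$res_labels,
      cell_ids = assign$cell_ids, n_cells = length(assign$cell_ids),
      layout = NULL, overlays = list(),
      node_annotations = data.frame(node_id = nd$nodes$node_id,
                                    stringsAsFactors = FALSE)
    ),
    class = "sankey_graph"
  )
  validate_sankey_graph(g)
  g
}

#' Check the structural invariants of a cluster-flow graph
#'
#' Verifies exact integer conservation (per column, node sizes sum to the
#' total cell count; per interior node, incoming and outgoing flow counts sum
#' to the node size), positivity of all flows and proportions, adjacency of
#' flow endpoints (acyclicity by construction), and size-ordering of labels.
#'
#' @param g A `sankey_graph`.
#' @return `TRUE` invisibly; errors on any violation.
#' @export
validate_sankey_graph <- function(g) {
  stopifnot(inherits(g, "sankey_graph"))
  nodes <- g$nodes; flows <- g$flows
  for (rl in g$res_labels) {
    sz <- nodes$size[nodes$res_label == rl]
    if (sum(sz) != g$n_cells) stop("column ", rl, ": sizes sum to ",
                                   sum(sz), ", expected ", g$n_cells)
    if (is.unsorted(rev(sz))) {
      # labels are in ascending order per column, so sizes must be
      # weakly decreasing
      stop("column ", rl, ": labels not size-ordered")
    }
  }
  if (any(flows$count < 1L)) stop("zero-count flow present")
  if (any(flows$forward_prop <= 0 | flows$forward_prop > 1) ||
      any(flows$backward_prop <= 0 | flows$backward_prop > 1)) {
    stop("flow proportions outside (0, 1]")
  }
  col_of <- stats::setNames(match(nodes$res_label, g$res_labels),
                            nodes$node_id)
  if (any(col_of[flows$target] - col_of[flows$source] != 1L)) {
    stop("flow connecting non-adjacent columns")
  }
  out_sum <- tapply(flows$count, flows$source, sum)
  in_sum <- tapply(flows$count, flows$target, sum)
  last <- g$res_labels[length(g$res_labels)]
  first <- g$res_labels[1L]
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$node_id[i]
    if (nodes$res_label[i] != last &&
        !identical(as.integer(out_sum[id]), nodes$size[i])) {
      stop("node ", id, ": outgoing flow counts do not sum to size")
    }
    if (nodes$res_label[i] != first &&
        !identical(as.integer(in_sum[id]), nodes$size[i])) {
      stop("node ", id, ": incoming flow counts do not sum to size")
    }
    if (length(g$members[[id]]) != nodes$size[i]) {
      stop("node ", id, ": member set size mismatch")
    }
  }
  invisible(TRUE)
}

#' @export
print.sankey_graph <- function(x, ...) {
  cat("<sankey_graph> ", x$n_cells, " cells, ",
      length(x$resolutions), " resolutions, ", nrow(x$nodes), " nodes, ",
      nrow(x$flows), " flows\n", sep = "")
  if (length(x$overlays) > 0L) {
    cat("  overlays: ", paste(names(x$overlays), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
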