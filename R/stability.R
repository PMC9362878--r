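#' Flows stable under a mutual-proportion threshold
#'
#' A flow is stable when it captures at least a fraction `tau` of both its
#' endpoints: `min(count / size(source), count / size(target)) >= tau`. The
#' definition is symmetric in direction, and for `tau > 0.5` each node can
#' have at most one stable incoming and one stable outgoing flow.
#'
#' @param g A `sankey_graph`.
#' @param tau Stability threshold in (0, 1]; default 0.9.
#' @return The subset of `g$flows` meeting the threshold, with a
#'   `stability` column (`min(forward_prop, backward_prop)`).
#' @export
stable_flows <- function(g, tau = 0.9) {
  stopifnot(inherits(g, "sankey_graph"))
  if (!(tau > 0 && tau <= 1)) stop("tau must lie in (0, 1]")
  fl <- g$flows
  fl$stability <- pmin(fl$forward_prop, fl$backward_prop)
  out <- fl[fl$stability >= tau, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trace stable cell communities across the resolution grid
#'
#' Chains stable flows ([stable_flows()]) into maximal paths: a step from a
#' node is taken only when its stable outgoing flow is unique and is also
#' the unique stable incoming flow of its target, so paths are well defined
#' (and node-disjoint) for any `tau`; for `tau > 0.5` uniqueness holds
#' automatically. Each maximal chain spanning at least two columns is
#' reported with its stability score (the minimum mutual proportion over
#' its steps) and its member core (the intersection of all step member
#' sets).
#'
#' @param g A `sankey_graph`.
#' @param tau Stability threshold in (0, 1]; default 0.9.
#' @return An object of class `stable_paths`: data.frame with `path_id`,
#'   `n_columns` (nodes spanned), `nodes` (semicolon-joined node ids),
#'   `score`, `core_size`; sorted by descending span, then descending core
#'   size, then first node id. Per-path node id vectors and member cores are
#'   carried in `attr(, "node_ids")` and `attr(, "cores")`.
#' @export
trace_paths <- function(g, tau = 0.9) {
  sf <- stable_flows(g, tau)
  # keep only flows that are the unique stable out-edge of their source and
  # the unique stable in-edge of their target
  uniq <- !(sf$source %in% sf$source[duplicated(sf$source)]) &
    !(sf$target %in% sf$target[duplicated(sf$target)])
  sf <- sf[uniq, , drop = FALSE]
  nxt <- stats::setNames(sf$target, sf$source)
  prv <- stats::setNames(sf$source, sf$target)
  starts <- sf$source[!(sf$source %in% sf$target)]
  starts <- starts[order(match(starts, g$nodes$node_id))]
  paths <- list(); cores <- list(); scores <- numeric(0)
  for (s in starts) {
    chain <- s
    while (chain[length(chain)] %in% names(nxt)) {
      chain <- c(chain, unname(nxt[[chain[length(chain)]]]))
    }
    step_ids <- paste(chain[-length(chain)], chain[-1L], sep = "->")
    rows <- match(step_ids, sf$flow_id)
    paths[[length(paths) + 1L]] <- chain
    cores[[length(cores) + 1L]] <-
      Reduce(intersect, g$flow_members[step_ids])
    scores <- c(scores, min(sf$stability[rows]))
  }
  span <- lengths(paths)
  core_size <- lengths(cores)
  first <- vapply(paths, `[`, "", 1L)
  ord <- order(-span, -core_size, first)
  out <- data.frame(
    path_id = seq_along(ord),
    n_columns = span[ord],
    nodes = vapply(paths[ord], paste, "", collapse = ";"),
    score = scores[ord],
    core_size = core_size[ord],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "node_ids") <- paths[ord]
  attr(out, "cores") <- cores[ord]
  attr(out, "tau") <- tau
  class(out) <- c("stable_paths", class(out))
  out
}

#' Write traced stable paths as TSV
#'
#' One row per path: id, number of columns spanned, node ids, stability
#' score and core size — the shell-facing companion of [trace_paths()].
#'
#' @param paths A `stable_paths` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_paths <- function(paths, path) {
  stopifnot(inherits(paths, "stable_paths"))
  utils::write.table(as.data.frame(paths), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
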