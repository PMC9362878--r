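#' Declare a planted hierarchical cluster fixture
#'
#' Describes a tree of cell populations whose branches become separate
#' clusters at known resolution values, together with a simple expression
#' model: every non-root tree node owns a block of marker genes elevated in
#' all cells beneath it, so populations that split late are molecularly
#' close. Cutting the tree at each grid resolution yields ground-truth
#' multi-resolution assignments in which finer columns nest inside coarser
#' ones, making expected flows exactly computable.
#'
#' Tree nodes are nested lists: a leaf is `list(name =, n =)` (cell count);
#' an internal node is `list(name =, split =, children = list(...))`, where
#' `split` is the grid resolution at which (and above which) its children
#' appear as separate clusters. A root `split` at or below `min(grid)` means
#' its children are separate in every column.
#'
#' @param tree Nested list as described above.
#' @param grid Strictly increasing resolution grid.
#' @param genes_per_node Marker genes owned by each non-root node.
#' @param baseline Baseline expression mean for non-marker genes.
#' @param boost Expression mean of a marker gene in the cells beneath its
#'   owner node.
#' @param sigma Standard deviation of the multiplicative lognormal noise.
#' @param n_noise_genes Unstructured genes at baseline mean everywhere.
#' @param coexpr Optional co-expression marker spec:
#'   `list(genes = <3 ids>, nodes = <3 node names>, high =, low =)`; gene i
#'   has mean `high` beneath node i and `low` elsewhere. Used to exercise
#'   the ternary chart's corners.
#' @param n_components Embedding dimensionality (principal components).
#' @return An object of class `planted_hierarchy`.
#' @export
planted_hierarchy <- function(tree, grid, genes_per_node = 2L,
                              baseline = 0.2, boost = 5, sigma = 0.3,
                              n_noise_genes = 5L, coexpr = NULL,
                              n_components = 10L) {
  grid <- as.numeric(grid)
  if (length(grid) < 2L || is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing with at least 2 values")
  }
  info <- walk_tree(tree, character(0))
  if (anyDuplicated(info$names)) stop("tree node names must be unique")
  internal_splits <- info$splits[!is.na(info$splits)]
  non_root <- internal_splits[-1L]   # root split may sit at/below grid min
  if (length(non_root) > 0L &&
      any(non_root < min(grid) | non_root > max(grid))) {
    stop("internal split resolutions must lie inside the grid range")
  }
  if (sum(info$leaf_n) < length(info$leaf_names)) {
    stop("fewer cells than leaves")
  }
  if (!is.null(coexpr)) {
    stopifnot(length(coexpr$genes) == 3L, length(coexpr$nodes) == 3L)
    if (!all(coexpr$nodes %in% info$names)) {
      stop("coexpr nodes must be tree node names")
    }
  }
  structure(
    list(tree = tree, grid = grid, genes_per_node = as.integer(genes_per_node),
         baseline = baseline, boost = boost, sigma = sigma,
         n_noise_genes = as.integer(n_noise_genes), coexpr = coexpr,
         n_components = as.integer(n_components)),
    class = "planted_hierarchy"
  )
}

walk_tree <- function(node, ancestors) {
  if (is.null(node$children)) {
    if (is.null(node$n) || node$n < 1L) stop("leaf '", node$name,
                                             "' needs a positive n")
    return(list(names = node$name, splits = NA_real_,
                leaf_names = node$name, leaf_n = node$n,
                leaf_lineage = list(c(ancestors, node$name))))
  }
  if (is.null(node$split)) stop("internal node '", node$name,
                                "' needs a split resolution")
  out <- list(names = node$name, splits = node$split,
              leaf_names = character(0), leaf_n = integer(0),
              leaf_lineage = list())
  for (ch in node$children) {
    sub <- walk_tree(ch, c(ancestors, node$name))
    out$names <- c(out$names, sub$names)
    out$splits <- c(out$splits, sub$splits)
    out$leaf_names <- c(out$leaf_names, sub$leaf_names)
    out$leaf_n <- c(out$leaf_n, sub$leaf_n)
    out$leaf_lineage <- c(out$leaf_lineage, sub$leaf_lineage)
  }
  out
}

# cluster name of each leaf when the tree is cut at resolution r: descend
# while a node's children have separated (split <= r)
cut_tree <- function(node, r) {
  if (is.null(node$children)) {
    return(stats::setNames(node$name, node$name))
  }
  if (node$split > r) {
    info <- walk_tree(node, character(0))
    return(stats::setNames(rep(node$name, length(info$leaf_names)),
                           info$leaf_names))
  }
  do.call(c, lapply(node$children, cut_tree, r = r))
}

#' Generate a synthetic fixture from a planted hierarchy
#'
#' Draws expression as prototype means under multiplicative lognormal noise
#' (`mu * exp(N(0, sigma^2))`, clipped at 0), computes a PCA embedding from
#' the generated matrix, and derives the ground-truth cell-by-resolution
#' assignment matrix by cutting the tree at each grid value (labels
#' size-ordered). Bit-identical under the same seed.
#'
#' @param h A [planted_hierarchy()].
#' @param seed Integer seed.
#' @return List with `expression` (cells x genes matrix), `embedding`
#'   (cells x components PCA scores), `assignments` (ground-truth
#'   [cell_assignments], size-ordered labels), and `truth` (per-cell leaf
#'   name and the per-resolution leaf-to-cluster maps).
#' @export
synth_generate <- function(h, seed = 1L) {
  stopifnot(inherits(h, "planted_hierarchy"))
  set.seed(as.integer(seed))
  info <- walk_tree(h$tree, character(0))
  leaves <- info$leaf_names
  n <- sum(info$leaf_n)
  owners <- setdiff(info$names, h$tree$name)   # non-root nodes own markers
  gene_ids <- c(
    unlist(lapply(owners, function(nm)
      paste0("M_", nm, "_", seq_len(h$genes_per_node)))),
    if (h$n_noise_genes > 0L) paste0("NOISE_", seq_len(h$n_noise_genes)),
    h$coexpr$genes
  )
  mu <- matrix(h$baseline, length(leaves), length(gene_ids),
               dimnames = list(leaves, gene_ids))
  lineage <- stats::setNames(info$leaf_lineage, leaves)
  for (nm in owners) {
    under <- leaves[vapply(lineage, function(x) nm %in% x, logical(1L))]
    mu[under, paste0("M_", nm, "_", seq_len(h$genes_per_node))] <- h$boost
  }
  if (!is.null(h$coexpr)) {
    for (i in 1:3) {
      nm <- h$coexpr$nodes[i]
      under <- leaves[vapply(lineage, function(x) nm %in% x, logical(1L))]
      mu[, h$coexpr$genes[i]] <- h$coexpr$low
      mu[under, h$coexpr$genes[i]] <- h$coexpr$high
    }
  }
  leaf_of <- rep(seq_along(leaves), info$leaf_n)
  cell_ids <- sprintf("cell_%05d", seq_len(n))
  x <- mu[leaf_of, , drop = FALSE] *
    exp(matrix(stats::rnorm(n * length(gene_ids), 0, h$sigma), n))
  x <- pmax(x, 0)
  dimnames(x) <- list(cell_ids, gene_ids)

  d <- min(h$n_components, n - 1L, length(gene_ids))
  emb <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(d),
                                                           drop = FALSE]
  rownames(emb) <- cell_ids

  cuts <- lapply(h$grid, function(r) cut_tree(h$tree, r))
  lab <- vapply(cuts, function(map) {
    cl <- factor(map[leaves])[leaf_of]
    as.integer(cl) - 1L
  }, integer(n))
  assign <- relabel_by_size(cell_assignments(cell_ids, lab, h$grid))
  list(
    expression = x, embedding = emb, assignments = assign,
    truth = list(leaf = leaves[leaf_of],
                 cuts = stats::setNames(cuts, assign$res_labels))
  )
}

#' PBMC-like preset hierarchy
#'
#' A three-level, eight-leaf hierarchy of 2700 cells over the resolution
#' grid 0.1-0.5 (step 0.1), shaped like a peripheral-blood dataset: four
#' coarse populations (T, myeloid, B, NK) separate at 0.1, the T branch
#' splits at 0.2 and again at 0.4, and the myeloid branch splits at 0.3 —
#' giving 4, 5, 7, 8, 8 ground-truth clusters across the grid. Three
#' designated co-expression markers (`CO1`, `CO2`, `CO3`) are high in the
#' T, myeloid and B lineages respectively, so GEP triples cover all three
#' ternary corners across flows.
#'
#' @return A [planted_hierarchy()].
#' @export
pbmc_like_preset <- function() {
  tree <- list(
    name = "root", split = 0.1, children = list(
      list(name = "T", split = 0.2, children = list(
        list(name = "CD4", split = 0.4, children = list(
          list(name = "CD4_naive", n = 650L),
          list(name = "CD4_memory", n = 480L)
        )),
        list(name = "CD8", n = 310L)
      )),
      list(name = "Myeloid", split = 0.3, children = list(
        list(name = "Mono_CD14", n = 480L),
        list(name = "Mono_CD16", n = 160L),
        list(name = "DC", n = 120L)
      )),
      list(name = "B", n = 342L),
      list(name = "NK", n = 158L)
    )
  )
  planted_hierarchy(
    tree, grid = seq(0.1, 0.5, by = 0.1),
    genes_per_node = 2L, baseline = 0.2, boost = 5, sigma = 0.3,
    n_noise_genes = 5L,
    coexpr = list(genes = c("CO1", "CO2", "CO3"),
                  nodes = c("T", "Myeloid", "B"),
                  high = 5, low = 0.02),
    n_components = 10L
  )
}

#' Write a generated fixture to the on-disk input formats
#'
#' Emits `assignments.csv`, `expression.mtx` (+ `features.tsv`,
#' `barcodes.tsv`) and `embedding.csv` into a directory, in exactly the
#' layouts the readers expect.
#'
#' @param fx A fixture list from [synth_generate()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_assignments(fx$assignments, file.path(dir, "assignments.csv"))
  write_expression(fx$expression, file.path(dir, "expression.mtx"))
  write_embedding(fx$embedding, file.path(dir, "embedding.csv"))
  invisible(dir)
}
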