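# SWC neuron morphometry: tree validation, arbor-level features (width,
# bifurcations, branch path length, contraction), Sholl profiles, PCA across
# neurons, and pairwise Wilcoxon group comparisons with FDR control.

#' Read and validate an SWC reconstruction
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent), comment lines
#' (`#`) skipped. The tree must have exactly one root (parent -1), every
#' parent must be declared before use, and no cycles are permitted.
#'
#' @param path SWC file path.
#' @return An object of class `neuron_tree`: data.frame `nodes` with columns
#'   `id`, `type`, `x`, `y`, `z`, `radius`, `parent`, plus `root` (root id).
#' @export
read_swc <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  as_neuron_tree(raw, source = path)
}

#' Construct a validated neuron tree from an SWC-style node table
#'
#' @param nodes data.frame with SWC columns.
#' @param source optional provenance label.
#' @return A `neuron_tree`.
#' @export
as_neuron_tree <- function(nodes, source = NA_character_) {
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  roots <- nodes$id[nodes$parent == -1]
  if (length(roots) != 1)
    stop("tree must have exactly one root, found ", length(roots))
  known <- nodes$parent == -1 | nodes$parent %in% nodes$id
  if (!all(known))
    stop("node ", nodes$id[!known][1], " references undeclared parent ",
         nodes$parent[!known][1])
  # cycle check: walk each node to the root
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  for (start in nodes$id) {
    seen <- character(0); cur <- as.character(start)
    while (parent_of[[cur]] != -1) {
      if (cur %in% seen) stop("cycle detected at node ", start)
      seen <- c(seen, cur)
      cur <- as.character(parent_of[[cur]])
    }
  }
  out <- list(nodes = nodes, root = roots, source = source)
  class(out) <- "neuron_tree"
  out
}

#' Write a neuron tree as SWC
#' @param tree a `neuron_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  n <- tree$nodes
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   n$id, n$type, n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c("# SWC export", lines), path)
  invisible(path)
}

# children lookup: list mapping id -> integer vector of child ids
.children_map <- function(tree) {
  n <- tree$nodes
  kids <- split(n$id[n$parent != -1], n$parent[n$parent != -1])
  kids
}

# Decompose the tree into branches: maximal paths between topological points
# (root, bifurcation, terminal). Returns list of id vectors (ordered from the
# proximal topological point to the distal one).
.branches <- function(tree) {
  n <- tree$nodes
  kids <- .children_map(tree)
  n_children <- stats::setNames(rep(0L, nrow(n)), n$id)
  tab <- table(n$parent[n$parent != -1])
  n_children[names(tab)] <- as.integer(tab)
  is_topo <- n$id == tree$root | n_children[as.character(n$id)] >= 2 |
    n_children[as.character(n$id)] == 0
  topo_ids <- n$id[is_topo]
  branches <- list()
  for (t in topo_ids) {
    for (child in kids[[as.character(t)]]) {
      path <- c(t, child)
      cur <- child
      while (!(cur %in% topo_ids)) {
        nxt <- kids[[as.character(cur)]]
        path <- c(path, nxt[1])
        cur <- nxt[1]
      }
      branches[[length(branches) + 1L]] <- path
    }
  }
  branches
}

.path_length <- function(tree, ids) {
  n <- tree$nodes
  idx <- match(ids, n$id)
  xyz <- as.matrix(n[idx, c("x", "y", "z")])
  sum(sqrt(rowSums(diff(xyz)^2)))
}

#' Morphometric feature battery for one neuron
#'
#' Computes the arbor-level features used to compare projection-neuron
#' groups: `width` (max minus min extent along the medial-lateral axis),
#' `n_bifurcations` (non-soma nodes with two or more children; a
#' multifurcation counts once), `branch_path_length` (mean summed segment
#' length over branches, where a branch is the path between consecutive
#' topological points: root, bifurcation, or terminal), and `contraction`
#' (mean over branches of euclidean end-to-end distance divided by path
#' length). Units follow the reconstruction (micrometers).
#'
#' @param tree a `neuron_tree` with at least 2 nodes.
#' @param width_axis coordinate axis measured as arbor width.
#' @return List of class `morphometry_record` with the four features plus
#'   `total_length` and `n_branches`.
#' @export
compute_metrics <- function(tree, width_axis = c("x", "y", "z")) {
  width_axis <- match.arg(width_axis)
  n <- tree$nodes
  if (nrow(n) < 2) stop("tree must have at least 2 nodes")
  branches <- .branches(tree)
  lens <- vapply(branches, function(b) .path_length(tree, b), numeric(1))
  if (all(lens == 0)) stop("degenerate tree: zero total length")
  chords <- vapply(branches, function(b) {
    idx <- match(b[c(1, length(b))], n$id)
    sqrt(sum((n[idx[2], c("x", "y", "z")] - n[idx[1], c("x", "y", "z")])^2))
  }, numeric(1))
  ok <- lens > 0
  tab <- table(n$parent[n$parent != -1])
  kids_count <- stats::setNames(as.integer(tab), names(tab))
  soma_ids <- n$id[n$type == 1]
  non_soma <- setdiff(names(kids_count),
                      as.character(unique(c(tree$root, soma_ids))))
  out <- list(
    width = diff(range(n[[width_axis]])),
    n_bifurcations = sum(kids_count[non_soma] >= 2),
    branch_path_length = mean(lens[ok]),
    contraction = mean(chords[ok] / lens[ok]),
    total_length = sum(lens),
    n_branches = length(branches)
  )
  class(out) <- "morphometry_record"
  out
}

#' Sholl profile of a neuron
#'
#' Counts, for each radius, the tree segments crossing the sphere of that
#' radius centered at the root (soma): segments whose endpoint distances
#' straddle the radius. Soma-type nodes other than the root are excluded.
#'
#' @param tree a `neuron_tree`.
#' @param radii positive ascending radii in micrometers.
#' @return Named integer vector of intersection counts per radius.
#' @export
sholl <- function(tree, radii) {
  stopifnot(all(radii > 0), !is.unsorted(radii))
  n <- tree$nodes
  root <- n[n$id == tree$root, ]
  d <- sqrt((n$x - root$x)^2 + (n$y - root$y)^2 + (n$z - root$z)^2)
  names(d) <- n$id
  seg <- n[n$parent != -1, ]
  seg <- seg[!(seg$type == 1 & n$type[match(seg$parent, n$id)] == 1), ]
  d_child <- d[as.character(seg$id)]
  d_parent <- d[as.character(seg$parent)]
  lo <- pmin(d_child, d_parent); hi <- pmax(d_child, d_parent)
  counts <- vapply(radii, function(r) sum(lo < r & hi >= r), integer(1))
  stats::setNames(counts, radii)
}

#' Morphometry table for a batch of neurons
#'
#' @param trees list of `neuron_tree`s.
#' @param group optional group label(s) recycled over neurons.
#' @param width_axis forwarded to [compute_metrics()].
#' @return data.frame with one row per neuron and the four features.
#' @export
morphometry_table <- function(trees, group = NA_character_,
                              width_axis = "x") {
  recs <- lapply(trees, compute_metrics, width_axis = width_axis)
  data.frame(
    neuron_id = seq_along(trees),
    group = rep_len(group, length(trees)),
    width = vapply(recs, `[[`, numeric(1), "width"),
    n_bifurcations = vapply(recs, `[[`, numeric(1), "n_bifurcations"),
    branch_path_length = vapply(recs, `[[`, numeric(1), "branch_path_length"),
    contraction = vapply(recs, `[[`, numeric(1), "contraction"),
    stringsAsFactors = FALSE
  )
}

#' PCA over morphometric features
#'
#' Features are centered and scaled to unit variance; zero-variance features
#' are dropped with a warning. Components come from the singular value
#' decomposition ([stats::prcomp()]).
#'
#' @param records data.frame of per-neuron features (e.g.
#'   [morphometry_table()]).
#' @param parameters character vector of feature columns.
#' @return List with `scores`, `loadings`, `variance_fraction`.
#' @export
morpho_pca <- function(records, parameters = c("width", "n_bifurcations",
                                               "branch_path_length",
                                               "contraction")) {
  stopifnot(nrow(records) >= 3)
  X <- as.matrix(records[, parameters, drop = FALSE])
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance parameter(s): ",
            paste(parameters[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  list(scores = p$x, loadings = p$rotation,
       variance_fraction = p$sdev^2 / sum(p$sdev^2))
}

#' Pairwise Wilcoxon rank-sum comparisons with FDR correction
#'
#' Two-sided pairwise Wilcoxon rank sum tests per parameter across all group
#' pairs: exact p-values when the combined sample is small and untied, the
#' normal approximation with continuity and tie correction otherwise
#' ([stats::wilcox.test()] defaults). Benjamini-Hochberg adjustment is
#' applied across all pair-by-parameter tests jointly; significance is
#' flagged at adjusted p < 0.05. Groups with fewer than 2 records are
#' excluded and reported in `attr(, "excluded_groups")`.
#'
#' @param records data.frame with a `group` column and feature columns.
#' @param parameters feature columns to test.
#' @param alpha significance threshold on the adjusted p-value.
#' @return data.frame with `group_a`, `group_b`, `parameter`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
group_compare <- function(records, parameters = c("width", "n_bifurcations",
                                                  "branch_path_length",
                                                  "contraction"),
                          alpha = 0.05) {
  sizes <- table(records$group)
  excluded <- names(sizes)[sizes < 2]
  groups <- names(sizes)[sizes >= 2]
  if (length(groups) < 2) stop("need at least two groups with >= 2 records")
  pairs <- utils::combn(groups, 2)
  rows <- list()
  for (par in parameters) {
    for (k in seq_len(ncol(pairs))) {
      a <- records[records$group == pairs[1, k], par]
      b <- records[records$group == pairs[2, k], par]
      p <- suppressWarnings(stats::wilcox.test(a, b,
                                               alternative = "two.sided")$p.value)
      # fully tied samples have zero-variance normal approximation (NaN);
      # no evidence against the null, so report p = 1
      if (is.nan(p)) p <- 1
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = pairs[1, k], group_b = pairs[2, k], parameter = par,
        p_raw = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adjusted < alpha
  attr(out, "excluded_groups") <- excluded
  out
}
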