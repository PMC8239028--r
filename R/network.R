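# Injection-overlap network analysis: directed/symmetrized overlap matrices,
# total-labeling normalization, weighted Louvain modularity maximization with
# seeded runs, consensus (modal) partitioning, matrix reordering, and the
# winner-takes-all community map.

#' Injection-by-compartment weight matrix
#'
#' One row per ROI (summed over atlas levels), one column per zone or
#' zone-by-layer compartment; entries are assigned pixel counts. Duplicate
#' ROI labels are merged with a warning.
#'
#' @param counts `compartment_counts` data.frame (see [quantify_cohort()]).
#' @param granularity `"zone"` or `"zone_layer"`.
#' @return Numeric matrix with ROI row names and compartment column names.
#' @export
build_weight_matrix <- function(counts, granularity = c("zone", "zone_layer")) {
  granularity <- match.arg(granularity)
  stopifnot(nrow(counts) > 0)
  counts <- as.data.frame(counts)
  col_id <- if (granularity == "zone") counts$zone else
    paste(counts$zone, counts$layer, sep = ".")
  cols <- if (granularity == "zone") SC_ZONES else {
    grid <- expand.grid(layer = SC_LAYERS, zone = SC_ZONES,
                        stringsAsFactors = FALSE)
    grid <- grid[compartment_exists(grid$zone, grid$layer), ]
    paste(grid$zone, grid$layer, sep = ".")
  }
  rois <- unique(counts$roi_name)
  if (anyDuplicated(counts[c("roi_name", "level")][!duplicated(
        counts[c("roi_name", "level", "zone", "layer")]), "roi_name"]) &&
      length(rois) < length(unique(paste(counts$roi_name))))
    warning("duplicate ROI labels merged")
  mat <- matrix(0, length(rois), length(cols),
                dimnames = list(rois, cols))
  agg <- stats::aggregate(list(count = counts$count),
                          by = list(roi = counts$roi_name, col = col_id),
                          FUN = sum)
  mat[cbind(match(agg$roi, rois), match(agg$col, cols))] <- agg$count
  mat
}

#' Overlap value between two labeled pixel sets
#'
#' The ratio of common labeling to total source labeling:
#' `|source intersect target| / |source|`. Directional: swap arguments for
#' the reverse ratio.
#'
#' @param source_pixels,target_pixels data.frames of pixel coordinates.
#' @return Ratio in `[0, 1]`.
#' @export
overlap <- function(source_pixels, target_pixels) {
  src <- unique(pixel_keys(source_pixels))
  if (length(src) == 0) stop("overlap is undefined for an empty source")
  tgt <- unique(pixel_keys(target_pixels))
  sum(src %in% tgt) / length(src)
}

# Terminal pixels of a case after passage exclusion, keyed per level so
# pixels at different levels never collide.
.case_terminal_keys <- function(case) {
  unlist(lapply(names(case$levels), function(key) {
    lv <- case$levels[[key]]
    surv <- exclude_passage(lv$terminal, lv$passage)
    if (nrow(surv) == 0) return(character(0))
    paste(key, pixel_keys(surv), sep = ":")
  }), use.names = FALSE)
}

#' Injection-by-injection overlap matrix for a cohort
#'
#' Computes every directed overlap value on pixel-level intersections of
#' terminal labeling (passage excluded) pooled across levels, then
#' symmetrizes as the mean of the two directions. The diagonal
#' (self-overlap) is 1.
#'
#' @param cases cohort list of `sc_injection_case` objects.
#' @return List of class `overlap_matrix` with `directed` and `symmetric`
#'   matrices (ROI-labeled).
#' @export
overlap_matrix <- function(cases) {
  n <- length(cases)
  stopifnot(n >= 2)
  labels <- vapply(cases, `[[`, character(1), "roi_name")
  keys <- lapply(cases, function(cs) unique(.case_terminal_keys(cs)))
  sizes <- lengths(keys)
  if (any(sizes == 0)) stop("overlap is undefined for an empty case: ",
                            paste(labels[sizes == 0], collapse = ", "))
  directed <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      directed[i, j] <- if (i == j) 1 else
        sum(keys[[i]] %in% keys[[j]]) / sizes[i]
    }
  }
  symmetric <- (directed + t(directed)) / 2
  out <- list(labels = labels, directed = directed, symmetric = symmetric)
  class(out) <- "overlap_matrix"
  out
}

#' Normalize rows to the maximum total labeling
#'
#' Scales each row multiplicatively so its total equals the row-total maximum,
#' leaving within-row proportions unchanged. All-zero rows are left as zero
#' and flagged in `attr(, "zero_rows")`.
#'
#' @param matrix numeric weight matrix.
#' @return The normalized matrix.
#' @export
normalize_totals <- function(matrix) {
  totals <- rowSums(matrix)
  if (all(totals == 0)) stop("all rows are zero")
  target <- max(totals)
  scale <- ifelse(totals > 0, target / totals, 0)
  out <- matrix * scale
  attr(out, "zero_rows") <- rownames(matrix)[totals == 0]
  out
}

#' Weighted modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - gamma * k_i * k_j / 2m) * delta(c_i, c_j)`
#' with `m` the total edge weight and `k` the node strengths. The diagonal is
#' ignored (no self-loops in the sum).
#'
#' @param weights symmetric nonnegative weight matrix.
#' @param membership integer community labels per node.
#' @param gamma resolution parameter.
#' @return Q value.
#' @export
modularity_q <- function(weights, membership, gamma = 1) {
  stopifnot(nrow(weights) == ncol(weights),
            length(membership) == nrow(weights), gamma > 0)
  w <- weights
  diag(w) <- 0
  two_m <- sum(w)
  if (two_m == 0) stop("modularity is undefined for zero total weight")
  k <- rowSums(w)
  # accumulate per community so closed-form cases (equal-strength blocks)
  # evaluate without floating-point drift from the full n x n expansion
  q <- 0
  for (cc in unique(membership)) {
    idx <- membership == cc
    q <- q + sum(w[idx, idx]) / two_m - gamma * (sum(k[idx]) / two_m)^2
  }
  q
}

# One Louvain level: local moving on (possibly aggregated) matrix `w` whose
# diagonal holds intra-supernode weight (counted once per ordered pair, i.e.
# A_cc = sum over ordered original pairs). Returns membership or NULL if no
# node moved. `m` is half the total off-diagonal weight of the ORIGINAL
# graph plus diagonal mass, fixed across levels.
.louvain_local_moving <- function(w, gamma, m, tol = 1e-12) {
  n <- nrow(w)
  k <- rowSums(w)                 # strength incl. internal (loop) mass
  comm <- seq_len(n)
  sigma_tot <- k                  # per community total strength
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      # detach i
      sigma_tot[ci] <- sigma_tot[ci] - k[i]
      wi <- w[i, ]
      # links from i to each community (excluding itself)
      link <- tapply(wi[-i], comm[-i], sum)
      cand <- as.integer(names(link))
      if (!(ci %in% cand)) { cand <- c(cand, ci); link <- c(link, 0) }
      gain <- link / m - gamma * k[i] * sigma_tot[cand] / (2 * m^2)
      best <- max(gain)
      winners <- cand[gain >= best - tol]
      new_c <- min(winners)       # tie-break: lowest community index
      cur_gain <- gain[match(ci, cand)]
      if (new_c != ci && best > cur_gain + tol) {
        comm[i] <- new_c
        sigma_tot[new_c] <- sigma_tot[new_c] + k[i]
        moved <- TRUE; moved_any <- TRUE
      } else {
        sigma_tot[ci] <- sigma_tot[ci] + k[i]
      }
    }
    if (!moved) break
  }
  if (moved_any) comm else NULL
}

#' Louvain community detection on a weighted graph
#'
#' Greedy two-phase modularity maximization: seeded random-order local moving
#' until no single-node move improves Q, then aggregation of communities into
#' supernodes, repeated until convergence. Equal-gain moves resolve to the
#' lowest community index. The returned partition's Q never falls below the
#' all-singletons baseline.
#'
#' @param weights symmetric nonnegative weight matrix (or an
#'   `overlap_matrix`, whose symmetric part is used with the diagonal
#'   removed).
#' @param gamma resolution parameter.
#' @param seed integer seed controlling the node-visit order.
#' @return List of class `sc_partition`: `membership` (named integer vector,
#'   labels contiguous from 1), `n_communities`, `modularity`.
#' @export
louvain <- function(weights, gamma = 1, seed = 1L) {
  if (inherits(weights, "overlap_matrix")) weights <- weights$symmetric
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (nrow(weights) == 0) stop("empty graph")
  if (max(abs(weights - t(weights))) > 1e-9) stop("weights must be symmetric")
  if (any(weights < 0)) stop("weights must be nonnegative")
  labels <- rownames(weights)
  w <- weights
  diag(w) <- 0
  m <- sum(w) / 2
  if (m == 0) stop("graph has zero total weight")
  n0 <- nrow(w)
  assignment <- seq_len(n0)   # original node -> current supernode
  with_seed(seed, {
    repeat {
      comm <- .louvain_local_moving(w, gamma, m)
      if (is.null(comm)) break
      # relabel contiguously and aggregate
      comm <- match(comm, sort(unique(comm)))
      assignment <- comm[assignment]
      nc <- max(comm)
      if (nc == nrow(w)) break
      agg <- matrix(0, nc, nc)
      for (a in seq_len(nc)) {
        for (b in seq_len(nc)) {
          agg[a, b] <- sum(w[comm == a, comm == b, drop = FALSE])
        }
      }
      w <- agg
    }
  })
  membership <- canonicalize_membership(assignment)
  names(membership) <- labels
  out <- list(membership = membership,
              n_communities = max(membership),
              modularity = modularity_q(weights, membership, gamma))
  class(out) <- "sc_partition"
  out
}

#' Canonicalize community labels
#'
#' Relabels communities by order of first occurrence over the fixed node
#' order, so partitions that differ only by a label permutation become
#' identical vectors (labels contiguous from 1).
#'
#' @param membership integer community labels.
#' @return Canonical integer labels.
#' @export
canonicalize_membership <- function(membership) {
  match(membership, unique(membership))
}

#' Consensus (modal) partition over repeated Louvain runs
#'
#' Runs are canonicalized up to label permutation; the partition occurring
#' most often is the consensus (ties broken by the lexicographically smallest
#' canonical labeling, for determinism). Also reports the mean and standard
#' deviation of the number of communities across runs.
#'
#' @param partitions list of `sc_partition` objects (or bare membership
#'   vectors) over identical node sets.
#' @return List of class `community_result`: `consensus` (an `sc_partition`),
#'   `mode_count`, `n_runs`, `n_communities_mean`, `n_communities_sd`,
#'   `modularity` (per-run Q, `NA` for bare vectors), `runs` (canonical
#'   memberships).
#' @export
consensus_partition <- function(partitions) {
  if (length(partitions) == 0) stop("no partitions supplied")
  memberships <- lapply(partitions, function(p)
    if (inherits(p, "sc_partition")) p$membership else p)
  nodes <- names(memberships[[1]])
  for (mb in memberships)
    if (length(mb) != length(memberships[[1]]) ||
        (!is.null(nodes) && !identical(names(mb), nodes)))
      stop("partitions cover different node sets")
  canon <- lapply(memberships, canonicalize_membership)
  sig <- vapply(canon, paste, character(1), collapse = ",")
  tab <- table(sig)
  top <- names(tab)[tab == max(tab)]
  winner <- sort(top)[1]
  consensus_mb <- canon[[match(winner, sig)]]
  names(consensus_mb) <- nodes
  qs <- vapply(partitions, function(p)
    if (inherits(p, "sc_partition")) p$modularity else NA_real_, numeric(1))
  ncs <- vapply(canon, max, integer(1))
  consensus <- list(membership = consensus_mb,
                    n_communities = max(consensus_mb),
                    modularity = qs[match(winner, sig)])
  class(consensus) <- "sc_partition"
  out <- list(consensus = consensus,
              mode_count = as.integer(max(tab)),
              n_runs = length(partitions),
              n_communities_mean = mean(ncs),
              n_communities_sd = stats::sd(ncs),
              modularity = qs,
              runs = canon)
  class(out) <- "community_result"
  out
}

#' Repeated seeded Louvain with consensus
#'
#' Run `i` uses seed `master_seed + i`, so the full consensus is reproducible
#' from the master seed alone.
#'
#' @param weights symmetric weight matrix or `overlap_matrix`.
#' @param gamma resolution parameter.
#' @param n_runs number of Louvain executions.
#' @param master_seed integer master seed.
#' @return A `community_result` (see [consensus_partition()]).
#' @export
louvain_consensus <- function(weights, gamma = 1, n_runs = 1000,
                              master_seed = 1L) {
  stopifnot(n_runs >= 1, gamma > 0)
  runs <- lapply(seq_len(n_runs), function(i)
    louvain(weights, gamma = gamma, seed = master_seed + i))
  consensus_partition(runs)
}

#' @export
print.community_result <- function(x, ...) {
  cat("consensus over", x$n_runs, "runs:", x$consensus$n_communities,
      "communities (mode occurred", x$mode_count, "times)\n")
  cat("communities per run:", round(x$n_communities_mean, 2), "+/-",
      round(x$n_communities_sd, 3), "| consensus Q =",
      round(x$consensus$modularity, 4), "\n")
  invisible(x)
}

#' Reorder a matrix by community
#'
#' Groups rows (and columns, when the matrix is square over the same labels)
#' by community so connections fall close to the diagonal; within a community
#' the original order is kept.
#'
#' @param mat labeled numeric matrix.
#' @param partition an `sc_partition` covering the row labels.
#' @return List with `matrix` (permuted), `order` (row permutation), and
#'   `block_boundaries` (last row index of each community block).
#' @export
reorder_matrix <- function(mat, partition) {
  mb <- partition$membership
  if (is.null(rownames(mat)) || !all(rownames(mat) %in% names(mb)))
    stop("partition does not cover matrix row labels")
  comm <- mb[rownames(mat)]
  ord <- order(comm, seq_along(comm))
  square <- nrow(mat) == ncol(mat) &&
    !is.null(colnames(mat)) && all(colnames(mat) == rownames(mat))
  res <- if (square) mat[ord, ord] else mat[ord, , drop = FALSE]
  bounds <- cumsum(table(comm[ord]))
  list(matrix = res, order = ord, block_boundaries = as.integer(bounds))
}

#' Winner-takes-all community map
#'
#' Tiles the SC raster into square cells and colors each cell with labeling
#' by the community whose member injections contribute the most terminal
#' pixels there (ties to the lowest community index); unlabeled cells stay
#' `NA`.
#'
#' @param cases cohort list of `sc_injection_case` objects.
#' @param partition an `sc_partition` covering the case ROIs.
#' @param level the `sc_atlas_level` to map.
#' @param cell_size cell edge length in pixels.
#' @return Integer matrix of community indices per cell (`NA` = unassigned).
#' @export
winner_takes_all <- function(cases, partition, level, cell_size = 10) {
  mb <- partition$membership
  labels <- vapply(cases, `[[`, character(1), "roi_name")
  if (!all(labels %in% names(mb)))
    stop("partition does not cover all case ROIs")
  nr <- ceiling(level$raster_shape[1] / cell_size)
  nc <- ceiling(level$raster_shape[2] / cell_size)
  ncomm <- max(mb)
  tall <- array(0L, c(nr, nc, ncomm))
  key <- as.character(level$ara_id)
  for (cs in cases) {
    lv <- cs$levels[[key]]
    if (is.null(lv)) next
    px <- exclude_passage(lv$terminal, lv$passage)
    if (nrow(px) == 0) next
    ci <- mb[[cs$roi_name]]
    cellr <- px$y %/% cell_size + 1L
    cellc <- px$x %/% cell_size + 1L
    tab <- stats::aggregate(list(n = rep(1L, nrow(px))),
                            by = list(r = cellr, c = cellc), FUN = sum)
    tall[cbind(tab$r, tab$c, ci)] <- tall[cbind(tab$r, tab$c, ci)] + tab$n
  }
  out <- matrix(NA_integer_, nr, nc)
  totals <- apply(tall, c(1, 2), sum)
  labeled <- which(totals > 0, arr.ind = TRUE)
  if (nrow(labeled) > 0) {
    for (i in seq_len(nrow(labeled))) {
      v <- tall[labeled[i, 1], labeled[i, 2], ]
      out[labeled[i, 1], labeled[i, 2]] <- which.max(v)  # lowest index on ties
    }
  }
  out
}

#' Write a partition (or community result) as JSON
#' @param x an `sc_partition` or `community_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
partition_to_json <- function(x, path) {
  payload <- if (inherits(x, "community_result")) {
    list(consensus = as.list(x$consensus$membership),
         n_communities = x$consensus$n_communities,
         mode_count = x$mode_count, n_runs = x$n_runs,
         n_communities_mean = x$n_communities_mean,
         n_communities_sd = x$n_communities_sd,
         consensus_modularity = x$consensus$modularity)
  } else {
    list(membership = as.list(x$membership),
         n_communities = x$n_communities, modularity = x$modularity)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Heat map of a (reordered) matrix
#'
#' @param mat numeric matrix.
#' @param path output PNG path.
#' @param block_boundaries optional community block boundaries to draw.
#' @return `path`, invisibly.
#' @export
plot_matrix <- function(mat, path, block_boundaries = NULL) {
  grDevices::png(path, width = 700, height = 700)
  op <- graphics::par(mar = c(6, 6, 2, 1))
  n <- nrow(mat); p <- ncol(mat)
  graphics::image(seq_len(p), seq_len(n), t(mat[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(p), labels = colnames(mat), las = 2, cex.axis = 0.5)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(mat)), las = 1, cex.axis = 0.5)
  if (!is.null(block_boundaries)) {
    for (b in block_boundaries[-length(block_boundaries)]) {
      graphics::abline(h = n - b + 0.5, col = "grey30")
      if (n == p) graphics::abline(v = b + 0.5, col = "grey30")
    }
  }
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
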