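# Synthetic SWC morphologies emulating thalamus-projecting SC neuron groups:
# arbor size grows from medial to lateral zones and is modulated by the
# thalamic target (LD-projecting cells smallest).

# expected dendritic-field width (micrometers) per zone, medial -> lateral
.zone_width_um <- c("SC.m" = 80, "SC.cm" = 110, "SC.cl" = 140, "SC.l" = 180)
# multiplicative modulation by thalamic target
.target_scale <- c("LD" = 0.7, "RE" = 1.0, "PF" = 1.1)

.unit_vector <- function(v) v / sqrt(sum(v^2))

# random direction within `spread` radians of `dir`
.jitter_dir <- function(dir, spread) {
  .unit_vector(dir + stats::rnorm(3, 0, spread))
}

#' Generate synthetic thalamus-projecting SC neurons
#'
#' Builds rooted dendritic trees whose expected arbor width follows the
#' medial-to-lateral zone trend (SC.m < SC.cm < SC.cl < SC.l) scaled by the
#' thalamic target (LD-projecting smallest). Each tree is a valid SWC
#' structure: single soma root, acyclic, parents declared before children.
#'
#' @param zone SC zone of the somata.
#' @param target thalamic target label (`"RE"`, `"LD"`, `"PF"`).
#' @param n number of neurons.
#' @param seed integer seed; neuron `i` uses a named substream.
#' @param dir optional directory; when given, each neuron is written as
#'   `<zone>_<target>_<i>.swc` and paths are attached as `attr(, "paths")`.
#' @return List of `neuron_tree` objects.
#' @export
generate_neurons <- function(zone, target = c("RE", "LD", "PF"), n, seed,
                             dir = NULL) {
  stopifnot(zone %in% SC_ZONES, n >= 1)
  target <- match.arg(target)
  scale_um <- .zone_width_um[[zone]] * .target_scale[[target]]
  trees <- lapply(seq_len(n), function(i) {
    with_seed(substream_seed(seed, sprintf("neuron-%s-%s-%d", zone, target, i)),
              .grow_neuron(scale_um))
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(seq_len(n), function(i) {
      p <- file.path(dir, sprintf("%s_%s_%03d.swc", gsub("\\.", "", zone),
                                  target, i))
      write_swc(trees[[i]], p)
      p
    }, character(1))
    attr(trees, "paths") <- paths
  }
  trees
}

# Grow one tree: a few stems from the soma, each a recursive binary
# branching process; segment lengths scale with the target arbor width so
# the realized extent tracks `scale_um`.
.grow_neuron <- function(scale_um) {
  rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = 6, parent = -1L))
  next_id <- 2L
  seg_len <- scale_um / 7
  grow <- function(parent_id, origin, dir, depth, radius) {
    # one branch: a short chain of jittered segments
    n_seg <- sample(2:4, 1)
    pos <- origin
    pid <- parent_id
    for (s in seq_len(n_seg)) {
      step <- .jitter_dir(dir, 0.25) * seg_len * stats::runif(1, 0.7, 1.3)
      pos <- pos + step
      rows[[length(rows) + 1L]] <<- data.frame(
        id = next_id, type = 3L, x = pos[1], y = pos[2], z = pos[3],
        radius = radius, parent = pid)
      pid <- next_id
      next_id <<- next_id + 1L
    }
    if (depth > 0 && stats::runif(1) < 0.85) {
      for (k in 1:2) {
        child_dir <- .jitter_dir(dir, 0.8)
        grow(pid, pos, child_dir, depth - 1, radius * 0.7)
      }
    }
  }
  n_stems <- sample(2:3, 1)
  for (s in seq_len(n_stems)) {
    dir0 <- .unit_vector(stats::rnorm(3))
    grow(1L, c(0, 0, 0), dir0, depth = 2, radius = 2)
  }
  as_neuron_tree(do.call(rbind, rows), source = "synthetic")
}

#' Generate the full synthetic reconstruction roster
#'
#' Emulates the study's nine zone-by-target groups of thalamus-projecting SC
#' neurons (RE-SC.m n=23, RE-SC.cm n=27, RE-SC.cl n=4; LD-SC.m n=4,
#' LD-SC.cm n=4; PF-SC.m n=10, PF-SC.cm n=6, PF-SC.cl n=9, PF-SC.l n=5).
#'
#' @param seed integer master seed.
#' @param groups data.frame with columns `zone`, `target`, `n`; defaults to
#'   the study roster.
#' @return data.frame from [morphometry_table()] with a `group` label
#'   `"<target>-<zone>"` per neuron, and the trees in `attr(, "trees")`.
#' @export
generate_neuron_cohort <- function(seed = 1L, groups = NULL) {
  if (is.null(groups)) {
    groups <- data.frame(
      zone = c("SC.m", "SC.cm", "SC.cl", "SC.m", "SC.cm",
               "SC.m", "SC.cm", "SC.cl", "SC.l"),
      target = c("RE", "RE", "RE", "LD", "LD", "PF", "PF", "PF", "PF"),
      n = c(23L, 27L, 4L, 4L, 4L, 10L, 6L, 9L, 5L),
      stringsAsFactors = FALSE)
  }
  tabs <- list(); all_trees <- list()
  for (g in seq_len(nrow(groups))) {
    trees <- generate_neurons(groups$zone[g], groups$target[g], groups$n[g],
                              seed = seed)
    label <- paste(groups$target[g], groups$zone[g], sep = "-")
    tabs[[g]] <- morphometry_table(trees, group = label)
    all_trees <- c(all_trees, trees)
  }
  out <- do.call(rbind, tabs)
  out$neuron_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "trees") <- all_trees
  out
}
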