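# Shared fixtures and independent oracles for the test suite.

# two disconnected unit-weight triangles on 6 labeled nodes
two_triangles <- function() {
  w <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (grp in list(1:3, 4:6)) {
    for (a in grp) for (b in grp) if (a != b) w[a, b] <- 1
  }
  w
}

# Enumerate all set partitions of n elements as restricted growth strings.
# Returns a list of integer membership vectors. Independent of the package's
# community code.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, max_label) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(max_label + 1L)) {
      recurse(c(prefix, lab), max(max_label, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Brute-force modularity oracle: direct per-community summation, written
# independently of modularity_q().
oracle_modularity <- function(w, membership, gamma = 1) {
  diag(w) <- 0
  two_m <- sum(w)
  k <- rowSums(w)
  q <- 0
  for (cc in unique(membership)) {
    idx <- membership == cc
    s_in <- sum(w[idx, idx])
    s_tot <- sum(k[idx])
    q <- q + s_in / two_m - gamma * (s_tot / two_m)^2
  }
  q
}

# Maximum modularity over all partitions by exhaustive search.
brute_force_best_q <- function(w, gamma = 1) {
  parts <- all_partitions(nrow(w))
  max(vapply(parts, function(p) oracle_modularity(w, p, gamma), numeric(1)))
}

# random symmetric nonnegative weighted graph with guaranteed positive weight
random_small_graph <- function(n) {
  w <- matrix(0, n, n)
  upper <- which(upper.tri(w))
  vals <- ifelse(stats::runif(length(upper)) < 0.6, stats::runif(length(upper)), 0)
  w[upper] <- vals
  w <- w + t(w)
  if (sum(w) == 0) w[1, 2] <- w[2, 1] <- 1
  dimnames(w) <- list(paste0("n", 1:n), paste0("n", 1:n))
  w
}

# hand-built small SWC tables
straight_cable_tree <- function() {
  as_neuron_tree(data.frame(
    id = 1:3, type = c(1, 3, 3), x = c(0, 50, 100), y = 0, z = 0,
    radius = 1, parent = c(-1, 1, 2)))
}

right_angle_tree <- function() {
  as_neuron_tree(data.frame(
    id = 1:3, type = c(1, 3, 3), x = c(0, 50, 50), y = c(0, 0, 50), z = 0,
    radius = 1, parent = c(-1, 1, 2)))
}

y_tree <- function() {
  as_neuron_tree(data.frame(
    id = 1:4, type = c(1, 3, 3, 3),
    x = c(0, 0, 30, -30), y = c(0, 50, 80, 80), z = 0,
    radius = 1, parent = c(-1, 1, 2, 2)))
}

# a small planted cohort for network/annotation checks
small_cohort <- function(seed = 7, per_zone = 3, n_px = 300) {
  atlas <- build_default_atlas()
  spec <- cohort_spec(
    groups = stats::setNames(rep(per_zone, 4), SC_ZONES),
    seed = seed, n_terminal_pixels = n_px)
  list(atlas = atlas, cases = generate_cohort(spec, atlas))
}
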