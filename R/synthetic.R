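# Synthetic tracer-labeling generator. Stands in for the tracer image
# archive: per-injection terminal fields concentrated in one or two
# zone-by-layer compartments, straight fibers-of-passage streaks, Gaussian
# background noise, and the cohort structure of 86 cortical injections.

#' Specification of one synthetic cortical injection
#'
#' @param roi_name cortical area label (e.g. `"MOp"`, `"VISam"`).
#' @param zone dominant SC zone the injection targets.
#' @param target_compartments data.frame with columns `zone`, `layer`,
#'   `weight` (weights sum to 1); defaults to a zone-typical laminar pattern.
#' @param n_terminal_pixels terminal pixels generated per atlas level.
#' @param dispersion angular jitter (degrees, sd of the truncated-normal
#'   kernel around the target zone's mid-angle).
#' @param passage_fraction fraction of all labeled pixels that are
#'   fibers-of-passage artifacts.
#' @param purity fraction of terminal pixels forced inside the target
#'   compartments; the remainder scatter uniformly over the rest of the SC.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(roi_name, zone,
                     target_compartments = NULL,
                     n_terminal_pixels = 600,
                     dispersion = 4,
                     passage_fraction = 0.10,
                     purity = 0.85) {
  stopifnot(zone %in% SC_ZONES, purity >= 0, purity <= 1,
            n_terminal_pixels >= 0, dispersion > 0,
            passage_fraction >= 0, passage_fraction < 1)
  if (is.null(target_compartments))
    target_compartments <- default_target_compartments(zone)
  stopifnot(abs(sum(target_compartments$weight) - 1) < 1e-9)
  if (any(!compartment_exists(target_compartments$zone, target_compartments$layer)))
    stop("target compartments include an anatomically empty compartment")
  out <- list(roi_name = roi_name, zone = zone,
              target_compartments = target_compartments,
              n_terminal_pixels = as.integer(n_terminal_pixels),
              dispersion = dispersion,
              passage_fraction = passage_fraction, purity = purity)
  class(out) <- "roi_spec"
  out
}

#' Zone-typical laminar termination pattern
#'
#' Default target compartments per dominant zone, mimicking the tiered
#' laminar patterns of representative cortico-tectal injections (parietal
#' inputs to intermediate SC.m layers, visual inputs to superficial SC.cm,
#' cingulate inputs to intermediate/deep SC.cl, motor inputs to lateral
#' intermediate layers).
#'
#' @param zone an SC zone id.
#' @return data.frame with columns `zone`, `layer`, `weight`.
#' @export
default_target_compartments <- function(zone) {
  layers <- switch(zone,
    "SC.m"  = c("ig", "iw"),
    "SC.cm" = c("sg", "ig"),
    "SC.cl" = c("ig", "dg"),
    "SC.l"  = c("ig", "iw"))
  data.frame(zone = zone, layer = layers, weight = c(0.6, 0.4),
             stringsAsFactors = FALSE)
}

# Convert polar samples (theta degrees, depth fraction from surface) to
# integer raster pixels for a level.
.polar_to_pixel <- function(level, theta, frac) {
  r <- level$sc_radius * (1 - frac)
  rad <- theta * pi / 180
  data.frame(
    x = as.integer(round(level$origin[["x"]] + r * cos(rad))),
    y = as.integer(round(level$origin[["y"]] - r * sin(rad)))
  )
}

# Batched rejection sampling of `n` unique pixels inside one compartment.
# Compartment membership is re-checked after integer rounding, so the purity
# contract is exact, not approximate.
.sample_in_compartment <- function(level, zone, layer, dispersion, n, seen,
                                   max_rounds = 60) {
  if (n == 0) return(data.frame(x = integer(0), y = integer(0)))
  rng <- level$zone_ranges[[zone]]
  mid <- mean(rng)
  band <- level$layer_bands[[layer]]
  out <- data.frame(x = integer(0), y = integer(0))
  for (round in seq_len(max_rounds)) {
    need <- n - nrow(out)
    if (need == 0) break
    m <- max(50L, 3L * need)
    # once the kernel core saturates with duplicates, spread the remaining
    # draws uniformly over the zone's angular range so dense requests can
    # still fill the compartment
    if (round <= max_rounds / 2) {
      theta <- stats::rnorm(m, mid, dispersion)
    } else {
      theta <- stats::runif(m, rng[2], rng[1])
    }
    frac <- stats::runif(m, band[1], band[2])
    keep <- theta > rng[2] & theta <= rng[1]
    px <- .polar_to_pixel(level, theta[keep], frac[keep])
    if (nrow(px) == 0) next
    keys <- paste(px$x, px$y, sep = ",")
    px <- px[!duplicated(keys) & !(keys %in% seen), , drop = FALSE]
    if (nrow(px) == 0) next
    comp <- compartments_of(level, px)
    px <- px[!is.na(comp$zone) & comp$zone == zone & comp$layer == layer, ,
             drop = FALSE]
    if (nrow(px) == 0) next
    take <- min(nrow(px), need)
    out <- rbind(out, px[seq_len(take), , drop = FALSE])
    seen <- c(seen, paste(out$x, out$y, sep = ","))
  }
  if (nrow(out) < n)
    stop("could not place ", n, " unique pixels in compartment ", zone, "/",
         layer, "; compartment may be saturated")
  rownames(out) <- NULL
  out
}

# Batched rejection sampling of `n` unique pixels inside the SC but outside
# all target compartments.
.sample_off_target <- function(level, targets, n, seen, max_rounds = 60) {
  if (n == 0) return(data.frame(x = integer(0), y = integer(0)))
  lat_low <- level$zone_ranges[["SC.l"]][2]
  tkey <- paste(targets$zone, targets$layer)
  out <- data.frame(x = integer(0), y = integer(0))
  for (round in seq_len(max_rounds)) {
    need <- n - nrow(out)
    if (need == 0) break
    m <- max(50L, 3L * need)
    theta <- stats::runif(m, lat_low, 90)
    frac <- stats::runif(m, 0, 1)
    px <- .polar_to_pixel(level, theta, frac)
    keys <- paste(px$x, px$y, sep = ",")
    px <- px[!duplicated(keys) & !(keys %in% seen), , drop = FALSE]
    if (nrow(px) == 0) next
    comp <- compartments_of(level, px)
    ok <- !is.na(comp$zone) & !(paste(comp$zone, comp$layer) %in% tkey)
    px <- px[ok, , drop = FALSE]
    if (nrow(px) == 0) next
    take <- min(nrow(px), need)
    out <- rbind(out, px[seq_len(take), , drop = FALSE])
    seen <- c(seen, paste(out$x, out$y, sep = ","))
  }
  if (nrow(out) < n) stop("could not place ", n, " unique off-target pixels")
  rownames(out) <- NULL
  out
}

# Straight fibers-of-passage streaks entering from the dorsal/medial edge of
# the raster, crossing the SC without terminating.
.sample_passage <- function(level, n, avoid_keys) {
  out <- data.frame(x = integer(0), y = integer(0))
  seen <- character(0)
  guard <- 0
  while (nrow(out) < n && guard < 50) {
    guard <- guard + 1
    # entry point on the dorsal edge of the SC, medial third
    x0 <- level$origin[["x"]] + stats::runif(1, 0.05, 0.35) * level$sc_radius
    y0 <- level$origin[["y"]] - level$sc_radius
    ang <- stats::runif(1, 60, 85) * pi / 180  # steep descent, slight lateral drift
    len <- seq(0, 2 * level$sc_radius, by = 0.7)
    px <- data.frame(
      x = as.integer(round(x0 + len * cos(ang))),
      y = as.integer(round(y0 + len * sin(ang)))
    )
    nr <- level$raster_shape[1]; nc <- level$raster_shape[2]
    px <- px[px$x >= 0 & px$x < nc & px$y >= 0 & px$y < nr, , drop = FALSE]
    if (nrow(px) == 0) next
    comp <- compartments_of(level, px)
    px <- px[!is.na(comp$zone), , drop = FALSE]
    keys <- paste(px$x, px$y, sep = ",")
    keep <- !(keys %in% avoid_keys) & !(keys %in% seen) & !duplicated(keys)
    px <- px[keep, , drop = FALSE]
    if (nrow(px) == 0) next
    take <- min(nrow(px), n - nrow(out))
    out <- rbind(out, px[seq_len(take), , drop = FALSE])
    seen <- c(seen, paste(px$x[seq_len(take)], px$y[seq_len(take)], sep = ","))
  }
  out
}

#' Generate one synthetic injection case
#'
#' Terminal pixels are drawn per level from a truncated-normal angular kernel
#' centered at the target zone's mid-angle (sd = `dispersion`), radially
#' uniform within the target layer band; a `1 - purity` fraction scatters
#' uniformly over the rest of the SC. Fibers-of-passage pixels are laid along
#' straight streaks entering from the dorsal/medial edge, kept disjoint from
#' the terminal set, and carried in a separate flagged set. The same
#' `(spec, seed)` yields bitwise-identical output.
#'
#' @param spec a [roi_spec()].
#' @param levels an `sc_atlas` (all levels) or a single `sc_atlas_level`.
#' @param seed integer seed for this case.
#' @return An object of class `sc_injection_case`: `roi_name`, `zone`, and a
#'   per-level list with `terminal` and `passage` pixel data.frames.
#' @export
generate_case <- function(spec, levels, seed) {
  stopifnot(inherits(spec, "roi_spec"))
  if (inherits(levels, "sc_atlas_level")) {
    levels <- structure(stats::setNames(list(levels), as.character(levels$ara_id)),
                        class = "sc_atlas")
  }
  stopifnot(inherits(levels, "sc_atlas"))
  if (spec$n_terminal_pixels == 0) {
    warning("empty case: n_terminal_pixels = 0 for ", spec$roi_name)
  }
  per_level <- with_seed(seed, lapply(levels, function(lvl) {
    n <- spec$n_terminal_pixels
    if (n == 0) {
      return(list(terminal = data.frame(x = integer(0), y = integer(0)),
                  passage = data.frame(x = integer(0), y = integer(0))))
    }
    n_in <- stats::rbinom(1, n, spec$purity)
    comps <- spec$target_compartments
    comp_idx <- sample.int(nrow(comps), n_in, replace = TRUE,
                           prob = comps$weight)
    seen <- character(0)
    rows <- vector("list", nrow(comps) + 1L)
    for (ci in seq_len(nrow(comps))) {
      px <- .sample_in_compartment(lvl, comps$zone[ci], comps$layer[ci],
                                   spec$dispersion, sum(comp_idx == ci), seen)
      rows[[ci]] <- px
      seen <- c(seen, paste(px$x, px$y, sep = ","))
    }
    rows[[nrow(comps) + 1L]] <- .sample_off_target(lvl, comps, n - n_in, seen)
    terminal <- do.call(rbind, rows)
    rownames(terminal) <- NULL
    n_pass <- round(n * spec$passage_fraction / (1 - spec$passage_fraction))
    passage <- .sample_passage(lvl, n_pass, seen)
    rownames(passage) <- NULL
    list(terminal = terminal, passage = passage)
  }))
  out <- list(roi_name = spec$roi_name, zone = spec$zone, spec = spec,
              seed = as.integer(seed), levels = per_level)
  class(out) <- "sc_injection_case"
  out
}

#' @export
print.sc_injection_case <- function(x, ...) {
  nterm <- sum(vapply(x$levels, function(l) nrow(l$terminal), integer(1)))
  npass <- sum(vapply(x$levels, function(l) nrow(l$passage), integer(1)))
  cat("injection case", x$roi_name, "->", x$zone, ":",
      nterm, "terminal +", npass, "passage pixels across",
      length(x$levels), "level(s)\n")
  invisible(x)
}

# Base cortical-area names per dominant zone (representative cortico-tectal
# sources); numbered suffixes distinguish repeated injections.
.zone_roi_names <- list(
  "SC.m"  = c("PTLp", "VISp", "VISpm", "RSPagl"),
  "SC.cm" = c("VISam", "VISal", "RSPd"),
  "SC.cl" = c("ACAd", "ACAv", "ORBvl", "MOs-medial"),
  "SC.l"  = c("MOp", "SSp-ul", "SSp-ll", "SSp-bfd", "SSs", "AUDp")
)

#' Specification of a synthetic injection cohort
#'
#' The default cohort reproduces the study structure: 86 injections whose
#' dominant-zone composition doubles the confined-projection subset sizes
#' (7, 4, 12, 20 for SC.m, SC.cm, SC.cl, SC.l).
#'
#' @param groups named integer vector of cases per dominant zone.
#' @param seed master seed; per-case seeds are derived substreams.
#' @param ... additional arguments forwarded to every [roi_spec()] (e.g.
#'   `purity`, `n_terminal_pixels`).
#' @return An object of class `cohort_spec` with a `roster` of `roi_spec`s
#'   and a `group_assignment` map.
#' @export
cohort_spec <- function(groups = c("SC.m" = 14, "SC.cm" = 8,
                                   "SC.cl" = 24, "SC.l" = 40),
                        seed = 1L, ...) {
  stopifnot(all(names(groups) %in% SC_ZONES), all(groups >= 1))
  roster <- list()
  for (z in names(groups)) {
    base <- .zone_roi_names[[z]]
    nm <- rep(base, length.out = groups[[z]])
    reps <- stats::ave(seq_along(nm), nm, FUN = seq_along)
    nm <- ifelse(reps > 1, paste0(nm, ".", reps), nm)
    for (r in nm) roster[[length(roster) + 1L]] <- roi_spec(r, z, ...)
  }
  assignment <- stats::setNames(
    vapply(roster, function(s) s$zone, character(1)),
    vapply(roster, function(s) s$roi_name, character(1))
  )
  out <- list(roster = roster, group_assignment = assignment,
              seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

#' Generate a full synthetic cohort
#'
#' One case per roster entry, each generated across all atlas levels from a
#' named substream of the master seed, so cohort regeneration from the same
#' spec is bitwise reproducible.
#'
#' @param spec a [cohort_spec()].
#' @param atlas an `sc_atlas`; defaults to [build_default_atlas()].
#' @return A named list of `sc_injection_case` objects, with the
#'   `group_assignment` attached as an attribute.
#' @export
generate_cohort <- function(spec, atlas = build_default_atlas()) {
  stopifnot(inherits(spec, "cohort_spec"))
  cases <- lapply(spec$roster, function(rs) {
    generate_case(rs, atlas, substream_seed(spec$seed, paste0("case-", rs$roi_name)))
  })
  names(cases) <- vapply(spec$roster, function(s) s$roi_name, character(1))
  attr(cases, "group_assignment") <- spec$group_assignment
  cases
}

#' Confined-projection subset of a cohort
#'
#' Selects the first 7/4/12/20 cases per dominant zone (SC.m, SC.cm, SC.cl,
#' SC.l), mirroring the subset of injections with projections confined to a
#' single zone that drives the angular-density validation.
#'
#' @param cases cohort list from [generate_cohort()].
#' @param sizes named integer vector of per-zone subset sizes.
#' @return Subset list of cases with the group assignment attribute restricted
#'   accordingly.
#' @export
confined_subset <- function(cases, sizes = c("SC.m" = 7, "SC.cm" = 4,
                                             "SC.cl" = 12, "SC.l" = 20)) {
  assignment <- attr(cases, "group_assignment")
  keep <- character(0)
  for (z in names(sizes)) {
    members <- names(assignment)[assignment == z]
    if (length(members) < sizes[[z]])
      stop("cohort has only ", length(members), " cases in ", z)
    keep <- c(keep, members[seq_len(sizes[[z]])])
  }
  out <- cases[keep]
  attr(out, "group_assignment") <- assignment[keep]
  out
}

#' Render a case's labeling at one level as a grayscale intensity image
#'
#' Labeled pixels (terminal and passage) are set to full intensity (255) on a
#' Gaussian background (mean 20, sd 5, clipped to `[0, 255]`), so the default
#' fixed threshold of 100 recovers exactly the planted pixels.
#'
#' @param case an `sc_injection_case`.
#' @param level the `sc_atlas_level` to render.
#' @param seed integer seed for the background noise; defaults to a substream
#'   of the case seed keyed by level, so rendering is deterministic.
#' @return Numeric matrix (`raster_shape`) of intensities in `[0, 255]`.
#' @export
render_intensity_image <- function(case, level, seed = NULL) {
  stopifnot(inherits(case, "sc_injection_case"),
            inherits(level, "sc_atlas_level"))
  key <- as.character(level$ara_id)
  if (!key %in% names(case$levels))
    stop("case has no data for level ", key)
  if (is.null(seed)) seed <- substream_seed(case$seed, paste0("render-", key))
  nr <- level$raster_shape[1]; nc <- level$raster_shape[2]
  img <- with_seed(seed, matrix(stats::rnorm(nr * nc, 20, 5), nr, nc))
  img[img < 0] <- 0; img[img > 255] <- 255
  lv <- case$levels[[key]]
  px <- rbind(lv$terminal, lv$passage)
  if (nrow(px) > 0) {
    # pixel (x, y) is column x, row y, both 0-based
    img[cbind(px$y + 1L, px$x + 1L)] <- 255
  }
  img
}

#' Write a case to disk as per-level PNG images plus a JSON sidecar
#'
#' The sidecar records the ROI name, seed, dominant zone, and the
#' fibers-of-passage coordinates per level so the exclusion mask travels with
#' the image.
#'
#' @param case an `sc_injection_case`.
#' @param atlas the `sc_atlas` used to generate it.
#' @param dir output directory (created if missing).
#' @return Invisible character vector of written file paths.
#' @export
write_case <- function(case, atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (key in names(case$levels)) {
    img <- render_intensity_image(case, atlas[[key]])
    p <- file.path(dir, sprintf("%s_ARA%s.png", case$roi_name, key))
    png::writePNG(img / 255, p)
    paths <- c(paths, p)
  }
  sidecar <- list(
    roi_name = case$roi_name, zone = case$zone, seed = case$seed,
    passage = lapply(case$levels, function(l) as.list(l$passage))
  )
  jp <- file.path(dir, paste0(case$roi_name, ".json"))
  jsonlite::write_json(sidecar, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
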