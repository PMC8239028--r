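# Polar-coordinate angular density analysis: per-case smoothed probability
# densities over the theta axis (midline = 90 deg, lateral edge = 0 deg),
# group averaging, peak detection, and boundary-alignment scoring against the
# atlas zone intervals.

#' Gaussian kernel density of angular samples on [0, 90]
#'
#' Reflects mass at both boundaries (0 and 90 deg) and renormalizes by the
#' trapezoidal integral so the area under the curve equals 1. Bandwidth
#' defaults to Scott's rule, `sd(theta) * n^(-1/5)`, floored at half the grid
#' step.
#'
#' @param theta numeric vector of angles in degrees (at least 2).
#' @param bandwidth kernel sd in degrees, or `NULL` for Scott's rule.
#' @param grid_step grid spacing in degrees.
#' @param case_id,level optional labels carried in the result.
#' @return An object of class `angular_distribution` with fields `grid`,
#'   `density`, `bandwidth`, `case_id`, `level`.
#' @export
angular_density <- function(theta, bandwidth = NULL, grid_step = 0.5,
                            case_id = NA_character_, level = NA_integer_) {
  if (length(theta) < 2) stop("need at least 2 angular samples")
  if (any(theta < 0 | theta > 90)) stop("theta must lie in [0, 90]")
  if (is.null(bandwidth)) {
    bandwidth <- stats::sd(theta) * length(theta)^(-1 / 5)
    bandwidth <- max(bandwidth, grid_step / 2)
  }
  grid <- seq(0, 90, by = grid_step)
  n <- length(theta)
  dens <- vapply(grid, function(g) {
    sum(stats::dnorm(g, theta, bandwidth) +
        stats::dnorm(g, -theta, bandwidth) +          # reflection at 0
        stats::dnorm(g, 180 - theta, bandwidth)) / n  # reflection at 90
  }, numeric(1))
  area <- trapz(grid, dens)
  out <- list(grid = grid, density = dens / area, bandwidth = bandwidth,
              case_id = case_id, level = level)
  class(out) <- "angular_distribution"
  out
}

#' Angular density of one case's terminal labeling at one level
#'
#' Excludes passage pixels, converts survivors to theta angles, and smooths.
#'
#' @param case an `sc_injection_case`.
#' @param level the `sc_atlas_level` to analyze.
#' @param ... passed to [angular_density()].
#' @return An `angular_distribution`.
#' @export
case_angular_density <- function(case, level, ...) {
  key <- as.character(level$ara_id)
  lv <- case$levels[[key]]
  if (is.null(lv)) stop("case has no data for level ", key)
  px <- exclude_passage(lv$terminal, lv$passage)
  theta <- compute_theta(px, level)
  angular_density(theta, case_id = case$roi_name, level = level$ara_id, ...)
}

#' Pointwise average of angular distributions
#'
#' @param distributions list of `angular_distribution` objects on identical
#'   grids.
#' @param case_id label for the averaged distribution.
#' @return An `angular_distribution`; unit area is preserved by linearity.
#' @export
average_density <- function(distributions, case_id = "average") {
  stopifnot(length(distributions) >= 1)
  g0 <- distributions[[1]]$grid
  for (d in distributions)
    if (!isTRUE(all.equal(d$grid, g0))) stop("distributions are on different grids")
  dens <- rowMeans(vapply(distributions, `[[`, numeric(length(g0)), "density"))
  out <- list(grid = g0, density = dens,
              bandwidth = mean(vapply(distributions, `[[`, numeric(1), "bandwidth")),
              case_id = case_id, level = distributions[[1]]$level)
  class(out) <- "angular_distribution"
  out
}

# Topographic prominence of local maxima on a sampled curve: height of the
# peak minus the higher of the two saddle minima separating it from higher
# terrain (curve edges count as terrain boundaries).
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    right <- if (p < length(y)) y[(p + 1):length(y)] else numeric(0)
    higher_l <- which(left >= h)
    base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):(p - 1)]) else
      min(c(left, h))
    higher_r <- which(right >= h)
    base_r <- if (length(higher_r)) {
      k <- min(higher_r) - 1
      if (k < 1) h else min(right[seq_len(k)])   # plateau neighbor: zero prominence
    } else min(c(right, h))
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Detect peaks in an angular distribution
#'
#' Local maxima are kept if their topographic prominence exceeds
#' `min_prominence_frac` of the global maximum and they are separated by at
#' least `min_separation` degrees (highest peak wins; closer, lower peaks are
#' suppressed).
#'
#' @param dist an `angular_distribution`.
#' @param min_prominence_frac prominence threshold as a fraction of the global
#'   maximum density.
#' @param min_separation minimum angular separation in degrees.
#' @return data.frame of class `peak_set` with columns `theta`, `height`,
#'   `prominence`, sorted by descending theta (medial to lateral).
#' @export
detect_peaks <- function(dist, min_prominence_frac = 0.10,
                         min_separation = 5) {
  y <- dist$density; g <- dist$grid; n <- length(y)
  empty <- data.frame(theta = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  class(empty) <- c("peak_set", "data.frame")
  if (n < 3 || diff(range(y)) == 0) return(empty)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max)
  if (length(idx) == 0) return(empty)
  prom <- .peak_prominence(y, idx)
  keep <- prom >= min_prominence_frac * max(y)
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) == 0) return(empty)
  ord <- order(y[idx], decreasing = TRUE)
  chosen <- integer(0); chosen_prom <- numeric(0)
  for (k in ord) {
    if (all(abs(g[idx[k]] - g[chosen]) >= min_separation) || length(chosen) == 0) {
      chosen <- c(chosen, idx[k]); chosen_prom <- c(chosen_prom, prom[k])
    }
  }
  o <- order(g[chosen], decreasing = TRUE)
  out <- data.frame(theta = g[chosen][o], height = y[chosen][o],
                    prominence = chosen_prom[o])
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Score group peak locations against the atlas zone intervals
#'
#' For each zone-named group, reports whether its dominant (highest) peak
#' falls inside that zone's angular interval at the given level, and the
#' distance to the nearest zone boundary.
#'
#' @param peak_sets named list (names are zone ids) of `peak_set` objects.
#' @param level an `sc_atlas_level`.
#' @return data.frame with columns `group`, `peak_theta`, `inside`,
#'   `boundary_distance`, `status` (`"aligned"`, `"misaligned"`, `"no peak"`).
#' @export
boundary_report <- function(peak_sets, level) {
  stopifnot(all(names(peak_sets) %in% SC_ZONES))
  rows <- lapply(names(peak_sets), function(z) {
    ps <- peak_sets[[z]]
    rng <- level$zone_ranges[[z]]
    if (nrow(ps) == 0) {
      return(data.frame(group = z, peak_theta = NA_real_, inside = NA,
                        boundary_distance = NA_real_, status = "no peak"))
    }
    top <- ps$theta[which.max(ps$height)]
    inside <- top > rng[2] && top <= rng[1]
    data.frame(group = z, peak_theta = top, inside = inside,
               boundary_distance = min(abs(top - rng)),
               status = if (inside) "aligned" else "misaligned")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Averaged per-zone angular distributions for a cohort at one level
#'
#' Groups cases by their dominant zone, computes each case's angular density,
#' and averages within groups — the validation analysis behind the four-peak
#' zonation check.
#'
#' @param cases cohort list (with a `group_assignment` attribute).
#' @param level the `sc_atlas_level` to analyze.
#' @param ... passed to [angular_density()].
#' @return Named list (by zone) of averaged `angular_distribution`s.
#' @export
zone_average_densities <- function(cases, level, ...) {
  assignment <- attr(cases, "group_assignment")
  if (is.null(assignment)) stop("cases carry no group_assignment attribute")
  zones <- intersect(SC_ZONES, unique(assignment))
  out <- lapply(zones, function(z) {
    members <- names(assignment)[assignment == z]
    dists <- lapply(cases[members], case_angular_density, level = level, ...)
    average_density(dists, case_id = z)
  })
  stats::setNames(out, zones)
}

#' Write angular distributions to CSV (long format)
#'
#' @param distributions list of `angular_distribution`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_densities_csv <- function(distributions, path) {
  rows <- do.call(rbind, lapply(distributions, function(d)
    data.frame(case_id = d$case_id, level = d$level, theta = d$grid,
               density = d$density)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Overlay plot of angular distributions
#'
#' @param distributions named list of `angular_distribution`s (typically per
#'   zone).
#' @param path output PNG path.
#' @param level_label label for the plot title.
#' @return `path`, invisibly.
#' @export
plot_densities <- function(distributions, path, level_label = "") {
  cols <- c("red3", "darkorange", "forestgreen", "purple3",
            grDevices::rainbow(max(0, length(distributions) - 4)))
  grDevices::png(path, width = 800, height = 500)
  ymax <- max(vapply(distributions, function(d) max(d$density), numeric(1)))
  g <- distributions[[1]]$grid
  plot(NA, xlim = rev(range(g)), ylim = c(0, ymax * 1.05),
       xlab = expression(theta ~ (degrees)), ylab = "probability density",
       main = paste("Angular distributions", level_label))
  for (i in seq_along(distributions))
    graphics::lines(distributions[[i]]$grid, distributions[[i]]$density,
                    col = cols[i], lwd = 2)
  graphics::legend("topright", legend = names(distributions), col =
                   cols[seq_along(distributions)], lwd = 2, bty = "n")
  grDevices::dev.off()
  invisible(path)
}
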