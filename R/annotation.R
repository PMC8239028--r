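# Thresholding, fibers-of-passage exclusion, and zone/layer pixel
# quantification: turns intensity rasters into per-compartment counts and
# proportion-of-labeling tables.

#' Threshold a grayscale intensity image
#'
#' @param image numeric matrix of intensities.
#' @param method `"fixed"` (absolute cutoff) or `"percentile"` (cutoff at the
#'   given percentile of the image's intensity distribution).
#' @param value threshold intensity, or percentile in `(0, 100)`.
#' @return data.frame of 0-based pixel coordinates `x` (column), `y` (row)
#'   with intensity strictly above the threshold.
#' @export
threshold_image <- function(image, method = c("fixed", "percentile"),
                            value = 100) {
  stopifnot(is.matrix(image), length(image) > 0)
  method <- match.arg(method)
  cut <- switch(method,
    fixed = value,
    percentile = {
      if (value <= 0 || value >= 100) stop("percentile must lie in (0, 100)")
      stats::quantile(image, value / 100, names = FALSE, type = 7)
    })
  hits <- which(image > cut, arr.ind = TRUE)
  data.frame(x = as.integer(hits[, "col"] - 1L),
             y = as.integer(hits[, "row"] - 1L))
}

#' Remove fibers-of-passage pixels from a labeled set
#'
#' Set difference against the passage mask: labeled axons traversing the SC
#' without terminating are excluded from terminal quantification.
#'
#' @param pixels data.frame of labeled pixel coordinates (`x`, `y`).
#' @param passage_mask data.frame of passage pixel coordinates.
#' @return The surviving pixels, disjoint from the mask.
#' @export
exclude_passage <- function(pixels, passage_mask) {
  if (is.null(passage_mask) || nrow(passage_mask) == 0L) return(pixels)
  keep <- !(pixel_keys(pixels) %in% pixel_keys(passage_mask))
  out <- pixels[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify a case's labeling per zone-by-layer compartment
#'
#' For each level, passage pixels are excluded, survivors are assigned to
#' exactly one compartment (or dropped as outside the SC), and counts are
#' tallied. Accounting is exact: `input = assigned + passage_excluded +
#' outside_sc` per level.
#'
#' @param case an `sc_injection_case` (or compatible list with `roi_name` and
#'   per-level `terminal`/`passage` pixel data).
#' @param atlas an `sc_atlas` covering the case's levels.
#' @return data.frame of class `compartment_counts` with one row per
#'   ROI-level-compartment (`roi_name`, `level`, `zone`, `layer`, `count`)
#'   plus per-level accounting in `attr(, "accounting")`.
#' @export
quantify <- function(case, atlas) {
  stopifnot(inherits(atlas, "sc_atlas"))
  missing_lv <- setdiff(names(case$levels), names(atlas))
  if (length(missing_lv) > 0)
    stop("atlas lacks level(s): ", paste(missing_lv, collapse = ", "))
  rows <- list(); acct <- list()
  for (key in names(case$levels)) {
    lv <- case$levels[[key]]
    surv <- exclude_passage(lv$terminal, lv$passage)
    n_in <- nrow(lv$terminal)
    n_excl <- n_in - nrow(surv)
    if (nrow(surv) > 0) {
      comp <- compartments_of(atlas[[key]], surv)
      ok <- !is.na(comp$zone)
      n_out <- sum(!ok)
      if (any(ok)) {
        tab <- stats::aggregate(
          list(count = rep(1L, sum(ok))),
          by = list(zone = comp$zone[ok], layer = comp$layer[ok]), FUN = sum)
        tab <- data.frame(roi_name = case$roi_name,
                          level = as.integer(key), tab,
                          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- tab
      }
    } else {
      n_out <- 0L
    }
    acct[[key]] <- c(input = n_in, assigned = n_in - n_excl - n_out,
                     passage_excluded = n_excl, outside_sc = n_out)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(roi_name = character(0), level = integer(0),
               zone = character(0), layer = character(0), count = integer(0))
  rownames(out) <- NULL
  attr(out, "accounting") <- acct
  class(out) <- c("compartment_counts", class(out))
  out
}

#' Quantify every case in a cohort
#'
#' @param cases cohort list from [generate_cohort()].
#' @param atlas an `sc_atlas`.
#' @return A single `compartment_counts` data.frame stacked over cases.
#' @export
quantify_cohort <- function(cases, atlas) {
  parts <- lapply(cases, quantify, atlas = atlas)
  out <- do.call(rbind, lapply(parts, function(p) { attr(p, "accounting") <- NULL; p }))
  rownames(out) <- NULL
  class(out) <- c("compartment_counts", "data.frame")
  out
}

#' Proportion-of-labeling table
#'
#' Normalizes each ROI's compartment counts by that ROI's total so rows sum
#' to 1, at zone or zone-by-layer granularity. ROIs with no labeling are
#' excluded and flagged in `attr(, "excluded")`.
#'
#' @param counts a `compartment_counts` data.frame.
#' @param collapse `"zone"` (sum over layers) or `"zone_layer"`.
#' @param pool_levels if `TRUE`, counts are pooled across atlas levels before
#'   normalization; otherwise proportions are per ROI and level.
#' @return data.frame with `roi_name` (and `level` unless pooled), one column
#'   per zone or zone-by-layer compartment, rows summing to 1.
#' @export
proportions_table <- function(counts, collapse = c("zone", "zone_layer"),
                              pool_levels = TRUE) {
  collapse <- match.arg(collapse)
  stopifnot(nrow(counts) > 0)
  counts <- as.data.frame(counts)
  key_cols <- if (pool_levels) "roi_name" else c("roi_name", "level")
  col_id <- if (collapse == "zone") counts$zone else
    paste(counts$zone, counts$layer, sep = ".")
  agg <- stats::aggregate(
    list(count = counts$count),
    by = c(lapply(key_cols, function(k) counts[[k]]), list(col = col_id)),
    FUN = sum)
  names(agg)[seq_along(key_cols)] <- key_cols
  all_cols <- if (collapse == "zone") SC_ZONES else {
    grid <- expand.grid(layer = SC_LAYERS, zone = SC_ZONES,
                        stringsAsFactors = FALSE)
    grid <- grid[compartment_exists(grid$zone, grid$layer), ]
    paste(grid$zone, grid$layer, sep = ".")
  }
  ids <- unique(agg[key_cols])
  rownames(ids) <- NULL
  mat <- matrix(0, nrow(ids), length(all_cols),
                dimnames = list(NULL, all_cols))
  idkey <- do.call(paste, c(ids, sep = "\r"))
  akey <- do.call(paste, c(agg[key_cols], sep = "\r"))
  mat[cbind(match(akey, idkey), match(agg$col, all_cols))] <- agg$count
  totals <- rowSums(mat)
  excluded <- ids[totals == 0, , drop = FALSE]
  keep <- totals > 0
  props <- mat[keep, , drop = FALSE] / totals[keep]
  out <- cbind(ids[keep, , drop = FALSE], as.data.frame(props))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Per-level pixel accounting of a quantified case
#'
#' @param counts output of [quantify()].
#' @return data.frame with columns `level`, `input`, `assigned`,
#'   `passage_excluded`, `outside_sc`.
#' @export
pixel_accounting <- function(counts) {
  acct <- attr(counts, "accounting")
  if (is.null(acct)) stop("counts carry no accounting attribute")
  out <- do.call(rbind, lapply(names(acct), function(k)
    data.frame(level = as.integer(k), t(acct[[k]]))))
  rownames(out) <- NULL
  out
}

#' Write a proportion table as a stacked-bar chart
#'
#' One horizontal stacked bar per ROI showing the proportion of labeling per
#' zone, using the conventional zone colors (SC.m red, SC.cm orange, SC.cl
#' green, SC.l purple).
#'
#' @param props zone-granularity output of [proportions_table()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_proportions <- function(props, path) {
  mat <- t(as.matrix(props[, SC_ZONES]))
  colnames(mat) <- props$roi_name
  grDevices::png(path, width = 900, height = 200 + 16 * ncol(mat))
  op <- graphics::par(mar = c(4, 8, 2, 1))
  graphics::barplot(mat, horiz = TRUE, las = 1,
                    col = c("red3", "darkorange", "forestgreen", "purple3"),
                    xlab = "proportion of labeling",
                    cex.names = 0.6, border = NA)
  graphics::legend("topright", legend = SC_ZONES, horiz = TRUE, bty = "n",
                   fill = c("red3", "darkorange", "forestgreen", "purple3"))
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
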