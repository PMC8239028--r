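# Custom superior-colliculus atlas: four medial-to-lateral zones crossed with
# seven superficial-to-deep layers at four coronal reference levels (ARA 86,
# 90, 96, 100). Zones are angular sectors measured from the midline (90 deg)
# toward the lateral edge (0 deg); layers are radial depth bands.

#' Zone identifiers, ordered medial to lateral
#' @export
SC_ZONES <- c("SC.m", "SC.cm", "SC.cl", "SC.l")

#' Layer identifiers, ordered superficial to deep
#'
#' zo zonal, sg superficial gray, op optic, ig intermediate gray,
#' iw intermediate white, dg deep gray, dw deep white.
#' @export
SC_LAYERS <- c("zo", "sg", "op", "ig", "iw", "dg", "dw")

# Angular ranges (theta upper, theta lower) in degrees per zone and level.
.zone_table <- list(
  `86`  = list("SC.m" = c(90, 75), "SC.cm" = c(75, 60), "SC.cl" = c(60, 45), "SC.l" = c(45, 30)),
  `90`  = list("SC.m" = c(90, 75), "SC.cm" = c(75, 55), "SC.cl" = c(55, 35), "SC.l" = c(35, 10)),
  `96`  = list("SC.m" = c(90, 75), "SC.cm" = c(75, 60), "SC.cl" = c(60, 45), "SC.l" = c(45, 5)),
  `100` = list("SC.m" = c(90, 75), "SC.cm" = c(75, 60), "SC.cl" = c(60, 45), "SC.l" = c(45, 0))
)

# Default radial depth bands (fraction of SC depth from the dorsal surface,
# 0 = surface, 1 = deepest). The source anatomy gives no numeric layer
# geometry; these are config-overridable constants approximating the relative
# laminar thicknesses.
.default_layer_bands <- list(
  zo = c(0.00, 0.05), sg = c(0.05, 0.25), op = c(0.25, 0.40),
  ig = c(0.40, 0.65), iw = c(0.65, 0.75), dg = c(0.75, 0.92),
  dw = c(0.92, 1.00)
)

# The three superficial visual layers do not extend into the far lateral SC:
# (SC.l x {zo, sg, op}) compartments are empty; lookups there fall through to
# the intermediate gray.
.empty_superficial_layers <- c("zo", "sg", "op")

# Per-level SC radius in pixels (caudal levels are smaller structures).
.default_sc_radius <- c(`86` = 220, `90` = 250, `96` = 230, `100` = 180)

#' Build the default four-level SC atlas
#'
#' Encodes the angular zone boundaries at coronal reference levels 86, 90, 96
#' and 100, the radial layer bands, and the raster geometry used by the
#' synthetic generator and quantification stages. The right-hemisphere SC is
#' modeled as a quarter disc in a `raster_shape` raster at `pixel_size`
#' micrometers per pixel, with the polar origin at the midline point at the
#' ventral base of the structure.
#'
#' @param layer_bands named list of `c(inner, outer)` depth fractions per
#'   layer; must tile `[0, 1]` without gaps or overlap.
#' @param raster_shape integer `c(rows, cols)` of the per-level raster.
#' @param pixel_size micrometers per pixel.
#' @return An object of class `sc_atlas`: a named list of four
#'   `sc_atlas_level` objects keyed by ARA id.
#' @examples
#' atlas <- build_default_atlas()
#' atlas$`90`$zone_ranges$SC.cm  # c(75, 55)
#' @export
build_default_atlas <- function(layer_bands = .default_layer_bands,
                                raster_shape = c(300L, 300L),
                                pixel_size = 10) {
  validate_layer_bands(layer_bands)
  levels <- lapply(names(.zone_table), function(id) {
    lvl <- list(
      ara_id = as.integer(id),
      zone_ranges = .zone_table[[id]],
      layer_bands = layer_bands,
      origin = c(x = 15, y = 285),
      raster_shape = as.integer(raster_shape),
      pixel_size = pixel_size,
      sc_radius = unname(.default_sc_radius[id])
    )
    class(lvl) <- "sc_atlas_level"
    lvl
  })
  names(levels) <- names(.zone_table)
  class(levels) <- "sc_atlas"
  levels
}

validate_layer_bands <- function(bands) {
  stopifnot(identical(sort(names(bands)), sort(SC_LAYERS)))
  edges <- t(vapply(bands[SC_LAYERS], identity, numeric(2)))
  if (abs(edges[1, 1]) > 1e-12 || abs(edges[nrow(edges), 2] - 1) > 1e-12)
    stop("layer bands must start at 0 and end at 1")
  if (any(abs(edges[-1, 1] - edges[-nrow(edges), 2]) > 1e-12))
    stop("layer bands must tile [0, 1] without gaps or overlap")
  widths <- edges[, 2] - edges[, 1]
  if (any(widths <= 0)) stop("layer bands must have positive width")
  invisible(TRUE)
}

#' @export
`[.sc_atlas` <- function(x, i) {
  structure(unclass(x)[i], class = "sc_atlas")
}

#' @export
print.sc_atlas <- function(x, ...) {
  cat("SC custom atlas:", length(x), "coronal levels (ARA",
      paste(names(x), collapse = ", "), ")\n")
  cat("zones:", paste(SC_ZONES, collapse = " "), "| layers:",
      paste(SC_LAYERS, collapse = " "), "\n")
  invisible(x)
}

#' Assign an angular position to an SC zone
#'
#' Zone intervals are half-open `(theta_lower, theta_upper]`, so a shared
#' boundary angle (e.g. 75 deg) belongs to the more lateral zone. An angle at
#' or below the lateral-most lower bound has no zone (`NA`), except that when
#' the atlas extends all the way to 0 deg the value 0 is included in the
#' lateral zone.
#'
#' @param level an `sc_atlas_level`.
#' @param theta angle in degrees, in `[0, 90]`; vectorized.
#' @return Character vector of zone ids (`NA` where no zone applies).
#' @export
assign_zone <- function(level, theta) {
  stopifnot(inherits(level, "sc_atlas_level"))
  if (any(theta < 0 | theta > 90, na.rm = TRUE))
    stop("theta must lie in [0, 90] degrees")
  out <- rep(NA_character_, length(theta))
  for (z in SC_ZONES) {
    rng <- level$zone_ranges[[z]]
    hit <- !is.na(theta) & theta > rng[2] & theta <= rng[1]
    out[hit] <- z
  }
  lat_low <- level$zone_ranges[["SC.l"]][2]
  if (lat_low == 0) out[!is.na(theta) & theta == 0] <- "SC.l"
  out
}

#' Assign a radial depth fraction to an SC layer
#'
#' Depth fraction 0 is the dorsal (superficial) surface, 1 the deepest extent.
#' Bands are half-open `[inner, outer)` with the innermost bound inclusive,
#' so 0 maps to `zo` and 1 to `dw`.
#'
#' @param level an `sc_atlas_level`.
#' @param radial_fraction numeric in `[0, 1]`; vectorized.
#' @return Character vector of layer ids.
#' @export
assign_layer <- function(level, radial_fraction) {
  stopifnot(inherits(level, "sc_atlas_level"))
  if (any(radial_fraction < 0 | radial_fraction > 1, na.rm = TRUE))
    stop("radial_fraction must lie in [0, 1]")
  edges <- vapply(level$layer_bands[SC_LAYERS], `[[`, numeric(1), 1)
  idx <- findInterval(radial_fraction, c(edges, 1), rightmost.closed = TRUE)
  SC_LAYERS[idx]
}

#' Polar angle of pixels relative to a level's origin
#'
#' The angle is `atan2(dorsal offset, lateral offset)` in degrees: a pixel
#' directly dorsal of the origin on the midline reads 90 deg, a pixel at the
#' origin's height with positive lateral offset reads 0 deg. Values are
#' clamped to `[0, 90]`.
#'
#' @param pixels data.frame with columns `x` (column, increasing laterally)
#'   and `y` (row, increasing ventrally), 0-based.
#' @param level an `sc_atlas_level`.
#' @return Numeric vector of angles in degrees.
#' @export
compute_theta <- function(pixels, level) {
  stopifnot(inherits(level, "sc_atlas_level"))
  dx <- pixels$x - level$origin[["x"]]
  dy <- level$origin[["y"]] - pixels$y
  if (any(dx == 0 & dy == 0))
    stop("theta is undefined at the polar origin")
  pmin(90, pmax(0, atan2(dy, dx) * 180 / pi))
}

#' Map pixels to zone-by-layer compartments (vectorized)
#'
#' Composes the angular zone lookup with the radial layer lookup. Pixels
#' outside the quarter-disc SC mask (negative offsets, radius beyond the SC
#' extent, angle outside any zone, or exactly at the origin) map to `NA`.
#' In the far-lateral zone the superficial compartments are empty, so
#' superficial lookups there fall through to the intermediate gray (`ig`).
#'
#' @param level an `sc_atlas_level`.
#' @param pixels data.frame with 0-based integer columns `x`, `y`.
#' @return data.frame with columns `zone`, `layer` (`NA` outside the SC).
#' @export
compartments_of <- function(level, pixels) {
  stopifnot(inherits(level, "sc_atlas_level"))
  nr <- level$raster_shape[1]; nc <- level$raster_shape[2]
  if (any(pixels$x < 0 | pixels$x >= nc | pixels$y < 0 | pixels$y >= nr))
    stop("pixel out of raster bounds")
  dx <- pixels$x - level$origin[["x"]]
  dy <- level$origin[["y"]] - pixels$y
  r <- sqrt(dx^2 + dy^2)
  inside <- dx >= 0 & dy >= 0 & r > 0 & r <= level$sc_radius
  zone <- rep(NA_character_, nrow(pixels))
  layer <- rep(NA_character_, nrow(pixels))
  if (any(inside)) {
    theta <- pmin(90, pmax(0, atan2(dy[inside], dx[inside]) * 180 / pi))
    z <- assign_zone(level, theta)
    frac <- 1 - r[inside] / level$sc_radius
    l <- assign_layer(level, frac)
    # empty superficial compartments in the far lateral zone
    trunc <- !is.na(z) & z == "SC.l" & l %in% .empty_superficial_layers
    l[trunc] <- "ig"
    l[is.na(z)] <- NA_character_
    zone[inside] <- z
    layer[inside] <- l
  }
  data.frame(zone = zone, layer = layer, stringsAsFactors = FALSE)
}

#' Map a single pixel to its compartment
#'
#' @param level an `sc_atlas_level`.
#' @param pixel numeric `c(x, y)`, 0-based.
#' @return A list with `zone` and `layer`, or `NULL` if the pixel falls
#'   outside the SC mask.
#' @export
compartment_of <- function(level, pixel) {
  res <- compartments_of(level, data.frame(x = pixel[1], y = pixel[2]))
  if (is.na(res$zone[1])) return(NULL)
  list(zone = res$zone[1], layer = res$layer[1])
}

#' Is a zone-by-layer compartment anatomically present?
#'
#' @param zone,layer compartment ids.
#' @return Logical; `FALSE` for the empty far-lateral superficial compartments.
#' @export
compartment_exists <- function(zone, layer) {
  !(zone == "SC.l" & layer %in% .empty_superficial_layers)
}

#' Logical SC mask for a level
#'
#' @param level an `sc_atlas_level`.
#' @return Logical matrix (`raster_shape`) that is `TRUE` inside the SC.
#' @export
sc_mask <- function(level) {
  nr <- level$raster_shape[1]; nc <- level$raster_shape[2]
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  dx <- xs - level$origin[["x"]]
  dy <- level$origin[["y"]] - ys
  r <- sqrt(dx^2 + dy^2)
  disc <- dx >= 0 & dy >= 0 & r > 0 & r <= level$sc_radius
  # the structure only spans the zone-covered angular sector at this level
  theta <- atan2(dy, dx) * 180 / pi
  lat_low <- level$zone_ranges[["SC.l"]][2]
  disc & (theta > lat_low | (lat_low == 0 & theta >= 0))
}

#' Serialize an atlas to JSON
#' @param atlas an `sc_atlas`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
atlas_to_json <- function(atlas, path) {
  payload <- lapply(atlas, function(lvl) {
    list(ara_id = lvl$ara_id, zone_ranges = lvl$zone_ranges,
         layer_bands = lvl$layer_bands, origin = as.list(lvl$origin),
         raster_shape = lvl$raster_shape, pixel_size = lvl$pixel_size,
         sc_radius = lvl$sc_radius)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an atlas back from JSON
#' @param path JSON file written by [atlas_to_json()].
#' @return An `sc_atlas`.
#' @export
atlas_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  levels <- lapply(payload, function(p) {
    lvl <- list(
      ara_id = as.integer(p$ara_id),
      zone_ranges = lapply(p$zone_ranges, as.numeric),
      layer_bands = lapply(p$layer_bands, as.numeric),
      origin = c(x = p$origin$x, y = p$origin$y),
      raster_shape = as.integer(p$raster_shape),
      pixel_size = p$pixel_size,
      sc_radius = p$sc_radius
    )
    class(lvl) <- "sc_atlas_level"
    lvl
  })
  names(levels) <- names(payload)
  class(levels) <- "sc_atlas"
  levels
}
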