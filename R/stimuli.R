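#' Random-dot symmetry stimuli
#'
#' Binary dot patterns at dot resolution (one cell per dot; the display
#' rasterises each dot as a 4' x 4' block, so `pixel_arcmin = 4` by default).
#' Coordinates follow the rotation convention used by the reverse-mapping
#' count: origin at the grid centre, x rightward, y upward, and the symmetry
#' axis at `theta` degrees from vertical so that theta = 0 is the vertical
#' axis and theta = 90 the horizontal one.
#'
#' @name stimuli
NULL

AXIS_ORIENTATIONS <- c(0, 45, 90, 135)

#' Construct a dot pattern
#'
#' @param grid integer or logical matrix; nonzero entries are dots.
#' @param pixel_arcmin arcmin subtended by one cell (one dot), default 4.
#' @return A `dot_pattern`: binary matrix with size/scale metadata and a
#'   `density` field equal to on-count / cell-count.
#' @export
dot_pattern <- function(grid, pixel_arcmin = 4) {
  grid <- matrix(as.integer(grid != 0), nrow = nrow(grid))
  structure(
    list(grid = grid,
         width_px = ncol(grid), height_px = nrow(grid),
         pixel_arcmin = pixel_arcmin,
         density = sum(grid) / length(grid)),
    class = "dot_pattern")
}

#' @export
print.dot_pattern <- function(x, ...) {
  cat(sprintf("<dot_pattern %dx%d cells (%.1f' each), %d dots, density %.4g>\n",
              x$width_px, x$height_px, x$pixel_arcmin,
              sum(x$grid), x$density))
  invisible(x)
}

n_dots <- function(pattern) sum(pattern$grid)

check_axis <- function(axis) {
  if (!is.numeric(axis) || length(axis) != 1 || !(axis %in% AXIS_ORIENTATIONS))
    stop("axis must be one of 0, 45, 90, 135 (degrees from vertical)")
  axis
}

## Reflect centred coordinates (u, v) about the axis at `theta` degrees from
## vertical: rotate by theta so the axis is vertical, negate the rotated x,
## rotate back. For the four canonical axes this is exact on the half-integer
## centred lattice; `round()` guards the general case.
reflect_coords <- function(u, v, theta) {
  a <- theta * pi / 180
  x1 <- u * cos(a) + v * sin(a)
  y1 <- v * cos(a) - u * sin(a)
  x1 <- -x1
  list(u = x1 * cos(a) - y1 * sin(a),
       v = y1 * cos(a) + x1 * sin(a))
}

## Cell index (row, col; 1-based) -> centred coordinates and back.
cell_coords <- function(i, j, nr, nc) {
  list(u = j - 1 - (nc - 1) / 2, v = (nr - 1) / 2 - (i - 1))
}
coords_cell <- function(u, v, nr, nc) {
  j <- round(u + (nc - 1) / 2) + 1
  i <- round((nr - 1) / 2 - v) + 1
  ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
  list(i = i, j = j, ok = ok)
}

## Linear index of each cell's mirror cell (NA if reflected outside the grid,
## which cannot happen for the four canonical axes on a centred grid).
mirror_index <- function(nr, nc, theta) {
  idx <- seq_len(nr * nc)
  i <- ((idx - 1) %% nr) + 1
  j <- ((idx - 1) %/% nr) + 1
  cc <- cell_coords(i, j, nr, nc)
  rf <- reflect_coords(cc$u, cc$v, theta)
  m <- coords_cell(rf$u, rf$v, nr, nc)
  out <- ifelse(m$ok, (m$j - 1) * nr + m$i, NA_integer_)
  out
}

#' Generate a mirror-symmetric random-dot pattern
#'
#' Seeds one half-plane at random and reflects it about the requested axis,
#' so every dot has a mirror correspondent. Dots are placed in whole
#' reflection orbits (a mirror pair, or a single cell on the axis line), so
#' the realised count is `round(density * cells)` or one more.
#'
#' @param width_px,height_px grid size in cells.
#' @param density requested fraction of on-cells in \[0, 1\].
#' @param axis axis orientation in degrees from vertical: 0, 45, 90 or 135.
#' @param seed integer RNG seed; identical seeds give identical grids.
#' @return A [dot_pattern] invariant under reflection about `axis`.
#' @export
generate_symmetric_pattern <- function(width_px, height_px, density, axis = 0,
                                       seed = NULL) {
  check_axis(axis)
  check_density(density)
  if (width_px < 1 || height_px < 1) stop("grid dimensions must be positive")
  if (!is.null(seed)) set.seed(seed)
  nr <- height_px; nc <- width_px
  k <- round(density * nr * nc)
  grid <- matrix(0L, nr, nc)
  if (k > 0) {
    mir <- mirror_index(nr, nc, axis)
    idx <- seq_len(nr * nc)
    ## orbit representative: smaller of (cell, mirror); drop out-of-grid mirrors
    keep <- !is.na(mir)
    rep_id <- pmin(idx, mir)[keep]
    orbits <- split(idx[keep], rep_id)
    orbits <- orbits[sample.int(length(orbits))]
    placed <- 0L
    for (orb in orbits) {
      cells <- unique(c(orb, mir[orb]))
      grid[cells] <- 1L
      placed <- placed + length(cells)
      if (placed >= k) break
    }
  }
  dot_pattern(grid)
}

check_density <- function(density) {
  if (!is.numeric(density) || length(density) != 1 || is.na(density) ||
      density < 0 || density > 1)
    stop("density must be a single value in [0, 1]")
  density
}

#' Generate a density-matched random control pattern
#'
#' Places exactly `round(density * cells)` dots (or `n_dots` if given,
#' e.g. to count-match a symmetric target) uniformly at random without
#' replacement.
#'
#' @inheritParams generate_symmetric_pattern
#' @param n_dots optional exact dot count overriding `density`.
#' @return A [dot_pattern].
#' @export
generate_control_pattern <- function(width_px, height_px, density,
                                     seed = NULL, n_dots = NULL) {
  check_density(density)
  if (width_px < 1 || height_px < 1) stop("grid dimensions must be positive")
  if (!is.null(seed)) set.seed(seed)
  ncell <- width_px * height_px
  k <- if (is.null(n_dots)) round(density * ncell) else as.integer(n_dots)
  if (k > ncell) stop("requested more dots than cells")
  grid <- matrix(0L, height_px, width_px)
  if (k > 0) grid[sample.int(ncell, k)] <- 1L
  dot_pattern(grid)
}

#' Superimpose a random-dot noise masker on a pattern
#'
#' The output grid is the union of the input and an independent uniform
#' random pattern of the requested density; overlapping dots are absorbed.
#'
#' @param pattern a [dot_pattern].
#' @param noise_density density of the independent masker in \[0, 1\].
#' @param seed integer RNG seed for the masker.
#' @return A [dot_pattern] with on-count at most the sum of the two.
#' @export
superimpose_noise <- function(pattern, noise_density, seed = NULL) {
  stopifnot(inherits(pattern, "dot_pattern"))
  check_density(noise_density)
  if (noise_density == 0) return(pattern)
  noise <- generate_control_pattern(pattern$width_px, pattern$height_px,
                                    noise_density, seed = seed)
  dot_pattern(pattern$grid | noise$grid, pattern$pixel_arcmin)
}

#' Build the 8-aperture viewing mask
#'
#' Eight apertures of 1.2 deg diameter evenly spaced around a 6 deg diameter
#' circle. High axial salience puts centres at 0, 45, ..., 315 deg from
#' horizontal so each candidate axis passes through a diametrically opposite
#' pair; low salience shifts all centres clockwise by 22.5 deg so no axis
#' line touches any aperture.
#'
#' @param salience `"high"` or `"low"`.
#' @return An `aperture_mask` with the geometry fields and centre angles.
#' @export
make_aperture_mask <- function(salience = c("high", "low")) {
  salience <- match.arg(salience)
  base <- seq(0, 315, by = 45)
  angles <- if (salience == "high") base else sort((base - 22.5) %% 360)
  structure(
    list(circle_diameter_deg = 6, aperture_diameter_deg = 1.2,
         n_apertures = 8, center_angles_deg = angles, salience = salience),
    class = "aperture_mask")
}

#' @export
print.aperture_mask <- function(x, ...) {
  cat(sprintf("<aperture_mask %s salience: %d x %.1f deg apertures on %.0f deg circle>\n",
              x$salience, x$n_apertures, x$aperture_diameter_deg,
              x$circle_diameter_deg))
  invisible(x)
}

#' Apply an aperture mask to a dot pattern
#'
#' Removes every dot whose cell centre lies outside all aperture discs;
#' dots inside an aperture are untouched.
#'
#' @param pattern a [dot_pattern] whose angular extent covers the mask
#'   (circle plus one aperture diameter).
#' @param mask an [make_aperture_mask()] result.
#' @return The masked [dot_pattern].
#' @export
apply_mask <- function(pattern, mask) {
  stopifnot(inherits(pattern, "dot_pattern"), inherits(mask, "aperture_mask"))
  extent_min <- (mask$circle_diameter_deg + mask$aperture_diameter_deg) * 60
  half_w <- (pattern$width_px - 1) / 2 * pattern$pixel_arcmin
  half_h <- (pattern$height_px - 1) / 2 * pattern$pixel_arcmin
  if (2 * half_w < extent_min || 2 * half_h < extent_min)
    stop("pattern extent smaller than the aperture mask")
  nr <- pattern$height_px; nc <- pattern$width_px
  idx <- which(pattern$grid == 1L)
  if (!length(idx)) return(pattern)
  i <- ((idx - 1) %% nr) + 1
  j <- ((idx - 1) %/% nr) + 1
  cc <- cell_coords(i, j, nr, nc)
  x <- cc$u * pattern$pixel_arcmin  # arcmin
  y <- cc$v * pattern$pixel_arcmin
  r_circ <- mask$circle_diameter_deg / 2 * 60
  r_ap <- mask$aperture_diameter_deg / 2 * 60
  ang <- mask$center_angles_deg * pi / 180
  cx <- r_circ * cos(ang); cy <- r_circ * sin(ang)
  inside <- rep(FALSE, length(idx))
  for (a in seq_along(ang))
    inside <- inside | ((x - cx[a])^2 + (y - cy[a])^2 <= r_ap^2)
  grid <- matrix(0L, nr, nc)
  grid[idx[inside]] <- 1L
  dot_pattern(grid, pattern$pixel_arcmin)
}

#' Aperture-free arc around a symmetry axis
#'
#' Length, in degrees of visual angle along the aperture circle, of the
#' blank region centred on the axis crossing: the arc between adjacent
#' aperture centres minus one aperture diameter. High salience returns 0
#' (the axis lies inside an aperture); low salience returns
#' 3*pi/4 - 1.2 = 1.156 deg.
#'
#' @param mask an aperture mask.
#' @param axis axis orientation (degrees from vertical).
#' @return Blank arc length in degrees of visual angle.
#' @export
axis_blank_arc <- function(mask, axis = 0) {
  stopifnot(inherits(mask, "aperture_mask"))
  check_axis(axis)
  if (mask$salience == "high") return(0)
  gap_deg <- 360 / mask$n_apertures
  arc <- pi * mask$circle_diameter_deg * (gap_deg / 360)
  arc - mask$aperture_diameter_deg
}

#' Reverse-mapping symmetry count
#'
#' Counts the dots whose mirror coordinate about the given axis (under the
#' rotation convention above) is also occupied. For a perfectly symmetric
#' pattern every dot has a partner, so `ns == n_total`.
#'
#' @param pattern a [dot_pattern].
#' @param axis axis orientation (degrees from vertical).
#' @return A list with `ns`, `n_total` and `axis`, class `symmetry_count`.
#' @export
count_mirror_pairs <- function(pattern, axis = 0) {
  stopifnot(inherits(pattern, "dot_pattern"))
  check_axis(axis)
  nr <- pattern$height_px; nc <- pattern$width_px
  on <- which(pattern$grid == 1L)
  if (!length(on))
    return(structure(list(ns = 0L, n_total = 0L, axis = axis),
                     class = "symmetry_count"))
  mir <- mirror_index(nr, nc, axis)
  partner <- mir[on]
  ns <- sum(!is.na(partner) & pattern$grid[partner] == 1L)
  structure(list(ns = as.integer(ns), n_total = length(on), axis = axis),
            class = "symmetry_count")
}

#' @export
print.symmetry_count <- function(x, ...) {
  cat(sprintf("<symmetry_count: %d of %d dots mirrored about axis %g deg>\n",
              x$ns, x$n_total, x$axis))
  invisible(x)
}

#' Write a dot pattern as plain PGM (P2)
#'
#' White dots (255) on black (0); plain-text format, byte-stable for a
#' given pattern.
#'
#' @param pattern a [dot_pattern].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(pattern, path) {
  stopifnot(inherits(pattern, "dot_pattern"))
  g <- pattern$grid * 255L
  lines <- c("P2",
             paste(pattern$width_px, pattern$height_px),
             "255",
             apply(g, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write a dot pattern as PNG
#'
#' Renders via the `grDevices` png device, one image pixel per cell.
#' @inheritParams write_pgm
#' @export
write_pattern_png <- function(pattern, path) {
  stopifnot(inherits(pattern, "dot_pattern"))
  grDevices::png(path, width = pattern$width_px, height = pattern$height_px)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({graphics::par(op); grDevices::dev.off()}, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(1 - pattern$grid, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}

#' Write the JSON metadata sidecar for a stimulus
#'
#' @param path image path; metadata is written to `<path>.json`.
#' @param ... named metadata fields (seed, density, axis, salience, ...).
#' @export
write_pattern_meta <- function(path, ...) {
  meta <- list(...)
  meta$package_version <- as.character(utils::packageVersion("symtvd"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paste0(path, ".json"))
}
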