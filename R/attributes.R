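#' Attribute stacks and derived per-cell attributes
#'
#' An `attribute_stack` holds the co-registered single-band grids the decision
#' tree consumes: bathymetry (metres below datum, positive down, `NaN`/`NA` =
#' nodata), significant wave height (m), sub-surface brightness (unitless,
#' clipped to 0-1), a land mask, and — once derived — slope angle (degrees),
#' categorical exposure, brightness texture and a deep-water mask. All grids
#' share one shape and one square cell size; row 1 is the northern edge.
#'
#' @name attribute-stack
NULL

#' Construct an attribute stack
#'
#' @param depth Matrix of depths in metres below datum (supratidal cells carry
#'   depth <= 0; `NA` = nodata).
#' @param hsig Matrix of significant wave heights (m).
#' @param brightness Matrix of unitless sub-surface brightness; values are
#'   clipped into `[0, 1]`.
#' @param cell_size Cell side length in metres.
#' @param land_mask Optional logical matrix; land cells are nodata for all
#'   water attributes.
#' @return An `attribute_stack` object.
#' @export
attribute_stack <- function(depth, hsig, brightness, cell_size,
                            land_mask = NULL) {
  stopifnot(is.matrix(depth), is.matrix(hsig), is.matrix(brightness))
  if (!isTRUE(cell_size > 0)) stop("cell_size must be positive")
  dims <- dim(depth)
  if (!identical(dim(hsig), dims) || !identical(dim(brightness), dims)) {
    stop("all grids must share one shape")
  }
  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, dims[1], dims[2])
  }
  stopifnot(is.logical(land_mask), identical(dim(land_mask), dims))
  brightness <- pmin(pmax(brightness, 0), 1)
  structure(list(
    depth = depth, hsig = hsig, brightness = brightness,
    slope = NULL, exposure = NULL, texture = NULL,
    land_mask = land_mask, deepwater_mask = NULL,
    cell_size = cell_size
  ), class = "attribute_stack")
}

#' @export
print.attribute_stack <- function(x, ...) {
  cat(sprintf("attribute_stack %d x %d, cell %g m (%s)\n",
              nrow(x$depth), ncol(x$depth), x$cell_size,
              if (is.null(x$slope)) "raw" else "derived"))
  invisible(x)
}

#' Slope angle from bathymetry
#'
#' Slope is `atan` of the gradient magnitude of the depth surface, in degrees.
#' Interior cells use centred 3x3 finite differences; edge cells fall back to
#' one-sided differences. When a neighbour is nodata the difference is taken
#' from the available side; a cell whose neighbours are all nodata (or that is
#' itself nodata) gets `NA`.
#'
#' @param depth Depth matrix (m below datum).
#' @param cell_size Cell side in metres.
#' @return Matrix of slope angles in degrees, in `[0, 90]` where defined.
#' @export
derive_slope <- function(depth, cell_size) {
  stopifnot(is.matrix(depth))
  if (nrow(depth) < 2L || ncol(depth) < 2L) {
    stop("depth grid extent too small for slope (need at least 2 x 2)")
  }
  if (!isTRUE(cell_size > 0)) stop("cell_size must be positive")
  axis_gradient <- function(prev, nxt) {
    # centred where both neighbours exist, one-sided otherwise, NA if neither
    g <- (nxt - prev) / (2 * cell_size)
    only_next <- is.na(prev) & !is.na(nxt)
    only_prev <- !is.na(prev) & is.na(nxt)
    g[only_next] <- (nxt[only_next] - depth[only_next]) / cell_size
    g[only_prev] <- (depth[only_prev] - prev[only_prev]) / cell_size
    g
  }
  gx <- axis_gradient(shift_mat(depth, 0L, 1L), shift_mat(depth, 0L, -1L))
  gy <- axis_gradient(shift_mat(depth, 1L, 0L), shift_mat(depth, -1L, 0L))
  both_na <- is.na(gx) & is.na(gy)
  gx[is.na(gx)] <- 0
  gy[is.na(gy)] <- 0
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope[both_na | is.na(depth)] <- NA_real_
  slope
}

#' Binary exposure from significant wave height
#'
#' Cells with wave height strictly above the threshold are `exposed`, all
#' others `sheltered` (the boundary value itself is sheltered). Nodata wave
#' heights give `NA`.
#'
#' @param hsig Significant wave height matrix (m).
#' @param threshold Exposure threshold in metres (default 2).
#' @return Character matrix of `"exposed"` / `"sheltered"` / `NA`.
#' @export
classify_exposure <- function(hsig, threshold = 2) {
  stopifnot(is.matrix(hsig))
  if (!isTRUE(threshold > 0)) stop("exposure threshold must be positive")
  out <- matrix(NA_character_, nrow(hsig), ncol(hsig))
  out[!is.na(hsig)] <- ifelse(hsig[!is.na(hsig)] > threshold,
                              "exposed", "sheltered")
  out
}

#' Local brightness texture
#'
#' Per-cell population standard deviation of brightness over the square
#' `(2 * radius + 1)^2` window, truncated at the grid edge and skipping nodata
#' neighbours. Nodata cells stay nodata.
#'
#' @param brightness Brightness matrix.
#' @param radius Window radius in cells (>= 1).
#' @return Texture matrix (same shape).
#' @export
texture_local_stddev <- function(brightness, radius = 1L) {
  stopifnot(is.matrix(brightness))
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  if (radius >= min(dim(brightness))) {
    stop("radius must be smaller than the grid extent")
  }
  n <- s <- s2 <- matrix(0, nrow(brightness), ncol(brightness))
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      v <- shift_mat(brightness, dr, dc)
      ok <- !is.na(v)
      v[!ok] <- 0
      n <- n + ok
      s <- s + v
      s2 <- s2 + v^2
    }
  }
  mu <- s / n
  out <- sqrt(pmax(s2 / n - mu^2, 0))
  out[n == 0 | is.na(brightness)] <- NA_real_
  out
}

#' Categorical depth band
#'
#' Maps depth to the band the decision tree uses: `supratidal` (depth <= 0),
#' `shallow` (0 < depth <= shallow/mid edge), `mid` (up to the mid/deep edge)
#' and `deep`. Band edges come from the threshold configuration (defaults 3 m
#' and 10 m). Comparisons keep the boundary value in the shallower band.
#'
#' @param depth Numeric vector or matrix of depths (m below datum).
#' @param config A [threshold_config()].
#' @return Character vector/matrix of bands (`NA` for nodata).
#' @export
depth_band <- function(depth, config = threshold_config()) {
  out <- rep(NA_character_, length(depth))
  ok <- !is.na(depth)
  d <- depth[ok]
  out[ok] <- ifelse(d <= 0, "supratidal",
             ifelse(d <= config$shallow_mid_edge, "shallow",
             ifelse(d <= config$mid_deep_edge, "mid", "deep")))
  if (is.matrix(depth)) out <- matrix(out, nrow(depth), ncol(depth))
  out
}

#' Derive slope, exposure, texture and the deep-water mask
#'
#' Fills the derived grids of an attribute stack in place of their `NULL`
#' placeholders. Land cells are nodata in every derived grid.
#'
#' @param stack An [attribute_stack()].
#' @param config A [threshold_config()] supplying the exposure and deep-water
#'   thresholds.
#' @param texture_radius Window radius for [texture_local_stddev()].
#' @return The stack with `slope`, `exposure`, `texture` and `deepwater_mask`
#'   populated.
#' @export
derive_attributes <- function(stack, config = threshold_config(),
                              texture_radius = 1L) {
  stopifnot(inherits(stack, "attribute_stack"))
  depth <- stack$depth
  depth[stack$land_mask] <- NA_real_
  stack$slope <- derive_slope(depth, stack$cell_size)
  hsig <- stack$hsig
  hsig[stack$land_mask] <- NA_real_
  stack$exposure <- classify_exposure(hsig, config$exposure_hsig)
  brightness <- stack$brightness
  brightness[stack$land_mask] <- NA_real_
  stack$texture <- texture_local_stddev(brightness, texture_radius)
  stack$deepwater_mask <- !is.na(depth) & depth > config$deepwater_depth &
    !stack$land_mask
  stack
}
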