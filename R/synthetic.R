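#' Synthetic reef archetypes with ground truth
#'
#' Parametric, seeded generators for four idealised reef forms — atoll,
#' fringing reef, platform reef and barrier reef — produce the same attribute
#' stacks the classifier consumes (depth, significant wave height, brightness,
#' land mask) together with a ground-truth zone map. Zonation follows the
#' canonical seaward-to-landward ordering: open deep water, fore-reef incline
#' (slope, then front), reef crest on the exposed margin, outer and inner reef
#' flat, back-reef slope, shallow then deep lagoon. Atolls and platforms are
#' radial (concentric rings); fringing and barrier reefs are shore-normal
#' linear profiles attached to a land strip. Exposure is a smoothly sharpened
#' cosine of bearing relative to the wind direction, scaled between the
#' leeward and windward significant wave heights, so the windward half carries
#' near-windward wave heights and both exposure classes appear on radial
#' archetypes.
#'
#' Ground-truth labels are assigned from the analytic geometry (each cell's
#' profile segment, exact depth and exposure) using the same thresholds the
#' classifier uses, so on noise-free input the classifier should recover the
#' truth everywhere except in the 1-2 cell band where the finite-difference
#' slope stencil straddles a segment boundary.
#'
#' @name synthetic-reef
NULL

# Brightness palette: per-class noise-free sub-surface brightness. The inner
# reef flat is markedly brighter than the outer flat (sand deposition), the
# deep classes darkest.
BRIGHTNESS_PALETTE <- c(
  "Reef Slope" = 0.12, "Sheltered Slope" = 0.12,
  "Reef Front" = 0.30, "Sheltered Front" = 0.30,
  "Wall" = 0.10, "Sheltered Wall" = 0.10,
  "Terrace" = 0.45, "Reef Crest" = 0.62,
  "Outer Reef Flat" = 0.55, "Inner Reef Flat" = 0.80,
  "Back Reef Slope" = 0.30, "Shallow Lagoon" = 0.60,
  "Lagoon" = 0.18, "Plateau" = 0.20,
  "Patch Reef" = 0.70, "Small Reef" = 0.50,
  "Reef Island" = 0.90, "Deep Water" = 0.05, "Land" = 0.95
)

#' Archetype parameters
#'
#' Defaults define the package's reference study conditions: 512 x 512 cells
#' of 10 m, a 0.3 m reef crest, 1 m reef flats 750 m wide, a 15 m deep lagoon
#' with a 5 m shallow-lagoon shelf, a 20 degree fore-reef incline, windward /
#' leeward significant wave heights of 2.5 / 1.0 m with wind from the east,
#' and deep water below 30 m on a 35 m open-water floor.
#'
#' @param archetype One of `"atoll"`, `"fringing"`, `"platform"`, `"barrier"`.
#' @param grid_shape Integer c(rows, cols), each >= 64.
#' @param cell_size Cell side (m).
#' @param rim_radius Radius of the reef rim's outer edge (m, radial
#'   archetypes); default 72% of the half-extent.
#' @param shelf_width Width of the land strip (m, linear archetypes).
#' @param crest_depth Reef-crest depth (m).
#' @param crest_width Width of the crest ring (m).
#' @param flat_depth Reef-flat depth (m).
#' @param flat_width Total reef-flat width (m); 60% inner, 40% outer.
#' @param lagoon_depth Deep-lagoon floor depth (m).
#' @param shallow_lagoon_depth Shallow-lagoon shelf depth (m).
#' @param shallow_lagoon_width Shallow-lagoon shelf width (m).
#' @param fore_reef_slope_angle Fore-reef incline angle (degrees).
#' @param back_reef_slope_angle Lagoonward incline angle (degrees).
#' @param wall_angle Wall angle (degrees; atoll only, used when
#'   `include_wall`).
#' @param include_wall Insert a near-vertical wall segment in the fore reef
#'   (needs a fine cell size to be resolvable).
#' @param windward_hsig,leeward_hsig Significant wave heights (m) on the
#'   windward / leeward side; windward must exceed leeward.
#' @param wind_direction Compass bearing waves come from (degrees, 90 = east).
#' @param n_patch_reefs,n_small_reefs,n_reef_islands Seeded feature counts
#'   (atoll only).
#' @param patch_radius,small_reef_radius,island_radius Flat-top radii (m) of
#'   the seeded features; features that cannot fit the geometry are skipped.
#' @param deepwater_depth Deep Water context threshold (m).
#' @param open_water_depth Open-water floor depth (m).
#' @param noise_sigma_depth,noise_sigma_brightness Gaussian noise standard
#'   deviations applied by [generate_reef()] after the deterministic geometry.
#' @param seed Integer seed driving feature placement and noise.
#' @return A validated `archetype_params` list.
#' @export
archetype_params <- function(archetype = c("atoll", "fringing", "platform",
                                           "barrier"),
                             grid_shape = c(512L, 512L),
                             cell_size = 10,
                             rim_radius = NULL,
                             shelf_width = 300,
                             crest_depth = 0.3,
                             crest_width = 30,
                             flat_depth = 1,
                             flat_width = 750,
                             lagoon_depth = 15,
                             shallow_lagoon_depth = 5,
                             shallow_lagoon_width = 200,
                             fore_reef_slope_angle = 20,
                             back_reef_slope_angle = 10,
                             wall_angle = 75,
                             include_wall = FALSE,
                             windward_hsig = 2.5,
                             leeward_hsig = 1,
                             wind_direction = 90,
                             n_patch_reefs = 3L,
                             n_small_reefs = 1L,
                             n_reef_islands = 1L,
                             patch_radius = 60,
                             small_reef_radius = 50,
                             island_radius = 80,
                             deepwater_depth = 30,
                             open_water_depth = 35,
                             noise_sigma_depth = 0,
                             noise_sigma_brightness = 0,
                             seed = 1L) {
  archetype <- match.arg(archetype)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 64L)) {
    stop("grid_shape must be c(rows, cols) with both dimensions >= 64")
  }
  if (!(crest_depth < flat_depth && flat_depth < lagoon_depth)) {
    stop("need crest_depth < flat_depth < lagoon_depth")
  }
  if (flat_width <= 0) stop("flat_width must be positive")
  if (windward_hsig <= leeward_hsig) {
    stop("windward_hsig must exceed leeward_hsig")
  }
  if (noise_sigma_depth < 0 || noise_sigma_brightness < 0) {
    stop("noise sigmas must be non-negative")
  }
  half_extent <- min(grid_shape) * cell_size / 2
  if (is.null(rim_radius)) rim_radius <- 0.72 * half_extent
  structure(list(
    archetype = archetype, grid_shape = grid_shape, cell_size = cell_size,
    rim_radius = rim_radius, shelf_width = shelf_width,
    crest_depth = crest_depth, crest_width = crest_width,
    flat_depth = flat_depth, flat_width = flat_width,
    lagoon_depth = lagoon_depth, shallow_lagoon_depth = shallow_lagoon_depth,
    shallow_lagoon_width = shallow_lagoon_width,
    fore_reef_slope_angle = fore_reef_slope_angle,
    back_reef_slope_angle = back_reef_slope_angle,
    wall_angle = wall_angle, include_wall = include_wall,
    windward_hsig = windward_hsig, leeward_hsig = leeward_hsig,
    wind_direction = wind_direction,
    n_patch_reefs = as.integer(n_patch_reefs),
    n_small_reefs = as.integer(n_small_reefs),
    n_reef_islands = as.integer(n_reef_islands),
    patch_radius = patch_radius, small_reef_radius = small_reef_radius,
    island_radius = island_radius,
    deepwater_depth = deepwater_depth, open_water_depth = open_water_depth,
    noise_sigma_depth = noise_sigma_depth,
    noise_sigma_brightness = noise_sigma_brightness,
    seed = as.integer(seed)
  ), class = "archetype_params")
}

# incline width (m) for a depth change at a slope angle
incline_width <- function(d_from, d_to, angle) {
  abs(d_to - d_from) / tan(angle * pi / 180)
}

# Profile segments from the reef rim seaward (shared by all archetypes):
# fore-reef incline (with optional wall) down to the open-water floor.
fore_segments <- function(p) {
  if (p$include_wall) {
    wall_top <- p$mid_depth_wall_top %||% 8
    wall_bottom <- wall_top + 12
    list(
      list(tag = "fore", d_in = p$crest_depth, d_out = wall_top,
           w = incline_width(p$crest_depth, wall_top, p$fore_reef_slope_angle)),
      list(tag = "wall", d_in = wall_top, d_out = wall_bottom,
           w = incline_width(wall_top, wall_bottom, p$wall_angle)),
      list(tag = "fore", d_in = wall_bottom, d_out = p$open_water_depth,
           w = incline_width(wall_bottom, p$open_water_depth,
                             p$fore_reef_slope_angle))
    )
  } else {
    list(list(tag = "fore", d_in = p$crest_depth, d_out = p$open_water_depth,
              w = incline_width(p$crest_depth, p$open_water_depth,
                                p$fore_reef_slope_angle)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build the landward-to-seaward segment table for an archetype. Radial
# archetypes measure position as radius from the grid centre, linear ones as
# easting from the western edge. Returns data.frame(tag, s_in, s_out, d_in,
# d_out) with s_out of the last segment = Inf.
archetype_profile <- function(p) {
  segs <- list()
  add <- function(tag, w, d_in, d_out = d_in) {
    segs[[length(segs) + 1L]] <<- list(tag = tag, w = w, d_in = d_in,
                                       d_out = d_out)
  }
  irf_w <- 0.6 * p$flat_width
  orf_w <- 0.4 * p$flat_width
  brs1_w <- incline_width(p$shallow_lagoon_depth, p$flat_depth,
                          p$back_reef_slope_angle)
  brs2_w <- incline_width(p$lagoon_depth, p$shallow_lagoon_depth,
                          p$back_reef_slope_angle)

  if (p$archetype %in% c("atoll", "platform")) {
    inner <- p$rim_radius - p$crest_width - p$flat_width
    if (p$archetype == "atoll") {
      dl_r <- inner - brs1_w - p$shallow_lagoon_width - brs2_w
      if (dl_r < 5 * p$cell_size) {
        stop("grid too small for the atoll lagoon; reduce flat/lagoon widths ",
             "or enlarge the grid")
      }
      add("dl", dl_r, p$lagoon_depth)
      add("brs", brs2_w, p$lagoon_depth, p$shallow_lagoon_depth)
      add("sl", p$shallow_lagoon_width, p$shallow_lagoon_depth)
      add("brs", brs1_w, p$shallow_lagoon_depth, p$flat_depth)
    } else {
      if (inner < 5 * p$cell_size) {
        stop("grid too small for the platform reef top")
      }
      irf_w <- inner - orf_w  # flat disk fills the interior
    }
    add("irf", irf_w, p$flat_depth)
    add("orf", orf_w, p$flat_depth)
    add("rim", p$crest_width, p$crest_depth)
    if (p$archetype == "platform") {
      add("fore", incline_width(p$crest_depth, 8, p$fore_reef_slope_angle),
          p$crest_depth, 8)
      add("terrace", 200, 8)
      add("fore", incline_width(8, 12, p$fore_reef_slope_angle), 8, 12)
      add("plateau", 250, 12)
      add("fore", incline_width(12, p$open_water_depth,
                                p$fore_reef_slope_angle), 12,
          p$open_water_depth)
    } else {
      for (s in fore_segments(p)) add(s$tag, s$w, s$d_in, s$d_out)
    }
    add("dw", Inf, p$open_water_depth)
  } else {
    add("land", p$shelf_width, NA_real_)
    if (p$archetype == "barrier") {
      add("sl", 300, p$shallow_lagoon_depth)
      add("brs", brs2_w, p$shallow_lagoon_depth, p$lagoon_depth)
      add("dl", 600, p$lagoon_depth)
      add("brs", incline_width(p$lagoon_depth, p$flat_depth,
                               p$back_reef_slope_angle),
          p$lagoon_depth, p$flat_depth)
    }
    add("irf", irf_w, p$flat_depth)
    add("orf", orf_w, p$flat_depth)
    add("rim", p$crest_width, p$crest_depth)
    for (s in fore_segments(p)) add(s$tag, s$w, s$d_in, s$d_out)
    add("dw", Inf, p$open_water_depth)
  }

  w <- vapply(segs, `[[`, 0, "w")
  s_out <- cumsum(w)
  data.frame(
    tag = vapply(segs, `[[`, "", "tag"),
    s_in = c(0, s_out[-length(s_out)]),
    s_out = s_out,
    d_in = vapply(segs, `[[`, 0, "d_in"),
    d_out = vapply(segs, `[[`, 0, "d_out"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic reef archetype
#'
#' Builds the deterministic geometry for the requested archetype, stamps the
#' seeded optional features (patch reefs in the lagoon, a small reef in open
#' water, a supratidal reef island on the flat — atoll only), derives the wave
#' field, assigns ground-truth labels from the analytic geometry, paints
#' brightness from the per-class palette, and finally adds seeded Gaussian
#' noise to depth and brightness if requested. Bit-identical output for
#' identical parameters and seed.
#'
#' @param params An [archetype_params()].
#' @param scheme A `reef_scheme` providing the legend.
#' @param config A [threshold_config()]; the ground truth uses the same
#'   thresholds the classifier will use.
#' @return List with `stack` (an [attribute_stack()]) and `truth` (a
#'   `zone_map` with the generating parameters attached as `provenance`).
#' @export
generate_reef <- function(params, scheme = load_scheme(),
                          config = threshold_config()) {
  stopifnot(inherits(params, "archetype_params"))
  p <- params
  set.seed(p$seed)
  nr <- p$grid_shape[1]; nc <- p$grid_shape[2]
  cell <- p$cell_size
  legend <- scheme_legend(scheme)
  code <- function(nm) legend[[nm]]

  # cell-centre coordinates; radial archetypes measure s from the centre,
  # linear ones from the western edge
  xs <- (seq_len(nc) - 0.5) * cell
  ys <- (nr - seq_len(nr) + 0.5) * cell
  x <- matrix(xs, nr, nc, byrow = TRUE)
  y <- matrix(ys, nr, nc)
  radial <- p$archetype %in% c("atoll", "platform")
  if (radial) {
    cx <- nc * cell / 2; cy <- nr * cell / 2
    s <- sqrt((x - cx)^2 + (y - cy)^2)
    bearing <- (atan2(x - cx, y - cy) * 180 / pi) %% 360
  } else {
    s <- x
    bearing <- matrix(p$wind_direction, nr, nc)  # open coast faces the wind
  }

  profile <- archetype_profile(p)
  seg_idx <- findInterval(s, profile$s_out, left.open = TRUE) + 1L
  seg_idx[seg_idx > nrow(profile)] <- nrow(profile)
  tag <- matrix(profile$tag[seg_idx], nr, nc)
  frac <- (s - profile$s_in[seg_idx]) /
    pmax(profile$s_out[seg_idx] - profile$s_in[seg_idx], 1e-9)
  frac <- pmin(pmax(frac, 0), 1)
  depth <- matrix(profile$d_in[seg_idx] +
                    frac * (profile$d_out[seg_idx] - profile$d_in[seg_idx]),
                  nr, nc)
  land_mask <- tag == "land"
  depth[land_mask] <- NA_real_

  # wave field: sharpened cosine of bearing relative to the wind direction
  cosang <- cos((bearing - p$wind_direction) * pi / 180)
  hsig <- p$leeward_hsig + (p$windward_hsig - p$leeward_hsig) *
    stats::plogis(12 * cosang)
  hsig[land_mask] <- NA_real_
  exposed <- !is.na(hsig) & hsig > config$exposure_hsig

  # seeded features (atoll only): patch reefs, a small reef, a reef island
  if (p$archetype == "atoll") {
    dl_outer <- profile$s_out[profile$tag == "dl"][1]
    reef_outer <- profile$s_out[nrow(profile) - 1L]  # start of open water
    patch_top_r <- p$patch_radius
    patch_ring <- incline_width(p$flat_depth, p$lagoon_depth, 45)
    patch_margin <- dl_outer - patch_top_r - patch_ring - 3 * cell
    # centres placed at evenly spread bearings, with a radius floor so two
    # stamps can never touch
    ctr_lo <- if (p$n_patch_reefs > 1L) {
      (2 * (patch_top_r + patch_ring) + 3 * cell) /
        (2 * sin(pi / p$n_patch_reefs))
    } else {
      0.2 * patch_margin
    }
    if (p$n_patch_reefs > 0L && patch_margin > ctr_lo) {
      base_ang <- stats::runif(1, 0, 360)
      ctr_r <- stats::runif(p$n_patch_reefs, ctr_lo, patch_margin)
      for (k in seq_len(p$n_patch_reefs)) {
        ang <- (base_ang + (k - 1) * 360 / p$n_patch_reefs) * pi / 180
        px <- (if (radial) cx else 0) + ctr_r[k] * sin(ang)
        py <- (if (radial) cy else 0) + ctr_r[k] * cos(ang)
        d2 <- sqrt((x - px)^2 + (y - py)^2)
        stamp_depth <- ifelse(
          d2 <= patch_top_r, p$flat_depth,
          p$flat_depth + (d2 - patch_top_r) * tan(45 * pi / 180))
        hit <- !land_mask & d2 <= patch_top_r + patch_ring &
          stamp_depth < depth
        depth[hit] <- stamp_depth[hit]
        tag[hit] <- "patch"
      }
    }
    if (p$n_small_reefs > 0L) {
      sr_top_r <- p$small_reef_radius
      sr_ring <- incline_width(p$flat_depth, p$open_water_depth, 45)
      sr_ctr <- reef_outer + 100 + sr_top_r + sr_ring
      half_extent <- min(nr, nc) * cell / 2
      if (sr_ctr + sr_top_r + sr_ring < half_extent - 2 * cell) {
        for (k in seq_len(p$n_small_reefs)) {
          ang <- stats::runif(1, 0, 2 * pi)
          px <- cx + sr_ctr * sin(ang)
          py <- cy + sr_ctr * cos(ang)
          d2 <- sqrt((x - px)^2 + (y - py)^2)
          stamp_depth <- ifelse(
            d2 <= sr_top_r, p$flat_depth,
            p$flat_depth + (d2 - sr_top_r) * tan(45 * pi / 180))
          hit <- !land_mask & d2 <= sr_top_r + sr_ring & stamp_depth < depth
          depth[hit] <- stamp_depth[hit]
          tag[hit] <- "smallreef"
        }
      }
    }
    if (p$n_reef_islands > 0L) {
      irf_rows <- profile$tag == "irf"
      irf_mid <- (profile$s_in[irf_rows][1] + profile$s_out[irf_rows][1]) / 2
      isl_r <- p$island_radius
      for (k in seq_len(p$n_reef_islands)) {
        ang <- stats::runif(1, 0, 2 * pi)
        px <- cx + irf_mid * sin(ang)
        py <- cy + irf_mid * cos(ang)
        d2 <- sqrt((x - px)^2 + (y - py)^2)
        hit <- !land_mask & d2 <= isl_r & tag == "irf"
        depth[hit] <- -0.4
        tag[hit] <- "island"
      }
    }
  }

  # ground-truth labels from the analytic geometry + shared thresholds
  labels <- matrix(NA_integer_, nr, nc)
  assign_cells <- function(mask, class_name) {
    if (any(mask)) labels[mask] <<- code(class_name)
  }
  assign_cells(land_mask, "Land")
  assign_cells(tag == "dw", "Deep Water")
  assign_cells(tag == "island", "Reef Island")
  assign_cells(tag == "patch", "Patch Reef")
  assign_cells(tag == "smallreef" & depth <= config$deepwater_depth,
               "Small Reef")
  assign_cells(tag == "smallreef" & depth > config$deepwater_depth,
               "Deep Water")
  assign_cells(tag == "dl" & depth > config$lagoon_depth_min, "Lagoon")
  assign_cells(tag == "dl" & depth <= config$lagoon_depth_min,
               "Shallow Lagoon")
  assign_cells(tag == "sl", "Shallow Lagoon")
  assign_cells(tag == "brs", "Back Reef Slope")
  assign_cells(tag == "irf", "Inner Reef Flat")
  assign_cells(tag == "orf", "Outer Reef Flat")
  assign_cells(tag == "rim" & exposed, "Reef Crest")
  assign_cells(tag == "rim" & !exposed, "Outer Reef Flat")
  assign_cells(tag == "terrace", "Terrace")
  assign_cells(tag == "plateau", "Plateau")
  fore <- tag %in% c("fore", "wall") & !land_mask
  crest_band <- fore & depth <= config$crest_depth_max
  assign_cells(crest_band & exposed, "Reef Crest")
  assign_cells(crest_band & !exposed, "Outer Reef Flat")
  wall_band <- tag == "wall" & depth > config$crest_depth_max
  assign_cells(wall_band & exposed, "Wall")
  assign_cells(wall_band & !exposed, "Sheltered Wall")
  front_band <- tag == "fore" & depth > config$crest_depth_max &
    depth <= config$mid_deep_edge
  assign_cells(front_band & exposed, "Reef Front")
  assign_cells(front_band & !exposed, "Sheltered Front")
  slope_band <- tag == "fore" & depth > config$mid_deep_edge &
    depth <= config$deepwater_depth
  assign_cells(slope_band & exposed, "Reef Slope")
  assign_cells(slope_band & !exposed, "Sheltered Slope")
  assign_cells(tag %in% c("fore", "wall") & depth > config$deepwater_depth,
               "Deep Water")

  brightness <- matrix(BRIGHTNESS_PALETTE[names(legend)[labels]], nr, nc)
  brightness[land_mask] <- BRIGHTNESS_PALETTE[["Land"]]

  stack <- attribute_stack(depth, hsig, brightness, cell, land_mask)
  if (p$noise_sigma_depth > 0 || p$noise_sigma_brightness > 0) {
    stack <- apply_field_noise(stack, p$noise_sigma_depth,
                               p$noise_sigma_brightness)
  }

  truth <- new_zone_map(labels, legend, config, scheme$version, cell)
  truth$provenance <- p
  list(stack = stack, truth = truth)
}

# Perturb depth and brightness in place using the current RNG stream; masks
# and nodata cells are never touched, brightness is re-clipped to [0, 1].
apply_field_noise <- function(stack, sigma_depth, sigma_brightness) {
  if (sigma_depth > 0) {
    ok <- !is.na(stack$depth) & !stack$land_mask
    stack$depth[ok] <- stack$depth[ok] +
      stats::rnorm(sum(ok), 0, sigma_depth)
  }
  if (sigma_brightness > 0) {
    ok <- !is.na(stack$brightness) & !stack$land_mask
    stack$brightness[ok] <- pmin(pmax(
      stack$brightness[ok] + stats::rnorm(sum(ok), 0, sigma_brightness),
      0), 1)
  }
  stack
}

#' Add seeded Gaussian noise to an attribute stack
#'
#' Independent zero-mean Gaussian perturbations are added per cell to depth
#' and brightness only; wave height, masks and nodata/land cells are never
#' altered. A zero sigma leaves the corresponding grid bit-identical.
#'
#' @param stack An [attribute_stack()].
#' @param sigma_depth Depth noise standard deviation (m, >= 0).
#' @param sigma_brightness Brightness noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return The perturbed stack (derived attributes are dropped so they can be
#'   re-derived from the noisy fields).
#' @export
add_noise <- function(stack, sigma_depth, sigma_brightness, seed) {
  stopifnot(inherits(stack, "attribute_stack"))
  if (sigma_depth < 0 || sigma_brightness < 0) {
    stop("noise sigmas must be non-negative")
  }
  if (sigma_depth == 0 && sigma_brightness == 0) return(stack)
  set.seed(as.integer(seed))
  stack <- apply_field_noise(stack, sigma_depth, sigma_brightness)
  stack$slope <- stack$exposure <- stack$texture <- NULL
  stack$deepwater_mask <- NULL
  stack
}
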