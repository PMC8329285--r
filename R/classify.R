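#' Threshold configuration for the zonation decision tree
#'
#' All tunable cutoffs live here; nothing is hard-coded in the classifier, so
#' the same ruleset can be recalibrated to regional conditions. Defaults follow
#' the published case-study calibrations: a 0.75 m depth ceiling for the reef
#' crest, 3 m / 10 m depth-band edges, a 10 m floor for true (deep) lagoons,
#' fore-reef slopes of 5-90 degrees, a 2 m significant-wave-height exposure
#' threshold, and an Otsu brightness split between outer and inner reef flat.
#' An alternative 18 m front/slope split reported in older regional work can be
#' selected by setting `mid_deep_edge = 18`.
#'
#' All depth comparisons keep the boundary value in the shallower (or less
#' exposed) class: thresholds are strict on the named side, e.g. exposure
#' requires wave height strictly above 2 m.
#'
#' @param crest_depth_max Maximum reef-crest depth (m), default 0.75.
#' @param shallow_mid_edge Shallow/mid depth-band edge (m), default 3.
#' @param mid_deep_edge Mid/deep depth-band edge (m), default 10.
#' @param lagoon_depth_min Per-cell depth separating shallow from deep lagoon
#'   (m), default 10.
#' @param fore_reef_slope_min,fore_reef_slope_max Fore-reef slope-angle window
#'   (degrees), defaults 5 and 90.
#' @param wall_slope_min Minimum wall slope (degrees), default 60.
#' @param flat_slope_max Maximum slope still treated as horizontal (degrees),
#'   default 5.
#' @param exposure_hsig Significant-wave-height exposure threshold (m),
#'   default 2.
#' @param flat_brightness_split `"otsu"` or a fixed numeric brightness split
#'   for the outer/inner reef-flat division.
#' @param min_mapping_unit Smallest object (cells) retained by repair,
#'   default 9.
#' @param patch_small_reef_max_area Maximum area (cells) of an isolated body
#'   relabelled Patch Reef / Small Reef, default 400.
#' @param deepwater_depth Depth (m) beyond which cells are Deep Water context,
#'   default 30.
#' @return A validated `threshold_config` list.
#' @export
threshold_config <- function(crest_depth_max = 0.75,
                             shallow_mid_edge = 3,
                             mid_deep_edge = 10,
                             lagoon_depth_min = 10,
                             fore_reef_slope_min = 5,
                             fore_reef_slope_max = 90,
                             wall_slope_min = 60,
                             flat_slope_max = 5,
                             exposure_hsig = 2,
                             flat_brightness_split = "otsu",
                             min_mapping_unit = 9L,
                             patch_small_reef_max_area = 400L,
                             deepwater_depth = 30) {
  cfg <- list(crest_depth_max = crest_depth_max,
              shallow_mid_edge = shallow_mid_edge,
              mid_deep_edge = mid_deep_edge,
              lagoon_depth_min = lagoon_depth_min,
              fore_reef_slope_min = fore_reef_slope_min,
              fore_reef_slope_max = fore_reef_slope_max,
              wall_slope_min = wall_slope_min,
              flat_slope_max = flat_slope_max,
              exposure_hsig = exposure_hsig,
              flat_brightness_split = flat_brightness_split,
              min_mapping_unit = as.integer(min_mapping_unit),
              patch_small_reef_max_area = as.integer(patch_small_reef_max_area),
              deepwater_depth = deepwater_depth)
  if (!(crest_depth_max < shallow_mid_edge && shallow_mid_edge < mid_deep_edge)) {
    stop("need crest_depth_max < shallow_mid_edge < mid_deep_edge")
  }
  if (flat_slope_max > fore_reef_slope_min) {
    stop("flat_slope_max must not exceed fore_reef_slope_min")
  }
  if (wall_slope_min >= fore_reef_slope_max) {
    stop("wall_slope_min must be below fore_reef_slope_max")
  }
  if (!identical(flat_brightness_split, "otsu") &&
      !is.numeric(flat_brightness_split)) {
    stop("flat_brightness_split must be \"otsu\" or a numeric split value")
  }
  structure(cfg, class = "threshold_config")
}

# Zone map container: integer label grid plus its legend and provenance.
new_zone_map <- function(labels, legend, config, scheme_version, cell_size) {
  structure(list(labels = labels, legend = legend, config_used = config,
                 scheme_version = scheme_version, cell_size = cell_size),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("zone_map %d x %d (scheme v%s)\n", nrow(x$labels),
              ncol(x$labels), x$scheme_version))
  tab <- table(factor(x$labels, levels = x$legend,
                      labels = names(x$legend)), useNA = "no")
  tab <- tab[tab > 0]
  for (nm in names(tab)) cat(sprintf("  %-18s %d\n", nm, tab[[nm]]))
  invisible(x)
}

# Otsu's threshold by exhaustive scan: candidates are midpoints between
# consecutive distinct values; the split maximising the between-class variance
# w0*w1*(mu0-mu1)^2 wins, ties going to the lower split. NA when degenerate.
otsu_threshold <- function(x) {
  x <- x[!is.na(x)]
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NA_real_)
  cand <- (ux[-1] + ux[-length(ux)]) / 2
  best <- NA_real_
  best_var <- -Inf
  n <- length(x)
  for (t in cand) {
    lo <- x <= t
    n0 <- sum(lo)
    if (n0 == 0L || n0 == n) next
    v <- (n0 / n) * (1 - n0 / n) * (mean(x[lo]) - mean(x[!lo]))^2
    if (v > best_var + 1e-15) {
      best_var <- v
      best <- t
    }
  }
  best
}

#' Split reef-flat cells into outer and inner flat
#'
#' The reef flat is divided on brightness: the inner flat is the brighter,
#' sand-depositional portion, the outer flat the darker coral/algal portion.
#' The split value is Otsu's threshold over the flat cells' brightness (or a
#' fixed configured value); brightness above the split is inner, at or below
#' it outer. Cells directly adjacent to the reef crest are forced outer
#' regardless of brightness.
#'
#' @param brightness Numeric vector of flat-cell brightness values.
#' @param crest_adjacent Logical vector: is the cell adjacent to Reef Crest?
#' @param config A [threshold_config()].
#' @return Character vector of `"outer"` / `"inner"`.
#' @export
split_reef_flat <- function(brightness, crest_adjacent = NULL,
                            config = threshold_config()) {
  if (!length(brightness)) stop("no reef-flat cells to split")
  if (is.null(crest_adjacent)) crest_adjacent <- rep(FALSE, length(brightness))
  stopifnot(length(crest_adjacent) == length(brightness))
  split <- config$flat_brightness_split
  if (identical(split, "otsu")) {
    split <- otsu_threshold(brightness)
    if (is.na(split)) {
      warning("degenerate flat brightness; falling back to fixed split 0.5")
      split <- 0.5
    }
  }
  out <- ifelse(!is.na(brightness) & brightness > split, "inner", "outer")
  out[crest_adjacent] <- "outer"
  out
}

#' Classify a single context-resolved cell
#'
#' The pure per-cell core of the decision tree, useful for unit testing and
#' for documenting the branch structure. Spatial context (which side of the
#' crest a cell lies on, and whether its water body is enclosed) must already
#' be resolved; [classify_zones()] does that resolution for whole grids.
#'
#' Branches: supratidal cells are Reef Island. Lagoonward (enclosed) water is
#' Back Reef Slope when sloped, otherwise Lagoon / Shallow Lagoon / Inner Reef
#' Flat by depth. Seaward water is Wall, Slope or Front (with Sheltered
#' variants) when sloped — Reef Crest first when shallower than the crest
#' ceiling and exposed — and Plateau / Terrace / Outer Reef Flat by depth band
#' when horizontal. Reef-top water is Reef Crest on the exposed margin, Back
#' Reef Slope when sloped, otherwise Outer Reef Flat (the outer/inner split
#' needs the brightness context of the full grid).
#'
#' @param depth_band One of `"supratidal"`, `"shallow"`, `"mid"`, `"deep"`.
#' @param slope Slope angle in degrees.
#' @param exposure `"exposed"` or `"sheltered"`.
#' @param side `"seaward"`, `"reef_top"` or `"lagoonward"`.
#' @param enclosed Is the cell part of an enclosed water body?
#' @param supratidal Is the cell above datum?
#' @param depth Optional cell depth (m); enables the crest-ceiling branch.
#' @param config A [threshold_config()].
#' @return A Reef Cover class standard name.
#' @export
classify_cell <- function(depth_band, slope, exposure,
                          side = c("seaward", "reef_top", "lagoonward"),
                          enclosed = FALSE, supratidal = FALSE, depth = NA,
                          config = threshold_config()) {
  side <- match.arg(side)
  if (supratidal && depth_band %in% c("mid", "deep")) {
    stop("inconsistent attributes: supratidal cell in band '", depth_band, "'")
  }
  if (supratidal || identical(depth_band, "supratidal")) return("Reef Island")
  sloped <- slope > config$flat_slope_max
  if (side == "lagoonward" || (enclosed && side != "seaward")) {
    if (sloped) return("Back Reef Slope")
    if (depth_band == "deep") return("Lagoon")
    if (depth_band == "mid") return("Shallow Lagoon")
    return("Inner Reef Flat")
  }
  if (side == "seaward") {
    if (!is.na(depth) && depth <= config$crest_depth_max &&
        identical(exposure, "exposed")) {
      return("Reef Crest")
    }
    if (sloped) {
      if (slope >= config$wall_slope_min) {
        return(if (identical(exposure, "exposed")) "Wall" else "Sheltered Wall")
      }
      if (depth_band == "deep") {
        return(if (identical(exposure, "exposed")) "Reef Slope"
               else "Sheltered Slope")
      }
      return(if (identical(exposure, "exposed")) "Reef Front"
             else "Sheltered Front")
    }
    if (depth_band == "deep") return("Plateau")
    if (depth_band == "mid") return("Terrace")
    return("Outer Reef Flat")
  }
  # reef_top
  if (!is.na(depth) && depth <= config$crest_depth_max &&
      identical(exposure, "exposed")) {
    return("Reef Crest")
  }
  if (sloped) return("Back Reef Slope")
  "Outer Reef Flat"
}

#' Classify an attribute stack into Reef Cover zones
#'
#' Applies the decision-tree ruleset with explicit spatial context, in a fixed
#' pipeline order:
#' \enumerate{
#'   \item context masks: Land from the land mask; Deep Water where depth
#'     exceeds the deep-water threshold;
#'   \item water that cannot reach Deep Water without crossing the crest-depth
#'     contour is lagoonward: sloped cells become Back Reef Slope, flat cells
#'     Lagoon or Shallow Lagoon by depth, and the shallowest join the reef-flat
#'     pool;
#'   \item seaward water (connected to Deep Water) becomes Wall, Slope or
#'     Front — Sheltered variants when sheltered — by slope and depth band;
#'     horizontal seaward cells become Terrace (mid band) or Plateau (deep
#'     band), shallow ones join the reef-flat pool;
#'   \item cells at or above the crest-depth contour whose contour band touches
#'     open water become Reef Crest where exposed;
#'   \item the pooled flat cells are split into Outer / Inner Reef Flat on
#'     brightness, crest-adjacent cells forced outer;
#'   \item small isolated reef bodies are relabelled Patch Reef (enclosed in a
#'     lagoon) or Small Reef (surrounded by Deep Water); supratidal non-land
#'     cells are Reef Island.
#' }
#' The run is fully deterministic.
#'
#' @param stack An [attribute_stack()]; derived attributes are computed when
#'   absent.
#' @param scheme A `reef_scheme` (for the legend), default the packaged one.
#' @param config A [threshold_config()].
#' @return A `zone_map`.
#' @export
classify_zones <- function(stack, scheme = load_scheme(),
                           config = threshold_config()) {
  stopifnot(inherits(stack, "attribute_stack"))
  if (is.null(stack$depth)) stop("attribute stack lacks a depth grid")
  if (is.null(stack$slope) || is.null(stack$exposure)) {
    stack <- derive_attributes(stack, config)
  }
  legend <- scheme_legend(scheme)
  code <- function(nm) legend[[nm]]
  depth <- stack$depth
  depth[stack$land_mask] <- NA_real_
  nr <- nrow(depth); nc <- ncol(depth)
  labels <- matrix(NA_integer_, nr, nc)

  # 1. context
  labels[stack$land_mask] <- code("Land")
  dw <- !stack$land_mask & !is.na(depth) & depth > config$deepwater_depth
  labels[dw] <- code("Deep Water")
  supra <- !stack$land_mask & !is.na(depth) & depth <= 0
  labels[supra] <- code("Reef Island")
  water <- !stack$land_mask & !is.na(depth) & depth > 0 & !dw
  if (!any(water)) {
    warning("no subtidal reef cells; returning context-only map")
    return(new_zone_map(labels, legend, config, scheme$version,
                        stack$cell_size))
  }
  exposed <- !is.na(stack$exposure) & stack$exposure == "exposed"
  sloped <- !is.na(stack$slope) & stack$slope > config$flat_slope_max

  # 2/3. seaward vs lagoonward water, split by the crest-depth contour
  band <- water & depth <= config$crest_depth_max
  open <- water & depth > config$crest_depth_max
  seaward <- reachable_from(open, dw, connectivity = 4L)
  enclosed <- open & !seaward

  flat_pool <- matrix(FALSE, nr, nc)

  idx <- which(enclosed)
  if (length(idx)) {
    lag_sloped <- sloped[idx]
    d <- depth[idx]
    lab <- ifelse(lag_sloped, code("Back Reef Slope"),
           ifelse(d > config$lagoon_depth_min, code("Lagoon"),
           ifelse(d > config$shallow_mid_edge, code("Shallow Lagoon"),
                  NA_integer_)))
    labels[idx] <- lab
    flat_pool[idx[is.na(lab)]] <- TRUE
  }

  idx <- which(seaward)
  if (length(idx)) {
    d <- depth[idx]
    sl <- stack$slope[idx]
    exp_i <- exposed[idx]
    deep_band <- d > config$mid_deep_edge
    mid_band <- !deep_band & d > config$shallow_mid_edge
    is_sloped <- sloped[idx]
    lab <- rep(NA_integer_, length(idx))
    wall <- is_sloped & !is.na(sl) & sl >= config$wall_slope_min
    lab[wall & exp_i] <- code("Wall")
    lab[wall & !exp_i] <- code("Sheltered Wall")
    rest <- is_sloped & !wall
    lab[rest & deep_band & exp_i] <- code("Reef Slope")
    lab[rest & deep_band & !exp_i] <- code("Sheltered Slope")
    lab[rest & !deep_band & exp_i] <- code("Reef Front")
    lab[rest & !deep_band & !exp_i] <- code("Sheltered Front")
    lab[!is_sloped & deep_band] <- code("Plateau")
    lab[!is_sloped & mid_band] <- code("Terrace")
    labels[idx] <- lab
    flat_pool[idx[is.na(lab)]] <- TRUE  # shallow horizontal seaward cells
  }

  # 4. reef crest: contour-band components that touch open water, where exposed
  crest <- matrix(FALSE, nr, nc)
  if (any(band)) {
    comp <- label_components(band, connectivity = 8L)
    touch <- adjacent_to(seaward | dw, connectivity = 8L)
    open_comps <- unique(comp[band & touch])
    crest <- band & matrix(comp %in% open_comps, nr, nc) & exposed
    labels[crest] <- code("Reef Crest")
    flat_pool[band & !crest] <- TRUE
  }

  # 5. outer/inner reef flat split on brightness
  if (any(flat_pool)) {
    idx <- which(flat_pool)
    crest_adj <- adjacent_to(crest, connectivity = 8L)
    part <- split_reef_flat(stack$brightness[idx], crest_adj[idx], config)
    labels[idx] <- ifelse(part == "inner", code("Inner Reef Flat"),
                          code("Outer Reef Flat"))
  }

  # 6. small isolated reef bodies
  body_mask <- !is.na(labels) &
    !matrix(labels %in% c(code("Deep Water"), code("Land"), code("Lagoon"),
                          code("Shallow Lagoon")), nr, nc)
  bodies <- label_components(body_mask, connectivity = 4L)
  nbody <- max(bodies)
  if (nbody > 0L) {
    sizes <- tabulate(bodies[bodies > 0L], nbody)
    small <- which(sizes <= config$patch_small_reef_max_area)
    for (b in small) {
      cells <- bodies == b
      ring <- adjacent_to(cells, connectivity = 8L) & !cells
      nb <- unique(labels[ring])
      nb <- nb[!is.na(nb)]
      if (!length(nb)) next
      if (all(nb %in% c(code("Lagoon"), code("Shallow Lagoon")))) {
        labels[cells] <- code("Patch Reef")
      } else if (all(nb == code("Deep Water"))) {
        labels[cells] <- code("Small Reef")
      }
    }
  }

  new_zone_map(labels, legend, config, scheme$version, stack$cell_size)
}
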