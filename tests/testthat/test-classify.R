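test_that("threshold configuration enforces its ordering invariants", {
  cfg <- threshold_config()
  expect_identical(cfg$crest_depth_max, 0.75)
  expect_identical(cfg$exposure_hsig, 2)
  expect_error(threshold_config(crest_depth_max = 5), "crest_depth_max")
  expect_error(threshold_config(flat_slope_max = 10), "flat_slope_max")
  expect_error(threshold_config(wall_slope_min = 95), "wall_slope_min")
  expect_error(threshold_config(flat_brightness_split = "median"),
               "otsu")
})

test_that("the per-cell decision tree reproduces the case-study assignments", {
  cfg <- threshold_config()
  expect_identical(classify_cell("mid", 15, "exposed", "seaward",
                                 config = cfg), "Reef Front")
  expect_identical(classify_cell("deep", 20, "sheltered", "seaward",
                                 config = cfg), "Sheltered Slope")
  expect_identical(classify_cell("deep", 2, "sheltered", "lagoonward",
                                 depth = 15, config = cfg), "Lagoon")
  expect_identical(classify_cell("mid", 75, "exposed", "seaward",
                                 config = cfg), "Wall")
  expect_identical(classify_cell("shallow", 1, "exposed", "seaward",
                                 depth = 0.5, config = cfg), "Reef Crest")
  expect_identical(classify_cell("mid", 2, "sheltered", "lagoonward",
                                 config = cfg), "Shallow Lagoon")
  expect_identical(classify_cell("mid", 2, "exposed", "seaward",
                                 config = cfg), "Terrace")
  expect_identical(classify_cell("deep", 2, "exposed", "seaward",
                                 config = cfg), "Plateau")
  expect_identical(classify_cell("shallow", 20, "exposed", "lagoonward",
                                 config = cfg), "Back Reef Slope")
  expect_identical(classify_cell("supratidal", 0, "exposed", "reef_top",
                                 supratidal = TRUE, config = cfg),
                   "Reef Island")
  expect_error(classify_cell("deep", 0, "exposed", "seaward",
                             supratidal = TRUE), "inconsistent")
})

test_that("the decision tree is total over the consistent attribute lattice", {
  cfg <- threshold_config()
  valid <- c(test_scheme()$reef_class_names, "Deep Water", "Land")
  for (side in c("seaward", "reef_top", "lagoonward")) {
    for (band in c("supratidal", "shallow", "mid", "deep")) {
      for (expo in c("exposed", "sheltered")) {
        for (slope in c(0, 2, 20, 75)) {
          for (enc in c(TRUE, FALSE)) {
            cl <- classify_cell(band, slope, expo, side, enclosed = enc,
                                supratidal = band == "supratidal",
                                config = cfg)
            expect_true(cl %in% valid,
                        label = paste(side, band, expo, slope, enc, "->", cl))
          }
        }
      }
    }
  }
})

test_that("flipping exposure swaps sheltered variants and nothing else", {
  cfg <- threshold_config()
  dual <- c("Reef Front" = "Sheltered Front", "Reef Slope" = "Sheltered Slope",
            "Wall" = "Sheltered Wall")
  for (band in c("shallow", "mid", "deep")) {
    for (slope in c(10, 30, 70)) {
      a <- classify_cell(band, slope, "exposed", "seaward", config = cfg)
      b <- classify_cell(band, slope, "sheltered", "seaward", config = cfg)
      expect_identical(unname(dual[a]), b)
    }
    # horizontal seaward cells are exposure-neutral
    expect_identical(
      classify_cell(band, 1, "exposed", "seaward", config = cfg),
      classify_cell(band, 1, "sheltered", "seaward", config = cfg))
  }
})

test_that("reef-flat splitting follows brightness with a crest override", {
  cfg <- threshold_config()
  # bimodal brightness: dark cluster outer, bright cluster inner
  b <- c(rep(0.3, 40), rep(0.8, 60))
  part <- split_reef_flat(b, config = cfg)
  expect_identical(part, c(rep("outer", 40), rep("inner", 60)))
  # the Otsu split lands between the clusters (brute-force scan oracle)
  expect_identical(reefzoner:::otsu_threshold(b), 0.55)

  # crest-adjacent cell forced outer despite bright sand
  part2 <- split_reef_flat(c(0.3, 0.9, 0.9), c(FALSE, TRUE, FALSE), cfg)
  expect_identical(part2, c("outer", "outer", "inner"))

  # single flat cell at a fixed split: boundary value goes outer
  cfg_fixed <- threshold_config(flat_brightness_split = 0.5)
  expect_identical(split_reef_flat(0.5, config = cfg_fixed), "outer")

  # degenerate all-equal brightness falls back with a warning
  expect_warning(split_reef_flat(rep(0.4, 5), config = cfg), "fixed split")
})

test_that("otsu matches an independent between-class-variance scan", {
  set.seed(3)
  for (k in 1:10) {
    x <- c(stats::rnorm(30, 0.3, 0.05), stats::rnorm(30, 0.75, 0.05))
    x <- pmin(pmax(x, 0), 1)
    got <- reefzoner:::otsu_threshold(x)
    ux <- sort(unique(x))
    cands <- (ux[-1] + ux[-length(ux)]) / 2
    scores <- sapply(cands, function(t) {
      lo <- x <= t
      if (!any(lo) || all(lo)) return(-Inf)
      mean(lo) * (1 - mean(lo)) * (mean(x[lo]) - mean(x[!lo]))^2
    })
    expect_equal(got, cands[which.max(scores)])
  }
})

test_that("classification is deterministic and handles degenerate maps", {
  s <- test_scheme()
  g <- generate_reef(small_params("atoll", seed = 7), s)
  z1 <- classify_zones(g$stack, s)
  z2 <- classify_zones(g$stack, s)
  expect_identical(z1$labels, z2$labels)

  land <- matrix(TRUE, 64, 64)
  st <- attribute_stack(matrix(NA_real_, 64, 64), matrix(NA_real_, 64, 64),
                        matrix(NA_real_, 64, 64), 10, land)
  expect_warning(zl <- classify_zones(st, s), "context-only")
  expect_true(all(zl$labels == zl$legend[["Land"]]))
})

test_that("the classifier recovers noise-free ground truth", {
  s <- test_scheme()
  for (arch in c("atoll", "fringing")) {
    g <- generate_reef(small_params(arch, seed = 7), s)
    zm <- classify_zones(g$stack, s)
    cm <- confusion_matrix(zm, g$truth)
    expect_gt(cm$overall_accuracy, 0.99)
    # disagreement confined to the stencil band along zone boundaries:
    # every mismatching cell is within 2 cells of a truth-label boundary
    mism <- !is.na(zm$labels) & !is.na(g$truth$labels) &
      zm$labels != g$truth$labels
    tl <- g$truth$labels
    boundary <- matrix(FALSE, nrow(tl), ncol(tl))
    for (off in list(c(0, 1), c(1, 0))) {
      sh <- reefzoner:::shift_mat(tl, off[1], off[2])
      boundary <- boundary | (!is.na(tl) & !is.na(sh) & tl != sh)
      sh <- reefzoner:::shift_mat(tl, -off[1], -off[2])
      boundary <- boundary | (!is.na(tl) & !is.na(sh) & tl != sh)
    }
    near_boundary <- boundary |
      reefzoner:::adjacent_to(boundary, connectivity = 8L)
    expect_true(all(near_boundary[mism]))
  }
})

test_that("near-vertical walls are recovered on a fine-grid profile", {
  # a 75 degree wall is sub-cell at the 10 m reference resolution, so the
  # wall variant runs on a 1 m cell shore-normal profile
  s <- test_scheme()
  p <- archetype_params("fringing", grid_shape = c(64, 768), cell_size = 1,
                        shelf_width = 60, flat_width = 150, crest_width = 10,
                        include_wall = TRUE, seed = 2)
  g <- generate_reef(p, s)
  expect_identical(nrow(validate_zones(g$truth, s)$violations), 0L)
  zm <- classify_zones(g$stack, s)
  cm <- confusion_matrix(zm, g$truth)
  expect_gt(cm$overall_accuracy, 0.99)
  expect_equal(unname(cm$producer_accuracy[["Wall"]]), 1)
})

test_that("raising the crest ceiling never shrinks the crest set", {
  s <- test_scheme()
  g <- generate_reef(small_params("atoll", seed = 7), s)
  crest_code <- g$truth$legend[["Reef Crest"]]
  prev <- NULL
  for (ceiling in c(0.3, 0.5, 0.75, 1.2)) {
    cfg <- threshold_config(crest_depth_max = ceiling)
    zm <- classify_zones(g$stack, s, cfg)
    cur <- which(zm$labels == crest_code)
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})
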