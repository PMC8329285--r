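# Ring/disk fixtures expressed as class-name matrices make the expected
# topology explicit; random grids are cross-checked against the queue-based
# flood-fill, pairwise-scan and edge-flood oracles in helper-oracles.R.

ring_map <- function(outer = "Outer Reef Flat", inner = "Inner Reef Flat",
                     core = "Back Reef Slope", n = 11) {
  m <- matrix(outer, n, n)
  m[3:(n - 2), 3:(n - 2)] <- inner
  m[5:(n - 4), 5:(n - 4)] <- core
  m
}

test_that("segmentation uses 4-connectivity with scan-order ids", {
  s <- test_scheme()
  zm <- zone_map_from_names(matrix("Lagoon", 5, 5), s)
  seg <- segment_zones(zm)
  expect_identical(sum(!seg$objects$is_nodata), 1L)

  # diagonal-only contact separates same-class objects
  m <- matrix("Lagoon", 4, 4)
  m[1, 1] <- "Patch Reef"; m[2, 2] <- "Patch Reef"
  seg2 <- segment_zones(zone_map_from_names(m, s))
  pr <- seg2$objects[seg2$objects$class_name %in% "Patch Reef", ]
  expect_identical(nrow(pr), 2L)

  # ids follow raster scan order of each object's first cell
  expect_identical(seg2$ids[1, 1], 1L)
  expect_true(all(diff(seg2$objects$object_id) == 1))
})

test_that("segmentation partitions match the flood-fill oracle", {
  set.seed(101)
  s <- test_scheme()
  classes <- c("Lagoon", "Patch Reef", "Shallow Lagoon")
  for (k in 1:30) {
    vals <- matrix(sample(classes, 144, replace = TRUE), 12, 12)
    if (k %% 3 == 0) vals[stats::runif(144) < 0.15] <- NA
    zm <- zone_map_from_names(vals, s)
    seg <- segment_zones(zm)
    oracle <- oracle_flood_components(zm$labels)
    # identical partitions: each oracle region maps to exactly one id and
    # vice versa
    expect_identical(max(oracle), max(seg$ids))
    expect_true(all(tapply(seg$ids, oracle, function(x) length(unique(x)))
                    == 1L))
  }
})

test_that("adjacency edges match the exhaustive pairwise scan", {
  s <- test_scheme()
  zm <- zone_map_from_names(ring_map(), s)
  seg <- segment_zones(zm)
  edges <- adjacency_graph(seg)
  # crest-style ring topology: outer-inner and inner-core contacts only
  expect_identical(nrow(edges), 2L)

  # objects separated everywhere by nodata are not neighbours
  m <- matrix("Lagoon", 5, 5)
  m[, 3] <- NA
  m[, 4:5] <- "Shallow Lagoon"
  seg2 <- segment_zones(zone_map_from_names(m, s))
  expect_identical(nrow(adjacency_graph(seg2)), 0L)

  set.seed(202)
  for (k in 1:30) {
    vals <- matrix(sample(c("Lagoon", "Patch Reef", "Reef Crest"), 144,
                          replace = TRUE), 12, 12)
    seg3 <- segment_zones(zone_map_from_names(vals, s))
    got <- adjacency_graph(seg3)
    want <- oracle_adjacency(seg3$ids)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("enclosure detects nested rings and honours the grid edge", {
  s <- test_scheme()
  seg <- segment_zones(zone_map_from_names(ring_map(), s))
  enc <- enclosure_relations(seg)
  obj <- seg$objects
  id_of <- function(nm) obj$object_id[match(nm, obj$class_name)]
  # core enclosed by middle ring, middle by outer; outer touches the edge
  expect_identical(enc$enclosed_by[enc$object_id == id_of("Back Reef Slope")],
                   id_of("Inner Reef Flat"))
  expect_identical(enc$enclosed_by[enc$object_id == id_of("Inner Reef Flat")],
                   id_of("Outer Reef Flat"))
  expect_true(is.na(enc$enclosed_by[enc$object_id ==
                                      id_of("Outer Reef Flat")]))

  # an object reaching the map edge is never enclosed
  m <- ring_map()
  m[5, 1:6] <- "Back Reef Slope"  # breach out to the western edge
  enc2 <- enclosure_relations(segment_zones(zone_map_from_names(m, s)))
  expect_true(all(is.na(enc2$enclosed_by[
    enc2$object_id %in%
      segment_zones(zone_map_from_names(m, s))$objects$object_id[
        segment_zones(zone_map_from_names(m, s))$objects$class_name %in%
          "Back Reef Slope"]])))
})

test_that("enclosure matches the edge-flood oracle on random grids", {
  set.seed(303)
  s <- test_scheme()
  for (k in 1:30) {
    vals <- matrix(sample(c("Lagoon", "Patch Reef", "Shallow Lagoon"), 144,
                          replace = TRUE, prob = c(0.5, 0.25, 0.25)), 12, 12)
    seg <- segment_zones(zone_map_from_names(vals, s))
    enc <- enclosure_relations(seg)
    want <- oracle_enclosure(seg$ids,
                             seg$objects$object_id[!seg$objects$is_nodata])
    got <- stats::setNames(enc$enclosed_by, enc$object_id)
    expect_identical(got[names(want)], want)
  }
})

test_that("relabelling class codes permutes classes but not the partition", {
  set.seed(404)
  s <- test_scheme()
  vals <- matrix(sample(c("Lagoon", "Patch Reef", "Reef Crest"), 100,
                        replace = TRUE), 10, 10)
  zm <- zone_map_from_names(vals, s)
  seg1 <- segment_zones(zm)
  swapped <- vals
  swapped[vals == "Lagoon"] <- "Reef Crest"
  swapped[vals == "Reef Crest"] <- "Lagoon"
  seg2 <- segment_zones(zone_map_from_names(swapped, s))
  expect_identical(seg1$ids, seg2$ids)
  expect_identical(seg1$objects$cell_count, seg2$objects$cell_count)
})

test_that("rule checking flags never-level relations only", {
  s <- test_scheme()
  # a reef crest surrounded by inner reef flat is an enclosure violation
  m <- matrix("Inner Reef Flat", 9, 9)
  m[4:6, 4:6] <- "Reef Crest"
  v <- validate_zones(zone_map_from_names(m, s), s)
  expect_identical(nrow(v$violations), 2L)  # illegal contact + enclosure
  expect_setequal(v$violations$kind, c("adjacency", "enclosure"))
  expect_true(all(v$violations$class_a == "Reef Crest" |
                    v$violations$class_b == "Reef Crest"))

  # crest beside outer reef flat is typical: no violation
  m2 <- matrix("Outer Reef Flat", 6, 6)
  m2[, 1:2] <- "Reef Crest"
  v2 <- validate_zones(zone_map_from_names(m2, s), s)
  expect_identical(nrow(v2$violations), 0L)

  # uniform map: single object, nothing to violate
  v3 <- validate_zones(zone_map_from_names(matrix("Lagoon", 5, 5), s), s)
  expect_identical(nrow(v3$violations), 0L)
})

test_that("repair removes violations deterministically and conserves legend", {
  s <- test_scheme()
  # 2-cell crest island inside the inner flat is absorbed by the flat
  m <- matrix("Inner Reef Flat", 9, 9)
  m[5, 4:5] <- "Reef Crest"
  m[1, 1] <- NA
  zm <- zone_map_from_names(m, s)
  res <- repair_zones(zm, s)
  expect_identical(nrow(res$remaining_violations), 0L)
  expect_identical(res$report$class_from, "Reef Crest")
  expect_identical(res$report$class_to, "Inner Reef Flat")
  expect_true(is.na(res$zonemap$labels[1, 1]))       # nodata untouched
  expect_identical(sort(unique(as.vector(res$zonemap$labels))),
                   zm$legend[["Inner Reef Flat"]])   # no new classes

  # a violation-free map is a fixed point
  clean <- zone_map_from_names(ring_map(), s)
  res2 <- repair_zones(clean, s)
  expect_identical(res2$zonemap$labels, clean$labels)
  expect_identical(nrow(res2$report), 0L)
})

test_that("repair is idempotent on noisy classified maps", {
  s <- test_scheme()
  g <- generate_reef(small_params("atoll", seed = 5,
                                  noise_sigma_depth = 0.2), s)
  zm <- classify_zones(g$stack, s)
  r1 <- repair_zones(zm, s)
  expect_identical(nrow(r1$remaining_violations), 0L)
  r2 <- repair_zones(r1$zonemap, s)
  expect_identical(r1$zonemap$labels, r2$zonemap$labels)
  # min-mapping-unit cleanup: no sub-MMU objects remain
  seg <- segment_zones(r1$zonemap)
  real <- seg$objects[!seg$objects$is_nodata, ]
  expect_true(all(real$cell_count >= zm$config_used$min_mapping_unit))
})
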