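# Independent brute-force oracles and shared fixtures. These deliberately
# avoid the package's vectorised/graph-based code paths: flood fills use an
# explicit queue over cells, adjacency is an exhaustive pairwise cell scan,
# and window statistics are computed cell by cell.

# Population standard deviation over each truncated window, nested loops.
oracle_texture <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(m[r, c])) next
      vals <- c()
      for (rr in max(1, r - radius):min(nr, r + radius)) {
        for (cc in max(1, c - radius):min(nc, c + radius)) {
          if (!is.na(m[rr, cc])) vals <- c(vals, m[rr, cc])
        }
      }
      mu <- mean(vals)
      out[r, c] <- sqrt(mean((vals - mu)^2))
    }
  }
  out
}

# Queue-based flood fill labelling of equal-valued 4-connected regions
# (NA == NA). Returns an integer matrix of region ids (arbitrary numbering).
oracle_flood_components <- function(vals) {
  nr <- nrow(vals); nc <- ncol(vals)
  v <- vals
  v[is.na(v)] <- -.Machine$integer.max
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (lab[r0, c0] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- nxt
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          r <- cur[1] + d[1]; c <- cur[2] + d[2]
          if (r < 1 || r > nr || c < 1 || c > nc) next
          if (lab[r, c] == 0L && v[r, c] == v[cur[1], cur[2]]) {
            lab[r, c] <- nxt
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive pairwise scan for 8-connected object contacts.
oracle_adjacency <- function(ids) {
  nr <- nrow(ids); nc <- ncol(ids)
  counts <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        a <- ids[r, c]; b <- ids[r2, c2]
        if (a != b) {
          key <- paste(min(a, b), max(a, b))
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  if (!length(counts)) {
    return(data.frame(a = integer(0), b = integer(0), weight = integer(0)))
  }
  parts <- strsplit(names(counts), " ")
  out <- data.frame(a = as.integer(sapply(parts, `[`, 1)),
                    b = as.integer(sapply(parts, `[`, 2)),
                    weight = as.integer(unlist(counts)))
  out[order(out$a, out$b), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Does a 4-connected flood from the grid edge, barred from object `b`, reach
# object `a`? Used to decide enclosure the slow way.
oracle_flood_reaches <- function(ids, a, b) {
  nr <- nrow(ids); nc <- ncol(ids)
  seen <- matrix(FALSE, nr, nc)
  queue <- list()
  for (r in seq_len(nr)) for (c in c(1L, nc)) {
    if (ids[r, c] != b && !seen[r, c]) { seen[r, c] <- TRUE; queue[[length(queue) + 1L]] <- c(r, c) }
  }
  for (c in seq_len(nc)) for (r in c(1L, nr)) {
    if (ids[r, c] != b && !seen[r, c]) { seen[r, c] <- TRUE; queue[[length(queue) + 1L]] <- c(r, c) }
  }
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (ids[cur[1], cur[2]] == a) return(TRUE)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- cur[1] + d[1]; c <- cur[2] + d[2]
      if (r < 1 || r > nr || c < 1 || c > nc) next
      if (!seen[r, c] && ids[r, c] != b) {
        seen[r, c] <- TRUE
        queue[[length(queue) + 1L]] <- c(r, c)
      }
    }
  }
  any(ids[c(1, nr), ] == a) || any(ids[, c(1, nc)] == a)
}

# Innermost encloser per object: enclosing set by cell-level flood fill, then
# nearest encloser by breadth-first search over 4-adjacent objects (hand-rolled).
oracle_enclosure <- function(ids, real_ids) {
  nr <- nrow(ids); nc <- ncol(ids)
  all_ids <- sort(unique(as.vector(ids)))
  touches <- vapply(all_ids, function(o) {
    any(ids[c(1, nr), ] == o) || any(ids[, c(1, nc)] == o)
  }, TRUE)
  names(touches) <- all_ids
  # 4-adjacency between objects (exhaustive scan)
  nb <- lapply(all_ids, function(o) integer(0))
  names(nb) <- all_ids
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (d in list(c(0, 1), c(1, 0))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > nr || c2 > nc) next
      a <- ids[r, c]; b <- ids[r2, c2]
      if (a != b) {
        nb[[as.character(a)]] <- union(nb[[as.character(a)]], b)
        nb[[as.character(b)]] <- union(nb[[as.character(b)]], a)
      }
    }
  }
  bfs_dist <- function(from) {
    dist <- stats::setNames(rep(Inf, length(all_ids)), all_ids)
    dist[as.character(from)] <- 0
    queue <- from
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (x in nb[[as.character(cur)]]) {
        if (is.infinite(dist[as.character(x)])) {
          dist[as.character(x)] <- dist[as.character(cur)] + 1
          queue <- c(queue, x)
        }
      }
    }
    dist
  }
  out <- stats::setNames(rep(NA_integer_, length(real_ids)), real_ids)
  for (a in real_ids) {
    if (touches[[as.character(a)]]) next
    enclosers <- c()
    for (b in real_ids) {
      if (b == a) next
      if (!oracle_flood_reaches(ids, a, b)) enclosers <- c(enclosers, b)
    }
    if (length(enclosers)) {
      d <- bfs_dist(a)
      out[[as.character(a)]] <- enclosers[which.min(d[as.character(enclosers)])]
    }
  }
  out
}

# Random label grid with few classes; class 0 encoded as nodata when asked.
random_label_grid <- function(nr = 12, nc = 12, n_classes = 3,
                              p_nodata = 0) {
  vals <- sample.int(n_classes, nr * nc, replace = TRUE)
  m <- matrix(vals, nr, nc)
  if (p_nodata > 0) m[stats::runif(nr * nc) < p_nodata] <- NA
  m
}

# Zone map straight from a matrix of class names (NA = nodata).
zone_map_from_names <- function(name_matrix, scheme = test_scheme(),
                                cell_size = 10) {
  legend <- stats::setNames(seq_along(scheme$class_names), scheme$class_names)
  labels <- matrix(legend[name_matrix], nrow(name_matrix), ncol(name_matrix))
  reefzoner:::new_zone_map(labels, legend, threshold_config(),
                           scheme$version, cell_size)
}

# One shared scheme per test session.
test_scheme <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_scheme()
    cached
  }
})

# Small archetypes used throughout the tests: 192 x 192 cells of 10 m with
# proportionally narrowed flats so all rings fit the smaller grid.
small_params <- function(archetype, seed = 7, ...) {
  archetype_params(archetype, grid_shape = c(192L, 192L), cell_size = 10,
                   flat_width = 300, shallow_lagoon_width = 100,
                   rim_radius = 0.72 * 960, patch_radius = 30,
                   island_radius = 50, seed = seed, ...)
}
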