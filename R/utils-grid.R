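# Internal raster-grid helpers.
#
# Grids are plain R matrices in the package's raster convention: row 1 is the
# northern (top) edge, column 1 the western edge, cells are square with side
# `cell_size` metres. Connectivity helpers use 4- or 8-neighbourhoods.

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr
  cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (connectivity == 8L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  } else {
    stop("connectivity must be 4 or 8")
  }
}

# Half set of offsets (each unordered neighbour pair visited once).
half_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    list(c(1L, 0L), c(0L, 1L))
  } else {
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  }
}

# Row/column of 1-based column-major positions.
pos_row <- function(pos, nr) ((pos - 1L) %% nr) + 1L
pos_col <- function(pos, nr) ((pos - 1L) %/% nr) + 1L

# Row-major scan rank of column-major positions (ids are assigned in raster
# scan order: left-to-right within rows, top row first).
scan_rank <- function(pos, nr, nc) {
  (pos_row(pos, nr) - 1L) * nc + pos_col(pos, nr)
}

# Connected-component labelling of a logical mask. Returns an integer matrix:
# 0 outside the mask, components numbered 1..k by the scan rank of their first
# cell. Components are built as graph components of the cell lattice.
label_components <- function(mask, connectivity = 4L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(out)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  edge_list <- list()
  for (off in half_offsets(connectivity)) {
    r <- pos_row(idx, nr); c <- pos_col(idx, nr)
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- idx[ok]
    j2 <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j2]
    if (any(keep)) {
      edge_list[[length(edge_list) + 1L]] <- rbind(vid[j[keep]], vid[j2[keep]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edge_list)) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edge_list)))
  }
  memb <- igraph::components(g)$membership
  # renumber components by first cell in scan order
  rk <- scan_rank(idx, nr, nc)
  first_rank <- tapply(rk, memb, min)
  new_id <- integer(length(first_rank))
  new_id[order(first_rank)] <- seq_along(first_rank)
  out[idx] <- new_id[memb]
  out
}

# Cells of `allowed` 4/8-connected to any cell of `seeds` (seeds need not be
# in `allowed`; paths run through allowed | seeds).
reachable_from <- function(allowed, seeds, connectivity = 4L) {
  comb <- allowed | seeds
  lab <- label_components(comb, connectivity)
  seed_comps <- unique(lab[seeds & lab > 0L])
  res <- matrix(FALSE, nrow(allowed), ncol(allowed))
  if (length(seed_comps)) res[lab %in% seed_comps] <- TRUE
  res & allowed
}

# TRUE for cells having at least one neighbour (given connectivity) in `mask`.
adjacent_to <- function(mask, connectivity = 8L) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (off in neighbour_offsets(connectivity)) {
    out <- out | shift_mat(mask, off[1], off[2], fill = FALSE)
  }
  out
}
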