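#' Object segmentation and relational rule engine
#'
#' A `zone_map` is segmented into reef objects (4-connected regions of one
#' class); objects are related by adjacency (8-connectivity across class
#' boundaries) and enclosure (an object is enclosed by another when every
#' 4-connected path from it to the grid edge crosses that object). Observed
#' relations are checked against the scheme's relational rules, and `never`
#' -level violations are repaired deterministically by merging the smaller
#' object of each violating pair into a compatible neighbour.
#'
#' @name relational-engine
NULL

#' Segment a zone map into reef objects
#'
#' Connected-component labelling with 4-connectivity within each class.
#' Object ids are deterministic: objects are numbered by the raster scan rank
#' (row-major, top-left origin) of their first cell. Nodata regions are
#' carried as pseudo-objects (class `NA`) so that relational queries can route
#' paths through them, but they are not reef objects.
#'
#' @param zonemap A `zone_map`.
#' @return A `reef_segmentation`: list with `ids` (integer object-id grid),
#'   `objects` (data.frame: object_id, class_code, class_name, cell_count,
#'   touches_edge, is_nodata) and the source legend.
#' @export
segment_zones <- function(zonemap) {
  stopifnot(inherits(zonemap, "zone_map"))
  labels <- zonemap$labels
  nr <- nrow(labels); nc <- ncol(labels)
  vals <- labels
  vals[is.na(vals)] <- 0L  # sentinel class for nodata pseudo-objects

  # components of the "same label" relation over the full grid
  idx <- seq_len(nr * nc)
  edge_list <- list()
  for (off in half_offsets(4L)) {
    r <- pos_row(idx, nr); c <- pos_col(idx, nr)
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- idx[ok]
    j2 <- (c2[ok] - 1L) * nr + r2[ok]
    same <- vals[j] == vals[j2]
    if (any(same)) {
      edge_list[[length(edge_list) + 1L]] <- rbind(j[same], j2[same])
    }
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(edge_list)) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edge_list)))
  }
  memb <- igraph::components(g)$membership
  rk <- scan_rank(idx, nr, nc)
  first_rank <- tapply(rk, memb, min)
  new_id <- integer(length(first_rank))
  new_id[order(first_rank)] <- seq_along(first_rank)
  ids <- matrix(new_id[memb], nr, nc)

  n_obj <- max(ids)
  first_cell <- match(seq_len(n_obj), ids)
  class_code <- labels[first_cell]
  on_edge <- matrix(FALSE, nr, nc)
  on_edge[c(1L, nr), ] <- TRUE
  on_edge[, c(1L, nc)] <- TRUE
  objects <- data.frame(
    object_id = seq_len(n_obj),
    class_code = class_code,
    class_name = names(zonemap$legend)[match(class_code, zonemap$legend)],
    cell_count = tabulate(ids, n_obj),
    touches_edge = as.logical(tabulate(ids[on_edge], n_obj) > 0L),
    is_nodata = is.na(class_code),
    stringsAsFactors = FALSE
  )
  structure(list(ids = ids, objects = objects, legend = zonemap$legend),
            class = "reef_segmentation")
}

#' @export
print.reef_segmentation <- function(x, ...) {
  real <- x$objects[!x$objects$is_nodata, ]
  cat(sprintf("reef_segmentation: %d objects (%d classes), %d nodata regions\n",
              nrow(real), length(unique(real$class_name)),
              sum(x$objects$is_nodata)))
  invisible(x)
}

# Object-pair contacts for a set of offsets; returns data.frame(a, b, weight)
# with a < b, weight = number of adjacent cell pairs.
object_contacts <- function(ids, connectivity) {
  nr <- nrow(ids); nc <- ncol(ids)
  pos <- seq_len(nr * nc)
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (off in half_offsets(connectivity)) {
    r <- pos_row(pos, nr); c <- pos_col(pos, nr)
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- pos[ok]
    j2 <- (c2[ok] - 1L) * nr + r2[ok]
    diff <- ids[j] != ids[j2]
    pairs_a <- c(pairs_a, pmin(ids[j][diff], ids[j2][diff]))
    pairs_b <- c(pairs_b, pmax(ids[j][diff], ids[j2][diff]))
  }
  if (!length(pairs_a)) {
    return(data.frame(a = integer(0), b = integer(0), weight = integer(0)))
  }
  key <- paste(pairs_a, pairs_b)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  out <- data.frame(a = as.integer(vapply(parts, `[[`, "", 1L)),
                    b = as.integer(vapply(parts, `[[`, "", 2L)),
                    weight = as.integer(tab))
  out[order(out$a, out$b), , drop = FALSE]
}

#' Adjacency graph of reef objects
#'
#' Edges connect objects sharing at least one cell contact under
#' 8-connectivity; the edge weight counts the adjacent cell pairs. Edges
#' involving nodata pseudo-objects are dropped, so objects separated
#' everywhere by nodata are not neighbours.
#'
#' @param seg A [segment_zones()] result.
#' @return data.frame with columns `a`, `b` (object ids, `a < b`) and `weight`.
#' @export
adjacency_graph <- function(seg) {
  stopifnot(inherits(seg, "reef_segmentation"))
  edges <- object_contacts(seg$ids, 8L)
  nodata_ids <- seg$objects$object_id[seg$objects$is_nodata]
  edges[!(edges$a %in% nodata_ids | edges$b %in% nodata_ids), , drop = FALSE]
}

# 4-connected object graph with a virtual border vertex (id n_obj + 1),
# used for enclosure queries: cell paths correspond to walks on this graph.
object_graph4 <- function(seg) {
  n_obj <- nrow(seg$objects)
  contacts <- object_contacts(seg$ids, 4L)
  border_id <- n_obj + 1L
  border_edges <- seg$objects$object_id[seg$objects$touches_edge]
  el <- rbind(as.matrix(contacts[, c("a", "b")]),
              cbind(border_edges, rep(border_id, length(border_edges))))
  g <- igraph::make_empty_graph(n = border_id, directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, as.vector(t(el)))
  g
}

#' Enclosure relations between reef objects
#'
#' Object A is enclosed by object B when A does not touch the grid edge and
#' every 4-connected path from A to the edge crosses B. When several objects
#' enclose A (nested rings) the innermost — the encloser nearest to A in
#' 4-adjacency object hops — is reported. Computed by cut-vertex removal on
#' the object graph: removing B must disconnect A from the virtual border
#' vertex. Nodata regions can carry paths but never enclose.
#'
#' @param seg A [segment_zones()] result.
#' @return data.frame with columns `object_id` and `enclosed_by` (innermost
#'   enclosing object id, `NA` when not enclosed), one row per real object.
#' @export
enclosure_relations <- function(seg) {
  stopifnot(inherits(seg, "reef_segmentation"))
  objects <- seg$objects
  n_obj <- nrow(objects)
  g <- object_graph4(seg)
  border_id <- n_obj + 1L
  candidates_a <- which(!objects$touches_edge & !objects$is_nodata)
  enclosed_by <- rep(NA_integer_, n_obj)
  if (length(candidates_a)) {
    # only articulation vertices can disconnect anything
    arts <- as.integer(igraph::articulation_points(g))
    arts <- arts[arts <= n_obj & !objects$is_nodata[arts]]
    enclosers <- vector("list", n_obj)
    for (b in arts) {
      gb <- igraph::delete_vertices(g, b)
      memb <- igraph::components(gb)$membership
      # vertex ids shift after deletion: vertex v>b becomes v-1
      vid <- function(v) ifelse(v > b, v - 1L, v)
      border_comp <- memb[vid(border_id)]
      cut_off <- candidates_a[candidates_a != b &
                                memb[vid(candidates_a)] != border_comp]
      for (a in cut_off) enclosers[[a]] <- c(enclosers[[a]], b)
    }
    has <- which(vapply(enclosers, length, 0L) > 0L)
    if (length(has)) {
      dists <- igraph::distances(g, v = has,
                                 to = seq_len(n_obj))
      for (k in seq_along(has)) {
        a <- has[k]
        cand <- enclosers[[a]]
        enclosed_by[a] <- cand[which.min(dists[k, cand])]
      }
    }
  }
  data.frame(object_id = objects$object_id, enclosed_by = enclosed_by)[
    !objects$is_nodata, , drop = FALSE]
}

#' Build the full object graph of a zone map
#'
#' Convenience wrapper running segmentation, adjacency and enclosure in one
#' pass.
#'
#' @param zonemap A `zone_map`.
#' @return List with `seg`, `edges` (adjacency) and `enclosure`.
#' @export
build_object_graph <- function(zonemap) {
  seg <- segment_zones(zonemap)
  list(seg = seg, edges = adjacency_graph(seg),
       enclosure = enclosure_relations(seg))
}

#' Check observed relations against the scheme rules
#'
#' One violation is reported for every observed adjacency or (innermost)
#' enclosure whose rule level is `never`; `typical` and `sometimes` relations
#' pass. Same-class contacts (diagonally touching objects of one class) are
#' always compatible.
#'
#' @param graph A [build_object_graph()] result.
#' @param scheme A `reef_scheme`.
#' @return data.frame of violations: `kind`, `object_a`, `object_b`,
#'   `class_a`, `class_b`, `rule_level`, `boundary_cells`.
#' @export
check_rules <- function(graph, scheme) {
  seg <- graph$seg
  objects <- seg$objects
  map_classes <- unique(objects$class_name[!objects$is_nodata])
  unknown <- setdiff(map_classes, scheme$class_names)
  if (length(unknown)) {
    stop("classes in map missing from the scheme rules: ",
         paste(unknown, collapse = ", "))
  }
  empty <- data.frame(kind = character(0), object_a = integer(0),
                      object_b = integer(0), class_a = character(0),
                      class_b = character(0), rule_level = character(0),
                      boundary_cells = integer(0), stringsAsFactors = FALSE)
  rows <- list(empty)

  edges <- graph$edges
  if (nrow(edges)) {
    ca <- objects$class_name[edges$a]
    cb <- objects$class_name[edges$b]
    lev <- scheme$adjacency[cbind(ca, cb)]
    bad <- which(lev == "never" & ca != cb)
    if (length(bad)) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "adjacency", object_a = edges$a[bad], object_b = edges$b[bad],
        class_a = ca[bad], class_b = cb[bad], rule_level = "never",
        boundary_cells = edges$weight[bad], stringsAsFactors = FALSE)
    }
  }

  enc <- graph$enclosure
  enc <- enc[!is.na(enc$enclosed_by), , drop = FALSE]
  if (nrow(enc)) {
    ca <- objects$class_name[enc$object_id]
    cb <- objects$class_name[enc$enclosed_by]
    lev <- scheme$enclosure[cbind(ca, cb)]
    bad <- which(!is.na(lev) & lev == "never")
    if (length(bad)) {
      w <- integer(length(bad))
      for (k in seq_along(bad)) {
        e <- graph$edges
        hit <- (e$a == pmin(enc$object_id[bad[k]], enc$enclosed_by[bad[k]])) &
               (e$b == pmax(enc$object_id[bad[k]], enc$enclosed_by[bad[k]]))
        w[k] <- if (any(hit)) e$weight[hit][1] else 0L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "enclosure", object_a = enc$object_id[bad],
        object_b = enc$enclosed_by[bad], class_a = ca[bad], class_b = cb[bad],
        rule_level = "never", boundary_cells = w, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$object_a, out$object_b), , drop = FALSE]
}

#' Validate a zone map against the relational rules
#'
#' @param zonemap A `zone_map`.
#' @param scheme A `reef_scheme`.
#' @return List with the object `graph` and the `violations` data.frame.
#' @export
validate_zones <- function(zonemap, scheme = load_scheme()) {
  graph <- build_object_graph(zonemap)
  list(graph = graph, violations = check_rules(graph, scheme))
}

#' Repair rule violations and sub-MMU objects
#'
#' Iteratively reassigns, in deterministic order (ascending cell count, then
#' ascending object id), the smaller object of every `never`-level violating
#' pair — plus any object below the minimum mapping unit — to the class of its
#' largest-boundary neighbour whose relations to the object's remaining
#' neighbours are not `never`. Each pass re-segments; the loop stops when no
#' candidates remain, when a pass changes nothing, or at the oscillation guard
#' (initial object count), in which case unresolved objects are reported as
#' irreparable rather than silently kept.
#'
#' Repair never touches nodata cells and never introduces a class absent from
#' the map, and is idempotent: repairing a repaired map changes nothing.
#'
#' @param zonemap A `zone_map`.
#' @param scheme A `reef_scheme`.
#' @param config A [threshold_config()] (for the minimum mapping unit);
#'   defaults to the map's own configuration.
#' @return List: `zonemap` (repaired), `report` (data.frame of reassignments),
#'   `irreparable` (data.frame), `passes`, `converged`.
#' @export
repair_zones <- function(zonemap, scheme = load_scheme(), config = NULL) {
  stopifnot(inherits(zonemap, "zone_map"))
  if (is.null(config)) config <- zonemap$config_used
  if (is.null(config)) config <- threshold_config()
  labels <- zonemap$labels
  legend <- zonemap$legend
  report <- list()
  irreparable <- list()
  graph <- build_object_graph(zonemap)
  max_pass <- max(2L, sum(!graph$seg$objects$is_nodata))
  pass <- 0L
  converged <- FALSE

  repeat {
    pass <- pass + 1L
    if (pass > 1L) {
      zonemap$labels <- labels
      graph <- build_object_graph(zonemap)
    }
    objects <- graph$seg$objects
    violations <- check_rules(graph, scheme)
    n_real <- sum(!objects$is_nodata)

    victims <- integer(0)
    if (nrow(violations)) {
      smaller <- ifelse(
        objects$cell_count[violations$object_a] <
          objects$cell_count[violations$object_b], violations$object_a,
        ifelse(objects$cell_count[violations$object_b] <
                 objects$cell_count[violations$object_a], violations$object_b,
               pmin(violations$object_a, violations$object_b)))
      victims <- smaller
    }
    if (n_real > 1L) {
      tiny <- objects$object_id[!objects$is_nodata &
                                  objects$cell_count < config$min_mapping_unit]
      victims <- c(victims, tiny)
    }
    victims <- sort(unique(victims))
    if (!length(victims)) {
      converged <- TRUE
      break
    }
    if (pass > max_pass) break
    ord <- order(objects$cell_count[victims], victims)
    victims <- victims[ord]

    edges <- graph$edges
    changed <- FALSE
    irreparable <- list()  # object ids are per-pass; keep only the last state
    for (v in victims) {
      v_class <- objects$class_name[v]
      nb_rows <- edges[edges$a == v | edges$b == v, , drop = FALSE]
      if (!nrow(nb_rows)) next
      nb_id <- ifelse(nb_rows$a == v, nb_rows$b, nb_rows$a)
      nb_class <- objects$class_name[nb_id]
      keep <- nb_class != v_class
      nb_id <- nb_id[keep]; nb_class <- nb_class[keep]
      w <- nb_rows$weight[keep]
      if (!length(nb_id)) next
      cand <- tapply(w, nb_class, sum)
      cand <- cand[order(-cand, names(cand))]  # boundary weight, then name
      chosen <- NA_character_
      for (cl in names(cand)) {
        others <- unique(nb_class[nb_class != cl])
        if (!length(others) ||
            all(scheme$adjacency[cbind(rep(cl, length(others)), others)] !=
                  "never")) {
          chosen <- cl
          break
        }
      }
      if (is.na(chosen)) {
        irreparable[[length(irreparable) + 1L]] <- data.frame(
          object_id = v, class_name = v_class,
          cell_count = objects$cell_count[v], pass = pass,
          stringsAsFactors = FALSE)
        next
      }
      labels[graph$seg$ids == v] <- legend[[chosen]]
      report[[length(report) + 1L]] <- data.frame(
        pass = pass, object_id = v, class_from = v_class, class_to = chosen,
        cell_count = objects$cell_count[v], stringsAsFactors = FALSE)
      changed <- TRUE
    }
    if (!changed) break
  }

  zonemap$labels <- labels
  final <- validate_zones(zonemap, scheme)
  list(
    zonemap = zonemap,
    report = if (length(report)) do.call(rbind, report) else
      data.frame(pass = integer(0), object_id = integer(0),
                 class_from = character(0), class_to = character(0),
                 cell_count = integer(0), stringsAsFactors = FALSE),
    irreparable = if (length(irreparable)) do.call(rbind, irreparable) else
      data.frame(object_id = integer(0), class_name = character(0),
                 cell_count = integer(0), pass = integer(0),
                 stringsAsFactors = FALSE),
    passes = pass,
    converged = converged,
    remaining_violations = final$violations
  )
}
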