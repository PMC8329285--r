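#' Reef Cover scheme registry
#'
#' The Reef Cover typology is shipped as a single human-editable YAML document
#' containing the 17 internal reef classes, the two non-reef context classes
#' (Deep Water, Land), their attribute memberships (depth, slope, exposure,
#' substrate, colour categories), the relational adjacency/enclosure rules and
#' the two case-study crosswalks. `load_scheme()` parses and validates it into
#' a `reef_scheme` object used throughout the package.
#'
#' @name scheme-registry
NULL

RULE_LEVELS <- c("never", "sometimes", "typical")
NOT_USED <- "NOT_USED"

DEPTH_CATEGORIES <- c("supratidal", "intertidal", "subtidal-shallow",
                      "subtidal-mid", "subtidal-deep")
SLOPE_CATEGORIES <- c("horizontal", "shallow", "steep", "vertical")
EXPOSURE_CATEGORIES <- c("exposed", "average", "sheltered")
SUBSTRATE_CATEGORIES <- c("hard", "mixed", "soft")
COLOUR_CATEGORIES <- c("bright", "medium", "darker")
CLASS_GROUPS <- c("Fore Reef", "Reef Crest", "Reef Flat", "Back Reef",
                  "Other", "Not Reef")

#' Path of the packaged Reef Cover scheme file
#'
#' @return Path to the YAML scheme document installed with the package.
#' @export
reef_scheme_file <- function() {
  system.file("extdata", "reef_cover_scheme.yaml", package = "reefzoner",
              mustWork = TRUE)
}

#' Load and validate a Reef Cover scheme
#'
#' Parses the packaged typology (or a user file in the same format) and
#' validates every structural invariant: exactly 17 reef classes and 2 context
#' classes, unique names, at least one depth/slope/exposure category per reef
#' class, symmetric adjacency rules over all 19 classes, directional enclosure
#' rules, and complete crosswalk coverage. Loading is idempotent and
#' order-stable.
#'
#' @param source Path to a scheme YAML file, or `NULL` for the packaged scheme.
#' @return A validated `reef_scheme` object.
#' @export
load_scheme <- function(source = NULL) {
  path <- if (is.null(source)) reef_scheme_file() else source
  doc <- yaml::read_yaml(path)
  scheme <- build_scheme(doc)
  issues <- validate_scheme(scheme)
  if (length(issues)) {
    stop("invalid scheme '", path, "':\n  ", paste(issues, collapse = "\n  "))
  }
  scheme
}

# Assemble a reef_scheme from the parsed YAML document, raising schema errors
# for structurally unusable input (unknown names, malformed levels).
build_scheme <- function(doc) {
  for (field in c("version", "classes", "context_classes", "adjacency",
                  "enclosure", "crosswalks")) {
    if (is.null(doc[[field]])) stop("scheme document lacks field '", field, "'")
  }
  classes <- lapply(doc$classes, normalise_class)
  context <- lapply(doc$context_classes, normalise_class)
  reef_names <- vapply(classes, `[[`, "", "standard_name")
  context_names <- vapply(context, `[[`, "", "standard_name")
  all_names <- c(reef_names, context_names)
  if (anyDuplicated(all_names)) {
    stop("duplicate class name: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  }
  if (length(reef_names) != 17L) {
    stop("expected 17 reef classes, found ", length(reef_names))
  }

  check_rule_entries <- function(entries, kind) {
    for (e in entries) {
      if (length(e) != 3L) {
        stop(kind, " rule entry must be [a, b, level]: ",
             paste(unlist(e), collapse = ", "))
      }
      if (!e[[3]] %in% RULE_LEVELS) {
        stop("malformed rule level '", e[[3]], "' in ", kind, " entry ",
             e[[1]], " / ", e[[2]])
      }
      for (nm in c(e[[1]], e[[2]])) {
        if (!nm %in% all_names) {
          stop("unknown class '", nm, "' in ", kind, " rules")
        }
      }
    }
  }
  check_rule_entries(doc$adjacency, "adjacency")
  check_rule_entries(doc$enclosure, "enclosure")

  n <- length(all_names)
  adjacency <- matrix("never", n, n, dimnames = list(all_names, all_names))
  diag(adjacency) <- "typical"  # objects of one class are always compatible
  for (e in doc$adjacency) {
    adjacency[e[[1]], e[[2]]] <- e[[3]]
    adjacency[e[[2]], e[[1]]] <- e[[3]]
  }
  enclosure <- matrix("never", n, n, dimnames = list(all_names, all_names))
  diag(enclosure) <- NA_character_  # self-enclosure undefined
  for (e in doc$enclosure) {
    if (e[[1]] == e[[2]]) stop("self-enclosure entry for ", e[[1]])
    enclosure[e[[1]], e[[2]]] <- e[[3]]
  }

  crosswalks <- list()
  for (cw in doc$crosswalks) {
    if (is.null(cw$scheme_name)) stop("crosswalk lacks scheme_name")
    mapping <- vapply(cw$mapping, as.character, "")
    crosswalks[[cw$scheme_name]] <- list(
      scheme_name = cw$scheme_name,
      mapping = mapping,
      extra_classes = as.character(unlist(cw$extra_classes)),
      confidence = cw$confidence
    )
  }

  structure(list(
    version = as.character(doc$version),
    reef_classes = classes,
    context_classes = context,
    reef_class_names = reef_names,
    context_class_names = context_names,
    class_names = all_names,
    adjacency = adjacency,
    enclosure = enclosure,
    crosswalks = crosswalks,
    glossary = doc$glossary
  ), class = "reef_scheme")
}

normalise_class <- function(cl) {
  for (field in c("standard_name", "standard_label", "description", "group")) {
    if (is.null(cl[[field]])) {
      stop("class entry lacks field '", field, "': ",
           paste(unlist(cl["standard_name"]), collapse = ""))
    }
  }
  list(
    standard_name = cl$standard_name,
    standard_label = cl$standard_label,
    description = cl$description,
    group = cl$group,
    depth = as.character(unlist(cl$depth)),
    slope = as.character(unlist(cl$slope)),
    exposure = as.character(unlist(cl$exposure)),
    substrate = as.character(unlist(cl$substrate)),
    colour = as.character(unlist(cl$colour)),
    synonyms = as.character(unlist(cl$synonyms))
  )
}

#' Validate a Reef Cover scheme
#'
#' Checks every type invariant and returns issues as a character vector (empty
#' when the scheme is valid). Unlike [load_scheme()], nothing is raised, so a
#' deliberately broken scheme can be inspected.
#'
#' @param scheme A `reef_scheme` object.
#' @return Character vector of human-readable issues; `character(0)` if valid.
#' @export
validate_scheme <- function(scheme) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)

  if (length(scheme$reef_classes) != 17L) {
    add(sprintf("expected 17 reef classes, found %d", length(scheme$reef_classes)))
  }
  if (length(scheme$context_classes) != 2L) {
    add(sprintf("expected 2 context classes, found %d", length(scheme$context_classes)))
  }
  if (anyDuplicated(scheme$class_names)) {
    add(paste("duplicate class names:",
              paste(unique(scheme$class_names[duplicated(scheme$class_names)]),
                    collapse = ", ")))
  }
  for (cl in scheme$reef_classes) {
    for (attr in c("depth", "slope", "exposure")) {
      if (!length(cl[[attr]])) {
        add(sprintf("reef class '%s' has no %s category", cl$standard_name, attr))
      }
    }
  }
  cats <- list(depth = DEPTH_CATEGORIES, slope = SLOPE_CATEGORIES,
               exposure = EXPOSURE_CATEGORIES, substrate = SUBSTRATE_CATEGORIES,
               colour = COLOUR_CATEGORIES)
  for (cl in c(scheme$reef_classes, scheme$context_classes)) {
    if (!cl$group %in% CLASS_GROUPS) {
      add(sprintf("class '%s' has unknown group '%s'", cl$standard_name, cl$group))
    }
    for (attr in names(cats)) {
      bad <- setdiff(cl[[attr]], cats[[attr]])
      if (length(bad)) {
        add(sprintf("class '%s' has unknown %s categories: %s",
                    cl$standard_name, attr, paste(bad, collapse = ", ")))
      }
    }
  }

  n <- length(scheme$class_names)
  for (mat_name in c("adjacency", "enclosure")) {
    m <- scheme[[mat_name]]
    if (!is.matrix(m) || any(dim(m) != n) ||
        !identical(rownames(m), scheme$class_names) ||
        !identical(colnames(m), scheme$class_names)) {
      add(sprintf("%s rules do not cover all %d classes", mat_name, n))
      next
    }
    off_diag <- m[row(m) != col(m)]
    bad <- setdiff(unique(off_diag), RULE_LEVELS)
    if (length(bad)) {
      add(sprintf("%s rules contain malformed levels: %s", mat_name,
                  paste(bad, collapse = ", ")))
    }
  }
  adj <- scheme$adjacency
  if (is.matrix(adj) && all(dim(adj) == n)) {
    asym <- which(adj != t(adj), arr.ind = TRUE)
    asym <- asym[asym[, 1] < asym[, 2], , drop = FALSE]
    for (k in seq_len(nrow(asym))) {
      add(sprintf("adjacency asymmetry: (%s, %s) is '%s' but (%s, %s) is '%s'",
                  rownames(adj)[asym[k, 1]], colnames(adj)[asym[k, 2]],
                  adj[asym[k, 1], asym[k, 2]],
                  colnames(adj)[asym[k, 2]], rownames(adj)[asym[k, 1]],
                  adj[asym[k, 2], asym[k, 1]]))
    }
  }
  enc <- scheme$enclosure
  if (is.matrix(enc) && all(dim(enc) == n) && !all(is.na(diag(enc)))) {
    add("enclosure diagonal must be undefined (self-enclosure disallowed)")
  }

  for (cw in scheme$crosswalks) {
    keys <- names(cw$mapping)
    missing <- setdiff(scheme$reef_class_names, keys)
    if (length(missing)) {
      add(sprintf("crosswalk '%s' misses reef classes: %s", cw$scheme_name,
                  paste(missing, collapse = ", ")))
    }
    extra <- setdiff(keys, scheme$reef_class_names)
    if (length(extra)) {
      add(sprintf("crosswalk '%s' maps unknown classes: %s", cw$scheme_name,
                  paste(extra, collapse = ", ")))
    }
    if (anyDuplicated(keys)) {
      add(sprintf("crosswalk '%s' has duplicate keys", cw$scheme_name))
    }
    used <- cw$mapping[cw$mapping != NOT_USED]
    if (anyDuplicated(used)) {
      add(sprintf("crosswalk '%s' has duplicate target labels: %s",
                  cw$scheme_name,
                  paste(unique(used[duplicated(used)]), collapse = ", ")))
    }
  }
  issues
}

#' Write a scheme back to its YAML document form
#'
#' Serialises a `reef_scheme` so that [load_scheme()] on the result returns an
#' identical object (round-trip stability).
#'
#' @param scheme A `reef_scheme` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  pair_entries <- function(m, symmetric) {
    entries <- list()
    nms <- rownames(m)
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        if (i == j) next
        if (symmetric && j < i) next
        lv <- m[i, j]
        if (!is.na(lv) && lv != "never") {
          entries[[length(entries) + 1L]] <- list(nms[i], nms[j], lv)
        }
      }
    }
    entries
  }
  strip_empty <- function(cl) {
    cl[vapply(cl, length, 0L) > 0L]
  }
  doc <- list(
    version = scheme$version,
    classes = lapply(scheme$reef_classes, strip_empty),
    context_classes = lapply(scheme$context_classes, strip_empty),
    adjacency = pair_entries(scheme$adjacency, symmetric = TRUE),
    enclosure = pair_entries(scheme$enclosure, symmetric = FALSE),
    crosswalks = unname(lapply(scheme$crosswalks, function(cw) {
      out <- list(scheme_name = cw$scheme_name, mapping = as.list(cw$mapping),
                  extra_classes = cw$extra_classes)
      if (!is.null(cw$confidence)) out$confidence <- cw$confidence
      out
    })),
    glossary = scheme$glossary
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Query a relational rule level
#'
#' Returns the rule level (`never`, `sometimes` or `typical`) for a pair of
#' classes. Adjacency is symmetric in its arguments; enclosure is directional
#' with `a` the inner (enclosed) class and `b` the outer (enclosing) class.
#' Pairs without an explicit entry in the scheme are `never` ("not usually
#' neighbours / enclosed by").
#'
#' @param scheme A `reef_scheme`.
#' @param kind `"adjacency"` or `"enclosure"`.
#' @param a,b Class standard names.
#' @return One of `"never"`, `"sometimes"`, `"typical"`.
#' @export
relational_rule <- function(scheme, kind = c("adjacency", "enclosure"), a, b) {
  kind <- match.arg(kind)
  for (nm in c(a, b)) {
    if (!nm %in% scheme$class_names) stop("unknown class name '", nm, "'")
  }
  if (kind == "enclosure" && a == b) {
    stop("self-enclosure is undefined ('", a, "')")
  }
  scheme[[kind]][a, b]
}

#' Look up a crosswalk label
#'
#' Translates a Reef Cover class into the label used by one of the case-study
#' map legends, or the sentinel `"NOT_USED"` when the class was not mapped in
#' that exercise.
#'
#' @param scheme A `reef_scheme`.
#' @param table Crosswalk name (`"case_study_1_gbr"` or `"case_study_2_aca"`).
#' @param reef_cover_class Reef Cover class standard name.
#' @return The target label, or `"NOT_USED"`.
#' @export
crosswalk_label <- function(scheme, table, reef_cover_class) {
  cw <- scheme$crosswalks[[table]]
  if (is.null(cw)) {
    stop("unknown crosswalk table '", table, "' (available: ",
         paste(names(scheme$crosswalks), collapse = ", "), ")")
  }
  if (!reef_cover_class %in% names(cw$mapping)) {
    stop("unknown reef class '", reef_cover_class, "'")
  }
  unname(cw$mapping[reef_cover_class])
}

# Canonical integer legend: reef classes 1..17 in scheme order, then context.
scheme_legend <- function(scheme) {
  stats::setNames(seq_along(scheme$class_names), scheme$class_names)
}

#' @export
print.reef_scheme <- function(x, ...) {
  cat("Reef Cover scheme v", x$version, "\n", sep = "")
  cat("  reef classes:   ", length(x$reef_classes), "\n")
  cat("  context classes:", paste(x$context_class_names, collapse = ", "), "\n")
  for (cw in x$crosswalks) {
    used <- sum(cw$mapping != NOT_USED)
    cat(sprintf("  crosswalk %s: %d used, %d extra\n", cw$scheme_name, used,
                length(cw$extra_classes)))
  }
  invisible(x)
}
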