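#' Areal-extent summaries, crosswalked summaries and accuracy assessment
#'
#' @name reporting-evaluation
NULL

#' Areal extent per class
#'
#' Cell counts, areas and percentages per mapped class. Percentages are of the
#' mapped reef area: the Deep Water and Land context classes are excluded from
#' the denominator (and get `NA` percentages). Area is
#' `cell_count * cell_size^2 * 1e-6` square kilometres.
#'
#' @param zonemap A `zone_map`.
#' @param cell_size Cell side in metres; defaults to the map's own.
#' @return A data.frame (`class_name`, `cell_count`, `area_km2`, `percent`,
#'   `is_context`) with attributes `total_reef_area_km2` and `no_reef`.
#' @export
extent_summary <- function(zonemap, cell_size = NULL) {
  stopifnot(inherits(zonemap, "zone_map"))
  if (is.null(cell_size)) cell_size <- zonemap$cell_size
  if (is.null(cell_size) || !isTRUE(cell_size > 0)) {
    stop("cell_size must be positive")
  }
  legend <- zonemap$legend
  counts <- table(factor(zonemap$labels, levels = legend,
                         labels = names(legend)))
  counts <- counts[counts > 0]
  context <- names(counts) %in% c("Deep Water", "Land")
  area <- as.numeric(counts) * cell_size^2 * 1e-6
  reef_total <- sum(area[!context])
  percent <- rep(NA_real_, length(counts))
  if (reef_total > 0) percent[!context] <- 100 * area[!context] / reef_total
  out <- data.frame(class_name = names(counts),
                    cell_count = as.integer(counts),
                    area_km2 = area, percent = percent, is_context = context,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$is_context * 1L, -out$area_km2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_reef_area_km2") <- reef_total
  attr(out, "cell_size") <- cell_size
  attr(out, "no_reef") <- reef_total == 0
  if (reef_total == 0) {
    warning("map has no reef cells; percentages undefined")
  }
  out
}

#' Confusion matrix between a predicted map and ground truth
#'
#' Counts are over cells that are data in both maps (nodata in either is
#' excluded), truth in rows and prediction in columns, over the shared legend.
#'
#' @param predicted A `zone_map`.
#' @param truth A `zone_map` (e.g. the generator's ground truth) of the same
#'   shape and legend universe.
#' @return List with `table` (square count matrix), `overall_accuracy`,
#'   `producer_accuracy` and `user_accuracy` (per class), and `n_cells`.
#' @export
confusion_matrix <- function(predicted, truth) {
  stopifnot(inherits(predicted, "zone_map"), inherits(truth, "zone_map"))
  if (!identical(dim(predicted$labels), dim(truth$labels))) {
    stop("predicted and truth maps differ in shape")
  }
  if (!identical(predicted$legend, truth$legend)) {
    stop("predicted and truth maps use different legends")
  }
  legend <- predicted$legend
  ok <- !is.na(predicted$labels) & !is.na(truth$labels)
  t_f <- factor(truth$labels[ok], levels = legend, labels = names(legend))
  p_f <- factor(predicted$labels[ok], levels = legend, labels = names(legend))
  tab <- table(truth = t_f, predicted = p_f)
  total <- sum(tab)
  overall <- if (total > 0) sum(diag(tab)) / total else NA_real_
  producer <- diag(tab) / rowSums(tab)
  user <- diag(tab) / colSums(tab)
  list(table = tab, overall_accuracy = overall,
       producer_accuracy = producer, user_accuracy = user, n_cells = total)
}

#' Crosswalk an extent summary to a case-study legend
#'
#' Renames used classes to their target labels (aggregating rows that share a
#' target), keeps classes the target scheme did not use under their Reef Cover
#' names with a `not_mapped` flag, and leaves context classes untouched. Areas
#' are conserved exactly.
#'
#' @param summary An [extent_summary()] result.
#' @param scheme A `reef_scheme`.
#' @param table Crosswalk name.
#' @return data.frame: `target_label`, `cell_count`, `area_km2`, `percent`,
#'   `is_context`, `not_mapped`.
#' @export
crosswalked_summary <- function(summary, scheme, table) {
  cw <- scheme$crosswalks[[table]]
  if (is.null(cw)) stop("unknown crosswalk table '", table, "'")
  target <- summary$class_name
  not_mapped <- rep(FALSE, nrow(summary))
  for (i in seq_len(nrow(summary))) {
    nm <- summary$class_name[i]
    if (summary$is_context[i] || !nm %in% names(cw$mapping)) next
    lab <- cw$mapping[[nm]]
    if (identical(lab, NOT_USED)) {
      not_mapped[i] <- TRUE
    } else {
      target[i] <- lab
    }
  }
  agg <- stats::aggregate(
    cbind(cell_count, area_km2) ~ target_label + is_context + not_mapped,
    data = data.frame(target_label = target, cell_count = summary$cell_count,
                      area_km2 = summary$area_km2,
                      is_context = summary$is_context, not_mapped = not_mapped,
                      stringsAsFactors = FALSE),
    FUN = sum)
  reef_total <- sum(agg$area_km2[!agg$is_context])
  agg$percent <- ifelse(agg$is_context | reef_total == 0, NA_real_,
                        100 * agg$area_km2 / reef_total)
  agg <- agg[order(-agg$is_context * 1L, -agg$area_km2), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "total_reef_area_km2") <- reef_total
  agg
}
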