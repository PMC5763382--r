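## Bin quality from conserved single-copy gene (CSCG) hits.
##
## Completeness and contamination are the two quotients over a fixed
## 139-marker universe:
##   completeness  = 100 * (distinct markers detected) / (total markers)
##   contamination = 100 * (markers detected in > 1 copy) / (markers detected)
## Marker detection itself (an HMM search) is upstream of this package; the
## module consumes hit tables with realized copy counts.

validate_marker_hits <- function(hits, markers = marker_ids()) {
  req <- c("bin", "marker_id", "copy_count")
  if (!all(req %in% names(hits))) {
    stop_chemobin("hit table needs columns ", paste(req, collapse = ", "),
                  class = "chemobin_invalid_spec")
  }
  unknown <- setdiff(unique(hits$marker_id), markers)
  if (length(unknown) > 0) {
    stop_chemobin("unknown marker id(s): ",
                  paste(utils::head(unknown, 5), collapse = ", "),
                  class = "chemobin_unknown_marker")
  }
  if (any(hits$copy_count < 1) || any(hits$copy_count != round(hits$copy_count))) {
    stop_chemobin("copy_count must be an integer >= 1",
                  class = "chemobin_invalid_spec")
  }
  if (anyDuplicated(hits[, c("bin", "marker_id")])) {
    stop_chemobin("(bin, marker_id) pairs must be unique",
                  class = "chemobin_invalid_spec")
  }
  invisible(hits)
}

#' Bin completeness from marker hits
#'
#' Percentage of the marker universe detected in the bin (each marker counts
#' once no matter how many copies), reported to one decimal (half-up).
#'
#' @param hits Hit table for one bin (columns `bin`, `marker_id`,
#'   `copy_count`), or a character vector of detected marker ids.
#' @param total_markers Size of the marker universe (default 139).
#' @param markers Valid marker identifiers.
#' @return Completeness in percent, 1 decimal.
#' @examples
#' completeness(marker_ids()[1:118])   # 84.9
#' @export
completeness <- function(hits, total_markers = 139, markers = marker_ids()) {
  if (total_markers <= 0) {
    stop_chemobin("total_markers must be > 0", class = "chemobin_invalid_spec")
  }
  detected <- if (is.character(hits)) unique(hits) else {
    validate_marker_hits(hits, markers)
    unique(hits$marker_id)
  }
  unknown <- setdiff(detected, markers)
  if (length(unknown) > 0) {
    stop_chemobin("unknown marker id(s): ", paste(unknown, collapse = ", "),
                  class = "chemobin_unknown_marker")
  }
  round_half_up(100 * length(detected) / total_markers, 1)
}

#' Bin contamination from marker hits
#'
#' Percentage of detected markers present in more than one copy, reported to
#' one decimal (half-up).  Undefined when no marker was detected: returns
#' `NA` (flagged missing), never 0.
#'
#' @param hits Hit table for one bin (columns `bin`, `marker_id`,
#'   `copy_count`).
#' @param markers Valid marker identifiers.
#' @return Contamination in percent (1 decimal), or `NA_real_`.
#' @export
contamination <- function(hits, markers = marker_ids()) {
  validate_marker_hits(hits, markers)
  n_detected <- length(unique(hits$marker_id))
  if (n_detected == 0) return(NA_real_)
  n_multi <- sum(hits$copy_count > 1)
  round_half_up(100 * n_multi / n_detected, 1)
}

#' Quality report over all bins
#'
#' One row per bin with the detected-marker count, multi-copy count, and the
#' two quality percentages.  Bins listed in `bins` but absent from the hit
#' table are reported with completeness 0 and contamination `NA`.
#'
#' @param hit_table Hit table (columns `bin`, `marker_id`, `copy_count`).
#' @param bins Optional character vector of bins to report (default: bins
#'   present in the table).
#' @param total_markers Size of the marker universe.
#' @param markers Valid marker identifiers.
#' @return Data frame: bin, n_detected, n_multicopy, completeness,
#'   contamination.
#' @export
quality_report <- function(hit_table, bins = NULL, total_markers = 139,
                           markers = marker_ids()) {
  if (nrow(hit_table) == 0 && is.null(bins)) {
    return(data.frame(bin = character(), n_detected = integer(),
                      n_multicopy = integer(), completeness = numeric(),
                      contamination = numeric(), stringsAsFactors = FALSE))
  }
  validate_marker_hits(hit_table, markers)
  if (is.null(bins)) bins <- sort(unique(hit_table$bin))
  rows <- lapply(bins, function(b) {
    h <- hit_table[hit_table$bin == b, , drop = FALSE]
    data.frame(bin = b,
               n_detected = length(unique(h$marker_id)),
               n_multicopy = sum(h$copy_count > 1),
               completeness = round_half_up(
                 100 * length(unique(h$marker_id)) / total_markers, 1),
               contamination = if (nrow(h) == 0) NA_real_ else contamination(h, markers),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
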