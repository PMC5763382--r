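## Coverage-based relative bin abundance.
##
## Read-mapping summaries are filtered (minimum identity 0.98, maximum read
## length 500 bp - the defaults of the mapping step this emulates), summed
## into per-bin mean coverage (aligned bases / bin size), and normalized to
## relative abundances over the assigned bins.

#' Filter a read-mapping table
#'
#' Drops rows below the identity threshold or above the read-length cap.
#' `max_read_length` plays the role of a maximum accepted read length in the
#' upstream mapper; here it is applied to the aligned length column.
#'
#' @param readmap Data frame with columns `read_id`, `contig_id`,
#'   `aligned_length` (bp), `identity` (fraction in \[0, 1\]).
#' @param min_identity Minimum identity fraction kept (default 0.98).
#' @param max_read_length Maximum aligned length kept, bp (default 500).
#' @return The filtered table; attribute `n_removed` gives the counts of
#'   rows dropped by each rule (also reported via `message()`).
#' @export
filter_mappings <- function(readmap, min_identity = 0.98,
                            max_read_length = 500) {
  if (min_identity < 0 || min_identity > 1 || max_read_length < 1) {
    stop_chemobin("thresholds out of range", class = "chemobin_invalid_spec")
  }
  if (nrow(readmap) == 0) {
    attr(readmap, "n_removed") <- c(low_identity = 0L, too_long = 0L)
    return(readmap)
  }
  low_id <- readmap$identity < min_identity
  too_long <- readmap$aligned_length > max_read_length
  out <- readmap[!(low_id | too_long), , drop = FALSE]
  rownames(out) <- NULL
  removed <- c(low_identity = sum(low_id), too_long = sum(too_long & !low_id))
  if (sum(removed) > 0) {
    message("filter_mappings: removed ", removed[["low_identity"]],
            " low-identity and ", removed[["too_long"]], " over-length rows")
  }
  attr(out, "n_removed") <- removed
  out
}

#' Mean coverage per bin
#'
#' coverage(bin) = (sum of aligned bases over reads mapped to the bin's
#' contigs) / (bin size in bp).  Aligned bases rather than read counts are
#' summed so unequal read lengths contribute proportionally.
#'
#' @param readmap (Filtered) read-mapping table.
#' @param assignment Data frame `contig_id`, `bin`; every mapped contig must
#'   appear.  Reads on `"unassigned"` contigs are excluded and reported.
#' @param bin_sizes Named numeric, bin -> size in bp.
#' @return Named numeric vector of mean coverages, one per bin in
#'   `bin_sizes` (0 where no reads mapped).
#' @export
bin_coverage <- function(readmap, assignment, bin_sizes) {
  bin_of <- setNames(assignment$bin, assignment$contig_id)
  orphan <- setdiff(unique(readmap$contig_id), names(bin_of))
  if (length(orphan) > 0) {
    stop_chemobin("contig(s) missing from assignment: ",
                  paste(utils::head(orphan, 5), collapse = ", "),
                  class = "chemobin_orphan_contig")
  }
  rb <- bin_of[readmap$contig_id]
  drop <- rb == "unassigned"
  if (any(drop)) {
    message("bin_coverage: ", sum(drop),
            " read(s) on unassigned contigs excluded")
  }
  bases <- tapply(readmap$aligned_length[!drop], rb[!drop], sum)
  cov <- setNames(numeric(length(bin_sizes)), names(bin_sizes))
  hit <- intersect(names(bases), names(cov))
  cov[hit] <- as.numeric(bases[hit]) / bin_sizes[hit]
  cov
}

#' Relative abundance profile from bin coverages
#'
#' abundance(bin) = coverage(bin) / sum of coverages; the profile sums to 1
#' over the assigned bins.
#'
#' @param coverages Named numeric vector of mean coverages (>= 0, at least
#'   one positive).
#' @param sample Optional sample label attached to the result.
#' @return Data frame: sample, bin, abundance.
#' @examples
#' relative_abundance(c(bin_1 = 1, bin_2 = 2))
#' @export
relative_abundance <- function(coverages, sample = "sample_1") {
  if (any(coverages < 0)) {
    stop_chemobin("coverages must be >= 0", class = "chemobin_invalid_spec")
  }
  total <- sum(coverages)
  if (length(coverages) == 0 || total <= 0) {
    stop_chemobin("no bin has positive coverage", class = "chemobin_no_signal")
  }
  data.frame(sample = sample, bin = names(coverages),
             abundance = as.numeric(coverages) / total,
             stringsAsFactors = FALSE, row.names = NULL)
}
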