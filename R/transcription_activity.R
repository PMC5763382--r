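## Per-gene relative transcriptional activity.
##
## For gene g in bin B and one sample:
##
##   activity(g) = (r_g / L_g) / (R_B / L_B)
##
## with r_g the mapped reads of g, L_g its coding length, and R_B, L_B the
## read and length totals over the bin's coding genes.  The quotient makes
## the length-weighted mean activity of every bin exactly 1 in every sample,
## so activities are comparable within and between bins and treatments.
## Non-coding features take no part in either the numerator set or the bin
## totals.

#' Relative transcriptional activity per gene
#'
#' @param counts Integer matrix, genes x samples (mapped read counts);
#'   rownames are gene ids.
#' @param genes Gene metadata with columns `gene_id`, `length` (coding
#'   length, bp), `bin`, and optionally `is_coding` (default all `TRUE`).
#' @return Numeric matrix of activities, same shape as `counts`.  Non-coding
#'   genes are `NA`.  For a (bin, sample) with zero mapped coding reads every
#'   activity in that bin/sample is `NA` (flagged missing, not 0).
#' @examples
#' counts <- matrix(c(10, 10), 2, 1,
#'                  dimnames = list(c("g1", "g2"), "s1"))
#' genes <- data.frame(gene_id = c("g1", "g2"), length = c(100, 300),
#'                     bin = "bin_1")
#' gene_activity(counts, genes)    # 2.0 and 0.667
#' @export
gene_activity <- function(counts, genes) {
  req <- c("gene_id", "length", "bin")
  if (!all(req %in% names(genes))) {
    stop_chemobin("genes must have columns ", paste(req, collapse = ", "),
                  class = "chemobin_invalid_spec")
  }
  if (is.null(rownames(counts)) ||
      !all(rownames(counts) %in% genes$gene_id)) {
    stop_chemobin("every counted gene needs a metadata row",
                  class = "chemobin_invalid_spec")
  }
  if (any(counts < 0)) {
    stop_chemobin("counts must be >= 0", class = "chemobin_invalid_spec")
  }
  meta <- genes[match(rownames(counts), genes$gene_id), ]
  if (any(meta$length < 1)) {
    stop_chemobin("gene lengths must be >= 1", class = "chemobin_invalid_spec")
  }
  coding <- if ("is_coding" %in% names(meta)) meta$is_coding else
    rep(TRUE, nrow(meta))
  act <- matrix(NA_real_, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (b in unique(meta$bin[coding])) {
    sel <- coding & meta$bin == b
    if (!any(sel)) next
    L <- meta$length[sel]
    L_bin <- sum(L)
    for (s in seq_len(ncol(counts))) {
      R_bin <- sum(counts[sel, s])
      if (R_bin == 0) next            # flagged missing for the whole bin/sample
      act[sel, s] <- (counts[sel, s] / L) / (R_bin / L_bin)
    }
  }
  act
}

#' Cap activities for display
#'
#' Values above the cap are shown as the cap with a ">=" flag; the
#' underlying table is not modified.  Idempotent.
#'
#' @param activity Numeric vector or matrix of activities.
#' @param cap Display ceiling (> 0, default 3.0).
#' @return List with `values` (capped copy) and `capped` (logical, `TRUE`
#'   where the original exceeded the cap, to be rendered as ">= cap").
#' @export
cap_for_display <- function(activity, cap = 3.0) {
  if (cap <= 0) stop_chemobin("cap must be > 0", class = "chemobin_invalid_spec")
  flag <- !is.na(activity) & activity > cap
  list(values = pmin(activity, cap), capped = flag)
}

#' Log2 treatment-response ratio
#'
#' `log2((after + eps) / (before + eps))` for paired activities from the
#' same culture: +1 means transcription doubled after the treatment, -2 a
#' fourfold decrease.  The pseudocount is applied per pair only where a zero
#' is present (`eps = 0` whenever both sides are positive, so the ratio of
#' positive activities is untouched); pairs with both sides zero are `NA`.
#'
#' @param after,before Numeric vectors or matrices of activities (same
#'   shape).
#' @param pseudocount Offset used when a side is zero (default 0.5).
#' @return Log2 ratios, same shape as the inputs.
#' @examples
#' log2_response(2, 1)      #  1
#' log2_response(0.25, 1)   # -2
#' @export
log2_response <- function(after, before, pseudocount = 0.5) {
  if (length(after) != length(before)) {
    stop_chemobin("after and before must be paired (same shape)",
                  class = "chemobin_invalid_spec")
  }
  if (any(c(after, before) < 0, na.rm = TRUE)) {
    stop_chemobin("activities must be >= 0", class = "chemobin_invalid_spec")
  }
  eps <- ifelse(after > 0 & before > 0, 0, pseudocount)
  out <- log2((after + eps) / (before + eps))
  out[!is.na(after) & !is.na(before) & after == 0 & before == 0] <- NA_real_
  out
}

#' Abundance-standardized activity shares across bins
#'
#' Activities are normalized within each bin by construction; to compare a
#' gene category *across* bins the bin activity is weighted by the bin's
#' relative abundance and expressed as a percentage share:
#' share(bin, category) = 100 * activity * abundance(bin) / column total.
#' Shares sum to 100 across bins for every category.
#'
#' @param activity Numeric matrix, bins x gene categories (rownames = bins),
#'   or a named vector for a single category.
#' @param abundance Named numeric, bin -> relative abundance for the sample.
#' @return Matrix of percentage shares (bins x categories).  Bins without an
#'   abundance are dropped with a warning.
#' @examples
#' standardized_activity(c(bin_1 = 1, bin_2 = 1),
#'                       c(bin_1 = 0.75, bin_2 = 0.25))
#' @export
standardized_activity <- function(activity, abundance) {
  if (is.null(dim(activity))) {
    activity <- matrix(activity, ncol = 1,
                       dimnames = list(names(activity), "category"))
  }
  known <- rownames(activity) %in% names(abundance)
  if (!all(known)) {
    warning("bins without abundance excluded: ",
            paste(rownames(activity)[!known], collapse = ", "))
    activity <- activity[known, , drop = FALSE]
  }
  w <- activity * abundance[rownames(activity)]
  tot <- colSums(w, na.rm = TRUE)
  if (any(tot <= 0)) {
    stop_chemobin("a gene category has zero weighted activity in every bin",
                  class = "chemobin_no_signal")
  }
  sweep(w, 2, tot, `/`) * 100
}
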