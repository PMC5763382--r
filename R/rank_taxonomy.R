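## Rank-threshold clade delineation on 16S rRNA identity matrices.
##
## A single hierarchical clustering (default average linkage on distance
## 100 - identity) is cut at the five published rank thresholds; two
## sequences share a rank-R clade iff they merge at distance
## <= 100 - threshold(R).  Cutting one tree at nested heights guarantees
## genus within family within order within class within phylum.

#' Taxonomic rank identity thresholds
#'
#' The percent-identity cutoffs used to delineate nested 16S rRNA clades:
#' genus 94.5, family 86.5, order 82.0, class 78.5, phylum 75.0.
#'
#' @return Named numeric vector, strictly decreasing genus -> phylum.
#' @export
rank_thresholds <- function() {
  c(genus = 94.5, family = 86.5, order = 82.0, class = 78.5, phylum = 75.0)
}

#' Pairwise percent identity of aligned sequences
#'
#' Identity = matches / compared columns x 100, where columns in which
#' either sequence carries a gap (`-` or `.`) are excluded from both
#' numerator and denominator.  A pair with zero comparable columns is `NA`
#' (flagged missing) with a warning.
#'
#' @param seqs Equal-length aligned sequences: character vector or
#'   [Biostrings::XStringSet], optionally gapped.
#' @return Symmetric numeric matrix of identities in \[0, 100\], diagonal
#'   100.
#' @examples
#' pairwise_identity(c(a = "ACGT", b = "ACGA"))
#' @export
pairwise_identity <- function(seqs) {
  x <- as_dna_character(seqs, "aligned sequences")
  if (length(unique(nchar(x))) != 1) {
    stop_chemobin("aligned sequences must have equal length",
                  class = "chemobin_invalid_spec")
  }
  n <- length(x)
  ids <- names(x) %||% sprintf("seq_%02d", seq_len(n))
  chars <- do.call(rbind, strsplit(toupper(x), ""))
  is_gap <- chars == "-" | chars == "."
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is_gap[i, ] & !is_gap[j, ]
      cmp <- sum(ok)
      if (cmp == 0) {
        warning("no comparable columns for pair ", ids[i], " / ", ids[j])
        m[i, j] <- m[j, i] <- NA_real_
      } else {
        m[i, j] <- m[j, i] <- 100 * sum(chars[i, ok] == chars[j, ok]) / cmp
      }
    }
  }
  m
}

#' Delineate nested clades at rank thresholds
#'
#' Clusters the identity matrix once (hierarchical, `linkage` on distance
#' 100 - identity) and cuts the tree at each rank threshold.  Sequences are
#' processed in lexicographic id order and clades are numbered by first
#' occurrence in that order, so labels are stable under permutation of the
#' input.
#'
#' @param idmat Symmetric identity matrix (percent, diagonal 100), e.g. from
#'   [pairwise_identity()].
#' @param thresholds Named identity thresholds, default [rank_thresholds()].
#' @param linkage One of `"average"` (default), `"single"`, `"complete"`.
#' @return Data frame with `seq_id` and one clade-label column per rank
#'   (`genus_1`, `family_2`, ...); the partitions are nested by
#'   construction.
#' @examples
#' m <- matrix(c(100, 96, 85, 96, 100, 85, 85, 85, 100), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' cluster_at_thresholds(m)
#' @export
cluster_at_thresholds <- function(idmat, thresholds = rank_thresholds(),
                                  linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  idmat <- as.matrix(idmat)
  if (any(!is.finite(idmat))) {
    stop_chemobin("identity matrix contains non-finite entries",
                  class = "chemobin_invalid_matrix")
  }
  if (any(abs(idmat - t(idmat)) > 1e-8) || any(diag(idmat) != 100)) {
    stop_chemobin("identity matrix must be symmetric with diagonal 100",
                  class = "chemobin_invalid_matrix")
  }
  if (is.null(names(thresholds)) || any(diff(thresholds) >= 0)) {
    stop_chemobin("thresholds must be named and strictly decreasing",
                  class = "chemobin_invalid_spec")
  }
  ids <- rownames(idmat) %||% sprintf("seq_%02d", seq_len(nrow(idmat)))
  ord <- order(ids)
  idmat <- idmat[ord, ord, drop = FALSE]
  ids <- ids[ord]
  out <- data.frame(seq_id = ids, stringsAsFactors = FALSE)
  if (length(ids) == 1) {
    for (r in names(thresholds)) out[[r]] <- paste0(r, "_1")
    return(out)
  }
  hc <- stats::hclust(stats::as.dist(100 - idmat), method = linkage)
  for (r in names(thresholds)) {
    grp <- stats::cutree(hc, h = 100 - thresholds[[r]])
    out[[r]] <- paste0(r, "_", match(grp, unique(grp)))
  }
  out
}

#' Clade counts per rank
#'
#' @param partition Output of [cluster_at_thresholds()].
#' @return Named integer vector of clade counts per rank; non-increasing
#'   from genus to phylum.
#' @export
clade_counts <- function(partition) {
  ranks <- setdiff(names(partition), "seq_id")
  vapply(setNames(ranks, ranks),
         function(r) length(unique(partition[[r]])), integer(1))
}
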