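## Tetranucleotide-frequency binning.
##
## Contigs are profiled by their canonical 4-mer relative frequencies (a
## strand-invariant compositional signature), projected onto principal
## components and clustered into bins; Table-style summary statistics
## (size, contig count, N50, GC) are computed per bin.

#' Canonical tetranucleotide index
#'
#' Maps each of the 256 tetranucleotides to its canonical class: the
#' lexicographic minimum of the 4-mer and its reverse complement.  16 4-mers
#' are their own reverse complement, so there are (256 - 16) / 2 + 16 = 136
#' classes.  Canonicalization makes profiles independent of which strand of
#' a contig was assembled.
#'
#' @return Named integer vector of length 256 (4-mer -> class index in
#'   1..136), with attribute `classes`: the 136 canonical 4-mers in
#'   lexicographic order.
#' @examples
#' ci <- canonical_index()
#' ci["AAAA"] == ci["TTTT"]
#' @export
canonical_index <- function() {
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(bases, bases, bases, bases,
                                       stringsAsFactors = FALSE)[, 4:1])
  kmers <- sort(kmers)
  rc <- chartr("ACGT", "TGCA", kmers)
  rc <- vapply(strsplit(rc, ""), function(x) paste(rev(x), collapse = ""),
               character(1))
  canon <- pmin(kmers, rc)
  classes <- sort(unique(canon))
  idx <- match(canon, classes)
  names(idx) <- kmers
  attr(idx, "classes") <- classes
  idx
}

#' Tetranucleotide frequency profiles
#'
#' Slides a 4-bp window (step 1) over each sequence; windows containing
#' non-ACGT characters are skipped.  Window counts are pooled by canonical
#' class ([canonical_index()]) and normalized to relative frequencies.
#' Sequences shorter than 4 bp (or all-ambiguous) get an all-zero profile
#' with `n_valid_windows = 0`; they are excluded from clustering rather than
#' treated as errors.
#'
#' @param seqs [Biostrings::DNAStringSet] or character vector of sequences
#'   over A, C, G, T, N.
#' @return Numeric matrix (sequences x 136 canonical classes), rows summing
#'   to 1 where any valid window exists; attribute `n_valid_windows` holds
#'   the per-sequence window counts.
#' @examples
#' p <- tnf_profile(c(ctg = "ACGTACGTACGT"))
#' rowSums(p)
#' @export
tnf_profile <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = 4, step = 1)
  idx <- canonical_index()
  classes <- attr(idx, "classes")
  pool <- t(rowsum(t(counts[, names(idx), drop = FALSE]), group = idx))
  colnames(pool) <- classes
  n_valid <- rowSums(pool)
  prof <- pool / ifelse(n_valid > 0, n_valid, 1)
  rownames(prof) <- names(seqs)
  attr(prof, "n_valid_windows") <- setNames(as.integer(n_valid), names(seqs))
  prof
}

#' Cluster contigs into bins by tetranucleotide composition
#'
#' Profiles of contigs passing the length floor are centred, projected onto
#' the leading principal components and clustered - k-means when `n_bins`
#' is given, otherwise a Gaussian mixture with BIC model selection
#' ([mclust::Mclust]).  Contigs are processed in lexicographic id order and
#' bins are relabelled `bin_1`, `bin_2`, ... by first occurrence in that
#' order, so the partition is stable under permutation of the input.
#' Contigs below the floor (or without valid windows) are marked
#' `"unassigned"`: short contigs carry too little 4-mer signal to place
#' reliably.
#'
#' @param contigs [Biostrings::DNAStringSet], or a profile matrix from
#'   [tnf_profile()] together with `contig_lengths`.
#' @param contig_lengths Named lengths (bp); derived from `contigs` when a
#'   sequence set is given.
#' @param min_length Length floor in bp (default 1000).
#' @param n_components Number of principal components retained.
#' @param n_bins Number of bins, or `NULL` for automatic selection.
#' @param max_bins Upper bound on bins tried when `n_bins` is `NULL`.
#' @param seed Seed for the stochastic clustering steps.
#' @return Data frame `contig_id`, `bin` (one row per contig; `"unassigned"`
#'   below the floor).
#' @export
cluster_contigs <- function(contigs, contig_lengths = NULL, min_length = 1000,
                            n_components = 5, n_bins = NULL, max_bins = 10,
                            seed = 42) {
  if (is.matrix(contigs)) {
    prof <- contigs
    if (is.null(contig_lengths)) {
      stop_chemobin("contig_lengths required when profiles are supplied",
                    class = "chemobin_invalid_spec")
    }
    n_valid <- attr(prof, "n_valid_windows") %||%
      setNames(rep(1L, nrow(prof)), rownames(prof))
  } else {
    if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
    prof <- tnf_profile(contigs)
    n_valid <- attr(prof, "n_valid_windows")
    contig_lengths <- setNames(Biostrings::width(contigs), names(contigs))
  }
  ids <- rownames(prof)
  if (is.null(ids)) {
    stop_chemobin("contigs must be named", class = "chemobin_invalid_spec")
  }
  pass <- contig_lengths[ids] >= min_length & n_valid[ids] > 0
  if (sum(pass) < 2) {
    stop_chemobin("fewer than 2 contigs pass the length floor",
                  class = "chemobin_no_input")
  }
  ord <- order(ids[pass])                 # permutation stability
  X <- prof[pass, , drop = FALSE][ord, , drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  d <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(d), drop = FALSE]
  cl <- withr::with_seed(seed, {
    if (!is.null(n_bins)) {
      if (n_bins == 1) rep(1L, nrow(scores))
      else stats::kmeans(scores, centers = n_bins, nstart = 25,
                         iter.max = 100)$cluster
    } else {
      fit <- mclust::Mclust(scores, G = seq_len(min(max_bins, nrow(scores) - 1)),
                            verbose = FALSE)
      fit$classification
    }
  })
  # canonical labels by first occurrence in id-sorted order
  relab <- match(cl, unique(cl))
  bin <- setNames(rep("unassigned", length(ids)), ids)
  bin[rownames(scores)] <- paste0("bin_", relab)
  data.frame(contig_id = ids, bin = unname(bin[ids]), stringsAsFactors = FALSE)
}

#' Per-bin assembly statistics
#'
#' Computes, for each bin, its total size, number of contigs, N50 contig
#' length (largest-first cumulative rule: the length L such that contigs of
#' length >= L cover at least half the bin) and GC content over the
#' concatenated members - the usual per-bin summary columns.
#'
#' @param contigs [Biostrings::DNAStringSet].
#' @param assignment Data frame `contig_id`, `bin` (e.g. from
#'   [cluster_contigs()]); `"unassigned"` rows are skipped.
#' @return Data frame: bin, size_mb, n_contigs, n50_kb, gc_percent.
#' @export
bin_stats <- function(contigs, assignment) {
  if (!all(assignment$contig_id %in% names(contigs))) {
    stop_chemobin("assignment refers to unknown contigs",
                  class = "chemobin_invalid_spec")
  }
  asn <- assignment[assignment$bin != "unassigned", , drop = FALSE]
  bins <- sort(unique(asn$bin))
  rows <- lapply(bins, function(b) {
    members <- contigs[asn$contig_id[asn$bin == b]]
    if (length(members) == 0) {
      warning("bin ", b, " is empty; skipped")
      return(NULL)
    }
    lens <- sort(Biostrings::width(members), decreasing = TRUE)
    total <- sum(lens)
    n50 <- lens[which(cumsum(lens) >= total / 2)[1]]
    gc <- sum(Biostrings::letterFrequency(members, "GC")) / total * 100
    data.frame(bin = b, size_mb = total / 1e6, n_contigs = length(members),
               n50_kb = n50 / 1e3, gc_percent = gc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
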