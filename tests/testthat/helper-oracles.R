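# Independent oracles used to check the implementation by a second route.

# dictionary-count tetranucleotide oracle: slide a window by hand, skip
# non-ACGT windows, canonicalize by reverse complement, tally in a named list
naive_tnf <- function(seq) {
  revcomp <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                            "")[[1]]), collapse = "")
  counts <- list()
  n <- nchar(seq)
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      w <- substr(seq, i, i + 3)
      if (grepl("[^ACGT]", w)) next
      key <- min(w, revcomp(w))
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  tot <- sum(unlist(counts))
  out <- setNames(rep(0, 136), attr(chemobin::canonical_index(), "classes"))
  if (tot > 0) for (k in names(counts)) out[k] <- counts[[k]] / tot
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force agglomerative clustering: repeatedly merge the two clusters at
# minimum linkage distance; return the partition after all merges at height
# <= h (distance = 100 - identity)
brute_partition <- function(idmat, threshold,
                            linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- 100 - idmat
  clusters <- as.list(seq_len(nrow(idmat)))
  link <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    switch(linkage, average = mean(vals), single = min(vals),
           complete = max(vals))
  }
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- link(clusters[[i]], clusters[[j]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    if (best_d > 100 - threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  grp <- integer(nrow(idmat))
  for (k in seq_along(clusters)) grp[clusters[[k]]] <- k
  grp
}

# delta-method standard errors for the coverage-based abundance estimator:
# reads ~ Multinomial(N, q), q_c = w_g * L_c / sum(w L); the estimator is
# est_b = (n_b / L_b) / sum_c (n_c / L_c) over bins
abundance_se <- function(weights, bin_sizes, n_reads) {
  q <- weights * bin_sizes
  q <- q / sum(q)
  X <- q / bin_sizes               # expected n_b / (N L_b)
  S <- sum(X)
  grad <- function(b) {
    g <- -X[b] / (S^2 * bin_sizes)
    g[b] <- g[b] + 1 / (bin_sizes[b] * S)
    g
  }
  vapply(seq_along(weights), function(b) {
    g <- grad(b)
    # multinomial covariance: N (diag(q) - q q^T)
    v <- (sum(g^2 * q) - sum(g * q)^2) / n_reads
    sqrt(max(v, 0))
  }, numeric(1))
}

# majority-vote agreement between a clustering and the truth labels
cluster_agreement <- function(bin, truth) {
  majority <- tapply(truth, bin, function(x) names(which.max(table(x))))
  mean(truth == majority[bin])
}

# random ultrametric identity matrix built by merging random clusters at
# increasing distances (so a perfect tree exists by construction)
rand_ultrametric <- function(n, id_range = c(70, 99)) {
  ids <- sprintf("s%02d", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  clusters <- as.list(seq_len(n))
  h <- sort(runif(n - 1, 100 - id_range[2], 100 - id_range[1]))
  for (k in seq_len(n - 1)) {
    pick <- sample(length(clusters), 2)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    m[a, b] <- 100 - h[k]
    m[b, a] <- 100 - h[k]
    clusters[[pick[1]]] <- c(a, b)
    clusters <- clusters[-pick[2]]
  }
  m
}

# small ready-made synthetic community shared across tests
small_community <- function(seed = 7, genome_length = 60000) {
  spec <- community_spec(n_genomes = 3, genome_length = genome_length,
                         seed = seed)
  gen <- generate_genomes(spec)
  frag <- fragment_contigs(gen$genomes, spec$contig_length_law,
                           seed = seed + 1)
  list(spec = spec, genomes = gen, frag = frag)
}
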