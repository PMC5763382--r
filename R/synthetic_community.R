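## Synthetic community generator.
##
## Every downstream stage (binning, quality scoring, abundance estimation,
## activity normalization, clade delineation) is exercised against data with
## known ground truth produced here.  All stochastic steps are seeded and
## deterministic given the seed.

MARKER_SET_SIZE <- 139L

#' Identifiers of the conserved single-copy marker set
#'
#' The bin-quality module scores bins against a fixed universe of 139
#' conserved single-copy genes (CSCGs); this helper returns their
#' identifiers, `m001` ... `m139`.
#'
#' @return Character vector of length 139.
#' @export
marker_ids <- function() sprintf("m%03d", seq_len(MARKER_SET_SIZE))

#' Specify a synthetic microbial community
#'
#' Bundles the genome-level parameters of the generator: how many genomes,
#' how long, their GC targets (which drive tetranucleotide separability),
#' their relative abundances, and the contig-length law used to fragment
#' them.  The defaults describe a small three-population community with one
#' dominant member and two rarer ones, with GC contents spread widely enough
#' (0.35 / 0.50 / 0.65) that compositional binning has a clean signal.
#'
#' Genome sequences are drawn from per-genome Markov chains of order
#' `markov_order` (default 3).  Tetranucleotide frequencies are exactly the
#' sufficient statistics of an order-3 chain, so the compositional contrast
#' between genomes - and hence the difficulty of the binning problem - is
#' fully controlled by these transition tables.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Length of each genome in bp (scalar or vector).
#' @param markov_order Order of the per-genome compositional Markov model.
#' @param gc_targets Per-genome GC content targets in (0, 1).  Default:
#'   evenly spread over 0.35-0.65.
#' @param abundances Per-genome relative abundances, summing to 1.
#' @param contig_length_law List with `meanlog`, `sdlog` (log-normal contig
#'   length law, bp) and `min_length` (shorter fragments are discarded).
#' @param context_sd Standard deviation (log scale) of the per-context
#'   multiplicative tilt applied to each genome's transition table; gives
#'   each genome a compositional signature beyond its GC content.
#' @param seed Integer seed; the whole generator is deterministic given it.
#'
#' @return An object of class `community_spec`.
#' @examples
#' spec <- community_spec(n_genomes = 2, genome_length = 20000, seed = 1)
#' @export
community_spec <- function(n_genomes = 3,
                           genome_length = 150000,
                           markov_order = 3,
                           gc_targets = NULL,
                           abundances = NULL,
                           contig_length_law = list(meanlog = log(8000),
                                                    sdlog = 0.35,
                                                    min_length = 1000),
                           context_sd = 0.2,
                           seed = 42) {
  n_genomes <- as.integer(n_genomes)
  if (n_genomes < 1) {
    stop_chemobin("n_genomes must be >= 1", class = "chemobin_invalid_spec")
  }
  genome_length <- as.integer(rep_len(genome_length, n_genomes))
  if (any(genome_length <= 0)) {
    stop_chemobin("genome lengths must be > 0", class = "chemobin_invalid_spec")
  }
  markov_order <- as.integer(markov_order)
  if (markov_order < 0) {
    stop_chemobin("markov_order must be >= 0", class = "chemobin_invalid_spec")
  }
  if (any(genome_length < 4^(markov_order + 1))) {
    stop_chemobin("genome_length must be >= 4^(markov_order + 1)",
                  class = "chemobin_invalid_spec")
  }
  if (is.null(gc_targets)) {
    gc_targets <- if (n_genomes == 1) 0.5 else
      seq(0.35, 0.65, length.out = n_genomes)
  }
  gc_targets <- rep_len(gc_targets, n_genomes)
  if (any(gc_targets <= 0 | gc_targets >= 1)) {
    stop_chemobin("gc_targets must lie in (0, 1)", class = "chemobin_invalid_spec")
  }
  if (is.null(abundances)) {
    # one dominant population plus progressively rarer ones
    abundances <- 2^-(seq_len(n_genomes) - 1)
    abundances <- abundances / sum(abundances)
  }
  if (length(abundances) != n_genomes) {
    stop_chemobin("abundances must have one entry per genome",
                  class = "chemobin_invalid_spec")
  }
  if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-9) {
    stop_chemobin("abundances must be non-negative and sum to 1 (tol 1e-9)",
                  class = "chemobin_invalid_spec")
  }
  law <- contig_length_law
  if (is.null(law$meanlog) || is.null(law$sdlog) || is.null(law$min_length)) {
    stop_chemobin("contig_length_law needs meanlog, sdlog, min_length",
                  class = "chemobin_invalid_spec")
  }
  if (law$sdlog < 0) {
    stop_chemobin("contig_length_law$sdlog must be >= 0",
                  class = "chemobin_invalid_spec")
  }
  if (any(law$min_length > genome_length)) {
    stop_chemobin("contig min_length exceeds a genome length",
                  class = "chemobin_invalid_spec")
  }
  structure(
    list(n_genomes = n_genomes,
         genome_length = genome_length,
         markov_order = markov_order,
         gc_targets = gc_targets,
         abundances = setNames(as.numeric(abundances),
                               sprintf("genome_%02d", seq_len(n_genomes))),
         contig_length_law = law,
         context_sd = context_sd,
         seed = as.integer(seed)),
    class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec> ", x$n_genomes, " genomes, ",
      paste(unique(x$genome_length), collapse = "/"), " bp, order-",
      x$markov_order, " composition, seed ", x$seed, "\n", sep = "")
  cat("  GC targets: ", paste(format(x$gc_targets), collapse = ", "), "\n",
      sep = "")
  cat("  abundances: ", paste(format(round(x$abundances, 3)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

## order-k Markov sequence sampler; trans_cum has 4^k rows of cumulative
## next-base probabilities, base_cum is the marginal for the first k bases
sample_markov_chain <- function(len, trans_cum, base_cum, k) {
  u <- stats::runif(len)
  bases <- integer(len)
  n_init <- max(k, 1L)
  for (i in seq_len(min(n_init, len))) {
    bases[i] <- 1L + (u[i] > base_cum[1L]) + (u[i] > base_cum[2L]) +
      (u[i] > base_cum[3L])
  }
  if (k == 0L) {
    for (i in seq_len(len)) {
      bases[i] <- 1L + (u[i] > base_cum[1L]) + (u[i] > base_cum[2L]) +
        (u[i] > base_cum[3L])
    }
    return(bases)
  }
  if (len <= k) return(bases[seq_len(len)])
  ctx <- 0L
  for (i in seq_len(k)) ctx <- ctx * 4L + (bases[i] - 1L)
  mod <- as.integer(4^(k - 1L))
  for (i in (k + 1L):len) {
    row <- trans_cum[ctx + 1L, ]
    b <- 1L + (u[i] > row[1L]) + (u[i] > row[2L]) + (u[i] > row[3L])
    bases[i] <- b
    ctx <- (ctx %% mod) * 4L + (b - 1L)
  }
  bases
}

#' Generate genome sequences for a synthetic community
#'
#' Each genome is drawn from its own order-`markov_order` Markov chain.  The
#' chain's transition rows start from the genome's GC-target base composition
#' and receive an independent multiplicative tilt per context (log-normal,
#' sd `context_sd`), so genomes differ both in GC and in higher-order
#' composition - the signal that tetranucleotide binning exploits.
#'
#' @param spec A [community_spec()].
#' @return A list with `genomes` (named [Biostrings::DNAStringSet]), and
#'   `truth` (data frame: genome_id, length, gc_target, abundance).
#' @examples
#' g <- generate_genomes(community_spec(n_genomes = 2, genome_length = 5000))
#' names(g$genomes)
#' @export
generate_genomes <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  k <- spec$markov_order
  n_ctx <- as.integer(4^k)
  seqs <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_genomes), function(g) {
      gc <- spec$gc_targets[g]
      base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      tilt <- matrix(exp(stats::rnorm(n_ctx * 4, 0, spec$context_sd)),
                     nrow = n_ctx)
      trans <- sweep(tilt, 2, base_p, `*`)
      trans <- trans / rowSums(trans)
      trans_cum <- t(apply(trans, 1, cumsum))
      base_cum <- cumsum(base_p)
      b <- sample_markov_chain(spec$genome_length[g], trans_cum, base_cum, k)
      paste(c("A", "C", "G", "T")[b], collapse = "")
    })
  })
  ids <- sprintf("genome_%02d", seq_len(spec$n_genomes))
  genomes <- Biostrings::DNAStringSet(setNames(unlist(seqs), ids))
  list(genomes = genomes,
       truth = data.frame(genome_id = ids,
                          length = spec$genome_length,
                          gc_target = spec$gc_targets,
                          abundance = as.numeric(spec$abundances),
                          stringsAsFactors = FALSE))
}

#' Fragment genomes into contigs
#'
#' Tiles each genome left to right with non-overlapping fragments whose
#' lengths are drawn from the log-normal contig-length law, truncating the
#' final fragment at the genome end.  Fragments shorter than `min_length`
#' are discarded but recorded, so kept plus discarded lengths always sum to
#' the genome length.
#'
#' @param genomes Named [Biostrings::DNAStringSet] (e.g. from
#'   [generate_genomes()]).
#' @param contig_length_law List with `meanlog`, `sdlog`, `min_length`;
#'   `sdlog = 0` gives fixed-length fragments of `exp(meanlog)` bp.
#' @param seed Integer seed.
#' @return List with `contigs` ([Biostrings::DNAStringSet]), `truth`
#'   (data frame: contig_id, genome_id, start, end, length; 1-based inclusive
#'   coordinates) and `discarded` (same columns, fragments below the floor).
#' @export
fragment_contigs <- function(genomes, contig_length_law, seed = 42) {
  law <- contig_length_law
  if (is.null(law$sdlog) || law$sdlog < 0) {
    stop_chemobin("contig_length_law$sdlog must be >= 0",
                  class = "chemobin_invalid_spec")
  }
  min_len <- law$min_length %||% 1
  glens <- Biostrings::width(genomes)
  if (any(min_len > glens)) {
    stop_chemobin("min_length exceeds a genome length",
                  class = "chemobin_invalid_spec")
  }
  res <- withr::with_seed(seed, {
    lapply(seq_along(genomes), function(g) {
      G <- glens[g]
      starts <- integer(0); ends <- integer(0)
      pos <- 1L
      while (pos <= G) {
        len <- max(1L, as.integer(round(stats::rlnorm(1, law$meanlog, law$sdlog))))
        end <- min(pos + len - 1L, G)
        starts <- c(starts, pos); ends <- c(ends, end)
        pos <- end + 1L
      }
      data.frame(genome_id = names(genomes)[g], start = starts, end = ends,
                 length = ends - starts + 1L, stringsAsFactors = FALSE)
    })
  })
  frag <- do.call(rbind, res)
  keep <- frag$length >= min_len
  kept <- frag[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop_chemobin("all fragments fell below min_length",
                  class = "chemobin_no_input")
  }
  # stable per-genome numbering in genome order
  kept$contig_id <- paste0(kept$genome_id, "_c",
                           sprintf("%03d", stats::ave(seq_len(nrow(kept)),
                                                      kept$genome_id,
                                                      FUN = seq_along)))
  seqs <- Biostrings::DNAStringSet(mapply(function(g, s, e) {
    as.character(Biostrings::subseq(genomes[[g]], s, e))
  }, kept$genome_id, kept$start, kept$end))
  names(seqs) <- kept$contig_id
  discarded <- frag[!keep, , drop = FALSE]
  if (nrow(discarded) > 0) {
    message(nrow(discarded), " fragment(s) below min_length (",
            sum(discarded$length), " bp) discarded")
  }
  list(contigs = seqs,
       truth = kept[, c("contig_id", "genome_id", "start", "end", "length")],
       discarded = discarded)
}

#' Build a per-genome marker plan
#'
#' A marker plan states, for each genome and each of the 139 conserved
#' single-copy markers, the intended copy count (0 = missing, 1 = single
#' copy, >= 2 = duplicated).  The default plants every marker exactly once,
#' i.e. perfectly complete, uncontaminated genomes.
#'
#' @param n_genomes Number of genomes.
#' @param missing Named list: genome id -> marker ids to drop.
#' @param duplicated Named list: genome id -> marker ids to set to 2 copies
#'   (or a named integer vector of copy counts).
#' @return Integer matrix, genomes x 139 markers.
#' @examples
#' mp <- marker_plan(2, missing = list(genome_01 = marker_ids()[1:21]))
#' rowSums(mp > 0)
#' @export
marker_plan <- function(n_genomes, missing = list(), duplicated = list()) {
  ids <- sprintf("genome_%02d", seq_len(n_genomes))
  plan <- matrix(1L, nrow = n_genomes, ncol = MARKER_SET_SIZE,
                 dimnames = list(ids, marker_ids()))
  for (g in names(missing)) plan[g, missing[[g]]] <- 0L
  for (g in names(duplicated)) {
    d <- duplicated[[g]]
    if (is.null(names(d))) plan[g, d] <- 2L
    else plan[g, names(d)] <- as.integer(d)
  }
  if (any(plan < 0)) {
    stop_chemobin("marker copy counts must be >= 0",
                  class = "chemobin_invalid_spec")
  }
  plan
}

#' Plant genes and marker copies on contigs
#'
#' Lays out non-overlapping gene intervals (1-based, inclusive ends, random
#' strand) along each contig, then assigns marker identities to randomly
#' chosen gene slots of each genome so that realized per-genome copy counts
#' equal the plan; the remaining slots are ordinary coding genes
#' (`marker_id = "."`).
#'
#' @param contigs [Biostrings::DNAStringSet] of contigs.
#' @param contig_truth Data frame with `contig_id`, `genome_id` (from
#'   [fragment_contigs()]).
#' @param plan Marker-plan matrix from [marker_plan()].
#' @param gene_length Planted gene length (bp).
#' @param intergenic Gap between consecutive genes (bp).
#' @param seed Integer seed.
#' @return List with `genes` (gene feature table: gene_id, contig_id, bin,
#'   start, end, strand, length, marker_id) and `marker_hits`
#'   (bin, marker_id, copy_count; realized counts).
#' @export
plant_genes_and_markers <- function(contigs, contig_truth, plan,
                                    gene_length = 900, intergenic = 50,
                                    seed = 42) {
  stopifnot(all(contig_truth$contig_id %in% names(contigs)))
  if (!all(rownames(plan) %in% contig_truth$genome_id)) {
    stop_chemobin("plan rows must match genome ids in contig_truth",
                  class = "chemobin_invalid_spec")
  }
  lens <- setNames(Biostrings::width(contigs), names(contigs))
  step <- gene_length + intergenic
  out <- withr::with_seed(seed, {
    lapply(rownames(plan), function(g) {
      ctg <- contig_truth$contig_id[contig_truth$genome_id == g]
      slot_tab <- do.call(rbind, lapply(ctg, function(cc) {
        n_slots <- (lens[[cc]] + intergenic) %/% step
        if (n_slots == 0) return(NULL)
        data.frame(contig_id = cc, slot = seq_len(n_slots),
                   start = 1L + (seq_len(n_slots) - 1L) * step,
                   stringsAsFactors = FALSE)
      }))
      marker_copies <- rep(colnames(plan), plan[g, ])
      if (is.null(slot_tab) || length(marker_copies) > nrow(slot_tab)) {
        stop_chemobin("marker plan for ", g, " demands more gene slots (",
                      length(marker_copies), ") than fit (",
                      if (is.null(slot_tab)) 0 else nrow(slot_tab), ")",
                      class = "chemobin_invalid_spec")
      }
      slot_tab$marker_id <- "."
      idx <- sample(nrow(slot_tab), length(marker_copies))
      slot_tab$marker_id[idx] <- sample(marker_copies)
      slot_tab$strand <- sample(c("+", "-"), nrow(slot_tab), replace = TRUE)
      slot_tab$bin <- g
      slot_tab
    })
  })
  genes <- do.call(rbind, out)
  genes$end <- genes$start + gene_length - 1L
  genes$length <- gene_length
  genes$gene_id <- sprintf("%s_g%04d", genes$bin,
                           stats::ave(seq_len(nrow(genes)), genes$bin,
                                      FUN = seq_along))
  genes <- genes[, c("gene_id", "contig_id", "bin", "start", "end", "strand",
                     "length", "marker_id")]
  hits <- genes[genes$marker_id != ".", c("bin", "marker_id")]
  marker_hits <- as.data.frame(table(bin = hits$bin, marker_id = hits$marker_id),
                               stringsAsFactors = FALSE)
  names(marker_hits)[3] <- "copy_count"
  marker_hits <- marker_hits[marker_hits$copy_count > 0, ]
  marker_hits <- marker_hits[order(marker_hits$bin, marker_hits$marker_id), ]
  rownames(marker_hits) <- NULL
  list(genes = genes, marker_hits = marker_hits)
}

#' Simulate a read-mapping summary table
#'
#' Reads are assigned to contigs with probability proportional to
#' (genome abundance) x (contig length), emulating shotgun sequencing of a
#' mixed community followed by mapping.  The mapping itself is not
#' performed; the summary table an external mapper would produce is emitted
#' directly, one row per read.
#'
#' @param contigs [Biostrings::DNAStringSet].
#' @param contig_truth Data frame with `contig_id`, `genome_id`.
#' @param abundances Named numeric, relative abundance per genome (sums to 1).
#' @param n_reads Number of reads (> 0).
#' @param read_length Nominal read length, bp; aligned length is capped at
#'   the contig length.
#' @param identity_law Either a single number (constant identity fraction) or
#'   a `function(n)` returning `n` identity fractions in \[0, 1\].  Default
#'   `Beta(197, 3)`: mean 0.985, emulating mostly high-identity mappings with
#'   a tail below a 0.98 filter.
#' @param seed Integer seed.
#' @return Data frame: read_id, contig_id, aligned_length, identity.
#' @export
simulate_read_map <- function(contigs, contig_truth, abundances, n_reads,
                              read_length = 400,
                              identity_law = function(n) stats::rbeta(n, 197, 3),
                              seed = 42) {
  if (length(contigs) == 0) {
    stop_chemobin("empty contig set", class = "chemobin_no_input")
  }
  if (!is.numeric(n_reads) || n_reads <= 0) {
    stop_chemobin("n_reads must be > 0", class = "chemobin_invalid_spec")
  }
  n_reads <- as.integer(n_reads)
  lens <- setNames(Biostrings::width(contigs), names(contigs))
  w <- abundances[contig_truth$genome_id] * lens[contig_truth$contig_id]
  if (anyNA(w)) {
    stop_chemobin("every contig needs a genome with an abundance",
                  class = "chemobin_invalid_spec")
  }
  ident_fun <- if (is.function(identity_law)) identity_law else {
    v <- as.numeric(identity_law)
    function(n) rep(v, n)
  }
  withr::with_seed(seed, {
    idx <- sample.int(nrow(contig_truth), n_reads, replace = TRUE,
                      prob = w / sum(w))
    cid <- contig_truth$contig_id[idx]
    ident <- ident_fun(n_reads)
    if (any(ident < 0 | ident > 1)) {
      stop_chemobin("identity_law must yield values in [0, 1]",
                    class = "chemobin_invalid_spec")
    }
    data.frame(read_id = sprintf("read_%07d", seq_len(n_reads)),
               contig_id = cid,
               aligned_length = pmin(read_length, lens[cid]),
               identity = ident,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Build a per-gene expression plan
#'
#' Assigns every gene a baseline mean, a negative-binomial dispersion (the
#' `size` parameter: larger = closer to Poisson) and a treatment multiplier.
#' A random subset of genes ("stress genes") receives `stress_multiplier`;
#' all others have multiplier 1.  Baseline means are log-normal with a floor
#' of 50 counts so that planted effects are identifiable above shot noise.
#'
#' @param genes Gene feature table (needs `gene_id`).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline means.
#' @param min_base_mean Floor on baseline means (counts).
#' @param dispersion Negative-binomial size parameter, shared across genes.
#' @param stress_fraction Fraction of genes planted with a treatment effect.
#' @param stress_multiplier Condition multiplier for stress genes.
#' @param seed Integer seed.
#' @return Data frame: gene_id, base_mean, dispersion, multiplier, is_stress.
#' @export
expression_plan <- function(genes, base_meanlog = log(200), base_sdlog = 0.6,
                            min_base_mean = 50, dispersion = 10,
                            stress_fraction = 0.2, stress_multiplier = 2,
                            seed = 42) {
  if (dispersion <= 0) {
    stop_chemobin("dispersion must be > 0", class = "chemobin_invalid_spec")
  }
  if (stress_multiplier <= 0) {
    stop_chemobin("multipliers must be > 0", class = "chemobin_invalid_spec")
  }
  n <- nrow(genes)
  withr::with_seed(seed, {
    base <- pmax(min_base_mean, stats::rlnorm(n, base_meanlog, base_sdlog))
    stress <- rep(FALSE, n)
    stress[sample.int(n, round(stress_fraction * n))] <- TRUE
    data.frame(gene_id = genes$gene_id,
               base_mean = base,
               dispersion = dispersion,
               multiplier = ifelse(stress, stress_multiplier, 1),
               is_stress = stress,
               stringsAsFactors = FALSE)
  })
}

#' Simulate before/after transcript counts
#'
#' Draws per-gene counts from a negative-binomial law with mean
#' `base_mean` (before) or `base_mean * multiplier` (after) and the plan's
#' dispersion, for `n_replicates` replicate cultures per condition.  The
#' truth multipliers are returned for effect-recovery tests.
#'
#' @param plan Expression plan from [expression_plan()] (columns `gene_id`,
#'   `base_mean`, `dispersion`, `multiplier`).
#' @param n_replicates Replicate cultures per condition.
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples integer matrix), `samples`
#'   (sample, condition, replicate) and `truth` (the plan).
#' @export
simulate_expression <- function(plan, n_replicates = 2, seed = 42) {
  req <- c("gene_id", "base_mean", "dispersion", "multiplier")
  if (!all(req %in% names(plan))) {
    stop_chemobin("plan must have columns ", paste(req, collapse = ", "),
                  class = "chemobin_invalid_spec")
  }
  if (any(plan$base_mean <= 0) || any(plan$multiplier <= 0)) {
    stop_chemobin("base_mean and multiplier must be > 0",
                  class = "chemobin_invalid_spec")
  }
  if (any(plan$dispersion <= 0)) {
    stop_chemobin("dispersion must be > 0", class = "chemobin_invalid_spec")
  }
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         condition = c("before", "after"),
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample <- paste0(samples$condition, "_rep", samples$replicate)
  counts <- withr::with_seed(seed, {
    vapply(seq_len(nrow(samples)), function(s) {
      mu <- plan$base_mean *
        (if (samples$condition[s] == "after") plan$multiplier else 1)
      stats::rnbinom(nrow(plan), mu = mu, size = plan$dispersion)
    }, numeric(nrow(plan)))
  })
  dimnames(counts) <- list(plan$gene_id, samples$sample)
  list(counts = counts, samples = samples[, c("sample", "condition", "replicate")],
       truth = plan)
}

#' Simulate an aligned 16S-like sequence set at controlled identities
#'
#' Builds equal-length, gap-free sequences whose pairwise identities match a
#' target matrix to within 0.5 percentage points.  The targets must be
#' ultrametric (tree-like): the generator clusters them (average linkage),
#' then evolves a random ancestor down the tree, substituting a calibrated
#' number of sites on each branch.  Substituted site sets are disjoint
#' across branches and every substitution changes the base, so realized
#' mismatch counts are exact up to rounding (at most one site per pair,
#' i.e. 100/L percentage points).
#'
#' @param n_seqs Number of sequences.
#' @param identity_ladder Either a single target identity (%) applied to all
#'   pairs, or an `n_seqs` x `n_seqs` symmetric matrix of target identities.
#' @param seq_length Alignment length (>= 1000 columns; near-full-length 16S).
#' @param seed Integer seed.
#' @return Named [Biostrings::DNAStringSet] (`seq_01` ...) with attribute
#'   `target`, the target identity matrix.
#' @examples
#' s <- simulate_identity_ladder(2, 94.5, 1300, seed = 1)
#' @export
simulate_identity_ladder <- function(n_seqs, identity_ladder,
                                     seq_length = 1300, seed = 42) {
  if (seq_length < 1000) {
    stop_chemobin("seq_length must be >= 1000", class = "chemobin_invalid_spec")
  }
  n_seqs <- as.integer(n_seqs)
  target <- if (length(identity_ladder) == 1) {
    matrix(identity_ladder, n_seqs, n_seqs)
  } else as.matrix(identity_ladder)
  if (!all(dim(target) == n_seqs)) {
    stop_chemobin("identity_ladder matrix must be n_seqs x n_seqs",
                  class = "chemobin_invalid_spec")
  }
  diag(target) <- 100
  if (any(target != t(target))) {
    stop_chemobin("identity_ladder must be symmetric",
                  class = "chemobin_invalid_spec")
  }
  off <- target[upper.tri(target)]
  if (any(off <= 0 | off > 100)) {
    stop_chemobin("target identities must lie in (0, 100]",
                  class = "chemobin_invalid_spec")
  }
  # two random DNA sequences already agree at ~25% of sites; targets near or
  # below that are unreachable by substitution alone
  if (any(off < 30)) {
    stop_chemobin("target identities below 30% are unreachable",
                  class = "chemobin_invalid_spec")
  }
  ids <- sprintf("seq_%02d", seq_len(n_seqs))
  bases <- c("A", "C", "G", "T")
  seqs <- withr::with_seed(seed, {
    anc <- sample.int(4, seq_length, replace = TRUE)
    if (n_seqs == 1) {
      list(anc)
    } else {
      hc <- stats::hclust(stats::as.dist(100 - target), method = "average")
      coph <- as.matrix(stats::cophenetic(hc))
      if (max(abs(coph - (100 - target))) > 0.5) {
        stop_chemobin("identity_ladder is not ultrametric within 0.5 points",
                      class = "chemobin_invalid_spec")
      }
      # cumulative mutated-site budget from a node of height h down to a leaf
      cum_sites <- function(h) round(seq_length * h / 200)
      root_h <- max(hc$height)
      if (2 * cum_sites(root_h) > seq_length) {
        stop_chemobin("targets too divergent for the alignment length",
                      class = "chemobin_invalid_spec")
      }
      pool <- sample.int(seq_length)   # disjoint substitution sites
      ptr <- 0L
      leaves <- vector("list", n_seqs)
      mutate <- function(seq, m) {
        if (m == 0) return(seq)
        sites <- pool[(ptr + 1L):(ptr + m)]
        ptr <<- ptr + m
        seq[sites] <- ((seq[sites] - 1L + sample.int(3, m, replace = TRUE)) %% 4L) + 1L
        seq
      }
      descend <- function(node, seq, h_parent) {
        if (node < 0) {                       # leaf
          leaves[[-node]] <<- mutate(seq, cum_sites(h_parent))
        } else {
          h <- hc$height[node]
          s <- mutate(seq, cum_sites(h_parent) - cum_sites(h))
          descend(hc$merge[node, 1], s, h)
          descend(hc$merge[node, 2], s, h)
        }
      }
      root <- nrow(hc$merge)
      descend(hc$merge[root, 1], anc, root_h)
      descend(hc$merge[root, 2], anc, root_h)
      leaves   # indexed by original sequence order
    }
  })
  out <- Biostrings::DNAStringSet(vapply(seqs, function(b)
    paste(bases[b], collapse = ""), character(1)))
  names(out) <- ids
  attr(out, "target") <- target
  out
}
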