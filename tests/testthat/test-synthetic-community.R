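# Synthetic community generator: determinism, conservation, ground truth.

test_that("genome generation is deterministic and hits its GC targets", {
  spec <- community_spec(n_genomes = 2, genome_length = 30000,
                         gc_targets = c(0.60, 0.35), seed = 7)
  g1 <- generate_genomes(spec)
  g2 <- generate_genomes(spec)
  expect_identical(as.character(g1$genomes), as.character(g2$genomes))
  gc <- Biostrings::letterFrequency(g1$genomes, "GC", as.prob = TRUE)[, 1]
  expect_lt(abs(gc[1] - 0.60), 0.03)   # direct nucleotide tally oracle
  expect_lt(abs(gc[2] - 0.35), 0.03)
  expect_setequal(g1$truth$genome_id, c("genome_01", "genome_02"))
  expect_equal(g1$truth$abundance, spec$abundances, ignore_attr = TRUE)
})

test_that("invalid community specs are rejected", {
  expect_error(community_spec(markov_order = -1), class = "chemobin_invalid_spec")
  expect_error(community_spec(genome_length = 100, markov_order = 3),
               class = "chemobin_invalid_spec")
  expect_error(community_spec(abundances = c(0.5, 0.2, 0.2)),
               class = "chemobin_invalid_spec")
  expect_error(
    community_spec(contig_length_law = list(meanlog = 8, sdlog = -1,
                                            min_length = 500)),
    class = "chemobin_invalid_spec")
})

test_that("fragmentation tiles genomes exactly and respects the length floor", {
  spec <- community_spec(n_genomes = 1, genome_length = 10000, seed = 3)
  gen <- generate_genomes(spec)
  # fixed-length law: sdlog = 0 gives exact 1000 bp fragments
  fixed <- fragment_contigs(gen$genomes,
                            list(meanlog = log(1000), sdlog = 0,
                                 min_length = 500), seed = 1)
  expect_equal(length(fixed$contigs), 10)
  expect_identical(paste(as.character(fixed$contigs), collapse = ""),
                   as.character(gen$genomes[[1]]))

  lawful <- fragment_contigs(gen$genomes,
                             list(meanlog = log(1200), sdlog = 0.6,
                                  min_length = 500), seed = 2)
  expect_equal(sum(lawful$truth$length) + sum(lawful$discarded$length), 10000)
  expect_true(all(Biostrings::width(lawful$contigs) >= 500))
  expect_error(fragment_contigs(gen$genomes,
                                list(meanlog = 7, sdlog = -0.1,
                                     min_length = 500)),
               class = "chemobin_invalid_spec")
})

test_that("marker planting realizes the plan exactly", {
  com <- small_community()
  plan <- marker_plan(3,
                      missing = list(genome_02 = marker_ids()[1:21]),
                      duplicated = list(genome_03 = c(m005 = 3)))
  pg <- plant_genes_and_markers(com$frag$contigs, com$frag$truth, plan,
                                gene_length = 300, intergenic = 20, seed = 5)
  h1 <- pg$marker_hits[pg$marker_hits$bin == "genome_01", ]
  expect_equal(nrow(h1), 139)
  expect_true(all(h1$copy_count == 1))
  expect_equal(sum(pg$marker_hits$bin == "genome_02"), 118)
  expect_equal(pg$marker_hits$copy_count[
    pg$marker_hits$bin == "genome_03" & pg$marker_hits$marker_id == "m005"], 3)
  # gene intervals stay inside their contig and do not overlap
  w <- setNames(Biostrings::width(com$frag$contigs),
                names(com$frag$contigs))
  expect_true(all(pg$genes$end <= w[pg$genes$contig_id]))
  by_ctg <- split(pg$genes, pg$genes$contig_id)
  overlaps <- vapply(by_ctg, function(g) {
    g <- g[order(g$start), ]
    any(g$start[-1] <= g$end[-nrow(g)])
  }, logical(1))
  expect_false(any(overlaps))
  # a plan that cannot fit errors out
  tiny <- fragment_contigs(generate_genomes(
    community_spec(1, 5000, seed = 1))$genomes,
    list(meanlog = log(2500), sdlog = 0, min_length = 1000), seed = 1)
  expect_error(plant_genes_and_markers(tiny$contigs, tiny$truth,
                                       marker_plan(1), gene_length = 900),
               class = "chemobin_invalid_spec")
})

test_that("read assignment follows abundance x length", {
  contigs <- Biostrings::DNAStringSet(c(
    c1 = paste(rep("ACGT", 250), collapse = ""),     # 1000 bp
    c2 = paste(rep("ACGT", 750), collapse = "")))    # 3000 bp
  truth <- data.frame(contig_id = c("c1", "c2"),
                      genome_id = c("g1", "g1"))
  rm <- simulate_read_map(contigs, truth, c(g1 = 1), n_reads = 100000,
                          read_length = 100, identity_law = 1.0, seed = 11)
  frac <- mean(rm$contig_id == "c2")
  se <- sqrt(0.75 * 0.25 / 100000)                   # binomial oracle
  expect_lt(abs(frac - 0.75), 3 * se)
  expect_true(all(rm$identity == 1))
  expect_equal(nrow(filter_mappings(rm)), 100000)    # all pass a 0.98 filter
  expect_error(simulate_read_map(contigs, truth, c(g1 = 1), n_reads = 0),
               class = "chemobin_invalid_spec")
  expect_error(simulate_read_map(Biostrings::DNAStringSet(), truth,
                                 c(g1 = 1), 10),
               class = "chemobin_no_input")
})

test_that("expression simulation recovers planted multipliers and the Poisson limit", {
  plan <- data.frame(gene_id = c("g1", "g2"), base_mean = c(500, 500),
                     dispersion = c(10, 1e9), multiplier = c(2, 1))
  sim <- simulate_expression(plan, n_replicates = 400, seed = 13)
  before <- sim$samples$sample[sim$samples$condition == "before"]
  after <- sim$samples$sample[sim$samples$condition == "after"]
  ratio <- mean(sim$counts["g1", after]) / mean(sim$counts["g1", before])
  expect_lt(abs(log2(ratio) - 1), 0.1)
  # near-infinite size parameter: variance/mean -> 1 (Poisson limit)
  vm <- var(sim$counts["g2", before]) / mean(sim$counts["g2", before])
  expect_lt(abs(vm - 1), 0.25)
  expect_error(simulate_expression(transform(plan, dispersion = -1)),
               class = "chemobin_invalid_spec")
  expect_error(simulate_expression(transform(plan, multiplier = 0)),
               class = "chemobin_invalid_spec")
})

test_that("identity ladders realize their targets within 0.5 points", {
  two <- simulate_identity_ladder(2, 94.5, 1300, seed = 17)
  id2 <- pairwise_identity(two)
  expect_gte(id2[1, 2], 94.0)
  expect_lte(id2[1, 2], 95.0)

  same <- simulate_identity_ladder(2, 100, 1300, seed = 17)
  expect_identical(as.character(same[[1]]), as.character(same[[2]]))

  tri <- matrix(c(100, 96, 85, 96, 100, 85, 85, 85, 100), 3, 3)
  lad <- simulate_identity_ladder(3, tri, 1300, seed = 19)
  got <- pairwise_identity(lad)
  expect_true(all(abs(got[upper.tri(got)] - tri[upper.tri(tri)]) <= 0.5))

  expect_error(simulate_identity_ladder(2, 20, 1300),
               class = "chemobin_invalid_spec")
  expect_error(simulate_identity_ladder(2, 94.5, 800),
               class = "chemobin_invalid_spec")
  # non-ultrametric targets are rejected rather than silently missed
  bad <- matrix(c(100, 96, 60, 96, 100, 90, 60, 90, 100), 3, 3)
  expect_error(simulate_identity_ladder(3, bad, 1300),
               class = "chemobin_invalid_spec")
})

test_that("every emitted id appears in the truth tables exactly once", {
  com <- small_community(seed = 23)
  expect_identical(sort(names(com$frag$contigs)),
                   sort(com$frag$truth$contig_id))
  expect_false(anyDuplicated(com$frag$truth$contig_id) > 0)
  pg <- plant_genes_and_markers(com$frag$contigs, com$frag$truth,
                                marker_plan(3), gene_length = 300,
                                intergenic = 20, seed = 2)
  expect_false(anyDuplicated(pg$genes$gene_id) > 0)
  rm <- simulate_read_map(com$frag$contigs, com$frag$truth,
                          com$spec$abundances, 1000, seed = 3)
  expect_equal(nrow(rm), 1000)
  expect_false(anyDuplicated(rm$read_id) > 0)
  expect_true(all(rm$contig_id %in% com$frag$truth$contig_id))
})
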