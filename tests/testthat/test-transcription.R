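# Per-gene relative transcriptional activity and treatment responses.

two_gene_bin <- function(counts = c(10, 10), lengths = c(100, 300)) {
  list(counts = matrix(counts, 2, 1, dimnames = list(c("g1", "g2"), "s1")),
       genes = data.frame(gene_id = c("g1", "g2"), length = lengths,
                          bin = "bin_1", stringsAsFactors = FALSE))
}

test_that("the activity quotient matches the hand-worked example", {
  tg <- two_gene_bin()
  act <- gene_activity(tg$counts, tg$genes)
  expect_equal(act["g1", "s1"], 2.0)          # (10/100)/(20/400)
  expect_equal(act["g2", "s1"], 2 / 3)        # (10/300)/(20/400)
  # identical genes -> all activities 1 by symmetry
  sym <- gene_activity(matrix(5, 4, 2, dimnames = list(paste0("g", 1:4),
                                                       c("a", "b"))),
                       data.frame(gene_id = paste0("g", 1:4), length = 200,
                                  bin = "bin_1"))
  expect_true(all(sym == 1))
})

test_that("length-weighted mean activity is 1 for every bin and sample", {
  withr::with_seed(61, {
    for (i in 1:10) {
      n <- sample(5:60, 1)
      genes <- data.frame(gene_id = sprintf("g%03d", 1:n),
                          length = sample(100:3000, n, replace = TRUE),
                          bin = sample(c("bA", "bB"), n, replace = TRUE))
      counts <- matrix(rnbinom(n * 3, mu = 50, size = 5), n, 3,
                       dimnames = list(genes$gene_id, c("s1", "s2", "s3")))
      act <- gene_activity(counts, genes)
      for (b in c("bA", "bB")) {
        sel <- genes$bin == b
        for (s in 1:3) {
          if (sum(counts[sel, s]) == 0) {
            expect_true(all(is.na(act[sel, s])))
          } else {
            wm <- sum(genes$length[sel] * act[sel, s]) / sum(genes$length[sel])
            expect_equal(wm, 1, tolerance = 1e-9)
          }
        }
      }
    }
  })
})

test_that("activities are depth-invariant and flag empty bins as missing", {
  tg <- two_gene_bin()
  act1 <- gene_activity(tg$counts, tg$genes)
  act10 <- gene_activity(tg$counts * 10, tg$genes)
  expect_equal(act1, act10)
  zero <- gene_activity(matrix(0, 2, 1, dimnames = dimnames(tg$counts)),
                        tg$genes)
  expect_true(all(is.na(zero)))
  # non-coding features excluded from totals: coding genes renormalize alone
  genes <- data.frame(gene_id = c("g1", "g2", "rrna"),
                      length = c(100, 300, 1500), bin = "bin_1",
                      is_coding = c(TRUE, TRUE, FALSE))
  counts <- matrix(c(10, 10, 9000), 3, 1,
                   dimnames = list(genes$gene_id, "s1"))
  act <- gene_activity(counts, genes)
  expect_equal(act["g1", "s1"], 2.0)
  expect_true(is.na(act["rrna", "s1"]))
})

test_that("display capping flags values above 3.0 and is idempotent", {
  capped <- cap_for_display(c(5.2, 1.7, NA))
  expect_equal(capped$values, c(3.0, 1.7, NA))
  expect_equal(capped$capped, c(TRUE, FALSE, FALSE))
  twice <- cap_for_display(capped$values)
  expect_equal(twice$values, capped$values)
  expect_false(any(twice$capped))
  expect_error(cap_for_display(1, cap = 0), class = "chemobin_invalid_spec")
})

test_that("log2 responses encode doubling as +1 and fourfold decrease as -2", {
  expect_equal(log2_response(2, 1), 1)
  expect_equal(log2_response(0.25, 1), -2)
  expect_equal(log2_response(1, 1), 0)
  # antisymmetry when no zeros are involved
  withr::with_seed(67, {
    a <- runif(50, 0.1, 5); b <- runif(50, 0.1, 5)
    expect_equal(log2_response(a, b), -log2_response(b, a))
  })
  # zeros: pseudocount on that pair only; both-zero is missing
  expect_equal(log2_response(1, 0, pseudocount = 0.5), log2(1.5 / 0.5))
  expect_true(is.na(log2_response(0, 0)))
})

test_that("planted stress effects are recovered from simulated counts", {
  com <- small_community(seed = 71)
  pg <- plant_genes_and_markers(com$frag$contigs, com$frag$truth,
                                marker_plan(3), gene_length = 300,
                                intergenic = 20, seed = 72)
  genes <- pg$genes[seq_len(min(1000, nrow(pg$genes))), ]
  plan <- expression_plan(genes, stress_fraction = 0.2,
                          stress_multiplier = 2, seed = 73)
  sim <- simulate_expression(plan, n_replicates = 2, seed = 74)
  act <- gene_activity(sim$counts, genes)
  before <- rowMeans(act[, sim$samples$sample[sim$samples$condition == "before"]])
  after <- rowMeans(act[, sim$samples$sample[sim$samples$condition == "after"]])
  resp <- log2_response(after, before)
  stress <- plan$is_stress
  # activity renormalization shifts every gene by the same bin-level offset;
  # the planted contrast survives as the difference between groups
  contrast <- median(resp[stress]) - median(resp[!stress])
  expect_lt(abs(contrast - 1), 0.2)
})

test_that("abundance standardization yields shares summing to 100", {
  sh <- standardized_activity(c(bin_1 = 1, bin_2 = 1),
                              c(bin_1 = 0.75, bin_2 = 0.25))
  expect_equal(unname(sh[, 1]), c(75, 25))
  expect_equal(unname(standardized_activity(c(b = 2.4), c(b = 0.3))[, 1]), 100)
  mat <- matrix(c(1, 0, 2, 2), 2, 2,
                dimnames = list(c("b1", "b2"), c("dsr", "gap")))
  sh2 <- standardized_activity(mat, c(b1 = 0.5, b2 = 0.5))
  expect_equal(unname(colSums(sh2)), c(100, 100))
  expect_equal(sh2["b2", "dsr"], 0)
  expect_warning(standardized_activity(mat, c(b1 = 1)), "excluded")
})
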