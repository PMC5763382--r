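## Shared readers/writers and the end-to-end pipeline driver.
##
## All tables are UTF-8, LF, tab-separated with a header row; "." is the
## missing-value sentinel.  Every file written by the pipeline starts with
## comment lines recording the package version, the seed and a hash of the
## stage parameters.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", ".")

#' Read a FASTA file
#'
#' Sequences are upper-cased and U is normalized to T.  Duplicate record
#' ids, empty files and non-IUPAC characters (reported with record and
#' offset) are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_chemobin("no such file: ", path, class = "chemobin_format_error")
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) {
    stop_chemobin("empty FASTA file: ", path, class = "chemobin_format_error")
  }
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop_chemobin("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
                  class = "chemobin_format_error")
  }
  seqs <- chartr("u", "t", as.character(raw))
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) {
    ok <- strsplit(seqs[i], "")[[1]] %in% IUPAC_DNA
    if (!all(ok)) {
      stop_chemobin("non-IUPAC character in record '", ids[i],
                    "' at position ", which(!ok)[1],
                    class = "chemobin_format_error")
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs [Biostrings::XStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

pkg_version <- function() {
  as.character(utils::packageVersion("chemobin"))
}

#' Write a pipeline table as TSV
#'
#' Adds comment header lines (`# chemobin <version>`, seed, parameter hash),
#' writes "." for missing values, tab separators, LF line endings.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param params Named list of stage parameters; hashed into the header.
#' @return `path`, invisibly.
#' @export
write_tsv_out <- function(df, path, seed = NA, params = list()) {
  hash <- substr(digest_params(params), 1, 8)
  con <- file(path, open = "w")
  on.exit(close(con))
  header <- sprintf("# chemobin %s\tseed=%s\tparams=%s",
                    pkg_version(), seed, hash)
  writeLines(header, con, sep = "\n")
  df[] <- lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "."
    col
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", eol = "\n")
  invisible(path)
}

digest_params <- function(params) {
  if (length(params) == 0) return("00000000")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(params), vapply(params, function(p)
    paste(format(p, digits = 15), collapse = ","), character(1)), sep = "="),
    tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline TSV
#'
#' Skips `#` comment lines and converts "." back to `NA`.
#'
#' @param path Path to a TSV written by [write_tsv_out()] (or compatible).
#' @return Data frame.
#' @export
read_tsv_in <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = ".",
                    stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage with their defaults; see
#' the methods vignette for the rationale behind each value.
#'
#' @param spec A [community_spec()] describing the synthetic community.
#' @param min_length Binning length floor, bp.
#' @param gene_length,intergenic Planted gene length and spacing, bp.
#' @param n_bins Number of bins (`NULL` = automatic).
#' @param n_reads Reads simulated per sample.
#' @param min_identity,max_read_length Mapping filter thresholds.
#' @param cap Activity display cap.
#' @param pseudocount Log2-response pseudocount.
#' @param thresholds Rank identity thresholds.
#' @param linkage Clade-clustering linkage.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec = community_spec(),
                            min_length = 1000,
                            gene_length = 900,
                            intergenic = 50,
                            n_bins = spec$n_genomes,
                            n_reads = 20000,
                            min_identity = 0.98,
                            max_read_length = 500,
                            cap = 3.0,
                            pseudocount = 0.5,
                            thresholds = rank_thresholds(),
                            linkage = "average",
                            seed = 42) {
  structure(list(spec = spec, min_length = min_length,
                 gene_length = gene_length, intergenic = intergenic,
                 n_bins = n_bins,
                 n_reads = n_reads, min_identity = min_identity,
                 max_read_length = max_read_length, cap = cap,
                 pseudocount = pseudocount, thresholds = thresholds,
                 linkage = linkage, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> bin -> qc -> abundance -> activity -> respond ->
#' taxcluster -> chem on the configured synthetic community and writes all
#' stage tables plus a manifest (versions, seed, parameters, md5 checksums)
#' into `outdir`.  Identical configurations yield byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  spec <- config$spec

  stage <- "simulate"
  res <- tryCatch({
    gen <- generate_genomes(spec)
    frag <- fragment_contigs(gen$genomes, spec$contig_length_law,
                             seed = seed + 1L)
    plan <- marker_plan(spec$n_genomes)
    pg <- plant_genes_and_markers(frag$contigs, frag$truth, plan,
                                  gene_length = config$gene_length,
                                  intergenic = config$intergenic,
                                  seed = seed + 2L)
    rmap <- simulate_read_map(frag$contigs, frag$truth, spec$abundances,
                              n_reads = config$n_reads, seed = seed + 3L)
    eplan <- expression_plan(pg$genes, seed = seed + 4L)
    expr <- simulate_expression(eplan, seed = seed + 5L)

    stage <- "bin"
    assignment <- cluster_contigs(frag$contigs, min_length = config$min_length,
                                  n_bins = config$n_bins, seed = seed)
    stats_tab <- bin_stats(frag$contigs, assignment)

    stage <- "qc"
    qc <- quality_report(pg$marker_hits)

    stage <- "abundance"
    filt <- filter_mappings(rmap, config$min_identity, config$max_read_length)
    truth_asn <- data.frame(contig_id = frag$truth$contig_id,
                            bin = frag$truth$genome_id,
                            stringsAsFactors = FALSE)
    sizes <- tapply(frag$truth$length, frag$truth$genome_id, sum)
    cov <- bin_coverage(filt, truth_asn, setNames(as.numeric(sizes),
                                                  names(sizes)))
    abund <- relative_abundance(cov)

    stage <- "activity"
    act <- gene_activity(expr$counts, pg$genes)
    capped <- cap_for_display(act, config$cap)

    stage <- "respond"
    before <- rowMeans(act[, expr$samples$sample[expr$samples$condition == "before"],
                           drop = FALSE])
    after <- rowMeans(act[, expr$samples$sample[expr$samples$condition == "after"],
                          drop = FALSE])
    resp <- log2_response(after, before, config$pseudocount)

    stage <- "taxcluster"
    ladder <- simulate_identity_ladder(
      6, ladder_matrix_default(), seq_length = 1300, seed = seed + 6L)
    idmat <- pairwise_identity(ladder)
    clades <- cluster_at_thresholds(idmat, config$thresholds,
                                    linkage = config$linkage)

    stage <- "chem"
    D <- dilution_rate(0.17, 0.4)
    chem <- data.frame(
      quantity = c("dilution_rate_per_day", "pulse_dose_mmol",
                   "peak_nitrate_mM", "doubling_time_h"),
      value = c(D, pulse_dose(1.4, 20, 7),
                post_pulse_concentration(pulse_dose(1.4, 20, 7), 0.4),
                doubling_time(D)),
      stringsAsFactors = FALSE)

    list(genomes = gen, contigs = frag, genes = pg, readmap = rmap,
         expression = expr, assignment = assignment, bin_stats = stats_tab,
         quality = qc, abundance = abund, activity = act, capped = capped,
         response = resp, clades = clades, chem = chem)
  }, chemobin_error = function(e) {
    stop_chemobin("pipeline failed in stage '", stage, "': ",
                  conditionMessage(e), class = "chemobin_stage_error")
  })

  params <- config[setdiff(names(config), "spec")]
  p <- function(f) file.path(outdir, f)
  write_fasta(res$contigs$contigs, p("contigs.fasta"))
  write_tsv_out(res$genes$genes, p("genes.tsv"), seed, params)
  write_tsv_out(res$genes$marker_hits, p("marker_hits.tsv"), seed, params)
  write_tsv_out(res$readmap, p("read_map.tsv"), seed, params)
  write_tsv_out(data.frame(gene_id = rownames(res$expression$counts),
                           res$expression$counts, check.names = FALSE),
                p("counts.tsv"), seed, params)
  write_tsv_out(res$assignment, p("bin_assignment.tsv"), seed, params)
  write_tsv_out(res$bin_stats, p("bin_stats.tsv"), seed, params)
  write_tsv_out(res$quality, p("bin_quality.tsv"), seed, params)
  write_tsv_out(res$abundance, p("abundance.tsv"), seed, params)
  write_tsv_out(data.frame(gene_id = rownames(res$activity), res$activity,
                           check.names = FALSE),
                p("activity.tsv"), seed, params)
  write_tsv_out(data.frame(gene_id = names(res$response),
                           log2_response = res$response),
                p("response.tsv"), seed, params)
  write_tsv_out(res$clades, p("clade_partition.tsv"), seed, params)
  write_tsv_out(res$chem, p("chemostat.tsv"), seed, params)

  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(package = "chemobin", version = pkg_version(),
                   seed = seed, params = params,
                   checksums = as.list(setNames(unname(tools::md5sum(files)),
                                                basename(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(res, list(manifest = manifest)))
}

# planted 2-genus / 1-family / 1-order demonstration ladder: two tight
# genus-level pairs (97%) joined at family level (90%), plus two outliers
# at order (84%) and class (77%) depth
ladder_matrix_default <- function() {
  ids <- sprintf("seq_%02d", 1:6)
  m <- matrix(77, 6, 6, dimnames = list(ids, ids))
  m[1:5, 1:5] <- 84
  m[1:4, 1:4] <- 90
  m[1:2, 1:2] <- 97
  m[3:4, 3:4] <- 97
  diag(m) <- 100
  m
}
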