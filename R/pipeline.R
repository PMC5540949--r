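#' Run the full amplicon pipeline
#'
#' One call from mapping file to results directory: read preparation (merge,
#' primer trim, expected-error filter, pooling), dereplication with singleton
#' removal, greedy OTU clustering with chimera flagging, read mapping to
#' centroids, rarefaction, optional taxonomy, alpha diversity, the four beta
#' dissimilarities with UPGMA trees, PCoA/NMDS ordination, AMOVA/HOMOVA on
#' the mapping's treatment groups, and the co-occurrence network. All
#' randomness (rarefaction, bootstraps, NMDS starts, permutations) flows from
#' one seed; rerunning with the same inputs and seed reproduces identical
#' tabular outputs.
#'
#' @param mapping_path path to the mapping file.
#' @param oligos_path path to the oligos (primer) file.
#' @param out_dir results directory (created).
#' @param analysis_name name stamped into the run log.
#' @param input_dir directory read paths are relative to (default: the
#'   mapping file's directory).
#' @param seqformat "fastq" or "fasta".
#' @param similarity_cutoff OTU identity cutoff.
#' @param minoverlen,maxdiffs merge parameters.
#' @param pdiffs,maxee,trunclen primer/quality-filter parameters.
#' @param rarefy_depth rarefaction depth (default: smallest sample total).
#' @param reference optional classifier training set (see
#'   [train_classifier()]) or a `reference_db`.
#' @param net a [network_params()].
#' @param n_perm permutations for AMOVA/HOMOVA.
#' @param seed RNG seed.
#' @return invisible list with the main in-memory results (`prep_stats`,
#'   `otus`, `table`, `rarefied`, `taxonomy`, `alpha`, `distances`, `trees`,
#'   `ordination`, `tests`, `network`).
#' @export
run_pipeline <- function(mapping_path, oligos_path, out_dir,
                         analysis_name = "analysis",
                         input_dir = dirname(mapping_path),
                         seqformat = c("fastq", "fasta"),
                         similarity_cutoff = 0.97,
                         minoverlen = 100L, maxdiffs = 8L,
                         pdiffs = 2L, maxee = 1.0, trunclen = 250L,
                         rarefy_depth = NULL, reference = NULL,
                         net = network_params(), n_perm = 999L, seed = 1L) {
  seqformat <- match.arg(seqformat)
  if (!file.exists(mapping_path))
    stop(sprintf("-map file not found: %s", mapping_path))
  if (!file.exists(oligos_path))
    stop(sprintf("-oligos file not found: %s", oligos_path))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("analysis_name\t%s", analysis_name)
  logline("seed\t%d", as.integer(seed))
  for (p in c("similarity_cutoff", "minoverlen", "maxdiffs", "pdiffs",
              "maxee", "trunclen"))
    logline("%s\t%s", p, format(get(p)))

  mapping <- read_mapping(mapping_path)
  primers <- read_oligos(oligos_path)
  mp <- merge_params(minoverlen, maxdiffs)
  fp <- filter_params(trunclen, maxee, pdiffs)
  prep <- pool_samples(mapping, primers, mp, fp, input_dir = input_dir,
                       seqformat = seqformat)
  write.table(prep$stats, file.path(out_dir, "prep_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  logline("reads_pooled\t%d", length(prep$reads))
  if (!length(prep$reads)) stop("no reads survived read preparation")

  cp <- cluster_params(similarity_cutoff = similarity_cutoff)
  uniq <- dereplicate(prep$reads)
  nonsingle <- remove_singletons(uniq, cp$min_size)
  otus <- cluster_otus(nonsingle, cp)
  logline("uniques\t%d", length(uniq))
  logline("otus\t%d", nrow(otus))
  logline("chimeras_discarded\t%d", length(attr(otus, "chimeras")))
  write_fasta(stats::setNames(otus$centroid, otus$otu_id),
              file.path(out_dir, "otus.fasta"))

  table <- build_otu_table(uniq, otus, cp)
  logline("reads_dropped_at_mapping\t%d", attr(table, "dropped"))
  write_shared_table(table, file.path(out_dir, "otu_table.shared"),
                     label = format(1 - similarity_cutoff))
  rarefied <- rarefy_table(table, depth = rarefy_depth, seed = seed)
  write_shared_table(rarefied, file.path(out_dir, "otu_table.rarefied.shared"),
                     label = format(1 - similarity_cutoff))

  taxonomy <- NULL
  if (!is.null(reference)) {
    db <- if (inherits(reference, "reference_db")) reference
          else train_classifier(reference)
    taxonomy <- classify_otus(otus, db, seed = seed)
    write.table(taxonomy, file.path(out_dir, "taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  alpha <- list(raw = alpha_diversity_table(table),
                rarefied = alpha_diversity_table(rarefied))
  write.table(alpha$raw, file.path(out_dir, "alpha_diversity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(alpha$rarefied, file.path(out_dir, "alpha_diversity.rarefied.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  measures <- c("jclass", "jest", "thetayc", "braycurtis")
  distances <- list(); trees <- list()
  for (ms in measures) {
    dm <- beta_distance(rarefied, ms)
    distances[[ms]] <- dm
    write.table(as.matrix(dm), file.path(out_dir, sprintf("dist_%s.tsv", ms)),
                sep = "\t", quote = FALSE)
    tr <- upgma_tree(dm)
    trees[[ms]] <- tr
    write_newick(tr, file.path(out_dir, sprintf("upgma_%s.nwk", ms)))
  }

  ordination <- list(); tests <- list()
  groups <- mapping$treatment[match(rownames(rarefied$counts), mapping$sample)]
  dm <- distances$braycurtis
  n_samp <- nrow(rarefied$counts)
  if (n_samp >= 3L) {
    pc <- pcoa(dm, k = min(3L, n_samp - 1L))
    ordination$pcoa <- pc
    write.table(pc$coordinates, file.path(out_dir, "pcoa_braycurtis.tsv"),
                sep = "\t", quote = FALSE)
  }
  if (n_samp >= 4L) {
    nm <- nmds(dm, seed = seed)
    ordination$nmds <- nm
    write.table(nm$coordinates, file.path(out_dir, "nmds_braycurtis.tsv"),
                sep = "\t", quote = FALSE)
    logline("nmds_stress\t%.6f", nm$stress)
  }
  gtab <- table(groups)
  if (length(gtab) >= 2L && all(gtab >= 2L)) {
    tests$amova <- amova(dm, groups, n_perm = n_perm, seed = seed)
    tests$homova <- homova(dm, groups, n_perm = n_perm, seed = seed)
    tdf <- data.frame(test = c("amova", "homova"),
                      statistic = c(tests$amova$statistic,
                                    tests$homova$statistic),
                      p_value = c(tests$amova$p_value, tests$homova$p_value),
                      n_permutations = n_perm)
    write.table(tdf, file.path(out_dir, "hypothesis_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  network <- NULL
  if (n_samp >= 4L) {
    ft <- filter_network_otus(table, net)
    if (ncol(ft$counts) >= 2L) {
      pairs <- suppressWarnings(correlate_pairs(ft, net$method))
      network <- build_network(pairs, ft, taxonomy, net)
      write_gexf(network, file.path(out_dir, "network.gexf"))
      write.table(network$edges, file.path(out_dir, "network_edges.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      logline("network_edges\t%d", nrow(network$edges))
    }
  }
  invisible(list(prep_stats = prep$stats, otus = otus, table = table,
                 rarefied = rarefied, taxonomy = taxonomy, alpha = alpha,
                 distances = distances, trees = trees,
                 ordination = ordination, tests = tests, network = network,
                 groups = groups))
}

#' Detect candidate cross-talk between multiplexed samples
#'
#' For each OTU the report lists the samples where it is a major community
#' member (relative abundance above `major`) versus a trace presence (present,
#' but below `trace`), and flags every (OTU, trace sample) pair for which the
#' same OTU is major in at least one other sample — the classic signature of
#' index cross-talk. Raising `min_reads` or lowering `trace` can only reduce
#' the number of flags.
#'
#' @param table an [otu_table()] covering all samples of a run.
#' @param major minimum in-sample relative abundance counted as major.
#' @param trace maximum in-sample relative abundance counted as trace.
#' @param min_reads minimum read count for a trace presence to be considered.
#' @return data.frame with one row per flagged pair: `otu_id`, `sample`,
#'   `reads`, `rel_abundance`, `major_in` (comma-joined donor candidates).
#' @export
crosstalk_report <- function(table, major = 0.01, trace = 0.001,
                             min_reads = 1L) {
  m <- table$counts
  stopifnot(nrow(m) >= 2L)
  rel <- m / pmax(rowSums(m), 1L)
  flags <- list()
  for (j in seq_len(ncol(m))) {
    is_major <- rel[, j] > major
    if (!any(is_major)) next
    is_trace <- m[, j] >= min_reads & rel[, j] < trace & !is_major
    for (i in which(is_trace)) {
      flags[[length(flags) + 1L]] <- data.frame(
        otu_id = colnames(m)[j], sample = rownames(m)[i],
        reads = m[i, j], rel_abundance = rel[i, j],
        major_in = paste(rownames(m)[is_major], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(flags))
    return(data.frame(otu_id = character(0), sample = character(0),
                      reads = integer(0), rel_abundance = numeric(0),
                      major_in = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}
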