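# Mock-community read simulator: known 16S reference sets, ECC/EPC/UEC
# abundance designs with rRNA copy-number weighting, Illumina-like
# substitution errors with position-dependent qualities, and between-sample
# index cross-talk. Used to validate every pipeline stage end to end.

FWD_PRIMER <- "CCTACGGGAGGCAGCAG"
REV_PRIMER <- "GACTACHVGGGTATCTAATCC"

#' Mock community design
#'
#' The default design mirrors a classic three-way mock-community benchmark:
#' 25 bacterial members forming 21 distinct 16S sequence classes (three
#' multi-strain species — two groups of 2 and one of 3 — are indistinguishable
#' at the 16S level), four of which occur only in the uneven community at a
#' very low (~0.01%) abundance. The equal-cell (ECC) and equal-protein (EPC)
#' communities contain the remaining 21 members (17 classes).
#'
#' @param n_species number of community members (strains).
#' @param strain_groups list of member-index vectors sharing an identical 16S
#'   sequence.
#' @param uec_only member indices present only in the uneven community.
#' @param copy_numbers per-member 16S copies per genome (identical within a
#'   strain group); default: drawn in [generate_references()].
#' @param low_abundance_tail UEC abundance of the `uec_only` members.
#' @param divergence per-lineage substitution rate used when evolving the
#'   members from a common ancestor (pairwise divergence is about twice
#'   this).
#' @param insert_len length of the inter-primer amplicon insert.
#' @return a `mock_spec` list.
#' @export
mock_community_spec <- function(n_species = 25L,
                                strain_groups = list(c(12L, 13L), c(14L, 15L),
                                                     c(16L, 17L, 18L)),
                                uec_only = c(22L, 23L, 24L, 25L),
                                copy_numbers = NULL,
                                low_abundance_tail = 1e-4,
                                divergence = 0.04,
                                insert_len = 427L) {
  stopifnot(n_species >= 2L, divergence > 0, low_abundance_tail > 0)
  grouped <- unlist(strain_groups)
  if (anyDuplicated(grouped) || any(grouped > n_species))
    stop("invalid strain groups")
  if (any(uec_only %in% grouped))
    stop("uec_only members must be single strains")
  structure(list(n_species = as.integer(n_species),
                 strain_groups = strain_groups,
                 uec_only = as.integer(uec_only),
                 copy_numbers = copy_numbers,
                 low_abundance_tail = low_abundance_tail,
                 divergence = divergence,
                 insert_len = as.integer(insert_len)),
            class = "mock_spec")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_dna <- function(s, rate) {
  ch <- strsplit(s, "")[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

concretise_iupac <- function(p) {
  ch <- strsplit(p, "")[[1L]]
  paste(vapply(ch, function(c) {
    opts <- strsplit(IUPAC_CODES[[c]], "")[[1L]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Generate the mock community reference sequences
#'
#' Each member gets a ~1.5 kb 16S-like gene: a 5' flank, an exact forward
#' primer site, the insert, the reverse complement of a (concretised) reverse
#' primer site, and a 3' flank — so in-silico PCR yields an amplicon of
#' exactly `insert_len` nt after primer removal. Members are evolved from a
#' random common ancestor on a star topology and rejection-sampled until all
#' inter-class insert identities (full insert and its first 250 nt) fall
#' safely below 97%; strain-group members share identical sequences. Each
#' class receives a nested six-rank lineage and a 16S copy number.
#'
#' @param spec a [mock_community_spec()].
#' @param seed RNG seed.
#' @return data.frame with one row per member: `member`, `species`, `class_id`,
#'   `gene`, `amplicon`, `insert`, `lineage`, `copy_number`, `uec_only`.
#' @export
generate_references <- function(spec = mock_community_spec(), seed = 1L) {
  set.seed(seed)
  grouped <- spec$strain_groups
  n <- spec$n_species
  # class id per member
  class_id <- seq_len(n)
  for (g in grouped) class_id[g] <- min(g)
  class_id <- as.integer(factor(class_id, levels = unique(class_id)))
  n_class <- max(class_id)
  rev_site <- concretise_iupac(REV_PRIMER)
  anc_insert <- random_dna(spec$insert_len)
  flank5 <- random_dna(300L)
  flank3 <- random_dna(600L)
  margin <- 0.01
  lim_full <- floor((1 - (0.97 - margin)) * spec$insert_len)
  win <- min(250L, spec$insert_len)
  lim_win <- floor((1 - (0.97 - margin)) * win)
  inserts <- character(n_class)
  for (cl in seq_len(n_class)) {
    for (try in seq_len(200L)) {
      cand <- mutate_dna(anc_insert, spec$divergence)
      if (cl == 1L) { inserts[cl] <- cand; break }
      prev <- inserts[seq_len(cl - 1L)]
      dfull <- cpp_hamming_matrix(cand, prev)[1L, ]
      dwin <- cpp_hamming_matrix(substr(cand, 1L, win),
                                 substr(prev, 1L, win))[1L, ]
      if (all(dfull > lim_full) && all(dwin > lim_win)) {
        inserts[cl] <- cand; break
      }
      if (try == 200L)
        stop("divergence target unreachable for the requested number of species")
    }
  }
  copy_cls <- spec$copy_numbers
  if (is.null(copy_cls)) copy_cls <- sample(1:12, n_class, replace = TRUE)
  if (length(copy_cls) == n) copy_cls <- copy_cls[match(seq_len(n_class), class_id)]
  stopifnot(length(copy_cls) == n_class)
  lineage_of <- function(cl)
    paste(c("Bacteria",
            sprintf("Phylum_%02d", (cl - 1L) %/% 8L + 1L),
            sprintf("Class_%02d", (cl - 1L) %/% 4L + 1L),
            sprintf("Order_%02d", (cl - 1L) %/% 2L + 1L),
            sprintf("Family_%02d", (cl - 1L) %/% 2L + 1L),
            sprintf("Genus_%02d", cl)), collapse = ";")
  amplicon <- paste0(FWD_PRIMER, inserts, revcomp(rev_site))
  data.frame(
    member = sprintf("sp%02d", seq_len(n)),
    species = sprintf("Species_%02d", class_id),
    class_id = class_id,
    gene = paste0(flank5, amplicon[class_id], flank3),
    amplicon = amplicon[class_id],
    insert = inserts[class_id],
    lineage = vapply(class_id, lineage_of, character(1)),
    copy_number = copy_cls[class_id],
    uec_only = seq_len(n) %in% spec$uec_only,
    stringsAsFactors = FALSE)
}

#' Expected community profile for one design
#'
#' ECC: equal cells per member, weighted by 16S copy number and renormalised
#' (UEC-only members absent). EPC: cells proportional to the inverse of a
#' log-normal per-member protein mass, copy-number weighted (UEC-only members
#' absent). UEC: a log-uniform abundance ladder spanning four orders of
#' magnitude over the regular members, with the UEC-only members pinned at
#' `low_abundance_tail`.
#'
#' @param spec a [mock_community_spec()].
#' @param refs data.frame from [generate_references()].
#' @param profile "ECC", "EPC" or "UEC".
#' @param seed RNG seed (EPC mass draws, UEC ladder shuffle).
#' @return numeric vector of per-member relative abundances (zero for absent
#'   members), summing to 1.
#' @export
community_profile <- function(spec, refs, profile = c("ECC", "EPC", "UEC"),
                              seed = 1L) {
  profile <- match.arg(profile)
  set.seed(seed)
  n <- spec$n_species
  present <- if (profile == "UEC") rep(TRUE, n) else !refs$uec_only
  ab <- numeric(n)
  if (profile == "ECC") {
    ab[present] <- refs$copy_number[present]
  } else if (profile == "EPC") {
    mass <- rlnorm(n, meanlog = 0, sdlog = 0.5)
    ab[present] <- refs$copy_number[present] / mass[present]
  } else {
    main <- which(!refs$uec_only)
    ladder <- 10^(-3.5 * (seq_along(main) - 1L) / (length(main) - 1L))
    ab[sample(main)] <- ladder
    tail_members <- which(refs$uec_only)
    if (length(tail_members))
      ab[tail_members] <- spec$low_abundance_tail * sum(ab[main]) /
        (1 - length(tail_members) * spec$low_abundance_tail)
  }
  ab / sum(ab)
}

#' Position-dependent substitution error model
#'
#' Per-position error probability rises exponentially from `p0` at the read
#' start to `p0 * inflation` at the 3' end; the emitted Phred score is the
#' rounded `-10 log10 p`, clamped to \[2, 40\], and errors are injected with
#' probability exactly `10^(-Q/10)` so qualities and error rates agree by
#' construction.
#'
#' @param p0 error probability at the first cycle.
#' @param inflation fold increase of the error rate at the last cycle.
#' @return an `error_model` list.
#' @export
error_model <- function(p0 = 0.001, inflation = 10) {
  stopifnot(p0 >= 0, p0 < 0.75, inflation >= 1)
  structure(list(p0 = p0, inflation = inflation), class = "error_model")
}

error_profile <- function(model, read_len) {
  if (model$p0 == 0)
    return(list(p = rep(0, read_len), q = rep(40L, read_len)))
  raw <- model$p0 * model$inflation^((seq_len(read_len) - 1L) / max(read_len - 1L, 1L))
  q <- pmax(2L, pmin(40L, as.integer(round(-10 * log10(raw)))))
  list(p = 10^(-q / 10), q = q)
}

apply_errors <- function(seqs, p) {
  n <- length(seqs)
  if (!n || all(p == 0)) return(seqs)
  L <- nchar(seqs[1L])
  err <- matrix(runif(n * L), nrow = L) < p
  hits <- which(err, arr.ind = TRUE)
  if (nrow(hits)) {
    bases <- c("A", "C", "G", "T")
    for (h in seq_len(nrow(hits))) {
      pos <- hits[h, 1L]; rd <- hits[h, 2L]
      cur <- substr(seqs[rd], pos, pos)
      substr(seqs[rd], pos, pos) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

#' Simulate paired-end amplicon reads from a community
#'
#' Each pair is drawn from a member with probability equal to its abundance;
#' the forward read is the 5' prefix of the primered amplicon and the reverse
#' read the reverse complement of its 3' end, with substitution errors and
#' matching qualities injected per the error model.
#'
#' @param refs data.frame from [generate_references()].
#' @param abundances per-member relative abundances.
#' @param n_pairs number of read pairs.
#' @param read_len read length (2 x 300 MiSeq-style by default).
#' @param model an [error_model()].
#' @param seed RNG seed.
#' @param sample_name sample label stamped on the reads.
#' @return list with `fwd` and `rev` [seq_set()]s and `truth` (data.frame of
#'   per-member emitted read counts).
#' @export
simulate_reads <- function(refs, abundances, n_pairs, read_len = 300L,
                           model = error_model(), seed = 1L,
                           sample_name = "S1") {
  stopifnot(length(abundances) == nrow(refs), n_pairs >= 1L)
  set.seed(seed)
  member <- sample.int(nrow(refs), n_pairs, replace = TRUE, prob = abundances)
  prof <- error_profile(model, read_len)
  fwd_t <- substr(refs$amplicon, 1L, read_len)
  rev_t <- substr(revcomp(refs$amplicon), 1L, read_len)
  if (any(nchar(refs$amplicon) < read_len))
    stop("amplicon shorter than the read length")
  fwd <- apply_errors(fwd_t[member], prof$p)
  rev <- apply_errors(rev_t[member], prof$p)
  qstr <- intToUtf8(prof$q + 33L)
  # the emitting member rides along in the read id so truth can be traced
  ids <- sprintf("%s_r%06d_%s", sample_name, seq_len(n_pairs),
                 refs$member[member])
  truth <- data.frame(member = refs$member,
                      species = refs$species,
                      reads = tabulate(member, nbins = nrow(refs)),
                      stringsAsFactors = FALSE)
  list(fwd = seq_set(ids, fwd, quals = rep(qstr, n_pairs),
                     sample = sample_name),
       rev = seq_set(ids, rev, quals = rep(qstr, n_pairs),
                     sample = sample_name),
       truth = truth)
}

#' Inject between-sample index cross-talk
#'
#' Every read pair is reassigned to a uniformly chosen other sample with
#' probability `rate`; a truth log records each reassignment.
#'
#' @param samples named list, one entry per sample, each a list with `fwd` and
#'   `rev` [seq_set()]s (as produced by [simulate_reads()]).
#' @param rate per-read misassignment probability (0 <= rate < 0.1).
#' @param seed RNG seed.
#' @return list with `samples` (same shape, reads moved) and `log`
#'   (data.frame `read_id`, `from`, `to`).
#' @export
inject_crosstalk <- function(samples, rate, seed = 1L) {
  stopifnot(length(samples) >= 2L, rate >= 0, rate < 0.1)
  set.seed(seed)
  nms <- names(samples)
  moved <- list()
  dest_extra <- lapply(nms, function(x) integer(0))
  names(dest_extra) <- nms
  keep_idx <- list()
  for (s in nms) {
    n <- length(samples[[s]]$fwd)
    mv <- which(runif(n) < rate)
    keep_idx[[s]] <- setdiff(seq_len(n), mv)
    if (length(mv)) {
      dest <- sample(setdiff(nms, s), length(mv), replace = TRUE)
      moved[[s]] <- data.frame(read_id = samples[[s]]$fwd$id[mv],
                               from = s, to = dest,
                               stringsAsFactors = FALSE)
    }
  }
  log <- if (length(moved)) do.call(rbind, moved) else
    data.frame(read_id = character(0), from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  rownames(log) <- NULL
  out <- samples
  for (s in nms) {
    fwd_parts <- list(samples[[s]]$fwd[keep_idx[[s]]])
    rev_parts <- list(samples[[s]]$rev[keep_idx[[s]]])
    inc <- log[log$to == s, , drop = FALSE]
    for (src in unique(inc$from)) {
      idx <- match(inc$read_id[inc$from == src], samples[[src]]$fwd$id)
      fwd_parts <- c(fwd_parts, list(samples[[src]]$fwd[idx]))
      rev_parts <- c(rev_parts, list(samples[[src]]$rev[idx]))
    }
    fwd <- do.call(concat_seq_sets, fwd_parts)
    rev <- do.call(concat_seq_sets, rev_parts)
    if (length(fwd)) fwd$sample <- rep(s, length(fwd))
    if (length(rev)) rev$sample <- rep(s, length(rev))
    out[[s]]$fwd <- fwd
    out[[s]]$rev <- rev
  }
  list(samples = out, log = log)
}

#' Simulate a complete multi-sample mock run on disk
#'
#' Generates references, one set of per-type expected profiles, `n_replicates`
#' samples per community type at `n_pairs` pairs each, optional cross-talk,
#' and writes paired FASTQ files, `mapping.txt`, `oligos.txt`, the reference
#' FASTA + taxonomy file, and truth tables.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [mock_community_spec()].
#' @param profiles community types to simulate.
#' @param n_replicates samples per type.
#' @param n_pairs read pairs per sample.
#' @param read_len read length.
#' @param model an [error_model()].
#' @param crosstalk_rate per-read misassignment probability (0 disables).
#' @param seed RNG seed governing everything.
#' @return invisible list: `refs`, `expected` (per-member abundance matrix,
#'   samples x members), `mapping_path`, `oligos_path`, `crosstalk_log`,
#'   `truth` (per-sample emitted read counts).
#' @export
simulate_mock_dataset <- function(out_dir,
                                  spec = mock_community_spec(),
                                  profiles = c("ECC", "EPC", "UEC"),
                                  n_replicates = 4L, n_pairs = 5000L,
                                  read_len = 300L, model = error_model(),
                                  crosstalk_rate = 0, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- generate_references(spec, seed = seed)
  prof_ab <- sapply(profiles, function(p)
    community_profile(spec, refs, p, seed = seed + match(p, profiles)))
  samples <- list(); expected <- list(); truth <- list(); treatments <- character(0)
  for (p in profiles) for (r in seq_len(n_replicates)) {
    nm <- sprintf("%s_%d", p, r)
    sim <- simulate_reads(refs, prof_ab[, p], n_pairs, read_len, model,
                          seed = seed + 1000L * match(p, profiles) + r,
                          sample_name = nm)
    samples[[nm]] <- sim[c("fwd", "rev")]
    expected[[nm]] <- prof_ab[, p]
    truth[[nm]] <- sim$truth$reads
    treatments[nm] <- p
  }
  xlog <- NULL
  if (crosstalk_rate > 0) {
    xt <- inject_crosstalk(samples, crosstalk_rate, seed = seed + 77L)
    samples <- xt$samples
    xlog <- xt$log
    write.table(xlog, file.path(out_dir, "crosstalk_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  map <- character(0)
  for (nm in names(samples)) {
    f1 <- sprintf("%s_R1.fastq", nm); f2 <- sprintf("%s_R2.fastq", nm)
    write_fastq(samples[[nm]]$fwd, file.path(out_dir, f1))
    write_fastq(samples[[nm]]$rev, file.path(out_dir, f2))
    map <- c(map, paste(nm, treatments[nm], "+", f1, f2))
  }
  mapping_path <- file.path(out_dir, "mapping.txt")
  writeLines(c("#Sample treatment strand read1 read2", map), mapping_path)
  oligos_path <- file.path(out_dir, "oligos.txt")
  writeLines(c(paste("forward", FWD_PRIMER), paste("reverse", REV_PRIMER)),
             oligos_path)
  write_fasta(stats::setNames(refs$gene, refs$member),
              file.path(out_dir, "reference.fasta"))
  writeLines(paste0(refs$member, "\t", refs$lineage, ";"),
             file.path(out_dir, "reference.tax"))
  exp_m <- do.call(rbind, expected)
  colnames(exp_m) <- refs$member
  truth_m <- do.call(rbind, truth)
  colnames(truth_m) <- refs$member
  exp_df <- data.frame(sample = rownames(exp_m), treatment = treatments,
                       exp_m, check.names = FALSE)
  write.table(exp_df, file.path(out_dir, "expected_abundance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(refs = refs, expected = exp_m, truth = truth_m,
                 treatments = treatments,
                 mapping_path = mapping_path, oligos_path = oligos_path,
                 crosstalk_log = xlog))
}

#' Match OTU centroids back to reference sequence classes
#'
#' @param otus data.frame from [cluster_otus()].
#' @param refs data.frame from [generate_references()].
#' @param cutoff minimum identity for a match.
#' @return character vector: matched `species` (class) per OTU, NA when no
#'   reference reaches the cutoff.
#' @export
match_otus_to_references <- function(otus, refs, cutoff = 0.97) {
  classes <- refs[!duplicated(refs$class_id), ]
  vapply(otus$centroid, function(cen) {
    tpl <- substr(classes$insert, 1L, nchar(cen))
    ident <- identity_to_refs(cen, tpl)
    best <- which.max(ident)
    if (ident[best] >= cutoff) classes$species[best] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}
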