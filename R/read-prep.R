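#' Merging parameters
#'
#' @param min_overlap_len minimum length of the read-pair overlap, in bases.
#' @param max_diffs maximum number of mismatches tolerated inside the overlap.
#' @return a `merge_params` list.
#' @export
merge_params <- function(min_overlap_len = 100L, max_diffs = 8L) {
  stopifnot(min_overlap_len >= 1L, max_diffs >= 0L)
  structure(list(min_overlap_len = as.integer(min_overlap_len),
                 max_diffs = as.integer(max_diffs)), class = "merge_params")
}

#' Quality-filtering parameters
#'
#' @param trunclen fixed length every surviving read is truncated to.
#' @param maxee maximum expected errors over the truncated read.
#' @param pdiffs maximum mismatches tolerated against each primer.
#' @return a `filter_params` list.
#' @export
filter_params <- function(trunclen = 250L, maxee = 1.0, pdiffs = 2L) {
  stopifnot(trunclen >= 1L, maxee >= 0, pdiffs >= 0L)
  structure(list(trunclen = as.integer(trunclen), maxee = as.numeric(maxee),
                 pdiffs = as.integer(pdiffs)), class = "filter_params")
}

#' Merge paired-end reads
#'
#' Aligns each forward read against the reverse complement of its mate over
#' every ungapped offset whose overlap is at least `min_overlap_len`, scoring
#' matches minus mismatches and breaking ties toward the longer overlap. In
#' the overlap a single base and posterior quality are derived per column:
#' agreeing bases get `min(Q1 + Q2, 45)`; disagreeing columns keep the
#' higher-quality base with quality `max(2, |Q1 - Q2|)`. N never matches.
#'
#' A pair is rejected as `short_overlap` when no overlap of the required
#' length scores above chance (best score <= 0, or the reads are shorter than
#' the minimum overlap), and as `too_many_diffs` when the best overlap carries
#' more than `max_diffs` mismatches.
#'
#' @param fwd,rev [seq_set()]s of equal length with qualities (rev as read,
#'   i.e. not yet reverse-complemented).
#' @param params a [merge_params()].
#' @return list with `merged` (a [seq_set()] of fused reads), `status` (per
#'   input pair: "merged", "short_overlap" or "too_many_diffs"), `overlap` and
#'   `diffs` (per merged pair).
#' @export
merge_pairs <- function(fwd, rev, params = merge_params()) {
  stopifnot(inherits(fwd, "seq_set"), inherits(rev, "seq_set"),
            length(fwd) == length(rev))
  if (is.null(fwd$quals) || is.null(rev$quals))
    stop("merging requires qualities on both reads (posterior quality undefined)")
  if (!length(fwd))
    return(list(merged = seq_set(character(0), character(0), quals = character(0)),
                status = character(0), overlap = integer(0), diffs = integer(0)))
  res <- cpp_merge_pairs(fwd$bases, fwd$quals, rev$bases, rev$quals,
                         params$min_overlap_len, 45L)
  status <- rep("merged", length(fwd))
  status[is.na(res$score) | res$score <= 0L] <- "short_overlap"
  status[status == "merged" & res$diffs > params$max_diffs] <- "too_many_diffs"
  keep <- status == "merged"
  merged <- seq_set(fwd$id[keep], res$seq[keep], quals = res$qual[keep],
                    sample = if (!is.null(fwd$sample)) fwd$sample[keep] else NULL)
  list(merged = merged, status = status,
       overlap = res$overlap[keep], diffs = res$diffs[keep])
}

#' Trim amplicon primers off both read ends
#'
#' The best-matching forward primer is searched anchored at the 5' end and the
#' reverse complement of the best-matching reverse primer anchored at the 3'
#' end, IUPAC-aware, each allowing at most `pdiffs` mismatches (an N in the
#' read counts as a mismatch). Reads failing either primer are rejected, not
#' errored; both primers are removed from survivors and qualities are sliced
#' identically.
#'
#' @param recs a [seq_set()] of merged or single-end reads.
#' @param primers a `primer_set` (see [read_oligos()]).
#' @param pdiffs maximum mismatches against each primer.
#' @return list with `trimmed` (a [seq_set()]) and `status` per input read:
#'   "trimmed", "no_forward_primer" or "no_reverse_primer".
#' @export
trim_primers <- function(recs, primers, pdiffs = 2L) {
  stopifnot(inherits(recs, "seq_set"), inherits(primers, "primer_set"))
  n <- length(recs)
  if (!n) return(list(trimmed = recs, status = character(0)))
  fmm <- sapply(primers$forward, function(p)
    cpp_primer_mismatch(recs$bases, p, FALSE))
  fmm <- matrix(fmm, nrow = n)
  fbest <- max.col(-replace(fmm, is.na(fmm), .Machine$integer.max), "first")
  fdist <- fmm[cbind(seq_len(n), fbest)]
  rmm <- sapply(primers$reverse, function(p)
    cpp_primer_mismatch(recs$bases, revcomp(p), TRUE))
  rmm <- matrix(rmm, nrow = n)
  rbest <- max.col(-replace(rmm, is.na(rmm), .Machine$integer.max), "first")
  rdist <- rmm[cbind(seq_len(n), rbest)]
  status <- rep("trimmed", n)
  status[is.na(fdist) | fdist > pdiffs] <- "no_forward_primer"
  status[status == "trimmed" & (is.na(rdist) | rdist > pdiffs)] <- "no_reverse_primer"
  keep <- which(status == "trimmed")
  flen <- nchar(primers$forward)[fbest[keep]]
  rlen <- nchar(primers$reverse)[rbest[keep]]
  tot <- nchar(recs$bases[keep])
  status[keep[tot - flen - rlen < 1L]] <- "no_reverse_primer"
  keep <- which(status == "trimmed")
  flen <- nchar(primers$forward)[fbest[keep]]
  rlen <- nchar(primers$reverse)[rbest[keep]]
  tot <- nchar(recs$bases[keep])
  trimmed <- seq_set(recs$id[keep],
                     substr(recs$bases[keep], flen + 1L, tot - rlen),
                     quals = if (!is.null(recs$quals))
                       substr(recs$quals[keep], flen + 1L, tot - rlen) else NULL,
                     sample = if (!is.null(recs$sample)) recs$sample[keep] else NULL)
  list(trimmed = trimmed, status = status)
}

#' Expected errors of each read
#'
#' EE = sum over positions of 10^(-Q/10), optionally over a fixed-length
#' prefix only.
#'
#' @param recs a [seq_set()] with qualities.
#' @param trunclen optional prefix length (`NULL` = whole read).
#' @return numeric vector of expected-error sums.
#' @export
expected_errors <- function(recs, trunclen = NULL) {
  if (is.null(recs$quals)) stop("expected errors require qualities")
  cpp_expected_errors(recs$quals, if (is.null(trunclen)) 0L else as.integer(trunclen))
}

#' Truncate reads to a fixed length and filter on expected errors
#'
#' Reads shorter than `trunclen` are rejected (`too_short`); survivors are
#' truncated to exactly `trunclen` bases and rejected (`maxee_exceeded`) when
#' the expected errors of the truncated read exceed `maxee`.
#'
#' @param recs a [seq_set()] with qualities.
#' @param params a [filter_params()].
#' @return list with `passed` (truncated [seq_set()]) and `status` per read:
#'   "passed", "too_short" or "maxee_exceeded".
#' @export
quality_filter <- function(recs, params = filter_params()) {
  stopifnot(inherits(recs, "seq_set"))
  if (is.null(recs$quals)) stop("quality filtering requires qualities")
  n <- length(recs)
  if (!n) return(list(passed = recs, status = character(0)))
  status <- rep("passed", n)
  status[nchar(recs$bases) < params$trunclen] <- "too_short"
  ee <- cpp_expected_errors(recs$quals, params$trunclen)
  # tolerate float accumulation at the boundary: EE == maxee passes
  status[status == "passed" & ee > params$maxee + 1e-9] <- "maxee_exceeded"
  keep <- status == "passed"
  passed <- seq_set(recs$id[keep],
                    substr(recs$bases[keep], 1L, params$trunclen),
                    quals = substr(recs$quals[keep], 1L, params$trunclen),
                    sample = if (!is.null(recs$sample)) recs$sample[keep] else NULL)
  list(passed = passed, status = status)
}

#' Run the full read-preparation stage over all samples and pool the survivors
#'
#' For every mapping entry: read the input files, merge pairs (skipped for
#' single-end entries), trim primers, quality-filter, label each surviving
#' read with its sample name, and pool everything. Per-sample, per-reason
#' accounting is returned alongside; at every stage input = passed + sum of
#' discard reasons.
#'
#' @param mapping data.frame from [read_mapping()].
#' @param primers a `primer_set`.
#' @param mparams a [merge_params()].
#' @param fparams a [filter_params()].
#' @param input_dir directory the mapping's read paths are relative to.
#' @param seqformat "fastq" or "fasta" (FASTA expects sibling `.qual` files).
#' @return list with `reads` (pooled sample-labelled [seq_set()]) and `stats`
#'   (data.frame, one row per sample).
#' @export
pool_samples <- function(mapping, primers, mparams = merge_params(),
                         fparams = filter_params(), input_dir = ".",
                         seqformat = c("fastq", "fasta")) {
  seqformat <- match.arg(seqformat)
  read_one <- function(p) {
    fp <- file.path(input_dir, p)
    if (!file.exists(fp)) stop(sprintf("cannot read input file '%s'", fp))
    if (seqformat == "fastq") read_fastq(fp)
    else read_fasta_with_qual(fp, paste0(sub("\\.[^.]+$", "", fp), ".qual"))
  }
  pooled <- list()
  stats <- vector("list", nrow(mapping))
  for (i in seq_len(nrow(mapping))) {
    smp <- mapping$sample[i]
    fwd <- tryCatch(read_one(mapping$read1[i]), error = function(e)
      stop(sprintf("sample %s: %s", smp, conditionMessage(e)), call. = FALSE))
    paired <- !is.na(mapping$read2[i])
    if (paired) {
      rev <- tryCatch(read_one(mapping$read2[i]), error = function(e)
        stop(sprintf("sample %s: %s", smp, conditionMessage(e)), call. = FALSE))
      mg <- merge_pairs(fwd, rev, mparams)
      merged <- mg$merged
      n_short <- sum(mg$status == "short_overlap")
      n_diffs <- sum(mg$status == "too_many_diffs")
    } else {
      merged <- fwd
      n_short <- 0L; n_diffs <- 0L
    }
    tr <- trim_primers(merged, primers, fparams$pdiffs)
    qf <- quality_filter(tr$trimmed, fparams)
    surv <- qf$passed
    if (length(surv)) surv$sample <- rep(smp, length(surv))
    pooled[[i]] <- surv
    stats[[i]] <- data.frame(
      sample = smp,
      input = length(fwd),
      merged = length(merged),
      short_overlap = n_short,
      too_many_diffs = n_diffs,
      primer_trimmed = length(tr$trimmed),
      no_forward_primer = sum(tr$status == "no_forward_primer"),
      no_reverse_primer = sum(tr$status == "no_reverse_primer"),
      passed = length(surv),
      too_short = sum(qf$status == "too_short"),
      maxee_exceeded = sum(qf$status == "maxee_exceeded"),
      stringsAsFactors = FALSE)
  }
  list(reads = do.call(concat_seq_sets, pooled),
       stats = do.call(rbind, stats))
}
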