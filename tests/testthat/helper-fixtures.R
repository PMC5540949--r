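# Fixtures are built in code, deterministically.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(s, pos) {
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  }
  s
}

FWD_P <- "CCTACGGGAGGCAGCAG"
REV_P <- "GACTACHVGGGTATCTAATCC"
REV_SITE <- "GACTACACGGGTATCTAATCC"  # H -> A, V -> C

q_string <- function(q, len) paste(rep(intToUtf8(q + 33L), len), collapse = "")

# A toy amplicon: fwd primer + insert + revcomp(concrete reverse site).
toy_amplicon <- function(insert_len = 427L, seed = 42L) {
  paste0(FWD_P, rand_dna(insert_len, seed), revcomp(REV_SITE))
}

# One clean 2 x 300 read pair from an amplicon, uniform quality q.
toy_pair <- function(amplicon, read_len = 300L, q = 35L) {
  list(fwd = substr(amplicon, 1L, read_len),
       rev = substr(revcomp(amplicon), 1L, read_len),
       qual = q_string(q, read_len))
}

# Hand-constructed read set exercising every discard reason, with
# hand-enumerated truth counts. Layout (2 x 300 reads, amplicon 465 nt,
# overlap 135, trunclen 250):
#   4 clean pairs                                  -> passed
#   3 pairs of 250 nt reads (overlap 35 < 100)     -> short_overlap
#   2 pairs with 9 mismatches inside the overlap   -> too_many_diffs
#   2 pairs with 3 errors in the forward primer    -> no_forward_primer
#   1 pair  with 3 errors in the reverse primer    -> no_reverse_primer
#   2 pairs at uniform Q20 (EE(250) = 1.66 > 1)    -> maxee_exceeded
#   2 pairs from a 240 nt insert (trimmed 240<250) -> too_short
toy_filter_set <- function() {
  amp <- toy_amplicon()
  p <- toy_pair(amp)
  fwd <- character(0); rev <- character(0); quals <- character(0)
  add <- function(f, r, q) {
    fwd <<- c(fwd, f); rev <<- c(rev, r); quals <<- c(quals, q)
  }
  for (i in 1:4) add(p$fwd, p$rev, p$qual)
  short <- toy_pair(amp, read_len = 250L)
  for (i in 1:3) add(short$fwd, short$rev, short$qual)
  # overlap region of the forward read is positions 166..300
  bad_ov <- mutate_at(p$fwd, seq(170L, 290L, by = 15L))
  for (i in 1:2) add(bad_ov, p$rev, p$qual)
  bad_fp <- mutate_at(p$fwd, c(2L, 8L, 15L))
  for (i in 1:2) add(bad_fp, p$rev, p$qual)
  # reverse primer site = last 21 nt of the amplicon = start of the rev read
  bad_rp <- mutate_at(p$rev, c(3L, 9L, 20L))
  add(p$fwd, bad_rp, p$qual)
  lowq <- q_string(20L, 300L)
  for (i in 1:2) add(p$fwd, p$rev, lowq)
  amp2 <- toy_amplicon(insert_len = 240L, seed = 43L)  # amplicon 278 nt
  p2 <- toy_pair(amp2, read_len = 190L)                # overlap 102
  for (i in 1:2) add(p2$fwd, p2$rev, p2$qual)
  n <- length(fwd)
  list(fwd = seq_set(sprintf("r%02d", seq_len(n)), fwd, quals = quals),
       rev = seq_set(sprintf("r%02d", seq_len(n)), rev, quals = quals),
       truth = c(input = n, passed = 4L, short_overlap = 3L,
                 too_many_diffs = 2L, no_forward_primer = 2L,
                 no_reverse_primer = 1L, maxee_exceeded = 2L,
                 too_short = 2L))
}

toy_primers <- function() primer_set(FWD_P, REV_P)

# Write a toy sample to FASTQ pair + mapping + oligos in a temp dir.
write_toy_sample <- function(dir, set, sample = "S1", treatment = "T1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(set$fwd, file.path(dir, paste0(sample, "_R1.fastq")))
  write_fastq(set$rev, file.path(dir, paste0(sample, "_R2.fastq")))
  writeLines(c("#Sample treatment strand read1 read2",
               paste(sample, treatment, "+",
                     paste0(sample, "_R1.fastq"), paste0(sample, "_R2.fastq"))),
             file.path(dir, "mapping.txt"))
  writeLines(c(paste("forward", FWD_P), paste("reverse", REV_P)),
             file.path(dir, "oligos.txt"))
  invisible(dir)
}

# Small OTU table builder.
toy_table <- function(counts, samples = NULL, otus = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- samples %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- otus %||% paste0("OTU_", seq_len(ncol(m)))
  otu_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Distance matrix from a coordinate matrix.
dist_from_points <- function(pts) stats::dist(pts)

# Independent re-implementation of the greedy clustering definition, used as
# a brute-force oracle on tiny inputs (identity via pairwise_identity only).
oracle_greedy <- function(bases, sizes, cutoff) {
  cents <- character(0); csize <- integer(0)
  for (i in seq_along(bases)) {
    if (length(cents)) {
      ident <- vapply(cents, function(cc) pairwise_identity(bases[i], cc),
                      numeric(1))
      b <- which.max(ident)
      if (ident[b] >= cutoff) { csize[b] <- csize[b] + sizes[i]; next }
    }
    cents <- c(cents, bases[i]); csize <- c(csize, sizes[i])
  }
  list(centroids = cents, sizes = csize)
}
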