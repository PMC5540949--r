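test_that("merging recovers the template and enforces overlap thresholds", {
  tpl <- rand_dna(200L, seed = 1L)
  fwd <- seq_set("p", substr(tpl, 1, 150), quals = q_string(30L, 150L))
  rev <- seq_set("p", revcomp(substr(tpl, 51, 200)), quals = q_string(30L, 150L))
  m <- merge_pairs(fwd, rev)
  expect_equal(m$status, "merged")
  expect_equal(m$merged$bases, tpl)
  expect_equal(m$overlap, 100L)
  expect_equal(m$diffs, 0L)

  # overlap 99 -> short_overlap
  rev99 <- seq_set("p", revcomp(substr(tpl, 52, 200)), quals = q_string(30L, 149L))
  m99 <- merge_pairs(fwd, rev99)
  expect_equal(m99$status, "short_overlap")

  # 9 mismatches in a 100 nt overlap -> too_many_diffs at the default 8
  fwd9 <- fwd
  fwd9$bases <- mutate_at(fwd9$bases, seq(52L, 148L, by = 12L))
  m9 <- merge_pairs(fwd9, rev)
  expect_equal(m9$status, "too_many_diffs")
  expect_equal(merge_pairs(fwd9, rev, merge_params(max_diffs = 9L))$status,
               "merged")

  expect_error(merge_pairs(seq_set("a", "ACGT"), seq_set("a", "ACGT")),
               "qualities")
})

test_that("posterior quality rule: agreement boosts, disagreement keeps the better base", {
  tpl <- rand_dna(200L, seed = 2L)
  q30 <- q_string(30L, 150L)
  fwd <- seq_set("p", substr(tpl, 1, 150), quals = q30)
  rev <- seq_set("p", revcomp(substr(tpl, 51, 200)), quals = q30)
  m <- merge_pairs(fwd, rev)
  qs <- qual_scores(m$merged)[[1]]
  # agreeing Q30/Q30 columns in the overlap (positions 51..150) -> min(60,45)=45
  expect_true(all(qs[51:150] == 45L))
  expect_true(all(qs[1:50] == 30L))

  # disagreeing Q40/Q20 column: base of the Q40 read wins, Q becomes 20
  fwd2 <- fwd
  fwd2$quals <- paste0(strrep("I", 99), q_string(40L, 1L), strrep("I", 50))
  fwd2$bases <- mutate_at(fwd2$bases, 100L)  # now disagrees with rev in overlap
  fwd2$quals <- q_string(40L, 150L)
  rev2 <- rev
  rev2$quals <- q_string(20L, 150L)
  m2 <- merge_pairs(fwd2, rev2)
  expect_equal(m2$diffs, 1L)
  expect_equal(substr(m2$merged$bases, 100, 100), substr(fwd2$bases, 100, 100))
  expect_equal(qual_scores(m2$merged)[[1]][100], 20L)
})

test_that("error-free pairs reconstruct templates across a length sweep", {
  for (L in seq(180L, 200L, by = 4L)) {
    tpl <- rand_dna(L, seed = L)
    fwd <- seq_set("p", substr(tpl, 1, 150), quals = q_string(30L, 150L))
    rev <- seq_set("p", revcomp(substr(tpl, L - 149L, L)),
                   quals = q_string(30L, 150L))
    m <- merge_pairs(fwd, rev)
    expect_equal(m$merged$bases, tpl, info = sprintf("L=%d", L))
  }
})

test_that("primer trimming is anchored, IUPAC-aware and threshold-exact", {
  amp <- toy_amplicon()
  rec <- seq_set("a", amp, quals = q_string(35L, nchar(amp)))
  tr <- trim_primers(rec, toy_primers(), pdiffs = 0L)
  expect_equal(tr$status, "trimmed")
  expect_equal(nchar(tr$trimmed$bases), 427L)

  # read missing the reverse primer
  norev <- seq_set("a", paste0(FWD_P, rand_dna(427, 5)),
                   quals = q_string(35L, 444L))
  expect_equal(trim_primers(norev, toy_primers())$status, "no_reverse_primer")

  # 1 mismatch at the primer site: pdiffs 2 accepts, pdiffs 0 rejects
  amp1 <- mutate_at(amp, 5L)
  rec1 <- seq_set("a", amp1, quals = q_string(35L, nchar(amp1)))
  expect_equal(trim_primers(rec1, toy_primers(), pdiffs = 2L)$status, "trimmed")
  expect_equal(trim_primers(rec1, toy_primers(), pdiffs = 0L)$status,
               "no_forward_primer")

  # IUPAC H in the reverse primer matches A, C or T at zero cost
  for (b in c("A", "C", "T")) {
    site <- sub("H", b, REV_P, fixed = TRUE)
    site <- gsub("V", "G", site, fixed = TRUE)
    amp_b <- paste0(FWD_P, rand_dna(50, 6), revcomp(site))
    rec_b <- seq_set("a", amp_b, quals = q_string(35L, nchar(amp_b)))
    expect_equal(trim_primers(rec_b, toy_primers(), pdiffs = 0L)$status,
                 "trimmed")
  }

  # exact-match trim length identity
  expect_equal(nchar(tr$trimmed$bases),
               nchar(amp) - nchar(FWD_P) - nchar(REV_P))
})

test_that("expected-error filter matches the closed form and is monotone", {
  r <- seq_set("a", strrep("A", 100), quals = q_string(20L, 100L))
  expect_equal(expected_errors(r), 1.0)
  qf <- quality_filter(r, filter_params(trunclen = 100L, maxee = 1.0))
  expect_equal(qf$status, "passed")
  expect_equal(nchar(qf$passed$bases), 100L)
  expect_equal(quality_filter(r, filter_params(trunclen = 100L, maxee = 0.5))$status,
               "maxee_exceeded")
  short <- seq_set("a", strrep("A", 99), quals = q_string(20L, 99L))
  expect_equal(quality_filter(short, filter_params(trunclen = 100L))$status,
               "too_short")

  # EE monotone in prefix length; lowering maxee never passes more reads
  set.seed(3)
  qs <- lapply(1:20, function(i) sample(5:40, 120, replace = TRUE))
  recs <- seq_set(paste0("r", 1:20), rep(strrep("A", 120), 20), quals = qs)
  ee80 <- expected_errors(recs, 80)
  ee120 <- expected_errors(recs, 120)
  expect_true(all(ee120 >= ee80))
  for (me in c(0.25, 0.5, 1, 2)) {
    lo <- sum(quality_filter(recs, filter_params(100L, me / 2))$status == "passed")
    hi <- sum(quality_filter(recs, filter_params(100L, me))$status == "passed")
    expect_lte(lo, hi)
  }
})

test_that("pool_samples labels reads and its accounting reconciles", {
  set <- toy_filter_set()
  d <- withr::local_tempdir()
  write_toy_sample(d, set)
  mapping <- read_mapping(file.path(d, "mapping.txt"))
  primers <- read_oligos(file.path(d, "oligos.txt"))
  out <- pool_samples(mapping, primers, input_dir = d)
  st <- out$stats
  expect_equal(st$input, unname(set$truth["input"]))
  expect_equal(st$passed, unname(set$truth["passed"]))
  expect_equal(st$short_overlap, unname(set$truth["short_overlap"]))
  expect_equal(st$too_many_diffs, unname(set$truth["too_many_diffs"]))
  expect_equal(st$no_forward_primer, unname(set$truth["no_forward_primer"]))
  expect_equal(st$no_reverse_primer, unname(set$truth["no_reverse_primer"]))
  expect_equal(st$maxee_exceeded, unname(set$truth["maxee_exceeded"]))
  expect_equal(st$too_short, unname(set$truth["too_short"]))
  # stage-wise conservation
  expect_equal(st$input, st$merged + st$short_overlap + st$too_many_diffs)
  expect_equal(st$merged,
               st$primer_trimmed + st$no_forward_primer + st$no_reverse_primer)
  expect_equal(st$primer_trimmed, st$passed + st$too_short + st$maxee_exceeded)
  expect_true(all(out$reads$sample == "S1"))
  expect_error(pool_samples(data.frame(sample = "X", treatment = "t",
                                       strand = "+", read1 = "nope.fq",
                                       read2 = NA),
                            primers, input_dir = d),
               "sample X")
})
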