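test_that("pairwise identity handles substitutions and terminal overhangs", {
  a <- rand_dna(100L, seed = 11L)
  expect_equal(pairwise_identity(a, a), 1.0)
  b <- mutate_at(a, c(10L, 50L, 90L))
  expect_equal(pairwise_identity(a, b), 0.97)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  # terminal gaps excluded: a vs a + "ACGT" is identical
  expect_equal(pairwise_identity(a, paste0(a, "ACGT")), 1.0)
})

test_that("dereplication collapses, sorts by abundance and keeps sample splits", {
  reads <- seq_set(paste0("r", 1:3), c("AAA", "AAA", "CCC"),
                   sample = c("S1", "S1", "S2"))
  u <- dereplicate(reads)
  expect_equal(u$bases, c("AAA", "CCC"))
  expect_equal(u$size, c(2L, 1L))
  expect_equal(sum(u$size), 3L)
  reads2 <- seq_set(paste0("r", 1:3), rep("AAA", 3),
                    sample = c("S1", "S1", "S2"))
  u2 <- dereplicate(reads2)
  expect_equal(unname(u2$per_sample[1, c("S1", "S2")]), c(2L, 1L))
  expect_equal(length(dereplicate(seq_set(character(0), character(0)))), 0L)
})

test_that("singleton removal keeps only size >= 2", {
  u <- structure(list(bases = c("A", "C", "G", "T"), size = c(5L, 2L, 1L, 1L),
                      per_sample = matrix(c(5L, 2L, 1L, 1L), 4, 1,
                                          dimnames = list(NULL, "S1"))),
                 class = "unique_seqs")
  expect_equal(remove_singletons(u)$size, c(5L, 2L))
  expect_equal(length(remove_singletons(structure(list(
    bases = "A", size = 1L,
    per_sample = matrix(1L, 1, 1, dimnames = list(NULL, "S1"))),
    class = "unique_seqs"))), 0L)
})

test_that("chimera flagging detects two-parent crossovers and nothing else", {
  set.seed(21)
  A <- rand_dna(200L)
  B <- mutate_at(A, seq(3L, 198L, by = 7L))  # ~86% identical to A
  query <- paste0(substr(A, 1, 100), substr(B, 101, 200))
  expect_true(flag_chimera(query, c(A, B)))
  expect_false(flag_chimera(A, c(A, B)))       # identical to a parent
  expect_false(flag_chimera(query, character(0)))
  expect_false(flag_chimera(query, A))          # a single parent cannot chimerise
})

test_that("greedy clustering matches the identity cutoff semantics", {
  base <- rand_dna(200L, seed = 31L)
  near <- mutate_at(base, 1:2)             # 99% identical
  far <- mutate_at(base, seq(1L, 191L, by = 10L))  # 90% identical
  u <- function(bases, sizes) structure(
    list(bases = bases, size = as.integer(sizes),
         per_sample = matrix(as.integer(sizes), length(sizes), 1,
                             dimnames = list(NULL, "S1"))),
    class = "unique_seqs")
  expect_equal(nrow(cluster_otus(u(c(base, near), c(5, 3)))), 1L)
  expect_equal(nrow(cluster_otus(u(c(base, far), c(5, 3)))), 2L)
  otus <- cluster_otus(u(c(base, far), c(5, 3)))
  expect_equal(otus$otu_id, c("OTU_1", "OTU_2"))
  expect_equal(otus$size, c(5L, 3L))
})

test_that("clustering agrees with an independent greedy oracle; OTUs decrease with cutoff", {
  set.seed(41)
  anc <- rand_dna(150L)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    bases <- vapply(seq_len(n), function(i)
      mutate_at(anc, sample(150L, sample(0:12, 1))), character(1))
    sizes <- sort(sample(2:50, n), decreasing = TRUE)
    uq <- structure(list(bases = bases, size = as.integer(sizes),
                         per_sample = matrix(as.integer(sizes), n, 1,
                                             dimnames = list(NULL, "S1"))),
                    class = "unique_seqs")
    got <- cluster_otus(uq, cluster_params(chimera_skew = Inf))
    want <- oracle_greedy(bases, sizes, 0.97)
    expect_equal(got$centroid, want$centroids)
    expect_equal(got$size, want$sizes)
    n_otus <- vapply(c(0.90, 0.95, 0.97, 0.99, 1.0), function(s)
      nrow(cluster_otus(uq, cluster_params(similarity_cutoff = s,
                                           chimera_skew = Inf))),
      numeric(1))
    expect_true(all(diff(n_otus) >= 0))
  }
})

test_that("chimera flagging never fires when parents are within the cutoff", {
  set.seed(51)
  q <- rand_dna(200L)
  parents <- vapply(1:3, function(i) mutate_at(q, sample(200L, 3)), character(1))
  expect_false(flag_chimera(q, parents))
})

test_that("read mapping to centroids conserves counts and drops the unmatchable", {
  base <- rand_dna(200L, seed = 61L)
  far <- mutate_at(base, seq(1L, 191L, by = 10L))
  otus <- data.frame(otu_id = c("OTU_1", "OTU_2"), centroid = c(base, far),
                     size = c(0L, 0L), stringsAsFactors = FALSE)
  nowhere <- mutate_at(base, seq(2L, 192L, by = 5L))  # ~80% to both
  reads <- seq_set(paste0("r", 1:7),
                   c(rep(base, 3), rep(far, 2), mutate_at(base, 1L), nowhere),
                   sample = c("S1", "S1", "S2", "S2", "S2", "S1", "S1"))
  tab <- build_otu_table(reads, otus)
  expect_equal(unname(colSums(tab$counts)), c(4L, 2L))
  expect_equal(attr(tab, "dropped"), 1L)
  expect_equal(sum(tab$counts) + attr(tab, "dropped"), length(reads))
  # assignment is order-independent
  set.seed(62)
  tab2 <- build_otu_table(reads[sample(7)], otus)
  expect_identical(tab2$counts[rownames(tab$counts), colnames(tab$counts)],
                   tab$counts)
})

test_that("rarefaction subsamples exactly and matches the hypergeometric mean", {
  tab <- toy_table(rbind(c(100L, 0L), c(60L, 40L)))
  r <- rarefy_table(tab, depth = 10L, seed = 1L)
  expect_equal(unname(rowSums(r$counts)), c(10L, 10L))
  expect_equal(unname(r$counts[1, ]), c(10L, 0L))
  # depth = total leaves counts unchanged
  r2 <- rarefy_table(tab, depth = 100L, seed = 1L)
  expect_identical(r2$counts, tab$counts)
  expect_error(rarefy_table(tab, depth = 0L), "depth")
  tab_uneven <- toy_table(rbind(c(100L, 0L), c(30L, 40L)))
  expect_warning(rarefy_table(tab_uneven, depth = 80L), "dropping")

  tab5050 <- toy_table(matrix(c(50L, 50L), 1))
  draws <- vapply(seq_len(4000L), function(s)
    rarefy_table(tab5050, depth = 10L, seed = s)$counts[1, 1], integer(1))
  se <- sqrt(10 * 0.5 * 0.5 * 90 / 99) / sqrt(4000)
  expect_lt(abs(mean(draws) - 5), 3 * se)
  # determinism
  expect_identical(rarefy_table(tab, depth = 50L, seed = 9L)$counts,
                   rarefy_table(tab, depth = 50L, seed = 9L)$counts)
})
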