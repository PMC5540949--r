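# Alpha diversity, rarefaction, beta dissimilarity, UPGMA, ordination and
# distance-matrix permutation tests. Index definitions follow the Mothur
# calculators so shared tables moved between the two tools agree.

#' Alpha diversity of one sample
#'
#' Supported indices: `sobs` (observed richness), `chao` (Chao1), `ace`
#' (abundance-based coverage estimator, rare cutoff 10), `jackknife`
#' (first-order), `shannon` (natural log), `npshannon` (Chao-Shen
#' coverage-adjusted Shannon) and `simpson` (unbiased
#' `sum n_i (n_i - 1) / (N (N - 1))`).
#'
#' @param counts non-negative integer vector of OTU counts, not all zero.
#' @param index index name.
#' @return the index value.
#' @export
alpha_diversity <- function(counts,
                            index = c("sobs", "chao", "ace", "jackknife",
                                      "shannon", "npshannon", "simpson")) {
  index <- match.arg(index)
  x <- counts[counts > 0]
  if (!length(x)) stop("counts must not be all zero")
  N <- sum(x); S <- length(x)
  n1 <- sum(x == 1); n2 <- sum(x == 2)
  switch(index,
    sobs = S,
    chao = S + n1 * (n1 - 1) / (2 * (n2 + 1)),
    jackknife = S + n1 * (N - 1) / N,
    shannon = { p <- x / N; -sum(p * log(p)) },
    simpson = if (N < 2) 0 else sum(x * (x - 1)) / (N * (N - 1)),
    npshannon = {
      C <- 1 - n1 / N
      if (C <= 0) return(0)
      p <- C * x / N
      -sum(p * log(p) / (1 - (1 - p)^N))
    },
    ace = {
      rare <- x[x <= 10]; Sab <- sum(x > 10); Sr <- length(rare)
      Nr <- sum(rare)
      if (!Sr) return(Sab)
      Cace <- 1 - n1 / Nr
      if (Cace <= 0) return(S + n1 * (n1 - 1) / (2 * (n2 + 1)))
      i <- seq_len(10)
      Fi <- vapply(i, function(j) sum(rare == j), numeric(1))
      g2 <- max(Sr / Cace * sum(i * (i - 1) * Fi) / (Nr * (Nr - 1)) - 1, 0)
      Sab + Sr / Cace + n1 / Cace * g2
    })
}

#' Alpha diversity table for every sample
#' @param table an [otu_table()].
#' @param indices character vector of index names.
#' @return data.frame, one row per sample, one column per index.
#' @export
alpha_diversity_table <- function(table, indices = c("sobs", "chao", "ace",
                                                     "jackknife", "shannon",
                                                     "npshannon", "simpson")) {
  out <- data.frame(sample = rownames(table$counts), stringsAsFactors = FALSE)
  for (ix in indices)
    out[[ix]] <- apply(table$counts, 1L, alpha_diversity, index = ix)
  out
}

#' Rarefaction curve for one sample
#'
#' Mean observed richness over random subsamples without replacement at an
#' increasing ladder of depths; the final depth is the sample total, where the
#' curve equals `sobs` exactly.
#'
#' @param counts OTU count vector.
#' @param step depth increment.
#' @param n_resamples subsamples averaged per depth.
#' @param seed RNG seed.
#' @return data.frame with columns `depth` and `sobs`.
#' @export
rarefaction_curve <- function(counts, step = 100L, n_resamples = 100L, seed = 1L) {
  stopifnot(step >= 1L)
  N <- sum(counts)
  depths <- unique(c(1L, seq(step, N, by = step), N))
  set.seed(seed)
  pool <- rep.int(seq_along(counts), counts)
  sobs_at <- vapply(depths, function(d) {
    if (d >= N) return(sum(counts > 0))
    mean(vapply(seq_len(n_resamples), function(r)
      length(unique(pool[sample.int(N, d)])), numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, sobs = sobs_at)
}

#' Rank-abundance profile of one sample
#'
#' @param counts OTU count vector.
#' @return data.frame with `rank` and `rel_abundance`, sorted descending;
#'   zero-count OTUs are excluded and ties keep their original OTU order.
#' @export
rank_abundance <- function(counts) {
  x <- counts[counts > 0]
  if (!length(x)) stop("counts must not be all zero")
  x <- x[order(-x)]  # stable: ties keep original order
  data.frame(rank = seq_along(x), rel_abundance = as.numeric(x) / sum(x))
}

beta_pair <- function(a, b, measure) {
  switch(measure,
    braycurtis = sum(abs(a - b)) / sum(a + b),
    jclass = {
      SA <- sum(a > 0); SB <- sum(b > 0); SAB <- sum(a > 0 & b > 0)
      if (SA + SB == 0) 0 else 1 - SAB / (SA + SB - SAB)
    },
    jest = {
      chA <- alpha_diversity(a, "chao"); chB <- alpha_diversity(b, "chao")
      SAB <- sum(a > 0 & b > 0)
      1 - SAB / (chA + chB - SAB)
    },
    thetayc = {
      pa <- a / sum(a); pb <- b / sum(b)
      1 - sum(pa * pb) / (sum(pa^2) + sum(pb^2) - sum(pa * pb))
    })
}

#' Beta-diversity distance matrix
#'
#' Supported measures: `jclass` (Jaccard on membership), `jest` (Jaccard with
#' Chao1-estimated richnesses), `thetayc` (Yue-Clayton on relative
#' abundances) and `braycurtis` (on counts).
#'
#' @param table an [otu_table()] with >= 2 samples.
#' @param measure dissimilarity name.
#' @return a `dist` object over the samples.
#' @export
beta_distance <- function(table, measure = c("braycurtis", "jclass", "jest",
                                             "thetayc")) {
  measure <- match.arg(measure)
  m <- table$counts
  stopifnot(nrow(m) >= 2L)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d[i, j] <- d[j, i] <- beta_pair(m[i, ], m[j, ], measure)
  }
  as.dist(d)
}

#' UPGMA tree of samples
#'
#' Average-linkage agglomerative clustering of the distance matrix; the
#' resulting tree is ultrametric with leaf-to-root height equal to half the
#' final merge distance.
#'
#' @param dm a `dist` object (e.g. from [beta_distance()]).
#' @return an `ape` `phylo` tree.
#' @export
upgma_tree <- function(dm) {
  stopifnot(inherits(dm, "dist"), attr(dm, "Size") >= 2L)
  ape::as.phylo(hclust(dm, method = "average"))
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of `-d^2/2`,
#' eigendecomposition, coordinates scaled by the square roots of the positive
#' eigenvalues, axes ordered by descending eigenvalue.
#'
#' @param dm a `dist` object over >= 3 samples.
#' @param k number of axes (default: all positive-eigenvalue axes).
#' @return list with `coordinates` (samples x axes), `eigenvalues`, and
#'   `prop_explained` over the positive eigenvalues.
#' @export
pcoa <- function(dm, k = NULL) {
  n <- attr(dm, "Size")
  stopifnot(n >= 3L)
  if (is.null(k)) k <- n - 1L
  # cmdscale warns when k exceeds the embeddable rank; fewer axes come back
  sc <- suppressWarnings(cmdscale(dm, k = k, eig = TRUE))
  eig <- sc$eig
  pos <- eig[eig > 1e-12]
  list(coordinates = sc$points, eigenvalues = eig,
       prop_explained = if (length(pos)) pos / sum(pos) else numeric(0))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimisation (via [MASS::isoMDS()]) from a metric-scaling
#' start plus `n_starts - 1` random restarts; the lowest-stress configuration
#' wins. Deterministic given `seed`.
#'
#' @param dm a `dist` object over >= 4 samples.
#' @param n_axes embedding dimension.
#' @param n_starts number of starts.
#' @param seed RNG seed.
#' @return list with `coordinates`, `stress` (stress-1, as a fraction) and
#'   `seed`.
#' @export
nmds <- function(dm, n_axes = 2L, n_starts = 20L, seed = 1L) {
  n <- attr(dm, "Size")
  stopifnot(n >= 4L)
  d <- as.matrix(dm)
  # isoMDS cannot digest ties at zero; nudge exact zeros off the floor
  eps <- max(d) * 1e-9
  d[d <= 0] <- eps
  diag(d) <- 0
  dmx <- as.dist(d)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- if (s == 1L) cmdscale(dmx, k = n_axes)
            else matrix(rnorm(n * n_axes), n, n_axes)
    fit <- tryCatch(MASS::isoMDS(dmx, y = init, k = n_axes, trace = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("NMDS failed from every start")
  coords <- best$points
  rownames(coords) <- attr(dm, "Labels")
  list(coordinates = coords, stress = best$stress / 100, seed = seed)
}

ss_parts <- function(d2, groups) {
  N <- nrow(d2)
  tot <- sum(d2[upper.tri(d2)]) / N
  within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    within <- within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(total = tot, within = within)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Partitions squared distances into among- and within-group components and
#' tests `F = (SS_among / (k - 1)) / (SS_within / (N - k))` by label
#' permutation. P-values are `(1 + more extreme) / (1 + n_perm)`.
#'
#' @param dm a `dist` object.
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `statistic`, `p_value`, `n_permutations`, `seed`.
#' @export
amova <- function(dm, groups, n_perm = 999L, seed = 1L) {
  d2 <- as.matrix(dm)^2
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d2))
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("AMOVA needs at least 2 groups")
  if (any(sizes < 2L)) stop("every group must contain at least 2 samples")
  N <- nrow(d2); k <- length(sizes)
  fstat <- function(g) {
    ss <- ss_parts(d2, g)
    ((ss["total"] - ss["within"]) / (k - 1)) / (ss["within"] / (N - k))
  }
  obs <- fstat(groups)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) fstat(sample(groups)), numeric(1))
  list(statistic = unname(obs),
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_permutations = n_perm, seed = seed)
}

#' Homogeneity of molecular variance (HOMOVA)
#'
#' Bartlett-style test of equal within-group dispersion: the statistic
#' compares the pooled within-group mean squared distance against the
#' group-wise ones on a log scale and is zero when all dispersions are equal;
#' significance is assessed by label permutation.
#'
#' @inheritParams amova
#' @return list with `statistic`, `p_value`, `n_permutations`, `seed`.
#' @export
homova <- function(dm, groups, n_perm = 999L, seed = 1L) {
  d2 <- as.matrix(dm)^2
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d2))
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("HOMOVA needs at least 2 groups")
  if (any(sizes < 2L)) stop("every group must contain at least 2 samples")
  N <- nrow(d2); k <- length(sizes)
  bstat <- function(g) {
    ssw <- vapply(unique(g), function(gr) {
      idx <- which(g == gr)
      sub <- d2[idx, idx, drop = FALSE]
      sum(sub[upper.tri(sub)]) / length(idx)
    }, numeric(1))
    ng <- as.integer(table(g)[unique(g)])
    pooled <- sum(ssw) / (N - k)
    (N - k) * log(pooled) - sum((ng - 1) * log(ssw / (ng - 1)))
  }
  obs <- bstat(groups)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) bstat(sample(groups)), numeric(1))
  list(statistic = unname(obs),
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_permutations = n_perm, seed = seed)
}
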