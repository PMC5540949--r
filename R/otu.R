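#' Clustering parameters
#'
#' @param similarity_cutoff centroid-joining identity cutoff (fraction).
#' @param min_size minimum dereplicated abundance for centroid formation
#'   (2 = discard singletons).
#' @param chimera_skew minimum parent/query abundance ratio for chimera
#'   parents.
#' @param chimera_segment_identity per-segment identity both chimera halves
#'   must reach.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(similarity_cutoff = 0.97, min_size = 2L,
                           chimera_skew = 2.0, chimera_segment_identity = 0.99) {
  stopifnot(similarity_cutoff > 0, similarity_cutoff <= 1)
  structure(list(similarity_cutoff = similarity_cutoff,
                 min_size = as.integer(min_size),
                 chimera_skew = chimera_skew,
                 chimera_segment_identity = chimera_segment_identity),
            class = "cluster_params")
}

#' Pairwise identity of two DNA sequences
#'
#' Global alignment with free terminal gaps (match +1, mismatch -1, gap -2);
#' identity = matches / alignment columns, terminal gaps excluded. Symmetric.
#' For equal-length sequences the ungapped comparison is used directly.
#'
#' @param a,b DNA strings.
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    d <- cpp_hamming_matrix(a, b)[1L, 1L]
    return((nchar(a) - d) / nchar(a))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  cols <- length(pa)
  if (!cols) return(0)
  matches <- sum(pa == sa & pa != "-" & pa != "N")
  matches / cols
}

identity_to_refs <- function(query, refs) {
  L <- nchar(query)
  same <- nchar(refs) == L
  out <- numeric(length(refs))
  if (any(same)) {
    d <- cpp_hamming_matrix(query, refs[same])[1L, ]
    out[same] <- (L - d) / L
  }
  if (any(!same))
    out[!same] <- vapply(refs[!same], function(r) pairwise_identity(query, r),
                         numeric(1))
  out
}

#' Dereplicate reads into unique sequences
#'
#' Collapses identical base strings, keeping total and per-sample counts.
#' Output is sorted by abundance descending with ties broken lexicographically
#' by sequence, which makes the downstream greedy clustering deterministic.
#'
#' @param reads a sample-labelled [seq_set()].
#' @return a `unique_seqs` object: list with `bases`, `size` and a
#'   `per_sample` count matrix (uniques x samples).
#' @export
dereplicate <- function(reads) {
  stopifnot(inherits(reads, "seq_set"))
  if (!length(reads)) {
    out <- list(bases = character(0), size = integer(0),
                per_sample = matrix(0L, 0, 0))
    return(structure(out, class = "unique_seqs"))
  }
  samples <- reads$sample %||% rep("all", length(reads))
  tab <- table(bases = reads$bases, sample = samples)
  per_sample <- matrix(as.integer(tab), nrow = nrow(tab),
                       dimnames = list(rownames(tab), colnames(tab)))
  size <- as.integer(rowSums(per_sample))
  ord <- order(-size, rownames(per_sample))
  structure(list(bases = rownames(per_sample)[ord], size = size[ord],
                 per_sample = per_sample[ord, , drop = FALSE]),
            class = "unique_seqs")
}

#' @export
length.unique_seqs <- function(x) length(x$bases)

#' Drop unique sequences below an abundance floor
#'
#' With the default `min_size = 2` this discards singletons so that
#' error-derived sequences cannot seed OTU centroids.
#'
#' @param uniques a `unique_seqs` object.
#' @param min_size minimum total abundance retained.
#' @return a filtered `unique_seqs`.
#' @export
remove_singletons <- function(uniques, min_size = 2L) {
  keep <- uniques$size >= min_size
  structure(list(bases = uniques$bases[keep], size = uniques$size[keep],
                 per_sample = uniques$per_sample[keep, , drop = FALSE]),
            class = "unique_seqs")
}

chimera_flag_one <- function(query, parent_bases, cutoff, seg_identity) {
  if (length(parent_bases) < 2L) return(FALSE)
  L <- nchar(query)
  equal <- nchar(parent_bases) == L
  parent_bases <- parent_bases[equal]
  if (length(parent_bases) < 2L) return(FALSE)
  q <- strsplit(query, "")[[1L]]
  mism <- vapply(strsplit(parent_bases, ""),
                 function(p) cumsum(p != q | q == "N"), numeric(L))
  mism <- matrix(mism, nrow = L)  # positions x parents
  full <- mism[L, ]
  if (max((L - full) / L) >= cutoff) return(FALSE)
  maxm_left <- floor((1 - seg_identity) * seq_len(L - 1L))
  maxm_right <- floor((1 - seg_identity) * (L - seq_len(L - 1L)))
  for (cpos in seq_len(L - 1L)) {
    A <- which(mism[cpos, ] <= maxm_left[cpos])
    B <- which((full - mism[cpos, ]) <= maxm_right[cpos])
    # two distinct parents must supply the prefix and the suffix
    if (length(A) && length(B) &&
        !(length(A) == 1L && length(B) == 1L && A == B)) return(TRUE)
  }
  FALSE
}

#' Flag a candidate chimera against a set of parents
#'
#' Simplified two-parent, single-crossover model: the query is chimeric when
#' some crossover column splits it into a prefix >= 99% identical to one
#' parent and a suffix >= 99% identical to a different parent, while no single
#' parent reaches the clustering identity cutoff, and all parents are at least
#' `chimera_skew` times as abundant as the query.
#'
#' @param query a `unique_seqs` entry as a list with `bases` and `size`, or a
#'   bare DNA string.
#' @param parents character vector of candidate parent sequences (already
#'   abundance-screened) or a `unique_seqs`.
#' @param params a [cluster_params()].
#' @return logical.
#' @export
flag_chimera <- function(query, parents, params = cluster_params()) {
  qbases <- if (is.list(query)) query$bases else query
  pbases <- if (inherits(parents, "unique_seqs") || is.list(parents))
    parents$bases else parents
  if (!length(pbases)) return(FALSE)
  chimera_flag_one(qbases, pbases, params$similarity_cutoff,
                   params$chimera_segment_identity)
}

#' Greedy centroid clustering of unique sequences into OTUs
#'
#' One pass over the abundance-sorted uniques: each sequence joins the
#' highest-identity existing centroid at or above the similarity cutoff; a
#' sequence matching no centroid is discarded if it looks chimeric against
#' sufficiently abundant current centroids, and otherwise founds a new OTU.
#' OTU ids are numbered in creation order.
#'
#' @param uniques a `unique_seqs`, sorted by abundance (as [dereplicate()]
#'   returns) and singleton-free (see [remove_singletons()]).
#' @param params a [cluster_params()].
#' @return data.frame with columns `otu_id`, `centroid`, `size` (total
#'   abundance of member uniques); attribute `chimeras` holds discarded
#'   sequences.
#' @export
cluster_otus <- function(uniques, params = cluster_params()) {
  n <- length(uniques$bases)
  cents <- character(0); csize <- integer(0); cabund <- integer(0)
  chim <- character(0)
  for (i in seq_len(n)) {
    qy <- uniques$bases[i]; qsz <- uniques$size[i]
    if (length(cents)) {
      ident <- identity_to_refs(qy, cents)
      best <- which.max(ident)
      if (ident[best] >= params$similarity_cutoff) {
        csize[best] <- csize[best] + qsz
        next
      }
      parents <- cents[cabund >= params$chimera_skew * qsz]
      if (length(parents) >= 2L &&
          chimera_flag_one(qy, parents, params$similarity_cutoff,
                           params$chimera_segment_identity)) {
        chim <- c(chim, qy)
        next
      }
    }
    cents <- c(cents, qy)
    csize <- c(csize, qsz)
    cabund <- c(cabund, qsz)
  }
  out <- data.frame(otu_id = paste0("OTU_", seq_along(cents)),
                    centroid = cents, size = csize,
                    stringsAsFactors = FALSE)
  attr(out, "chimeras") <- chim
  out
}

#' Construct an OTU table
#'
#' @param counts samples x OTUs matrix of non-negative integer counts with
#'   dimnames.
#' @param otus optional data.frame of OTU metadata (`otu_id`, `centroid`,
#'   `size`) aligned with the columns of `counts`.
#' @return an `amp_otu_table`.
#' @export
otu_table <- function(counts, otus = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0L))
    stop("OTU counts must be non-negative integers")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU_", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (!is.null(otus)) {
    stopifnot(nrow(otus) == ncol(counts))
    otus$size <- as.integer(colSums(counts))
  }
  structure(list(counts = counts, otus = otus), class = "amp_otu_table")
}

#' @export
print.amp_otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d sample(s) x %d OTU(s), %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Map all reads (including former singletons) onto OTU centroids
#'
#' Every read is assigned to the highest-identity centroid at or above the
#' similarity cutoff; unassignable reads are dropped and counted. Counts are
#' split by sample label.
#'
#' @param reads the pooled, filtered, sample-labelled [seq_set()] (or a
#'   `unique_seqs` from [dereplicate()]).
#' @param otus data.frame from [cluster_otus()].
#' @param params a [cluster_params()].
#' @return an [otu_table()]; attribute `dropped` gives the unassigned read
#'   count.
#' @export
build_otu_table <- function(reads, otus, params = cluster_params()) {
  stopifnot(nrow(otus) > 0L)
  uniq <- if (inherits(reads, "unique_seqs")) reads else dereplicate(reads)
  k <- nrow(otus)
  nu <- length(uniq$bases)
  samples <- colnames(uniq$per_sample)
  counts <- matrix(0L, nrow = ncol(uniq$per_sample), ncol = k,
                   dimnames = list(samples, otus$otu_id))
  dropped <- 0L
  if (nu) {
    L <- nchar(uniq$bases)
    cl <- nchar(otus$centroid)
    ident <- matrix(0, nu, k)
    if (length(unique(c(L, cl))) == 1L) {
      d <- cpp_hamming_matrix(uniq$bases, otus$centroid)
      ident <- (L[1L] - d) / L[1L]
    } else {
      for (i in seq_len(nu)) ident[i, ] <- identity_to_refs(uniq$bases[i], otus$centroid)
    }
    best <- max.col(ident, "first")
    bestv <- ident[cbind(seq_len(nu), best)]
    assigned <- bestv >= params$similarity_cutoff
    dropped <- sum(uniq$size[!assigned])
    for (j in which(assigned)) {
      counts[, best[j]] <- counts[, best[j]] + uniq$per_sample[j, ]
    }
  }
  out <- otu_table(counts, otus)
  attr(out, "dropped") <- dropped
  out
}

#' Rarefy an OTU table to an even depth
#'
#' Each sample's counts are replaced by a uniform subsample without
#' replacement of exactly `depth` reads; samples with fewer reads than `depth`
#' are dropped with a warning. Deterministic given `seed`.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (default: smallest sample total).
#' @param seed RNG seed.
#' @return a rarefied [otu_table()].
#' @export
rarefy_table <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "amp_otu_table"))
  totals <- rowSums(table$counts)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0L) stop("rarefaction depth must be >= 1")
  keep <- totals >= depth
  if (any(!keep))
    warning(sprintf("dropping %d sample(s) with fewer than %d reads",
                    sum(!keep), depth))
  counts <- table$counts[keep, , drop = FALSE]
  set.seed(seed)
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    if (sum(x) == depth) next
    picked <- sample.int(sum(x), depth)
    cum <- cumsum(x)
    counts[i, ] <- tabulate(findInterval(picked - 1L, c(0L, cum),
                                         rightmost.closed = FALSE),
                            nbins = length(x))
  }
  otu_table(counts, table$otus)
}
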