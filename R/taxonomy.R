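# Naive-Bayes k-mer classifier with bootstrap confidence (the Wang method
# behind Mothur's classify.seqs), on word presence rather than word counts.

seq_words <- function(s, k) {
  L <- nchar(s)
  if (L < k) stop(sprintf("sequence shorter than word size k = %d", k))
  starts <- seq_len(L - k + 1L)
  w <- substring(s, starts, starts + k - 1L)
  unique(w[!grepl("N", w, fixed = TRUE)])
}

#' Train the k-mer taxonomy classifier
#'
#' Builds per-genus word-presence profiles over the reference sequences. A
#' word's prior is `P(w) = (n_w + 0.5) / (N + 1)` over the `N` references, and
#' its per-genus conditional is `(m_w + P(w)) / (M + 1)` where `m_w` counts
#' genus members containing the word and `M` is the genus size.
#'
#' @param refs list of reference records, each a list with `bases` (DNA) and
#'   `lineage` (character vector of ranks, domain to genus; equal depth across
#'   references). A data.frame with columns `bases` and `lineage`
#'   (semicolon-separated) is also accepted.
#' @param k word size (4-12).
#' @return a `reference_db`.
#' @export
train_classifier <- function(refs, k = 8L) {
  stopifnot(k >= 4L, k <= 12L)
  if (is.data.frame(refs))
    refs <- lapply(seq_len(nrow(refs)), function(i)
      list(bases = refs$bases[i], lineage = strsplit(refs$lineage[i], ";")[[1L]]))
  depths <- lengths(lapply(refs, `[[`, "lineage"))
  if (length(unique(depths)) != 1L)
    stop("inconsistent lineage depths across references")
  lineages <- do.call(rbind, lapply(refs, `[[`, "lineage"))
  genera <- lineages[, ncol(lineages)]
  if (length(unique(genera)) < 2L)
    stop("training requires at least 2 distinct genera")
  words_per_ref <- lapply(refs, function(r) seq_words(toupper(r$bases), k))
  vocab <- unique(unlist(words_per_ref))
  N <- length(refs)
  nw <- table(factor(unlist(words_per_ref), levels = vocab))
  prior <- (as.numeric(nw) + 0.5) / (N + 1)
  glev <- unique(genera)
  M <- as.integer(table(factor(genera, levels = glev)))
  logp <- matrix(0, nrow = length(vocab), ncol = length(glev),
                 dimnames = list(vocab, glev))
  for (g in seq_along(glev)) {
    members <- which(genera == glev[g])
    mw <- table(factor(unlist(words_per_ref[members]), levels = vocab))
    logp[, g] <- log((as.numeric(mw) + prior) / (M[g] + 1))
  }
  unseen <- log((0.5 / (N + 1)) / (M + 1))
  glin <- lineages[match(glev, genera), , drop = FALSE]
  rownames(glin) <- glev
  structure(list(k = as.integer(k), vocab = vocab, logp = logp,
                 unseen = unseen, genera = glev, lineages = glin),
            class = "reference_db")
}

#' Classify a sequence with bootstrap confidence
#'
#' Scores each genus as the sum of log word probabilities over the query's
#' word set; bootstrap confidence at every rank is the fraction of `n_boot`
#' resamples of `floor(W/8)` words whose winning genus falls under that rank's
#' taxon. Ranks below `conf_cutoff` are reported as "unclassified".
#'
#' @param seq query DNA string (length >= k).
#' @param db a `reference_db` from [train_classifier()].
#' @param n_boot number of bootstrap resamples.
#' @param conf_cutoff minimum bootstrap confidence to report a rank.
#' @param seed RNG seed for resampling.
#' @return data.frame with columns `rank`, `taxon`, `confidence`.
#' @export
classify <- function(seq, db, n_boot = 100L, conf_cutoff = 0.80, seed = 1L) {
  stopifnot(inherits(db, "reference_db"))
  words <- seq_words(toupper(seq), db$k)
  idx <- match(words, db$vocab)  # NA = unseen word
  W <- length(idx)
  contrib <- matrix(db$unseen, nrow = W, ncol = length(db$genera), byrow = TRUE)
  seen <- !is.na(idx)
  contrib[seen, ] <- db$logp[idx[seen], , drop = FALSE]
  full_win <- which.max(colSums(contrib))
  nsub <- max(1L, W %/% 8L)
  set.seed(seed)
  wins <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    pick <- sample.int(W, nsub, replace = TRUE)
    wins[b] <- which.max(colSums(contrib[pick, , drop = FALSE]))
  }
  ranks <- colnames(db$lineages) %||%
    c("domain", "phylum", "class", "order", "family", "genus")[seq_len(ncol(db$lineages))]
  lin <- db$lineages[full_win, ]
  conf <- vapply(seq_along(lin), function(r)
    mean(db$lineages[wins, r] == lin[r]), numeric(1))
  taxon <- ifelse(conf >= conf_cutoff, lin, "unclassified")
  # once a rank is unclassified, everything below it is too
  if (any(taxon == "unclassified")) {
    first <- which(taxon == "unclassified")[1L]
    taxon[first:length(taxon)] <- "unclassified"
  }
  data.frame(rank = ranks, taxon = taxon, confidence = conf,
             stringsAsFactors = FALSE)
}

#' Classify every OTU centroid
#'
#' @param otus data.frame from [cluster_otus()].
#' @param db a `reference_db`.
#' @param ... passed to [classify()].
#' @return data.frame with one row per OTU: `otu_id`, `taxonomy`
#'   (semicolon-joined taxa with bootstrap percentages), `genus`.
#' @export
classify_otus <- function(otus, db, ...) {
  rows <- lapply(seq_len(nrow(otus)), function(i) {
    a <- classify(otus$centroid[i], db, ...)
    data.frame(otu_id = otus$otu_id[i],
               taxonomy = paste(sprintf("%s(%d)", a$taxon,
                                        round(100 * a$confidence)),
                                collapse = ";"),
               genus = a$taxon[nrow(a)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a reference database from FASTA plus a Mothur-style taxonomy file
#'
#' The taxonomy file is tab-separated `id<TAB>Domain;Phylum;...;Genus;` with
#' an optional trailing semicolon.
#'
#' @param fasta_path reference sequences.
#' @param tax_path taxonomy file.
#' @return a list of records suitable for [train_classifier()].
#' @export
read_reference_db <- function(fasta_path, tax_path) {
  seqs <- read_fasta_with_qual(fasta_path)
  tax <- read.table(tax_path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("id", "lineage"))
  ord <- match(seqs$id, tax$id)
  if (any(is.na(ord))) stop("taxonomy file is missing ids present in the FASTA")
  lapply(seq_along(seqs$id), function(i)
    list(bases = seqs$bases[i],
         lineage = strsplit(sub(";$", "", tax$lineage[ord[i]]), ";")[[1L]]))
}
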