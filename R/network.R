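#' Co-occurrence network parameters
#'
#' @param min_rel_abundance minimum overall relative abundance an OTU must
#'   reach to enter the network (default 0.1%).
#' @param min_samples minimum number of samples an OTU must occur in.
#' @param method correlation method.
#' @param r_min minimum absolute correlation for an edge.
#' @param p_max maximum p-value for an edge.
#' @param positive_only if `TRUE`, threshold on the signed coefficient rather
#'   than its magnitude (discards negative correlations).
#' @return a `network_params` list.
#' @export
network_params <- function(min_rel_abundance = 0.001, min_samples = 2L,
                           method = c("spearman", "pearson"), r_min = 0.6,
                           p_max = 0.01, positive_only = FALSE) {
  method <- match.arg(method)
  stopifnot(min_rel_abundance >= 0, min_rel_abundance < 1,
            r_min > 0, r_min <= 1, p_max > 0, p_max < 1)
  structure(list(min_rel_abundance = min_rel_abundance,
                 min_samples = as.integer(min_samples), method = method,
                 r_min = r_min, p_max = p_max, positive_only = positive_only),
            class = "network_params")
}

#' Filter infrequent OTUs before network inference
#'
#' Retains OTUs whose overall relative abundance is at least
#' `min_rel_abundance` and which occur in at least `min_samples` samples.
#'
#' @param table an [otu_table()].
#' @param params a [network_params()].
#' @return the filtered [otu_table()].
#' @export
filter_network_otus <- function(table, params = network_params()) {
  m <- table$counts
  rel <- colSums(m) / sum(m)
  occ <- colSums(m > 0)
  keep <- rel >= params$min_rel_abundance & occ >= params$min_samples
  otus <- table$otus
  if (!is.null(otus)) otus <- otus[keep, , drop = FALSE]
  otu_table(m[, keep, drop = FALSE], otus)
}

#' Pairwise OTU correlations with p-values
#'
#' Computes, for every unordered OTU pair, the Pearson correlation of the
#' count vectors (Spearman = Pearson on midranks) and a two-sided p-value
#' from `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs involving a constant vector are skipped with a warning.
#'
#' @param table an [otu_table()] with >= 4 samples.
#' @param method "spearman" or "pearson".
#' @return data.frame with columns `otu_i`, `otu_j`, `r`, `p`, `method`.
#' @export
correlate_pairs <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- table$counts
  n <- nrow(m)
  stopifnot(n >= 4L)
  v <- if (method == "spearman") apply(m, 2L, rank) else m
  const <- apply(v, 2L, function(x) sd(x) == 0)
  if (any(const))
    warning(sprintf("skipping %d constant OTU vector(s)", sum(const)))
  ids <- colnames(m)
  keep <- which(!const)
  if (length(keep) < 2L)
    return(data.frame(otu_i = character(0), otu_j = character(0),
                      r = numeric(0), p = numeric(0), method = character(0)))
  cm <- cor(v[, keep, drop = FALSE])
  pr <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[pr]
  r_cl <- pmin(pmax(r, -1), 1)
  tt <- r_cl * sqrt((n - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(r_cl) == 1] <- 0
  data.frame(otu_i = ids[keep][pr[, 1L]], otu_j = ids[keep][pr[, 2L]],
             r = r, p = p, method = method, stringsAsFactors = FALSE)
}

#' Build the thresholded co-occurrence graph
#'
#' Keeps pairs with `|r| >= r_min` (or `r >= r_min` when `positive_only`) and
#' `p <= p_max`. Isolated OTUs are excluded from the node set by default.
#'
#' @param pairs data.frame from [correlate_pairs()] computed on the filtered
#'   table.
#' @param table the filtered [otu_table()] the pairs came from (for node
#'   abundances).
#' @param taxonomy optional data.frame from [classify_otus()].
#' @param params a [network_params()].
#' @param keep_isolated include edge-less OTUs as nodes.
#' @return a `cooccurrence_graph`: list with `nodes` and `edges` data.frames.
#' @export
build_network <- function(pairs, table, taxonomy = NULL,
                          params = network_params(), keep_isolated = FALSE) {
  strength <- if (params$positive_only) pairs$r else abs(pairs$r)
  keep <- strength >= params$r_min & pairs$p <= params$p_max
  edges <- data.frame(from = pairs$otu_i[keep], to = pairs$otu_j[keep],
                      r = pairs$r[keep], p = pairs$p[keep],
                      method = pairs$method[keep], stringsAsFactors = FALSE)
  ids <- colnames(table$counts)
  if (!keep_isolated) ids <- ids[ids %in% c(edges$from, edges$to)]
  tax <- rep("", length(ids))
  if (!is.null(taxonomy)) {
    hit <- match(ids, taxonomy$otu_id)
    tax[!is.na(hit)] <- taxonomy$taxonomy[hit[!is.na(hit)]]
  }
  nodes <- data.frame(id = ids, taxonomy = tax,
                      abundance = colSums(table$counts)[ids],
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "cooccurrence_graph")
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  cat(sprintf("co-occurrence graph: %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
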