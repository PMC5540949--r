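#' Construct a set of sequence records
#'
#' A `seq_set` holds one or more reads/sequences as parallel vectors: an id, a
#' DNA string over A/C/G/T/N, an optional Phred+33-encoded quality string of
#' the same length, and an optional sample label. It is the container every
#' pipeline stage consumes and produces.
#'
#' @param id character vector of non-empty record identifiers.
#' @param bases character vector of DNA strings.
#' @param quals per-record qualities: either a character vector of Phred+33
#'   strings, a list of integer vectors (Phred scores in \[0, 45\]), or `NULL`
#'   when qualities are absent.
#' @param sample optional character vector of sample labels (recycled).
#' @return an object of class `seq_set`.
#' @export
seq_set <- function(id, bases, quals = NULL, sample = NULL) {
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  if (length(id) != length(bases)) stop("id and bases lengths differ")
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  if (is.list(quals)) {
    qv <- unlist(quals, use.names = FALSE)
    if (length(qv) && (min(qv) < 0L || max(qv) > 45L))
      stop("Phred scores must lie in [0, 45]")
    quals <- phred_to_char(quals)
  }
  if (!is.null(quals)) {
    quals <- as.character(quals)
    if (length(quals) != length(bases)) stop("quals and bases lengths differ")
    if (any(nchar(quals) != nchar(bases)))
      stop("quality string length must equal sequence length")
  }
  if (!is.null(sample)) sample <- rep_len(as.character(sample), length(bases))
  structure(list(id = id, bases = bases, quals = quals, sample = sample),
            class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$bases)

#' @export
`[.seq_set` <- function(x, i) {
  seq_set(x$id[i], x$bases[i],
          quals = if (!is.null(x$quals)) x$quals[i] else NULL,
          sample = if (!is.null(x$sample)) x$sample[i] else NULL)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d record(s)%s%s\n", length(x),
              if (is.null(x$quals)) ", no qualities" else ", with qualities",
              if (is.null(x$sample)) "" else ", sample-labelled"))
  invisible(x)
}

#' Concatenate sequence sets
#' @param ... `seq_set` objects.
#' @return a single `seq_set`.
#' @export
concat_seq_sets <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, length, integer(1)) > 0L]
  if (!length(xs)) return(seq_set(character(0), character(0)))
  has_q <- all(vapply(xs, function(x) !is.null(x$quals), logical(1)))
  has_s <- all(vapply(xs, function(x) !is.null(x$sample), logical(1)))
  seq_set(unlist(lapply(xs, `[[`, "id")),
          unlist(lapply(xs, `[[`, "bases")),
          quals = if (has_q) unlist(lapply(xs, `[[`, "quals")) else NULL,
          sample = if (has_s) unlist(lapply(xs, `[[`, "sample")) else NULL)
}

#' Per-record Phred scores as integer vectors
#' @param x a `seq_set` with qualities.
#' @return list of integer vectors.
#' @export
qual_scores <- function(x) {
  if (is.null(x$quals)) stop("seq_set has no qualities")
  char_to_phred(x$quals)
}
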