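#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records with Phred+33 qualities (the MiSeq convention;
#' Phred+64 is not supported). Record structure is validated: the separator
#' line must start with `+`, and base and quality strings must have equal
#' length. Phred scores outside \[0, 45\] are rejected.
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @return a [seq_set()].
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(seq_set(character(0), character(0), quals = character(0)))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("FASTQ parse error: %d lines is not a multiple of 4 in %s",
                 length(lines), path))
  idx <- seq(1L, length(lines), by = 4L)
  heads <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(substr(heads, 1L, 1L) != "@")
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: header does not start with '@'",
                 idx[bad[1L]]))
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: missing '+' separator",
                 idx[bad[1L]] + 2L))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: sequence and quality lengths differ",
                 idx[bad[1L]] + 3L))
  ids <- sub("^@", "", heads)
  ids <- sub("\\s.*$", "", ids)
  qr <- range(utf8ToInt(paste(quals, collapse = "")) - 33L)
  if (length(quals) && (qr[1L] < 0L || qr[2L] > 45L))
    stop("FASTQ parse error: Phred score outside [0, 45] (Phred+33 assumed)")
  seq_set(ids, seqs, quals = quals)
}

#' Write a FASTQ file
#' @param x a [seq_set()] with qualities.
#' @param path output path.
#' @export
write_fastq <- function(x, path) {
  if (is.null(x$quals)) stop("cannot write FASTQ: records have no qualities")
  out <- character(4L * length(x))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", x$id)
  out[seq(2L, length(out), by = 4L)] <- x$bases
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- x$quals
  writeLines(out, path)
  invisible(path)
}

#' Read FASTA, optionally paired with a matching quality file
#'
#' The quality file uses the space-separated integer dialect: a `>` header per
#' record followed by whitespace-separated Phred scores. Record ids must match
#' the FASTA ids in order.
#'
#' @param fasta_path path to a FASTA file.
#' @param qual_path optional path to the matching quality file.
#' @return a [seq_set()]; qualities absent when `qual_path` is `NULL`.
#' @export
read_fasta_with_qual <- function(fasta_path, qual_path = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(dna))
  bases <- toupper(as.character(dna))
  if (is.null(qual_path))
    return(seq_set(ids, unname(bases)))
  lines <- readLines(qual_path)
  hdr <- grep("^>", lines)
  if (!length(hdr) && length(ids)) stop("quality file contains no records")
  qids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (length(qids) != length(ids) || any(qids != ids))
    stop("pairing error: quality file ids do not match FASTA ids")
  ends <- c(hdr[-1L] - 1L, length(lines))
  quals <- lapply(seq_along(hdr), function(i) {
    body <- paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = " ")
    as.integer(strsplit(trimws(body), "\\s+")[[1L]])
  })
  if (any(lengths(quals) != nchar(bases)))
    stop("pairing error: quality length does not match sequence length")
  seq_set(ids, unname(bases), quals = quals)
}

#' Write a FASTA file
#' @param x a [seq_set()] (or named character vector of sequences).
#' @param path output path.
#' @param width line width for wrapping (0 = no wrapping).
#' @export
write_fasta <- function(x, path, width = 0L) {
  if (inherits(x, "seq_set")) {
    ids <- x$id; seqs <- x$bases
  } else {
    ids <- names(x); seqs <- as.character(x)
  }
  if (width > 0L)
    seqs <- vapply(seqs, function(s)
      paste(substring(s, seq(1L, nchar(s), width),
                      pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))),
            collapse = "\n"), character(1))
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

#' Read a sample mapping file
#'
#' Five whitespace-separated columns — sample name, treatment (group), strand,
#' read1 path, read2 path — with header lines starting with `#`. Four-column
#' lines describe single-end samples (read2 absent). The strand column is
#' recorded but not acted upon.
#'
#' @param path path to the mapping file.
#' @return a data.frame with columns `sample`, `treatment`, `strand`, `read1`,
#'   `read2` (NA for single-end samples).
#' @export
read_mapping <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(sample = character(0), treatment = character(0),
                      strand = character(0), read1 = character(0),
                      read2 = character(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("mapping parse error: line with %d column(s); at least 4 required",
                 min(nf)))
  m <- data.frame(
    sample = vapply(fields, `[`, character(1), 1L),
    treatment = vapply(fields, `[`, character(1), 2L),
    strand = vapply(fields, `[`, character(1), 3L),
    read1 = vapply(fields, `[`, character(1), 4L),
    read2 = vapply(fields, function(f) if (length(f) >= 5L) f[5L] else NA_character_,
                   character(1)),
    stringsAsFactors = FALSE)
  dup <- m$sample[duplicated(m$sample)]
  if (length(dup))
    stop(sprintf("mapping validation error: duplicate sample name '%s'", dup[1L]))
  if (any(!nzchar(m$read1))) stop("mapping validation error: empty read1 path")
  m
}

#' Read an oligos (primer) file
#'
#' Mothur-style dialect: one primer per line as `forward <seq>` or
#' `reverse <seq>`; IUPAC degeneracy codes are allowed; sequences are
#' uppercased. Bare-sequence lines are rejected.
#'
#' @param path path to the oligos file.
#' @return a `primer_set`: list with character vectors `forward` and `reverse`.
#' @export
read_oligos <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fwd <- character(0); rev <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1L]]
    if (length(f) != 2L || !(tolower(f[1L]) %in% c("forward", "reverse")))
      stop(sprintf("oligos parse error: expected 'forward <seq>' or 'reverse <seq>', got '%s'", ln))
    s <- toupper(f[2L])
    if (grepl(sprintf("[^%s]", paste(names(IUPAC_CODES), collapse = "")), s))
      stop(sprintf("oligos parse error: non-IUPAC character in primer '%s'", s))
    if (tolower(f[1L]) == "forward") fwd <- c(fwd, s) else rev <- c(rev, s)
  }
  primer_set(fwd, rev)
}

#' Construct a primer set
#' @param forward,reverse character vectors of IUPAC primer sequences.
#' @return a `primer_set`.
#' @export
primer_set <- function(forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (!length(forward) || !length(reverse))
    stop("a primer set needs at least one forward and one reverse primer")
  ok <- !grepl(sprintf("[^%s]", paste(names(IUPAC_CODES), collapse = "")),
               c(forward, reverse))
  if (!all(ok)) stop("non-IUPAC character in primer")
  structure(list(forward = forward, reverse = reverse), class = "primer_set")
}

#' Write an OTU table in the Mothur shared format
#'
#' Tab-separated with columns `label`, `Group`, `numOtus`, then one column per
#' OTU; one row per sample. This lets downstream Mothur-aware tools consume
#' the table directly.
#'
#' @param table an [otu_table()].
#' @param path output path.
#' @param label shared-file label column (conventionally the OTU distance).
#' @export
write_shared_table <- function(table, path, label = "0.03") {
  stopifnot(inherits(table, "amp_otu_table"))
  df <- data.frame(label = label, Group = rownames(table$counts),
                   numOtus = ncol(table$counts),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Mothur-format shared OTU table
#' @param path path to a shared file written by [write_shared_table()].
#' @return an [otu_table()] (centroid sequences unknown, hence absent).
#' @export
read_shared_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("label", "Group", "numOtus")
  if (!all(need %in% names(df))) stop("shared table parse error: missing header columns")
  counts <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  rownames(counts) <- df$Group
  storage.mode(counts) <- "integer"
  if (any(is.na(counts))) stop("shared table parse error: non-integer count")
  if (any(counts < 0L)) stop("shared table validation error: negative count")
  otu_table(counts)
}

#' Write a tree in Newick format
#' @param tree an `ape` `phylo` object (e.g. from [upgma_tree()]).
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels are not representable in Newick output")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a co-occurrence graph as GEXF 1.2
#'
#' Emits an undirected GEXF 1.2 document with node attributes `taxonomy` and
#' `abundance` and edge attributes `r` (correlation coefficient), `p` and
#' `method`, readable by Gephi and other GEXF-aware tools.
#'
#' @param graph a `cooccurrence_graph` from [build_network()].
#' @param path output path.
#' @export
write_gexf <- function(graph, path) {
  stopifnot(inherits(graph, "cooccurrence_graph"))
  doc <- xml2::xml_new_root("gexf", xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  g <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                           mode = "static")
  natt <- xml2::xml_add_child(g, "attributes", class = "node")
  xml2::xml_add_child(natt, "attribute", id = "0", title = "taxonomy", type = "string")
  xml2::xml_add_child(natt, "attribute", id = "1", title = "abundance", type = "double")
  eatt <- xml2::xml_add_child(g, "attributes", class = "edge")
  xml2::xml_add_child(eatt, "attribute", id = "0", title = "r", type = "double")
  xml2::xml_add_child(eatt, "attribute", id = "1", title = "p", type = "double")
  xml2::xml_add_child(eatt, "attribute", id = "2", title = "method", type = "string")
  nodes <- xml2::xml_add_child(g, "nodes")
  nd <- graph$nodes
  for (i in seq_len(nrow(nd))) {
    node <- xml2::xml_add_child(nodes, "node", id = nd$id[i], label = nd$id[i])
    av <- xml2::xml_add_child(node, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = nd$taxonomy[i] %||% "")
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = format(nd$abundance[i]))
  }
  edges <- xml2::xml_add_child(g, "edges")
  ed <- graph$edges
  for (i in seq_len(nrow(ed))) {
    edge <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                                source = ed$from[i], target = ed$to[i],
                                weight = format(abs(ed$r[i])))
    av <- xml2::xml_add_child(edge, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = format(ed$r[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "1", value = format(ed$p[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "2", value = ed$method[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
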