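#' Indexed store of directed fast-comparison edges
#'
#' A `neighbor_store` holds the precomputed directed graph of fast structural
#' comparisons (source id, target id, e-value) and answers per-source neighbor
#' queries under an e-value ceiling. Edges are directed: the fast aligner's
#' output is asymmetric and a source's hit list need not mirror its targets'.
#' Duplicate (source, target) pairs are resolved by keeping the smallest
#' e-value; self-edges are dropped at load time.
#'
#' @param edges data.frame with columns `source`, `target`, `evalue`.
#' @return An object of class `neighbor_store`.
#' @examples
#' st <- neighbor_store(data.frame(source = "a", target = c("b", "c"),
#'                                 evalue = c(0.5, 0.005)))
#' store_neighbors(st, "a", 0.01)
#' @export
neighbor_store <- function(edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        evalue = numeric())
  }
  edges <- validate_edges(edges)
  edges <- dedup_edges(edges)
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(edges)) {
    # pre-sort once by (source, evalue, target) so per-source slices come out
    # in the deterministic traversal order
    edges <- edges[order(edges$source, edges$evalue, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    split_idx <- split(seq_len(nrow(edges)), edges$source)
    for (s in names(split_idx)) assign(s, split_idx[[s]], envir = idx)
  }
  structure(list(edges = edges, index = idx), class = "neighbor_store")
}

validate_edges <- function(edges) {
  stopifnot(is.data.frame(edges))
  need <- c("source", "target", "evalue")
  if (!all(need %in% names(edges))) {
    stop("edge table must have columns source, target, evalue")
  }
  edges <- edges[need]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  ev <- suppressWarnings(as.numeric(edges$evalue))
  bad <- which(is.na(ev) | ev <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive or non-numeric e-value in edge rows: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  edges$evalue <- ev
  edges[edges$source != edges$target, , drop = FALSE]
}

dedup_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  o <- order(edges$source, edges$target, edges$evalue)
  edges <- edges[o, , drop = FALSE]
  keep <- !duplicated(edges[c("source", "target")])
  edges[keep, , drop = FALSE]
}

#' @export
print.neighbor_store <- function(x, ...) {
  cat(sprintf("neighbor_store: %d directed edges, %d sources\n",
              nrow(x$edges), length(ls(x$index))))
  invisible(x)
}

#' Number of stored edges
#' @param store a `neighbor_store`
#' @return integer edge count
#' @export
edge_count <- function(store) {
  stopifnot(inherits(store, "neighbor_store"))
  nrow(store$edges)
}

#' Dump all stored edges
#'
#' Returns the deduplicated edge table, sorted by (source, evalue, target).
#' @param store a `neighbor_store`
#' @return data.frame with columns source, target, evalue
#' @export
dump_edges <- function(store) {
  stopifnot(inherits(store, "neighbor_store"))
  store$edges
}

#' Fast-comparison neighbors of a source under an e-value ceiling
#'
#' Returns all and only the stored hits of `source` with `evalue < e_cutoff`
#' (strict, matching the convention that only pairs with e-value below the
#' ceiling are kept), sorted ascending by (evalue, target id) so traversal
#' order is deterministic. An unknown source yields an empty table.
#'
#' @param store a `neighbor_store`
#' @param source source structure id
#' @param e_cutoff positive e-value ceiling
#' @return data.frame with columns source, target, evalue
#' @export
store_neighbors <- function(store, source, e_cutoff) {
  stopifnot(inherits(store, "neighbor_store"))
  if (!is.numeric(e_cutoff) || length(e_cutoff) != 1L || e_cutoff <= 0) {
    stop("e_cutoff must be a single positive number")
  }
  rows <- store$index[[as.character(source)]]
  if (is.null(rows)) {
    return(store$edges[0, , drop = FALSE])
  }
  out <- store$edges[rows, , drop = FALSE]
  out <- out[out$evalue < e_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target ids within the masking radius of a source
#'
#' The target-id set of `store_neighbors(store, source, mask_e)`; used to
#' defer redundant, near-identical candidates behind one representative.
#'
#' @inheritParams store_neighbors
#' @param mask_e positive masking e-value radius
#' @return character vector of target ids
#' @export
mask_neighbors <- function(store, source, mask_e) {
  store_neighbors(store, source, mask_e)$target
}

#' Read a three-column edge TSV
#'
#' Format: `source<TAB>target<TAB>evalue`, no header, UTF-8; lines starting
#' with `#` are ignored. Rows with non-positive or non-numeric e-values are
#' rejected with their line numbers.
#'
#' @param path path to the TSV file
#' @return data.frame with columns source, target, evalue
#' @export
read_edge_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) {
    return(data.frame(source = character(), target = character(),
                      evalue = numeric()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop(sprintf("malformed edge row (need 3 tab-separated fields) at line %d",
                 lineno[which(nf < 3L)[1L]]))
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:3))
  ev <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(ev) | ev <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive or non-numeric e-value at line(s): %s",
                 paste(lineno[utils::head(bad, 10L)], collapse = ", ")))
  }
  data.frame(source = m[, 1L], target = m[, 2L], evalue = ev)
}

#' Write a three-column edge TSV
#' @param edges data.frame with columns source, target, evalue
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_tsv <- function(edges, path) {
  utils::write.table(edges[c("source", "target", "evalue")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a structure metadata TSV
#'
#' Columns `id, accession, description, taxonomy, gene`; header row required.
#' @param path path to the TSV file
#' @return data.frame
#' @export
read_metadata_tsv <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          quote = "")
  need <- c("id", "accession", "description", "taxonomy", "gene")
  if (!all(need %in% names(md))) {
    stop("metadata TSV must have header columns: ",
         paste(need, collapse = ", "))
  }
  md[need]
}

#' Read a domain-label TSV
#'
#' Hierarchy labels per structure id. Accepts either SCOP-style columns
#' `id, family, superfamily, fold` or Pfam-style `id, family, clan`
#' (header required).
#' @param path path to the TSV file
#' @return data.frame
#' @export
read_label_tsv <- function(path) {
  lb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          quote = "")
  if (!"id" %in% names(lb)) stop("label TSV must have an 'id' column")
  ok <- all(c("family", "superfamily", "fold") %in% names(lb)) ||
    all(c("family", "clan") %in% names(lb))
  if (!ok) {
    stop("label TSV must have columns family+superfamily+fold or family+clan")
  }
  lb
}
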