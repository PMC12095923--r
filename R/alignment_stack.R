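#' Query-anchored stacked alignment
#'
#' Builds a fixed-width stack of pairwise alignments against a common
#' query: the row for target `t` has, at column `q`, the target residue (or
#' secondary-structure state) aligned to query position `q`, and a gap mark
#' elsewhere. The projection is query-anchored: target residues not aligned
#' to any query position (insertions relative to the query) are dropped, so
#' every row has exactly `query_length` columns and a row's non-gap count
#' equals the pair's alignment length.
#'
#' @param query_length number of query residues (columns of the stack)
#' @param results list of validation results; each element needs `target`,
#'   `aligned_pairs` (2-column matrix of 1-based (query, target) positions,
#'   strictly increasing in the query coordinate) and `target_seq` (the
#'   target residue string; a per-residue secondary-structure string may be
#'   supplied instead to stack secondary structure)
#' @return object of class `stacked_alignment`: fields `query_id` (optional,
#'   attached by callers), `query_length`, `rows` (named character vector of
#'   gapped strings) and `row_order`
#' @export
stack_alignments <- function(query_length, results) {
  stopifnot(is.numeric(query_length), query_length >= 1)
  query_length <- as.integer(query_length)
  rows <- character()
  for (v in results) {
    id <- v$target
    ap <- v$aligned_pairs
    seq_t <- v$target_seq
    if (is.null(ap) || is.null(dim(ap))) ap <- matrix(ap, ncol = 2L)
    if (nrow(ap)) {
      if (any(ap[, 1L] < 1L | ap[, 1L] > query_length)) {
        stop(sprintf("row %s: query position out of range in pair (%d, %d)",
                     id, ap[which(ap[, 1L] < 1L | ap[, 1L] > query_length)[1L], 1L],
                     ap[which(ap[, 1L] < 1L | ap[, 1L] > query_length)[1L], 2L]))
      }
      if (any(ap[, 2L] < 1L | ap[, 2L] > nchar(seq_t))) {
        stop(sprintf("row %s: target position out of range", id))
      }
      if (any(diff(ap[, 1L]) <= 0)) {
        stop(sprintf("row %s: aligned pairs must be strictly increasing in the query coordinate",
                     id))
      }
    }
    cells <- rep("-", query_length)
    if (nrow(ap)) {
      cells[ap[, 1L]] <- strsplit(seq_t, "")[[1]][ap[, 2L]]
    }
    rows[id] <- paste(cells, collapse = "")
  }
  structure(list(query_length = query_length, rows = rows,
                 row_order = names(rows)),
            class = "stacked_alignment")
}

#' @export
print.stacked_alignment <- function(x, ...) {
  cat(sprintf("stacked_alignment: %d rows x %d columns\n",
              length(x$rows), x$query_length))
  invisible(x)
}

#' Export a stacked alignment to FASTA
#'
#' One record per row in row order; header is the target id, sequence the
#' gapped row (gap character `-`), wrapped at 60 columns.
#'
#' @param stack a `stacked_alignment`
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
stack_to_fasta <- function(stack, path) {
  stopifnot(inherits(stack, "stacked_alignment"))
  rows <- stack$rows[stack$row_order]
  set <- Biostrings::BStringSet(rows)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Extract the ungapped fragment sequence of one row
#'
#' Gaps are removed with residue order preserved, yielding the concatenated
#' sequence fragments covering only the structurally aligned regions — the
#' input used for downstream profile-based family assignment.
#'
#' @param stack a `stacked_alignment`
#' @param target a row (target) id
#' @return character string of the ungapped row
#' @export
extract_fragments <- function(stack, target) {
  stopifnot(inherits(stack, "stacked_alignment"))
  if (!target %in% names(stack$rows)) {
    stop(sprintf("unknown target id: %s", target))
  }
  gsub("-", "", stack$rows[[target]], fixed = TRUE)
}

# column-wise agreement of two equally long gapped strings; columns where
# both rows hold a gap are excluded from the comparison
ss_agreement <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  use <- !(ca == "-" & cb == "-")
  sum(ca[use] == cb[use])
}

#' Seriate stacked-alignment rows by secondary-structure similarity
#'
#' Greedy nearest-neighbor chaining for display: start from the row most
#' similar to the query's secondary-structure string (the anchor), then
#' repeatedly append the unplaced row with maximal column-wise agreement to
#' the last placed row. Gap-gap columns are excluded from the agreement;
#' ties break deterministically on lexicographic row id. The result is a
#' permutation of the input rows.
#'
#' @param stack a `stacked_alignment`
#' @param ss_rows named character vector of per-row secondary-structure
#'   strings, aligned to the same columns as the stack rows
#' @param query_ss the query's (ungapped) secondary-structure string, used
#'   to pick the anchor row
#' @return the reordered `stacked_alignment`
#' @export
seriate_stack <- function(stack, ss_rows, query_ss) {
  stopifnot(inherits(stack, "stacked_alignment"))
  if (length(ss_rows) != length(stack$rows) ||
      !setequal(names(ss_rows), names(stack$rows))) {
    stop("ss_rows must provide exactly one string per stack row")
  }
  if (any(nchar(ss_rows) != stack$query_length)) {
    stop("ss_rows must have the stack's column count")
  }
  stack$row_order <- seriate_rows(ss_rows, query_ss)
  stack
}

#' Greedy seriation order of secondary-structure rows
#'
#' @inheritParams seriate_stack
#' @return character vector: the seriated permutation of `names(ss_rows)`
#' @export
seriate_rows <- function(ss_rows, query_ss) {
  ids <- sort(names(ss_rows))
  if (length(ids) <= 1L) return(ids)
  pad <- substr(paste0(query_ss, strrep("-", nchar(ss_rows[[1]]))),
                1L, nchar(ss_rows[[1]]))
  score_to <- function(ref, pool) {
    s <- vapply(pool, function(i) ss_agreement(ref, ss_rows[[i]]),
                numeric(1))
    pool[order(-s, pool)][1L]
  }
  placed <- score_to(pad, ids)
  pool <- setdiff(ids, placed)
  while (length(pool)) {
    nxt <- score_to(ss_rows[[placed[length(placed)]]], pool)
    placed <- c(placed, nxt)
    pool <- setdiff(pool, nxt)
  }
  placed
}

#' Write a stacked alignment as TSV (id + row string)
#' @param stack a `stacked_alignment`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_stack_tsv <- function(stack, path) {
  stopifnot(inherits(stack, "stacked_alignment"))
  utils::write.table(
    data.frame(id = stack$row_order,
               row = unname(stack$rows[stack$row_order])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the stacked alignment of a search result
#'
#' Convenience wrapper joining a `closure_result` with the target sequences
#' of a synthetic universe (or any id -> sequence map).
#'
#' @param result a `closure_result`
#' @param query_length query residue count
#' @param sequences named character vector mapping target id to residue
#'   string
#' @return a `stacked_alignment`
#' @export
result_stack <- function(result, query_length, sequences) {
  stopifnot(inherits(result, "closure_result"))
  rs <- lapply(result$hits$target, function(id) {
    v <- result$results[[id]]
    list(target = id, aligned_pairs = v$aligned_pairs,
         target_seq = sequences[[id]])
  })
  stack_alignments(query_length, rs)
}
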