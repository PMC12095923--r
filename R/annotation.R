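#' Crosslink hit identifiers with database metadata
#'
#' One annotation record per input id, in input order. Ids absent from the
#' metadata table yield records with empty metadata fields; the number of
#' such misses is attached as the `n_missing` attribute and reported as a
#' warning. Duplicate metadata rows for one id keep the first occurrence
#' (with a warning).
#'
#' @param ids character vector of structure ids
#' @param metadata data.frame with columns id, accession, description,
#'   taxonomy, gene (as from [read_metadata_tsv()])
#' @return data.frame of annotation records, attribute `n_missing`
#' @export
crosslink <- function(ids, metadata) {
  need <- c("id", "accession", "description", "taxonomy", "gene")
  stopifnot(is.data.frame(metadata), all(need %in% names(metadata)))
  if (anyDuplicated(metadata$id)) {
    warning("duplicate metadata rows; keeping first occurrence per id")
    metadata <- metadata[!duplicated(metadata$id), , drop = FALSE]
  }
  i <- match(ids, metadata$id)
  out <- data.frame(id = as.character(ids),
                    accession = metadata$accession[i],
                    description = metadata$description[i],
                    taxonomy = metadata$taxonomy[i],
                    gene = metadata$gene[i])
  n_missing <- sum(is.na(i))
  if (n_missing) {
    warning(sprintf("%d id(s) missing from the metadata table", n_missing))
    out[is.na(i), -1L] <- ""
  }
  attr(out, "n_missing") <- n_missing
  out
}

#' Assign one family label from profile-search domain hits
#'
#' Among hits that met the profile's trusted cutoff, the family with the
#' best (smallest) e-value is retained; ties break on lexicographic family
#' accession. If no hit is above the trusted cutoff the target is left
#' unassigned (`NA`). The winning hit's e-value and clan are surfaced so
#' spurious fragment-based assignments can be filtered downstream.
#'
#' @param hits data.frame of domain hits for a single target: columns
#'   `target`, `family`, `clan` (optional), `evalue`, `above_trusted`
#' @return list with `family`, `clan`, `evalue` (all NA when unassigned)
#' @export
assign_family <- function(hits) {
  empty <- list(family = NA_character_, clan = NA_character_,
                evalue = NA_real_)
  if (is.null(hits) || !nrow(hits)) return(empty)
  stopifnot(all(c("target", "family", "evalue", "above_trusted") %in%
                  names(hits)))
  if (length(unique(hits$target)) > 1L) {
    stop("assign_family expects hits for a single target")
  }
  ok <- hits[as.logical(hits$above_trusted), , drop = FALSE]
  if (!nrow(ok)) return(empty)
  best <- ok[order(ok$evalue, ok$family), , drop = FALSE][1L, ]
  has_clan <- "clan" %in% names(best) && !is.na(best$clan) &&
    nzchar(best$clan)
  list(family = best$family,
       clan = if (has_clan) best$clan else NA_character_,
       evalue = best$evalue)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign families for a whole domain-hit table
#'
#' @param hits data.frame of domain hits for any number of targets
#' @return data.frame with one row per distinct target: `id`,
#'   `assigned_family`, `assigned_clan`, `family_evalue`
#' @export
assign_families <- function(hits) {
  targets <- sort(unique(hits$target))
  rows <- lapply(targets, function(t) {
    a <- assign_family(hits[hits$target == t, , drop = FALSE])
    data.frame(id = t, assigned_family = a$family, assigned_clan = a$clan,
               family_evalue = a$evalue)
  })
  if (!length(rows)) {
    return(data.frame(id = character(), assigned_family = character(),
                      assigned_clan = character(),
                      family_evalue = numeric()))
  }
  do.call(rbind, rows)
}

#' Read a domain-hit TSV
#'
#' Columns `target, family, clan, evalue, above_trusted` with a header row;
#' `above_trusted` parsed as logical.
#' @param path path to the TSV file
#' @return data.frame of domain hits
#' @export
read_domain_hits_tsv <- function(path) {
  h <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", comment.char = "#",
                         quote = "")
  need <- c("target", "family", "clan", "evalue", "above_trusted")
  if (!all(need %in% names(h))) {
    stop("domain-hit TSV must have columns: ", paste(need, collapse = ", "))
  }
  h$evalue <- as.numeric(h$evalue)
  h$above_trusted <- as.logical(h$above_trusted) |
    h$above_trusted %in% c("1", "yes")
  h
}

#' Query coverage as an integer percent
#'
#' The common-core size divided by the query length, reported to integer
#' percent with round-half-up.
#'
#' @param core_size aligned core size (residues), 0 < core_size <=
#'   query_length
#' @param query_length query residue count
#' @return integer percent
#' @examples
#' q_cov(50, 100)  # 50
#' @export
q_cov <- function(core_size, query_length) {
  stopifnot(core_size > 0, query_length > 0)
  if (core_size > query_length) {
    stop("core_size must not exceed query_length")
  }
  as.integer(floor(100 * core_size / query_length + 0.5))
}
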