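#' Search configuration for transitive-closure search
#'
#' Thresholds controlling search depth and cost. `zcut` is the minimum
#' precise (Dali-style) Z-score for a match, fixed at its floor of 2 by
#' default. `minlali` is the minimum alignment length (the common-core
#' size); when `NULL` it is derived from the query's secondary structure as
#' nH + nE (helix plus strand residues) at search time. `e_first` is the
#' relaxed first-shell e-value cutoff (sensitivity at the entry points),
#' `e_later` the stricter cutoff for later shells (precision as the search
#' expands), and `e_mask` the masking radius within which candidates are
#' treated as redundant and deferred behind a representative; `e_mask = 0`
#' disables masking. `lali_strict` switches the alignment-length test from
#' `lali >= minlali` (default) to strict `>`.
#'
#' @param zcut minimum precise score; must be >= 2 (the aligner's reporting
#'   floor)
#' @param minlali minimum alignment length, or NULL to derive from query
#'   secondary structure
#' @param e_first first-shell e-value cutoff
#' @param e_later later-shell e-value cutoff
#' @param e_mask masking radius (0 disables masking)
#' @param lali_strict logical; require lali strictly greater than minlali
#' @param timeout wall-clock limit in seconds (Inf = none)
#' @param run_id prefix string for output files
#' @return list of class `search_config`
#' @export
search_config <- function(zcut = 2, minlali = NULL, e_first = 1,
                          e_later = 0.01, e_mask = 1e-5,
                          lali_strict = FALSE, timeout = Inf,
                          run_id = "run") {
  if (zcut < 2) stop("zcut must be >= 2 (precise-score reporting floor)")
  if (!is.null(minlali) && minlali < 0) stop("minlali must be >= 0")
  if (e_mask < 0 || e_later <= 0 || e_first <= 0) {
    stop("e-value cutoffs must be non-negative (e_first, e_later positive)")
  }
  if (!(e_mask <= e_later && e_later <= e_first)) {
    stop("cutoffs must satisfy e_mask <= e_later <= e_first")
  }
  structure(list(zcut = zcut, minlali = minlali, e_first = e_first,
                 e_later = e_later, e_mask = e_mask,
                 lali_strict = isTRUE(lali_strict), timeout = timeout,
                 run_id = run_id),
            class = "search_config")
}

SS_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' Default minimum core size from secondary structure
#'
#' nH + nE: the number of residues assigned to helix (H) plus strand (E)
#' states, reflecting the assumption that the common core consists of
#' secondary-structure elements. The string must use the 8-state alphabet
#' H, G, I, E, B, T, S, C; an empty string gives 0.
#'
#' @param ss secondary-structure string
#' @return integer count of H plus E residues
#' @examples
#' default_minlali("HHHHCCEEEE")  # 8
#' @export
default_minlali <- function(ss) {
  stopifnot(is.character(ss), length(ss) == 1L)
  if (!nzchar(ss)) return(0L)
  chars <- strsplit(ss, "")[[1]]
  bad <- setdiff(unique(chars), SS_ALPHABET)
  if (length(bad)) {
    stop(sprintf("secondary-structure string contains invalid character(s): %s",
                 paste(sQuote(bad), collapse = ", ")))
  }
  sum(chars == "H" | chars == "E")
}

passes_filter <- function(v, config, minlali) {
  if (is.null(v) || is.null(v$z) || is.na(v$z)) return(FALSE)
  lali_ok <- if (config$lali_strict) v$lali > minlali else v$lali >= minlali
  v$z > config$zcut && lali_ok
}

#' Greedy representative selection with redundancy masking
#'
#' Candidates are processed in ascending (e-value, id) order. A candidate
#' that has not been masked becomes a representative, and every remaining
#' candidate within its masking radius (fast e-value < `e_mask` in the
#' store) is masked under it, deferred to the final validation round. A
#' candidate already masked is recorded under the representative that
#' masked it. With `e_mask = 0` every candidate is its own representative.
#'
#' @param candidates data.frame with columns `id` and `evalue` (e-value
#'   relative to the parent protein), deduplicated on id
#' @param store a `neighbor_store`
#' @param e_mask masking radius (0 disables masking)
#' @return list with `representatives` (ordered character vector) and
#'   `masked` (named list: representative id -> character vector of ids
#'   masked under it)
#' @export
select_representatives <- function(candidates, store, e_mask) {
  if (is.null(candidates) || !nrow(candidates)) {
    return(list(representatives = character(), masked = list()))
  }
  stopifnot(all(c("id", "evalue") %in% names(candidates)))
  if (anyDuplicated(candidates$id)) {
    stop("candidates must be deduplicated on id")
  }
  ord <- order(candidates$evalue, candidates$id)
  ids <- candidates$id[ord]
  masked_by <- stats::setNames(rep(NA_character_, length(ids)), ids)
  reps <- character()
  for (id in ids) {
    if (!is.na(masked_by[[id]])) next
    reps <- c(reps, id)
    if (e_mask > 0) {
      ball <- mask_neighbors(store, id, e_mask)
      hit <- intersect(ball, ids[is.na(masked_by) & ids != id])
      hit <- setdiff(hit, reps)
      if (length(hit)) masked_by[hit] <- id
    }
  }
  masked <- split(names(masked_by)[!is.na(masked_by)],
                  masked_by[!is.na(masked_by)])
  masked <- lapply(masked, sort)
  list(representatives = reps, masked = masked)
}

new_result_set <- function(hits, results, stats, shell_log, config) {
  if (is.null(hits) || !nrow(hits)) {
    hits <- data.frame(target = character(), z = numeric(),
                       lali = integer(), shell = integer(),
                       deferred = logical())
  }
  structure(list(hits = hits, results = results, stats = stats,
                 shell_log = shell_log, config = config),
            class = "closure_result")
}

#' @export
print.closure_result <- function(x, ...) {
  cat(sprintf(
    "closure_result: %d hits, %d shells, %d validations%s\n",
    nrow(x$hits), x$stats$n_shells, x$stats$n_validations,
    if (isTRUE(x$stats$timed_out)) " (timed out)" else ""))
  invisible(x)
}

# shared candidate bookkeeping: aggregate to minimum e-value per target id
aggregate_candidates <- function(df) {
  if (is.null(df) || !nrow(df)) {
    return(data.frame(id = character(), evalue = numeric()))
  }
  o <- order(df$target, df$evalue)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df$target), , drop = FALSE]
  out <- data.frame(id = df$target, evalue = df$evalue)
  out[order(out$evalue, out$id), , drop = FALSE]
}

#' Iterative transitive-closure structural similarity search
#'
#' Explores the fast-comparison neighbor graph in shells starting from the
#' query's live fast-search hits (cutoff `e_first`), validating candidates
#' against the original query with the precise aligner. Each shell is
#' thinned by greedy representative selection: candidates within the
#' masking radius of a representative are deferred, unvalidated, to the
#' final round. Newly accepted representatives contribute their store
#' neighbors (cutoff `e_later`) to the next shell; rejected representatives
#' are dead ends. The iteration terminates when a shell brings no new
#' candidates (or on timeout), after which the final validation round
#' evaluates the deferred neighbors of accepted representatives. The search
#' is deterministic: candidates are processed in ascending (e-value, id)
#' order, with later-shell e-values taken as the minimum over all parents.
#'
#' @param query query structure id; must not be present in the store
#' @param fast_searcher function(id, e_cutoff) returning a data.frame with
#'   columns source, target, evalue — the live fast search of the query
#' @param store a `neighbor_store` of the precomputed all-vs-all graph
#' @param validator function(query, target) returning a list with fields
#'   `z` (NA when below the reporting floor), `lali`, and optionally
#'   `aligned_pairs`
#' @param config a `search_config`
#' @param query_ss optional query secondary-structure string, used to derive
#'   the default minimum core size when `config$minlali` is NULL
#' @return object of class `closure_result`: `hits` (data.frame target, z,
#'   lali, shell of first acceptance, deferred flag), `results` (named list
#'   of full validation results), `stats` (validations, shells, timed_out),
#'   and a per-shell `shell_log`
#' @export
transitive_closure <- function(query, fast_searcher, store, validator,
                               config = search_config(), query_ss = NULL) {
  stopifnot(inherits(store, "neighbor_store"))
  if (query %in% store$edges$source || query %in% store$edges$target) {
    stop("query id is present in the target database; the query must be held out")
  }
  minlali <- config$minlali
  if (is.null(minlali)) {
    minlali <- if (!is.null(query_ss)) default_minlali(query_ss) else 0L
  }
  t0 <- Sys.time()
  timed_out <- FALSE
  cache <- new.env(parent = emptyenv())   # target id -> validation result
  n_val <- 0L
  validate1 <- function(target) {
    v <- cache[[target]]
    if (!is.null(v)) return(v)
    v <- tryCatch(validator(query, target), error = function(e) {
      warning(sprintf("validator failed for pair (%s, %s): %s",
                      query, target, conditionMessage(e)), call. = FALSE)
      list(z = NA_real_, lali = 0L, failed = TRUE)
    })
    n_val <<- n_val + 1L
    cache[[target]] <- v
    v
  }

  visited <- character()
  accepted <- character()
  rejected <- character()
  rep_shell <- integer()      # named: representative -> shell of acceptance
  masked_map <- list()        # representative -> deferred ids
  hit_rows <- list()
  log_rows <- list()
  shell <- 0L

  first <- fast_searcher(query, config$e_first)
  cand <- aggregate_candidates(first)

  repeat {
    shell <- shell + 1L
    cand <- cand[!cand$id %in% visited & cand$id != query, , drop = FALSE]
    sel <- select_representatives(cand, store, config$e_mask)
    visited <- c(visited, cand$id)
    for (r in names(sel$masked)) {
      masked_map[[r]] <- sort(unique(c(masked_map[[r]], sel$masked[[r]])))
    }
    new_accept <- character()
    for (r in sel$representatives) {
      v <- validate1(r)
      if (passes_filter(v, config, minlali)) {
        accepted <- c(accepted, r)
        new_accept <- c(new_accept, r)
        rep_shell[r] <- shell
        hit_rows[[r]] <- data.frame(target = r, z = v$z,
                                    lali = as.integer(v$lali),
                                    shell = shell, deferred = FALSE)
      } else {
        rejected <- c(rejected, r)
      }
    }
    log_rows[[shell]] <- data.frame(
      shell = shell, candidates = nrow(cand),
      representatives = length(sel$representatives),
      accepted = length(new_accept),
      rejected = length(sel$representatives) - length(new_accept),
      masked = sum(lengths(sel$masked)), validations = n_val)
    if (is.finite(config$timeout) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) >
        config$timeout) {
      timed_out <- TRUE
      break
    }
    if (!length(new_accept)) break
    nxt <- lapply(new_accept, function(r) {
      store_neighbors(store, r, config$e_later)
    })
    cand <- aggregate_candidates(do.call(rbind, nxt))
    cand <- cand[!cand$id %in% visited & cand$id != query, , drop = FALSE]
    if (!nrow(cand)) break
  }

  # final validation round: deferred redundant neighbors of accepted
  # representatives only; masked ids under rejected representatives are
  # never validated, and no pair is validated twice
  if (!timed_out) {
    for (r in accepted) {
      for (m in masked_map[[r]]) {
        if (!is.null(cache[[m]]) || m %in% c(accepted, rejected)) next
        v <- validate1(m)
        if (passes_filter(v, config, minlali)) {
          accepted <- c(accepted, m)
          hit_rows[[m]] <- data.frame(target = m, z = v$z,
                                      lali = as.integer(v$lali),
                                      shell = rep_shell[[r]],
                                      deferred = TRUE)
        } else {
          rejected <- c(rejected, m)
        }
      }
      if (is.finite(config$timeout) &&
          as.numeric(difftime(Sys.time(), t0, units = "secs")) >
          config$timeout) {
        timed_out <- TRUE
        break
      }
    }
  }

  hits <- if (length(hit_rows)) do.call(rbind, hit_rows[accepted]) else NULL
  if (!is.null(hits)) rownames(hits) <- NULL
  results <- as.list(cache)
  new_result_set(hits, results[intersect(accepted, names(results))],
                 stats = list(n_validations = n_val, n_shells = shell,
                              timed_out = timed_out),
                 shell_log = do.call(rbind, log_rows), config = config)
}

#' Exhaustive breadth-first closure (no representative sampling)
#'
#' Validates every candidate in every shell instead of thinning shells by
#' representative selection; frontier expansion proceeds only from passed
#' candidates under `e_later`. Intended as a reference implementation for
#' small universes (the hit set equals [transitive_closure()] with
#' `e_mask = 0`).
#'
#' @inheritParams transitive_closure
#' @return a `closure_result`
#' @export
brute_force_closure <- function(query, fast_searcher, store, validator,
                                config = search_config(e_mask = 0),
                                query_ss = NULL) {
  minlali <- config$minlali
  if (is.null(minlali)) {
    minlali <- if (!is.null(query_ss)) default_minlali(query_ss) else 0L
  }
  seen <- character()
  accepted <- character()
  results <- list()
  hit_rows <- list()
  n_val <- 0L
  shell <- 0L
  frontier <- aggregate_candidates(fast_searcher(query, config$e_first))
  repeat {
    shell <- shell + 1L
    frontier <- frontier[!frontier$id %in% seen & frontier$id != query, ,
                         drop = FALSE]
    seen <- c(seen, frontier$id)
    passed_now <- character()
    for (id in frontier$id) {
      v <- validator(query, id)
      n_val <- n_val + 1L
      results[[id]] <- v
      if (passes_filter(v, config, minlali)) {
        passed_now <- c(passed_now, id)
        accepted <- c(accepted, id)
        hit_rows[[id]] <- data.frame(target = id, z = v$z,
                                     lali = as.integer(v$lali),
                                     shell = shell, deferred = FALSE)
      }
    }
    if (!length(passed_now)) break
    nxt <- do.call(rbind, lapply(passed_now, function(id) {
      store_neighbors(store, id, config$e_later)
    }))
    frontier <- aggregate_candidates(nxt)
    frontier <- frontier[!frontier$id %in% seen & frontier$id != query, ,
                         drop = FALSE]
    if (!nrow(frontier)) break
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows[accepted]) else NULL
  if (!is.null(hits)) rownames(hits) <- NULL
  new_result_set(hits, results[accepted],
                 stats = list(n_validations = n_val, n_shells = shell,
                              timed_out = FALSE),
                 shell_log = NULL, config = config)
}

#' Single-shot search: first shell only, every candidate validated
#'
#' The non-iterative baseline: the query's direct fast-search hits under
#' `e_first`, each validated against the query. No expansion, no masking.
#'
#' @inheritParams transitive_closure
#' @return a `closure_result` with `n_shells = 1`
#' @export
single_shot_search <- function(query, fast_searcher, validator,
                               config = search_config(), query_ss = NULL) {
  minlali <- config$minlali
  if (is.null(minlali)) {
    minlali <- if (!is.null(query_ss)) default_minlali(query_ss) else 0L
  }
  cand <- aggregate_candidates(fast_searcher(query, config$e_first))
  cand <- cand[cand$id != query, , drop = FALSE]
  hit_rows <- list()
  results <- list()
  n_val <- 0L
  for (id in cand$id) {
    v <- validator(query, id)
    n_val <- n_val + 1L
    results[[id]] <- v
    if (passes_filter(v, config, minlali)) {
      hit_rows[[id]] <- data.frame(target = id, z = v$z,
                                   lali = as.integer(v$lali),
                                   shell = 1L, deferred = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else NULL
  if (!is.null(hits)) rownames(hits) <- NULL
  new_result_set(hits, results[names(hit_rows)],
                 stats = list(n_validations = n_val, n_shells = 1L,
                              timed_out = FALSE),
                 shell_log = data.frame(shell = 1L, candidates = nrow(cand),
                                        representatives = nrow(cand),
                                        accepted = length(hit_rows),
                                        rejected = nrow(cand) -
                                          length(hit_rows),
                                        masked = 0L, validations = n_val),
                 config = config)
}

#' Write the hit table of a search as TSV
#'
#' One row per accepted target: `run_id, target_id, shell, z, lali,
#' accession, description, taxonomy, pfam_family, pfam_clan` (header row,
#' UTF-8). Annotation columns are filled from `annotations` when given
#' (see [crosslink()]), otherwise left empty.
#'
#' @param result a `closure_result`
#' @param path output path
#' @param annotations optional data.frame keyed by `id` with columns
#'   accession, description, taxonomy and optionally family/clan
#' @param run_id run identifier written in the first column
#' @return `path`, invisibly
#' @export
write_hit_tsv <- function(result, path, annotations = NULL,
                          run_id = result$config$run_id) {
  h <- result$hits
  blank <- rep("", nrow(h))
  out <- data.frame(run_id = rep(run_id, nrow(h)), target_id = h$target,
                    shell = h$shell, z = h$z, lali = h$lali,
                    accession = blank, description = blank,
                    taxonomy = blank, pfam_family = blank,
                    pfam_clan = blank)
  if (!is.null(annotations) && nrow(h)) {
    i <- match(h$target, annotations$id)
    pick <- function(col) {
      if (col %in% names(annotations)) {
        v <- annotations[[col]][i]
        ifelse(is.na(v), "", v)
      } else rep("", nrow(h))
    }
    out$accession <- pick("accession")
    out$description <- pick("description")
    out$taxonomy <- pick("taxonomy")
    out$pfam_family <- if ("assigned_family" %in% names(annotations)) {
      pick("assigned_family")
    } else pick("family")
    out$pfam_clan <- if ("assigned_clan" %in% names(annotations)) {
      pick("assigned_clan")
    } else pick("clan")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
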