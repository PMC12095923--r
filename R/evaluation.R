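#' Suffix-filtered evaluation counts
#'
#' Compares a result set against a reference classification under three
#' nested filtering levels. Suffix 0 is raw classification membership;
#' suffix 1 keeps only findable members, i.e. those validated by the
#' precise aligner with Z > 2; suffix 2 additionally requires the common
#' core, i.e. Z > `zcut` and alignment length >= `minlali`. The positive
#' (result) sets are filtered identically, and TP_k is the intersection of
#' P_k with TRUE_k. Ids without a validation record are treated as not
#' findable (excluded beyond suffix 0).
#'
#' @param reference_ids character vector: the reference (TRUE_0) set
#' @param result_ids character vector: the reported positives (P_0)
#' @param validations data.frame with columns `id`, `z`, `lali`
#' @param zcut precise-score threshold for the suffix-2 filter
#' @param minlali minimum alignment length for the suffix-2 filter
#' @return object of class `evaluation_counts`: the nine counts plus the
#'   underlying id sets
#' @export
suffix_counts <- function(reference_ids, result_ids, validations,
                          zcut = 2, minlali = 0) {
  if (minlali < 0) stop("minlali must be >= 0")
  stopifnot(all(c("id", "z", "lali") %in% names(validations)))
  reference_ids <- unique(as.character(reference_ids))
  result_ids <- unique(as.character(result_ids))
  v <- validations[!duplicated(validations$id), , drop = FALSE]
  z_of <- stats::setNames(v$z, v$id)
  lali_of <- stats::setNames(v$lali, v$id)
  findable <- function(ids) {
    z <- z_of[ids]
    ids[!is.na(z) & z > 2]
  }
  core <- function(ids) {
    z <- z_of[ids]
    l <- lali_of[ids]
    ids[!is.na(z) & z > zcut & !is.na(l) & l >= minlali]
  }
  sets <- list(
    true_0 = reference_ids, true_1 = findable(reference_ids),
    true_2 = core(findable(reference_ids)),
    p_0 = result_ids, p_1 = findable(result_ids),
    p_2 = core(findable(result_ids)))
  sets$tp_0 <- intersect(sets$p_0, sets$true_0)
  sets$tp_1 <- intersect(sets$p_1, sets$true_1)
  sets$tp_2 <- intersect(sets$p_2, sets$true_2)
  counts <- lapply(sets, length)
  names(counts) <- names(sets)
  structure(c(counts, list(sets = sets)), class = "evaluation_counts")
}

#' @export
print.evaluation_counts <- function(x, ...) {
  cat(sprintf("TRUE: %d / %d / %d   P: %d / %d / %d   TP: %d / %d / %d\n",
              x$true_0, x$true_1, x$true_2, x$p_0, x$p_1, x$p_2,
              x$tp_0, x$tp_1, x$tp_2))
  invisible(x)
}

#' Precision, recall and F1 from counts
#'
#' `pr = |TP|/|P|`, `rc = |TP|/|TRUE|`, `F1 = 2 pr rc / (pr + rc)`.
#' Undefined ratios (zero denominators) are reported as 0 with an explicit
#' flag rather than as errors, so batch evaluation never aborts; `pr + rc
#' = 0` gives F1 = 0.
#'
#' @param p positives count
#' @param tp true-positives count (`tp <= p`, `tp <= true_n`)
#' @param true_n reference count
#' @return list with `pr`, `rc`, `f1`, and logical flags `pr_defined`,
#'   `rc_defined`
#' @export
precision_recall_f1 <- function(p, tp, true_n) {
  if (tp > p || tp > true_n) {
    stop("tp must not exceed p or the reference count")
  }
  pr_defined <- p > 0
  rc_defined <- true_n > 0
  pr <- if (pr_defined) tp / p else 0
  rc <- if (rc_defined) tp / true_n else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  list(pr = pr, rc = rc, f1 = f1, pr_defined = pr_defined,
       rc_defined = rc_defined)
}

rank_items <- function(ranked, direction = c("smaller", "larger")) {
  direction <- match.arg(direction)
  stopifnot(all(c("id", "score") %in% names(ranked)))
  s <- if (direction == "smaller") ranked$score else -ranked$score
  ranked[order(s, ranked$id), , drop = FALSE]
}

#' Best F1 over all cut points of a ranked list
#'
#' F1 is evaluated at every distinct score cutoff (each prefix of the
#' ranked list ending at a score boundary) and the maximum is returned.
#' `direction` states whether smaller scores are better (e-values) or
#' larger (Z-scores). Ties on the maximum resolve to the most inclusive
#' cutoff.
#'
#' @param ranked data.frame with columns `id`, `score`
#' @param true_set character vector of relevant ids
#' @param direction "smaller" or "larger"
#' @return list with `fmax`, `cutoff` (score at the best cut, NA for an
#'   empty list), `n_at_cutoff`
#' @export
fmax <- function(ranked, true_set, direction = c("smaller", "larger")) {
  if (is.null(ranked) || !nrow(ranked)) {
    return(list(fmax = 0, cutoff = NA_real_, n_at_cutoff = 0L))
  }
  direction <- match.arg(direction)
  r <- rank_items(ranked, direction)
  rel <- cumsum(r$id %in% true_set)
  n_true <- length(unique(true_set))
  k <- seq_len(nrow(r))
  # distinct cutoffs = last index of each tied score block
  last_of_block <- which(c(r$score[-1] != r$score[-nrow(r)], TRUE))
  f1 <- vapply(last_of_block, function(i) {
    precision_recall_f1(i, rel[i], n_true)$f1
  }, numeric(1))
  best <- max(f1)
  at <- last_of_block[max(which(f1 == best))]
  list(fmax = best, cutoff = r$score[at], n_at_cutoff = at)
}

#' Precision-recall curve and step-wise AUPRC
#'
#' One precision/recall point per distinct score cutoff of the ranked list;
#' the area is the right-continuous step sum of precision over recall
#' increments (no interpolation). An empty `true_set` gives area 0 with
#' `auprc_defined = FALSE`.
#'
#' @inheritParams fmax
#' @return list with `points` (data.frame cutoff, precision, recall),
#'   `auprc`, `auprc_defined`
#' @export
pr_curve_auprc <- function(ranked, true_set,
                           direction = c("smaller", "larger")) {
  direction <- match.arg(direction)
  n_true <- length(unique(true_set))
  if (is.null(ranked) || !nrow(ranked) || n_true == 0L) {
    return(list(points = data.frame(cutoff = numeric(),
                                    precision = numeric(),
                                    recall = numeric()),
                auprc = 0, auprc_defined = n_true > 0L))
  }
  r <- rank_items(ranked, direction)
  rel <- cumsum(r$id %in% true_set)
  last_of_block <- which(c(r$score[-1] != r$score[-nrow(r)], TRUE))
  pts <- data.frame(cutoff = r$score[last_of_block],
                    precision = rel[last_of_block] / last_of_block,
                    recall = rel[last_of_block] / n_true)
  area <- sum(pts$precision * diff(c(0, pts$recall)))
  list(points = pts, auprc = area, auprc_defined = TRUE)
}

#' Stratify structure pairs by hierarchy level
#'
#' Partitions all unordered pairs of labeled structures into the three
#' strata of a nested classification: family pairs are in the same family;
#' superfamily pairs are in the same superfamily but different families;
#' fold pairs are in the same fold but different superfamilies. Pairs in
#' different folds are excluded. Pairs with a missing label at any level
#' are skipped and counted.
#'
#' @param labels data.frame with columns `id`, `family`, `superfamily`,
#'   `fold`
#' @return list with data.frames `family`, `superfamily`, `fold` (columns
#'   `a`, `b`, with `a < b`) and `n_skipped`
#' @export
stratify_pairs <- function(labels) {
  stopifnot(all(c("id", "family", "superfamily", "fold") %in% names(labels)))
  lab <- labels[!duplicated(labels$id), , drop = FALSE]
  miss <- is.na(lab$family) | is.na(lab$superfamily) | is.na(lab$fold) |
    lab$family == "" | lab$superfamily == "" | lab$fold == ""
  n_all <- nrow(lab)
  lab <- lab[!miss, , drop = FALSE]
  n <- nrow(lab)
  n_skipped <- (choose(n_all, 2) - choose(n, 2))
  empty <- data.frame(a = character(), b = character())
  if (n < 2L) {
    return(list(family = empty, superfamily = empty, fold = empty,
                n_skipped = n_skipped))
  }
  o <- order(lab$id)
  lab <- lab[o, , drop = FALSE]
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  same_fold <- lab$fold[i] == lab$fold[j]
  same_sf <- same_fold & lab$superfamily[i] == lab$superfamily[j]
  same_fam <- same_sf & lab$family[i] == lab$family[j]
  pair_df <- function(keep) {
    data.frame(a = lab$id[i[keep]], b = lab$id[j[keep]])
  }
  list(family = pair_df(same_fam),
       superfamily = pair_df(same_sf & !same_fam),
       fold = pair_df(same_fold & !same_sf),
       n_skipped = n_skipped)
}

#' Recall by stratum, pooled and query-wise
#'
#' For (query, target) reference pairs stratified by hierarchy level,
#' computes recall as a pooled global ratio, a query-wise mean and a
#' query-wise median of per-query recalls. Queries with zero reference
#' pairs in a stratum are excluded from the query-wise statistics; an empty
#' stratum reports NA.
#'
#' @param true_pairs data.frame with columns `query`, `target`, `stratum`
#' @param hit_pairs data.frame with columns `query`, `target`: the
#'   recovered pairs
#' @return data.frame with one row per stratum (plus an `all` row) and
#'   columns `stratum`, `pooled`, `query_mean`, `query_median`, `n_true`
#' @export
recall_by_stratum <- function(true_pairs, hit_pairs) {
  stopifnot(all(c("query", "target", "stratum") %in% names(true_pairs)))
  key <- function(q, t) paste(q, t, sep = "\r")
  hit_keys <- key(hit_pairs$query, hit_pairs$target)
  tp <- true_pairs
  tp$hit <- key(tp$query, tp$target) %in% hit_keys
  strata <- c("all", sort(unique(tp$stratum)))
  rows <- lapply(strata, function(s) {
    sub <- if (s == "all") tp else tp[tp$stratum == s, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(stratum = s, pooled = NA_real_,
                        query_mean = NA_real_, query_median = NA_real_,
                        n_true = 0L))
    }
    per_q <- tapply(sub$hit, sub$query, mean)
    data.frame(stratum = s, pooled = mean(sub$hit),
               query_mean = mean(per_q),
               query_median = stats::median(per_q),
               n_true = nrow(sub))
  })
  do.call(rbind, rows)
}

#' Sequence-based label-transfer rule
#'
#' Accepts a classification-label transfer across a sequence alignment iff
#' the alignment covers at least 80% of both query and target, sequence
#' identity exceeds 40%, and the e-value is below 1e-5.
#'
#' @param qcov,tcov query/target coverage fractions in \[0,1\]
#' @param identity percent sequence identity in \[0,100\]
#' @param evalue alignment e-value
#' @return logical: accept (TRUE) or reject
#' @export
transfer_labels <- function(qcov, tcov, identity, evalue) {
  stopifnot(qcov >= 0, qcov <= 1, tcov >= 0, tcov <= 1,
            identity >= 0, identity <= 100)
  qcov >= 0.80 & tcov >= 0.80 & identity > 40 & evalue < 1e-5
}

#' Packaged clan-benchmark evaluation counts
#'
#' Evaluation counts for the twelve clan-based test cases distributed with
#' the package: reference counts (TRUE_0/1/2) and, for both the closure
#' search and the direct fast search, the positives and true positives
#' under the three suffix filters. These counts are the worked-example
#' input for the ratio-level analyses in the package vignette and README.
#'
#' @return data.frame, one row per test case
#' @export
clan_benchmark <- function() {
  path <- system.file("extdata", "clan_benchmark_counts.tsv",
                      package = "foldclosure", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#")
}

#' Packaged clan-benchmark query descriptions
#'
#' Query-level inputs of the packaged clan benchmark: query id, chosen
#' common-core size, query coverage percent, clan accession, median precise
#' score among reference members, clan description and search wall time.
#'
#' @return data.frame, one row per test case
#' @export
clan_benchmark_queries <- function() {
  path <- system.file("extdata", "clan_benchmark_queries.tsv",
                      package = "foldclosure", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", quote = "")
}

#' Per-case precision/recall/F1 of the packaged clan benchmark
#'
#' Derives, for every test case and both search methods, suffix-2 recall
#' (TP_2/TRUE_2), precision (TP_2/P_2) and F1, plus suffix-1 recall.
#'
#' @param counts benchmark count table, as from [clan_benchmark()]
#' @return data.frame with one row per case
#' @export
benchmark_metrics <- function(counts = clan_benchmark()) {
  m <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    cl <- precision_recall_f1(r$closure_p2, r$closure_tp2, r$true_2)
    fs <- precision_recall_f1(r$foldseek_p2, r$foldseek_tp2, r$true_2)
    data.frame(case = r$case,
               closure_recall_1 = r$closure_tp1 / r$true_1,
               closure_recall_2 = cl$rc, closure_precision_2 = cl$pr,
               closure_f1_2 = cl$f1,
               foldseek_recall_1 = r$foldseek_tp1 / r$true_1,
               foldseek_recall_2 = fs$rc, foldseek_precision_2 = fs$pr,
               foldseek_f1_2 = fs$f1)
  })
  do.call(rbind, m)
}

#' Write an evaluation report TSV
#'
#' One row per evaluated result set: the nine suffix counts plus precision,
#' recall and F1 per suffix level.
#'
#' @param counts an `evaluation_counts` object or a named list of them
#' @param path output path
#' @return the report data.frame, invisibly
#' @export
write_evaluation_report <- function(counts, path) {
  if (inherits(counts, "evaluation_counts")) counts <- list(result = counts)
  rows <- lapply(names(counts), function(nm) {
    x <- counts[[nm]]
    row <- data.frame(name = nm, true_0 = x$true_0, true_1 = x$true_1,
                      true_2 = x$true_2, p_0 = x$p_0, p_1 = x$p_1,
                      p_2 = x$p_2, tp_0 = x$tp_0, tp_1 = x$tp_1,
                      tp_2 = x$tp_2)
    for (k in 0:2) {
      m <- precision_recall_f1(x[[paste0("p_", k)]],
                               x[[paste0("tp_", k)]],
                               x[[paste0("true_", k)]])
      row[[paste0("pr_", k)]] <- m$pr
      row[[paste0("rc_", k)]] <- m$rc
      row[[paste0("f1_", k)]] <- m$f1
    }
    row
  })
  report <- do.call(rbind, rows)
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
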