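#' Parameters for a synthetic hierarchical fold-space universe
#'
#' The generator places structures in a latent feature space with nested
#' fold / superfamily / family / member dispersion, so that a precise
#' Z-like score (deterministic, decaying with latent distance) and a fast
#' e-value-like score (noisy, incomplete) can be derived analytically.
#' Spreads must be strictly ordered `spread_fold > spread_superfamily >
#' spread_family > spread_member`: each level of the classification
#' disperses less than the one above it.
#'
#' Defaults give a universe of 60 structures over 3 folds in which members
#' of a family sit close enough for near-certain fast-graph edges
#' (e-values near 1e-10), members of a superfamily are reliably connected
#' below the later-shell cutoff, and cross-superfamily (same fold) pairs
#' sit near e-value 1, so that single-shot search underperforms traversal.
#'
#' @param n_folds,superfamilies_per_fold,families_per_superfamily,members_per_family
#'   positive integers giving the nesting of the synthetic classification
#' @param spread_fold,spread_superfamily,spread_family,spread_member positive
#'   dispersions (dimensionless latent units) of the hierarchical offsets
#' @param dim latent dimension
#' @param z_max maximum precise score (score of a self-comparison)
#' @param z_decay latent distance scale of precise-score decay
#' @param p_miss probability in \[0,1\] that a true fast edge is dropped
#'   (false-negative rate of the fast comparison)
#' @param e_noise_sd standard deviation of log10 e-value noise
#' @param seed integer seed; all generator outputs are reproducible given it
#' @return a list of class `universe_params`
#' @export
universe_params <- function(n_folds = 3L,
                            superfamilies_per_fold = 2L,
                            families_per_superfamily = 2L,
                            members_per_family = 5L,
                            spread_fold = 8,
                            spread_superfamily = 3,
                            spread_family = 1.2,
                            spread_member = 0.4,
                            dim = 8L,
                            z_max = 60,
                            z_decay = 8,
                            p_miss = 0.3,
                            e_noise_sd = 0.5,
                            seed = 1L) {
  p <- list(n_folds = as.integer(n_folds),
            superfamilies_per_fold = as.integer(superfamilies_per_fold),
            families_per_superfamily = as.integer(families_per_superfamily),
            members_per_family = as.integer(members_per_family),
            spread_fold = spread_fold,
            spread_superfamily = spread_superfamily,
            spread_family = spread_family,
            spread_member = spread_member,
            dim = as.integer(dim), z_max = z_max, z_decay = z_decay,
            p_miss = p_miss, e_noise_sd = e_noise_sd,
            seed = as.integer(seed))
  viol <- character()
  counts <- p[c("n_folds", "superfamilies_per_fold",
                "families_per_superfamily", "members_per_family", "dim")]
  if (any(unlist(counts) < 1L)) {
    viol <- c(viol, "count parameters and dim must be positive integers")
  }
  sp <- c(p$spread_fold, p$spread_superfamily, p$spread_family,
          p$spread_member)
  if (any(sp <= 0) || any(diff(sp) >= 0)) {
    viol <- c(viol,
      "spreads must be positive and strictly ordered fold > superfamily > family > member")
  }
  if (p$p_miss < 0 || p$p_miss > 1) viol <- c(viol, "p_miss must be in [0,1]")
  if (p$e_noise_sd < 0) viol <- c(viol, "e_noise_sd must be >= 0")
  if (p$z_max <= 2 || p$z_decay <= 0) {
    viol <- c(viol, "z_max must exceed 2 and z_decay must be positive")
  }
  if (length(viol)) {
    stop("invalid universe parameters:\n  - ", paste(viol, collapse = "\n  - "))
  }
  class(p) <- "universe_params"
  p
}

# Expected latent distance between structures differing by independent
# offsets of total per-coordinate variance v (difference ~ N(0, 2v) per
# coordinate): sqrt(2 v dim) is used as the typical-scale anchor.
typical_distance <- function(var_sum, dim) sqrt(2 * var_sum * dim)

# Calibrate the log10-e-value line log10(e) = alpha * d - gamma so that
# family-level pairs land near 1e-10 and same-fold cross-superfamily pairs
# land near 1. Recorded in the universe for reproducibility.
calibrate_evalue <- function(p) {
  d_fam <- typical_distance(p$spread_member^2, p$dim)
  d_fold <- typical_distance(p$spread_superfamily^2 + p$spread_family^2 +
                               p$spread_member^2, p$dim)
  alpha <- 10 / (d_fold - d_fam)
  list(alpha = alpha, gamma = alpha * d_fold)
}

# Secondary-structure string with helix/strand/coil runs; 8-state DSSP-like
# alphabet, but only H/E/C/T are emitted.
synth_ss <- function(len, frac_h = 0.35, frac_e = 0.25) {
  states <- character(0)
  while (length(states) < len) {
    kind <- sample(c("H", "E", "C", "T"), 1L,
                   prob = c(frac_h, frac_e, 1 - frac_h - frac_e - 0.1, 0.1))
    run <- sample(3:9, 1L)
    states <- c(states, rep(kind, run))
  }
  paste(states[seq_len(len)], collapse = "")
}

synth_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

#' Generate a synthetic fold-space universe
#'
#' Latent feature vectors are drawn hierarchically: a fold center plus a
#' superfamily offset plus a family offset plus member noise, each level
#' with its own spread. Residue lengths are uniform in \[80, 400\];
#' secondary-structure strings are synthesized with realistic helix/strand
#' fractions. Output is fully reproducible given `params$seed`.
#'
#' @param params a `universe_params` object
#' @return an object of class `fold_universe` with fields `structures`
#'   (data.frame of structure records), `latent` (matrix, one row per
#'   structure), `params`, and `calib` (the recorded e-value calibration)
#' @export
generate_universe <- function(params = universe_params()) {
  if (!inherits(params, "universe_params")) {
    params <- do.call(universe_params, params)
  }
  p <- params
  withr::with_seed(p$seed, {
    n <- p$n_folds * p$superfamilies_per_fold * p$families_per_superfamily *
      p$members_per_family
    lat <- matrix(0, n, p$dim)
    rec <- vector("list", n)
    i <- 0L
    for (fo in seq_len(p$n_folds)) {
      fold_c <- stats::rnorm(p$dim, 0, p$spread_fold)
      for (sf in seq_len(p$superfamilies_per_fold)) {
        sf_c <- fold_c + stats::rnorm(p$dim, 0, p$spread_superfamily)
        for (fa in seq_len(p$families_per_superfamily)) {
          fa_c <- sf_c + stats::rnorm(p$dim, 0, p$spread_family)
          for (me in seq_len(p$members_per_family)) {
            i <- i + 1L
            lat[i, ] <- fa_c + stats::rnorm(p$dim, 0, p$spread_member)
            len <- sample(80:400, 1L)
            fold_id <- sprintf("f%02d", fo)
            sf_id <- sprintf("%s.s%02d", fold_id, sf)
            fam_id <- sprintf("%s.a%02d", sf_id, fa)
            rec[[i]] <- data.frame(
              id = sprintf("m%04d", i), length = len,
              ss = synth_ss(len), seq = synth_seq(len),
              family = fam_id, superfamily = sf_id, fold = fold_id,
              clan = sf_id,
              accession = sprintf("ACC%05d", i),
              description = sprintf("synthetic member %d of %s", me, fam_id),
              taxonomy = sprintf("Synthetica organismus %d", fo),
              gene = sprintf("gene%04d", i))
          }
        }
      }
    }
    structures <- do.call(rbind, rec)
    rownames(lat) <- structures$id
    structure(list(structures = structures, latent = lat, params = p,
                   calib = calibrate_evalue(p)),
              class = "fold_universe")
  })
}

#' @export
print.fold_universe <- function(x, ...) {
  s <- x$structures
  cat(sprintf(
    "fold_universe: %d structures, %d folds / %d superfamilies / %d families\n",
    nrow(s), length(unique(s$fold)), length(unique(s$superfamily)),
    length(unique(s$family))))
  invisible(x)
}

latent_distance <- function(u, a, b) {
  missing <- setdiff(c(a, b), rownames(u$latent))
  if (length(missing)) {
    stop(sprintf("unknown structure id: %s", paste(missing, collapse = ", ")))
  }
  sqrt(sum((u$latent[a, ] - u$latent[b, ])^2))
}

#' Precise pairwise validation of two synthetic structures
#'
#' The synthetic stand-in for a precise structural aligner. Deterministic
#' given the universe and symmetric in its arguments:
#' `Z = z_max * exp(-d^2 / z_decay^2)` with `d` the latent Euclidean
#' distance, and `lali = round(min(len_a, len_b) * exp(-d^2 / (2 z_decay^2)))`.
#' Scores are reported only above the aligner floor Z > 2; below it a
#' below-threshold marker is returned (`reported = FALSE`, `z = NA`).
#' Aligned position pairs are emitted as the first `lali` positions of both
#' structures, which keeps the non-gap count of stacked-alignment rows equal
#' to `lali` by construction.
#'
#' @param u a `fold_universe`
#' @param a,b structure ids in the universe
#' @return list with fields `query`, `target`, `z`, `lali`,
#'   `aligned_pairs` (2-column matrix, 1-based), `reported`
#' @export
synth_validate <- function(u, a, b) {
  stopifnot(inherits(u, "fold_universe"))
  d <- latent_distance(u, a, b)
  p <- u$params
  z <- p$z_max * exp(-d^2 / p$z_decay^2)
  len_a <- u$structures$length[match(a, u$structures$id)]
  len_b <- u$structures$length[match(b, u$structures$id)]
  lali <- round(min(len_a, len_b) * exp(-d^2 / (2 * p$z_decay^2)))
  reported <- z > 2
  list(query = a, target = b,
       z = if (reported) z else NA_real_,
       lali = as.integer(lali),
       aligned_pairs = if (lali > 0) cbind(seq_len(lali), seq_len(lali)),
       reported = reported)
}

#' Validator closure over a synthetic universe
#'
#' Wraps [synth_validate()] as a `function(query, target)` suitable for the
#' `validator` argument of [transitive_closure()].
#' @param u a `fold_universe`
#' @return a function of (query, target) returning a validation list
#' @export
synth_validator <- function(u) {
  force(u)
  function(query, target) synth_validate(u, query, target)
}

#' Generate the fast-comparison edge table of a universe
#'
#' Emulates an all-vs-all run of a fast structural comparison: for each
#' ordered pair, `log10(e) = alpha * d - gamma + Normal(0, e_noise_sd)` with
#' (alpha, gamma) the universe's recorded calibration (family-level pairs
#' near 1e-10, same-fold cross-superfamily pairs near 1). Each directed edge
#' is independently dropped with probability `p_miss` (fast-method false
#' negatives), and only edges with e-value < 1 are retained. Reproducible
#' given `seed`.
#'
#' @param u a `fold_universe`
#' @param p_miss,e_noise_sd,seed override the universe parameters
#' @return data.frame with columns source, target, evalue
#' @export
synth_fast_edges <- function(u, p_miss = u$params$p_miss,
                             e_noise_sd = u$params$e_noise_sd,
                             seed = u$params$seed + 1000L) {
  stopifnot(inherits(u, "fold_universe"))
  ids <- u$structures$id
  n <- length(ids)
  d <- as.matrix(stats::dist(u$latent))
  withr::with_seed(as.integer(seed), {
    log_e <- u$calib$alpha * d - u$calib$gamma +
      matrix(stats::rnorm(n * n, 0, e_noise_sd), n, n)
    keep <- log_e < 0 & !diag(n)
    if (p_miss > 0) {
      keep <- keep & matrix(stats::runif(n * n) >= p_miss, n, n)
    }
    idx <- which(keep, arr.ind = TRUE)
    data.frame(source = ids[idx[, 1L]], target = ids[idx[, 2L]],
               evalue = 10^log_e[idx])
  })
}

#' Build a linear-chain universe, the worst case for single-shot search
#'
#' Places a query structure and `k` member structures on a latent line with
#' spacing chosen so that only adjacent pairs have fast-comparison edges
#' (adjacent e-value 1e-3, next-nearest 10, above the e < 1 retention rule),
#' while precise validation against the query passes for every member. All
#' `k` members carry the same superfamily/family labels; the designated
#' query id is `"q"` (recorded in the `query_id` field). Fast edges for a
#' chain are deterministic (no noise, no drops).
#'
#' @param k integer >= 3, number of chain members
#' @param len residue length shared by every structure
#' @param z_max maximum precise score
#' @return a `fold_universe` with an extra `query_id` field
#' @export
chain_universe <- function(k, len = 200L, z_max = 60) {
  if (!is.numeric(k) || length(k) != 1L || k < 3) {
    stop("k must be a single integer >= 3")
  }
  k <- as.integer(k)
  spacing <- 4
  dim <- 8L
  n <- k + 1L
  ids <- c("q", sprintf("m%04d", seq_len(k)))
  lat <- matrix(0, n, dim, dimnames = list(ids, NULL))
  lat[, 1L] <- (0:k) * spacing
  # 50% helix+strand pattern so the default minimum-core size stays below
  # the alignment length of even the farthest chain member
  ss_unit <- "HHHHEEEECCCCCCCC"
  ss <- paste(rep(ss_unit, ceiling(len / nchar(ss_unit))), collapse = "")
  ss <- substr(ss, 1L, len)
  structures <- data.frame(
    id = ids, length = len, ss = ss,
    seq = vapply(seq_len(n), function(i) {
      paste(rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                length.out = len), collapse = "")
    }, character(1)),
    family = "chain.a01", superfamily = "chain.s01", fold = "chain",
    clan = "chain.s01",
    accession = sprintf("CH%05d", seq_len(n) - 1L),
    description = "synthetic chain member",
    taxonomy = "Synthetica organismus", gene = ids)
  params <- list(dim = dim, z_max = z_max, z_decay = k * spacing,
                 p_miss = 0, e_noise_sd = 0, seed = 0L)
  # log10(e) = alpha * d - gamma: e(spacing) = 1e-3, e(2 * spacing) = 10
  calib <- list(alpha = 4 / spacing, gamma = 7)
  structure(list(structures = structures, latent = lat, params = params,
                 calib = calib, query_id = "q"),
            class = "fold_universe")
}

#' Assemble search inputs for a query held out of a synthetic universe
#'
#' The query structure itself is never part of the target database: edges
#' touching `query_id` are removed from the persistent store, while the live
#' fast search of the query is served from the query's own rows of the full
#' edge table. Returns everything [transitive_closure()] needs.
#'
#' @param u a `fold_universe`
#' @param query_id id of the structure to use as query (default: the
#'   universe's designated query, if any)
#' @param edges optional precomputed edge table from [synth_fast_edges()]
#' @return list with `query_id`, `query` (structure record row), `store`
#'   (a `neighbor_store` excluding the query), `fast_searcher`
#'   (function(id, e_cutoff)), and `validator` (function(query, target))
#' @export
universe_search_inputs <- function(u, query_id = u$query_id, edges = NULL) {
  stopifnot(inherits(u, "fold_universe"))
  if (is.null(query_id)) stop("query_id must be given")
  if (!query_id %in% u$structures$id) {
    stop(sprintf("unknown structure id: %s", query_id))
  }
  if (is.null(edges)) edges <- synth_fast_edges(u)
  db_edges <- edges[edges$source != query_id & edges$target != query_id, ,
                    drop = FALSE]
  q_edges <- edges[edges$source == query_id, , drop = FALSE]
  q_edges <- q_edges[order(q_edges$evalue, q_edges$target), , drop = FALSE]
  fast_searcher <- function(id, e_cutoff) {
    out <- q_edges[q_edges$source == id & q_edges$evalue < e_cutoff, ,
                   drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(query_id = query_id,
       query = u$structures[u$structures$id == query_id, , drop = FALSE],
       store = neighbor_store(db_edges),
       fast_searcher = fast_searcher,
       validator = synth_validator(u))
}

#' Members of the query's own classification group
#'
#' Reference set for completeness evaluation: all structures sharing the
#' query's label at the given level, excluding the query itself.
#' @param u a `fold_universe`
#' @param query_id a structure id
#' @param level one of "family", "superfamily", "fold", "clan"
#' @return character vector of member ids
#' @export
group_members <- function(u, query_id,
                          level = c("superfamily", "family", "fold", "clan")) {
  level <- match.arg(level)
  s <- u$structures
  lab <- s[[level]][match(query_id, s$id)]
  if (is.na(lab)) stop(sprintf("unknown structure id: %s", query_id))
  setdiff(s$id[s[[level]] == lab], query_id)
}

#' Export a universe as interchangeable TSV inputs
#'
#' Writes metadata, label, and edge TSVs in the same formats the search
#' consumes for real data, plus a JSON file of validator parameters and a
#' latent-coordinate TSV so the universe can be reloaded exactly.
#'
#' @param u a `fold_universe`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @param edges optional precomputed edge table
#' @return named character vector of the written paths, invisibly
#' @export
export_universe <- function(u, dir, prefix = "universe", edges = NULL) {
  stopifnot(inherits(u, "fold_universe"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- u$structures
  paths <- c(
    metadata = file.path(dir, paste0(prefix, "_metadata.tsv")),
    labels = file.path(dir, paste0(prefix, "_labels.tsv")),
    edges = file.path(dir, paste0(prefix, "_edges.tsv")),
    structures = file.path(dir, paste0(prefix, "_structures.tsv")),
    latent = file.path(dir, paste0(prefix, "_latent.tsv")),
    validator = file.path(dir, paste0(prefix, "_validator.json")))
  utils::write.table(s[c("id", "accession", "description", "taxonomy",
                         "gene")],
                     paths["metadata"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(s[c("id", "family", "superfamily", "fold", "clan")],
                     paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (is.null(edges)) edges <- synth_fast_edges(u)
  write_edge_tsv(edges, paths["edges"])
  utils::write.table(s[c("id", "length", "ss", "seq")], paths["structures"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lat <- data.frame(id = rownames(u$latent), u$latent, check.names = FALSE)
  utils::write.table(lat, paths["latent"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- c(u$params[c("dim", "z_max", "z_decay", "p_miss", "e_noise_sd",
                       "seed")],
            u$calib)
  if (!is.null(u$query_id)) meta$query_id <- u$query_id
  jsonlite::write_json(meta, paths["validator"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Reload a universe exported with [export_universe()]
#' @param dir directory holding the exported files
#' @param prefix file-name prefix used at export
#' @return a `fold_universe`
#' @export
load_universe <- function(dir, prefix = "universe") {
  sp <- file.path(dir, paste0(prefix, "_structures.tsv"))
  lp <- file.path(dir, paste0(prefix, "_latent.tsv"))
  vp <- file.path(dir, paste0(prefix, "_validator.json"))
  gp <- file.path(dir, paste0(prefix, "_labels.tsv"))
  for (f in c(sp, lp, vp, gp)) {
    if (!file.exists(f)) stop("missing universe file: ", f)
  }
  st <- utils::read.delim(sp, colClasses = c(id = "character",
                                             ss = "character",
                                             seq = "character"))
  lb <- utils::read.delim(gp, colClasses = "character")
  st <- merge(st, lb, by = "id", sort = FALSE)
  mp <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  if (file.exists(mp)) st <- merge(st, read_metadata_tsv(mp), by = "id",
                                   sort = FALSE)
  lat <- utils::read.delim(lp, check.names = FALSE)
  latm <- as.matrix(lat[-1L])
  rownames(latm) <- lat$id
  meta <- jsonlite::read_json(vp, simplifyVector = TRUE)
  u <- list(structures = st, latent = latm,
            params = meta[c("dim", "z_max", "z_decay", "p_miss",
                            "e_noise_sd", "seed")],
            calib = meta[c("alpha", "gamma")])
  if (!is.null(meta$query_id)) u$query_id <- meta$query_id
  structure(u, class = "fold_universe")
}
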