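# Shared fixture builders and independent oracles used across test files.

# random edge table over n_ids structures
random_edges <- function(n_edges, n_ids = 8, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("x%02d", seq_len(n_ids))
    data.frame(source = sample(ids, n_edges, replace = TRUE),
               target = sample(ids, n_edges, replace = TRUE),
               evalue = 10^stats::runif(n_edges, -12, -0.01))
  })
}

# brute-force linear-scan oracle for store_neighbors: dedup (min e-value),
# drop self-edges, filter, sort
scan_neighbors <- function(edges, source, e_cutoff) {
  e <- edges[edges$source != edges$target, , drop = FALSE]
  e <- e[order(e$source, e$target, e$evalue), , drop = FALSE]
  e <- e[!duplicated(e[c("source", "target")]), , drop = FALSE]
  e <- e[e$source == source & e$evalue < e_cutoff, , drop = FALSE]
  e <- e[order(e$evalue, e$target), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# literal sequential simulation of the greedy masking rule, written
# independently of select_representatives
greedy_selection_oracle <- function(candidates, store, e_mask) {
  ord <- order(candidates$evalue, candidates$id)
  ids <- candidates$id[ord]
  reps <- character()
  masked_under <- list()
  masked <- character()
  for (id in ids) {
    if (id %in% masked) next
    reps <- c(reps, id)
    if (e_mask > 0) {
      ball <- mask_neighbors(store, id, e_mask)
      newly <- setdiff(intersect(ball, ids), c(reps, masked))
      if (length(newly)) {
        masked_under[[id]] <- sort(newly)
        masked <- c(masked, newly)
      }
    }
  }
  list(representatives = reps, masked = masked_under)
}

# exhaustive prefix enumeration oracle for fmax and step-wise AUPRC
enumerate_pr <- function(ranked, true_set, direction = "smaller") {
  s <- if (direction == "smaller") ranked$score else -ranked$score
  r <- ranked[order(s, ranked$id), , drop = FALSE]
  n_true <- length(unique(true_set))
  cut_idx <- which(c(r$score[-1] != r$score[-nrow(r)], TRUE))
  pr <- rc <- f1 <- numeric(length(cut_idx))
  for (k in seq_along(cut_idx)) {
    i <- cut_idx[k]
    tp <- sum(r$id[seq_len(i)] %in% true_set)
    pr[k] <- tp / i
    rc[k] <- if (n_true) tp / n_true else 0
    f1[k] <- if (pr[k] + rc[k] > 0) 2 * pr[k] * rc[k] / (pr[k] + rc[k]) else 0
  }
  area <- sum(pr * diff(c(0, rc)))
  list(fmax = if (length(f1)) max(f1) else 0, auprc = area,
       precision = pr, recall = rc)
}

# small universe tuned so representative masking actually triggers
masked_universe <- function(seed) {
  generate_universe(universe_params(
    n_folds = 2, superfamilies_per_fold = 2, families_per_superfamily = 2,
    members_per_family = 4, p_miss = 0.15, e_noise_sd = 0.4, seed = seed))
}

# minimal fixed-width PDB ATOM line
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          alt = " ", icode = " ", record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, elety, alt, resid, chain, resno, icode,
          x, y, z, 1.0, 20.0)
}
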