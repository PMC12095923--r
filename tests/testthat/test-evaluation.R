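test_that("suffix filtering matches a set-comprehension oracle and nests", {
  withr::with_seed(41, {
    ids <- sprintf("s%03d", 1:50)
    vals <- data.frame(id = ids, z = round(runif(50, 0, 12), 2),
                       lali = sample(10:200, 50, replace = TRUE))
    vals$z[sample(50, 5)] <- NA  # some never validated
    ref <- sample(ids, 25)
    res <- sample(ids, 30)
    zcut <- 3; minlali <- 80
    got <- suffix_counts(ref, res, vals, zcut = zcut, minlali = minlali)

    z_of <- setNames(vals$z, vals$id); l_of <- setNames(vals$lali, vals$id)
    oracle <- function(set, level) {
      if (level == 0) return(set)
      keep <- vapply(set, function(i) {
        z <- z_of[[i]]
        if (is.na(z) || z <= 2) return(FALSE)
        if (level == 1) return(TRUE)
        z > zcut && l_of[[i]] >= minlali
      }, logical(1))
      set[keep]
    }
    for (k in 0:2) {
      expect_setequal(got$sets[[paste0("true_", k)]], oracle(ref, k))
      expect_setequal(got$sets[[paste0("p_", k)]], oracle(res, k))
      expect_setequal(got$sets[[paste0("tp_", k)]],
                      intersect(oracle(ref, k), oracle(res, k)))
    }
    # nesting
    expect_true(all(got$sets$true_2 %in% got$sets$true_1))
    expect_true(all(got$sets$true_1 %in% got$sets$true_0))
    expect_true(all(got$sets$p_2 %in% got$sets$p_1))
    expect_true(all(got$sets$p_1 %in% got$sets$p_0))
    expect_lte(got$tp_2, min(got$p_2, got$true_2))
  })
  expect_error(suffix_counts("a", "a",
                             data.frame(id = "a", z = 5, lali = 10),
                             minlali = -1), "minlali")
})

test_that("members below the findability floor are excluded from suffix 1", {
  vals <- data.frame(id = c("a", "b"), z = c(1.5, 9), lali = c(100, 100))
  got <- suffix_counts(c("a", "b"), c("a", "b"), vals, minlali = 0)
  expect_equal(got$true_0, 2L)
  expect_equal(got$true_1, 1L)
  expect_false("a" %in% got$sets$true_1)
})

test_that("precision, recall and F1 follow the exact formulas", {
  m <- precision_recall_f1(65, 64, 64)
  expect_equal(m$pr, 64 / 65)
  expect_equal(m$rc, 1.0)
  expect_equal(m$f1, 2 * (64 / 65) / (64 / 65 + 1))
  expect_equal(round(m$pr, 5), 0.98462)
  expect_equal(round(m$f1, 5), 0.99225)

  expect_equal(round(precision_recall_f1(794, 613, 719)$rc, 5), 0.85257)

  perfect <- precision_recall_f1(7, 7, 7)
  expect_equal(unlist(perfect[c("pr", "rc", "f1")]), c(pr = 1, rc = 1, f1 = 1))

  zero <- precision_recall_f1(0, 0, 0)
  expect_equal(zero$f1, 0)
  expect_false(zero$pr_defined)
  expect_false(zero$rc_defined)

  expect_error(precision_recall_f1(5, 6, 10), "exceed")
  expect_error(precision_recall_f1(10, 6, 5), "exceed")
})

test_that("Fmax equals exhaustive prefix enumeration", {
  # perfect ranking: all relevant items first
  ranked <- data.frame(id = letters[1:6], score = 1:6)
  expect_equal(fmax(ranked, letters[1:3], "smaller")$fmax, 1)
  expect_equal(fmax(ranked, letters[1:3], "smaller")$n_at_cutoff, 3L)

  # single relevant item ranked last of 4
  r4 <- data.frame(id = c("a", "b", "c", "d"), score = c(1, 2, 3, 4))
  got <- fmax(r4, "d", "smaller")
  want <- enumerate_pr(r4, "d", "smaller")
  expect_equal(got$fmax, want$fmax)
  expect_equal(got$fmax, 2 * (1 / 4) * 1 / (1 / 4 + 1))

  expect_equal(fmax(r4[0, ], "d", "smaller")$fmax, 0)

  withr::with_seed(51, {
    for (i in 1:10) {
      n <- sample(5:20, 1)
      ranked <- data.frame(id = sprintf("i%02d", 1:n),
                           score = sample(round(runif(n, 0, 5), 1)))
      true_set <- sample(ranked$id, sample.int(n, 1))
      dir <- sample(c("smaller", "larger"), 1)
      got <- fmax(ranked, true_set, dir)
      want <- enumerate_pr(ranked, true_set, dir)
      expect_equal(got$fmax, want$fmax)
      # fmax dominates F1 at an arbitrary fixed cutoff
      k <- sample(n, 1)
      tp_k <- sum(ranked$id[order(if (dir == "smaller") ranked$score
                                  else -ranked$score)][1:k] %in% true_set)
      f1_k <- precision_recall_f1(k, tp_k, length(true_set))$f1
      expect_gte(got$fmax + 1e-12, f1_k)
    }
  })
})

test_that("precision-recall curves and step-wise AUPRC match enumeration", {
  ranked <- data.frame(id = letters[1:5], score = 1:5)
  expect_equal(pr_curve_auprc(ranked, letters[1:2], "smaller")$auprc, 1)
  none <- pr_curve_auprc(ranked, "zz", "smaller")
  expect_equal(none$auprc, 0)

  empty_true <- pr_curve_auprc(ranked, character(), "smaller")
  expect_equal(empty_true$auprc, 0)
  expect_false(empty_true$auprc_defined)

  # 6-item fixture, hand-computed step sum: relevant at ranks 1, 3, 4
  r6 <- data.frame(id = c("a", "b", "c", "d", "e", "f"), score = 1:6)
  res <- pr_curve_auprc(r6, c("a", "c", "d"), "smaller")
  hand <- 1 * (1 / 3) + (2 / 3) * (1 / 3) + (3 / 4) * (1 / 3)
  expect_equal(res$auprc, hand)
  expect_equal(res$points$precision, c(1, 1/2, 2/3, 3/4, 3/5, 3/6))
  expect_equal(res$points$recall, c(1/3, 1/3, 2/3, 1, 1, 1))

  withr::with_seed(52, {
    for (i in 1:10) {
      n <- sample(5:20, 1)
      ranked <- data.frame(id = sprintf("i%02d", 1:n),
                           score = sample(round(runif(n, 0, 5), 1)))
      true_set <- sample(ranked$id, sample.int(n, 1))
      dir <- sample(c("smaller", "larger"), 1)
      got <- pr_curve_auprc(ranked, true_set, dir)
      want <- enumerate_pr(ranked, true_set, dir)
      expect_equal(got$auprc, want$auprc)
      expect_equal(got$points$precision, want$precision)
      expect_equal(got$points$recall, want$recall)
    }
  })
})

test_that("pair stratification partitions same-fold pairs into disjoint strata", {
  two <- data.frame(id = c("a", "b"), family = "f", superfamily = "sf",
                    fold = "fo")
  got <- stratify_pairs(two)
  expect_equal(nrow(got$family), 1L)
  expect_equal(nrow(got$superfamily) + nrow(got$fold), 0L)

  # 2 families x 2 members in one superfamily: 2 family + 4 superfamily pairs
  lab <- data.frame(id = c("a1", "a2", "b1", "b2"),
                    family = c("fa", "fa", "fb", "fb"),
                    superfamily = "sf", fold = "fo")
  got2 <- stratify_pairs(lab)
  expect_equal(nrow(got2$family), 2L)
  expect_equal(nrow(got2$superfamily), 4L)
  expect_equal(nrow(got2$fold), 0L)

  # random hierarchy against an O(n^2) double-loop oracle
  withr::with_seed(61, {
    n <- 30
    lab3 <- data.frame(id = sprintf("p%02d", 1:n),
                       family = sample(sprintf("fam%d", 1:6), n, TRUE),
                       superfamily = NA, fold = NA)
    fam2sf <- setNames(sample(sprintf("sf%d", 1:3), 6, TRUE),
                       sprintf("fam%d", 1:6))
    sf2fold <- setNames(sample(sprintf("fo%d", 1:2), 3, TRUE),
                        sprintf("sf%d", 1:3))
    lab3$superfamily <- fam2sf[lab3$family]
    lab3$fold <- sf2fold[lab3$superfamily]
    got3 <- stratify_pairs(lab3)
    counts <- c(family = 0L, superfamily = 0L, fold = 0L, none = 0L)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- lab3[i, ]; b <- lab3[j, ]
      s <- if (a$fold != b$fold) "none"
      else if (a$superfamily != b$superfamily) "fold"
      else if (a$family != b$family) "superfamily"
      else "family"
      counts[s] <- counts[s] + 1L
    }
    expect_equal(nrow(got3$family), unname(counts["family"]))
    expect_equal(nrow(got3$superfamily), unname(counts["superfamily"]))
    expect_equal(nrow(got3$fold), unname(counts["fold"]))
    # strata are disjoint
    keys <- function(df) paste(df$a, df$b)
    expect_length(intersect(keys(got3$family), keys(got3$superfamily)), 0L)
    expect_length(intersect(keys(got3$family), keys(got3$fold)), 0L)
  })

  # missing labels skip pairs and count them
  lab4 <- data.frame(id = c("a", "b", "c"), family = c("f", "f", NA),
                     superfamily = "sf", fold = "fo")
  got4 <- stratify_pairs(lab4)
  expect_equal(got4$n_skipped, 2)  # pairs (a,c) and (b,c)
  expect_equal(nrow(got4$family), 1L)
})

test_that("recall by stratum aggregates pooled and query-wise statistics", {
  tp <- data.frame(query = "q1", target = c("a", "b", "c"),
                   stratum = "family")
  hits <- data.frame(query = "q1", target = c("a", "b"))
  got <- recall_by_stratum(tp, hits)
  fam <- got[got$stratum == "family", ]
  expect_equal(fam$pooled, 2 / 3)
  expect_equal(fam$query_mean, 2 / 3)
  expect_equal(fam$query_median, 2 / 3)

  # two queries with recalls 0 and 1: mean 0.5, median 0.5, pooled weighted
  tp2 <- data.frame(query = c("q1", "q2", "q2", "q2"),
                    target = c("a", "b", "c", "d"), stratum = "family")
  hits2 <- data.frame(query = "q2", target = c("b", "c", "d"))
  got2 <- recall_by_stratum(tp2, hits2)
  fam2 <- got2[got2$stratum == "family", ]
  expect_equal(fam2$query_mean, 0.5)
  expect_equal(fam2$query_median, 0.5)
  expect_equal(fam2$pooled, 3 / 4)

  # when at least half the queries reach full recall the median is 1
  tp3 <- data.frame(query = rep(c("q1", "q2", "q3"), each = 2),
                    target = sprintf("t%d", 1:6), stratum = "family")
  hits3 <- data.frame(query = c("q1", "q1", "q2", "q2", "q3"),
                      target = c("t1", "t2", "t3", "t4", "t5"))
  got3 <- recall_by_stratum(tp3, hits3)
  expect_equal(got3$query_median[got3$stratum == "family"], 1)
})

test_that("the label-transfer rule enforces its boundaries exactly", {
  expect_true(transfer_labels(0.85, 0.90, 45, 1e-10))
  expect_false(transfer_labels(0.85, 0.90, 40, 1e-10))  # identity strict
  expect_false(transfer_labels(0.79, 0.90, 45, 1e-10))
  expect_false(transfer_labels(0.90, 0.79, 45, 1e-10))
  expect_true(transfer_labels(0.80, 0.80, 40.01, 1e-6)) # coverage inclusive
  expect_false(transfer_labels(0.85, 0.90, 45, 1e-5))   # e-value strict
})

test_that("the packaged benchmark counts satisfy the row-level invariants", {
  b <- clan_benchmark()
  expect_equal(nrow(b), 12L)
  expect_true(all(b$true_2 <= b$true_1 & b$true_1 <= b$true_0))
  expect_true(all(b$closure_p2 <= b$closure_p1 &
                    b$closure_p1 <= b$closure_p0))
  expect_true(all(b$foldseek_p2 <= b$foldseek_p1 &
                    b$foldseek_p1 <= b$foldseek_p0))
  expect_true(all(b$closure_tp1 <= pmin(b$closure_p1, b$true_1)))
  expect_true(all(b$closure_tp2 <= pmin(b$closure_p2, b$true_2)))
  expect_true(all(b$foldseek_tp1 <= pmin(b$foldseek_p1, b$true_1)))
  expect_true(all(b$foldseek_tp2 <= pmin(b$foldseek_p2, b$true_2)))
  expect_true(all(b$closure_tp2 <= b$closure_tp1))

  q <- clan_benchmark_queries()
  expect_equal(q$case, 1:12)
  expect_equal(q$clan, b$clan)
})

test_that("the evaluation report writes counts and derived metrics losslessly", {
  vals <- data.frame(id = c("a", "b", "c"), z = c(9, 4, 1),
                     lali = c(90, 40, 10))
  counts <- suffix_counts(c("a", "b", "c"), c("a", "c"), vals,
                          minlali = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  rep <- write_evaluation_report(counts, path)
  back <- read.delim(path)
  expect_equal(back$true_0, 3L)
  expect_equal(back$true_1, 2L)
  expect_equal(back$true_2, 1L)
  expect_equal(back$p_2, 1L)
  expect_equal(back$tp_2, 1L)
  expect_equal(back$rc_2, 1)
  expect_equal(back$pr_1, 1)
})
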