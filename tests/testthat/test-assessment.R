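# Benchmark evaluation: classification, precision/recall, ranking bins,
# overlap partitions and the orchestrated assessment.

test_that("classify_at_threshold counts the four cells correctly", {
  p <- c(0, 0, 1, 1, 1)
  case <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  cc <- classify_at_threshold(p, case, 0.5)
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               c(TP = 2L, FP = 0L, FN = 0L, TN = 3L), ignore_attr = TRUE)
  cc1 <- classify_at_threshold(p, case, 1)
  expect_equal(precision_recall(cc1)[["recall"]], 1)
  # brute-force recount on random inputs
  set.seed(12)
  p <- runif(200); case <- runif(200) < 0.1
  for (t in c(0.05, 0.3, 0.9)) {
    cc <- classify_at_threshold(p, case, t)
    expect_equal(cc[["TP"]], sum(p <= t & case))
    expect_equal(cc[["FP"]], sum(p <= t & !case))
    expect_equal(cc[["TP"]] + cc[["FN"]], sum(case))
    expect_equal(cc[["FP"]] + cc[["TN"]], sum(!case))
  }
  expect_error(classify_at_threshold(p, case[-1], 0.5), "lengths")
})

test_that("precision_recall computes the two ratios with NA when undefined", {
  cc <- c(TP = 5, FP = 5, FN = 5, TN = 100)
  pr <- precision_recall(cc)
  expect_equal(pr[["precision"]], 0.5)
  expect_equal(pr[["recall"]], 0.5)
  expect_equal(precision_recall(c(TP = 3, FP = 0, FN = 7, TN = 1))[["precision"]], 1)
  expect_true(is.na(precision_recall(c(TP = 0, FP = 0, FN = 4, TN = 9))[["precision"]]))
  set.seed(5)
  for (rep in 1:5) {
    cc <- c(TP = rpois(1, 5) + 1, FP = rpois(1, 5), FN = rpois(1, 5),
            TN = rpois(1, 50))
    pr <- precision_recall(cc)
    expect_equal(pr[["precision"]], cc[["TP"]] / (cc[["TP"]] + cc[["FP"]]))
    expect_equal(pr[["recall"]], cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]))
  }
})

test_that("pr_curve is a step curve over distinct thresholds", {
  # perfectly separated: precision 1 up to recall 1
  p <- c(0.01, 0.02, 0.5, 0.6, 0.7)
  case <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  curve <- pr_curve(p, case)
  expect_equal(nrow(curve), 5)
  expect_true(all(diff(curve$recall) >= 0))
  expect_equal(curve$precision[2], 1)
  expect_equal(curve$recall[2], 1)
  # all-tied P values collapse to one point at the case prevalence
  curve <- pr_curve(rep(0.04, 10), c(rep(TRUE, 2), rep(FALSE, 8)))
  expect_equal(nrow(curve), 1)
  expect_equal(curve$precision, 0.2)
  expect_equal(curve$recall, 1)
  expect_true(curve$operating)
  # a tie mixing cases and controls yields an intermediate precision step
  p <- c(1e-4, 1e-4, 1e-4, 0.2, 0.9)
  case <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  curve <- pr_curve(p, case)
  expect_equal(curve$precision[1], 1 / 3)
  # operating point: largest threshold <= 0.05
  expect_equal(curve$threshold[curve$operating], 1e-4)
})

test_that("rank_case ties-averages and ranks NA families last", {
  p <- c(f1 = 0.01, f2 = 0.5, f3 = 0.2)
  expect_equal(rank_case(p, "f1"), 1)
  expect_equal(rank_case(c(f1 = 0.01, f2 = 0.01, f3 = 0.2), "f1"), 1.5)
  expect_equal(rank_case(c(f1 = NA, f2 = 0.3, f3 = 0.2), "f1"), 3)
  set.seed(77)
  for (rep in 1:5) {
    p <- stats::setNames(sample(round(runif(12), 1)), paste0("f", 1:12))
    expect_equal(rank_case(p, "f7"), manual_ranks(ifelse(is.na(p), Inf, p))[7])
  }
  expect_error(rank_case(p, "nope"), "absent")
})

test_that("bin_ranks partitions family sets by rank and significance", {
  rs <- bin_ranks(ranks = rep(1, 4), significant = rep(TRUE, 4),
                  top_ranked = rep(TRUE, 4))
  expect_equal(rs$significant_top3, 4)
  expect_equal(rs$top_rank_significant, 4)
  rs <- bin_ranks(ranks = c(1, 2, 7, 15), significant = c(TRUE, FALSE, FALSE, TRUE),
                  top_ranked = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unlist(rs[c("significant_top3", "insignificant_top3",
                           "rank4to10", "above10")]),
               c(significant_top3 = 1L, insignificant_top3 = 1L,
                 rank4to10 = 1L, above10 = 1L))
  expect_equal(rs$top_rank_total, 1)
  expect_equal(rs$top_rank_significant, 1)
  # bins always sum to the number of family sets
  set.seed(31)
  ranks <- sample(1:50, 30, replace = TRUE)
  rs <- bin_ranks(ranks, runif(30) < 0.3, ranks == 1)
  expect_equal(rs$significant_top3 + rs$insignificant_top3 + rs$rank4to10 +
                 rs$above10, 30)
})

test_that("overlap_sets partitions sets by the exact subset of top-ranking tests", {
  all_sets <- paste0("s", 1:6)
  identical_sets <- list(A = all_sets[1:3], B = all_sets[1:3])
  ov <- overlap_sets(identical_sets, all_sets)
  expect_equal(ov$count[ov$subset == "A+B"], 3)
  expect_equal(ov$count[ov$subset == "none"], 3)
  disjoint <- list(A = "s1", B = "s2", C = "s3")
  ov <- overlap_sets(disjoint, all_sets)
  expect_setequal(ov$subset, c("A", "B", "C", "none"))
  expect_equal(sum(ov$count), 6)
  # random sets against a brute-force per-element partition
  set.seed(9)
  tests <- c("IF", "KS", "PB")
  tops <- lapply(tests, function(t) sample(all_sets, sample(0:6, 1)))
  names(tops) <- tests
  ov <- overlap_sets(tops, all_sets)
  expect_equal(sum(ov$count), length(all_sets))
  for (s in all_sets) {
    members <- tests[vapply(tops, function(x) s %in% x, logical(1))]
    key <- if (length(members)) paste(members, collapse = "+") else "none"
    expect_true(key %in% ov$subset)
  }
})

test_that("run_assessment orchestrates sets, pools and summaries deterministically", {
  ped <- generate_pedigree(pedigree_spec(3, mean_sibship = 2.5), seed = 43)
  scen <- scenario(Q = 1, R = 1 / 10, G = "all")
  out <- run_assessment(ped, scen, tests = c("KS", "PB"), B = 200, seed = 47)
  expect_length(out, 1)
  r <- out[[1]]
  expect_equal(r$n_cases, 3)
  expect_equal(r$n_controls, 6)
  for (tt in c("KS", "PB")) {
    rs <- r[[tt]]$rank_summary
    expect_equal(rs$significant_top3 + rs$insignificant_top3 + rs$rank4to10 +
                   rs$above10, 3)
    cc <- r[[tt]]$confusion
    expect_equal(cc[["TP"]] + cc[["FN"]], 3)
    expect_equal(cc[["FP"]] + cc[["TN"]], 6)
    expect_length(r[[tt]]$case_ranks, 3)
  }
  expect_equal(sum(r$overlap$count), 3)
  out2 <- run_assessment(ped, scen, tests = c("KS", "PB"), B = 200, seed = 47)
  expect_identical(out, out2)
})

test_that("KS and PB top-rank counts dominate IF on an easy scenario", {
  # 50 families, Q = 1, R = 1/25, G = 3, B = 2000, five seeds: the KS and PB
  # tests should each top-rank at least as many cases as IF in >= 4/5 seeds
  ks_wins <- pb_wins <- 0
  for (s in 1:5) {
    ped <- generate_pedigree(pedigree_spec(50), seed = 500 + s)
    out <- run_assessment(ped, scenario(Q = 1, R = 1 / 25, G = 3),
                          tests = c("IF", "KS", "PB"), B = 2000,
                          seed = 600 + s)
    r <- out[[1]]
    top_if <- r$IF$rank_summary$top_rank_total
    ks_wins <- ks_wins + (r$KS$rank_summary$top_rank_total >= top_if)
    pb_wins <- pb_wins + (r$PB$rank_summary$top_rank_total >= top_if)
  }
  expect_gte(ks_wins, 4)
  expect_gte(pb_wins, 4)
})
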