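# Aggregation test statistics, the binomial test, the resampling null and
# the empirical-P machinery, adjustment, summarization and ranking.

test_that("statistics reproduce hand-computed values on small families", {
  K <- kinship_matrix(cousins_ped())
  # two affected full sibs
  expect_equal(if_statistic(c("a", "b"), K), 0.25)
  # affected parent + two affected children: three pairs of 0.25
  Kn <- kinship_matrix(nuclear_ped())
  expect_equal(if_statistic(c("f", "s1", "s2"), Kn), 0.25)
  # cross-branch trio: sib pair 0.25, uncle-niece 0.125, grandparent 0.125
  expect_equal(if_statistic(c("a", "b", "bc"), K),
               (0.25 + 0.125 + 0.25) / 3)
  expect_equal(if_statistic(c("a", "b", "bc"), K),
               brute_if(K, c("a", "b", "bc")))
  expect_true(is.na(if_statistic("a", K)))

  # kinship sums
  expect_equal(ks_statistic("s1", c("s1", "s2", "s3"), Kn), 0.5)
  expect_equal(ks_statistic("ac", c("ac", "a", "bc"), K), 0.25 + 0.0625)
  expect_true(is.na(ks_statistic("ac", "ac", K)))

  # group tests: group of ac with affected sib-parent a and cousin bc
  expect_equal(gr_statistic("ac", c("ac", "a", "bc"), K), 3L)
  expect_equal(gc_statistic("ac", c("ac", "a", "bc"), K), 0.25)
  expect_equal(gc_statistic("ac", c("ac", "bc"), K), 0.0625)
  expect_true(is.na(gr_statistic("ac", "ac", K)))
  expect_true(is.na(gc_statistic("ac", "ac", K)))
})

test_that("pb_test equals the exact binomial upper tail", {
  R <- 265 / 4373
  # printed worked examples, 3 significant figures
  expect_equal(signif(pb_test(20, 5, R), 3), 5.88e-3)
  expect_equal(signif(pb_test(67, 9, R), 3), 1.95e-2)
  expect_equal(signif(pb_test(63, 8, R), 3), 3.60e-2)
  expect_equal(signif(pb_test(82, 8, R), 3), 1.24e-1)
  expect_equal(signif(pb_test(114, 10, R), 3), 1.54e-1)
  expect_equal(pb_test(10, 0, 0.3), 1)
  # independent oracle: direct pmf summation; pmf mass sums to one
  for (n in c(1, 7, 20)) for (r in c(0.05, 0.3)) {
    expect_equal(sum(dbinom(0:n, n, r)), 1, tolerance = 1e-12)
    for (k in c(0, 1, n)) {
      expect_equal(pb_test(n, k, r), sum(dbinom(k:n, n, r)),
                   tolerance = 1e-12)
    }
  }
  expect_error(pb_test(10, 2, 0), "prevalence")
  expect_error(pb_test(10, 2, 1), "prevalence")
  expect_error(pb_test(10, 12, 0.1), "0 <= k <= n")
})

test_that("resample_null draws uniform without-replacement samples reproducibly", {
  d1 <- resample_null(letters[1:3], 3, 5, seed = 7)
  for (b in 1:5) expect_setequal(null_draw_ids(d1, b), letters[1:3])
  d2 <- resample_null(letters[1:10], 4, 50, seed = 7)
  d3 <- resample_null(letters[1:10], 4, 50, seed = 7)
  expect_identical(unclass(d2), unclass(d3))
  # marginal inclusion frequency ~ n/N within 4 sigma at B = 10000
  B <- 10000
  d <- resample_null(letters[1:10], 4, B, seed = 1)
  freq <- tabulate(as.integer(d), nbins = 10) / B
  se <- sqrt(0.4 * 0.6 / B)
  expect_true(all(abs(freq - 0.4) < 4 * se))
  expect_error(resample_null(letters[1:3], 4, 10), "exceeds")
})

test_that("empirical_p uses the add-one estimator with tail ties", {
  expect_equal(empirical_p(10, (1:999) / 1000), 1 / 1000)
  expect_equal(empirical_p(0, (1:999) / 1000), 1)
  expect_equal(empirical_p(5, c(4, 5, 6)), 3 / 4)  # tie counts toward tail
  expect_error(empirical_p(1, numeric(0)), "empty")
  expect_error(empirical_p(Inf, 1:3), "finite")
})

test_that("bh_adjust matches an independent step-up implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(42)
  for (rep in 1:5) {
    p <- runif(20)^2
    adj <- bh_adjust(p)
    expect_equal(adj, manual_bh(p))
    expect_true(all(adj >= p))
    # monotone non-decreasing in sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # permutation equivariance
    perm <- sample(20)
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("rank_units averages tied positions", {
  expect_equal(rank_units(c(0.001, 0.002, 0.002)), c(1, 2.5, 2.5))
  p <- c(0.5, 0.1, 0.9, 0.3)
  expect_equal(rank_units(p), c(3, 1, 4, 2))
  set.seed(8)
  p <- sample(round(runif(30), 2))  # forced ties
  expect_equal(rank_units(p), manual_ranks(p))
})

test_that("family_min_p takes the per-family minimum over ok units", {
  res <- data.frame(
    unit_id = c("i1", "i2", "i3", "i4", "i5"),
    family_id = c("f1", "f1", "f2", "f2", "f3"),
    P_raw = c(0.2, 0.05, 0.4, NA, NA),
    status = c("ok", "ok", "ok", "not_applicable", "not_applicable"),
    stringsAsFactors = FALSE)
  fm <- family_min_p(res)
  expect_equal(fm$P_raw[fm$family_id == "f1"], 0.05)
  expect_equal(fm$unit_id[fm$family_id == "f1"], "i2")
  expect_equal(fm$P_raw[fm$family_id == "f2"], 0.4)
  expect_false("f3" %in% fm$family_id)  # all-NA family excluded
  # brute-force group-by min on random inputs
  set.seed(3)
  res <- data.frame(unit_id = paste0("u", 1:40),
                    family_id = sample(paste0("f", 1:8), 40, replace = TRUE),
                    P_raw = runif(40), status = "ok",
                    stringsAsFactors = FALSE)
  fm <- family_min_p(res)
  expect_equal(fm$P_raw,
               as.vector(tapply(res$P_raw, res$family_id, min)[fm$family_id]))
})

test_that("run_fa_tests completes on a multi-family pedigree with coherent output", {
  ped <- generate_pedigree(pedigree_spec(10, mean_sibship = 2.5), seed = 7)
  scen <- scenario(Q = 1, R = 1 / 10, G = "all")
  sets <- build_family_sets(ped, scen, seed = 3)
  res <- run_fa_tests(ped, phenotypes = assignment_phenotypes(sets[[2]]$assignment),
                      B = 400, seed = 5)
  expect_named(res, c("IF", "KS", "GR", "GC", "PB"))
  for (tt in names(res)) {
    df <- res[[tt]]
    ok <- df$status == "ok"
    expect_true(any(ok))
    expect_true(all(df$P_raw[ok] > 0 & df$P_raw[ok] <= 1))
    expect_true(all(df$P_adj[ok] >= df$P_raw[ok] - 1e-12))
    expect_true(all(df$rank[ok] >= 1))
    expect_true(all(is.finite(df$statistic[ok])))
    expect_true(all(is.na(df$P_raw[!ok])))
  }
  expect_equal(res$PB$unit_type[1], "family")
  expect_equal(res$KS$unit_type[1], "individual")
  # engine statistics agree with the granular statistic functions
  K <- kinship_matrix(ped)
  affected <- res$KS$unit_id[res$KS$status == "ok"]
  aff_all <- names(which(assignment_phenotypes(sets[[2]]$assignment) == "affected"))
  for (i in affected[1:5]) {
    expect_equal(res$KS$statistic[res$KS$unit_id == i],
                 ks_statistic(i, aff_all, K))
    expect_equal(res$GR$statistic[res$GR$unit_id == i],
                 as.numeric(gr_statistic(i, aff_all, K)))
    expect_equal(res$GC$statistic[res$GC$unit_id == i],
                 gc_statistic(i, aff_all, K))
  }
  fam1 <- res$IF$unit_id[res$IF$status == "ok"][1]
  expect_equal(res$IF$statistic[res$IF$unit_id == fam1],
               if_statistic(intersect(aff_all, ped$id[ped$family == fam1]), K))
  # family-min-P equals the min over that family's affected members
  fm <- family_min_p(res$KS)
  for (f in fm$family_id) {
    expect_equal(fm$P_raw[fm$family_id == f],
                 min(res$KS$P_raw[res$KS$family_id == f & res$KS$status == "ok"]))
  }
  # determinism
  res2 <- run_fa_tests(ped, phenotypes = assignment_phenotypes(sets[[2]]$assignment),
                       B = 400, seed = 5)
  expect_identical(res, res2)
})

test_that("Monte-Carlo P values converge to the exact conditional permutation P", {
  # single 8-member family: exhaustive enumeration over all label assignments
  fam <- nuclear_ped()
  two <- rbind(as.data.frame(fam), data.frame(
    family = "n1", id = c("s1c1", "s1c2", "s1sp"),
    father = c("s1", "s1", NA), mother = c("s1sp", "s1sp", NA),
    sex = c("male", "female", "female"), phenotype = "unaffected",
    stringsAsFactors = FALSE))
  fam <- pedigree(two$family, two$id, two$father, two$mother, two$sex,
                  two$phenotype)
  K <- kinship_matrix(fam)
  pool <- fam$id
  affected <- c("f", "s1", "s1c1")   # three affected across generations
  k <- length(affected)
  ph <- stats::setNames(ifelse(pool %in% affected, "affected", "unaffected"),
                        pool)
  B <- 20000
  res <- run_fa_tests(fam, phenotypes = ph, tests = c("IF", "KS"),
                      B = B, seed = 11)

  # IF: null conditioned on >= 2 labels in the family (always true here)
  obs_if <- if_statistic(affected, K)
  exact_if <- enumerate_exact_p(K, pool, k, obs_if,
                                statistic_fun = function(s) if_statistic(s, K),
                                condition_fun = function(s) TRUE)
  mc_if <- res$IF$P_raw[1]
  se <- sqrt(exact_if * (1 - exact_if) / B)
  expect_lt(abs(mc_if - exact_if), 4 * se + 2 / B)

  # KS for individual "f": null conditioned on f being drawn affected
  obs_ks <- ks_statistic("f", affected, K)
  exact_ks <- enumerate_exact_p(
    K, pool, k, obs_ks,
    statistic_fun = function(s) sum(kinship_phi(K, "f", setdiff(s, "f"))),
    condition_fun = function(s) "f" %in% s)
  mc_ks <- res$KS$P_raw[res$KS$unit_id == "f"]
  effB <- res$KS$effective_B[res$KS$unit_id == "f"]
  se <- sqrt(exact_ks * (1 - exact_ks) / effB)
  expect_lt(abs(mc_ks - exact_ks), 4 * se + 2 / effB)
})

test_that("PB uses the pool prevalence by default and honors overrides", {
  ped <- trio_ped(phen = c("affected", "unaffected", "affected"))
  res <- run_fa_tests(ped, tests = "PB", B = 1, seed = 1)
  expect_equal(res$PB$P_raw, pb_test(3, 2, 2 / 3))
  res <- run_fa_tests(ped, tests = "PB", B = 1, seed = 1,
                      prevalence = 265 / 4373)
  expect_equal(res$PB$P_raw, pb_test(3, 2, 265 / 4373))
  expect_equal(attr(res, "config")$prevalence, 265 / 4373)
})
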