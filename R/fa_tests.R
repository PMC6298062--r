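# Familial aggregation tests: IF, KS, GR, GC (Monte-Carlo empirical nulls by
# resampling affected labels across the whole pedigree pool) and the exact
# binomial PB test; BH adjustment, family-level min-P summarization and
# tie-averaged ranking.

FA_TESTS <- c("IF", "KS", "GR", "GC", "PB")

#' Genealogical index of familiality statistic
#'
#' Mean kinship coefficient over all unordered pairs of affected individuals
#' of one family.
#'
#' @param affected character vector of affected ids (one family).
#' @param K a [kinship_matrix()].
#' @return The mean pairwise kinship, or `NA` if fewer than 2 affected.
#' @export
if_statistic <- function(affected, K) {
  affected <- unique(as.character(affected))
  if (length(affected) < 2) return(NA_real_)
  fam <- unique(K$family[affected])
  if (length(fam) != 1) stop("affected ids span multiple families")
  b <- kinship_block_of(K, fam, affected)
  sum(b[upper.tri(b)]) / choose(length(affected), 2)
}

#' Kinship sum statistic
#'
#' Sum of kinship coefficients between individual `i` and all other affected
#' members of its family.
#'
#' @param i an affected individual id.
#' @param affected character vector of affected ids.
#' @param K a [kinship_matrix()].
#' @return The kinship sum, or `NA` if no other family member is affected.
#' @export
ks_statistic <- function(i, affected, K) {
  i <- as.character(i)
  fam <- K$family[i]
  others <- setdiff(intersect(affected, names(K$family)[K$family == fam]), i)
  if (!length(others)) return(NA_real_)
  sum(kinship_phi(K, i, others))
}

#' Kinship group ratio statistic
#'
#' Number of affected members (including `i`) of i's kinship group, the set
#' of phenotyped relatives at least as close to i as i's most distant
#' affected relative (see [kinship_group()]).
#'
#' @inheritParams ks_statistic
#' @param phenotyped character vector of phenotyped ids (defaults to all).
#' @return Integer count, or `NA` when the group is undefined for `i`.
#' @export
gr_statistic <- function(i, affected, K, phenotyped = NULL) {
  grp <- tryCatch(kinship_group(K, i, affected, phenotyped),
                  pedagg_not_applicable = function(e) NULL)
  if (is.null(grp)) return(NA_integer_)
  length(intersect(grp, affected))
}

#' Kinship group closest relative statistic
#'
#' Kinship coefficient between `i` and the closest affected relative within
#' i's kinship group.
#'
#' @inheritParams gr_statistic
#' @return Numeric kinship, or `NA` when the group is undefined for `i`.
#' @export
gc_statistic <- function(i, affected, K, phenotyped = NULL) {
  grp <- tryCatch(kinship_group(K, i, affected, phenotyped),
                  pedagg_not_applicable = function(e) NULL)
  if (is.null(grp)) return(NA_real_)
  others <- setdiff(intersect(grp, affected), i)
  if (!length(others)) return(NA_real_)
  max(kinship_phi(K, i, others))
}

#' Exact binomial familial aggregation test
#'
#' Probability of observing by chance at least `k` affected among `n`
#' phenotyped family members when each is independently affected with
#' probability `R` (the trait prevalence): the exact upper tail
#' P(X >= k) for X ~ Binomial(n, R), with no normal approximation.
#'
#' @param n family phenotyped size (>= 1).
#' @param k observed affected count (0 <= k <= n); vectors are recycled.
#' @param R trait prevalence in (0, 1).
#' @return The upper-tail probability; exactly 1 when `k = 0`.
#' @examples
#' pb_test(20, 5, 265 / 4373)  # 5.88e-3
#' @export
pb_test <- function(n, k, R) {
  if (any(R <= 0 | R >= 1)) stop("prevalence R must lie in (0, 1)")
  if (any(n < 1)) stop("family size n must be >= 1")
  if (any(k < 0 | k > n)) stop("affected count k must satisfy 0 <= k <= n")
  stats::pbinom(k - 1, n, R, lower.tail = FALSE)
}

#' Resample affected labels for the empirical null
#'
#' Draws `B` independent samples, without replacement, of `n_affected` ids
#' from the pool of all phenotyped individuals across all families of the
#' pedigree. This is the shared resampling scheme from which every
#' Monte-Carlo test statistic's null distribution is derived.
#'
#' @param ped a [pedigree()] (the whole multi-family pool), or a character
#'   vector of phenotyped pool ids.
#' @param n_affected number of affected labels per replicate.
#' @param B number of replicates.
#' @param seed RNG seed.
#' @return Object of class `fa_null_draws`: an integer matrix with `B` rows
#'   (pool indices) carrying the pool ids as attribute `"pool"`. Use
#'   [null_draw_ids()] to materialize one replicate's id set.
#' @export
resample_null <- function(ped, n_affected, B, seed = 1) {
  pool <- if (inherits(ped, "pedigree")) phenotyped_ids(ped) else as.character(ped)
  N <- length(pool)
  if (n_affected > N)
    stop("n_affected (", n_affected, ") exceeds phenotyped pool size (", N, ")")
  if (B < 1) stop("B must be >= 1")
  draws <- with_seed(seed, {
    m <- matrix(0L, nrow = B, ncol = n_affected)
    for (b in seq_len(B)) m[b, ] <- sample.int(N, n_affected)
    m
  })
  structure(draws, pool = pool, class = "fa_null_draws")
}

#' @rdname resample_null
#' @param draws an `fa_null_draws` object.
#' @param b replicate index.
#' @export
null_draw_ids <- function(draws, b) attr(draws, "pool")[draws[b, ]]

#' Empirical (Monte-Carlo) P value
#'
#' Add-one upper-tail estimator: `(1 + #\{null >= observed\}) / (B + 1)`,
#' never zero, always in (0, 1]. Ties between the observed statistic and
#' null values count toward the tail (a small relative tolerance guards
#' against floating-point drift).
#'
#' @param observed observed statistic (finite scalar).
#' @param null_values numeric vector of null statistics (length >= 1).
#' @return The empirical P value.
#' @export
empirical_p <- function(observed, null_values) {
  if (!length(null_values)) stop("empty null distribution")
  if (!is.finite(observed)) stop("observed statistic must be finite")
  tol <- 1e-9 * (1 + abs(observed))
  (1 + sum(null_values >= observed - tol)) / (length(null_values) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjusted P values (restored to input order),
#' controlling the false discovery rate.
#'
#' @param p numeric vector of raw P values in (0, 1].
#' @return Adjusted P values, `P_adj >= P_raw`, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("P values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Tie-averaged ascending ranks
#'
#' Ranks a vector of raw P values ascending, replacing ties by the mean of
#' the tied positions (so two values sharing positions 6 and 7 both get
#' rank 6.5). Ranking is always performed on unadjusted P values, which
#' preserves order and avoids the tie clusters BH adjustment introduces.
#'
#' @param p numeric vector (finite).
#' @return Numeric vector of ranks (>= 1).
#' @export
rank_units <- function(p) {
  if (any(!is.finite(p))) stop("ranks require finite P values")
  rank(p, ties.method = "average")
}

#' Family-level summary of per-individual results
#'
#' For tests reporting one P value per affected individual (KS, GR, GC),
#' takes the lowest raw P value within each family. Families whose units are
#' all `NA` are excluded.
#'
#' @param results a per-unit result data frame (from [run_test()]) with
#'   columns `family_id`, `unit_id` and `P_raw`.
#' @return Data frame with columns `family_id`, `P_raw` (the family minimum)
#'   and `unit_id` (the minimizing unit, first by id on ties).
#' @export
family_min_p <- function(results) {
  ok <- results[results$status == "ok" & is.finite(results$P_raw), , drop = FALSE]
  if (!nrow(ok))
    return(data.frame(family_id = character(0), P_raw = numeric(0),
                      unit_id = character(0), stringsAsFactors = FALSE))
  ok <- ok[order(ok$family_id, ok$P_raw, ok$unit_id), , drop = FALSE]
  first <- !duplicated(ok$family_id)
  data.frame(family_id = ok$family_id[first], P_raw = ok$P_raw[first],
             unit_id = ok$unit_id[first], stringsAsFactors = FALSE)
}

#' Run familial aggregation tests
#'
#' Computes the observed statistic for every testable unit (families for IF
#' and PB; affected individuals for KS, GR and GC), builds the Monte-Carlo
#' empirical null for the kinship-based tests by resampling the observed
#' number of affected labels from the whole phenotyped pool
#' ([resample_null()]), scores each unit against its own conditional null,
#' applies BH adjustment across the testable units of each test, and attaches
#' tie-averaged ranks on raw P values.
#'
#' Conditional nulls: a per-individual unit i is scored against the
#' replicates in which i itself was drawn affected (and, for GR/GC, in which
#' i's kinship group is defined); an IF family against the replicates with
#' at least two draws in that family. The number of qualifying replicates is
#' reported as `effective_B`; a unit with `effective_B = 0` receives
#' `P_raw = 1`.
#'
#' @param ped a [pedigree()] (multi-family pool).
#' @param phenotypes optional named character vector (`"affected"`,
#'   `"unaffected"`, `"unphenotyped"`) overriding `ped$phenotype`.
#' @param tests subset of `c("IF", "KS", "GR", "GC", "PB")`.
#' @param B number of null replicates (default 50000).
#' @param seed RNG seed for the resampling stream.
#' @param fdr_level nominal FDR for the significance flag (default 0.05).
#' @param prevalence PB prevalence override; default is the pool's
#'   affected / phenotyped ratio.
#' @param kinship optional precomputed [kinship_matrix()] for `ped`.
#' @return Named list of per-test data frames with columns `unit_id`,
#'   `unit_type`, `family_id`, `statistic`, `effective_B`, `P_raw`, `P_adj`,
#'   `significant`, `rank`, `status`.
#' @export
run_fa_tests <- function(ped, phenotypes = NULL, tests = FA_TESTS,
                         B = 50000, seed = 1, fdr_level = 0.05,
                         prevalence = NULL, kinship = NULL) {
  tests <- match.arg(tests, FA_TESTS, several.ok = TRUE)
  if (B < 1) stop("B must be >= 1")
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must lie in (0, 1)")
  if (!is.null(phenotypes)) {
    if (is.null(names(phenotypes))) stop("phenotypes must be a named vector")
    if (!all(phenotypes %in% PHENO_LEVELS)) stop("invalid phenotype values")
    ped$phenotype[match(names(phenotypes), ped$id)] <- unname(phenotypes)
  }
  phen <- phenotyped_ids(ped)
  aff <- affected_ids(ped)
  if (!length(phen)) stop("no phenotyped individuals")
  K <- kinship %||% kinship_matrix(ped)
  R <- prevalence %||% (length(aff) / length(phen))

  fam_of <- stats::setNames(ped$family, ped$id)
  families <- unique(ped$family)
  mc_tests <- intersect(tests, c("IF", "KS", "GR", "GC"))
  out <- list()

  if (length(mc_tests) && length(aff) >= 1) {
    eng <- mc_null_engine(ped, K, phen, aff, fam_of, B, seed, mc_tests)
    for (tt in mc_tests) out[[tt]] <- eng[[tt]]
  } else {
    for (tt in mc_tests) {
      out[[tt]] <- empty_unit_result()
    }
  }

  if ("PB" %in% tests) {
    n_phen <- as.integer(table(fam_of[phen])[families])
    n_phen[is.na(n_phen)] <- 0L
    k_aff <- as.integer(table(factor(fam_of[aff], levels = families)))
    ok <- n_phen >= 1
    p_raw <- rep(NA_real_, length(families))
    p_raw[ok] <- pb_test(n_phen[ok], k_aff[ok], R)
    out$PB <- data.frame(
      unit_id = families, unit_type = "family", family_id = families,
      statistic = as.numeric(k_aff), effective_B = NA_integer_,
      P_raw = p_raw, stringsAsFactors = FALSE)
    out$PB$status <- ifelse(ok, "ok", "not_applicable")
  }

  out <- lapply(out[tests], finalize_results, fdr_level = fdr_level)
  attr(out, "config") <- list(tests = tests, B = B, seed = seed,
                              fdr_level = fdr_level, prevalence = R)
  out
}

#' @rdname run_fa_tests
#' @param test_id a single test id.
#' @param ... passed on to [run_fa_tests()].
#' @export
run_test <- function(test_id, ped, ...) {
  test_id <- match.arg(test_id, FA_TESTS)
  run_fa_tests(ped, tests = test_id, ...)[[test_id]]
}

empty_unit_result <- function() {
  data.frame(unit_id = character(0), unit_type = character(0),
             family_id = character(0), statistic = numeric(0),
             effective_B = integer(0), P_raw = numeric(0),
             status = character(0), stringsAsFactors = FALSE)
}

# BH adjustment, significance flag and tie-averaged ranks over testable units
finalize_results <- function(df, fdr_level) {
  df$P_adj <- NA_real_
  df$significant <- NA
  df$rank <- NA_real_
  ok <- df$status == "ok" & is.finite(df$P_raw)
  if (any(ok)) {
    df$P_adj[ok] <- bh_adjust(df$P_raw[ok])
    df$significant[ok] <- df$P_adj[ok] <= fdr_level
    df$rank[ok] <- rank_units(df$P_raw[ok])
  }
  df[c("unit_id", "unit_type", "family_id", "statistic", "effective_B",
       "P_raw", "P_adj", "significant", "rank", "status")]
}

# Vectorized Monte-Carlo engine for the IF/KS/GR/GC nulls. One shared
# resampling stream serves all requested tests. Per family the flattened
# draws (local row, replicate column) drive rowsum-based accumulation of
# per-unit kinship sums (KS) and positive-kinship relative counts (GR);
# per-replicate sampled-member lists drive the IF pair sums and GC maxima.
mc_null_engine <- function(ped, K, phen, aff, fam_of, B, seed, mc_tests) {
  N <- length(phen)
  n_aff <- length(aff)
  draws <- resample_null(phen, n_aff, B, seed)
  pool_fam <- fam_of[phen]
  fam_levels <- unique(pool_fam)
  fam_int <- match(pool_fam, fam_levels)
  local_pos <- stats::ave(seq_len(N), fam_int, FUN = seq_along)
  # flatten the draw matrix: entry (b, k) -> pool index draws[b, k]
  all_idx <- as.integer(draws)
  all_b <- rep.int(seq_len(B), ncol(draws))
  sel_by_fam <- split(seq_along(all_idx), fam_int[all_idx])
  acc <- lapply(mc_tests, function(tt) collector())
  names(acc) <- mc_tests
  tol <- function(x) 1e-9 * (1 + abs(x))
  need_gc <- "GC" %in% mc_tests
  need_grc <- any(c("GR", "GC") %in% mc_tests)
  need_if_any <- "IF" %in% mc_tests
  need_ks <- "KS" %in% mc_tests

  for (fi in seq_along(fam_levels)) {
    fam <- fam_levels[fi]
    rows <- which(fam_int == fi)
    ids <- phen[rows]
    n_f <- length(ids)
    aff_f <- intersect(aff, ids)
    need_if <- need_if_any && length(aff_f) >= 2
    need_ind <- (need_ks || need_grc) && length(aff_f) >= 1
    if (need_if_any && !need_if)
      collect(acc$IF, fam, "family", fam, NA_real_, NA_integer_, NA_real_,
              "not_applicable")
    if (!need_if && !need_ind) next
    Kf <- kinship_block_of(K, fam, ids)
    sel <- sel_by_fam[[as.character(fi)]]
    lr <- local_pos[all_idx[sel]]   # local sampled rows
    cb <- all_b[sel]                # their replicate columns
    samp_cols <- if (need_if || need_gc)
      split(lr, factor(cb, levels = seq_len(B))) else NULL
    cols_of_row <- split(cb, lr)    # replicates containing each local row

    if (need_if) {
      kcount <- tabulate(cb, nbins = B)
      valid <- which(kcount >= 2)
      diagK <- diag(Kf)
      if (length(lr) * n_f <= 2e6) {
        # vectorized quadratic form: per replicate b with sampled rows m_b,
        # q_b = sum(Kf[m_b, m_b]) via two rowsum passes
        S <- rowsum(Kf[lr, , drop = FALSE], cb)      # row sums per replicate
        ridx <- match(cb, as.integer(rownames(S)))
        q <- rowsum(S[cbind(ridx, lr)], cb)
        d <- rowsum(diagK[lr], cb)
        reps_present <- as.integer(rownames(q))
        pairsum <- stats::setNames((q[, 1] - d[, 1]) / 2,
                                   as.character(reps_present))
        nullv <- pairsum[as.character(valid)] /
          choose(kcount[valid], 2)
      } else {
        nullv <- vapply(valid, function(b) {
          m <- samp_cols[[b]]
          (sum(Kf[m, m]) - sum(diagK[m])) / 2 / choose(length(m), 2)
        }, numeric(1))
      }
      bb <- Kf[match(aff_f, ids), match(aff_f, ids), drop = FALSE]
      obs <- sum(bb[upper.tri(bb)]) / choose(length(aff_f), 2)
      effB <- length(valid)
      p <- if (effB) (1 + sum(nullv >= obs - tol(obs))) / (effB + 1) else 1
      collect(acc$IF, fam, "family", fam, obs, as.integer(effB), p, "ok")
    }

    if (need_ind) {
      u_rows <- match(aff_f, ids)
      nu <- length(u_rows)
      kc <- if (need_ks) tabulate(cb, nbins = B) else NULL
      # null kinship sums / relative counts per (replicate, unit) via rowsum
      Tu_t <- Cu_t <- NULL
      if (need_ks) {
        KuT <- t(Kf[u_rows, , drop = FALSE])       # n_f x nu
        rs <- rowsum(KuT[lr, , drop = FALSE], cb)  # per-replicate sums
        Tu_t <- matrix(0, B, nu)
        Tu_t[as.integer(rownames(rs)), ] <- rs
      }
      if (need_grc) {
        AdjT <- Kf[u_rows, , drop = FALSE] > 0
        AdjT[cbind(seq_len(nu), u_rows)] <- FALSE
        AdjT <- t(AdjT) + 0
        rs <- rowsum(AdjT[lr, , drop = FALSE], cb)
        Cu_t <- matrix(0, B, nu)
        Cu_t[as.integer(rownames(rs)), ] <- rs
      }
      for (ui in seq_len(nu)) {
        i <- aff_f[ui]
        r <- u_rows[ui]
        reps_i <- cols_of_row[[as.character(r)]]
        if (is.null(reps_i)) reps_i <- integer(0)
        others_obs <- u_rows[-ui]
        phi_obs <- Kf[r, others_obs]

        if (need_ks) {
          if (length(others_obs)) {
            # condition on the unit's own precondition: i drawn affected AND
            # at least one other family member drawn (mirrors the >= 2
            # affected conditioning of the family-level IF null)
            reps_ks <- reps_i[kc[reps_i] >= 2]
            nullv <- Tu_t[reps_ks, ui] - Kf[r, r]
            obs <- sum(phi_obs)
            effB <- length(reps_ks)
            p <- if (effB) (1 + sum(nullv >= obs - tol(obs))) / (effB + 1) else 1
            collect(acc$KS, i, "individual", fam, obs, effB, p, "ok")
          } else {
            collect(acc$KS, i, "individual", fam, NA_real_, NA_integer_,
                    NA_real_, "not_applicable")
          }
        }

        if (need_grc) {
          rel_obs <- sum(phi_obs > 0)
          reps_g <- if (rel_obs >= 1) {
            cc <- Cu_t[reps_i, ui]
            reps_i[cc >= 1]
          } else integer(0)
          if ("GR" %in% mc_tests) {
            if (rel_obs >= 1) {
              nullv <- Cu_t[reps_g, ui] + 1
              obs <- rel_obs + 1
              effB <- length(reps_g)
              p <- if (effB) (1 + sum(nullv >= obs - tol(obs))) / (effB + 1) else 1
              collect(acc$GR, i, "individual", fam, obs, effB, p, "ok")
            } else {
              collect(acc$GR, i, "individual", fam, NA_real_, NA_integer_,
                      NA_real_, "not_applicable")
            }
          }
          if (need_gc) {
            if (rel_obs >= 1) {
              krow <- Kf[r, ]
              nullv <- vapply(reps_g, function(b) {
                m <- samp_cols[[b]]
                max(krow[m[m != r]])
              }, numeric(1))
              obs <- max(phi_obs)
              effB <- length(reps_g)
              p <- if (effB) (1 + sum(nullv >= obs - tol(obs))) / (effB + 1) else 1
              collect(acc$GC, i, "individual", fam, obs, effB, p, "ok")
            } else {
              collect(acc$GC, i, "individual", fam, NA_real_, NA_integer_,
                      NA_real_, "not_applicable")
            }
          }
        }
      }
    }
  }

  lapply(acc, collector_df)
}

# growing-vector accumulator for unit results (avoids per-unit data frames)
collector <- function() {
  e <- new.env(parent = emptyenv())
  e$unit_id <- character(0); e$unit_type <- character(0)
  e$family_id <- character(0); e$statistic <- numeric(0)
  e$effective_B <- integer(0); e$P_raw <- numeric(0); e$status <- character(0)
  e
}

collect <- function(e, unit_id, unit_type, family_id, statistic, effective_B,
                    P_raw, status) {
  k <- length(e$unit_id) + 1L
  e$unit_id[k] <- unit_id; e$unit_type[k] <- unit_type
  e$family_id[k] <- family_id; e$statistic[k] <- statistic
  e$effective_B[k] <- effective_B; e$P_raw[k] <- P_raw; e$status[k] <- status
}

collector_df <- function(e) {
  if (!length(e$unit_id)) return(empty_unit_result())
  data.frame(unit_id = e$unit_id, unit_type = e$unit_type,
             family_id = e$family_id, statistic = e$statistic,
             effective_B = e$effective_B, P_raw = e$P_raw, status = e$status,
             stringsAsFactors = FALSE)
}

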