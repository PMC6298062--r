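# Benchmark evaluation: confusion counts, precision/recall curves,
# case-family rank summaries and top-rank overlap tables over simulated
# family sets.

#' Binary classification at a P value threshold
#'
#' @param p numeric vector of P values pooled over family sets.
#' @param is_case logical vector marking the case units.
#' @param t threshold: units with `p <= t` are called positive.
#' @return A `confusion_counts` object (named integer vector `TP`, `FP`,
#'   `FN`, `TN` with attribute `threshold`).
#' @export
classify_at_threshold <- function(p, is_case, t) {
  if (length(p) != length(is_case)) stop("p and is_case lengths differ")
  pos <- p <= t
  structure(c(TP = sum(pos & is_case), FP = sum(pos & !is_case),
              FN = sum(!pos & is_case), TN = sum(!pos & !is_case)),
            threshold = t, class = "confusion_counts")
}

#' Precision and recall from confusion counts
#'
#' precision = TP / (TP + FP) (`NA` when no positives are called) and
#' recall = TP / (TP + FN).
#'
#' @param cc a `confusion_counts` object (or named vector with `TP`, `FP`,
#'   `FN`).
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(cc) {
  tp <- cc[["TP"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Precision/recall step curve
#'
#' Computes (threshold, recall, precision) at every distinct observed P
#' value (no interpolation, which would be optimistic in PR space), and
#' marks the operating point whose threshold is nearest to `mark` (default
#' 0.05, the customary FDR cutoff).
#'
#' @param p pooled P values (cases and controls).
#' @param is_case logical case indicator.
#' @param mark threshold to flag as the operating point.
#' @return Data frame `threshold`, `recall`, `precision`, `operating`
#'   (logical); recall is non-decreasing in threshold.
#' @export
pr_curve <- function(p, is_case, mark = 0.05) {
  if (length(p) != length(is_case)) stop("p and is_case lengths differ")
  ord <- order(p)
  p_s <- p[ord]; case_s <- is_case[ord]
  keep <- !duplicated(p_s, fromLast = TRUE)  # last index of each distinct P
  cum_tp <- cumsum(case_s)[keep]
  cum_pos <- seq_along(p_s)[keep]
  n_case <- sum(is_case)
  out <- data.frame(threshold = p_s[keep],
                    recall = cum_tp / n_case,
                    precision = cum_tp / cum_pos)
  out$operating <- FALSE
  if (nrow(out)) {
    # operating point: largest threshold still <= mark (none above the cutoff
    # is called positive); fallback to the closest threshold
    le <- which(out$threshold <= mark)
    out$operating[if (length(le)) max(le) else
      which.min(abs(out$threshold - mark))] <- TRUE
  }
  out
}

#' Tie-averaged rank of the case family within one family set
#'
#' @param p named numeric vector of per-family P values (raw) for one family
#'   set; `NA` entries (untestable families) are ranked last.
#' @param case_family the case family's name.
#' @return The case family's tie-averaged ascending rank.
#' @export
rank_case <- function(p, case_family) {
  if (!(case_family %in% names(p))) stop("case family absent from P vector")
  p_filled <- ifelse(is.na(p), Inf, p)
  r <- rank(p_filled, ties.method = "average")
  unname(r[case_family])
}

#' Bin case-family ranks into a rank summary
#'
#' Partitions the family sets into: significant hit in the top three;
#' in the top three but insignificant; rank between four and ten; rank above
#' ten. Also records the number of top-ranked cases (`top_rank_total`) and
#' of top-ranked significant cases (`top_rank_significant`). A case is
#' "top-ranked" when its raw P equals the set's minimum (ties included).
#'
#' @param ranks numeric vector of case ranks (one per family set).
#' @param significant logical vector of case significance flags.
#' @param top_ranked logical vector: case shares the set's best raw P.
#' @return A `rank_summary` object (named list of counts).
#' @export
bin_ranks <- function(ranks, significant, top_ranked = ranks <= 1.5) {
  stopifnot(length(ranks) == length(significant),
            length(ranks) == length(top_ranked))
  top3 <- ranks <= 3
  structure(list(
    significant_top3 = sum(top3 & significant),
    insignificant_top3 = sum(top3 & !significant),
    rank4to10 = sum(ranks > 3 & ranks <= 10),
    above10 = sum(ranks > 10),
    top_rank_total = sum(top_ranked),
    top_rank_significant = sum(top_ranked & significant),
    n_sets = length(ranks)), class = "rank_summary")
}

#' Overlap table of top-ranked case families across tests
#'
#' Partitions the family sets by the exact subset of tests that placed the
#' set's case family on the top rank (the UpSet-plot partition).
#'
#' @param top_sets named list (one element per test) of family-set ids whose
#'   case was top-ranked by that test.
#' @param all_sets character vector of all family-set ids.
#' @return Data frame `subset` (test ids joined by `+`, `"none"` for sets no
#'   test top-ranked) and `count`; counts sum to `length(all_sets)`.
#' @export
overlap_sets <- function(top_sets, all_sets) {
  membership <- vapply(top_sets, function(s) all_sets %in% s,
                       logical(length(all_sets)))
  if (length(all_sets) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, names(top_sets)))
  key <- apply(membership, 1, function(m)
    if (any(m)) paste(names(top_sets)[m], collapse = "+") else "none")
  tab <- table(key)
  out <- data.frame(subset = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$subset), , drop = FALSE]
}

#' Run the case-family detection benchmark
#'
#' For each scenario, builds all family sets ([build_family_sets()]), runs
#' the requested aggregation tests on every set, summarizes per-individual
#' tests to family level by minimum raw P, adjusts family-level P values by
#' BH within each set, and pools results into rank summaries, top-rank
#' overlap tables, confusion counts at `P_adj <= fdr_level` and
#' precision/recall curves. With `n` families, each scenario pools `n` cases
#' and `n * (n - 1)` control instances.
#'
#' Untestable families (e.g. fewer than two affected for IF) enter the
#' pooled classification with P = 1 and are ranked last.
#'
#' @param ped a filtered multi-family [pedigree()].
#' @param scenarios a list of [scenario()] objects (or a single one).
#' @param tests subset of `c("IF", "KS", "GR", "GC", "PB")`.
#' @param B Monte-Carlo replicates per test run.
#' @param seed master seed; per-set substreams derive from it.
#' @param fdr_level significance cutoff on within-set adjusted P (default
#'   0.05).
#' @param classify_on `"P_adj"` (default) or `"P_raw"` for the pooled
#'   classification.
#' @return A list of per-scenario results, each with elements `scenario`,
#'   `n_cases`, `n_controls`, and per-test `rank_summary`, `overlap`,
#'   `confusion`, `pr` and `case_ranks`.
#' @export
run_assessment <- function(ped, scenarios, tests = FA_TESTS, B = 200,
                           seed = 1, fdr_level = 0.05,
                           classify_on = c("P_adj", "P_raw")) {
  classify_on <- match.arg(classify_on)
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  tests <- match.arg(tests, FA_TESTS, several.ok = TRUE)
  K <- kinship_matrix(ped)
  fam_names <- names(split_families(ped))
  n_fam <- length(fam_names)
  out <- vector("list", length(scenarios))
  for (sc_i in seq_along(scenarios)) {
    scen <- scenarios[[sc_i]]
    sets <- build_family_sets(ped, scen, seed = substream_seed(seed, sc_i))
    per_test <- lapply(tests, function(tt) list(
      ranks = numeric(0), signif = logical(0), top = logical(0),
      pooled_p = numeric(0), pooled_case = logical(0)))
    names(per_test) <- tests
    for (a in seq_along(sets)) {
      fs <- sets[[a]]
      res <- run_fa_tests(ped, phenotypes = assignment_phenotypes(fs$assignment),
                          tests = tests, B = B,
                          seed = substream_seed(seed, sc_i, a, 1),
                          fdr_level = fdr_level, prevalence = scen$R,
                          kinship = K)
      for (tt in tests) {
        famp <- family_level_p(res[[tt]], tt, fam_names)
        p_fill <- ifelse(is.na(famp), 1, famp)
        p_adj <- bh_adjust(p_fill)
        r <- rank_case(stats::setNames(famp, fam_names), fs$case_family)
        case_i <- match(fs$case_family, fam_names)
        sig <- p_adj[case_i] <= fdr_level
        top <- p_fill[case_i] <= min(p_fill) + 1e-12
        pool_p <- if (classify_on == "P_adj") p_adj else p_fill
        pt <- per_test[[tt]]
        pt$ranks <- c(pt$ranks, r)
        pt$signif <- c(pt$signif, sig)
        pt$top <- c(pt$top, top)
        pt$pooled_p <- c(pt$pooled_p, pool_p)
        pt$pooled_case <- c(pt$pooled_case, seq_len(n_fam) == case_i)
        per_test[[tt]] <- pt
      }
    }
    scen_res <- list(scenario = scen,
                     n_cases = length(sets),
                     n_controls = length(sets) * (n_fam - 1L))
    top_sets <- lapply(per_test, function(pt) names(sets)[pt$top])
    scen_res$overlap <- overlap_sets(top_sets, names(sets))
    for (tt in tests) {
      pt <- per_test[[tt]]
      scen_res[[tt]] <- list(
        rank_summary = bin_ranks(pt$ranks, pt$signif, pt$top),
        confusion = classify_at_threshold(pt$pooled_p, pt$pooled_case,
                                          fdr_level),
        pr = pr_curve(pt$pooled_p, pt$pooled_case, mark = fdr_level),
        case_ranks = pt$ranks,
        case_significant = pt$signif)
    }
    out[[sc_i]] <- scen_res
  }
  names(out) <- vapply(scenarios, function(s)
    sprintf("Q%g_R%g_G%s", s$Q, s$R, as.character(s$G)), character(1))
  out
}

# family-level raw P for one test: direct for IF/PB, min-P for KS/GR/GC;
# NA for families without a testable unit
family_level_p <- function(df, test, fam_names) {
  p <- rep(NA_real_, length(fam_names))
  if (test %in% c("IF", "PB")) {
    ok <- df[df$status == "ok" & is.finite(df$P_raw), , drop = FALSE]
    p[match(ok$family_id, fam_names)] <- ok$P_raw
  } else {
    fm <- family_min_p(df)
    p[match(fm$family_id, fam_names)] <- fm$P_raw
  }
  p
}
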