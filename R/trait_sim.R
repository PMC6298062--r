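# Mendelian trait simulation: autosomal-dominant gene dropping, penetrance
# masking, generation (sub-branch) masking, prevalence-matched Bernoulli
# controls, and construction of case/control family sets.

#' Simulation scenario
#'
#' One cell of the benchmark parameter grid: penetrance `Q` (fraction of
#' carriers expressing the trait), prevalence `R` (proportion of affected
#' among phenotyped individuals, driving the control background) and the
#' number of affected generations `G` (2, 3 or `"all"`).
#'
#' The canonical grid pairs each prevalence with specific penetrances and
#' generation counts; combinations outside it are allowed with a warning
#' when `strict = FALSE`.
#'
#' @param Q penetrance in (0, 1].
#' @param R prevalence in (0, 1).
#' @param G `2`, `3`, or `"all"`.
#' @param strict error (TRUE) or warn (FALSE, default) on combinations
#'   outside the canonical grid.
#' @return A `scenario` object (named list).
#' @export
scenario <- function(Q, R, G = "all", strict = FALSE) {
  if (Q <= 0 || Q > 1) stop("penetrance Q must lie in (0, 1]")
  if (R <= 0 || R >= 1) stop("prevalence R must lie in (0, 1)")
  G <- if (identical(G, "all")) "all" else as.integer(G)
  if (!identical(G, "all") && !(G %in% c(2L, 3L)))
    stop("G must be 2, 3 or \"all\"")
  if (!in_scenario_grid(Q, R, G)) {
    msg <- sprintf("scenario (Q=%g, R=%g, G=%s) is outside the canonical grid",
                   Q, R, as.character(G))
    if (strict) stop(msg) else warning(msg)
  }
  structure(list(Q = Q, R = R, G = G), class = "scenario")
}

# canonical penetrance/prevalence/generation grid
in_scenario_grid <- function(Q, R, G) {
  eq <- function(a, b) abs(a - b) < 1e-9
  g23a <- list(2L, 3L, "all")
  cells <- list(
    list(R = 1 / 10, Q = c(1, 0.6), G = list(3L, "all")),
    list(R = 1 / 16, Q = c(1, 0.6), G = list(3L, "all")),
    list(R = 1 / 25, Q = c(1, 0.6, 0.3), G = g23a),
    list(R = 1 / 50, Q = c(1, 0.6, 0.3), G = g23a),
    list(R = 1 / 80, Q = c(1, 0.6), G = g23a)
  )
  for (cell in cells) {
    if (eq(R, cell$R) && any(vapply(cell$Q, eq, logical(1), a = Q)) &&
        any(vapply(cell$G, identical, logical(1), y = G)))
      return(TRUE)
  }
  FALSE
}

#' The canonical scenario grid
#'
#' All penetrance/prevalence/generation combinations of the benchmark design.
#'
#' @return A data frame with columns `Q`, `R`, `G` (`G` as character).
#' @export
scenario_grid <- function() {
  rows <- list()
  add <- function(R, Qs, Gs) for (q in Qs) for (g in Gs)
    rows[[length(rows) + 1L]] <<- data.frame(Q = q, R = R, G = as.character(g),
                                             stringsAsFactors = FALSE)
  add(1 / 10, c(1, 0.6), c("3", "all"))
  add(1 / 16, c(1, 0.6), c("3", "all"))
  add(1 / 25, c(1, 0.6, 0.3), c("2", "3", "all"))
  add(1 / 50, c(1, 0.6, 0.3), c("2", "3", "all"))
  add(1 / 80, c(1, 0.6), c("2", "3", "all"))
  do.call(rbind, rows)
}

new_assignment <- function(ids, affected, provenance) {
  data.frame(id = as.character(ids), affected = as.logical(affected),
             provenance = as.character(provenance), stringsAsFactors = FALSE)
}

#' Gene-drop an autosomal-dominant trait through one family
#'
#' Seeds one heterozygous carrier founder (chosen uniformly among founders
#' with at least one child; fallback: any founder) and transmits the allele
#' in topological order: a child of exactly one carrier parent inherits it
#' with probability 1/2, a child of two carrier parents with probability 3/4.
#' Under full penetrance and no phenocopies, carriers are affected and
#' non-carriers unaffected.
#'
#' @param family a single-family [pedigree()].
#' @param seed RNG seed.
#' @param seed_carrier set `FALSE` for the diagnostic no-mutation mode (no
#'   carrier, hence zero affected).
#' @return List with `assignment` (a data frame `id`, `affected`,
#'   `provenance`, restricted to phenotyped members), `carriers` (carrier
#'   ids, phenotyped or not) and `founder` (the seeded founder id or `NA`).
#' @export
gene_drop_dominant <- function(family, seed = 1, seed_carrier = TRUE) {
  if (!nrow(family)) stop("empty family")
  comp <- complete_parents(family)
  fam <- comp$ped
  ord <- topo_order(fam)
  idx <- stats::setNames(seq_len(nrow(fam)), fam$id)
  fa <- idx[fam$father]; mo <- idx[fam$mother]
  founders <- fam$id[is.na(fa)]
  real_founders <- setdiff(founders, comp$added)
  if (!length(real_founders)) real_founders <- founders
  with_seed(seed, {
    carrier <- rep(FALSE, nrow(fam))
    founder_id <- NA_character_
    if (seed_carrier) {
      has_child <- real_founders[real_founders %in% c(fam$father, fam$mother)]
      cand <- if (length(has_child)) has_child else real_founders
      founder_id <- cand[sample.int(length(cand), 1)]
      carrier[idx[founder_id]] <- TRUE
    }
    for (i in ord) {
      if (is.na(fa[i])) next
      ncar <- carrier[fa[i]] + carrier[mo[i]]
      if (ncar == 1) carrier[i] <- stats::runif(1) < 0.5
      else if (ncar == 2) carrier[i] <- stats::runif(1) < 0.75
    }
    phen <- fam$id %in% phenotyped_ids(family)
    list(assignment = new_assignment(fam$id[phen], carrier[phen], "mendelian"),
         carriers = fam$id[carrier], founder = founder_id)
  })
}

#' Apply incomplete penetrance to a Mendelian assignment
#'
#' Turns exactly `round_half_up((1 - Q) * A)` of the `A` affected
#' individuals to unaffected, chosen uniformly without replacement.
#'
#' @param assignment a phenotype assignment data frame (`id`, `affected`,
#'   `provenance`).
#' @param Q penetrance in (0, 1].
#' @param seed RNG seed.
#' @return The updated assignment; masked individuals carry provenance
#'   `"penetrance-masked"`.
#' @export
apply_penetrance <- function(assignment, Q, seed = 1) {
  if (Q <= 0 || Q > 1) stop("penetrance Q must lie in (0, 1]")
  if (Q == 1) return(assignment)
  aff_rows <- which(assignment$affected)
  n_mask <- round_half_up((1 - Q) * length(aff_rows))
  if (n_mask == 0) return(assignment)
  with_seed(seed, {
    masked <- aff_rows[sample.int(length(aff_rows), n_mask)]
    assignment$affected[masked] <- FALSE
    assignment$provenance[masked] <- "penetrance-masked"
    assignment
  })
}

#' Restrict a Mendelian assignment to a G-generation sub-branch
#'
#' Keeps the simulated disease status inside the sub-branch anchored at the
#' seeded carrier founder — the founder, its spouses, and all descendants
#' (plus their spouses) whose generation index lies within
#' `[g0, g0 + G - 1]`, where `g0` is the founder's generation — and
#' reassigns every phenotyped member outside the branch by an independent
#' Bernoulli(`R`) draw. `G = "all"` is the identity.
#'
#' @param family a single-family [pedigree()].
#' @param assignment phenotype assignment from the gene-drop/penetrance steps.
#' @param G `2`, `3` or `"all"`.
#' @param R prevalence for the reassigned background.
#' @param generations generation map from [assign_generations()] (computed
#'   when `NULL`).
#' @param founder the seeded carrier founder id.
#' @param seed RNG seed.
#' @return The updated assignment; reassigned members carry provenance
#'   `"generation-cleared"`.
#' @export
mask_generations <- function(family, assignment, G, R, generations = NULL,
                             founder = NULL, seed = 1) {
  if (identical(G, "all")) return(assignment)
  G <- as.integer(G)
  if (is.null(founder)) stop("generation masking requires the seeded founder id")
  gen <- generations %||% assign_generations(family)$generation
  depth <- max(gen) - gen[[founder]] + 1L
  if (G > depth)
    stop("G = ", G, " exceeds the ", depth,
         " generations below the seeded founder")
  idx <- stats::setNames(seq_len(nrow(family)), family$id)
  # descendants of the seeded founder
  desc <- rep(FALSE, nrow(family))
  desc[idx[[founder]]] <- TRUE
  for (i in topo_order(family)) {
    f <- family$father[i]; m <- family$mother[i]
    if ((!is.na(f) && desc[idx[[f]]]) || (!is.na(m) && desc[idx[[m]]]))
      desc[i] <- TRUE
  }
  # spouses of branch members (share a child)
  spouse <- rep(FALSE, nrow(family))
  for (i in seq_len(nrow(family))) {
    f <- family$father[i]; m <- family$mother[i]
    if (is.na(f) || is.na(m)) next
    if (desc[idx[[f]]] && !desc[idx[[m]]]) spouse[idx[[m]]] <- TRUE
    if (desc[idx[[m]]] && !desc[idx[[f]]]) spouse[idx[[f]]] <- TRUE
  }
  g0 <- gen[[founder]]
  window <- gen[family$id] >= g0 & gen[family$id] <= g0 + G - 1L
  branch <- family$id[(desc | spouse) & window]
  outside <- setdiff(assignment$id, branch)
  if (length(outside)) {
    rows <- match(outside, assignment$id)
    assignment$affected[rows] <- with_seed(seed, stats::runif(length(rows)) < R)
    assignment$provenance[rows] <- "generation-cleared"
  }
  assignment
}

#' Generate a prevalence-matched control phenotype assignment
#'
#' Every phenotyped member of the family is independently affected with
#' probability `R` (Bernoulli trial).
#'
#' @param family a single-family [pedigree()].
#' @param R prevalence in (0, 1).
#' @param seed RNG seed.
#' @return A phenotype assignment with provenance `"bernoulli"`.
#' @export
generate_controls <- function(family, R, seed = 1) {
  if (R <= 0 || R >= 1) stop("prevalence R must lie in (0, 1)")
  ids <- phenotyped_ids(family)
  with_seed(seed, new_assignment(ids, stats::runif(length(ids)) < R, "bernoulli"))
}

#' Build case/control family sets
#'
#' For each family `a` of the pedigree, builds the family set `F_a`: family
#' `a` carries a simulated Mendelian case phenotype (gene drop, then
#' penetrance masking, then generation masking) and every other family an
#' independently drawn Bernoulli(`R`) control phenotype. A case pipeline
#' ending with fewer than 2 affected is redrawn with a fresh substream (the
#' redraw count is recorded).
#'
#' @param ped a filtered multi-family [pedigree()].
#' @param scen a [scenario()].
#' @param seed master seed; all substreams derive from it via
#'   [substream_seed()], so sets are reproducible and order-independent.
#' @param max_redraws cap on case redraws per family (default 100); if no
#'   draw reaches 2 affected (possible for very small families under
#'   penetrance masking), the draw with the most affected is kept and the
#'   family is untestable for tests requiring two affected.
#' @return A list of `family_set` objects, one per family, each with
#'   elements `case_family`, `assignment` (phenotype assignment over all
#'   phenotyped individuals of the pedigree), `scenario` and `redraws`.
#' @export
build_family_sets <- function(ped, scen, seed = 1, max_redraws = 100) {
  stopifnot(inherits(scen, "scenario"))
  fams <- split_families(ped)
  gens <- lapply(fams, function(f) assign_generations(f)$generation)
  phen_by_fam <- lapply(fams, phenotyped_ids)
  sets <- vector("list", length(fams))
  for (a in seq_along(fams)) {
    case <- simulate_case(fams[[a]], scen, gens[[a]],
                          seed_base = substream_seed(seed, a, 0),
                          max_redraws = max_redraws)
    # control draws, one Bernoulli(R) block per family, each on its own
    # substream (same stream as generate_controls would use)
    others <- setdiff(seq_along(fams), a)
    ctrl_ids <- unlist(phen_by_fam[others], use.names = FALSE)
    ctrl_aff <- logical(length(ctrl_ids))
    pos <- 0L
    for (b in others) {
      n_b <- length(phen_by_fam[[b]])
      if (n_b)
        ctrl_aff[pos + seq_len(n_b)] <-
          with_seed(substream_seed(seed, a, b), stats::runif(n_b) < scen$R)
      pos <- pos + n_b
    }
    assignment <- data.frame(
      id = c(case$assignment$id, ctrl_ids),
      affected = c(case$assignment$affected, ctrl_aff),
      provenance = c(case$assignment$provenance,
                     rep("bernoulli", length(ctrl_ids))),
      stringsAsFactors = FALSE)
    sets[[a]] <- structure(
      list(case_family = names(fams)[a], assignment = assignment,
           scenario = scen, redraws = case$redraws),
      class = "family_set")
  }
  names(sets) <- names(fams)
  sets
}

# Case pipeline with redraw-until->=2-affected. An integer G larger than the
# depth below the seeded founder is capped at that depth (i.e. the whole
# branch is kept), so shallow families remain usable in deep-G scenarios.
# For families where penetrance masking makes >= 2 affected unreachable
# (e.g. a 3-member family at Q = 0.6, where 2 affected are masked down to 1),
# the draw with the most affected is kept after max_redraws attempts; such a
# case family is then untestable for the tests requiring >= 2 affected.
simulate_case <- function(family, scen, gen, seed_base, max_redraws = 100) {
  best <- NULL
  best_n <- -1L
  for (attempt in 0:max_redraws) {
    s <- substream_seed(seed_base, attempt)
    drop <- gene_drop_dominant(family, seed = s)
    asg <- apply_penetrance(drop$assignment, scen$Q,
                            seed = substream_seed(s, 1))
    G_eff <- scen$G
    if (!identical(G_eff, "all"))
      G_eff <- min(G_eff, max(gen) - gen[[drop$founder]] + 1L)
    asg <- mask_generations(family, asg, G_eff, scen$R, generations = gen,
                            founder = drop$founder,
                            seed = substream_seed(s, 2))
    if (sum(asg$affected) >= 2)
      return(list(assignment = asg, redraws = attempt, founder = drop$founder))
    if (sum(asg$affected) > best_n) {
      best_n <- sum(asg$affected)
      best <- list(assignment = asg, redraws = attempt, founder = drop$founder)
    }
  }
  best
}

#' Convert a phenotype assignment to run_fa_tests phenotypes
#'
#' @param assignment a phenotype assignment data frame.
#' @return Named character vector (`"affected"` / `"unaffected"`).
#' @export
assignment_phenotypes <- function(assignment) {
  stats::setNames(ifelse(assignment$affected, "affected", "unaffected"),
                  assignment$id)
}
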