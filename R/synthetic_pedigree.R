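# Synthetic multi-family pedigree generator emulating the shape of a large
# genealogical study: independent families of two to five generations with a
# median family size around 36 individuals, no consanguinity (spouses are
# always new unrelated founders), so kinship ground truth stays analytic.

#' Specification for the synthetic pedigree generator
#'
#' @param n_families number of independent families (>= 1).
#' @param generations integer range (length-2 vector) of family generation
#'   counts, drawn uniformly per family; default `c(2, 5)`.
#' @param mean_sibship mean number of children per reproducing couple
#'   (zero-truncated Poisson); the default 4.0 is tuned so that, with the
#'   default reproduction probability, the median family size is close
#'   to 36.
#' @param p_repro probability that a child marries (a new unrelated founder)
#'   and reproduces, while the family's generation count has not been
#'   reached (default 0.9).
#' @param sex_ratio probability that a child is male (default 0.5).
#' @param fixed_sibship optional integer: every couple has exactly this many
#'   children (overrides `mean_sibship`; useful for deterministic fixtures).
#' @return A `pedigree_spec` object.
#' @export
pedigree_spec <- function(n_families, generations = c(2, 5),
                          mean_sibship = 4.0, p_repro = 0.9,
                          sex_ratio = 0.5, fixed_sibship = NULL) {
  if (n_families < 1) stop("n_families must be >= 1")
  generations <- as.integer(generations)
  if (length(generations) != 2 || generations[1] < 2 || generations[2] > 10 ||
      generations[1] > generations[2])
    stop("generations must be an increasing range within [2, 10]")
  if (is.null(fixed_sibship) && mean_sibship <= 1)
    stop("mean_sibship must exceed 1")
  if (p_repro <= 0 || p_repro > 1) stop("p_repro must lie in (0, 1]")
  structure(list(n_families = as.integer(n_families),
                 generations = generations, mean_sibship = mean_sibship,
                 p_repro = p_repro, sex_ratio = sex_ratio,
                 fixed_sibship = fixed_sibship),
            class = "pedigree_spec")
}

#' Generate a synthetic multi-family pedigree
#'
#' Each family is built top-down from a founder couple: every reproducing
#' couple draws a sibship from a zero-truncated Poisson with mean
#' `mean_sibship`; while the family's drawn generation count has not been
#' reached, each child reproduces with probability `p_repro`, marrying a new
#' unrelated founder (so pedigrees contain no loops). At least one child per
#' level is forced to reproduce until the target depth is reached, making
#' the generation count exact. All individuals are phenotyped (status
#' `"unaffected"`; phenotypes are assigned later by the trait simulator).
#'
#' @param spec a [pedigree_spec()].
#' @param seed RNG seed; identical spec and seed give byte-identical output.
#' @return A validated multi-family [pedigree()] with families `F001`,
#'   `F002`, ... and ids `F001-1`, `F001-2`, ...
#' @export
generate_pedigree <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "pedigree_spec"))
  lambda <- if (is.null(spec$fixed_sibship)) ztpois_lambda(spec$mean_sibship) else NULL
  draw_sibship <- function() {
    if (!is.null(spec$fixed_sibship)) spec$fixed_sibship
    else rztpois(1, lambda)
  }
  fam_width <- max(3L, nchar(as.character(spec$n_families)))
  acc <- list()
  with_seed(seed, {
    for (f in seq_len(spec$n_families)) {
      fam <- sprintf(paste0("F%0", fam_width, "d"), f)
      gs <- spec$generations[1]:spec$generations[2]
      target_g <- gs[sample.int(length(gs), 1)]
      id <- c("1", "2"); father <- c(NA, NA); mother <- c(NA, NA)
      sex <- c("male", "female")
      counter <- 2L
      nid <- function() { counter <<- counter + 1L; as.character(counter) }
      # couples reproducing into the next generation: (father, mother) pairs
      couples <- list(c("1", "2"))
      for (g in seq_len(target_g - 1L)) {
        children <- character(0)
        for (cp in couples) {
          ns <- draw_sibship()
          for (k in seq_len(ns)) {
            ch <- nid()
            id <- c(id, ch); father <- c(father, cp[1]); mother <- c(mother, cp[2])
            sex <- c(sex, if (stats::runif(1) < spec$sex_ratio) "male" else "female")
            children <- c(children, ch)
          }
        }
        if (g == target_g - 1L) break
        repro <- stats::runif(length(children)) < spec$p_repro
        if (!any(repro)) repro[sample.int(length(children), 1)] <- TRUE
        couples <- lapply(children[repro], function(ch) {
          sp <- nid()
          ch_sex <- sex[match(ch, id)]
          id <<- c(id, sp); father <<- c(father, NA); mother <<- c(mother, NA)
          sex <<- c(sex, if (ch_sex == "male") "female" else "male")
          if (ch_sex == "male") c(ch, sp) else c(sp, ch)
        })
      }
      acc[[f]] <- data.frame(family = fam, id = paste0(fam, "-", id),
                             father = ifelse(is.na(father), NA,
                                             paste0(fam, "-", father)),
                             mother = ifelse(is.na(mother), NA,
                                             paste0(fam, "-", mother)),
                             sex = sex, phenotype = "unaffected",
                             stringsAsFactors = FALSE)
    }
  })
  df <- data.frame(family = unlist(lapply(acc, `[[`, "family")),
                   id = unlist(lapply(acc, `[[`, "id")),
                   father = unlist(lapply(acc, `[[`, "father")),
                   mother = unlist(lapply(acc, `[[`, "mother")),
                   sex = unlist(lapply(acc, `[[`, "sex")),
                   phenotype = unlist(lapply(acc, `[[`, "phenotype")),
                   stringsAsFactors = FALSE)
  as_pedigree(df, validate = TRUE)
}

#' Summarize a pedigree
#'
#' @param ped a [pedigree()].
#' @return A list with `n_individuals`, `n_families`, `family_sizes` (named),
#'   `size_quantiles` (0, 25, 50, 75, 100%), `median_family_size` and
#'   `generation_counts` (per-family table).
#' @export
pedigree_summary <- function(ped) {
  if (!nrow(ped))
    return(list(n_individuals = 0L, n_families = 0L,
                family_sizes = integer(0),
                size_quantiles = stats::quantile(numeric(0)),
                median_family_size = NA_real_,
                generation_counts = table(integer(0))))
  fams <- split_families(ped)
  sizes <- vapply(fams, nrow, integer(1))
  gens <- vapply(fams, function(f) assign_generations(f)$n_generations,
                 integer(1))
  list(n_individuals = nrow(ped), n_families = length(fams),
       family_sizes = sizes,
       size_quantiles = stats::quantile(sizes),
       median_family_size = stats::median(sizes),
       generation_counts = table(gens))
}
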