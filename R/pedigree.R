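# Pedigree data model: construction, validation, PED/FAM I/O, filtering,
# family decomposition and generation assignment.

SEX_LEVELS <- c("male", "female", "unknown")
PHENO_LEVELS <- c("affected", "unaffected", "unphenotyped")

#' Construct a pedigree
#'
#' A `pedigree` is a data frame with one row per individual and columns
#' `family`, `id`, `father`, `mother`, `sex` and `phenotype`. Parent columns
#' hold `NA` for founders; `sex` is one of `"male"`, `"female"`, `"unknown"`;
#' `phenotype` is one of `"affected"`, `"unaffected"`, `"unphenotyped"`.
#' Unphenotyped individuals carry no trait information but still connect
#' relatives, and therefore contribute to kinship.
#'
#' @param family,id,father,mother,sex,phenotype column vectors (recycled
#'   where scalar). Ids must be unique across the whole pedigree.
#' @param validate run structural validation (default `TRUE`).
#' @return An object of class `pedigree` (also a `data.frame`).
#' @examples
#' trio <- pedigree(family = "f1", id = c("p1", "p2", "c1"),
#'                  father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
#'                  sex = c("male", "female", "female"),
#'                  phenotype = c("unaffected", "affected", "affected"))
#' @export
pedigree <- function(family, id, father = NA, mother = NA,
                     sex = "unknown", phenotype = "unphenotyped",
                     validate = TRUE) {
  n <- length(id)
  ped <- data.frame(
    family = rep_len(as.character(family), n),
    id = as.character(id),
    father = rep_len(as.character(father), n),
    mother = rep_len(as.character(mother), n),
    sex = rep_len(as.character(sex), n),
    phenotype = rep_len(as.character(phenotype), n),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  if (validate) validate_pedigree(ped)
  ped
}

as_pedigree <- function(df, validate = TRUE) {
  stopifnot(all(c("family", "id", "father", "mother", "sex", "phenotype")
                %in% names(df)))
  pedigree(df$family, df$id, df$father, df$mother, df$sex, df$phenotype,
           validate = validate)
}

#' Validate pedigree structure
#'
#' Checks id uniqueness, parent references (existing, sex-consistent,
#' non-self), level codes and acyclicity of the parentage graph. Single-parent
#' records are permitted (see [complete_parents()] for the both-or-none
#' completion used by kinship and simulation code).
#'
#' @param ped a [pedigree()].
#' @return `ped`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id))
    stop("duplicated individual ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (!all(ped$sex %in% SEX_LEVELS))
    stop("invalid sex codes: ",
         paste(setdiff(unique(ped$sex), SEX_LEVELS), collapse = ", "))
  if (!all(ped$phenotype %in% PHENO_LEVELS))
    stop("invalid phenotype codes: ",
         paste(setdiff(unique(ped$phenotype), PHENO_LEVELS), collapse = ", "))
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !(ref %in% ped$id)
    if (any(bad))
      stop("dangling ", col, " reference(s): ",
           paste(unique(ref[bad]), collapse = ", "))
    if (any(!is.na(ref) & ref == ped$id))
      stop("individual(s) listed as own ", col, ": ",
           paste(ped$id[!is.na(ref) & ref == ped$id], collapse = ", "))
  }
  # unknown-sex parents are tolerated (they are dropped by filter_pedigree);
  # only an outright contradiction is an error
  sex_of <- stats::setNames(ped$sex, ped$id)
  badf <- !is.na(ped$father) & sex_of[ped$father] == "female"
  if (any(badf))
    stop("referenced father(s) not male: ",
         paste(unique(ped$father[badf]), collapse = ", "))
  badm <- !is.na(ped$mother) & sex_of[ped$mother] == "male"
  if (any(badm))
    stop("referenced mother(s) not female: ",
         paste(unique(ped$mother[badm]), collapse = ", "))
  topo_order(ped)  # errors on parentage cycles
  invisible(ped)
}

# Topological order of individuals (parents before children); Kahn's
# algorithm on the parent -> child graph. Errors if the graph has a cycle.
topo_order <- function(ped) {
  n <- nrow(ped)
  if (n == 0) return(integer(0))
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- idx[ped$father]
  mo <- idx[ped$mother]
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fa[i])) children[[fa[i]]] <- c(children[[fa[i]]], i)
    if (!is.na(mo[i])) children[[mo[i]]] <- c(children[[mo[i]]], i)
  }
  out <- integer(n)
  m <- length(which(indeg == 0))
  out[seq_len(m)] <- which(indeg == 0)
  head <- 1L
  while (head <= m) {
    v <- out[head]; head <- head + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) { m <- m + 1L; out[m] <- ch }
    }
  }
  out <- out[seq_len(m)]
  if (length(out) < n)
    stop("parentage cycle detected involving: ",
         paste(ped$id[setdiff(seq_len(n), out)], collapse = ", "))
  out
}

#' Complete single-parent records with anonymous founders
#'
#' The kinship recursion and gene-dropping both require every individual to
#' have either two recorded parents or none. Records with exactly one parent
#' are completed by inserting an anonymous unphenotyped founder of the
#' opposite sex (one per missing partner, shared by full siblings).
#'
#' @param ped a [pedigree()].
#' @return A list with elements `ped` (completed pedigree) and `added`
#'   (character vector of inserted founder ids, possibly empty).
#' @export
complete_parents <- function(ped) {
  added <- character(0)
  repeat {
    single <- which(is.na(ped$father) != is.na(ped$mother))
    if (!length(single)) break
    # group by (family, known parent, missing side) so full sibs share the
    # same anonymous partner
    miss_father <- single[is.na(ped$father[single])]
    miss_mother <- single[is.na(ped$mother[single])]
    new_rows <- list()
    if (length(miss_father)) {
      for (key in unique(paste(ped$family[miss_father], ped$mother[miss_father]))) {
        rows <- miss_father[paste(ped$family[miss_father], ped$mother[miss_father]) == key]
        aid <- paste0(ped$family[rows[1]], ".anon", length(added) + length(new_rows) + 1L)
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          family = ped$family[rows[1]], id = aid, father = NA_character_,
          mother = NA_character_, sex = "male", phenotype = "unphenotyped",
          stringsAsFactors = FALSE)
        ped$father[rows] <- aid
      }
    }
    if (length(miss_mother)) {
      for (key in unique(paste(ped$family[miss_mother], ped$father[miss_mother]))) {
        rows <- miss_mother[paste(ped$family[miss_mother], ped$father[miss_mother]) == key]
        aid <- paste0(ped$family[rows[1]], ".anon", length(added) + length(new_rows) + 1L)
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          family = ped$family[rows[1]], id = aid, father = NA_character_,
          mother = NA_character_, sex = "female", phenotype = "unphenotyped",
          stringsAsFactors = FALSE)
        ped$mother[rows] <- aid
      }
    }
    new_df <- do.call(rbind, new_rows)
    added <- c(added, new_df$id)
    ped <- as_pedigree(rbind(as.data.frame(ped), new_df), validate = FALSE)
  }
  validate_pedigree(ped)
  list(ped = ped, added = added)
}

#' Read a pedigree from a PED/FAM file
#'
#' Parses the whitespace-delimited 6-column PLINK-FAM dialect: family id,
#' individual id, father id, mother id, sex (1 = male, 2 = female,
#' 0 = unknown), phenotype (2 = affected, 1 = unaffected, 0 or -9 =
#' unphenotyped). Parent id `"0"` encodes a missing parent.
#'
#' @param path path to the file.
#' @param complete complete single-parent records with anonymous founders
#'   via [complete_parents()] (default `TRUE`).
#' @return A validated [pedigree()]. When founders were inserted, their ids
#'   are available as `attr(ped, "added_parents")`.
#' @export
read_ped <- function(path, complete = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(pedigree(character(0), character(0), validate = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6))
    stop("malformed PED line(s) (expected 6 fields): line ",
         paste(which(nf != 6), collapse = ", "))
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  sex_map <- c("1" = "male", "2" = "female", "0" = "unknown")
  phe_map <- c("2" = "affected", "1" = "unaffected",
               "0" = "unphenotyped", "-9" = "unphenotyped")
  if (!all(m[, 5] %in% names(sex_map)))
    stop("invalid sex code(s) on line ",
         paste(which(!(m[, 5] %in% names(sex_map))), collapse = ", "))
  if (!all(m[, 6] %in% names(phe_map)))
    stop("invalid phenotype code(s) on line ",
         paste(which(!(m[, 6] %in% names(phe_map))), collapse = ", "))
  ped <- pedigree(
    family = m[, 1], id = m[, 2],
    father = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = unname(sex_map[m[, 5]]),
    phenotype = unname(phe_map[m[, 6]])
  )
  if (complete) {
    comp <- complete_parents(ped)
    ped <- comp$ped
    if (length(comp$added)) attr(ped, "added_parents") <- comp$added
  }
  ped
}

#' Write a pedigree to a PED/FAM file
#'
#' Emits the same 6-column dialect parsed by [read_ped()], ordered by family
#' then id, with missing parents encoded as `"0"`.
#'
#' @param ped a [pedigree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  validate_pedigree(ped)
  ord <- order(ped$family, ped$id)
  p <- ped[ord, , drop = FALSE]
  sex_code <- c(male = "1", female = "2", unknown = "0")
  phe_code <- c(affected = "2", unaffected = "1", unphenotyped = "0")
  lines <- paste(p$family, p$id,
                 ifelse(is.na(p$father), "0", p$father),
                 ifelse(is.na(p$mother), "0", p$mother),
                 sex_code[p$sex], phe_code[p$phenotype])
  writeLines(lines, path)
  invisible(path)
}

# adjacency of the relationship graph: parent-child links only (a spouse is
# connected through the shared child)
relative_edges <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  ch <- seq_len(nrow(ped))
  rbind(cbind(ch[!is.na(fa)], fa[!is.na(fa)]),
        cbind(ch[!is.na(mo)], mo[!is.na(mo)]))
}

#' Filter a pedigree: drop unknown-sex individuals and singletons
#'
#' Removes individuals with unknown sex, then iteratively removes individuals
#' with no relatives (no parent and no child among the remaining
#' individuals) until a fixed point is reached. Children of a removed parent
#' keep their remaining parent link. The operation is idempotent.
#'
#' @param ped a [pedigree()].
#' @return The filtered [pedigree()] (possibly empty) with an attached
#'   removal report, retrievable with [removal_report()]: a data frame with
#'   columns `id` and `reason` (`"no_sex"` or `"singleton"`).
#' @export
filter_pedigree <- function(ped) {
  removed <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_ids <- ped$id[ped$sex == "unknown"]
  if (length(drop_ids))
    removed <- rbind(removed, data.frame(id = drop_ids, reason = "no_sex",
                                         stringsAsFactors = FALSE))
  keep <- ped[!(ped$id %in% drop_ids), , drop = FALSE]
  keep$father[!is.na(keep$father) & !(keep$father %in% keep$id)] <- NA
  keep$mother[!is.na(keep$mother) & !(keep$mother %in% keep$id)] <- NA
  repeat {
    if (!nrow(keep)) break
    has_parent <- !is.na(keep$father) | !is.na(keep$mother)
    is_parent <- keep$id %in% c(keep$father, keep$mother)
    lone <- !has_parent & !is_parent
    if (!any(lone)) break
    removed <- rbind(removed, data.frame(id = keep$id[lone],
                                         reason = "singleton",
                                         stringsAsFactors = FALSE))
    keep <- keep[!lone, , drop = FALSE]
    keep$father[!is.na(keep$father) & !(keep$father %in% keep$id)] <- NA
    keep$mother[!is.na(keep$mother) & !(keep$mother %in% keep$id)] <- NA
  }
  out <- as_pedigree(as.data.frame(keep), validate = FALSE)
  attr(out, "removal_report") <- removed
  out
}

#' @rdname filter_pedigree
#' @export
removal_report <- function(ped) {
  attr(ped, "removal_report") %||%
    data.frame(id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
}

#' Split a pedigree into independent families
#'
#' Returns the connected components of the relationship graph (parent-child
#' links). Components inherit the `family` label of their members; if one
#' family label spans several components, components are suffixed `.1`,
#' `.2`, ... in order of appearance.
#'
#' @param ped a [pedigree()].
#' @return A named list of single-family [pedigree()] objects whose sizes sum
#'   to `nrow(ped)`.
#' @export
split_families <- function(ped) {
  n <- nrow(ped)
  if (n == 0) return(list())
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  edges <- relative_edges(ped)
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) comp[a] <- b
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  labels <- vapply(groups, function(g) ped$family[g[1]], character(1))
  dup <- labels[duplicated(labels)]
  for (lab in unique(dup)) {
    k <- which(labels == lab)
    labels[k] <- paste(lab, seq_along(k), sep = ".")
  }
  out <- lapply(seq_along(groups), function(g) {
    fam <- ped[groups[[g]], , drop = FALSE]
    fam$family <- labels[g]
    as_pedigree(as.data.frame(fam), validate = FALSE)
  })
  names(out) <- labels
  out
}

#' Assign generation indices within one family
#'
#' Founders at the top of the family receive generation 1; a child's
#' generation is one more than the deepest of its parents' generations, and a
#' married-in founder (a parentless individual whose only tie is a shared
#' child) inherits the generation of its co-parent. Depths are made
#' consistent by monotone constraint propagation to a fixed point, giving
#' each individual the minimal consistent depth.
#'
#' @param family a single connected-family [pedigree()].
#' @return A list with `generation` (named integer vector, 1-based) and
#'   `n_generations` (max index).
#' @export
assign_generations <- function(family) {
  n <- nrow(family)
  if (n == 0) return(list(generation = integer(0), n_generations = 0L))
  ord <- topo_order(family)
  idx <- stats::setNames(seq_len(n), family$id)
  fa <- idx[family$father]; mo <- idx[family$mother]
  is_founder <- is.na(fa) & is.na(mo)
  # co-parents of each founder (spouse = shares a child)
  spouses <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fa[i]) && !is.na(mo[i])) {
      spouses[[fa[i]]] <- c(spouses[[fa[i]]], mo[i])
      spouses[[mo[i]]] <- c(spouses[[mo[i]]], fa[i])
    } else if (!is.na(fa[i]) || !is.na(mo[i])) {
      # single-parent record: no spouse tie implied
    }
  }
  depth <- rep(1L, n)
  for (pass in seq_len(n + 1L)) {
    changed <- FALSE
    for (i in ord) {
      if (!is_founder[i]) {
        d <- 1L + max(depth[c(fa[i], mo[i])], na.rm = TRUE)
      } else {
        sp <- unique(spouses[[i]])
        d <- if (length(sp)) max(1L, max(depth[sp])) else 1L
      }
      if (d > depth[i]) { depth[i] <- d; changed <- TRUE }
    }
    if (!changed) break
    if (pass == n + 1L) stop("generation assignment did not converge")
  }
  list(generation = stats::setNames(as.integer(depth), family$id),
       n_generations = as.integer(max(depth)))
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals in %d famil%s\n", nrow(x),
              length(unique(x$family)),
              if (length(unique(x$family)) == 1) "y" else "ies"))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# convenience accessors used across modules
phenotyped_ids <- function(ped) ped$id[ped$phenotype %in% c("affected", "unaffected")]
affected_ids <- function(ped) ped$id[ped$phenotype == "affected"]
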