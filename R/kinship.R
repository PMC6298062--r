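# Kinship coefficients: recursive computation over pedigrees, neighborhood
# queries used by the group tests, a gene-dropping Monte-Carlo IBD estimator
# for validation, and TSV/MatrixMarket export.

#' Compute the kinship matrix of a pedigree
#'
#' The kinship coefficient phi(i, j) is the probability that two alleles
#' sampled at random, one from each of i and j, are identical by descent.
#' It is computed by the standard recursion in topological order: founders
#' have phi(i, i) = 1/2 and phi(i, j) = 0 to other founders; for a
#' non-founder i with parents f and m, phi(i, i) = (1 + phi(f, m)) / 2 and
#' phi(i, j) = (phi(f, j) + phi(m, j)) / 2 for any j that is not a
#' descendant of i. Inbreeding is accommodated through the self-kinship
#' recursion. Unphenotyped individuals are included: they connect relatives.
#'
#' Single-parent records are completed internally with anonymous founders
#' (see [complete_parents()]); the returned matrix covers only the original
#' individuals. The matrix is block-diagonal by family and stored as one
#' dense block per family.
#'
#' @param ped a [pedigree()].
#' @return An object of class `kinship_matrix`: per-family dense blocks plus
#'   an id-to-family index. Use [kinship_phi()] to query coefficients,
#'   `as.matrix()` for the assembled symmetric matrix.
#' @examples
#' trio <- pedigree(family = "f1", id = c("p1", "p2", "c1"),
#'                  father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
#'                  sex = c("male", "female", "female"),
#'                  phenotype = "unaffected")
#' K <- kinship_matrix(trio)
#' kinship_phi(K, "p1", "c1")  # 0.25
#' @export
kinship_matrix <- function(ped) {
  validate_pedigree(ped)
  orig_ids <- ped$id
  comp <- complete_parents(ped)
  ped <- comp$ped
  fams <- split(seq_len(nrow(ped)), ped$family)
  blocks <- list()
  for (fam in names(fams)) {
    rows <- fams[[fam]]
    sub <- ped[rows, , drop = FALSE]
    # parents must live in the same family block
    out_ref <- c(sub$father, sub$mother)
    out_ref <- out_ref[!is.na(out_ref)]
    if (!all(out_ref %in% sub$id))
      stop("family ", fam, " references parents outside the family: ",
           paste(setdiff(out_ref, sub$id), collapse = ", "))
    blocks[[fam]] <- kinship_block(sub)
  }
  # drop internally added anonymous founders from the output
  added <- comp$added
  if (length(added)) {
    blocks <- lapply(blocks, function(b) {
      keep <- !(rownames(b) %in% added)
      b[keep, keep, drop = FALSE]
    })
    blocks <- blocks[vapply(blocks, nrow, integer(1)) > 0]
  }
  fam_of <- stats::setNames(rep(names(blocks), vapply(blocks, nrow, integer(1))),
                            unlist(lapply(blocks, rownames)))
  structure(list(blocks = blocks, family = fam_of,
                 ids = orig_ids[orig_ids %in% names(fam_of)]),
            class = "kinship_matrix")
}

# dense kinship recursion within one family (both-or-none parents required)
kinship_block <- function(sub) {
  n <- nrow(sub)
  ord <- topo_order(sub)
  idx <- stats::setNames(seq_len(n), sub$id)
  fa <- idx[sub$father]; mo <- idx[sub$mother]
  K <- matrix(0, n, n, dimnames = list(sub$id, sub$id))
  seen <- integer(0)
  for (i in ord) {
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      if (length(seen)) {
        v <- 0.5 * (K[fa[i], seen] + K[mo[i], seen])
        K[i, seen] <- v
        K[seen, i] <- v
      }
      K[i, i] <- 0.5 * (1 + K[fa[i], mo[i]])
    }
    seen <- c(seen, i)
  }
  K
}

#' Query kinship coefficients
#'
#' @param K a [kinship_matrix()].
#' @param i,j individual ids (vectors of equal length are queried pairwise).
#' @return Numeric vector of phi(i, j); 0 for members of different families.
#' @export
kinship_phi <- function(K, i, j) {
  i <- as.character(i); j <- as.character(j)
  n <- max(length(i), length(j))
  i <- rep_len(i, n); j <- rep_len(j, n)
  unknown <- setdiff(c(i, j), names(K$family))
  if (length(unknown)) stop("unknown id(s): ", paste(unknown, collapse = ", "))
  out <- numeric(n)
  same <- K$family[i] == K$family[j]
  for (k in which(same)) out[k] <- K$blocks[[K$family[i[k]]]][i[k], j[k]]
  out
}

# dense per-family block (rows/cols restricted and ordered by `ids` if given)
kinship_block_of <- function(K, family, ids = NULL) {
  b <- K$blocks[[family]]
  if (is.null(b)) stop("unknown family: ", family)
  if (!is.null(ids) && !identical(ids, rownames(b)))
    b <- b[ids, ids, drop = FALSE]
  b
}

#' @export
as.matrix.kinship_matrix <- function(x, ...) {
  ids <- x$ids
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (b in x$blocks) M[rownames(b), colnames(b)] <- b
  M
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("Kinship matrix: %d individuals, %d family block(s)\n",
              length(x$ids), length(x$blocks)))
  invisible(x)
}

#' Most distant affected relative
#'
#' Among affected relatives j of i within i's family with phi(i, j) > 0,
#' returns the one with minimal kinship to i (ties broken by lexicographic
#' id), or `NA` if there is none. This relative sets the kinship threshold
#' that defines i's kinship group.
#'
#' @param K a [kinship_matrix()].
#' @param i an affected individual id.
#' @param affected character vector of affected ids.
#' @return A single id, or `NA_character_`.
#' @export
most_distant_affected <- function(K, i, affected) {
  i <- as.character(i)
  if (!(i %in% affected)) stop("individual ", i, " is not affected")
  fam <- K$family[i]
  if (is.na(fam)) stop("unknown id: ", i)
  others <- setdiff(intersect(affected, names(K$family)[K$family == fam]), i)
  if (!length(others)) return(NA_character_)
  phi <- kinship_phi(K, i, others)
  pos <- phi > 0
  if (!any(pos)) return(NA_character_)
  others <- others[pos]; phi <- phi[pos]
  cand <- others[phi == min(phi)]
  sort(cand)[1]
}

#' Kinship group of an affected individual
#'
#' The group of individuals at least as closely related to i as i's most
#' distant affected relative: all phenotyped family members j (including i)
#' with phi(i, j) >= phi(i, most_distant_affected(i)). Unphenotyped
#' relatives contribute to kinship but are not group members.
#'
#' @param K a [kinship_matrix()].
#' @param i an affected individual id.
#' @param affected character vector of affected ids.
#' @param phenotyped character vector of phenotyped ids (defaults to all ids
#'   in the matrix).
#' @return Character vector of group member ids (always contains i and at
#'   least one affected relative). Errors with condition class
#'   `pedagg_not_applicable` when i has no affected relative with positive
#'   kinship, i.e. the group tests are undefined for i.
#' @export
kinship_group <- function(K, i, affected, phenotyped = NULL) {
  i <- as.character(i)
  md <- most_distant_affected(K, i, affected)
  if (is.na(md))
    stop(structure(class = c("pedagg_not_applicable", "error", "condition"),
                   list(message = paste0("no affected relative with positive kinship for ", i),
                        call = sys.call())))
  fam <- K$family[i]
  members <- names(K$family)[K$family == fam]
  if (!is.null(phenotyped)) members <- intersect(members, c(phenotyped, i))
  thr <- kinship_phi(K, i, md)
  phi <- kinship_phi(K, i, members)
  sort(members[phi >= thr])
}

#' Gene-dropping Monte-Carlo estimate of kinship
#'
#' Independent validation of the recursive kinship computation: assigns two
#' uniquely labelled alleles to every founder, drops them through the
#' pedigree (each child inherits one allele at random from each parent) and
#' estimates phi(i, j) as the proportion, over drops, of randomly chosen
#' allele pairs (one from i, one from j) that are identical by descent. The
#' per-drop IBD probability is averaged analytically over the four allele
#' pairings, so the estimator's standard error is available in closed form.
#'
#' @param family a single-family [pedigree()].
#' @param pairs two-column character matrix of id pairs to estimate.
#' @param n_drops number of gene drops (default 200000).
#' @param seed RNG seed.
#' @return Data frame with columns `i`, `j`, `phi_hat` and `se`.
#' @export
kinship_gene_drop <- function(family, pairs, n_drops = 200000, seed = 1) {
  comp <- complete_parents(family)
  fam <- comp$ped
  n <- nrow(fam)
  ord <- topo_order(fam)
  idx <- stats::setNames(seq_len(n), fam$id)
  fa <- idx[fam$father]; mo <- idx[fam$mother]
  with_seed(seed, {
    P <- matrix(0L, n_drops, n)  # paternal allele label
    M <- matrix(0L, n_drops, n)  # maternal allele label
    next_allele <- 1L
    for (i in ord) {
      if (is.na(fa[i])) {
        P[, i] <- next_allele
        M[, i] <- next_allele + 1L
        next_allele <- next_allele + 2L
      } else {
        pick <- stats::runif(n_drops) < 0.5
        P[, i] <- ifelse(pick, P[, fa[i]], M[, fa[i]])
        pick <- stats::runif(n_drops) < 0.5
        M[, i] <- ifelse(pick, P[, mo[i]], M[, mo[i]])
      }
    }
    res <- data.frame(i = pairs[, 1], j = pairs[, 2],
                      phi_hat = NA_real_, se = NA_real_,
                      stringsAsFactors = FALSE)
    for (r in seq_len(nrow(pairs))) {
      a <- idx[pairs[r, 1]]; b <- idx[pairs[r, 2]]
      if (a == b) {
        share <- 0.5 * (1 + (P[, a] == M[, a]))
      } else {
        share <- ((P[, a] == P[, b]) + (P[, a] == M[, b]) +
                  (M[, a] == P[, b]) + (M[, a] == M[, b])) / 4
      }
      res$phi_hat[r] <- mean(share)
      res$se[r] <- stats::sd(share) / sqrt(n_drops)
    }
    res
  })
}

#' Export a kinship matrix
#'
#' Writes either a long-format TSV (`i`, `j`, `phi`; nonzero upper triangle
#' including the diagonal) or a symmetric sparse matrix in MatrixMarket
#' coordinate format.
#'
#' @param K a [kinship_matrix()].
#' @param path output file.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(K, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  ids <- K$ids
  pos <- stats::setNames(seq_along(ids), ids)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (b in K$blocks) {
    bi <- pos[rownames(b)]
    w <- which(b != 0 & upper.tri(b, diag = TRUE), arr.ind = TRUE)
    ii <- c(ii, bi[w[, 1]]); jj <- c(jj, bi[w[, 2]]); xx <- c(xx, b[w])
  }
  swap <- ii > jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  if (format == "tsv") {
    utils::write.table(
      data.frame(i = ids[ii], j = ids[jj], phi = xx),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(length(ids), length(ids)),
                              symmetric = TRUE)
    Matrix::writeMM(S, path)
  }
  invisible(path)
}
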