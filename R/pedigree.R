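#' Validate and index a pedigree table
#'
#' Checks that a pedigree is topologically ordered (parents appear before
#' their offspring) and returns integer parent indices. Unknown parents are
#' coded `NA` and treated as unrelated, non-inbred founders.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (any atomic id
#'   type; `NA` or `""` = unknown). Extra columns are ignored.
#' @return list with `ids` (character), `sire`, `dam` (integer indices or NA).
#' @keywords internal
ped_index <- function(pedigree) {
  stopifnot(is.data.frame(pedigree), all(c("id", "sire", "dam") %in% names(pedigree)))
  ids <- as.character(pedigree$id)
  if (anyDuplicated(ids)) stop("duplicated animal ids in pedigree")
  blank <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    x
  }
  s <- match(blank(pedigree$sire), ids)
  d <- match(blank(pedigree$dam), ids)
  known_s <- !is.na(blank(pedigree$sire))
  known_d <- !is.na(blank(pedigree$dam))
  if (any(known_s & is.na(s)) || any(known_d & is.na(d))) {
    stop("pedigree references parents that are not listed as animals")
  }
  n <- length(ids)
  if (any(s >= seq_len(n), na.rm = TRUE) || any(d >= seq_len(n), na.rm = TRUE)) {
    stop("pedigree is not ordered parents-first (or contains a cycle)")
  }
  list(ids = ids, sire = s, dam = d)
}

#' Sort a pedigree so parents precede offspring
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam`.
#' @return the pedigree with rows reordered topologically.
#' @export
order_pedigree <- function(pedigree) {
  ids <- as.character(pedigree$id)
  s <- match(as.character(pedigree$sire), ids)
  d <- match(as.character(pedigree$dam), ids)
  n <- length(ids)
  depth <- rep(NA_integer_, n)
  calc <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    ds <- if (is.na(s[i])) 0L else calc(s[i]) + 1L
    dd <- if (is.na(d[i])) 0L else calc(d[i]) + 1L
    depth[i] <<- max(ds, dd)
    depth[i]
  }
  for (i in seq_len(n)) calc(i)
  pedigree[order(depth, seq_len(n)), , drop = FALSE]
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive genetic relationship matrix A for an ordered pedigree:
#' a(i,i) = 1 + F_i with F_i = a(sire_i, dam_i)/2, and
#' a(i,j) = (a(sire_i, j) + a(dam_i, j))/2, unknown parents contributing 0.
#' Dense; intended for pedigrees up to a few thousand animals (the mixed-model
#' equations only ever use the sparse inverse, see [build_A_inverse()]).
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam`, parents first.
#' @return symmetric numeric matrix with dimnames = animal ids.
#' @export
build_A <- function(pedigree) {
  px <- ped_index(pedigree)
  n <- length(px$ids)
  A <- matrix(0, n, n, dimnames = list(px$ids, px$ids))
  for (i in seq_len(n)) {
    si <- px$sire[i]; di <- px$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + A[si, j]
      if (!is.na(di)) row <- row + A[di, j]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) A[si, di] / 2 else 0
  }
  A
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes F for every animal from the L (gametic contribution) rows and the
#' within-family variances, without forming A.
#'
#' @inheritParams build_A
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(pedigree) {
  px <- ped_index(pedigree)
  n <- length(px$ids)
  F <- numeric(n)
  dvec <- numeric(n)  # within-family (Mendelian sampling) variances
  for (i in seq_len(n)) {
    si <- px$sire[i]; di <- px$dam[i]
    dvec[i] <- 0.5 -
      0.25 * ((if (is.na(si)) -1 else F[si]) + (if (is.na(di)) -1 else F[di]))
    if (is.na(si) || is.na(di)) {
      F[i] <- 0
      next
    }
    # accumulate L-row of animal i over its ancestors
    L <- numeric(i)
    L[i] <- 1
    acc <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      sj <- px$sire[j]; dj <- px$dam[j]
      if (!is.na(sj)) L[sj] <- L[sj] + 0.5 * L[j]
      if (!is.na(dj)) L[dj] <- L[dj] + 0.5 * L[j]
      acc <- acc + L[j]^2 * dvec[j]
    }
    F[i] <- acc - 1
  }
  names(F) <- px$ids
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules, with
#' inbreeding coefficients from [inbreeding()]. The log-determinant of A
#' (sum of log Mendelian-sampling variances) is attached as attribute
#' `"logdet_A"`; it is reused by the REML engine.
#'
#' @inheritParams build_A
#' @return sparse symmetric `Matrix::dsCMatrix` with dimnames = animal ids.
#' @export
build_A_inverse <- function(pedigree) {
  px <- ped_index(pedigree)
  n <- length(px$ids)
  F <- inbreeding(pedigree)
  Fp <- function(idx) ifelse(is.na(idx), -1, F[ifelse(is.na(idx), 1L, idx)])
  d <- 0.5 - 0.25 * (Fp(px$sire) + Fp(px$dam))
  b <- 1 / d
  # vectorized triplet assembly of Henderson's rules
  anml <- seq_len(n)
  s <- px$sire; dm <- px$dam
  ii <- anml; jj <- anml; xx <- b
  hs <- !is.na(s)
  ii <- c(ii, anml[hs], s[hs], s[hs])
  jj <- c(jj, s[hs], anml[hs], s[hs])
  xx <- c(xx, -b[hs] / 2, -b[hs] / 2, b[hs] / 4)
  hd <- !is.na(dm)
  ii <- c(ii, anml[hd], dm[hd], dm[hd])
  jj <- c(jj, dm[hd], anml[hd], dm[hd])
  xx <- c(xx, -b[hd] / 2, -b[hd] / 2, b[hd] / 4)
  hb <- hs & hd
  ii <- c(ii, s[hb], dm[hb])
  jj <- c(jj, dm[hb], s[hb])
  xx <- c(xx, b[hb] / 4, b[hb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(px$ids, px$ids))
  Ainv <- methods::as(Matrix::forceSymmetric(Ainv), "symmetricMatrix")
  attr(Ainv, "logdet_A") <- sum(log(d))
  attr(Ainv, "F") <- F
  Ainv
}

#' Restrict a pedigree to a set of animals and their ancestors
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam`, parents first.
#' @param keep ids of animals that must remain (e.g. those carrying records).
#' @return the pruned pedigree, original ordering preserved.
#' @export
prune_pedigree <- function(pedigree, keep) {
  px <- ped_index(pedigree)
  need <- px$ids %in% as.character(keep)
  if (!any(need)) stop("none of the requested ids are in the pedigree")
  for (i in rev(seq_along(px$ids))) {
    if (need[i]) {
      if (!is.na(px$sire[i])) need[px$sire[i]] <- TRUE
      if (!is.na(px$dam[i])) need[px$dam[i]] <- TRUE
    }
  }
  pedigree[need, , drop = FALSE]
}

#' Write a relationship matrix in coordinate text format
#'
#' Upper triangle (including diagonal) as `row,col,value` with 1-based indices
#' and a header naming the ids.
#'
#' @param A matrix from [build_A()] (or any symmetric matrix with dimnames).
#' @param file path of the CSV to write.
#' @export
write_A_coord <- function(A, file) {
  ut <- which(upper.tri(A, diag = TRUE) & A != 0, arr.ind = TRUE)
  out <- data.frame(row = ut[, 1], col = ut[, 2], value = A[ut])
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
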