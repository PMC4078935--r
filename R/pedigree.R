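#' Construct a validated, topologically sorted pedigree
#'
#' A pedigree holds one parental line of the crossbreeding design (the common
#' dam line or the Muscovy sire line). Records are sorted so that parents
#' always precede their offspring; unknown parents are coded `0` (or `NA`).
#'
#' @param id integer or character vector of animal identifiers (unique).
#' @param sire,dam parent identifiers, `0`/`NA` for unknown.
#' @param line line tag, `"common"` or `"muscovy"` (free-form allowed).
#' @param sex optional sex vector (`"M"`/`"F"`), carried through unchanged.
#' @return An object of class `"pedigree"`: a data frame with columns
#'   `id`, `sire`, `dam` (and `sex` if supplied) in topological order, with
#'   attributes `line` and `founders` (logical).
#' @examples
#' ped <- pedigree(id = c(3, 1, 2), sire = c(1, 0, 0), dam = c(2, 0, 0))
#' ped$id  # parents first
#' @export
pedigree <- function(id, sire, dam, line = "common", sex = NULL) {
  id <- as.vector(id); sire <- as.vector(sire); dam <- as.vector(dam)
  n <- length(id)
  if (length(sire) != n || length(dam) != n)
    stop("id, sire and dam must have equal length")
  if (anyDuplicated(id))
    stop("duplicate animal ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  sire[is.na(sire)] <- 0L
  dam[is.na(dam)] <- 0L
  known <- function(p) p != 0
  bad <- setdiff(c(sire[known(sire)], dam[known(dam)]), id)
  if (length(bad))
    stop("parents absent from pedigree: ", paste(bad, collapse = ", "))
  if (any(sire == id) || any(dam == id))
    stop("animal listed as its own parent: ",
         paste(id[sire == id | dam == id], collapse = ", "))

  # Kahn topological sort; detects cycles.
  idx <- seq_len(n)
  pos <- integer(0)
  placed <- logical(n)
  imap <- match(id, id)  # identity; we match parents below
  si <- match(sire, id, nomatch = 0L)
  di <- match(dam, id, nomatch = 0L)
  remaining <- idx
  while (length(remaining)) {
    placed0 <- c(TRUE, placed)  # position 1 = unknown parent
    ready <- remaining[placed0[si[remaining] + 1L] &
                       placed0[di[remaining] + 1L]]
    if (!length(ready))
      stop("pedigree contains a cycle involving ids: ",
           paste(id[remaining], collapse = ", "))
    ready <- ready[order(id[ready])]  # canonical order within a wave
    placed[ready] <- TRUE
    pos <- c(pos, ready)
    remaining <- setdiff(remaining, ready)
  }
  out <- data.frame(id = id[pos], sire = sire[pos], dam = dam[pos],
                    stringsAsFactors = FALSE)
  if (!is.null(sex)) out$sex <- sex[pos]
  class(out) <- c("pedigree", "data.frame")
  attr(out, "line") <- line
  attr(out, "founders") <- out$sire == 0 & out$dam == 0
  out
}

#' Read a pedigree from CSV
#'
#' Expects a header row and three columns (animal, sire, dam); `0` codes an
#' unknown parent. Rows may appear in any order.
#'
#' @param file path to a CSV file.
#' @param line line tag to attach.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(file, line = "common") {
  d <- utils::read.csv(file)
  if (ncol(d) < 3) stop("pedigree file needs 3 columns (animal, sire, dam)")
  pedigree(d[[1]], d[[2]], d[[3]], line = line)
}

#' Write a pedigree to CSV
#' @param ped a [pedigree].
#' @param file output path.
#' @export
write_pedigree <- function(ped, file) {
  utils::write.csv(as.data.frame(ped)[c("id", "sire", "dam")], file,
                   row.names = FALSE, quote = FALSE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree (", attr(x, "line"), " line): ", nrow(x), " animals, ",
      sum(attr(x, "founders")), " founders\n", sep = "")
  invisible(x)
}

# parent positions (0 = unknown) in sorted order
.parent_index <- function(ped) {
  list(s = match(ped$sire, ped$id, nomatch = 0L),
       d = match(ped$dam, ped$id, nomatch = 0L))
}

#' Additive (numerator) relationship matrix
#'
#' Tabular method with exact inbreeding accumulation: for sorted animals,
#' \eqn{a_{ij} = (a_{sj} + a_{dj})/2} for j preceding i, and
#' \eqn{a_{ii} = 1 + a_{sd}/2}. Founders are assumed non-inbred and unrelated.
#'
#' @param ped a [pedigree].
#' @return A symmetric dense matrix with dimnames set to animal ids.
#' @examples
#' ped <- pedigree(c(1, 2, 3), c(0, 0, 1), c(0, 0, 2))
#' build_A(ped)[1, 3]  # parent-offspring = 0.5
#' @export
build_A <- function(ped) {
  n <- nrow(ped)
  pi <- .parent_index(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pi$s[i]; d <- pi$d[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- numeric(i - 1)
      if (s > 0) row <- row + A[s, j]
      if (d > 0) row <- row + A[d, j]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) A[s, d] / 2 else 0
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Inbreeding coefficients
#'
#' @param ped a [pedigree].
#' @return Named numeric vector, F = diag(A) - 1.
#' @export
inbreeding <- function(ped) {
  diag(build_A(ped)) - 1
}

#' Inverse of the additive relationship matrix
#'
#' Henderson's rules with the Quaas correction for inbred parents: each
#' animal contributes \eqn{1/d_i} terms built from its Mendelian-sampling
#' variance \eqn{d_i = 1/2 - (F_s + F_d)/4} (both parents known),
#' \eqn{3/4 - F_p/4} (one known) or 1 (none).
#'
#' @param ped a [pedigree].
#' @param sparse return a `Matrix::dsCMatrix` (default) or dense matrix.
#' @return The inverse relationship matrix, dimnames = animal ids.
#' @export
build_A_inverse <- function(ped, sparse = TRUE) {
  n <- nrow(ped)
  pi <- .parent_index(ped)
  Fcoef <- inbreeding(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- pi$s[i]; d <- pi$d[i]
    dmi <- if (s > 0 && d > 0) 0.5 - (Fcoef[s] + Fcoef[d]) / 4
           else if (s > 0)     0.75 - Fcoef[s] / 4
           else if (d > 0)     0.75 - Fcoef[d] / 4
           else                1
    a <- 1 / dmi
    add(i, i, a)
    for (p in c(s, d)[c(s, d) > 0]) {
      add(i, p, -a / 2); add(p, i, -a / 2)
    }
    ps <- c(s, d)[c(s, d) > 0]
    if (length(ps)) for (p in ps) for (q in ps) add(p, q, a / 4)
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  M <- Matrix::forceSymmetric(M)
  if (sparse) M else as.matrix(M)
}

#' Export a relationship matrix as triplets
#'
#' Writes `(row_id, col_id, value)` rows for the non-zero upper triangle;
#' handy for eyeballing small pedigrees.
#' @param A matrix from [build_A] or [build_A_inverse].
#' @param file output CSV path.
#' @export
write_relationship_triplets <- function(A, file) {
  A <- as.matrix(A)
  keep <- which(upper.tri(A, diag = TRUE) & A != 0, arr.ind = TRUE)
  utils::write.csv(
    data.frame(row = rownames(A)[keep[, 1]], col = colnames(A)[keep[, 2]],
               value = A[keep]),
    file, row.names = FALSE, quote = FALSE)
}
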