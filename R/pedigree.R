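#' Validate and order a pedigree table
#'
#' Checks a pedigree data frame (columns `animal`, `sire`, `dam`, optionally
#' `birth_year`), recodes unknown parents to 0, rejects duplicate ids and
#' ancestor cycles, and returns the rows topologically sorted so that parents
#' always precede offspring. All downstream pedigree operations assume this
#' ordering.
#'
#' @param ped Data frame with columns `animal`, `sire`, `dam` and optionally
#'   `birth_year`. Unknown parents may be coded 0, `NA` or empty.
#' @return A tibble with integer columns `animal`, `sire`, `dam`,
#'   `birth_year`, topologically ordered.
#' @examples
#' as_pedigree(data.frame(animal = c(3, 1, 2), sire = c(1, 0, 0),
#'                        dam = c(2, 0, 0)))
#' @export
as_pedigree <- function(ped) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped))) {
    abort("pedigree needs columns `animal`, `sire`, `dam`.")
  }
  ped <- tibble::as_tibble(ped)
  if (!"birth_year" %in% names(ped)) ped$birth_year <- NA_integer_
  for (cl in c("animal", "sire", "dam", "birth_year")) {
    v <- ped[[cl]]
    if (is.character(v)) v[v == ""] <- NA
    v <- suppressWarnings(as.integer(v))
    if (cl != "birth_year" && anyNA(v) && cl == "animal") {
      abort("non-integer or missing animal id in pedigree.")
    }
    v[is.na(v) & cl %in% c("sire", "dam")] <- 0L
    ped[[cl]] <- v
  }
  if (anyDuplicated(ped$animal)) {
    abort(sprintf("duplicate animal id(s) in pedigree: %s",
                  paste(unique(ped$animal[duplicated(ped$animal)]),
                        collapse = ", ")))
  }
  if (any(ped$animal <= 0L)) abort("animal ids must be positive integers.")
  self <- ped$animal == ped$sire | ped$animal == ped$dam
  if (any(self)) {
    abort(sprintf("animal %d is recorded as its own parent.",
                  ped$animal[which(self)[1]]))
  }
  # parents that never appear as animals are treated as unknown base parents
  known <- ped$sire %in% c(0L, ped$animal) & ped$dam %in% c(0L, ped$animal)
  if (!all(known)) {
    miss_s <- setdiff(ped$sire, c(0L, ped$animal))
    miss_d <- setdiff(ped$dam, c(0L, ped$animal))
    abort(sprintf("parent id(s) absent from pedigree: %s",
                  paste(unique(c(miss_s, miss_d)), collapse = ", ")))
  }

  # Kahn topological sort; a leftover node means an ancestry cycle
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal, nomatch = 0L)
  di <- match(ped$dam, ped$animal, nomatch = 0L)
  indeg <- (si > 0L) + (di > 0L)                  # in-degree of each child
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    bad <- ped$animal[setdiff(seq_len(n), order)]
    abort(sprintf("ancestry cycle involving animal id(s): %s",
                  paste(bad, collapse = ", ")))
  }
  ped[order, ]
}

# integer parent indices (0 = unknown) for an ordered pedigree
ped_index <- function(ped) {
  list(
    si = match(ped$sire, ped$animal, nomatch = 0L),
    di = match(ped$dam, ped$animal, nomatch = 0L)
  )
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive relationship matrix A by the recursive tabular
#' method: \eqn{A_{ij} = 0.5 (A_{j,s_i} + A_{j,d_i})} for \eqn{j < i} and
#' \eqn{A_{ii} = 1 + F_i} with \eqn{F_i = 0.5 A_{s_i d_i}}. Intended as the
#' small-scale oracle (a few thousand animals); the mixed-model equations
#' only ever use the sparse inverse from [build_A_inverse()].
#'
#' @param ped An ordered pedigree from [as_pedigree()].
#' @return Dense symmetric matrix with dimnames = animal ids.
#' @export
build_A <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  pi <- ped_index(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pi$si[i]; d <- pi$di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s > 0L) A[j, s] else 0) +
                    (if (d > 0L) A[j, d] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes \eqn{F_i = 0.5 A_{s_i d_i}} for every animal without forming A,
#' using the L D L' decomposition of A traced through ancestors. Linear-ish
#' cost per animal in pedigree depth, suitable for large pedigrees.
#'
#' @param ped An ordered pedigree from [as_pedigree()].
#' @return Numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  pi <- ped_index(ped)
  meuwissen_luo_f(pi$si, pi$di, n)
}

# R implementation of Meuwissen & Luo (1992): F from diag(A) = sum_j L_ij^2 d_j
meuwissen_luo_f <- function(si, di, n) {
  F <- numeric(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; dd <- di[i]
    d[i] <- 0.5 - 0.25 * ((if (s > 0L) F[s] else -1) +
                          (if (dd > 0L) F[dd] else -1))
    if (s == 0L && dd == 0L) { F[i] <- 0; next }
    # trace ancestors, accumulating L contributions
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * d[j]
      if (si[j] > 0L) L[si[j]] <- L[si[j]] + 0.5 * L[j]
      if (di[j] > 0L) L[di[j]] <- L[di[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles \eqn{A^{-1}} directly from the pedigree by Henderson's rules
#' with inbreeding: each animal contributes the pattern
#' \eqn{d_i^{-1} (1, -0.5, -0.5)} over (animal, sire, dam), where the
#' Mendelian sampling variance is \eqn{d_i = 0.5 - 0.25 (F_s + F_d)} with
#' both parents known, \eqn{0.75 - 0.25 F_p} with one, and 1 with none.
#'
#' @param ped An ordered pedigree from [as_pedigree()].
#' @param use_inbreeding If `FALSE`, all F are taken as 0 (classical
#'   Henderson rules without inbreeding). Default `TRUE`, which makes the
#'   result the exact inverse of [build_A()] on any pedigree.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with attribute
#'   `"F"` holding the inbreeding coefficients.
#' @export
build_A_inverse <- function(ped, use_inbreeding = TRUE) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  pi <- ped_index(ped)
  F <- if (use_inbreeding) meuwissen_luo_f(pi$si, pi$di, n) else numeric(n)
  Fs <- ifelse(pi$si > 0L, F[pmax(pi$si, 1L)], -1)
  Fd <- ifelse(pi$di > 0L, F[pmax(pi$di, 1L)], -1)
  dinv <- 1 / (0.5 - 0.25 * (Fs + Fd))

  ii <- jj <- integer(0); xx <- numeric(0)
  anim <- seq_len(n)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  add(anim, anim, dinv)
  hs <- pi$si > 0L
  hd <- pi$di > 0L
  add(anim[hs], pi$si[hs], -0.5 * dinv[hs])
  add(pi$si[hs], anim[hs], -0.5 * dinv[hs])
  add(anim[hd], pi$di[hd], -0.5 * dinv[hd])
  add(pi$di[hd], anim[hd], -0.5 * dinv[hd])
  add(pi$si[hs], pi$si[hs], 0.25 * dinv[hs])
  add(pi$di[hd], pi$di[hd], 0.25 * dinv[hd])
  both <- hs & hd
  add(pi$si[both], pi$di[both], 0.25 * dinv[both])
  add(pi$di[both], pi$si[both], 0.25 * dinv[both])

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- methods::as(Matrix::forceSymmetric(Ainv), "symmetricMatrix")
  attr(Ainv, "F") <- F
  Ainv
}

#' Read / write pedigree CSV
#'
#' Comma-separated with header `animal,sire,dam,birth_year`; unknown parents
#' coded 0 or empty. [read_pedigree()] validates and topologically orders the
#' animals via [as_pedigree()].
#'
#' @param path File path.
#' @return [read_pedigree()]: an ordered pedigree tibble.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_csv(
    path,
    col_types = readr::cols(
      animal = readr::col_integer(),
      sire = readr::col_integer(),
      dam = readr::col_integer(),
      birth_year = readr::col_integer()
    ),
    na = c("", "NA")
  )
  as_pedigree(ped)
}

#' @param ped Pedigree tibble.
#' @rdname read_pedigree
#' @return [write_pedigree()]: `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  readr::write_csv(ped[, c("animal", "sire", "dam", "birth_year")], path,
                   na = "")
  invisible(path)
}
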