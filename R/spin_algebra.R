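# Determinant expansions of HLSP structures, structure overlaps, Gramian
# linear-independence tests, branching-diagram counts, and Chirgwin-Coulson
# weights.

#' Expand a structure over spin-orbital determinants
#'
#' Each singlet-coupled pair \eqn{(a,b)} contributes a factor
#' \eqn{\alpha_a\beta_b - \beta_a\alpha_b}; every unpaired orbital is assigned
#' \eqn{\alpha} (the highest-projection \eqn{M_S = S} component); doubly
#' occupied orbitals contribute a fixed \eqn{\alpha\beta} factor and do not
#' enter the expansion keys.  The expansion of a structure with \eqn{p}
#' pairs therefore has \eqn{2^p} terms with coefficients \eqn{\pm 1}.
#'
#' Sign convention: determinant keys list the singly occupied orbitals in the
#' (ascending, unless overridden) global orbital order, and pair factors are
#' multiplied in ascending order of their smaller index.  Any consistent
#' convention changes at most the overall sign of a vector, never overlaps'
#' magnitudes or independence verdicts.
#'
#' @param structure a \code{\link{vb_structure}}.
#' @param orbital_order optional permutation of the singly occupied orbitals
#'   fixing the determinant key order.
#' @return object of class \code{vb_expansion}: fields \code{orbitals},
#'   \code{keys} (strings of \code{"a"}/\code{"b"} per orbital), \code{coef}
#'   (signed integers), \code{norm}.
#' @examples
#' expand_structure(vb_structure(pairs = "1-2"))
#' @export
expand_structure <- function(structure, orbital_order = NULL) {
  singles <- singly_occupied(structure)
  if (is.null(orbital_order)) orbital_order <- singles
  orbital_order <- as.integer(orbital_order)
  if (!identical(sort(orbital_order), singles))
    stop("orbital_order must be a permutation of the singly occupied orbitals")
  pos <- stats::setNames(seq_along(orbital_order), orbital_order)

  base <- rep(NA_character_, length(orbital_order))
  base[pos[as.character(structure$unpaired)]] <- "a"

  assigns <- list(list(spins = base, coef = 1L))
  pr <- structure$pairs
  if (nrow(pr) > 0L) {
    for (k in seq_len(nrow(pr))) {  # rows already ascend by smaller index
      i <- pos[as.character(pr[k, 1L])]
      j <- pos[as.character(pr[k, 2L])]
      nxt <- vector("list", 2L * length(assigns))
      m <- 0L
      for (a in assigns) {
        s1 <- a$spins; s1[i] <- "a"; s1[j] <- "b"
        s2 <- a$spins; s2[i] <- "b"; s2[j] <- "a"
        nxt[[m + 1L]] <- list(spins = s1, coef = a$coef)
        nxt[[m + 2L]] <- list(spins = s2, coef = -a$coef)
        m <- m + 2L
      }
      assigns <- nxt
    }
  }
  keys <- vapply(assigns, function(a) paste(a$spins, collapse = ""), character(1))
  coef <- vapply(assigns, function(a) a$coef, integer(1))
  o <- order(keys, method = "radix")
  structure(list(orbitals = orbital_order, keys = keys[o], coef = coef[o],
                 norm = sqrt(2^nrow(pr))),
            class = "vb_expansion")
}

#' @export
print.vb_expansion <- function(x, ...) {
  cat(sprintf("Expansion over orbitals (%s), %d determinants:\n",
              paste(x$orbitals, collapse = ","), length(x$keys)))
  cat(paste(sprintf("%+d |%s>", x$coef, x$keys), collapse = "  "), "\n")
  invisible(x)
}

#' Inner product of two structure expansions
#'
#' Sum over shared spin assignments of coefficient products.  Expansions must
#' live over the same singly occupied orbital set at the same \eqn{M_S}.
#'
#' @param e1,e2 \code{vb_expansion} objects (a \code{vb_structure} is expanded
#'   on the fly).
#' @param normalize divide by the product of norms so a structure's overlap
#'   with itself is 1 (default) rather than the raw \eqn{\pm1}-count.
#' @return a real number.
#' @examples
#' s1 <- vb_structure(pairs = list(c(1, 2), c(3, 4)))
#' s2 <- vb_structure(pairs = list(c(1, 4), c(2, 3)))
#' structure_overlap(s1, s2)  # -1/2
#' @export
structure_overlap <- function(e1, e2, normalize = TRUE) {
  if (inherits(e1, "vb_structure")) e1 <- expand_structure(e1)
  if (inherits(e2, "vb_structure")) e2 <- expand_structure(e2)
  if (!identical(sort(e1$orbitals), sort(e2$orbitals)))
    stop("expansions are over different singly occupied orbital sets")
  if (!identical(e1$orbitals, e2$orbitals))
    e2 <- reorder_expansion(e2, e1$orbitals)
  m <- match(e1$keys, e2$keys)
  hit <- !is.na(m)
  raw <- sum(e1$coef[hit] * e2$coef[m[hit]])
  if (normalize) raw / (e1$norm * e2$norm) else raw
}

# re-express an expansion's keys in a different orbital order
reorder_expansion <- function(e, new_order) {
  perm <- match(new_order, e$orbitals)
  keys <- vapply(strsplit(e$keys, ""), function(ch) paste(ch[perm], collapse = ""),
                 character(1))
  o <- order(keys, method = "radix")
  structure(list(orbitals = as.integer(new_order), keys = keys[o],
                 coef = e$coef[o], norm = e$norm),
            class = "vb_expansion")
}

# structures -> matrix of unit-normalized determinant coefficient vectors
# (rows = structures, columns = union of determinant keys)
expansion_matrix <- function(structures, normalize = TRUE) {
  exps <- lapply(structures, function(s)
    if (inherits(s, "vb_expansion")) s else expand_structure(s))
  ref <- exps[[1L]]$orbitals
  exps <- lapply(exps, function(e)
    if (identical(e$orbitals, ref)) e else reorder_expansion(e, ref))
  keys <- sort(unique(unlist(lapply(exps, `[[`, "keys"))))
  M <- matrix(0, nrow = length(exps), ncol = length(keys))
  for (i in seq_along(exps)) {
    e <- exps[[i]]
    M[i, match(e$keys, keys)] <- if (normalize) e$coef / e$norm else e$coef
  }
  M
}

#' Gramian independence test for a set of structures
#'
#' Builds the overlap (Gram) matrix of the unit-normalized determinant
#' vectors of the given structures and diagonalizes it; the set is declared
#' linearly independent when every eigenvalue's absolute value exceeds the
#' threshold (default \code{1e-11}).
#'
#' @param structures nonempty list of \code{\link{vb_structure}} objects, all
#'   from one lone-pair/vacant subspace.
#' @param threshold eigenvalue magnitude below which the Gramian counts as
#'   singular.
#' @return object of class \code{vb_gramian_report} with fields
#'   \code{matrix}, \code{eigenvalues}, \code{min_abs_eigenvalue},
#'   \code{independent}, \code{threshold}.
#' @examples
#' s1 <- vb_structure(pairs = list(c(1, 2), c(3, 4)))
#' s2 <- vb_structure(pairs = list(c(1, 4), c(2, 3)))
#' gramian(list(s1, s2))$independent  # TRUE
#' @export
gramian <- function(structures, threshold = 1e-11) {
  if (length(structures) == 0L) stop("need at least one structure")
  subs <- vapply(structures, function(s) subspace_key_string(subspace_of(s)),
                 character(1))
  if (length(unique(subs)) > 1L)
    stop("structures come from different subspaces; their determinant bases differ")
  M <- expansion_matrix(structures)
  G <- M %*% t(M)
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  mae <- min(abs(ev))
  structure(list(matrix = G, eigenvalues = ev, min_abs_eigenvalue = mae,
                 independent = mae > threshold, threshold = threshold),
            class = "vb_gramian_report")
}

#' @export
print.vb_gramian_report <- function(x, ...) {
  cat(sprintf("Gramian %dx%d: min |eigenvalue| = %.3e (threshold %.1e) -> %s\n",
              nrow(x$matrix), ncol(x$matrix), x$min_abs_eigenvalue, x$threshold,
              if (x$independent) "independent" else "DEPENDENT"))
  invisible(x)
}

#' Number of linearly independent spin structures
#'
#' The branching-diagram count for \eqn{N} singly occupied orbitals at total
#' spin \eqn{S}:
#' \deqn{N_{IS} = \binom{N}{N/2-S} - \binom{N}{N/2-S-1}.}
#' For spaces with \eqn{n > N} orbitals multiply by \eqn{\binom{n}{n-N}}, the
#' number of lone-pair/vacant placements, or sum over subspaces.
#'
#' @param N number of singly occupied orbitals.
#' @param S total spin (half-integer), \eqn{N \ge 2S}, matching parity.
#' @return a count.
#' @examples
#' count_independent(5, 1/2)  # 5
#' count_independent(8, 0)    # 14
#' @export
count_independent <- function(N, S) {
  N <- as.integer(N)
  two_s <- as.integer(round(2 * S))
  if (abs(2 * S - two_s) > 1e-9 || two_s < 0) stop("S must be a non-negative half-integer")
  if (N < two_s) stop("N must be at least 2S")
  if ((N - two_s) %% 2L != 0L)
    stop(sprintf("N = %d and 2S = %d have different parity", N, two_s))
  p <- (N - two_s) %/% 2L
  choose(N, p) - choose(N, p - 1L)
}

#' Chirgwin-Coulson structure weights
#'
#' \deqn{W_i = c_i \sum_j c_j S_{ij} \,/\, c^T S c,}
#' the standard population-style weight of structure \eqn{i} in a
#' non-orthogonal expansion with coefficients \eqn{c} and structure overlap
#' matrix \eqn{S}.  Weights sum to 1; individual weights can be negative
#' (the familiar "unphysical negative weight" diagnostic).
#'
#' @param coefficients numeric vector \eqn{c}.
#' @param overlaps symmetric numeric matrix with unit diagonal.
#' @return numeric vector of weights summing to 1.
#' @examples
#' chirgwin_coulson_weights(c(0.6, 0.8), diag(2))  # 0.36 0.64
#' @export
chirgwin_coulson_weights <- function(coefficients, overlaps) {
  c_ <- as.numeric(coefficients)
  S <- as.matrix(overlaps)
  if (length(c_) != nrow(S) || nrow(S) != ncol(S))
    stop("dimension mismatch between coefficients and overlap matrix")
  if (max(abs(S - t(S))) > 1e-8) stop("overlap matrix must be symmetric")
  if (max(abs(diag(S) - 1)) > 1e-8) stop("overlap matrix must have unit diagonal")
  norm2 <- drop(crossprod(c_, S %*% c_))
  if (norm2 <= 0) stop("c'Sc <= 0: coefficients/overlaps do not describe a normalizable state")
  drop(c_ * (S %*% c_)) / norm2
}
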