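# Rumer pictorial rules: non-crossing spin pairings on a circle with dummy
# centers for unpaired electrons, plus the combinatorics of distinct Rumer
# sets over orbital orderings.

#' Circle ordering for the Rumer construction
#'
#' The singly occupied orbitals of a subspace are placed on an imaginary
#' circle in the given cyclic order; one dummy center per unpaired electron
#' is appended after the last real orbital (dummy-dummy bonds are forbidden).
#' Lone-pair/vacant orbitals never enter the circle.
#'
#' @param cycle permutation of the singly occupied orbital indices, in circle
#'   order.
#' @param dummy_count number of dummy centers (defaults to the structure's
#'   radical count when the ordering is applied).
#' @return object of class \code{vb_rumer_ordering}.
#' @export
rumer_ordering <- function(cycle, dummy_count = NULL) {
  cycle <- as.integer(cycle)
  if (anyDuplicated(cycle)) stop("cycle must not repeat orbitals")
  structure(list(cycle = cycle, dummy_count = dummy_count),
            class = "vb_rumer_ordering")
}

# do chords (a,b) and (c,d) on a circle of L positions interleave?
chords_cross <- function(a, b, c, d, L) {
  arc <- function(x) {
    # is position x strictly inside the arc a -> b (clockwise)?
    ((x - a) %% L) < ((b - a) %% L) && x != a
  }
  xor(arc(c), arc(d))
}

# all permutations of 1..n as an n! x n integer matrix, lexicographic
perms <- function(n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  if (n == 1L) return(matrix(1L))
  sub <- perms(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- seq_len(n)[-first]
    block <- cbind(first, matrix(rest[sub], nrow = nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Does a structure obey the Rumer non-crossing rule under an ordering?
#'
#' Real bonds are chords between circle positions; each radical is joined to
#' a dummy center.  The structure is allowed when some assignment of radicals
#' to dummy centers leaves no two chords crossing (for a single radical the
#' assignment is unique; dummy centers are interchangeable placeholders).
#'
#' @param structure a \code{\link{vb_structure}}.
#' @param ordering a \code{\link{rumer_ordering}} over the structure's singly
#'   occupied orbitals.
#' @return logical.
#' @examples
#' ord <- rumer_ordering(1:4)
#' is_noncrossing(vb_structure(pairs = list(c(1, 2), c(3, 4))), ord)  # TRUE
#' is_noncrossing(vb_structure(pairs = list(c(1, 3), c(2, 4))), ord)  # FALSE
#' @export
is_noncrossing <- function(structure, ordering) {
  cyc <- ordering$cycle
  singles <- singly_occupied(structure)
  if (!identical(sort(cyc), singles))
    stop("ordering cycle does not match the structure's singly occupied orbitals")
  k <- length(structure$unpaired)
  dummies <- ordering$dummy_count
  if (is.null(dummies)) dummies <- k
  if (dummies < k) stop("fewer dummy centers than unpaired electrons")
  N <- length(cyc)
  L <- N + dummies
  pos <- stats::setNames(seq_len(N), cyc)

  bond_chords <- if (nrow(structure$pairs) > 0L)
    cbind(pos[as.character(structure$pairs[, 1L])],
          pos[as.character(structure$pairs[, 2L])]) else
    matrix(integer(0), ncol = 2L)

  rad_pos <- unname(pos[as.character(structure$unpaired)])
  assignments <- if (k == 0L) list(integer(0)) else {
    pm <- perms(k)
    lapply(seq_len(nrow(pm)), function(i) N + pm[i, ])
  }
  for (dpos in assignments) {
    chords <- rbind(bond_chords,
                    if (k > 0L) cbind(rad_pos, dpos) else NULL)
    ok <- TRUE
    nc <- nrow(chords)
    if (nc >= 2L) {
      for (i in seq_len(nc - 1L)) {
        for (j in (i + 1L):nc) {
          if (chords_cross(chords[i, 1L], chords[i, 2L],
                           chords[j, 1L], chords[j, 2L], L)) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Generate the Rumer set of a subspace for a given ordering
#'
#' Filters the exhaustive enumeration of the subspace down to the structures
#' allowed by the non-crossing rule.  The result always has exactly
#' \code{count_independent(N, S)} members and passes the Gramian test --
#' the defining property of a Rumer set.
#'
#' @param space an \code{\link{active_space}}.
#' @param ordering a \code{\link{rumer_ordering}}; defaults to the ascending
#'   sequential ordering of the subspace's singly occupied orbitals.
#' @param subspace a \code{\link{vb_subspace}} (default: the all-singly-occupied
#'   covalent block).
#' @return a \code{\link{structure_set}} with provenance \code{"rumer"}.
#' @export
generate_rumer_set <- function(space, ordering = NULL, subspace = vb_subspace()) {
  singles <- subspace_singles(space, subspace)
  if (is.null(ordering)) ordering <- rumer_ordering(singles)
  if (!identical(sort(ordering$cycle), singles))
    stop("ordering cycle must be a permutation of the subspace's singly occupied orbitals")
  cands <- enumerate_structures(space, subspace = subspace)
  keep <- vapply(cands, is_noncrossing, logical(1), ordering = ordering)
  sel <- cands[keep]
  two_s <- as.integer(round(2 * space$spin))
  nis <- count_independent(length(singles), space$spin)
  if (length(sel) != nis)
    stop(sprintf("internal error: Rumer filter yielded %d structures, expected %d",
                 length(sel), nis))
  structure_set(sel, subspace = subspace,
                provenance = rep("rumer", length(sel)),
                gramian = gramian(sel))
}

#' Number of distinct bonds appearing across a structure set
#'
#' Counts the distinct unordered real-orbital pairs occurring as singlet
#' bonds anywhere in the set (radical/dummy attachments are not bonds).
#'
#' @param set a \code{\link{structure_set}} or plain list of structures.
#' @return a count.
#' @export
count_distinct_bonds <- function(set) {
  structures <- if (inherits(set, "vb_structure_set")) set$structures else set
  if (length(structures) == 0L) stop("empty structure set")
  bonds <- do.call(rbind, lapply(structures, `[[`, "pairs"))
  if (is.null(bonds) || nrow(bonds) == 0L) return(0L)
  nrow(unique(bonds))
}

#' Closed-form count of distinct Rumer sets
#'
#' For \eqn{N} singly occupied orbitals the \eqn{N!} orderings collapse to
#' \eqn{N!/(2r)} distinct Rumer sets, where \eqn{r} is the rotation order of
#' the principal axis of the Rumer cycle for even \eqn{N} (\eqn{r = N} for a
#' plain cycle) and \eqn{r = 1} for odd \eqn{N}.  Multiply by
#' \eqn{\binom{n}{n-N}} when lone pairs/vacancies are present.  The value is
#' clamped below at 1 (the \eqn{N = 2} cycle is fully degenerate).
#'
#' @param N number of singly occupied orbitals on the circle.
#' @param r rotation order of the cycle's principal axis.
#' @return a count.
#' @examples
#' count_rumer_sets(8, r = 8)  # 2520
#' @export
count_rumer_sets <- function(N, r) {
  N <- as.integer(N)
  if (N < 2L) stop("need at least two orbitals on the circle")
  if (r < 1L) stop("rotation order r must be >= 1")
  max(1, factorial(N) / (2 * r))
}

# ---- distinct-set enumeration ----------------------------------------------

# position-level Rumer templates: all structures on circle positions
# 1..N (with two_s radicals) allowed under the identity sequential ordering.
rumer_templates <- function(N, two_s) {
  pseudo <- active_space(N, n_electrons = N, spin = two_s / 2)
  ord <- rumer_ordering(seq_len(N))
  cands <- enumerate_structures(pseudo, subspace = vb_subspace())
  keep <- vapply(cands, is_noncrossing, logical(1), ordering = ord)
  cands[keep]
}

# partner-slot code for one template under all permutations at once.
# P: n! x N matrix of slot permutations (slot at position i); returns a
# character vector of length n!: partner slot per orbital slot, "." separated,
# 0 marking radicals.
template_codes <- function(template, P) {
  R <- nrow(P)
  N <- ncol(P)
  M <- matrix(0L, nrow = R, ncol = N)
  pr <- template$pairs  # position pairs
  if (nrow(pr) > 0L) {
    for (k in seq_len(nrow(pr))) {
      a <- P[, pr[k, 1L]]
      b <- P[, pr[k, 2L]]
      M[cbind(seq_len(R), a)] <- b
      M[cbind(seq_len(R), b)] <- a
    }
  }
  do.call(paste, c(as.data.frame(M), list(sep = ".")))
}

decode_code <- function(code, singles, subspace) {
  q <- as.integer(strsplit(code, ".", fixed = TRUE)[[1L]])
  pairs <- list()
  unpaired <- integer(0)
  for (i in seq_along(q)) {
    if (q[i] == 0L) unpaired <- c(unpaired, singles[i])
    else if (q[i] > i) pairs[[length(pairs) + 1L]] <- c(singles[i], singles[q[i]])
  }
  vb_structure(pairs = pairs, unpaired = unpaired,
               doubly_occupied = subspace$doubly_occupied,
               vacant = subspace$vacant)
}

#' Enumerate every distinct Rumer set of a subspace
#'
#' Runs the Rumer construction over all \eqn{N!} circle orderings of the
#' subspace's singly occupied orbitals and deduplicates by set identity
#' (orderings related by rotation or reflection collapse automatically).
#' The resulting count equals \code{count_rumer_sets(N, r)} with the cycle's
#' rotation order \eqn{r}; the closed form is thereby a test oracle, not the
#' implementation.
#'
#' @param space an \code{\link{active_space}}.
#' @param subspace a \code{\link{vb_subspace}} (default covalent block).
#' @param max_n guard: refuse \eqn{N!} enumeration beyond this many orbitals.
#' @return list of \code{\link{structure_set}} objects (Gramian not
#'   precomputed), in a deterministic order.
#' @examples
#' sp <- active_space(4, 4, spin = 0)
#' length(enumerate_distinct_rumer_sets(sp))  # 3
#' @export
enumerate_distinct_rumer_sets <- function(space, subspace = vb_subspace(),
                                          max_n = 10L) {
  singles <- subspace_singles(space, subspace)
  N <- length(singles)
  if (N > max_n)
    stop(sprintf("N = %d orderings (%s) are infeasible to enumerate; consider sampling orderings instead",
                 N, format(factorial(N), big.mark = ",")))
  two_s <- as.integer(round(2 * space$spin))
  templates <- rumer_templates(N, two_s)
  P <- perms(N)
  codes <- vapply(templates, template_codes, character(nrow(P)), P = P)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(P))
  keys <- vapply(seq_len(nrow(codes)), function(r)
    paste(sort.int(codes[r, ], method = "radix"), collapse = "|"), character(1))
  first <- !duplicated(keys)
  o <- order(keys[first], method = "radix")
  rows <- which(first)[o]
  lapply(rows, function(r) {
    sts <- lapply(sort.int(codes[r, ], method = "radix"), decode_code,
                  singles = singles, subspace = subspace)
    structure_set(sts, subspace = subspace,
                  provenance = rep("rumer", length(sts)))
  })
}

#' Does a structure set contain a given structure?
#' @param set a \code{\link{structure_set}}.
#' @param structure a \code{\link{vb_structure}}.
#' @return logical.
#' @export
set_contains <- function(set, structure) {
  key <- structure_key(structure)
  any(vapply(set$structures, function(s) structure_key(s) == key, logical(1)))
}
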