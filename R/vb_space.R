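# Active-space definition and exhaustive enumeration of HLSP (covalent-type
# spin-paired) valence bond structures, grouped into lone-pair/vacant
# subspaces.

#' Define a valence bond active space
#'
#' An active space is the \eqn{n}-orbital / \eqn{N_e}-electron / spin-\eqn{S}
#' problem a VB wavefunction is built in.  Each active orbital carries an
#' atom (or fragment) assignment used by the intra-atomic-bond criterion and
#' the bond-length criterion, and optionally a symmetry label (e.g.
#' \code{"sigma"}, \code{"pi"}) used by the symmetry criterion.
#'
#' @param orbitals either a single integer \eqn{n} (orbitals are then labelled
#'   \code{1..n}, each on its own pseudo-atom \code{a1..an}) or a data frame
#'   with columns \code{index} (distinct positive integers), \code{atom}
#'   (non-empty character) and optionally \code{symmetry}.
#' @param n_electrons number of active electrons, \eqn{0 \le N_e \le 2n}.
#' @param spin total spin \eqn{S}, a non-negative half-integer (e.g. 0, 0.5, 1).
#' @return an object of class \code{vb_active_space}.
#' @examples
#' sp <- active_space(5, n_electrons = 5, spin = 1/2)
#' count_total_structures(sp)
#' @export
active_space <- function(orbitals, n_electrons, spin) {
  if (is.numeric(orbitals) && length(orbitals) == 1L) {
    n <- as.integer(orbitals)
    orbitals <- data.frame(index = seq_len(n),
                           atom = paste0("a", seq_len(n)),
                           symmetry = NA_character_,
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(orbitals))
  if (!all(c("index", "atom") %in% names(orbitals)))
    stop("orbitals data frame needs columns 'index' and 'atom'")
  if (!"symmetry" %in% names(orbitals)) orbitals$symmetry <- NA_character_
  orbitals$index <- as.integer(orbitals$index)
  orbitals$atom <- as.character(orbitals$atom)
  if (anyDuplicated(orbitals$index))
    stop("orbital indices must be unique")
  if (any(orbitals$index < 1L))
    stop("orbital indices must be positive")
  if (any(!nzchar(orbitals$atom)) || anyNA(orbitals$atom))
    stop("every orbital needs a non-empty atom id")
  orbitals <- orbitals[order(orbitals$index), , drop = FALSE]
  rownames(orbitals) <- NULL

  n <- nrow(orbitals)
  n_electrons <- as.integer(n_electrons)
  spin <- as.numeric(spin)
  if (abs(2 * spin - round(2 * spin)) > 1e-9 || spin < 0)
    stop("spin must be a non-negative half-integer")
  if (n_electrons < 0L || n_electrons > 2L * n)
    stop("n_electrons must lie in [0, 2n]")
  sp <- structure(list(orbitals = orbitals, n_electrons = n_electrons,
                       spin = spin),
                  class = "vb_active_space")
  if (length(valid_double_counts(sp)) == 0L)
    stop("empty space: no occupancy pattern satisfies N >= 2S with matching parity")
  sp
}

#' @export
print.vb_active_space <- function(x, ...) {
  cat(sprintf("Active space: %de/%do, S = %s\n", x$n_electrons,
              nrow(x$orbitals), format(x$spin)))
  cat("Orbitals:\n")
  print(x$orbitals, row.names = FALSE)
  invisible(x)
}

# numbers d of doubly occupied orbitals compatible with the space:
# N = n_electrons - 2d singly occupied, need N >= 2S, N + v + d = n with
# v >= 0, and N == 2S (mod 2).
valid_double_counts <- function(space) {
  n <- nrow(space$orbitals)
  two_s <- as.integer(round(2 * space$spin))
  out <- integer(0)
  for (d in 0:(space$n_electrons %/% 2L)) {
    N <- space$n_electrons - 2L * d
    v <- n - d - N
    if (N < two_s || v < 0L) next
    if ((N - two_s) %% 2L != 0L) next
    out <- c(out, d)
  }
  out
}

# ---- structures -------------------------------------------------------------

# canonical pair container: 2-column integer matrix, each row (a, b) with
# a < b, rows ordered by a then b.  Accepts a list of length-2 vectors,
# a 2-column matrix, or strings like "1-2".
as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || (is.list(pairs) && length(pairs) == 0L))
    return(matrix(integer(0), ncol = 2L))
  if (is.character(pairs))
    pairs <- lapply(strsplit(pairs, "[-–]"), as.integer)
  if (is.list(pairs)) {
    if (!all(lengths(pairs) == 2L)) stop("each bond must reference two orbitals")
    pairs <- do.call(rbind, lapply(pairs, as.integer))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  if (any(pairs[, 1L] == pairs[, 2L])) stop("a bond cannot pair an orbital with itself")
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' Construct a single VB structure
#'
#' A structure assigns every orbital of its space one of four roles: doubly
#' occupied (lone pair), vacant, member of a singlet-coupled pair (bond), or
#' singly occupied by an unpaired electron (radical).
#'
#' @param pairs singlet-coupled bonds: a list of length-2 integer vectors,
#'   a 2-column matrix, or strings like \code{"1-2"}.
#' @param unpaired orbital indices carrying unpaired (radical) electrons.
#' @param doubly_occupied orbital indices holding lone pairs.
#' @param vacant vacant orbital indices.
#' @return an object of class \code{vb_structure}.
#' @examples
#' vb_structure(pairs = list(c(1, 2), c(3, 4)))
#' vb_structure(pairs = "1-2", unpaired = 3)
#' @export
vb_structure <- function(pairs = list(), unpaired = integer(),
                         doubly_occupied = integer(), vacant = integer()) {
  pr <- as_pair_matrix(pairs)
  unpaired <- sort(as.integer(unpaired))
  doubly_occupied <- sort(as.integer(doubly_occupied))
  vacant <- sort(as.integer(vacant))
  all_idx <- c(as.vector(pr), unpaired, doubly_occupied, vacant)
  if (anyDuplicated(all_idx)) {
    dup <- all_idx[duplicated(all_idx)][1L]
    stop(sprintf("orbital %d is used more than once", dup))
  }
  structure(list(doubly_occupied = doubly_occupied, vacant = vacant,
                 pairs = pr, unpaired = unpaired),
            class = "vb_structure")
}

#' @export
print.vb_structure <- function(x, ...) {
  cat(write_structure_notation(x), "\n")
  invisible(x)
}

#' Singly occupied orbitals of a structure
#'
#' @param structure a \code{vb_structure}.
#' @return sorted integer vector of the orbitals engaged in bonds or radicals.
#' @export
singly_occupied <- function(structure) {
  sort(c(as.vector(structure$pairs), structure$unpaired))
}

# canonical text key; also the deduplication identity
structure_key <- function(s) {
  paste0("D{", paste(s$doubly_occupied, collapse = ","),
         "}V{", paste(s$vacant, collapse = ","),
         "}P{", paste(paste0(s$pairs[, 1L], "-", s$pairs[, 2L]), collapse = ","),
         "}R{", paste(s$unpaired, collapse = ","), "}")
}

#' Test two structures for identity
#' @param a,b \code{vb_structure} objects.
#' @return logical.
#' @export
same_structure <- function(a, b) structure_key(a) == structure_key(b)

# ---- subspaces --------------------------------------------------------------

#' Lone-pair/vacant subspace key
#'
#' Structures sharing one placement of doubly occupied and vacant orbitals
#' form a linearly independent block; ranking and selection operate per block.
#'
#' @param doubly_occupied,vacant orbital index sets.
#' @return an object of class \code{vb_subspace}.
#' @export
vb_subspace <- function(doubly_occupied = integer(), vacant = integer()) {
  structure(list(doubly_occupied = sort(as.integer(doubly_occupied)),
                 vacant = sort(as.integer(vacant))),
            class = "vb_subspace")
}

#' @rdname vb_subspace
#' @param structure a \code{vb_structure} whose subspace is wanted.
#' @export
subspace_of <- function(structure) {
  vb_subspace(structure$doubly_occupied, structure$vacant)
}

subspace_key_string <- function(sub) {
  paste0("D{", paste(sub$doubly_occupied, collapse = ","),
         "}V{", paste(sub$vacant, collapse = ","), "}")
}

#' @export
print.vb_subspace <- function(x, ...) {
  cat("Subspace", subspace_key_string(x), "\n")
  invisible(x)
}

# singly occupied orbitals of a subspace within a space
subspace_singles <- function(space, subspace) {
  idx <- space$orbitals$index
  bad <- setdiff(c(subspace$doubly_occupied, subspace$vacant), idx)
  if (length(bad))
    stop(sprintf("subspace references orbital %d which is not in the space", bad[1L]))
  if (length(intersect(subspace$doubly_occupied, subspace$vacant)))
    stop("subspace lists an orbital as both doubly occupied and vacant")
  singles <- setdiff(idx, c(subspace$doubly_occupied, subspace$vacant))
  N <- space$n_electrons - 2L * length(subspace$doubly_occupied)
  if (N != length(singles))
    stop(sprintf("subspace inconsistent with electron count: %d singly occupied orbitals but N = %d",
                 length(singles), N))
  two_s <- as.integer(round(2 * space$spin))
  if (N < two_s || (N - two_s) %% 2L != 0L)
    stop("subspace incompatible with the total spin")
  sort(singles)
}

# ---- counting ---------------------------------------------------------------

# number of ways to spin-couple N singly occupied orbitals at spin S:
# choose the 2S radicals, perfect-pair the rest
pairing_count <- function(N, two_s) {
  p <- (N - two_s) %/% 2L
  factorial(N) / (2^p * factorial(p) * factorial(two_s))
}

#' Total number of HLSP structures of an active space
#'
#' Counts, in closed form, every structure the space admits: for each valid
#' number \eqn{d} of lone pairs it multiplies the number of placements of the
#' \eqn{d} lone pairs and \eqn{v} vacant orbitals by the number of distinct
#' spin couplings \eqn{N!/(2^{N/2-S} (N/2-S)!\,(2S)!)} of the \eqn{N}
#' remaining singly occupied orbitals.  The result equals
#' \code{length(enumerate_structures(space))}.
#'
#' @param space an \code{\link{active_space}}; alternatively pass \code{n},
#'   \code{n_electrons} and \code{spin} directly.
#' @param n,n_electrons,spin used when \code{space} is missing.
#' @param d restrict to a single number of doubly occupied orbitals
#'   (\code{NULL} = sum over all valid values).
#' @return a count.
#' @examples
#' count_total_structures(n = 5, n_electrons = 5, spin = 1/2)  # 15
#' @export
count_total_structures <- function(space = NULL, n = NULL, n_electrons = NULL,
                                   spin = NULL, d = NULL) {
  if (is.null(space)) space <- active_space(n, n_electrons, spin)
  nn <- nrow(space$orbitals)
  two_s <- as.integer(round(2 * space$spin))
  ds <- valid_double_counts(space)
  if (!is.null(d)) {
    if (!d %in% ds) stop(sprintf("d = %d is not a valid lone-pair count for this space", d))
    ds <- as.integer(d)
  }
  total <- 0
  for (dd in ds) {
    N <- space$n_electrons - 2L * dd
    v <- nn - dd - N
    total <- total + choose(nn, dd) * choose(nn - dd, v) * pairing_count(N, two_s)
  }
  total
}

# combn that never interprets a length-1 vector as 1:n
combn_sets <- function(x, k) {
  if (k == 0L) return(list(integer(0)))
  if (length(x) < k) return(list())
  if (length(x) == 1L) return(list(as.integer(x)))
  asplit(utils::combn(x, k), 2L)
}

# all perfect pairings of a sorted index vector, as a list of 2-col matrices;
# deterministic recursive order (first element paired with each partner)
all_pairings <- function(v) {
  if (length(v) == 0L) return(list(matrix(integer(0), ncol = 2L)))
  a <- v[1L]
  out <- list()
  for (j in seq_along(v)[-1L]) {
    rest <- v[-c(1L, j)]
    for (sub in all_pairings(rest))
      out[[length(out) + 1L]] <- rbind(c(a, v[j]), sub)
  }
  out
}

#' Enumerate all HLSP structures of a space
#'
#' Exhaustively generates every structure, optionally restricted to one
#' lone-pair/vacant subspace or one lone-pair count \code{d}.  Output order is
#' canonical (sorted by subspace key, then bond list, then radical list) and
#' therefore reproducible.
#'
#' @param space an \code{\link{active_space}}.
#' @param subspace optional \code{\link{vb_subspace}} restriction.
#' @param d optional lone-pair count restriction.
#' @return list of \code{\link{vb_structure}} objects.
#' @examples
#' sp <- active_space(4, 4, spin = 0)
#' length(enumerate_structures(sp))  # 3 covalent pairings + ionic blocks
#' @export
enumerate_structures <- function(space, subspace = NULL, d = NULL) {
  nn <- nrow(space$orbitals)
  idx <- space$orbitals$index
  two_s <- as.integer(round(2 * space$spin))

  blocks <- list()  # list of (doubly, vacant)
  if (!is.null(subspace)) {
    subspace_singles(space, subspace)  # validates
    blocks[[1L]] <- subspace
  } else {
    ds <- valid_double_counts(space)
    if (!is.null(d)) {
      if (!d %in% ds) stop(sprintf("d = %d is not valid for this space", d))
      ds <- as.integer(d)
    }
    for (dd in ds) {
      N <- space$n_electrons - 2L * dd
      v <- nn - dd - N
      for (docc in combn_sets(idx, dd)) {
        remaining <- setdiff(idx, docc)
        for (vac in combn_sets(remaining, v))
          blocks[[length(blocks) + 1L]] <- vb_subspace(docc, vac)
      }
    }
  }

  out <- list()
  for (sub in blocks) {
    singles <- subspace_singles(space, sub)
    N <- length(singles)
    for (rads in combn_sets(singles, two_s)) {
      paired <- setdiff(singles, rads)
      for (pr in all_pairings(paired)) {
        out[[length(out) + 1L]] <- vb_structure(
          pairs = pr, unpaired = rads,
          doubly_occupied = sub$doubly_occupied, vacant = sub$vacant)
      }
    }
  }
  keys <- vapply(out, structure_key, character(1))
  if (anyDuplicated(keys)) stop("internal error: duplicate structures enumerated")
  out[order(keys, method = "radix")]
}

#' Group structures by lone-pair/vacant subspace
#'
#' @param structures list of \code{\link{vb_structure}} objects from one space.
#' @return named list mapping subspace key strings to structure lists;
#'   within-group order is preserved.
#' @export
group_by_subspace <- function(structures) {
  if (length(structures) == 0L) return(structure(list(), names = character(0)))
  keys <- vapply(structures, function(s) subspace_key_string(subspace_of(s)),
                 character(1))
  out <- split(structures, factor(keys, levels = unique(keys)))
  out
}
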