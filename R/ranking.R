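# Chemical-insight scoring of VB structures: five criteria (user bonds,
# user radicals, intra-atomic bonds, bond length, orbital symmetry) merged
# lexicographically into one quality score.  Rank 1 is best throughout.

CRITERIA <- c("user_bonds", "user_radicals", "intra_atomic", "bond_length",
              "symmetry")

#' Ranking criteria configuration
#'
#' Holds the user-defined bonds (UDB), user-defined radicals (UDR) and the
#' priority order in which the per-criterion scores are merged.  Criteria
#' absent from the priority order are never computed.
#'
#' @param priority ordered subset of
#'   \code{c("user_bonds", "user_radicals", "intra_atomic", "bond_length",
#'   "symmetry")}.  Defaults to that order, restricted to the criteria that
#'   have the data they need (\code{user_bonds}/\code{user_radicals} require
#'   \code{user_bonds=}/\code{user_radicals=} arguments; \code{bond_length}
#'   requires a geometry at ranking time).
#' @param user_bonds bonds the user wants in the final set, as a list of
#'   index pairs or \code{"1-2"} strings.
#' @param user_radicals orbital indices the user wants to carry radicals.
#' @return object of class \code{vb_criteria_config}.
#' @examples
#' criteria_config(priority = c("intra_atomic", "bond_length"))
#' @export
criteria_config <- function(priority = NULL, user_bonds = list(),
                            user_radicals = integer()) {
  udb <- as_pair_matrix(user_bonds)
  udr <- sort(as.integer(user_radicals))
  if (is.null(priority)) {
    priority <- CRITERIA
    if (nrow(udb) == 0L) priority <- setdiff(priority, "user_bonds")
    if (length(udr) == 0L) priority <- setdiff(priority, "user_radicals")
  }
  priority <- as.character(priority)
  if (length(priority) == 0L) stop("priority order must name at least one criterion")
  if (anyDuplicated(priority)) stop("priority order must not repeat criteria")
  bad <- setdiff(priority, CRITERIA)
  if (length(bad)) stop("unknown criterion: ", bad[1L])
  if ("user_bonds" %in% priority && nrow(udb) == 0L)
    stop("criterion 'user_bonds' requires a nonempty user_bonds set")
  if ("user_radicals" %in% priority && length(udr) == 0L)
    stop("criterion 'user_radicals' requires a nonempty user_radicals set")
  if (priority[1L] == "bond_length")
    warning("bond_length is geometry dependent; it is not recommended as the sole or highest-priority criterion")
  structure(list(priority = priority, user_bonds = udb, user_radicals = udr),
            class = "vb_criteria_config")
}

#' @export
print.vb_criteria_config <- function(x, ...) {
  cat("Criteria priority:", paste(x$priority, collapse = " > "), "\n")
  if (nrow(x$user_bonds))
    cat("  user bonds:", paste(paste0(x$user_bonds[, 1], "-", x$user_bonds[, 2]),
                               collapse = ", "), "\n")
  if (length(x$user_radicals))
    cat("  user radicals:", paste(x$user_radicals, collapse = ", "), "\n")
  invisible(x)
}

#' Per-criterion scores
#'
#' \code{score_user_bonds}: \eqn{S = N_B - N_{UDB} + 1} where \eqn{N_B} is
#' the structure's bond count and \eqn{N_{UDB}} the number of those bonds
#' that are user-defined; 1 iff every bond is user-defined.
#'
#' \code{score_user_radicals}: \eqn{S = N_R - N_{UDR} + 1}, the radical
#' analogue (a structure with no radicals scores 1).
#'
#' \code{score_intra_atomic}: \eqn{S = N_{IAB} + 1}, one penalty point per
#' bond whose two orbitals sit on the same atom.
#'
#' \code{score_symmetry}: \eqn{S = N_{SBB} + 1}, one penalty point per bond
#' between orbitals of different symmetry labels; unlabelled orbitals share
#' one wildcard label.
#'
#' @param structure a \code{\link{vb_structure}}.
#' @param udb user-defined bonds (pair list/matrix), nonempty.
#' @param udr user-defined radical orbital indices, nonempty.
#' @param atom_map named map orbital index -> atom id (character vector with
#'   names; an \code{\link{active_space}} also works).
#' @param labels named map orbital index -> symmetry label (or an
#'   \code{active_space}); \code{NA} entries share a wildcard label.
#' @return positive integer score (1 = best).
#' @name criterion_scores
NULL

#' @rdname criterion_scores
#' @export
score_user_bonds <- function(structure, udb) {
  udb <- as_pair_matrix(udb)
  if (nrow(udb) == 0L) stop("user-defined bond set must be nonempty")
  nb <- nrow(structure$pairs)
  hit <- 0L
  if (nb > 0L) {
    keys <- paste0(structure$pairs[, 1], "-", structure$pairs[, 2])
    hit <- sum(keys %in% paste0(udb[, 1], "-", udb[, 2]))
  }
  as.integer(nb - hit + 1L)
}

#' @rdname criterion_scores
#' @export
score_user_radicals <- function(structure, udr) {
  udr <- as.integer(udr)
  if (length(udr) == 0L) stop("user-defined radical set must be nonempty")
  nr <- length(structure$unpaired)
  as.integer(nr - sum(structure$unpaired %in% udr) + 1L)
}

orbital_atom_map <- function(x) {
  if (inherits(x, "vb_active_space"))
    return(stats::setNames(x$orbitals$atom, x$orbitals$index))
  if (is.null(names(x))) stop("atom_map must be named by orbital index")
  x
}

#' @rdname criterion_scores
#' @export
score_intra_atomic <- function(structure, atom_map) {
  atom_map <- orbital_atom_map(atom_map)
  n_iab <- count_intra_atomic(structure, atom_map)
  as.integer(n_iab + 1L)
}

count_intra_atomic <- function(structure, atom_map) {
  pr <- structure$pairs
  if (nrow(pr) == 0L) return(0L)
  a1 <- atom_map[as.character(pr[, 1L])]
  a2 <- atom_map[as.character(pr[, 2L])]
  if (anyNA(a1) || anyNA(a2)) stop("atom_map does not cover every bonded orbital")
  sum(a1 == a2)
}

#' @rdname criterion_scores
#' @export
score_symmetry <- function(structure, labels) {
  if (inherits(labels, "vb_active_space"))
    labels <- stats::setNames(labels$orbitals$symmetry, labels$orbitals$index)
  pr <- structure$pairs
  if (nrow(pr) == 0L) return(1L)
  l1 <- labels[as.character(pr[, 1L])]
  l2 <- labels[as.character(pr[, 2L])]
  # unlabelled orbitals share one wildcard label
  l1[is.na(l1)] <- ".wild"
  l2[is.na(l2)] <- ".wild"
  as.integer(sum(l1 != l2) + 1L)
}

#' Bond-length criterion: stretch measure and dense ranks
#'
#' For each structure, every inter-atomic bond \eqn{k} between atoms A and B
#' contributes \eqn{\max(0, R_k(AB) - R^{cov}_k(AB)) / R^{cov}_k(AB)} to the
#' stretch measure \eqn{D_{NAB}}: bonds no longer than the covalent-radii sum
#' ("neighbouring atom bonds") contribute zero, stretched bonds grow the
#' measure; intra-atomic bonds contribute nothing.  Structures are then
#' sorted by \eqn{D_{NAB}} and given dense ranks (ties share a rank).
#'
#' @param structures list of \code{\link{vb_structure}} objects.
#' @param geometry a \code{\link{read_xyz}} geometry covering every mapped atom.
#' @param atom_map orbital -> atom map (or an \code{\link{active_space}}).
#' @return list with \code{scores} (integer dense ranks, 1 = shortest bonds)
#'   and \code{d_nab} (the real-valued measure).
#' @export
rank_by_bond_length <- function(structures, geometry, atom_map) {
  atom_map <- orbital_atom_map(atom_map)
  d <- vapply(structures, bond_stretch, numeric(1),
              geometry = geometry, atom_map = atom_map)
  r <- match(d, sort(unique(d)))  # dense ranking: ties share a score
  list(scores = as.integer(r), d_nab = d)
}

bond_stretch <- function(structure, geometry, atom_map) {
  pr <- structure$pairs
  if (nrow(pr) == 0L) return(0)
  total <- 0
  for (k in seq_len(nrow(pr))) {
    a1 <- atom_map[as.character(pr[k, 1L])]
    a2 <- atom_map[as.character(pr[k, 2L])]
    if (anyNA(c(a1, a2))) stop("atom_map does not cover every bonded orbital")
    if (a1 == a2) next  # intra-atomic: no distance contribution
    r <- atom_distance(geometry, a1, a2)
    rcov <- atom_radius(geometry, a1) + atom_radius(geometry, a2)
    total <- total + max(0, r - rcov) / rcov
  }
  total
}

#' Merge per-criterion scores into one lexicographic quality score
#'
#' Scores are folded pairwise in priority order via
#' \eqn{S_{new} = (S_n - 1)\max(S_m) + S_m}, which preserves both the
#' priority between criteria and the ordering within each criterion: the
#' resulting total order is exactly the lexicographic order of the score
#' tuples.
#'
#' @param score_lists list of equal-length integer score vectors, highest
#'   priority first; every score \eqn{\ge 1}.
#' @return integer vector of unified scores (\eqn{\ge 1}).
#' @examples
#' merge_scores(list(c(1, 2), c(2, 1)))  # 2 3
#' @export
merge_scores <- function(score_lists) {
  stopifnot(is.list(score_lists), length(score_lists) >= 1L)
  lens <- lengths(score_lists)
  if (length(unique(lens)) != 1L) stop("score vectors must have equal length")
  if (any(unlist(score_lists) < 1)) stop("scores must be >= 1")
  s <- as.numeric(score_lists[[1L]])
  for (m in score_lists[-1L]) {
    s <- (s - 1) * max(m) + m
  }
  as.integer(s)
}

#' Score and rank a list of structures
#'
#' Computes every criterion named in the configuration's priority order and
#' merges them into a unified quality score (1 = best).
#'
#' @param structures list of \code{\link{vb_structure}} objects (one
#'   subspace).
#' @param space their \code{\link{active_space}} (atom and symmetry maps).
#' @param config a \code{\link{criteria_config}}.
#' @param geometry geometry, required when \code{bond_length} is among the
#'   priorities.
#' @return a \code{data.frame} with one row per structure: the occupancy
#'   notation, each criterion's score, \code{d_nab} when computed, and
#'   \code{unified}.  The structure list is attached as
#'   \code{attr(, "structures")}.
#' @export
rank_structures <- function(structures, space, config, geometry = NULL) {
  if (length(structures) == 0L) stop("no structures to rank")
  score_lists <- list()
  d_nab <- NULL
  for (crit in config$priority) {
    score_lists[[crit]] <- switch(
      crit,
      user_bonds = vapply(structures, score_user_bonds, integer(1),
                          udb = config$user_bonds),
      user_radicals = vapply(structures, score_user_radicals, integer(1),
                             udr = config$user_radicals),
      intra_atomic = vapply(structures, score_intra_atomic, integer(1),
                            atom_map = space),
      symmetry = vapply(structures, score_symmetry, integer(1),
                        labels = space),
      bond_length = {
        if (is.null(geometry))
          stop("criterion 'bond_length' requires a geometry")
        bl <- rank_by_bond_length(structures, geometry, space)
        d_nab <- bl$d_nab
        bl$scores
      })
  }
  unified <- merge_scores(score_lists)
  df <- data.frame(structure = vapply(structures, write_structure_notation,
                                      character(1)),
                   stringsAsFactors = FALSE)
  for (crit in names(score_lists)) df[[crit]] <- score_lists[[crit]]
  if (!is.null(d_nab)) df$d_nab <- d_nab
  df$unified <- unified
  attr(df, "structures") <- structures
  df
}
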