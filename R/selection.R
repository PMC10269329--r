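# Greedy selection of a complete, linearly independent, highest-quality set
# of VB structures per lone-pair/vacant subspace.

#' Select a chemically insightful independent structure set
#'
#' Candidates are the exhaustive enumeration of the subspace, sorted by the
#' unified quality score (ties broken by canonical structure order).  Pinned
#' structures are placed first after a mutual-independence check; remaining
#' slots are filled greedily, skipping any candidate whose addition drops the
#' Gramian's smallest absolute eigenvalue to the threshold or below.  The
#' returned set always has exactly \code{count_independent(N, S)} members
#' and passes the Gramian test.
#'
#' @param space an \code{\link{active_space}}.
#' @param subspace a \code{\link{vb_subspace}} (default covalent block).
#' @param config a \code{\link{criteria_config}}.
#' @param geometry geometry, when the configuration uses \code{bond_length}.
#' @param pinned optional list of \code{\link{vb_structure}} objects that
#'   must be in the set.
#' @param threshold Gramian eigenvalue threshold (default \code{1e-11}).
#' @param verbose log candidate acceptance/rejection.
#' @return a \code{\link{structure_set}} with provenance tags
#'   \code{"pinned"}/\code{"selected"} and the ranking table attached.
#' @examples
#' sys <- builtin_system("c5h5")
#' sel <- select_insightful_set(sys$space, config = sys$config,
#'                              geometry = sys$geometry)
#' @export
select_insightful_set <- function(space, subspace = vb_subspace(), config,
                                  geometry = NULL, pinned = NULL,
                                  threshold = 1e-11, verbose = FALSE) {
  singles <- subspace_singles(space, subspace)
  nis <- count_independent(length(singles), space$spin)

  cands <- enumerate_structures(space, subspace = subspace)
  ranking <- rank_structures(cands, space, config, geometry = geometry)
  ord <- order(ranking$unified)  # stable: preserves canonical order on ties
  cands <- cands[ord]
  unified <- ranking$unified[ord]

  chosen <- list()
  provenance <- character(0)
  sub_key <- subspace_key_string(subspace)
  if (!is.null(pinned) && length(pinned)) {
    for (p in pinned) {
      if (subspace_key_string(subspace_of(p)) != sub_key)
        stop(sprintf("pinned structure %s does not belong to subspace %s",
                     write_structure_notation(p), sub_key))
    }
    if (length(pinned) > 1L) {
      g0 <- gramian(pinned, threshold = threshold)
      if (!g0$independent)
        stop(sprintf("pinned structures are mutually dependent (min |eigenvalue| %.3e): %s",
                     g0$min_abs_eigenvalue,
                     paste(vapply(pinned, write_structure_notation, character(1)),
                           collapse = "; ")))
    }
    chosen <- pinned
    provenance <- rep("pinned", length(pinned))
  }

  chosen_keys <- vapply(chosen, structure_key, character(1))
  n_rejected <- 0L
  for (i in seq_along(cands)) {
    if (length(chosen) >= nis) break
    cand <- cands[[i]]
    key <- structure_key(cand)
    if (key %in% chosen_keys) next
    g <- gramian(c(chosen, list(cand)), threshold = threshold)
    if (g$independent) {
      chosen <- c(chosen, list(cand))
      chosen_keys <- c(chosen_keys, key)
      provenance <- c(provenance, "selected")
      if (verbose)
        message(sprintf("accepted %-28s unified %d, min |eig| %.3e",
                        write_structure_notation(cand), unified[i],
                        g$min_abs_eigenvalue))
    } else {
      n_rejected <- n_rejected + 1L
      if (verbose)
        message(sprintf("rejected %-28s (dependent, min |eig| %.3e)",
                        write_structure_notation(cand), g$min_abs_eigenvalue))
    }
  }
  if (length(chosen) < nis)
    stop(sprintf("exhausted %d candidates after selecting only %d of %d structures",
                 length(cands), length(chosen), nis))
  g <- gramian(chosen, threshold = threshold)
  stopifnot(g$independent)
  if (verbose)
    message(sprintf("subspace %s: %d candidates, %d rejected as dependent, final min |eig| %.3e",
                    sub_key, length(cands), n_rejected, g$min_abs_eigenvalue))
  structure_set(chosen, subspace = subspace, provenance = provenance,
                gramian = g, ranking = ranking)
}

#' Select complete sets for every lone-pair/vacant subspace
#'
#' Runs \code{\link{select_insightful_set}} independently in each subspace of
#' the covalent block (minimal lone-pair count; override via \code{d}).
#' The total structure count over all subspaces is
#' \eqn{\binom{n}{n-N} N_{IS}}.
#'
#' @inheritParams select_insightful_set
#' @param d lone-pair count defining the block (default: the minimal valid
#'   count, i.e. the paper-style covalent block).
#' @return named list of \code{\link{structure_set}} objects keyed by
#'   subspace.
#' @export
select_all_subspaces <- function(space, config, geometry = NULL, d = NULL,
                                 threshold = 1e-11, verbose = FALSE) {
  if (is.null(d)) d <- min(valid_double_counts(space))
  all_structs <- enumerate_structures(space, d = d)
  groups <- group_by_subspace(all_structs)
  out <- list()
  for (key in names(groups)) {
    sub <- subspace_of(groups[[key]][[1L]])
    out[[key]] <- select_insightful_set(space, subspace = sub, config = config,
                                        geometry = geometry,
                                        threshold = threshold,
                                        verbose = verbose)
  }
  out
}
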