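# Ordered collection of VB structures with provenance and (optionally) its
# Gramian independence report.

#' Construct a structure set
#'
#' @param structures ordered list of \code{\link{vb_structure}} objects.
#' @param subspace the \code{\link{vb_subspace}} all members belong to.
#' @param provenance character vector, one tag per structure
#'   (\code{"pinned"}, \code{"selected"} or \code{"rumer"}).
#' @param gramian optional \code{vb_gramian_report}.
#' @param ranking optional ranking table (see \code{\link{rank_structures}}).
#' @return object of class \code{vb_structure_set}.
#' @export
structure_set <- function(structures, subspace = NULL,
                          provenance = rep("selected", length(structures)),
                          gramian = NULL, ranking = NULL) {
  stopifnot(is.list(structures), length(provenance) == length(structures))
  if (is.null(subspace) && length(structures))
    subspace <- subspace_of(structures[[1L]])
  for (s in structures) {
    if (subspace_key_string(subspace_of(s)) != subspace_key_string(subspace))
      stop("all structures in a set must share one subspace")
  }
  structure(list(structures = structures, subspace = subspace,
                 provenance = provenance, gramian = gramian,
                 ranking = ranking),
            class = "vb_structure_set")
}

#' @export
print.vb_structure_set <- function(x, ...) {
  cat(sprintf("Structure set (%d structures, subspace %s)\n",
              length(x$structures), subspace_key_string(x$subspace)))
  for (i in seq_along(x$structures)) {
    cat(sprintf("  %2d. %-30s [%s]\n", i,
                write_structure_notation(x$structures[[i]]),
                x$provenance[i]))
  }
  if (!is.null(x$gramian)) print(x$gramian)
  invisible(x)
}

#' @export
length.vb_structure_set <- function(x) length(x$structures)
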