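# Independent oracles used across the suite.  These deliberately take
# different routes from the package: factorial enumeration with string
# deduplication instead of recursive construction, QR rank instead of
# Gramian eigenvalues, explicit tuple sorting instead of score folding.

# all permutations of a vector (tiny n only)
oracle_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# canonical string for (doubly, vacant, pairs given as flat vector, radicals)
oracle_struct_string <- function(docc, vac, flat_pairs, rads) {
  pair_str <- ""
  if (length(flat_pairs)) {
    m <- matrix(flat_pairs, ncol = 2L, byrow = TRUE)
    m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    pair_str <- paste(paste0(m[, 1], "-", m[, 2]), collapse = ",")
  }
  paste0("D", paste(sort(docc), collapse = ","),
         "|V", paste(sort(vac), collapse = ","),
         "|P", pair_str,
         "|R", paste(sort(rads), collapse = ","))
}

# exhaustive structure enumeration by brute force over permutations:
# every structure string for every valid occupancy pattern, deduplicated
oracle_enumerate_strings <- function(n, n_electrons, two_s, d_only = NULL) {
  idx <- seq_len(n)
  seen <- character(0)
  for (d in 0:(n_electrons %/% 2L)) {
    if (!is.null(d_only) && d != d_only) next
    N <- n_electrons - 2L * d
    v <- n - d - N
    if (N < two_s || v < 0L || (N - two_s) %% 2L != 0L) next
    safe_combn <- function(x, k) {
      if (k == 0L) return(list(integer(0)))
      if (length(x) < k) return(list())
      if (length(x) == 1L) return(list(as.integer(x)))
      cm <- utils::combn(x, k)
      lapply(seq_len(ncol(cm)), function(i) cm[, i])
    }
    for (docc in safe_combn(idx, d)) {
      rem <- setdiff(idx, docc)
      for (vac in safe_combn(rem, v)) {
        singles <- setdiff(rem, vac)
        p <- (N - two_s) %/% 2L
        for (perm in oracle_perms(singles)) {
          flat <- if (p > 0L) perm[seq_len(2L * p)] else integer(0)
          rads <- if (two_s > 0L) perm[(2L * p + 1L):N] else integer(0)
          seen <- c(seen, oracle_struct_string(docc, vac, flat, rads))
        }
      }
    }
  }
  unique(seen)
}

# package structure -> the oracle's string form, for set comparisons
pkg_struct_string <- function(s) {
  oracle_struct_string(s$doubly_occupied, s$vacant, as.vector(t(s$pairs)),
                       s$unpaired)
}

# exact rank of the (+/-1) determinant coefficient matrix by QR
oracle_rank <- function(structures) {
  M <- vbstruct:::expansion_matrix(structures, normalize = FALSE)
  qr(M)$rank
}

catalan <- function(k) choose(2 * k, k) / (k + 1)

# Kekule set of the 5-orbital pentagon: radical k, adjacent bonds elsewhere
kekule_c5h5 <- function() {
  adj <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5))
  lapply(1:5, function(k) {
    keep <- Filter(function(b) !(k %in% b), adj)
    # the two disjoint adjacent bonds avoiding k
    for (i in seq_along(keep)) {
      for (j in seq_along(keep)) {
        if (i < j && length(intersect(keep[[i]], keep[[j]])) == 0L)
          return(vb_structure(pairs = list(keep[[i]], keep[[j]]), unpaired = k))
      }
    }
  })
}
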