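# Readers/writers: XYZ geometries, covalent radii, occupancy-notation
# structures, plain-text matrices, and the structured config file.

#' Covalent radii table
#'
#' Single-bond covalent radii (Angstrom) from the standard crystallographic
#' compilation (Cordero et al. 2008) for the common main-group elements;
#' user entries override or extend the table.
#'
#' @param override named numeric vector of element -> radius overrides.
#' @return named numeric vector, element symbol -> radius in Angstrom.
#' @examples
#' covalent_radii()[c("H", "C", "N", "O")]
#' @export
covalent_radii <- function(override = NULL) {
  r <- c(H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
         N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
         Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
         K = 2.03, Ca = 1.76, Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20,
         Br = 1.20, Kr = 1.16, I = 1.39)
  if (!is.null(override)) r[names(override)] <- as.numeric(override)
  r
}

normalize_element <- function(sym) {
  sym <- tolower(sym)
  paste0(toupper(substr(sym, 1L, 1L)), substr(sym, 2L, nchar(sym)))
}

make_geometry <- function(atoms, radii = covalent_radii()) {
  atoms$element <- normalize_element(atoms$element)
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown))
    stop("no covalent radius known for element '", unknown[1L], "'")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinate")
  if (!"name" %in% names(atoms)) {
    atoms$name <- stats::ave(atoms$element, atoms$element,
                             FUN = function(e) paste0(e, seq_along(e)))
  }
  structure(list(atoms = atoms, radii = radii), class = "vb_geometry")
}

#' @export
print.vb_geometry <- function(x, ...) {
  cat(sprintf("Geometry: %d atoms\n", nrow(x$atoms)))
  print(x$atoms, row.names = FALSE)
  invisible(x)
}

geometry_atom_row <- function(geometry, atom_id) {
  i <- match(atom_id, geometry$atoms$name)
  if (is.na(i)) {
    hits <- which(geometry$atoms$element == atom_id)
    if (length(hits) == 1L) i <- hits
  }
  if (is.na(i)) stop("geometry has no coordinates for atom '", atom_id, "'")
  i
}

atom_distance <- function(geometry, a, b) {
  i <- geometry_atom_row(geometry, a)
  j <- geometry_atom_row(geometry, b)
  sqrt(sum((unlist(geometry$atoms[i, c("x", "y", "z")]) -
            unlist(geometry$atoms[j, c("x", "y", "z")]))^2))
}

atom_radius <- function(geometry, a) {
  i <- geometry_atom_row(geometry, a)
  geometry$radii[[geometry$atoms$element[i]]]
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count line, comment line, then one
#' \code{element x y z} record per atom (Angstrom).  Atoms are auto-named
#' \code{C1, C2, ...} per element for orbital-to-atom references.
#'
#' @param path path to the file.
#' @param radii covalent radii table (see \code{\link{covalent_radii}}).
#' @return object of class \code{vb_geometry}.
#' @export
read_xyz <- function(path, radii = covalent_radii()) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("line 1: malformed atom count in ", path)
  rec <- lines[-(1:2)]
  rec <- rec[nzchar(trimws(rec))]
  if (length(rec) != n)
    stop(sprintf("line 1 declares %d atoms but %d records follow", n, length(rec)))
  parts <- strsplit(trimws(rec), "\\s+")
  atoms <- data.frame(element = character(n), x = numeric(n), y = numeric(n),
                      z = numeric(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) < 4L) stop(sprintf("line %d: expected 'element x y z'", i + 2L))
    xyz <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(xyz)) stop(sprintf("line %d: malformed coordinates", i + 2L))
    atoms$element[i] <- p[1L]
    atoms[i, c("x", "y", "z")] <- as.list(xyz)
  }
  make_geometry(atoms, radii)
}

# ---- occupancy notation -----------------------------------------------------

#' Occupancy notation for VB structures
#'
#' Structures print as e.g. \code{"[1 1 2 2] 3 3 4-6 5-7"}: inactive valence
#' orbitals (if declared) in brackets with multiplicity two, then each active
#' doubly occupied orbital twice, unpaired orbitals once, and bonds as
#' \code{a-b} pairs.  The parser accepts both the ASCII hyphen and the
#' en-dash; the writer emits ASCII.
#'
#' @param structure a \code{\link{vb_structure}}.
#' @param inactive indices of inactive (always doubly occupied) valence
#'   orbitals printed in the bracket prefix.
#' @return \code{write_structure_notation}: a string.
#' @export
write_structure_notation <- function(structure, inactive = integer()) {
  parts <- character(0)
  if (length(inactive))
    parts <- sprintf("[%s]", paste(rep(sort(as.integer(inactive)), each = 2L),
                                   collapse = " "))
  if (length(structure$doubly_occupied))
    parts <- c(parts, paste(rep(structure$doubly_occupied, each = 2L),
                            collapse = " "))
  if (length(structure$unpaired))
    parts <- c(parts, paste(structure$unpaired, collapse = " "))
  if (nrow(structure$pairs))
    parts <- c(parts, paste(paste0(structure$pairs[, 1L], "-",
                                   structure$pairs[, 2L]), collapse = " "))
  if (length(parts) == 0L) return("(empty)")
  paste(parts, collapse = " ")
}

#' @rdname write_structure_notation
#' @param text occupancy-notation string.
#' @param space optional \code{\link{active_space}}: orbitals of the space
#'   not mentioned in the string become vacant, and bracketed inactive
#'   orbitals outside the space are folded into \code{doubly_occupied}.
#' @return \code{parse_structure_notation}: a \code{\link{vb_structure}}.
#' @export
parse_structure_notation <- function(text, space = NULL) {
  text <- gsub("–", "-", text)  # en-dash -> hyphen
  doubly <- integer(0)
  m <- regmatches(text, regexpr("\\[[^]]*\\]", text))
  if (length(m)) {
    inside <- as.integer(strsplit(trimws(gsub("[][]", "", m)), "\\s+")[[1L]])
    tab <- table(inside)
    if (any(tab != 2L)) stop("bracketed inactive orbitals must appear exactly twice each")
    doubly <- as.integer(names(tab))
    text <- sub("\\[[^]]*\\]", "", text)
  }
  tokens <- strsplit(trimws(text), "\\s+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  pairs <- list()
  bare <- integer(0)
  for (tk in tokens) {
    if (grepl("-", tk, fixed = TRUE)) {
      ab <- as.integer(strsplit(tk, "-", fixed = TRUE)[[1L]])
      if (length(ab) != 2L || anyNA(ab)) stop("malformed bond token '", tk, "'")
      pairs[[length(pairs) + 1L]] <- ab
    } else {
      v <- suppressWarnings(as.integer(tk))
      if (is.na(v)) stop("malformed token '", tk, "'")
      bare <- c(bare, v)
    }
  }
  tab <- table(bare)
  if (any(tab > 2L)) stop(sprintf("orbital %s appears more than twice", names(tab)[tab > 2L][1L]))
  doubly <- c(doubly, as.integer(names(tab)[tab == 2L]))
  unpaired <- as.integer(names(tab)[tab == 1L])
  vacant <- integer(0)
  if (!is.null(space)) {
    used <- c(doubly, unpaired, unlist(pairs))
    vacant <- setdiff(space$orbitals$index, used)
  }
  vb_structure(pairs = pairs, unpaired = unpaired, doubly_occupied = doubly,
               vacant = vacant)
}

# ---- matrices and config ----------------------------------------------------

#' Plain-text numeric matrix/vector files
#'
#' Whitespace-delimited numbers with a one-line dimension header: matrices
#' use \code{"n"} followed by \code{n} rows of \code{n} values, vectors use
#' \code{"n"} followed by the values.
#'
#' @param path file path.
#' @param x matrix or vector to write.
#' @return the matrix (\code{read_matrix_file}) or vector
#'   (\code{read_vector_file}).
#' @name matrix_files
NULL

#' @rdname matrix_files
#' @export
read_matrix_file <- function(path) {
  vals <- scan(path, quiet = TRUE)
  n <- as.integer(vals[1L])
  body <- vals[-1L]
  if (length(body) != n * n)
    stop(sprintf("matrix file declares n = %d but holds %d values", n, length(body)))
  matrix(body, nrow = n, byrow = TRUE)
}

#' @rdname matrix_files
#' @export
write_matrix_file <- function(x, path) {
  x <- as.matrix(x)
  lines <- c(as.character(nrow(x)),
             apply(x, 1L, function(r) paste(format(r, digits = 17), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname matrix_files
#' @export
read_vector_file <- function(path) {
  vals <- scan(path, quiet = TRUE)
  n <- as.integer(vals[1L])
  body <- vals[-1L]
  if (length(body) != n)
    stop(sprintf("vector file declares n = %d but holds %d values", n, length(body)))
  body
}

#' Read an active-space + criteria config file
#'
#' JSON with fields \code{n_orbitals}, \code{n_electrons}, \code{spin}
#' (as the integer \eqn{2S} to avoid fractional spins), optional
#' \code{orbitals} (objects with \code{index}, \code{atom}, optional
#' \code{symmetry}), optional \code{criteria} (\code{priority},
#' \code{user_bonds} as \code{"1-2"} strings, \code{user_radicals}) and
#' optional \code{radii} overrides.
#'
#' @param path path to the JSON config.
#' @return list with \code{space}, \code{config}, \code{radii}.
#' @export
read_space_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  orbitals <- if (!is.null(cfg$orbitals)) {
    as.data.frame(cfg$orbitals, stringsAsFactors = FALSE)
  } else {
    if (is.null(cfg$n_orbitals)) stop("config needs 'orbitals' or 'n_orbitals'")
    data.frame(index = seq_len(cfg$n_orbitals),
               atom = paste0("a", seq_len(cfg$n_orbitals)),
               stringsAsFactors = FALSE)
  }
  if (is.null(cfg$n_electrons)) stop("config needs 'n_electrons'")
  if (is.null(cfg$spin)) stop("config needs 'spin' (the integer 2S)")
  space <- active_space(orbitals, n_electrons = cfg$n_electrons,
                        spin = cfg$spin / 2)
  config <- if (!is.null(cfg$criteria)) {
    criteria_config(priority = cfg$criteria$priority,
                    user_bonds = as.list(cfg$criteria$user_bonds %||% character(0)),
                    user_radicals = cfg$criteria$user_radicals %||% integer(0))
  } else criteria_config(priority = "intra_atomic")
  radii <- covalent_radii(override = unlist(cfg$radii))
  list(space = space, config = config, radii = radii)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
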