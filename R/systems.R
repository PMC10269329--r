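# Built-in example systems: active spaces with atom/symmetry metadata and
# synthetic fixture geometries (topologically faithful; only relative
# distance orderings feed the bond-length criterion).

#' Built-in example systems
#'
#' Four ready-made active spaces with synthetic fixture geometries:
#' \describe{
#'   \item{\code{"c5h5"}}{cyclopentadienyl radical, doublet, 5e/5o; one pi
#'     orbital per carbon of a regular pentagon.}
#'   \item{\code{"c2"}}{the C2 molecule, singlet, 8e/8o; two sigma-type and
#'     two pi-type orbitals per carbon, orbital \eqn{k} on the first carbon
#'     facing orbital \eqn{k+4} on the second.}
#'   \item{\code{"hnc_ts"}}{the HNC -> HCN hydrogen-transfer transition
#'     state, singlet, 6e/5o; active orbitals numbered 3-7 (1 and 2 are the
#'     inactive CN sigma/pi bonds): 3 on H, 4/5 on C, 6/7 on N.}
#'   \item{\code{"h_oh_ts"}}{the H + OH -> O + H2 transition state, triplet,
#'     4e/4o; sigma orbitals on each H and on O, plus one pi orbital on O.
#'     Named structures for the reaction roles are included: \code{"7"} the
#'     forming H-H bond, \code{"8"} the breaking O-H bond, \code{"9"} the
#'     intra-atomic O pair, \code{"10"} the completion that avoids the O
#'     pair but is unreachable as a Rumer complement of 7 and 8, \code{"11"}
#'     the Rumer complement available after reordering.}
#' }
#' Geometries are synthetic stand-ins with the correct topology, not the
#' published quantum-chemistry geometries.
#'
#' @param name one of \code{"c5h5"}, \code{"c2"}, \code{"hnc_ts"},
#'   \code{"h_oh_ts"}.
#' @return list with \code{space}, \code{geometry}, \code{config} (default
#'   criteria), \code{inactive} (inactive orbital indices, for notation) and
#'   optionally \code{structures}.
#' @examples
#' builtin_system("c2")$space
#' @export
builtin_system <- function(name) {
  name <- match.arg(name, c("c5h5", "c2", "hnc_ts", "h_oh_ts"))
  switch(name, c5h5 = system_c5h5(), c2 = system_c2(), hnc_ts = system_hnc(),
         h_oh_ts = system_hoh())
}

system_c5h5 <- function() {
  side <- 1.42
  rc <- side / (2 * sin(pi / 5))
  ang <- pi / 2 + 2 * pi * (0:4) / 5
  atoms <- data.frame(element = rep("C", 5),
                      x = rc * cos(ang), y = rc * sin(ang), z = 0)
  geom <- make_geometry(atoms)
  orbitals <- data.frame(index = 1:5, atom = paste0("C", 1:5),
                         symmetry = "pi", stringsAsFactors = FALSE)
  list(space = active_space(orbitals, n_electrons = 5, spin = 1/2),
       geometry = geom,
       config = criteria_config(priority = c("intra_atomic", "bond_length")),
       inactive = integer(0))
}

system_c2 <- function() {
  atoms <- data.frame(element = c("C", "C"),
                      x = 0, y = 0, z = c(0, 1.2425))
  geom <- make_geometry(atoms)
  orbitals <- data.frame(
    index = 1:8,
    atom = rep(c("C1", "C2"), each = 4),
    symmetry = rep(c("sigma", "sigma", "pi_x", "pi_y"), 2),
    stringsAsFactors = FALSE)
  list(space = active_space(orbitals, n_electrons = 8, spin = 0),
       geometry = geom,
       config = criteria_config(priority = c("intra_atomic", "symmetry")),
       inactive = integer(0),
       structures = list(
         # the quadruply bonded perfect pairing (orbital k with k+4)
         "15" = vb_structure(pairs = list(c(1, 5), c(2, 6), c(3, 7), c(4, 8)))))
}

system_hnc <- function() {
  atoms <- data.frame(element = c("N", "C", "H"),
                      x = c(0, 1.19, 0.55), y = c(0, 0, 1.25), z = 0)
  geom <- make_geometry(atoms)
  orbitals <- data.frame(
    index = 3:7,
    atom = c("H1", "C1", "C1", "N1", "N1"),
    symmetry = c("sigma", "sigma", "pi", "sigma", "pi"),
    stringsAsFactors = FALSE)
  list(space = active_space(orbitals, n_electrons = 6, spin = 0),
       geometry = geom,
       config = criteria_config(priority = c("intra_atomic", "bond_length")),
       inactive = c(1L, 2L))
}

system_hoh <- function() {
  atoms <- data.frame(element = c("H", "H", "O"),
                      x = c(0, 1.0, 2.2), y = 0, z = 0)
  geom <- make_geometry(atoms)
  orbitals <- data.frame(
    index = 1:4,
    atom = c("H1", "H2", "O1", "O1"),
    symmetry = c("sigma", "sigma", "sigma", "pi"),
    stringsAsFactors = FALSE)
  list(space = active_space(orbitals, n_electrons = 4, spin = 1),
       geometry = geom,
       config = criteria_config(priority = c("intra_atomic", "bond_length")),
       inactive = integer(0),
       structures = list(
         "7" = vb_structure(pairs = "1-2", unpaired = c(3, 4)),   # H-H forming
         "8" = vb_structure(pairs = "2-3", unpaired = c(1, 4)),   # O-H breaking
         "9" = vb_structure(pairs = "3-4", unpaired = c(1, 2)),   # intra O pair
         "10" = vb_structure(pairs = "2-4", unpaired = c(1, 3)),  # H-O(pi), non-Rumer complement
         "11" = vb_structure(pairs = "1-4", unpaired = c(2, 3)))) # Rumer complement after reordering
}
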