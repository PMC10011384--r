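# Atomic hydrogen-bond donor/acceptor strengths.
#
# Donor strength of a hydrogen:   sd = D * (qH + delta_q)
# Acceptor strength of an atom
# with lone pairs:                sa = A * (qa + delta_q)
#
# delta_q propagates the partial charges of topological neighbours through
# the alpha/beta/gamma shells (bond distance 1/2/3), attenuated by the
# bond reduction factor T, T^2, T^3. Atoms reachable by several paths
# contribute once, at their shortest distance; shells contain all atoms,
# hydrogens included. Strengths are dimensionless and water-referenced:
# D and A are calibrated so that the hydrogens and oxygen of
# MMFF94-minimised water score exactly 1.0.

#' Corrective shell charge
#'
#' Sum of neighbour partial charges over the alpha/beta/gamma topological
#' shells of an atom, weighted `T`, `T^2`, `T^3`. Atoms beyond bond
#' distance 3 contribute nothing.
#'
#' @param atom_index 1-based atom index.
#' @param record A `mol_record` with charges populated.
#' @param T Bond reduction factor.
#' @param dist Optional precomputed topological distance matrix.
#' @return Corrective charge in e.
#' @export
delta_q <- function(atom_index, record, T = 0.274, dist = NULL) {
  q <- record$atoms$q
  if (anyNA(q)) stop("state error: charges missing; run ",
                     "compute_charges_radii() first", call. = FALSE)
  if (is.null(dist)) dist <- topo_distances(record)
  d <- dist[atom_index, ]
  sum(T * q[d == 1]) + sum(T^2 * q[d == 2]) + sum(T^3 * q[d == 3])
}

#' Donor strength of a hydrogen atom
#'
#' `sd = D * (qH + delta_q)`. May be negative for strongly hydridic
#' hydrogens; no clamping is applied.
#'
#' @param hydrogen_index 1-based index of a hydrogen atom.
#' @param record A `mol_record` with charges populated.
#' @param params A [strength_params()] object.
#' @param dist Optional precomputed distance matrix.
#' @return Dimensionless donor strength.
#' @export
donor_strength <- function(hydrogen_index, record,
                           params = strength_params(), dist = NULL) {
  if (record$atoms$element[hydrogen_index] != "H") {
    stop("atom ", hydrogen_index, " is not a hydrogen", call. = FALSE)
  }
  params$D * (record$atoms$q[hydrogen_index] +
              delta_q(hydrogen_index, record, params$T, dist))
}

#' Acceptor strength of a lone-pair-bearing atom
#'
#' `sa = A * (qa + delta_q)`. Only atoms with at least one lone pair are
#' acceptors (this includes halogens, divalent sulfur and pyridine-type
#' nitrogens); the hybridisation-dipole, quadrupole and offset corrections
#' of the antecedent method are intentionally absent.
#'
#' @inheritParams donor_strength
#' @param atom_index 1-based index of an atom with `n_LP >= 1`.
#' @return Dimensionless acceptor strength.
#' @export
acceptor_strength <- function(atom_index, record,
                              params = strength_params(), dist = NULL) {
  if (is.na(record$atoms$n_LP[atom_index]) ||
      record$atoms$n_LP[atom_index] < 1) {
    stop("atom ", atom_index, " has no lone pairs and is not an acceptor",
         call. = FALSE)
  }
  params$A * (record$atoms$q[atom_index] +
              delta_q(atom_index, record, params$T, dist))
}

#' Atomic and molecular hydrogen-bond strengths
#'
#' Computes the donor strength of every hydrogen and the acceptor strength
#' of every lone-pair-bearing atom, plus the molecular aggregates: `sdx_mol`
#' (sum of X-H donor strengths, X any non-carbon atom), `sdc_mol` (sum of
#' C-H donor strengths), `sd_mol = sdx_mol + sdc_mol`, and
#' `sa_mol = sum(sa_i * n_LP_i)`.
#'
#' @param record A `mol_record` with charges populated.
#' @param params A [strength_params()] object.
#' @return An object of class `strength_set`: list with `donor` (named
#'   vector over hydrogen indices), `acceptor` (named vector over acceptor
#'   indices), the four molecular aggregates, and `id`.
#' @export
molecular_strengths <- function(record, params = strength_params()) {
  if (anyNA(record$atoms$q)) {
    stop("state error: charges missing; run compute_charges_radii() first",
         call. = FALSE)
  }
  dist <- topo_distances(record)
  a <- record$atoms
  h_idx <- which(a$element == "H")
  acc_idx <- which(a$n_LP >= 1)
  donor <- vapply(h_idx, donor_strength, numeric(1), record = record,
                  params = params, dist = dist)
  names(donor) <- h_idx
  acceptor <- vapply(acc_idx, acceptor_strength, numeric(1),
                     record = record, params = params, dist = dist)
  names(acceptor) <- acc_idx
  # heavy neighbour of each hydrogen decides X-H vs C-H bookkeeping
  parent <- heavy_neighbour(record)
  par_elem <- a$element[parent[h_idx]]
  sdx <- sum(donor[par_elem != "C"])
  sdc <- sum(donor[par_elem == "C"])
  structure(list(
    id = record$id,
    donor = donor,
    acceptor = acceptor,
    sdx_mol = sdx,
    sdc_mol = sdc,
    sd_mol = sdx + sdc,
    sa_mol = sum(acceptor * a$n_LP[acc_idx])
  ), class = "strength_set")
}

#' @export
print.strength_set <- function(x, ...) {
  cat(sprintf("<strength_set> %s: %d donors, %d acceptors\n", x$id,
              length(x$donor), length(x$acceptor)))
  cat(sprintf("  sdx_mol = %.2f, sdc_mol = %.2f, sd_mol = %.2f, sa_mol = %.2f\n",
              x$sdx_mol, x$sdc_mol, x$sd_mol, x$sa_mol))
  invisible(x)
}

# index of the (single) heavy neighbour of each hydrogen; NA elsewhere
heavy_neighbour <- function(record) {
  n <- n_atoms(record)
  parent <- rep(NA_integer_, n)
  b <- record$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (record$atoms$element[i] == "H") parent[i] <- j
    if (record$atoms$element[j] == "H") parent[j] <- i
  }
  parent
}

#' Export per-atom strengths as a data frame
#'
#' One row per donor hydrogen and per acceptor atom, suitable for CSV
#' export; strengths are unrounded (round at the formatting stage to match
#' 2-decimal table conventions).
#'
#' @param record A `mol_record`.
#' @param strengths A `strength_set` for the record.
#' @return data.frame with molecule id, 1-based atom index, element, role
#'   and strength.
#' @export
strengths_table <- function(record, strengths) {
  di <- as.integer(names(strengths$donor))
  ai <- as.integer(names(strengths$acceptor))
  data.frame(
    id = record$id,
    atom = c(di, ai),
    element = c(record$atoms$element[di], record$atoms$element[ai]),
    role = c(rep("donor", length(di)), rep("acceptor", length(ai))),
    strength = c(unname(strengths$donor), unname(strengths$acceptor)),
    stringsAsFactors = FALSE
  )
}
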