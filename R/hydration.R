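# Hydration free energy: polar + apolar + interaction terms, kJ/mol.
#
# The three terms are additive and share one strength set. Fitting
# re-evaluates the energy for many parameter sets on fixed geometries and
# charges, so the term evaluation is split into (i) feature extraction
# from a record + strength set and (ii) cheap algebra on those features.

#' Polar contribution to the hydration free energy
#'
#' `dG_p = g_d * sum_donors sd_i * n_H^exp_d +
#'         g_a * sum_acceptors sa_i * n_LP^exp_a`.
#' The donor sum runs over hydrogen-bearing heavy atoms (by default only
#' non-carbon ones), with `sd_i` the mean strength of the atom's
#' hydrogens; the acceptor sum runs over atoms with `n_LP >= 1`.
#'
#' @param strengths A `strength_set`.
#' @param record The corresponding `mol_record`.
#' @param params A [hydration_params()] object.
#' @param donor_scope `"xh-only"` (default: only X-H, X != C, enters the
#'   polar term) or `"all-h"`.
#' @param donor_aggregation How multiple hydrogens on one heavy atom map
#'   to its representative strength: `"mean"` (default) or `"max"`.
#' @return Energy in kJ/mol.
#' @export
polar_term <- function(strengths, record, params = hydration_params(),
                       donor_scope = c("xh-only", "all-h"),
                       donor_aggregation = c("mean", "max")) {
  f <- hydration_features(record, strengths,
                          donor_scope = match.arg(donor_scope),
                          donor_aggregation = match.arg(donor_aggregation))
  polar_from_features(f, params)
}

polar_from_features <- function(f, params) {
  dsum <- if (nrow(f$donors)) {
    sum(f$donors$sd * f$donors$n_H^params$exp_d)
  } else 0
  asum <- if (nrow(f$acceptors)) {
    sum(f$acceptors$sa * f$acceptors$n_LP^params$exp_a)
  } else 0
  params$g_d * dsum + params$g_a * asum
}

#' Atomic contribution to the topological surface area
#'
#' `N_s_i = 4 * pi * r_vdw^2 * (1 - n_l / (h + 1))` with the
#' hybridisation number h = 1, 2, 3 for sp1, sp2, sp3.
#'
#' @param r_vdw Van der Waals radius in Angstrom.
#' @param n_l Number of non-hydrogen neighbours.
#' @param hyb `"sp1"`, `"sp2"` or `"sp3"`.
#' @return Area in Angstrom^2.
#' @export
atomic_surface <- function(r_vdw, n_l, hyb) {
  h <- match(hyb, c("sp1", "sp2", "sp3"))
  if (anyNA(h)) stop("hybridisation must be sp1/sp2/sp3", call. = FALSE)
  if (any(n_l > h + 1)) {
    stop("valence error: atom with n_l = ", n_l[n_l > h + 1][1],
         " exceeds its hybridisation capacity", call. = FALSE)
  }
  4 * pi * r_vdw^2 * (1 - n_l / (h + 1))
}

#' Apolar contribution to the hydration free energy
#'
#' `dG_a = g_0 + g_s * N_s + g_r * N_r + g_pi2 * N_pi2 + g_pi1 * N_pi1`,
#' with the surface `N_s` summed over non-hydrogen atoms.
#'
#' @param record A `mol_record` with radii populated.
#' @param params A [hydration_params()] object.
#' @param counts Optional list from [count_pi_and_rings()].
#' @return Energy in kJ/mol.
#' @export
apolar_term <- function(record, params = hydration_params(),
                        counts = count_pi_and_rings(record)) {
  f <- list(N_s = surface_area(record), N_r = counts$N_r,
            N_pi2 = counts$N_pi2, N_pi1 = counts$N_pi1)
  apolar_from_features(f, params)
}

apolar_from_features <- function(f, params) {
  params$g_0 + params$g_s * f$N_s + params$g_r * f$N_r +
    params$g_pi2 * f$N_pi2 + params$g_pi1 * f$N_pi1
}

surface_area <- function(record) {
  a <- record$atoms
  heavy <- which(a$element != "H")
  if (!length(heavy)) return(0)
  if (anyNA(a$r_vdw[heavy])) {
    stop("state error: radii missing; run compute_charges_radii() first",
         call. = FALSE)
  }
  sum(atomic_surface(a$r_vdw[heavy], a$n_l[heavy], a$hyb[heavy]))
}

#' Acceptor-acceptor interaction contribution
#'
#' `dG_i = g_i * sum_j a_j * (sum_n a_k + sum_nn a_l + F * sum_nnn a_m)`
#' where `a_p = sa_p * n_LP^exp_a` and n/nn/nnn are acceptor atoms at
#' topological distance 1/2/3 from the origin acceptor j. Every ordered
#' pair contributes once, exactly as written, so an unordered pair is
#' counted from both origins.
#'
#' @param strengths A `strength_set`.
#' @param record The corresponding `mol_record`.
#' @param params A [hydration_params()] object.
#' @return Energy in kJ/mol.
#' @export
interaction_term <- function(strengths, record,
                             params = hydration_params()) {
  f <- hydration_features(record, strengths)
  interaction_from_features(f, params)
}

interaction_from_features <- function(f, params) {
  acc <- f$acceptors
  if (nrow(acc) < 2) return(0)
  a <- acc$sa * acc$n_LP^params$exp_a
  near <- if (nrow(f$pairs_near)) {
    sum(a[f$pairs_near[, 1]] * a[f$pairs_near[, 2]])
  } else 0
  far <- if (nrow(f$pairs_nnn)) {
    sum(a[f$pairs_nnn[, 1]] * a[f$pairs_nnn[, 2]])
  } else 0
  # unordered pairs stored once; ordered-pair sum doubles them
  params$g_i * 2 * (near + params$F * far)
}

#' Extract the per-molecule features consumed by the energy terms
#'
#' Everything the three terms need, independent of the free parameters:
#' donor (strength, multiplicity) rows, acceptor (strength, lone pairs)
#' rows, surface/ring/pi counts, and acceptor pair lists by topological
#' shell (unordered, distance 1-2 and distance 3).
#'
#' @inheritParams polar_term
#' @return A list of class `hydration_features`.
#' @export
hydration_features <- function(record, strengths,
                               donor_scope = c("xh-only", "all-h"),
                               donor_aggregation = c("mean", "max")) {
  donor_scope <- match.arg(donor_scope)
  donor_aggregation <- match.arg(donor_aggregation)
  a <- record$atoms
  parent <- heavy_neighbour(record)
  h_idx <- as.integer(names(strengths$donor))
  keep <- if (donor_scope == "xh-only") {
    a$element[parent[h_idx]] != "C"
  } else rep(TRUE, length(h_idx))
  donors <- data.frame(atom = integer(0), sd = numeric(0),
                       n_H = numeric(0))
  if (any(keep)) {
    sd_by_parent <- split(unname(strengths$donor)[keep],
                          parent[h_idx][keep])
    agg <- if (donor_aggregation == "mean") {
      vapply(sd_by_parent, mean, numeric(1))
    } else {
      vapply(sd_by_parent, max, numeric(1))
    }
    pidx <- as.integer(names(sd_by_parent))
    donors <- data.frame(atom = pidx, sd = unname(agg),
                         n_H = vapply(sd_by_parent, length, numeric(1)))
  }
  acc_idx <- as.integer(names(strengths$acceptor))
  acceptors <- data.frame(atom = acc_idx,
                          sa = unname(strengths$acceptor),
                          n_LP = a$n_LP[acc_idx])
  stopifnot(all(acceptors$n_LP >= 1))
  pairs_near <- matrix(integer(0), 0, 2)
  pairs_nnn <- matrix(integer(0), 0, 2)
  if (length(acc_idx) >= 2) {
    dist <- topo_distances(record)[acc_idx, acc_idx, drop = FALSE]
    for (p in seq_len(length(acc_idx) - 1)) {
      for (qq in seq(p + 1, length(acc_idx))) {
        d <- dist[p, qq]
        if (d <= 2) pairs_near <- rbind(pairs_near, c(p, qq))
        else if (d == 3) pairs_nnn <- rbind(pairs_nnn, c(p, qq))
      }
    }
  }
  counts <- count_pi_and_rings(record)
  structure(list(
    id = record$id,
    donors = donors, acceptors = acceptors,
    N_s = surface_area(record),
    N_r = counts$N_r, N_pi2 = counts$N_pi2, N_pi1 = counts$N_pi1,
    pairs_near = pairs_near, pairs_nnn = pairs_nnn,
    strengths = strengths
  ), class = "hydration_features")
}

energy_from_features <- function(f, params) {
  dg_p <- polar_from_features(f, params)
  dg_a <- apolar_from_features(f, params)
  dg_i <- interaction_from_features(f, params)
  structure(list(
    id = f$id,
    dG_polar = dg_p, dG_apolar = dg_a, dG_interaction = dg_i,
    dG_total = dg_p + dg_a + dg_i,
    N_s = f$N_s, N_r = f$N_r, N_pi2 = f$N_pi2, N_pi1 = f$N_pi1,
    strengths = f$strengths
  ), class = "hydration_result")
}

#' Total hydration free energy of one molecule
#'
#' Computes the strength set once and evaluates the polar, apolar and
#' interaction terms on it; the total is their exact sum.
#'
#' @param record A `mol_record` with conformer and charges (charges are
#'   computed on the fly if missing).
#' @param params A [hydration_params()] object.
#' @param donor_scope,donor_aggregation See [polar_term()].
#' @return An object of class `hydration_result` with the three
#'   contributions and their total in kJ/mol, plus the surface/ring/pi
#'   counts and the underlying `strength_set`.
#' @export
total_hydration <- function(record, params = hydration_params(),
                            donor_scope = "xh-only",
                            donor_aggregation = "mean") {
  if (anyNA(record$atoms$q)) {
    record <- compute_charges_radii(record)
  }
  strengths <- molecular_strengths(record, params$strength)
  f <- hydration_features(record, strengths, donor_scope,
                          donor_aggregation)
  energy_from_features(f, params)
}

#' @export
print.hydration_result <- function(x, ...) {
  cat(sprintf("<hydration_result> %s\n", x$id))
  cat(sprintf("  dG_polar = %.2f, dG_apolar = %.2f, dG_interaction = %.2f kJ/mol\n",
              x$dG_polar, x$dG_apolar, x$dG_interaction))
  cat(sprintf("  dG_total = %.2f kJ/mol\n", x$dG_total))
  invisible(x)
}

#' Batch hydration prediction
#'
#' Applies [total_hydration()] to a list of prepared records; per-molecule
#' failures are collected, not fatal, and reported in the `failures`
#' attribute.
#'
#' @param records List of `mol_record`.
#' @param params A [hydration_params()] object.
#' @param ... Passed to [total_hydration()].
#' @return data.frame with one row per successful molecule: id, the three
#'   terms, the total, and the four molecular strength aggregates.
#' @export
predict_hydration <- function(records, params = hydration_params(), ...) {
  if (inherits(records, "mol_record")) records <- list(records)
  rows <- list()
  fails <- list()
  for (r in records) {
    res <- tryCatch(total_hydration(r, params, ...), error = identity)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <-
        data.frame(id = r$id, error = conditionMessage(res))
    } else {
      s <- res$strengths
      rows[[length(rows) + 1]] <- data.frame(
        id = res$id, dG_polar = res$dG_polar, dG_apolar = res$dG_apolar,
        dG_interaction = res$dG_interaction, dG_total = res$dG_total,
        sdx_mol = s$sdx_mol, sdc_mol = s$sdc_mol, sd_mol = s$sd_mol,
        sa_mol = s$sa_mol, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0))
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(id = character(0), error = character(0))
  out
}
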