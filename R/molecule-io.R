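# Molecule input, conformer preparation and atomic feature perception.
#
# A `mol_record` carries everything downstream equations consume: the atom
# table (element, formal charge, hybridisation, neighbour counts, lone
# pairs, and - once a charge backend has run - partial charges and vdW
# radii), the bond list, and 3D coordinates in Angstrom.

SUPPORTED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                        "Cl", "Br", "I")

# group valence electron counts for the lone-pair table
VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
                       Si = 4, P = 5, S = 6, Cl = 7, Br = 7, I = 7)

new_mol_record <- function(helper_entry, id = NULL,
                           conformer_source = NA_character_) {
  e <- helper_entry
  atoms <- data.frame(
    element = vapply(e$atoms, `[[`, character(1), "element"),
    formal_charge = vapply(e$atoms, `[[`, numeric(1), "fc"),
    hyb = vapply(e$atoms, `[[`, character(1), "hyb"),
    aromatic = vapply(e$atoms, `[[`, logical(1), "aromatic"),
    in_ring = vapply(e$atoms, `[[`, logical(1), "in_ring"),
    n_H = vapply(e$atoms, `[[`, numeric(1), "n_H"),
    n_l = vapply(e$atoms, `[[`, numeric(1), "n_l"),
    valence = vapply(e$atoms, `[[`, numeric(1), "valence"),
    stringsAsFactors = FALSE
  )
  atoms$n_LP <- NA_real_
  atoms$q <- NA_real_
  atoms$r_vdw <- NA_real_
  bonds <- if (length(e$bonds)) {
    data.frame(
      i = vapply(e$bonds, function(b) b[[1]], numeric(1)) + 1,
      j = vapply(e$bonds, function(b) b[[2]], numeric(1)) + 1,
      order = vapply(e$bonds, function(b) b[[3]], numeric(1))
    )
  } else {
    data.frame(i = numeric(0), j = numeric(0), order = numeric(0))
  }
  coords <- NULL
  if (!is.null(e$coords)) {
    coords <- do.call(rbind, lapply(e$coords, unlist))
    colnames(coords) <- c("x", "y", "z")
  }
  coords2d <- NULL
  if (!is.null(e$coords2d)) {
    coords2d <- do.call(rbind, lapply(e$coords2d, unlist))
    colnames(coords2d) <- c("x", "y")
  }
  rec <- structure(list(
    id = if (is.null(id)) e$id else id,
    smiles = e$smiles,
    atoms = atoms,
    bonds = bonds,
    coords = coords,
    coords2d = coords2d,
    n_sssr = e$n_sssr,
    total_charge = e$total_charge,
    conformer_source = conformer_source,
    backend = NA_character_
  ), class = "mol_record")
  perceive_features(rec)
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record> %s  %s\n", x$id, x$smiles))
  cat(sprintf("  %d atoms (%d heavy), %d bonds, conformer: %s, charges: %s\n",
              nrow(x$atoms), sum(x$atoms$element != "H"), nrow(x$bonds),
              ifelse(is.na(x$conformer_source), "none", x$conformer_source),
              ifelse(all(is.na(x$atoms$q)), "unset", x$backend)))
  invisible(x)
}

n_atoms <- function(record) nrow(record$atoms)

#' Load molecules from a SMILES or SDF file
#'
#' SMILES files carry one molecule per line with an optional
#' whitespace-separated identifier; SDF files are split on `$$$$` and the
#' first conformer block of each record is read (coordinates kept, flagged
#' `as-provided`, when the block is 3D). Unparseable entries are reported
#' with their line/record number via a warning and returned in the
#' `failures` attribute; they are never silently dropped.
#'
#' @param path Input file.
#' @param format `"smiles"` or `"sdf"`.
#' @return A list of `mol_record` objects, input order preserved, with
#'   attribute `failures` (data.frame of entry, id, error).
#' @export
load_molecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty input: no molecules in ", path,
                             call. = FALSE)
    entries <- lapply(seq_along(lines), function(k) {
      tok <- strsplit(trimws(lines[[k]]), "\\s+")[[1]]
      id <- if (length(tok) > 1) paste(tok[-1], collapse = " ")
            else sprintf("mol%03d", k)
      list(id = id, smiles = tok[[1]])
    })
    res <- run_molprep(entries, embed = FALSE, minimise = FALSE)
    src <- rep(NA_character_, length(entries))
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    blocks <- strsplit(txt, "\\${4}\\s*\n?")[[1]]
    blocks <- blocks[grepl("M  END", blocks, fixed = TRUE)]
    if (!length(blocks)) stop("empty input: no molecules in ", path,
                              call. = FALSE)
    blocks <- sub("^\n+", "", blocks)
    entries <- lapply(seq_along(blocks), function(k) {
      title <- trimws(strsplit(blocks[[k]], "\n")[[1]][1])
      id <- if (nzchar(title)) title else sprintf("mol%03d", k)
      list(id = id, molblock = blocks[[k]])
    })
    res <- run_molprep(entries, embed = FALSE, minimise = FALSE,
                       preserve = TRUE)
    src <- rep("as-provided", length(entries))
  }
  ok <- vapply(res, `[[`, logical(1), "ok")
  errors <- vapply(seq_along(res), function(k) {
    if (ok[[k]]) NA_character_ else res[[k]]$error %||% "unknown"
  }, character(1))
  records <- vector("list", length(res))
  for (k in which(ok)) {
    rec <- tryCatch(new_mol_record(res[[k]], id = entries[[k]]$id,
                                   conformer_source = src[[k]]),
                    error = identity)
    if (inherits(rec, "error")) {  # e.g. unsupported element
      ok[k] <- FALSE
      errors[k] <- conditionMessage(rec)
      next
    }
    # an SDF block with all-zero z is a 2D sketch, not a conformation
    if (identical(src[[k]], "as-provided") &&
        (is.null(rec$coords) || all(abs(rec$coords[, "z"]) < 1e-8))) {
      rec$conformer_source <- NA_character_
      rec$coords <- NULL
    }
    records[[k]] <- rec
  }
  failures <- data.frame(
    entry = which(!ok),
    id = vapply(which(!ok), function(k) entries[[k]]$id, character(1)),
    error = errors[!ok]
  )
  if (nrow(failures)) {
    warning(sprintf("%d entr%s failed to parse (see attr(, 'failures')): %s",
                    nrow(failures), ifelse(nrow(failures) == 1, "y", "ies"),
                    paste(failures$entry, collapse = ", ")), call. = FALSE)
  }
  if (!any(ok)) stop("empty input: zero parseable molecules in ", path,
                     call. = FALSE)
  records <- records[ok]
  attr(records, "failures") <- failures
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prepare 3D conformers for a batch of molecule records
#'
#' Hydrogens are made explicit, one conformer is embedded deterministically
#' from `seed` (distance-geometry ETKDG) and minimised with MMFF94.
#' Records already carrying 3D coordinates keep them untouched when
#' `preserve = TRUE` (hydrogens are still added). Repeated calls with the
#' same seed give identical coordinates.
#'
#' @param records A list of `mol_record`, or a single record.
#' @param seed Integer embedding seed.
#' @param preserve Keep provided 3D coordinates instead of re-embedding.
#' @param minimise MMFF94-minimise after embedding.
#' @return A list of prepared records (or a single record if a single
#'   record was given), with attribute `failures` listing conformer errors
#'   by molecule identifier.
#' @export
prepare_conformers <- function(records, seed = 1L, preserve = FALSE,
                               minimise = TRUE) {
  single <- inherits(records, "mol_record")
  if (single) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "mol_record")))
  entries <- lapply(records, function(r) {
    if (preserve && !is.null(r$coords)) {
      list(id = r$id, molblock = as_molblock(r))
    } else {
      list(id = r$id, smiles = r$smiles)
    }
  })
  res <- run_molprep(entries, seed = seed, embed = TRUE,
                     minimise = minimise, preserve = preserve)
  ok <- vapply(res, `[[`, logical(1), "ok")
  out <- vector("list", length(res))
  for (k in which(ok)) {
    out[[k]] <- new_mol_record(
      res[[k]], id = records[[k]]$id,
      conformer_source = if (preserve && !is.null(records[[k]]$coords))
        "as-provided" else "embedded-minimised")
  }
  failures <- data.frame(
    id = vapply(which(!ok), function(k) records[[k]]$id, character(1)),
    error = vapply(res[!ok], function(r) r$error %||% "unknown",
                   character(1))
  )
  if (single) {
    if (!ok[[1]]) stop("conformer error for molecule '", records[[1]]$id,
                       "': ", failures$error[[1]], call. = FALSE)
    return(out[[1]])
  }
  if (nrow(failures)) {
    warning(sprintf("conformer errors for %d molecule(s): %s",
                    nrow(failures), paste(failures$id, collapse = ", ")),
            call. = FALSE)
  }
  out <- out[ok]
  attr(out, "failures") <- failures
  out
}

#' @rdname prepare_conformers
#' @export
prepare_conformer <- function(records, seed = 1L, preserve = FALSE,
                              minimise = TRUE) {
  prepare_conformers(records, seed = seed, preserve = preserve,
                     minimise = minimise)
}

# minimal V2000 writer (coordinates + bonds), used to hand conformations
# back to the helper when preserving deposited geometries
as_molblock <- function(record) {
  stopifnot(!is.null(record$coords))
  n <- n_atoms(record)
  nb <- nrow(record$bonds)
  lines <- c(record$id, "  hbhydro", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (k in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              record$coords[k, 1], record$coords[k, 2],
                              record$coords[k, 3], record$atoms$element[k]))
  }
  for (k in seq_len(nb)) {
    ord <- record$bonds$order[k]
    lines <- c(lines, sprintf("%3d%3d%3d  0", record$bonds$i[k],
                              record$bonds$j[k],
                              if (ord == 1.5) 4 else as.integer(ord)))
  }
  chg <- which(record$atoms$formal_charge != 0)
  for (k in chg) {
    lines <- c(lines, sprintf("M  CHG  1%4d%4d", k,
                              as.integer(record$atoms$formal_charge[k])))
  }
  paste(c(lines, "M  END"), collapse = "\n")
}

#' Perceive lone pairs and validate atomic features
#'
#' Lone pairs follow a fixed element/valence table:
#' `n_LP = (group valence electrons - total bond order - formal charge)/2`,
#' with one pair removed when the atom donates it to an aromatic pi system
#' (pyrrole-type nitrogen, aromatic oxygen/sulfur). Carbon and hydrogen
#' carry no lone pairs. Elements outside the supported set and heavy atoms
#' with hybridisation outside sp1/sp2/sp3 are rejected.
#'
#' @param record A `mol_record`.
#' @return The record with the `n_LP` column filled.
#' @export
perceive_features <- function(record) {
  a <- record$atoms
  bad <- setdiff(unique(a$element), SUPPORTED_ELEMENTS)
  if (length(bad)) {
    stop("unsupported element(s) in molecule '", record$id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hyp <- a$element != "H" & !(a$hyb %in% c("sp1", "sp2", "sp3"))
  if (any(hyp)) {
    stop("unsupported hybridisation ('other') on atom(s) ",
         paste(which(hyp), collapse = ", "), " of molecule '", record$id,
         "'", call. = FALSE)
  }
  v <- VALENCE_ELECTRONS[a$element]
  nlp <- (v - a$valence - a$formal_charge) / 2
  nlp[a$element %in% c("C", "H")] <- 0
  # aromatic atoms donating their lone pair into the ring pi system
  donates <- (a$element == "N" & a$aromatic & (a$n_l + a$n_H) == 3) |
             (a$element %in% c("O", "S") & a$aromatic)
  nlp[donates] <- nlp[donates] - 1
  nlp <- floor(pmax(nlp, 0))
  record$atoms$n_LP <- as.numeric(nlp)
  record
}

#' Ring and pi-orbital counts for the apolar term
#'
#' The pi-orbital count gains two per sp1-hybridised and one per
#' sp2-hybridised non-hydrogen atom; the ring count is the
#' smallest-set-of-smallest-rings (SSSR) size of the whole molecule.
#'
#' @param record A `mol_record`.
#' @return A list with `N_pi2`, `N_pi1` and `N_r`.
#' @export
count_pi_and_rings <- function(record) {
  heavy <- record$atoms$element != "H"
  list(N_pi2 = 2 * sum(record$atoms$hyb[heavy] == "sp1"),
       N_pi1 = 1 * sum(record$atoms$hyb[heavy] == "sp2"),
       N_r = record$n_sssr)
}

# unweighted topological distance matrix over the bond graph
topo_distances <- function(record) {
  n <- n_atoms(record)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(record$bonds)) {
    g <- igraph::add_edges(g, rbind(record$bonds$i, record$bonds$j))
  }
  igraph::distances(g)
}
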