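# Synthetic molecule records and brute-force oracles.
#
# A synthetic record bypasses the preparation pipeline entirely: the bond
# graph, charges and lone-pair counts are set directly, which lets
# property tests explore topologies and charge patterns independently of
# any chemistry toolkit.

make_record <- function(elements, bonds, q = NULL, n_LP = NULL,
                        hyb = NULL, r_vdw = NULL, coords = NULL,
                        id = "synthetic", n_sssr = 0) {
  n <- length(elements)
  bonds_df <- if (length(bonds)) {
    data.frame(i = vapply(bonds, `[[`, numeric(1), 1),
               j = vapply(bonds, `[[`, numeric(1), 2),
               order = 1)
  } else data.frame(i = numeric(0), j = numeric(0), order = numeric(0))
  nH <- nl <- numeric(n)
  for (k in seq_len(nrow(bonds_df))) {
    i <- bonds_df$i[k]; j <- bonds_df$j[k]
    if (elements[j] == "H") nH[i] <- nH[i] + 1 else nl[i] <- nl[i] + 1
    if (elements[i] == "H") nH[j] <- nH[j] + 1 else nl[j] <- nl[j] + 1
  }
  structure(list(
    id = id, smiles = NA_character_,
    atoms = data.frame(
      element = elements, formal_charge = 0,
      hyb = if (is.null(hyb)) ifelse(elements == "H", "h", "sp3") else hyb,
      aromatic = FALSE, in_ring = FALSE,
      n_H = nH, n_l = nl - nH * 0,
      valence = nH + nl,
      n_LP = if (is.null(n_LP)) ifelse(elements %in% c("O", "N"), 1, 0)
             else n_LP,
      q = if (is.null(q)) rep(0, n) else q,
      r_vdw = if (is.null(r_vdw)) rep(1.5, n) else r_vdw,
      stringsAsFactors = FALSE),
    bonds = bonds_df,
    coords = coords, coords2d = NULL,
    n_sssr = n_sssr, total_charge = 0,
    conformer_source = "as-provided", backend = "synthetic"
  ), class = "mol_record")
}

# random connected molecule-like graph with random charges and a random
# subset of acceptor atoms
random_record <- function(n_atoms = 8) {
  elements <- sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE)
  elements[1] <- "C"  # guarantee a heavy root
  degree <- numeric(n_atoms)
  bonds <- vector("list", n_atoms - 1)
  for (k in 2:n_atoms) {
    open <- which(seq_len(k - 1) > 0 & degree[seq_len(k - 1)] < 4 &
                    elements[seq_len(k - 1)] != "H")
    if (!length(open)) open <- 1
    p <- open[sample.int(length(open), 1)]
    bonds[[k - 1]] <- c(p, k)
    degree[p] <- degree[p] + 1
    degree[k] <- degree[k] + 1
  }
  # occasionally close a ring between two under-coordinated heavy atoms
  heavy <- which(elements != "H" & degree < 4)
  if (length(heavy) > 3 && stats::runif(1) < 0.5) {
    extra <- sort(sample(heavy, 2))
    already <- any(vapply(bonds, function(b) all(sort(b) == extra),
                          logical(1)))
    if (!already) bonds <- c(bonds, list(extra))
  }
  q <- round(stats::runif(n_atoms, -0.5, 0.5), 3)
  n_LP <- ifelse(elements %in% c("O", "N"),
                 sample(1:3, n_atoms, replace = TRUE), 0)
  make_record(elements, bonds, q = q, n_LP = n_LP,
              id = paste0("rand", n_atoms))
}

# breadth-first shell enumeration, independent of igraph
bfs_distances_from <- function(record, start) {
  n <- nrow(record$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(record$bonds))) {
    i <- record$bonds$i[k]; j <- record$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- rep(Inf, n)
  d[start] <- 0
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) if (d[w] > d[v] + 1) {
        d[w] <- d[v] + 1
        nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
  }
  d
}

# oracle for the corrective shell charge: explicit BFS shells
bf_delta_q <- function(atom_index, record, T) {
  d <- bfs_distances_from(record, atom_index)
  q <- record$atoms$q
  sum(T * q[d == 1]) + sum(T^2 * q[d == 2]) + sum(T^3 * q[d == 3])
}

# oracle for the interaction term: literal ordered double loop over
# acceptor atoms with BFS distances
bf_interaction <- function(record, sa, params) {
  acc <- which(record$atoms$n_LP >= 1)
  if (length(acc) < 2) return(0)
  a <- sa[acc] * record$atoms$n_LP[acc]^params$exp_a
  total <- 0
  for (jj in seq_along(acc)) {
    d <- bfs_distances_from(record, acc[jj])
    for (kk in seq_along(acc)) {
      if (jj == kk) next
      dd <- d[acc[kk]]
      if (dd <= 2) total <- total + a[jj] * a[kk]
      else if (dd == 3) total <- total + params$F * a[jj] * a[kk]
    }
  }
  params$g_i * total
}

# strength_set wrapper around explicit per-atom strengths
make_strengths <- function(record, donor = NULL, acceptor = NULL) {
  a <- record$atoms
  if (is.null(donor)) {
    h <- which(a$element == "H")
    donor <- stats::setNames(rep(0, length(h)), h)
  }
  if (is.null(acceptor)) {
    acc <- which(a$n_LP >= 1)
    acceptor <- stats::setNames(rep(1, length(acc)), acc)
  }
  parent <- hbhydro:::heavy_neighbour(record)
  di <- as.integer(names(donor))
  par_elem <- a$element[parent[di]]
  sdx <- sum(donor[par_elem != "C"])
  sdc <- sum(donor[par_elem == "C"])
  structure(list(id = record$id, donor = donor, acceptor = acceptor,
                 sdx_mol = sdx, sdc_mol = sdc, sd_mol = sdx + sdc,
                 sa_mol = sum(acceptor *
                                a$n_LP[as.integer(names(acceptor))])),
            class = "strength_set")
}

# one shared prepared-and-charged molecule set for the whole suite
prepared_examples <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- tempfile(fileext = ".smi")
      writeLines(c("O water", "CCO ethanol", "c1ccccc1 benzene",
                   "C#C acetylene", "c1ccncc1 pyridine",
                   "c1cc[nH]c1 pyrrole", "c1ccoc1 furan", "CC ethane",
                   "CC(=O)Nc1ccc(O)cc1 paracetamol", "CCCl chloroethane"),
                 f)
      mols <- load_molecules(f, "smiles")
      mols <- prepare_conformers(mols, seed = 42)
      mols <- lapply(mols, compute_charges_radii)
      names(mols) <- vapply(mols, `[[`, character(1), "id")
      cache <<- mols
    }
    cache
  }
})
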