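# Parsing, conformer preparation and atomic perception.

test_that("SMILES loading preserves order, ids and heavy-atom counts", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("O water", "CCO ethanol"), f)
  mols <- load_molecules(f, "smiles")
  expect_length(mols, 2)
  expect_equal(vapply(mols, `[[`, character(1), "id"),
               c("water", "ethanol"))
  expect_equal(sum(mols[[1]]$atoms$element != "H"), 1)
  expect_equal(nrow(mols[[1]]$atoms), 3)  # hydrogens made explicit
  expect_true(all(mols[[1]]$bonds$i <= nrow(mols[[1]]$atoms)))
})

test_that("corrupt entries are reported with their line number, not dropped", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("O water", "C1CC garbage", "CC ethane"), f)
  expect_warning(mols <- load_molecules(f, "smiles"), "failed to parse")
  expect_length(mols, 2)
  fails <- attr(mols, "failures")
  expect_equal(fails$entry, 2)
  expect_match(fails$error, "unparseable")
  expect_error(load_molecules(tempfile(), "smiles"), "cannot read")
  f2 <- tempfile(fileext = ".smi")
  writeLines("not_a_smiles_at_all!!", f2)
  expect_error(suppressWarnings(load_molecules(f2, "smiles")),
               "zero parseable")
})

test_that("unsupported elements fail per molecule with a typed error", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("O water", "[SeH2] selane"), f)
  expect_warning(mols <- load_molecules(f, "smiles"), "failed to parse")
  expect_length(mols, 1)
  expect_match(attr(mols, "failures")$error, "unsupported element")
})

test_that("conformer embedding is seed-deterministic and minimised", {
  f <- tempfile(fileext = ".smi")
  writeLines("O water", f)
  w <- load_molecules(f, "smiles")[[1]]
  expect_true(is.na(w$conformer_source))
  a <- prepare_conformer(w, seed = 11)
  b <- prepare_conformer(w, seed = 11)
  expect_identical(a$coords, b$coords)
  expect_equal(a$conformer_source, "embedded-minimised")
  # different seeds converge to the same minimised O-H bond length
  c2 <- prepare_conformer(w, seed = 99)
  bond_len <- function(m) {
    o <- which(m$atoms$element == "O")
    h <- which(m$atoms$element == "H")[1]
    sqrt(sum((m$coords[o, ] - m$coords[h, ])^2))
  }
  expect_lt(abs(bond_len(a) - bond_len(c2)), 0.01)
})

test_that("SDF conformations are preserved and hydrogens added", {
  eth <- prepared_examples()$ethanol
  sdf <- tempfile(fileext = ".sdf")
  writeLines(c(hbhydro:::as_molblock(eth), "$$$$"), sdf)
  back <- load_molecules(sdf, "sdf")
  expect_length(back, 1)
  expect_equal(back[[1]]$conformer_source, "as-provided")
  expect_equal(back[[1]]$id, "ethanol")
  # preservation keeps heavy-atom coordinates up to molblock formatting
  prep <- prepare_conformer(back[[1]], preserve = TRUE)
  expect_equal(prep$conformer_source, "as-provided")
  heavy <- back[[1]]$atoms$element != "H"
  expect_equal(prep$coords[heavy, ], back[[1]]$coords[heavy, ],
               tolerance = 1e-3)
})

test_that("perception fills hybridisation, neighbour and lone-pair counts", {
  ex <- prepared_examples()
  w <- ex$water
  o <- which(w$atoms$element == "O")
  expect_equal(unlist(w$atoms[o, c("n_H", "n_l", "n_LP")]),
               c(n_H = 2, n_l = 0, n_LP = 2))
  expect_equal(w$atoms$hyb[o], "sp3")

  bz <- ex$benzene
  carbons <- which(bz$atoms$element == "C")
  expect_true(all(bz$atoms$hyb[carbons] == "sp2"))
  expect_true(all(bz$atoms$n_l[carbons] == 2))
  expect_true(all(bz$atoms$n_LP[carbons] == 0))
  expect_true(all(bz$atoms$in_ring[carbons]))

  py <- ex$pyridine
  n <- which(py$atoms$element == "N")
  expect_equal(py$atoms$n_LP[n], 1)
  expect_equal(py$atoms$hyb[n], "sp2")

  # pyrrole nitrogen donates its pair to the ring; furan oxygen keeps one
  expect_equal(ex$pyrrole$atoms$n_LP[ex$pyrrole$atoms$element == "N"], 0)
  expect_equal(ex$furan$atoms$n_LP[ex$furan$atoms$element == "O"], 1)
  expect_equal(ex$chloroethane$atoms$n_LP[
    ex$chloroethane$atoms$element == "Cl"], 3)
})

test_that("pi and ring counts follow the hybridisation increments", {
  ex <- prepared_examples()
  expect_equal(unlist(count_pi_and_rings(ex$ethane)),
               c(N_pi2 = 0, N_pi1 = 0, N_r = 0))
  expect_equal(unlist(count_pi_and_rings(ex$benzene)),
               c(N_pi2 = 0, N_pi1 = 6, N_r = 1))
  expect_equal(unlist(count_pi_and_rings(ex$acetylene)),
               c(N_pi2 = 4, N_pi1 = 0, N_r = 0))
})
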