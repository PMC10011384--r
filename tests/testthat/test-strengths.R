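# Corrective shell charges and donor/acceptor strengths.

test_that("delta_q evaluates the attenuated shell sums", {
  # H-X with X carrying q = 1: single alpha neighbour
  r <- make_record(c("H", "O"), list(c(1, 2)), q = c(0, 1))
  expect_equal(delta_q(1, r, T = 0.274), 0.274)
  # chain H-A-B-C with q(B)=1 (beta), q(C)=-1 (gamma)
  r2 <- make_record(c("H", "C", "C", "C"),
                    list(c(1, 2), c(2, 3), c(3, 4)),
                    q = c(0, 0, 1, -1))
  expect_equal(delta_q(1, r2, T = 0.274), 0.274^2 - 0.274^3)
  # all neighbour charges zero
  expect_equal(delta_q(1, make_record(c("H", "C"), list(c(1, 2)))), 0)
  # atoms beyond distance 3 contribute nothing
  r3 <- make_record(c("H", "C", "C", "C", "O"),
                    list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
                    q = c(0, 0, 0, 0, 99))
  expect_equal(delta_q(1, r3), 0)
})

test_that("multiply-reachable atoms count once, at shortest distance", {
  # triangle: atom 3 is alpha of 1 via direct bond, despite the 1-2-3 path
  r <- make_record(c("C", "C", "C"), list(c(1, 2), c(2, 3), c(1, 3)),
                   q = c(0, 0, 1))
  expect_equal(delta_q(1, r, T = 0.274), 0.274)
})

test_that("explicit BFS oracle matches delta_q on random graphs", {
  set.seed(101)
  for (k in 1:100) {
    r <- random_record(sample(4:12, 1))
    i <- sample(nrow(r$atoms), 1)
    expect_equal(delta_q(i, r, T = 0.274), bf_delta_q(i, r, 0.274),
                 tolerance = 1e-12)
  }
})

test_that("donor and acceptor strengths are linear in D and A", {
  r <- make_record(c("H", "O", "H"), list(c(1, 2), c(2, 3)),
                   q = c(0.3, -0.6, 0.3), n_LP = c(0, 2, 0))
  p1 <- strength_params(D = 10, A = -2)
  p2 <- strength_params(D = 20, A = -4)
  expect_equal(donor_strength(1, r, p2), 2 * donor_strength(1, r, p1))
  expect_equal(acceptor_strength(2, r, p2), 2 * acceptor_strength(2, r, p1))
  # T -> 0 limit: corrective term vanishes
  p0 <- strength_params(D = 10, A = -2, T = 1e-12)
  expect_equal(donor_strength(1, r, p0), 10 * 0.3, tolerance = 1e-9)
  expect_equal(acceptor_strength(2, r, p0), -2 * -0.6, tolerance = 1e-9)
})

test_that("role errors are raised for wrong atom types", {
  r <- make_record(c("H", "O"), list(c(1, 2)), q = c(0.3, -0.3),
                   n_LP = c(0, 2))
  expect_error(donor_strength(2, r), "not a hydrogen")
  expect_error(acceptor_strength(1, r), "no lone pairs")
})

test_that("locality: charges beyond distance 3 never move a strength", {
  r <- make_record(c("H", "C", "C", "C", "C", "O"),
                   list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6)),
                   q = c(0.1, -0.1, 0.2, -0.2, 0.1, -0.1),
                   n_LP = c(0, 0, 0, 0, 0, 2))
  s1 <- donor_strength(1, r)
  r$atoms$q[6] <- 5  # distance 5 from the hydrogen
  expect_equal(donor_strength(1, r), s1)
})

test_that("molecular aggregates split X-H from C-H and weight lone pairs", {
  eth <- prepared_examples()$ethanol
  s <- molecular_strengths(eth)
  expect_equal(s$sd_mol, s$sdx_mol + s$sdc_mol)
  expect_equal(s$sd_mol, sum(s$donor), tolerance = 1e-9)
  # every hydrogen in the donor map, every lone-pair atom in the acceptor map
  expect_setequal(as.integer(names(s$donor)),
                  which(eth$atoms$element == "H"))
  expect_setequal(as.integer(names(s$acceptor)),
                  which(eth$atoms$n_LP >= 1))
  # one O-H donor -> sdx has exactly that hydrogen's strength
  parent <- hbhydro:::heavy_neighbour(eth)
  oh <- which(eth$atoms$element == "H" &
                eth$atoms$element[parent] == "O")
  expect_equal(s$sdx_mol, unname(s$donor[as.character(oh)]))
  o <- which(eth$atoms$element == "O")
  expect_equal(s$sa_mol, unname(s$acceptor[as.character(o)]) *
                 eth$atoms$n_LP[o])
})

test_that("a molecule with no hydrogens and no lone pairs aggregates to zero", {
  r <- make_record(c("C", "C"), list(c(1, 2)), q = c(0.1, -0.1),
                   n_LP = c(0, 0))
  s <- molecular_strengths(r)
  expect_equal(s$sd_mol, 0)
  expect_equal(s$sa_mol, 0)
  expect_length(s$donor, 0)
  expect_length(s$acceptor, 0)
})

test_that("strengths export table mirrors the per-atom maps", {
  eth <- prepared_examples()$ethanol
  s <- molecular_strengths(eth)
  tab <- strengths_table(eth, s)
  expect_equal(nrow(tab), length(s$donor) + length(s$acceptor))
  expect_equal(tab$strength[tab$role == "donor"], unname(s$donor))
  expect_true(all(tab$element[tab$role == "donor"] == "H"))
})
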