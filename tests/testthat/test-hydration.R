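# Polar, apolar and interaction terms and their total.

test_that("atomic surface follows the substitution-scaled sphere", {
  expect_equal(atomic_surface(1.5, 0, "sp3"), 4 * pi * 2.25)
  expect_equal(atomic_surface(1.5, 4, "sp3"), 0)
  expect_equal(atomic_surface(1.5, 2, "sp2"), 4 * pi * 2.25 / 3)
  expect_error(atomic_surface(1.5, 3, "sp1"), "valence error")
  expect_error(atomic_surface(1.5, 1, "other"), "sp1/sp2/sp3")
})

test_that("apolar term assembles constant, surface, ring and pi parts", {
  p <- hydration_params()
  # single sp3 atom, r = 1.7 A, unsubstituted, acyclic
  r <- make_record("C", list(), r_vdw = 1.7, hyb = "sp3")
  expect_equal(apolar_term(r, p), 1.884 + 0.0467 * 4 * pi * 1.7^2,
               tolerance = 1e-6)
  # one extra ring at fixed surface and pi counts shifts by g_r
  base <- apolar_term(r, p)
  r_ring <- r; r_ring$n_sssr <- 1
  expect_equal(apolar_term(r_ring, p) - base, -3.643)
  # surface bound: every atomic contribution within [0, full sphere]
  for (m in prepared_examples()) {
    a <- m$atoms[m$atoms$element != "H", ]
    ns <- atomic_surface(a$r_vdw, a$n_l, a$hyb)
    expect_true(all(ns >= 0 - 1e-12))
    expect_true(all(ns <= 4 * pi * a$r_vdw^2 + 1e-12))
  }
})

test_that("polar term indexes donors by heavy atom with mean strengths", {
  p <- hydration_params()
  # water with unit strengths: g_d*1*2^0.5 + g_a*1*2^0.34
  w <- make_record(c("O", "H", "H"), list(c(1, 2), c(1, 3)),
                   n_LP = c(2, 0, 0))
  s <- make_strengths(w, donor = stats::setNames(c(1, 1), c(2, 3)),
                      acceptor = stats::setNames(1, 1))
  expect_equal(polar_term(s, w, p),
               0.908 * sqrt(2) - 16.131 * 2^0.34, tolerance = 1e-9)
  # single X-H donor, sd = 1, n_H = 1, no acceptors -> g_d
  r <- make_record(c("N", "H"), list(c(1, 2)), n_LP = c(0, 0))
  s2 <- make_strengths(r, donor = stats::setNames(1, 2),
                       acceptor = stats::setNames(numeric(0), integer(0)))
  expect_equal(polar_term(s2, r, p), 0.908)
  # no X-H donors and no acceptors -> 0
  r3 <- make_record(c("C", "H"), list(c(1, 2)), n_LP = c(0, 0))
  s3 <- make_strengths(r3, donor = stats::setNames(5, 2),
                       acceptor = stats::setNames(numeric(0), integer(0)))
  expect_equal(polar_term(s3, r3, p), 0)
  # but C-H hydrogens do enter under the all-h scope flag
  expect_equal(polar_term(s3, r3, p, donor_scope = "all-h"), 0.908 * 5)
})

test_that("interaction term pairs acceptors through n/nn/nnn shells", {
  p <- hydration_params()
  # two acceptors at distance 3: both ordered pairs, attenuated by F
  r <- make_record(c("O", "C", "C", "O"),
                   list(c(1, 2), c(2, 3), c(3, 4)), n_LP = c(1, 0, 0, 1))
  s <- make_strengths(r, donor = stats::setNames(numeric(0), integer(0)),
                      acceptor = stats::setNames(c(1, 1), c(1, 4)))
  expect_equal(interaction_term(s, r, p), 4.9996 * 2 * 0.514,
               tolerance = 1e-9)
  # distance >= 4: beyond the nnn range
  r4 <- make_record(c("O", "C", "C", "C", "O"),
                    list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
                    n_LP = c(1, 0, 0, 0, 1))
  s4 <- make_strengths(r4, donor = stats::setNames(numeric(0), integer(0)),
                       acceptor = stats::setNames(c(1, 1), c(1, 5)))
  expect_equal(interaction_term(s4, r4, p), 0)
  # zero or one acceptor -> no pairs
  r1 <- make_record(c("O", "H"), list(c(1, 2)), n_LP = c(2, 0))
  s1 <- make_strengths(r1)
  expect_equal(interaction_term(s1, r1, p), 0)
})

test_that("interaction term equals the brute-force ordered double loop", {
  p <- hydration_params()
  set.seed(202)
  for (k in 1:100) {
    r <- random_record(sample(5:12, 1))
    acc <- which(r$atoms$n_LP >= 1)
    sa <- stats::runif(nrow(r$atoms), -0.2, 1.5)
    s <- make_strengths(r, donor = stats::setNames(numeric(0), integer(0)),
                        acceptor = stats::setNames(sa[acc], acc))
    expect_equal(interaction_term(s, r, p), bf_interaction(r, sa, p),
                 tolerance = 1e-9)
  }
})

test_that("the three terms add exactly and batch prediction preserves order", {
  ex <- prepared_examples()
  for (m in ex[c("water", "ethanol", "paracetamol")]) {
    res <- total_hydration(m)
    expect_identical(res$dG_total,
                     res$dG_polar + res$dG_apolar + res$dG_interaction)
  }
  pred <- predict_hydration(ex)
  expect_equal(pred$id, unname(vapply(ex, `[[`, character(1), "id")))
  expect_equal(pred$dG_total,
               pred$dG_polar + pred$dG_apolar + pred$dG_interaction)
  # water: polar dominates, total negative
  wrow <- pred[pred$id == "water", ]
  expect_lt(wrow$dG_total, 0)
  expect_gt(abs(wrow$dG_polar), abs(wrow$dG_apolar))
})

test_that("every term is invariant under atom relabelling", {
  set.seed(303)
  p <- hydration_params()
  for (k in 1:20) {
    r <- random_record(sample(5:10, 1))
    perm <- sample(nrow(r$atoms))
    r2 <- r
    inv <- order(perm)
    r2$atoms <- r$atoms[perm, ]
    rownames(r2$atoms) <- NULL
    r2$bonds$i <- inv[r$bonds$i]
    r2$bonds$j <- inv[r$bonds$j]
    s1 <- molecular_strengths(r, strength_params())
    s2 <- molecular_strengths(r2, strength_params())
    expect_equal(s1$sd_mol, s2$sd_mol, tolerance = 1e-9)
    expect_equal(s1$sa_mol, s2$sa_mol, tolerance = 1e-9)
    f1 <- hydration_features(r, s1)
    f2 <- hydration_features(r2, s2)
    e1 <- hbhydro:::energy_from_features(f1, p)
    e2 <- hbhydro:::energy_from_features(f2, p)
    expect_equal(e1$dG_total, e2$dG_total, tolerance = 1e-9)
  }
})

test_that("rigid-motion invariance propagates to the total energy", {
  w <- prepared_examples()$ethanol
  w2 <- w
  theta <- 1.2
  rot <- matrix(c(1, 0, 0,
                  0, cos(theta), -sin(theta),
                  0, sin(theta), cos(theta)), 3, 3)
  w2$coords <- sweep(w$coords %*% rot, 2, c(-2, 0.5, 8), `+`)
  colnames(w2$coords) <- colnames(w$coords)
  w2$atoms$q <- NA_real_
  expect_equal(total_hydration(w2)$dG_total, total_hydration(w)$dG_total,
               tolerance = 1e-7)
})

test_that("raising an acceptor strength never shrinks the interaction", {
  p <- hydration_params()
  r <- make_record(c("O", "C", "O"), list(c(1, 2), c(2, 3)),
                   n_LP = c(1, 0, 1))
  sa <- c(0.5, 0.8)
  s <- make_strengths(r, donor = stats::setNames(numeric(0), integer(0)),
                      acceptor = stats::setNames(sa, c(1, 3)))
  base <- interaction_term(s, r, p)
  s$acceptor[1] <- 0.9
  expect_gte(interaction_term(s, r, p), base)
})
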