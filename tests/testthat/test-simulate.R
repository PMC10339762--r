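test_that("fraction_bound matches the depletion quadratic and its limits", {
  expect_equal(fraction_bound(50, 0, 0.85), 0)
  # hand evaluation of the quadratic root at P_T = 0.05 mM, L_T = kd = 0.85
  expect_equal(fraction_bound(50, 0.85, 0.85), 0.4927, tolerance = 2e-4)
  # saturation limit
  expect_equal(fraction_bound(50, 1e4 * 0.85, 0.85), 1, tolerance = 1e-3)
  expect_error(fraction_bound(50, -1, 1), "L_T")
  expect_error(fraction_bound(50, Inf, 1), "finite")
})

test_that("fraction_bound is monotone in ligand, Kd, and dilute-limit exact", {
  L <- seq(0, 20, by = 0.25)
  f <- fraction_bound(50, L, 2)
  expect_true(all(diff(f) > 0))
  kds <- c(0.1, 0.5, 1, 5, 20, 100)
  fk <- vapply(kds, function(k) fraction_bound(50, 2, k), 0)
  expect_true(all(diff(fk) < 0))
  # P_T -> 0: f -> L/(L + kd) with relative error < 1e-3 at P_T <= 1e-3 kd
  for (kd in c(0.5, 2, 10)) {
    f_dep <- fraction_bound(1e-3 * kd * 1000 * 1e-3, 1.7, kd)  # P in uM
    f_lin <- 1.7 / (1.7 + kd)
    expect_lt(abs(f_dep - f_lin) / f_lin, 1e-3)
  }
})

test_that("dual occupancy solver conserves mass and matches closed forms", {
  P_T <- 50
  sol <- solve_dual_occupancy(P_T, 3, 3, 0.85, 6.6, "independent_sites")
  P <- P_T / 1000
  # mass balance of both ligands to solver tolerance
  expect_equal(sol$A_free + P * sol$f_A, 3, tolerance = 1e-9)
  expect_equal(sol$B_free + P * sol$f_B, 3, tolerance = 1e-9)
  # independent sites decouple: each occupancy equals the single-ligand
  # depletion quadratic
  expect_equal(sol$f_A, fraction_bound(P_T, 3, 0.85), tolerance = 1e-8)
  expect_equal(sol$f_B, fraction_bound(P_T, 3, 6.6), tolerance = 1e-8)

  comp <- solve_dual_occupancy(P_T, 2, 2, 1.5, 1.5, "competitive")
  single <- fraction_bound(P_T, 2, 1.5)
  # equal kd, equal totals: each occupancy suppressed below single-ligand
  expect_lt(comp$f_A, single)
  expect_lt(comp$f_B, single)
  expect_equal(comp$f_A, comp$f_B, tolerance = 1e-8)
  expect_equal(comp$A_free + P * comp$f_A, 2, tolerance = 1e-9)
  # shared site: total occupancy below 1
  expect_lt(comp$f_A + comp$f_B, 1)
})

test_that("simulate_sample applies fast-exchange shifts and is seed-pure", {
  assign <- tiny_assignments()
  apo <- simulate_sample(assign, noise_sd = c(0, 0), seed = 1)
  expect_equal(apo$peaks$w_H, assign$w_H)
  expect_equal(apo$peaks$w_N, assign$w_N)

  frag <- fragment_record("F1", site_label = "site2_sY_cleft", kd = 2,
                          dmax = data.frame(residue = c(11L, 20L),
                                            d_H = c(0.2, -0.1),
                                            d_N = c(1, -0.5)))
  # L_T = kd with P_T << kd: shift ~ 0.5 dmax (depletion-corrected)
  f <- fraction_bound(50, 2, 2)
  s <- simulate_sample(assign, list(frag), 2, noise_sd = c(0, 0), seed = 1)
  i <- match(c(11L, 20L), assign$residue)
  expect_equal(s$peaks$w_H[i] - assign$w_H[i], f * c(0.2, -0.1))
  expect_equal(s$peaks$w_N[i] - assign$w_N[i], f * c(1, -0.5))
  expect_equal(f, 0.5, tolerance = 0.02)
  # untouched residues stay put
  expect_equal(s$peaks$w_H[-i], assign$w_H[-i])

  a <- simulate_sample(assign, list(frag), 2, seed = 77)
  b <- simulate_sample(assign, list(frag), 2, seed = 77)
  c2 <- simulate_sample(assign, list(frag), 2, seed = 78)
  expect_identical(a$peaks, b$peaks)
  expect_false(identical(a$peaks, c2$peaks))
})

test_that("titrations follow the binding isotherm point by point", {
  assign <- tiny_assignments()
  frag <- fragment_record("F1", site_label = "site2_sY_cleft", kd = 2,
                          dmax = data.frame(residue = 11L, d_H = 0.3,
                                            d_N = 0))
  ladder <- c(0, 0.5, 1, 2, 4, 6)
  ts <- simulate_titration(assign, frag, ladder, noise_sd = c(0, 0),
                           seed = 1)
  i <- match(11L, assign$residue)
  shifts <- vapply(ts$points, function(p) p$peaks$w_H[[i]], 0) - assign$w_H[[i]]
  expect_equal(shifts, 0.3 * fraction_bound(50, ladder, 2))
  # endpoint shift / dmax equals fraction bound at the top point
  expect_equal(shifts[[length(shifts)]] / 0.3,
               fraction_bound(50, 6, 2))

  # huge kd: response is linear in L_T
  lin <- fragment_record("L", site_label = "site2_sY_cleft", kd = 6000,
                         dmax = data.frame(residue = 11L, d_H = 60, d_N = 0))
  tl <- simulate_titration(assign, lin, ladder, noise_sd = c(0, 0), seed = 1)
  sl <- vapply(tl$points, function(p) p$peaks$w_H[[i]], 0) - assign$w_H[[i]]
  fitlm <- stats::lm(sl ~ ladder)
  expect_gt(summary(fitlm)$r.squared, 1 - 1e-6)

  expect_error(simulate_titration(assign, frag, numeric(0)), "at least")
  expect_error(simulate_titration(assign, frag, c(0.5, 1)), "apo")
  expect_error(simulate_titration(assign, frag, c(0, 1, 1)), "increasing")
})

test_that("dual simulation degenerates and saturates correctly", {
  assign <- tiny_assignments()
  fa <- fragment_record("A", site_label = "site2_sY_cleft", kd = 1,
                        dmax = data.frame(residue = 11L, d_H = 0.2, d_N = 1))
  fb <- fragment_record("B", site_label = "site1_Nloop_helix", kd = 2,
                        dmax = data.frame(residue = 20L, d_H = -0.1,
                                          d_N = 0.5))
  ladder <- c(0, 1, 3)
  # fixed ligand absent -> identical to the plain titration (same seeds)
  sch0 <- dual_schedule("B", 0, "A", ladder, "independent_sites")
  d0 <- simulate_dual(assign, fa, fb, sch0, noise_sd = c(0, 0), seed = 4)
  t0 <- simulate_titration(assign, fa, ladder, noise_sd = c(0, 0), seed = 4)
  for (k in seq_along(ladder)) {
    expect_equal(d0$points[[k]]$peaks$w_H, t0$points[[k]]$peaks$w_H,
                 tolerance = 1e-9)
  }
  # both ligands saturating, independent sites: shifts add fully
  sch <- dual_schedule("B", 5000, "A", c(0, 2500, 5000),
                       "independent_sites")
  ds <- simulate_dual(assign, fa, fb, sch, noise_sd = c(0, 0), seed = 4)
  iA <- match(11L, assign$residue); iB <- match(20L, assign$residue)
  last <- ds$points[[3L]]$peaks
  expect_equal(last$w_H[[iA]] - assign$w_H[[iA]], 0.2, tolerance = 1e-3)
  expect_equal(last$w_H[[iB]] - assign$w_H[[iB]], -0.1, tolerance = 1e-3)
  expect_error(simulate_dual(assign, fa, fa, sch), "distinct")
})
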