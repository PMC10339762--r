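test_that("combined CSP is the nitrogen-weighted Euclidean norm", {
  expect_equal(combined_csp(0, 0), 0)
  expect_equal(combined_csp(0.6, 0), 0.6)
  # sqrt(0.03^2 + (0.2 * 0.2)^2) = sqrt(0.0009 + 0.0016)
  expect_equal(combined_csp(0.03, 0.2), 0.05)
  expect_error(combined_csp(0.1, 0.1, weight = 0), "weight")
})

test_that("combined CSP satisfies the norm axioms", {
  set.seed(2)
  dH <- rnorm(50); dN <- rnorm(50, sd = 3)
  v <- combined_csp(dH, dN)
  expect_true(all(v >= 0))
  expect_true(all((v == 0) == (dH == 0 & dN == 0)))
  # symmetric under sign flips, homogeneous of degree 1
  expect_equal(combined_csp(-dH, dN), v)
  expect_equal(combined_csp(dH, -dN), v)
  expect_equal(combined_csp(2.5 * dH, 2.5 * dN), 2.5 * v)
  # triangle inequality
  expect_true(all(combined_csp(dH[1:25] + dH[26:50], dN[1:25] + dN[26:50]) <=
                    v[1:25] + v[26:50] + 1e-12))
})

test_that("peak tracking matches nearest neighbours and respects the cutoff", {
  ref <- simulate_sample(tiny_assignments(), noise_sd = c(0, 0), seed = 1)
  # identity matching
  tr <- track_peaks(ref, ref)
  expect_equal(nrow(tr$pairs), 8L)
  expect_equal(tr$pairs$dist, rep(0, 8))
  expect_equal(tr$lost, character(0))

  # one peak moved by a scaled 0.1 ppm, rest static
  moved <- ref
  moved$peaks$w_H[[2L]] <- moved$peaks$w_H[[2L]] + 0.06
  moved$peaks$w_N[[2L]] <- moved$peaks$w_N[[2L]] + 0.4
  tr2 <- track_peaks(ref, moved)
  i <- which(tr2$pairs$label == ref$peaks$label[[2L]])
  expect_equal(tr2$pairs$dist[i], sqrt(0.06^2 + (0.2 * 0.4)^2))
  expect_equal(tr2$pairs$dist[-i], rep(0, 7))

  # peak moved beyond max_jump is reported lost, not force-matched
  far <- ref
  far$peaks$w_H[[3L]] <- far$peaks$w_H[[3L]] + 1.5
  tr3 <- track_peaks(ref, far, max_jump = 0.25)
  expect_equal(tr3$lost, ref$peaks$label[[3L]])
  expect_false(ref$peaks$label[[3L]] %in% tr3$pairs$label)
})

test_that("CSP profiles recover per-residue shifts with mean + 2 SD threshold", {
  assign <- tiny_assignments()
  frag <- fragment_record("F", site_label = "site2_sY_cleft", kd = 1,
                          dmax = data.frame(residue = 11L, d_H = 0.3,
                                            d_N = -1.5))
  ts <- simulate_titration(assign, frag, c(0, 0.5, 1, 2, 4, 6),
                           noise_sd = c(0, 0), seed = 1)
  prof <- csp_profile(ts)
  f6 <- fraction_bound(50, 6, 1)
  i <- which(prof$per_residue$label == "C11")
  expect_equal(prof$per_residue$d_H[i], 0.3 * f6, tolerance = 1e-10)
  expect_equal(prof$per_residue$d_N[i], -1.5 * f6, tolerance = 1e-10)
  expect_equal(prof$per_residue$csp[i],
               combined_csp(0.3, -1.5) * f6, tolerance = 1e-10)
  expect_equal(prof$threshold, prof$mean_csp + 2 * prof$sd_csp)
  expect_equal(significant_residues(prof), "C11")

  # inert ligand, no noise: all CSP zero, threshold zero
  inert <- fragment_record("Z")
  tz <- simulate_titration(assign, inert, c(0, 1, 6), noise_sd = c(0, 0),
                           seed = 1)
  pz <- csp_profile(tz)
  expect_equal(max(pz$per_residue$csp), 0)
  expect_equal(pz$threshold, 0)

  # a titration that tracks fewer than 5 residues is refused
  small <- assignment_table(residue = c(1L, 2L), code = c("A", "G"),
                            w_H = c(8, 9), w_N = c(110, 120))
  t2 <- simulate_titration(small, inert, c(0, 1), noise_sd = c(0, 0),
                           seed = 1)
  expect_error(csp_profile(t2), "fewer than 5")
})

test_that("significance selection responds to n_sd as specified", {
  assign <- tiny_assignments()
  inert <- fragment_record("Z")
  ts <- simulate_titration(assign, inert, c(0, 1), noise_sd = c(0.004, 0.02),
                           seed = 3)
  prof <- csp_profile(ts)
  # uniform noise profile: mean + 2 sd leaves at most an outlier or two;
  # n_sd = 0 selects everything above the mean
  above_mean <- sum(prof$per_residue$csp > prof$mean_csp)
  expect_equal(length(significant_residues(prof, 0)), above_mean)
  expect_error(significant_residues(prof, -1), "n_sd")
})

test_that("absolute hotspot rule is a simple cutoff on combined CSP", {
  per <- data.frame(label = c("C11", "K49", "S20"),
                    residue = c(11L, 49L, 20L),
                    d_H = c(0.7, 0.61, 0.1), d_N = c(0, 0, 0),
                    csp = c(0.7, 0.61, 0.1))
  prof <- hsqcscreen:::new_csp_profile("sTyr", per)
  expect_equal(hotspot_by_absolute_threshold(prof, 0.6), c("C11", "K49"))
  expect_equal(hotspot_by_absolute_threshold(prof, 0),
               c("C11", "K49", "S20"))
  expect_equal(hotspot_by_absolute_threshold(prof, 1), character(0))
})

test_that("profile similarity is cosine on shared residues", {
  mk <- function(labs, csp) {
    hsqcscreen:::new_csp_profile("x", data.frame(
      label = labs, residue = seq_along(labs), d_H = csp, d_N = 0,
      csp = csp))
  }
  a <- mk(c("A1", "B2", "C3", "D4"), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(profile_similarity(a, a), 1)
  b <- mk(c("A1", "B2", "C3", "D4"), 2 * c(0.1, 0.2, 0.3, 0.4))
  expect_equal(profile_similarity(a, b), 1)  # scale invariance
  short <- mk(c("A1", "B2"), c(0.1, 0.2))
  expect_error(profile_similarity(a, short), "fewer than 3")
})

test_that("site assignment follows majority and the two-site 'both' rule", {
  sites <- list(s1 = c("E25", "Q69"), s2 = c("C11", "R52", "C54"))
  # profiles with a broad unperturbed background, so the mean + 2 SD rule
  # keeps the genuinely shifted residues significant
  mk <- function(labs, csp) {
    labs <- c(labs, paste0("Z", seq_len(30 - length(labs))))
    csp <- c(csp, rep(0, 30 - length(csp)))
    hsqcscreen:::new_csp_profile("x", data.frame(
      label = labs, residue = seq_along(labs), d_H = csp, d_N = 0,
      csp = csp))
  }
  # strong perturbations only in s2
  p2 <- mk(c("C11", "R52", "C54", "E25"), c(1, 1, 1, 0.01))
  expect_equal(assign_site(p2, sites)$site, "s2")
  # at least two significant residues in each site -> both
  pb <- mk(c("C11", "R52", "E25", "Q69"), c(1, 1, 1, 1))
  expect_equal(assign_site(pb, sites)$site, "both")
  # nothing significant in any site -> unassigned
  pu <- mk(c("Y1", "Y2"), c(1, 0.9))
  expect_equal(assign_site(pu, sites)$site, "unassigned")
  expect_error(assign_site(p2, list(a = "X1", b = "X1")), "disjoint")
})
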