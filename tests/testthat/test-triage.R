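mk_spec <- function(w_H = 8, w_N = 115, h = 1, id = "s",
                    ax_H = c(7, 9, 128), ax_N = c(110, 120, 64)) {
  render_spectrum(peak_list(data.frame(label = "A5", w_H = w_H, w_N = w_N,
                                       height = h), id), ax_H, ax_N)
}

test_that("DIA sums supra-floor magnitude and shrinks with the floor", {
  s <- mk_spec()
  z <- difference_spectrum(s, s)
  expect_equal(dia_statistic(z, 0), 0)
  d <- difference_spectrum(mk_spec(w_H = 8.03), s)
  # direct grid summation oracle at floor 0
  expect_equal(dia_statistic(d, 0), sum(abs(d$grid)))
  floors <- c(0, 0.01, 0.05, 0.2, 0.5)
  vals <- vapply(floors, function(f) dia_statistic(d, f), 0)
  expect_true(all(diff(vals) <= 0))
  expect_error(dia_statistic(d, -1), "noise_floor")
})

test_that("noise floor estimation reflects the region standard deviation", {
  s <- mk_spec()
  # a signal-free corner of a noiseless spectrum
  expect_equal(estimate_noise_floor(s, list(H = c(7, 7.5), N = c(110, 112))),
               0)
  # pure Gaussian grid noise of sd sigma -> about 5 sigma
  sn <- s
  set.seed(9)
  sn$grid <- matrix(rnorm(length(s$grid), 0, 0.02), nrow(s$grid))
  fl <- estimate_noise_floor(sn, list(H = c(7, 9), N = c(110, 120)))
  expect_equal(fl, 5 * 0.02, tolerance = 0.2)
  # region overlapping the peak inflates the estimate (documented hazard)
  sp <- s; sp$grid <- sp$grid + sn$grid
  fl_peak <- estimate_noise_floor(sp, list(H = c(7.8, 8.2), N = c(113, 117)))
  fl_clean <- estimate_noise_floor(sp, list(H = c(7, 7.6), N = c(110, 113)))
  expect_gt(fl_peak, fl_clean)
  expect_error(estimate_noise_floor(s, list(H = c(6, 7), N = c(110, 112))),
               "outside")
  expect_error(estimate_noise_floor(s, list(H = c(7, 7.01),
                                            N = c(110, 110.1))),
               "100 grid nodes")
})

test_that("PCA embedding is centred, sign-fixed and variance-bounded", {
  s1 <- mk_spec(w_H = 8)
  s2 <- mk_spec(w_H = 8.1, id = "t")
  # identical spectra: all coordinates zero
  same <- pca_embed(list(s1, s1, s1), 2)
  expect_equal(max(abs(same$scores)), 0, tolerance = 1e-10)
  # two distinct spectra: symmetric about the origin on component 1
  two <- pca_embed(list(s1, s2), 1)
  expect_equal(two$scores[1L, 1L], -two$scores[2L, 1L])
  expect_true(all(two$explained_variance <= 1 + 1e-12))
  expect_lte(sum(pca_embed(list(s1, s2, mk_spec(w_N = 116)),
                           2)$explained_variance), 1 + 1e-12)
  # deterministic, including component signs
  a <- pca_embed(list(s1, s2, mk_spec(w_N = 116)), 2)
  b <- pca_embed(list(s1, s2, mk_spec(w_N = 116)), 2)
  expect_identical(a$scores, b$scores)
  expect_error(pca_embed(list(s1), 2), "at least 2")
  s3 <- mk_spec(ax_H = c(7, 9, 64))
  expect_error(pca_embed(list(s1, s3), 2), "incompatible")
})

test_that("k-means clustering matches brute-force partitioning on small sets", {
  # two well-separated clouds: exhaustive search over all assignments
  set.seed(3)
  pts <- rbind(matrix(rnorm(8, 0, 0.1), 4), matrix(rnorm(8, 5, 0.1), 4))
  brute_best <- function(pts, k = 2L) {
    n <- nrow(pts); best <- NULL; best_ss <- Inf
    for (code in 0:(2^n - 1)) {
      lab <- as.integer(intToBits(code)[1:n]) + 1L
      if (length(unique(lab)) != k) next
      ss <- sum(vapply(1:k, function(g) {
        m <- pts[lab == g, , drop = FALSE]
        sum(sweep(m, 2, colMeans(m))^2)
      }, 0))
      if (ss < best_ss) { best_ss <- ss; best <- lab }
    }
    best
  }
  want <- brute_best(pts)
  got <- kmeans_cluster(pts, k = 2, seed = 1, reference_index = 1L)
  # same partition (labels may permute, but cluster 1 holds the reference)
  expect_equal(got == got[[1L]], want == want[[1L]])
  expect_equal(got[[1L]], 1L)

  expect_equal(kmeans_cluster(pts, k = 1, seed = 1), rep(1L, 8))
  expect_identical(kmeans_cluster(pts, 2, seed = 5),
                   kmeans_cluster(pts, 2, seed = 5))
  expect_error(kmeans_cluster(pts, k = 9, seed = 1), "between")
})

test_that("hit flagging needs both a foreign cluster and a high DIA", {
  res <- data.frame(sample_id = c("REF", "a", "b", "c"),
                    dia = c(0.1, 0.2, 9, 0.3),
                    cluster = c(1L, 1L, 2L, 2L))
  out <- flag_hits(res, "REF", dia_mult = 3)
  expect_equal(out$is_hit, c(FALSE, FALSE, TRUE, FALSE))
  # reference-only input: no hits
  solo <- flag_hits(data.frame(sample_id = "REF", dia = 0, cluster = 1L),
                    "REF")
  expect_false(any(solo$is_hit))
  # all-identical spectra: one cluster, nothing can be flagged
  same <- flag_hits(data.frame(sample_id = c("REF", "x", "y"),
                               dia = c(0, 0, 0), cluster = c(1L, 1L, 1L)),
                    "REF")
  expect_false(any(same$is_hit))
  expect_error(flag_hits(res, "nope"), "reference")
})

test_that("deconvolution regroups hit-plex fragments in manifest order", {
  d12 <- plex_design(sprintf("F%02d", 1:24), 12L, "12plex")
  plan <- deconvolution_plan("12plex-002", d12, 3L)
  expect_equal(length(plan$assignments), 4L)
  expect_true(all(lengths(plan$assignments) == 3L))
  expect_equal(unlist(plan$assignments, use.names = FALSE),
               sprintf("F%02d", 13:24))
  expect_equal(unname(plan$parent_of_fragment[["F13"]]), "12plex-002")
  singles <- deconvolution_plan(names(plan$assignments)[[1L]], plan, 1L)
  expect_equal(lengths(singles$assignments), c(1L, 1L, 1L),
               ignore_attr = TRUE)
  # empty hit set: empty plan, not an error
  none <- deconvolution_plan(character(0), d12, 3L)
  expect_equal(length(none$assignments), 0L)
  expect_error(deconvolution_plan("12plex-001", d12, 12L), "smaller")
  expect_error(deconvolution_plan("bogus", d12, 3L), "unknown")
})
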