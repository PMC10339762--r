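test_that("the depletion isotherm evaluates the bound-fraction model", {
  expect_equal(isotherm(0, 50, 0.85, 0.1), 0)
  expect_equal(isotherm(0.85, 50, 0.85, 0.1), 0.04927, tolerance = 2e-4)
  expect_equal(isotherm(1e4 * 0.85, 50, 0.85, 0.1), 0.1, tolerance = 1e-3)
})

test_that("noiseless Kd round-trips recover the generating constant", {
  assign <- tiny_assignments()
  for (kd in c(0.85, 6.6)) {
    frag <- fragment_record("F", site_label = "site2_sY_cleft", kd = kd,
                            dmax = data.frame(residue = assign$residue[1:5],
                                              d_H = c(0.1, 0.12, 0.08,
                                                      0.15, 0.1),
                                              d_N = c(0.5, -0.4, 0.3,
                                                      -0.2, 0.6)))
    ts <- simulate_titration(assign, frag, c(0, 0.25, 0.5, 1, 2, 4, 6),
                             noise_sd = c(0, 0), seed = 1)
    fit <- fit_kd(ts, mode = "global")
    expect_lt(abs(fit$kd_estimate - kd) / kd, 1e-3)
    expect_lt(fit$rss, 1e-12)
    expect_true(fit$converged)
    expect_false(fit$poorly_determined)
    # per-residue mode agrees on noiseless data
    pr <- fit_kd(ts, mode = "per_residue")
    expect_lt(abs(pr$kd_estimate - kd) / kd, 1e-3)
  }
})

test_that("fit_kd agrees with an independent nonlinear least-squares fit", {
  skip_if_not_installed("minpack.lm")
  assign <- tiny_assignments()
  frag <- fragment_record("F", site_label = "site2_sY_cleft", kd = 2.4,
                          dmax = data.frame(residue = 11L, d_H = 0.25,
                                            d_N = 0.8))
  ts <- simulate_titration(assign, frag, c(0, 0.25, 0.5, 1, 2, 4, 6),
                           noise_sd = c(0.004, 0.02), seed = 11)
  fit <- fit_kd(ts, residue_subset = "C11")
  y <- fit$csp["C11", ]
  L <- fit$ligand_totals
  nls_fit <- minpack.lm::nlsLM(
    y ~ dmax * hsqcscreen::fraction_bound(50, L, kd),
    start = list(dmax = max(y), kd = 1),
    lower = c(0, 1e-3), upper = c(10, 1e3))
  expect_equal(fit$kd_estimate, coef(nls_fit)[["kd"]], tolerance = 1e-3)
  expect_equal(unname(fit$per_residue_dmax["C11"]),
               coef(nls_fit)[["dmax"]], tolerance = 1e-3)
})

test_that("a strictly linear response pins Kd at the bound and is flagged", {
  assign <- tiny_assignments()
  lin <- fragment_record("L", site_label = "site2_sY_cleft", kd = 1e5,
                         dmax = data.frame(residue = 11L, d_H = 1e3,
                                           d_N = 0))
  ts <- simulate_titration(assign, lin, c(0, 0.5, 1, 2, 4, 6),
                           noise_sd = c(0, 0), seed = 1)
  fit <- fit_kd(ts)
  expect_true(fit$at_upper_bound)
  expect_true(fit$poorly_determined)
  expect_error(fit_kd(simulate_titration(assign, lin, c(0, 1, 2),
                                         noise_sd = c(0, 0), seed = 1)),
               "3 non-zero")
})

test_that("binding classification applies its rules in order", {
  fx <- test_fixture()
  assign <- fx$assignments
  ladder <- c(0, 0.25, 0.5, 1, 2, 4, 6)
  run1 <- function(id, seed = 5) {
    ts <- simulate_titration(assign, fx$fragments[[id]], ladder,
                             noise_sd = c(0, 0), seed = seed)
    classify_binding(ts, fit_kd(ts), csp_profile(ts), assign,
                     fx$site_definitions)
  }
  spec_id <- "SPB07625"
  ph_id <- fx$truth$fragment_id[fx$truth$class == "pH_artifact"][[1L]]
  ns_id <- fx$truth$fragment_id[fx$truth$class == "nonspecific"][[1L]]
  expect_equal(run1(spec_id)$label, "specific")
  expect_equal(run1(ph_id)$label, "pH_artifact")
  expect_equal(run1(ns_id)$label, "nonspecific")
  # an inert fragment gives a featureless titration -> inconclusive
  inert_id <- fx$truth$fragment_id[fx$truth$class == "inert"][[1L]]
  ts <- simulate_titration(assign, fx$fragments[[inert_id]], ladder,
                           noise_sd = c(0.004, 0.02), seed = 5)
  cls <- classify_binding(ts, fit_kd(ts), csp_profile(ts), assign,
                          fx$site_definitions)
  expect_equal(cls$label, "inconclusive")
})

test_that("candidate validation aggregates fits and classifications", {
  fx <- test_fixture()
  ladder <- c(0, 0.25, 0.5, 1, 2, 4, 6)
  ids <- c("SPB07625", "CC10501",
           fx$truth$fragment_id[fx$truth$class == "pH_artifact"][[1L]],
           fx$truth$fragment_id[fx$truth$class == "nonspecific"][[1L]])
  series <- lapply(seq_along(ids), function(i) {
    simulate_titration(fx$assignments, fx$fragments[[ids[[i]]]], ladder,
                       noise_sd = c(0.004, 0.02), seed = 40 + i)
  })
  out <- validate_candidates(series, fx$assignments, fx$site_definitions)
  expect_equal(unname(out$counts["specific"]), 2L)
  expect_equal(sum(out$counts[c("nonspecific", "pH_artifact")]), 2L)
  expect_setequal(out$hits, c("SPB07625", "CC10501"))
  expect_lt(abs(out$table$kd[out$table$fragment_id == "SPB07625"] - 0.85) /
              0.85, 0.25)
  # empty input: zero counts, no hits
  empty <- validate_candidates(list(), fx$assignments)
  expect_equal(sum(empty$counts), 0L)
  expect_equal(empty$hits, character(0))
  # classification is invariant to candidate ordering
  out_rev <- validate_candidates(rev(series), fx$assignments,
                                 fx$site_definitions)
  expect_equal(sort(out_rev$hits), sort(out$hits))
})
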