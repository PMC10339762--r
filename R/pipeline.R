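## End-to-end deterministic orchestration of the screening fixture:
## simulate -> 12-plex / 3-plex / single triage -> titration validation ->
## site assignment -> dual titration.

#' Pipeline configuration
#'
#' Collects every concentration, threshold, grid and seed the pipeline
#' consumes. All randomised stages derive their seeds from `seed`, so a
#' config determines the run completely.
#'
#' @param seed master integer seed.
#' @param protein_conc protein concentration (uM) used throughout.
#' @param screen_conc per-fragment concentration in pooled screen samples
#'   (mM).
#' @param plex_sizes pool sizes of the successive screening rounds.
#' @param validation_totals titration ladder (mM) for candidate
#'   validation, starting at 0.
#' @param sty_totals sulfotyrosine probe ladder (mM).
#' @param dual_totals varied-ligand ladder of the dual titrations (mM);
#'   the fixed ligand sits at `max(dual_totals)`.
#' @param noise_sd positional noise standard deviations `c(H, N)` (ppm).
#' @param axis_H,axis_N rendering grid of the triage rounds (coarser than
#'   the display default; the triage statistics do not need display
#'   resolution).
#' @param linewidth_H,linewidth_N Gaussian linewidths (ppm).
#' @param k,n_components k-means cluster count and PCA dimensionality.
#' @param dia_mult hit threshold multiplier on the reference-cluster
#'   median DIA.
#' @param floor_quantile quantile of the blank difference-spectrum
#'   magnitudes used as the DIA noise floor: the floor is set where a
#'   known-negative difference retains essentially no intensity.
#' @param consistency_min minimum cosine similarity between a flagged
#'   single compound's difference pattern and the pattern of at least one
#'   pooled sample it was deconvoluted from; flags whose perturbations do
#'   not reproduce the plex patterns are dropped as noise.
#' @param consistency_floor minimum similarity required against *every*
#'   ancestor pooled sample: a real active appears in all of its parent
#'   pools, so contradicting any one of them disqualifies the flag.
#' @param csp_n_sd CSP significance level (standard deviations above the
#'   mean).
#' @param hotspot_cutoff absolute CSP cutoff (ppm) for probe hotspots.
#' @param dual_tolerance verdict tolerance (scaled ppm) of the dual
#'   analysis.
#' @param kd_bounds Kd search bounds (mM).
#' @param outdir optional directory for TSV/CSV artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 20230223L,
                            protein_conc = 50,
                            screen_conc = 0.5,
                            plex_sizes = c(12L, 3L, 1L),
                            validation_totals = c(0, 0.25, 0.5, 1, 2, 4, 6),
                            sty_totals = c(0, 1, 5, 10, 20, 50, 75, 100),
                            dual_totals = c(0, 0.5, 1, 2, 3),
                            noise_sd = c(0.004, 0.02),
                            axis_H = c(6.8, 10.3, 256),
                            axis_N = c(101, 134, 128),
                            linewidth_H = 0.02, linewidth_N = 0.15,
                            k = 8L, n_components = 16L,
                            dia_mult = 3, floor_quantile = 0.9999,
                            consistency_min = 0.3,
                            consistency_floor = 0.1,
                            csp_n_sd = 2, hotspot_cutoff = 0.6,
                            dual_tolerance = 0.02,
                            kd_bounds = c(1e-3, 1e3),
                            outdir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialise / restore a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path JSON file.
#' @return The path (write) or the restored config (read).
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, lst[!vapply(lst, is.null, TRUE)])
  cfg
}

# blank-difference noise floor: the difference of two independent noise
# realisations of the reference sample carries exactly the
# positional-noise signal a true negative shows; the floor is placed at
# an extreme quantile of its magnitude so a negative difference keeps
# essentially no above-floor intensity
screen_noise_floor <- function(assign, config, seed, n_blanks = 3L) {
  vals <- unlist(lapply(seq_len(n_blanks), function(b) {
    r1 <- simulate_sample(assign, protein_conc = config$protein_conc,
                          noise_sd = config$noise_sd, seed = seed + 2L * b,
                          sample_id = "BLANK1")
    r2 <- simulate_sample(assign, protein_conc = config$protein_conc,
                          noise_sd = config$noise_sd,
                          seed = seed + 2L * b + 1L,
                          sample_id = "BLANK2")
    s1 <- render_spectrum(r1, config$axis_H, config$axis_N,
                          config$linewidth_H, config$linewidth_N)
    s2 <- render_spectrum(r2, config$axis_H, config$axis_N,
                          config$linewidth_H, config$linewidth_N)
    abs(s1$grid - s2$grid)
  }))
  stats::quantile(vals, config$floor_quantile, names = FALSE)
}

# one triage round: simulate every pooled sample plus a reference, render,
# DIA against the reference, PCA + k-means across the noise-floor
# thresholded difference spectra, flag hits. Thresholding the differences
# before the embedding removes the positional-noise background that every
# sample shares, so true negatives collapse onto the reference and the
# clusters reflect perturbation patterns rather than noise.
screen_round <- function(fixture, design, config, seed,
                         parent_of_fragment = NULL) {
  assign <- fixture$assignments
  plexes <- design$assignments
  ref_pl <- simulate_sample(assign, protein_conc = config$protein_conc,
                            noise_sd = config$noise_sd, seed = seed,
                            sample_id = "REF")
  sample_pls <- lapply(seq_along(plexes), function(i) {
    frags <- fixture$fragments[plexes[[i]]]
    simulate_sample(assign, frags,
                    rep(config$screen_conc, length(frags)),
                    protein_conc = config$protein_conc,
                    noise_sd = config$noise_sd, seed = seed + i,
                    sample_id = names(plexes)[[i]])
  })
  all_pl <- c(list(ref_pl), sample_pls)
  spectra <- lapply(all_pl, render_spectrum, axis_H = config$axis_H,
                    axis_N = config$axis_N,
                    linewidth_H = config$linewidth_H,
                    linewidth_N = config$linewidth_N)
  floor <- screen_noise_floor(assign, config, seed + 500000L)
  diffs <- lapply(spectra, function(s) {
    d <- difference_spectrum(s, spectra[[1L]])
    d$grid[abs(d$grid) <= floor] <- 0
    d
  })
  dia <- vapply(diffs, function(d) dia_statistic(d, 0), 0)
  emb <- pca_embed(diffs, min(config$n_components, length(diffs) - 1L))
  # cluster on the pattern embedding augmented with a robust DIA outlier
  # score (zero for the bulk of samples, positive beyond median + 2 MAD
  # of log-DIA): the reference cluster keeps the unperturbed bulk
  # together while strongly perturbed samples separate even when their
  # perturbation pattern is not captured by the leading components
  z <- log1p(dia)
  cut <- stats::median(z) + 2 * stats::mad(z)
  sd1 <- max(stats::sd(emb$scores[, 1L]), 1e-12)
  coords <- cbind(emb$scores, dia_outlier = pmax(z - cut, 0) * 5 * sd1)
  cl <- kmeans_cluster(coords, k = min(config$k, length(spectra)),
                       seed = seed, reference_index = 1L)
  lineage <- c("", vapply(names(plexes), function(p) {
    if (is.null(parent_of_fragment)) "" else {
      paste(unique(parent_of_fragment[plexes[[p]]]), collapse = ",")
    }
  }, ""))
  res <- data.frame(sample_id = vapply(all_pl, `[[`, "", "sample_id"),
                    dia = dia, cluster = cl, is_hit = FALSE,
                    round = design$round_label, lineage = lineage,
                    stringsAsFactors = FALSE)
  res <- cbind(res, emb$scores)
  res <- flag_hits(res, "REF", config$dia_mult)
  class(res) <- c("triage_result", "data.frame")
  vecs <- do.call(rbind, lapply(diffs, function(d) as.vector(d$grid)))
  rownames(vecs) <- res$sample_id
  list(results = res, noise_floor = floor,
       hit_plexes = res$sample_id[res$is_hit],
       explained_variance = emb$explained_variance,
       diff_vectors = vecs)
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Run the full screening pipeline on a fixture
#'
#' Executes the deterministic end-to-end analysis: iterative pooled
#' triage (12-plex, 3-plex, single by default), titration validation with
#' Kd fitting and binding classification of every single-compound
#' candidate, sub-site assignment of the specific hits, the sulfotyrosine
#' hotspot map, and a dual titration of the exemplar fragment pair.
#'
#' @param config a [pipeline_config()].
#' @param fixture a fixture as returned by [make_ccl28_fixture()];
#'   generated from `config$seed` when omitted.
#' @return A `pipeline_report` list: `summary` (screened / candidate /
#'   hit counts and rate), `rounds` (triage tables), `validation`
#'   (classification table), `site_assignments`, `sty_hotspots`, `dual`
#'   and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), fixture = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(fixture)) fixture <- make_ccl28_fixture(config$seed)
  assign <- fixture$assignments
  n_screened <- nrow(fixture$manifest)

  if (n_screened == 0L) {
    report <- list(summary = list(n_screened = 0L, n_candidates = 0L,
                                  n_hits = 0L, n_nonhits = 0L,
                                  candidate_hit_rate_pct = NA_real_),
                   rounds = list(), validation = NULL,
                   site_assignments = NULL, sty_hotspots = character(0),
                   dual = NULL, config = config)
    class(report) <- "pipeline_report"
    return(report)
  }

  # --- iterative triage -------------------------------------------------
  design <- fixture$plex_design
  designs <- list(design)
  parent_map <- NULL
  rounds <- list()
  for (r in seq_along(config$plex_sizes)) {
    round_seed <- config$seed + 10000L * r
    sr <- screen_round(fixture, design, config, round_seed, parent_map)
    rounds[[design$round_label]] <- sr
    if (r < length(config$plex_sizes)) {
      design <- deconvolution_plan(sr$hit_plexes, design,
                                   config$plex_sizes[[r + 1L]])
      parent_map <- design$parent_of_fragment
      designs[[r + 1L]] <- design
      if (!length(design$assignments)) break
    }
  }
  last <- rounds[[length(rounds)]]
  final_design <- designs[[length(rounds)]]
  flagged <- unlist(final_design$assignments[last$hit_plexes],
                    use.names = FALSE)

  # candidate gate: a flagged single qualifies only when its perturbation
  # pattern is consistent with the pattern of the pooled samples it was
  # deconvoluted from (intermediate-round flags that fail to reproduce
  # are dropped as noise)
  candidates <- character(0)
  consistency <- numeric(0)
  single_of <- stats::setNames(
    rep(names(final_design$assignments),
        lengths(final_design$assignments)),
    unlist(final_design$assignments, use.names = FALSE))
  for (f in flagged) {
    v_single <- rounds[[length(rounds)]]$diff_vectors[single_of[[f]], ]
    cos_all <- 1  # no ancestors -> nothing to contradict
    if (length(rounds) > 1L) {
      cos_all <- vapply(seq_len(length(rounds) - 1L), function(r) {
        parent <- designs[[r + 1L]]$parent_of_fragment[[f]]
        cosine(v_single, rounds[[r]]$diff_vectors[parent, ])
      }, 0)
    }
    # a real active reproduces in every round it appeared in: it must
    # match at least one pooled pattern well and contradict none
    if (max(cos_all) >= config$consistency_min &&
        min(cos_all) >= config$consistency_floor) {
      candidates <- c(candidates, f)
      consistency <- c(consistency, max(cos_all))
    }
  }

  # --- titration validation of candidates -------------------------------
  val_series <- lapply(seq_along(candidates), function(i) {
    simulate_titration(assign, fixture$fragments[[candidates[[i]]]],
                       config$validation_totals,
                       protein_conc = config$protein_conc,
                       noise_sd = config$noise_sd,
                       seed = config$seed + 700000L + 100L * i)
  })
  validation <- validate_candidates(val_series, assign,
                                    fixture$site_definitions,
                                    bounds = config$kd_bounds)

  # --- sub-site assignment of the specific hits -------------------------
  site_assignments <- list()
  for (i in seq_along(val_series)) {
    s <- val_series[[i]]
    if (s$ligand_id %in% validation$hits) {
      prof <- csp_profile(s)
      site_assignments[[s$ligand_id]] <-
        assign_site(prof, fixture$site_definitions, config$csp_n_sd)
    }
  }
  site_counts <- table(factor(
    vapply(site_assignments, `[[`, "", "site"),
    levels = c(names(fixture$site_definitions), "both", "unassigned")))

  # --- sulfotyrosine hotspot map ----------------------------------------
  sty_series <- simulate_titration(assign, fixture$sty, config$sty_totals,
                                   protein_conc = config$protein_conc,
                                   noise_sd = config$noise_sd,
                                   seed = config$seed + 900000L)
  sty_prof <- csp_profile(sty_series)
  sty_hot <- hotspot_by_absolute_threshold(sty_prof, config$hotspot_cutoff)

  # --- dual titration of the exemplar pair ------------------------------
  dual <- NULL
  if (all(c("SPB07625", "CC10501") %in% validation$hits)) {
    fragA <- fixture$fragments[["SPB07625"]]
    fragB <- fixture$fragments[["CC10501"]]
    dual <- run_dual_experiment(assign, fragA, fragB,
                                mode = "independent_sites",
                                totals = config$dual_totals,
                                protein_conc = config$protein_conc,
                                noise_sd = config$noise_sd,
                                seed = config$seed + 950000L,
                                tolerance = config$dual_tolerance)
  }

  n_cand <- length(candidates)
  n_hits <- length(validation$hits)
  n_nonhits <- n_cand - n_hits
  report <- list(
    summary = list(n_screened = n_screened, n_candidates = n_cand,
                   n_hits = n_hits, n_nonhits = n_nonhits,
                   candidate_hit_rate_pct = 100 * n_cand / n_screened),
    rounds = lapply(rounds, function(r) r$results),
    noise_floors = vapply(rounds, `[[`, 0, "noise_floor"),
    candidates = candidates,
    validation = validation,
    site_assignments = site_assignments,
    site_counts = site_counts,
    sty_profile = sty_prof,
    sty_hotspots = sty_hot,
    dual = dual,
    config = config)
  class(report) <- "pipeline_report"
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Simulate and analyse a complete dual-titration experiment
#'
#' Convenience wrapper: simulates the two single titrations (0 to
#' `max(totals)`) and the two orders of dual addition under the given
#' mode, then calls [analyze_dual()].
#'
#' @param assign an [assignment_table()].
#' @param fragA,fragB [fragment_record()]s.
#' @param mode `"independent_sites"` or `"competitive"` (ground truth of
#'   the simulation).
#' @param totals varied-ligand ladder (mM) starting at 0.
#' @param protein_conc protein (uM); `noise_sd`, `seed` as elsewhere.
#' @param tolerance verdict tolerance passed to [analyze_dual()].
#' @return A `dual_result`.
#' @export
run_dual_experiment <- function(assign, fragA, fragB,
                                mode = "independent_sites",
                                totals = c(0, 0.5, 1, 2, 3),
                                protein_conc = 50,
                                noise_sd = c(0.004, 0.02),
                                seed = 1L, tolerance = 0.02) {
  idA <- fragA$fragment_id; idB <- fragB$fragment_id
  top <- max(totals)
  single_A <- simulate_titration(assign, fragA, totals,
                                 protein_conc, noise_sd, seed)
  single_B <- simulate_titration(assign, fragB, totals,
                                 protein_conc, noise_sd, seed + 10L)
  sched_AB <- dual_schedule(idB, top, idA, totals, mode)
  sched_BA <- dual_schedule(idA, top, idB, totals, mode)
  dual_AB <- simulate_dual(assign, fragA, fragB, sched_AB,
                           protein_conc, noise_sd, seed + 20L)
  dual_BA <- simulate_dual(assign, fragB, fragA, sched_BA,
                           protein_conc, noise_sd, seed + 30L)
  analyze_dual(dual_AB, dual_BA, single_A, single_B, tolerance = tolerance)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report>\n")
  cat(sprintf("  fragments screened : %d\n", s$n_screened))
  cat(sprintf("  candidates         : %d (%.2f%%)\n", s$n_candidates,
              s$candidate_hit_rate_pct))
  cat(sprintf("  validated hits     : %d | non-hits: %d\n",
              s$n_hits, s$n_nonhits))
  if (!is.null(x$site_counts)) {
    cat("  site split         :",
        paste(sprintf("%s=%d", names(x$site_counts), x$site_counts),
              collapse = " "), "\n")
  }
  if (length(x$sty_hotspots)) {
    cat("  sY hotspots        :", paste(x$sty_hotspots, collapse = ", "),
        "\n")
  }
  if (!is.null(x$dual)) {
    cat(sprintf("  dual verdict       : %s (residual %0.4f)\n",
                x$dual$verdict, x$dual$aggregate_residual))
  }
  invisible(x)
}

# write TSV/CSV artifacts plus a config snapshot
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$rounds)) {
    utils::write.table(report$rounds[[nm]],
                       file.path(outdir, paste0("triage_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$validation) && nrow(report$validation$table)) {
    utils::write.table(report$validation$table,
                       file.path(outdir, "validation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary_df <- data.frame(key = names(unlist(report$summary)),
                           value = unlist(report$summary))
  utils::write.table(summary_df, file.path(outdir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_pipeline_config(report$config, file.path(outdir, "config.json"))
  invisible(outdir)
}
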