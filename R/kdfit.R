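## Dissociation-constant fitting from titration-derived CSP data and
## binding-mode classification.

#' Single-site binding isotherm with ligand depletion
#'
#' Predicted combined CSP at total ligand `L_T`:
#' `dmax * fraction_bound(P_T, L_T, kd)`.
#'
#' @inheritParams fraction_bound
#' @param dmax maximal shift at full occupancy (ppm).
#' @return Predicted CSP (ppm); vectorised over `L_T`.
#' @export
isotherm <- function(L_T, P_T, kd, dmax) {
  dmax * fraction_bound(P_T, L_T, kd)
}

# Per-residue CSP-vs-concentration matrix from a titration series: peaks
# chain-tracked in concentration order, CSP of every point measured
# against the apo point. Rows = residues tracked at all points.
titration_csp_matrix <- function(series, max_jump = 0.25, weight = 0.2) {
  frames <- chain_track(series$points, max_jump = max_jump, weight = weight)
  apo <- frames[[1L]]
  labs <- apo$label
  Y <- vapply(frames, function(fr) {
    combined_csp(fr$w_H - apo$w_H, fr$w_N - apo$w_N, weight)
  }, numeric(length(labs)))
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  rownames(Y) <- labs
  Y
}

# Residual sum of squares of the shared-kd model at a given kd, with the
# per-residue dmax profiled out analytically (linear in dmax).
profiled_rss <- function(kd, Y, L, P_T) {
  f <- fraction_bound(P_T, L, kd)
  ss_f <- sum(f^2)
  if (ss_f == 0) return(sum(Y^2))
  dmax <- as.vector(Y %*% f) / ss_f
  sum((Y - outer(dmax, f))^2)
}

#' Fit a dissociation constant to a CSP titration series
#'
#' Nonlinear least-squares fit of the ligand-depletion isotherm to
#' combined CSP versus total ligand concentration. In `"global"` mode a
#' single shared Kd is fitted with one maximal-shift amplitude per
#' residue (the amplitudes are profiled out analytically, leaving a 1-D
#' optimisation over log Kd started from several log-spaced initial
#' values). In `"per_residue"` mode each residue is fitted independently.
#'
#' @param series a `titration_series` with at least 3 non-zero ligand
#'   points.
#' @param mode `"global"` (default) or `"per_residue"`.
#' @param residue_subset optional character vector of residue labels to
#'   fit (default: every residue tracked across all points).
#' @param bounds Kd search bounds (mM).
#' @param n_starts number of log-spaced starting values.
#' @param max_jump,weight peak-tracking parameters.
#' @return A `kd_fit`: `kd_estimate` (mM), `kd_stderr` (mM, from the
#'   curvature of the profiled objective), `per_residue_dmax`, `rss`,
#'   `n_points`, `mode`, `converged`, `at_upper_bound` /
#'   `poorly_determined` flags and the data actually fitted.
#' @export
fit_kd <- function(series, mode = c("global", "per_residue"),
                   residue_subset = NULL, bounds = c(1e-3, 1e3),
                   n_starts = 7L, max_jump = 0.25, weight = 0.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "titration_series"))
  L <- series$ligand_totals
  if (sum(L > 0) < 3L) {
    stop("need at least 3 non-zero ligand points to fit a Kd", call. = FALSE)
  }
  Y <- titration_csp_matrix(series, max_jump = max_jump, weight = weight)
  if (!is.null(residue_subset)) {
    keep <- rownames(Y) %in% residue_subset
    if (!any(keep)) stop("no requested residue was tracked", call. = FALSE)
    Y <- Y[keep, , drop = FALSE]
  }
  P_T <- series$protein_conc
  lb <- log10(bounds[[1L]]); ub <- log10(bounds[[2L]])

  fit_block <- function(Yb) {
    obj <- function(lk) profiled_rss(10^lk, Yb, L, P_T)
    starts <- seq(lb, ub, length.out = n_starts)
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, obj, method = "L-BFGS-B", lower = lb, upper = ub,
                        control = list(factr = 1e4))
      if (is.null(best) || o$value < best$value) best <- o
    }
    # Brent polish in a bracket around the best start: derivative-free, so
    # it is untroubled by the flat machine-precision floor of noiseless fits
    po <- stats::optim(best$par, obj, method = "Brent",
                       lower = max(lb, best$par - 1),
                       upper = min(ub, best$par + 1))
    if (po$value <= best$value) best <- po
    lk <- best$par
    kd <- 10^lk
    f <- fraction_bound(P_T, L, kd)
    dmax <- as.vector(Yb %*% f) / sum(f^2)
    names(dmax) <- rownames(Yb)
    rss <- best$value
    n_obs <- length(Yb)
    n_par <- 1L + length(dmax)
    # stderr from the curvature of the profiled RSS at the optimum
    h <- 1e-4 * max(abs(kd), 1e-6)
    rss_p <- profiled_rss(kd + h, Yb, L, P_T)
    rss_m <- profiled_rss(max(kd - h, bounds[[1L]] / 10), Yb, L, P_T)
    curv <- (rss_p - 2 * rss + rss_m) / h^2
    sigma2 <- if (n_obs > n_par) rss / (n_obs - n_par) else NA_real_
    stderr <- if (is.finite(curv) && curv > 0 && is.finite(sigma2)) {
      sqrt(2 * sigma2 / curv)
    } else NA_real_
    at_upper <- lk >= ub - 1e-4
    at_lower <- lk <= lb + 1e-4
    list(kd = kd, stderr = stderr, dmax = dmax, rss = rss,
         converged = best$convergence == 0,
         at_upper_bound = at_upper,
         poorly_determined = at_upper || at_lower)
  }

  if (mode == "global") {
    fb <- fit_block(Y)
    out <- list(kd_estimate = fb$kd, kd_stderr = fb$stderr,
                per_residue_dmax = fb$dmax, rss = fb$rss,
                n_points = length(L), mode = mode,
                converged = fb$converged,
                at_upper_bound = fb$at_upper_bound,
                poorly_determined = fb$poorly_determined,
                ligand_totals = L, csp = Y, bounds = bounds,
                ligand_id = series$ligand_id)
  } else {
    per <- lapply(rownames(Y), function(r) fit_block(Y[r, , drop = FALSE]))
    names(per) <- rownames(Y)
    kd_all <- vapply(per, `[[`, 0, "kd")
    out <- list(kd_estimate = stats::median(kd_all),
                kd_stderr = stats::mad(kd_all),
                per_residue_dmax = vapply(per, function(p) p$dmax[[1L]], 0),
                per_residue_kd = kd_all,
                rss = sum(vapply(per, `[[`, 0, "rss")),
                n_points = length(L), mode = mode,
                converged = all(vapply(per, `[[`, TRUE, "converged")),
                at_upper_bound = stats::median(kd_all) >=
                  bounds[[2L]] * (1 - 1e-3),
                poorly_determined = any(vapply(per, `[[`, TRUE,
                                               "poorly_determined")),
                ligand_totals = L, csp = Y, bounds = bounds,
                ligand_id = series$ligand_id)
  }
  class(out) <- "kd_fit"
  out
}

#' @export
print.kd_fit <- function(x, ...) {
  kd_txt <- if (x$kd_estimate < 1) {
    sprintf("%.0f uM", x$kd_estimate * 1000)
  } else sprintf("%.2f mM", x$kd_estimate)
  cat(sprintf("<kd_fit '%s'> Kd = %s (stderr %s) | %s fit, %d points, rss %0.3g%s\n",
              x$ligand_id, kd_txt,
              ifelse(is.finite(x$kd_stderr), sprintf("%0.3g", x$kd_stderr), "NA"),
              x$mode, x$n_points, x$rss,
              if (isTRUE(x$poorly_determined)) " [poorly determined]" else ""))
  invisible(x)
}

#' Classify the binding behaviour of a validated candidate
#'
#' Decision rules, applied in order:
#' \enumerate{
#'   \item `pH_artifact` -- every significant residue is a histidine
#'     (protonation-shift signature rather than binding);
#'   \item `inconclusive` -- no significant residues at all;
#'   \item `nonspecific` -- the fitted Kd sits at the upper search bound,
#'     or the occupancy reached at the highest ligand point is below
#'     `saturation_cutoff`, or fewer than `min_site_evidence` significant
#'     residues fall inside the defined sub-sites (spatially unstructured
#'     perturbation);
#'   \item `specific` otherwise.
#' }
#'
#' @param series the validation `titration_series`.
#' @param fit the [fit_kd()] result for that series.
#' @param profile the endpoint [csp_profile()] for that series.
#' @param assign the [assignment_table()] (supplies residue codes).
#' @param site_definitions named list of sub-site residue sets.
#' @param saturation_cutoff minimum bound fraction at the top ligand
#'   point for saturable binding (default 0.2).
#' @param min_site_evidence minimum number of significant residues inside
#'   the sub-site definitions for a site-directed (specific) call; a
#'   single site residue could be a chance excursion.
#' @param min_csp absolute detection limit (ppm): when no residue's
#'   combined CSP reaches it, the titration is featureless and the
#'   relative mean + 2 SD threshold only picks noise, so the candidate is
#'   `inconclusive`.
#' @param n_sd significance level.
#' @return A `binding_class`: list with `label` and `rationale`.
#' @export
classify_binding <- function(series, fit, profile, assign,
                             site_definitions = ccl28_site_definitions(),
                             saturation_cutoff = 0.2,
                             min_site_evidence = 2L, min_csp = 0.03,
                             n_sd = 2) {
  sig <- significant_residues(profile, n_sd)
  if (length(sig) &&
      max(profile$per_residue$csp[profile$per_residue$label %in% sig]) <
        min_csp) {
    return(structure(
      list(label = "inconclusive",
           rationale = sprintf(
             "largest perturbation below the %.3g ppm detection limit",
             min_csp)),
      class = "binding_class"))
  }
  codes <- assign$code[match(sig, assign$label)]
  label <- NULL; why <- NULL
  if (length(sig) && all(codes == "H", na.rm = TRUE)) {
    label <- "pH_artifact"
    why <- sprintf("all %d significant residues are histidines (%s)",
                   length(sig), paste(sig, collapse = ", "))
  } else if (!length(sig)) {
    label <- "inconclusive"
    why <- "no residue shows a significant perturbation"
  } else {
    sat <- fraction_bound(series$protein_conc,
                          max(series$ligand_totals), fit$kd_estimate)
    in_site <- intersect(sig, unlist(site_definitions, use.names = FALSE))
    if (isTRUE(fit$at_upper_bound)) {
      label <- "nonspecific"
      why <- "Kd estimate pinned at the upper search bound (no curvature)"
    } else if (sat < saturation_cutoff) {
      label <- "nonspecific"
      why <- sprintf("occupancy at the top point is only %.2f (< %.2f)",
                     sat, saturation_cutoff)
    } else if (length(in_site) < min_site_evidence) {
      label <- "nonspecific"
      why <- sprintf(
        "only %d significant residue(s) inside the defined sub-sites",
        length(in_site))
    } else {
      label <- "specific"
      why <- sprintf("saturable (occupancy %.2f), Kd %.3g mM, site residues: %s",
                     sat, fit$kd_estimate, paste(in_site, collapse = ", "))
    }
  }
  structure(list(label = label, rationale = why), class = "binding_class")
}

#' @export
print.binding_class <- function(x, ...) {
  cat(sprintf("<binding_class> %s: %s\n", x$label, x$rationale))
  invisible(x)
}

#' Validate a set of candidate titrations
#'
#' Runs [fit_kd()], [csp_profile()] and [classify_binding()] on every
#' candidate series; a candidate counts as a hit when classified
#' `specific`.
#'
#' @param candidates list of `titration_series`.
#' @param assign the [assignment_table()].
#' @param site_definitions sub-site definitions.
#' @param ... passed on to [fit_kd()].
#' @return List with `table` (data frame: ligand id, Kd, stderr, class,
#'   rationale), `counts` (per class), `hits` (specific ligand ids) and
#'   the per-candidate `fits`.
#' @export
validate_candidates <- function(candidates, assign,
                                site_definitions = ccl28_site_definitions(),
                                ...) {
  if (!length(candidates)) {
    return(list(table = data.frame(fragment_id = character(0),
                                   kd = numeric(0), kd_stderr = numeric(0),
                                   class = character(0),
                                   rationale = character(0)),
                counts = c(specific = 0L, nonspecific = 0L,
                           pH_artifact = 0L, inconclusive = 0L),
                hits = character(0), fits = list()))
  }
  rows <- list(); fits <- list()
  for (series in candidates) {
    fit <- fit_kd(series, ...)
    prof <- csp_profile(series)
    cls <- classify_binding(series, fit, prof, assign, site_definitions)
    fits[[series$ligand_id]] <- fit
    rows[[series$ligand_id]] <- data.frame(
      fragment_id = series$ligand_id, kd = fit$kd_estimate,
      kd_stderr = fit$kd_stderr, class = cls$label,
      rationale = cls$rationale, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  lv <- c("specific", "nonspecific", "pH_artifact", "inconclusive")
  counts <- table(factor(tab$class, levels = lv))
  list(table = tab, counts = stats::setNames(as.integer(counts), lv),
       hits = tab$fragment_id[tab$class == "specific"], fits = fits)
}
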