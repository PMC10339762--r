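## Dual-fragment titration analysis: does the two-ligand endpoint shift
## equal the vector sum of the single-ligand shifts, irrespective of the
## order of addition?

#' Vector-sum prediction of dual-ligand shifts
#'
#' Componentwise addition of the two single-ligand shift vectors per
#' residue; residues present in only one input carry the other's
#' contribution as zero. This is the expected dual-sample displacement
#' when both fragments occupy independent sub-sites.
#'
#' @param shifts_A,shifts_B data frames with columns `label`, `d_H`,
#'   `d_N` (ppm).
#' @return Data frame `label`, `d_H`, `d_N` over the union of residues.
#' @export
vector_sum_prediction <- function(shifts_A, shifts_B) {
  labs <- union(shifts_A$label, shifts_B$label)
  ia <- match(labs, shifts_A$label)
  ib <- match(labs, shifts_B$label)
  gH <- function(df, i) ifelse(is.na(i), 0, df$d_H[i])
  gN <- function(df, i) ifelse(is.na(i), 0, df$d_N[i])
  data.frame(label = labs,
             d_H = gH(shifts_A, ia) + gH(shifts_B, ib),
             d_N = gN(shifts_A, ia) + gN(shifts_B, ib),
             stringsAsFactors = FALSE)
}

# endpoint shift vectors of a titration series relative to its own apo
# point, as a data frame (label, d_H, d_N)
endpoint_shifts <- function(series, max_jump = 0.25, weight = 0.2) {
  frames <- chain_track(series$points, max_jump = max_jump, weight = weight)
  apo <- frames[[1L]]; end <- frames[[length(frames)]]
  data.frame(label = end$label, d_H = end$w_H - apo$w_H,
             d_N = end$w_N - apo$w_N, stringsAsFactors = FALSE)
}

# absolute endpoint peak positions of a dual series whose first point
# already contains the fixed ligand: enter the dual series from the
# matching single-ligand series (tracked apo -> fixed-only state), then
# chain through the dual points.
dual_endpoint_positions <- function(dual_series, single_fixed,
                                    max_jump = 0.25, weight = 0.2) {
  single_frames <- chain_track(single_fixed$points, max_jump = max_jump,
                               weight = weight)
  entry <- single_frames[[length(single_frames)]]
  frames <- chain_track(dual_series$points, start = entry,
                        max_jump = max_jump, weight = weight)
  frames[[length(frames)]]
}

#' Analyse a pair of dual-fragment titrations for shift additivity
#'
#' Compares the observed two-ligand endpoint displacement (averaged over
#' the two orders of addition, which probe the identical final state)
#' with the vector sum of the single-ligand displacements at the same
#' concentrations. Per-residue residuals are scaled-space norms; the
#' aggregate is their root mean square over the significant residues of
#' either single-ligand profile. The order discrepancy is the RMS
#' distance between the two dual endpoints (A-into-B vs B-into-A).
#'
#' Verdicts: `simultaneous` when both the aggregate residual and the
#' order discrepancy are at or below `tolerance`; `competitive` when the
#' residual exceeds tolerance *and* the observed shifts are
#' systematically smaller than the vector-sum prediction (occupancy
#' suppression, regression slope < 0.9); `inconclusive` otherwise.
#'
#' @param series_AB dual series: A titrated into B (from
#'   [simulate_dual()] or equivalent).
#' @param series_BA dual series: B titrated into A.
#' @param single_A,single_B single-ligand `titration_series` whose
#'   endpoints match the dual endpoint concentrations.
#' @param tolerance verdict tolerance in scaled ppm (default 0.02,
#'   about 5x the default \eqn{^1}H positional noise).
#' @param max_jump,weight tracking parameters.
#' @return A `dual_result` with `per_residue` (observed, predicted,
#'   residual), `aggregate_residual`, `order_discrepancy`, `slope` and
#'   `verdict`.
#' @export
analyze_dual <- function(series_AB, series_BA, single_A, single_B,
                         tolerance = 0.02, max_jump = 0.25, weight = 0.2) {
  for (s in list(series_AB, series_BA, single_A, single_B)) {
    stopifnot(inherits(s, "titration_series"))
  }
  pc <- unique(vapply(list(series_AB, series_BA, single_A, single_B),
                      `[[`, 0, "protein_conc"))
  if (length(pc) != 1L) {
    stop("all four series must share the protein concentration",
         call. = FALSE)
  }
  endA <- max(single_A$ligand_totals)
  endB <- max(single_B$ligand_totals)
  if (!isTRUE(all.equal(max(series_AB$ligand_totals), endA)) ||
      !isTRUE(all.equal(series_AB$fixed_conc, endB)) ||
      !isTRUE(all.equal(max(series_BA$ligand_totals), endB)) ||
      !isTRUE(all.equal(series_BA$fixed_conc, endA))) {
    stop("single-ligand endpoints must match the dual endpoint ",
         "concentrations", call. = FALSE)
  }

  shifts_A <- endpoint_shifts(single_A, max_jump, weight)
  shifts_B <- endpoint_shifts(single_B, max_jump, weight)
  pred <- vector_sum_prediction(shifts_A, shifts_B)

  apo_A <- single_A$points[[1L]]$peaks[c("label", "w_H", "w_N")]
  apo_B <- single_B$points[[1L]]$peaks[c("label", "w_H", "w_N")]
  end_AB <- dual_endpoint_positions(series_AB, single_B, max_jump, weight)
  end_BA <- dual_endpoint_positions(series_BA, single_A, max_jump, weight)

  labs <- Reduce(intersect, list(pred$label, end_AB$label, end_BA$label,
                                 apo_A$label, apo_B$label))
  obs_AB <- data.frame(
    label = labs,
    d_H = end_AB$w_H[match(labs, end_AB$label)] -
      apo_B$w_H[match(labs, apo_B$label)],
    d_N = end_AB$w_N[match(labs, end_AB$label)] -
      apo_B$w_N[match(labs, apo_B$label)])
  obs_BA <- data.frame(
    label = labs,
    d_H = end_BA$w_H[match(labs, end_BA$label)] -
      apo_A$w_H[match(labs, apo_A$label)],
    d_N = end_BA$w_N[match(labs, end_BA$label)] -
      apo_A$w_N[match(labs, apo_A$label)])
  obs <- data.frame(label = labs,
                    d_H = (obs_AB$d_H + obs_BA$d_H) / 2,
                    d_N = (obs_AB$d_N + obs_BA$d_N) / 2)
  ip <- match(labs, pred$label)
  resid <- combined_csp(obs$d_H - pred$d_H[ip], obs$d_N - pred$d_N[ip],
                        weight)
  per <- data.frame(label = labs,
                    obs_d_H = obs$d_H, obs_d_N = obs$d_N,
                    pred_d_H = pred$d_H[ip], pred_d_N = pred$d_N[ip],
                    residual = resid, stringsAsFactors = FALSE)

  profA <- csp_profile(single_A, max_jump = max_jump, weight = weight)
  profB <- csp_profile(single_B, max_jump = max_jump, weight = weight)
  sig <- intersect(labs, union(significant_residues(profA),
                               significant_residues(profB)))
  if (!length(sig)) sig <- labs
  use <- per$label %in% sig
  aggregate <- sqrt(mean(per$residual[use]^2))
  order_disc <- sqrt(mean(combined_csp(obs_AB$d_H[use] - obs_BA$d_H[use],
                                       obs_AB$d_N[use] - obs_BA$d_N[use],
                                       weight)^2))
  # occupancy-suppression signature: observed vs predicted regression
  # slope through the origin, in scaled space
  num <- sum(obs$d_H[use] * pred$d_H[ip][use] +
               (weight^2) * obs$d_N[use] * pred$d_N[ip][use])
  den <- sum(pred$d_H[ip][use]^2 + (weight^2) * pred$d_N[ip][use]^2)
  slope <- if (den > 0) num / den else NA_real_

  verdict <- if (aggregate <= tolerance && order_disc <= tolerance) {
    "simultaneous"
  } else if (aggregate > tolerance && is.finite(slope) && slope < 0.9) {
    "competitive"
  } else {
    "inconclusive"
  }
  structure(list(pair = c(series_AB$ligand_id, series_BA$ligand_id),
                 per_residue = per, significant = sig,
                 aggregate_residual = aggregate,
                 order_discrepancy = order_disc, slope = slope,
                 tolerance = tolerance, verdict = verdict),
            class = "dual_result")
}

#' @export
print.dual_result <- function(x, ...) {
  cat(sprintf(paste0("<dual_result %s + %s> verdict: %s | residual %0.4f, ",
                     "order discrepancy %0.4f (tol %0.3g), slope %0.2f\n"),
              x$pair[[1L]], x$pair[[2L]], x$verdict, x$aggregate_residual,
              x$order_discrepancy, x$tolerance, x$slope))
  invisible(x)
}
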