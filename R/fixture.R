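## Packaged CCL28-like screening fixture: a ~75-peak pseudo-chemokine
## fingerprint, a 2,678-fragment manifest arranged into 12-plexes, ground
## truth for 25 active fragments (13 specific binders split 4/8/1 across
## two sub-sites, 12 non-specific or pH-artifact actives), and a
## sulfotyrosine probe for hotspot mapping.

# 108-residue pseudo-sequence. The N-terminus SEAILPIASS precedes the CC
# motif at 11-12; a short helix spans 21-26; the sY-recognition cleft is
# bordered by the beta3 region around 49-54; three histidines provide
# pH-artifact reporters.
ccl28_pseudo_sequence <- function() {
  strsplit(paste0(
    "SEAILPIASS", "CC", "LTKYGFT",          #  1-19
    "SRAILEV",                               # 20-26
    "KTGCA", "PGDVF", "LTVHK", "AGPQD",     # 27-46
    "STKRA", "RICAD", "VHLEV", "PSDAM",     # 47-66
    "VTQKL", "AGNES", "VDACV", "AKTEG",     # 67-86
    "APSLT", "SAEGH", "ALDTK", "SAGET", "AS"), "")[[1]]
}

# residues with no observable NH in the fixture (N-terminus, prolines,
# unassigned)
ccl28_unassigned <- function() {
  sort(c(1L, 2L, 3L,                    # exchange-broadened N-terminus
         6L, 32L, 44L, 62L, 88L,       # prolines
         5L, 9L, 13L, 16L, 19L, 28L, 31L, 34L, 36L, 39L, 43L, 46L, 48L,
         51L, 57L, 61L, 64L, 68L, 72L, 76L, 79L, 86L, 90L, 94L, 99L, 103L))
}

#' Operational sub-site definitions for the fixture
#'
#' Residue labels defining the two candidate ligand-binding sub-sites used
#' for site assignment: the cleft between the N-loop and the short helix
#' (`site1_Nloop_helix`) and the sulfotyrosine-recognition cleft by the
#' beta3 strand (`site2_sY_cleft`). Residues in the middle of the shared
#' cleft (S20, R21, L24, I53) are perturbed by ligands of either site and
#' are deliberately affiliated with neither definition.
#'
#' @return Named list of two disjoint character vectors of residue labels.
#' @export
ccl28_site_definitions <- function() {
  list(site1_Nloop_helix = c("E25", "Q69", "Q69sc", "M66"),
       site2_sY_cleft = c("C11", "K49", "R50", "R52", "C54", "K83"))
}

# Poisson-disk placement of NH peaks in the scaled (1H, 0.2 * 15N) plane,
# minimum separation r, inside H [7.3, 9.8] x N [104, 131].
place_fingerprint <- function(n, r = 0.18) {
  H <- numeric(n); N <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:4000) {
      h <- stats::runif(1, 7.3, 9.8)
      nn <- stats::runif(1, 104, 131)
      if (i == 1L) break
      d2 <- (h - H[seq_len(i - 1L)])^2 + (0.2 * (nn - N[seq_len(i - 1L)]))^2
      if (min(d2) >= r^2) break
      if (try == 4000) stop("fingerprint placement failed", call. = FALSE)
    }
    H[[i]] <- h; N[[i]] <- nn
  }
  list(w_H = round(H, 4), w_N = round(N, 4))
}

## ---- planar geometry for trajectory clearance ------------------------

dist_point_seg <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab * ab), 1e-300)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

segs_intersect <- function(a, b, c, d) {
  o <- function(p, q, r) {
    v <- (q[2] - p[2]) * (r[1] - q[1]) - (q[1] - p[1]) * (r[2] - q[2])
    sign(v)
  }
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  (o1 != o2 && o3 != o4)
}

dist_seg_seg <- function(a, b, c, d) {
  if (segs_intersect(a, b, c, d)) return(0)
  min(dist_point_seg(a, c, d), dist_point_seg(b, c, d),
      dist_point_seg(c, a, b), dist_point_seg(d, a, b))
}

# Choose a shift direction (radians, scaled space) for every moving peak
# so that its full titration trajectory keeps a clearance from all other
# peaks and from previously chosen trajectories. Entities sharing a peak
# but belonging to different samples are not checked against each other;
# the S20 pair (opposite directions for the two sub-sites) is chosen
# jointly.
choose_directions <- function(start, entities, clearance = 0.12,
                              tries = 300L) {
  npk <- nrow(start)
  fixed <- list()  # list of list(label, a, b)
  dirs <- list()
  ord <- order(-vapply(entities, function(e) max(e$L), 0))
  for (e in entities[ord]) {
    p <- unlist(start[e$label, ])
    others <- start[setdiff(rownames(start), e$label), , drop = FALSE]
    score <- function(theta) {
      m <- Inf
      for (k in seq_along(e$L)) {
        th <- theta + e$offset[[k]]
        q <- p + e$L[[k]] * c(cos(th), sin(th))
        m <- min(m, min(apply(others, 1L,
                              function(o) dist_point_seg(o, p, q))))
        for (fs in fixed) {
          if (fs$label == e$label) next
          m <- min(m, dist_seg_seg(p, q, fs$a, fs$b))
        }
        if (m < clearance) break
      }
      m
    }
    best_th <- NA_real_; best_m <- -Inf
    for (t in seq_len(tries)) {
      th <- stats::runif(1, 0, 2 * pi)
      m <- score(th)
      if (m > best_m) { best_m <- m; best_th <- th }
      if (m >= clearance) break
    }
    for (k in seq_along(e$L)) {
      th <- best_th + e$offset[[k]]
      fixed[[length(fixed) + 1L]] <-
        list(label = e$label,
             a = p, b = p + e$L[[k]] * c(cos(th), sin(th)))
      dirs[[e$key[[k]]]] <- th
    }
  }
  unlist(dirs)
}

# direction theta (radians, scaled space) and combined magnitude c for one
# support residue become (d_H, d_N) with combined CSP (weight 0.2) == c
dir_to_dmax <- function(theta, cmb) {
  data.frame(d_H = cmb * cos(theta), d_N = cmb * sin(theta) / 0.2)
}

# ground-truth design for the 25 active fragments: sub-site role, Kd (mM)
# and support residues. Kds span the ~1 to >10 mM range typical of
# fragment hits; SPB07625, CC10501 and ZT0784 reproduce the screen's
# exemplar compounds.
fixture_active_design <- function() {
  list(
    list(id = "SPB07625", class = "specific", site = "site2_sY_cleft",
         kd = 0.85,
         support = c("C11", "S20", "R21", "L24", "R52", "I53", "C54")),
    list(id = "MBX1107", class = "specific", site = "site2_sY_cleft",
         kd = 1.3, support = c("C11", "R52", "C54", "K83", "I53")),
    list(id = "ZBA0212", class = "specific", site = "site2_sY_cleft",
         kd = 1.8, support = c("R52", "C54", "K83", "S20", "I53")),
    list(id = "TMC2291", class = "specific", site = "site2_sY_cleft",
         kd = 2.6, support = c("C11", "C54", "K83", "I53", "R21")),
    list(id = "ENB0844", class = "specific", site = "site2_sY_cleft",
         kd = 3.4, support = c("C11", "R52", "K83", "I53", "L24")),
    list(id = "MBX0561", class = "specific", site = "site2_sY_cleft",
         kd = 4.5, support = c("R52", "C54", "K83", "I53", "S20", "R21")),
    list(id = "TMC0930", class = "specific", site = "site2_sY_cleft",
         kd = 6.0, support = c("C11", "R52", "C54", "I53", "L24")),
    list(id = "ENB1502", class = "specific", site = "site2_sY_cleft",
         kd = 11.0, support = c("C11", "R52", "C54", "K83", "I53")),
    list(id = "CC10501", class = "specific", site = "site1_Nloop_helix",
         kd = 6.6,
         support = c("S20", "R21", "I53", "E25", "Q69", "Q69sc", "M66")),
    list(id = "MBX0774", class = "specific", site = "site1_Nloop_helix",
         kd = 2.0, support = c("E25", "Q69", "Q69sc", "S20", "R21")),
    list(id = "ZBA0147", class = "specific", site = "site1_Nloop_helix",
         kd = 3.0, support = c("E25", "Q69", "M66", "L24", "S20")),
    list(id = "TMC4418", class = "specific", site = "site1_Nloop_helix",
         kd = 4.8, support = c("E25", "Q69sc", "M66", "R21")),
    list(id = "ZT0784", class = "specific", site = "both",
         kd = 2.8, support = c("R52", "C54", "K49", "E25", "Q69", "I53")),
    list(id = "MBN0092", class = "nonspecific", kd = 13),
    list(id = "MBN0355", class = "nonspecific", kd = 15),
    list(id = "ZBN0078", class = "nonspecific", kd = 14),
    list(id = "TMN1206", class = "nonspecific", kd = 17),
    list(id = "TMN3340", class = "nonspecific", kd = 16),
    list(id = "ENN0410", class = "nonspecific", kd = 18),
    list(id = "ENN1177", class = "nonspecific", kd = 15),
    list(id = "MBP0688", class = "pH_artifact", kd = 12),
    list(id = "ZBP0301", class = "pH_artifact", kd = 14),
    list(id = "TMP2754", class = "pH_artifact", kd = 16),
    list(id = "TMP5019", class = "pH_artifact", kd = 13),
    list(id = "ENP0533", class = "pH_artifact", kd = 15))
}

# which direction pool a fragment's residue uses
pool_of <- function(d, residue) {
  if (d$class == "nonspecific") return("ns")
  if (d$class == "pH_artifact") return("ph")
  if (d$site == "site1_Nloop_helix") return("s1")
  if (d$site == "site2_sY_cleft") return("s2")
  # "both": site1 definition residues use the site1 pool
  if (residue %in% c("E25", "Q69", "Q69sc", "M66")) "s1" else "s2"
}

# one candidate realisation of the fixture ground truth (directions,
# amplitudes); verified functionally by the caller
build_fixture_truth <- function(assign, design) {
  label_to_res <- stats::setNames(assign$residue, assign$label)
  screen_conc <- 0.5   # mM per fragment in the pooled screen
  target <- 0.046      # combined primary-screen response of a hit (ppm)
  amp_floor <- 0.22    # minimum combined dmax (ppm) of an active
  ph_boost <- 1.5      # histidine protonation shifts are large

  # per-fragment amplitude and per-residue weights
  for (i in seq_along(design)) {
    d <- design[[i]]
    if (d$class %in% c("nonspecific", "pH_artifact")) {
      design[[i]]$support <- if (d$class == "nonspecific") {
        sample(c("V35", "L37", "Q45", "E60", "V67", "E85"), 5)
      } else c("H40", "H58", "H96")
    }
    f_screen <- fraction_bound(50, screen_conc, d$kd)
    u <- stats::runif(1, 0.9, 1.15)
    # standardise the total screen response across reporter counts, so a
    # hit with few reporters is as visible as one with many; histidine
    # protonation shifts carry their own (large) characteristic scale
    tgt <- target * (if (d$class == "pH_artifact") ph_boost else
      sqrt(6 / length(design[[i]]$support)))
    design[[i]]$amp <- max(tgt * u / f_screen, amp_floor * u)
    design[[i]]$v <- stats::runif(length(design[[i]]$support), 0.75, 1)
    design[[i]]$f6 <- fraction_bound(50, 6, d$kd)
  }

  # sulfotyrosine probe magnitudes (kd 10 mM): six hotspot reporters above
  # the 0.6 ppm rule at 100 mM, minor cleft residues well below it
  f100 <- fraction_bound(50, 100, 10)
  sty_hot <- c("C11", "K49", "R50", "R52", "I53", "K83")
  sty_min <- c("S20", "R21", "L24", "C54")
  sty_cmb <- c(stats::runif(length(sty_hot), 0.70, 0.80),
               stats::runif(length(sty_min), 0.15, 0.32)) / f100

  # realised trajectory length (scaled ppm) of every moving peak
  L_need <- list()
  bump <- function(pool, lab, L) {
    key <- paste0(pool, ".", lab)
    L_need[[key]] <<- max(L_need[[key]] %||% 0, L)
  }
  for (d in design) {
    for (j in seq_along(d$support)) {
      # 1.25 covers the largest direction-compensation factor below
      bump(pool_of(d, d$support[[j]]), d$support[[j]],
           d$amp * d$v[[j]] * d$f6 * 1.25)
    }
  }
  for (j in seq_along(c(sty_hot, sty_min))) {
    bump("s2", c(sty_hot, sty_min)[[j]], sty_cmb[[j]] * f100)
  }

  start <- cbind(assign$w_H, 0.2 * assign$w_N)
  rownames(start) <- assign$label
  keys <- names(L_need)
  labs <- sub("^[a-z0-9]+\\.", "", keys)
  entities <- list()
  done <- character(0)
  for (i in seq_along(keys)) {
    lab <- labs[[i]]
    if (lab %in% done) next
    idx <- which(labs == lab)
    if (lab == "S20" && length(idx) == 2L) {
      # S20 moves in opposite directions for the two sub-sites
      s2i <- idx[grepl("^s2\\.", keys[idx])]
      s1i <- setdiff(idx, s2i)
      entities[[length(entities) + 1L]] <- list(
        label = lab, key = keys[c(s2i, s1i)],
        L = unlist(L_need[c(s2i, s1i)]), offset = c(0, pi))
      done <- c(done, lab)
      next
    }
    for (k in idx) {
      entities[[length(entities) + 1L]] <- list(
        label = lab, key = keys[[k]], L = L_need[[k]], offset = 0)
    }
    done <- c(done, lab)
  }
  dirs <- choose_directions(start, entities)

  records <- list()
  for (d in design) {
    th <- dirs[paste0(vapply(d$support, function(r) pool_of(d, r), ""),
                      ".", d$support)]
    th <- th + stats::runif(length(th), -0.06, 0.06)
    # visibility in a spectrum is set by the displacement in linewidth
    # units; nitrogen-heavy directions render weaker lobes per scaled
    # ppm, so per-residue magnitudes are compensated to a common
    # rendered response
    R <- sqrt((cos(th) / 0.02)^2 + (sin(th) / 0.03)^2)
    fac <- pmin(1.25, 40 / R)
    dm <- dir_to_dmax(th, d$amp * d$v * fac)
    dm$residue <- unname(label_to_res[d$support])
    rec <- fragment_record(d$id, library_name = "pending",
                           site_label = if (d$class == "specific") d$site
                                        else "none",
                           kd = d$kd,
                           dmax = dm[c("residue", "d_H", "d_N")])
    rec$truth_class <- d$class
    records[[d$id]] <- rec
  }

  th_sty <- dirs[paste0("s2.", c(sty_hot, sty_min))] +
    stats::runif(length(sty_cmb), -0.04, 0.04)
  dm_sty <- dir_to_dmax(th_sty, sty_cmb)
  dm_sty$residue <- unname(label_to_res[c(sty_hot, sty_min)])
  sty <- fragment_record("sTyr", library_name = "probe",
                         site_label = "site2_sY_cleft", kd = 10,
                         dmax = dm_sty[c("residue", "d_H", "d_N")])
  list(records = records, sty = sty)
}

# noiseless functional check that the ground truth is resolvable by the
# analysis: every active's support is recovered as its significant set
# with the intended classification and site call, the sY hotspot rule
# returns exactly its six reporters, and the exemplar dual pair is
# additive (independent sites) / suppressed (competitive)
verify_fixture_truth <- function(assign, truth, sites) {
  no_noise <- c(0, 0)
  sty_series <- simulate_titration(assign, truth$sty,
                                   c(0, 1, 5, 10, 20, 50, 75, 100),
                                   50, no_noise, 1L)
  prof <- csp_profile(sty_series)
  hot <- hotspot_by_absolute_threshold(prof, 0.6)
  if (!setequal(hot, c("C11", "K49", "R50", "R52", "I53", "K83"))) {
    return(FALSE)
  }
  for (rec in truth$records) {
    ts <- simulate_titration(assign, rec, c(0, 0.25, 0.5, 1, 2, 4, 6),
                             50, no_noise, 1L)
    pr <- csp_profile(ts)
    sup <- assign$label[match(rec$dmax$residue, assign$residue)]
    if (!setequal(significant_residues(pr), sup)) return(FALSE)
    fit <- fit_kd(ts)
    cls <- classify_binding(ts, fit, pr, assign, sites)
    want <- rec$truth_class
    if (cls$label != want) return(FALSE)
    if (want == "specific" &&
        assign_site(pr, sites)$site != rec$site_label) return(FALSE)
  }
  dual <- run_dual_experiment(assign, truth$records[["SPB07625"]],
                              truth$records[["CC10501"]],
                              mode = "independent_sites",
                              noise_sd = no_noise, seed = 1L)
  if (dual$verdict != "simultaneous" || dual$aggregate_residual > 1e-4) {
    return(FALSE)
  }
  comp <- run_dual_experiment(assign, truth$records[["SPB07625"]],
                              truth$records[["ZBA0212"]],
                              mode = "competitive",
                              noise_sd = no_noise, seed = 1L)
  if (comp$verdict != "competitive") return(FALSE)
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the packaged CCL28-like screening fixture
#'
#' Deterministically (given `seed`) generates the pseudo-chemokine
#' assignment table (~75 NH peaks placed with a minimum-separation rule),
#' a 2,678-fragment manifest drawn from four commercial-style libraries
#' (1000 + 352 + 726 + 600), the 12-plex design of the first screening
#' round, ground-truth fragment records for 25 actives (13 specific
#' binders: 4 site1 / 8 site2 / 1 both; 7 non-specific binders; 5
#' histidine-only pH artifacts), and a sulfotyrosine probe whose six
#' strongest reporters (C11, K49, R50, R52, I53, K83) exceed 0.6 ppm
#' combined CSP at 100 mM.
#'
#' Shift directions are coherent within a sub-site (small per-fragment
#' jitter) so site-mates cluster in PCA, S20 moves in opposite directions
#' for the two sites, and every moving peak's full titration trajectory
#' is chosen to keep clear of all other peaks so that the fingerprint
#' remains trackable -- the synthetic analogue of picking resolvable
#' reporter peaks. Per-fragment maximal shifts are scaled so each active
#' produces a visible primary-screen response (about 0.03 ppm \eqn{^1}H
#' at 500 uM fragment, 50 uM protein) with a floor of about 0.22 ppm
#' combined maximal shift. A candidate realisation is accepted only after
#' a noiseless end-to-end resolvability check (tracking, significance,
#' classification, site calls, dual additivity).
#'
#' @param seed integer seed controlling all randomised aspects.
#' @return List with components `assignments` ([assignment_table()]),
#'   `fragments` (named list of [fragment_record()], all 2,678),
#'   `manifest` (data frame: `fragment_id`, `library_name`, `position`),
#'   `plex_design` (first-round [plex_design()]), `site_definitions`,
#'   `truth` (data frame of ground-truth class/site/kd per fragment) and
#'   `sty` (the sulfotyrosine probe [fragment_record()]).
#' @export
make_ccl28_fixture <- function(seed = 20230223L) {
  with_seed(seed, {
    seqv <- ccl28_pseudo_sequence()
    res <- setdiff(seq_along(seqv), ccl28_unassigned())
    pos <- place_fingerprint(length(res) + 1L)
    assign <- assignment_table(
      residue = c(res, 200L),
      code = c(seqv[res], "Q"),
      w_H = pos$w_H, w_N = pos$w_N,
      label = c(paste0(seqv[res], res), "Q69sc"),
      name = "pseudo-CCL28(1-108)")

    sites <- ccl28_site_definitions()
    design <- fixture_active_design()

    truth <- NULL
    for (attempt in 1:50) {
      cand <- build_fixture_truth(assign, design)
      if (verify_fixture_truth(assign, cand, sites)) { truth <- cand; break }
    }
    if (is.null(truth)) {
      stop("could not realise a trackable fixture for this seed",
           call. = FALSE)
    }
    records <- truth$records

    # manifest: four libraries in catalogue order
    libs <- c(Core1000 = 1000L, Zenobia1 = 352L, L5700 = 726L,
              ShapeDiverse3D = 600L)
    prefix <- c(Core1000 = "MB", Zenobia1 = "ZB", L5700 = "TM",
                ShapeDiverse3D = "EN")
    ids <- unlist(lapply(names(libs), function(nm) {
      sprintf("%s-%04d", prefix[[nm]], seq_len(libs[[nm]]))
    }), use.names = FALSE)
    libcol <- rep(names(libs), times = libs)
    n_total <- length(ids)

    # scatter the actives: SPB07625/CC10501 in the Maybridge block, ZT0784
    # in the Zenobia block, the rest anywhere free
    mb_pos <- sample(seq_len(1000L), 2)
    zb_pos <- sample(1000L + seq_len(352L), 1)
    rest <- sample(setdiff(seq_len(n_total), c(mb_pos, zb_pos)), 22)
    active_ids <- names(records)
    named <- match(c("SPB07625", "CC10501", "ZT0784"), active_ids)
    active_pos <- integer(length(active_ids))
    active_pos[named] <- c(mb_pos, zb_pos)
    active_pos[setdiff(seq_along(active_ids), named)] <- rest
    ids[active_pos] <- active_ids
    manifest <- data.frame(fragment_id = ids, library_name = libcol,
                           position = seq_len(n_total),
                           stringsAsFactors = FALSE)

    fragments <- vector("list", n_total)
    names(fragments) <- ids
    for (i in seq_len(n_total)) {
      id <- ids[[i]]
      if (!is.null(records[[id]])) {
        rec <- records[[id]]
        rec$library_name <- libcol[[i]]
        fragments[[id]] <- rec
      } else {
        fragments[[id]] <- fragment_record(id, library_name = libcol[[i]],
                                           site_label = "none")
      }
    }

    truth_df <- data.frame(
      fragment_id = ids,
      class = vapply(fragments, function(fr) {
        if (is.null(fr$truth_class)) "inert" else fr$truth_class
      }, ""),
      site_label = vapply(fragments, `[[`, "", "site_label"),
      kd = vapply(fragments, function(fr) {
        if (is.null(fr$kd)) NA_real_ else fr$kd
      }, 0),
      row.names = NULL, stringsAsFactors = FALSE)

    list(assignments = assign, fragments = fragments, manifest = manifest,
         plex_design = plex_design(manifest$fragment_id, plex_size = 12L,
                                   round_label = "12plex"),
         site_definitions = sites, truth = truth_df, sty = truth$sty)
  })
}

#' Group fragments into screening plexes
#'
#' Fragments are assigned to consecutive groups of at most `plex_size` in
#' manifest order, the pooling scheme of an iterative multiplexed screen.
#'
#' @param fragment_ids character vector in manifest order.
#' @param plex_size maximum fragments per pooled sample (12, 3 or 1).
#' @param round_label text tag for the screening round.
#' @return A `plex_design`: list with `assignments` (named list plex id ->
#'   fragment ids), `plex_size` and `round_label`.
#' @export
plex_design <- function(fragment_ids, plex_size, round_label = "round") {
  stopifnot(plex_size >= 1L)
  if (!length(fragment_ids)) {
    return(structure(list(assignments = list(), plex_size = plex_size,
                          round_label = round_label),
                     class = "plex_design"))
  }
  grp <- ceiling(seq_along(fragment_ids) / plex_size)
  assignments <- split(fragment_ids, grp)
  names(assignments) <- sprintf("%s-%03d", round_label,
                                seq_along(assignments))
  structure(list(assignments = assignments, plex_size = plex_size,
                 round_label = round_label),
            class = "plex_design")
}

#' @export
print.plex_design <- function(x, ...) {
  cat(sprintf("<plex_design '%s'> %d groups of <= %d fragments\n",
              x$round_label, length(x$assignments), x$plex_size))
  invisible(x)
}

#' Write / read a fragment manifest and plex design as CSV
#'
#' The manifest CSV has columns `fragment_id`, `library_name`,
#' `position`; the plex CSV has columns `plex_id`, `fragment_id`.
#'
#' @param manifest,design objects to serialise.
#' @param path destination CSV.
#' @return The written path (write) or the reconstructed object (read).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_manifest
#' @export
write_plex_design <- function(design, path) {
  df <- data.frame(
    plex_id = rep(names(design$assignments),
                  lengths(design$assignments)),
    fragment_id = unlist(design$assignments, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param plex_size,round_label metadata not stored in the CSV body.
#' @export
read_plex_design <- function(path, plex_size, round_label = "round") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assignments <- split(df$fragment_id, df$plex_id)
  assignments <- assignments[unique(df$plex_id)]
  structure(list(assignments = assignments, plex_size = plex_size,
                 round_label = round_label),
            class = "plex_design")
}
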