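# Readouts: infiltrate percentages, convex-hull CTL density in a z-slice,
# shell-normalized radial profiles, kernel-smoothed endpoint histograms,
# percent reduction, response bins, the minimal-best-therapy rule and the
# FGFR3 fitness-landscape sweep.

#' CTL infiltrate percentage
#'
#' Percentage of all cells in the TME that are CTLs:
#' `100 * n_CTL / (n_CTL + n_tumor)`.
#'
#' @param snapshot agent table (see [snapshot_agents()]).
#' @return percentage; `NA` with a warning if the snapshot holds no cells.
#' @export
ctl_infiltrate_pct <- function(snapshot) {
  n_ctl <- sum(snapshot$type == "ctl")
  n_tum <- sum(snapshot$type == "tumor")
  if (n_ctl + n_tum == 0) {
    warning("empty snapshot: infiltrate undefined")
    return(NA_real_)
  }
  100 * n_ctl / (n_ctl + n_tum)
}

# Signed polygon area (shoelace); vertices in order.
#' @keywords internal
polygon_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  sum(px[j] * py - px * py[j]) / 2
}

# Inclusive point-in-convex-polygon test; vertices counter-clockwise.
#' @keywords internal
in_convex_polygon <- function(x, y, px, py, tol = 1e-9) {
  n <- length(px)
  inside <- rep(TRUE, length(x))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    cr <- (px[k2] - px[k]) * (y - py[k]) - (py[k2] - py[k]) * (x - px[k])
    inside <- inside & cr >= -tol
  }
  inside
}

#' Active-CTL density inside the tumor convex hull of a z-slice
#'
#' Computes the 2D convex hull of tumor cell positions in one z-plane
#' (default: the slice holding the median tumor z-coordinate, the "middle"
#' slice of the mass) and returns the number of active CTLs on or inside
#' the hull divided by the hull area (cells per site^2). Mirrors a tissue
#' section through the tumor.
#'
#' @param snapshot agent table.
#' @param z_slice z-plane to section; default the median tumor z.
#' @return density; `NA` with a warning if fewer than three non-collinear
#'   tumor cells lie in the slice (degenerate hull).
#' @export
hull_ctl_density <- function(snapshot, z_slice = NULL) {
  tum <- snapshot[snapshot$type == "tumor", ]
  if (is.null(z_slice)) {
    if (nrow(tum) == 0) {
      warning("no tumor cells: hull undefined")
      return(NA_real_)
    }
    z_slice <- round(stats::median(tum$z))
  }
  ts <- tum[tum$z == z_slice, ]
  pts <- unique(ts[, c("x", "y")])
  if (nrow(pts) < 3) {
    warning("fewer than 3 tumor positions in slice: hull undefined")
    return(NA_real_)
  }
  h <- chull(pts$x, pts$y)
  px <- pts$x[h]; py <- pts$y[h]
  area <- polygon_area(px, py)
  if (area < 0) {            # ensure counter-clockwise orientation
    px <- rev(px); py <- rev(py); area <- -area
  }
  if (area <= 1e-12) {
    warning("collinear tumor positions in slice: hull degenerate")
    return(NA_real_)
  }
  ctl <- snapshot[snapshot$type == "ctl" & snapshot$state == "active" &
                    snapshot$z == z_slice, ]
  n_in <- if (nrow(ctl)) sum(in_convex_polygon(ctl$x, ctl$y, px, py)) else 0L
  n_in / area
}

#' Shell-normalized radial probability density
#'
#' Histogram of distances from `center`, where each bin count is divided by
#' the number of lattice sites whose center falls in that radial shell
#' (the lattice-based shell volume), then normalized so the densities
#' integrate to 1 over the bins. A uniformly occupied lattice therefore
#' yields a flat profile, and enrichment at a radius reads directly as
#' density above the baseline.
#'
#' @param positions numeric matrix (n x 3) of agent coordinates.
#' @param center length-3 center (e.g. the live-tumor centroid).
#' @param bin_width radial bin width (site lengths).
#' @param dims lattice dimensions (needed to enumerate shell volumes).
#' @return data.frame with `r_mid`, `count`, `n_sites`, `density`.
#' @export
radial_pdf <- function(positions, center, bin_width, dims) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 1, ncol(positions) == 3, bin_width > 0)
  d <- sqrt(colSums((t(positions) - center)^2))
  lat <- make_lattice(dims)
  ds <- sqrt((lat$x - center[1])^2 + (lat$y - center[2])^2 +
               (lat$z - center[3])^2)
  breaks <- seq(0, max(d, ds) + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                  length(breaks) - 1L)
  vol <- tabulate(findInterval(ds, breaks, rightmost.closed = TRUE),
                  length(breaks) - 1L)
  raw <- ifelse(vol > 0, cnt / vol, 0)
  dens <- raw / (sum(raw) * bin_width)
  data.frame(r_mid = breaks[-length(breaks)] + bin_width / 2,
             count = cnt, n_sites = vol, density = dens)
}

#' Percent reduction in tumor burden relative to control
#'
#' `100 * (1 - mean treated burden(day) / mean control burden(day))`,
#' with means across replicates.
#'
#' @param treated,control lists of `tme_trial` objects (or single trials).
#' @param day endpoint day (default 25).
#' @return percentage; `NA` with a warning if the control burden is zero.
#' @export
percent_reduction <- function(treated, control, day = 25) {
  bt <- burden_at_day(treated, day)
  bc <- burden_at_day(control, day)
  if (bc == 0) {
    warning("zero control burden: reduction undefined")
    return(NA_real_)
  }
  100 * (1 - bt / bc)
}

#' Bin a percent reduction into a response class
#'
#' Decision bins on Day-25 percent reduction: `not_effective` (< 30%),
#' `effective` (30% <= reduction < 90%) and `highly_effective` (>= 90%),
#' with inclusive lower bounds.
#'
#' @param reduction finite percentage (vectorized).
#' @return ordered factor with the three response levels.
#' @export
classify_response <- function(reduction) {
  if (any(!is.finite(reduction))) stop("reduction must be finite")
  lev <- c("not_effective", "effective", "highly_effective")
  out <- ifelse(reduction >= 90, 3L, ifelse(reduction >= 30, 2L, 1L))
  factor(lev[out], levels = lev, ordered = TRUE)
}

#' Minimal therapy achieving the maximal response
#'
#' Given per-arm percent reductions, finds the best response bin achieved
#' over all treatment arms and returns the minimal-tier arms that achieve
#' it: monotherapies (`ICI`, `aFGFR3`) rank below staggered combinations
#' (`FGFR3_first`, `ICI_first`). Ties within a tier return both members.
#' If the best bin is `not_effective` the set is empty.
#'
#' @param reductions named numeric vector of percent reductions; must
#'   contain the four treatment arms (a `control` entry is ignored).
#' @return character vector of arm names (possibly empty).
#' @export
minimal_best_therapy <- function(reductions) {
  mono <- c("ICI", "aFGFR3")
  combo <- c("FGFR3_first", "ICI_first")
  need <- c(mono, combo)
  if (!all(need %in% names(reductions)))
    stop("reductions must include arms: ", paste(need, collapse = ", "))
  bins <- classify_response(unname(reductions[need]))
  names(bins) <- need
  best <- max(bins)
  if (best == "not_effective") return(character(0))
  winners <- names(bins)[bins == best]
  if (any(winners %in% mono)) intersect(winners, mono)
  else intersect(winners, combo)
}

#' Gaussian kernel-smoothed endpoint histogram
#'
#' Gaussian kernel density estimate of replicate endpoint values (e.g.
#' Day-25 tumor burdens); integrates to 1. Bandwidth defaults to
#' Silverman's rule.
#'
#' @param values numeric vector, length >= 2.
#' @param bandwidth kernel bandwidth; `NULL` for Silverman's rule.
#' @return data.frame with `x`, `density`.
#' @export
kde_histogram <- function(values, bandwidth = NULL) {
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0)
    stop("zero variance: density degenerates to a spike at ", values[1])
  d <- if (is.null(bandwidth))
    density(values, kernel = "gaussian", n = 2048, cut = 6)
  else density(values, bw = bandwidth, kernel = "gaussian", n = 2048, cut = 6)
  # renormalize the discrete grid so the curve integrates to exactly 1
  dx <- d$x[2] - d$x[1]
  area <- sum((d$y[-1] + d$y[-length(d$y)]) / 2) * dx
  data.frame(x = d$x, density = d$y / area)
}

#' Default sweep grid over FGFR3 effect parameters
#'
#' A 10 x 5 grid of `(alpha_F, eps_F)` pairs (50 parameter combinations)
#' whose drug-free equilibrium fitness spans proliferation rates from the
#' wild-type base up beyond 1.75 per day and expected apoptosis times from
#' about a week to multiple months.
#'
#' @param config configuration providing the base rates and kinetics.
#' @param n_alpha,n_eps grid resolution (defaults 10 and 5).
#' @return data.frame with `alpha_F`, `eps_F` and the equilibrium-axis
#'   columns of [equilibrium_fitness()].
#' @export
sweep_grid <- function(config = default_config(), n_alpha = 10, n_eps = 5) {
  cfg <- validate_config(config)
  eq1 <- equilibrium_fitness(1, 0, cfg)
  phi <- eq1$phi_eq
  a_hi <- max((1.9 - cfg$tumor$alpha_T_per_day) / max(phi, 1e-6), 2)
  alphas <- seq(0, a_hi, length.out = n_alpha)
  eps_hi <- 0.999
  epss <- 1 - exp(seq(log(1), log(1 - eps_hi), length.out = n_eps))
  g <- expand.grid(alpha_F = alphas, eps_F = epss)
  eq <- equilibrium_fitness(g$alpha_F, g$eps_F, cfg)
  eq
}

#' Run the FGFR3 fitness-landscape sweep
#'
#' For every `(alpha_F, eps_F)` pair in the grid, runs replicate
#' simulations of the control arm and of each treatment arm, computes the
#' Day-25 percent reduction per arm, bins the responses, and applies the
#' minimal-best-therapy rule. Rows carry the drug-free equilibrium fitness
#' coordinates used as landscape axes.
#'
#' @param config base configuration (initial composition etc.).
#' @param grid data.frame with columns `alpha_F`, `eps_F` (default:
#'   [sweep_grid()], 50 pairs).
#' @param arms treatment arms to test (default all four).
#' @param n_reps replicates per arm and parameter set.
#' @param base_seed seed offset; each (pair, arm) block gets its own
#'   deterministic sub-seed.
#' @param day endpoint day.
#' @return data.frame, one row per pair: equilibrium axes, per-arm
#'   reductions (`red_<arm>`), bins (`bin_<arm>`) and the minimal best
#'   therapy set (`best`, comma-separated).
#' @export
run_fitness_sweep <- function(config = default_config(), grid = NULL,
                              arms = c("ICI", "aFGFR3", "FGFR3_first",
                                       "ICI_first"),
                              n_reps = NULL, base_seed = 1L, day = 25) {
  cfg <- validate_config(config)
  if (is.null(grid)) grid <- sweep_grid(cfg)
  stopifnot(nrow(grid) >= 1)
  n_reps <- n_reps %||% cfg$run$n_reps
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg_g <- cfg
    cfg_g$tumor$alpha_F_per_day <- grid$alpha_F[g]
    cfg_g$tumor$eps_F <- grid$eps_F[g]
    seed_g <- base_seed + (g - 1L) * 1000L
    cfg_g$therapy$arm <- "control"
    ctrl <- run_replicates(cfg_g, n_reps, base_seed = seed_g)
    red <- setNames(numeric(length(arms)), arms)
    for (ai in seq_along(arms)) {
      cfg_a <- cfg_g
      cfg_a$therapy$arm <- arms[ai]
      tr <- run_replicates(cfg_a, n_reps, base_seed = seed_g + ai * 100L)
      red[ai] <- percent_reduction(tr, ctrl, day)
    }
    eq <- equilibrium_fitness(grid$alpha_F[g], grid$eps_F[g], cfg)
    row <- data.frame(alpha_F = grid$alpha_F[g], eps_F = grid$eps_F[g],
                      prolif_per_day = eq$prolif_per_day,
                      t_apop_days = eq$t_apop_days)
    for (a in arms) row[[paste0("red_", a)]] <- red[[a]]
    for (a in arms) row[[paste0("bin_", a)]] <-
      if (is.finite(red[[a]])) as.character(classify_response(red[[a]]))
      else NA_character_
    full_menu <- all(c("ICI", "aFGFR3", "FGFR3_first", "ICI_first") %in% arms)
    row$best <- if (full_menu && all(is.finite(red)))
      paste(minimal_best_therapy(red), collapse = ",") else NA_character_
    rows[[g]] <- row
  }
  do.call(rbind, rows)
}
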