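# Synthetic-data generators: everything the analysis chain consumes can be
# produced here with known ground truth, so the full pipeline runs and is
# testable without any external image data.

#' Lumped first-order chip oxygen response
#'
#' Oxygen reaches the fluid channel by diffusion through the PDMS chip body;
#' the diffusion time scales as t ~ d^2/D with membrane/chip thickness d and
#' diffusion coefficient D (~1e-9 m^2/s for oxygen in PDMS). The generator
#' lumps this into a single first-order time constant. The default T = 37
#' min puts the 90% switching time T*ln(10) ~ 85 min inside the 80-90 min
#' band typical for millimetre-thick chips.
#'
#' @param response_time_constant_min time constant T in minutes; ignored if
#'   both `membrane_thickness_m` and `diffusion_coefficient_m2_s` are given,
#'   in which case `T = d^2 / D` (converted to minutes).
#' @param membrane_thickness_m optional thickness d (m).
#' @param diffusion_coefficient_m2_s optional diffusion coefficient D (m^2/s).
#' @return object of class `o2_response_model`.
#' @export
o2_response_model <- function(response_time_constant_min = 37,
                              membrane_thickness_m = NULL,
                              diffusion_coefficient_m2_s = 1e-9) {
  if (!is.null(membrane_thickness_m))
    response_time_constant_min <-
      membrane_thickness_m^2 / diffusion_coefficient_m2_s / 60
  if (response_time_constant_min <= 0) stop("time constant must be > 0")
  structure(list(response_time_constant_min = response_time_constant_min),
            class = "o2_response_model")
}

#' Monolayer cultivation chamber geometry
#'
#' The default chamber is 50 x 30 um with a height of 1 um - the diameter of
#' a typical *E. coli* cell - which confines growth to a monolayer. The two
#' short chamber ends open into the fluid supply channels.
#'
#' @param width_um,depth_um,height_um chamber dimensions (um).
#' @return object of class `chamber_geometry` with derived `volume_pl`.
#' @export
chamber_geometry <- function(width_um = 50, depth_um = 30, height_um = 1) {
  structure(list(width_um = width_um, depth_um = depth_um,
                 height_um = height_um,
                 volume_pl = width_um * depth_um * height_um * 1e-3),
            class = "chamber_geometry")
}

#' GFP expression and oxygen-gated maturation kinetics
#'
#' GFP is modeled in two intracellular pools: an immature (dark) pool fed by
#' constitutive expression, and a mature (fluorescent) pool. The final
#' chromophore maturation step requires molecular oxygen: conversion runs at
#' `maturation_rate_per_h` only while the ambient oxygen is at or above
#' `o2_min`, and halts completely below it. GFP is therefore a one-way
#' intracellular oxygen indicator: once matured, fluorescence no longer
#' depends on oxygen and is diluted only by division (and optional
#' bleaching).
#'
#' Expression does not jump to full speed at induction: expression capacity
#' builds up gradually after the inducer reaches the cells, so the per-cell
#' production rate ramps linearly from 0 to `expression_rate` over
#' `induction_ramp_h` hours (default 12 h, i.e. still ramping over a 9 h
#' culture). This slow buildup is what makes the population-mean
#' fluorescence rise nearly linearly over a whole culture instead of
#' saturating within ~1/mu hours at the expression/dilution balance.
#' Set `induction_ramp_h = 0` for a constant rate.
#'
#' @param expression_rate immature-GFP production per cell (a.u./h) at full
#'   induction.
#' @param maturation_rate_per_h first-order maturation rate once oxygen is
#'   available (default 1.4/h, i.e. a ~30 min maturation half-time).
#' @param o2_min maturation threshold on the oxygen fraction scale; default
#'   1e-6 (effectively zero: any measurable oxygen enables maturation).
#' @param bleaching_rate_per_h first-order loss of the mature pool
#'   (default 0).
#' @param induction_ramp_h time over which the expression rate ramps
#'   linearly from 0 to `expression_rate` (default 12; 0 = constant rate).
#' @return object of class `gfp_kinetics`.
#' @export
gfp_kinetics <- function(expression_rate = 100, maturation_rate_per_h = 1.4,
                         o2_min = 1e-6, bleaching_rate_per_h = 0,
                         induction_ramp_h = 12) {
  if (expression_rate < 0 || maturation_rate_per_h < 0 ||
      bleaching_rate_per_h < 0 || o2_min < 0 || induction_ramp_h < 0)
    stop("all rates and the threshold must be >= 0")
  structure(list(expression_rate = expression_rate,
                 maturation_rate_per_h = maturation_rate_per_h,
                 o2_min = o2_min, bleaching_rate_per_h = bleaching_rate_per_h,
                 induction_ramp_h = induction_ramp_h),
            class = "gfp_kinetics")
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate the chip oxygen response to a step schedule
#'
#' Within each step toward setpoint `s`, starting from entry value `c0`, the
#' concentration relaxes as \eqn{c(t) = s + (c_0 - s) e^{-t/T}}; the value is
#' continuous across step boundaries. Sampling follows the schedule's
#' imaging interval.
#'
#' @param schedule a [step_schedule()].
#' @param model an [o2_response_model()].
#' @param initial_fraction starting concentration (fraction); defaults to the
#'   first setpoint (system pre-equilibrated).
#' @return ground-truth [o2_trace()].
#' @export
simulate_o2_response <- function(schedule, model = o2_response_model(),
                                 initial_fraction = NULL) {
  stopifnot(inherits(schedule, "step_schedule"),
            inherits(model, "o2_response_model"))
  b <- schedule_boundaries(schedule)
  Ts <- model$response_time_constant_min * 60
  sp <- b$setpoint_percent / 100
  entry <- numeric(nrow(b))
  entry[1] <- if (is.null(initial_fraction)) sp[1] else initial_fraction
  for (i in seq_len(nrow(b) - 1))
    entry[i + 1] <- sp[i] + (entry[i] - sp[i]) * exp(-(b$end_s[i] - b$start_s[i]) / Ts)
  total <- max(b$end_s)
  times <- seq(0, total, by = schedule$sample_interval_min * 60)
  step_of <- findInterval(times, b$start_s)
  step_of[times >= total] <- nrow(b)
  o2 <- sp[step_of] + (entry[step_of] - sp[step_of]) *
    exp(-(times - b$start_s[step_of]) / Ts)
  o2_trace(times, o2, source_roi = "simulated")
}

#' Simulate modulated FLIM stacks from an oxygen trace
#'
#' Forward model of the sensor imaging chain: per frame the expected RTDP
#' lifetime is [lifetime_from_o2()]; a mono-exponential emitter at lifetime
#' tau under sinusoidal excitation at frequency f has first-harmonic phase
#' `atan(omega*tau)` and modulation depth `1/sqrt(1 + (omega*tau)^2)`, so
#' each pixel's phase series is
#' `I_k = dc * (1 + m * cos(2*pi*k/K - phase))` plus optional noise.
#'
#' @param trace an [o2_trace()] (one stack per sample).
#' @param calib a [fit_stern_volmer()] calibration.
#' @param image_shape `c(rows, cols)` of the synthetic sensor image.
#' @param dc_level mean intensity level (a.u. or photons).
#' @param k_phases number of phase steps per period (default 8).
#' @param f_hz modulation frequency (default 550 kHz).
#' @param noise one of `"none"`, `"gaussian"` (additive, sd =
#'   `noise_sd`), `"poisson"` (shot noise on the intensity).
#' @param noise_sd additive noise sd in intensity units.
#' @param seed RNG seed for the noise (local; caller's RNG is untouched).
#' @return list of [modulated_stack()], one per trace sample.
#' @export
simulate_flim_series <- function(trace, calib, image_shape = c(16, 16),
                                 dc_level = 1000, k_phases = 8, f_hz = 550e3,
                                 noise = c("none", "gaussian", "poisson"),
                                 noise_sd = 0, seed = NULL) {
  stopifnot(inherits(trace, "o2_trace"))
  noise <- match.arg(noise)
  w <- 2 * pi * f_hz
  k <- 0:(k_phases - 1)
  with_seed(seed, {
    lapply(seq_along(trace$times_s), function(i) {
      tau_s <- lifetime_from_o2(max(trace$o2_fraction[i], 0), calib) * 1e-9
      ph <- atan(w * tau_s)
      m <- 1 / sqrt(1 + (w * tau_s)^2)
      series <- dc_level * (1 + m * cos(2 * pi * k / k_phases - ph))
      px <- array(rep(series, times = prod(image_shape)),
                  dim = c(k_phases, image_shape))
      if (noise == "gaussian" && noise_sd > 0)
        px <- px + stats::rnorm(length(px), 0, noise_sd)
      else if (noise == "poisson")
        px <- array(stats::rpois(length(px), pmax(px, 0)), dim = dim(px))
      px[px < 0] <- 0
      modulated_stack(px, modulation_frequency_hz = f_hz,
                      timestamp_s = trace$times_s[i])
    })
  })
}

# ---------------------------------------------------------------------------
# agent-based monolayer colony
# ---------------------------------------------------------------------------

# meanlog of the lognormal interdivision-time distribution such that a
# population with i.i.d. division times T ~ lognormal(meanlog, sdlog) grows
# asymptotically at rate mu: Euler-Lotka, 2 * E[exp(-mu T)] = 1.
interdivision_meanlog <- function(mu_per_h, cv) {
  if (cv < 0) stop("division_cv must be >= 0")
  if (cv == 0) return(log(log(2) / mu_per_h))
  sdlog <- sqrt(log(1 + cv^2))
  g <- function(ml)
    2 * stats::integrate(function(t) exp(-mu_per_h * t) *
                           stats::dlnorm(t, ml, sdlog),
                         0, Inf, rel.tol = 1e-10)$value - 1
  base <- log(log(2) / mu_per_h)
  stats::uniroot(g, c(base - 1, base + 1), tol = 1e-12)$root
}

# minimum distance between 2-d segments (vectorized over pairs);
# segments given by centers, unit axes and half-lengths
segment_pair_distance <- function(cx1, cy1, ax1, ay1, h1,
                                  cx2, cy2, ax2, ay2, h2) {
  p1x <- cx1 - ax1 * h1; p1y <- cy1 - ay1 * h1
  q1x <- cx2 - ax2 * h2; q1y <- cy2 - ay2 * h2
  d1x <- 2 * ax1 * h1; d1y <- 2 * ay1 * h1
  d2x <- 2 * ax2 * h2; d2y <- 2 * ay2 * h2
  rx <- p1x - q1x; ry <- p1y - q1y
  a <- pmax(d1x^2 + d1y^2, 1e-12)
  e <- pmax(d2x^2 + d2y^2, 1e-12)
  b <- d1x * d2x + d1y * d2y
  c_ <- d1x * rx + d1y * ry
  f <- d2x * rx + d2y * ry
  den <- a * e - b^2
  s <- ifelse(den > 1e-12, pmin(pmax((b * f - c_ * e) / den, 0), 1), 0)
  t <- (b * s + f) / e
  t <- pmin(pmax(t, 0), 1)
  s <- pmin(pmax((b * t - c_) / a, 0), 1)
  px <- p1x + s * d1x; py <- p1y + s * d1y
  qx <- q1x + t * d2x; qy <- q1y + t * d2y
  list(d = sqrt((px - qx)^2 + (py - qy)^2),
       px = px, py = py, qx = qx, qy = qy)
}

# push overlapping rods apart and keep them inside the chamber walls
# (y-walls closed; x-ends open into the supply channels)
relax_rods <- function(st, geom, rod_width, max_iter = 30) {
  n <- length(st$x)
  if (n > 1) {
    for (it in seq_len(max_iter)) {
      ax <- cos(st$angle); ay <- sin(st$angle)
      h <- (st$length - rod_width) / 2          # axis half-length of the rod core
      h <- pmax(h, 0)
      # candidate pairs by center distance
      reach <- h + rod_width
      dx <- outer(st$x, st$x, `-`); dy <- outer(st$y, st$y, `-`)
      lim <- outer(reach, reach, `+`)
      cand <- which(upper.tri(lim) & dx^2 + dy^2 < lim^2, arr.ind = TRUE)
      if (!nrow(cand)) break
      i <- cand[, 1]; j <- cand[, 2]
      sd <- segment_pair_distance(st$x[i], st$y[i], ax[i], ay[i], h[i],
                                  st$x[j], st$y[j], ax[j], ay[j], h[j])
      ov <- rod_width - sd$d
      hit <- ov > 1e-9
      if (!any(hit)) break
      i <- i[hit]; j <- j[hit]; ov <- ov[hit]
      ux <- sd$qx[hit] - sd$px[hit]; uy <- sd$qy[hit] - sd$py[hit]
      nn <- sqrt(ux^2 + uy^2)
      # coincident closest points: separate along the inter-center direction
      zero <- nn < 1e-9
      if (any(zero)) {
        ux[zero] <- st$x[j][zero] - st$x[i][zero]
        uy[zero] <- st$y[j][zero] - st$y[i][zero]
        nn2 <- sqrt(ux[zero]^2 + uy[zero]^2)
        ux[zero] <- ifelse(nn2 > 1e-9, ux[zero] / nn2, 1)
        uy[zero] <- ifelse(nn2 > 1e-9, uy[zero] / nn2, 0)
        nn[zero] <- 1
      }
      ux <- ux / nn; uy <- uy / nn
      # accumulate half-overlap displacements per cell
      mvx <- numeric(n); mvy <- numeric(n)
      for (kk in seq_along(i)) {
        mvx[i[kk]] <- mvx[i[kk]] - ux[kk] * ov[kk] / 2
        mvy[i[kk]] <- mvy[i[kk]] - uy[kk] * ov[kk] / 2
        mvx[j[kk]] <- mvx[j[kk]] + ux[kk] * ov[kk] / 2
        mvy[j[kk]] <- mvy[j[kk]] + uy[kk] * ov[kk] / 2
      }
      st$x <- st$x + mvx
      st$y <- st$y + mvy
      st <- clamp_walls(st, geom, rod_width)
    }
  }
  clamp_walls(st, geom, rod_width)
}

clamp_walls <- function(st, geom, rod_width) {
  # closed walls at y = 0 and y = depth
  ey <- abs(sin(st$angle)) * pmax(st$length - rod_width, 0) / 2 + rod_width / 2
  st$y <- pmin(pmax(st$y, ey), geom$depth_um - ey)
  st
}

#' Simulate a monolayer micro-colony with oxygen-gated GFP maturation
#'
#' Agent-based simulation of rod-shaped cells growing as a monolayer in a
#' rectangular cultivation chamber. Each cell elongates exponentially and
#' divides into two equal daughters when it has doubled its birth length;
#' interdivision times are drawn from a lognormal distribution whose mean is
#' calibrated (via the Euler-Lotka relation) so the expected population
#' growth rate equals `target_mu_per_h`, with coefficient of variation
#' `division_cv`. Overlapping rods are pushed apart pairwise; the long
#' chamber walls confine the colony while cells drifting past the open
#' chamber ends (which connect to the fluid supply channels) leave the
#' chamber and are removed (logged in `$exited`).
#'
#' GFP follows expression -> oxygen-gated maturation -> dilution by
#' division (see [gfp_kinetics()]); the ambient oxygen comes from
#' `o2_trace`. Pool updates use the exact linear-kinetics solution per
#' interval, so immature + mature GFP over all cells (including exited
#' ones) equals cumulative expression when bleaching is off. GFP pools
#' split in proportion to daughter lengths at division.
#'
#' @param target_mu_per_h target population growth rate (1/h).
#' @param o2_trace ambient oxygen as an [o2_trace()]; a constant trace works
#'   (e.g. aerobic 21%).
#' @param duration_h simulated time span (h).
#' @param geometry a [chamber_geometry()].
#' @param division_cv CV of the interdivision-time distribution (default 0.2).
#' @param gfp a [gfp_kinetics()].
#' @param frame_interval_min imaging period (min, default 5).
#' @param n_seed_cells number of founder cells (default 2).
#' @param birth_length_um mean cell length right after division (default 2).
#' @param rod_width_um cell width (default 1, the chamber height).
#' @param seed RNG seed; identical (parameters, seed) give identical output.
#' @return object of class `synthetic_colony`: `cells` (per frame and cell:
#'   label, position, length, GFP pools, concentration, generation, ...),
#'   `divisions`, `exited`, `frames_h`, `cumulative_expression_au`,
#'   `crowding_stopped`, `params`.
#' @export
simulate_colony <- function(target_mu_per_h, o2_trace, duration_h,
                            geometry = chamber_geometry(), division_cv = 0.2,
                            gfp = gfp_kinetics(), frame_interval_min = 5,
                            n_seed_cells = 2, birth_length_um = 2,
                            rod_width_um = 1, seed = 1) {
  stopifnot(inherits(o2_trace, "o2_trace"), inherits(gfp, "gfp_kinetics"),
            inherits(geometry, "chamber_geometry"))
  if (n_seed_cells < 1) stop("need at least one seed cell")
  if (n_seed_cells * birth_length_um * rod_width_um >
      0.5 * geometry$width_um * geometry$depth_um)
    stop("chamber too small for the requested number of seed cells")
  meanlog <- interdivision_meanlog(target_mu_per_h, division_cv)
  sdlog <- if (division_cv > 0) sqrt(log(1 + division_cv^2)) else 0
  draw_T <- function(n) if (sdlog > 0) stats::rlnorm(n, meanlog, sdlog)
                        else rep(exp(meanlog), n)
  o2_at <- stats::approxfun(o2_trace$times_s / 3600, o2_trace$o2_fraction,
                            rule = 2)
  e_rate <- gfp$expression_rate
  k_mat <- gfp$maturation_rate_per_h
  bleach <- gfp$bleaching_rate_per_h

  with_seed(seed, {
    # founder cells, desynchronized by a uniform cell-cycle phase
    n <- n_seed_cells
    Tdiv <- draw_T(n)
    phase <- stats::runif(n)
    st <- list(
      id = seq_len(n), parent = rep(NA_integer_, n),
      generation = rep(0L, n), birth_h = -phase * Tdiv,
      x = geometry$width_um * seq_len(n) / (n + 1),
      y = rep(geometry$depth_um / 2, n) + stats::runif(n, -2, 2),
      angle = stats::runif(n, 0, pi),
      length = birth_length_um * 2^phase,
      alpha = log(2) / Tdiv,
      next_div = (1 - phase) * Tdiv,
      immature = rep(0, n), mature = rep(0, n))
    next_id <- n + 1L
    cum_expr <- 0
    divisions <- list()
    exited <- list()
    frames <- list()
    frames_h <- seq(0, duration_h, by = frame_interval_min / 60)
    crowding_stopped <- FALSE
    recorded_h <- numeric(0)

    # mean expression rate over [t0, t1] under the linear induction ramp
    # (exact integral, so GFP bookkeeping conserves total expression)
    ramp_rate <- function(t0, t1) {
      tr <- gfp$induction_ramp_h
      if (tr <= 0) return(e_rate)
      a <- max(t0, 0); b <- t1
      if (b <= a) return(if (b >= tr) e_rate else e_rate * max(b, 0) / tr)
      ramp_part <- (min(b, tr)^2 - min(a, tr)^2) / (2 * tr)
      full_part <- max(b - tr, 0) - max(a - tr, 0)
      e_rate * (ramp_part + full_part) / (b - a)
    }

    advance <- function(st, t0, t1) {
      dt <- t1 - t0
      if (dt <= 0 || !length(st$id)) return(st)
      st$length <- st$length * exp(st$alpha * dt)
      e_eff <- ramp_rate(t0, t1)
      gate <- o2_at(t1) >= gfp$o2_min
      if (gate && k_mat > 0) {
        dec <- exp(-k_mat * dt)
        I0 <- st$immature
        st$immature <- e_eff / k_mat + (I0 - e_eff / k_mat) * dec
        converted <- e_eff * dt + (I0 - e_eff / k_mat) * (1 - dec)
        if (bleach > 0) {
          bdec <- exp(-bleach * dt)
          st$mature <- st$mature * bdec +
            converted * (1 - bdec) / (bleach * dt)
        } else st$mature <- st$mature + converted
      } else {
        st$immature <- st$immature + e_eff * dt
        if (bleach > 0) st$mature <- st$mature * exp(-bleach * dt)
      }
      cum_expr <<- cum_expr + e_eff * dt * length(st$id)
      st
    }

    subset_state <- function(st, keep) lapply(st, `[`, keep)

    for (fi in seq_along(frames_h)) {
      t_frame <- frames_h[fi]
      t_now <- if (fi == 1) 0 else frames_h[fi - 1]
      # process division events inside (t_now, t_frame]
      repeat {
        if (!length(st$id)) break
        td <- min(st$next_div)
        if (td > t_frame) break
        st <- advance(st, t_now, td)
        t_now <- td
        div_idx <- which(st$next_div <= td + 1e-12)
        for (ii in div_idx) {
          len <- st$length[ii]
          dl <- len / 2
          frac <- c(0.5, 0.5)          # daughters of equal length
          Tn <- draw_T(2)
          jitter <- stats::rnorm(2, 0, 0.05)
          for (d in 1:2) {
            sgn <- if (d == 1) -1 else 1
            st$id <- c(st$id, next_id)
            st$parent <- c(st$parent, st$id[ii])
            st$generation <- c(st$generation, st$generation[ii] + 1L)
            st$birth_h <- c(st$birth_h, td)
            st$x <- c(st$x, st$x[ii] + sgn * cos(st$angle[ii]) * len / 4)
            st$y <- c(st$y, st$y[ii] + sgn * sin(st$angle[ii]) * len / 4)
            st$angle <- c(st$angle, st$angle[ii] + jitter[d])
            st$length <- c(st$length, dl)
            st$alpha <- c(st$alpha, log(2) / Tn[d])
            st$next_div <- c(st$next_div, td + Tn[d])
            st$immature <- c(st$immature, st$immature[ii] * frac[d])
            st$mature <- c(st$mature, st$mature[ii] * frac[d])
            next_id <- next_id + 1L
          }
          divisions[[length(divisions) + 1L]] <- data.frame(
            time_h = td, parent_id = st$id[ii],
            daughter1 = st$id[length(st$id) - 1L],
            daughter2 = st$id[length(st$id)],
            generation = st$generation[ii] + 1L)
        }
        st <- subset_state(st, setdiff(seq_along(st$id), div_idx))
      }
      st <- advance(st, t_now, t_frame)
      st <- relax_rods(st, geometry, rod_width_um)
      # exits through the open chamber ends
      out <- st$x < 0 | st$x > geometry$width_um
      if (any(out)) {
        ex <- subset_state(st, out)
        exited[[length(exited) + 1L]] <- data.frame(
          time_h = t_frame, cell_id = ex$id, immature = ex$immature,
          mature = ex$mature, generation = ex$generation)
        st <- subset_state(st, !out)
      }
      if (!length(st$id)) break
      packing <- sum(st$length * rod_width_um) /
        (geometry$width_um * geometry$depth_um)
      if (packing > 0.9) {
        crowding_stopped <- TRUE
        warning(sprintf("packing fraction %.2f > 0.9 at t = %.2f h; simulation stopped early",
                        packing, t_frame))
        break
      }
      ord <- order(st$id)
      area <- st$length * rod_width_um
      frames[[fi]] <- data.frame(
        frame_index = fi, time_h = t_frame, cell_id = st$id[ord],
        label = seq_along(ord), parent_id = st$parent[ord],
        generation = st$generation[ord], x_um = st$x[ord], y_um = st$y[ord],
        angle_rad = st$angle[ord], length_um = st$length[ord],
        width_um = rod_width_um, immature_gfp = st$immature[ord],
        mature_gfp = st$mature[ord],
        concentration = st$mature[ord] / area[ord])
      recorded_h <- c(recorded_h, t_frame)
    }

    structure(list(
      cells = do.call(rbind, frames),
      divisions = if (length(divisions)) do.call(rbind, divisions) else
        data.frame(time_h = numeric(), parent_id = integer(),
                   daughter1 = integer(), daughter2 = integer(),
                   generation = integer()),
      exited = if (length(exited)) do.call(rbind, exited) else
        data.frame(time_h = numeric(), cell_id = integer(),
                   immature = numeric(), mature = numeric(),
                   generation = integer()),
      frames_h = recorded_h,
      cumulative_expression_au = cum_expr,
      crowding_stopped = crowding_stopped,
      params = list(target_mu_per_h = target_mu_per_h,
                    division_cv = division_cv, gfp = gfp,
                    geometry = geometry,
                    frame_interval_min = frame_interval_min,
                    n_seed_cells = n_seed_cells,
                    birth_length_um = birth_length_um,
                    rod_width_um = rod_width_um, duration_h = duration_h,
                    seed = seed)),
      class = "synthetic_colony")
  })
}

#' @export
print.synthetic_colony <- function(x, ...) {
  nf <- length(x$frames_h)
  nlast <- if (nf) sum(x$cells$frame_index == max(x$cells$frame_index)) else 0
  cat(sprintf("<synthetic_colony> %d frames over %.2f h, %d -> %d cells, %d divisions, %d exits%s\n",
              nf, if (nf) max(x$frames_h) else 0, x$params$n_seed_cells,
              nlast, nrow(x$divisions), nrow(x$exited),
              if (x$crowding_stopped) " [stopped: crowding]" else ""))
  invisible(x)
}

#' Ground-truth cell records of a synthetic colony
#'
#' Returns the simulator's per-frame truth in the format produced by
#' [cell_intensities()] (one row per cell per frame, `cell_id` = frame-local
#' label, `mean_intensity` = mature-GFP concentration). This is what a
#' perfect segmentation + intensity measurement of the rendered frames would
#' recover, and serves as an alternative input wherever the external
#' tracker/segmenter is not under study.
#'
#' @param colony a [simulate_colony()] result.
#' @return data.frame of cell records.
#' @export
truth_records <- function(colony) {
  stopifnot(inherits(colony, "synthetic_colony"))
  cells <- colony$cells
  data.frame(frame_index = cells$frame_index,
             timestamp_s = cells$time_h * 3600,
             cell_id = cells$label,
             centroid_row = cells$y_um, centroid_col = cells$x_um,
             area_um2 = cells$length_um * cells$width_um,
             mean_intensity = cells$concentration)
}

#' Ground-truth lineage forest of a synthetic colony
#'
#' Builds the (frame, label) lineage forest implied by the simulation:
#' chains for cells present in consecutive frames and parent-to-daughter
#' edges across division intervals, with the simulator's generation numbers
#' attached. Comparable node-for-node with [track_cells()] output on the
#' rendered masks.
#'
#' @param colony a [simulate_colony()] result.
#' @return a generation-assigned [lineage_forest()].
#' @export
truth_forest <- function(colony) {
  stopifnot(inherits(colony, "synthetic_colony"))
  cells <- colony$cells
  frames <- sort(unique(cells$frame_index))
  nodes <- data.frame(frame_index = cells$frame_index, cell_id = cells$label)
  parent_of <- cells$parent_id[!duplicated(cells$cell_id)]
  names(parent_of) <- cells$cell_id[!duplicated(cells$cell_id)]
  edges <- list()
  for (i in seq_len(length(frames) - 1)) {
    a <- cells[cells$frame_index == frames[i], c("cell_id", "label")]
    b <- cells[cells$frame_index == frames[i + 1], c("cell_id", "label")]
    amap <- stats::setNames(a$label, a$cell_id)
    # ancestor of each cell in frame i+1 that was alive in frame i
    anc <- b$cell_id
    for (rep_ in 1:5) {          # divisions per 5-min interval are rare
      missing <- !(anc %in% a$cell_id)
      if (!any(missing)) break
      anc[missing] <- as.integer(parent_of[as.character(anc[missing])])
    }
    ok <- anc %in% a$cell_id
    if (any(ok))
      edges[[i]] <- data.frame(parent_frame = frames[i],
                               parent_id = unname(amap[as.character(anc[ok])]),
                               child_frame = frames[i + 1],
                               child_id = b$label[ok])
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(parent_frame = integer(), parent_id = integer(),
               child_frame = integer(), child_id = integer())
  fo <- lineage_forest(nodes, edges)
  # use the simulator's generations rather than re-deriving them
  key <- paste(cells$frame_index, cells$label)
  fo$nodes$generation <-
    cells$generation[match(paste(fo$nodes$frame_index, fo$nodes$cell_id), key)]
  fo
}

#' Render fluorescence and label-mask frames from a synthetic colony
#'
#' Rasterizes each cell as a rounded rod (all pixels whose centers lie
#' within `rod_width/2` of the cell's axis segment). The fluorescence value
#' painted over a cell is its mature-GFP concentration; the image is then
#' optionally blurred with a Gaussian PSF and corrupted with background and
#' additive noise. Where two rods would claim the same pixel the cell whose
#' axis is closer wins, so label masks never overlap.
#'
#' @param colony a [simulate_colony()] result.
#' @param pixel_size_um pixel size (um/px, default 0.065); a warning is
#'   issued above 0.5 um/px where neighbouring cells can no longer be
#'   separated.
#' @param psf_sigma_um Gaussian PSF sigma (um); 0 disables blurring.
#' @param background constant background added to the fluorescence channel.
#' @param noise_sd additive Gaussian noise sd (a.u.); 0 disables noise.
#' @param seed RNG seed for the noise.
#' @param frames which frame indices to render (default: all).
#' @return list with one element per frame: `fluor` (numeric matrix) and
#'   `mask` (a [label_frame()]).
#' @export
render_frames <- function(colony, pixel_size_um = 0.065, psf_sigma_um = 0.2,
                          background = 0, noise_sd = 0, seed = NULL,
                          frames = NULL) {
  stopifnot(inherits(colony, "synthetic_colony"))
  if (pixel_size_um > 0.5)
    warning("pixel size > 0.5 um/px: neighbouring cells may merge in the mask")
  geom <- colony$params$geometry
  nr <- ceiling(geom$depth_um / pixel_size_um)   # rows = y
  nc <- ceiling(geom$width_um / pixel_size_um)   # cols = x
  all_frames <- sort(unique(colony$cells$frame_index))
  if (is.null(frames)) frames <- all_frames
  with_seed(seed, {
    lapply(frames, function(fi) {
      sub <- colony$cells[colony$cells$frame_index == fi, ]
      lab <- matrix(0L, nr, nc)
      flu <- matrix(0, nr, nc)
      best <- matrix(Inf, nr, nc)
      w2 <- sub$width_um[1] / 2
      for (i in seq_len(nrow(sub))) {
        hx <- cos(sub$angle_rad[i]) * pmax(sub$length_um[i] - sub$width_um[i], 0) / 2
        hy <- sin(sub$angle_rad[i]) * pmax(sub$length_um[i] - sub$width_um[i], 0) / 2
        x1 <- sub$x_um[i] - hx; x2 <- sub$x_um[i] + hx
        y1 <- sub$y_um[i] - hy; y2 <- sub$y_um[i] + hy
        cmin <- max(1L, floor((min(x1, x2) - w2) / pixel_size_um))
        cmax <- min(nc, ceiling((max(x1, x2) + w2) / pixel_size_um) + 1L)
        rmin <- max(1L, floor((min(y1, y2) - w2) / pixel_size_um))
        rmax <- min(nr, ceiling((max(y1, y2) + w2) / pixel_size_um) + 1L)
        if (cmin > cmax || rmin > rmax) next
        rr <- rmin:rmax; cc <- cmin:cmax
        pxx <- (rep(cc, each = length(rr)) - 0.5) * pixel_size_um
        pyy <- (rep(rr, times = length(cc)) - 0.5) * pixel_size_um
        dx <- x2 - x1; dy <- y2 - y1
        len2 <- max(dx^2 + dy^2, 1e-12)
        tpar <- pmin(pmax(((pxx - x1) * dx + (pyy - y1) * dy) / len2, 0), 1)
        dist <- sqrt((pxx - (x1 + tpar * dx))^2 + (pyy - (y1 + tpar * dy))^2)
        inside <- dist <= w2
        if (!any(inside)) next
        idx <- cbind(rep(rr, times = length(cc))[inside],
                     rep(cc, each = length(rr))[inside])
        closer <- dist[inside] < best[idx]
        if (!any(closer)) next
        idx <- idx[closer, , drop = FALSE]
        best[idx] <- dist[inside][closer]
        lab[idx] <- sub$label[i]
        flu[idx] <- sub$concentration[i]
      }
      if (psf_sigma_um > 0)
        flu <- EBImage::imageData(EBImage::gblur(flu, sigma = psf_sigma_um / pixel_size_um))
      flu <- flu + background
      if (noise_sd > 0) flu <- flu + stats::rnorm(length(flu), 0, noise_sd)
      list(fluor = flu,
           mask = label_frame(lab, pixel_size_um = pixel_size_um,
                              frame_index = fi,
                              timestamp_s = sub$time_h[1] * 3600))
    })
  })
}

#' Preset synthetic experiments
#'
#' Bundles the three study designs into ready-made synthetic datasets:
#' \describe{
#'   \item{aerobic}{constant 21% oxygen, 9 h, colonies at mu = 0.55 1/h.}
#'   \item{anaerobic_switch}{0% oxygen for 8 h, then a gas switch to 21%
#'     filtered through the first-order chip response; colonies at
#'     mu = 0.52 1/h over 9 h.}
#'   \item{step_test}{the default 30 h step schedule (0-100% oxygen) passed
#'     through the chip response model; no colonies.}
#' }
#' Five replicate chambers are generated by default, with chamber sub-seeds
#' derived deterministically from `seed`.
#'
#' @param preset one of `"aerobic"`, `"anaerobic_switch"`, `"step_test"`.
#' @param seed base RNG seed.
#' @param n_chambers number of replicate chambers (default 5).
#' @param duration_h culture duration for the colony presets (default 9).
#' @param response_model [o2_response_model()] used for gas switches.
#' @param ... passed on to [simulate_colony()] (e.g. `gfp`, `division_cv`).
#' @return object of class `flimox_experiment`: `preset`, `o2` (ground-truth
#'   [o2_trace()]), `schedule` (step_test/switch presets), `colonies` (list
#'   of [simulate_colony()] results, or `NULL`), `chamber_seeds`.
#' @export
make_experiment <- function(preset = c("aerobic", "anaerobic_switch", "step_test"),
                            seed = 1, n_chambers = 5, duration_h = 9,
                            response_model = o2_response_model(), ...) {
  preset <- match.arg(preset)
  chamber_seeds <- (as.numeric(seed) * 7919 + 104729 * seq_len(n_chambers)) %%
    2147483647
  if (preset == "step_test") {
    schedule <- default_step_schedule()
    trace <- simulate_o2_response(schedule, response_model)
    return(structure(list(preset = preset, o2 = trace, schedule = schedule,
                          colonies = NULL, chamber_seeds = chamber_seeds),
                     class = "flimox_experiment"))
  }
  if (preset == "aerobic") {
    times <- seq(0, duration_h * 3600, by = 5 * 60)
    trace <- o2_trace(times, rep(0.21, length(times)), source_roi = "simulated")
    schedule <- NULL
    mu <- 0.55
  } else {
    if (duration_h <= 8) stop("the switch preset needs duration_h > 8")
    schedule <- step_schedule(c(0, 21), initial_hold_h = 8,
                              step_duration_h = duration_h - 8,
                              sample_interval_min = 5)
    trace <- simulate_o2_response(schedule, response_model)
    mu <- 0.52
  }
  colonies <- lapply(chamber_seeds, function(s)
    simulate_colony(target_mu_per_h = mu, o2_trace = trace,
                    duration_h = duration_h, seed = s, ...))
  structure(list(preset = preset, o2 = trace, schedule = schedule,
                 colonies = colonies, chamber_seeds = chamber_seeds),
            class = "flimox_experiment")
}

#' @export
print.flimox_experiment <- function(x, ...) {
  cat(sprintf("<flimox_experiment> preset '%s', %d chamber(s)\n", x$preset,
              length(x$colonies)))
  invisible(x)
}
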