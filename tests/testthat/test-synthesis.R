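# ground-truth generators: chip response, FLIM forward model, colonies

test_that("chamber volume follows from the printed dimensions", {
  geom <- chamber_geometry()
  expect_equal(geom$volume_pl, 1.5)
  expect_equal(chamber_geometry(100, 30, 1)$volume_pl, 3.0)
})

test_that("first-order chip response follows the closed form", {
  # single step 0 -> 21%: value after one time constant
  sched <- step_schedule(c(0, 21), initial_hold_h = 1, step_duration_h = 3,
                         sample_interval_min = 1)
  tr <- simulate_o2_response(sched, o2_response_model(37))
  v_at <- function(min) tr$o2_fraction[tr$times_s == min * 60]
  expect_equal(v_at(60 + 37), 0.21 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(v_at(60), 0)                       # continuous at the switch
  expect_equal(v_at(30), 0)
  # derived time constant from geometry: d^2 / D
  m <- o2_response_model(membrane_thickness_m = 1.5e-3,
                         diffusion_coefficient_m2_s = 1e-9)
  expect_equal(m$response_time_constant_min, 1.5e-3^2 / 1e-9 / 60)
})

test_that("noise-free FLIM forward model inverts exactly through the chain", {
  c30 <- calib_30c()
  # anoxic frame recovers tau0
  tr0 <- o2_trace(0, 0)
  st <- simulate_flim_series(tr0, c30, image_shape = c(3, 3))[[1]]
  tau <- mean_lifetime(lifetime_from_phase(compute_phasor(st)))
  expect_equal(as.numeric(tau), 526, tolerance = 1e-9)

  # full-range sweep: lifetime -> O2 round trip within 1e-6 of ground truth
  o2 <- seq(0, 1, by = 0.1)
  tr <- o2_trace(seq_along(o2) * 300, o2)
  stacks <- simulate_flim_series(tr, c30, image_shape = c(2, 2))
  taus <- vapply(stacks, function(s)
    as.numeric(mean_lifetime(lifetime_from_phase(compute_phasor(s)))),
    numeric(1))
  back <- trace_from_lifetimes(tr$times_s, taus, c30)
  expect_equal(back$o2_fraction, o2, tolerance = 1e-6)

  # Gaussian pixel noise: ROI-mean lifetime unbiased within 3 standard errors
  set.seed(11)
  noisy <- simulate_flim_series(o2_trace(0, 0.21), c30,
                                image_shape = c(100, 100),
                                noise = "gaussian", noise_sd = 20, seed = 5)[[1]]
  li <- lifetime_from_phase(compute_phasor(noisy))
  tau_true <- lifetime_from_o2(0.21, c30)
  vals <- li$tau_ns[is.finite(li$tau_ns)]
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - tau_true), 3 * se + 1e-9)
})

test_that("colony generation is deterministic and conserves GFP", {
  tr <- flat_trace(0.21, 4)
  a <- simulate_colony(0.55, tr, 4, seed = 99)
  b <- simulate_colony(0.55, tr, 4, seed = 99)
  expect_identical(a, b)
  c2 <- simulate_colony(0.55, tr, 4, seed = 100)
  expect_false(identical(a$cells, c2$cells))

  # conservation: immature + mature over alive + exited cells equals
  # cumulative expression (no bleaching)
  last <- a$cells[a$cells$frame_index == max(a$cells$frame_index), ]
  total <- sum(last$immature_gfp) + sum(last$mature_gfp) +
    sum(a$exited$immature) + sum(a$exited$mature)
  expect_equal(total, a$cumulative_expression_au,
               tolerance = 1e-6)

  # near-instant maturation: everything produced ends up mature
  fast <- gfp_kinetics(maturation_rate_per_h = 1e6, induction_ramp_h = 0)
  d <- simulate_colony(0.55, tr, 4, gfp = fast, seed = 7)
  lastd <- d$cells[d$cells$frame_index == max(d$cells$frame_index), ]
  # the immature residual is O(expression_rate / k_mat) per cell
  expect_equal(sum(lastd$mature_gfp) + sum(d$exited$mature),
               d$cumulative_expression_au, tolerance = 1e-6)
  expect_equal(sum(lastd$mature_gfp) + sum(lastd$immature_gfp) +
                 sum(d$exited$mature) + sum(d$exited$immature),
               d$cumulative_expression_au, tolerance = 1e-9)
  expect_lt(max(lastd$immature_gfp), 1e-6 * max(lastd$mature_gfp))
})

test_that("colony growth matches the target rate before crowding", {
  tr <- flat_trace(0.21, 9)
  mus <- vapply(1:20, function(s) {
    cl <- simulate_colony(0.55, tr, 9, seed = 1000 + s)
    growth_rate(population_series(truth_records(cl)))$mu_per_h
  }, numeric(1))
  expect_lt(abs(mean(mus) - 0.55), 0.02)
})

test_that("cells respect the monolayer chamber and masks are consistent", {
  tr <- flat_trace(0.21, 6)
  cl <- simulate_colony(0.55, tr, 6, seed = 21)
  geom <- cl$params$geometry
  ey <- abs(sin(cl$cells$angle_rad)) *
    pmax(cl$cells$length_um - cl$cells$width_um, 0) / 2 +
    cl$cells$width_um / 2
  expect_true(all(cl$cells$y_um - ey >= -1e-6))
  expect_true(all(cl$cells$y_um + ey <= geom$depth_um + 1e-6))
  expect_true(all(cl$cells$x_um >= 0 & cl$cells$x_um <= geom$width_um))

  # rendered masks: one label per simulated cell, all inside the frame
  fr <- render_frames(cl, pixel_size_um = 0.2, psf_sigma_um = 0,
                      frames = max(cl$cells$frame_index))[[1]]
  truth_n <- sum(cl$cells$frame_index == max(cl$cells$frame_index))
  expect_equal(length(setdiff(unique(as.vector(fr$mask$labels)), 0L)), truth_n)
})

test_that("rendering is linear: identity, background and blur conservation", {
  tr <- flat_trace(0.21, 1)
  cl <- simulate_colony(0.4, tr, 1, n_seed_cells = 1, seed = 3)
  last <- max(cl$cells$frame_index)
  fr <- render_frames(cl, pixel_size_um = 0.1, psf_sigma_um = 0,
                      frames = last)[[1]]
  rec <- cell_intensities(fr$mask, fr$fluor)
  truth <- cl$cells[cl$cells$frame_index == last, ]
  expect_equal(rec$mean_intensity[order(rec$cell_id)],
               truth$concentration[order(truth$label)], tolerance = 1e-12)

  # constant background inflates each cell mean by exactly that amount
  fr_bg <- render_frames(cl, pixel_size_um = 0.1, psf_sigma_um = 0,
                         background = 10, frames = last)[[1]]
  rec_bg <- cell_intensities(fr_bg$mask, fr_bg$fluor)
  expect_equal(rec_bg$mean_intensity, rec$mean_intensity + 10,
               tolerance = 1e-12)

  # Gaussian blur preserves total intensity of an interior cell within 1%
  fr_bl <- render_frames(cl, pixel_size_um = 0.1, psf_sigma_um = 0.2,
                         frames = last)[[1]]
  expect_equal(sum(fr_bl$fluor), sum(fr$fluor), tolerance = 0.01)

  expect_warning(render_frames(cl, pixel_size_um = 0.6, psf_sigma_um = 0,
                               frames = last), "0.5 um")
})

test_that("overlap tracking recovers the simulated lineage", {
  tr <- flat_trace(0.21, 5)
  cl <- simulate_colony(0.55, tr, 5, seed = 2)
  fr <- render_frames(cl, pixel_size_um = 0.2, psf_sigma_um = 0)
  masks <- lapply(fr, `[[`, "mask")
  tracked <- assign_generations(track_cells(masks))
  truth <- truth_forest(cl)
  ek <- function(e) paste(e$parent_frame, e$parent_id, e$child_frame, e$child_id)
  recall <- mean(ek(truth$edges) %in% ek(tracked$edges))
  expect_gte(recall, 0.95)
  # generations agree for the vast majority of nodes
  tk <- paste(truth$nodes$frame_index, truth$nodes$cell_id)
  ok <- paste(tracked$nodes$frame_index, tracked$nodes$cell_id)
  agree <- mean(truth$nodes$generation ==
                  tracked$nodes$generation[match(tk, ok)], na.rm = TRUE)
  expect_gte(agree, 0.95)
})

test_that("experiment presets encode the three study designs", {
  ex <- make_experiment("step_test", seed = 1)
  expect_equal(length(ex$o2$times_s), 28 * 12 + 1)  # 4 h hold + 8 x 3 h steps
  expect_null(ex$colonies)
  plat <- plateau_values(ex$o2, ex$schedule)
  expect_true(all(abs(plat$plateau_fraction - plat$setpoint_percent / 100)
                  < 0.02))

  ex2 <- make_experiment("aerobic", seed = 1, n_chambers = 2, duration_h = 2)
  expect_equal(length(ex2$colonies), 2)
  expect_true(all(ex2$o2$o2_fraction == 0.21))
  # deterministic chamber sub-seeds
  ex3 <- make_experiment("aerobic", seed = 1, n_chambers = 2, duration_h = 2)
  expect_identical(ex2$colonies[[1]]$cells, ex3$colonies[[1]]$cells)

  ex4 <- make_experiment("anaerobic_switch", seed = 1, n_chambers = 1,
                         duration_h = 9)
  # oxygen is exactly zero until the 8 h switch, then rises
  pre <- ex4$o2$times_s <= 8 * 3600
  expect_true(all(ex4$o2$o2_fraction[pre] == 0))
  expect_true(all(diff(ex4$o2$o2_fraction[!pre]) > 0))
})
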