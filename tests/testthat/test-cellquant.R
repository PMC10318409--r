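# mask-based single-cell and population quantification

test_that("border filter removes cells with pixels near the image edges", {
  fr <- label_frame(three_cell_mask(), pixel_size_um = 0.065)
  # margin 0 is the identity
  expect_identical(border_filter(fr, 0)$labels, fr$labels)
  # at 0.5 um only the edge-touching cell goes (pixel centers within 0.5 um
  # of an edge: the first ceiling(0.5/0.065 - 0.5) = 7 rows/cols)
  out <- border_filter(fr, 0.5)
  expect_equal(attr(out, "removed"), 1L)
  expect_setequal(setdiff(unique(as.vector(out$labels)), 0L), c(2L, 3L))
  # a margin wider than the image removes everything with a warning
  expect_warning(all_gone <- border_filter(fr, 10), "every cell")
  expect_equal(sum(all_gone$labels), 0)
  # retained count is monotone in the margin
  n_cells <- function(f) length(setdiff(unique(as.vector(f$labels)), 0L))
  counts <- vapply(c(0, 0.3, 0.5, 1, 2, 10),
                   function(m) n_cells(suppressWarnings(border_filter(fr, m))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-cell intensities are exact pixel means", {
  fr <- label_frame(three_cell_mask(), pixel_size_um = 0.065)
  flu <- matrix(42, nrow(fr$labels), ncol(fr$labels))
  rec <- cell_intensities(fr, flu)
  expect_equal(rec$mean_intensity, rep(42, 3))
  expect_equal(rec$area_um2[1], sum(fr$labels == 1L) * 0.065^2)

  # hand-computed mean on a 2x2 cell
  m <- matrix(0L, 4, 4); m[2:3, 2:3] <- 1L
  flu2 <- matrix(0, 4, 4); flu2[2:3, 2:3] <- c(10, 20, 30, 40)
  rec2 <- cell_intensities(label_frame(m), flu2)
  expect_equal(rec2$mean_intensity, 25)
  expect_equal(rec2$centroid_row, 1.5)  # 0-based coordinates
  expect_equal(rec2$centroid_col, 1.5)

  # background-only mask and shape mismatch
  expect_equal(nrow(cell_intensities(label_frame(matrix(0L, 4, 4)), flu2)), 0)
  expect_error(cell_intensities(fr, flu2), "dimensions differ")
})

test_that("static masks track as generation-zero chains without divisions", {
  m <- three_cell_mask()
  frames <- lapply(1:5, function(i) label_frame(m, frame_index = i,
                                                timestamp_s = (i - 1) * 300))
  fo <- assign_generations(track_cells(frames))
  expect_equal(nrow(fo$nodes), 15)
  expect_equal(nrow(fo$edges), 12)          # 3 cells x 4 transitions
  expect_true(all(fo$nodes$generation == 0L))
  # tracking sanity: roots + divisions = cells in the final frame
  ndiv <- sum(table(paste(fo$edges$parent_frame, fo$edges$parent_id)) == 2)
  nroots <- sum(!(paste(fo$nodes$frame_index, fo$nodes$cell_id) %in%
                    paste(fo$edges$child_frame, fo$edges$child_id)))
  expect_equal(nroots + ndiv, 3)
})

test_that("a mask splitting in two is recorded as a division", {
  m1 <- matrix(0L, 20, 20); m1[8:12, 4:16] <- 1L
  m2 <- matrix(0L, 20, 20); m2[8:12, 4:9] <- 1L; m2[8:12, 11:16] <- 2L
  frames <- list(label_frame(m1, frame_index = 1),
                 label_frame(m2, frame_index = 2, timestamp_s = 300))
  fo <- assign_generations(track_cells(frames))
  expect_equal(nrow(fo$edges), 2)
  gen2 <- fo$nodes$generation[fo$nodes$frame_index == 2]
  expect_equal(gen2, c(1L, 1L))
})

test_that("generations propagate through constructed forests", {
  # perfect binary tree over 4 frames: 1 -> 2 -> 4 -> 8 cells
  nodes <- do.call(rbind, lapply(1:4, function(f)
    data.frame(frame_index = f, cell_id = seq_len(2^(f - 1)))))
  edges <- do.call(rbind, lapply(1:3, function(f)
    data.frame(parent_frame = f, parent_id = rep(seq_len(2^(f - 1)), each = 2),
               child_frame = f + 1, child_id = seq_len(2^f))))
  fo <- assign_generations(lineage_forest(nodes, edges))
  leaves <- fo$nodes[fo$nodes$frame_index == 4, ]
  expect_equal(nrow(leaves), 8)
  expect_true(all(leaves$generation == 3L))

  # root divides once; one daughter divides again; the other only persists
  nodes2 <- data.frame(frame_index = c(1, 2, 2, 3, 3, 3),
                       cell_id = c(1, 1, 2, 1, 2, 3))
  edges2 <- data.frame(parent_frame = c(1, 1, 2, 2, 2),
                       parent_id = c(1, 1, 1, 1, 2),
                       child_frame = c(2, 2, 3, 3, 3),
                       child_id = c(1, 2, 1, 2, 3))
  fo2 <- assign_generations(lineage_forest(nodes2, edges2))
  g <- function(f, id) fo2$nodes$generation[fo2$nodes$frame_index == f &
                                              fo2$nodes$cell_id == id]
  expect_equal(c(g(2, 1), g(2, 2)), c(1L, 1L))
  expect_equal(c(g(3, 1), g(3, 2), g(3, 3)), c(2L, 2L, 1L))

  # malformed forests are refused
  expect_error(lineage_forest(nodes2,
                              data.frame(parent_frame = c(1, 1, 1),
                                         parent_id = c(1, 1, 1),
                                         child_frame = 2, child_id = 1:3)),
               "more than two children")
})

test_that("population series, growth rate and slopes match closed forms", {
  recs <- data.frame(frame_index = c(1, 1, 1, 2),
                     timestamp_s = c(0, 0, 0, 300),
                     cell_id = c(1, 2, 3, 1),
                     mean_intensity = c(10, 20, 30, 5))
  ps <- population_series(recs)
  expect_equal(ps$n_population, c(3L, 1L))
  expect_equal(ps$i_population, c(20, 5))

  # noise-free exponential counts, integer-rounded: mu recovered to 0.01/h
  h <- seq(0, 9, by = 5 / 60)
  mk_series <- function(mu) {
    structure(data.frame(frame_index = seq_along(h), timestamp_s = h * 3600,
                         n_population = pmax(round(2 * exp(mu * h)), 1),
                         i_population = NA_real_),
              class = c("population_series", "data.frame"))
  }
  for (mu in c(0.3, 0.52, 0.55, 0.7)) {
    fit <- growth_rate(mk_series(mu))
    expect_lt(abs(fit$mu_per_h - mu), 0.01)
  }
  # constant population: mu = 0; hourly doubling: mu = ln 2
  const <- mk_series(0); const$n_population <- rep(5L, length(h))
  expect_equal(growth_rate(const)$mu_per_h, 0, tolerance = 1e-12)
  dbl <- mk_series(0); dbl$n_population <- 2^(h)   # doubles every hour
  expect_equal(suppressWarnings(growth_rate(dbl))$mu_per_h, log(2),
               tolerance = 1e-9)

  # zero-count frames are skipped with a warning
  z <- mk_series(0.5); z$n_population[3] <- 0L
  expect_warning(growth_rate(z), "zero cells")

  # linear intensity: exact slope recovery
  lin <- mk_series(0.5)
  lin$i_population <- 5 + 23 * h
  expect_equal(as.numeric(suppressWarnings(intensity_slope(lin))), 23,
               tolerance = 1e-12)
  lin$i_population <- rep(7, length(h))
  expect_equal(as.numeric(suppressWarnings(intensity_slope(lin))), 0,
               tolerance = 1e-12)
})

test_that("fold-change rounds the slope ratio", {
  fc <- fold_change(165, 23)
  expect_equal(fc$ratio, 165 / 23, tolerance = 1e-12)
  expect_equal(fc$fold, 7L)
  expect_equal(fold_change(10, 10), list(ratio = 1, fold = 1L))
  neg <- fold_change(-5, 10)
  expect_equal(neg$ratio, -0.5)
  expect_equal(neg$fold, 0L)
  expect_error(fold_change(1, 0), "zero")
})

test_that("intensity-versus-generation tables join generations correctly", {
  nodes <- data.frame(frame_index = 1, cell_id = 1:2)
  fo <- assign_generations(lineage_forest(
    nodes, data.frame(parent_frame = integer(), parent_id = integer(),
                      child_frame = integer(), child_id = integer())))
  fo$nodes$generation <- c(1L, 3L)
  recs <- data.frame(frame_index = 1, timestamp_s = 0, cell_id = 1:2,
                     mean_intensity = c(50, 20))
  tbl <- intensity_vs_generation(recs, fo, time_h = 0)
  expect_equal(nrow(tbl), 2)
  expect_equal(attr(tbl, "spearman_rho"), -1)
  expect_equal(summarize_generations(tbl)$n, c(1L, 1L))

  # all cells in one generation: a single group, undefined correlation
  fo$nodes$generation <- c(0L, 0L)
  tbl0 <- intensity_vs_generation(recs, fo, time_h = 0)
  expect_true(is.na(attr(tbl0, "spearman_rho")))
  expect_equal(nrow(summarize_generations(tbl0)), 1)

  # off-grid query snaps to the nearest frame with a warning
  expect_warning(intensity_vs_generation(recs, fo, time_h = 0.02), "nearest")
})
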