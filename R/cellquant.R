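#' Integer label-mask frame
#'
#' One time point of a segmented time-lapse: an integer image in which 0 is
#' background and each positive label is one cell. Labels are frame-local;
#' global identity only exists in a lineage forest built by [track_cells()].
#'
#' @param labels integer matrix (0 = background).
#' @param pixel_size_um physical pixel size (um / pixel), default 0.065
#'   (100x objective class).
#' @param frame_index integer frame number (1-based).
#' @param timestamp_s acquisition time (s since experiment start).
#' @param validate if `TRUE`, check that every label forms one connected
#'   component (4-connectivity); violations are logged with a warning and
#'   only the largest component of each offending label is kept.
#' @return object of class `label_frame`.
#' @export
label_frame <- function(labels, pixel_size_um = 0.065, frame_index = 1L,
                        timestamp_s = 0, validate = FALSE) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (validate && any(labels > 0)) {
    for (lb in sort(unique(labels[labels > 0]))) {
      comp <- EBImage::bwlabel(labels == lb)
      ncomp <- max(comp)
      if (ncomp > 1L) {
        warning(sprintf("label %d in frame %d splits into %d components; keeping the largest",
                        lb, frame_index, ncomp))
        sizes <- tabulate(comp[comp > 0], nbins = ncomp)
        labels[comp > 0 & comp != which.max(sizes)] <- 0L
      }
    }
  }
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 frame_index = as.integer(frame_index),
                 timestamp_s = timestamp_s),
            class = "label_frame")
}

#' @export
print.label_frame <- function(x, ...) {
  cat(sprintf("<label_frame> #%d, %d x %d px (%g um/px), %d cells, t = %g s\n",
              x$frame_index, nrow(x$labels), ncol(x$labels), x$pixel_size_um,
              length(setdiff(unique(as.vector(x$labels)), 0L)), x$timestamp_s))
  invisible(x)
}

#' Remove cells touching the image border
#'
#' Segmentation artifacts accumulate at chamber/image borders, so any cell
#' with at least one pixel whose center lies closer than `margin_um` to any
#' image edge is discarded. Pixel centers sit at (i + 0.5) pixels from the
#' edge (0-based), so a zero margin never removes anything.
#'
#' @param frame a [label_frame()].
#' @param margin_um border margin in micrometres (default 0.5).
#' @return the filtered `label_frame`; removed labels are available via
#'   `attr(, "removed")`.
#' @export
border_filter <- function(frame, margin_um = 0.5) {
  stopifnot(inherits(frame, "label_frame"))
  if (margin_um < 0) stop("margin_um must be >= 0")
  px <- frame$pixel_size_um
  nr <- nrow(frame$labels); nc <- ncol(frame$labels)
  r <- seq_len(nr); cc <- seq_len(nc)
  row_band <- pmin(r - 0.5, nr - r + 0.5) * px < margin_um
  col_band <- pmin(cc - 0.5, nc - cc + 0.5) * px < margin_um
  band <- outer(row_band, col_band, `|`)
  removed <- sort(unique(frame$labels[band & frame$labels > 0]))
  out <- frame
  out$labels[out$labels %in% removed] <- 0L
  if (length(removed) && !any(out$labels > 0) && any(frame$labels > 0))
    warning("border margin removed every cell in frame ", frame$frame_index)
  attr(out, "removed") <- removed
  out
}

#' Per-cell mean fluorescence
#'
#' The fluorescence signal of a cell is the mean of the fluorescence-channel
#' intensities over the pixels of its label. Centroids are reported in
#' 0-based pixel coordinates; areas in um^2.
#'
#' @param frame a [label_frame()] (typically after [border_filter()]).
#' @param fluor numeric matrix of the fluorescence channel, same dimensions.
#' @return data.frame with one row per cell: `frame_index`, `timestamp_s`,
#'   `cell_id`, `centroid_row`, `centroid_col`, `area_um2`, `mean_intensity`.
#' @export
cell_intensities <- function(frame, fluor) {
  stopifnot(inherits(frame, "label_frame"))
  if (!identical(dim(frame$labels), dim(fluor)))
    stop("fluorescence image and label mask dimensions differ")
  lab <- frame$labels
  sel <- lab > 0
  if (!any(sel))
    return(data.frame(frame_index = integer(), timestamp_s = numeric(),
                      cell_id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_um2 = numeric(),
                      mean_intensity = numeric()))
  ids <- lab[sel]
  f <- factor(ids)
  rows <- row(lab)[sel] - 1  # 0-based
  cols <- col(lab)[sel] - 1
  npx <- as.vector(table(f))
  data.frame(
    frame_index = frame$frame_index,
    timestamp_s = frame$timestamp_s,
    cell_id = as.integer(levels(f)),
    centroid_row = as.vector(tapply(rows, f, mean)),
    centroid_col = as.vector(tapply(cols, f, mean)),
    area_um2 = npx * frame$pixel_size_um^2,
    mean_intensity = as.vector(tapply(fluor[sel], f, mean)),
    row.names = NULL)
}

#' Greedy overlap tracking of label masks
#'
#' Links cells across consecutive frames by descending intersection-over-
#' union (IoU). Candidate pairs with `IoU >= min_iou` are accepted greedily
#' in order (IoU descending, then target label ascending, then source label
#' ascending - a fixed, documented tie-break); every target receives at most
#' one parent and every source at most two children (two children = a
#' division). Targets left unmatched start new lineage roots. An empty frame
#' terminates all running lineages.
#'
#' This is a deliberately simple stand-in tracker: it is adequate for
#' slowly moving monolayer colonies imaged at short intervals, and the
#' synthetic generator's ground-truth lineages can be used instead wherever
#' tracking accuracy itself is not under study.
#'
#' @param frames list of [label_frame()] objects in time order (>= 2).
#' @param min_iou minimum IoU for a link (default 0.2).
#' @return object of class `lineage_forest`: `nodes` (frame_index, cell_id,
#'   generation - `NA` until [assign_generations()]), `edges` (parent_frame,
#'   parent_id, child_frame, child_id).
#' @export
track_cells <- function(frames, min_iou = 0.2) {
  if (length(frames) < 2L) stop("at least 2 frames are required")
  dims <- vapply(frames, function(f) dim(f$labels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same geometry")
  nodes <- do.call(rbind, lapply(frames, function(f) {
    ids <- setdiff(sort(unique(as.vector(f$labels))), 0L)
    if (!length(ids)) return(NULL)
    data.frame(frame_index = f$frame_index, cell_id = ids)
  }))
  edges <- vector("list", length(frames) - 1L)
  for (t in seq_len(length(frames) - 1L)) {
    a <- frames[[t]]$labels
    b <- frames[[t + 1L]]$labels
    sel <- a > 0 & b > 0
    if (!any(sel) || !any(a > 0) || !any(b > 0)) next
    pa <- factor(a[sel]); pb <- factor(b[sel])
    inter <- table(pa, pb)
    area_a <- table(factor(a[a > 0], levels = levels(pa)))
    area_b <- table(factor(b[b > 0], levels = levels(pb)))
    cand <- as.data.frame(inter, stringsAsFactors = FALSE)
    names(cand) <- c("source", "target", "inter")
    cand <- cand[cand$inter > 0, ]
    cand$source <- as.integer(cand$source)
    cand$target <- as.integer(cand$target)
    cand$iou <- cand$inter /
      (as.numeric(area_a[as.character(cand$source)]) +
       as.numeric(area_b[as.character(cand$target)]) - cand$inter)
    cand <- cand[cand$iou >= min_iou, ]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$iou, cand$target, cand$source), ]
    used_target <- integer(0)
    n_children <- integer(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      s <- cand$source[i]; tg <- cand$target[i]
      if (tg %in% used_target) next
      nk <- if (as.character(s) %in% names(n_children))
        n_children[[as.character(s)]] else 0L
      if (nk >= 2L) next
      keep[i] <- TRUE
      used_target <- c(used_target, tg)
      n_children[[as.character(s)]] <- nk + 1L
    }
    cand <- cand[keep, ]
    if (nrow(cand))
      edges[[t]] <- data.frame(
        parent_frame = frames[[t]]$frame_index, parent_id = cand$source,
        child_frame = frames[[t + 1L]]$frame_index, child_id = cand$target)
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(parent_frame = integer(), parent_id = integer(),
                        child_frame = integer(), child_id = integer())
  lineage_forest(nodes, edges)
}

#' Lineage forest constructor
#'
#' @param nodes data.frame with `frame_index`, `cell_id`.
#' @param edges data.frame with `parent_frame`, `parent_id`, `child_frame`,
#'   `child_id`; each child has at most one parent, each parent at most two
#'   children per transition.
#' @return object of class `lineage_forest`.
#' @export
lineage_forest <- function(nodes, edges) {
  nodes$generation <- NA_integer_
  ck <- paste(edges$child_frame, edges$child_id)
  if (anyDuplicated(ck)) stop("a node has more than one parent")
  pk <- paste(edges$parent_frame, edges$parent_id)
  if (any(table(pk) > 2)) stop("a node has more than two children")
  structure(list(nodes = nodes, edges = edges), class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  ndiv <- sum(table(paste(x$edges$parent_frame, x$edges$parent_id)) == 2)
  cat(sprintf("<lineage_forest> %d nodes, %d edges, %d division events\n",
              nrow(x$nodes), nrow(x$edges), ndiv))
  invisible(x)
}

#' Assign generation numbers
#'
#' Cells present in the first frame (and any cell appearing without a
#' parent) carry generation zero; both daughters of a recorded division gain
#' one generation, while a cell simply tracked into the next frame keeps its
#' generation.
#'
#' @param forest a [lineage_forest()].
#' @return the forest with `nodes$generation` filled in.
#' @export
assign_generations <- function(forest) {
  stopifnot(inherits(forest, "lineage_forest"))
  nodes <- forest$nodes
  edges <- forest$edges
  key <- paste(nodes$frame_index, nodes$cell_id)
  gen <- rep(NA_integer_, nrow(nodes))
  names(gen) <- key
  child_keys <- paste(edges$child_frame, edges$child_id)
  roots <- !(key %in% child_keys)
  gen[roots] <- 0L
  if (nrow(edges)) {
    if (any(edges$child_frame <= edges$parent_frame))
      stop("corrupt forest: edge does not advance in time")
    n_children <- table(paste(edges$parent_frame, edges$parent_id))
    ord <- order(edges$parent_frame)
    for (i in ord) {
      pk <- paste(edges$parent_frame[i], edges$parent_id[i])
      ck <- paste(edges$child_frame[i], edges$child_id[i])
      if (is.na(gen[pk])) stop("corrupt forest: parent without generation")
      gen[ck] <- gen[pk] + as.integer(n_children[pk] == 2L)
    }
  }
  forest$nodes$generation <- as.integer(gen[key])
  forest
}

#' Population time series
#'
#' Per frame: the number of retained cells `n_population` and the unweighted
#' mean of the per-cell fluorescence `i_population` (missing when the frame
#' is empty).
#'
#' @param records data.frame of cell records ([cell_intensities()] output,
#'   possibly row-bound over frames).
#' @return data.frame (class `population_series`): `frame_index`,
#'   `timestamp_s`, `n_population`, `i_population`.
#' @export
population_series <- function(records) {
  if (!nrow(records))
    return(structure(data.frame(frame_index = integer(), timestamp_s = numeric(),
                                n_population = integer(), i_population = numeric()),
                     class = c("population_series", "data.frame")))
  f <- factor(records$frame_index)
  out <- data.frame(
    frame_index = as.integer(levels(f)),
    timestamp_s = as.vector(tapply(records$timestamp_s, f, `[`, 1)),
    n_population = as.vector(table(f)),
    i_population = as.vector(tapply(records$mean_intensity, f, mean)))
  out <- out[order(out$frame_index), ]
  rownames(out) <- NULL
  class(out) <- c("population_series", "data.frame")
  out
}

#' Population growth rate
#'
#' Ordinary least-squares fit of `ln(n_population)` against time in hours;
#' the slope is the specific growth rate mu (1/h). Replicate chambers are
#' typically fitted separately and reported as mean +/- SD across chambers.
#'
#' @param series a [population_series()].
#' @param window optional time window in hours, `c(from, to)` inclusive.
#' @return list (class `growth_fit`): `mu_per_h`, `se`, `n_frames`, `window`.
#' @export
growth_rate <- function(series, window = NULL) {
  h <- series$timestamp_s / 3600
  keep <- rep(TRUE, nrow(series))
  if (!is.null(window)) keep <- h >= window[1] & h <= window[2]
  zero <- keep & series$n_population == 0
  if (any(zero)) {
    warning(sum(zero), " frame(s) with zero cells skipped")
    keep <- keep & series$n_population > 0
  }
  if (sum(keep) < 3) stop("need at least 3 frames with cells in the window")
  fit <- stats::lm(log(series$n_population[keep]) ~ h[keep])
  structure(list(mu_per_h = unname(stats::coef(fit)[2]),
                 se = unname(summary(fit)$coefficients[2, 2]),
                 n_frames = sum(keep), window = window),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> mu = %.4f +/- %.4f 1/h (%d frames)\n",
              x$mu_per_h, x$se, x$n_frames))
  invisible(x)
}

#' Population fluorescence slope
#'
#' OLS slope of `i_population` against time in hours (a.u. / h) inside a
#' window; frames with missing intensity are skipped.
#'
#' @param series a [population_series()].
#' @param window optional time window in hours, `c(from, to)` inclusive.
#' @return slope in a.u./h with attribute `se`.
#' @export
intensity_slope <- function(series, window = NULL) {
  h <- series$timestamp_s / 3600
  keep <- is.finite(series$i_population)
  if (!is.null(window)) keep <- keep & h >= window[1] & h <= window[2]
  if (sum(keep) < 3) stop("need at least 3 frames with intensities in the window")
  fit <- stats::lm(series$i_population[keep] ~ h[keep])
  structure(unname(stats::coef(fit)[2]),
            se = unname(summary(fit)$coefficients[2, 2]))
}

#' Fold-change between two intensity slopes
#'
#' @param slope_post slope after the condition change (a.u./h).
#' @param slope_pre reference slope (a.u./h); must be non-zero.
#' @return list: `ratio` (`slope_post / slope_pre`, sign preserved) and
#'   `fold` (ratio rounded to the nearest integer).
#' @export
fold_change <- function(slope_post, slope_pre) {
  if (slope_pre == 0) stop("reference slope is zero; fold-change undefined")
  r <- slope_post / slope_pre
  list(ratio = r, fold = as.integer(round(r)))
}

#' Single-cell intensity versus generation
#'
#' For all cells alive at one time point, pairs each cell's fluorescence
#' with its generation number. Useful to visualize GFP dilution: lineages
#' that divided more often carry less accumulated fluorophore per cell.
#'
#' @param records cell records carrying `frame_index`, `timestamp_s`,
#'   `cell_id`, `mean_intensity` (possibly several frames).
#' @param forest a generation-assigned [lineage_forest()].
#' @param time_h time point in hours; snapped to the nearest frame (with a
#'   warning if not an exact frame time).
#' @return data.frame (class `generation_table`): `cell_id`, `generation`,
#'   `mean_intensity`; Spearman rank correlation between generation and
#'   intensity in `attr(, "spearman_rho")`.
#' @export
intensity_vs_generation <- function(records, forest, time_h) {
  stopifnot(inherits(forest, "lineage_forest"))
  if (any(is.na(forest$nodes$generation)))
    stop("generations not assigned; call assign_generations() first")
  h <- records$timestamp_s / 3600
  dt <- abs(h - time_h)
  if (min(dt) > 1e-9)
    warning(sprintf("t = %g h is not a frame time; using nearest frame (%g h)",
                    time_h, h[which.min(dt)]))
  sel <- records[dt == min(dt), ]
  key <- paste(sel$frame_index, sel$cell_id)
  nkey <- paste(forest$nodes$frame_index, forest$nodes$cell_id)
  gen <- forest$nodes$generation[match(key, nkey)]
  out <- data.frame(cell_id = sel$cell_id, generation = gen,
                    mean_intensity = sel$mean_intensity)
  rho <- if (nrow(out) >= 2 && stats::sd(out$generation) > 0 &&
             stats::sd(out$mean_intensity) > 0)
    stats::cor(out$generation, out$mean_intensity, method = "spearman")
  else NA_real_
  attr(out, "spearman_rho") <- rho
  class(out) <- c("generation_table", "data.frame")
  out
}

#' Per-generation summary
#'
#' @param tbl an [intensity_vs_generation()] table.
#' @return data.frame: `generation`, `n`, `mean_intensity`, `sd_intensity`.
#' @export
summarize_generations <- function(tbl) {
  f <- factor(tbl$generation)
  data.frame(generation = as.integer(levels(f)),
             n = as.vector(table(f)),
             mean_intensity = as.vector(tapply(tbl$mean_intensity, f, mean)),
             sd_intensity = as.vector(tapply(tbl$mean_intensity, f, stats::sd)))
}
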