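# Microwell, cell and bead detection in grayscale images, and the sixteen
# per-cell morphology/intensity features. Images are plain numeric matrices
# indexed [row, col]; pixel coordinates are 0-based with x rightward
# (columns) and y downward (rows). EBImage supplies thresholding, labeling
# and contour primitives; the feature definitions are computed here.

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass.
label8 <- function(mask) {
  l <- EBImage::bwlabel(mask)
  l <- matrix(as.integer(l), nrow(mask), ncol(mask))
  k <- max(l)
  if (k < 2) return(l)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) return(invisible())
    for (p in unique(cbind(a[sel], b[sel]))[, 1:2, drop = FALSE] |> asplit(1)) {
      ra <- find(p[1]); rb <- find(p[2])
      if (ra != rb) parent[ra] <<- rb
    }
  }
  nr <- nrow(l); nc <- ncol(l)
  link(l[-nr, -nc], l[-1, -1])   # down-right diagonal
  link(l[-nr, -1], l[-1, -nc])   # down-left diagonal
  roots <- vapply(seq_len(k), find, integer(1))
  relabel <- match(roots, unique(roots))
  out <- l
  out[l > 0L] <- relabel[l[l > 0L]]
  out
}

# Pixel coordinate list (0-based x, y) per label.
label_pixels <- function(labels) {
  idx <- which(labels > 0L, arr.ind = TRUE)
  split.data.frame(
    data.frame(x = idx[, "col"] - 1L, y = idx[, "row"] - 1L),
    labels[idx]
  )
}

# Mean image intensity within a disk.
disk_mean <- function(img, x, y, r) {
  rows <- pmax(1, floor(y + 1 - r)):pmin(nrow(img), ceiling(y + 1 + r))
  cols <- pmax(1, floor(x + 1 - r)):pmin(ncol(img), ceiling(x + 1 + r))
  sub <- img[rows, cols, drop = FALSE]
  dy <- (rows - 1) - y
  dx <- (cols - 1) - x
  inside <- outer(dy^2, dx^2, `+`) <= r^2
  mean(sub[inside])
}

#' Detect microwells in a bright-field image
#'
#' Wells appear as dark disks on a bright background; the image is inverted,
#' locally mean-thresholded (making detection invariant to global intensity
#' offsets), labeled, and size-gated. Returns well centers and the median
#' well radius.
#'
#' @param brightfield numeric matrix (single-channel image).
#' @param window half-width of the local-mean threshold window in px
#'   (default 15; should exceed the well radius).
#' @param offset threshold offset as a fraction of the image dynamic range
#'   (default 0.05).
#' @param min_area,max_area component area gates in px^2.
#' @return object of class `microwell_grid`: list with `wells` (data.frame
#'   `well_id`, `x`, `y`), `radius` (median well radius, px) and `dim`.
#' @export
detect_microwells <- function(brightfield, window = 15, offset = 0.05,
                              min_area = 50, max_area = Inf) {
  rng <- range(brightfield)
  if (diff(rng) == 0) stop("no microwells found: blank image")
  inv <- (rng[2] - brightfield) / (rng[2] - rng[1])
  mask <- EBImage::thresh(EBImage::Image(inv), w = window, h = window,
                          offset = offset)
  mask <- EBImage::fillHull(mask)
  labels <- label8(matrix(as.numeric(mask), nrow(brightfield)))
  px <- label_pixels(labels)
  areas <- vapply(px, nrow, integer(1))
  px <- px[areas >= min_area & areas <= max_area]
  if (length(px) == 0) stop("no microwells found")
  centers <- do.call(rbind, lapply(px, function(p) {
    data.frame(x = mean(p$x), y = mean(p$y))
  }))
  centers <- centers[order(centers$y, centers$x), ]
  structure(
    list(
      wells = data.frame(well_id = seq_len(nrow(centers)),
                         x = centers$x, y = centers$y),
      radius = median(sqrt(vapply(px, nrow, integer(1)) / pi)),
      dim = dim(brightfield)
    ),
    class = "microwell_grid"
  )
}

#' @export
print.microwell_grid <- function(x, ...) {
  cat("microwell_grid:", nrow(x$wells), "wells, radius",
      round(x$radius, 1), "px\n")
  invisible(x)
}

#' Call occupied wells from a fluorescence image
#'
#' Measures the mean fluorescence inside each well and thresholds the
#' (bimodal) per-well means with [bimodal_threshold()]; wells in the higher
#' mode are occupied. If the distribution is not separably bimodal every
#' well is called unoccupied, with a warning.
#'
#' @param grid a `microwell_grid`.
#' @param fluorescence numeric matrix, same frame as the bright-field.
#' @return data.frame `well_id`, `mean_intensity`, `occupied` (logical).
#' @export
call_occupied_wells <- function(grid, fluorescence) {
  means <- vapply(seq_len(nrow(grid$wells)), function(i) {
    disk_mean(fluorescence, grid$wells$x[i], grid$wells$y[i], grid$radius)
  }, numeric(1))
  thr <- tryCatch(bimodal_threshold(means), error = function(e) {
    warning("well intensities not bimodal (", conditionMessage(e),
            "); calling all wells unoccupied")
    Inf
  })
  if (is.finite(thr)) {
    fit <- attr(thr, "fit")
    # bimodality gates: Ashman's D and an empty valley between the modes
    D <- abs(diff(fit$mu)) / sqrt(mean(fit$sigma^2))
    breaks <- seq(min(means), max(means), length.out = 51)
    counts <- tabulate(pmin(pmax(findInterval(means, breaks,
                                              rightmost.closed = TRUE), 1L),
                            50L), nbins = 50L)
    t_bin <- pmin(pmax(findInterval(as.numeric(thr), breaks,
                                    rightmost.closed = TRUE), 1L), 50L)
    peak_lo <- max(counts[seq_len(t_bin)])
    peak_hi <- max(counts[t_bin:50])
    if (D < 2 || counts[t_bin] > 0.5 * min(peak_lo, peak_hi)) {
      warning("well intensity distribution looks unimodal; ",
              "calling all wells unoccupied")
      thr <- Inf
    }
  }
  data.frame(well_id = grid$wells$well_id, mean_intensity = means,
             occupied = means > as.numeric(thr))
}

# Convex hull helpers on 0-based pixel centers.
hull_points <- function(p) {
  h <- chull(p$x, p$y)
  p[h, , drop = FALSE]
}

shoelace_area <- function(h) {
  n <- nrow(h)
  j <- c(2:n, 1)
  abs(sum(h$x * h$y[j] - h$x[j] * h$y)) / 2
}

# Max and min Feret diameters over convex hull vertices (min via rotating
# calipers: smallest width across all hull edge directions).
feret_diameters <- function(h) {
  n <- nrow(h)
  if (n == 1) return(c(feret = 0, min_feret = 0))
  d <- as.matrix(stats::dist(h))
  feret <- max(d)
  if (n == 2) return(c(feret = feret, min_feret = 0))
  j <- c(2:n, 1)
  ex <- h$x[j] - h$x
  ey <- h$y[j] - h$y
  len <- sqrt(ex^2 + ey^2)
  widths <- vapply(which(len > 0), function(e) {
    max(abs((h$x - h$x[e]) * (-ey[e] / len[e]) +
            (h$y - h$y[e]) * (ex[e] / len[e])))
  }, numeric(1))
  c(feret = feret, min_feret = min(widths))
}

# Chain-code perimeter from the traced object contour (diagonal steps
# count sqrt(2)).
contour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask))[[1]]
  if (nrow(oc) < 2) return(4)  # single pixel: unit square
  nxt <- oc[c(2:nrow(oc), 1), , drop = FALSE]
  sum(sqrt(rowSums((oc - nxt)^2)))
}

#' Extract the sixteen imaging features of a single cell
#'
#' The well crop is Otsu-thresholded and 8-connected components of at least
#' `min_area` px^2 are taken as particles. Wells with no particle or with
#' two or more particles are excluded (multiplet rule). For the single
#' particle the features are: area; mean/sd/min/max/median intensity;
#' perimeter (chain code); bounding-box width and height; major and minor
#' moment-ellipse axes; circularity = 4*pi*area/perimeter^2 (clamped to
#' [0, 1]); Feret's diameter and minimum Feret's diameter (convex hull
#' calipers); roundness = 4*area/(pi*major^2); solidity = area / convex hull
#' area (clamped to 1).
#'
#' @param crop numeric matrix: the smallest bounding square of one well.
#' @param well_id identifier carried into the record.
#' @param min_area minimum particle area in px^2 (default 20).
#' @return list with `record` (one-row data.frame, or NULL) and `excluded`
#'   (NA, or the reason: "no_particle" / "multiple_particles").
#' @export
extract_cell_features <- function(crop, well_id, min_area = 20) {
  rng <- range(crop)
  if (diff(rng) == 0) {
    return(list(record = NULL, excluded = "no_particle"))
  }
  norm <- (crop - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm))
  labels <- label8((norm > thr) * 1)
  px <- label_pixels(labels)
  px <- px[vapply(px, nrow, integer(1)) >= min_area]
  if (length(px) == 0) return(list(record = NULL, excluded = "no_particle"))
  if (length(px) >= 2) return(list(record = NULL, excluded = "multiple_particles"))
  p <- px[[1]]
  mask <- matrix(0, nrow(crop), ncol(crop))
  mask[cbind(p$y + 1, p$x + 1)] <- 1
  vals <- crop[cbind(p$y + 1, p$x + 1)]
  area <- nrow(p)
  perim <- contour_perimeter(mask)
  cv <- cov(cbind(p$x, p$y)) * (area - 1) / area  # population moments
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  major <- 4 * sqrt(max(ev[1], 0))
  minor <- 4 * sqrt(max(ev[2], 0))
  h <- hull_points(p)
  fer <- feret_diameters(h)
  hull_area <- shoelace_area(h)
  list(
    record = data.frame(
      well_id = well_id,
      area = area,
      mean_intensity = mean(vals),
      sd_intensity = if (area > 1) sd(vals) else 0,
      min_intensity = min(vals),
      max_intensity = max(vals),
      median_intensity = median(vals),
      perimeter = perim,
      width = diff(range(p$x)) + 1,
      height = diff(range(p$y)) + 1,
      major_axis = major,
      minor_axis = minor,
      circularity = min(1, 4 * pi * area / perim^2),
      feret = fer[["feret"]],
      min_feret = fer[["min_feret"]],
      roundness = min(1, 4 * area / (pi * major^2)),
      solidity = min(1, area / max(hull_area, .Machine$double.eps))
    ),
    excluded = NA_character_
  )
}

# Smallest bounding square of a well, clipped to the image.
well_crop <- function(img, x, y, radius) {
  r <- ceiling(radius)
  rows <- pmax(1, round(y + 1 - r)):pmin(nrow(img), round(y + 1 + r))
  cols <- pmax(1, round(x + 1 - r)):pmin(ncol(img), round(x + 1 + r))
  img[rows, cols, drop = FALSE]
}

#' Extract features for every occupied well
#'
#' @param fluorescence numeric matrix.
#' @param grid a `microwell_grid`.
#' @param occupancy output of [call_occupied_wells()] (NULL: call it here).
#' @param min_area minimum particle area in px^2.
#' @return list with `features` (data.frame, one row per kept cell) and
#'   `excluded` (data.frame `well_id`, `reason`).
#' @export
extract_all_features <- function(fluorescence, grid, occupancy = NULL,
                                 min_area = 20) {
  if (is.null(occupancy)) occupancy <- call_occupied_wells(grid, fluorescence)
  recs <- list(); excl <- list()
  for (i in which(occupancy$occupied)) {
    crop <- well_crop(fluorescence, grid$wells$x[i], grid$wells$y[i],
                      grid$radius)
    r <- extract_cell_features(crop, grid$wells$well_id[i], min_area)
    if (is.null(r$record)) {
      excl[[length(excl) + 1]] <- data.frame(well_id = grid$wells$well_id[i],
                                             reason = r$excluded)
    } else {
      recs[[length(recs) + 1]] <- r$record
    }
  }
  list(
    features = if (length(recs)) do.call(rbind, recs) else NULL,
    excluded = if (length(excl)) do.call(rbind, excl) else NULL
  )
}

#' Track beads across decoding cycles
#'
#' Beads detected in cycles B..H are matched to the nearest cycle-A bead
#' (within `radius`); their per-cycle mean Cy5/Cy3 intensities fill the
#' 8 x 2 intensity table. Later-cycle detections with no cycle-A bead within
#' `radius` are dropped. When a cycle-A bead has no match in some cycle, its
#' intensities for that cycle are re-measured at the cycle-A position from
#' the supplied images (or left NA), and the bead is flagged.
#'
#' @param detections list of 8 data.frames (cycles A..H), each with columns
#'   `x`, `y`, `ch5`, `ch3`.
#' @param radius matching radius in px.
#' @param images optional list of 8 lists with `ch5`, `ch3` image matrices,
#'   used for the missing-bead fallback.
#' @param bead_radius radius for fallback intensity measurement (px).
#' @return bead intensity table (see [decode_bead_by_bead()]) with an extra
#'   `n_missing_cycles` column.
#' @export
track_beads_across_cycles <- function(detections, radius, images = NULL,
                                      bead_radius = 3) {
  stopifnot(length(detections) == 8, nrow(detections[[1]]) > 0)
  a <- detections[[1]]
  n <- nrow(a)
  tab <- data.frame(bead_id = seq_len(n), x = a$x, y = a$y)
  inten <- array(NA_real_, c(n, 8, 2))
  inten[, 1, 1] <- a$ch5
  inten[, 1, 2] <- a$ch3
  missing <- integer(n)
  for (k in 2:8) {
    det <- detections[[k]]
    claimed <- rep(NA_integer_, n)  # detection index claimed per A bead
    if (nrow(det) > 0) {
      d2 <- outer(det$x, a$x, `-`)^2 + outer(det$y, a$y, `-`)^2
      nearest <- max.col(-d2, ties.method = "first")
      dist <- sqrt(d2[cbind(seq_len(nrow(det)), nearest)])
      for (j in order(dist)) {
        if (dist[j] <= radius && is.na(claimed[nearest[j]])) {
          claimed[nearest[j]] <- j
        }
      }
    }
    for (i in seq_len(n)) {
      if (!is.na(claimed[i])) {
        inten[i, k, 1] <- det$ch5[claimed[i]]
        inten[i, k, 2] <- det$ch3[claimed[i]]
      } else {
        missing[i] <- missing[i] + 1L
        if (!is.null(images)) {
          inten[i, k, 1] <- disk_mean(images[[k]]$ch5, a$x[i], a$y[i], bead_radius)
          inten[i, k, 2] <- disk_mean(images[[k]]$ch3, a$x[i], a$y[i], bead_radius)
        }
      }
    }
  }
  for (k in 1:8) {
    tab[[paste0("ch5_cycle", CYCLES[k])]] <- inten[, k, 1]
    tab[[paste0("ch3_cycle", CYCLES[k])]] <- inten[, k, 2]
  }
  tab$n_missing_cycles <- missing
  tab
}

#' Identify multiplets from two-color fluorescence
#'
#' Particles are detected globally per channel (Otsu + 8-connected
#' components) and assigned to the nearest well within a well radius. A well
#' with at least one green and one magenta particle is a mixed-species
#' multiplet; at least two particles of a single color is a single-species
#' multiplet; exactly one particle is a singlet.
#'
#' @param green,magenta numeric matrices (two live-stain channels).
#' @param grid a `microwell_grid`.
#' @param min_area minimum particle area in px^2.
#' @return data.frame `well_id`, `n_green`, `n_magenta`, `label` in
#'   {"empty", "singlet", "single_multiplet", "mixed_multiplet"}.
#' @export
identify_multiplets <- function(green, magenta, grid, min_area = 20) {
  count_channel <- function(img) {
    rng <- range(img)
    counts <- integer(nrow(grid$wells))
    if (diff(rng) == 0) return(counts)
    norm <- (img - rng[1]) / (rng[2] - rng[1])
    labels <- label8((norm > EBImage::otsu(EBImage::Image(norm))) * 1)
    px <- label_pixels(labels)
    px <- px[vapply(px, nrow, integer(1)) >= min_area]
    for (p in px) {
      cx <- mean(p$x); cy <- mean(p$y)
      d <- sqrt((grid$wells$x - cx)^2 + (grid$wells$y - cy)^2)
      i <- which.min(d)
      if (d[i] <= grid$radius) counts[i] <- counts[i] + 1L
    }
    counts
  }
  ng <- count_channel(green)
  nm <- count_channel(magenta)
  label <- ifelse(ng >= 1 & nm >= 1, "mixed_multiplet",
           ifelse(ng >= 2 | nm >= 2, "single_multiplet",
           ifelse(ng + nm == 1, "singlet", "empty")))
  data.frame(well_id = grid$wells$well_id, n_green = ng, n_magenta = nm,
             label = label)
}
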