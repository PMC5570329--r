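# Rendering synthetic nanowell image frames.
#
# Objects are drawn as isotropic 2D Gaussian spots on a dark background at a
# single focal plane. The spot amplitude is scaled so that the mean pixel
# value over the half-maximum core equals the object's nominal MFI
# (mean-over-core of a Gaussian = amplitude * 0.5/ln 2), which makes the
# renderer and the core-based segmenter a consistent round trip. The summed
# pixel intensity of a spot above background is
# `2 * pi * (sigma / pixel_size)^2 * amplitude` up to quadrature error.

.CORE_MEAN_FACTOR <- 0.5 / log(2)   # mean over half-max core / amplitude

.grid_dims <- function(layout) {
  nc <- as.numeric(ceiling(sqrt(layout$n_wells)))
  nr <- as.numeric(ceiling(layout$n_wells / nc))
  c(nr = nr, nc = nc)
}

.well_origin_um <- function(layout, well_index) {
  gd <- .grid_dims(layout)
  row <- (well_index - 1L) %/% unname(gd["nc"]) + 1L
  col <- (well_index - 1L) %% unname(gd["nc"]) + 1L
  margin <- (layout$well_pitch - layout$well_size) / 2
  c(x = (col - 1) * layout$well_pitch + margin,
    y = (row - 1) * layout$well_pitch + margin)
}

.add_spot <- function(img, x_px, y_px, amplitude, sigma_px) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(4 * sigma_px)
  j0 <- max(1, floor(x_px - w)); j1 <- min(nc, ceiling(x_px + w))
  i0 <- max(1, floor(y_px - w)); i1 <- min(nr, ceiling(y_px + w))
  if (j0 > j1 || i0 > i1) return(img)
  jc <- (j0:j1) - 0.5; ic <- (i0:i1) - 0.5
  gx <- exp(-((jc - x_px)^2) / (2 * sigma_px^2))
  gy <- exp(-((ic - y_px)^2) / (2 * sigma_px^2))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amplitude * outer(gy, gx)
  img
}

#' Render one synthetic image frame
#'
#' Draws the requested channels of one time-lapse frame for a generated
#' dataset: `"bf"` (brightfield proxy: elevated well floors), `"cd16"` and
#' `"cd56"` (cells at their channel intensities), `"beads"` (bead marker at a
#' fixed intensity) and `"ifng"` (beads at their trace MFI for this frame).
#'
#' @param dataset A [generate_dataset()] result.
#' @param frame Frame index (1-based into `dataset$schedule`).
#' @param channels Character vector of channels to render.
#' @param pixel_size Pixel size (um), default 0.65 (20x objective scale).
#' @param background Background level (arbitrary units).
#' @param sigma_cell,sigma_bead Gaussian spot sigma (um) for cells and beads.
#' @param bead_marker_mfi Nominal MFI of the bead identification channel.
#' @return Named list of numeric matrices (row = y, column = x).
#' @export
render_frames <- function(dataset, frame = 1,
                          channels = c("bf", "cd16", "cd56", "beads", "ifng"),
                          pixel_size = 0.65, background = 20,
                          sigma_cell = 2, sigma_bead = 1.2,
                          bead_marker_mfi = 500) {
  stopifnot(inherits(dataset, "nanowell_dataset"),
            frame >= 1, frame <= length(dataset$schedule))
  layout <- dataset$layout
  gd <- .grid_dims(layout)
  nc_px <- ceiling(gd["nc"] * layout$well_pitch / pixel_size)
  nr_px <- ceiling(gd["nr"] * layout$well_pitch / pixel_size)
  blank <- matrix(background, nr_px, nc_px)

  obj_px <- function(tbl) {
    if (nrow(tbl) == 0) {
      return(tibble::tibble(x_px = numeric(0), y_px = numeric(0)))
    }
    wi <- match(tbl$well_id, dataset$occupancy$well_id)
    org <- t(vapply(wi, function(i) .well_origin_um(layout, i), numeric(2)))
    tibble::tibble(x_px = (org[, 1] + tbl$x_um) / pixel_size,
                   y_px = (org[, 2] + tbl$y_um) / pixel_size)
  }
  cells_px <- obj_px(dataset$cells)
  beads_px <- obj_px(dataset$beads)
  s_cell <- sigma_cell / pixel_size
  s_bead <- sigma_bead / pixel_size
  t_now <- dataset$schedule[frame]

  out <- list()
  for (ch in channels) {
    img <- blank
    if (ch == "bf") {
      for (w in seq_len(layout$n_wells)) {
        org <- .well_origin_um(layout, w) / pixel_size
        sz <- layout$well_size / pixel_size
        i0 <- max(1, ceiling(org["y"])); i1 <- min(nr_px, floor(org["y"] + sz))
        j0 <- max(1, ceiling(org["x"])); j1 <- min(nc_px, floor(org["x"] + sz))
        img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + 30
      }
      for (k in seq_len(nrow(cells_px)))
        img <- .add_spot(img, cells_px$x_px[k], cells_px$y_px[k],
                         100 / .CORE_MEAN_FACTOR, s_cell)
      for (k in seq_len(nrow(beads_px)))
        img <- .add_spot(img, beads_px$x_px[k], beads_px$y_px[k],
                         100 / .CORE_MEAN_FACTOR, s_bead)
    } else if (ch %in% c("cd16", "cd56")) {
      vals <- dataset$cells[[paste0(ch, "_mfi")]]
      for (k in seq_len(nrow(cells_px)))
        img <- .add_spot(img, cells_px$x_px[k], cells_px$y_px[k],
                         vals[k] / .CORE_MEAN_FACTOR, s_cell)
    } else if (ch == "beads") {
      for (k in seq_len(nrow(beads_px)))
        img <- .add_spot(img, beads_px$x_px[k], beads_px$y_px[k],
                         bead_marker_mfi / .CORE_MEAN_FACTOR, s_bead)
    } else if (ch == "ifng") {
      tr <- dataset$traces[abs(dataset$traces$time_min - t_now) < 1e-9, ]
      mfi <- tr$mfi[match(dataset$beads$bead_id, tr$bead_id)]
      for (k in seq_len(nrow(beads_px))) {
        if (!is.na(mfi[k]) && mfi[k] > 0)
          img <- .add_spot(img, beads_px$x_px[k], beads_px$y_px[k],
                           mfi[k] / .CORE_MEAN_FACTOR, s_bead)
      }
    } else {
      stop(sprintf("unknown channel '%s'", ch), call. = FALSE)
    }
    out[[ch]] <- img
  }
  out
}

#' Write rendered channels as single-plane grayscale TIFF files
#'
#' @param frames Named list of matrices from [render_frames()].
#' @param dir Output directory.
#' @param frame Frame index used in the file names.
#' @param scale Intensity divisor mapping values into `[0, 1]` for storage.
#' @return Invisibly, the written file paths.
#' @export
write_frame_tiffs <- function(frames, dir, frame = 1, scale = 65535) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(frames)) {
    p <- file.path(dir, sprintf("frame%03d_%s.tiff", frame, ch))
    tiff::writeTIFF(pmin(pmax(frames[[ch]] / scale, 0), 1), p,
                    bits.per.sample = 16)
    paths <- c(paths, p)
  }
  invisible(paths)
}
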