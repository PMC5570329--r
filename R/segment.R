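# Simplified segmentation of synthetic nanowell image frames.
#
# Wells are located from the known array grid (the synthetic renderer and the
# segmenter share the layout), objects inside each well are found by
# intensity thresholding plus connected-component labelling, components are
# split at their internal intensity peaks, and each object's MFI is the mean
# pixel value over the half-maximum core of its peak minus the local well
# background (median of non-object pixels in the well). This closes the
# render -> segment loop for synthetic data; it is not a general-purpose
# microscopy segmenter.

.well_bounds_px <- function(layout, well_index, pixel_size, dims) {
  org <- .well_origin_um(layout, well_index) / pixel_size
  sz <- layout$well_size / pixel_size
  # one-pixel margin so spots at the well edge keep their core
  i0 <- max(1, floor(org["y"]) - 1); i1 <- min(dims[1], ceiling(org["y"] + sz) + 1)
  j0 <- max(1, floor(org["x"]) - 1); j1 <- min(dims[2], ceiling(org["x"] + sz) + 1)
  c(i0 = i0, i1 = i1, j0 = j0, j1 = j1)
}

.local_maxima <- function(m, mask) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  mx <- matrix(-Inf, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1 && dj == 1) next
    mx <- pmax(mx, pad[(1 + di):(nr + di), (1 + dj):(nc + dj)])
  }
  which(mask & m >= mx, arr.ind = TRUE)
}

#' Segment one rendered frame into per-well objects
#'
#' @param img Numeric image matrix (the detection channel).
#' @param layout The [array_layout()] used to render the frame.
#' @param pixel_size Pixel size (um).
#' @param psf_sigma Spot sigma (um) of the objects being detected (bead or
#'   cell scale); sets the measurement core radius.
#' @param min_signal Detection threshold above the local background.
#' @param measure_img Optional second channel measured at the detected
#'   positions (e.g. detect on the bead channel, measure the cytokine
#'   channel); defaults to `img`.
#' @param kind Label stored in the `kind` column (`"cell"` or `"bead"`).
#' @return Tibble with `object_id`, `well_id`, `kind`, `x_px`, `y_px`,
#'   `mfi` (background-corrected, from `measure_img`) and `detect_mfi`.
#' @export
segment_frame <- function(img, layout, pixel_size = 0.65, psf_sigma = 1.2,
                          min_signal = 30, measure_img = NULL,
                          kind = "object") {
  stopifnot(is.matrix(img), inherits(layout, "array_layout"))
  if (is.null(measure_img)) measure_img <- img
  if (!all(dim(measure_img) == dim(img)))
    stop("`measure_img` dimensions do not match `img`", call. = FALSE)
  gd <- .grid_dims(layout)
  need <- ceiling(gd * layout$well_pitch / pixel_size)
  if (any(dim(img) < need[c("nr", "nc")] - 1))
    stop("image dimensions are inconsistent with the array layout", call. = FALSE)

  s_px <- psf_sigma / pixel_size
  r_core <- sqrt(2 * log(2)) * s_px      # half-maximum radius
  rows <- list()
  occ_ids <- sprintf("W%06d", seq_len(layout$n_wells))
  for (w in seq_len(layout$n_wells)) {
    b <- .well_bounds_px(layout, w, pixel_size, dim(img))
    crop <- img[b["i0"]:b["i1"], b["j0"]:b["j1"]]
    mcrop <- measure_img[b["i0"]:b["i1"], b["j0"]:b["j1"]]
    bg <- stats::median(crop)
    mask <- crop >= bg + min_signal
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    bg_det <- stats::median(crop[!mask])
    bg_mea <- stats::median(mcrop[!mask])
    peaks <- .local_maxima(crop, mask)
    if (nrow(peaks) == 0) next
    # deduplicate plateau/nearby maxima: keep the brightest within 2 sigma
    v <- crop[peaks]
    ord <- order(-v)
    keep <- logical(nrow(peaks))
    for (p in ord) {
      if (any(keep & (peaks[, 1] - peaks[p, 1])^2 +
              (peaks[, 2] - peaks[p, 2])^2 < (2 * s_px)^2)) next
      keep[p] <- TRUE
    }
    peaks <- peaks[keep, , drop = FALSE]
    nrp <- nrow(crop); ncp <- ncol(crop)
    for (p in seq_len(nrow(peaks))) {
      pi <- peaks[p, 1]; pj <- peaks[p, 2]
      rad <- ceiling(r_core)
      ii <- max(1, pi - rad):min(nrp, pi + rad)
      jj <- max(1, pj - rad):min(ncp, pj + rad)
      dd <- outer((ii - pi)^2, (jj - pj)^2, "+")
      core <- dd <= r_core^2
      sub <- crop[ii, jj]
      msub <- mcrop[ii, jj]
      wgt <- pmax(sub[core] - bg_det, 0)
      ci <- sum(rep(ii, times = length(jj))[core] * wgt) / sum(wgt)
      cj <- sum(rep(jj, each = length(ii))[core] * wgt) / sum(wgt)
      rows[[length(rows) + 1]] <- tibble::tibble(
        well_id = occ_ids[w], kind = kind,
        x_px = b["j0"] - 1 + cj - 0.5, y_px = b["i0"] - 1 + ci - 0.5,
        mfi = mean(msub[core]) - bg_mea,
        detect_mfi = mean(sub[core]) - bg_det
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(object_id = character(0), well_id = character(0),
                          kind = character(0), x_px = numeric(0),
                          y_px = numeric(0), mfi = numeric(0),
                          detect_mfi = numeric(0)))
  }
  out <- dplyr::bind_rows(rows)
  out$object_id <- sprintf("%s_%s%d", out$well_id, substr(kind, 1, 1),
                           stats::ave(seq_len(nrow(out)), out$well_id,
                                      FUN = seq_along))
  out[, c("object_id", "well_id", "kind", "x_px", "y_px", "mfi", "detect_mfi")]
}

#' Assemble bead traces from per-frame segmentations
#'
#' Matches beads across frames by nearest centroid within the same well
#' (beads are sessile and well-confined), taking frame 1 as the reference
#' set. Ambiguous matches (two reference beads claiming one detection) mark
#' the trace low-confidence.
#'
#' @param frame_objects List (one element per frame) of segmentation tables
#'   from [segment_frame()] run on the bead channel with the cytokine channel
#'   as `measure_img`.
#' @param schedule Frame times (min), same length as `frame_objects`.
#' @param single_bead_only If `TRUE`, keep only wells with exactly one
#'   detected bead in the reference frame.
#' @param max_shift_px Largest allowed centroid shift between frames.
#' @return Tibble `bead_id`, `well_id`, `time_min`, `mfi`, `low_confidence`.
#' @export
extract_bead_traces <- function(frame_objects, schedule,
                                single_bead_only = FALSE,
                                max_shift_px = 5) {
  stopifnot(length(frame_objects) == length(schedule),
            length(frame_objects) >= 2)
  ref <- frame_objects[[1]]
  if (single_bead_only) {
    counts <- table(ref$well_id)
    ref <- ref[ref$well_id %in% names(counts)[counts == 1], ]
  }
  if (nrow(ref) == 0) {
    return(tibble::tibble(bead_id = character(0), well_id = character(0),
                          time_min = numeric(0), mfi = numeric(0),
                          low_confidence = logical(0)))
  }
  ref$bead_id <- sprintf("%s_B%d", ref$well_id,
                         stats::ave(seq_len(nrow(ref)), ref$well_id,
                                    FUN = seq_along))
  out <- vector("list", length(schedule))
  lowconf <- setNames(rep(FALSE, nrow(ref)), ref$bead_id)
  for (f in seq_along(schedule)) {
    fo <- frame_objects[[f]]
    mfi <- rep(NA_real_, nrow(ref))
    match_idx <- rep(NA_integer_, nrow(ref))
    for (r in seq_len(nrow(ref))) {
      cand <- which(fo$well_id == ref$well_id[r])
      if (length(cand) == 0) next
      d2 <- (fo$x_px[cand] - ref$x_px[r])^2 + (fo$y_px[cand] - ref$y_px[r])^2
      j <- cand[which.min(d2)]
      if (min(d2) <= max_shift_px^2) {
        match_idx[r] <- j
        mfi[r] <- fo$mfi[j]
      }
    }
    dup <- match_idx[!is.na(match_idx)][duplicated(match_idx[!is.na(match_idx)])]
    if (length(dup)) lowconf[ref$bead_id[match_idx %in% dup]] <- TRUE
    out[[f]] <- tibble::tibble(bead_id = ref$bead_id, well_id = ref$well_id,
                               time_min = schedule[f], mfi = mfi)
  }
  res <- dplyr::bind_rows(out)
  res$low_confidence <- lowconf[res$bead_id]
  res[order(res$bead_id, res$time_min), ]
}
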