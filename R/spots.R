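#' Detect immobile DNA-template spots
#'
#' Identifies the surface-tethered template spots that anchor all per-spot
#' analysis. Each DNA frame is binarized at a global background threshold
#' (default: median + `nmads` x MAD of the temporal-median image, robust to
#' sparse bright spots), connected components within `size_range` become
#' candidate detections, detections are linked across DNA frames by
#' proximity (`link_radius`), and linked spots seen in fewer than
#' `min_persistency` of the frames are discarded. The reported centroid is
#' the mean of the per-frame detection centroids.
#'
#' @param stack Drift-corrected DNA-channel [image_stack()].
#' @param threshold `"mad"` for the robust global policy, or a single
#'   absolute intensity value.
#' @param nmads MAD multiplier of the robust threshold policy.
#' @param size_range Connected-component area limits in px, `c(min, max)`.
#' @param min_persistency Minimum fraction of DNA frames in which a spot must
#'   be detected (0 bypasses the filter, e.g. single-snapshot mode).
#' @param link_radius Maximum centroid distance (px) to link detections of
#'   one spot across frames; templates are immobile after drift correction.
#' @return A `spot_map`: tibble with `spot`, `r`, `c` (px centroid), `area`
#'   (mean px area) and `persistency` (fraction of frames detected).
#' @export
detect_dna_spots <- function(stack, threshold = "mad", nmads = 4,
                             size_range = c(2, 30), min_persistency = 0.5,
                             link_radius = 2) {
  stopifnot(inherits(stack, "image_stack"))
  n_frames <- length(stack$frames)
  if (n_frames == 0) stop("empty stack")
  # global threshold: background centre from the temporal-median image,
  # noise scale from the single-frame MAD (the scale binarization sees)
  med_img <- if (n_frames == 1) stack$frames[[1]] else {
    apply(simplify2array(stack$frames), c(1, 2), stats::median)
  }
  thr <- if (identical(threshold, "mad")) {
    noise <- stats::median(vapply(stack$frames, function(f) stats::mad(f), 0))
    stats::median(med_img) + nmads * noise
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    threshold
  }
  # per-frame connected components with size filter
  det <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    mask <- stack$frames[[fi]] > thr
    if (!any(mask)) next
    lab <- EBImage::bwlabel(EBImage::as.Image(mask))
    labm <- EBImage::imageData(lab)
    areas <- tabulate(labm[labm > 0])
    keep <- which(areas >= size_range[1] & areas <= size_range[2])
    if (!length(keep)) next
    idx <- which(labm > 0 & labm %in% keep, arr.ind = TRUE)
    ids <- labm[labm > 0 & labm %in% keep]
    det[[fi]] <- tibble::tibble(
      frame = fi,
      r = as.numeric(tapply(idx[, 1], ids, mean)),
      c = as.numeric(tapply(idx[, 2], ids, mean)),
      area = as.numeric(tapply(idx[, 1], ids, length))
    )
  }
  det <- dplyr::bind_rows(det)
  empty <- tibble::tibble(spot = integer(), r = numeric(), c = numeric(),
                          area = numeric(), persistency = numeric())
  if (!nrow(det)) return(new_spot_map(empty, thr))
  # link detections across frames: nearest running-centroid within radius
  cr <- numeric(); cc <- numeric(); cnt <- integer(); car <- numeric()
  assign_id <- integer(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (length(cr)) {
      d2 <- (cr / cnt - det$r[i])^2 + (cc / cnt - det$c[i])^2
      j <- which.min(d2)
    } else j <- NA_integer_
    if (!is.na(j) && d2[j] <= link_radius^2) {
      cr[j] <- cr[j] + det$r[i]; cc[j] <- cc[j] + det$c[i]
      cnt[j] <- cnt[j] + 1L; car[j] <- car[j] + det$area[i]
      assign_id[i] <- j
    } else {
      cr <- c(cr, det$r[i]); cc <- c(cc, det$c[i])
      cnt <- c(cnt, 1L); car <- c(car, det$area[i])
      assign_id[i] <- length(cr)
    }
  }
  # one detection per spot per frame at most: persistency over distinct frames
  frames_seen <- tapply(det$frame, assign_id, function(f) length(unique(f)))
  spots <- tibble::tibble(
    r = cr / cnt, c = cc / cnt, area = car / cnt,
    persistency = as.numeric(frames_seen) / n_frames
  )
  spots <- spots[spots$persistency >= min_persistency, , drop = FALSE]
  spots <- dplyr::arrange(spots, .data$r, .data$c)
  spots$spot <- seq_len(nrow(spots))
  new_spot_map(spots[, c("spot", "r", "c", "area", "persistency")], thr)
}

new_spot_map <- function(tbl, threshold = NA_real_) {
  structure(tbl, class = c("spot_map", class(tbl)), threshold = threshold)
}

#' Extract per-spot background-subtracted z-normalized traces
#'
#' For every spot and frame: `raw` is the mean intensity in a disc of
#' `aperture_radius` px at the spot centroid; `bg` is the median intensity in
#' an annulus `(r_in, r_out)`, excluding pixels within `aperture_radius` of
#' any other spot; and `z = (raw - bg - center) / scale`, where `center` and
#' `scale` are the median and scaled MAD of the full background-subtracted
#' series of that trace (one pair per trace). The MAD is floored at the
#' frame-to-frame noise estimate `mad(diff(x)) / sqrt(2)` and a tiny absolute
#' floor, so constant traces give z = 0 and the z-values are invariant to
#' affine rescaling of the raw intensities.
#'
#' Spots whose annulus extends past the field edge are returned with
#' `valid = FALSE` and should be excluded from downstream statistics.
#'
#' @param stack Drift-corrected [image_stack()] of the channel to sample.
#' @param spots A `spot_map` in the same (drift-corrected) frame of reference.
#' @param aperture_radius Signal disc radius (px).
#' @param annulus Background annulus `c(r_in, r_out)` (px).
#' @return Tibble with `spot`, `channel`, `frame`, `t`, `raw`, `bg`, `z`,
#'   `valid`; one row per spot per scheduled frame.
#' @export
extract_traces <- function(stack, spots, aperture_radius = 3, annulus = c(5, 8)) {
  stopifnot(inherits(stack, "image_stack"))
  if (!nrow(spots)) {
    return(tibble::tibble(spot = integer(), channel = character(),
                          frame = integer(), t = numeric(), raw = numeric(),
                          bg = numeric(), z = numeric(), valid = logical()))
  }
  fld <- dim(stack$frames[[1]])
  n_frames <- length(stack$frames)
  # offset masks around an integer centre
  half <- ceiling(annulus[2])
  og <- expand.grid(dr = -half:half, dc = -half:half)
  od <- sqrt(og$dr^2 + og$dc^2)
  disc_off <- og[od <= aperture_radius, ]
  ann_off <- og[od >= annulus[1] & od <= annulus[2], ]
  res <- vector("list", nrow(spots))
  for (si in seq_len(nrow(spots))) {
    r0 <- round(spots$r[si]); c0 <- round(spots$c[si])
    valid <- r0 - half >= 1 && r0 + half <= fld[1] &&
             c0 - half >= 1 && c0 + half <= fld[2]
    if (!valid) {
      res[[si]] <- tibble::tibble(spot = spots$spot[si], channel = stack$channel,
                                  frame = seq_len(n_frames), t = stack$frame_times,
                                  raw = NA_real_, bg = NA_real_, z = NA_real_,
                                  valid = FALSE)
      next
    }
    disc_idx <- cbind(r0 + disc_off$dr, c0 + disc_off$dc)
    ann_r <- r0 + ann_off$dr; ann_c <- c0 + ann_off$dc
    # drop annulus pixels lying within the aperture of any other spot
    other <- spots[-si, , drop = FALSE]
    if (nrow(other)) {
      keep <- rep(TRUE, length(ann_r))
      for (oi in seq_len(nrow(other))) {
        keep <- keep & ((ann_r - other$r[oi])^2 + (ann_c - other$c[oi])^2 >
                          aperture_radius^2)
      }
      ann_idx <- cbind(ann_r[keep], ann_c[keep])
    } else ann_idx <- cbind(ann_r, ann_c)
    raw <- numeric(n_frames); bg <- numeric(n_frames)
    for (fi in seq_len(n_frames)) {
      f <- stack$frames[[fi]]
      raw[fi] <- mean(f[disc_idx])
      bg[fi] <- if (nrow(ann_idx)) stats::median(f[ann_idx]) else stats::median(f)
    }
    bs <- raw - bg
    center <- stats::median(bs)
    noise_est <- if (n_frames > 1) stats::mad(diff(bs)) / sqrt(2) else 0
    scale <- max(stats::mad(bs), noise_est, 1e-9)
    res[[si]] <- tibble::tibble(spot = spots$spot[si], channel = stack$channel,
                                frame = seq_len(n_frames), t = stack$frame_times,
                                raw = raw, bg = bg, z = (bs - center) / scale,
                                valid = TRUE)
  }
  dplyr::bind_rows(res)
}
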