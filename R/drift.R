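#' Estimate lateral stage drift of an image stack
#'
#' Estimates per-frame translation relative to the first frame, either by
#' phase correlation (FFT cross-power spectrum, robust to intensity changes)
#' or by plain FFT cross-correlation of background-subtracted frames
#' (`translation_fit`, more tolerant of severe drift with low overlap).
#' `"auto"` runs phase correlation first and switches to `translation_fit`
#' when the cumulative displacement exceeds `auto_threshold` px. Sub-pixel
#' refinement uses a separable parabolic fit around the correlation peak.
#'
#' @param stack An [image_stack()] with at least 2 frames.
#' @param method `"phase_correlation"`, `"translation_fit"` or `"auto"`.
#' @param auto_threshold Cumulative displacement (px) above which `"auto"`
#'   prefers `translation_fit`.
#' @return An object of class `drift_model`: tibble with `frame`, `t`, `dr`,
#'   `dc` (displacement of each frame relative to frame 1, px), carrying the
#'   source channel as an attribute. Displacement at `t = 0` is `(0, 0)`;
#'   interpolation between reference times is linear (see [drift_at()]).
#' @export
estimate_drift <- function(stack,
                           method = c("auto", "phase_correlation", "translation_fit"),
                           auto_threshold = 5) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  if (n < 2) stop("need at least 2 frames to estimate drift")
  ref <- stack$frames[[1]]
  if (stats::sd(ref) == 0) {
    warning("degenerate (constant) reference frame; returning zero drift")
    return(new_drift_model(tibble::tibble(frame = seq_len(n), t = stack$frame_times,
                                          dr = 0, dc = 0), stack$channel))
  }
  est_one <- function(img, how) {
    if (stats::sd(img) == 0) return(c(0, 0))
    xcorr_peak(ref, img, phase = (how == "phase_correlation"))
  }
  run <- function(how) {
    d <- t(vapply(stack$frames[-1], est_one, numeric(2), how = how))
    rbind(c(0, 0), d)
  }
  d <- run(if (method == "translation_fit") "translation_fit" else "phase_correlation")
  if (method == "auto" && max(abs(d)) > auto_threshold) {
    d <- run("translation_fit")
  }
  new_drift_model(tibble::tibble(frame = seq_len(n), t = stack$frame_times,
                                 dr = d[, 1], dc = d[, 2]), stack$channel)
}

new_drift_model <- function(tbl, channel = NULL) {
  structure(tbl, class = c("drift_model", class(tbl)), channel = channel)
}

# FFT cross-correlation peak between two equally sized frames; returns the
# sub-pixel displacement (dr, dc) that maps `ref` onto `img`.
xcorr_peak <- function(ref, img, phase = TRUE) {
  a <- ref - mean(ref); b <- img - mean(img)
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Fb * Conj(Fa)
  if (phase) {
    mag <- Mod(R)
    R <- R / pmax(mag, .Machine$double.eps)
  }
  cc <- Re(stats::fft(R, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  nr <- nrow(cc); nc <- ncol(cc)
  # parabolic sub-pixel refinement along each axis (circular indexing)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  pr <- pk[1]; pc <- pk[2]
  yr <- cc[wrap(pr + c(-1, 0, 1), nr), pc]
  yc <- cc[pr, wrap(pc + c(-1, 0, 1), nc)]
  sub <- function(y) {
    den <- y[1] - 2 * y[2] + y[3]
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (y[1] - y[3]) / den))
  }
  dr <- (pr - 1) + sub(yr); dc <- (pc - 1) + sub(yc)
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  c(dr, dc)
}

#' Drift displacement at arbitrary times
#'
#' Linearly interpolates a [estimate_drift()] model between its reference
#' frame times; constant extrapolation outside the observed window.
#'
#' @param drift A `drift_model`.
#' @param t Numeric vector of times (s).
#' @return Matrix with columns `dr`, `dc` (px), one row per element of `t`.
#' @export
drift_at <- function(drift, t) {
  stopifnot(inherits(drift, "drift_model"))
  dr <- stats::approx(drift$t, drift$dr, xout = t, rule = 2)$y
  dc <- stats::approx(drift$t, drift$dc, xout = t, rule = 2)$y
  cbind(dr = dr, dc = dc)
}

#' Resample a stack onto the drift-corrected frame of reference
#'
#' Each frame is translated by minus its estimated displacement using
#' bilinear interpolation; pixels shifted in from outside the field are
#' filled with the frame's median background.
#'
#' @param stack An [image_stack()].
#' @param drift A `drift_model` covering the stack's frame times (any times
#'   not at a reference point are linearly interpolated).
#' @return A drift-corrected [image_stack()].
#' @export
apply_drift_correction <- function(stack, drift) {
  stopifnot(inherits(stack, "image_stack"))
  d <- drift_at(drift, stack$frame_times)
  fld <- dim(stack$frames[[1]])
  if (any(abs(d) > max(fld)))
    stop("drift displacement exceeds the field size")
  frames <- vector("list", length(stack$frames))
  for (i in seq_along(frames)) {
    f <- stack$frames[[i]]
    if (all(d[i, ] == 0)) { frames[[i]] <- f; next }
    bg <- stats::median(f)
    shifted <- EBImage::translate(EBImage::as.Image(f),
                                  v = c(-d[i, 1], -d[i, 2]),
                                  filter = "bilinear", bg.col = bg)
    frames[[i]] <- EBImage::imageData(shifted)
  }
  image_stack(frames, stack$frame_times, channel = stack$channel,
              pixel_size = stack$pixel_size)
}
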