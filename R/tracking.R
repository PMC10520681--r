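#' Tracking configuration
#'
#' @param px_per_mm pixel scale of the video (required; the package never
#'   infers it from image content).
#' @param threshold `"otsu"` for automatic inter-class-variance
#'   thresholding, or a fixed numeric threshold in `(0, 1)`.
#' @param clamp_px number of image columns (from the left) belonging to
#'   the fixed clamp region; these columns seed the component search and
#'   are excluded from the fit. The physical `x` origin sits at the clamp
#'   edge, i.e. at column `clamp_px + 0.5`.
#' @param fit_window fraction of the detected beam extent (from the clamp)
#'   used for the quadratic fit, in `(0, 1]`.
#' @param sg_window Savitzky-Golay window (frames) for the smoothed tip
#'   velocity.
#' @param min_cols minimum number of usable midline columns per frame.
#' @param qual_rms_px residual-RMS quality gate (px); frames above it are
#'   flagged.
#' @param L0 optional free length (m) used to check that the detected
#'   beam spans at least half the free length.
#' @return A `tracking_config` list.
#' @export
tracking_config <- function(px_per_mm, threshold = "otsu", clamp_px = 0L,
                            fit_window = 1, sg_window = 7L,
                            min_cols = 10L, qual_rms_px = 0.5,
                            L0 = NULL) {
  if (px_per_mm <= 0) stop("px_per_mm must be > 0", call. = FALSE)
  if (is.numeric(threshold) && (threshold <= 0 || threshold >= 1))
    stop("fixed threshold must be in (0, 1)", call. = FALSE)
  if (fit_window <= 0 || fit_window > 1)
    stop("fit_window must be in (0, 1]", call. = FALSE)
  list(px_per_mm = px_per_mm, px = px_per_mm * 1e3,
       threshold = threshold, clamp_px = as.integer(clamp_px),
       fit_window = fit_window, sg_window = as.integer(sg_window),
       min_cols = as.integer(min_cols), qual_rms_px = qual_rms_px,
       L0 = L0)
}

#' Otsu automatic threshold
#'
#' Maximizes the inter-class intensity variance on a 256-bin histogram.
#'
#' @param frame numeric matrix in `[0, 1]`.
#' @return Threshold in `(0, 1)`.
#' @export
otsu_threshold <- function(frame) {
  v <- pmin(255L, pmax(0L, as.integer(frame * 255)))
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  (which.max(sb) - 0.5) / 255
}

#' Binarize a frame and keep the beam component
#'
#' Thresholds the frame (automatic Otsu by default) and retains the
#' largest 4-connected foreground component that intersects the clamp
#' region (the beam silhouette); isolated noise specks are dropped.
#'
#' @param frame single-channel numeric matrix in `[0, 1]`.
#' @param config a [tracking_config()].
#' @return A logical mask with attribute `threshold`.
#' @export
binarize <- function(frame, config) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("frame must be a single-channel numeric matrix", call. = FALSE)
  thr <- if (identical(config$threshold, "otsu")) {
    otsu_threshold(frame)
  } else config$threshold
  mask <- frame > thr
  if (!any(mask))
    stop("tracking lost: empty mask after thresholding", call. = FALSE)
  seeds <- if (config$clamp_px > 0L) seq_len(config$clamp_px) else integer(0)
  out <- keep_largest_component(mask, seeds)
  if (!any(out))
    stop("tracking lost: no component intersects the clamp region",
         call. = FALSE)
  attr(out, "threshold") <- thr
  out
}

#' Extract the beam midline from a mask
#'
#' One midline point per occupied image column between the upper and
#' lower beam edges. Columns inside the clamp region and columns whose
#' foreground run is interrupted (holes) are skipped. When the grayscale
#' frame is supplied, edges are refined to subpixel precision by linear
#' interpolation of the threshold crossing.
#'
#' @param mask logical mask from [binarize()].
#' @param config a [tracking_config()].
#' @param frame optional grayscale frame for subpixel refinement.
#' @return data.frame with `col` (image column), `x` (m, from the clamp
#'   edge) and `y` (m, image row scale, downward positive).
#' @export
extract_midline <- function(mask, config, frame = NULL) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  gray <- if (is.null(frame)) matrix(0, 0, 0) else frame
  thr <- attr(mask, "threshold")
  if (is.null(thr)) thr <- 0.5
  e <- column_edges(mask, gray, thr)
  cols <- seq_len(ncol(mask))
  keep <- e[, 4] == 1 & cols > config$clamp_px
  if (sum(keep) < config$min_cols)
    stop("insufficient beam extent: only ", sum(keep),
         " usable columns", call. = FALSE)
  data.frame(col = cols[keep],
             x = (cols[keep] - config$clamp_px - 0.5) / config$px,
             y = e[keep, 3] / config$px)
}

#' Fit a quadratic to midline points
#'
#' Least-squares fit of `w(x) = a0 + a1 x + a2 x^2` in physical units.
#' The curvature estimate is `2 a2` (small-slope convention); the tip is
#' the polynomial evaluated at the furthest detected column (no
#' extrapolation to the nominal free length).
#'
#' @param points data.frame from [extract_midline()] (`x`, `y` in m).
#' @param config a [tracking_config()].
#' @return A `frame_fit` list: `coef` (a0, a1, a2), `curvature` (1/m),
#'   `tip` (`x`, `y` in m), `rms` (m), `ok` quality flag, `tip_fit_diff`
#'   (m, fitted minus measured midline at the tip column).
#' @export
fit_parabola <- function(points, config) {
  if (nrow(points) < config$min_cols)
    stop("need at least ", config$min_cols, " midline points", call. = FALSE)
  if (!is.null(config$L0) &&
      diff(range(points$x)) < config$L0 / 2)
    stop("detected beam spans less than half the free length", call. = FALSE)
  x_tip <- max(points$x)
  use <- points$x <= config$fit_window * x_tip + 1e-12
  pts <- points[use, , drop = FALSE]
  if (length(unique(pts$x)) < 3L)
    stop("ill-conditioned fit: fewer than 3 distinct x positions",
         call. = FALSE)
  # centred/scaled design for conditioning; coefficients mapped back
  xs <- pts$x / x_tip
  X <- cbind(1, xs, xs^2)
  fit <- stats::.lm.fit(X, pts$y)
  cf <- fit$coefficients
  coef <- c(a0 = cf[1], a1 = cf[2] / x_tip, a2 = cf[3] / x_tip^2)
  rms <- sqrt(mean(fit$residuals^2))
  tip_y <- coef[1] + coef[2] * x_tip + coef[3] * x_tip^2
  mid_tip <- points$y[which.max(points$x)]
  list(coef = coef,
       curvature = 2 * unname(coef[3]),
       tip = c(x = x_tip, y = unname(tip_y)),
       rms = rms,
       ok = rms * config$px <= config$qual_rms_px,
       tip_fit_diff = unname(tip_y - mid_tip))
}

resolve_frames <- function(frames) {
  if (is.function(frames)) {
    n <- attr(frames, "n_frames")
    if (is.null(n)) stop("frame provider needs an 'n_frames' attribute",
                         call. = FALSE)
    list(n = n, get = frames)
  } else if (is.character(frames)) {
    files <- sort(list.files(frames, pattern = "\\.pgm$", full.names = TRUE))
    if (!length(files)) stop("no .pgm frames in ", frames, call. = FALSE)
    list(n = length(files), get = function(i) read_pgm(files[i]))
  } else if (is.list(frames)) {
    list(n = length(frames), get = function(i) frames[[i]])
  } else if (is.array(frames) && length(dim(frames)) == 3L) {
    list(n = dim(frames)[3], get = function(i) frames[, , i])
  } else stop("frames must be a list, 3D array, directory or provider",
              call. = FALSE)
}

#' Track a side-view video into a deflection trace
#'
#' Per frame: binarize, keep the beam component, extract the subpixel
#' midline, fit a quadratic; the tip deflection is the fitted tip row
#' minus the reference tip row (downward positive). Frames where tracking
#' fails are tolerated up to 5% (linearly interpolated and flagged);
#' beyond that an error lists the lost frames.
#'
#' @param frames a list of matrices, a 3D array (`nrow x ncol x n`), a
#'   directory of `.pgm` frames, or a provider function with attribute
#'   `n_frames`.
#' @param config a [tracking_config()].
#' @param beam a [beam_spec()] (owns the curvature convention of the
#'   output trace).
#' @param fps frame rate (frames per second).
#' @param reference frame index/indices defining `W = 0`; the median tip
#'   row over these frames is the reference.
#' @return A [deflection_trace()] (provenance `"tracked"`) with extra
#'   columns `curvature_fit` (2 a2 from the per-frame fit), `rms` and
#'   `ok`, and attributes `alpha` (per-frame tip angle, rad),
#'   `alpha_r2` (R^2 of the alpha-vs-W linearity diagnostic) and
#'   `lost` (interpolated frame indices).
#' @export
track <- function(frames, config, beam, fps, reference = 1L) {
  src <- resolve_frames(frames)
  n <- src$n
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  tip_y <- rep(NA_real_, n)
  tip_x <- rep(NA_real_, n)
  curv <- rep(NA_real_, n)
  rms <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      fr <- src$get(i)
      mask <- binarize(fr, config)
      pts <- extract_midline(mask, config, frame = fr)
      fit_parabola(pts, config)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      tip_y[i] <- res$tip["y"]; tip_x[i] <- res$tip["x"]
      curv[i] <- res$curvature; rms[i] <- res$rms; ok[i] <- res$ok
    }
  }
  lost <- which(is.na(tip_y))
  if (length(lost) > 0.05 * n)
    stop("tracking lost on ", length(lost), "/", n, " frames (indices ",
         paste(utils::head(lost, 10), collapse = ", "),
         if (length(lost) > 10) ", ..." else "", ")", call. = FALSE)
  if (length(lost)) {
    good <- which(!is.na(tip_y))
    tip_y[lost] <- stats::approx(good, tip_y[good], xout = lost,
                                 rule = 2)$y
    curv[lost] <- stats::approx(good, curv[good], xout = lost, rule = 2)$y
    tip_x[lost] <- stats::approx(good, tip_x[good], xout = lost, rule = 2)$y
  }
  ref_y <- stats::median(tip_y[reference])
  ref_c <- stats::median(curv[reference])
  W <- tip_y - ref_y
  tr <- deflection_trace((seq_len(n) - 1L) / fps, W, beam,
                         provenance = "tracked",
                         sg_window = config$sg_window, check = FALSE)
  tr$curvature_fit <- curv - ref_c
  tr$rms <- rms
  tr$ok <- ok
  alpha <- atan2(W, tip_x)
  r2 <- if (stats::sd(W) > 0) stats::cor(alpha, W)^2 else NA_real_
  attr(tr, "alpha") <- alpha
  attr(tr, "alpha_r2") <- r2
  attr(tr, "lost") <- lost
  tr
}
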