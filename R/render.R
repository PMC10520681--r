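#' Rendering configuration for synthetic side-view videos
#'
#' Frames are grayscale silhouettes (foreground 1, background 0) of the
#' film seen from the side: a static clamped stretch on the left and the
#' free cantilever bending along `w(x) = W x^2 / L0^2`, drawn `h` thick
#' with 1-px linear anti-aliasing on all edges.
#'
#' @param beam a [beam_spec()]; sets the drawn length and thickness.
#' @param px_per_mm pixel scale (default 20, i.e. 50 µm/px).
#' @param clamp_mm visible clamped film length left of the clamp edge (mm).
#' @param w_range deflection range (m, `c(min, max)`) the frame must
#'   accommodate; default +/- 0.3 `L0` (the model's hard validity limit).
#' @param noise_sd per-pixel Gaussian intensity noise (fraction of the
#'   0..1 range) added by [render_video()].
#' @return A `render_config` list, including the derived frame size and
#'   the row `y0` of the undeflected midline.
#' @export
render_config <- function(beam, px_per_mm = 20, clamp_mm = 5,
                          w_range = NULL, noise_sd = 0.02) {
  stopifnot_beam(beam)
  if (px_per_mm <= 0) stop("px_per_mm must be > 0", call. = FALSE)
  px <- px_per_mm * 1e3                      # px per metre
  if (is.null(w_range))
    w_range <- c(-.w_hard_limit, .w_hard_limit) * beam$L0
  h_px <- beam$h * px
  pad <- 3
  ncol <- ceiling(clamp_mm * px_per_mm + beam$L0 * px) + pad
  # half-integer midline row: the undeflected film then covers whole
  # pixel rows exactly, avoiding rasterization bias at rest
  y0 <- ceiling(-w_range[1] * px + h_px / 2 + pad + 1) + 0.5
  nrow <- ceiling(y0 + w_range[2] * px + h_px / 2 + pad)
  list(px_per_mm = px_per_mm, px = px, clamp_px = clamp_mm * px_per_mm,
       nrow = as.integer(nrow), ncol = as.integer(ncol), y0 = y0,
       h_px = h_px, noise_sd = noise_sd, beam = beam)
}

#' Render one silhouette frame
#'
#' @param W tip deflection (m, downward positive = increasing row).
#' @param rc a [render_config()].
#' @return A `nrow x ncol` numeric matrix in `[0, 1]` (noiseless).
#' @export
render_frame <- function(W, rc) {
  beam <- rc$beam
  j <- seq_len(rc$ncol)
  x <- (j - 0.5 - rc$clamp_px) / rc$px       # metres from the clamp edge
  yc <- rep(rc$y0, rc$ncol)
  free <- x > 0
  yc[free] <- rc$y0 + W * pmin(x[free], beam$L0)^2 / beam$L0^2 * rc$px
  # anti-aliased coverage along x at the free tip
  cov <- pmin(1, pmax(0, 0.5 + (beam$L0 - x) * rc$px))
  ymin <- min(yc) - rc$h_px / 2; ymax <- max(yc) + rc$h_px / 2
  if (ymin < 1 || ymax > rc$nrow)
    stop("beam out of frame: enlarge w_range in render_config()",
         call. = FALSE)
  i <- seq_len(rc$nrow)
  M <- pmin(1, pmax(0, rc$h_px / 2 + 0.5 - abs(outer(i, yc, `-`))))
  matrix(M * rep(cov, each = rc$nrow), rc$nrow, rc$ncol)
}

#' Render a deflection sequence as a frame stack
#'
#' Adds seeded per-pixel Gaussian intensity noise (clipped to `[0, 1]`).
#' Each frame's noise is derived from `(seed, frame index)`, so frames are
#' reproducible independently of rendering order; the same seed yields a
#' byte-identical stack.
#'
#' @param W tip-deflection series (m), one value per frame.
#' @param rc a [render_config()].
#' @param seed integer noise seed; `NULL` for noiseless frames.
#' @return A list of frame matrices.
#' @export
render_video <- function(W, rc, seed = NULL) {
  lapply(seq_along(W), function(i) {
    f <- render_frame(W[i], rc)
    if (!is.null(seed) && rc$noise_sd > 0)
      f <- with_local_seed(seed + i, {
        f[] <- pmin(1, pmax(0, f + stats::rnorm(length(f), 0, rc$noise_sd)))
        f
      })
    f
  })
}

# Closure-based provider for streamed render -> track pipelines: avoids
# materializing long clips in memory.
frame_provider <- function(W, rc, seed = NULL) {
  force(W); force(rc); force(seed)
  structure(function(i) {
    f <- render_frame(W[i], rc)
    if (!is.null(seed) && rc$noise_sd > 0)
      f <- with_local_seed(seed + i, {
        f[] <- pmin(1, pmax(0, f + stats::rnorm(length(f), 0, rc$noise_sd)))
        f
      })
    f
  }, n_frames = length(W))
}

#' Write / read a grayscale frame as PGM
#'
#' Portable graymap (Netpbm) IO in base R: `P5` (binary, default) or `P2`
#' (ASCII). Used to serialize synthetic frame stacks without an external
#' image library.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path.
#' @param ascii write ASCII `P2` instead of binary `P5`.
#' @param maxval maximum gray value (<= 255).
#' @return `write_pgm`: `path` invisibly; `read_pgm`: a numeric matrix in
#'   `[0, 1]`.
#' @export
write_pgm <- function(img, path, ascii = FALSE, maxval = 255L) {
  v <- img
  v[] <- round(pmin(1, pmax(0, img)) * maxval)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
               con)
    write(t(v), file = con, ncolumns = ncol(img))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(img), nrow(img)), as.character(maxval)),
               con)
    writeBin(as.raw(as.integer(t(v))), con)
  }
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  ws <- as.raw(c(0x20, 0x09, 0x0a, 0x0d))
  hash <- as.raw(0x23); nl <- as.raw(0x0a)
  pos <- 1L; tok <- character(0)
  # tokenize the header byte-wise (a line-based reader would buffer past
  # the header and swallow binary payload)
  while (length(tok) < 4L && pos <= length(bytes)) {
    while (pos <= length(bytes) && bytes[pos] %in% ws) pos <- pos + 1L
    if (bytes[pos] == hash) {
      while (pos <= length(bytes) && bytes[pos] != nl) pos <- pos + 1L
      next
    }
    start <- pos
    while (pos <= length(bytes) && !(bytes[pos] %in% ws)) pos <- pos + 1L
    tok <- c(tok, rawToChar(bytes[start:(pos - 1L)]))
  }
  magic <- tok[1]
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  pos <- pos + 1L                     # single whitespace after maxval
  if (magic == "P5") {
    v <- as.integer(bytes[pos:(pos + nr * nc - 1L)])
  } else if (magic == "P2") {
    v <- scan(text = rawToChar(bytes[pos:length(bytes)]),
              what = integer(), n = nr * nc, quiet = TRUE)
  } else stop("not a PGM (P2/P5) file: ", path, call. = FALSE)
  matrix(v / maxval, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write / read a frame stack as a numbered PGM sequence
#'
#' @param frames list of frame matrices.
#' @param dir output directory (created if needed).
#' @param ... passed to [write_pgm()].
#' @return `write_frames`: the directory invisibly; `read_frames`: a list
#'   of matrices, in filename order.
#' @export
write_frames <- function(frames, dir, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(frames))
    write_pgm(frames[[i]], file.path(dir, sprintf("frame_%06d.pgm", i)), ...)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (!length(files)) stop("no .pgm frames in ", dir, call. = FALSE)
  lapply(files, read_pgm)
}
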