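#' Radiograph container
#'
#' A 2-D intensity array together with its projection view and units:
#' `"HU"` for Hounsfield-valued arrays, `"gray8"` after window
#' normalization to `[0, 255]`.
#'
#' @param pixels numeric matrix; finite, nonempty (NAs allowed only to mark
#'   missing pixels for [mean_fill()]).
#' @param view `"frontal"` or `"lateral"`.
#' @param units `"HU"` or `"gray8"`.
#' @return Object of class `radiograph`.
#' @export
radiograph <- function(pixels, view = c("frontal", "lateral"),
                       units = c("HU", "gray8")) {
  view <- match.arg(view); units <- match.arg(units)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("pixels must be a nonempty matrix", call. = FALSE)
  if (any(is.infinite(pixels)))
    stop("pixels must be finite", call. = FALSE)
  structure(list(pixels = pixels, view = view, units = units),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph %s %s %dx%d range [%g, %g]>\n", x$view, x$units,
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels, na.rm = TRUE), max(x$pixels, na.rm = TRUE)))
  invisible(x)
}

as_pixels <- function(img) if (inherits(img, "radiograph")) img$pixels else img

#' Hounsfield-unit window normalization
#'
#' Linearly maps HU values inside the window
#' `[level - width/2, level + width/2]` to `[0, 255]`, clipping outside it,
#' and rounds half away from zero to integers. The chest-radiograph default
#' window (width 1500 HU, level -500 HU) maps -1250 HU to 0 and 250 HU
#' to 255, enhancing lung-field contrast.
#'
#' @param img a `radiograph` in HU units (or a bare HU matrix/vector).
#' @param width window width in HU, `> 0`.
#' @param level window level (center) in HU.
#' @return A `radiograph` with `units = "gray8"` (or a bare array if a bare
#'   array was supplied), values in `{0, ..., 255}`.
#' @export
#' @examples
#' window_normalize(c(-2000, -1250, -500, 250, 1000))
window_normalize <- function(img, width = 1500, level = -500) {
  if (width <= 0) stop("window width must be > 0, got ", width, call. = FALSE)
  if (inherits(img, "radiograph") && img$units != "HU")
    stop("window_normalize expects HU-valued input, got units '",
         img$units, "'", call. = FALSE)
  v <- if (inherits(img, "radiograph")) img$pixels else img
  lo <- level - width / 2
  t <- pmin(pmax((v - lo) / width, 0), 1)
  out <- round_half_away(255 * t)
  if (inherits(img, "radiograph")) radiograph(out, img$view, "gray8") else out
}

#' Bilinear image resizing
#'
#' Resizes a 2-D array to `side x side` with bilinear interpolation
#' (corner-aligned sample grid). Output values are convex combinations of
#' input values, hence bounded by the source min/max.
#'
#' @param img a `radiograph` or numeric matrix with at least 2 rows/cols.
#' @param side target side length in pixels.
#' @return Resized `radiograph` (or matrix).
#' @export
resize_bilinear <- function(img, side = 224L) {
  P <- as_pixels(img)
  side <- as.integer(side)
  if (nrow(P) < 2L || ncol(P) < 2L)
    stop("source image must be at least 2x2, got ",
         nrow(P), "x", ncol(P), call. = FALSE)
  if (side < 1L) stop("target side must be >= 1", call. = FALSE)
  map_axis <- function(n_src, n_dst) {
    # corner-aligned: destination i (1-based) samples source coordinate
    if (n_dst == 1L) return(list(i0 = 1L, i1 = 1L, w = 0))
    pos <- (seq_len(n_dst) - 1) * (n_src - 1) / (n_dst - 1) + 1
    i0 <- pmin(floor(pos), n_src - 1)
    list(i0 = as.integer(i0), i1 = as.integer(i0 + 1), w = pos - i0)
  }
  ry <- map_axis(nrow(P), side)
  rx <- map_axis(ncol(P), side)
  A <- P[ry$i0, rx$i0, drop = FALSE]; B <- P[ry$i0, rx$i1, drop = FALSE]
  C <- P[ry$i1, rx$i0, drop = FALSE]; D <- P[ry$i1, rx$i1, drop = FALSE]
  wy <- matrix(ry$w, side, side); wx <- matrix(rx$w, side, side, byrow = TRUE)
  out <- (1 - wy) * ((1 - wx) * A + wx * B) + wy * ((1 - wx) * C + wx * D)
  if (inherits(img, "radiograph")) radiograph(out, img$view, img$units) else out
}

#' Split an image into non-overlapping square patches
#'
#' Divides an `L x L` image into `(L/s)^2` patches of side `s`, ordered
#' row-major over the patch grid; each patch is flattened row-major into a
#' length `s^2` vector. [unpatchify()] reconstructs the image bit-exactly.
#'
#' @param img `radiograph` or numeric matrix with sides divisible by `s`.
#' @param patch_side patch side length `s` in pixels (default 16).
#' @return Object of class `patch_grid` with fields `patches`
#'   (`P x s^2` matrix), `grid_shape` and `patch_side`.
#' @export
#' @examples
#' nrow(patchify(matrix(0, 224, 224))$patches)  # 196
patchify <- function(img, patch_side = 16L) {
  P <- as_pixels(img)
  s <- as.integer(patch_side)
  nr <- nrow(P); nc <- ncol(P)
  if (nr %% s != 0L || nc %% s != 0L)
    stop(sprintf("image %dx%d not divisible by patch side %d", nr, nc, s),
         call. = FALSE)
  gr <- nr %/% s; gc <- nc %/% s
  # row index within patch varies fastest in the flattened patch (row-major)
  out <- matrix(0, gr * gc, s * s)
  for (i in seq_len(gr)) {
    rows <- (i - 1L) * s + seq_len(s)
    for (j in seq_len(gc)) {
      cols <- (j - 1L) * s + seq_len(s)
      out[(i - 1L) * gc + j, ] <- as.vector(t(P[rows, cols]))
    }
  }
  structure(list(patches = out, grid_shape = c(gr, gc), patch_side = s),
            class = "patch_grid")
}

#' Reassemble an image from its patch grid
#'
#' @param grid a `patch_grid` from [patchify()].
#' @return Numeric matrix of the original image size.
#' @export
unpatchify <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  s <- grid$patch_side
  gr <- grid$grid_shape[1]; gc <- grid$grid_shape[2]
  out <- matrix(0, gr * s, gc * s)
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    out[(i - 1L) * s + seq_len(s), (j - 1L) * s + seq_len(s)] <-
      matrix(grid$patches[(i - 1L) * gc + j, ], s, s, byrow = TRUE)
  }
  out
}

#' Sample an exact-count binary patch mask
#'
#' Places exactly `floor(rate * P)` zeros (masked patches) uniformly at
#' random without replacement; the remaining `P - floor(rate * P)` entries
#' are ones (retained). Deterministic for a fixed `(P, rate, seed)`; the
#' caller's RNG state is untouched. At the default 75% rate a 196-patch
#' view retains exactly 49 patches.
#'
#' @param P number of patches.
#' @param rate mask fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return Object of class `patch_mask` with fields `bits` (length-`P`
#'   0/1 integer vector), `rate`, `seed`.
#' @export
sample_mask <- function(P, rate = 0.75, seed = 1L) {
  P <- as.integer(P)
  if (rate < 0 || rate >= 1)
    stop("mask rate must lie in [0, 1), got ", rate, call. = FALSE)
  n_masked <- floor(rate * P)
  bits <- rep(1L, P)
  if (n_masked > 0) {
    idx <- with_seed(seed, sample.int(P, n_masked))
    bits[idx] <- 0L
  }
  structure(list(bits = bits, rate = rate, seed = as.integer(seed)),
            class = "patch_mask")
}

#' Deterministic per-record, per-view, per-epoch mask seed
#'
#' Masks are resampled every epoch; this derives the seed from the base
#' seed, the record identifier, the view and the epoch so runs are
#' reproducible end to end.
#'
#' @param base_seed integer experiment seed.
#' @param record_id record identifier (string or integer).
#' @param view `"frontal"` or `"lateral"`.
#' @param epoch epoch counter.
#' @return 31-bit integer seed.
#' @export
mask_seed_for <- function(base_seed, record_id, view, epoch = 1L) {
  mix_seed(base_seed, record_id, view, epoch)
}

#' Select the visible (retained) patches
#'
#' @param grid a `patch_grid`.
#' @param mask a `patch_mask` of matching length.
#' @return List with `visible_patches` (`K x s^2` matrix) and
#'   `visible_indices` (strictly increasing 1-based indices, length
#'   `K = sum(mask$bits)`).
#' @export
apply_mask <- function(grid, mask) {
  stopifnot(inherits(grid, "patch_grid"), inherits(mask, "patch_mask"))
  P <- nrow(grid$patches)
  if (length(mask$bits) != P)
    stop_shape("apply_mask bits", P, length(mask$bits))
  idx <- which(mask$bits == 1L)
  list(visible_patches = grid$patches[idx, , drop = FALSE],
       visible_indices = idx)
}

#' Fill missing pixels by iterated 4-neighbour means
#'
#' Replaces `NA` pixels with the mean of their valid 4-neighbours,
#' iterating until no holes remain (holes with no valid neighbour are
#' filled on a later sweep as their neighbours fill in).
#'
#' @param pixels numeric matrix with `NA`s marking missing pixels.
#' @param max_iter safety cap on sweeps.
#' @return Matrix with no `NA`s.
#' @export
mean_fill <- function(pixels, max_iter = 1000L) {
  P <- pixels
  nr <- nrow(P); nc <- ncol(P)
  if (all(!is.na(P))) return(P)
  if (all(is.na(P))) stop("image is entirely missing", call. = FALSE)
  for (it in seq_len(max_iter)) {
    holes <- which(is.na(P), arr.ind = TRUE)
    if (nrow(holes) == 0L) return(P)
    newvals <- rep(NA_real_, nrow(holes))
    for (k in seq_len(nrow(holes))) {
      i <- holes[k, 1]; j <- holes[k, 2]
      nb <- c(if (i > 1) P[i - 1, j], if (i < nr) P[i + 1, j],
              if (j > 1) P[i, j - 1], if (j < nc) P[i, j + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb)) newvals[k] <- mean(nb)
    }
    P[holes] <- newvals
  }
  if (anyNA(P)) stop("mean_fill failed to converge", call. = FALSE)
  P
}

#' Read / write plain (ASCII) PGM grayscale images
#'
#' Minimal text-based image IO used by the command-line tools and tests
#' (P2 "plain PGM": a portable, human-readable grayscale format).
#'
#' @param path file path.
#' @return `read_pgm`: numeric matrix. `write_pgm`: the path, invisibly.
#' @name pgm_io
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!startsWith(trimws(txt), "#")]
  toks <- scan(text = paste(txt, collapse = " "), what = character(),
               quiet = TRUE)
  if (toks[1] != "P2") stop("not a plain (P2) PGM file: ", path, call. = FALSE)
  vals <- as.numeric(toks[-1])
  nc <- vals[1]; nr <- vals[2]
  px <- vals[-(1:3)]
  if (length(px) != nr * nc) stop("corrupt PGM payload: ", path, call. = FALSE)
  matrix(px, nr, nc, byrow = TRUE)
}

#' @param pixels numeric matrix in `[0, maxval]`.
#' @param maxval maximum gray value written to the header.
#' @rdname pgm_io
#' @export
write_pgm <- function(pixels, path, maxval = 255L) {
  pixels <- as_pixels(pixels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), as.character(maxval)),
             con)
  apply_rows <- apply(round_half_away(pixels), 1, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}
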