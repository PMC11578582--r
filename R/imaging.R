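## Imaging chain: background subtraction -> hot-pixel removal ->
## Richardson-Lucy deconvolution with a peak-based iteration selector ->
## masked density measurement. Order matters and is enforced by run_pipeline().

#' Normalized 2-D Gaussian point-spread function
#'
#' @param sigma_px Gaussian sigma in pixels (> 0).
#' @param size odd kernel side length; default covers +-4 sigma.
#' @return a `size x size` matrix summing to exactly 1.
#' @export
gaussian_psf <- function(sigma_px, size = NULL) {
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  if (is.null(size)) size <- 2L * ceiling(4 * sigma_px) + 1L
  size <- as.integer(size)
  if (size %% 2L == 0L) stop("PSF size must be odd")
  r <- (size - 1L) / 2L
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

## Pad a matrix by `pr` rows / `pc` cols using the given mode, then either
## mirror-reflect the border or replicate the edge. Pad width must not exceed
## the image size.
pad_matrix <- function(x, pr, pc, mode = c("reflect", "replicate")) {
  mode <- match.arg(mode)
  nr <- nrow(x); nc <- ncol(x)
  if (pr >= nr || pc >= nc)
    stop("padding exceeds image size; use a smaller kernel or larger image")
  ri <- if (mode == "reflect") c(rev(seq_len(pr) + 1L), seq_len(nr),
                                 nr - seq_len(pr))
        else c(rep(1L, pr), seq_len(nr), rep(nr, pr))
  ci <- if (mode == "reflect") c(rev(seq_len(pc) + 1L), seq_len(nc),
                                 nc - seq_len(pc))
        else c(rep(1L, pc), seq_len(nc), rep(nc, pc))
  x[ri, ci, drop = FALSE]
}

#' 2-D convolution with reflective (mirror) boundary handling
#'
#' Linear convolution of an image with an odd-sized kernel, computed by
#' mirror-padding the image by the kernel radius and running a circular FFT
#' convolution on the padded frame. Inside the frame this equals direct
#' convolution with reflected boundaries.
#'
#' @param image numeric matrix.
#' @param kernel odd-sized numeric matrix.
#' @return matrix of the same shape as `image`.
#' @export
conv2_reflect <- function(image, kernel) {
  kr <- dim(kernel)
  if (any(kr %% 2L == 0L)) stop("kernel dimensions must be odd")
  pr <- (kr[1] - 1L) %/% 2L; pc <- (kr[2] - 1L) %/% 2L
  pad <- pad_matrix(image, pr, pc, "reflect")
  np <- dim(pad)
  kbig <- matrix(0, np[1], np[2])
  kbig[seq_len(kr[1]), seq_len(kr[2])] <- kernel
  # center the kernel at (1,1) for circular convolution
  kbig <- kbig[c((pr + 1):np[1], seq_len(pr)), c((pc + 1):np[2], seq_len(pc))]
  out <- Re(stats::fft(stats::fft(pad) * stats::fft(kbig), inverse = TRUE)) /
    length(pad)
  out[pr + seq_len(nrow(image)), pc + seq_len(ncol(image)), drop = FALSE]
}

## Offsets within a disc of the given radius (in pixel units).
disc_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

## Grey-scale erosion (min) or dilation (max) with a flat/graded structuring
## element given as offsets + heights; edge-replicated boundary.
grey_morph <- function(image, offsets, heights, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(image); nc <- ncol(image)
  pr <- max(abs(offsets$dr)); pc <- max(abs(offsets$dc))
  pad <- pad_matrix(image, pr, pc, "replicate")
  acc <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    shifted <- pad[pr + offsets$dr[k] + seq_len(nr),
                   pc + offsets$dc[k] + seq_len(nc), drop = FALSE]
    acc <- if (op == "erode") pmin(acc, shifted - heights[k])
           else pmax(acc, shifted + heights[k])
  }
  acc
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grey-scale opening of the image with
#' a ball structuring element of the given radius (the standard definition of
#' the ImageJ rolling-ball algorithm, without downscaling) and subtracts it,
#' clipping at zero. A flat image maps to all zeros; features narrower than
#' the ball are preserved.
#'
#' @param image non-negative numeric matrix.
#' @param ball_radius_px ball radius in pixels (> 0); default 20.
#' @return background-subtracted image, same shape, >= 0.
#' @export
subtract_background <- function(image, ball_radius_px = 20) {
  if (ball_radius_px <= 0) stop("ball_radius_px must be > 0")
  if (any(!is.finite(image)) || any(image < 0))
    stop("image must be finite and non-negative")
  off <- disc_offsets(ball_radius_px)
  # spherical cap: ball surface height above the tangent plane
  heights <- sqrt(pmax(ball_radius_px^2 - off$dr^2 - off$dc^2, 0))
  # the ImageJ algorithm presmooths (3x3 mean) and rolls the ball on a
  # shrunk copy (factor 4 for radii up to 30, 8 beyond); the shrink is
  # emulated here by an equivalent odd-width mean filter so the ball rides
  # on the noise mean rather than the noise minima, without resampling.
  # The estimate is subtracted from the unsmoothed image.
  shrink <- if (ball_radius_px <= 10) 1L else if (ball_radius_px <= 30) 5L
            else 9L
  sm <- conv2_reflect(image, matrix(1 / 9, 3, 3))
  if (shrink > 1L)
    sm <- conv2_reflect(sm, matrix(1 / shrink^2, shrink, shrink))
  ero <- grey_morph(sm, off, heights, "erode")
  bg <- grey_morph(ero, off, heights, "dilate")
  pmax(image - pmin(bg, image), 0)
}

#' Median-based hot-pixel removal
#'
#' Replaces any pixel deviating from the median of its local cross-shaped
#' neighborhood (radius 0.5 px: the 4-connected neighbors plus the pixel
#' itself) by more than `threshold` with that median; all other pixels are
#' untouched.
#'
#' @param image numeric matrix.
#' @param threshold intensity-difference threshold (> 0); default 1000.
#' @param radius_px neighborhood radius; values < 1 give the 4-connected
#'   cross, larger values a disc of that radius. Default 0.5.
#' @return cleaned image, same shape.
#' @export
remove_outliers <- function(image, threshold = 1000, radius_px = 0.5) {
  if (threshold <= 0) stop("threshold must be > 0")
  off <- if (radius_px < 1) data.frame(dr = c(0, -1, 1, 0, 0),
                                       dc = c(0, 0, 0, -1, 1))
         else disc_offsets(radius_px)
  nr <- nrow(image); nc <- ncol(image)
  pr <- max(abs(off$dr)); pc <- max(abs(off$dc))
  pad <- pad_matrix(image, pr, pc, "replicate")
  stack <- vapply(seq_len(nrow(off)), function(k) {
    pad[pr + off$dr[k] + seq_len(nr), pc + off$dc[k] + seq_len(nc),
        drop = FALSE]
  }, matrix(0, nr, nc))
  med <- apply(stack, c(1, 2), stats::median)
  out <- image
  bad <- abs(image - med) > threshold
  out[bad] <- med[bad]
  out
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy update with reflective boundary
#' handling: `est <- est * conv(obs / conv(est, psf), flip(psf))`, starting
#' from the observed image. Output is non-negative; total flux is conserved
#' on interior-supported scenes. With a delta-function PSF the output equals
#' the input for any number of iterations.
#'
#' @param image non-negative numeric matrix.
#' @param psf odd-sized kernel summing to 1 (tolerance 1e-6).
#' @param n_iterations number of RL iterations (>= 1).
#' @return deconvolved image, same shape.
#' @export
lucy_richardson <- function(image, psf, n_iterations) {
  est <- rl_init(image, psf)
  for (i in seq_len(n_iterations)) est <- rl_step(est, image, psf)
  est
}

rl_init <- function(image, psf) {
  if (abs(sum(psf) - 1) > 1e-6) stop("PSF must sum to 1")
  if (any(!is.finite(image)))
    stop("image must be finite and non-negative")
  # FFT-based convolution upstream can leave round-off negatives ~ -1e-14
  if (min(image) < -1e-8 * max(abs(image), 1))
    stop("image must be finite and non-negative")
  pmax(image, 0)
}

rl_step <- function(est, obs, psf) {
  eps <- .Machine$double.eps^0.5
  denom <- conv2_reflect(est, psf)
  ratio <- obs / pmax(denom, eps)
  est * conv2_reflect(ratio, psf[rev(seq_len(nrow(psf))),
                                 rev(seq_len(ncol(psf))), drop = FALSE])
}

#' Choose the Richardson-Lucy iteration count from the within-mask peak
#'
#' Runs RL up to `max_iter` iterations, recording the sum of the pixels
#' inside the mask after each iteration. Under-iteration leaves scattered
#' light outside the cells; over-iteration produces ringing, in which bright
#' background pixels siphon intensity away from true emitters inside the
#' cells. The within-mask sum therefore rises and then falls, and the
#' iteration at its peak (earliest, on ties) balances the two effects.
#'
#' @param image corrected (background-subtracted, outlier-free) image.
#' @param psf normalized PSF.
#' @param mask logical matrix: the cell (or union-of-cells) mask.
#' @param max_iter iteration cap; default 200.
#' @return a `deconvolution_trace`: list with `masked_sums` (one per
#'   iteration run), `selected` (iteration index), `image` (estimate at the
#'   selected iteration), `peak_bracketed` (FALSE if the series was still
#'   rising at `max_iter`, with a warning).
#' @export
select_optimal_iterations <- function(image, psf, mask, max_iter = 200L) {
  if (!is.logical(mask) || !all(dim(mask) == dim(image)))
    stop("mask must be a logical matrix matching the image")
  if (!any(mask)) stop("mask is empty")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  est <- rl_init(image, psf)
  sums <- numeric(max_iter)
  best <- -Inf; best_iter <- 1L; best_img <- NULL
  for (i in seq_len(max_iter)) {
    est <- rl_step(est, image, psf)
    sums[i] <- sum(est[mask])
    if (sums[i] > best) { best <- sums[i]; best_iter <- i; best_img <- est }
  }
  bracketed <- !(best_iter == max_iter && all(diff(sums) > 0))
  if (!bracketed)
    warning("masked sum still increasing at max_iter; peak not bracketed")
  structure(list(masked_sums = sums, selected = best_iter,
                 image = best_img, peak_bracketed = bracketed),
            class = "deconvolution_trace")
}

#' Mean fluorescence density over a region
#'
#' The region's pixel values are summed and divided by the region area,
#' giving the average pixel value (A.U. per pixel).
#'
#' @param image numeric matrix.
#' @param region_mask logical matrix, same shape, with at least one pixel.
#' @return scalar mean density.
#' @export
measure_density <- function(image, region_mask) {
  if (!all(dim(region_mask) == dim(image)))
    stop("region mask shape must match image")
  if (!any(region_mask)) stop("empty region")
  mean(image[region_mask])
}
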