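# Independent oracles, kept deliberately naive: direct loops, no shared code
# with the implementation under test.

# grey-scale erosion/dilation by double loop, edge-replicated boundary
brute_morph <- function(image, offsets, heights, op) {
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    vals <- numeric(nrow(offsets))
    for (k in seq_len(nrow(offsets))) {
      rr <- min(max(r + offsets$dr[k], 1L), nr)
      ck <- min(max(cc + offsets$dc[k], 1L), nc)
      vals[k] <- if (op == "erode") image[rr, ck] - heights[k]
                 else image[rr, ck] + heights[k]
    }
    out[r, cc] <- if (op == "erode") min(vals) else max(vals)
  }
  out
}

# textbook Richardson-Lucy with direct spatial convolution, mirror boundary
rl_reference <- function(image, psf, n_iter) {
  conv_direct <- function(img, k) {
    kr <- (nrow(k) - 1L) / 2L; kc <- (ncol(k) - 1L) / 2L
    nr <- nrow(img); nc <- ncol(img)
    mirror <- function(i, n) { # reflect without repeating the edge pixel
      i <- ifelse(i < 1L, 2L - i, i)
      ifelse(i > n, 2L * n - i, i)
    }
    out <- matrix(0, nr, nc)
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      acc <- 0
      for (dr in -kr:kr) for (dc in -kc:kc) {
        acc <- acc + k[kr + dr + 1L, kc + dc + 1L] *
          img[mirror(r - dr, nr), mirror(cc - dc, nc)]
      }
      out[r, cc] <- acc
    }
    out
  }
  flip <- function(k) k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))),
                        drop = FALSE]
  est <- image
  eps <- .Machine$double.eps^0.5
  for (i in seq_len(n_iter)) {
    denom <- conv_direct(est, psf)
    est <- est * conv_direct(image / pmax(denom, eps), flip(psf))
  }
  est
}

# antisymmetric normalized pairs from raw draws
rand_norm_pairs <- function(n, lo = 0.9, hi = 1.4) {
  pair_normalize(runif(n, lo, hi), runif(n, lo, hi))
}

# variance decomposition by definition-level enumeration (population moments)
brute_decomposition <- function(old_raw, new_raw) {
  n <- length(old_raw)
  zo <- zn <- numeric(n)
  for (i in seq_len(n)) {
    u <- (old_raw[i] + new_raw[i]) / 2
    zo[i] <- (old_raw[i] - u) / u
    zn[i] <- (new_raw[i] - u) / u
  }
  pooled <- c(zo, zn)
  pv <- function(x) sum((x - mean(x))^2) / length(x)
  list(D = mean(zn) - mean(zo), V_T = pv(pooled),
       V_old = pv(zo), V_new = pv(zn))
}
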