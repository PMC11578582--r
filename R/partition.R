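## Spatial partitioning of a rod cell along its long axis into
## polarity-labeled halves (new-pole half, old-pole half) or quartiles
## (NP, L2, L3, OP, ordered from the new pole).

## Medial axis of a rod-shaped mask as an arc-length-parameterized polyline:
## pixels are projected onto the principal axis, binned, and the mean
## perpendicular offset per bin traces the ridge. Robust for straight and
## gently curved rods; no thinning needed.
mask_centerline <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 2L) stop("degenerate mask")
  xy <- cbind(pix[, 2], pix[, 1])  # (col, row)
  ctr <- colMeans(xy)
  xc <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  ax <- ev$vectors[, 1]            # long axis
  pe <- ev$vectors[, 2]
  s <- xc %*% ax
  t <- xc %*% pe
  if (max(s) - min(s) < 1e-9) stop("degenerate centerline")
  nb <- max(2L, min(64L, round((max(s) - min(s)))))
  br <- seq(min(s) - 1e-9, max(s) + 1e-9, length.out = nb + 1L)
  bi <- findInterval(s, br, rightmost.closed = TRUE)
  keep <- sort(unique(bi))
  mid_s <- vapply(keep, function(k) mean(s[bi == k]), 0)
  mid_t <- vapply(keep, function(k) mean(t[bi == k]), 0)
  # extend to the pole tips: bin centers stop half a bin short of the
  # extreme pixel projections, which would shift every quartile boundary
  if (mid_s[1] > min(s))
    { mid_s <- c(min(s), mid_s); mid_t <- c(mid_t[1], mid_t) }
  if (mid_s[length(mid_s)] < max(s))
    { mid_s <- c(mid_s, max(s)); mid_t <- c(mid_t, mid_t[length(mid_t)]) }
  pts <- cbind(mid_s, mid_t) %*% rbind(ax, pe)
  pts <- sweep(pts, 2, ctr, "+")
  seg <- sqrt(rowSums(diff(pts)^2))
  list(points = pts,                       # (col, row) coordinates
       arclen = c(0, cumsum(seg)),
       length = sum(seg))
}

## Arc-length position of each mask pixel: project onto nearest centerline
## segment.
pixel_arclength <- function(mask, cl) {
  pix <- which(mask, arr.ind = TRUE)
  xy <- cbind(pix[, 2], pix[, 1])
  p <- cl$points
  nseg <- nrow(p) - 1L
  best_s <- rep(Inf, nrow(xy))
  best_d <- rep(Inf, nrow(xy))
  for (k in seq_len(nseg)) {
    a <- p[k, ]; b <- p[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tproj <- ((xy[, 1] - a[1]) * ab[1] + (xy[, 2] - a[2]) * ab[2]) /
      max(len2, 1e-12)
    tproj <- pmin(pmax(tproj, 0), 1)
    dx <- xy[, 1] - (a[1] + tproj * ab[1])
    dy <- xy[, 2] - (a[2] + tproj * ab[2])
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d
    best_d[upd] <- d2[upd]
    best_s[upd] <- cl$arclen[k] + tproj[upd] * sqrt(len2)
  }
  list(pix = pix, s = best_s)
}

#' Split a cell mask into polarity-ordered halves or quartiles
#'
#' Computes the cell's medial axis, projects every mask pixel onto it, and
#' assigns pixels to `n_parts` partitions by equal arc-length fractions.
#' Partitions are returned ordered from the new pole (so for quartiles the
#' order is NP, L2, L3, OP). A pixel projecting exactly onto an interior
#' boundary goes to the partition nearer the old pole.
#'
#' @param mask logical matrix, one connected rod-shaped cell.
#' @param new_pole_end `c(row, col)` of the centerline endpoint at the new
#'   pole (nearest endpoint is used).
#' @param n_parts 2 (halves) or 4 (quartiles).
#' @return list of `n_parts` logical masks: disjoint, union equals `mask`,
#'   first element adjacent to the new pole.
#' @export
split_cell <- function(mask, new_pole_end, n_parts = 4L) {
  n_parts <- as.integer(n_parts)
  if (!n_parts %in% c(2L, 4L)) stop("n_parts must be 2 or 4")
  cl <- mask_centerline(mask)
  pa <- pixel_arclength(mask, cl)
  # orient arc length to start at the new pole
  ends <- cl$points[c(1L, nrow(cl$points)), , drop = FALSE]
  d1 <- sum((ends[1, ] - c(new_pole_end[2], new_pole_end[1]))^2)
  d2 <- sum((ends[2, ] - c(new_pole_end[2], new_pole_end[1]))^2)
  s <- if (d1 <= d2) pa$s else cl$length - pa$s
  L <- cl$length
  # boundary pixels (s exactly at k*L/n) fall to the later, old-pole-ward
  # partition: floor convention counting from the new pole
  part <- pmin(floor(s / (L / n_parts)) + 1L, n_parts)
  out <- lapply(seq_len(n_parts), function(k) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    sel <- pa$pix[part == k, , drop = FALSE]
    m[sel] <- TRUE
    m
  })
  names(out) <- if (n_parts == 4L) c("NP", "L2", "L3", "OP")
                else c("new_half", "old_half")
  out
}

#' New-pole-half over old-pole-half density ratio
#'
#' @param new_half,old_half mean densities of the two polar halves
#'   (A.U./px); `old_half` must be > 0.
#' @return scalar ratio.
#' @export
pole_ratio <- function(new_half, old_half) {
  if (any(old_half <= 0)) stop("old-half density must be > 0")
  new_half / old_half
}

#' Quartile-based pole ratio (NP + L2) / (L3 + OP)
#'
#' Equals [pole_ratio()] exactly when the two quartiles within each half
#' cover equal areas.
#'
#' @param NP,L2,L3,OP quartile mean densities, ordered from the new pole.
#' @return scalar ratio.
#' @export
quartile_pole_ratio <- function(NP, L2, L3, OP) {
  if (any(L3 + OP <= 0)) stop("L3 + OP must be > 0")
  (NP + L2) / (L3 + OP)
}

#' Mean per-pair new/old daughter ratio
#'
#' One ratio per mother (new daughter value / old daughter value); the
#' population statistic is the mean of the per-pair ratios, never the ratio
#' of the means.
#'
#' @param old_values,new_values matched vectors of daughter values; all
#'   `old_values` > 0.
#' @return list with `ratios` (per pair), `mean`, `sem`, `n`, and `p_gt_1`
#'   (one-tailed paired t-test of ratio > 1).
#' @export
daughter_ratio <- function(old_values, new_values) {
  if (length(old_values) != length(new_values))
    stop("old and new values must be matched")
  if (any(old_values <= 0)) stop("old-daughter values must be > 0")
  r <- new_values / old_values
  n <- length(r)
  p <- if (n >= 2 && stats::sd(r) > 0)
    stats::t.test(r, mu = 1, alternative = "greater")$p.value
  else NA_real_
  list(ratios = r, mean = mean(r), sem = stats::sd(r) / sqrt(n), n = n,
       p_gt_1 = p)
}
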