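#' Configuration for simulating daughter-pair tables
#'
#' Describes two populations of dividing mothers (old and new mothers), each
#' producing one (old daughter, new daughter) value pair per mother. The pair
#' asymmetry is parameterized on the pair-normalized scale used throughout
#' the analysis: for a pair with raw values `(old, new)` and pair mean
#' `u = (old + new)/2`, the normalized values are `±d/2` where
#' `d = (new - old)/u`. Each pair draws `d ~ Normal(D, 4 * V_E)` so that the
#' population decomposition (see [variance_decomposition()]) recovers `D`
#' (deterministic asymmetry) and `V_E` (stochastic variance) up to sampling
#' error.
#'
#' Defaults mirror the measured ribosome-density asymmetry of *E. coli*
#' daughter pairs: old mothers D = 0.101, V_E = 0.00381, n = 89; new mothers
#' D = 0.0184, V_E = 0.00338, n = 91. The linear density-to-rate map defaults
#' to the published ribosome-content/elongation-rate regression
#' (content = 337.046 * rate + 87.167 A.U.), inverted to derive rates from
#' densities.
#'
#' @param n_mothers_old,n_mothers_new number of mothers per population (>= 2).
#' @param D_old,D_new deterministic normalized asymmetry, in (-2, 2).
#' @param V_E_old,V_E_new stochastic variance of normalized daughter values
#'   (>= 0).
#' @param base_density mean raw fluorescence density (A.U.), > 0.
#' @param elongation_slope,elongation_intercept linear map between elongation
#'   rate (1/hr) and density (A.U.): `density = slope * rate + intercept`.
#' @param rate_noise_sd sd of independent Gaussian noise added to each
#'   daughter's elongation rate (1/hr).
#' @param seed integer seed; all randomness is reproducible from it.
#' @return an object of class `lineage_sim_config`.
#' @seealso [simulate_pair_table()], [simulate_lineage()]
#' @export
lineage_sim_config <- function(n_mothers_old = 89L, n_mothers_new = 91L,
                               D_old = 0.101, D_new = 0.0184,
                               V_E_old = 0.00381, V_E_new = 0.00338,
                               base_density = 780,
                               elongation_slope = 337.046,
                               elongation_intercept = 87.167,
                               rate_noise_sd = 0.05,
                               seed = 1L) {
  cfg <- list(n_mothers_old = as.integer(n_mothers_old),
              n_mothers_new = as.integer(n_mothers_new),
              D_old = D_old, D_new = D_new,
              V_E_old = V_E_old, V_E_new = V_E_new,
              base_density = base_density,
              elongation_slope = elongation_slope,
              elongation_intercept = elongation_intercept,
              rate_noise_sd = rate_noise_sd,
              seed = as.integer(seed))
  if (cfg$n_mothers_old < 2L || cfg$n_mothers_new < 2L)
    stop("need at least 2 mothers per population")
  if (cfg$V_E_old < 0 || cfg$V_E_new < 0)
    stop("variances must be >= 0")
  if (abs(cfg$D_old) >= 2 || abs(cfg$D_new) >= 2)
    stop("D must lie in (-2, 2) to keep simulated densities positive")
  if (cfg$base_density <= 0) stop("base_density must be > 0")
  if (cfg$rate_noise_sd < 0) stop("rate_noise_sd must be >= 0")
  class(cfg) <- "lineage_sim_config"
  cfg
}

#' Simulate a table of matched old/new daughter pairs
#'
#' For each mother, draws the pair-level normalized asymmetry
#' `d ~ Normal(D, 4 * V_E)` and a pair mean density `u` (log-normal around
#' `base_density`, CV 10%), then emits raw daughter values `u * (1 - d/2)`
#' (old) and `u * (1 + d/2)` (new). Elongation rates are derived from each
#' daughter's density through the inverse linear map plus independent
#' Gaussian noise. Draws giving a non-positive density are rejected and
#' redrawn; more than 100 consecutive rejections for one mother aborts with
#' an error (the configuration is implausible).
#'
#' @param config a [lineage_sim_config()].
#' @return a `data.frame` (the pair table) with columns `mother_id`,
#'   `mother_type` ("old"/"new"), `old_value`, `new_value`, `old_rate`,
#'   `new_rate`.
#' @export
simulate_pair_table <- function(config) {
  stopifnot(inherits(config, "lineage_sim_config"))
  set.seed(config$seed)
  sim_pop <- function(n, D, V_E, type, id0) {
    sd_d <- 2 * sqrt(V_E)
    d <- numeric(n)
    for (i in seq_len(n)) {
      for (try in seq_len(101L)) {
        if (try > 100L)
          stop("simulate_pair_table: >100 redraws needed; ",
               "config gives non-positive densities")
        di <- stats::rnorm(1L, mean = D, sd = sd_d)
        if (abs(di) < 2) { d[i] <- di; break }
      }
    }
    u <- config$base_density *
      stats::rlnorm(n, meanlog = -0.5 * log(1 + 0.1^2),
                    sdlog = sqrt(log(1 + 0.1^2)))
    old_value <- u * (1 - d / 2)
    new_value <- u * (1 + d / 2)
    to_rate <- function(v)
      (v - config$elongation_intercept) / config$elongation_slope +
        stats::rnorm(n, sd = config$rate_noise_sd)
    data.frame(mother_id = paste0(type, "_", id0 + seq_len(n)),
               mother_type = type,
               old_value = old_value, new_value = new_value,
               old_rate = to_rate(old_value), new_rate = to_rate(new_value),
               stringsAsFactors = FALSE)
  }
  rbind(sim_pop(config$n_mothers_old, config$D_old, config$V_E_old, "old", 0L),
        sim_pop(config$n_mothers_new, config$D_new, config$V_E_new, "new", 0L))
}

#' Simulate per-quartile density trajectories over the cell cycle
#'
#' Plumbing for the quartile-trajectory stage: emits, for each mother and
#' each time quartile (B, T2, T3, D), the normalized densities of the four
#' length quartiles (NP, L2, L3, OP; normalized to sum 1 per cell). Each
#' quartile follows a linear trend over time-quartile index 1..4 with
#' Gaussian noise; trends are renormalized per observation so the sum-to-one
#' invariant holds exactly. Default slopes mirror the measured old-mother
#' redistribution (ribosomes leaving the poles for the future new poles).
#'
#' @param n_mothers mothers per time quartile (the real data pool different
#'   cells per time bin; each row here is one cell x one time quartile).
#' @param start named start values at time quartile B for NP, L2, L3, OP
#'   (before renormalization).
#' @param slope named per-time-quartile-step slopes.
#' @param noise_sd sd of pre-normalization Gaussian noise.
#' @param mother_type label for the output column.
#' @param seed integer seed.
#' @return `data.frame` with `mother_id`, `mother_type`, `time_quartile`
#'   (factor B/T2/T3/D), `NP`, `L2`, `L3`, `OP`.
#' @export
simulate_quartile_table <- function(n_mothers = 80L,
                                    start = c(NP = 0.270, L2 = 0.235,
                                              L3 = 0.235, OP = 0.260),
                                    slope = c(NP = -0.0039, L2 = 0.0079,
                                              L3 = 0.0041, OP = -0.0080),
                                    noise_sd = 0.012,
                                    mother_type = "old",
                                    seed = 1L) {
  stopifnot(n_mothers >= 2L, noise_sd >= 0,
            all(c("NP", "L2", "L3", "OP") %in% names(start)),
            all(c("NP", "L2", "L3", "OP") %in% names(slope)))
  set.seed(seed)
  tq <- time_quartile_levels()
  out <- do.call(rbind, lapply(seq_along(tq), function(k) {
    q <- vapply(c("NP", "L2", "L3", "OP"), function(nm) {
      pmax(start[[nm]] + slope[[nm]] * (k - 1) +
             stats::rnorm(n_mothers, sd = noise_sd), 1e-6)
    }, numeric(n_mothers))
    q <- q / rowSums(q)
    data.frame(mother_id = paste0(mother_type, "_", seq_len(n_mothers),
                                  "_", tq[k]),
               mother_type = mother_type,
               time_quartile = tq[k],
               NP = q[, 1], L2 = q[, 2], L3 = q[, 3], OP = q[, 4],
               stringsAsFactors = FALSE)
  }))
  out$time_quartile <- factor(out$time_quartile, levels = tq)
  out
}

#' Configuration for rendering synthetic image pairs
#'
#' Describes the synthetic microscope: rod cells drawn as axis-aligned
#' rectangles with per-length-quartile ground-truth densities, blurred by a
#' normalized Gaussian PSF, with constant background, Poisson-scaled shot
#' noise and sparse hot pixels (amplitude 10x the image maximum) to exercise
#' the outlier-removal stage.
#'
#' The ground-truth quartile densities of a cell, ordered new pole to old
#' pole, are `base_density * c(b*e, b, 1, e)` with `b = pole_bias` and
#' `e = polar_enrichment`, so that the new-half/old-half density ratio is
#' exactly `pole_bias` and the pole quartiles are `polar_enrichment`-fold
#' denser than their neighboring mid quartiles.
#'
#' @param cell_length_px,cell_width_px cell size in pixels.
#' @param polar_enrichment pole-quartile / mid-quartile density ratio (>= 0).
#' @param pole_bias new-half / old-half density ratio (> 0).
#' @param base_density ground-truth density scale (A.U.).
#' @param psf_sigma_px Gaussian PSF sigma in pixels (> 0).
#' @param background_level constant background added to the fluorescence
#'   frame (A.U.).
#' @param shot_noise_scale scale of Poisson-like noise: each pixel gets
#'   `shot_noise_scale * sqrt(signal)` Gaussian sd.
#' @param outlier_fraction fraction of pixels replaced by hot pixels.
#' @param image_shape integer c(rows, cols).
#' @param seed integer seed.
#' @return an object of class `image_sim_config`.
#' @export
image_sim_config <- function(cell_length_px = 40L, cell_width_px = 9L,
                             polar_enrichment = 1.3, pole_bias = 1.10,
                             base_density = 800,
                             psf_sigma_px = 2,
                             background_level = 100,
                             shot_noise_scale = 1,
                             outlier_fraction = 1e-4,
                             image_shape = c(64L, 96L),
                             seed = 1L) {
  cfg <- list(cell_length_px = as.integer(cell_length_px),
              cell_width_px = as.integer(cell_width_px),
              polar_enrichment = polar_enrichment, pole_bias = pole_bias,
              base_density = base_density, psf_sigma_px = psf_sigma_px,
              background_level = background_level,
              shot_noise_scale = shot_noise_scale,
              outlier_fraction = outlier_fraction,
              image_shape = as.integer(image_shape),
              seed = as.integer(seed))
  if (cfg$psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  if (cfg$polar_enrichment < 0 || cfg$pole_bias <= 0 || cfg$base_density < 0)
    stop("densities must be >= 0 and pole_bias > 0")
  if (cfg$background_level < 0 || cfg$shot_noise_scale < 0 ||
      cfg$outlier_fraction < 0 || cfg$outlier_fraction > 1)
    stop("invalid noise parameters")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 8L))
    stop("image_shape must be two integers >= 8")
  margin <- ceiling(4 * cfg$psf_sigma_px)
  if (cfg$cell_length_px + 2 * margin > cfg$image_shape[2] ||
      cfg$cell_width_px + 2 * margin > cfg$image_shape[1])
    stop("cell does not fit inside image with a PSF support margin")
  class(cfg) <- "image_sim_config"
  cfg
}

## Rectangle footprint of one cell; row0/col0 are top-left (1-based).
cell_footprint <- function(row0, col0, length_px, width_px) {
  list(rows = row0 + seq_len(width_px) - 1L,
       cols = col0 + seq_len(length_px) - 1L)
}

#' Render a matched phase/fluorescence image pair with ground truth
#'
#' Places one or more rod cells (horizontal rectangles) into an empty frame,
#' builds the ground-truth density map from the per-quartile densities of
#' [image_sim_config()], then forms the fluorescence frame as
#' `conv(truth, PSF) + background + shot noise + hot pixels`. The phase frame
#' encodes silhouettes (bright background, dark cells). Masks are exact
#' label images. Overlapping silhouettes violate the monolayer assumption
#' and raise an error.
#'
#' @param config an [image_sim_config()].
#' @param cells `data.frame` with one row per cell: `row0`, `col0` (top-left
#'   pixel), optional `new_pole_side` ("left"/"right", default "left"). If
#'   `NULL`, a single centered cell is rendered.
#' @return list with `phase`, `fluorescence`, `truth` (noiseless, unblurred
#'   density map), `masks` (integer label matrix), `psf`, `cells` (the cell
#'   table with pole geometry columns filled in), `outliers` (logical matrix
#'   of injected hot pixels), `config`.
#' @export
render_image_pair <- function(config, cells = NULL) {
  stopifnot(inherits(config, "image_sim_config"))
  set.seed(config$seed)
  shp <- config$image_shape
  if (is.null(cells)) {
    cells <- data.frame(
      row0 = as.integer((shp[1] - config$cell_width_px) %/% 2 + 1L),
      col0 = as.integer((shp[2] - config$cell_length_px) %/% 2 + 1L),
      new_pole_side = "left", stringsAsFactors = FALSE)
  }
  if (is.null(cells$new_pole_side)) cells$new_pole_side <- "left"
  truth <- matrix(0, shp[1], shp[2])
  masks <- matrix(0L, shp[1], shp[2])
  b <- config$pole_bias; e <- config$polar_enrichment
  qdens <- config$base_density * c(b * e, b, 1, e)  # NP, L2, L3, OP
  for (i in seq_len(nrow(cells))) {
    fp <- cell_footprint(cells$row0[i], cells$col0[i],
                         config$cell_length_px, config$cell_width_px)
    if (min(fp$rows) < 1 || max(fp$rows) > shp[1] ||
        min(fp$cols) < 1 || max(fp$cols) > shp[2])
      stop("cell ", i, " extends outside the image")
    if (any(masks[fp$rows, fp$cols] != 0L))
      stop("overlapping cell silhouettes (monolayer assumption violated)")
    masks[fp$rows, fp$cols] <- i
    # assign each column of the footprint to a length quartile, NP first
    L <- config$cell_length_px
    qidx <- pmin(floor((seq_len(L) - 0.5) / L * 4) + 1, 4)
    if (cells$new_pole_side[i] == "right") qidx <- rev(qidx)
    truth[fp$rows, fp$cols] <-
      matrix(qdens[qidx], nrow = length(fp$rows), ncol = L, byrow = TRUE)
  }
  psf <- gaussian_psf(config$psf_sigma_px)
  signal <- conv2_reflect(truth, psf)
  fluor <- signal + config$background_level
  if (config$shot_noise_scale > 0)
    fluor <- fluor + stats::rnorm(length(fluor)) *
      config$shot_noise_scale * sqrt(pmax(fluor, 0))
  outliers <- matrix(FALSE, shp[1], shp[2])
  n_out <- round(config$outlier_fraction * length(fluor))
  if (n_out > 0) {
    pos <- sample.int(length(fluor), n_out)
    outliers[pos] <- TRUE
    fluor[pos] <- fluor[pos] + 10 * max(fluor)
  }
  fluor <- pmax(fluor, 0)
  phase <- matrix(1000, shp[1], shp[2])
  phase[masks > 0L] <- 300
  cells$new_pole_col <- ifelse(cells$new_pole_side == "left",
                               cells$col0, cells$col0 + config$cell_length_px - 1L)
  cells$old_pole_col <- ifelse(cells$new_pole_side == "left",
                               cells$col0 + config$cell_length_px - 1L, cells$col0)
  cells$centerline_row <- cells$row0 + (config$cell_width_px - 1L) / 2
  list(phase = phase, fluorescence = fluor, truth = truth, masks = masks,
       psf = psf, cells = cells, outliers = outliers, config = config)
}
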