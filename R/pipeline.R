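## Orchestration: synthetic or tabular inputs -> imaging chain ->
## partition/lineage measurements -> decomposition, ratio, trajectory and
## space-model reports, with seeds and config recorded in every output.

#' Full image-correction chain on one fluorescence frame
#'
#' Applies, in order: rolling-ball background subtraction, median-based
#' hot-pixel removal, and Richardson-Lucy deconvolution stopped at the
#' within-mask peak. The frame is deconvolved once (using the union of the
#' cell masks by default) and cells are then measured on the result.
#'
#' @param fluorescence numeric matrix.
#' @param masks integer label matrix (0 = background).
#' @param psf normalized PSF matrix.
#' @param ball_radius_px rolling-ball radius; default 20.
#' @param outlier_threshold,outlier_radius hot-pixel removal parameters.
#' @param max_iter deconvolution iteration cap.
#' @param per_cell if `TRUE`, deconvolve and peak-select separately per cell
#'   mask instead of once per frame.
#' @return list with `image` (corrected, deconvolved frame or per-cell list),
#'   `trace` (deconvolution trace(s)), `corrected` (pre-deconvolution frame).
#' @export
process_frame <- function(fluorescence, masks, psf,
                          ball_radius_px = 20, outlier_threshold = 1000,
                          outlier_radius = 0.5, max_iter = 200L,
                          per_cell = FALSE) {
  corrected <- subtract_background(fluorescence, ball_radius_px)
  corrected <- remove_outliers(corrected, outlier_threshold, outlier_radius)
  if (!per_cell) {
    tr <- select_optimal_iterations(corrected, psf, masks > 0L, max_iter)
    list(image = tr$image, trace = tr, corrected = corrected)
  } else {
    ids <- setdiff(sort(unique(as.integer(masks))), 0L)
    trs <- lapply(ids, function(id)
      select_optimal_iterations(corrected, psf, masks == id, max_iter))
    names(trs) <- ids
    list(image = lapply(trs, `[[`, "image"), trace = trs,
         corrected = corrected)
  }
}

#' Measure polarity-ordered partition densities of one cell
#'
#' @param image processed fluorescence frame.
#' @param mask logical mask of the cell.
#' @param new_pole_end `c(row, col)` of the new-pole end of the centerline.
#' @param n_parts 2 or 4.
#' @return named numeric vector of partition mean densities, new pole first.
#' @export
measure_cell_partitions <- function(image, mask, new_pole_end, n_parts = 2L) {
  parts <- split_cell(mask, new_pole_end, n_parts)
  vapply(parts, function(m) measure_density(image, m), 0)
}

#' Quartile-trajectory regressions over the cell cycle
#'
#' For each length quartile (NP, L2, L3, OP), regresses the normalized
#' quartile density on the time-quartile index (1..4) by ordinary least
#' squares, then compares the NP vs OP and L2 vs L3 slopes with
#' [compare_slopes()] (do the new-pole-side trajectories mirror the old-pole
#' side?). Also reports the pole-ratio trajectory (NP+L2)/(L3+OP) slope.
#'
#' @param quartile_table `data.frame` as from [simulate_quartile_table()]:
#'   columns `time_quartile` (B/T2/T3/D) and `NP`, `L2`, `L3`, `OP`.
#' @return list with `slopes` (`data.frame`: quartile, slope, sem, n, p),
#'   `comparisons` (NP_vs_OP, L2_vs_L3), and `pole_ratio_trend`.
#' @export
quartile_trajectory_analysis <- function(quartile_table) {
  q <- quartile_normalize(as.matrix(quartile_table[, c("NP", "L2", "L3",
                                                       "OP")]))
  tq <- as.integer(factor(quartile_table$time_quartile,
                          levels = time_quartile_levels()))
  if (any(is.na(tq))) stop("time_quartile must be one of B, T2, T3, D")
  fit_one <- function(yv) {
    fit <- stats::lm(yv ~ tq)
    s <- summary(fit)$coefficients
    data.frame(slope = s["tq", "Estimate"], sem = s["tq", "Std. Error"],
               n = length(yv), p = s["tq", "Pr(>|t|)"])
  }
  slopes <- do.call(rbind, lapply(c("NP", "L2", "L3", "OP"), function(nm)
    cbind(quartile = nm, fit_one(q[, nm]))))
  cmp <- function(a, b) {
    ra <- slopes[slopes$quartile == a, ]; rb <- slopes[slopes$quartile == b, ]
    compare_slopes(ra$slope, ra$sem, ra$n, rb$slope, rb$sem, rb$n)
  }
  ratio <- quartile_pole_ratio(q[, "NP"], q[, "L2"], q[, "L3"], q[, "OP"])
  list(slopes = slopes,
       comparisons = list(NP_vs_OP = cmp("NP", "OP"),
                          L2_vs_L3 = cmp("L2", "L3")),
       pole_ratio_trend = fit_one(ratio))
}

#' Build a run configuration
#'
#' @param mode "synthetic" (generate everything), "tables" (read a pair
#'   table CSV), or "images" (read fluorescence/mask CSV matrices).
#' @param seed integer master seed, recorded in every output.
#' @param out_dir output directory.
#' @param lineage a [lineage_sim_config()] (synthetic mode).
#' @param image an [image_sim_config()] or `NULL` to skip the imaging stage.
#' @param pair_table_csv input CSV (tables mode).
#' @param fluorescence_csv,masks_csv input matrices (images mode).
#' @param space_rates `c(rate_new, rate_old)` in 1/hr for the space-model
#'   report.
#' @param space_params [space_model_params()].
#' @param aggregate_volume optional measured aggregate volume (um^3).
#' @param n_quartile_mothers mothers per time bin for the synthetic
#'   quartile-trajectory stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "tables", "images"),
                       seed = 1L, out_dir = tempfile("polequant_run_"),
                       lineage = NULL, image = NULL,
                       pair_table_csv = NULL,
                       fluorescence_csv = NULL, masks_csv = NULL,
                       space_rates = c(2.148, 1.964),
                       space_params = space_model_params(),
                       aggregate_volume = 0.0852,
                       n_quartile_mothers = 80L) {
  mode <- match.arg(mode)
  if (mode == "tables" && is.null(pair_table_csv))
    stop("tables mode needs pair_table_csv")
  if (mode == "images" && (is.null(fluorescence_csv) || is.null(masks_csv)))
    stop("images mode needs fluorescence_csv and masks_csv")
  if (is.null(lineage)) lineage <- lineage_sim_config(seed = seed)
  structure(list(mode = mode, seed = as.integer(seed), out_dir = out_dir,
                 lineage = lineage, image = image,
                 pair_table_csv = pair_table_csv,
                 fluorescence_csv = fluorescence_csv, masks_csv = masks_csv,
                 space_rates = space_rates, space_params = space_params,
                 aggregate_volume = aggregate_volume,
                 n_quartile_mothers = as.integer(n_quartile_mothers)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `lineage`,
#' `image` and `space_params` are nested maps passed to their constructors.
#'
#' @param path YAML file.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$lineage)) y$lineage <- do.call(lineage_sim_config, y$lineage)
  if (!is.null(y$image)) y$image <- do.call(image_sim_config, y$image)
  if (!is.null(y$space_params))
    y$space_params <- do.call(space_model_params, y$space_params)
  if (!is.null(y$space_rates)) y$space_rates <- as.numeric(y$space_rates)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Deterministic given (config, seed). Emits, under `config$out_dir`:
#' `pair_table.csv`, `decomposition_report.csv` (variance-component blocks),
#' `ratio_report.csv` (mean per-pair daughter ratios per mother class),
#' `quartile_slopes.csv` + `slope_comparisons.csv` (trajectory regressions),
#' `space_model.json`, and `manifest.json` (config hash, seed, package
#' version). In images mode only the imaging stage runs and per-cell half
#' densities are written instead.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(seed = config$seed)

  if (config$mode == "images") {
    fl <- read_image_csv(config$fluorescence_csv)
    mk <- read_image_csv(config$masks_csv)
    if (!all(dim(fl) == dim(mk)))
      stop("fluorescence and mask shapes differ: ", config$fluorescence_csv,
           " vs ", config$masks_csv)
    psf <- gaussian_psf(if (!is.null(config$image))
      config$image$psf_sigma_px else 2)
    pr <- process_frame(fl, mk, psf)
    write_image_csv(pr$image, file.path(config$out_dir, "deconvolved.csv"))
    write_trace_csv(pr$trace, file.path(config$out_dir, "trace.csv"))
    res$processed <- pr
  } else {
    pairs <- if (config$mode == "tables")
      read_pair_table(config$pair_table_csv)
    else simulate_pair_table(config$lineage)
    write_pair_table(pairs, file.path(config$out_dir, "pair_table.csv"))
    res$pairs <- pairs

    decomp <- analyze_pair_table(pairs)
    rep_df <- cbind(block = "value", decomp$value)
    if (!is.null(decomp$rate))
      rep_df <- rbind(rep_df, cbind(block = "rate", decomp$rate))
    utils::write.csv(rep_df,
                     file.path(config$out_dir, "decomposition_report.csv"),
                     row.names = FALSE)
    res$decomposition <- decomp

    classes <- sort(unique(pairs$mother_type), decreasing = TRUE)
    ratios <- do.call(rbind, lapply(classes, function(cl) {
      sub <- pairs[pairs$mother_type == cl, ]
      dr <- daughter_ratio(sub$old_value, sub$new_value)
      data.frame(mother_class = cl, mean_ratio = dr$mean, sem = dr$sem,
                 n = dr$n, p_gt_1 = dr$p_gt_1)
    }))
    utils::write.csv(ratios, file.path(config$out_dir, "ratio_report.csv"),
                     row.names = FALSE)
    res$ratios <- ratios

    if (config$mode == "synthetic") {
      qt <- simulate_quartile_table(n_mothers = config$n_quartile_mothers,
                                    seed = config$seed + 17L)
      traj <- quartile_trajectory_analysis(qt)
      utils::write.csv(traj$slopes,
                       file.path(config$out_dir, "quartile_slopes.csv"),
                       row.names = FALSE)
      cmpdf <- do.call(rbind, lapply(names(traj$comparisons), function(nm) {
        x <- traj$comparisons[[nm]]
        data.frame(comparison = nm, t = x$t, df = x$df, p = x$p)
      }))
      utils::write.csv(cmpdf,
                       file.path(config$out_dir, "slope_comparisons.csv"),
                       row.names = FALSE)
      res$trajectories <- traj
    }
  }

  sm <- evaluate_space_competition(config$space_rates[1],
                                   config$space_rates[2],
                                   config$space_params,
                                   aggregate_volume = config$aggregate_volume)
  jsonlite::write_json(sm, file.path(config$out_dir, "space_model.json"),
                       auto_unbox = TRUE, digits = NA)
  res$space_model <- sm

  manifest <- list(
    seed = config$seed,
    mode = config$mode,
    config_hash = digest::digest(unclass(config)[setdiff(names(config),
                                                         "out_dir")]),
    package_version = as.character(utils::packageVersion("polequant")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (pair table CSV), `deconvolve` (imaging chain on
#' CSV matrices), `analyze` (decomposition report from a pair table CSV),
#' `space-model` (worked space-competition report), `run` (full pipeline
#' from a YAML config). Arguments are `--key value` flags; see each
#' subcommand's `--help` equivalent in the README.
#'
#' @param args character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
polequant_cli <- function(args) {
  if (length(args) < 1L) {
    cat("usage: polequant <simulate|deconvolve|analyze|space-model|run> ",
        "[--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest) >= 2L) {
    key <- sub("^--", "", rest[1])
    opts[[key]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  num <- function(key, default) if (!is.null(opts[[key]]))
    as.numeric(opts[[key]]) else default
  chr <- function(key, default = NULL) if (!is.null(opts[[key]]))
    opts[[key]] else default
  seed <- as.integer(num("seed", 1))
  out <- chr("out", ".")
  switch(cmd,
    "simulate" = {
      cfg <- lineage_sim_config(seed = seed)
      write_pair_table(simulate_pair_table(cfg),
                       file.path(out, "pair_table.csv"))
    },
    "deconvolve" = {
      cfg <- run_config(mode = "images", seed = seed, out_dir = out,
                        fluorescence_csv = chr("fluorescence"),
                        masks_csv = chr("masks"))
      run_pipeline(cfg)
    },
    "analyze" = {
      cfg <- run_config(mode = "tables", seed = seed, out_dir = out,
                        pair_table_csv = chr("pairs"))
      run_pipeline(cfg)
    },
    "space-model" = {
      sm <- evaluate_space_competition(
        num("rate-new", 2.148), num("rate-old", 1.964),
        space_model_params(slope = num("slope", 337.046),
                           intercept = num("intercept", 87.167),
                           V_ribo = num("v-ribo", 0.79)),
        aggregate_volume = num("aggregate-volume", NA))
      if (is.na(sm$aggregate_volume)) sm$aggregate_volume <- NULL
      cat(jsonlite::toJSON(sm, auto_unbox = TRUE, digits = NA), "\n")
    },
    "run" = {
      cfg <- if (!is.null(opts[["config"]])) read_run_config(opts[["config"]])
             else run_config(mode = "synthetic", seed = seed, out_dir = out)
      cfg$seed <- seed
      cfg$out_dir <- out
      run_pipeline(cfg)
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
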