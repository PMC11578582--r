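## Space-competition model: polar damage aggregates occupy volume that would
## otherwise hold ribosomes. The ribosome content lost by the slower (old)
## daughter, expressed as a fraction p of the faster daughter's content and
## scaled by the total ribosome-occupied volume V_ribo, gives the displaced
## ribosome volume Delta; if measured aggregate volumes reach Delta, space
## competition can quantitatively account for the elongation-rate deficit.

#' Parameters of the space-competition model
#'
#' Defaults are the published linear relation between ribosomal content Y
#' (A.U.) and elongation rate X (1/hr), `Y = 337.046 X + 87.167`, and the
#' estimated total ribosome-occupied volume `V_ribo = 0.79` um^3 in rich
#' media.
#'
#' @param slope A.U. per 1/hr (> 0).
#' @param intercept A.U.
#' @param V_ribo total ribosome-occupied volume, um^3 (> 0).
#' @param aggregate_radius optional aggregate radius (um) used to compute a
#'   comparison sphere volume.
#' @return object of class `space_model_params`.
#' @export
space_model_params <- function(slope = 337.046, intercept = 87.167,
                               V_ribo = 0.79, aggregate_radius = NULL) {
  if (slope <= 0) stop("slope must be > 0")
  if (V_ribo <= 0) stop("V_ribo must be > 0")
  if (!is.null(aggregate_radius) && aggregate_radius < 0)
    stop("aggregate_radius must be >= 0")
  structure(list(slope = slope, intercept = intercept, V_ribo = V_ribo,
                 aggregate_radius = aggregate_radius),
            class = "space_model_params")
}

#' Ribosomal content at a given elongation rate
#'
#' @param rate elongation rate in 1/hr (>= 0).
#' @param params [space_model_params()].
#' @return content in A.U.
#' @export
ribosome_content <- function(rate, params = space_model_params()) {
  if (any(rate < 0)) stop("rate must be >= 0")
  params$slope * rate + params$intercept
}

#' Proportional ribosome reduction of the old daughter
#'
#' @param Y_new,Y_old ribosomal contents (A.U.); `Y_new` must be > 0.
#' @return fraction `p = (Y_new - Y_old)/Y_new`.
#' @export
proportional_reduction <- function(Y_new, Y_old) {
  if (any(Y_new <= 0)) stop("Y_new must be > 0")
  (Y_new - Y_old) / Y_new
}

#' Displaced ribosome volume
#'
#' @param p fraction in `[0, 1]`.
#' @param V_ribo total ribosome-occupied volume (um^3).
#' @return `Delta = p * V_ribo` in um^3.
#' @export
displaced_volume <- function(p, V_ribo = 0.79) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  p * V_ribo
}

#' Sphere volume from radius
#'
#' @param radius in um (>= 0).
#' @return `(4 pi / 3) radius^3` in um^3.
#' @export
sphere_volume <- function(radius) {
  if (any(radius < 0)) stop("radius must be >= 0")
  (4 * pi / 3) * radius^3
}

#' Evaluate the space-competition calculation
#'
#' Chains content -> proportional reduction -> displaced volume and, if an
#' aggregate radius (or volume) is available, states whether the aggregate
#' volume is at least the displaced ribosome volume (i.e., whether space
#' competition is quantitatively sufficient to explain the rate deficit).
#'
#' @param rate_new,rate_old elongation rates, `rate_new >= rate_old >= 0`.
#' @param params [space_model_params()].
#' @param aggregate_volume optional measured aggregate volume (um^3);
#'   overrides the sphere volume from `params$aggregate_radius`.
#' @param printed_mode if `TRUE`, round intermediates as a publication
#'   would print them (Y to 2 decimals, p to 4) before chaining.
#' @return list with `Y_new`, `Y_old`, `p`, `Delta`, `aggregate_volume`
#'   (or `NA`), `sufficient` (logical or `NA`).
#' @export
evaluate_space_competition <- function(rate_new, rate_old,
                                       params = space_model_params(),
                                       aggregate_volume = NULL,
                                       printed_mode = FALSE) {
  if (rate_old < 0 || rate_new < rate_old)
    stop("model is directional: need rate_new >= rate_old >= 0")
  Y_new <- ribosome_content(rate_new, params)
  Y_old <- ribosome_content(rate_old, params)
  if (printed_mode) { Y_new <- round(Y_new, 2); Y_old <- round(Y_old, 2) }
  p <- proportional_reduction(Y_new, Y_old)
  if (printed_mode) p <- round(p, 4)
  Delta <- displaced_volume(p, params$V_ribo)
  agg <- if (!is.null(aggregate_volume)) aggregate_volume
         else if (!is.null(params$aggregate_radius))
           sphere_volume(params$aggregate_radius)
         else NA_real_
  list(Y_new = Y_new, Y_old = Y_old, p = p, Delta = Delta,
       aggregate_volume = agg,
       sufficient = if (is.na(agg)) NA else agg >= Delta)
}
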