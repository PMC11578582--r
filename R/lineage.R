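## Lineage polarity: every division forms two new poles (age 0) at the
## septum; the distal pole of each daughter is inherited from the mother and
## ages by one division. The daughter inheriting the mother's younger pole is
## the "new" daughter, the other the "old" daughter. The starting cell's
## poles predate the movie, so its own daughters cannot be classified; after
## two tracked divisions every cell can.

time_quartile_levels <- function() c("B", "T2", "T3", "D")

#' Simulate a lineage tree of dividing rod cells
#'
#' Builds a full binary tree of `generations` synchronous divisions starting
#' from one cell of unknown polarity. Pole ages are tracked exactly
#' (divisions since formation; the root's poles are unknown/ancient) and
#' polarity classes are filled in with [assign_polarity()]. Division times
#' and lengths are drawn around a 30-min doubling time with exponential
#' elongation, giving realistic elongation rates.
#'
#' @param generations number of divisions (>= 2; old/new classification is
#'   undefined before two divisions).
#' @param config a [lineage_sim_config()] (used for the seed).
#' @return `data.frame` of cell records: `cell_id`, `parent_id`,
#'   `generation`, `birth_time`, `division_time` (minutes; `NA` for leaves),
#'   `birth_length`, `division_length` (um), `pole_A_age`, `pole_B_age`
#'   (`NA` = unknown/ancient), `daughter_class`, `mother_class`
#'   ("old"/"new"/"unknown").
#' @export
simulate_lineage <- function(generations, config = lineage_sim_config()) {
  generations <- as.integer(generations)
  if (generations < 2L)
    stop("generations must be >= 2: old/new assignment is undefined ",
         "before two divisions")
  set.seed(config$seed + 1L)
  rows <- list()
  root <- list(cell_id = "c1", parent_id = NA_character_, generation = 0L,
               birth_time = 0, birth_length = 2.0,
               pole_A_age = NA_real_, pole_B_age = NA_real_)
  frontier <- list(root)
  next_id <- 2L
  for (g in seq_len(generations)) {
    new_frontier <- vector("list", 2L * length(frontier))
    for (j in seq_along(frontier)) {
      cell <- frontier[[j]]
      dt <- stats::rnorm(1L, 30, 3)
      cell$division_time <- cell$birth_time + max(dt, 5)
      cell$division_length <- cell$birth_length *
        exp(stats::rnorm(1L, log(2), 0.05))
      rows[[cell$cell_id]] <- cell
      # children: each inherits one maternal pole (aged +1) as pole A and a
      # fresh septum pole (age 0) as pole B
      for (side in 1:2) {
        inherited <- if (side == 1L) cell$pole_A_age else cell$pole_B_age
        child <- list(cell_id = paste0("c", next_id),
                      parent_id = cell$cell_id,
                      generation = g,
                      birth_time = cell$division_time,
                      birth_length = cell$division_length / 2,
                      pole_A_age = if (is.na(inherited)) NA_real_
                                   else inherited + 1,
                      pole_B_age = 0)
        next_id <- next_id + 1L
        new_frontier[[2L * (j - 1L) + side]] <- child
      }
    }
    frontier <- new_frontier
  }
  for (cell in frontier) {
    cell$division_time <- NA_real_
    cell$division_length <- NA_real_
    rows[[cell$cell_id]] <- cell
  }
  df <- do.call(rbind, lapply(rows, function(x)
    data.frame(x[c("cell_id", "parent_id", "generation", "birth_time",
                   "division_time", "birth_length", "division_length",
                   "pole_A_age", "pole_B_age")], stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df <- df[order(df$generation, df$cell_id), ]
  assign_polarity(df)
}

## Rank two pole ages: a known (septum-derived) age is always younger than an
## unknown/ancient root pole. Returns "A", "B" for the younger pole, or NA if
## incomparable (both unknown).
younger_pole <- function(age_A, age_B) {
  if (is.na(age_A) && is.na(age_B)) return(NA_character_)
  if (is.na(age_A)) return("B")
  if (is.na(age_B)) return("A")
  if (age_A == age_B) stop("pole ages within a cell cannot be equal")
  if (age_A < age_B) "A" else "B"
}

#' Assign old/new daughter and mother classes from pole ages
#'
#' For every cell with a parent, compares the ages of the parent's two poles:
#' the child that inherited the parent's younger pole is the new daughter,
#' the other is the old daughter. Children of the root (whose distal pole age
#' is unknown) stay "unknown". A cell's mother class equals its own daughter
#' class. Pole-label orientation (which physical pole is recorded as A or B)
#' does not affect the result.
#'
#' @param tree `data.frame` of cell records as produced by
#'   [simulate_lineage()]; requires columns `cell_id`, `parent_id`,
#'   `pole_A_age`, `pole_B_age`.
#' @return the tree with `daughter_class` and `mother_class` columns filled.
#' @export
assign_polarity <- function(tree) {
  need <- c("cell_id", "parent_id", "pole_A_age", "pole_B_age")
  if (!all(need %in% names(tree)))
    stop("tree must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tree$cell_id)) stop("duplicate cell ids")
  kids <- split(seq_len(nrow(tree)), tree$parent_id)
  bad <- vapply(kids, length, 1L) != 2L
  if (any(bad))
    stop("cell(s) ", paste(names(kids)[bad], collapse = ", "),
         " divided into != 2 children")
  tree$daughter_class <- "unknown"
  parent_row <- match(tree$parent_id, tree$cell_id)
  # the inherited maternal pole is the one that is not the age-0 septum pole;
  # this makes the classification independent of A/B labeling
  inherited_age <- function(i) {
    a <- tree$pole_A_age[i]; b <- tree$pole_B_age[i]
    if (!is.na(a) && a == 0) {
      if (!is.na(b) && b == 0) stop("cell ", tree$cell_id[i],
                                    " has two age-0 poles")
      b
    } else if (!is.na(b) && b == 0) a
    else stop("cell ", tree$cell_id[i], " has no age-0 septum pole at birth")
  }
  for (i in seq_len(nrow(tree))) {
    p <- parent_row[i]
    if (is.na(p)) next
    sibs <- kids[[tree$parent_id[i]]]
    sib <- setdiff(sibs, i)
    my_inh <- inherited_age(i)
    sib_inh <- inherited_age(sib)
    who <- tryCatch(younger_pole(my_inh, sib_inh), error = function(e) {
      stop("siblings inherited poles of equal age under parent ",
           tree$parent_id[i])
    })
    tree$daughter_class[i] <-
      if (is.na(who)) "unknown" else if (who == "A") "new" else "old"
  }
  tree$mother_class <- tree$daughter_class
  tree
}

#' Exponential elongation rate
#'
#' `r = ln(division length / birth length) / T`, with `T` the birth-to-
#' division time in minutes, reported per hour. Elongation is exponential,
#' so the log-ratio of lengths per unit time is the rate.
#'
#' @param birth_length,division_length cell lengths (> 0, any common unit).
#' @param T_minutes time from birth to division in minutes (> 0).
#' @return elongation rate in 1/hr.
#' @export
elongation_rate <- function(birth_length, division_length, T_minutes) {
  if (any(birth_length <= 0) || any(division_length <= 0) ||
      any(T_minutes <= 0))
    stop("lengths and time must be positive")
  log(division_length / birth_length) / (T_minutes / 60)
}

#' Bin timestamps into cell-cycle time quartiles
#'
#' Divides the birth-to-division interval into four equal windows labeled
#' B, T2, T3, D. Interior boundaries follow the half-open convention
#' `[lo, hi)` (a timestamp exactly on a boundary goes to the later quartile);
#' the final window is closed so the division timepoint maps to D.
#'
#' @param timestamps times in minutes, all within `[birth, division]`.
#' @param birth,division cell birth and division times (minutes).
#' @return factor with levels B, T2, T3, D.
#' @export
bin_time_quartiles <- function(timestamps, birth, division) {
  if (division <= birth) stop("division must be after birth")
  if (any(timestamps < birth | timestamps > division))
    stop("timestamp outside [birth, division]")
  frac <- (timestamps - birth) / (division - birth)
  idx <- pmin(floor(frac * 4) + 1L, 4L)
  factor(time_quartile_levels()[idx], levels = time_quartile_levels())
}
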