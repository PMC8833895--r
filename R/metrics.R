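#' Reliability of repeated optimisation trials
#'
#' The percentage of independent trials that reached the success threshold:
#' `100 * n_successful / n`.
#'
#' @param runs A tibble of runs with a logical `success` column (for
#'   example the `$runs` table of [run_benchmark()]), or a list of
#'   [dfo_optimise()] results.
#' @return A single percentage in `[0, 100]`.
#' @export
reliability <- function(runs) {
  runs <- as_run_tbl(runs)
  100 * sum(runs$success) / nrow(runs)
}

#' Efficiency of repeated optimisation trials
#'
#' Efficiency is the number of fitness evaluations spent before reaching
#' the success threshold, summarised over the *successful* trials of an
#' experiment; failed trials are excluded (an experiment with no successes
#' has undefined efficiency, reported as `NA`).
#'
#' @inheritParams reliability
#' @return A one-row tibble with `best`, `worst`, `median` and `mean`
#'   evaluations-to-success, plus `cases` (number of successes) and `n`.
#' @export
efficiency_stats <- function(runs) {
  runs <- as_run_tbl(runs)
  ok <- runs$fes_used[runs$success]
  if (length(ok) == 0) {
    return(tibble(best = NA_real_, worst = NA_real_, median = NA_real_,
                  mean = NA_real_, cases = 0L, n = nrow(runs)))
  }
  tibble(best = min(ok), worst = max(ok), median = median(ok),
         mean = mean(ok), cases = length(ok), n = nrow(runs))
}

as_run_tbl <- function(runs) {
  if (is.data.frame(runs)) {
    if (!all(c("success", "fes_used") %in% names(runs)) &&
        !"success" %in% names(runs)) {
      abort("runs table needs 'success' (and 'fes_used') columns")
    }
    if (!"fes_used" %in% names(runs)) runs$fes_used <- NA_real_
    return(runs)
  }
  if (is.list(runs) && all(vapply(runs, inherits, TRUE, "dfo_result"))) {
    return(dplyr::bind_rows(lapply(runs, glance)))
  }
  abort("runs must be a data frame or a list of dfo_result objects")
}

#' Swarm diversity: average distance around the population centre
#'
#' The mean, over all positions, of the Euclidean distance to the
#' per-dimension centroid — a diversity measure robust to outliers. All
#' amounts are first converted to canonical kilogram units so gram-scale
#' hops and kilogram-scale malts contribute on a common scale. Zero if and
#' only if all positions coincide.
#'
#' @param positions A matrix of positions (rows), a `dfo_population`, or a
#'   `dfo_result` (its final swarm is used).
#' @param inventory The [brew_inventory()] the positions live in.
#' @return A non-negative scalar.
#' @export
swarm_diversity <- function(positions, inventory) {
  if (inherits(positions, "dfo_result")) positions <- positions$population
  if (inherits(positions, "dfo_population")) positions <- positions$positions
  X <- canonical_amounts(positions, inventory)
  centre <- colMeans(X)
  dev <- sweep(X, 2, centre, "-")
  mean(sqrt(rowSums(dev^2)))
}

#' Pairwise distances between discovered recipes
#'
#' Euclidean distances between solution vectors in canonical kilogram
#' units, as a symmetric matrix with zero diagonal. Used to quantify how
#' *different* the recipes found in independent runs are; by convention only
#' the successful runs' best recipes are included upstream.
#'
#' @param solutions A matrix of recipes (rows) or a list of recipe vectors.
#' @param inventory The [brew_inventory()].
#' @return A symmetric numeric matrix of class `recipe_dist`.
#' @export
recipe_distances <- function(solutions, inventory) {
  if (is.list(solutions) && !is.data.frame(solutions)) {
    solutions <- do.call(rbind, solutions)
  }
  X <- canonical_amounts(solutions, inventory)
  m <- as.matrix(dist(X))
  dimnames(m) <- list(seq_len(nrow(m)), seq_len(nrow(m)))
  class(m) <- c("recipe_dist", class(m))
  m
}

#' Summary statistics of a solution-distance matrix
#'
#' @param d A `recipe_dist` matrix from [recipe_distances()].
#' @return A one-row tibble with `mean`, `min`, `max` and `sd` of the
#'   off-diagonal distances and the indices of the farthest pair. With
#'   fewer than two solutions all statistics are `NA`.
#' @export
distance_summary <- function(d) {
  n <- nrow(d)
  if (is.null(n) || n < 2) {
    return(tibble(mean = NA_real_, min = NA_real_, max = NA_real_,
                  sd = NA_real_, farthest_i = NA_integer_,
                  farthest_j = NA_integer_, n_solutions = n %||% 0L))
  }
  up <- upper.tri(d)
  vals <- d[up]
  far <- which(d == max(vals) & up, arr.ind = TRUE)[1, ]
  tibble(mean = mean(vals), min = min(vals), max = max(vals),
         sd = sd(vals), farthest_i = unname(far[1]),
         farthest_j = unname(far[2]), n_solutions = n)
}

#' @method autoplot recipe_dist
#' @export
autoplot.recipe_dist <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("i", "j", "distance")
  df$i <- as.integer(df$i)
  df$j <- as.integer(df$j)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "solution", y = "solution",
                  title = "Pairwise recipe distances (kg units)")
}
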