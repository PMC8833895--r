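#' Optimiser configuration
#'
#' Parameters of the dispersive flies optimiser (DFO). The defaults are the
#' benchmark settings used throughout the package: a swarm of 50 flies on a
#' ring topology with elitism, a per-component restart probability of 0.001,
#' a budget of 50,000 fitness evaluations and a success threshold of 0.05 on
#' the Euclidean property error.
#'
#' @param population_size Number of flies N (>= 3; the ring topology needs
#'   two distinct neighbours).
#' @param restart_threshold Per-component probability of resampling a
#'   position entry uniformly within its bounds after the update (the
#'   disturbance threshold, escaping local minima).
#' @param fe_budget Maximum number of fitness evaluations per run.
#' @param success_error A run succeeds when the best error reaches this
#'   value or below.
#' @param seed Optional integer seed; identical seeds give identical runs.
#' @param elitism Keep the swarm-best fly untouched each iteration (exempt
#'   from both the position update and the restart).
#' @param error_form `"euclidean"` (default) reports the root of the sum of
#'   squared property differences; `"sum_of_squares"` reports the sum
#'   itself.
#' @return A list of class `dfo_config`.
#' @export
dfo_config <- function(population_size = 50, restart_threshold = 0.001,
                       fe_budget = 50000, success_error = 0.05,
                       seed = NULL, elitism = TRUE,
                       error_form = c("euclidean", "sum_of_squares")) {
  error_form <- match.arg(error_form)
  stopifnot(population_size >= 3,
            restart_threshold >= 0, restart_threshold <= 1,
            fe_budget >= population_size, success_error >= 0)
  structure(list(population_size = as.integer(population_size),
                 restart_threshold = restart_threshold,
                 fe_budget = as.integer(fe_budget),
                 success_error = success_error, seed = seed,
                 elitism = isTRUE(elitism), error_form = error_form),
            class = "dfo_config")
}

# coerce a target (named vector / one-row data frame) to the canonical
# property order used everywhere: abv, ibu, srm, og, fg
as_target <- function(target) {
  props <- c("abv", "ibu", "srm", "og", "fg")
  if (is.data.frame(target)) {
    if (nrow(target) != 1) abort("a target must be a single product row")
    target <- unlist(target[intersect(names(target), props)])
  }
  if (!all(props %in% names(target))) {
    abort("target must supply abv, ibu, srm, og and fg")
  }
  as.numeric(target[props])
}

# error of each row-recipe in X against the target vector
error_matrix <- function(X, target_vec, cf, error_form) {
  P <- sim_properties(X, cf)
  sq <- (P - matrix(target_vec, nrow(P), 5, byrow = TRUE))^2
  e <- rowSums(sq)
  if (error_form == "euclidean") sqrt(e) else e
}

#' Property-space error of a recipe against a target
#'
#' The fitness the optimiser minimises: the distance between a recipe's
#' simulated five properties and the target's. With
#' `error_form = "sum_of_squares"` this is the plain sum of squared
#' differences over (ABV, IBU, SRM, OG, FG); the default `"euclidean"` form
#' is its square root, on the same scale as a single-property shortfall.
#'
#' @inheritParams brew_properties
#' @param target A target: a one-row tibble (as returned by
#'   [brew_products()]) or a named vector with `abv`, `ibu`, `srm`, `og`,
#'   `fg`.
#' @param error_form `"euclidean"` or `"sum_of_squares"`.
#' @return Numeric vector of errors, one per recipe.
#' @export
evaluate_error <- function(recipe, target, inventory,
                           settings = brew_settings(),
                           error_form = c("euclidean", "sum_of_squares")) {
  error_form <- match.arg(error_form)
  X <- as_recipe_matrix(recipe, inventory)
  cf <- sim_coefs(inventory, settings)
  unname(error_matrix(X, as_target(target), cf, error_form))
}

# resolve `fixed` (named amounts) against the inventory; errors above stock
resolve_fixed <- function(fixed, inventory) {
  if (is.null(fixed) || length(fixed) == 0) {
    return(list(idx = integer(0), values = numeric(0)))
  }
  unknown <- setdiff(names(fixed), inventory$name)
  if (length(unknown)) abort(paste0("unknown fixed ingredient: ", unknown[1]))
  idx <- match(names(fixed), inventory$name)
  vals <- as.numeric(fixed)
  over <- vals > inventory$stock_amount[idx] + 1e-9 | vals < 0
  if (any(over)) {
    abort(paste0("fixed amount for '", names(fixed)[over][1],
                 "' is outside the in-stock bounds"))
  }
  list(idx = idx, values = vals)
}

#' Initialise a swarm
#'
#' Draws every component of every fly independently and uniformly on
#' `[0, stock_amount]` of its ingredient, pins any fixed dimensions, and
#' evaluates the whole swarm (consuming `population_size` fitness
#' evaluations). Uses the current state of R's random number generator; seed
#' control lives in [dfo_optimise()].
#'
#' @inheritParams evaluate_error
#' @param config A [dfo_config()].
#' @param fixed Optional named numeric vector of ingredient amounts pinned
#'   during the whole run (excluded from update and restart).
#' @return A list of class `dfo_population` with elements `positions`
#'   (N x D matrix), `errors`, `best` (index of the swarm best) and `fe`
#'   (fitness evaluations consumed so far).
#' @export
dfo_init <- function(inventory, target, settings = brew_settings(),
                     config = dfo_config(), fixed = NULL) {
  if (nrow(inventory) < 1) abort("cannot optimise over an empty inventory")
  N <- config$population_size
  D <- nrow(inventory)
  fx <- resolve_fixed(fixed, inventory)
  X <- matrix(runif(N * D), N, D)
  X <- sweep(X, 2, inventory$stock_amount, "*")
  if (length(fx$idx)) X[, fx$idx] <- rep(fx$values, each = N)
  colnames(X) <- inventory$name
  cf <- sim_coefs(inventory, settings)
  E <- error_matrix(X, as_target(target), cf, config$error_form)
  structure(list(positions = X, errors = E, best = which.min(E),
                 fe = N), class = "dfo_population")
}

#' Best ring-topology neighbour of a fly
#'
#' On the ring, fly `i` communicates with flies `i - 1` and `i + 1`
#' (wrapping around). Returns the index of whichever neighbour currently
#' holds the lower error; on an exact tie the lower index wins, keeping the
#' update deterministic.
#'
#' @param population A `dfo_population`.
#' @param i Fly index (1-based).
#' @return The neighbour's index.
#' @export
best_neighbour <- function(population, i) {
  N <- length(population$errors)
  left <- if (i == 1) N else i - 1
  right <- if (i == N) 1 else i + 1
  e <- population$errors
  if (e[left] < e[right]) left
  else if (e[right] < e[left]) right
  else min(left, right)
}

# vectorised neighbour-best indices for all flies at once
neighbour_indices <- function(E) {
  N <- length(E)
  left <- c(N, seq_len(N - 1))
  right <- c(seq_len(N - 1) + 1, 1)
  ifelse(E[left] < E[right], left,
         ifelse(E[right] < E[left], right, pmin(left, right)))
}

#' One DFO iteration
#'
#' Flies are swept in index order and updated in place: every component of
#' fly `i` moves to `x' = x_neighbour + u * (x_swarmbest - x)` with
#' `u ~ U(0, 1)` drawn afresh per component per fly, where the neighbour is
#' the better (by the previous evaluation) of the two ring neighbours at
#' its *current* position — an already-updated neighbour is seen at its new
#' position, so improvements cascade around the ring within one iteration.
#' Each updated component is then restarted (resampled uniformly within its
#' bounds) with probability `restart_threshold` and clamped to
#' `[0, stock]`; the swarm is re-evaluated at the end of the sweep. With
#' elitism the swarm-best fly is exempt from update and restart and is not
#' re-evaluated.
#'
#' @inheritParams dfo_init
#' @param population A `dfo_population` from [dfo_init()] or a previous
#'   step.
#' @return The updated `dfo_population`.
#' @export
dfo_step <- function(population, target, inventory,
                     settings = brew_settings(), config = dfo_config(),
                     fixed = NULL) {
  cf <- sim_coefs(inventory, settings)
  step_core(population, as_target(target), cf, config,
            resolve_fixed(fixed, inventory))
}

step_core <- function(pop, target_vec, cf, config, fx) {
  X <- pop$positions
  E <- pop$errors
  N <- nrow(X)
  D <- ncol(X)
  s <- pop$best
  stock <- cf$stock
  delta <- config$restart_threshold
  cn <- dimnames(X)
  dimnames(X) <- NULL
  xs <- X[s, ]
  for (i in seq_len(N)) {
    if (config$elitism && i == s) next
    left <- if (i == 1L) N else i - 1L
    right <- if (i == N) 1L else i + 1L
    nb <- if (E[left] < E[right]) left
          else if (E[right] < E[left]) right
          else min(left, right)
    u <- runif(D)
    xn <- X[nb, ] + u * (xs - X[i, ])
    if (delta > 0) {
      mask <- runif(D) < delta
      if (any(mask)) xn[mask] <- runif(sum(mask)) * stock[mask]
    }
    low <- xn < 0
    if (any(low)) xn[low] <- 0
    high <- xn > stock
    if (any(high)) xn[high] <- stock[high]
    if (length(fx$idx)) xn[fx$idx] <- fx$values
    X[i, ] <- xn
    if (!config$elitism && i == s) xs <- xn
  }
  dimnames(X) <- cn
  Enew <- error_matrix(X, target_vec, cf, config$error_form)
  if (config$elitism) Enew[s] <- E[s]
  pop$positions <- X
  pop$errors <- Enew
  pop$best <- which.min(Enew)
  # the evaluation counter advances by N per sweep: the elite's fitness is
  # deterministic and not recomputed, but its evaluation slot is counted,
  # keeping the counter a multiple of the swarm size
  pop$fe <- pop$fe + N
  pop
}

#' Discover a recipe for a target property profile
#'
#' Runs dispersive flies optimisation over the box `[0, stock]^D` defined by
#' the inventory: a swarm is initialised uniformly, then iterates the ring
#' topology update with elitism, per-component restarts and clamping until
#' the best property-space error reaches `success_error` or the evaluation
#' budget is exhausted. With elitism the best error is non-increasing over
#' iterations, and a run is fully reproducible from its seed.
#'
#' @inheritParams dfo_init
#' @return An object of class `dfo_result`: a list with `best_recipe`
#'   (tibble of ingredient amounts), `best_properties` (tibble row of the
#'   five simulated properties), `best_error`, `fes_used`, `iterations`,
#'   `success`, `trace` (tibble of `(fes, best_error)` per iteration) and
#'   `population` (final swarm). Use [tidy()] for the recipe, [glance()]
#'   for a one-row run summary and [autoplot()] for the convergence trace.
#' @examples
#' \donttest{
#' inv <- brew_inventory()
#' guinness <- dplyr::filter(brew_products(), product_no == 2)
#' fit <- dfo_optimise(inv, guinness, config = dfo_config(seed = 1))
#' glance(fit)
#' tidy(fit)
#' }
#' @export
dfo_optimise <- function(inventory, target, settings = brew_settings(),
                         config = dfo_config(), fixed = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  fx <- resolve_fixed(fixed, inventory)
  cf <- sim_coefs(inventory, settings)
  target_vec <- as_target(target)
  pop <- dfo_init(inventory, target, settings, config, fixed)
  per_iter <- config$population_size
  trace_fes <- pop$fe
  trace_err <- pop$errors[pop$best]
  iter <- 0L
  while (pop$errors[pop$best] > config$success_error &&
         pop$fe + per_iter <= config$fe_budget) {
    pop <- step_core(pop, target_vec, cf, config, fx)
    iter <- iter + 1L
    trace_fes[iter + 1L] <- pop$fe
    trace_err[iter + 1L] <- pop$errors[pop$best]
  }
  finish_result(pop, inventory, settings, config, target_vec, iter,
                tibble(iteration = seq_along(trace_fes) - 1L,
                       fes = trace_fes, best_error = trace_err))
}

finish_result <- function(pop, inventory, settings, config, target_vec,
                          iterations, trace) {
  best <- pop$positions[pop$best, ]
  props <- brew_properties(matrix(best, nrow = 1), inventory, settings)
  structure(list(
    best_recipe = tibble(name = inventory$name,
                         category = inventory$category,
                         amount = unname(best), unit = inventory$unit,
                         stock_amount = inventory$stock_amount),
    best_position = unname(best),
    best_properties = props,
    best_error = unname(pop$errors[pop$best]),
    fes_used = pop$fe,
    iterations = iterations,
    success = pop$errors[pop$best] <= config$success_error,
    trace = trace,
    population = pop,
    target = setNames(target_vec, c("abv", "ibu", "srm", "og", "fg")),
    config = config, settings = settings,
    inventory = inventory), class = "dfo_result")
}

#' @export
print.dfo_result <- function(x, ...) {
  cat("Dispersive flies optimisation run\n")
  cat(sprintf("  %s after %d evaluations (%d iterations); best error %.4f\n",
              if (x$success) "converged" else "budget exhausted",
              x$fes_used, x$iterations, x$best_error))
  used <- x$best_recipe[x$best_recipe$amount > 1e-6, ]
  cat(sprintf("  recipe uses %d of %d ingredients\n",
              nrow(used), nrow(x$best_recipe)))
  invisible(x)
}

#' @describeIn dfo_optimise Per-ingredient tibble of the best recipe with
#'   the fraction of stock consumed.
#' @param x,object A `dfo_result`.
#' @param ... Unused.
#' @method tidy dfo_result
#' @export
tidy.dfo_result <- function(x, ...) {
  dplyr::mutate(x$best_recipe,
                stock_fraction = ifelse(.data$stock_amount > 0,
                                        .data$amount / .data$stock_amount, 0))
}

#' @describeIn dfo_optimise One-row run summary: best error, evaluations,
#'   iterations, success flag and the five achieved properties.
#' @method glance dfo_result
#' @export
glance.dfo_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(best_error = x$best_error, fes_used = x$fes_used,
           iterations = x$iterations, success = x$success),
    x$best_properties)
}

#' Optimise through a schedule of changing targets
#'
#' Dynamic-target mode: the swarm is carried over from one target to the
#' next without re-initialisation, so the optimiser adapts to on-the-fly
#' preference changes. When the target switches, the whole swarm is
#' re-evaluated against the new target (counted in the evaluation budget)
#' before the first step; the best error at that moment is the segment's
#' *transition error*, reflecting the property-space distance between the
#' incumbent solution and the new target.
#'
#' Each segment runs until its error reaches `success_error` or the
#' segment's iteration cap is hit; the overall evaluation counter and error
#' trace are continuous across segments.
#'
#' @inheritParams dfo_init
#' @param targets A tibble of target rows (in schedule order), or a list of
#'   targets accepted by [evaluate_error()].
#' @param segment_iterations Per-segment iteration cap (recycled); default
#'   1000.
#' @param fixed Optional named amounts pinned for the whole schedule, or a
#'   list of such vectors, one per segment.
#' @return An object of class `dfo_schedule_result`: list with `segments`
#'   (tibble: one row per segment with transition error, iterations to
#'   success, final error, evaluations), `trace` (continuous, with a
#'   `segment` column) and `final` (the last segment's `dfo_result`).
#' @export
dfo_schedule <- function(inventory, targets, settings = brew_settings(),
                         config = dfo_config(), segment_iterations = 1000,
                         fixed = NULL) {
  if (is.data.frame(targets)) {
    targets <- lapply(seq_len(nrow(targets)), function(i) targets[i, ])
  }
  n_seg <- length(targets)
  if (n_seg < 1) abort("schedule needs at least one target")
  caps <- rep_len(segment_iterations, n_seg)
  fixed_list <- if (is.list(fixed) && !is.data.frame(fixed)) {
    rep_len(fixed, n_seg)
  } else rep_len(list(fixed), n_seg)
  if (!is.null(config$seed)) set.seed(config$seed)
  cf <- sim_coefs(inventory, settings)
  per_iter <- config$population_size
  pop <- NULL
  seg_rows <- vector("list", n_seg)
  traces <- vector("list", n_seg)
  result <- NULL
  for (k in seq_len(n_seg)) {
    tv <- as_target(targets[[k]])
    fx <- resolve_fixed(fixed_list[[k]], inventory)
    if (is.null(pop)) {
      pop <- dfo_init(inventory, targets[[k]], settings, config,
                      fixed_list[[k]])
      transition_error <- pop$errors[pop$best]
    } else {
      # re-target: pin any newly fixed dimensions, re-evaluate every fly;
      # the transition error is the incumbent best solution's error
      # against the new target
      incumbent <- pop$best
      if (length(fx$idx)) {
        pop$positions[, fx$idx] <- rep(fx$values, each = nrow(pop$positions))
      }
      pop$errors <- error_matrix(pop$positions, tv, cf, config$error_form)
      transition_error <- pop$errors[incumbent]
      pop$best <- which.min(pop$errors)
      pop$fe <- pop$fe + nrow(pop$positions)
    }
    t_fes <- pop$fe
    t_err <- transition_error
    it <- 0L
    while (pop$errors[pop$best] > config$success_error && it < caps[k]) {
      pop <- step_core(pop, tv, cf, config, fx)
      it <- it + 1L
      t_fes[it + 1L] <- pop$fe
      t_err[it + 1L] <- pop$errors[pop$best]
    }
    succ <- pop$errors[pop$best] <= config$success_error
    seg_rows[[k]] <- tibble(
      segment = k, transition_error = unname(transition_error),
      iterations = it, success = succ,
      final_error = unname(pop$errors[pop$best]), fes_cum = pop$fe,
      best_position = list(unname(pop$positions[pop$best, ])))
    traces[[k]] <- tibble(segment = k, iteration = seq_along(t_fes) - 1L,
                          fes = t_fes, best_error = t_err)
    result <- finish_result(pop, inventory, settings, config, tv, it,
                            traces[[k]])
  }
  structure(list(segments = dplyr::bind_rows(seg_rows),
                 trace = dplyr::bind_rows(traces),
                 final = result, config = config),
            class = "dfo_schedule_result")
}

#' @export
print.dfo_schedule_result <- function(x, ...) {
  cat("DFO dynamic-target schedule:", nrow(x$segments), "segments\n")
  print(x$segments)
  invisible(x)
}

#' @describeIn dfo_schedule Per-segment summary tibble.
#' @param x A `dfo_schedule_result`.
#' @param ... Unused.
#' @method tidy dfo_schedule_result
#' @export
tidy.dfo_schedule_result <- function(x, ...) x$segments
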