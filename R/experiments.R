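#' Benchmark the optimiser over a product set
#'
#' Runs `n_runs` independent seeded optimisations for every product and
#' summarises error, efficiency, reliability, swarm diversity and
#' solution-distance statistics per product. Seeds follow the policy
#' `base_seed + product_index * 1000 + run_index`, so the whole benchmark
#' is reproducible from `base_seed`.
#'
#' @param products Tibble of target products ([brew_products()] or a subset
#'   of its rows).
#' @param inventory A [brew_inventory()].
#' @param settings A [brew_settings()].
#' @param config A [dfo_config()] (the per-run `seed` field is overridden
#'   by the seed policy).
#' @param n_runs Independent runs per product.
#' @param base_seed Integer base of the seed policy.
#' @param verbose Print a progress line per product.
#' @return An object of class `brew_benchmark`: list with `runs` (one row
#'   per run, including the best position as a list column and the final
#'   swarm diversity), `product_stats` (one row per product mirroring the
#'   error/efficiency/reliability/diversity tables), `distance_stats`
#'   (per-product solution-distance summaries over successful runs),
#'   `products`, `config`, `n_runs`, `base_seed`. [tidy()] returns
#'   `product_stats`; [glance()] the overall feasibility and efficiency
#'   aggregates.
#' @export
run_benchmark <- function(products = brew_products(),
                          inventory = brew_inventory(),
                          settings = brew_settings(),
                          config = dfo_config(), n_runs = 50,
                          base_seed = 1L, verbose = FALSE) {
  stopifnot(n_runs >= 1)
  if (anyDuplicated(products$product_no)) {
    abort("product numbers must be unique")
  }
  run_rows <- vector("list", nrow(products) * n_runs)
  r <- 0L
  for (p in seq_len(nrow(products))) {
    prod <- products[p, ]
    for (run in seq_len(n_runs)) {
      cfg <- config
      cfg$seed <- base_seed + prod$product_no * 1000L + run
      fit <- dfo_optimise(inventory, prod, settings, cfg)
      r <- r + 1L
      run_rows[[r]] <- tibble(
        product_no = prod$product_no, product = prod$name, run = run,
        seed = cfg$seed, success = fit$success,
        best_error = fit$best_error, fes_used = fit$fes_used,
        iterations = fit$iterations,
        diversity = swarm_diversity(fit$population, inventory),
        best_position = list(fit$best_position))
    }
    if (verbose) {
      done <- dplyr::bind_rows(run_rows[(r - n_runs + 1L):r])
      message(sprintf("product %2d %-22s reliability %5.1f%%",
                      prod$product_no, prod$name, reliability(done)))
    }
  }
  runs <- dplyr::bind_rows(run_rows)
  product_stats <- runs |>
    dplyr::group_by(.data$product_no, .data$product) |>
    dplyr::summarise(
      error_best = min(.data$best_error),
      error_worst = max(.data$best_error),
      error_median = median(.data$best_error),
      error_mean = mean(.data$best_error),
      error_sd = sd(.data$best_error),
      diversity_successful = mean(.data$diversity[.data$success]),
      diversity_failed = mean(.data$diversity[!.data$success]),
      fes_best = if (any(.data$success)) min(.data$fes_used[.data$success])
                 else NA_real_,
      fes_worst = if (any(.data$success)) max(.data$fes_used[.data$success])
                  else NA_real_,
      fes_median = if (any(.data$success))
                     median(.data$fes_used[.data$success]) else NA_real_,
      cases = sum(.data$success),
      reliability = 100 * sum(.data$success) / dplyr::n(),
      .groups = "drop")
  distance_stats <- runs |>
    dplyr::filter(.data$success) |>
    dplyr::group_by(.data$product_no, .data$product) |>
    dplyr::group_modify(function(g, key) {
      distance_summary(recipe_distances(do.call(rbind, g$best_position),
                                        inventory))
    }) |>
    dplyr::ungroup()
  structure(list(runs = runs, product_stats = product_stats,
                 distance_stats = distance_stats, products = products,
                 inventory = inventory, settings = settings,
                 config = config, n_runs = n_runs, base_seed = base_seed),
            class = "brew_benchmark")
}

#' @export
print.brew_benchmark <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Recipe-discovery benchmark: %d products x %d runs\n",
              g$n_products, x$n_runs))
  cat(sprintf("  feasible: %d/%d products (%.0f%%); overall median FEs %s\n",
              g$n_solved, g$n_products, g$feasibility_pct,
              format(g$median_fes)))
  invisible(x)
}

#' @describeIn run_benchmark Per-product statistics table.
#' @param x A `brew_benchmark`.
#' @param ... Unused.
#' @method tidy brew_benchmark
#' @export
tidy.brew_benchmark <- function(x, ...) x$product_stats

#' @describeIn run_benchmark Overall aggregates: number and percentage of
#'   feasible products (at least one successful run), the median over
#'   solvable products of each product's median evaluations-to-success, its
#'   maximum, and the minimum per-product reliability among solvable
#'   products.
#' @method glance brew_benchmark
#' @export
glance.brew_benchmark <- function(x, ...) {
  st <- x$product_stats
  solved <- st[st$cases > 0, ]
  tibble(n_products = nrow(st), n_solved = nrow(solved),
         feasibility_pct = 100 * nrow(solved) / nrow(st),
         median_fes = median(solved$fes_median),
         max_median_fes = max(solved$fes_median),
         min_reliability_solvable = min(solved$reliability))
}

#' @method autoplot brew_benchmark
#' @export
autoplot.brew_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$product_stats,
                  ggplot2::aes(factor(.data$product_no),
                               .data$reliability,
                               fill = .data$cases > 0)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "steelblue"),
                               guide = "none") +
    ggplot2::labs(x = "product", y = "reliability (%)",
                  title = "Per-product reliability")
}

#' Write delimited benchmark reports
#'
#' Emits one CSV per report family — per-product error and diversity,
#' efficiency and reliability, and solution-distance statistics — plus a
#' JSON run manifest (configuration, seed policy, package version).
#'
#' @param benchmark A `brew_benchmark`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_benchmark_report <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- benchmark$product_stats
  readr::write_csv(
    st[, c("product_no", "product", "error_best", "error_worst",
           "error_median", "error_mean", "error_sd",
           "diversity_successful", "diversity_failed")],
    file.path(dir, "error_diversity.csv"), na = "-")
  readr::write_csv(
    st[, c("product_no", "product", "fes_best", "fes_worst", "fes_median",
           "cases", "reliability")],
    file.path(dir, "efficiency_reliability.csv"), na = "-")
  readr::write_csv(benchmark$distance_stats,
                   file.path(dir, "solution_distances.csv"), na = "-")
  manifest <- list(
    package = "brewdfo",
    version = as.character(utils::packageVersion("brewdfo")),
    n_runs = benchmark$n_runs, base_seed = benchmark$base_seed,
    seed_policy = "base_seed + product_no * 1000 + run_index",
    config = benchmark$config[c("population_size", "restart_threshold",
                                "fe_budget", "success_error", "elitism",
                                "error_form")],
    settings = unclass(benchmark$settings))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Drastic preference switching
#'
#' Cycles the optimiser through a loop of products (by default the stout /
#' dark lager / black IPA trio) without re-initialising the swarm,
#' emulating a user who repeatedly changes product choice mid-run. Each
#' switch re-evaluates the swarm against the new target; segments run to
#' success or the iteration cap.
#'
#' @param product_names Names of products in [brew_products()] (cycled in
#'   order).
#' @param cycles How many times to loop over the products.
#' @inheritParams run_benchmark
#' @param segment_iterations Iteration cap per segment.
#' @return A `dfo_schedule_result` whose `segments` table carries an
#'   `item` column naming the product of each segment.
#' @export
drastic_switch_experiment <- function(product_names = c(
                                        "Guinness Extra Stout",
                                        "Kozel Dark",
                                        "Imperial Black IPA"),
                                      cycles = 2,
                                      inventory = brew_inventory(),
                                      settings = brew_settings(),
                                      config = dfo_config(),
                                      segment_iterations = 1000) {
  products <- brew_products()
  missing_p <- setdiff(product_names, products$name)
  if (length(missing_p)) {
    abort(paste0("unknown product: ", missing_p[1]))
  }
  order_names <- rep(product_names, cycles)
  targets <- products[match(order_names, products$name), ]
  res <- dfo_schedule(inventory, targets, settings, config,
                      segment_iterations = segment_iterations)
  res$segments$item <- order_names
  res
}

#' Gradual preference ramp
#'
#' After converging on a base product, one property of the target is
#' changed by a fixed increment per segment (by default the bitterness is
#' raised in +5 IBU steps), and the swarm re-converges without restart.
#' Post-convergence recoveries are expected to need far fewer iterations
#' than the initial convergence, since the population remains concentrated
#' near the previous optimum while retaining diversity.
#'
#' @param base_target A product name in [brew_products()] or a target row.
#' @param property One of `"abv"`, `"ibu"`, `"srm"`, `"og"`, `"fg"`.
#' @param increment Change applied per segment.
#' @param steps Number of increments after the initial convergence.
#' @inheritParams drastic_switch_experiment
#' @return A list of class `ramp_experiment`: the schedule result plus
#'   `initial_iterations` (to first convergence) and
#'   `mean_recovery_iterations` (mean over the increment segments).
#' @export
gradual_ramp_experiment <- function(base_target = "Guinness Extra Stout",
                                    property = "ibu", increment = 5,
                                    steps = 8,
                                    inventory = brew_inventory(),
                                    settings = brew_settings(),
                                    config = dfo_config(),
                                    segment_iterations = 1000) {
  property <- match.arg(property, c("abv", "ibu", "srm", "og", "fg"))
  if (is.character(base_target)) {
    products <- brew_products()
    if (!base_target %in% products$name) {
      abort(paste0("unknown product: ", base_target))
    }
    base_target <- products[match(base_target, products$name), ]
  }
  tv <- as_target(base_target)
  names(tv) <- c("abv", "ibu", "srm", "og", "fg")
  targets <- lapply(0:steps, function(s) {
    t2 <- tv
    t2[property] <- t2[property] + s * increment
    t2
  })
  res <- dfo_schedule(inventory, targets, settings, config,
                      segment_iterations = segment_iterations)
  res$segments$property_value <- vapply(targets, `[[`, numeric(1), property)
  structure(list(schedule = res,
                 initial_iterations = res$segments$iterations[1],
                 mean_recovery_iterations =
                   mean(res$segments$iterations[-1]),
                 property = property, increment = increment),
            class = "ramp_experiment")
}

#' @export
print.ramp_experiment <- function(x, ...) {
  cat(sprintf(paste0("Gradual %s ramp (+%g per step): initial convergence ",
                     "%d iterations, mean recovery %.1f iterations\n"),
              x$property, x$increment, x$initial_iterations,
              x$mean_recovery_iterations))
  invisible(x)
}

#' Forced full-consumption sweep
#'
#' Emulates a brewer who insists, one ingredient at a time, that a chosen
#' fermentable be consumed entirely. Starting from an unconstrained
#' optimisation of the target, each non-exempt fermentable is pinned at its
#' full stock in turn (the swarm carried over, the previous pin released)
#' and the optimiser re-converges under the constraint. The heaviest base
#' malts are exempt by default since fixing kilograms of base malt moves
#' the gravity far off target.
#'
#' @param target A product name or target row.
#' @param exempt Ingredient names never pinned.
#' @inheritParams drastic_switch_experiment
#' @return A list of class `consumption_sweep`: `pins` (tibble: pinned
#'   ingredient per segment, success, iterations, final error, and the
#'   discovered recipe as a list column) and `schedule` (the underlying
#'   `dfo_schedule_result`; its first segment is the unconstrained run).
#' @export
forced_consumption_sweep <- function(target = "Guinness Extra Stout",
                                     inventory = brew_inventory(),
                                     exempt = c("Pale Malt (UK)",
                                                "Pilsner (German)"),
                                     settings = brew_settings(),
                                     config = dfo_config(),
                                     segment_iterations = 1000) {
  if (is.character(target)) {
    products <- brew_products()
    if (!target %in% products$name) {
      abort(paste0("unknown product: ", target))
    }
    target <- products[match(target, products$name), ]
  }
  sweep_ingredients <- inventory$name[inventory$category == "fermentable" &
                                        !inventory$name %in% exempt]
  if (length(sweep_ingredients) == 0) abort("nothing to sweep")
  fixed_list <- c(list(NULL),
                  lapply(sweep_ingredients, function(nm) {
                    setNames(
                      inventory$stock_amount[inventory$name == nm], nm)
                  }))
  targets <- lapply(seq_along(fixed_list), function(i) target)
  res <- dfo_schedule(inventory, targets, settings, config,
                      segment_iterations = segment_iterations,
                      fixed = fixed_list)
  pins <- res$segments[-1, ]
  pins$pinned <- sweep_ingredients
  pins$recipe <- res$segments$best_position[-1]
  structure(list(pins = pins[, c("pinned", "segment", "transition_error",
                                 "iterations", "success", "final_error",
                                 "recipe")],
                 unconstrained = res$segments[1, ],
                 schedule = res),
            class = "consumption_sweep")
}

#' @export
print.consumption_sweep <- function(x, ...) {
  cat("Forced full-consumption sweep\n")
  print(x$pins[, c("pinned", "iterations", "success", "final_error")])
  invisible(x)
}
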