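# Small benchmark shared by the accounting tests: two contrasting products
# (an easy pale ale and an infeasible SRM-100 stout), few runs.
small_benchmark <- function(n_runs = 3) {
  prods <- brew_products()
  run_benchmark(prods[prods$product_no %in% c(7, 22), ],
                n_runs = n_runs, base_seed = 5,
                config = dfo_config(fe_budget = 20000))
}

test_that("benchmark rows aggregate exactly from the stored runs", {
  bm <- small_benchmark()
  st <- tidy(bm)
  expect_equal(nrow(st), 2)
  for (p in st$product_no) {
    rr <- bm$runs[bm$runs$product_no == p, ]
    row <- st[st$product_no == p, ]
    expect_equal(row$error_best, min(rr$best_error))
    expect_equal(row$error_worst, max(rr$best_error))
    expect_equal(row$error_median, median(rr$best_error))
    expect_equal(row$error_mean, mean(rr$best_error))
    expect_equal(row$reliability, 100 * mean(rr$success))
    if (any(rr$success)) {
      expect_equal(row$fes_median, median(rr$fes_used[rr$success]))
    } else {
      expect_true(is.na(row$fes_median))
    }
  }
  # overall aggregates recompute from the per-product rows
  g <- glance(bm)
  solved <- st[st$cases > 0, ]
  expect_equal(g$n_solved, nrow(solved))
  expect_equal(g$median_fes, median(solved$fes_median))
})

test_that("the benchmark is deterministic under the seed policy", {
  a <- small_benchmark(n_runs = 2)
  b <- small_benchmark(n_runs = 2)
  expect_equal(a$runs$best_error, b$runs$best_error)
  expect_equal(a$runs$fes_used, b$runs$fes_used)
  expect_equal(a$runs$seed, b$runs$seed)
})

test_that("a single-run benchmark collapses to that run's values", {
  prods <- brew_products()
  bm <- run_benchmark(prods[prods$product_no == 22, ], n_runs = 1,
                      base_seed = 3)
  st <- tidy(bm)
  rr <- bm$runs
  expect_equal(st$error_best, rr$best_error)
  expect_equal(st$error_worst, rr$best_error)
  expect_equal(st$error_median, rr$best_error)
  expect_true(is.na(st$error_sd) || st$error_sd == 0)
})

test_that("an over-the-ceiling colour target fails while a pale target succeeds", {
  bm <- small_benchmark()
  st <- tidy(bm)
  expect_equal(st$cases[st$product_no == 7], 0L)   # SRM 100 target
  expect_gt(st$cases[st$product_no == 22], 0L)     # SRM 7.6 target
})

test_that("benchmark reports and manifest are written", {
  bm <- small_benchmark(n_runs = 2)
  dir <- withr::local_tempdir()
  write_benchmark_report(bm, dir)
  expect_true(file.exists(file.path(dir, "error_diversity.csv")))
  expect_true(file.exists(file.path(dir, "efficiency_reliability.csv")))
  expect_true(file.exists(file.path(dir, "solution_distances.csv")))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(manifest$n_runs, 2)
  expect_equal(manifest$config$population_size, 50)
})

test_that("cycling a single product converges instantly after the first pass", {
  res <- drastic_switch_experiment(rep("Punk IPA", 3), cycles = 1,
                                   config = dfo_config(seed = 17))
  expect_true(all(res$segments$success))
  expect_equal(res$segments$iterations[2:3], c(0, 0))
})

test_that("the three-product switching loop adapts without restart", {
  res <- drastic_switch_experiment(cycles = 2,
                                   config = dfo_config(seed = 2),
                                   segment_iterations = 3000)
  expect_equal(nrow(res$segments), 6)
  expect_true(all(res$segments$success))
  # transition errors reflect the property-space jump to the new target
  expect_true(all(res$segments$transition_error[-1] > 0.05))
  # the continuous trace never rewinds the evaluation counter
  expect_true(all(diff(res$trace$fes) > 0))
})

test_that("a zero-increment ramp recovers in zero iterations", {
  ramp <- gradual_ramp_experiment(increment = 0, steps = 3,
                                  config = dfo_config(seed = 13))
  expect_equal(ramp$schedule$segments$iterations[-1], rep(0, 3))
})

test_that("gradual IBU steps re-converge faster than the initial search", {
  ramp <- gradual_ramp_experiment(increment = 5, steps = 8,
                                  config = dfo_config(seed = 23))
  segs <- ramp$schedule$segments
  expect_true(all(segs$success))
  expect_lt(ramp$mean_recovery_iterations, ramp$initial_iterations)
  # each +5 IBU step moves the error by about the increment
  expect_equal(segs$transition_error[-1], rep(5, 8), tolerance = 0.05)
  # the ramp walks the bitterness from 40 to 80
  expect_equal(segs$property_value, seq(40, 80, by = 5))
})

test_that("forced consumption pins each swept fermentable at full stock", {
  inv <- brew_inventory()
  sweep_res <- forced_consumption_sweep("Guinness Extra Stout", inv,
                                        config = dfo_config(seed = 3))
  pins <- sweep_res$pins
  # the two heaviest base malts are exempt
  expect_equal(nrow(pins), 8)
  expect_false(any(pins$pinned %in% c("Pale Malt (UK)", "Pilsner (German)")))
  for (i in seq_len(nrow(pins))) {
    stock <- inv$stock_amount[inv$name == pins$pinned[i]]
    d <- which(inv$name == pins$pinned[i])
    expect_equal(pins$recipe[[i]][d], stock)
  }
  expect_true(is.logical(pins$success))
})

test_that("recipes export to well-formed BeerXML", {
  inv <- brew_inventory()
  fit <- dfo_optimise(inv, guinness_target(),
                      config = dfo_config(seed = 6))
  path <- withr::local_tempfile(fileext = ".xml")
  write_beerxml(fit, inv, path, name = "test brew")
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "RECIPES")
  rec <- xml2::xml_find_first(doc, ".//RECIPE")
  expect_equal(xml2::xml_text(xml2::xml_find_first(rec, "./NAME")),
               "test brew")
  og <- as.numeric(xml2::xml_text(xml2::xml_find_first(rec, "./OG")))
  expect_equal(og, fit$best_properties$og, tolerance = 1e-3)
  n_ing <- length(xml2::xml_find_all(rec, ".//HOP | .//FERMENTABLE | .//YEAST"))
  expect_equal(n_ing, sum(fit$best_position > 1e-9))
})
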