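#' Forward fermentation simulator
#'
#' Maps a recipe — an amount for every ingredient in the inventory — to the
#' five organoleptic properties used as the optimisation targets:
#'
#' * **OG** (original gravity): the classic extract-potential model. Each
#'   fermentable contributes `mass_lb * (potential - 1) * 1000` gravity
#'   points per US gallon, scaled by the brewhouse efficiency and divided by
#'   the batch volume.
#' * **FG** (final gravity): each fermentable's gravity points are attenuated
#'   by the yeast's apparent attenuation scaled by that fermentable's own
#'   fermentability, so dextrine and crystal malts leave residual extract
#'   while base malts ferment out.
#' * **ABV**: `(76.08 (OG - FG) / (1.775 - OG)) * (FG / 0.794)`, the
#'   alcohol-by-volume estimate that stays accurate for strong beers.
#' * **IBU**: Tinseth utilisation. Each hop contributes
#'   `alpha_acid * mass_g * 1000 / batch_L * U(G_b, t)` with
#'   `U = 1.65 * 0.000125^(G_b - 1) * (1 - exp(-0.04 t)) / 4.15`, where the
#'   boil gravity `G_b` spreads the total extract over the boil volume.
#' * **SRM** colour: Morey's model, `SRM = 1.4922 * MCU^0.6859` with
#'   `MCU = sum(mass_lb * lovibond) / batch_gal`.
#'
#' The simulator is a pure function: identical inputs always give identical
#' outputs. The yeast amount never affects the properties (attenuation is a
#' strain property, not a pitch-rate effect); only the strain's attenuation
#' value matters.
#'
#' @param recipe A recipe: a numeric vector of amounts in inventory row
#'   order (optionally named by ingredient), a named subset of ingredients,
#'   or a data frame with `name` and `amount` columns. Amounts are in each
#'   ingredient's native unit (hops g, fermentables kg, yeast mL). A matrix
#'   with one recipe per row (D columns) is also accepted.
#' @param inventory A [brew_inventory()] tibble.
#' @param settings A [brew_settings()] object.
#' @return A tibble with columns `abv`, `ibu`, `srm`, `og`, `fg`, one row
#'   per recipe.
#' @examples
#' inv <- brew_inventory()
#' brew_properties(c("Pale Malt (UK)" = 4, "Cascade" = 50), inv)
#' @export
brew_properties <- function(recipe, inventory, settings = brew_settings()) {
  X <- as_recipe_matrix(recipe, inventory)
  cf <- sim_coefs(inventory, settings)
  as_tibble(as.data.frame(sim_properties(X, cf)))
}

# Precompute per-dimension linear coefficients so a whole population can be
# evaluated with a handful of matrix products.
sim_coefs <- function(inventory, settings) {
  stopifnot(inherits(inventory, "brew_inventory") || is.data.frame(inventory))
  batch_gal <- settings$batch_volume * GAL_PER_L
  is_ferm <- inventory$category == "fermentable"
  is_hop <- inventory$category == "hop"
  is_yeast <- inventory$category == "yeast"
  atten <- if (any(is_yeast)) inventory$attenuation[which(is_yeast)[1]] else 0
  if (is.na(atten) || atten < 0 || atten > 1) {
    abort("yeast attenuation must lie in [0, 1]")
  }
  D <- nrow(inventory)
  # gravity points (per 1000) contributed to the batch per unit amount
  c_og <- numeric(D)
  c_og[is_ferm] <- LB_PER_KG *
    (inventory$potential[is_ferm] - 1) * 1000 *
    settings$efficiency / batch_gal
  c_fg <- numeric(D)
  c_fg[is_ferm] <- c_og[is_ferm] *
    (1 - atten * inventory$fermentability[is_ferm])
  c_mcu <- numeric(D)
  c_mcu[is_ferm] <- LB_PER_KG * inventory$colour[is_ferm] / batch_gal
  # mg/L of alpha acids per gram of hop
  c_aa <- numeric(D)
  c_aa[is_hop] <- inventory$alpha_acid[is_hop] * 1000 / settings$batch_volume
  list(c_og = c_og, c_fg = c_fg, c_mcu = c_mcu, c_aa = c_aa,
       boil_scale = settings$batch_volume / settings$boil_volume,
       boil_time = settings$boil_time, stock = inventory$stock_amount)
}

# X: n x D matrix of recipes (rows). Returns n x 5 matrix abv/ibu/srm/og/fg.
sim_properties <- function(X, cf) {
  og_pts <- drop(X %*% cf$c_og)
  fg_pts <- drop(X %*% cf$c_fg)
  og <- 1 + og_pts / 1000
  fg <- 1 + fg_pts / 1000
  abv <- abv_formula(og, fg)
  gb <- 1 + og_pts * cf$boil_scale / 1000
  util <- tinseth_utilisation(gb, cf$boil_time)
  ibu <- drop(X %*% cf$c_aa) * util
  mcu <- drop(X %*% cf$c_mcu)
  srm <- 1.4922 * mcu^0.6859
  cbind(abv = abv, ibu = ibu, srm = srm, og = og, fg = fg)
}

abv_formula <- function(og, fg) {
  if (any(og >= 1.775)) {
    abort("original gravity >= 1.775 is outside the alcohol formula's domain")
  }
  (76.08 * (og - fg) / (1.775 - og)) * (fg / 0.794)
}

tinseth_utilisation <- function(boil_gravity, boil_time) {
  (1.65 * 0.000125^(boil_gravity - 1)) *
    (1 - exp(-0.04 * boil_time)) / 4.15
}

#' Individual property calculators
#'
#' The component models behind [brew_properties()], exposed separately.
#' `compute_og()` applies the extract-potential model; `compute_fg()`
#' attenuates each fermentable's share of the original extract by the
#' yeast's attenuation times that fermentable's fermentability;
#' `compute_abv()` converts an (OG, FG) pair to percent alcohol by volume;
#' `compute_ibu()` applies Tinseth utilisation; `compute_srm()` applies
#' Morey's colour model to the malt colour units.
#'
#' @inheritParams brew_properties
#' @param og,fg Specific gravities (1.0xx scale).
#' @param boil_gravity Specific gravity of the boil; when `NULL`,
#'   `compute_ibu()` derives it from the recipe's total extract spread over
#'   the boil volume.
#' @return A numeric vector (one value per recipe, or per (og, fg) pair for
#'   `compute_abv()`).
#' @examples
#' compute_abv(1.070, 1.034)  # 5.06 -> the classic dry stout, 5.1%
#' @name property-calculators
NULL

#' @rdname property-calculators
#' @export
compute_og <- function(recipe, inventory, settings = brew_settings()) {
  X <- as_recipe_matrix(recipe, inventory)
  cf <- sim_coefs(inventory, settings)
  unname(1 + drop(X %*% cf$c_og) / 1000)
}

#' @rdname property-calculators
#' @export
compute_fg <- function(og, recipe, inventory) {
  if (any(og < 1 - 1e-9)) abort("original gravity must be >= 1.000")
  X <- as_recipe_matrix(recipe, inventory)
  # split the given OG's points across fermentables by their extract share,
  # then attenuate each share by attenuation * fermentability
  cf <- sim_coefs(inventory, brew_settings())
  raw <- drop(X %*% cf$c_og)
  resid <- drop(X %*% cf$c_fg)
  frac_residual <- ifelse(raw > 0, resid / raw, 1)
  unname(1 + (og - 1) * frac_residual)
}

#' @rdname property-calculators
#' @export
compute_abv <- function(og, fg) {
  if (any(fg > og + 1e-9)) abort("final gravity cannot exceed original gravity")
  pmax(abv_formula(og, fg), 0)
}

#' @rdname property-calculators
#' @export
compute_ibu <- function(recipe, inventory, settings = brew_settings(),
                        boil_gravity = NULL) {
  X <- as_recipe_matrix(recipe, inventory)
  cf <- sim_coefs(inventory, settings)
  if (is.null(boil_gravity)) {
    boil_gravity <- 1 + drop(X %*% cf$c_og) * cf$boil_scale / 1000
  }
  util <- tinseth_utilisation(boil_gravity, settings$boil_time)
  unname(drop(X %*% cf$c_aa) * util)
}

#' @rdname property-calculators
#' @export
compute_srm <- function(recipe, inventory, settings = brew_settings()) {
  X <- as_recipe_matrix(recipe, inventory)
  cf <- sim_coefs(inventory, settings)
  unname(1.4922 * drop(X %*% cf$c_mcu)^0.6859)
}

# Coerce a recipe (vector, named vector, name/amount data frame, or matrix
# of row-recipes) to an n x D matrix in inventory order, checking bounds.
as_recipe_matrix <- function(recipe, inventory, check_bounds = TRUE) {
  D <- nrow(inventory)
  if (is.data.frame(recipe)) {
    if (!all(c("name", "amount") %in% names(recipe))) {
      abort("a recipe data frame needs 'name' and 'amount' columns")
    }
    recipe <- setNames(recipe$amount, recipe$name)
  }
  if (is.matrix(recipe)) {
    if (ncol(recipe) != D) {
      abort(paste0("recipe matrix must have ", D, " columns (one per ingredient)"))
    }
    X <- recipe
  } else if (is.numeric(recipe)) {
    if (!is.null(names(recipe))) {
      unknown <- setdiff(names(recipe), inventory$name)
      if (length(unknown)) {
        abort(paste0("unknown ingredient in recipe: ", unknown[1]))
      }
      full <- setNames(numeric(D), inventory$name)
      full[names(recipe)] <- recipe
      X <- matrix(full, nrow = 1)
    } else {
      if (length(recipe) != D) {
        abort(paste0("unnamed recipe must have length ", D))
      }
      X <- matrix(recipe, nrow = 1)
    }
  } else {
    abort("recipe must be a numeric vector, matrix or name/amount data frame")
  }
  if (check_bounds) {
    if (any(X < -1e-9)) abort("recipe amounts must be non-negative")
    over <- sweep(X, 2, inventory$stock_amount + 1e-9, ">")
    if (any(over)) {
      d <- which(apply(over, 2, any))[1]
      abort(paste0("amount of '", inventory$name[d],
                   "' exceeds the in-stock amount (",
                   inventory$stock_amount[d], " ", inventory$unit[d], ")"))
    }
  }
  colnames(X) <- inventory$name
  X
}

#' Express recipe amounts in canonical units (kilograms)
#'
#' Distance-based measures (swarm diversity, solution-distance matrices,
#' clustering inputs) need all dimensions on a common mass scale: hop grams
#' and yeast millilitres (at unit density) are converted to kilograms,
#' fermentables are already in kilograms.
#'
#' @inheritParams brew_properties
#' @return A numeric matrix (recipes in rows) in kilograms.
#' @export
canonical_amounts <- function(recipe, inventory) {
  X <- as_recipe_matrix(recipe, inventory, check_bounds = FALSE)
  scale <- ifelse(inventory$unit %in% c("g", "mL"), 1e-3, 1)
  sweep(X, 2, scale, "*")
}
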