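#' Load an ingredient inventory
#'
#' An inventory is a tibble with one row per in-stock ingredient: its
#' `name`, `category` (`"hop"`, `"fermentable"` or `"yeast"`), `stock_amount`
#' in the ingredient's native unit (`"g"` for hops, `"kg"` for fermentables,
#' `"mL"` for yeast) and the physicochemical attributes the fermentation
#' simulator needs: `alpha_acid` (mass fraction of alpha acids, hops),
#' `potential` (extract potential as specific gravity per pound per US
#' gallon, fermentables), `colour` (degrees Lovibond, fermentables),
#' `fermentability` (fraction of the extract accessible to yeast,
#' fermentables) and `attenuation` (apparent attenuation fraction, yeast).
#'
#' The row order defines the dimension index of the optimiser's search
#' space; `stock_amount` is the per-dimension upper bound (the lower bound
#' is always zero).
#'
#' Called with no arguments this returns the packaged 16-ingredient
#' microbrewery inventory (5 hops, 10 fermentables, 1 yeast) merged with the
#' packaged attribute table. The attribute table is a calibrated synthetic
#' stand-in assembled from standard maltster and hop references; every value
#' can be overridden by supplying your own `attributes` file.
#'
#' @param path Optional path to an inventory file (CSV with a header, or a
#'   JSON array of records) with columns/fields `name`, `category`,
#'   `stock_amount`, `unit`. May also carry the attribute columns directly.
#' @param attributes Optional path to an attribute table (CSV or JSON) keyed
#'   by `name`, merged into the inventory.
#' @return A tibble of class `brew_inventory`.
#' @examples
#' inv <- brew_inventory()
#' nrow(inv)   # 16
#' @export
brew_inventory <- function(path = NULL, attributes = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "inventory.csv", package = "brewdfo")
  }
  inv <- read_structured(path)
  has_attrs <- any(c("alpha_acid", "potential", "colour", "fermentability",
                     "attenuation") %in% names(inv))
  if (is.null(attributes) && !has_attrs) {
    attributes <- system.file("extdata", "attributes_synthetic.csv",
                              package = "brewdfo")
  }
  if (!is.null(attributes)) {
    attr_tbl <- read_structured(attributes)
    keep <- intersect(names(attr_tbl),
                      c("name", "alpha_acid", "potential", "colour",
                        "fermentability", "attenuation"))
    inv <- dplyr::left_join(inv, attr_tbl[keep], by = "name")
  }
  validate_inventory(inv)
}

#' Load target beer properties
#'
#' Returns a tibble of target products, one row per product, with the five
#' organoleptic properties the optimiser matches: `abv` (% alcohol by
#' volume), `ibu` (international bitterness units), `srm` (colour on the
#' Standard Reference Method scale), `og` and `fg` (original and final
#' specific gravity). With no arguments the packaged benchmark of 22
#' commercial products is returned.
#'
#' @param path Optional CSV/JSON file with columns `name`, `abv`, `ibu`,
#'   `srm`, `og`, `fg` (and optionally `product_no`).
#' @return A tibble with one row per product.
#' @export
brew_products <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "products.csv", package = "brewdfo")
  }
  prods <- read_structured(path)
  need <- c("name", "abv", "ibu", "srm", "og", "fg")
  missing_cols <- setdiff(need, names(prods))
  if (length(missing_cols)) {
    abort(paste0("product table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("abv", "ibu", "srm", "og", "fg")) {
    if (!is.numeric(prods[[col]])) {
      abort(paste0("product column '", col, "' must be numeric"))
    }
  }
  if (!"product_no" %in% names(prods)) {
    prods$product_no <- seq_len(nrow(prods))
  }
  as_tibble(prods[, c("product_no", need)])
}

#' Brewhouse settings
#'
#' The fixed process parameters of the simulated small-scale brewery.
#'
#' @param efficiency Brewhouse efficiency, the fraction of the laboratory
#'   extract potential realised in the mash. Default 0.58, typical of
#'   small-scale equipment.
#' @param batch_volume Post-boil batch volume in litres (default 20).
#' @param boil_volume Pre-boil volume in litres (default 24); the hop
#'   utilisation's boil gravity is computed over this volume.
#' @param boil_time Boil length in minutes (default 60).
#' @return A list of class `brew_settings`.
#' @export
brew_settings <- function(efficiency = 0.58, batch_volume = 20,
                          boil_volume = 24, boil_time = 60) {
  stopifnot(efficiency > 0, efficiency <= 1, batch_volume > 0,
            boil_volume > 0, boil_time >= 0)
  structure(list(efficiency = efficiency, batch_volume = batch_volume,
                 boil_volume = boil_volume, boil_time = boil_time),
            class = "brew_settings")
}

# read a CSV (header) or JSON-array-of-records file into a tibble
read_structured <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Write an inventory or product table
#'
#' Writes to CSV or JSON depending on the file extension; reading the file
#' back yields the same table (round-trip identity).
#'
#' @param x A tibble (inventory, attribute or product table).
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_brew_table <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    readr::write_csv(as.data.frame(x), path, na = "NA")
  }
  invisible(path)
}

validate_inventory <- function(inv) {
  need <- c("name", "category", "stock_amount", "unit")
  missing_cols <- setdiff(need, names(inv))
  if (length(missing_cols)) {
    abort(paste0("inventory is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("alpha_acid", "potential", "colour", "fermentability",
                "attenuation")) {
    if (!col %in% names(inv)) inv[[col]] <- NA_real_
  }
  if (nrow(inv) < 1) abort("inventory must contain at least one ingredient")
  if (anyDuplicated(inv$name)) {
    abort(paste0("duplicate ingredient name: ",
                 inv$name[duplicated(inv$name)][1]))
  }
  bad_cat <- !inv$category %in% c("hop", "fermentable", "yeast")
  if (any(bad_cat)) {
    abort(paste0("unknown category '", inv$category[bad_cat][1],
                 "' for ingredient '", inv$name[bad_cat][1], "'"))
  }
  if (any(is.na(inv$stock_amount) | inv$stock_amount < 0)) {
    bad <- which(is.na(inv$stock_amount) | inv$stock_amount < 0)[1]
    abort(paste0("negative or missing stock for ingredient '",
                 inv$name[bad], "'"))
  }
  check_attr <- function(rows, col, lo = 0, hi = 1, bounded = TRUE) {
    vals <- inv[[col]][rows]
    if (any(is.na(vals))) {
      abort(paste0(inv$category[rows][1], " '",
                   inv$name[rows][is.na(vals)][1],
                   "' is missing required attribute '", col, "'"))
    }
    if (bounded && any(vals < lo | vals > hi)) {
      abort(paste0("attribute '", col, "' of '",
                   inv$name[rows][vals < lo | vals > hi][1],
                   "' is outside [", lo, ", ", hi, "]"))
    }
  }
  hops <- which(inv$category == "hop")
  ferm <- which(inv$category == "fermentable")
  yst <- which(inv$category == "yeast")
  if (length(hops)) check_attr(hops, "alpha_acid")
  if (length(ferm)) {
    check_attr(ferm, "potential", bounded = FALSE)
    if (any(inv$potential[ferm] < 1)) {
      abort("fermentable extract potential must be a specific gravity >= 1")
    }
    check_attr(ferm, "colour", bounded = FALSE)
    if (any(inv$colour[ferm] < 0)) abort("fermentable colour must be >= 0")
    check_attr(ferm, "fermentability")
  }
  if (length(yst)) check_attr(yst, "attenuation")
  out <- as_tibble(inv[, c(need, "alpha_acid", "potential", "colour",
                           "fermentability", "attenuation")])
  class(out) <- c("brew_inventory", class(out))
  out
}

#' Generate a synthetic ingredient inventory
#'
#' Draws a random but reproducible inventory for property-based testing of
#' the optimiser and the metrics: `n_hops` hops, `n_fermentables`
#' fermentables and `n_yeast` yeast strains, with stocks and attributes
#' drawn uniformly from the given ranges.
#'
#' @param n_hops,n_fermentables,n_yeast Ingredient counts per category.
#' @param hop_stock_g,fermentable_stock_kg,yeast_stock_ml Stock ranges
#'   (length-2 numeric) in the category's native unit.
#' @param alpha_acid,potential,colour,fermentability,attenuation Attribute
#'   ranges (length-2 numeric).
#' @param seed Integer seed; the same seed yields the same inventory.
#' @return A `brew_inventory` tibble.
#' @export
generate_synthetic_inventory <- function(n_hops = 5, n_fermentables = 10,
                                         n_yeast = 1,
                                         hop_stock_g = c(20, 150),
                                         fermentable_stock_kg = c(0.25, 7),
                                         yeast_stock_ml = c(5, 20),
                                         alpha_acid = c(0.03, 0.15),
                                         potential = c(1.025, 1.040),
                                         colour = c(1, 450),
                                         fermentability = c(0, 1),
                                         attenuation = c(0.65, 0.85),
                                         seed = 1L) {
  stopifnot(n_hops >= 0, n_fermentables >= 0, n_yeast >= 0,
            n_hops + n_fermentables + n_yeast >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  runif2 <- function(n, r) runif(n, r[1], r[2])
  rows <- list()
  if (n_hops > 0) {
    rows$hop <- tibble(
      name = paste0("hop_", seq_len(n_hops)), category = "hop",
      stock_amount = runif2(n_hops, hop_stock_g), unit = "g",
      alpha_acid = runif2(n_hops, alpha_acid), potential = NA_real_,
      colour = NA_real_, fermentability = NA_real_, attenuation = NA_real_)
  }
  if (n_fermentables > 0) {
    rows$fermentable <- tibble(
      name = paste0("fermentable_", seq_len(n_fermentables)),
      category = "fermentable",
      stock_amount = runif2(n_fermentables, fermentable_stock_kg),
      unit = "kg", alpha_acid = NA_real_,
      potential = runif2(n_fermentables, potential),
      colour = runif2(n_fermentables, colour),
      fermentability = runif2(n_fermentables, fermentability),
      attenuation = NA_real_)
  }
  if (n_yeast > 0) {
    rows$yeast <- tibble(
      name = paste0("yeast_", seq_len(n_yeast)), category = "yeast",
      stock_amount = runif2(n_yeast, yeast_stock_ml), unit = "mL",
      alpha_acid = NA_real_, potential = NA_real_, colour = NA_real_,
      fermentability = NA_real_, attenuation = runif2(n_yeast, attenuation))
  }
  validate_inventory(dplyr::bind_rows(rows))
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
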