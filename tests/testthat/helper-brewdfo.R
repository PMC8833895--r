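# Shared fixture builders. Everything is generated in code; no files.

# A minimal hand-specified inventory with round-number attributes, small
# enough that expected property values can be derived by hand.
tiny_inventory <- function() {
  brewdfo:::validate_inventory(tibble::tibble(
    name = c("hopA", "base", "crystal", "yeastA"),
    category = c("hop", "fermentable", "fermentable", "yeast"),
    stock_amount = c(100, 5, 2, 10),
    unit = c("g", "kg", "kg", "mL"),
    alpha_acid = c(0.055, NA, NA, NA),
    potential = c(NA, 1.037, 1.034, NA),
    colour = c(NA, 3, 60, NA),
    fermentability = c(NA, 1, 0.2, NA),
    attenuation = c(NA, NA, NA, 0.75)))
}

# Inventory with a single fermentable, for scalar-oracle tests.
one_malt_inventory <- function(potential = 1.037, colour = 3,
                               fermentability = 1, stock = 10,
                               attenuation = 0.75) {
  brewdfo:::validate_inventory(tibble::tibble(
    name = c("malt", "yeastA"),
    category = c("fermentable", "yeast"),
    stock_amount = c(stock, 10),
    unit = c("kg", "mL"),
    alpha_acid = NA_real_,
    potential = c(potential, NA),
    colour = c(colour, NA),
    fermentability = c(fermentability, NA),
    attenuation = c(NA, attenuation)))
}

# All-fermentable inventory with unit stocks: normalised and raw coordinates
# coincide, convenient for clustering fixtures.
unit_box_inventory <- function(D = 6) {
  brewdfo:::validate_inventory(tibble::tibble(
    name = paste0("f", seq_len(D)),
    category = "fermentable",
    stock_amount = 1, unit = "kg",
    alpha_acid = NA_real_, potential = 1.035, colour = 5,
    fermentability = 1, attenuation = NA_real_))
}

# k well-separated Gaussian clouds along the diagonal of [0,1]^D, with
# between-centre distance >= `separation` times the within-cloud scale.
planted_clouds <- function(k, n_per = 25, D = 6, separation = 5,
                           seed = 1) {
  set.seed(seed)
  pos <- seq(0.1, 0.9, length.out = k)
  centres <- matrix(rep(pos, each = D), nrow = k, byrow = TRUE)
  d_min <- if (k > 1) (pos[2] - pos[1]) * sqrt(D) else 1
  sigma <- d_min / (separation * sqrt(D))
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(stats::rnorm(n_per * D, sd = sigma), n_per, D), 2,
          centres[j, ], "+")
  }))
  X <- pmin(pmax(X, 0), 1)
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# agreement of two partitions up to label permutation (for small k)
same_partition <- function(a, b) {
  ka <- sort(unique(a))
  kb <- sort(unique(b))
  if (length(ka) != length(kb)) return(FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  for (p in perms(kb)) {
    if (all(p[match(a, ka)] == b)) return(TRUE)
  }
  FALSE
}

guinness_target <- function() {
  p <- brew_products()
  p[p$product_no == 2, ]
}
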