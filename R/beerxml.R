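#' Export a recipe to BeerXML
#'
#' Writes a discovered recipe as a minimal BeerXML 1.0 `<RECIPES>` document
#' (write-only; the package never reads BeerXML back). Hops are exported
#' with their alpha-acid percentage and the full boil time, fermentables
#' with their yield and colour, yeast with its attenuation.
#'
#' @param recipe A recipe accepted by [brew_properties()], or a
#'   `dfo_result` (its best recipe is exported).
#' @param inventory A [brew_inventory()].
#' @param path Output file.
#' @param name Recipe name written into the document.
#' @param settings A [brew_settings()].
#' @return `path`, invisibly.
#' @export
write_beerxml <- function(recipe, inventory, path, name = "brewdfo recipe",
                          settings = brew_settings()) {
  if (inherits(recipe, "dfo_result")) recipe <- recipe$best_position
  X <- as_recipe_matrix(recipe, inventory)
  amounts <- X[1, ]
  props <- brew_properties(X, inventory, settings)

  doc <- xml2::xml_new_root("RECIPES")
  rec <- xml2::xml_add_child(doc, "RECIPE")
  add <- function(node, tag, value) {
    xml2::xml_add_child(node, tag, as.character(value))
  }
  add(rec, "NAME", name)
  add(rec, "VERSION", 1)
  add(rec, "TYPE", "All Grain")
  add(rec, "BATCH_SIZE", settings$batch_volume)
  add(rec, "BOIL_SIZE", settings$boil_volume)
  add(rec, "BOIL_TIME", settings$boil_time)
  add(rec, "EFFICIENCY", settings$efficiency * 100)
  add(rec, "OG", round(props$og, 4))
  add(rec, "FG", round(props$fg, 4))
  add(rec, "IBU", round(props$ibu, 1))
  add(rec, "EST_COLOR", round(props$srm, 1))
  add(rec, "ABV", round(props$abv, 2))

  hops_node <- xml2::xml_add_child(rec, "HOPS")
  ferm_node <- xml2::xml_add_child(rec, "FERMENTABLES")
  yeast_node <- xml2::xml_add_child(rec, "YEASTS")
  for (d in seq_len(nrow(inventory))) {
    amt <- amounts[d]
    if (amt <= 1e-9) next
    row <- inventory[d, ]
    if (row$category == "hop") {
      h <- xml2::xml_add_child(hops_node, "HOP")
      add(h, "NAME", row$name)
      add(h, "VERSION", 1)
      add(h, "AMOUNT", amt / 1000)  # BeerXML amounts are kilograms
      add(h, "ALPHA", row$alpha_acid * 100)
      add(h, "USE", "Boil")
      add(h, "TIME", settings$boil_time)
    } else if (row$category == "fermentable") {
      f <- xml2::xml_add_child(ferm_node, "FERMENTABLE")
      add(f, "NAME", row$name)
      add(f, "VERSION", 1)
      add(f, "TYPE", "Grain")
      add(f, "AMOUNT", amt)
      # BeerXML YIELD is percent of sucrose's 46.21 points/lb/gal
      add(f, "YIELD", round((row$potential - 1) * 1000 / 46.21 * 100, 1))
      add(f, "COLOR", row$colour)
    } else {
      y <- xml2::xml_add_child(yeast_node, "YEAST")
      add(y, "NAME", row$name)
      add(y, "VERSION", 1)
      add(y, "AMOUNT", amt / 1000)  # litres
      add(y, "ATTENUATION", row$attenuation * 100)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
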