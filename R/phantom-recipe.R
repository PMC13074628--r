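# Gelatin-Intralipid phantom recipe bookkeeping: component masses to nominal
# (recipe-defined) true water fraction.

#' Gelatin-Intralipid phantom recipe
#'
#' A gravimetric recipe for one phantom batch. The Intralipid 20\% stock is an
#' emulsion in a water background and carries solvent water, assumed 80\% of
#' the stock mass by default (`il_water_mass_fraction`); that assumption is a
#' parameter because it is a dominant uncertainty of the nominal reference.
#'
#' @param label free-text phantom label (e.g. "70% AW").
#' @param m_water added distilled water mass (g).
#' @param m_gelatin gelatin powder mass (g).
#' @param m_il Intralipid 20\% stock mass (g).
#' @param il_water_mass_fraction water mass fraction of the Intralipid stock.
#' @param m_total optional total batch mass (g); must agree with the
#'   component sum within 1e-6 g when supplied.
#' @return object of class `phantom_recipe`.
#' @export
phantom_recipe <- function(label, m_water, m_gelatin, m_il,
                           il_water_mass_fraction = 0.8, m_total = NULL) {
  if (any(c(m_water, m_gelatin, m_il) < 0))
    stop_srswater("component masses must be non-negative",
                  "srswater_domain_error")
  if (il_water_mass_fraction < 0 || il_water_mass_fraction > 1)
    stop_srswater("il_water_mass_fraction must lie in [0, 1]",
                  "srswater_domain_error")
  total <- m_water + m_gelatin + m_il
  if (!is.null(m_total) && abs(m_total - total) > 1e-6)
    stop_srswater(sprintf(
      "m_total (%.6f g) does not match component sum (%.6f g)", m_total,
      total), "srswater_domain_error")
  structure(list(label = as.character(label), m_water = m_water,
                 m_gelatin = m_gelatin, m_il = m_il,
                 il_water_mass_fraction = il_water_mass_fraction,
                 m_total = total),
            class = "phantom_recipe")
}

#' Recipe-defined true water fraction
#'
#' Mass balance including the solvent water carried by the Intralipid stock:
#' \deqn{f_{w,true} = (m_{water} + 0.8\, m_{IL}) / m_{total}}
#' with the 0.8 factor given by the recipe's `il_water_mass_fraction`.
#'
#' @param recipe a [phantom_recipe()].
#' @return water fraction in \[0, 1\].
#' @export
true_water_fraction <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  if (recipe$m_total <= 0)
    stop_srswater("m_total must be positive", "srswater_domain_error")
  (recipe$m_water + recipe$il_water_mass_fraction * recipe$m_il) /
    recipe$m_total
}

#' Added-water fraction of a recipe
#'
#' Added distilled water divided by total batch mass; the quantity the "AW"
#' phantom labels refer to (it excludes solvent water in the Intralipid
#' stock).
#'
#' @param recipe a [phantom_recipe()].
#' @return fraction in \[0, 1\].
#' @export
added_water_fraction <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  if (recipe$m_total <= 0)
    stop_srswater("m_total must be positive", "srswater_domain_error")
  recipe$m_water / recipe$m_total
}

#' Load a recipe table from CSV
#'
#' Expected columns: `label`, `m_water_g`, `m_gelatin_g`, `m_il_g`, and
#' optionally `il_water_mass_fraction`. Rows violating recipe invariants are
#' rejected with an error naming the row.
#'
#' @param path CSV file path.
#' @return list of [phantom_recipe()] objects (empty list for an empty file).
#' @export
load_recipe_table <- function(path) {
  if (!file.exists(path))
    stop_srswater(sprintf("recipe file not found: %s", path),
                  "srswater_io_error")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) return(list())
  need <- c("label", "m_water_g", "m_gelatin_g", "m_il_g")
  if (!all(need %in% names(df)))
    stop_srswater(paste("recipe CSV must contain columns:",
                        paste(need, collapse = ", ")),
                  "srswater_parse_error")
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    ilw <- if ("il_water_mass_fraction" %in% names(df) &&
               is.finite(row$il_water_mass_fraction))
      row$il_water_mass_fraction else 0.8
    tryCatch(
      phantom_recipe(row$label, row$m_water_g, row$m_gelatin_g, row$m_il_g,
                     il_water_mass_fraction = ilw),
      srswater_error = function(e)
        stop_srswater(sprintf("recipe row %d ('%s'): %s", i, row$label,
                              conditionMessage(e)), "srswater_parse_error"))
  })
}
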