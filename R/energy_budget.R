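# Food-store intake, metabolizable energy, and PUFA accounting.
# Composition constants are data, not code: they ship in a versioned JSON
# config (inst/extdata/compositions.json) seeded with the study diets —
# standard rodent pellets and sunflower seeds — so other diets can be
# modelled by pointing at a different file.

#' Food composition constants
#'
#' Per-100 g composition of one food item: metabolizable energy (MJ/100 g),
#' total fat, total PUFA, and its linoleic (LA, 18:2 n-6) and alpha-linolenic
#' (ALA, 18:3 n-3) acid components (g/100 g). Components must satisfy
#' `la + ala <= pufa <= fat` within a 0.1 g/100 g slack for unlisted minor
#' PUFAs.
#'
#' @param name Item name, e.g. `"pellets"`.
#' @param energy_mj_per_100g Metabolizable energy, MJ per 100 g.
#' @param fat_g_per_100g Total fat, g per 100 g.
#' @param pufa_g_per_100g Total PUFA, g per 100 g.
#' @param la_g_per_100g Linoleic acid, g per 100 g.
#' @param ala_g_per_100g Alpha-linolenic acid, g per 100 g.
#' @return A list of class `food_composition`.
#' @export
food_composition <- function(name, energy_mj_per_100g, fat_g_per_100g,
                             pufa_g_per_100g, la_g_per_100g,
                             ala_g_per_100g = 0) {
  vals <- c(energy_mj_per_100g, fat_g_per_100g, pufa_g_per_100g,
            la_g_per_100g, ala_g_per_100g)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("composition values must be finite and non-negative", call. = FALSE)
  slack <- 0.1  # g/100 g allowance for minor PUFAs not itemized
  if (la_g_per_100g + ala_g_per_100g > pufa_g_per_100g + slack)
    stop("LA + ALA exceed total PUFA beyond the 0.1 g/100 g slack",
         call. = FALSE)
  if (pufa_g_per_100g > fat_g_per_100g + slack)
    stop("PUFA exceeds total fat", call. = FALSE)
  structure(list(name = name,
                 energy_mj_per_100g = energy_mj_per_100g,
                 fat_g_per_100g = fat_g_per_100g,
                 pufa_g_per_100g = pufa_g_per_100g,
                 la_g_per_100g = la_g_per_100g,
                 ala_g_per_100g = ala_g_per_100g),
            class = "food_composition")
}

#' Load food compositions from a JSON config
#'
#' @param path JSON file: an array of objects with the fields of
#'   [food_composition()]. Defaults to the packaged study-diet constants
#'   (pellets at 1.32 MJ/100 g, sunflower seeds at 2.45 MJ/100 g).
#' @return Named list of `food_composition` objects.
#' @export
read_compositions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compositions.json",
                        package = "hiberphen", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- lapply(raw, function(x)
    food_composition(x$name, x$energy_mj_per_100g, x$fat_g_per_100g,
                     x$pufa_g_per_100g, x$la_g_per_100g,
                     if (is.null(x$ala_g_per_100g)) 0 else x$ala_g_per_100g))
  names(comps) <- vapply(comps, `[[`, "", "name")
  comps
}

#' Metabolizable energy of a food mass
#'
#' Exactly linear: `mass_g * energy_mj_per_100g / 100`. 2000 g of pellets at
#' 1.32 MJ/100 g is 26.4 MJ.
#'
#' @param mass_g Mass in grams, non-negative (vectorized).
#' @param comp A [food_composition()].
#' @return Energy in MJ.
#' @export
energy_of <- function(mass_g, comp) {
  stopifnot(inherits(comp, "food_composition"))
  if (any(mass_g < 0)) stop("mass must be non-negative", call. = FALSE)
  mass_g * comp$energy_mj_per_100g / 100
}

#' PUFA content of a food mass
#'
#' Linear scaling of total PUFA and its LA / ALA components.
#'
#' @inheritParams energy_of
#' @return A data frame with columns `pufa_g`, `la_g`, `ala_g`.
#' @export
pufa_of <- function(mass_g, comp) {
  stopifnot(inherits(comp, "food_composition"))
  if (any(mass_g < 0)) stop("mass must be non-negative", call. = FALSE)
  data.frame(pufa_g = mass_g * comp$pufa_g_per_100g / 100,
             la_g = mass_g * comp$la_g_per_100g / 100,
             ala_g = mass_g * comp$ala_g_per_100g / 100)
}

#' Food budget for one individual
#'
#' Intake is provided minus remaining per item; the budget reports per-item
#' intake mass, intake as percent of provided, metabolizable energy and PUFA
#' of both provision and intake, plus totals across items.
#'
#' @param cohort_row One row of a validated cohort table ([read_cohort()]).
#' @param comps Named list of [food_composition()]s containing `pellets`
#'   and `seeds` (see [read_compositions()]).
#' @return A one-row data frame: `individual_id`, then per item
#'   `<item>_provided_g`, `<item>_remaining_g`, `<item>_intake_g`,
#'   `<item>_intake_pct`, `<item>_provided_mj`, `<item>_intake_mj`,
#'   `<item>_intake_pufa_g`, and totals `provided_mj`, `intake_mj`,
#'   `intake_pufa_g`, `intake_la_g`, `intake_ala_g`.
#' @export
budget_for <- function(cohort_row, comps = read_compositions()) {
  stopifnot(nrow(cohort_row) == 1L, all(c("pellets", "seeds") %in%
                                          names(comps)))
  out <- data.frame(individual_id = cohort_row$individual_id,
                    stringsAsFactors = FALSE)
  tot_prov_mj <- tot_in_mj <- tot_pufa <- tot_la <- tot_ala <- 0
  for (item in c("pellets", "seeds")) {
    comp <- comps[[item]]
    prov <- cohort_row[[paste0(item, "_provided_g")]]
    rem <- cohort_row[[paste0(item, "_remaining_g")]]
    if (rem > prov)
      stop(item, " remaining exceeds provided", call. = FALSE)
    intake <- prov - rem
    p <- pufa_of(intake, comp)
    out[[paste0(item, "_provided_g")]] <- prov
    out[[paste0(item, "_remaining_g")]] <- rem
    out[[paste0(item, "_intake_g")]] <- intake
    out[[paste0(item, "_intake_pct")]] <-
      if (prov > 0) 100 * intake / prov else NA_real_
    out[[paste0(item, "_provided_mj")]] <- energy_of(prov, comp)
    out[[paste0(item, "_intake_mj")]] <- energy_of(intake, comp)
    out[[paste0(item, "_intake_pufa_g")]] <- p$pufa_g
    tot_prov_mj <- tot_prov_mj + energy_of(prov, comp)
    tot_in_mj <- tot_in_mj + energy_of(intake, comp)
    tot_pufa <- tot_pufa + p$pufa_g
    tot_la <- tot_la + p$la_g
    tot_ala <- tot_ala + p$ala_g
  }
  out$provided_mj <- tot_prov_mj
  out$intake_mj <- tot_in_mj
  out$intake_pufa_g <- tot_pufa
  out$intake_la_g <- tot_la
  out$intake_ala_g <- tot_ala
  out
}

#' Food budgets for a whole cohort
#'
#' @param cohort Validated cohort table.
#' @inheritParams budget_for
#' @return Data frame of [budget_for()] rows, one per individual.
#' @export
budget_table <- function(cohort, comps = read_compositions()) {
  do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
    budget_for(cohort[i, , drop = FALSE], comps)))
}
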