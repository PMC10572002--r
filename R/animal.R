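#' Animal specification
#'
#' Bundles everything the balance solver needs to know about one cow:
#' morphology (mass, optional measured shoulder height), haircoat,
#' physiological limits, lactation targets and milk composition, diet
#' mixes and excretion properties. Physiological limits (core
#' temperature band, sweating cap, panting cap, vasomotor conductivity
#' band) default to the calibrated values in [bt_params()] but can be
#' overridden per animal.
#'
#' @param mass_kg body mass, kg
#' @param height_cm optional measured shoulder height (cm); default is
#'   isometric scaling from the 682 kg / 147.3 cm reference
#' @param coat a [coat_spec()]
#' @param milk_target_kgd target (maximum expected) daily milk, kg/day;
#'   0 for a nonlactating animal
#' @param milk_fat_pct,milk_protein_pct milk composition, percent
#' @param milk_efficiency thermodynamic feed-to-milk energy conversion
#'   efficiency, fraction in (0, 1)
#' @param fecal_water_frac mass fraction of water in faeces, \[0, 1)
#' @param calving_month,calving_day calving date (non-leap calendar)
#' @param shade_available may the animal use shade outdoors?
#' @param diet_summer,diet_winter named percentages over the diet types
#'   `HPG`, `HEG`, `MPG`, `HPF`, `HEF`; each must sum to 100
#' @param sweat_cap_g_m2h cutaneous evaporation cap override
#' @return an `animal_spec`
#' @export
animal_spec <- function(mass_kg,
                        height_cm = NULL,
                        coat = coat_spec(),
                        milk_target_kgd = 0,
                        milk_fat_pct = 3.2,
                        milk_protein_pct = 3.5,
                        milk_efficiency = bt_params()$milk_efficiency,
                        fecal_water_frac = 0.80,
                        calving_month = 9,
                        calving_day = 5,
                        shade_available = TRUE,
                        diet_summer = c(HPF = 100),
                        diet_winter = c(HPF = 100),
                        sweat_cap_g_m2h = bt_params()$sweat_cap_g_m2h) {
  stopifnot_scalar(mass_kg, "mass_kg")
  if (mass_kg <= 0) stop("mass_kg must be positive")
  stopifnot(inherits(coat, "coat_spec"))
  if (milk_target_kgd < 0) stop("milk_target_kgd must be >= 0")
  if (milk_efficiency <= 0 || milk_efficiency >= 1)
    stop("milk_efficiency must be in (0, 1)")
  if (fecal_water_frac < 0 || fecal_water_frac >= 1)
    stop("fecal_water_frac must be in [0, 1)")
  if (!(calving_month %in% 1:12)) stop("calving_month must be in 1..12")
  check_mix <- function(mix, what) {
    bad <- setdiff(names(mix), diet_types())
    if (length(bad)) stop(what, ": unknown diet type(s) ",
                          paste(bad, collapse = ", "))
    if (abs(sum(mix) - 100) > 0.1)
      stop(what, " percentages must sum to 100")
    mix
  }
  structure(list(mass_kg = mass_kg,
                 height_cm = height_cm,
                 coat = coat,
                 milk_target_kgd = milk_target_kgd,
                 milk_fat_pct = milk_fat_pct,
                 milk_protein_pct = milk_protein_pct,
                 milk_efficiency = milk_efficiency,
                 fecal_water_frac = fecal_water_frac,
                 calving_month = calving_month,
                 calving_day = calving_day,
                 shade_available = isTRUE(shade_available),
                 diet_summer = check_mix(diet_summer, "diet_summer"),
                 diet_winter = check_mix(diet_winter, "diet_winter"),
                 sweat_cap_g_m2h = sweat_cap_g_m2h),
            class = "animal_spec")
}

#' @export
print.animal_spec <- function(x, ...) {
  cat(sprintf("<animal_spec> %.0f kg%s, milk target %.1f kg/d (%.2f%% fat, %.2f%% protein)\n",
              x$mass_kg,
              if (is.null(x$height_cm)) "" else sprintf(", %.1f cm", x$height_cm),
              x$milk_target_kgd, x$milk_fat_pct, x$milk_protein_pct))
  cat(sprintf("  calving %d/%d, shade %s, fecal water %.0f%%\n",
              x$calving_day, x$calving_month,
              if (x$shade_available) "available" else "absent",
              100 * x$fecal_water_frac))
  invisible(x)
}

## geometry for an animal, honouring a measured height override
animal_geometry <- function(animal, posture = "standing",
                            params = bt_params()) {
  h <- if (is.null(animal$height_cm)) NULL else animal$height_cm / 100
  scale_morphology(animal$mass_kg, posture = posture, height_m = h,
                   params = params)
}
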