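#' Diet type composition table
#'
#' Five diet archetypes (high-protein grain, high-energy grain, medium
#' protein+grain, high-protein forage, high-energy forage) with dry
#' matter fraction, composition, metabolisable energy density,
#' digestibility and fermentation-heat fraction. The two forage
#' dry-matter fractions (77.5% HPF, 31.5% HEF) are measured fixture
#' values; the remaining magnitudes are representative feed-table
#' values and can be replaced via the CSV interface.
#'
#' @return data.frame, one row per diet type.
#' @export
diet_table <- function() {
  data.frame(
    diet_type = c("HPG", "HEG", "MPG", "HPF", "HEF"),
    dm_frac   = c(0.86, 0.87, 0.60, 0.775, 0.315),
    cp_pct    = c(22,   14,   16,   20,    13),
    fat_pct   = c(4.0,  4.5,  3.5,  2.8,   3.0),
    fiber_pct = c(18,   16,   25,   42,    48),
    starch_pct = c(28,  38,   24,   4,     6),
    me_mj_per_kg_dm = c(12.0, 12.5, 11.0, 9.5, 10.5),
    digestibility = c(0.75, 0.75, 0.68, 0.62, 0.68),
    ferment_heat_frac = c(0.05, 0.05, 0.06, 0.07, 0.07),
    stringsAsFactors = FALSE
  )
}

diet_types <- function() diet_table()$diet_type

#' Read a diet composition CSV
#'
#' Schema-checked reader for the editable diet table (same columns as
#' [diet_table()]).
#' @param path CSV path
#' @return data.frame in the [diet_table()] schema
#' @export
read_diet_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- names(diet_table())
  if (!setequal(names(tab), need))
    stop("diet CSV must have exactly the columns: ",
         paste(need, collapse = ", "))
  if (any(tab$dm_frac <= 0 | tab$dm_frac > 1))
    stop("dm_frac must be in (0, 1]")
  tab[, need]
}

## Mix-weighted property of a diet percentage mix.
diet_property <- function(mix, column, table = diet_table()) {
  if (abs(sum(mix) - 100) > 0.1) stop("diet mix must sum to 100%")
  idx <- match(names(mix), table$diet_type)
  if (anyNA(idx)) stop("unknown diet type in mix")
  sum(mix / 100 * table[[column]][idx])
}

#' Wood (gamma) lactation curve
#'
#' Daily yield `a t^b exp(-|c| t)` over days in milk, with the scale `a`
#' normalised so the curve's maximum equals the animal's target peak.
#' The peak falls at `t = b/|c|`; yield is zero beyond the 305-day
#' milking period.
#'
#' @param t_days days in milk (vectorised, >= 0)
#' @param peak_target_kgd peak daily milk, kg/day
#' @param b,c shape constants (defaults near a day-50 peak)
#' @param milking_days length of lactation (days)
#' @return daily yield, kg/day
#' @export
wood_yield <- function(t_days, peak_target_kgd,
                       b = bt_params()$wood_b, c = bt_params()$wood_c,
                       milking_days = bt_params()$milking_days) {
  if (b <= 0) stop("Wood parameter b must be positive")
  if (c == 0) stop("Wood parameter c must be nonzero")
  if (any(t_days < 0)) stop("days in milk must be >= 0")
  cc <- abs(c)
  t_peak <- b / cc
  a <- peak_target_kgd / (t_peak ^ b * exp(-b))
  y <- a * t_days ^ b * exp(-cc * t_days)
  y[t_days == 0] <- 0
  y[t_days > milking_days] <- 0
  y
}

#' Energy-corrected milk
#'
#' Standardises milk mass to reference fat and protein content with the
#' fixed linear formula
#' `ECM = 0.3246 milk + 12.86 fat + 7.04 protein` (all kg).
#'
#' @param milk_kg,fat_kg,protein_kg component masses (>= 0)
#' @return ECM, kg
#' @export
ecm <- function(milk_kg, fat_kg, protein_kg) {
  if (any(milk_kg < 0) || any(fat_kg < 0) || any(protein_kg < 0))
    stop("ECM inputs must be non-negative")
  0.3246 * milk_kg + 12.86 * fat_kg + 7.04 * protein_kg
}

#' Energy flow into milk
#'
#' Milk energy density from its composition (fat, protein and a fixed
#' lactose fraction at standard combustion energies), converted to a
#' steady power.
#'
#' @param milk_kgd daily milk, kg/day
#' @param fat_pct,protein_pct composition, percent
#' @param params see [bt_params()]
#' @return energy flow, W
#' @export
milk_energy <- function(milk_kgd, fat_pct, protein_pct,
                        params = bt_params()) {
  e_kj_per_kg <- 10 * (params$e_fat_kJ_g * fat_pct +
                         params$e_protein_kJ_g * protein_pct +
                         params$e_lactose_kJ_g * params$lactose_pct)
  milk_kgd * e_kj_per_kg * 1000 / 86400
}

#' Feed requirement from the energy budget
#'
#' Dry matter intake covers maintenance (at the maintenance efficiency
#' of metabolisable energy) plus milk energy at the milk conversion
#' efficiency, divided by the mix-weighted ME density; as-fed mass adds
#' the feed water via the dry-matter fraction. Fermentation heat (a
#' diet-specific fraction of ME intake) is returned for crediting to
#' the generation term.
#'
#' @param maintenance_W maintenance heat production, W
#' @param milk_energy_W milk energy flow, W
#' @param efficiency feed-to-milk conversion efficiency (0, 1)
#' @param diet_mix named diet percentages (sum 100)
#' @param table diet composition table
#' @param params see [bt_params()]
#' @return list: `dmi_kgd`, `as_fed_kgd`, `feed_water_kgd`,
#'   `ferment_W`, `me_intake_W`
#' @export
feed_requirement <- function(maintenance_W, milk_energy_W, efficiency,
                             diet_mix, table = diet_table(),
                             params = bt_params()) {
  if (efficiency <= 0 || efficiency >= 1)
    stop("efficiency must be in (0, 1)")
  me_density <- diet_property(diet_mix, "me_mj_per_kg_dm", table)
  if (me_density <= 0) stop("diet mix has zero ME density")
  dm_frac <- diet_property(diet_mix, "dm_frac", table)
  me_need_W <- maintenance_W / params$maint_km + milk_energy_W / efficiency
  me_need_MJd <- me_need_W * 86400 / 1e6
  dmi <- me_need_MJd / me_density
  as_fed <- dmi / dm_frac
  list(dmi_kgd = dmi, as_fed_kgd = as_fed,
       feed_water_kgd = as_fed - dmi,
       ferment_W = diet_property(diet_mix, "ferment_heat_frac", table) *
         me_need_W,
       me_intake_W = me_need_W)
}

#' Daily water mass balance
#'
#' Itemises the water budget and returns the drinking water that closes
#' it: outputs are milk water, fecal water (fecal dry matter scaled by
#' the fecal water fraction), urine (baseline plus a protein-intake
#' term) and evaporative losses; inputs are feed water, metabolic water
#' (fixed yield per kg dry matter oxidised) and drinking. Drinking is
#' floored at zero.
#'
#' @param dmi_kgd dry matter intake, kg/day
#' @param diet_mix named diet percentages
#' @param milk_kgd milk production, kg/day
#' @param fecal_water_frac water mass fraction of faeces \[0, 1)
#' @param evap_kgd cutaneous + respiratory vapour, kg/day
#' @param milk_fat_pct,milk_protein_pct milk composition for its solids
#' @param table diet composition table
#' @param params see [bt_params()]
#' @return a `mass_budget` list with all components (kg/day) and the
#'   closure residual
#' @export
water_balance <- function(dmi_kgd, diet_mix, milk_kgd, fecal_water_frac,
                          evap_kgd, milk_fat_pct = 3.2,
                          milk_protein_pct = 3.5, table = diet_table(),
                          params = bt_params()) {
  if (fecal_water_frac >= 1 || fecal_water_frac < 0)
    stop("fecal_water_frac must be in [0, 1)")
  dm_frac <- diet_property(diet_mix, "dm_frac", table)
  digest <- diet_property(diet_mix, "digestibility", table)
  cp <- diet_property(diet_mix, "cp_pct", table)

  as_fed <- dmi_kgd / dm_frac
  feed_water <- as_fed - dmi_kgd
  fecal_dm <- (1 - digest) * dmi_kgd
  fecal_water <- fecal_dm * fecal_water_frac / (1 - fecal_water_frac)
  solids_frac <- (milk_fat_pct + milk_protein_pct +
                    params$lactose_pct + params$ash_pct) / 100
  milk_water <- milk_kgd * (1 - solids_frac)
  dm_ox <- digest * dmi_kgd                       # oxidisable mass
  metab_water <- params$metab_water_kg_kgdm * dm_ox
  urine <- params$urine_base_kg + params$urine_cp_coef * (cp / 100) * dmi_kgd
  out_total <- milk_water + fecal_water + urine + evap_kgd
  drinking <- max(0, out_total - feed_water - metab_water)
  budget <- list(drinking_kgd = drinking, feed_water_kgd = feed_water,
                 metab_water_kgd = metab_water, milk_water_kgd = milk_water,
                 fecal_dm_kgd = fecal_dm, fecal_water_kgd = fecal_water,
                 urine_kgd = urine, evap_kgd = evap_kgd,
                 dmi_kgd = dmi_kgd, as_fed_kgd = as_fed,
                 residual_kgd = drinking + feed_water + metab_water -
                   out_total)
  # residual is nonzero only when the zero floor binds
  class(budget) <- "mass_budget"
  budget
}

#' @export
print.mass_budget <- function(x, ...) {
  cat(sprintf("<mass_budget> drinking %.1f kg/d (feed water %.1f, metabolic %.1f)\n",
              x$drinking_kgd, x$feed_water_kgd, x$metab_water_kgd))
  cat(sprintf("  out: milk water %.1f, fecal %.1f, urine %.1f, vapour %.1f kg/d\n",
              x$milk_water_kgd, x$fecal_water_kgd, x$urine_kgd, x$evap_kgd))
  invisible(x)
}
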