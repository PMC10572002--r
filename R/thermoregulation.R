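#' Metabolic band: resting and active-target rates
#'
#' Resting heat production follows `a * M^0.75`. The active target adds
#' the activity multiplier, the heat increment of milk synthesis (milk
#' energy flow times `1/efficiency - 1`) and rumen fermentation heat
#' (credited as a fraction of metabolisable-energy intake). The
#' cold-action threshold is 5% above the active target.
#'
#' @param animal an [animal_spec()]
#' @param milk_fraction fraction (0..1) of the daily milk target
#' @param milk_target_kgd target daily milk; defaults to the animal's
#' @param diet_mix named diet percentages for fermentation heat
#' @param params see [bt_params()]
#' @return list: `resting_W`, `active_W`, `cold_threshold_W`,
#'   `milk_heat_W`, `ferment_W`, `milk_energy_W`, `me_intake_W`
#' @export
metabolic_band <- function(animal, milk_fraction = 1,
                           milk_target_kgd = animal$milk_target_kgd,
                           diet_mix = animal$diet_summer,
                           params = bt_params()) {
  if (milk_fraction < 0 || milk_fraction > 1)
    stop("milk_fraction must be within [0, 1]")
  rest <- params$rest_coef * animal$mass_kg ^ 0.75
  milk_e <- milk_energy(milk_fraction * milk_target_kgd,
                        animal$milk_fat_pct, animal$milk_protein_pct, params)
  milk_heat <- milk_e * (1 / animal$milk_efficiency - 1)
  me_intake <- rest / params$maint_km + milk_e / animal$milk_efficiency
  ferm <- diet_property(diet_mix, "ferment_heat_frac") * me_intake
  active <- rest * params$act_mult + milk_heat + ferm
  list(resting_W = rest, active_W = active,
       cold_threshold_W = params$cold_margin * active,
       milk_heat_W = milk_heat, ferment_W = ferm,
       milk_energy_W = milk_e, me_intake_W = me_intake)
}

## Map a cascade coordinate to a regulation state.
## Hot direction (c >= 0), one unit per stage in fixed order:
##   shade (free) -> vasodilation -> sweating -> panting -> core rise.
## Cold direction (c < 0): vasoconstriction then piloerection.
## The shade stage is skipped (zero width) when no shade is available.
cascade_state <- function(c_val, shade_width, params = bt_params()) {
  ramp <- function(x) pmin(1, pmax(0, x))
  if (c_val >= 0) {
    s <- c_val
    shade <- if (shade_width > 0) ramp(s) else 0
    s <- s - shade_width
    dilate <- ramp(s)
    sweat <- ramp(s - 1)
    pant_f <- ramp(s - 2)
    core_f <- ramp(s - 3)
    regulation_state(
      shade_frac = shade,
      k_flesh = params$k_flesh_mid +
        dilate * (params$k_flesh_max - params$k_flesh_mid),
      sweat_level = sweat,
      panting = 1 + pant_f * (params$pant_max - 1),
      tcore_c = params$tcore_set + core_f * (params$tcore_hi - params$tcore_set))
  } else {
    constrict <- ramp(-c_val)
    pilo <- ramp(-c_val - 1)
    regulation_state(
      k_flesh = params$k_flesh_mid -
        constrict * (params$k_flesh_mid - params$k_flesh_min),
      piloerection = 1 + pilo * (params$pilo_max - 1))
  }
}

## Blend paired sun/shade microhabitats for a partial shade fraction.
## Air temperature is shared; radiation and ground temperature mix
## linearly with the shade fraction.
blend_env <- function(env_sun, env_shade, frac) {
  if (is.null(env_shade) || frac <= 0) return(env_sun)
  mix <- function(a, b) (1 - frac) * a + frac * b
  hourly_env(env_sun$hour, env_sun$tair_c,
             mix(env_sun$tground_c, env_shade$tground_c),
             env_sun$tsky_c, env_sun$wind_ms, env_sun$rh_pct,
             mix(env_sun$solar_direct_Wm2, env_shade$solar_direct_Wm2),
             mix(env_sun$solar_diffuse_Wm2, env_shade$solar_diffuse_Wm2),
             env_sun$zenith_deg, frac >= 1)
}

#' One hour of behavioural and physiological thermoregulation
#'
#' Applies the response cascade in a fixed order until the required heat
#' generation matches the animal's target rate. Hot side: shade use (if
#' available, continuous 0-100%), vasodilation, sweating up to the
#' per-area cap, panting up to the ventilation cap, then a core
#' temperature rise to the top of the allowed band; if the target still
#' cannot be dissipated, the milk fraction is reduced by bisection to
#' the feasibility boundary (the model maximises milk production). Cold
#' side: vasoconstriction then piloerection; beyond that the animal
#' raises generation above target, and is flagged cold-stressed past 5%
#' above the active target, hypothermic when the generation bracket is
#' exhausted. Stages are engaged minimally (the cascade stops at the
#' first state that meets the target), which also minimises water use.
#'
#' @param animal an [animal_spec()]
#' @param env_sun the sun-microhabitat (or chamber) environment
#' @param env_shade optional paired full-shade environment
#' @param milk_target_kgd the day's milk target (defaults to the
#'   animal's maximum)
#' @param params see [bt_params()]
#' @param geom optional precomputed geometry
#' @return list: `state`, `budget`, `metab_W`, `milk_fraction`,
#'   `milk_kgd`, `water_g_h` (cutaneous + respiratory), `flag` (one of
#'   none, heat-stressed, hyperthermic, cold-stressed, hypothermic),
#'   `band` (the metabolic band at the achieved milk), `cascade_c`.
#' @export
regulate_hour <- function(animal, env_sun, env_shade = NULL,
                          milk_target_kgd = animal$milk_target_kgd,
                          params = bt_params(), geom = NULL) {
  geom <- geom %||% animal_geometry(animal, "standing", params)
  shade_w <- if (!is.null(env_shade) && animal$shade_available) 1 else 0
  n_hot <- 4 + shade_w

  req <- function(c_val) {
    st <- cascade_state(c_val, shade_w, params)
    ev <- blend_env(env_sun, env_shade, st$shade_frac)
    solve_required_generation(animal, ev, st, params, geom)
  }
  target_at <- function(mf)
    metabolic_band(animal, mf, milk_target_kgd, params = params)

  band_full <- target_at(1)
  target <- band_full$active_W

  r0 <- req(0)
  flag <- "none"
  milk_frac <- 1

  if (r0$q_gen_W < target || r0$feasible == "hot_limit") {
    ## -- hot side: walk stages until dissipation reaches the target ----
    budget <- r0; c_op <- 0; solved <- FALSE
    prev <- 0
    for (s in seq_len(n_hot)) {
      rs <- req(s)
      if (rs$q_gen_W >= target && rs$feasible != "hot_limit") {
        c_op <- stats::uniroot(function(cc) req(cc)$q_gen_W - target,
                               c(prev, s), tol = 1e-4)$root
        budget <- req(c_op)
        solved <- TRUE
        break
      }
      prev <- s
      budget <- rs
    }
    if (!solved) {
      ## full cascade cannot carry the full-milk target: cut milk back
      mr_max <- budget$q_gen_W            # dissipation ceiling
      c_op <- n_hot
      if (target_at(0)$active_W >= mr_max) {
        milk_frac <- 0
        flag <- "hyperthermic"
      } else {
        lo <- 0; hi <- 1
        for (i in 1:40) {                 # bisect to the feasibility edge
          mid <- (lo + hi) / 2
          if (target_at(mid)$active_W <= mr_max) lo <- mid else hi <- mid
        }
        milk_frac <- lo
        flag <- "heat-stressed"
      }
    }
    metab <- if (solved) target else target_at(milk_frac)$active_W
  } else {
    ## -- cold side ------------------------------------------------------
    c_op <- 0; budget <- r0
    for (s in c(-1, -2)) {
      if (budget$q_gen_W <= target) break
      rs <- req(s)
      if (rs$q_gen_W <= target) {
        c_op <- stats::uniroot(function(cc) req(cc)$q_gen_W - target,
                               c(s, s + 1), tol = 1e-4)$root
        budget <- req(c_op)
        break
      }
      c_op <- s
      budget <- rs
    }
    metab <- max(target, budget$q_gen_W)
    if (budget$feasible == "cold_limit") flag <- "hypothermic"
    else if (budget$q_gen_W > band_full$cold_threshold_W) flag <- "cold-stressed"
  }

  band <- target_at(milk_frac)
  list(state = budget$state, budget = budget, metab_W = metab,
       milk_fraction = milk_frac,
       milk_kgd = milk_frac * milk_target_kgd,
       water_g_h = budget$water_cut_g_h + budget$water_resp_g_h,
       flag = flag, band = band, cascade_c = c_op)
}
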