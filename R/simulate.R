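#' Metabolic chamber sweep
#'
#' Runs the thermoregulation model over a grid of chamber conditions
#' (air = radiant temperature, wind, relative humidity, optional solar
#' beam) and returns one row per grid point with the achieved milk,
#' metabolic rate, water fluxes and engaged responses. This is the
#' response-surface driver behind thermal-neutral-zone curves, milk
#' "climate cliff" maps and water-needs surfaces.
#'
#' @param animal an [animal_spec()]
#' @param temps_c,winds_ms,rh_pct,solar_Wm2 grid axes (numeric vectors)
#' @param milk_target_kgd daily milk target (0 for nonlactating curves)
#' @param params see [bt_params()]
#' @return data.frame with columns `tair_c`, `wind_ms`, `rh_pct`,
#'   `solar_Wm2`, `milk_kgd`, `milk_fraction`, `metab_W`,
#'   `water_cut_g_h`, `water_resp_g_h`, `cut_flux_max_g_m2h`,
#'   `sweat_level`, `panting`, `tcore_c`, `flag`
#' @export
chamber_sweep <- function(animal, temps_c, winds_ms = 1, rh_pct = 50,
                          solar_Wm2 = 0,
                          milk_target_kgd = animal$milk_target_kgd,
                          params = bt_params()) {
  grid <- expand.grid(tair_c = temps_c, wind_ms = winds_ms,
                      rh_pct = rh_pct, solar_Wm2 = solar_Wm2,
                      KEEP.OUT.ATTRS = FALSE)
  geom <- animal_geometry(animal, "standing", params)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gpt <- grid[i, ]
    env <- chamber_env(gpt$tair_c, gpt$wind_ms, gpt$rh_pct, gpt$solar_Wm2)
    r <- regulate_hour(animal, env, env_shade = NULL,
                       milk_target_kgd = milk_target_kgd,
                       params = params, geom = geom)
    out[[i]] <- data.frame(
      gpt,
      milk_kgd = r$milk_kgd, milk_fraction = r$milk_fraction,
      metab_W = r$metab_W,
      water_cut_g_h = r$budget$water_cut_g_h,
      water_resp_g_h = r$budget$water_resp_g_h,
      cut_flux_max_g_m2h = r$budget$cut_flux_max_g_m2h,
      sweat_level = r$state$sweat_level,
      panting = r$state$panting,
      tcore_c = r$state$tcore_c,
      flag = r$flag,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Onset of thermoregulatory water loss along a temperature sweep
#'
#' Scans air temperature upward and reports the first temperature at
#' which active evaporative recruitment (sweating, or panting above the
#' resting ventilation) is engaged.
#'
#' @param sweep a [chamber_sweep()] result for a single wind/RH/solar
#'   combination
#' @return onset temperature (deg C), or NA if never engaged
#' @export
evaporation_onset <- function(sweep) {
  sweep <- sweep[order(sweep$tair_c), ]
  hit <- sweep$sweat_level > 1e-6 | sweep$panting > 1 + 1e-6
  if (!any(hit)) return(NA_real_)
  sweep$tair_c[which(hit)[1]]
}

#' Lower critical temperature along a temperature sweep
#'
#' The highest air temperature at which the required heat generation
#' exceeds the thermoneutral target rate, i.e. the cold edge of the
#' thermal neutral zone.
#'
#' @param sweep a [chamber_sweep()] result for a single wind/RH/solar
#'   combination
#' @param tol_W detection margin on the metabolic rise (default 0.5 W)
#' @return LCT (deg C), or NA if the animal never leaves thermoneutral
#' @export
lower_critical_temperature <- function(sweep, tol_W = 0.5) {
  sweep <- sweep[order(sweep$tair_c), ]
  target <- min(sweep$metab_W)
  cold <- sweep$metab_W > target + tol_W &
    sweep$tair_c < sweep$tair_c[which.min(sweep$metab_W)]
  if (!any(cold)) return(NA_real_)
  sweep$tair_c[max(which(cold))]
}

#' Milk-cliff edge along a temperature sweep
#'
#' The highest air temperature at which the full milk target is still
#' achieved (milk fraction = 1).
#'
#' @param sweep a [chamber_sweep()] result
#' @return cliff-edge temperature (deg C), or NA
#' @export
cliff_edge <- function(sweep) {
  sweep <- sweep[order(sweep$tair_c), ]
  full <- sweep$milk_fraction >= 1 - 1e-6
  if (!any(full)) return(NA_real_)
  sweep$tair_c[max(which(full))]
}

## lactation timeline for one calendar year (non-leap): per month, the
## number of in-milk days, their mean days-in-milk, and the mean relative
## Wood-curve yield over those days (so that summing n_lact x mean daily
## yield reproduces the day-by-day curve total exactly)
lactation_calendar <- function(calving_month, calving_day,
                               milking_days = 305,
                               wood_b = bt_params()$wood_b,
                               wood_c = bt_params()$wood_c) {
  doy <- 1:365
  calving_doy <- cumsum(c(0, month_days))[calving_month] + calving_day
  dim_days <- (doy - calving_doy) %% 365
  in_milk <- dim_days <= milking_days - 1
  month_of <- rep(1:12, month_days)
  shape <- function(t) wood_yield(t, 1, wood_b, wood_c, milking_days)
  data.frame(
    month = 1:12,
    n_lact = vapply(1:12, function(m) sum(in_milk[month_of == m]), 0L),
    mid_dim = vapply(1:12, function(m) {
      d <- dim_days[month_of == m & in_milk]
      if (length(d)) mean(d) + 0.5 else NA_real_
    }, numeric(1)),
    mean_rel_yield = vapply(1:12, function(m) {
      d <- dim_days[month_of == m & in_milk]
      if (length(d)) mean(shape(d + 0.5)) else 0
    }, numeric(1))
  )
}

#' Simulate a full year at a site
#'
#' For the average day of each month: build the 24-hour sun/shade
#' microclimate, run the thermoregulation cascade hour by hour against
#' the day's Wood-curve milk target (days in milk from the calving
#' date), and convert the energy solution into feed and water needs.
#' Monthly totals scale the average day by the days in the month (milk
#' by the in-milk days).
#'
#' @param site a [site_climate()]
#' @param animal an [animal_spec()]
#' @param warming_offset_C uniform warming added to monthly Tmin/Tmax
#' @param shade_available overrides the animal's shade flag if given
#' @param calving_month,calving_day override the animal's calving date
#' @param params see [bt_params()]
#' @return an `annual_result`: `monthly` data.frame and annual totals
#'   `milk_kg`, `water_kg` (drinking), `feed_dm_kg`, `feed_as_fed_kg`
#' @export
simulate_year <- function(site, animal, warming_offset_C = 0,
                          shade_available = NULL,
                          calving_month = animal$calving_month,
                          calving_day = animal$calving_day,
                          params = bt_params()) {
  shade_ok <- shade_available %||% animal$shade_available
  animal$shade_available <- shade_ok
  geom <- animal_geometry(animal, "standing", params)
  cal <- lactation_calendar(calving_month, calving_day,
                            params$milking_days, params$wood_b,
                            params$wood_c)
  peak <- animal$milk_target_kgd
  monthly <- vector("list", 12)
  for (m in 1:12) {
    day <- build_day(site, m, warming_offset_C,
                     animal_height_m = geom$height_m / 2, params = params)
    sun <- day[day$habitat == "sun", ]
    shd <- day[day$habitat == "shade", ]
    target <- if (cal$n_lact[m] > 0 && peak > 0)
      peak * cal$mean_rel_yield[m] else 0
    mix <- if (m %in% params$summer_months) animal$diet_summer else
      animal$diet_winter
    frac <- metab <- water_evap <- numeric(24)
    flags <- character(24)
    for (h in 1:24) {
      es <- env_from_row(sun[h, ])
      eh <- if (shade_ok) env_from_row(shd[h, ]) else NULL
      r <- regulate_hour(animal, es, eh, milk_target_kgd = target,
                         params = params, geom = geom)
      frac[h] <- r$milk_fraction
      metab[h] <- r$metab_W
      water_evap[h] <- r$water_g_h
      flags[h] <- r$flag
    }
    milk_day <- mean(frac) * target
    milk_e <- milk_energy(milk_day, animal$milk_fat_pct,
                          animal$milk_protein_pct, params)
    rest <- params$rest_coef * animal$mass_kg ^ 0.75
    feed <- feed_requirement(rest, milk_e, animal$milk_efficiency, mix,
                             params = params)
    wb <- water_balance(feed$dmi_kgd, mix, milk_day,
                        animal$fecal_water_frac,
                        sum(water_evap) / 1000,
                        animal$milk_fat_pct, animal$milk_protein_pct,
                        params = params)
    monthly[[m]] <- data.frame(
      month = m, days = month_days[m], n_lact = cal$n_lact[m],
      milk_target_kgd = target, milk_kgd = milk_day,
      metab_mean_W = mean(metab),
      dmi_kgd = feed$dmi_kgd, as_fed_kgd = feed$as_fed_kgd,
      drinking_kgd = wb$drinking_kgd,
      evap_kgd = wb$evap_kgd,
      hours_heat_stressed = sum(flags %in% c("heat-stressed", "hyperthermic")),
      hours_cold_stressed = sum(flags %in% c("cold-stressed", "hypothermic")))
  }
  monthly <- do.call(rbind, monthly)
  structure(list(
    monthly = monthly,
    milk_kg = sum(monthly$milk_kgd * monthly$n_lact),
    water_kg = sum(monthly$drinking_kgd * monthly$days),
    feed_dm_kg = sum(monthly$dmi_kgd * monthly$days),
    feed_as_fed_kg = sum(monthly$as_fed_kgd * monthly$days),
    warming_offset_C = warming_offset_C, shade_available = shade_ok,
    calving = c(month = calving_month, day = calving_day)),
    class = "annual_result")
}

#' @export
print.annual_result <- function(x, ...) {
  cat(sprintf("<annual_result> warming +%.1f C, shade %s, calving %d/%d\n",
              x$warming_offset_C,
              if (x$shade_available) "yes" else "no",
              x$calving["day"], x$calving["month"]))
  cat(sprintf("  milk %.0f kg/y, drinking water %.0f kg/y, feed DM %.0f kg/y\n",
              x$milk_kg, x$water_kg, x$feed_dm_kg))
  invisible(x)
}

#' Temperature-humidity index
#'
#' The standard empirical index
#' `THI = (1.8 Ta + 32) - (0.55 - 0.0055 RH)(1.8 Ta - 26)`, provided for
#' side-by-side comparison with the mechanistic milk maps; the balance
#' model itself never uses it.
#'
#' @param ta_c air temperature, deg C
#' @param rh_pct relative humidity, percent
#' @return index value (vectorised)
#' @export
thi <- function(ta_c, rh_pct) {
  (1.8 * ta_c + 32) - (0.55 - 0.0055 * rh_pct) * (1.8 * ta_c - 26)
}
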