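#' Site climate tables
#'
#' A `site_climate` object holds the location (latitude, longitude,
#' elevation) and twelve monthly records of minimum and maximum air
#' temperature, wind speed at the 2 m reference height, relative humidity
#' and cloud fraction. It is the macroclimate input from which hourly sun
#' and shade microenvironments are interpolated.
#'
#' @param latitude degrees north (-90..90)
#' @param longitude degrees east
#' @param elevation_m metres above sea level
#' @param monthly data.frame with columns `month` (1:12), `tmin_C`,
#'   `tmax_C`, `wind_ms`, `rh_pct`, `cloud_frac`
#' @return A validated `site_climate` object.
#' @export
site_climate <- function(latitude, longitude, elevation_m, monthly) {
  stopifnot_scalar(latitude, "latitude")
  stopifnot_scalar(longitude, "longitude")
  stopifnot_scalar(elevation_m, "elevation_m")
  if (latitude < -90 || latitude > 90)
    stop("latitude must be within [-90, 90]")
  need <- c("month", "tmin_C", "tmax_C", "wind_ms", "rh_pct", "cloud_frac")
  if (!is.data.frame(monthly) || !all(need %in% names(monthly)))
    stop("monthly must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  monthly <- monthly[order(monthly$month), need]
  if (nrow(monthly) != 12L || !identical(as.integer(monthly$month), 1:12))
    stop("monthly must contain exactly one record per month 1..12")
  with(monthly, {
    if (any(tmin_C > tmax_C)) stop("tmin_C must not exceed tmax_C")
    if (any(rh_pct < 0 | rh_pct > 100)) stop("rh_pct must be in [0, 100]")
    if (any(cloud_frac < 0 | cloud_frac > 1)) stop("cloud_frac must be in [0, 1]")
    if (any(wind_ms < 0)) stop("wind_ms must be non-negative")
  })
  structure(list(latitude = latitude, longitude = longitude,
                 elevation_m = elevation_m, monthly = monthly),
            class = "site_climate")
}

#' @export
print.site_climate <- function(x, ...) {
  cat(sprintf("<site_climate> lat %.2f, lon %.2f, elev %.0f m\n",
              x$latitude, x$longitude, x$elevation_m))
  cat(sprintf("  annual Tmin %.1f..%.1f C, Tmax %.1f..%.1f C\n",
              min(x$monthly$tmin_C), max(x$monthly$tmin_C),
              min(x$monthly$tmax_C), max(x$monthly$tmax_C)))
  invisible(x)
}

#' Read/write a site climate CSV
#'
#' The CSV carries a three-line `#`-prefixed header (`lat`, `lon`,
#' `elev_m`) followed by the 12-row monthly table. The schema is strict:
#' missing or extra columns are an error.
#'
#' @param path file path
#' @return `read_site_climate()` returns a `site_climate`;
#'   `write_site_climate()` returns `path` invisibly.
#' @export
read_site_climate <- function(path) {
  if (!file.exists(path)) stop("site climate file not found: ", path)
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(\\w+)\\s*=\\s*(-?[0-9.]+)", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- as.numeric(m[3])
  }
  for (k in c("lat", "lon", "elev_m"))
    if (is.null(kv[[k]])) stop("site header missing '", k, "' line")
  tab <- utils::read.csv(path, comment.char = "#")
  site_climate(kv$lat, kv$lon, kv$elev_m, tab)
}

#' @rdname read_site_climate
#' @param site a `site_climate` object
#' @export
write_site_climate <- function(site, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s = %.6g",
                     c("lat", "lon", "elev_m"),
                     c(site$latitude, site$longitude, site$elevation_m)), con)
  utils::write.csv(site$monthly, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Solar position from a closed-form declination model
#'
#' Declination follows the Cooper approximation; the zenith angle comes
#' from the spherical law of cosines with the hour angle measured from
#' solar noon. Azimuth is measured clockwise from north.
#'
#' @param latitude,longitude degrees
#' @param elevation_m metres (unused by the geometry, kept for interface
#'   symmetry with [solar_flux()])
#' @param day_of_year 1..366
#' @param solar_hour local solar time, 0..24
#' @return list with `zenith` and `azimuth` in degrees.
#' @export
solar_position <- function(latitude, longitude = 0, elevation_m = 0,
                           day_of_year, solar_hour) {
  if (latitude < -90 || latitude > 90)
    stop("latitude must be within [-90, 90]")
  if (any(day_of_year < 1) || any(day_of_year > 366))
    stop("day_of_year must be within 1..366")
  decl <- 23.45 * sin(2 * pi * (284 + day_of_year) / 365)
  hang <- 15 * (solar_hour - 12)              # degrees
  rad <- pi / 180
  cosz <- sin(latitude * rad) * sin(decl * rad) +
    cos(latitude * rad) * cos(decl * rad) * cos(hang * rad)
  cosz <- pmin(1, pmax(-1, cosz))
  zen <- acos(cosz) / rad
  # azimuth via atan2 on horizontal sun vector components
  saz <- cos(decl * rad) * sin(hang * rad)
  caz <- cos(latitude * rad) * sin(decl * rad) -
    sin(latitude * rad) * cos(decl * rad) * cos(hang * rad)
  az <- (atan2(saz, caz) / rad + 180) %% 360
  list(zenith = zen, azimuth = az, declination = decl)
}

## Kasten-Young relative optical air mass, scaled by station pressure.
air_mass <- function(zenith, elevation_m) {
  p_ratio <- exp(-elevation_m / 8434)    # scale-height barometric profile
  z <- pmin(zenith, 89.9)
  m <- 1 / (cos(z * pi / 180) + 0.50572 * (96.07995 - z) ^ (-1.6364))
  m * p_ratio
}

#' Clear-sky and cloudy solar fluxes
#'
#' Bulk-transmittance beam model: direct-normal flux is
#' `S0 * tau^m * (1 - cloud)` with optical air mass `m` from the zenith
#' angle and elevation-scaled pressure. Clear-sky diffuse on the
#' horizontal is a fixed fraction of `S0 * cos(z)`; the cloud-blocked
#' portion of the beam is partly recovered as additional diffuse.
#'
#' @param zenith degrees, 0..180
#' @param elevation_m metres
#' @param cloud_frac 0..1
#' @param params see [bt_params()]
#' @return list with `direct_normal` and `diffuse_horizontal` (W/m2).
#' @export
solar_flux <- function(zenith, elevation_m = 0, cloud_frac = 0,
                       params = bt_params()) {
  if (any(zenith < 0 | zenith > 180)) stop("zenith must be in [0, 180]")
  if (any(cloud_frac < 0 | cloud_frac > 1)) stop("cloud_frac must be in [0, 1]")
  up <- zenith < 90
  direct <- diffuse <- rep(0, length(zenith))
  if (any(up)) {
    m <- air_mass(zenith[up], elevation_m)
    cosz <- cos(zenith[up] * pi / 180)
    beam_clear <- params$solar_constant * params$tau_atm ^ m
    direct[up] <- beam_clear * (1 - cloud_frac)
    diffuse[up] <- params$diffuse_frac * params$solar_constant * cosz +
      params$cloud_scatter * cloud_frac * beam_clear * cosz
  }
  list(direct_normal = direct, diffuse_horizontal = diffuse)
}

#' Hourly air temperature interpolation
#'
#' Piecewise sinusoid through the day: the minimum falls exactly at
#' sunrise and the maximum at solar noon plus a configurable lag
#' (default 1 h); the curve is continuous across midnight.
#'
#' @param tmin,tmax daily extremes, deg C
#' @param sunrise_hour solar hour of sunrise
#' @param hour solar hour (vectorised), 0..24
#' @param tmax_hour solar hour of the maximum (default noon + 1)
#' @return air temperature(s), deg C
#' @export
hourly_air_temperature <- function(tmin, tmax, sunrise_hour, hour,
                                   tmax_hour = 13) {
  if (tmin > tmax) stop("tmin must not exceed tmax")
  rise_len <- tmax_hour - sunrise_hour          # warming branch length
  fall_len <- 24 - rise_len                     # cooling branch length
  # phase position relative to sunrise, in [0, 24)
  ph <- (hour - sunrise_hour) %% 24
  mid <- (tmin + tmax) / 2
  amp <- (tmax - tmin) / 2
  ifelse(ph <= rise_len,
         mid - amp * cos(pi * ph / rise_len),
         mid + amp * cos(pi * (ph - rise_len) / fall_len))
}

#' Effective sky radiant temperature
#'
#' Clear-sky emissivity from a quadratic air-temperature regression
#' (Swinbank family); cloud raises emissivity linearly toward 1, so a
#' fully overcast sky radiates at air temperature.
#'
#' @param ta_c air temperature at 2 m, deg C
#' @param rh_pct relative humidity (kept in the signature for alternative
#'   emissivity regressions; the default model does not use it)
#' @param cloud_frac 0..1
#' @param params see [bt_params()]
#' @return sky radiant temperature, deg C
#' @export
sky_longwave <- function(ta_c, rh_pct = 50, cloud_frac = 0,
                         params = bt_params()) {
  ta_k <- ta_c + 273.15
  e_clear <- pmin(1, params$swinbank_coef * ta_k ^ 2)
  e <- e_clear * (1 - cloud_frac) + cloud_frac
  e ^ 0.25 * ta_k - 273.15
}

#' Ground surface energy balance
#'
#' Finds the ground surface temperature closing absorbed solar + incoming
#' sky IR - emitted IR - convection - conduction into the substrate = 0.
#' Returns the root found by [stats::uniroot()] with a residual below
#' 1e-3 W/m2.
#'
#' @param solar_Wm2 absorbed-side global solar on the horizontal (W/m2,
#'   before the ground absorptivity is applied)
#' @param ta_c air temperature, deg C
#' @param tsky_c sky radiant temperature, deg C
#' @param wind_ms wind speed near the surface
#' @param tdeep_c deep-substrate temperature, deg C
#' @param params see [bt_params()]
#' @return list with `tground_c` and `residual_Wm2`
#' @export
ground_surface_balance <- function(solar_Wm2, ta_c, tsky_c, wind_ms,
                                   tdeep_c, params = bt_params()) {
  sig <- params$sigma
  em <- params$ground_emis
  # flat-plate forced convection with a modest floor for calm hours
  h <- params$ground_h_fac * max(2.0, 5.0 + 4.0 * wind_ms)
  f <- function(tg) {
    params$ground_abs * solar_Wm2 +
      em * sig * (tsky_c + 273.15) ^ 4 -
      em * sig * (tg + 273.15) ^ 4 -
      h * (tg - ta_c) -
      params$ground_cond * (tg - tdeep_c)
  }
  lo <- min(ta_c, tsky_c, tdeep_c) - 5
  hi <- max(ta_c, tsky_c, tdeep_c) + 60
  if (f(lo) < 0 || f(hi) > 0)
    stop("ground surface balance: root not bracketed in [",
         round(lo, 1), ", ", round(hi, 1), "] C")
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-8)
  list(tground_c = r$root, residual_Wm2 = f(r$root))
}

#' Logarithmic wind profile
#'
#' @param u_ref wind speed at the reference height
#' @param z_ref reference height, m
#' @param z0 roughness length, m
#' @param z target height, m (must be >= z0)
#' @return wind speed at `z`, m/s
#' @export
wind_profile <- function(u_ref, z_ref, z0, z) {
  if (z0 <= 0 || z_ref <= z0) stop("need z_ref > roughness length > 0")
  if (any(z < z0)) stop("z must be at or above the roughness length")
  u_ref * log(z / z0) / log(z_ref / z0)
}

## mid-month day-of-year, non-leap calendar
month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
month_mid_doy <- function(month) {
  cumsum(c(0, month_days))[month] + ceiling(month_days[month] / 2)
}

hourly_env <- function(hour, tair, tground, tsky, wind, rh,
                       solar_direct, solar_diffuse, zenith, shade) {
  structure(list(hour = hour, tair_c = tair, tground_c = tground,
                 tsky_c = tsky, wind_ms = wind, rh_pct = rh,
                 solar_direct_Wm2 = solar_direct,
                 solar_diffuse_Wm2 = solar_diffuse,
                 zenith_deg = zenith, shade = shade),
            class = "hourly_env")
}

#' Build the 24-hour sun/shade microclimate for one month
#'
#' Interpolates the monthly climate record to 24 hourly paired
#' microhabitats for the average day of the month: solar geometry and
#' fluxes, a sinusoidal air temperature anchored to sunrise and the
#' post-noon maximum, sky radiant temperature, a ground-surface energy
#' balance solved separately for the sun patch and the shade patch, and
#' the log-profile wind at animal mid-height. Shade removes the direct
#' beam and reduces diffuse per the shade factor; air temperature at
#' animal height is shared between the habitats.
#'
#' @param site a [site_climate()] object
#' @param month 1..12
#' @param warming_offset_C uniform offset added to Tmin and Tmax
#' @param animal_height_m height used for the wind profile (mid-height)
#' @param params see [bt_params()]
#' @return data.frame, one row per (hour, habitat), 48 rows.
#' @export
build_day <- function(site, month, warming_offset_C = 0,
                      animal_height_m = 0.75, params = bt_params()) {
  if (!inherits(site, "site_climate")) stop("site must be a site_climate")
  if (!(month %in% 1:12)) stop("month must be in 1..12")
  if (warming_offset_C < 0) stop("warming_offset_C must be >= 0")
  rec <- site$monthly[site$monthly$month == month, ]
  tmin <- rec$tmin_C + warming_offset_C
  tmax <- rec$tmax_C + warming_offset_C
  tmean <- (tmin + tmax) / 2
  doy <- month_mid_doy(month)
  hours <- 0:23

  pos <- solar_position(site$latitude, site$longitude, site$elevation_m,
                        doy, hours + 0.5)
  zen <- pos$zenith
  # sunrise from the zenith = 90 crossing on a fine grid
  fine <- seq(0, 12, by = 0.05)
  zf <- solar_position(site$latitude, site$longitude, site$elevation_m,
                       doy, fine)$zenith
  sunrise <- if (all(zf >= 90)) 6 else if (all(zf < 90)) 0 else
    fine[which(zf < 90)[1]]

  flux <- solar_flux(zen, site$elevation_m, rec$cloud_frac, params)
  ta <- hourly_air_temperature(tmin, tmax, sunrise, hours + 0.5,
                               tmax_hour = 12 + params$tmax_lag_h)
  tsky <- sky_longwave(ta, rec$rh_pct, rec$cloud_frac, params)
  wind_anim <- wind_profile(rec$wind_ms, params$wind_ref_z,
                            params$roughness_z0, max(animal_height_m,
                                                     params$roughness_z0))

  global <- flux$direct_normal * pmax(0, cos(zen * pi / 180)) +
    flux$diffuse_horizontal
  tg_sun <- tg_shade <- numeric(24)
  for (i in seq_len(24)) {
    tg_sun[i] <- ground_surface_balance(global[i], ta[i], tsky[i],
                                        rec$wind_ms, tmean, params)$tground_c
    tg_shade[i] <- ground_surface_balance(global[i] * (1 - params$shade_factor),
                                          ta[i], tsky[i], rec$wind_ms, tmean,
                                          params)$tground_c
  }

  sun <- data.frame(month = month, hour = hours, habitat = "sun",
                    tair_c = ta, tground_c = tg_sun, tsky_c = tsky,
                    wind_ms = wind_anim, rh_pct = rec$rh_pct,
                    solar_direct_Wm2 = flux$direct_normal,
                    solar_diffuse_Wm2 = flux$diffuse_horizontal,
                    zenith_deg = zen)
  shade <- sun
  shade$habitat <- "shade"
  shade$tground_c <- tg_shade
  shade$solar_direct_Wm2 <- 0
  shade$solar_diffuse_Wm2 <- flux$diffuse_horizontal * (1 - params$shade_factor)
  out <- rbind(sun, shade)
  rownames(out) <- NULL
  out
}

## Convert one row of a build_day table into an hourly_env object.
env_from_row <- function(row) {
  hourly_env(row$hour, row$tair_c, row$tground_c, row$tsky_c, row$wind_ms,
             row$rh_pct, row$solar_direct_Wm2, row$solar_diffuse_Wm2,
             row$zenith_deg, identical(row$habitat, "shade"))
}

#' Uniform-radiant chamber environment
#'
#' Metabolic-chamber convention: the radiant environment (walls, floor,
#' "sky") is at air temperature; any solar load is added as a separate
#' horizontal beam on the animal silhouette.
#'
#' @param ta_c air (= radiant) temperature
#' @param wind_ms wind speed at the animal
#' @param rh_pct relative humidity
#' @param solar_Wm2 incident beam flux (W/m2 on the silhouette)
#' @return an `hourly_env`
#' @export
chamber_env <- function(ta_c, wind_ms = 1, rh_pct = 50, solar_Wm2 = 0) {
  hourly_env(hour = 12, tair = ta_c, tground = ta_c, tsky = ta_c,
             wind = wind_ms, rh = rh_pct, solar_direct = solar_Wm2,
             solar_diffuse = 0, zenith = 90, shade = FALSE)
}
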