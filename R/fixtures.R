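#' Synthetic monthly site climate
#'
#' Deterministic generator of plausible monthly climate tables for
#' testing and scenario work, standing in for a real gridded climate
#' database. Monthly mean temperature follows a latitude-dependent
#' seasonal sinusoid (annual mean decreasing with latitude, amplitude
#' increasing with it); the warmest month is July poleward of the
#' tropics and April within them (the pre-monsoon heat peak typical of
#' tropical lowlands), mirrored for the southern hemisphere. A fixed
#' diurnal range splits the mean into Tmin/Tmax, and a small seeded
#' jitter decorrelates the months; the same seed always reproduces the
#' same table.
#'
#' @param latitude degrees north
#' @param seed integer random seed for the jitter
#' @param annual_mean_C,amplitude_C optional overrides of the
#'   latitude-driven defaults
#' @param diurnal_range_C Tmax - Tmin, deg C
#' @param rh_pct,wind_ms,cloud_frac monthly baselines
#' @param elevation_m site elevation
#' @param longitude degrees east
#' @return a [site_climate()]
#' @export
synthetic_site <- function(latitude, seed = 1,
                           annual_mean_C = NULL, amplitude_C = NULL,
                           diurnal_range_C = 9, rh_pct = NULL,
                           wind_ms = 2.5, cloud_frac = 0.4,
                           elevation_m = 30, longitude = 0) {
  al <- abs(latitude) / 60
  mean_t <- annual_mean_C %||% (28.5 - 26.5 * al ^ 1.4)
  amp <- amplitude_C %||% (13 * al ^ 1.3)
  rh <- rh_pct %||% (78 - 15 * al)
  warm_month <- if (abs(latitude) < 23.44) 4 else 7
  if (latitude < 0) warm_month <- ((warm_month + 5) %% 12) + 1
  m <- 1:12
  set.seed(seed)
  tmean <- mean_t + amp * cos(2 * pi * (m - warm_month) / 12) +
    stats::rnorm(12, 0, 0.2)
  monthly <- data.frame(
    month = m,
    tmin_C = tmean - diurnal_range_C / 2,
    tmax_C = tmean + diurnal_range_C / 2,
    wind_ms = pmax(0.5, wind_ms + stats::rnorm(12, 0, 0.1)),
    rh_pct = pmin(95, pmax(30, rh + stats::rnorm(12, 0, 1))),
    cloud_frac = pmin(1, pmax(0, cloud_frac + stats::rnorm(12, 0, 0.03))))
  site_climate(latitude, longitude, elevation_m, monthly)
}

#' Named animal and environment fixtures
#'
#' Ready-made [animal_spec()] objects for the worked examples and tests:
#' \describe{
#'   \item{table1}{682 kg, 147.3 cm Holstein, 50/50 black-white coat
#'     (0.336 cm deep, 0.635 cm hair), 80% fecal water, 36.4 kg/day
#'     target at 3.2% fat / 3.5% protein, 5 September calving, HPF diet.}
#'   \item{wisconsin}{761 kg, 153 cm barn cow, 52.4 kg/day target at
#'     3.12% fat / 2.71% protein.}
#'   \item{literature}{533 kg, 135 cm cow, 23.5 kg/day target
#'     (confinement validation conditions, ~18 C).}
#'   \item{chamber_black}{643 kg, 100% black coat, chamber simulations.}
#'   \item{chamber_white}{643 kg, 100% white coat.}
#' }
#'
#' @param name fixture name
#' @param ... overrides passed to [animal_spec()] (e.g. `mass_kg` to
#'   resize the chamber animal)
#' @return an `animal_spec`
#' @export
fixture_animal <- function(name = c("table1", "wisconsin", "literature",
                                    "chamber_black", "chamber_white"),
                           ...) {
  name <- match.arg(name)
  base <- switch(name,
    table1 = list(mass_kg = 682, height_cm = 147.3,
                  coat = coat_spec(0.336, 0.635,
                                   c(black = 50, white = 50, brown = 0, tan = 0)),
                  milk_target_kgd = 36.4, milk_fat_pct = 3.2,
                  milk_protein_pct = 3.5, fecal_water_frac = 0.80,
                  calving_month = 9, calving_day = 5,
                  shade_available = TRUE,
                  diet_summer = c(HPF = 100), diet_winter = c(HPF = 100)),
    wisconsin = list(mass_kg = 761, height_cm = 153,
                     coat = coat_spec(0.336, 0.635,
                                      c(black = 50, white = 50, brown = 0, tan = 0)),
                     milk_target_kgd = 52.4, milk_fat_pct = 3.12,
                     milk_protein_pct = 2.71, fecal_water_frac = 0.80),
    literature = list(mass_kg = 533, height_cm = 135,
                      coat = coat_spec(0.336, 0.635,
                                       c(black = 50, white = 50, brown = 0, tan = 0)),
                      milk_target_kgd = 23.5, milk_fat_pct = 3.2,
                      milk_protein_pct = 3.5),
    chamber_black = list(mass_kg = 643,
                         coat = coat_spec(0.336, 0.635,
                                          c(black = 100, white = 0, brown = 0, tan = 0)),
                         milk_target_kgd = 50),
    chamber_white = list(mass_kg = 643,
                         coat = coat_spec(0.336, 0.635,
                                          c(black = 0, white = 100, brown = 0, tan = 0)),
                         milk_target_kgd = 50))
  ov <- list(...)
  base[names(ov)] <- ov
  do.call(animal_spec, base)
}

#' Wisconsin barn fixture environment
#'
#' The measured barn microclimate of the confinement validation:
#' 3 deg C, 3.1 m/s cross-ventilation, 79.2% relative humidity.
#' @return an `hourly_env`
#' @export
wisconsin_barn_env <- function() chamber_env(3, 3.1, 79.2)

#' Benchmark annual milk table (literature values)
#'
#' Published annual milk production figures (kg/year) for three body
#' sizes at six sites under current climate and a warming scenario,
#' used as a fixed reference input for summary arithmetic and
#' regression checks. These numbers are inputs, not model output.
#'
#' @return data.frame with `site`, `mass_kg`, `scenario`
#'   ("current"/"future") and `milk_kg_y`
#' @export
benchmark_annual_milk <- function() {
  sites <- c("Philippines", "China", "Russia", "Nicaragua", "Texas", "Canada")
  vals <- rbind(
    c(6864, 7008, 7008, 6897, 6967, 7008),   # current, 364 kg
    c(5669, 6988, 7008, 5753, 6921, 7008),   # future,  364 kg
    c(6576, 7008, 7008, 6630, 6967, 7008),   # current, 818 kg
    c(4506, 6915, 7008, 4494, 6670, 7008),   # future,  818 kg
    c(5659, 6970, 7008, 5729, 6886, 7008),   # current, 1273 kg
    c(2496, 6503, 7008, 2236, 6272, 7008))   # future,  1273 kg
  data.frame(
    site = rep(sites, times = 6),
    mass_kg = rep(c(364, 364, 818, 818, 1273, 1273), each = 6),
    scenario = rep(rep(c("current", "future"), each = 6), times = 3),
    milk_kg_y = as.vector(t(vals)))
}

#' Benchmark factorial-design mean responses (literature values)
#'
#' Published overall means of the annual factorial analysis: milk
#' production and water needs under the current climate and a +3 C
#' warming scenario (kg/year). Fixed reference inputs for summary
#' arithmetic.
#' @return named numeric vector
#' @export
benchmark_factorial_means <- function() {
  c(milk_current = 6918, milk_future = 6330,
    water_current = 9316, water_future = 9061,
    water_future_ratio_base = 9016)
}

#' Summary statistics over paired current/future annual means
#'
#' Computes the milk/water percentage ratios, the warming-induced mean
#' milk drop and the mean water percentage difference from annual mean
#' milk production and water needs under two climate scenarios.
#'
#' @param milk_current,milk_future mean annual milk, kg/y
#' @param water_current,water_future mean annual water, kg/y
#' @return list: `ratio_current_pct`, `ratio_future_pct`,
#'   `milk_drop_kg`, `water_diff_pct`
#' @export
annual_summary_stats <- function(milk_current, milk_future,
                                 water_current, water_future) {
  list(ratio_current_pct = 100 * milk_current / water_current,
       ratio_future_pct = 100 * milk_future / water_future,
       milk_drop_kg = milk_current - milk_future,
       water_diff_pct = 100 * (water_current - water_future) / water_current)
}

#' Largest percentage milk reduction in an annual milk table
#'
#' @param tab a table in the [benchmark_annual_milk()] layout
#' @return maximum percent reduction from current to future over all
#'   (site, mass) pairs
#' @export
max_milk_reduction_pct <- function(tab = benchmark_annual_milk()) {
  cur <- tab[tab$scenario == "current", ]
  fut <- tab[tab$scenario == "future", ]
  key <- paste(cur$site, cur$mass_kg)
  fut <- fut[match(key, paste(fut$site, fut$mass_kg)), ]
  max(100 * (cur$milk_kg_y - fut$milk_kg_y) / cur$milk_kg_y)
}
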