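#' Core-to-skin temperature drop with distributed heat generation
#'
#' Steady conduction with uniform volumetric generation gives
#' `Tcore - Tskin = q_v R^2 / (4 k)` for a cylinder and `q_v R^2 / (6 k)`
#' for a spheroid, where `q_v` is the volumetric generation rate and `k`
#' the effective flesh conductivity (set by vasomotor tone).
#'
#' @param qv_Wm3 volumetric generation, W/m3
#' @param radius_m part radius, m
#' @param k_flesh flesh conductivity, W/mK
#' @param tcore_c core temperature, deg C
#' @param shape `"cylinder"` or `"spheroid"`
#' @return skin temperature, deg C (vectorised)
#' @export
core_to_skin <- function(qv_Wm3, radius_m, k_flesh, tcore_c = 39,
                         shape = "cylinder") {
  if (any(radius_m <= 0)) stop("radius must be positive")
  if (any(k_flesh <= 0)) stop("conductivity must be positive")
  divisor <- ifelse(shape == "spheroid", 6, 4)
  tcore_c - qv_Wm3 * radius_m ^ 2 / (divisor * k_flesh)
}

#' Respiratory evaporative water loss
#'
#' Ventilation is tied to oxygen demand: the metabolic rate sets the
#' oxygen consumption (20.1 J per mL O2), which at a fixed extraction
#' fraction sets the air throughput; panting multiplies it. Exhaled air
#' is saturated at a temperature that warms from `Tcore - 4` at rest to
#' `Tcore` at the panting cap. The flux is never negative.
#'
#' @param metabolic_W metabolic rate, W
#' @param ta_c,rh_pct ambient air state
#' @param panting ventilation multiplier in \[1, pant_max\]
#' @param tcore_c core temperature
#' @param params see [bt_params()]
#' @return list with `g_per_h` and `watts`
#' @export
respiratory_evaporation <- function(metabolic_W, ta_c, rh_pct, panting = 1,
                                    tcore_c = 39, params = bt_params()) {
  if (any(panting < 1 - 1e-9) || any(panting > params$pant_max + 1e-9))
    stop("panting must be within [1, pant_max]")
  vent <- metabolic_W / (params$o2_J_per_ml * 1e6) /
    (params$o2_frac_air * params$o2_extraction) * panting   # m3/s
  frac_rest <- if (params$pant_max > 1)
    (params$pant_max - panting) / (params$pant_max - 1) else 0
  t_ex <- tcore_c - params$exhale_dT_rest * frac_rest
  dp <- pmax(0, sat_vapour_density(t_ex) - vapour_density(ta_c, rh_pct))
  g_s <- vent * dp
  list(g_per_h = g_s * 3600, watts = g_s * params$latent_heat_Jg)
}

#' Cutaneous (sweating) evaporative water loss
#'
#' Sweat evaporates at the skin and diffuses out through the coat; the
#' achievable flux is the mass-transfer limit (heat/mass analogy on the
#' convective coefficient, derated by the coat vapour-transfer
#' efficiency) scaled by the recruitment level, and hard-capped at the
#' physiological limit of 400 g/m2-h.
#'
#' @param sweat_level recruitment in \[0, 1\]
#' @param area_m2 wetted skin area
#' @param tskin_c,ta_c,rh_pct skin and air states
#' @param wind_ms wind speed (used to form the transfer coefficient when
#'   `h_Wm2K` is not supplied)
#' @param diameter_m characteristic size for the default coefficient
#' @param h_Wm2K optional convective coefficient override
#' @param cap_g_m2h per-area cap (default 400)
#' @param params see [bt_params()]
#' @return list with `g_per_h`, `watts`, `flux_g_m2h`
#' @export
cutaneous_evaporation <- function(sweat_level, area_m2, tskin_c, ta_c,
                                  rh_pct, wind_ms = 1, diameter_m = 0.6,
                                  h_Wm2K = NULL,
                                  cap_g_m2h = bt_params()$sweat_cap_g_m2h,
                                  params = bt_params()) {
  if (any(sweat_level < 0 | sweat_level > 1))
    stop("sweat_level must be within [0, 1]")
  h <- h_Wm2K %||% convection_coefficient(diameter_m, wind_ms, ta_c,
                                          tskin_c, params)
  hm <- params$fur_vapour_eff * h / (params$rho_cp_air * params$lewis_23)
  dp <- pmax(0, sat_vapour_density(tskin_c) - vapour_density(ta_c, rh_pct))
  flux <- pmin(sweat_level * hm * dp * 3600, cap_g_m2h)   # g/m2-h
  g_h <- flux * area_m2
  list(g_per_h = g_h, watts = g_h / 3600 * params$latent_heat_Jg,
       flux_g_m2h = flux)
}

#' Thermoregulatory state of the animal
#'
#' @param shade_frac fraction of full shade used (0..1)
#' @param posture `"standing"` or `"lying"`
#' @param piloerection coat depth multiplier >= 1
#' @param k_flesh flesh conductivity (vasomotor tone), W/mK
#' @param sweat_level sweating recruitment 0..1
#' @param panting ventilation multiplier 1..cap
#' @param tcore_c core temperature within the allowed band
#' @return a `regulation_state`
#' @export
regulation_state <- function(shade_frac = 0, posture = "standing",
                             piloerection = 1,
                             k_flesh = bt_params()$k_flesh_mid,
                             sweat_level = 0, panting = 1,
                             tcore_c = bt_params()$tcore_set) {
  structure(list(shade_frac = shade_frac, posture = posture,
                 piloerection = piloerection, k_flesh = k_flesh,
                 sweat_level = sweat_level, panting = panting,
                 tcore_c = tcore_c),
            class = "regulation_state")
}

## ---------------------------------------------------------------------------
## Internal vectorised part machinery.
##
## A "part context" precomputes everything that does not change while the
## generation root-find iterates: convective coefficients, absorbed solar
## per part, radiant temperatures and view factors.
part_context <- function(geom, coat, env, state, absorptivity,
                         params = bt_params()) {
  g <- geom$parts
  tsurf_guess <- (state$tcore_c + env$tair_c) / 2
  hc <- convection_coefficient(g$diameter_m, env$wind_ms, env$tair_c,
                               tsurf_guess, params)
  sil <- silhouette_area(geom, env$zenith_deg, params)$by_part_m2
  global_h <- env$solar_direct_Wm2 * max(0, cos(env$zenith_deg * pi / 180)) +
    env$solar_diffuse_Wm2
  # absorbed solar per part, W: beam on silhouette + diffuse and
  # ground-reflected on half the skin area
  q_sol <- absorptivity *
    (env$solar_direct_Wm2 * sil * params$sil_intercept +
       (env$solar_diffuse_Wm2 * 0.5 +
          (1 - params$ground_abs) * global_h * 0.5) * g$area_m2)
  # coat structural constants (depth is state-dependent via piloerection)
  fill <- coat$hair_density_m2 * pi * coat$hair_diam_m ^ 2 / 4
  list(g = g, hc = hc, q_sol_W = q_sol,
       tsky_k = env$tsky_c + 273.15, tgnd_k = env$tground_c + 273.15,
       ta = env$tair_c, rh = env$rh_pct,
       rad_frac = params$rad_area_frac * params$coat_emis,
       f_sky = 0.5, f_gnd = 0.5,
       radius = g$diameter_m / 2,
       coat_k_cond = params$k_air * (1 - fill) +
         params$keratin_eff * params$k_keratin * fill,
       coat_beta = coat$hair_density_m2 * coat$hair_diam_m,
       coat_depth_m = coat$depth_cm / 100)
}

## vectorised coat resistance used inside the node iteration; must agree
## with fur_resistance() (tested)
coat_resistance_vec <- function(ctx, tmean_k, piloerection, sigma) {
  depth <- ctx$coat_depth_m * piloerection
  if (depth <= 0) return(rep(0, length(ctx$radius)))
  k_eff <- ctx$coat_k_cond + 16 * sigma * tmean_k ^ 3 / (3 * ctx$coat_beta)
  ctx$radius * log((ctx$radius + depth) / ctx$radius) / k_eff
}

## Solve the coat-surface node for every part at once (exact T^4
## radiation via iterated exact linearisation) and return itemised
## fluxes. tskin is a vector over parts.
parts_balance <- function(ctx, coat, state, tskin, params = bt_params()) {
  g <- ctx$g
  n <- nrow(g)
  sig <- params$sigma
  tf <- pmax(tskin, ctx$ta)               # initial coat-surface guess
  q_sol_area <- ctx$q_sol_W / g$area_m2
  hr_s <- hr_g <- rep(5, n)
  rf <- rep(0, n)
  bare <- ctx$coat_depth_m <= 0          # one coat spec for all parts
  tsky_c <- ctx$tsky_k - 273.15
  tgnd_c <- ctx$tgnd_k - 273.15
  for (it in 1:10) {
    tf_k <- tf + 273.15
    hr_s <- ctx$rad_frac * ctx$f_sky * sig *
      (tf_k * tf_k + ctx$tsky_k * ctx$tsky_k) * (tf_k + ctx$tsky_k)
    hr_g <- ctx$rad_frac * ctx$f_gnd * sig *
      (tf_k * tf_k + ctx$tgnd_k * ctx$tgnd_k) * (tf_k + ctx$tgnd_k)
    if (bare) { rf <- rep(0, n); tf <- tskin; break }
    tmean_k <- (tskin + tf) / 2 + 273.15
    rf <- coat_resistance_vec(ctx, tmean_k, state$piloerection, sig)
    tf_new <- (tskin / rf + ctx$hc * ctx$ta + hr_s * tsky_c +
                 hr_g * tgnd_c + q_sol_area) /
      (1 / rf + ctx$hc + hr_s + hr_g)
    if (max(abs(tf_new - tf)) < 1e-6) { tf <- tf_new; break }
    tf <- tf_new
  }
  # sensible flux leaving the skin through the coat (W per part)
  sens <- if (bare)
    (ctx$hc * (tskin - ctx$ta) + hr_s * (tskin - tsky_c) +
       hr_g * (tskin - tgnd_c) - q_sol_area) * g$area_m2
  else (tskin - tf) / rf * g$area_m2
  # itemised surface exchange (coat surface <-> environment)
  tf_k <- tf + 273.15
  q_conv <- ctx$hc * (tf - ctx$ta) * g$area_m2
  q_ir_out <- ctx$rad_frac * sig * tf_k ^ 4 * g$area_m2
  q_ir_in <- ctx$rad_frac * sig *
    (ctx$f_sky * ctx$tsky_k ^ 4 + ctx$f_gnd * ctx$tgnd_k ^ 4) * g$area_m2
  list(tfur = tf, rf = rf, sens_W = sens, q_conv_W = q_conv,
       q_ir_out_W = q_ir_out, q_ir_in_W = q_ir_in)
}

#' Coat-surface node balance for a single body part
#'
#' Solves the interface condition (conduction through the coat equals
#' convection plus net thermal radiation minus solar absorbed at the
#' coat surface) and returns the net sensible heat leaving the skin.
#'
#' @param diameter_m,length_m,area_m2,shape part geometry
#' @param tskin_c skin temperature
#' @param env an `hourly_env` (e.g. [chamber_env()])
#' @param coat a [coat_spec()]
#' @param piloerection coat depth multiplier
#' @param q_sol_Wm2 solar absorbed at the coat surface, W per m2 of part
#'   area (already weighted by absorptivity and interception)
#' @param params see [bt_params()]
#' @return list with `net_flux_W` and `tfur_c`
#' @export
part_balance <- function(diameter_m, length_m, area_m2, shape = "cylinder",
                         tskin_c, env, coat, piloerection = 1,
                         q_sol_Wm2 = 0, params = bt_params()) {
  geom <- list(parts = data.frame(part = "part", shape = shape,
                                  length_m = length_m,
                                  diameter_m = diameter_m,
                                  area_m2 = area_m2,
                                  volume_m3 = pi * diameter_m ^ 2 / 4 * length_m,
                                  stringsAsFactors = FALSE),
               posture = "standing")
  ctx <- part_context(structure(geom, class = "body_geometry"), coat, env,
                      regulation_state(), absorptivity = 1, params)
  ctx$q_sol_W <- q_sol_Wm2 * area_m2        # caller supplies absorbed flux
  pb <- parts_balance(ctx, coat, regulation_state(), tskin_c, params)
  list(net_flux_W = pb$sens_W, tfur_c = pb$tfur)
}

#' Required endogenous heat generation for a fixed regulation state
#'
#' Finds the whole-animal generation `Q_gen` that closes the steady-state
#' balance `Q_in + Q_gen = Q_out` at the state's core temperature: skin
#' temperatures follow from the distributed-generation conduction
#' solution, each part sheds heat through its coat-surface node, sweat
#' evaporates at the skin, respiration scales with `Q_gen` itself, and
#' ground conduction applies to the lying contact area. The residual at
#' the returned root is below 1e-3 W.
#'
#' @param animal an [animal_spec()]
#' @param env an `hourly_env`
#' @param state a [regulation_state()]
#' @param params see [bt_params()]
#' @param geom optional precomputed [scale_morphology()] geometry
#' @return an `energy_budget` list: `q_gen_W`, itemised terms, per-part
#'   temperatures, water fluxes, `feasible` ("ok", "hot_limit" when the
#'   required generation would be negative, "cold_limit" when it exceeds
#'   the bracket), and `residual_W`.
#' @export
solve_required_generation <- function(animal, env, state = regulation_state(),
                                      params = bt_params(), geom = NULL) {
  geom <- geom %||% animal_geometry(animal, state$posture, params)
  coat <- animal$coat
  absorp <- mixed_absorptivity(coat)
  ctx <- part_context(geom, coat, env, state, absorp, params)
  g <- geom$parts
  rest <- params$rest_coef * animal$mass_kg ^ 0.75
  q_max <- params$q_max_mult * rest
  shp <- g$shape
  rad <- g$diameter_m / 2
  vol_tot <- geom$total_volume_m3

  loss_at <- function(q_gen) {
    resp <- respiratory_evaporation(q_gen, ctx$ta, ctx$rh, state$panting,
                                    state$tcore_c, params)
    resp_w <- min(resp$watts, 0.95 * max(q_gen, 0))
    qv <- max(0, (q_gen - resp_w)) / vol_tot
    tskin <- core_to_skin(qv, rad, state$k_flesh, state$tcore_c, shp)
    pb <- parts_balance(ctx, coat, state, tskin, params)
    cut <- cutaneous_evaporation(state$sweat_level, 1, tskin, ctx$ta,
                                 ctx$rh, env$wind_ms, h_Wm2K = ctx$hc,
                                 cap_g_m2h = animal$sweat_cap_g_m2h,
                                 params = params)
    cut_w <- sum(cut$flux_g_m2h * g$area_m2) / 3600 * params$latent_heat_Jg
    cond_w <- if (geom$contact_area_m2 > 0)
      params$contact_cond * geom$contact_area_m2 *
        (tskin[g$part == "torso"] - env$tground_c) else 0
    list(total = sum(pb$sens_W) + cut_w + cond_w + resp_w,
         pb = pb, tskin = tskin, resp = resp, resp_w = resp_w,
         cut = cut, cut_w = cut_w, cond_w = cond_w)
  }

  resid <- function(q) q - loss_at(q)$total
  r0 <- resid(0)
  feasible <- "ok"
  if (r0 >= 0) {                      # environment overheats even at zero gen
    q_sol <- 0
    feasible <- "hot_limit"
  } else if (resid(q_max) < 0) {      # cannot generate enough to stay warm
    q_sol <- q_max
    feasible <- "cold_limit"
  } else {
    q_sol <- stats::uniroot(resid, c(0, q_max), tol = 1e-4)$root
  }
  l <- loss_at(q_sol)

  budget <- list(
    q_gen_W = q_sol,
    q_sol_W = sum(ctx$q_sol_W),
    q_ir_in_W = sum(l$pb$q_ir_in_W),
    q_ir_out_W = sum(l$pb$q_ir_out_W),
    q_conv_W = sum(l$pb$q_conv_W),
    q_cond_W = l$cond_w,
    q_evap_cut_W = l$cut_w,
    q_evap_resp_W = l$resp_w,
    q_stored_W = 0,
    water_cut_g_h = sum(l$cut$flux_g_m2h * g$area_m2),
    water_resp_g_h = l$resp_w / params$latent_heat_Jg * 3600,
    cut_flux_max_g_m2h = max(l$cut$flux_g_m2h),
    tskin_c = stats::setNames(l$tskin, g$part),
    tfur_c = stats::setNames(l$pb$tfur, g$part),
    residual_W = resid(q_sol),
    feasible = feasible,
    state = state
  )
  class(budget) <- "energy_budget"
  budget
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf("<energy_budget> Q_gen %.1f W (%s)\n", x$q_gen_W, x$feasible))
  cat(sprintf("  in : solar %.1f + IR %.1f W\n", x$q_sol_W, x$q_ir_in_W))
  cat(sprintf("  out: conv %.1f + cond %.1f + evap %.1f (cut %.1f, resp %.1f) + IR %.1f W\n",
              x$q_conv_W, x$q_cond_W, x$q_evap_cut_W + x$q_evap_resp_W,
              x$q_evap_cut_W, x$q_evap_resp_W, x$q_ir_out_W))
  cat(sprintf("  residual %.2e W\n", x$residual_W))
  invisible(x)
}
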