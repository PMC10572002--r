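#' Default model parameters
#'
#' Returns the full parameter set used throughout the simulator: physical
#' constants, microclimate settings, reference cow geometry, haircoat
#' structure, physiological limits, and lactation/diet coefficients.
#' Every simulation entry point accepts a `params` list so any value can be
#' overridden, but the defaults form a single calibrated set: they were
#' fixed once against the metabolic-chamber behaviour of a standard 643 kg
#' Holstein (thermal-neutral-zone bounds, onset of thermoregulatory
#' sweating with and without a solar load, and the temperature at which a
#' 50 kg/day milk target collapses) and are not tuned per scenario.
#'
#' @param ... named overrides, e.g. `bt_params(sweat_cap_g_m2h = 300)`.
#'   Unknown names are an error, so typos cannot silently fall through.
#' @return A named list of parameters.
#' @examples
#' p <- bt_params()
#' p$sweat_cap_g_m2h
#' @export
bt_params <- function(...) {
  p <- list(
    ## -- physical constants ------------------------------------------------
    sigma          = 5.670374e-8,  # Stefan-Boltzmann, W/m2K4
    solar_constant = 1367,         # W/m2
    tau_atm        = 0.70,         # bulk clear-sky transmittance per air mass
    diffuse_frac   = 0.10,         # clear-sky diffuse fraction of S0*cos(z)
    cloud_scatter  = 0.35,         # fraction of cloud-blocked beam re-emitted as diffuse
    latent_heat_Jg = 2426,         # latent heat of vaporisation at skin T, J/g
    k_air          = 0.0259,       # W/mK near 20 C
    nu_air         = 1.55e-5,      # m2/s kinematic viscosity
    pr_air         = 0.71,         # Prandtl number
    rho_cp_air     = 1200,         # J/m3K volumetric heat capacity
    lewis_23       = 1.22,         # Le^(2/3) for heat/mass transfer analogy

    ## -- microclimate ------------------------------------------------------
    wind_ref_z     = 2.0,          # m, reference height of site wind
    roughness_z0   = 0.01,         # m, surface roughness length
    tmax_lag_h     = 1.0,          # h after solar noon of the air-T maximum
    swinbank_coef  = 9.2e-6,       # clear-sky emissivity = coef * Ta_K^2
    shade_factor   = 0.90,         # total solar flux reduction in full shade
    ground_abs     = 0.75,         # ground solar absorptivity
    ground_emis    = 0.95,
    ground_cond    = 5.0,          # W/m2K conductance to deep substrate
    ground_h_fac   = 1.0,          # scales animal-level h for the ground surface

    ## -- reference morphology (682 kg, 147.3 cm Holstein) ------------------
    ref_mass_kg    = 682,
    ref_height_m   = 1.473,
    meeh_coef      = 0.14,         # total area = 0.14 * M^0.57 at reference
    meeh_exp       = 0.57,
    # per-part skin-area fractions (normalised internally) and slenderness
    part_fracs     = c(torso = 0.56, head = 0.07, neck = 0.05,
                       leg1 = 0.06, leg2 = 0.06, leg3 = 0.06, leg4 = 0.06,
                       tail = 0.03),
    part_shape     = c(torso = "cylinder", head = "spheroid", neck = "cylinder",
                       leg1 = "cylinder", leg2 = "cylinder", leg3 = "cylinder",
                       leg4 = "cylinder", tail = "cylinder"),
    part_aspect    = c(torso = 2.6, head = 1.0, neck = 1.3,
                       leg1 = 9, leg2 = 9, leg3 = 9, leg4 = 9, tail = 18),
    rad_area_frac  = 0.85,         # effective radiating fraction of skin area
    sil_intercept  = 0.80,         # beam interception factor (self-shading)
    lying_sil_fac  = 0.65,         # silhouette reduction when lying
    lying_contact  = 0.20,         # torso-area fraction in ground contact when lying
    contact_cond   = 20,           # W/m2K skin-ground contact conductance
    conv_enhance   = 1.50,         # turbulence enhancement on cylinder correlations
    coat_emis      = 0.95,         # thermal emissivity of the coat surface

    ## -- haircoat ----------------------------------------------------------
    hair_density_m2 = 5e7,         # hairs per m2 skin
    hair_diam_m     = 60e-6,
    k_keratin       = 0.19,        # W/mK
    keratin_eff     = 0.35,        # conduction effectiveness of hair solids (calibrated)
    pilo_max        = 1.35,        # piloerection depth multiplier cap (calibrated)
    reflectivity_default = c(black = 16, white = 48, brown = 40, tan = 45),

    ## -- physiology --------------------------------------------------------
    tcore_set      = 39.0,         # deg C
    tcore_lo       = 37.5,
    tcore_hi       = 39.4,
    k_flesh_min    = 1.05,         # W/mK, fully vasoconstricted (calibrated)
    k_flesh_mid    = 1.20,         # neutral vasomotor tone
    k_flesh_max    = 5.00,         # fully vasodilated (calibrated)
    rest_coef      = 3.10,         # W per kg^0.75 resting heat production (calibrated)
    act_mult       = 1.00,         # active-target multiplier on resting
    cold_margin    = 1.05,         # cold-action threshold = margin * active target
    q_max_mult     = 10,           # generation bracket = mult * resting
    sweat_cap_g_m2h = 400,         # cutaneous evaporation cap
    fur_vapour_eff = 0.05,         # fraction of free-skin mass transfer through coat (calibrated)
    pant_max       = 4.6,          # panting ventilation multiplier cap (calibrated)
    o2_J_per_ml    = 20.1,
    o2_extraction  = 0.15,
    o2_frac_air    = 0.2095,
    exhale_dT_rest = 4.0,          # exhaled air = Tcore - dT at rest, = Tcore panting

    ## -- lactation and diet ------------------------------------------------
    wood_b         = 0.2,
    wood_c         = 0.004,        # 1/day, magnitude of the decay constant
    milking_days   = 305,
    e_fat_kJ_g     = 38.7,
    e_protein_kJ_g = 23.9,
    e_lactose_kJ_g = 16.5,
    lactose_pct    = 4.8,
    ash_pct        = 0.7,
    milk_efficiency = 0.65,        # feed chemical energy -> milk chemical energy
    maint_km       = 0.65,         # efficiency of ME use for maintenance
    metab_water_kg_kgdm = 0.6,     # metabolic water per kg DM oxidised
    urine_base_kg  = 3.7,          # kg/day
    urine_cp_coef  = 3.0,          # kg urine water per kg crude-protein intake
    summer_months  = 4:9           # months using the summer diet mix (N hemisphere)
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("all parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p
}

## Saturated water-vapour density (g/m3) over liquid water, Buck equation.
## Used for skin, exhaled-air and ambient humidity throughout.
sat_vapour_density <- function(t_c) {
  es <- 611.21 * exp(17.502 * t_c / (240.97 + t_c))  # Pa
  1000 * es * 0.018015 / (8.314 * (t_c + 273.15))
}

## Ambient vapour density from air temperature and relative humidity (%).
vapour_density <- function(t_c, rh_pct) {
  (rh_pct / 100) * sat_vapour_density(t_c)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
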