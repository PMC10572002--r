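#' Haircoat specification
#'
#' Colour composition (area percentages of black, white, brown/red and
#' tan patches with per-colour solar reflectivities), coat depth, hair
#' length and the structural properties that set the porous-medium
#' thermal resistance.
#'
#' @param depth_cm coat depth (cm, >= 0)
#' @param hair_length_cm hair length (cm); informational, the resistance
#'   model works from depth
#' @param colour_pct named numeric, area percent per colour; must sum to
#'   100 within 0.1
#' @param reflectivity_pct named numeric, percent reflectivity per colour
#' @param hair_density_m2,hair_diam_m structural defaults from
#'   [bt_params()]
#' @return a `coat_spec`
#' @export
coat_spec <- function(depth_cm = 0.336, hair_length_cm = 0.635,
                      colour_pct = c(black = 50, white = 50, brown = 0, tan = 0),
                      reflectivity_pct = bt_params()$reflectivity_default,
                      hair_density_m2 = bt_params()$hair_density_m2,
                      hair_diam_m = bt_params()$hair_diam_m) {
  if (depth_cm < 0) stop("coat depth must be >= 0")
  if (abs(sum(colour_pct) - 100) > 0.1)
    stop("colour percentages must sum to 100 (got ",
         round(sum(colour_pct), 2), ")")
  if (any(reflectivity_pct < 0 | reflectivity_pct > 100))
    stop("reflectivities must be in [0, 100]")
  missing_refl <- setdiff(names(colour_pct)[colour_pct > 0],
                          names(reflectivity_pct))
  if (length(missing_refl))
    stop("no reflectivity given for colour(s): ",
         paste(missing_refl, collapse = ", "))
  structure(list(depth_cm = depth_cm, hair_length_cm = hair_length_cm,
                 colour_pct = colour_pct,
                 reflectivity_pct = reflectivity_pct,
                 hair_density_m2 = hair_density_m2,
                 hair_diam_m = hair_diam_m),
            class = "coat_spec")
}

#' @export
print.coat_spec <- function(x, ...) {
  mix <- paste(sprintf("%s %g%%", names(x$colour_pct), x$colour_pct)[
    x$colour_pct > 0], collapse = ", ")
  cat(sprintf("<coat_spec> depth %.3f cm, hair %.3f cm; %s; absorptivity %.2f\n",
              x$depth_cm, x$hair_length_cm, mix, mixed_absorptivity(x)))
  invisible(x)
}

#' Area-weighted solar absorptivity of a patchy coat
#'
#' Colour patches are mixed by area percentage (not spatially resolved):
#' the mean reflectivity is the percentage-weighted average and the
#' absorptivity is its complement.
#'
#' @param coat a [coat_spec()]
#' @return absorptivity fraction in \[0, 1\]
#' @export
mixed_absorptivity <- function(coat) {
  stopifnot(inherits(coat, "coat_spec"))
  w <- coat$colour_pct / 100
  refl <- coat$reflectivity_pct[names(coat$colour_pct)]
  1 - sum(w * refl) / 100
}

#' Porous-medium areal thermal resistance of the coat
#'
#' The coat conducts through still air and hair keratin in parallel and
#' leaks heat radiatively; radiation inside the coat is treated with the
#' diffusion approximation, adding `16 sigma T^3 / (3 beta)` to the
#' effective conductivity, with extinction coefficient
#' `beta = hair density x hair diameter`. Curved parts use the
#' cylindrical-shell log correction referenced to the skin area.
#' Piloerection multiplies the effective depth.
#'
#' @param coat a [coat_spec()]
#' @param mean_fur_T_K mean coat temperature (K) for the radiative term
#' @param skin_radius_m radius of the underlying part; `Inf` gives the
#'   flat-slab resistance
#' @param piloerection depth multiplier >= 1
#' @param params see [bt_params()]
#' @return areal resistance, m2K/W (0 for a bare skin of zero depth)
#' @export
fur_resistance <- function(coat, mean_fur_T_K = 308, skin_radius_m = Inf,
                           piloerection = 1, params = bt_params()) {
  stopifnot(inherits(coat, "coat_spec"))
  if (coat$depth_cm < 0) stop("coat depth must be >= 0")
  if (any(piloerection < 1)) stop("piloerection multiplier must be >= 1")
  depth <- coat$depth_cm / 100 * piloerection
  if (depth == 0) return(0)
  fill <- coat$hair_density_m2 * pi * coat$hair_diam_m ^ 2 / 4
  k_cond <- params$k_air * (1 - fill) +
    params$keratin_eff * params$k_keratin * fill
  beta <- coat$hair_density_m2 * coat$hair_diam_m       # 1/m extinction
  k_rad <- 16 * params$sigma * mean_fur_T_K ^ 3 / (3 * beta)
  k_eff <- k_cond + k_rad
  if (is.finite(skin_radius_m)) {
    r_i <- skin_radius_m
    r_i * log((r_i + depth) / r_i) / k_eff
  } else {
    depth / k_eff
  }
}
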