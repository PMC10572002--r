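## shared fixtures for the suite
P <- bt_params()

nonlactating_643 <- fixture_animal("chamber_black", milk_target_kgd = 0)
lactating_643 <- fixture_animal("chamber_black")          # 50 kg/d target

## a bare-skinned single-cylinder "animal" for closed-form oracles
single_cylinder_geometry <- function(diameter = 0.5, length = 1.5) {
  parts <- data.frame(part = "torso", shape = "cylinder",
                      length_m = length, diameter_m = diameter,
                      area_m2 = pi * diameter * length,
                      volume_m3 = pi * diameter ^ 2 / 4 * length,
                      stringsAsFactors = FALSE)
  structure(list(parts = parts, mass_kg = 500, height_m = 1.3,
                 posture = "standing", total_area_m2 = parts$area_m2,
                 total_volume_m3 = parts$volume_m3, contact_area_m2 = 0),
            class = "body_geometry")
}

bare_coat <- coat_spec(depth_cm = 0,
                       colour_pct = c(black = 100, white = 0, brown = 0, tan = 0))

## parameters that silence respiratory evaporation (exhaled air far below
## saturation) for closed-form energy oracles
no_resp_params <- bt_params(exhale_dT_rest = 80)
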