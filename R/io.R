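#' Read and write animal configuration files
#'
#' The YAML layout mirrors the standard input sheet: an `animal` block
#' (weight, height, coat depth and hair length, calving date, shade,
#' fecal water), a `coat_colours` block with per-colour reflectivity and
#' area percentages, a `milk` block (target, fat, protein, efficiency)
#' and a `diet` block with summer and winter mix percentages. Validation
#' is strict: unknown keys are rejected by name, and all type invariants
#' of [animal_spec()] apply.
#'
#' @param path file path
#' @return `read_animal_config()` returns an [animal_spec()];
#'   `write_animal_config()` returns `path` invisibly.
#' @export
read_animal_config <- function(path) {
  if (!file.exists(path)) stop("animal config not found: ", path)
  cfg <- yaml::read_yaml(path)
  known_top <- c("animal", "coat_colours", "milk", "diet")
  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  check_keys(cfg, known_top, "config")
  a <- cfg$animal %||% stop("config needs an 'animal' block")
  check_keys(a, c("weight_kg", "height_cm", "fur_depth_cm",
                  "hair_length_cm", "calving_month", "calving_day",
                  "shade_available", "fecal_water_pct"), "animal")
  cols <- cfg$coat_colours %||% list()
  colour_pct <- vapply(cols, function(x) x$area_pct %||% 0, numeric(1))
  refl_pct <- vapply(cols, function(x) x$reflectivity_pct %||%
                       stop("coat colour needs reflectivity_pct"), numeric(1))
  for (cn in names(cols))
    check_keys(cols[[cn]], c("reflectivity_pct", "area_pct"),
               paste0("coat_colours$", cn))
  m <- cfg$milk %||% list()
  check_keys(m, c("max_expected_kgd", "fat_pct", "protein_pct",
                  "efficiency"), "milk")
  d <- cfg$diet %||% list()
  check_keys(d, c("summer", "winter"), "diet")
  as_mix <- function(x) if (is.null(x)) c(HPF = 100) else unlist(x)

  animal_spec(
    mass_kg = a$weight_kg %||% stop("animal$weight_kg is required"),
    height_cm = a$height_cm,
    coat = coat_spec(depth_cm = a$fur_depth_cm %||% 0.336,
                     hair_length_cm = a$hair_length_cm %||% 0.635,
                     colour_pct = colour_pct,
                     reflectivity_pct = refl_pct),
    milk_target_kgd = m$max_expected_kgd %||% 0,
    milk_fat_pct = m$fat_pct %||% 3.2,
    milk_protein_pct = m$protein_pct %||% 3.5,
    milk_efficiency = m$efficiency %||% bt_params()$milk_efficiency,
    fecal_water_frac = (a$fecal_water_pct %||% 80) / 100,
    calving_month = a$calving_month %||% 9,
    calving_day = a$calving_day %||% 5,
    shade_available = a$shade_available %||% TRUE,
    diet_summer = as_mix(d$summer),
    diet_winter = as_mix(d$winter))
}

#' @rdname read_animal_config
#' @param animal an [animal_spec()]
#' @export
write_animal_config <- function(animal, path) {
  coat <- animal$coat
  cols <- lapply(names(coat$colour_pct), function(cn)
    list(reflectivity_pct = unname(coat$reflectivity_pct[cn]),
         area_pct = unname(coat$colour_pct[cn])))
  names(cols) <- names(coat$colour_pct)
  cfg <- list(
    animal = list(weight_kg = animal$mass_kg,
                  height_cm = animal$height_cm,
                  fur_depth_cm = coat$depth_cm,
                  hair_length_cm = coat$hair_length_cm,
                  calving_month = animal$calving_month,
                  calving_day = animal$calving_day,
                  shade_available = animal$shade_available,
                  fecal_water_pct = 100 * animal$fecal_water_frac),
    coat_colours = cols,
    milk = list(max_expected_kgd = animal$milk_target_kgd,
                fat_pct = animal$milk_fat_pct,
                protein_pct = animal$milk_protein_pct,
                efficiency = animal$milk_efficiency),
    diet = list(summer = as.list(animal$diet_summer),
                winter = as.list(animal$diet_winter)))
  cfg$animal <- cfg$animal[!vapply(cfg$animal, is.null, TRUE)]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write simulation results as tidy CSV files
#'
#' Writes each element of `results` (data.frames, or objects with a
#' `monthly` data.frame such as [simulate_year()] output) as
#' `<name>.csv` under `outdir`, each with a `#`-prefixed metadata
#' header (package version and seed) so runs are self-describing.
#' Ordering is deterministic.
#'
#' @param results named list of data.frames / `annual_result`s
#' @param outdir output directory (created if needed)
#' @param seed seed recorded in the header
#' @return character vector of files written, invisibly
#' @export
write_results <- function(results, outdir, seed = NA) {
  if (!length(results) || is.null(names(results)))
    stop("results must be a named list")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  ver <- as.character(utils::packageVersion("bovitherm"))
  files <- character(0)
  for (nm in sort(names(results))) {
    x <- results[[nm]]
    if (inherits(x, "annual_result")) x <- x$monthly
    if (!is.data.frame(x)) x <- as.data.frame(x)
    path <- file.path(outdir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# bovitherm %s, seed = %s", ver, seed), con)
    utils::write.csv(x, con, row.names = FALSE)
    close(con)
    files <- c(files, path)
  }
  invisible(files)
}
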