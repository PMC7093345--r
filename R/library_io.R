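# Material library container and its JSON serialization.

#' Material library
#'
#' Named collection of material parameter sets (Kelvin-Maxwell, transversely
#' isotropic, linear elastic, foam) with metadata.
#'
#' @param materials named list of material objects.
#' @param metadata list with free-form provenance notes; a `units` entry
#'   documents the unit system of the stored fields.
#' @export
material_library <- function(materials, metadata = list()) {
  stop_if(is.null(names(materials)) || any(names(materials) == ""),
          "all materials must be named")
  ok <- vapply(materials, function(m)
    inherits(m, c("kelvin_maxwell", "transverse_iso", "linear_elastic",
                  "foam_curves")), logical(1))
  stop_if(!all(ok), "unsupported material type in library")
  structure(list(materials = materials, metadata = metadata),
            class = "material_library")
}

#' @export
print.material_library <- function(x, ...) {
  cat(sprintf("Material library (%d entries)\n", length(x$materials)))
  for (nm in names(x$materials)) {
    cat(sprintf("  %-24s %s\n", nm, class(x$materials[[nm]])[1]))
  }
  invisible(x)
}

#' @export
`[[.material_library` <- function(x, i) {
  m <- NextMethod()
  if (is.character(i) && !i %in% c("materials", "metadata") && is.null(m)) {
    m <- x$materials[[i]]
  }
  m
}

#' Default material library
#'
#' The tissue and structure parameter sets of the rodent head model:
#' Kelvin-Maxwell rows for gray cortex, hippocampus, cerebellum,
#' pia-arachnoid and intervertebral disc; elastic rows for dura mater, the
#' skull diploe and cortical layers and the vertebral body; transversely
#' isotropic corpus-callosum and brainstem-tract materials calibrated by
#' [calibrate_fiber_params()] (matrix shear moduli 1.54 and 3.08 kPa, 2x
#' along-fiber reinforcement at a stretch of 1.02); and the rate-dependent
#' supporting foam. All brain tissues carry the 2 GPa bulk-modulus default.
#'
#' The tabulated rows are read from the JSON file shipped in
#' `inst/extdata/materials.json`; the fiber and foam entries are built in
#' code. Densities and the fiber-material Prony constants are documented
#' stand-ins (not tabulated in the source data).
#'
#' @return a [material_library()].
#' @export
default_material_library <- function() {
  path <- system.file("extdata", "materials.json", package = "headimpact")
  lib <- read_material_library(path)
  # stand-in Prony pairs for the fiber-reinforced materials (two active terms)
  prony <- data.frame(S = c(0.5, 0.2), T_ms = c(20, 2))
  cc <- calibrate_fiber_params(matrix_G_kPa = 1.54, target_ratio = 2,
                               lam_target = 1.02, lambda_star = 1.02,
                               prony = prony, name = "corpus callosum")
  bs <- calibrate_fiber_params(matrix_G_kPa = 2 * 1.54, target_ratio = 2,
                               lam_target = 1.02, lambda_star = 1.02,
                               prony = prony, name = "brainstem tracts")
  lib$materials[["corpus callosum"]] <- cc
  lib$materials[["brainstem tracts"]] <- bs
  lib$materials[["supporting foam"]] <- make_foam_curves()
  lib
}

mat_to_list <- function(m, name = NULL) {
  if (inherits(m, "foam_curves")) {
    return(list(type = "foam_curves", name = name %||% "foam",
                rates_per_s = m$rates,
                density_kg_mm3 = m$density_kg_mm3,
                curves = lapply(m$curves, function(cv)
                  list(strain = cv$strain, stress_MPa = cv$stress_MPa))))
  }
  out <- unclass(m)
  out$type <- class(m)[1]
  if (!is.null(out$prony)) {
    out$prony <- list(S = out$prony$S, T_ms = out$prony$T_ms)
  }
  out
}

mat_from_list <- function(x) {
  switch(x$type,
    kelvin_maxwell = kelvin_maxwell(x$name, x$G0_kPa, x$Ginf_kPa,
                                    x$beta_per_ms, K_GPa = x$K_GPa,
                                    density_kg_m3 = x$density_kg_m3 %||% 1040,
                                    brain = isTRUE(x$brain)),
    transverse_iso = transverse_iso(x$name, x$C1_kPa, x$C2_kPa %||% 0,
                                    x$C3_kPa %||% 0, x$C4 %||% 0,
                                    x$C5_kPa %||% 0, x$lambda_star %||% 1.02,
                                    x$K_GPa %||% 2,
                                    prony = if (!is.null(x$prony))
                                      data.frame(S = x$prony$S, T_ms = x$prony$T_ms),
                                    density_kg_m3 = x$density_kg_m3 %||% 1040),
    linear_elastic = linear_elastic(x$name, x$E_MPa, x$nu,
                                    density_kg_m3 = x$density_kg_m3 %||% 1800),
    foam_curves = foam_curves(x$rates_per_s,
                              lapply(x$curves, function(cv)
                                data.frame(strain = cv$strain,
                                           stress_MPa = cv$stress_MPa)),
                              density_kg_mm3 = x$density_kg_mm3),
    stop("unknown material type: ", x$type)
  )
}

#' Read a material library from JSON
#'
#' @param path JSON file produced by [write_material_library()] (or the
#'   shipped default).
#' @export
read_material_library <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  mats <- lapply(raw$materials, mat_from_list)
  names(mats) <- vapply(raw$materials, function(m) m$name, character(1))
  material_library(mats, metadata = raw$metadata %||% list())
}

#' Write a material library to JSON
#'
#' Doubles are written at full precision so that the file round-trips
#' bit-exactly through [read_material_library()].
#'
#' @param lib a [material_library()].
#' @param path output path.
#' @export
write_material_library <- function(lib, path) {
  stopifnot(inherits(lib, "material_library"))
  payload <- list(metadata = lib$metadata,
                  materials = unname(Map(mat_to_list, lib$materials,
                                         names(lib$materials))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}
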