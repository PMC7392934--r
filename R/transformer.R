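#' Tympanic-membrane to footplate area ratio
#'
#' @param A_TM pars-tensa tympanic-membrane area, mm².
#' @param A_FP (projected) stapes footplate / oval-window area, mm².
#' @return Dimensionless `A_TM / A_FP`.
#' @export
area_ratio <- function(A_TM, A_FP) {
  if (any(A_TM <= 0) || any(A_FP <= 0)) stop("areas must be > 0")
  A_TM / A_FP
}

#' Ideal-transformer middle-ear pressure gain
#'
#' The product of the tympanic-membrane/footplate area ratio and the
#' ossicular lever ratio — the pressure amplification an ideal-transformer
#' middle ear provides through the hinge-like rotational motion.
#'
#' @param area_ratio dimensionless, see [area_ratio()].
#' @param lever_ratio ossicular lever ratio L1/L2.
#' @return Dimensionless pressure gain.
#' @export
pressure_gain <- function(area_ratio, lever_ratio) {
  if (any(area_ratio <= 0) || any(lever_ratio <= 0))
    stop("inputs must be > 0")
  area_ratio * lever_ratio
}

#' Lever ratio expressed as a motion attenuation in dB
#'
#' The incus lenticular process moves less than the umbo by the lever
#' ratio; in decibels that is `20 log10(L1/L2)`.
#'
#' @param lever_ratio L1/L2 > 0.
#' @return dB.
#' @export
lever_db <- function(lever_ratio) {
  if (any(lever_ratio <= 0)) stop("`lever_ratio` must be > 0")
  20 * log10(lever_ratio)
}

#' Specific acoustic impedance of the tympanic membrane
#'
#' Ideal-transformer transformation of the cochlear input impedance back to
#' the tympanic membrane: `Z_TM = Z_cochlea / (area_ratio * lever_ratio^2)`.
#' The squared lever ratio reflects the velocity step-down and force step-up
#' of the ossicular lever.
#'
#' @param Z_cochlea specific acoustic impedance of the cochlea, Pa·s·m⁻¹.
#' @param area_ratio,lever_ratio transformer parameters.
#' @return `Z_TM`, Pa·s·m⁻¹.
#' @export
z_tm <- function(Z_cochlea, area_ratio, lever_ratio) {
  if (any(Z_cochlea <= 0) || any(area_ratio <= 0) || any(lever_ratio <= 0))
    stop("inputs must be > 0")
  Z_cochlea / (area_ratio * lever_ratio^2)
}

#' Fraction of incident sound energy transmitted across an impedance step
#'
#' Two-medium power-transmission coefficient
#' `T = 4 Z1 Z2 / (Z1 + Z2)^2`; equals 1 iff the impedances match, and is
#' symmetric in its arguments.
#'
#' @param Z_TM tympanic-membrane specific acoustic impedance, Pa·s·m⁻¹.
#' @param Z_air specific acoustic impedance of air, Pa·s·m⁻¹ (about 420).
#' @return Fraction in (0, 1].
#' @export
energy_fraction <- function(Z_TM, Z_air = 420) {
  if (any(Z_TM <= 0) || any(Z_air <= 0)) stop("impedances must be > 0")
  4 * Z_air * Z_TM / (Z_air + Z_TM)^2
}

#' Full ideal-transformer evaluation for one parameter set
#'
#' Chains [area_ratio()], [pressure_gain()], [lever_db()], [z_tm()] and
#' [energy_fraction()] for one species parameterisation.
#'
#' @param A_TM tympanic-membrane (pars tensa) area, mm².
#' @param A_FP projected footplate area, mm².
#' @param lever_ratio ossicular lever ratio L1/L2.
#' @param Z_cochlea cochlear specific acoustic impedance, Pa·s·m⁻¹
#'   (default 56 kPa·s·m⁻¹).
#' @param Z_air air specific acoustic impedance, Pa·s·m⁻¹.
#' @param species optional label.
#' @return Object of class `transformer_result`: `area_ratio`,
#'   `pressure_gain`, `lever_db`, `Z_TM`, `energy_fraction`, plus inputs.
#' @export
middle_ear_transformer <- function(A_TM, A_FP, lever_ratio,
                                   Z_cochlea = 56000, Z_air = 420,
                                   species = NA_character_) {
  ar <- area_ratio(A_TM, A_FP)
  ztm <- z_tm(Z_cochlea, ar, lever_ratio)
  structure(list(species = species, A_TM = A_TM, A_FP = A_FP,
                 lever_ratio = lever_ratio,
                 Z_cochlea = Z_cochlea, Z_air = Z_air,
                 area_ratio = ar,
                 pressure_gain = pressure_gain(ar, lever_ratio),
                 lever_db = lever_db(lever_ratio),
                 Z_TM = ztm,
                 energy_fraction = energy_fraction(ztm, Z_air)),
            class = "transformer_result")
}

#' @export
print.transformer_result <- function(x, ...) {
  cat("<transformer_result>",
      if (!is.na(x$species)) paste0(" [", x$species, "]"), "\n", sep = "")
  cat(sprintf("  area ratio      %.3g   (A_TM %.4g / A_FP %.4g mm^2)\n",
              x$area_ratio, x$A_TM, x$A_FP))
  cat(sprintf("  lever ratio     %.3g   (%.3g dB umbo-to-lenticular)\n",
              x$lever_ratio, x$lever_db))
  cat(sprintf("  pressure gain   %.3g\n", x$pressure_gain))
  cat(sprintf("  Z_TM            %.4g Pa s/m   (Z_cochlea %.4g)\n",
              x$Z_TM, x$Z_cochlea))
  cat(sprintf("  energy fraction %.3g   (Z_air %.4g Pa s/m)\n",
              x$energy_fraction, x$Z_air))
  invisible(x)
}

#' Default species parameter table
#'
#' Sheep and human parameter sets: tympanic-membrane pars-tensa areas 44.2
#' and 68.3 mm², projected footplate areas 1.45 and 2.86 mm², lever ratios
#' 2.47 and 1.25, cochlear impedance 56 kPa·s·m⁻¹ and air 420 Pa·s·m⁻¹.
#'
#' @return data.frame with one row per species.
#' @export
default_species_params <- function() {
  data.frame(species = c("sheep", "human"),
             A_TM = c(44.2, 68.3),
             A_FP = c(1.45, 2.86),
             lever_ratio = c(2.47, 1.25),
             Z_cochlea = c(56000, 56000),
             Z_air = c(420, 420),
             stringsAsFactors = FALSE)
}

#' Transformer comparison table across species
#'
#' @param params data.frame with columns `species`, `A_TM`, `A_FP`,
#'   `lever_ratio` and optionally `Z_cochlea`, `Z_air`
#'   (defaults 56000 / 420).  May be empty.
#' @return data.frame, one row per species, with columns `area_ratio`,
#'   `lever_ratio`, `pressure_gain`, `lever_db`, `Z_TM`,
#'   `energy_fraction`.
#' @export
species_report <- function(params = default_species_params()) {
  cols <- c("species", "area_ratio", "lever_ratio", "pressure_gain",
            "lever_db", "Z_TM", "energy_fraction")
  if (nrow(params) == 0L) {
    out <- as.data.frame(setNames(
      c(list(character(0)), rep(list(numeric(0)), length(cols) - 1L)), cols))
    return(out)
  }
  if (is.null(params$Z_cochlea)) params$Z_cochlea <- 56000
  if (is.null(params$Z_air)) params$Z_air <- 420
  rows <- lapply(seq_len(nrow(params)), function(i) {
    r <- middle_ear_transformer(params$A_TM[i], params$A_FP[i],
                                params$lever_ratio[i],
                                params$Z_cochlea[i], params$Z_air[i],
                                species = as.character(params$species[i]))
    data.frame(species = r$species, area_ratio = r$area_ratio,
               lever_ratio = r$lever_ratio, pressure_gain = r$pressure_gain,
               lever_db = r$lever_db, Z_TM = r$Z_TM,
               energy_fraction = r$energy_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a species parameter file (YAML)
#'
#' Expects a top-level `species:` list with per-species `A_TM`, `A_FP`,
#' `lever_ratio` and optional `Z_cochlea_kPa` (kPa·s·m⁻¹, converted) or
#' `Z_cochlea`, `Z_air` (Pa·s·m⁻¹).
#'
#' @param path YAML file path.
#' @return data.frame suitable for [species_report()].
#' @export
load_species_params <- function(path) {
  obj <- yaml::read_yaml(path)
  sp <- obj$species
  if (is.null(sp)) stop("parameter file lacks a `species` list: ", path)
  rows <- lapply(names(sp), function(nm) {
    e <- sp[[nm]]
    zc <- if (!is.null(e$Z_cochlea_kPa)) 1000 * e$Z_cochlea_kPa
          else e$Z_cochlea %||% 56000
    data.frame(species = nm, A_TM = e$A_TM, A_FP = e$A_FP,
               lever_ratio = e$lever_ratio, Z_cochlea = zc,
               Z_air = e$Z_air %||% 420, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
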