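#' Thermal and perfusion properties of one tissue type
#'
#' Per-domain material record for the Pennes bioheat model. Perfusion
#' couples the tissue to arterial blood through the volumetric sink
#' `rho_b C_b omega_b (T - T_b)`; `Q_met` is the distributed metabolic
#' source.
#'
#' @param rho Density, kg/m^3 (> 0).
#' @param C_p Heat capacity, J/kg/K (> 0).
#' @param k Thermal conductivity, W/m/K (> 0).
#' @param omega_b Blood perfusion rate, 1/s (>= 0).
#' @param Q_met Metabolic heat generation, W/m^3 (>= 0).
#' @return A list of class `tissue_material`.
#' @examples
#' tumor_material()
#' skin_material()
#' @export
tissue_material <- function(rho, C_p, k, omega_b = 0, Q_met = 0) {
  check_number(rho, "rho", min = 0, strict_min = TRUE)
  check_number(C_p, "C_p", min = 0, strict_min = TRUE)
  check_number(k, "k", min = 0, strict_min = TRUE)
  check_number(omega_b, "omega_b", min = 0)
  check_number(Q_met, "Q_met", min = 0)
  structure(list(rho = rho, C_p = C_p, k = k, omega_b = omega_b,
                 Q_met = Q_met),
            class = "tissue_material")
}

#' @rdname tissue_material
#' @details `tumor_material()` returns the tabled properties of cancerous
#'   skin tissue (muscle-equivalent: rho 1090, C_p 3421, k 0.563, perfusion
#'   1.34e-2 1/s, metabolic heat 13.08 kW/m^3); `skin_material()` those of
#'   normal skin (rho 1109, C_p 3391, k 0.37, perfusion 1.96e-3 1/s,
#'   metabolic heat 1.83 kW/m^3).
#' @export
tumor_material <- function() {
  tissue_material(rho = 1090, C_p = 3421, k = 0.563,
                  omega_b = 1.34e-2, Q_met = 13080)
}

#' @rdname tissue_material
#' @export
skin_material <- function() {
  tissue_material(rho = 1109, C_p = 3391, k = 0.37,
                  omega_b = 1.96e-3, Q_met = 1830)
}

#' Arterial blood properties
#'
#' Constants of the perfusion sink term: blood density, heat capacity and
#' arterial temperature.
#'
#' @param rho_b Blood density, kg/m^3. Default 1050.
#' @param C_b Blood heat capacity, J/kg/K. Default 3617.
#' @param T_b Arterial temperature, K. Default 310.15.
#' @return A list of class `blood_properties`.
#' @export
blood_properties <- function(rho_b = 1050, C_b = 3617, T_b = 310.15) {
  check_number(rho_b, "rho_b", min = 0, strict_min = TRUE)
  check_number(C_b, "C_b", min = 0, strict_min = TRUE)
  check_number(T_b, "T_b", min = 0, strict_min = TRUE)
  structure(list(rho_b = rho_b, C_b = C_b, T_b = T_b),
            class = "blood_properties")
}

#' Nested-cylinder tissue model
#'
#' The treated region is two coaxial cylinders of common height: a tumor core
#' of radius `tumor_radius` loaded uniformly with nanoparticles dissipating
#' `Q_nano`, surrounded by normal skin out to `skin_radius`. The lateral
#' outer surface exchanges heat convectively with the surroundings
#' (coefficient `h`, ambient `T_ext`); top and bottom faces are insulated by
#' default (configurable via `convective_faces`). The excitation coil and air
#' are excluded from the thermal domain.
#'
#' @param tumor_radius Tumor cylinder radius, m. Default 5e-3.
#' @param skin_radius Outer skin radius, m (> `tumor_radius`). Default 15e-3.
#' @param height Common cylinder height, m. Default 30e-3.
#' @param tumor,skin [tissue_material()] records for the two domains.
#' @param blood A [blood_properties()].
#' @param Q_nano Volumetric nanoparticle power in the tumor, W/m^3.
#'   Default 2.14e5. This is a direct input: it is not coupled to the
#'   linear-response chain (see [heating_power()]), whose tabled inputs do
#'   not reproduce this headline value.
#' @param h Convective surface coefficient, W/m^2/K (>= 0). Default 3.6.
#' @param T_ext External temperature, K. Default 310.15.
#' @param T_0 Initial temperature, K. Default 310.15.
#' @param convective_faces Character subset of
#'   `c("lateral", "top", "bottom")`; faces not listed are insulated.
#'   Default `"lateral"`.
#' @return A list of class `tissue_model`.
#' @examples
#' tissue_model()
#' @export
tissue_model <- function(tumor_radius = 5e-3, skin_radius = 15e-3,
                         height = 30e-3,
                         tumor = tumor_material(), skin = skin_material(),
                         blood = blood_properties(),
                         Q_nano = 2.14e5, h = 3.6,
                         T_ext = 310.15, T_0 = 310.15,
                         convective_faces = "lateral") {
  check_number(tumor_radius, "tumor_radius", min = 0, strict_min = TRUE)
  check_number(skin_radius, "skin_radius", min = 0, strict_min = TRUE)
  check_number(height, "height", min = 0, strict_min = TRUE)
  if (tumor_radius >= skin_radius) {
    abort("`tumor_radius` must be strictly less than `skin_radius`.")
  }
  stopifnot(inherits(tumor, "tissue_material"),
            inherits(skin, "tissue_material"),
            inherits(blood, "blood_properties"))
  check_number(Q_nano, "Q_nano", min = 0)
  check_number(h, "h", min = 0)
  check_number(T_ext, "T_ext", min = 0, strict_min = TRUE)
  check_number(T_0, "T_0", min = 0, strict_min = TRUE)
  faces <- match.arg(convective_faces, c("lateral", "top", "bottom"),
                     several.ok = TRUE)
  structure(list(
    tumor_radius = tumor_radius, skin_radius = skin_radius, height = height,
    tumor = tumor, skin = skin, blood = blood, Q_nano = Q_nano, h = h,
    T_ext = T_ext, T_0 = T_0, convective_faces = faces
  ), class = "tissue_model")
}

#' Space-time discretization of the bioheat solve
#'
#' Cell-centered axisymmetric finite-volume grid: cells of size `dr` x `dz`
#' span `[0, skin_radius] x [0, height]`, stepped implicitly with `dt`.
#' Full temperature fields are stored every `field_interval` seconds (plus
#' the initial and final states); probes are recorded every step.
#'
#' @param dr,dz Spatial steps, m. Default 0.5e-3.
#' @param dt Time step, s. Default 1.
#' @param duration Total simulated time, s. Default 3600.
#' @param field_interval Field storage cadence, s. Default 60.
#' @return A list of class `sim_grid`.
#' @examples
#' sim_grid()
#' @export
sim_grid <- function(dr = 0.5e-3, dz = 0.5e-3, dt = 1, duration = 3600,
                     field_interval = 60) {
  check_number(dr, "dr", min = 0, strict_min = TRUE)
  check_number(dz, "dz", min = 0, strict_min = TRUE)
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  check_number(field_interval, "field_interval", min = 0, strict_min = TRUE)
  structure(list(dr = dr, dz = dz, dt = dt, duration = duration,
                 field_interval = field_interval),
            class = "sim_grid")
}
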