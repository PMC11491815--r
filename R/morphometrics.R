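#' Derive wing morphology from mass and single-wing measurements
#'
#' Wing photos give a single wing's area and the semi-span; doubling them
#' yields the complete wing area `S = 2 * single_wing_area` and full span
#' `b = 2 * semi_span`. Derived quantities: mean chord `c = S / b`, aspect
#' ratio `AR = b^2 / S`, wing loading `N = m * g / S` (N m^-2) and the
#' weight-normalized wing area `S* = S / (m * g) = 1 / N` (m^2 N^-1), the
#' covariate expected to scale with in-flight acceleration. All identities
#' (`S* * N = 1`, `AR * c = b`) hold to machine precision. Vectorized.
#'
#' @param mass_kg body mass in kg (> 0).
#' @param single_wing_area_m2 one wing's area in m^2 (> 0).
#' @param semi_span_m semi-span in m (> 0).
#' @param g gravitational acceleration, 9.81 m s^-2.
#' @return data frame with columns `mass_kg`, `S_m2`, `b_m`, `chord_m`,
#'   `AR`, `N_Nm2`, `Sstar`.
#' @examples
#' derive_morphology(0.013, 8712e-6 / 2, 0.211 / 2)
#' @export
derive_morphology <- function(mass_kg, single_wing_area_m2, semi_span_m, g = 9.81) {
  if (any(mass_kg <= 0) || any(single_wing_area_m2 <= 0) || any(semi_span_m <= 0))
    stop("mass, wing area and semi-span must all be positive")
  S <- 2 * single_wing_area_m2
  b <- 2 * semi_span_m
  N <- mass_kg * g / S
  data.frame(mass_kg = mass_kg, S_m2 = S, b_m = b,
             chord_m = S / b, AR = b^2 / S, N_Nm2 = N, Sstar = 1 / N)
}

#' Derive morphology from a field-unit population table
#'
#' Converts the population CSV units (g, mm^2, mm) to SI and calls
#' [derive_morphology()].
#'
#' @param population data frame with `mass_g`, `single_wing_area_mm2`,
#'   `semi_span_mm` (e.g. from [generate_population()]); other columns
#'   (`bird_id`, `sex`, ...) are carried through.
#' @param g gravitational acceleration, m s^-2.
#' @return `population` with the derived SI morphology columns appended.
#' @export
morphology_from_field <- function(population, g = 9.81) {
  need <- c("mass_g", "single_wing_area_mm2", "semi_span_mm")
  miss <- setdiff(need, names(population))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  m <- derive_morphology(population$mass_g / 1000,
                         population$single_wing_area_mm2 * 1e-6,
                         population$semi_span_mm / 1000, g = g)
  cbind(population, m[, setdiff(names(m), "mass_kg")], mass_kg = m$mass_kg)
}

#' Percent difference between two group means
#'
#' `100 * (a - b) / b`, relative to the stated reference group `b`. E.g.
#' female vs male wing loading 15.9 vs 14.8 N m^-2 gives +7.4% ("~7% larger").
#'
#' @param group_mean mean of the focal group.
#' @param reference_mean mean of the reference group (> 0).
#' @return percent difference.
#' @export
sex_dimorphism <- function(group_mean, reference_mean) {
  if (any(reference_mean <= 0)) stop("`reference_mean` must be positive")
  100 * (group_mean - reference_mean) / reference_mean
}
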