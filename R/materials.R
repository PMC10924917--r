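# X-ray optical constants for the tissue classes present in a paraffin-embedded
# breast block. The complex refractive index is written n = 1 - delta + i*beta;
# delta drives phase contrast, beta absorption. Constants are computed from a
# frozen per-element tabulation (Z, A, imaginary scattering factor f2 at
# 20 keV) and mass-fraction compositions, plus an incoherent (Compton)
# contribution to beta so that beta is consistent with the total linear
# attenuation coefficient a CT reconstruction measures.

# hc in keV * m
.hc_keV_m <- 1.23984193e-9
.r_e <- 2.8179403262e-15      # classical electron radius, m
.N_A <- 6.02214076e23
# Klein-Nishina incoherent cross-section per electron near 20 keV, m^2.
.sigma_compton_20 <- 6.03e-29

# Frozen element data: Z, atomic mass, photoabsorption scattering factor f2
# at 20 keV (from standard atomic scattering-factor tabulations).
.element_data <- list(
  H  = c(Z = 1,  A = 1.008,  f2 = 2.38e-8),
  C  = c(Z = 6,  A = 12.011, f2 = 4.85e-4),
  N  = c(Z = 7,  A = 14.007, f2 = 1.03e-3),
  O  = c(Z = 8,  A = 15.999, f2 = 1.83e-3),
  P  = c(Z = 15, A = 30.974, f2 = 3.5e-2),
  Ca = c(Z = 20, A = 40.078, f2 = 1.09e-1)
)

# Material compositions: density (g/cm^3) and elemental mass fractions.
# Soft tissues follow ICRU-44-style compositions; paraffin is CH2; the
# calcification is hydroxyapatite Ca5(PO4)3OH.
.material_compositions <- list(
  paraffin      = list(rho = 0.90, w = c(H = 0.1437, C = 0.8563)),
  adipose       = list(rho = 0.95, w = c(H = 0.114, C = 0.598, N = 0.007, O = 0.278)),
  glandular     = list(rho = 1.04, w = c(H = 0.106, C = 0.332, N = 0.030, O = 0.527)),
  stroma_dense  = list(rho = 1.10, w = c(H = 0.106, C = 0.332, N = 0.030, O = 0.527)),
  blood         = list(rho = 1.06, w = c(H = 0.102, C = 0.110, N = 0.033, O = 0.745)),
  calcification = list(rho = 3.18, w = c(Ca = 0.3990, P = 0.18499, O = 0.41404, H = 0.002007))
)

#' X-ray wavelength from photon energy
#'
#' @param energy_keV photon energy in keV.
#' @return wavelength in metres (`lambda = hc / E`).
#' @export
xray_wavelength <- function(energy_keV) {
  stopifnot(energy_keV > 0)
  .hc_keV_m / energy_keV
}

.material_delta_beta <- function(name, energy_keV) {
  comp <- .material_compositions[[name]]
  lam <- xray_wavelength(energy_keV)
  K <- .r_e * lam^2 / (2 * pi)
  w <- comp$w / sum(comp$w)
  # number density of each element per m^3
  n_i <- vapply(names(w), function(e) {
    comp$rho * w[[e]] * .N_A / .element_data[[e]][["A"]] * 1e6
  }, numeric(1))
  Z <- vapply(names(w), function(e) .element_data[[e]][["Z"]], numeric(1))
  # f2 scales approximately as E^-2 away from absorption edges
  f2 <- vapply(names(w), function(e) .element_data[[e]][["f2"]], numeric(1)) *
    (20 / energy_keV)^2
  n_e <- sum(n_i * Z)
  delta <- K * n_e
  beta <- K * sum(n_i * f2) + n_e * .sigma_compton_20 * lam / (4 * pi)
  c(delta = delta, beta = beta)
}

#' Build the material refractive-index table
#'
#' Constructs the per-material (delta, beta) lookup used to convert labeled
#' phantoms into refractive-index maps, at a stated monochromatic energy.
#' "air" is treated as vacuum (delta = beta = 0). The table also carries the
#' default TIE-Hom filter ratio delta/beta = 350 used downstream for the
#' glandular/adipose interface.
#'
#' @param energy_keV photon energy, 5 to 100 keV.
#' @return an object of class `material_table` with fields `energy_keV`,
#'   `entries` (named list of `c(delta, beta)`) and `default_delta_beta`.
#' @examples
#' tab <- build_material_table(20)
#' material_lookup(tab, "glandular")
#' @export
build_material_table <- function(energy_keV = 20) {
  if (!is.numeric(energy_keV) || length(energy_keV) != 1 ||
      energy_keV < 5 || energy_keV > 100) {
    stop_vh("energy_keV must be a single value in [5, 100] keV (got %s)",
            format(energy_keV))
  }
  entries <- lapply(names(.material_compositions), .material_delta_beta,
                    energy_keV = energy_keV)
  names(entries) <- names(.material_compositions)
  entries$air <- c(delta = 0, beta = 0)
  structure(list(energy_keV = energy_keV,
                 entries = entries,
                 default_delta_beta = 350),
            class = "material_table")
}

#' Look up delta and beta for a material
#'
#' @param table a `material_table`.
#' @param name material name; unknown names are an error.
#' @return named numeric vector `c(delta, beta)`.
#' @export
material_lookup <- function(table, name) {
  stopifnot(inherits(table, "material_table"))
  if (!name %in% names(table$entries)) {
    stop_vh("material '%s' is not in the table (have: %s)",
            name, paste(names(table$entries), collapse = ", "))
  }
  table$entries[[name]]
}

#' Names of all materials in a table
#' @param table a `material_table`.
#' @export
material_names <- function(table) names(table$entries)

#' Linear attenuation coefficient of a material
#'
#' `mu = 4 * pi * beta / lambda`, in 1/m, at the table's energy.
#' @param table a `material_table`.
#' @param name material name.
#' @export
material_mu <- function(table, name) {
  db <- material_lookup(table, name)
  4 * pi * db[["beta"]] / xray_wavelength(table$energy_keV)
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("material_table at %.3g keV (default delta/beta = %g)\n",
              x$energy_keV, x$default_delta_beta))
  for (nm in names(x$entries)) {
    e <- x$entries[[nm]]
    cat(sprintf("  %-13s delta = %.4e  beta = %.4e\n", nm, e[["delta"]], e[["beta"]]))
  }
  invisible(x)
}
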