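# Quantitative ink physics: Ostwald power-law rheology, gel-point
# crossover, small-strain Hookean modulus, series-circuit conductivity,
# reservoir printability window, and a lumped Newtonian-cooling check for
# ink switching.

#' Fit the Ostwald (power-law) viscosity model
#'
#' Fits `eta = K * gamma_dot^(n - 1)` by ordinary least squares in log-log
#' space (`log eta = log K + (n - 1) log gamma_dot`), the standard
#' linearization for shear-thinning characterization; `n < 1` indicates
#' shear thinning and `n = 1` a Newtonian fluid.
#'
#' @param shear_rates Shear rates, 1/s; positive, length >= 3.
#' @param viscosities Apparent viscosities, Pa.s; positive, same length.
#' @return An object of class `power_law_fit` with `K` (consistency,
#'   Pa.s^n), `n` (flow index), and `residual` (sum of squared log-space
#'   residuals).
#' @examples
#' g <- 10^seq(-2, 2, length.out = 50)
#' fit_power_law(g, 12 * g^(0.3 - 1))$n  # 0.3
#' @export
fit_power_law <- function(shear_rates, viscosities) {
  if (length(shear_rates) < 3L || length(viscosities) != length(shear_rates)) {
    stop("fit_power_law: need >= 3 paired points", call. = FALSE)
  }
  if (any(shear_rates <= 0) || any(viscosities <= 0)) {
    stop("fit_power_law: shear rates and viscosities must be positive",
         call. = FALSE)
  }
  fit <- stats::lm(log(viscosities) ~ log(shear_rates))
  co <- stats::coef(fit)
  structure(
    list(K = exp(co[[1]]), n = 1 + co[[2]],
         residual = sum(stats::residuals(fit)^2)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> K = %.6g Pa.s^n, n = %.6g (logSSR %.3g)\n",
              x$K, x$n, x$residual))
  invisible(x)
}

#' Rheology curve container
#'
#' Storage/loss moduli and complex viscosity versus temperature, as
#' recorded in an oscillatory cooling sweep.
#'
#' @param temperature Temperatures, degrees C; strictly monotone.
#' @param G_storage,G_loss Storage and loss moduli G' and G'', Pa;
#'   positive.
#' @param complex_viscosity Optional complex viscosity, Pa.s.
#' @return An object of class `rheology_curve`.
#' @export
rheology_curve <- function(temperature, G_storage, G_loss,
                           complex_viscosity = NULL) {
  n <- length(temperature)
  stopifnot(n >= 2L, length(G_storage) == n, length(G_loss) == n)
  d <- diff(temperature)
  if (!(all(d > 0) || all(d < 0))) {
    stop("rheology_curve: temperatures must be strictly monotone",
         call. = FALSE)
  }
  if (any(G_storage <= 0) || any(G_loss <= 0)) {
    stop("rheology_curve: moduli must be positive", call. = FALSE)
  }
  if (!is.null(complex_viscosity)) stopifnot(length(complex_viscosity) == n)
  structure(
    list(temperature = temperature, G_storage = G_storage, G_loss = G_loss,
         complex_viscosity = complex_viscosity),
    class = "rheology_curve"
  )
}

#' Find the gel-point (G' = G'') crossover temperature
#'
#' Locates sign changes of `log G' - log G''` along the temperature axis and
#' interpolates linearly in log space between the bracketing samples. Below
#' the crossover the ink behaves as a gel (elastic response dominates);
#' above it, as a liquid. When several crossings exist the
#' highest-temperature one is returned — cooling from the reservoir, that is
#' the first gelation encountered.
#'
#' @param curve A [rheology_curve()].
#' @return Crossover temperature in degrees C, or `NULL` when G' and G''
#'   never cross.
#' @export
find_crossover <- function(curve) {
  stopifnot(inherits(curve, "rheology_curve"))
  temp <- curve$temperature
  d <- log(curve$G_storage) - log(curve$G_loss)
  crossings <- numeric(0)
  for (i in seq_len(length(d) - 1L)) {
    if (d[i] == 0) crossings <- c(crossings, temp[i])
    if (d[i] * d[i + 1L] < 0) {
      frac <- d[i] / (d[i] - d[i + 1L])
      crossings <- c(crossings, temp[i] + frac * (temp[i + 1L] - temp[i]))
    }
  }
  if (d[length(d)] == 0) crossings <- c(crossings, temp[length(d)])
  if (length(crossings) == 0L) return(NULL)
  max(crossings)
}

#' Stress-strain curve container
#'
#' @param strain Engineering strain, dimensionless; starts >= 0, monotone
#'   increasing.
#' @param stress Stress, kPa.
#' @return An object of class `stress_strain`.
#' @export
stress_strain <- function(strain, stress) {
  stopifnot(length(strain) == length(stress), length(strain) >= 2L)
  if (strain[1] < 0 || any(diff(strain) <= 0)) {
    stop("stress_strain: strain must start >= 0 and increase monotonically",
         call. = FALSE)
  }
  structure(list(strain = strain, stress = stress),
            class = "stress_strain")
}

#' Fit the small-strain Young's modulus
#'
#' Hookean fit `sigma = E * epsilon` on the linear-elastic portion of a
#' compression curve: a zero-intercept least-squares slope restricted to the
#' strain window (default 0–4\%, where agarose gels respond linearly).
#' Points outside the window never influence the fit. A free-intercept fit
#' is available for curves whose prestrain was not removed.
#'
#' @param curve A [stress_strain()].
#' @param strain_window Numeric `(lo, hi)` window of strains used, inclusive.
#' @param intercept Logical; `TRUE` fits `sigma = a + E * epsilon` and
#'   returns the slope.
#' @return Young's modulus E in kPa.
#' @export
fit_modulus <- function(curve, strain_window = c(0, 0.04),
                        intercept = FALSE) {
  stopifnot(inherits(curve, "stress_strain"), length(strain_window) == 2L)
  sel <- curve$strain >= strain_window[1] & curve$strain <= strain_window[2]
  if (sum(sel) < 2L) {
    stop("fit_modulus: fewer than 2 points inside the strain window",
         call. = FALSE)
  }
  eps <- curve$strain[sel]
  sig <- curve$stress[sel]
  if (intercept) {
    stats::coef(stats::lm(sig ~ eps))[["eps"]]
  } else {
    sum(sig * eps) / sum(eps^2)
  }
}

#' Conductivity segment specification
#'
#' @param ink_id Ink id.
#' @param length Segment length, mm; > 0.
#' @param sigma Specific conductivity of the segment's ink, S/m; > 0.
#' @return An object of class `conductivity_segment`.
#' @export
conductivity_segment <- function(ink_id, length, sigma) {
  stopifnot(length > 0)
  if (sigma <= 0) {
    stop("conductivity_segment: sigma must be > 0", call. = FALSE)
  }
  structure(list(ink_id = ink_id, length = length, sigma = sigma),
            class = "conductivity_segment")
}

#' Effective conductivity of segments in series
#'
#' Each single-ink segment of a filament acts as an independent resistor;
#' in series, with the cross-section cancelling, the effective specific
#' conductivity is the length-weighted harmonic mean
#' `sigma_eff = sum(L_i) / sum(L_i / sigma_i)`. Interface resistance between
#' segments is not modeled (the `interface_resistance` hook is an extra
#' series resistance in Ohm per interface, applied when a capillary
#' geometry is supplied; it defaults to zero).
#'
#' @param segments List of [conductivity_segment()]; length >= 1.
#' @param interface_resistance Extra resistance per segment interface, Ohm
#'   (default 0).
#' @param diameter Filament diameter in mm; only needed when
#'   `interface_resistance > 0`.
#' @return Effective specific conductivity, S/m (same units as the
#'   segments' `sigma`).
#' @export
series_conductivity <- function(segments, interface_resistance = 0,
                                diameter = NULL) {
  stopifnot(length(segments) >= 1L)
  lens <- vapply(segments, function(s) s$length, numeric(1))
  sig <- vapply(segments, function(s) s$sigma, numeric(1))
  if (any(sig <= 0)) {
    stop("series_conductivity: all sigma must be > 0", call. = FALSE)
  }
  resist_per_area <- sum(lens / sig)  # units mm / (S/m): R * A up to scale
  if (interface_resistance > 0) {
    if (is.null(diameter)) {
      stop("series_conductivity: diameter needed for interface resistance",
           call. = FALSE)
    }
    area_m2 <- pi * (diameter / 1000)^2 / 4
    n_if <- length(segments) - 1L
    # convert R*A (Ohm m^2) to the mm/(S/m) scale used above: L_mm / sigma
    resist_per_area <- resist_per_area +
      n_if * interface_resistance * area_m2 * 1000
  }
  sum(lens) / resist_per_area
}

#' Specific conductivity from a filament resistance measurement
#'
#' `sigma = L / (R * A)` with `A = pi d^2 / 4`, converted to S/m.
#'
#' @param R Measured resistance, Ohm; > 0.
#' @param length Filament length, mm; > 0.
#' @param diameter Filament diameter, mm; > 0.
#' @return Specific conductivity, S/m.
#' @examples
#' specific_conductivity_from_resistance(1e6, 24, 0.5)  # 0.1222 S/m
#' @export
specific_conductivity_from_resistance <- function(R, length, diameter) {
  if (R <= 0 || length <= 0 || diameter <= 0) {
    stop("specific_conductivity_from_resistance: all inputs must be > 0",
         call. = FALSE)
  }
  area_m2 <- pi * (diameter / 1000)^2 / 4
  (length / 1000) / (R * area_m2)
}

#' Resistance of a filament from its effective conductivity
#'
#' Inverse of [specific_conductivity_from_resistance()]; useful for
#' round-tripping series-circuit expectations against measurements.
#'
#' @param sigma Specific conductivity, S/m.
#' @param length Filament length, mm.
#' @param diameter Filament diameter, mm.
#' @return Resistance in Ohm.
#' @export
resistance_from_specific_conductivity <- function(sigma, length, diameter) {
  if (sigma <= 0 || length <= 0 || diameter <= 0) {
    stop("resistance_from_specific_conductivity: all inputs must be > 0",
         call. = FALSE)
  }
  area_m2 <- pi * (diameter / 1000)^2 / 4
  (length / 1000) / (sigma * area_m2)
}

#' Reservoir printability window
#'
#' The reservoir must sit above every ink's gel point (plus a safety
#' margin) so all inks stay liquid and aspirable, and below a ceiling set
#' by other constraints (cell viability for bio-inks, evaporation).
#'
#' @param inks List of [ink_spec()] objects, each with a `crossover_T`.
#' @param margin Safety margin above the highest crossover, degrees C.
#' @param ceiling Upper temperature bound, degrees C.
#' @return Numeric `c(T_low, T_high)` in degrees C.
#' @export
printability_window <- function(inks, margin = 5, ceiling = 60) {
  stopifnot(length(inks) >= 1L)
  tx <- vapply(inks, function(s) {
    if (is.null(s$crossover_T)) {
      stop("printability_window: ink ", s$ink_id, " lacks crossover_T",
           call. = FALSE)
    }
    s$crossover_T
  }, numeric(1))
  t_low <- max(tx) + margin
  if (t_low > ceiling) {
    stop(sprintf(
      "printability_window: empty window — need >= %.4g C but ceiling is %.4g C",
      t_low, ceiling), call. = FALSE)
  }
  c(T_low = t_low, T_high = ceiling)
}

#' Temperature drop of aspirated ink during switching
#'
#' Lumped-capacitance (Newtonian) cooling of the ink column while the
#' capillary travels between reservoirs:
#' `T(t) = T_env + (T0 - T_env) * exp(-t / tau)`. A short switching time
#' relative to the thermal time constant keeps the drop small, so viscosity
#' change during switching is negligible and no gelation occurs in transit.
#'
#' @param T0 Initial (reservoir) temperature, degrees C.
#' @param T_env Ambient temperature, degrees C.
#' @param elapsed Time out of the reservoir, s; >= 0.
#' @param tau Lumped thermal time constant of the filled capillary, s; > 0.
#' @return Temperature after `elapsed` seconds, degrees C.
#' @export
switching_temperature_drop <- function(T0, T_env, elapsed, tau) {
  if (tau <= 0) stop("switching_temperature_drop: tau must be > 0",
                     call. = FALSE)
  if (elapsed < 0) stop("switching_temperature_drop: elapsed must be >= 0",
                        call. = FALSE)
  T_env + (T0 - T_env) * exp(-elapsed / tau)
}

#' Flag gelation risk during ink switching
#'
#' @param inks List of [ink_spec()] with `crossover_T` set.
#' @inheritParams switching_temperature_drop
#' @return List with `temperature` (after cooling) and `at_risk` (character
#'   vector of ink ids whose crossover lies at or above that temperature).
#' @export
gelation_risk <- function(inks, T0, T_env, elapsed, tau) {
  temp <- switching_temperature_drop(T0, T_env, elapsed, tau)
  tx <- vapply(inks, function(s) s$crossover_T %||% -Inf, numeric(1))
  ids <- vapply(inks, function(s) s$ink_id, character(1))
  list(temperature = temp, at_risk = ids[tx >= temp])
}

# --- CSV readers -------------------------------------------------------------

#' Read ink characterization CSV files
#'
#' Plain `read.csv` wrappers returning the package's containers:
#' \describe{
#'   \item{`read_shear_sweep`}{columns `shear_rate` (1/s), `viscosity`
#'     (Pa.s) -> list of two vectors.}
#'   \item{`read_rheology_curve`}{columns `temperature`, `G_storage`,
#'     `G_loss`, optional `complex_viscosity` -> [rheology_curve()].}
#'   \item{`read_stress_strain`}{columns `strain`, `stress` (kPa) ->
#'     [stress_strain()].}
#'   \item{`read_filament_resistance`}{columns `filament_id`, `R_ohm`,
#'     `length_mm`, optional `diameter_mm` -> data.frame.}
#' }
#'
#' @param path CSV file path.
#' @return See details.
#' @name ink_csv_readers
NULL

#' @rdname ink_csv_readers
#' @export
read_shear_sweep <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("shear_rate", "viscosity") %in% names(d)))
  list(shear_rates = d$shear_rate, viscosities = d$viscosity)
}

#' @rdname ink_csv_readers
#' @export
read_rheology_curve <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("temperature", "G_storage", "G_loss") %in% names(d)))
  rheology_curve(d$temperature, d$G_storage, d$G_loss,
                 d$complex_viscosity)
}

#' @rdname ink_csv_readers
#' @export
read_stress_strain <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("strain", "stress") %in% names(d)))
  stress_strain(d$strain, d$stress)
}

#' @rdname ink_csv_readers
#' @export
read_filament_resistance <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("filament_id", "R_ohm", "length_mm") %in% names(d)))
  d
}
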