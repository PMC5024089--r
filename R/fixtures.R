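# Synthetic fixtures: the canonical patterned builds (nested squares,
# conductivity gradient, two-layer "T", striped cell pattern, 3-segment
# conductivity filaments) and synthetic measurement curves (power-law flow
# sweeps, gelation curves, stress-strain curves). All generators are
# deterministic under a fixed seed, and their noise-free variants satisfy
# their defining equations exactly, so they double as test oracles.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Nested concentric-squares pattern
#'
#' Square bands of distinct inks, outermost ink first, innermost last; band
#' `i` is the frame between insets `sum(band_widths[seq_len(i - 1)])` and
#' `sum(band_widths[seq_len(i)])` from each edge, and the innermost ink
#' fills the remaining central square of side `2 * band_widths[k]`. A
#' filament through the center therefore crosses the palindromic ink
#' sequence `ink_1 ... ink_k ... ink_1` — `2k - 1` segments with `2k - 2`
#' ink switches (7 segments and 6 switches for four inks), with center-row
#' segment lengths `w_1, ..., w_{k-1}, 2 w_k, w_{k-1}, ..., w_1`.
#'
#' @param band_widths Band widths in mm, outermost first; all > 0. The last
#'   entry is the half-side of the central square.
#' @param inks Ink ids, one per band (outermost first).
#' @param pixel_size Raster pixel size, mm.
#' @param palette Optional [ink_palette()]; defaults to a minimal palette
#'   of `inks`.
#' @return A [layer_pattern()] of side `2 * sum(band_widths)`.
#' @examples
#' pat <- gen_nested_squares(c(3, 3, 3, 3), c("A1", "A2", "A3", "A4"))
#' @export
gen_nested_squares <- function(band_widths, inks, pixel_size = 0.1,
                               palette = NULL) {
  k <- length(band_widths)
  if (k < 1L || length(inks) != k) {
    stop("gen_nested_squares: need one ink per band", call. = FALSE)
  }
  if (any(band_widths <= 0)) {
    stop("gen_nested_squares: zero-width band", call. = FALSE)
  }
  if (is.null(palette)) palette <- ink_palette(inks)
  side <- 2 * sum(band_widths)
  n <- as.integer(round(side / pixel_size))
  centers <- (seq_len(n) - 0.5) * pixel_size
  insets <- cumsum(c(0, band_widths[-k]))
  grid <- matrix(NA_character_, nrow = n, ncol = n)
  for (iy in seq_len(n)) {
    depth_y <- pmin(centers[iy], side - centers[iy])
    depth <- pmin(centers, side - centers, depth_y)
    grid[iy, ] <- inks[findInterval(depth, insets)]
  }
  layer_pattern(grid, pixel_size, palette)
}

#' Three-segment conductivity filament
#'
#' A filament of fixed total length with a middle segment of one ink and
#' equal head and tail segments of another — the geometry used to probe how
#' segment lengths set the series conductivity of a printed filament
#' (24 mm total with middles of 4, 8, and 12 mm gives heads of 10, 8, and
#' 6 mm).
#'
#' @param total Total filament length, mm.
#' @param middle Middle-segment length, mm; `0 < middle <= total`.
#' @param inks Character `(outer, middle)` ink ids.
#' @param index,start,orientation,z Passed to [filament_plan()].
#' @return A [filament_plan()] with segments `outer, middle, outer` (a
#'   single middle segment when `middle == total`).
#' @export
gen_three_segment_filament <- function(total = 24, middle,
                                       inks = c("AC3", "AC1"),
                                       index = 1L, start = c(0, 0),
                                       orientation = 0, z = 0) {
  stopifnot(total > 0, length(inks) == 2L)
  if (middle <= 0 || middle > total) {
    stop("gen_three_segment_filament: need 0 < middle <= total",
         call. = FALSE)
  }
  head_len <- (total - middle) / 2
  segs <- if (head_len == 0) {
    list(ink_segment(inks[2], middle))
  } else {
    list(ink_segment(inks[1], head_len),
         ink_segment(inks[2], middle),
         ink_segment(inks[1], head_len))
  }
  filament_plan(index, start, orientation, total, segs, z = z)
}

#' Gradient rectangle pattern
#'
#' Axis-aligned ink bands along x (so filaments sliced along x cross every
#' band; filaments along y stay single-ink) — the layout used to print a
#' conductivity gradient.
#'
#' @param inks Ink ids in band order (left to right).
#' @param band_length Length of each band along x, mm.
#' @param width Pattern height along y, mm.
#' @param pixel_size Raster pixel size, mm.
#' @param palette Optional [ink_palette()].
#' @return A [layer_pattern()].
#' @export
gen_gradient_rectangle <- function(inks, band_length, width,
                                   pixel_size = 0.1, palette = NULL) {
  stopifnot(length(inks) >= 1L, band_length > 0, width > 0)
  if (is.null(palette)) palette <- ink_palette(unique(inks))
  nx <- as.integer(round(length(inks) * band_length / pixel_size))
  ny <- as.integer(round(width / pixel_size))
  xc <- (seq_len(nx) - 0.5) * pixel_size
  band <- pmin(findInterval(xc, (seq_along(inks) - 1) * band_length),
               length(inks))
  grid <- matrix(inks[band], nrow = ny, ncol = nx, byrow = TRUE)
  layer_pattern(grid, pixel_size, palette)
}

#' Two-layer "T" build model
#'
#' Two congruent layers over a background ink: the first carries the
#' horizontal bar of a "T" in the foreground ink, the second the vertical
#' stem; the union of the foreground regions across layers forms the "T".
#'
#' @param ink_bg,ink_fg Background and foreground ink ids.
#' @param dims List with `width`, `height` (layer extent, mm),
#'   `bar_thickness` (bar height, mm), `stem_thickness` (stem width, mm),
#'   `pixel_size` (mm).
#' @param layer_height Vertical spacing of the two layers, mm.
#' @param palette Optional [ink_palette()].
#' @return A [stack_layers()] build model with two layers.
#' @export
gen_two_layer_T <- function(ink_bg = "A2", ink_fg = "AC5",
                            dims = list(width = 12, height = 12,
                                        bar_thickness = 3,
                                        stem_thickness = 3,
                                        pixel_size = 0.1),
                            layer_height = 0.5, palette = NULL) {
  w <- dims$width; h <- dims$height
  bt <- dims$bar_thickness; st <- dims$stem_thickness
  px <- dims$pixel_size
  if (any(c(w, h, bt, st) <= 0)) {
    stop("gen_two_layer_T: all dimensions must be > 0", call. = FALSE)
  }
  if (bt > h || st > w) {
    stop("gen_two_layer_T: bar/stem exceed the layer extent", call. = FALSE)
  }
  if (is.null(palette)) palette <- ink_palette(c(ink_bg, ink_fg))
  nx <- as.integer(round(w / px)); ny <- as.integer(round(h / px))
  xc <- (seq_len(nx) - 0.5) * px; yc <- (seq_len(ny) - 0.5) * px
  bar <- matrix(ink_bg, ny, nx)
  bar[yc >= h - bt, ] <- ink_fg           # top bar, full width
  stem <- matrix(ink_bg, ny, nx)
  x0 <- (w - st) / 2
  stem[yc < h - bt, xc >= x0 & xc < x0 + st] <- ink_fg  # stem below the bar
  stack_layers(list(layer_pattern(bar, px, palette),
                    layer_pattern(stem, px, palette)),
               layer_height)
}

#' Striped cell pattern
#'
#' Parallel filament lanes of matrix ink in which selected lanes carry a
#' cell-laden middle segment: the canonical biological pattern has six
#' filaments, four of them composed of three segments
#' (matrix / cell-laden / matrix) and two of plain matrix.
#'
#' @param matrix_ink,cell_ink Ink ids for the matrix and the cell-laden
#'   ink.
#' @param n_filaments Number of filament lanes.
#' @param striped_indices Lane indices (1-based, bottom lane first) that
#'   carry the cell-laden middle segment.
#' @param segment_fractions Numeric `(head, middle, tail)` fractions of the
#'   filament length; must sum to 1.
#' @param filament_length Lane length along x, mm.
#' @param filament_diameter Lane height along y, mm.
#' @param pixel_size Raster pixel size, mm.
#' @param palette Optional [ink_palette()].
#' @return A [layer_pattern()] of `n_filaments` lanes.
#' @export
gen_stripe_cell_pattern <- function(matrix_ink = "AS3", cell_ink = "A-NIH",
                                    n_filaments = 6,
                                    striped_indices = 2:5,
                                    segment_fractions = c(0.25, 0.5, 0.25),
                                    filament_length = 12,
                                    filament_diameter = 0.5,
                                    pixel_size = 0.1, palette = NULL) {
  stopifnot(n_filaments >= 1L, filament_length > 0, filament_diameter > 0)
  if (length(segment_fractions) != 3L ||
      abs(sum(segment_fractions) - 1) > 1e-9) {
    stop("gen_stripe_cell_pattern: segment_fractions must be 3 values summing to 1",
         call. = FALSE)
  }
  if (length(striped_indices) > 0 &&
      (min(striped_indices) < 1 || max(striped_indices) > n_filaments)) {
    stop("gen_stripe_cell_pattern: striped_indices out of range",
         call. = FALSE)
  }
  if (is.null(palette)) palette <- ink_palette(c(matrix_ink, cell_ink))
  nx <- as.integer(round(filament_length / pixel_size))
  ny_lane <- as.integer(round(filament_diameter / pixel_size))
  ny <- n_filaments * ny_lane
  xc <- (seq_len(nx) - 0.5) * pixel_size
  x_mid0 <- segment_fractions[1] * filament_length
  x_mid1 <- (segment_fractions[1] + segment_fractions[2]) * filament_length
  grid <- matrix(matrix_ink, nrow = ny, ncol = nx)
  for (lane in striped_indices) {
    rows <- ((lane - 1L) * ny_lane + 1L):(lane * ny_lane)
    grid[rows, xc >= x_mid0 & xc < x_mid1] <- cell_ink
  }
  layer_pattern(grid, pixel_size, palette)
}

#' Synthetic power-law shear sweep
#'
#' Log-spaced shear rates over `shear_range` with viscosities
#' `eta = K * gamma_dot^(n - 1)`, optionally under multiplicative
#' log-normal noise (`exp(rnorm(0, noise_sd))`), the noise model natural to
#' a positive, decades-spanning quantity.
#'
#' @param K Consistency index, Pa.s^n.
#' @param n Flow index.
#' @param shear_range Numeric `(lo, hi)` shear-rate range, 1/s.
#' @param points Number of points.
#' @param noise_sd Log-scale noise standard deviation; 0 for noise-free.
#' @param seed Optional seed for the noise (caller's RNG is untouched).
#' @return List with `shear_rates` and `viscosities`.
#' @export
gen_powerlaw_curve <- function(K, n, shear_range = c(0.01, 100),
                               points = 50, noise_sd = 0, seed = NULL) {
  stopifnot(K > 0, points >= 3L, all(shear_range > 0))
  g <- 10^seq(log10(shear_range[1]), log10(shear_range[2]),
              length.out = points)
  eta <- K * g^(n - 1)
  if (noise_sd > 0) {
    eta <- with_seed(seed, eta * exp(stats::rnorm(points, 0, noise_sd)))
  }
  list(shear_rates = g, viscosities = eta)
}

#' Synthetic gelation (cooling) curve
#'
#' Log-linear storage and loss moduli versus temperature constructed to
#' cross exactly at `T_x`:
#' `log10 G' = log10(G_x) + s_storage * (T_x - T)` and likewise for G''
#' with the shallower `s_loss`, so G' dominates below `T_x` (gel) and G''
#' above (liquid). The analytic crossover is `T_x` by construction, making
#' the curve an exact oracle for [find_crossover()]. A complex viscosity
#' `|G*| / (2 pi f)` at f = 1 Hz is included.
#'
#' @param T_x Crossover (gel-point) temperature, degrees C.
#' @param slopes Numeric `(storage, loss)` log10-modulus slopes per degree
#'   C; `storage > loss >= 0`.
#' @param T_range Numeric `(lo, hi)` temperature range, degrees C.
#' @param step Sampling step, degrees C.
#' @param G_x Common modulus at the crossover, Pa.
#' @return A [rheology_curve()] with ascending temperatures.
#' @export
gen_gelation_curve <- function(T_x = 35, slopes = c(0.15, 0.05),
                               T_range = c(20, 50), step = 0.5,
                               G_x = 100) {
  stopifnot(length(slopes) == 2L, slopes[1] > slopes[2], slopes[2] >= 0,
            G_x > 0, step > 0)
  temp <- seq(T_range[1], T_range[2], by = step)
  g1 <- 10^(log10(G_x) + slopes[1] * (T_x - temp))
  g2 <- 10^(log10(G_x) + slopes[2] * (T_x - temp))
  eta <- sqrt(g1^2 + g2^2) / (2 * pi)
  rheology_curve(temp, g1, g2, eta)
}

#' Synthetic stress-strain curve
#'
#' Linear-elastic response `sigma = E * epsilon` up to `linear_limit`
#' strain, then a stress plateau (strain confined to `max_strain`), with
#' optional additive Gaussian noise. With `noise_sd = 0` the small-strain
#' window recovers `E` exactly under [fit_modulus()].
#'
#' @param E Young's modulus, kPa.
#' @param max_strain Maximum strain (default 0.15).
#' @param points Number of points over `(0, max_strain]`.
#' @param noise_sd Additive stress noise SD, kPa.
#' @param seed Optional seed (caller's RNG untouched).
#' @param linear_limit Strain up to which the response is linear (default
#'   0.04).
#' @return A [stress_strain()].
#' @export
gen_stress_strain <- function(E, max_strain = 0.15, points = 60,
                              noise_sd = 0, seed = NULL,
                              linear_limit = 0.04) {
  stopifnot(E >= 0, max_strain > 0, points >= 2L, linear_limit > 0)
  eps <- seq(0, max_strain, length.out = points)
  sig <- E * pmin(eps, linear_limit)
  if (noise_sd > 0) {
    sig <- with_seed(seed, sig + stats::rnorm(points, 0, noise_sd))
  }
  stress_strain(eps, sig)
}

#' Write a fixture's files to a directory
#'
#' Convenience used by the command-line interface: writes the named fixture
#' as a label PNG + JSON sidecar (patterns/builds) or CSV (curves).
#'
#' @param fixture One of `"nested_squares"`, `"gradient_rectangle"`,
#'   `"two_layer_T"`, `"stripe_cell_pattern"`, `"powerlaw_curve"`,
#'   `"gelation_curve"`, `"stress_strain"`.
#' @param dir Output directory (created if needed).
#' @param ... Passed to the generator.
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(
    fixture,
    nested_squares = {
      p <- file.path(dir, "nested_squares.png")
      save_label_grid(gen_nested_squares(...), p)
      c(p, sidecar_path(p))
    },
    gradient_rectangle = {
      p <- file.path(dir, "gradient_rectangle.png")
      save_label_grid(gen_gradient_rectangle(...), p)
      c(p, sidecar_path(p))
    },
    two_layer_T = {
      model <- gen_two_layer_T(...)
      out <- character(0)
      for (i in seq_along(model$layers)) {
        p <- file.path(dir, sprintf("two_layer_T_layer%d.png", i))
        save_label_grid(model$layers[[i]], p)
        out <- c(out, p, sidecar_path(p))
      }
      out
    },
    stripe_cell_pattern = {
      p <- file.path(dir, "stripe_cell_pattern.png")
      save_label_grid(gen_stripe_cell_pattern(...), p)
      c(p, sidecar_path(p))
    },
    powerlaw_curve = {
      d <- gen_powerlaw_curve(...)
      p <- file.path(dir, "powerlaw_curve.csv")
      utils::write.csv(data.frame(shear_rate = d$shear_rates,
                                  viscosity = d$viscosities),
                       p, row.names = FALSE)
      p
    },
    gelation_curve = {
      cu <- gen_gelation_curve(...)
      p <- file.path(dir, "gelation_curve.csv")
      utils::write.csv(data.frame(temperature = cu$temperature,
                                  G_storage = cu$G_storage,
                                  G_loss = cu$G_loss,
                                  complex_viscosity = cu$complex_viscosity),
                       p, row.names = FALSE)
      p
    },
    stress_strain = {
      cu <- gen_stress_strain(...)
      p <- file.path(dir, "stress_strain.csv")
      utils::write.csv(data.frame(strain = cu$strain, stress = cu$stress),
                       p, row.names = FALSE)
      p
    },
    stop("write_fixture: unknown fixture name ", fixture, call. = FALSE)
  )
  invisible(paths)
}
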