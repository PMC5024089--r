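# Labeled layer patterns with physical units.
#
# Coordinate convention used throughout the package: x to the right, y up,
# origin at the lower-left corner of a layer, all lengths in mm. Pixel cells
# are half-open, [x, x + px) x [y, y + px), so every point of the extent
# belongs to exactly one pixel.

#' Ink specification
#'
#' Physical description of one ink: composition and the fitted physical
#' models used by the planner (power-law rheology, gel-point crossover,
#' Young's modulus, specific conductivity). All model fields are optional;
#' operations that need one check for it and fail informatively.
#'
#' @param ink_id Short identifier, e.g. `"A2"`, `"AC5"`, `"AS3"`.
#' @param agarose_concentration Agarose concentration, w/v\%.
#' @param swcnt_concentration Single-wall carbon-nanotube concentration,
#'   w/v\%.
#' @param cell_density Encapsulated cell density, cells/mL.
#' @param power_law Optional `power_law_fit` (see [fit_power_law()]).
#' @param crossover_T Optional gel-point temperature (G' = G'' crossover),
#'   degrees C.
#' @param youngs_modulus_E Optional small-strain Young's modulus, kPa.
#' @param specific_conductivity Optional specific conductivity, S/m.
#' @return An object of class `ink_spec`.
#' @export
ink_spec <- function(ink_id,
                     agarose_concentration = 0,
                     swcnt_concentration = 0,
                     cell_density = 0,
                     power_law = NULL,
                     crossover_T = NULL,
                     youngs_modulus_E = NULL,
                     specific_conductivity = NULL) {
  stopifnot(is.character(ink_id), length(ink_id) == 1L, nzchar(ink_id))
  if (agarose_concentration < 0 || swcnt_concentration < 0 ||
      cell_density < 0) {
    stop("ink_spec: concentrations and cell density must be >= 0",
         call. = FALSE)
  }
  structure(
    list(
      ink_id = ink_id,
      agarose_concentration = agarose_concentration,
      swcnt_concentration = swcnt_concentration,
      cell_density = cell_density,
      power_law = power_law,
      crossover_T = crossover_T,
      youngs_modulus_E = youngs_modulus_E,
      specific_conductivity = specific_conductivity
    ),
    class = "ink_spec"
  )
}

#' Ink palette
#'
#' A named collection of [ink_spec()] entries plus a display colour per ink.
#' Every label used by a [layer_pattern()] must exist in the palette.
#'
#' @param inks List of `ink_spec` objects, or a character vector of ink ids
#'   (bare ids are promoted to minimal specs).
#' @param colors Optional named character vector of display colours; unnamed
#'   entries are assigned from a default cycle.
#' @return An object of class `ink_palette`.
#' @examples
#' pal <- ink_palette(c("A1", "A2", "A3", "A4"))
#' ink_ids(pal)
#' @export
ink_palette <- function(inks, colors = NULL) {
  if (is.character(inks)) {
    inks <- lapply(inks, ink_spec)
  }
  stopifnot(length(inks) >= 1L)
  ids <- vapply(inks, function(s) s$ink_id, character(1))
  if (anyDuplicated(ids)) {
    stop("ink_palette: duplicate ink_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(inks) <- ids
  default_cols <- grDevices::hcl.colors(max(length(ids), 3L), "Dark 3")
  cols <- default_cols[seq_along(ids)]
  names(cols) <- ids
  if (!is.null(colors)) cols[names(colors)] <- colors
  structure(list(entries = inks, colors = cols), class = "ink_palette")
}

#' @rdname ink_palette
#' @param palette An `ink_palette`.
#' @export
ink_ids <- function(palette) {
  stopifnot(inherits(palette, "ink_palette"))
  names(palette$entries)
}

#' Labeled layer pattern
#'
#' A 2D grid of ink labels with isotropic physical pixel size. The grid is a
#' character matrix indexed `grid[iy, ix]` with row 1 at the bottom edge
#' (y = origin[2]) so that the matrix and the physical layer share
#' orientation under the x-right / y-up convention.
#'
#' @param grid Character matrix of ink ids; non-empty and rectangular.
#' @param pixel_size Pixel edge length, mm; > 0.
#' @param palette An [ink_palette()] containing every label in `grid`.
#' @param origin Lower-left corner `(x, y)`, mm.
#' @param z Layer height position, mm.
#' @return An object of class `layer_pattern`.
#' @export
layer_pattern <- function(grid, pixel_size, palette,
                          origin = c(0, 0), z = 0) {
  stopifnot(is.matrix(grid), is.character(grid),
            nrow(grid) >= 1L, ncol(grid) >= 1L)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      pixel_size <= 0) {
    stop("layer_pattern: pixel_size must be a single value > 0",
         call. = FALSE)
  }
  stopifnot(inherits(palette, "ink_palette"), length(origin) == 2L)
  unknown <- setdiff(unique(as.vector(grid)), ink_ids(palette))
  if (length(unknown) > 0L) {
    stop("layer_pattern: labels not in palette: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(grid = grid, pixel_size = pixel_size, palette = palette,
         origin = as.numeric(origin), z = as.numeric(z)),
    class = "layer_pattern"
  )
}

#' Physical extent of a layer pattern
#'
#' @param pattern A `layer_pattern`.
#' @return Named numeric vector `c(width, height)` in mm (x and y spans).
#' @export
pattern_extent <- function(pattern) {
  stopifnot(inherits(pattern, "layer_pattern"))
  c(width = ncol(pattern$grid) * pattern$pixel_size,
    height = nrow(pattern$grid) * pattern$pixel_size)
}

#' @export
print.layer_pattern <- function(x, ...) {
  ext <- pattern_extent(x)
  cat(sprintf(
    "<layer_pattern> %d x %d px (%.3g x %.3g mm at %.3g mm/px), z = %.3g mm\n",
    ncol(x$grid), nrow(x$grid), ext[["width"]], ext[["height"]],
    x$pixel_size, x$z))
  tab <- sort(table(x$grid), decreasing = TRUE)
  cat("  inks:", paste(sprintf("%s (%d px)", names(tab), tab),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Ink label at a physical point
#'
#' Looks up the ink of the pixel cell containing `point`. Cells are
#' half-open, so a point exactly on an interior pixel boundary belongs to
#' the cell on its +x/+y side; the far outer edges (x = width, y = height)
#' are outside the extent.
#'
#' @param pattern A [layer_pattern()].
#' @param point Numeric `(x, y)` in mm.
#' @return The ink id (length-1 character).
#' @export
ink_at <- function(pattern, point) {
  stopifnot(inherits(pattern, "layer_pattern"), length(point) == 2L)
  rel <- as.numeric(point) - pattern$origin
  ext <- pattern_extent(pattern)
  if (rel[1] < 0 || rel[2] < 0 || rel[1] >= ext[["width"]] ||
      rel[2] >= ext[["height"]]) {
    stop(sprintf("ink_at: point (%.4g, %.4g) outside pattern extent",
                 point[1], point[2]), call. = FALSE)
  }
  ix <- floor(rel[1] / pattern$pixel_size) + 1L
  iy <- floor(rel[2] / pattern$pixel_size) + 1L
  pattern$grid[iy, ix]
}

#' Stack congruent layers into a build model
#'
#' Layers must share grid dimensions and pixel size; the z of layer i is set
#' to `(i - 1) * layer_height`.
#'
#' @param layers List of [layer_pattern()] objects (at least one).
#' @param layer_height Vertical spacing between layers, mm; > 0.
#' @return An object of class `build_model`.
#' @export
stack_layers <- function(layers, layer_height) {
  if (length(layers) < 1L) {
    stop("stack_layers: need at least one layer", call. = FALSE)
  }
  stopifnot(all(vapply(layers, inherits, logical(1), "layer_pattern")),
            layer_height > 0)
  dims <- vapply(layers, function(p) dim(p$grid), integer(2))
  px <- vapply(layers, function(p) p$pixel_size, numeric(1))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]) ||
      any(px != px[1])) {
    stop("stack_layers: layers must share grid extent and pixel size",
         call. = FALSE)
  }
  for (i in seq_along(layers)) layers[[i]]$z <- (i - 1) * layer_height
  structure(list(layers = layers, layer_height = layer_height),
            class = "build_model")
}

#' @export
print.build_model <- function(x, ...) {
  cat(sprintf("<build_model> %d layer(s), layer height %.3g mm\n",
              length(x$layers), x$layer_height))
  for (p in x$layers) print(p)
  invisible(x)
}

# --- label-image I/O ---------------------------------------------------------

# The on-disk format is a grayscale PNG holding one small integer per pixel
# plus a JSON sidecar mapping integer -> ink_id and recording pixel_size_mm.
# Integer labels (not RGB inference) keep round-trips bit-exact. PNG row 1 is
# the top of the image, so rows are flipped relative to the y-up grid.

sidecar_path <- function(path) paste0(path, ".json")

#' Save a layer pattern as a label image
#'
#' Writes a grayscale PNG whose pixel values are small integer labels, and a
#' JSON sidecar `<path>.json` holding the integer-to-ink map and the pixel
#' size. [load_label_grid()] inverts this exactly.
#'
#' @param pattern A [layer_pattern()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_label_grid <- function(pattern, path) {
  stopifnot(inherits(pattern, "layer_pattern"))
  ids <- ink_ids(pattern$palette)
  if (length(ids) > 255L) {
    stop("save_label_grid: more than 255 inks cannot be stored in an ",
         "8-bit label image", call. = FALSE)
  }
  code <- stats::setNames(seq_along(ids) - 1L, ids)
  idx <- matrix(code[pattern$grid], nrow = nrow(pattern$grid))
  img <- idx[rev(seq_len(nrow(idx))), , drop = FALSE] / 255
  png::writePNG(img, target = path)
  side <- list(
    palette = as.list(stats::setNames(ids, as.character(code))),
    pixel_size_mm = pattern$pixel_size,
    origin_mm = pattern$origin,
    z_mm = pattern$z
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a layer pattern from a label image or JSON geometry
#'
#' Two dialects are supported:
#' \describe{
#'   \item{PNG/PGM label image}{grayscale image of integer labels with a
#'     JSON sidecar `<path>.json` written by [save_label_grid()] (or by
#'     hand) mapping each integer to an ink id.}
#'   \item{JSON geometry}{a file with fields `background`, `pixel_size_mm`,
#'     `extent_mm = [w, h]`, and `rects`: a list of
#'     `{ink_id, rect: [x0, y0, x1, y1]}` painted in order over the
#'     background.}
#' }
#'
#' @param path Path to a `.png`/`.pgm` label image or a `.json` geometry.
#' @param pixel_size Pixel size in mm; overrides the sidecar value when
#'   given (required if the sidecar lacks one).
#' @param palette An [ink_palette()]; every label in the file must resolve
#'   to one of its inks.
#' @return A [layer_pattern()].
#' @export
load_label_grid <- function(path, pixel_size = NULL, palette) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(load_rect_geometry(path, pixel_size, palette))
  }
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    raw <- read_pgm(path)
  } else {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]  # indexed saved as gray
    raw <- round(img * 255)
  }
  if (length(raw) == 0L) stop("load_label_grid: empty image", call. = FALSE)
  side_file <- sidecar_path(path)
  if (!file.exists(side_file)) {
    stop("load_label_grid: missing sidecar ", side_file, call. = FALSE)
  }
  side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
  code2ink <- unlist(side$palette)
  vals <- as.character(as.vector(raw))
  unknown <- setdiff(unique(vals), names(code2ink))
  if (length(unknown) > 0L) {
    stop("load_label_grid: label value(s) not in palette map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  grid <- matrix(code2ink[vals], nrow = nrow(raw))
  grid <- grid[rev(seq_len(nrow(grid))), , drop = FALSE]  # image top -> y-up
  px <- if (!is.null(pixel_size)) pixel_size else side$pixel_size_mm
  if (is.null(px)) {
    stop("load_label_grid: pixel_size not given and absent from sidecar",
         call. = FALSE)
  }
  origin <- if (!is.null(side$origin_mm)) side$origin_mm else c(0, 0)
  z <- if (!is.null(side$z_mm)) side$z_mm else 0
  layer_pattern(grid, px, palette, origin = origin, z = z)
}

# Minimal binary (P5) and ASCII (P2) PGM reader; label images are tiny.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) {
    stop("read_pgm: not a PGM file: ", path, call. = FALSE)
  }
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("read_pgm: truncated header", call. = FALSE)
    if (ch == "#") {  # comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf) > 0L) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (maxval > 255L) stop("read_pgm: only 8-bit PGM supported", call. = FALSE)
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- as.integer(scan(con, what = integer(), n = w * h, quiet = TRUE))
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

load_rect_geometry <- function(path, pixel_size, palette) {
  geo <- jsonlite::read_json(path, simplifyVector = TRUE)
  px <- if (!is.null(pixel_size)) pixel_size else geo$pixel_size_mm
  if (is.null(px)) {
    stop("load_label_grid: geometry file lacks pixel_size_mm", call. = FALSE)
  }
  if (is.null(geo$background) || is.null(geo$extent_mm)) {
    stop("load_label_grid: geometry needs 'background' and 'extent_mm'",
         call. = FALSE)
  }
  known <- ink_ids(palette)
  if (!geo$background %in% known) {
    stop("load_label_grid: unknown background ink ", geo$background,
         call. = FALSE)
  }
  nx <- as.integer(round(geo$extent_mm[1] / px))
  ny <- as.integer(round(geo$extent_mm[2] / px))
  if (nx < 1L || ny < 1L) stop("load_label_grid: empty extent", call. = FALSE)
  grid <- matrix(geo$background, nrow = ny, ncol = nx)
  rects <- geo$rects
  if (is.data.frame(rects)) {
    rects <- lapply(seq_len(nrow(rects)), function(i) {
      list(ink_id = rects$ink_id[i], rect = rects$rect[[i]])
    })
  }
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  for (r in rects) {
    if (!r$ink_id %in% known) {
      stop("load_label_grid: unknown ink in geometry: ", r$ink_id,
           call. = FALSE)
    }
    b <- as.numeric(r$rect)  # x0 y0 x1 y1, half-open like pixel cells
    sel_x <- which(xc >= b[1] & xc < b[3])
    sel_y <- which(yc >= b[2] & yc < b[4])
    if (length(sel_x) && length(sel_y)) grid[sel_y, sel_x] <- r$ink_id
  }
  layer_pattern(grid, px, palette)
}
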