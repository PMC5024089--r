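# G-code emission and the virtual printer.
#
# Dialect: a minimal Mach3-compatible subset. G21 (mm) + G90 (absolute)
# preamble; axes X Y Z for the stage and A for the plunger position; feed F
# in mm/min; `;` comments; 4 decimal places. Aspiration is a negative
# A-axis move over a reservoir; waste and deposition are positive A moves.
# Plunger displacement maps 1:1 to fluid-column length (same bore).

fmt_num <- function(x) sprintf("%.4f", x)

#' Emit G-code for a list of aspiration plans
#'
#' @param plans List of [plan_filament()] results.
#' @param machine A [machine_config()].
#' @return An object of class `gcode_program` (field `lines`).
#' @export
emit_gcode <- function(plans, machine) {
  stopifnot(inherits(machine, "machine_config"))
  lines <- c(
    "; aodprint program",
    "G21 ; units: mm",
    "G90 ; absolute positioning"
  )
  a <- 0  # absolute plunger position, mm of column
  for (pi in seq_along(plans)) {
    plan <- plans[[pi]]
    stopifnot(inherits(plan, "aspiration_plan"))
    lines <- c(lines, sprintf("; filament %d", plan$filament$index))
    for (st in plan$steps) {
      t <- st$target
      if (st$kind %in% c("move_to_reservoir", "move_to_start")) {
        lines <- c(lines, sprintf(
          "G0 X%s Y%s Z%s ; %s%s",
          fmt_num(t[1]), fmt_num(t[2]), fmt_num(t[3]), st$kind,
          if (!is.na(st$ink_id)) paste0(" ", st$ink_id) else ""))
      } else if (st$kind == "pre_extrude_waste") {
        a <- a + st$plunger_displacement
        lines <- c(lines, sprintf("G1 A%s F%s ; waste before %s",
                                  fmt_num(a), fmt_num(st$speed), st$ink_id))
      } else if (st$kind == "aspirate") {
        a <- a - st$plunger_displacement
        lines <- c(lines, sprintf("G1 A%s F%s ; aspirate %s %s mm",
                                  fmt_num(a), fmt_num(st$speed), st$ink_id,
                                  fmt_num(st$plunger_displacement)))
      } else if (st$kind == "deposit") {
        a <- a + st$plunger_displacement
        lines <- c(lines, sprintf("G1 X%s Y%s Z%s A%s F%s ; deposit",
                                  fmt_num(t[1]), fmt_num(t[2]),
                                  fmt_num(t[3]), fmt_num(a),
                                  fmt_num(st$speed)))
      } else {
        stop("emit_gcode: unknown step kind ", st$kind, call. = FALSE)
      }
    }
  }
  lines <- c(lines, "M2 ; end of program")
  structure(list(lines = lines), class = "gcode_program")
}

#' @export
print.gcode_program <- function(x, ...) {
  cat(sprintf("<gcode_program> %d lines\n", length(x$lines)))
  head_n <- min(8L, length(x$lines))
  cat(paste0("  ", x$lines[seq_len(head_n)]), sep = "\n")
  if (length(x$lines) > head_n) cat("  ...\n")
  invisible(x)
}

#' Write a G-code program to a file
#' @param program A `gcode_program`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gcode <- function(program, path) {
  stopifnot(inherits(program, "gcode_program"))
  writeLines(program$lines, path)
  invisible(path)
}

#' Read a G-code program from a file
#' @param path Input path.
#' @return A `gcode_program`.
#' @export
read_gcode <- function(path) {
  structure(list(lines = readLines(path)), class = "gcode_program")
}

parse_gcode_line <- function(line, lineno) {
  code <- sub(";.*$", "", line)
  code <- trimws(code)
  if (nchar(code) == 0L) return(NULL)
  tokens <- strsplit(code, "[[:space:]]+")[[1]]
  words <- list()
  for (tok in tokens) {
    letter <- toupper(substr(tok, 1, 1))
    value <- suppressWarnings(as.numeric(substring(tok, 2)))
    if (!letter %in% c("G", "M", "X", "Y", "Z", "A", "F") || is.na(value)) {
      stop(sprintf("simulate: unknown G-code word '%s' at line %d",
                   tok, lineno), call. = FALSE)
    }
    words[[length(words) + 1L]] <- list(letter = letter, value = value)
  }
  words
}

#' Simulate a G-code program (or plans) on a virtual printer
#'
#' Re-executes the program against the machine configuration, tracking the
#' capillary column as an ordered ink stack: aspiration over a reservoir
#' pushes that reservoir's ink onto the tip end, any extrusion pops from the
#' tip (last aspirated, first out). Extrusion over a reservoir is logged as
#' waste into that reservoir; extrusion during an XY move paints the popped
#' ink onto a raster at the capillary diameter (square-ended filaments,
#' sharp interfaces — the transition-zone estimate is reported by the
#' planner, not rasterized). Volume accounting is exact in mm of column
#' length: per ink, deposited + waste + residual = aspirated.
#'
#' @param program A `gcode_program`, or a list of [plan_filament()] results
#'   (converted through [emit_gcode()] first).
#' @param machine A [machine_config()] (reservoir positions identify inks).
#' @param grid_resolution Raster pixel size for the reconstructed label
#'   maps, mm.
#' @param origin,extent Optional raster origin `(x, y)` and extent
#'   `(width, height)` in mm; defaults to the bounding box of deposition
#'   moves padded by the filament half-width.
#' @return An object of class `deposition_trace`: per-ink
#'   `aspirated_mm3`/`deposited_mm3`, per-reservoir `waste_mm3`, residual
#'   column, reconstructed per-z label grids (`layers`), and an event log.
#' @export
simulate <- function(program, machine, grid_resolution = 0.1,
                     origin = NULL, extent = NULL) {
  stopifnot(inherits(machine, "machine_config"))
  if (!inherits(program, "gcode_program")) {
    program <- emit_gcode(program, machine)
  }
  width <- machine$capillary$inner_diameter
  area <- machine$capillary$cross_section_area
  res_names <- names(machine$reservoirs)
  res_pos <- machine$reservoirs

  reservoir_at <- function(p) {
    for (ink in res_names) {
      if (all(abs(p - res_pos[[ink]]) < 1e-6)) return(ink)
    }
    NA_character_
  }

  pos <- c(0, 0, 0)
  a <- 0
  absolute <- TRUE
  # column: tip at index 1 (last aspirated first)
  col_ink <- character(0)
  col_len <- numeric(0)
  aspirated <- numeric(0)  # named, mm of column
  wasted_res <- numeric(0) # named by reservoir
  wasted_ink <- numeric(0) # named by ink
  deposited <- numeric(0)  # named by ink
  events <- character(0)
  dep_runs <- list()       # painted runs: x0 y0 x1 y1 z ink

  pop_column <- function(demand, lineno) {
    runs_ink <- character(0)
    runs_len <- numeric(0)
    left <- demand
    while (left > 1e-12) {
      if (length(col_ink) == 0L) {
        stop(sprintf(
          "simulate: extrusion underflow at line %d (commanded %.6g mm more than column holds)",
          lineno, left), call. = FALSE)
      }
      take <- min(col_len[1], left)
      runs_ink <- c(runs_ink, col_ink[1])
      runs_len <- c(runs_len, take)
      col_len[1] <<- col_len[1] - take
      if (col_len[1] <= 1e-12) {
        col_ink <<- col_ink[-1]
        col_len <<- col_len[-1]
      }
      left <- left - take
    }
    list(ink = runs_ink, len = runs_len)
  }

  for (lineno in seq_along(program$lines)) {
    words <- parse_gcode_line(program$lines[lineno], lineno)
    if (is.null(words)) next
    letters <- vapply(words, function(w) w$letter, character(1))
    values <- vapply(words, function(w) w$value, numeric(1))
    g <- values[letters == "G"]
    m <- values[letters == "M"]
    if (length(m) > 0L) {
      if (!all(m %in% c(2, 30))) {
        stop(sprintf("simulate: unsupported M-code M%g at line %d",
                     m[1], lineno), call. = FALSE)
      }
      break
    }
    if (length(g) > 0L && !all(g %in% c(0, 1, 21, 90, 91))) {
      stop(sprintf("simulate: unsupported G-code G%g at line %d",
                   g[1], lineno), call. = FALSE)
    }
    if (any(g == 91)) absolute <- FALSE
    if (any(g == 90)) absolute <- TRUE
    if (!any(g %in% c(0, 1))) next
    new_pos <- pos
    new_a <- a
    for (i in seq_along(letters)) {
      v <- values[i]
      switch(letters[i],
             X = new_pos[1] <- if (absolute) v else new_pos[1] + v,
             Y = new_pos[2] <- if (absolute) v else new_pos[2] + v,
             Z = new_pos[3] <- if (absolute) v else new_pos[3] + v,
             A = new_a <- if (absolute) v else new_a + v,
             NULL)
    }
    da <- new_a - a
    xy_dist <- sqrt(sum((new_pos[1:2] - pos[1:2])^2))
    if (da < -1e-12) {
      ink <- reservoir_at(new_pos)
      if (is.na(ink)) {
        stop(sprintf(
          "simulate: aspiration at line %d occurs away from any reservoir",
          lineno), call. = FALSE)
      }
      col_ink <- c(ink, col_ink)
      col_len <- c(-da, col_len)
      aspirated[ink] <- (if (ink %in% names(aspirated)) aspirated[[ink]] else 0) - da
      if (sum(col_len) > machine$capillary$length + 1e-9) {
        stop(sprintf(
          "simulate: column %.4g mm exceeds capillary length %.4g mm at line %d",
          sum(col_len), machine$capillary$length, lineno), call. = FALSE)
      }
      events <- c(events, sprintf("line %d: aspirate %.4g mm of %s",
                                  lineno, -da, ink))
    } else if (da > 1e-12) {
      runs <- pop_column(da, lineno)
      if (xy_dist > 1e-12) {
        # deposition: map column runs onto the path proportionally
        s0 <- 0
        for (r in seq_along(runs$ink)) {
          frac0 <- s0 / da
          frac1 <- (s0 + runs$len[r]) / da
          p0 <- pos[1:2] + frac0 * (new_pos[1:2] - pos[1:2])
          p1 <- pos[1:2] + frac1 * (new_pos[1:2] - pos[1:2])
          dep_runs[[length(dep_runs) + 1L]] <-
            list(x0 = p0[1], y0 = p0[2], x1 = p1[1], y1 = p1[2],
                 z = new_pos[3], ink = runs$ink[r])
          ink <- runs$ink[r]
          deposited[ink] <-
            (if (ink %in% names(deposited)) deposited[[ink]] else 0) +
            runs$len[r]
          s0 <- s0 + runs$len[r]
        }
        events <- c(events, sprintf("line %d: deposit %.4g mm over %.4g mm path",
                                    lineno, da, xy_dist))
      } else {
        dest <- reservoir_at(new_pos)
        dest_key <- if (is.na(dest)) "environment" else dest
        wasted_res[dest_key] <-
          (if (dest_key %in% names(wasted_res)) wasted_res[[dest_key]] else 0) + da
        for (r in seq_along(runs$ink)) {
          ink <- runs$ink[r]
          wasted_ink[ink] <-
            (if (ink %in% names(wasted_ink)) wasted_ink[[ink]] else 0) +
            runs$len[r]
        }
        events <- c(events, sprintf("line %d: waste %.4g mm into %s",
                                    lineno, da, dest_key))
      }
    }
    pos <- new_pos
    a <- new_a
  }

  layers <- rasterize_runs(dep_runs, width, grid_resolution, origin, extent)
  structure(
    list(
      aspirated_mm3 = aspirated * area,
      deposited_mm3 = deposited * area,
      waste_mm3 = wasted_res * area,
      waste_by_ink_mm3 = wasted_ink * area,
      residual_mm3 = sum(col_len) * area,
      aspirated_mm = aspirated, deposited_mm = deposited,
      waste_mm = wasted_res, waste_by_ink_mm = wasted_ink,
      residual_mm = sum(col_len),
      layers = layers, events = events
    ),
    class = "deposition_trace"
  )
}

# Paint deposition runs onto one raster per distinct z. Pixel centers whose
# along-axis projection lies in [s0, s1) and perpendicular offset in
# [-w/2, w/2) take the run's ink; later runs overwrite earlier ones.
rasterize_runs <- function(runs, width, px, origin = NULL, extent = NULL) {
  if (length(runs) == 0L) return(list())
  xs <- unlist(lapply(runs, function(r) c(r$x0, r$x1)))
  ys <- unlist(lapply(runs, function(r) c(r$y0, r$y1)))
  if (is.null(origin)) origin <- c(min(xs), min(ys) - width / 2)
  if (is.null(extent)) {
    extent <- c(max(xs) - origin[1], max(ys) + width / 2 - origin[2])
  }
  nx <- max(1L, as.integer(round(extent[1] / px)))
  ny <- max(1L, as.integer(round(extent[2] / px)))
  xc <- origin[1] + (seq_len(nx) - 0.5) * px
  yc <- origin[2] + (seq_len(ny) - 0.5) * px
  zs <- sort(unique(vapply(runs, function(r) r$z, numeric(1))))
  layers <- vector("list", length(zs))
  names(layers) <- sprintf("z=%.4g", zs)
  for (zi in seq_along(zs)) {
    grid <- matrix(NA_character_, nrow = ny, ncol = nx)
    for (r in runs) {
      if (r$z != zs[zi]) next
      v <- c(r$x1 - r$x0, r$y1 - r$y0)
      len <- sqrt(sum(v^2))
      if (len <= 1e-12) next
      u <- v / len
      sel_x <- which(xc >= min(r$x0, r$x1) - width & xc <= max(r$x0, r$x1) + width)
      sel_y <- which(yc >= min(r$y0, r$y1) - width & yc <= max(r$y0, r$y1) + width)
      for (iy in sel_y) {
        dy <- yc[iy] - r$y0
        for (ix in sel_x) {
          dx <- xc[ix] - r$x0
          t <- dx * u[1] + dy * u[2]
          perp <- -dx * u[2] + dy * u[1]
          if (t >= 0 && t < len && perp >= -width / 2 && perp < width / 2) {
            grid[iy, ix] <- r$ink
          }
        }
      }
    }
    layers[[zi]] <- list(z = zs[zi], grid = grid, origin = origin,
                         pixel_size = px)
  }
  layers
}

#' Convert a reconstructed trace layer to a layer pattern
#'
#' @param trace A [simulate()] result.
#' @param layer Layer index into `trace$layers`.
#' @param palette An [ink_palette()] holding every deposited ink (plus
#'   `fill` if any raster cell was left unpainted).
#' @param fill Ink id to substitute for unpainted cells; an error is raised
#'   if unpainted cells exist and `fill` is `NULL`.
#' @return A [layer_pattern()].
#' @export
trace_layer_pattern <- function(trace, layer, palette, fill = NULL) {
  stopifnot(inherits(trace, "deposition_trace"))
  lay <- trace$layers[[layer]]
  grid <- lay$grid
  if (anyNA(grid)) {
    if (is.null(fill)) {
      stop("trace_layer_pattern: unpainted raster cells and no fill ink",
           call. = FALSE)
    }
    grid[is.na(grid)] <- fill
  }
  layer_pattern(grid, lay$pixel_size, palette, origin = lay$origin,
                z = lay$z)
}

#' @export
print.deposition_trace <- function(x, ...) {
  cat(sprintf("<deposition_trace> %d layer raster(s), residual %.4g mm3\n",
              length(x$layers), x$residual_mm3))
  for (ink in names(x$aspirated_mm3)) {
    dep <- if (ink %in% names(x$deposited_mm3)) x$deposited_mm3[[ink]] else 0
    wst <- if (ink %in% names(x$waste_by_ink_mm3)) x$waste_by_ink_mm3[[ink]] else 0
    cat(sprintf("  %s: aspirated %.4g, deposited %.4g, waste %.4g mm3\n",
                ink, x$aspirated_mm3[[ink]], dep, wst))
  }
  invisible(x)
}

#' Write a deposition trace summary to JSON
#'
#' @param trace A [simulate()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "deposition_trace"))
  out <- list(
    aspirated_mm3 = as.list(trace$aspirated_mm3),
    deposited_mm3 = as.list(trace$deposited_mm3),
    waste_mm3 = as.list(trace$waste_mm3),
    residual_mm3 = trace$residual_mm3,
    n_layers = length(trace$layers),
    events = trace$events
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
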