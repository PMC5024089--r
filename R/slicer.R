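# Scanline decomposition of a labeled layer into parallel multimaterial
# filaments, run-length segment extraction along each centerline, and
# pattern-fidelity metrics.

#' Filament segment
#'
#' A contiguous single-ink portion of a filament.
#'
#' @param ink_id Ink id.
#' @param length Segment length along the filament axis, mm; > 0.
#' @param start Offset of the segment start from the filament start, mm.
#' @return An object of class `ink_segment`.
#' @export
ink_segment <- function(ink_id, length, start = 0) {
  stopifnot(is.character(ink_id), length > 0, start >= 0)
  structure(list(ink_id = ink_id, length = length, start = start),
            class = "ink_segment")
}

#' Filament plan
#'
#' One deposition line: its axis (start point and direction), total length,
#' and its ordered single-ink segments in deposition order.
#'
#' @param index Filament index within its layer (1-based).
#' @param start Numeric `(x, y)` of the filament start, mm.
#' @param orientation Axis direction in degrees: `0` (along +x) or `90`
#'   (along +y). A reversed deposition direction is expressed by swapping
#'   `start` to the far end and setting `reversed = TRUE`.
#' @param total_length Filament length, mm.
#' @param segments List of [ink_segment()] in deposition order; their
#'   lengths must sum to `total_length` (tolerance 1e-9 mm) and consecutive
#'   segments must carry distinct inks.
#' @param z Layer height, mm.
#' @param reversed Logical; `TRUE` when the filament is deposited against
#'   its layer axis (serpentine ordering).
#' @return An object of class `filament_plan`.
#' @export
filament_plan <- function(index, start, orientation, total_length,
                          segments, z = 0, reversed = FALSE) {
  stopifnot(orientation %in% c(0, 90), total_length > 0,
            length(segments) >= 1L)
  lens <- vapply(segments, function(s) s$length, numeric(1))
  if (abs(sum(lens) - total_length) > 1e-9) {
    stop(sprintf(
      "filament_plan: segment lengths sum to %.12g, not total_length %.12g",
      sum(lens), total_length), call. = FALSE)
  }
  inks <- vapply(segments, function(s) s$ink_id, character(1))
  if (length(inks) > 1L && any(inks[-1] == inks[-length(inks)])) {
    stop("filament_plan: consecutive segments must have distinct inks",
         call. = FALSE)
  }
  starts <- cumsum(c(0, lens[-length(lens)]))
  for (i in seq_along(segments)) segments[[i]]$start <- starts[i]
  structure(
    list(index = index, start = as.numeric(start), orientation = orientation,
         total_length = total_length, segments = segments, z = z,
         reversed = reversed),
    class = "filament_plan"
  )
}

segment_inks <- function(segments) {
  vapply(segments, function(s) s$ink_id, character(1))
}

segment_lengths <- function(segments) {
  vapply(segments, function(s) s$length, numeric(1))
}

#' @export
print.filament_plan <- function(x, ...) {
  cat(sprintf("<filament_plan> #%d at (%.3g, %.3g) mm, %s, %.4g mm%s\n",
              x$index, x$start[1], x$start[2],
              if (x$orientation == 0) "along x" else "along y",
              x$total_length, if (x$reversed) " (reversed)" else ""))
  cat("  segments:",
      paste(sprintf("%s %.4g mm", segment_inks(x$segments),
                    segment_lengths(x$segments)), collapse = " | "), "\n")
  invisible(x)
}

#' Decompose a layer into parallel filaments
#'
#' Covers the layer with parallel scan lines at pitch
#' `filament_diameter + gap`, each lane centered (first lane center at
#' `pitch / 2` from the layer edge), and run-length-encodes the pattern
#' along each centerline into ordered ink segments. Structures can be built
#' with or without gaps between filaments; `gap = 0` gives contiguous
#' coverage.
#'
#' @param pattern A [layer_pattern()].
#' @param filament_diameter Extruded filament diameter, mm (normally the
#'   capillary inner diameter).
#' @param orientation `0` for filaments along x, `90` for along y.
#' @param gap Clear spacing between adjacent filaments, mm; >= 0.
#' @param min_segment_length Minimum aspiratable segment length, mm; runs
#'   shorter than this are merged into their longer neighbor (see
#'   [extract_segments()]).
#' @return List of [filament_plan()] objects, in lane order.
#' @export
decompose <- function(pattern, filament_diameter, orientation = 0,
                      gap = 0, min_segment_length = 0.5) {
  stopifnot(inherits(pattern, "layer_pattern"),
            filament_diameter > 0, gap >= 0, orientation %in% c(0, 90))
  ext <- pattern_extent(pattern)
  across <- if (orientation == 0) ext[["height"]] else ext[["width"]]
  along <- if (orientation == 0) ext[["width"]] else ext[["height"]]
  if (filament_diameter > across + 1e-12 || filament_diameter > along + 1e-12) {
    stop(sprintf(
      "decompose: filament diameter %.4g mm exceeds pattern extent",
      filament_diameter), call. = FALSE)
  }
  pitch <- filament_diameter + gap
  n_lanes <- floor(across / pitch + 1e-9)
  plans <- vector("list", n_lanes)
  for (k in seq_len(n_lanes)) {
    offset <- (k - 0.5) * pitch  # lane center
    if (orientation == 0) {
      start <- pattern$origin + c(0, offset)
    } else {
      start <- pattern$origin + c(offset, 0)
    }
    fp <- filament_plan(
      index = k, start = start, orientation = orientation,
      total_length = along,
      segments = list(ink_segment(pattern$grid[1, 1], along)),
      z = pattern$z
    )
    fp$segments <- extract_segments(pattern, fp, min_segment_length)
    plans[[k]] <- filament_plan(k, start, orientation, along, fp$segments,
                                z = pattern$z)
  }
  plans
}

#' Extract ordered ink segments along a filament centerline
#'
#' Samples the pattern at pixel resolution along the filament centerline and
#' run-length-encodes the labels; segment boundaries therefore lie on
#' pixel-cell boundaries (the grid is the ground truth; sub-pixel edges are
#' unresolvable). Runs shorter than `min_segment_length` are merged into
#' their longer neighbor — ties go to the preceding segment — and adjacent
#' same-ink runs are coalesced until every segment meets the minimum. Total
#' length is conserved exactly.
#'
#' @param pattern A [layer_pattern()].
#' @param filament A [filament_plan()] whose centerline lies inside the
#'   pattern extent.
#' @param min_segment_length Minimum segment length, mm; `0` disables
#'   merging.
#' @return List of [ink_segment()] in deposition order.
#' @export
extract_segments <- function(pattern, filament, min_segment_length = 0.5) {
  stopifnot(inherits(pattern, "layer_pattern"),
            inherits(filament, "filament_plan"), min_segment_length >= 0)
  px <- pattern$pixel_size
  n <- as.integer(round(filament$total_length / px))
  if (n < 1L) stop("extract_segments: filament shorter than one pixel",
                   call. = FALSE)
  s <- (seq_len(n) - 0.5) * px  # pixel centers along the axis
  dirsign <- if (filament$reversed) -1 else 1
  if (filament$orientation == 0) {
    pts_x <- filament$start[1] + dirsign * s
    pts_y <- rep(filament$start[2], n)
  } else {
    pts_x <- rep(filament$start[1], n)
    pts_y <- filament$start[2] + dirsign * s
  }
  labels <- character(n)
  for (i in seq_len(n)) labels[i] <- ink_at(pattern, c(pts_x[i], pts_y[i]))
  runs <- rle(labels)
  lens <- runs$lengths * px
  inks <- runs$values
  merged <- merge_short_runs(inks, lens, min_segment_length)
  segs <- vector("list", length(merged$inks))
  pos <- 0
  for (i in seq_along(segs)) {
    segs[[i]] <- ink_segment(merged$inks[i], merged$lens[i], start = pos)
    pos <- pos + merged$lens[i]
  }
  segs
}

# Repeatedly merge the shortest sub-minimum run into its longer neighbor
# (ties -> preceding neighbor), coalescing equal-ink neighbors, until all
# runs meet the minimum or one run remains. Length is conserved.
merge_short_runs <- function(inks, lens, min_len) {
  if (min_len <= 0) return(list(inks = inks, lens = lens))
  repeat {
    if (length(lens) <= 1L) break
    short <- which(lens < min_len - 1e-12)
    if (length(short) == 0L) break
    i <- short[which.min(lens[short])]
    left <- if (i > 1L) lens[i - 1L] else -Inf
    right <- if (i < length(lens)) lens[i + 1L] else -Inf
    into <- if (left >= right) i - 1L else i + 1L
    lens[into] <- lens[into] + lens[i]
    inks <- inks[-i]
    lens <- lens[-i]
    # coalesce any equal-ink neighbors created by the removal
    j <- 1L
    while (j < length(lens)) {
      if (inks[j] == inks[j + 1L]) {
        lens[j] <- lens[j] + lens[j + 1L]
        inks <- inks[-(j + 1L)]
        lens <- lens[-(j + 1L)]
      } else {
        j <- j + 1L
      }
    }
  }
  list(inks = inks, lens = lens)
}

#' Count ink switches along a filament
#'
#' For a coalesced segment list this equals the number of segments minus
#' one, i.e. the number of aspiration switches between different inks.
#'
#' @param segments Non-empty list of [ink_segment()].
#' @return Integer switch count.
#' @export
count_switches <- function(segments) {
  if (length(segments) == 0L) {
    stop("count_switches: empty segment list", call. = FALSE)
  }
  inks <- segment_inks(segments)
  sum(inks[-1] != inks[-length(inks)])
}

#' Pattern fidelity of a planned or reconstructed label map
#'
#' Compares a planned (or simulated) label map against the target pattern on
#' congruent grids. Per-ink agreement is the fraction of the target ink's
#' pixels carrying that ink in the planned map; `jagged_edge_length` is the
#' total physical length of interior pixel edges separating agreeing from
#' disagreeing pixels — a direct measure of jagged pattern boundaries.
#'
#' @param planned,target Congruent [layer_pattern()] objects.
#' @return An object of class `fidelity_report` with fields
#'   `per_ink` (named agreements in `[0, 1]`), `overall` (pixel fraction
#'   agreeing), and `jagged_edge_length` (mm).
#' @export
fidelity <- function(planned, target) {
  stopifnot(inherits(planned, "layer_pattern"),
            inherits(target, "layer_pattern"))
  if (!identical(dim(planned$grid), dim(target$grid)) ||
      planned$pixel_size != target$pixel_size) {
    stop("fidelity: planned and target grids are not congruent",
         call. = FALSE)
  }
  agree <- planned$grid == target$grid
  inks <- sort(unique(as.vector(target$grid)))
  per_ink <- vapply(inks, function(ink) {
    sel <- target$grid == ink
    sum(agree[sel]) / sum(sel)
  }, numeric(1))
  px <- target$pixel_size
  h_edges <- agree[-nrow(agree), , drop = FALSE] !=
    agree[-1, , drop = FALSE]
  v_edges <- agree[, -ncol(agree), drop = FALSE] !=
    agree[, -1, drop = FALSE]
  structure(
    list(per_ink = per_ink,
         overall = mean(agree),
         jagged_edge_length = (sum(h_edges) + sum(v_edges)) * px),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> overall %.4f, jagged edges %.4g mm\n",
              x$overall, x$jagged_edge_length))
  cat("  per ink:", paste(sprintf("%s %.4f", names(x$per_ink), x$per_ink),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Serialize filament plans to JSON
#'
#' One object per filament with segments as `[ink_id, length]` pairs, for
#' inspection and test fixtures.
#'
#' @param plans List of [filament_plan()].
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
filaments_to_json <- function(plans, path = NULL) {
  objs <- lapply(plans, function(fp) {
    list(index = fp$index, start = fp$start, orientation = fp$orientation,
         total_length = fp$total_length, z = fp$z, reversed = fp$reversed,
         segments = lapply(fp$segments, function(s) list(s$ink_id, s$length)))
  })
  txt <- jsonlite::toJSON(objs, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
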