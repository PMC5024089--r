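# Conversion of filament segment lists into executable aspiration and
# deposition step sequences.
#
# Capillary semantics: inks are drawn in through the tip, so the
# last-aspirated ink occupies the tip and exits first during extrusion
# (LIFO). Consequently the aspiration order of a filament is the REVERSE of
# its deposition order. The transition zone between two sequenced segments
# is set by extruding a small length of the previously aspirated ink inside
# the next ink's reservoir just before that aspiration (the "waste" step);
# the planner over-aspirates each wasted segment by exactly the waste
# displacement so the deposited column still carries the designed segment
# lengths.

#' Glass capillary geometry
#'
#' @param length Capillary length, mm (default 85). The column of aspirated
#'   ink can never exceed this, which bounds the printable filament length
#'   per extrusion.
#' @param inner_diameter Inner diameter, mm (default 0.5). Fixed bore means
#'   aspiration volume follows directly from column length.
#' @return An object of class `capillary` with the derived
#'   `cross_section_area` in mm^2.
#' @export
capillary <- function(length = 85, inner_diameter = 0.5) {
  stopifnot(length > 0, inner_diameter > 0)
  structure(
    list(length = length, inner_diameter = inner_diameter,
         cross_section_area = pi * inner_diameter^2 / 4),
    class = "capillary"
  )
}

#' Transition-zone policy
#'
#' Controls the interface between sequentially aspirated inks: the plunger
#' displacement extruded into the next reservoir before each aspiration
#' (0–500 um) and the plunger speed (50–100 mm/min). Larger pre-extrusion
#' gives a smoother, longer transition zone; speed at the top of the range
#' risks turbulent flow and a non-homogeneous interface.
#'
#' @param pre_extrusion_displacement Plunger displacement before each
#'   aspiration after the first, micrometers, in `[0, 500]`.
#' @param plunger_speed Aspiration/extrusion plunger speed, mm/min, in
#'   `[50, 100]`.
#' @return An object of class `tzl_policy`.
#' @export
tzl_policy <- function(pre_extrusion_displacement = 0, plunger_speed = 50) {
  if (pre_extrusion_displacement < 0 || pre_extrusion_displacement > 500) {
    stop("tzl_policy: pre_extrusion_displacement must be in [0, 500] um",
         call. = FALSE)
  }
  if (plunger_speed < 50 || plunger_speed > 100) {
    stop("tzl_policy: plunger_speed must be in [50, 100] mm/min",
         call. = FALSE)
  }
  structure(
    list(pre_extrusion_displacement = pre_extrusion_displacement,
         plunger_speed = plunger_speed),
    class = "tzl_policy"
  )
}

#' Aspirated segment volume
#'
#' With a fixed capillary bore the aspiration volume follows from column
#' length alone: `V = length * cross_section_area`.
#'
#' @param length Column length, mm; >= 0.
#' @param capillary A [capillary()].
#' @return Volume in mm^3.
#' @examples
#' segment_volume(24, capillary(inner_diameter = 0.5))  # 4.7124 mm^3
#' @export
segment_volume <- function(length, capillary) {
  stopifnot(inherits(capillary, "capillary"))
  if (length < 0) stop("segment_volume: negative length", call. = FALSE)
  length * capillary$cross_section_area
}

#' Check that a segment list fits the capillary
#'
#' A filament can only be printed in a single extrusion if its total column
#' length fits the capillary.
#'
#' @param segments List of [ink_segment()] (may be empty).
#' @param capillary A [capillary()].
#' @param margin Extra column length that must also fit (e.g. the transient
#'   over-aspiration used for waste steps), mm.
#' @return A list with `ok` (logical), `column_length`, and `overflow`
#'   (mm by which the capillary is exceeded; 0 when `ok`).
#' @export
check_capacity <- function(segments, capillary, margin = 0) {
  stopifnot(inherits(capillary, "capillary"), margin >= 0)
  total <- if (length(segments) == 0L) 0 else sum(segment_lengths(segments))
  need <- total + margin
  ok <- need <= capillary$length + 1e-9
  list(ok = ok, column_length = total,
       overflow = if (ok) 0 else need - capillary$length)
}

#' Estimate the transition-zone length for a policy
#'
#' Qualitative calibration model: the transition zone grows with the volume
#' of ink extruded into the reservoir before the next aspiration, and is
#' inflated by turbulent flow at the top plunger speed. Defaults are a
#' configurable placeholder calibration (baseline 50 um plus the
#' pre-extrusion displacement, times 4 when the plunger runs at
#' 100 mm/min), not measured constants.
#'
#' @param policy A [tzl_policy()].
#' @param calibration List with `baseline_um` and `turbulence_factor`.
#' @return List with `tzl_um` (estimate, micrometers) and `homogeneity`
#'   (`"homogeneous"`, `"non-homogeneous"`, or `"millimeter-scale mixing"`).
#' @export
estimate_tzl <- function(policy,
                         calibration = list(baseline_um = 50,
                                            turbulence_factor = 4)) {
  stopifnot(inherits(policy, "tzl_policy"))
  turbulent <- policy$plunger_speed >= 100
  tzl <- calibration$baseline_um + policy$pre_extrusion_displacement
  if (turbulent) tzl <- tzl * calibration$turbulence_factor
  homogeneity <- if (!turbulent) {
    "homogeneous"
  } else if (tzl >= 1000) {
    "millimeter-scale mixing"
  } else {
    "non-homogeneous"
  }
  list(tzl_um = tzl, homogeneity = homogeneity)
}

#' Validate a plunger speed
#'
#' Aspiration/extrusion speeds run 50–100 mm/min; the top of the range
#' risks turbulent ink flow at the interface.
#'
#' @param speed Plunger speed, mm/min; > 0.
#' @return List with `status` (`"ok"`, `"warn"`, `"error"`) and `message`.
#' @export
check_plunger_speed <- function(speed) {
  if (!is.numeric(speed) || length(speed) != 1L || speed <= 0) {
    stop("check_plunger_speed: speed must be a single positive value",
         call. = FALSE)
  }
  if (speed >= 50 && speed < 100) {
    list(status = "ok", message = "within operating range")
  } else if (speed == 100) {
    list(status = "warn",
         message = "turbulent-flow risk at 100 mm/min; expect an extended, non-homogeneous transition zone")
  } else {
    list(status = "error",
         message = sprintf("plunger speed %.4g mm/min outside operating range [50, 100]",
                           speed))
  }
}

#' Machine configuration
#'
#' Capillary geometry, reservoir layout and temperatures, speed settings,
#' and the transition-zone policy, matching the YAML layout read by
#' [read_machine_config()].
#'
#' @param capillary A [capillary()].
#' @param reservoirs Named list: ink id -> numeric `(x, y, z)` position in
#'   mm of that ink's reservoir.
#' @param reservoir_temperature_C Named numeric vector (or single value) of
#'   reservoir temperatures, degrees C (default 50: all standard inks are
#'   liquid and easily aspirated there; cell-laden inks use 38).
#' @param deposit_feed Filament deposition feed, mm/min (default 150).
#' @param tzl A [tzl_policy()].
#' @param orientation Default slicing orientation for [plan_build()], 0 or
#'   90 degrees.
#' @param gap Default gap between filaments, mm.
#' @param min_segment_length Minimum aspiratable segment length, mm.
#' @return An object of class `machine_config`.
#' @export
machine_config <- function(capillary = aodprint::capillary(),
                           reservoirs,
                           reservoir_temperature_C = 50,
                           deposit_feed = 150,
                           tzl = tzl_policy(),
                           orientation = 0,
                           gap = 0,
                           min_segment_length = 0.5) {
  stopifnot(inherits(capillary, "capillary"), inherits(tzl, "tzl_policy"),
            is.list(reservoirs), length(reservoirs) >= 1L,
            !is.null(names(reservoirs)), deposit_feed > 0)
  for (r in reservoirs) stopifnot(length(r) == 3L, is.numeric(r))
  structure(
    list(capillary = capillary, reservoirs = reservoirs,
         reservoir_temperature_C = reservoir_temperature_C,
         deposit_feed = deposit_feed, tzl = tzl,
         orientation = orientation, gap = gap,
         min_segment_length = min_segment_length),
    class = "machine_config"
  )
}

#' Read a machine configuration from YAML
#'
#' Expected layout:
#' ```yaml
#' capillary: {length_mm: 85, inner_diameter_mm: 0.5}
#' reservoirs:
#'   A2: {position: [0, -20, 5], temperature_C: 50}
#'   AC5: {position: [10, -20, 5], temperature_C: 50}
#' speeds: {deposit_feed: 150, plunger: 50}
#' tzl: {pre_extrusion_um: 0}
#' slicing: {orientation: 0, gap: 0, min_segment_length: 0.5}
#' ```
#'
#' @param path YAML file path.
#' @return A [machine_config()].
#' @export
read_machine_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cap <- capillary(
    length = cfg$capillary$length_mm %||% 85,
    inner_diameter = cfg$capillary$inner_diameter_mm %||% 0.5
  )
  res <- lapply(cfg$reservoirs, function(r) as.numeric(r$position))
  temps <- vapply(cfg$reservoirs,
                  function(r) as.numeric(r$temperature_C %||% 50),
                  numeric(1))
  pol <- tzl_policy(
    pre_extrusion_displacement = cfg$tzl$pre_extrusion_um %||% 0,
    plunger_speed = cfg$speeds$plunger %||% 50
  )
  sl <- cfg$slicing %||% list()
  machine_config(
    capillary = cap, reservoirs = res,
    reservoir_temperature_C = temps,
    deposit_feed = cfg$speeds$deposit_feed %||% 150,
    tzl = pol,
    orientation = sl$orientation %||% 0,
    gap = sl$gap %||% 0,
    min_segment_length = sl$min_segment_length %||% 0.5
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

aspiration_step <- function(kind, ink_id = NA_character_,
                            plunger_displacement = 0, speed = NA_real_,
                            target = c(NA_real_, NA_real_, NA_real_)) {
  structure(
    list(kind = kind, ink_id = ink_id,
         plunger_displacement = plunger_displacement, speed = speed,
         target = as.numeric(target)),
    class = "aspiration_step"
  )
}

#' Plan the aspiration and deposition of one filament
#'
#' Emits the executable step sequence for a multimaterial filament:
#' reservoirs are visited in the reverse of the deposition order (the
#' last-aspirated ink sits at the capillary tip and is deposited first),
#' each aspiration's plunger displacement maps 1:1 to the segment's column
#' length, and a pre-extrusion waste step of the policy displacement is
#' performed inside the next reservoir before every aspiration after the
#' first. Segments followed by a waste step are over-aspirated by exactly
#' the waste displacement, so the deposited column carries the designed
#' segment lengths and per-ink conservation (aspirated = deposited + waste)
#' holds. The final steps travel to the filament start and deposit the whole
#' column in one synchronized XY/plunger move at the deposition feed.
#'
#' @param filament A [filament_plan()].
#' @param capillary A [capillary()].
#' @param tzl A [tzl_policy()].
#' @param reservoirs Named list of `(x, y, z)` reservoir positions, one per
#'   ink appearing in the filament.
#' @param deposit_feed Deposition feed, mm/min.
#' @return An object of class `aspiration_plan`: ordered steps,
#'   `total_column_length` (mm deposited), the per-interface transition-zone
#'   estimate, and any warnings.
#' @export
plan_filament <- function(filament, capillary, tzl = tzl_policy(),
                          reservoirs, deposit_feed = 150) {
  stopifnot(inherits(filament, "filament_plan"),
            inherits(capillary, "capillary"), inherits(tzl, "tzl_policy"))
  segs <- filament$segments
  inks <- segment_inks(segs)
  missing <- setdiff(unique(inks), names(reservoirs))
  if (length(missing) > 0L) {
    stop("plan_filament: no reservoir for ink(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  waste_mm <- tzl$pre_extrusion_displacement / 1000
  n <- length(segs)
  # Peak column: all designed lengths plus one in-flight over-aspiration.
  margin <- if (n > 1L) waste_mm else 0
  cap_ok <- check_capacity(segs, capillary, margin = margin)
  if (!cap_ok$ok) {
    stop(sprintf(
      "plan_filament: column %.4g mm (+%.4g mm waste margin) exceeds capillary length %.4g mm by %.4g mm",
      cap_ok$column_length, margin, capillary$length, cap_ok$overflow),
      call. = FALSE)
  }
  warnings <- character(0)
  spd <- check_plunger_speed(tzl$plunger_speed)
  if (spd$status == "warn") warnings <- c(warnings, spd$message)

  steps <- list()
  asp_order <- rev(seq_len(n))  # aspiration order = reverse deposition order
  for (j in seq_along(asp_order)) {
    seg <- segs[[asp_order[j]]]
    pos <- reservoirs[[seg$ink_id]]
    steps[[length(steps) + 1L]] <-
      aspiration_step("move_to_reservoir", seg$ink_id, target = pos)
    if (j > 1L && waste_mm > 0) {
      steps[[length(steps) + 1L]] <-
        aspiration_step("pre_extrude_waste", seg$ink_id,
                        plunger_displacement = waste_mm,
                        speed = tzl$plunger_speed, target = pos)
    }
    over <- if (j < length(asp_order)) waste_mm else 0
    steps[[length(steps) + 1L]] <-
      aspiration_step("aspirate", seg$ink_id,
                      plunger_displacement = seg$length + over,
                      speed = tzl$plunger_speed, target = pos)
  }
  start3 <- c(filament$start, filament$z)
  steps[[length(steps) + 1L]] <-
    aspiration_step("move_to_start", target = start3)
  total <- sum(segment_lengths(segs))
  dirsign <- if (isTRUE(filament$reversed)) -1 else 1
  end3 <- start3
  if (filament$orientation == 0) {
    end3[1] <- end3[1] + dirsign * total
  } else {
    end3[2] <- end3[2] + dirsign * total
  }
  steps[[length(steps) + 1L]] <-
    aspiration_step("deposit", plunger_displacement = total,
                    speed = deposit_feed, target = end3)
  est <- estimate_tzl(tzl)
  if (est$homogeneity != "homogeneous") {
    warnings <- c(warnings, paste0("transition zones flagged ",
                                   est$homogeneity))
  }
  structure(
    list(filament = filament, steps = steps, total_column_length = total,
         tzl_um = est$tzl_um, homogeneity = est$homogeneity,
         warnings = warnings),
    class = "aspiration_plan"
  )
}

#' @export
print.aspiration_plan <- function(x, ...) {
  kinds <- vapply(x$steps, function(s) s$kind, character(1))
  cat(sprintf(
    "<aspiration_plan> filament #%d: %d steps (%d aspirations, %d waste), column %.4g mm\n",
    x$filament$index, length(x$steps), sum(kinds == "aspirate"),
    sum(kinds == "pre_extrude_waste"), x$total_column_length))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

plan_aspirated_inks <- function(plan) {
  kinds <- vapply(plan$steps, function(s) s$kind, character(1))
  vapply(plan$steps[kinds == "aspirate"], function(s) s$ink_id, character(1))
}

#' Plan a whole build
#'
#' Decomposes every layer of a build model into filaments at the machine's
#' capillary diameter and plans each one, layer by layer, alternating the
#' deposition direction of successive filaments (serpentine ordering) so
#' travel moves stay short. Zero-length filaments are dropped with a
#' warning; capacity and missing-reservoir errors are re-raised with the
#' offending layer and filament index.
#'
#' @param model A [stack_layers()] build model or a single
#'   [layer_pattern()].
#' @param machine A [machine_config()].
#' @return List of [plan_filament()] results in execution order.
#' @export
plan_build <- function(model, machine) {
  stopifnot(inherits(machine, "machine_config"))
  if (inherits(model, "layer_pattern")) {
    model <- structure(list(layers = list(model), layer_height = 0),
                       class = "build_model")
  }
  stopifnot(inherits(model, "build_model"))
  plans <- list()
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    filaments <- decompose(
      layer,
      filament_diameter = machine$capillary$inner_diameter,
      orientation = machine$orientation, gap = machine$gap,
      min_segment_length = machine$min_segment_length
    )
    for (fi in seq_along(filaments)) {
      fp <- filaments[[fi]]
      if (fp$total_length <= 0) {
        warning(sprintf("plan_build: dropping zero-length filament %d of layer %d",
                        fi, li))
        next
      }
      if (fi %% 2L == 0L) fp <- reverse_filament(fp)
      plan <- tryCatch(
        plan_filament(fp, machine$capillary, machine$tzl,
                      machine$reservoirs, machine$deposit_feed),
        error = function(e) {
          stop(sprintf("plan_build: layer %d, filament %d: %s",
                       li, fi, conditionMessage(e)), call. = FALSE)
        }
      )
      plans[[length(plans) + 1L]] <- plan
    }
  }
  plans
}

# Flip a filament for serpentine deposition: start moves to the far end,
# the segment order reverses, and sampling runs against the axis.
reverse_filament <- function(fp) {
  far <- fp$start
  if (fp$orientation == 0) far[1] <- far[1] + fp$total_length
  else far[2] <- far[2] + fp$total_length
  segs <- rev(fp$segments)
  filament_plan(fp$index, far, fp$orientation, fp$total_length, segs,
                z = fp$z, reversed = !isTRUE(fp$reversed))
}
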