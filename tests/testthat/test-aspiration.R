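test_that("segment_volume is pi d^2 L / 4 and scales as expected", {
  cap <- capillary(85, 0.5)
  expect_equal(cap$cross_section_area, pi * 0.5^2 / 4, tolerance = 1e-12)
  expect_equal(segment_volume(24, cap), 24 * pi * 0.25 / 4,
               tolerance = 1e-12)
  expect_equal(segment_volume(24, cap), 4.7124, tolerance = 1e-4)
  expect_equal(segment_volume(0, cap), 0)
  cap2 <- capillary(85, 1.0)
  expect_equal(segment_volume(10, cap2), 4 * segment_volume(10, cap))
  expect_error(segment_volume(-1, cap), "negative")
})

test_that("aspiration order is the reverse of deposition order", {
  # deposition order [A2 12 mm, AC5 12 mm] -> aspirate AC5 first
  fil <- filament_plan(1, c(0, 0), 0, 24,
                       list(ink_segment("A2", 12), ink_segment("AC5", 12)))
  mc <- test_machine(c("A2", "AC5"), pre_extrusion_um = 200)
  plan <- plan_filament(fil, mc$capillary, mc$tzl, mc$reservoirs)
  kinds <- vapply(plan$steps, function(s) s$kind, character(1))
  expect_identical(plan_aspirated_inks(plan), c("AC5", "A2"))
  # one waste step, inside the second (A2) reservoir, before its aspiration
  wi <- which(kinds == "pre_extrude_waste")
  expect_length(wi, 1)
  expect_identical(plan$steps[[wi]]$ink_id, "A2")
  expect_identical(kinds[wi + 1L], "aspirate")
  expect_equal(plan$steps[[wi]]$plunger_displacement, 0.2)
  # deposit comes last, at the deposition feed, extruding the whole column
  expect_identical(kinds[length(kinds)], "deposit")
  expect_equal(plan$steps[[length(kinds)]]$speed, 150)
  expect_equal(plan$total_column_length, 24)
})

test_that("reversal invariant holds across generated filaments", {
  pat <- gen_nested_squares(c(2, 1, 3), c("A1", "A2", "A3"))
  mc <- test_machine(c("A1", "A2", "A3"))
  for (fil in decompose(pat, 0.5)) {
    plan <- plan_filament(fil, mc$capillary, mc$tzl, mc$reservoirs)
    expect_identical(rev(plan_aspirated_inks(plan)),
                     segment_inks(fil$segments))
  }
})

test_that("single-segment filament needs no waste or switching", {
  fil <- filament_plan(1, c(0, 0), 0, 24, list(ink_segment("A2", 24)))
  mc <- test_machine("A2", pre_extrusion_um = 500)
  plan <- plan_filament(fil, mc$capillary, mc$tzl, mc$reservoirs)
  kinds <- vapply(plan$steps, function(s) s$kind, character(1))
  expect_equal(sum(kinds == "aspirate"), 1)
  expect_equal(sum(kinds == "pre_extrude_waste"), 0)
  expect_equal(sum(kinds == "move_to_reservoir"), 1)
})

test_that("the 7-segment center filament takes 7 aspirations and 6 waste steps", {
  pat <- gen_nested_squares(c(3, 3, 3, 3), c("A1", "A2", "A3", "A4"))
  fils <- decompose(pat, 0.5)
  center <- fils[[ceiling(length(fils) / 2)]]
  expect_length(center$segments, 7)
  mc <- test_machine(pre_extrusion_um = 100)
  plan <- plan_filament(center, mc$capillary, mc$tzl, mc$reservoirs)
  kinds <- vapply(plan$steps, function(s) s$kind, character(1))
  expect_equal(sum(kinds == "aspirate"), 7)
  expect_equal(sum(kinds == "pre_extrude_waste"), 6)
  expect_equal(sum(kinds == "move_to_reservoir"), 7)
})

test_that("net plunger bookkeeping matches the filament length", {
  fil <- filament_plan(1, c(0, 0), 0, 20,
                       list(ink_segment("A1", 5), ink_segment("A2", 10),
                            ink_segment("A3", 5)))
  mc <- test_machine(c("A1", "A2", "A3"), pre_extrusion_um = 300)
  plan <- plan_filament(fil, mc$capillary, mc$tzl, mc$reservoirs)
  asp <- sum(vapply(plan$steps, function(s)
    if (s$kind == "aspirate") s$plunger_displacement else 0, numeric(1)))
  waste <- sum(vapply(plan$steps, function(s)
    if (s$kind == "pre_extrude_waste") s$plunger_displacement else 0,
    numeric(1)))
  expect_equal(asp - waste, fil$total_length, tolerance = 1e-12)
  expect_equal(plan$total_column_length, fil$total_length)
})

test_that("capacity is enforced at the capillary length", {
  cap <- capillary(85, 0.5)
  ok <- check_capacity(list(ink_segment("A1", 84)), cap)
  expect_true(ok$ok)
  expect_true(check_capacity(list(ink_segment("A1", 85)), cap)$ok)
  bad <- check_capacity(list(ink_segment("A1", 90)), cap)
  expect_false(bad$ok)
  expect_equal(bad$overflow, 5)
  expect_true(check_capacity(list(), cap)$ok)
  expect_equal(check_capacity(list(), cap)$column_length, 0)
  # plan_filament raises a structured capacity error naming the bound
  fil <- filament_plan(1, c(0, 0), 0, 90, list(ink_segment("A1", 90)))
  mc <- test_machine("A1")
  expect_error(plan_filament(fil, cap, mc$tzl, mc$reservoirs), "85")
})

test_that("missing reservoirs are reported by ink name", {
  fil <- filament_plan(1, c(0, 0), 0, 10,
                       list(ink_segment("A1", 5), ink_segment("A9", 5)))
  mc <- test_machine("A1")
  expect_error(plan_filament(fil, mc$capillary, mc$tzl, mc$reservoirs), "A9")
})

test_that("estimate_tzl is monotone in displacement and flags turbulence", {
  grid_um <- seq(0, 500, by = 50)
  for (speed in c(50, 100)) {
    est <- vapply(grid_um, function(u)
      estimate_tzl(tzl_policy(u, speed))$tzl_um, numeric(1))
    expect_true(all(diff(est) >= 0))
  }
  base <- estimate_tzl(tzl_policy(0, 50))
  expect_identical(base$homogeneity, "homogeneous")
  expect_gte(estimate_tzl(tzl_policy(500, 50))$tzl_um,
             estimate_tzl(tzl_policy(100, 50))$tzl_um)
  worst <- estimate_tzl(tzl_policy(500, 100))
  expect_identical(worst$homogeneity, "millimeter-scale mixing")
  expect_gte(worst$tzl_um, 1000)
  expect_identical(estimate_tzl(tzl_policy(0, 100))$homogeneity,
                   "non-homogeneous")
  expect_error(tzl_policy(600, 50), "500")
  expect_error(tzl_policy(100, 120), "plunger_speed")
})

test_that("plunger speed policy: ok in [50, 100), warn at 100, error outside", {
  expect_identical(check_plunger_speed(50)$status, "ok")
  expect_identical(check_plunger_speed(99.9)$status, "ok")
  expect_identical(check_plunger_speed(100)$status, "warn")
  expect_match(check_plunger_speed(100)$message, "turbulent")
  expect_identical(check_plunger_speed(120)$status, "error")
  expect_identical(check_plunger_speed(40)$status, "error")
  expect_error(check_plunger_speed(0), "positive")
})

test_that("plan_build plans both layers of the T model with serpentine ordering", {
  model <- gen_two_layer_T()
  mc <- test_machine(c("A2", "AC5"))
  plans <- plan_build(model, mc)
  zs <- vapply(plans, function(p) p$filament$z, numeric(1))
  expect_setequal(unique(zs), c(0, 0.5))
  expect_equal(sort(unique(zs))[2] - sort(unique(zs))[1],
               model$layer_height)
  rev_flags <- vapply(plans[zs == 0], function(p) p$filament$reversed,
                      logical(1))
  expect_identical(rev_flags, rep(c(FALSE, TRUE), length.out = length(rev_flags)))
})

test_that("plan_build names the ink and filament when a reservoir is missing", {
  pat <- gen_gradient_rectangle(c("A2", "AC1"), 4, 2)
  mc <- test_machine("A2")
  expect_error(plan_build(pat, mc), "AC1")
  expect_error(plan_build(pat, mc), "filament")
})

test_that("machine config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "capillary: {length_mm: 85, inner_diameter_mm: 0.5}",
    "reservoirs:",
    "  A2: {position: [0, -20, 5], temperature_C: 50}",
    "  AC5: {position: [10, -20, 5], temperature_C: 50}",
    "speeds: {deposit_feed: 150, plunger: 50}",
    "tzl: {pre_extrusion_um: 100}",
    "slicing: {orientation: 0, gap: 0, min_segment_length: 0.5}"
  ), path)
  mc <- read_machine_config(path)
  expect_equal(mc$capillary$length, 85)
  expect_equal(mc$capillary$inner_diameter, 0.5)
  expect_equal(mc$reservoirs$AC5, c(10, -20, 5))
  expect_equal(mc$tzl$pre_extrusion_displacement, 100)
  expect_equal(mc$deposit_feed, 150)
  expect_equal(unname(mc$reservoir_temperature_C["A2"]), 50)
})
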