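# Shared builders for tests: a palette of the standard inks and a machine
# with one reservoir per ink, laid out along a line clear of the build area.

standard_palette <- function(ids = c("A1", "A2", "A3", "A4", "AC1", "AC3",
                                     "AC5", "AS3", "A-NIH")) {
  ink_palette(ids)
}

test_machine <- function(inks = c("A1", "A2", "A3", "A4"),
                         pre_extrusion_um = 0, plunger_speed = 50,
                         cap = capillary()) {
  res <- lapply(seq_along(inks), function(i) c(-20, 10 * (i - 1), 5))
  names(res) <- inks
  machine_config(
    capillary = cap, reservoirs = res,
    tzl = tzl_policy(pre_extrusion_um, plunger_speed)
  )
}

# Brute-force run-length oracle: per-pixel labels along a horizontal
# centerline, encoded with base rle(). Independent of extract_segments.
rle_oracle <- function(pattern, y) {
  px <- pattern$pixel_size
  n <- ncol(pattern$grid)
  labels <- vapply(seq_len(n) - 0.5,
                   function(i) ink_at(pattern, c(i * px, y)), character(1))
  r <- rle(labels)
  list(inks = r$values, lens = r$lengths * px)
}
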