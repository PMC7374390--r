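# shared fixtures: everything is generated in code at test time

# small rasters keep unit tests fast; fruit scaled to fill ~70% of the height
small_opts <- function(...) {
  render_options(width = 128, height = 96, fruit_shape = c(22, 22, 33), ...)
}

tiny_opts <- function(...) {
  render_options(width = 96, height = 72, fruit_shape = c(16, 16, 25), ...)
}

test_pepper <- function(colored_fraction = 0.6, color = "red",
                        front = c(1, 0, 0), seed = 42,
                        shape = c(22, 22, 33)) {
  generate_pepper(pepper_spec("tp", color, colored_fraction, front,
                              shape = shape, seed = seed))
}

# constant-color RGB raster, values in [0,1]
flat_rgb <- function(r, g, b, h = 20, w = 30) {
  array(rep(c(r, g, b), each = h * w), dim = c(h, w, 3))
}

# an analytic disk mask
disk_mask <- function(h, w, cy, cx, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= radius^2
}

# manual pixel sample for feature tests
manual_sample <- function(hue, red, rmg = red, convention = "unrotated") {
  structure(list(hue = hue, red = red, red_minus_green = rmg,
                 n = length(hue), hue_convention = convention),
            class = "pixel_sample")
}
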