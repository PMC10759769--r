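# Shared fixtures, built in code. Expensive objects are created lazily and
# cached for the session so several test files can share one computation.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# A small rendering scene: same geometry as the default, quarter scale.
small_scene <- function(noise_sd = 2, ...) {
  scene_spec(image_size = 400, noise_sd = noise_sd, ...)
}

# Uniform-colour RGB array.
flat_image <- function(n, rgb) {
  img <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Independent sRGB -> CIELAB reference (D65), written from the standard
# formulas; used as the colorimetric oracle for compute_color_means().
reference_lab <- function(rgb255) {
  v <- rgb255 / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  white <- c(0.95047, 1.0, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz / white)
  c(l = 116 * fx[2] - 16, a = 500 * (fx[1] - fx[2]), b = 200 * (fx[2] - fx[3]))
}

# A small but complete synthetic dataset shared across model-level tests.
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    generate_dataset(dataset_config(n_per_region = 12, seed = 42,
                                    separation = 1, noise_scale = 0.5,
                                    image_size = 320))
  })
}

tiny_features <- function() {
  fixture("tiny_features", function() {
    ds <- tiny_dataset()
    slim <- lapply(ds, extract_sample_features)
    list(tables = kiwifuse:::.feature_tables(slim),
         labels = dataset_labels(ds),
         physchem = t(vapply(ds, function(s) s$physchem, numeric(13))))
  })
}
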