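# In-code fixtures: a single rendered annulus frame, and a small fast movie
# spec used wherever a full-size field is not the point of the test.

render_annulus <- function(r_px, field = 128L, sigma_px = 2.4, amp = 1000,
                           bg = 100, gaussian_sd = 0, seed = 1L) {
  ctr <- (field + 1) / 2
  ax <- seq_len(field) - ctr
  d <- sqrt(outer(ax^2, ax^2, "+"))
  img <- bg + amp * exp(-(d - r_px)^2 / (2 * sigma_px^2))
  set.seed(seed)
  if (gaussian_sd > 0) img <- img + rnorm(length(img), 0, gaussian_sd)
  matrix(pmin(pmax(round(img), 0), 65535), field)
}

small_movie_spec <- function(frames = 70L, field_px = 160L,
                             formation_onset_s = 10, completion_time_s = 100,
                             initial_radius_um = 5, pixel_size_um = 0.124,
                             noise = list(gaussian_sd = 0, poisson_scale = 0),
                             seed = 1L, ...) {
  ring_movie_spec(frames = frames, field_px = field_px,
                  formation_onset_s = formation_onset_s,
                  completion_time_s = completion_time_s,
                  initial_radius_um = initial_radius_um,
                  pixel_size_um = pixel_size_um, noise = noise, seed = seed,
                  ...)
}

# independent normal-equations oracles for the least-squares fits
ols_slope_origin <- function(x, y) sum(x * y) / sum(x * x)
ols_affine <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  b <- sxy / sxx
  c(intercept = mean(y) - b * mean(x), slope = b)
}
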