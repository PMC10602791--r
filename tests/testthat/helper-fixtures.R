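# Small simulated plates shared across tests. Everything is generated in
# code at test time; tiny frames keep the suite fast.

tiny_plate <- function(dir, n_wells = 4, n_frames = 6, temperature = 28.5,
                       seed = 1, interval = 4, height = 32, width = 48, ...) {
  spec <- sim_plate_spec(n_wells = n_wells, temperature = temperature,
                         t_start = 4, interval = interval,
                         n_frames = n_frames, image_height = height,
                         image_width = width, seed = seed, ...)
  simulate_plate(spec, dir)
}

tiny_model <- function(height = 32, width = 48, seed = 3, ...) {
  build_stage_model(stage_model_config(
    input_height = height, input_width = width, n_conv_units = 2,
    filters_per_unit = c(4, 8), dense_width = 16, dropout_rate = 0,
    batch_size = 8, seed = seed, ...))
}

# brute-force grid minimiser of sum((y - m x)^2): the independent oracle
# for through-origin fits (coarse grid, then refined around the minimum).
grid_origin_slope <- function(x, y, lim = 10) {
  coarse <- seq(-lim, lim, by = 1e-2)
  sse <- vapply(coarse, function(m) sum((y - m * x)^2), numeric(1))
  m0 <- coarse[which.min(sse)]
  fine <- seq(m0 - 2e-2, m0 + 2e-2, by = 1e-6)
  sse <- vapply(fine, function(m) sum((y - m * x)^2), numeric(1))
  fine[which.min(sse)]
}
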