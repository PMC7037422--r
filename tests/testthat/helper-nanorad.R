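# shared fixtures, all built in code

# event table with hand-placed intensities; states give the intended
# quadrant under thresholds dioc = 100, pi = 100
manual_events <- function(n_live, n_apoptotic, n_dead) {
  states <- rep(c("live", "apoptotic", "dead"),
                c(n_live, n_apoptotic, n_dead))
  data.frame(
    sample_id = "manual",
    fsc = 200,
    ssc = 100,
    dioc = ifelse(states == "live", 1000, 10),
    pi = ifelse(states == "dead", 1000, 10))
}

# simulate paired NI/IR mortality curves for one nanomaterial/timepoint
sim_curves <- function(gp, nm = "TiO2", timepoint_h = 72,
                       n_events = 10000, seed = 1) {
  grid <- expand.grid(dose_surface = nm_dose_grid(),
                      irradiated = c(FALSE, TRUE))
  grid$nm_type <- ifelse(grid$dose_surface == 0, "none", nm)
  grid$timepoint_h <- timepoint_h
  tab <- simulate_mortality_table(grid, gp, n_events, seed = seed)
  list(
    ni = dose_response_data(tab$dose_surface[!tab$irradiated],
                            tab$mortality[!tab$irradiated]),
    ir = dose_response_data(tab$dose_surface[tab$irradiated],
                            tab$mortality[tab$irradiated]))
}

# deterministic field: `count` Gaussian nuclei on a lattice with ample
# separation (for imaging tests with known ground truth)
lattice_field <- function(count, field_size = 256, spacing = 24,
                          blob_sigma = 2, amplitude = 0.9) {
  px <- matrix(0.02, field_size, field_size)
  if (count > 0) {
    per_row <- floor((field_size - spacing) / spacing)
    stopifnot(count <= per_row^2)
    idx <- seq_len(count) - 1
    centers <- cbind(spacing + (idx %/% per_row) * spacing,
                     spacing + (idx %% per_row) * spacing)
    half <- ceiling(4 * blob_sigma)
    for (i in seq_len(count)) {
      rr <- (centers[i, 1] - half):(centers[i, 1] + half)
      cc <- (centers[i, 2] - half):(centers[i, 2] + half)
      g <- outer(rr - centers[i, 1], cc - centers[i, 2],
                 function(a, b) exp(-(a^2 + b^2) / (2 * blob_sigma^2)))
      px[rr, cc] <- px[rr, cc] + amplitude * g
    }
  }
  pmin(px, 1)
}

# closed-form Welch statistic, df and p (independent of stats::t.test)
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}
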