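#' Conditional kill fraction of irradiation ("IR impulse")
#'
#' Converts the mortality of the irradiated control and the
#' non-irradiated control into the conditional kill attributable to
#' irradiation beyond baseline:
#' \deqn{q = \frac{p_{IR} - p_{NI}}{1 - p_{NI}}.}
#' This is the impulse that is transferred onto every non-irradiated
#' condition to build the theoretical "NMs alone + 4 Gy alone" response.
#'
#' @param p_ir_ctrl mortality fraction of the irradiated, untreated
#'   control.
#' @param p_ni_ctrl mortality fraction of the non-irradiated, untreated
#'   control (< 1).
#' @return the conditional kill fraction `q`.
#' @export
#' @examples
#' ir_impulse(0.255, 0)      # 4 Gy alone at 72 h against a clean baseline
#' ir_impulse(0.634, 0.1)
ir_impulse <- function(p_ir_ctrl, p_ni_ctrl) {
  if (any(!is.finite(p_ir_ctrl)) || any(!is.finite(p_ni_ctrl)))
    stop("control mortalities must be finite")
  if (any(p_ni_ctrl < 0) || any(p_ni_ctrl >= 1))
    stop("'p_ni_ctrl' must lie in [0, 1)")
  if (any(p_ir_ctrl < p_ni_ctrl))
    stop("irradiated control mortality below non-irradiated control: ",
         "protective irradiation is not modelled")
  (p_ir_ctrl - p_ni_ctrl) / (1 - p_ni_ctrl)
}

#' Independent-action combination of two kill probabilities
#'
#' The Bliss-independence null: two agents that kill independently leave
#' a combined surviving fraction equal to the product of the single-agent
#' survivals, so
#' \deqn{p_{sim} = 1 - (1 - p_{NI})(1 - q) = p_{NI} + q - p_{NI}\,q.}
#' Commutative, associative, bounded in `[0, 1]`, and monotone
#' non-decreasing in both arguments.
#'
#' @param p_ni mortality under the nanomaterial alone (vectorized).
#' @param q conditional kill of irradiation alone.
#' @return the simulated combined mortality.
#' @export
#' @examples
#' transfer_impulse(0.2795, 0.255)   # -> 0.4632...
transfer_impulse <- function(p_ni, q) {
  if (any(!is.finite(p_ni)) || any(p_ni < 0) || any(p_ni > 1))
    stop("'p_ni' must be fractions in [0, 1]")
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("'q' must be a fraction in [0, 1]")
  1 - (1 - p_ni) * (1 - q)
}

#' Build the simulated irradiated dose-response curve
#'
#' Maps every non-irradiated response through [transfer_impulse()],
#' leaving doses unchanged: the expected irradiated curve if the
#' nanomaterial and 4 Gy acted independently.
#'
#' @param ni_data a [dose_response_data] of NM-alone mortalities.
#' @param q conditional irradiation kill from [ir_impulse()].
#' @return a [dose_response_data] of simulated combined mortalities.
#' @export
simulate_ir_curve <- function(ni_data, q) {
  if (!is.data.frame(ni_data) || !all(c("dose", "response") %in% names(ni_data)))
    stop("'ni_data' must contain 'dose' and 'response' columns")
  dose_response_data(ni_data$dose, transfer_impulse(ni_data$response, q),
                     replicate = ni_data$replicate)
}

ll4_coef_vector <- function(p, log_ed50 = TRUE) {
  p <- as_ll4_params(p)
  c(lower = p$lower, upper = p$upper,
    ed50 = if (log_ed50) log(p$ed50) else p$ed50,
    shape = p$shape)
}

#' Euclidean distance between LL4 coefficient vectors
#'
#' The synergy statistic: the Euclidean norm of the difference between
#' the coefficient vectors of the simulated-null fit and the observed
#' fit. Default coordinates are `(lower, upper, log ed50, shape)` — the
#' log keeps the half-effect dose from dominating the norm through its
#' units; set `log_ed50 = FALSE` for raw coefficients. `scaling` may be
#' `"unit"` or a positive length-4 vector of divisors (e.g. bootstrap
#' standard errors) applied coordinate-wise.
#'
#' @param p_sim,p_obs [ll4_params] of the simulated and observed fits.
#' @param scaling `"unit"` or numeric length-4 divisors.
#' @param log_ed50 compare `log(ed50)` (default) rather than `ed50`.
#' @return non-negative distance; symmetric in its arguments.
#' @export
coefficient_distance <- function(p_sim, p_obs, scaling = "unit",
                                 log_ed50 = TRUE) {
  v1 <- ll4_coef_vector(p_sim, log_ed50)
  v2 <- ll4_coef_vector(p_obs, log_ed50)
  w <- if (identical(scaling, "unit")) rep(1, 4) else {
    if (!is.numeric(scaling) || length(scaling) != 4 || any(scaling <= 0))
      stop("'scaling' must be \"unit\" or 4 positive divisors")
    scaling
  }
  sqrt(sum(((v1 - v2) / w)^2))
}

#' Score synergy between a nanomaterial and irradiation
#'
#' The full comparison for one nanomaterial and timepoint:
#' 1. estimate the irradiation impulse `q` from the dose-0 controls
#'    ([ir_impulse()]);
#' 2. transfer it onto the non-irradiated curve to get the simulated
#'    "NM alone + 4 Gy alone" response ([simulate_ir_curve()]);
#' 3. fit LL4 models to the simulated and the observed irradiated data
#'    ([fit_ll4()]);
#' 4. score their divergence as the coefficient distance, signed by the
#'    direction of the mean per-dose (observed - simulated) mortality over
#'    nonzero doses: `+1` = observed kill exceeds the independent-action
#'    null (synergy), `-1` = falls short (antagonism / saturation), `0`
#'    within `zero_tol`.
#'
#' @param obs [dose_response_data] of observed irradiated mortalities.
#' @param ni [dose_response_data] of NM-alone mortalities (same dose
#'   grid).
#' @param controls list with `p_ir_ctrl` and `p_ni_ctrl` (untreated
#'   control mortalities); if omitted, taken from the dose-0 rows of
#'   `obs` and `ni`.
#' @param scaling,log_ed50 passed to [coefficient_distance()].
#' @param zero_tol absolute mean per-dose delta below which the sign is 0.
#' @param n_starts,seed passed to [fit_ll4()].
#' @return a `synergy_result` list: `q_ir`, `simulated_points`,
#'   `simulated_fit`, `observed_fit`, `distance`, `sign`,
#'   `per_dose_delta`.
#' @export
synergy_call <- function(obs, ni, controls = NULL, scaling = "unit",
                         log_ed50 = TRUE, zero_tol = 1e-8,
                         n_starts = 5L, seed = 1L) {
  for (d in list(obs, ni))
    if (!is.data.frame(d) || !all(c("dose", "response") %in% names(d)))
      stop("'obs' and 'ni' must contain 'dose' and 'response' columns")
  if (!setequal(unique(obs$dose), unique(ni$dose)))
    stop("observed and non-irradiated dose grids do not match")
  if (is.null(controls)) {
    if (!any(obs$dose == 0) || !any(ni$dose == 0))
      stop("controls not supplied and no dose-0 rows present")
    controls <- list(p_ir_ctrl = mean(obs$response[obs$dose == 0]),
                     p_ni_ctrl = mean(ni$response[ni$dose == 0]))
  }
  q <- ir_impulse(controls$p_ir_ctrl, controls$p_ni_ctrl)
  sim <- simulate_ir_curve(ni, q)
  fit_sim <- fit_ll4(sim, n_starts = n_starts, seed = seed)
  fit_obs <- fit_ll4(obs, n_starts = n_starts, seed = seed)
  if (fit_sim$degenerate || fit_obs$degenerate)
    warning("degenerate LL4 fit entering the coefficient distance")
  dist <- coefficient_distance(fit_sim$params, fit_obs$params,
                               scaling = scaling, log_ed50 = log_ed50)

  obs_mean <- tapply(obs$response, obs$dose, mean)
  sim_mean <- tapply(sim$response, sim$dose, mean)
  doses <- as.numeric(names(obs_mean))
  delta <- obs_mean[match(names(sim_mean), names(obs_mean))] - sim_mean
  nz <- doses > 0
  mean_delta <- mean(delta[nz])
  sgn <- if (abs(mean_delta) <= zero_tol) 0L else as.integer(sign(mean_delta))

  structure(list(
    q_ir = q,
    simulated_points = sim,
    simulated_fit = fit_sim$params,
    observed_fit = fit_obs$params,
    distance = dist,
    sign = sgn,
    per_dose_delta = setNames(as.numeric(delta), names(sim_mean)),
    mean_delta = mean_delta),
    class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf(
    "synergy score: %s%.4g (q_ir = %.3f, mean per-dose delta = %+.4f)\n",
    c("-", "", "+")[x$sign + 2], x$distance, x$q_ir, x$mean_delta))
  invisible(x)
}

#' Signed synergy-score matrix over nanomaterials and timepoints
#'
#' Collects [synergy_call()] results into a matrix of `sign * distance`
#' (rows: nanomaterial, columns: timepoint) — the numeric content of a
#' synergy heat map.
#'
#' @param results a list of `synergy_result` objects.
#' @param nm_type,timepoint_h character/numeric vectors parallel to
#'   `results` giving each result's grid cell.
#' @return numeric matrix with nanomaterial rows and timepoint columns;
#'   cells without a result are `NA`.
#' @export
synergy_heatmap <- function(results, nm_type, timepoint_h) {
  if (length(results) < 1) stop("at least one synergy result is required")
  if (length(nm_type) != length(results) ||
      length(timepoint_h) != length(results))
    stop("'nm_type' and 'timepoint_h' must parallel 'results'")
  rows <- unique(as.character(nm_type))
  cols <- as.character(sort(unique(as.numeric(timepoint_h))))
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (!inherits(r, "synergy_result")) stop("results must be synergy_result objects")
    m[as.character(nm_type[i]), as.character(timepoint_h[i])] <-
      r$sign * r$distance
  }
  m
}

#' Null distribution of the synergy score by seeded simulation
#'
#' Repeatedly generates a no-interaction world (`synergy_coeff = 0`),
#' runs [synergy_call()] on each replicate, and returns the signed
#' scores. The 95th percentile of the absolute score is the recommended
#' tolerance below which a distance is treated as "zero" — the assay
#' gives no analytic threshold.
#'
#' @param nm one of [nm_types()] (not `"none"`).
#' @param timepoint_h timepoint in hours.
#' @param gp a [generative_params] with `synergy_coeff = 0`; defaults to
#'   [default_generative_params()].
#' @param n_reps number of seeded replicates.
#' @param n_events events per well.
#' @param doses dose grid.
#' @param seed master seed.
#' @return list: `scores` (signed, length `n_reps`), `tolerance`
#'   (95th percentile of `abs(scores)`).
#' @export
null_synergy_distribution <- function(nm = "TiO2", timepoint_h = 72,
                                      gp = default_generative_params(),
                                      n_reps = 200L, n_events = 10000L,
                                      doses = nm_dose_grid(), seed = 1L) {
  if (gp$synergy_coeff != 0)
    stop("null calibration requires synergy_coeff = 0")
  scores <- vapply(seq_len(n_reps), function(r) {
    grid <- expand.grid(dose_surface = doses, irradiated = c(FALSE, TRUE))
    grid$nm_type <- ifelse(grid$dose_surface == 0, "none", nm)
    grid$timepoint_h <- timepoint_h
    tab <- simulate_mortality_table(grid, gp, n_events,
                                    seed = derive_seed(seed, r))
    ni <- tab[!tab$irradiated, ]
    ir <- tab[tab$irradiated, ]
    res <- synergy_call(
      dose_response_data(ir$dose_surface, ir$mortality),
      dose_response_data(ni$dose_surface, ni$mortality))
    res$sign * res$distance
  }, numeric(1))
  list(scores = scores, tolerance = unname(quantile(abs(scores), 0.95)))
}
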