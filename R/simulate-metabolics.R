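#' Metabolic model parameters
#'
#' Parameters of the toy metabolic model used by [simulate_metabolics()].
#' Blood lactate follows a linear accumulation/clearance ODE around a
#' threshold load,
#' \deqn{dL/dt = a \cdot \max(0, \mathrm{load} - \theta) - c\,(L - L_{rest}),}
#' so below the threshold lactate relaxes back to its resting baseline, and
#' above it accumulates towards `L_rest + a (load - theta) / c`.  Oxygen
#' uptake follows a first-order lag towards a load-proportional setpoint
#' `vo2_rest + vo2_slope * load` with time constant `vo2_tau_s`.  A latent
#' dimensionless "exertion" trajectory (lagged load plus a lactate-coupled
#' fatigue term) is also produced; the EMG generator uses it to drive burst
#' amplitude and spectral drift.
#'
#' @param lactate_rest_mmol_l Resting blood lactate (mmol/L).
#' @param lactate_threshold Load fraction above which lactate accumulates.
#' @param lactate_gain Accumulation rate a (mmol/L/s per unit excess load, > 0).
#' @param lactate_clearance Clearance rate c (1/s, >= 0).
#' @param vo2_rest_l_min,vo2_slope_l_min Setpoint intercept/slope (L/min).
#' @param vo2_tau_s VO2 lag time constant (s, > 0).
#' @param exertion_tau_s Lag of the latent exertion behind load (s, > 0).
#' @param exertion_fatigue_gain Coupling of exertion to accumulated lactate
#'   (per mmol/L above rest).
#' @param lactate_noise_sd,vo2_noise_sd Additive Gaussian observation noise
#'   (truncated at 0) on the sampled series.
#'
#' @return A named list of class `metabolic_params`.
#' @export
metabolic_params <- function(lactate_rest_mmol_l = 1.0,
                             lactate_threshold = 0.75,
                             lactate_gain = 0.18,
                             lactate_clearance = 0.003,
                             vo2_rest_l_min = 0.5,
                             vo2_slope_l_min = 3.0,
                             vo2_tau_s = 30,
                             exertion_tau_s = 45,
                             exertion_fatigue_gain = 0.03,
                             lactate_noise_sd = 0.2,
                             vo2_noise_sd = 0.08) {
  if (lactate_gain <= 0) abort("lactate_gain must be > 0")
  if (lactate_clearance < 0) abort("lactate_clearance must be >= 0")
  if (vo2_tau_s <= 0 || exertion_tau_s <= 0) abort("time constants must be > 0")
  if (lactate_noise_sd < 0 || vo2_noise_sd < 0) abort("noise sd must be >= 0")
  structure(
    list(
      lactate_rest_mmol_l = lactate_rest_mmol_l,
      lactate_threshold = lactate_threshold,
      lactate_gain = lactate_gain,
      lactate_clearance = lactate_clearance,
      vo2_rest_l_min = vo2_rest_l_min,
      vo2_slope_l_min = vo2_slope_l_min,
      vo2_tau_s = vo2_tau_s,
      exertion_tau_s = exertion_tau_s,
      exertion_fatigue_gain = exertion_fatigue_gain,
      lactate_noise_sd = lactate_noise_sd,
      vo2_noise_sd = vo2_noise_sd
    ),
    class = "metabolic_params"
  )
}

# Exact update of dX/dt = (xinf - X)/tau over a step dt (tau = 1/rate).
step_towards <- function(x, xinf, rate, dt) {
  if (rate <= 0) {
    return(x)
  }
  xinf + (x - xinf) * exp(-rate * dt)
}

#' Simulate lactate and oxygen-uptake trajectories for a protocol
#'
#' Integrates the metabolic model of [metabolic_params()] on a 1-s grid
#' (exact per-step solution of the piecewise-linear ODEs), then samples blood
#' lactate every 60 s and oxygen uptake every 10 s -- the sampling grids of a
#' finger-prick analyser and a breath-by-breath gas analyser -- with additive
#' Gaussian observation noise truncated at zero.
#'
#' @param protocol An `emg_protocol` from [protocol_spec()].
#' @param params A `metabolic_params` list.
#' @param seed Integer seed; with `lactate_noise_sd = vo2_noise_sd = 0` the
#'   output is deterministic and `seed` is irrelevant.
#'
#' @return An object of class `metabolic_truth`: list with
#'   * `latent`: tibble (`time_s`, `load`, `exertion`, `lactate`, `vo2`) on
#'     the 1-s grid, noise-free;
#'   * `lactate`: tibble (`time_s`, `value`) sampled every 60 s (mmol/L);
#'   * `vo2`: tibble (`time_s`, `value`) sampled every 10 s (L/min);
#'   * `params`, `protocol`.
#' @export
#' @examples
#' tr <- simulate_metabolics(default_protocol(), seed = 1)
#' head(tr$lactate)
simulate_metabolics <- function(protocol,
                                params = metabolic_params(),
                                seed = 1L) {
  stopifnot(inherits(protocol, "emg_protocol"))
  if (!inherits(params, "metabolic_params")) params <- do.call(metabolic_params, params)
  dt <- 1
  times <- seq(0, protocol$total_s, by = dt)
  load <- load_profile(protocol, pmin(times, protocol$total_s - 1e-9))
  n <- length(times)

  lact <- numeric(n)
  vo2 <- numeric(n)
  exer <- numeric(n)
  lact[1] <- params$lactate_rest_mmol_l
  vo2[1] <- params$vo2_rest_l_min
  exer[1] <- load[1]
  for (i in seq_len(n - 1)) {
    excess <- max(0, load[i] - params$lactate_threshold)
    c_ <- params$lactate_clearance
    if (c_ > 0) {
      linf <- params$lactate_rest_mmol_l + params$lactate_gain * excess / c_
      lact[i + 1] <- step_towards(lact[i], linf, c_, dt)
    } else {
      lact[i + 1] <- lact[i] + params$lactate_gain * excess * dt
    }
    vset <- params$vo2_rest_l_min + params$vo2_slope_l_min * load[i]
    vo2[i + 1] <- step_towards(vo2[i], vset, 1 / params$vo2_tau_s, dt)
    exer[i + 1] <- step_towards(exer[i], load[i], 1 / params$exertion_tau_s, dt)
  }
  exer <- exer + params$exertion_fatigue_gain *
    pmax(0, lact - params$lactate_rest_mmol_l)

  latent <- tibble::tibble(
    time_s = times, load = load, exertion = exer,
    lactate = lact, vo2 = vo2
  )

  sample_series <- function(grid_s, values, sd) {
    ts <- seq(0, protocol$total_s, by = grid_s)
    v <- values[match(round(ts), round(times))]
    if (sd > 0) v <- pmax(0, v + rnorm(length(v), 0, sd))
    tibble::tibble(time_s = ts, value = v)
  }
  out <- withr::with_seed(seed, {
    list(
      lactate = sample_series(60, lact, params$lactate_noise_sd),
      vo2 = sample_series(10, vo2, params$vo2_noise_sd)
    )
  })

  structure(
    list(
      latent = latent, lactate = out$lactate, vo2 = out$vo2,
      params = params, protocol = protocol
    ),
    class = "metabolic_truth"
  )
}

#' @export
print.metabolic_truth <- function(x, ...) {
  cat(sprintf(
    "<metabolic_truth> %.0f s; peak lactate %.2f mmol/L, peak VO2 %.2f L/min\n",
    max(x$latent$time_s), max(x$latent$lactate), max(x$latent$vo2)
  ))
  invisible(x)
}
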