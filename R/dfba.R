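#' Kinetic parameters for dynamic FBA
#'
#' Defaults describe batch fermentation of a mixed glucose/xylose
#' hydrolysate with two-pool phosphate kinetics: an external phosphate pool
#' taken up at a Michaelis-Menten rate, and an internal store that is
#' filled while external phosphate lasts and consumed afterwards. Glucose
#' uptake has a passive component proportional to its concentration plus a
#' carrier with product inhibition; the xylose carrier is gated off while
#' glucose exceeds `glucose_gate`. A product (citrate) output cap can be
#' scheduled `cap_delay` hours after the simulation start.
#'
#' Units: rates in mmol gDW^-1 h^-1, Michaelis/inhibition constants in mM,
#' times in h.
#'
#' @param v_pe_max external phosphate maximum uptake rate (0.15).
#' @param k_pe external phosphate Michaelis constant (0.0333 mM).
#' @param v_p_max internal phosphate-store maximum uptake rate (0.06).
#' @param k_p internal store Michaelis constant (20 mM).
#' @param g_passive_coeff passive glucose uptake per mM glucose (0.0027).
#' @param v_g2_max glucose carrier maximum rate (0.08).
#' @param k_g2 glucose carrier Michaelis constant (0.26 mM).
#' @param k_i2 citrate inhibition constant on the glucose carrier (933 mM).
#' @param x_passive_coeff passive xylose uptake per mM xylose (0.00027).
#' @param v_x2_max xylose carrier maximum rate (0.18).
#' @param k_x2 xylose carrier Michaelis constant (3.33 mM).
#' @param v_cit_cap citrate output cap (0.12).
#' @param glucose_gate glucose concentration above which the xylose carrier
#'   is off (5 mM, strict `>`).
#' @param cap_delay delay before the citrate cap activates (32 h).
#' @param start_time simulation clock offset after inoculation (10 h).
#' @return list of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(v_pe_max = 0.15, k_pe = 0.0333,
                               v_p_max = 0.06, k_p = 20,
                               g_passive_coeff = 0.0027,
                               v_g2_max = 0.08, k_g2 = 0.26, k_i2 = 933,
                               x_passive_coeff = 0.00027,
                               v_x2_max = 0.18, k_x2 = 3.33,
                               v_cit_cap = 0.12, glucose_gate = 5,
                               cap_delay = 32, start_time = 10) {
  p <- as.list(environment())
  rates <- c("v_pe_max", "v_p_max", "g_passive_coeff", "v_g2_max",
             "x_passive_coeff", "v_x2_max", "v_cit_cap")
  if (any(unlist(p[rates]) < 0)) stop("rates must be >= 0")
  if (any(unlist(p[c("k_pe", "k_p", "k_g2", "k_i2", "k_x2")]) <= 0))
    stop("Michaelis/inhibition constants must be > 0")
  structure(p, class = "kinetic_parameters")
}

#' Initial culture state
#'
#' @param t clock time (h).
#' @param biomass biomass dry weight (g/L), must be > 0.
#' @param concentrations named vector of pool concentrations (mM); names
#'   are species keys matched by the `exchange_map` (e.g. `glucose`,
#'   `xylose`, `phosphate_ext`, `citrate`, `co2`).
#' @param pi_store internal phosphate store (mM equivalents).
#' @return list of class `culture_state`.
#' @export
culture_state <- function(t = 0, biomass, concentrations, pi_store = 0) {
  if (biomass <= 0) stop("biomass must be positive")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (pi_store < 0) stop("pi_store must be >= 0")
  structure(list(t = t, biomass = biomass,
                 concentrations = concentrations, pi_store = pi_store),
            class = "culture_state")
}

#' Substrate-dependent exchange bounds
#'
#' Converts the current culture state into flux bounds on the exchange
#' reactions named by `exchange_map`:
#' glucose capacity `v_G1 + v_G2` with
#' `v_G1 = g_passive_coeff * [GLC]` and
#' `v_G2 = v_g2_max * [GLC]/(k_g2+[GLC]) * 1/(1+[CIT]/k_i2)`;
#' xylose capacity `v_X1 + v_X2` with the carrier term zero while
#' `[GLC] > glucose_gate`; external phosphate is taken up *at* capacity
#' (luxury uptake: surplus is banked into the store via its exchange);
#' the store is only drawn on once external phosphate is exhausted.
#' When `dt` is given every uptake capacity is additionally clipped to
#' `pool/(X*dt)` so an Euler step cannot drive a pool negative.
#'
#' @param state a `culture_state`.
#' @param params a `kinetic_parameters`.
#' @param exchange_map named list of exchange reaction ids with keys
#'   `glucose`, `xylose`, `phosphate_ext`, `phosphate_store`, `citrate`,
#'   and optionally `co2`.
#' @param dt Euler step (h) for pool-depletion clipping, or `NULL`.
#' @return named list `reaction_id -> c(lb, ub)`.
#' @export
uptake_bounds <- function(state, params, exchange_map, dt = NULL) {
  conc <- state$concentrations
  if (any(conc < 0)) stop("negative concentration in state")
  glc <- conc[["glucose"]]
  xyl <- conc[["xylose"]]
  pie <- conc[["phosphate_ext"]]
  cit <- if ("citrate" %in% names(conc)) conc[["citrate"]] else 0
  X <- state$biomass
  clip <- function(cap, pool) {
    if (is.null(dt)) cap else min(cap, pool / (X * dt))
  }
  big <- default_bound()

  v_g <- params$g_passive_coeff * glc +
    params$v_g2_max * glc / (params$k_g2 + glc) / (1 + cit / params$k_i2)
  v_x <- params$x_passive_coeff * xyl +
    if (glc > params$glucose_gate) 0 else
      params$v_x2_max * xyl / (params$k_x2 + xyl)
  v_pe <- params$v_pe_max * pie / (params$k_pe + pie)

  b <- list()
  b[[exchange_map$glucose]] <- c(-clip(v_g, glc), 0)
  b[[exchange_map$xylose]] <- c(-clip(v_x, xyl), 0)
  # forced luxury uptake of external phosphate; the equality makes surplus
  # phosphate flow out through the store exchange
  vpe <- clip(v_pe, pie)
  b[[exchange_map$phosphate_ext]] <- c(-vpe, -vpe)
  if (pie > 1e-6) {
    b[[exchange_map$phosphate_store]] <- c(0, big)
  } else {
    v_ps <- params$v_p_max * state$pi_store / (params$k_p + state$pi_store)
    b[[exchange_map$phosphate_store]] <- c(-clip(v_ps, state$pi_store), 0)
  }
  b[[exchange_map$citrate]] <- c(0, big)
  if (!is.null(exchange_map$co2)) b[[exchange_map$co2]] <- c(0, big)
  b
}

#' Scheduled citrate output cap
#'
#' @param t clock time (h); the clock starts at `params$start_time`.
#' @param params a `kinetic_parameters`.
#' @param constrained logical; when `FALSE` the cap never applies.
#' @return upper bound for the citrate exchange flux: `v_cit_cap` once
#'   `t >= start_time + cap_delay` in a constrained run, otherwise the
#'   default open bound.
#' @export
citrate_cap_schedule <- function(t, params, constrained) {
  if (constrained && t >= params$start_time + params$cap_delay)
    params$v_cit_cap
  else default_bound()
}

#' One Euler step of dynamic FBA
#'
#' Solves the FBA problem under the state-dependent exchange bounds with a
#' lexicographic objective (maximize growth, then maximize citrate at the
#' fixed growth optimum), then advances biomass
#' `X <- X * (1 + mu*dt)` and every mapped pool
#' `C <- C + v * X * dt` (mmol gDW^-1 h^-1 x g/L x h = mM); the internal
#' store is advanced by its exchange flux. Pools are floored at zero
#' (uptake clipping makes this a numerical guard only).
#'
#' @param state a `culture_state`.
#' @param model a `metabolic_model`.
#' @param params a `kinetic_parameters`.
#' @param exchange_map see [uptake_bounds()].
#' @param dt Euler step (h).
#' @param constrained logical; apply the scheduled citrate cap.
#' @return list with the advanced `state` and the step's `fluxes`
#'   (named vector at the tracked exchanges plus growth rate `mu`).
#' @export
euler_step <- function(state, model, params, exchange_map, dt,
                       constrained = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  bounds <- uptake_bounds(state, params, exchange_map, dt = dt)
  cap <- citrate_cap_schedule(state$t, params, constrained)
  bounds[[exchange_map$citrate]][2] <- min(bounds[[exchange_map$citrate]][2], cap)

  s1 <- solve_fba(model, bounds, objective = model$biomass_id, sense = "max")
  if (s1$status != "optimal")
    stop("dynamic FBA step infeasible at t = ", format(state$t),
         " (status ", s1$status, ")")
  mu <- s1$objective_value
  bounds2 <- bounds
  bounds2[[model$biomass_id]] <- c(mu - max(1e-9, 1e-7 * abs(mu)), mu)
  s2 <- solve_fba(model, bounds2, objective = exchange_map$citrate,
                  sense = "max")
  v <- if (s2$status == "optimal") s2$fluxes else s1$fluxes

  X <- state$biomass
  conc <- state$concentrations
  for (key in names(conc)) {
    rid <- exchange_map[[key]]
    if (is.null(rid)) next
    conc[[key]] <- max(0, conc[[key]] + v[[rid]] * X * dt)
  }
  store <- max(0, state$pi_store + v[[exchange_map$phosphate_store]] * X * dt)
  newstate <- culture_state(t = state$t + dt,
                            biomass = X * (1 + mu * dt),
                            concentrations = conc, pi_store = store)
  tracked <- unlist(exchange_map)
  list(state = newstate,
       fluxes = c(setNames(v[tracked], names(tracked)), mu = mu))
}

#' Simulate a batch fermentation by dynamic FBA
#'
#' Euler time-stepping of [euler_step()] from an initial culture state.
#' The clock starts at `params$start_time`.
#'
#' @param model a `metabolic_model`.
#' @param params a `kinetic_parameters`.
#' @param init a `culture_state` (its `t` is overridden by
#'   `params$start_time`).
#' @param duration simulated hours.
#' @param dt Euler step (default 0.01 h).
#' @param constrained logical; apply the scheduled citrate cap.
#' @param exchange_map see [uptake_bounds()].
#' @param record_every record every n-th step (default 10) besides the
#'   first and last.
#' @return data.frame of class `dfba_trajectory`: `t_h`, `biomass_gL`,
#'   one column per pool (mM), `pi_store`, and the tracked exchange fluxes
#'   (`flux_` prefix) plus `mu`.
#' @export
simulate_batch <- function(model, params, init, duration, dt = 0.01,
                           constrained = FALSE, exchange_map,
                           record_every = 10L) {
  n <- max(1L, round(duration / dt))
  state <- init
  state$t <- params$start_time
  rows <- vector("list", floor(n / record_every) + 2L)
  k <- 0L
  snap <- function(state, fluxes) {
    c(t_h = state$t, biomass_gL = state$biomass,
      state$concentrations, pi_store = state$pi_store,
      if (!is.null(fluxes)) setNames(fluxes, paste0("flux_", names(fluxes))))
  }
  zero_flux <- setNames(rep(NA_real_, length(exchange_map) + 1L),
                        c(names(exchange_map), "mu"))
  k <- k + 1L; rows[[k]] <- snap(state, zero_flux)
  for (i in seq_len(n)) {
    step <- euler_step(state, model, params, exchange_map, dt, constrained)
    state <- step$state
    if (i %% record_every == 0L || i == n) {
      k <- k + 1L
      rows[[k]] <- snap(state, step$fluxes)
    }
  }
  traj <- as.data.frame(do.call(rbind, rows[seq_len(k)]))
  attr(traj, "dt") <- dt
  attr(traj, "constrained") <- constrained
  class(traj) <- c("dfba_trajectory", "data.frame")
  traj
}

#' Write a trajectory as CSV
#' @param traj a `dfba_trajectory`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#' @param path file path.
#' @return data.frame.
#' @export
read_trajectory_csv <- function(path) utils::read.csv(path)
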