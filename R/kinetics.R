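#' Right-hand side of the metabolic ODE system
#'
#' Reference (pure R) implementation of the coupled Michaelis-Menten
#' equations.  With `v_ij(x) = kcat_i * E_ij * x / (x + Km)` and writing `S`
#' for the substrate of each pathway's first step:
#' \deqn{dS/dt = \sum_i S_{in,i} - \sum_i v_{i,1}(S)}
#' \deqn{dP_{i,j}/dt = v_{i,j}(P_{i,j-1}) - v_{i,j+1}(P_{i,j}), \quad j < n}
#' \deqn{dP_{i,n}/dt = (1-\sigma_i)\, v_{i,n}(P_{i,n-1}) + f_i}
#' with secreted and imported amounts accumulating as
#' `dQ_i/dt = sigma_i v_{i,n}` and `dF_i/dt = f_i`.  Knocked-out pathways
#' have no enzymes, hence contribute no `v` terms; the inflow term is kept,
#' so their share of substrate is redistributed to the remaining pathways.
#'
#' This function is the specification of the dynamics; production runs use a
#' compiled RK4 integrator over the piecewise-constant enzyme segments.
#'
#' @param state list with `S` (substrate pool) and `P` (`p x n` matrix of
#'   metabolite pools).
#' @param enzymes `p x n` matrix of enzyme counts at the current time.
#' @param kinetics a [kinetic_params()] object.
#' @param exchange an [exchange_params()] object.
#' @return list with `dS`, `dP` (`p x n`), `dQ`, `dF` (length `p`).
#' @export
metabolic_rhs <- function(state, enzymes, kinetics, exchange = NULL) {
  p <- kinetics$p; n <- kinetics$n
  if (is.null(exchange)) exchange <- exchange_params(p)
  E <- as.matrix(enzymes)
  stopifnot(all(dim(E) == c(p, n)))
  E[exchange$knockout, ] <- 0
  kcat <- kinetics$kcat * kinetics$kcat_multiplier
  Km <- kinetics$km
  mm <- function(x) ifelse(x > 0, x / (x + Km), 0)
  S <- state$S
  P <- state$P
  v <- matrix(0, p, n)  # v[i, j] = rate of step j of pathway i
  for (i in seq_len(p)) {
    subs <- c(S, P[i, seq_len(n - 1)])[seq_len(n)]
    v[i, ] <- kcat[i] * E[i, ] * mm(subs)
  }
  dS <- sum(kinetics$s_in) - sum(v[, 1])
  dP <- matrix(0, p, n)
  if (n > 1) dP[, seq_len(n - 1)] <- v[, seq_len(n - 1), drop = FALSE] -
      v[, 2:n, drop = FALSE]
  dP[, n] <- (1 - exchange$secretion_ratio) * v[, n] + exchange$feed_rate
  list(dS = dS, dP = dP, dQ = exchange$secretion_ratio * v[, n],
       dF = exchange$feed_rate)
}

#' Integrate one cell cycle of the metabolic ODEs
#'
#' Integrates substrate and metabolite pools with piecewise-constant enzyme
#' counts (zero-order hold; integration restarts at every enzyme-count
#' breakpoint so the solver never smooths a jump) and stops at the first
#' time every pathway's final pool meets its division target.  The event
#' time is located by bisection to a relative tolerance of `event_rel_tol`.
#'
#' @param state a `cell_state` (see [new_cell_state()]).
#' @param enzymes either a `p x n` matrix of constant enzyme counts, or a
#'   list with `breaks` (segment boundaries, starting at 0) and `E` (matrix
#'   with one row per segment and `p * n` columns ordered pathway-major).
#' @param kinetics a [kinetic_params()] object.
#' @param exchange an [exchange_params()] object.
#' @param targets per-pathway final-pool targets from [division_targets()].
#' @param horizon integration horizon in cycle time (s); required when
#'   `enzymes` is a constant matrix.
#' @param h_max maximum integrator step (s).
#' @param event_rel_tol relative tolerance for the division-event time.
#' @param save_dt if positive, sample the trajectory about every `save_dt` s.
#' @return an `integration_result`: list with `division_time` (cycle time,
#'   `NA` if the horizon was reached first), `S`, `P`, `Q`, `F`, `V`
#'   (cumulative final-step production), `event_pathway` (last pathway to
#'   cross, ties to the lowest index), `crossing_times`, `n_steps`, and
#'   optionally `traj`.
#' @export
integrate_cycle <- function(state, enzymes, kinetics, exchange = NULL,
                            targets, horizon = NULL, h_max = 1,
                            event_rel_tol = 1e-8, save_dt = 0) {
  p <- kinetics$p; n <- kinetics$n
  if (is.null(exchange)) exchange <- exchange_params(p)
  if (!is.list(enzymes)) {
    if (is.null(horizon))
      stop("horizon is required with constant enzyme counts", call. = FALSE)
    E <- as.matrix(enzymes)
    stopifnot(all(dim(E) == c(p, n)))
    E[exchange$knockout, ] <- 0
    enzymes <- list(breaks = c(0, horizon),
                    E = matrix(as.vector(t(E)), nrow = 1))
  }
  stopifnot(length(targets) == p, all(is.finite(targets)))
  kcat <- kinetics$kcat * kinetics$kcat_multiplier
  res <- integrate_cycle_cpp(enzymes$breaks, t(enzymes$E),
                             state$S, as.vector(t(state$P)),
                             p, n, sum(kinetics$s_in), kcat, kinetics$km,
                             exchange$secretion_ratio, exchange$feed_rate,
                             as.numeric(targets), h_max, event_rel_tol,
                             save_dt)
  y <- res$y_end
  out <- list(division_time = res$division_time,
              t_end = res$t_end,
              S = y[1],
              P = matrix(y[2:(1 + p * n)], p, n, byrow = TRUE),
              Q = y[(2 + p * n):(1 + p * n + p)],
              F = y[(2 + p * n + p):(1 + p * n + 2 * p)],
              V = y[(2 + p * n + 2 * p):(1 + p * n + 3 * p)],
              event_pathway = res$event_pathway,
              crossing_times = res$crossing_times,
              n_steps = res$n_steps)
  if (!is.null(res$traj)) {
    traj <- as.data.frame(res$traj)
    names(traj) <- c("t", "S",
                     paste0("P_", rep(seq_len(p), each = n), "_",
                            rep(seq_len(n), p)),
                     paste0("Q_", seq_len(p)), paste0("F_", seq_len(p)),
                     paste0("V_", seq_len(p)))
    out$traj <- traj
  }
  class(out) <- "integration_result"
  out
}

#' @export
print.integration_result <- function(x, ...) {
  if (is.na(x$division_time))
    cat(sprintf("<integration_result> no division by t = %g s (%g steps)\n",
                x$t_end, x$n_steps))
  else
    cat(sprintf(
      "<integration_result> division at t = %g s (pathway %d last to cross)\n",
      x$division_time, x$event_pathway))
  invisible(x)
}
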