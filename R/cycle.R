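#' Create a cell state
#'
#' The state of one cell at birth: substrate pool, `p x n` metabolite pools,
#' inherited mRNA and enzyme counts (kept as real numbers across perfect
#' halving; rounded to the nearest integer only where molecules are
#' enumerated), and the birth time.  The simulation starts from the all-zero
#' state.
#'
#' @param p number of pathways.
#' @param n steps per pathway.
#' @param S substrate pool (molecules).
#' @param P `p x n` matrix of metabolite pools.
#' @param mrna length-`p` vector of mRNA counts (one operon per pathway).
#' @param prot `p x n` matrix of enzyme counts.
#' @param birth_time absolute birth time (s).
#' @return an object of class `cell_state`.
#' @export
new_cell_state <- function(p, n, S = 0, P = matrix(0, p, n),
                           mrna = rep(0, p), prot = matrix(0, p, n),
                           birth_time = 0) {
  P <- as.matrix(P); prot <- as.matrix(prot)
  stopifnot(all(dim(P) == c(p, n)), all(dim(prot) == c(p, n)),
            length(mrna) == p, S >= 0, all(P >= 0), all(mrna >= 0),
            all(prot >= 0))
  structure(list(p = p, n = n, S = S, P = P, mrna = mrna, prot = prot,
                 birth_time = birth_time, birth_pools = P[, n],
                 Q = rep(0, p), F = rep(0, p)),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> p = %d, n = %d, born at %g s\n", x$p, x$n,
              x$birth_time))
  cat(sprintf("  S = %g; final pools: %s\n", x$S,
              paste(format(x$P[, x$n], digits = 4), collapse = ", ")))
  invisible(x)
}

#' Per-pathway division targets
#'
#' Translates the division rule into absolute final-pool levels given the
#' pools at birth: the Adder requires producing a fixed `threshold` on top
#' of the inherited pool (`target = birth + threshold`); the Sizer requires
#' the pool to reach the absolute `threshold`
#' (`target = max(threshold, birth)`, so a pathway born above threshold is
#' divide-ready immediately).
#'
#' @param rule a [division_rule()] object.
#' @param birth_pools per-pathway final pools at birth (non-negative).
#' @return per-pathway target pool levels.
#' @export
division_targets <- function(rule, birth_pools) {
  stopifnot(inherits(rule, "division_rule"), all(birth_pools >= 0))
  thr <- rep(rule$threshold, length.out = length(birth_pools))
  if (rule$kind == "adder") birth_pools + thr else pmax(thr, birth_pools)
}

#' Divide a cell into two daughters
#'
#' Perfect halving: every pool (substrate, all metabolites, mRNA and enzyme
#' counts) is split exactly in half; cumulative secreted/imported counters
#' reset to zero; each daughter records its birth pools for the next cycle's
#' targets.  Daughters generate their own, independent burst schedules when
#' they are next simulated.
#'
#' @param state the `cell_state` at division.
#' @param targets per-pathway division targets; if supplied, the final pools
#'   are checked against them (to a 1e-6 relative tolerance) and calling
#'   [divide_cell()] on a non-dividing state is an error.
#' @param at absolute division time, used as the daughters' birth time;
#'   defaults to the state's own birth time.
#' @return list of two `cell_state` objects, `A` and `B`.
#' @export
divide_cell <- function(state, targets = NULL, at = NULL) {
  stopifnot(inherits(state, "cell_state"))
  if (!is.null(targets)) {
    ok <- state$P[, state$n] >= targets * (1 - 1e-6)
    if (!all(ok))
      stop("divide_cell() called on a non-dividing state: pathway ",
           which(!ok)[1], " below its division target", call. = FALSE)
  }
  if (is.null(at)) at <- state$birth_time
  daughter <- new_cell_state(state$p, state$n, S = state$S / 2,
                             P = state$P / 2, mrna = state$mrna / 2,
                             prot = state$prot / 2, birth_time = at)
  list(A = daughter, B = daughter)
}

#' Doubling time from generation time and size ratio
#'
#' `T_mu = T_div / log2(size_div / size_birth)`.  With exact division rules
#' and perfect halving the size ratio is 2, so generation time and doubling
#' time coincide.
#'
#' @param generation_time time between birth and division.
#' @param size_at_division,size_at_birth cell size proxies (final metabolite
#'   pools); must be positive with `size_at_division > size_at_birth`.
#' @return the doubling time, in the units of `generation_time`.
#' @export
doubling_time <- function(generation_time, size_at_division, size_at_birth) {
  if (any(size_at_birth <= 0) || any(size_at_division <= 0))
    stop("sizes must be positive", call. = FALSE)
  if (any(size_at_division <= size_at_birth))
    stop("size_at_division must exceed size_at_birth", call. = FALSE)
  generation_time / log2(size_at_division / size_at_birth)
}

#' Simulate one full cell cycle
#'
#' Seeds the cell's own RNG stream, draws the burst/expression realisation,
#' integrates the metabolic ODEs and stops at division.  If the initial
#' expression horizon is reached without division the realisation is
#' continued (never regenerated) and integration retried, up to the
#' configured `max_cycle_time`, after which the cell is flagged
#' non-dividing.
#'
#' @param state the newborn `cell_state`.
#' @param config a [growth_config()] object.
#' @param cell_seed integer seed for this cell's stream (see
#'   [derive_seed()]).
#' @return a list with `divided` (logical), `generation_time`,
#'   `division_time` (absolute), `event_pathway`, per-pathway `produced`,
#'   `secreted`, `imported`, the `cell_state` at division (`state_div`,
#'   carrying its `targets`), and solver diagnostics.
#' @export
simulate_cycle <- function(state, config, cell_seed = config$seed) {
  stopifnot(inherits(state, "cell_state"), inherits(config, "growth_config"))
  p <- config$kinetics$p; n <- config$kinetics$n
  set.seed(cell_seed)
  targets <- division_targets(config$rule, state$birth_pools)
  horizon <- config$plan$initial_horizon
  if (is.null(horizon)) {
    # best-case time to produce what this cycle still needs, with headroom
    need <- pmax(targets - state$birth_pools, 0.05 * targets)
    horizon <- 2.5 * max(need / .limit_rates(config))
  }
  max_t <- .max_cycle_time(config)
  horizon <- min(horizon, max_t)
  deterministic <- !is.null(config$constant_enzymes)
  gen <- NULL
  if (!deterministic) gen <- .generate_expression(config, state, horizon)
  extensions <- 0L
  repeat {
    enz <- if (deterministic) {
      list(breaks = c(0, horizon),
           E = matrix(as.vector(t(config$constant_enzymes)), nrow = 1))
    } else .collate_enzymes(gen, config, state, horizon)
    res <- integrate_cycle(state, enz, config$kinetics, config$exchange,
                           targets, h_max = if (deterministic) 5 else 1)
    if (!is.na(res$division_time)) break
    if (horizon >= max_t) {
      return(list(divided = FALSE, generation_time = NA_real_,
                  division_time = NA_real_, event_pathway = NA_integer_,
                  produced = res$V, secreted = res$Q, imported = res$F,
                  state_div = NULL, extensions = extensions,
                  n_steps = res$n_steps))
    }
    horizon <- min(2 * horizon, max_t)
    if (!deterministic) gen <- .extend_expression(gen, config, horizon)
    extensions <- extensions + 1L
  }
  tdiv <- res$division_time
  if (deterministic) {
    mrna_div <- state$mrna
    prot_div <- config$constant_enzymes
  } else {
    mrna_div <- vapply(seq_len(p), function(i)
      .alive_at(gen$mrna[[i]]$birth, gen$mrna[[i]]$death, tdiv), numeric(1))
    prot_div <- matrix(0, p, n)
    for (i in seq_len(p)) {
      pr <- gen$prot[[i]]
      for (j in seq_len(n)) {
        sel <- pr$step == j
        prot_div[i, j] <- round(state$prot[i, j]) -
          sum(gen$inherited_prot_deaths[[i]][[j]] <= tdiv) +
          .alive_at(pr$birth[sel], pr$death[sel], tdiv)
      }
    }
  }
  state_div <- new_cell_state(p, n, S = res$S, P = res$P, mrna = mrna_div,
                              prot = prot_div, birth_time = state$birth_time)
  state_div$birth_pools <- state$birth_pools  # pools at cycle start
  state_div$Q <- res$Q
  state_div$F <- res$F
  state_div$targets <- targets
  list(divided = TRUE, generation_time = tdiv,
       division_time = state$birth_time + tdiv,
       event_pathway = res$event_pathway,
       produced = res$V, secreted = res$Q, imported = res$F,
       state_div = state_div, targets = targets,
       crossing_times = res$crossing_times,
       extensions = extensions, n_steps = res$n_steps)
}
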