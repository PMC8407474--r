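# Shared fixtures: small simulation plans and an independent fixed-step
# Euler integrator used as an oracle against the package's RK4 core.

quick_plan <- function(burn = 20, g = 6, reps = 1) {
  simulation_plan(burn_in_generations = burn, tree_generations = g,
                  replicates = reps)
}

# deterministic constant-enzyme cell: closed-form behaviour, no RNG
det_config <- function(E = 40, p = 3, n = 3, s_in = 9000, kcat = 300,
                       rule = division_rule("sizer"), burn = 10, g = 3,
                       reps = 1, km = 6e4) {
  growth_config(kinetics = kinetic_params(p = p, n = n, s_in = s_in,
                                          kcat = kcat, km = km),
                rule = rule, plan = quick_plan(burn, g, reps),
                constant_enzymes = E)
}

# explicit fixed-step Euler on the same RHS definition, written against the
# R reference metabolic_rhs(); independent of the compiled RK4 path
euler_oracle <- function(state, enzymes, kinetics, exchange = NULL,
                         t_end, h = 0.01) {
  if (is.null(exchange)) exchange <- exchange_params(kinetics$p)
  S <- state$S; P <- state$P
  Q <- rep(0, kinetics$p); F <- rep(0, kinetics$p)
  nstep <- ceiling(t_end / h)
  h <- t_end / nstep
  for (k in seq_len(nstep)) {
    d <- metabolic_rhs(list(S = S, P = P), enzymes, kinetics, exchange)
    S <- max(S + h * d$dS, 0)
    P <- pmax(P + h * d$dP, 0)
    Q <- Q + h * d$dQ
    F <- F + h * d$dF
  }
  list(S = S, P = P, Q = Q, F = F)
}
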