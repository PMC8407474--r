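#' Sample a transcription-burst schedule
#'
#' Alternating OFF/ON segments, starting with an OFF draw, with iid
#' exponential durations of the configured means, generated iteratively
#' until the horizon is covered.  The returned `intervals` are the ON
#' windows truncated at the horizon; the raw (untruncated) segment sequence
#' is retained internally so a schedule can later be *continued* past the
#' horizon rather than regenerated.
#'
#' @param params an [expression_params()] object.
#' @param horizon simulation window length (s), > 0.
#' @return an object of class `burst_schedule` with fields `intervals`
#'   (data frame of `start`, `end` ON windows) and `horizon`.
#' @export
sample_burst_schedule <- function(params, horizon) {
  stopifnot(inherits(params, "expression_params"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be a single positive number", call. = FALSE)
  sched <- structure(list(intervals = NULL, horizon = horizon,
                          durations = numeric(0)),
                     class = "burst_schedule")
  .extend_schedule(sched, params, horizon)
}

# continue drawing OFF/ON pairs until the raw sequence covers new_horizon
.extend_schedule <- function(sched, params, new_horizon) {
  dur <- sched$durations
  total <- sum(dur)
  while (total < new_horizon) {
    pair <- c(stats::rexp(1, 1 / params$mean_t_off),
              stats::rexp(1, 1 / params$mean_t_on))
    dur <- c(dur, pair)
    total <- total + sum(pair)
  }
  sched$durations <- dur
  sched$horizon <- new_horizon
  sched$intervals <- .on_windows(dur, clip = new_horizon)
  sched
}

# ON windows from the alternating duration sequence (odd = OFF, even = ON)
.on_windows <- function(durations, clip = Inf) {
  if (!length(durations)) return(data.frame(start = numeric(0), end = numeric(0)))
  ends <- cumsum(durations)
  on_idx <- seq(2, length(durations), by = 2)
  start <- ends[on_idx - 1]
  end <- ends[on_idx]
  keep <- start < clip
  data.frame(start = start[keep], end = pmin(end[keep], clip))
}

# raw (unclipped) ON windows, for transcript generation and continuation
.on_windows_raw <- function(sched) .on_windows(sched$durations, clip = Inf)

#' @export
print.burst_schedule <- function(x, ...) {
  cat(sprintf("<burst_schedule> %d ON window(s) over %g s\n",
              nrow(x$intervals), x$horizon))
  invisible(x)
}

#' Simulate transcription over a burst schedule
#'
#' Within each ON window transcripts initiate at the constant rate
#' `mrna_rate_on` (regularly spaced, the first at the window start); a
#' transcript becomes an mRNA only if elongation completes before the window
#' closes, so windows shorter than `txn_elongation_time` yield nothing.
#' Each completed mRNA receives an exponential lifetime.
#'
#' @param schedule a [sample_burst_schedule()] result, or a data frame of ON
#'   windows with columns `start` and `end`.
#' @param params an [expression_params()] object.
#' @return a data frame of mRNA events with columns `birth` (completion
#'   time) and `death`.
#' @export
simulate_transcription <- function(schedule, params) {
  stopifnot(inherits(params, "expression_params"))
  win <- if (inherits(schedule, "burst_schedule"))
    .on_windows_raw(schedule) else as.data.frame(schedule)
  tau <- params$txn_elongation_time
  delta <- 1 / params$mrna_rate_on
  len <- win$end - win$start
  m <- ifelse(len >= tau, floor((len - tau) / delta) + 1, 0)
  if (!length(m) || sum(m) == 0)
    return(data.frame(birth = numeric(0), death = numeric(0)))
  init <- rep(win$start, m) + (sequence(m) - 1) * delta
  birth <- init + tau
  death <- birth + stats::rexp(length(birth), 1 / params$mean_mrna_lifetime)
  data.frame(birth = birth, death = death)
}

#' Simulate translation of mRNA events
#'
#' A single ribosome translates each mRNA back-to-back from its birth, one
#' completed protein every `tln_time_per_protein`; the protein in progress
#' when the mRNA decays is lost, so an mRNA of lifetime L yields
#' `floor(L / tln_time_per_protein)` proteins.  Because the `n` enzymes of a
#' pathway sit on one operon, each completed translation round emits one
#' copy of each of the `n_steps` enzyme species, every copy with its own
#' exponential lifetime.
#'
#' @param mrna_events data frame with columns `birth` and `death`.
#' @param params an [expression_params()] object.
#' @param n_steps number of operon enzyme species (pathway steps).
#' @return a data frame of protein events with columns `step`, `birth`,
#'   `death`.
#' @export
simulate_translation <- function(mrna_events, params, n_steps = 1L) {
  stopifnot(inherits(params, "expression_params"), n_steps >= 1)
  life <- mrna_events$death - mrna_events$birth
  if (any(life <= 0)) stop("mRNA events must have death > birth", call. = FALSE)
  tau <- params$tln_time_per_protein
  k <- floor(life / tau)
  tot <- sum(k)
  if (!length(k) || tot == 0)
    return(data.frame(step = integer(0), birth = numeric(0), death = numeric(0)))
  completion <- rep(mrna_events$birth, k) + sequence(k) * tau
  birth <- rep(completion, each = n_steps)
  step <- rep.int(seq_len(n_steps), tot)
  death <- birth + stats::rexp(length(birth), 1 / params$mean_protein_lifetime)
  data.frame(step = step, birth = birth, death = death)
}

#' Build an enzyme copy-number trajectory
#'
#' Zero-order-hold step function counting live enzyme molecules of one
#' species over a cell cycle: inherited copies plus completed translations,
#' minus decays.  Inherited molecules receive fresh exponential lifetimes
#' from `cycle_start` (exact by memorylessness).
#'
#' @param protein_events data frame with columns `birth`, `death` for this
#'   species (absolute times).
#' @param inherited non-negative count of molecules present at `cycle_start`.
#' @param cycle_start start time of the cycle.
#' @param horizon end time of the trajectory.
#' @param mean_protein_lifetime mean lifetime for inherited-molecule decay
#'   draws; `NULL` (or `Inf`) makes inherited molecules immortal.
#' @return an object of class `enzyme_trajectory`: list with `breakpoints`
#'   (ordered times from `cycle_start` to `horizon`) and `counts` (copy
#'   number on each interval, right-continuous).
#' @export
build_enzyme_trajectory <- function(protein_events, inherited = 0,
                                    cycle_start = 0, horizon,
                                    mean_protein_lifetime = NULL) {
  if (inherited < 0) stop("inherited count must be >= 0", call. = FALSE)
  inherited <- round(inherited)
  deaths_inh <- numeric(0)
  if (inherited > 0 && !is.null(mean_protein_lifetime) &&
      is.finite(mean_protein_lifetime))
    deaths_inh <- cycle_start +
      stats::rexp(inherited, 1 / mean_protein_lifetime)
  births <- protein_events$birth
  deaths <- c(protein_events$death, deaths_inh)
  ev_t <- c(births, deaths)
  ev_d <- c(rep.int(1L, length(births)), rep.int(-1L, length(deaths)))
  keep <- ev_t > cycle_start & ev_t < horizon
  ev_t <- ev_t[keep]; ev_d <- ev_d[keep]
  o <- order(ev_t, -ev_d)  # births before deaths at identical times
  ev_t <- ev_t[o]; ev_d <- ev_d[o]
  breakpoints <- c(cycle_start, ev_t, horizon)
  counts <- inherited + c(0, cumsum(ev_d))
  dup <- duplicated(breakpoints[-length(breakpoints)], fromLast = TRUE)
  if (any(dup)) {
    breakpoints <- c(breakpoints[-length(breakpoints)][!dup], horizon)
    counts <- counts[!dup]
  }
  if (any(counts < 0))
    stop("negative enzyme count: death events without matching molecules",
         call. = FALSE)
  structure(list(breakpoints = breakpoints, counts = counts),
            class = "enzyme_trajectory")
}

#' Evaluate an enzyme trajectory
#'
#' @param traj an `enzyme_trajectory`.
#' @param t times at which to read the (right-continuous) copy number.
#' @return integer copy numbers.
#' @export
trajectory_at <- function(traj, t) {
  idx <- findInterval(t, traj$breakpoints, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(traj$counts)] <- length(traj$counts)
  traj$counts[idx]
}

#' @export
print.enzyme_trajectory <- function(x, ...) {
  cat(sprintf("<enzyme_trajectory> %d segment(s) on [%g, %g], counts %d..%d\n",
              length(x$counts), x$breakpoints[1],
              x$breakpoints[length(x$breakpoints)],
              min(x$counts), max(x$counts)))
  invisible(x)
}

# ---- per-cycle expression machinery (internal) ----------------------------

# Generate the full expression realisation of one cell cycle (relative time,
# 0 = birth) out to `horizon`.  Event times are NOT clipped: deaths and
# translation rounds beyond the horizon are kept so the realisation can be
# continued exactly if the horizon is later extended.
.generate_expression <- function(cfg, state, horizon) {
  p <- cfg$kinetics$p; n <- cfg$kinetics$n
  ex <- cfg$expression
  gen <- list(schedules = vector("list", p), mrna = vector("list", p),
              prot = vector("list", p), windows_done = integer(p),
              inherited_prot_deaths = vector("list", p))
  for (i in seq_len(p)) {
    if (cfg$exchange$knockout[i]) {
      gen$mrna[[i]] <- data.frame(birth = numeric(0), death = numeric(0))
      gen$prot[[i]] <- data.frame(step = integer(0), birth = numeric(0),
                                  death = numeric(0))
      next
    }
    # inherited mRNAs: alive at birth, fresh lifetimes (memoryless)
    m_inh <- round(state$mrna[i])
    mrna_inh <- if (m_inh > 0)
      data.frame(birth = rep(0, m_inh),
                 death = stats::rexp(m_inh, 1 / ex$mean_mrna_lifetime))
    else data.frame(birth = numeric(0), death = numeric(0))
    sched <- sample_burst_schedule(ex, horizon)
    win <- .on_windows_raw(sched)
    mrna_new <- simulate_transcription(win, ex)
    mrna <- rbind(mrna_inh, mrna_new)
    prot <- simulate_translation(mrna, ex, n_steps = n)
    # inherited proteins: fresh exponential death times per step
    deaths_inh <- lapply(seq_len(n), function(j) {
      cnt <- round(state$prot[i, j])
      if (cnt > 0) stats::rexp(cnt, 1 / ex$mean_protein_lifetime) else numeric(0)
    })
    gen$schedules[[i]] <- sched
    gen$mrna[[i]] <- mrna
    gen$prot[[i]] <- prot
    gen$windows_done[i] <- nrow(win)
    gen$inherited_prot_deaths[[i]] <- deaths_inh
  }
  gen
}

# Continue an expression realisation to a larger horizon: the burst schedule
# is extended (not redrawn) and only the newly appearing ON windows generate
# new transcripts and translations.
.extend_expression <- function(gen, cfg, new_horizon) {
  p <- cfg$kinetics$p; n <- cfg$kinetics$n
  ex <- cfg$expression
  for (i in seq_len(p)) {
    if (cfg$exchange$knockout[i]) next
    gen$schedules[[i]] <- .extend_schedule(gen$schedules[[i]], ex, new_horizon)
    win <- .on_windows_raw(gen$schedules[[i]])
    done <- gen$windows_done[i]
    if (nrow(win) > done) {
      new_win <- win[(done + 1):nrow(win), , drop = FALSE]
      mrna_new <- simulate_transcription(new_win, ex)
      if (nrow(mrna_new)) {
        gen$mrna[[i]] <- rbind(gen$mrna[[i]], mrna_new)
        gen$prot[[i]] <- rbind(gen$prot[[i]],
                               simulate_translation(mrna_new, ex, n_steps = n))
      }
      gen$windows_done[i] <- nrow(win)
    }
  }
  gen
}

# number of live molecules at time t given births/deaths (right-continuous)
.alive_at <- function(births, deaths, t) {
  sum(births <= t) - sum(deaths <= t)
}

# Collate per-(pathway, step) events into shared segment boundaries and an
# enzyme-count matrix for the integrator.  inherited: p x n matrix of counts
# at cycle start (already rounded); inherited deaths drawn in `gen`.
.collate_enzymes <- function(gen, cfg, state, horizon) {
  p <- cfg$kinetics$p; n <- cfg$kinetics$n
  births <- vector("list", p * n)
  deaths <- vector("list", p * n)
  inh <- integer(p * n)
  for (i in seq_len(p)) {
    pr <- gen$prot[[i]]
    for (j in seq_len(n)) {
      k <- (i - 1L) * n + j
      sel <- pr$step == j
      births[[k]] <- pr$birth[sel]
      deaths[[k]] <- c(pr$death[sel], gen$inherited_prot_deaths[[i]][[j]])
      inh[k] <- round(state$prot[i, j])
    }
  }
  all_t <- unlist(c(births, deaths), use.names = FALSE)
  all_t <- all_t[all_t > 0 & all_t < horizon]
  breaks <- c(0, sort(unique(all_t)), horizon)
  heads <- breaks[-length(breaks)]
  E <- matrix(0, nrow = length(heads), ncol = p * n)
  for (k in seq_len(p * n)) {
    nb <- findInterval(heads, sort(births[[k]]))
    nd <- findInterval(heads, sort(deaths[[k]]))
    E[, k] <- inh[k] + nb - nd
  }
  if (any(E < 0))
    stop("internal error: negative enzyme count in collated trajectory")
  list(breaks = breaks, E = E)
}
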