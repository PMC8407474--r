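#' Burn in a lineage to steady cycling
#'
#' Starting from the all-zero state, simulates the configured number of
#' consecutive cell cycles, always following daughter A (daughters are
#' exchangeable under perfect halving), and returns the post-burn-in newborn
#' with its birth time reset to zero.
#'
#' @param config a [growth_config()] object.
#' @param replicate replicate index, used in the cells' seed streams.
#' @return the newborn `cell_state` after burn-in.
#' @export
burn_in <- function(config, replicate = 1L) {
  p <- config$kinetics$p; n <- config$kinetics$n
  state <- new_cell_state(p, n)
  g <- config$plan$burn_in_generations
  if (g == 0L) return(state)
  for (k in seq_len(g)) {
    cyc <- simulate_cycle(state, config,
                          derive_seed(config$seed, replicate, 0L, k))
    if (!cyc$divided)
      stop("burn-in failure: cell did not divide within max_cycle_time at ",
           "generation ", k, " (replicate ", replicate, "); ",
           "check substrate supply and feed rates", call. = FALSE)
    state <- divide_cell(cyc$state_div, cyc$targets, at = cyc$division_time)$A
  }
  state$birth_time <- 0
  state
}

#' Grow a complete binary lineage tree
#'
#' Breadth-first simulation of all daughter cells for `tree_generations`
#' generations starting from one newborn, producing one record per cell
#' (`2^g - 1` records for a complete tree of depth `g`).  Each cell's
#' expression is driven by its own seed stream keyed by
#' `(replicate, cell_id)`, so the result is invariant to traversal order.
#' A cell that fails to divide within `max_cycle_time` is recorded with `NA`
#' division time and its subtree is truncated with a warning.
#'
#' @param root the newborn `cell_state` at the tree root (e.g. from
#'   [burn_in()]).
#' @param config a [growth_config()] object.
#' @param replicate replicate index, used in the cells' seed streams.
#' @return a `lineage` data frame; see [simulate_lineage()] for columns.
#' @export
grow_tree <- function(root, config, replicate = 1L) {
  stopifnot(inherits(root, "cell_state"))
  p <- config$kinetics$p
  g <- config$plan$tree_generations
  ncell <- 2L^g - 1L
  states <- vector("list", ncell)
  states[[1L]] <- root
  birth <- division <- rep(NA_real_, ncell)
  event <- rep(NA_integer_, ncell)
  produced <- secreted <- imported <- matrix(NA_real_, ncell, p)
  truncated <- 0L
  for (id in seq_len(ncell)) {
    state <- states[[id]]
    states[id] <- list(NULL)  # free as we go
    if (is.null(state)) next  # ancestor failed to divide
    cyc <- simulate_cycle(state, config,
                          derive_seed(config$seed, replicate, 1L, id))
    birth[id] <- state$birth_time
    produced[id, ] <- cyc$produced
    secreted[id, ] <- cyc$secreted
    imported[id, ] <- cyc$imported
    if (!cyc$divided) {
      truncated <- truncated + 1L
      next
    }
    division[id] <- cyc$division_time
    event[id] <- cyc$event_pathway
    if (2L * id <= ncell) {
      kids <- divide_cell(cyc$state_div, cyc$targets, at = cyc$division_time)
      states[[2L * id]] <- kids$A
      states[[2L * id + 1L]] <- kids$B
    }
  }
  if (truncated > 0L)
    warning(truncated, " cell(s) did not divide within max_cycle_time; ",
            "their subtrees were truncated", call. = FALSE)
  ids <- seq_len(ncell)
  out <- data.frame(replicate = replicate, cell_id = ids,
                    parent_id = ids %/% 2L,
                    generation = floor(log2(ids)),
                    birth_time_s = birth, division_time_s = division,
                    generation_time_s = division - birth,
                    event_pathway = event)
  colnames(produced) <- paste0("produced_", seq_len(p))
  colnames(secreted) <- paste0("secreted_", seq_len(p))
  colnames(imported) <- paste0("imported_", seq_len(p))
  out <- cbind(out, produced, secreted, imported)
  class(out) <- c("lineage", "data.frame")
  out
}

#' Simulate a full lineage experiment
#'
#' Runs burn-in followed by a complete lineage tree for each replicate and
#' stacks the per-cell records.  This is the package's main entry point.
#'
#' @param config a [growth_config()] object.
#' @return a `lineage` data frame with one row per simulated cell and
#'   columns `replicate`, `cell_id`, `parent_id`, `generation`,
#'   `birth_time_s`, `division_time_s`, `generation_time_s`,
#'   `event_pathway`, and per-pathway `produced_i`, `secreted_i`,
#'   `imported_i` totals.  The full configuration and master seed are
#'   attached as attributes for provenance.
#' @examples
#' cfg <- growth_config(
#'   plan = simulation_plan(burn_in_generations = 5, tree_generations = 4,
#'                          replicates = 1))
#' lin <- simulate_lineage(cfg)
#' nrow(lin)  # 2^4 - 1 = 15 cells
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "growth_config"))
  reps <- lapply(seq_len(config$plan$replicates), function(r) {
    root <- burn_in(config, replicate = r)
    grow_tree(root, config, replicate = r)
  })
  out <- do.call(rbind, reps)
  attr(out, "config") <- config
  attr(out, "seed") <- config$seed
  class(out) <- c("lineage", "data.frame")
  out
}

#' Extract generation times or birth times from a lineage
#'
#' @param lineage a `lineage` data frame.
#' @param drop_na drop cells flagged non-dividing.
#' @return numeric vector (seconds).
#' @export
generation_times <- function(lineage, drop_na = TRUE) {
  x <- lineage$generation_time_s
  if (drop_na) x <- x[!is.na(x)]
  x
}

#' @rdname generation_times
#' @export
birth_times <- function(lineage, drop_na = TRUE) {
  x <- lineage$birth_time_s
  if (drop_na) x <- x[!is.na(x)]
  x
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("<lineage> %d cell(s), %d replicate(s)\n", nrow(x),
              length(unique(x$replicate))))
  gt <- generation_times(x)
  if (length(gt))
    cat(sprintf("  generation time: mean %.1f s (%.2f min), CV %.3f\n",
                mean(gt), mean(gt) / 60, stats::sd(gt) / mean(gt)))
  NextMethod()
}

#' @export
summary.lineage <- function(object, ...) {
  gt <- generation_times(object)
  res <- list(n_cells = nrow(object),
              n_replicates = length(unique(object$replicate)),
              n_non_dividing = sum(is.na(object$division_time_s)),
              generation_time = summarize_generation_times(gt))
  class(res) <- "summary.lineage"
  res
}

#' @export
print.summary.lineage <- function(x, ...) {
  cat(sprintf("Lineage of %d cells (%d replicates, %d non-dividing)\n",
              x$n_cells, x$n_replicates, x$n_non_dividing))
  s <- x$generation_time
  cat(sprintf("Generation times: mean %.1f s, CV %.3f, skewness %.3f, ",
              s$mean, s$cv, s$skewness))
  cat(sprintf("excess kurtosis %.3f\n", s$kurtosis))
  invisible(x)
}

#' @export
plot.lineage <- function(x, log = TRUE, breaks = "FD", ...) {
  gt <- generation_times(x)
  if (log) {
    h <- graphics::hist(log(gt), breaks = breaks, plot = FALSE)
    graphics::plot(h, freq = FALSE, xlab = "ln generation time (s)",
                   main = "Generation-time distribution (log scale)", ...)
  } else {
    graphics::hist(gt / 60, breaks = breaks, freq = FALSE,
                   xlab = "generation time (min)",
                   main = "Generation-time distribution", ...)
  }
  invisible(x)
}
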