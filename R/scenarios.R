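#' Effective substrate inflow per consuming pathway
#'
#' Total substrate inflow is fixed at the sum of the per-pathway supply
#' rates regardless of knockouts, so deleting one of `p` pathways
#' redistributes its share over the remaining `p - 1` consumers: with equal
#' supplies, each survivor's effective flux rises by a factor
#' `p / (p - 1)` (50% for `p = 3`).
#'
#' @param kinetics a [kinetic_params()] object.
#' @param exchange an [exchange_params()] object (`NULL` = no knockouts).
#' @return inflow per consuming pathway (molecules/s).
#' @export
per_pathway_inflow <- function(kinetics, exchange = NULL) {
  if (is.null(exchange)) exchange <- exchange_params(kinetics$p)
  active <- sum(!exchange$knockout)
  if (active == 0) stop("all pathways knocked out", call. = FALSE)
  sum(kinetics$s_in) / active
}

#' Specify a simulation scenario
#'
#' A scenario is a base configuration plus sweep axes.  Kinds:
#' \describe{
#'   \item{baseline}{prototroph; sweep `s_in` and/or `p`.}
#'   \item{uptake}{constant import of one limiting metabolite (the last
#'     pathway); sweep `s_in` and `feed_rate`.}
#'   \item{secretion}{a fraction of one metabolite's production (pathway 1)
#'     is exported; sweep `s_in` and `secretion_ratio`.}
#'   \item{auxotroph}{the last pathway is deleted and its metabolite
#'     imported at `feed_rate`; total substrate inflow is kept at
#'     `p * s_in` over the remaining `p - 1` pathways.}
#'   \item{crossfeeder}{single-cell proxy for a reciprocal cross-feeder: an
#'     auxotroph (last pathway deleted, fed) that overexpresses pathway 1
#'     (`kcat` multiplied by `overexpression_factor`) and secretes
#'     `secretion_ratio` of its production.}
#' }
#'
#' @param kind scenario kind.
#' @param config base [growth_config()]; its plan (burn-in, tree depth,
#'   replicates) applies to every grid point.
#' @param s_in substrate supply values to sweep (scalar or vector).
#' @param p pathway counts to sweep (baseline only).
#' @param feed_rate import rates to sweep (molecules/s).
#' @param secretion_ratio secretion ratios to sweep.
#' @param overexpression_factor `kcat` multiplier for the secreting pathway
#'   of a cross-feeder (default 2).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("baseline", "uptake", "secretion",
                                   "auxotroph", "crossfeeder"),
                          config = growth_config(),
                          s_in = NULL, p = NULL,
                          feed_rate = 0, secretion_ratio = 0,
                          overexpression_factor = 2) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "growth_config"))
  if (is.null(s_in)) s_in <- sum(config$kinetics$s_in) / config$kinetics$p
  if (is.null(p)) p <- config$kinetics$p
  if (kind != "baseline" && length(p) > 1)
    stop("p can only be swept in the baseline scenario", call. = FALSE)
  if (kind %in% c("auxotroph", "crossfeeder")) {
    if (any(feed_rate <= 0))
      stop("an auxotroph must be fed: the knocked-out metabolite can never ",
           "reach its division threshold with feed_rate = 0", call. = FALSE)
    if (min(p) < 2)
      stop("knocking out a pathway requires p >= 2", call. = FALSE)
  }
  if (kind == "crossfeeder" && all(secretion_ratio == 0))
    secretion_ratio <- 0.5
  structure(list(kind = kind, config = config, s_in = s_in, p = p,
                 feed_rate = feed_rate, secretion_ratio = secretion_ratio,
                 overexpression_factor = overexpression_factor),
            class = "scenario_spec")
}

# build the growth_config for one grid point of a scenario
.scenario_config <- function(spec, s_in, p, feed, sigma) {
  base <- spec$config
  kmult <- 1
  exch <- switch(spec$kind,
    baseline = exchange_params(p),
    uptake = exchange_params(p, feed_rate = c(rep(0, p - 1), feed)),
    secretion = exchange_params(p, secretion_ratio = c(sigma, rep(0, p - 1))),
    auxotroph = exchange_params(p, feed_rate = c(rep(0, p - 1), feed),
                                knockout = c(rep(FALSE, p - 1), TRUE)),
    crossfeeder = {
      kmult <- c(spec$overexpression_factor, rep(1, p - 1))
      exchange_params(p, secretion_ratio = c(sigma, rep(0, p - 1)),
                      feed_rate = c(rep(0, p - 1), feed),
                      knockout = c(rep(FALSE, p - 1), TRUE))
    })
  growth_config(expression = base$expression,
                kinetics = kinetic_params(p = p, n = base$kinetics$n,
                                          s_in = s_in, kcat = base$kinetics$kcat,
                                          km = base$kinetics$km,
                                          kcat_multiplier = kmult),
                exchange = exch, rule = base$rule, plan = base$plan,
                seed = base$seed,
                constant_enzymes = if (is.null(base$constant_enzymes)) NULL
                                   else base$constant_enzymes[1, 1])
}

#' Run a scenario sweep
#'
#' Simulates every grid point of the scenario (burn-in plus lineage tree per
#' replicate), estimates the population growth rate and generation-time
#' moments, and reports the relative change against a matched baseline
#' prototroph re-simulated with the same seeds (never cached across runs).
#' For exchange scenarios the matched baseline is the same cell without
#' exchange; for knockouts it is the intact `p`-pathway prototroph.
#'
#' @param spec a [scenario_spec()].
#' @param verbose print a line per grid point.
#' @return a data frame (one row per grid point) with the grid coordinates,
#'   `growth_rate`, `baseline_rate`, `rel_change`, generation-time moments,
#'   `mean_secretion_rate` and cell counts; the spec is attached as an
#'   attribute.
#' @export
run_scenario <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  grid <- expand.grid(s_in = spec$s_in,
                      p = spec$p,
                      feed_rate = if (spec$kind %in%
                                      c("uptake", "auxotroph", "crossfeeder"))
                        spec$feed_rate else 0,
                      secretion_ratio = if (spec$kind %in%
                                            c("secretion", "crossfeeder"))
                        spec$secretion_ratio else 0,
                      KEEP.OUT.ATTRS = FALSE)
  baselines <- new.env(parent = emptyenv())
  baseline_rate <- function(s_in, p) {
    key <- paste(s_in, p, sep = "|")
    if (!is.null(baselines[[key]])) return(baselines[[key]])
    cfg <- .scenario_config(list(kind = "baseline", config = spec$config),
                            s_in, p, 0, 0)
    r <- growth_rate(simulate_lineage(cfg))$rate
    baselines[[key]] <- r
    r
  }
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    cfg <- .scenario_config(spec, g$s_in, g$p, g$feed_rate, g$secretion_ratio)
    lin <- simulate_lineage(cfg)
    est <- growth_rate(lin)
    mom <- summarize_generation_times(lin)
    secpath <- if (spec$kind %in% c("secretion", "crossfeeder")) 1L else NA
    sec <- if (is.na(secpath)) 0 else mean_secretion_rate(lin, secpath)
    base <- baseline_rate(g$s_in, g$p)
    if (verbose)
      message(sprintf("%s: S_in=%g p=%d feed=%g sigma=%g -> mu=%.3g /s",
                      spec$kind, g$s_in, g$p, g$feed_rate, g$secretion_ratio,
                      est$rate))
    data.frame(kind = spec$kind, s_in = g$s_in, p = g$p,
               feed_rate = g$feed_rate, secretion_ratio = g$secretion_ratio,
               growth_rate = est$rate, baseline_rate = base,
               rel_change = (est$rate - base) / base,
               mean_generation_time = mom$mean, cv = mom$cv,
               skewness = mom$skewness, kurtosis = mom$kurtosis,
               mean_secretion_rate = sec,
               n_cells = sum(!is.na(lin$division_time_s)))
  })
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  out
}

#' Mean secretion rate over a lineage
#'
#' Total amount secreted on a pathway over all recorded cells divided by the
#' total simulated cell-time (sum of generation times).
#'
#' @param lineage a `lineage` data frame.
#' @param pathway pathway index.
#' @return secretion rate (molecules/s).
#' @export
mean_secretion_rate <- function(lineage, pathway) {
  col <- paste0("secreted_", pathway)
  if (!col %in% names(lineage))
    stop("no secretion record for pathway ", pathway, call. = FALSE)
  ok <- !is.na(lineage$generation_time_s)
  total_time <- sum(lineage$generation_time_s[ok])
  if (total_time <= 0) stop("zero total simulated time", call. = FALSE)
  sum(lineage[[col]][ok]) / total_time
}

#' Classify cross-feeding feasibility
#'
#' A parameter point sustains reciprocal cross-feeding if the cell secretes
#' at least as fast as it imports (`mean_secretion_rate >= feed_rate`) and
#' still grows strictly faster than the matched prototroph grown without any
#' metabolite feed.  The secretion condition is non-strict and the growth
#' condition strict (a cell exactly at the baseline gains nothing).
#'
#' @param points data frame with columns `feed_rate`,
#'   `mean_secretion_rate`, `growth_rate`, and either a
#'   `baseline_prototroph_rate` column or the `baseline_rate` column
#'   produced by [run_scenario()].
#' @return the input with logical column `feasible` added.
#' @export
classify_feasibility <- function(points) {
  base <- points$baseline_prototroph_rate
  if (is.null(base)) base <- points$baseline_rate
  if (is.null(base))
    stop("no matched baseline prototroph rate in `points`", call. = FALSE)
  need <- c("feed_rate", "mean_secretion_rate", "growth_rate")
  miss <- setdiff(need, names(points))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  points$baseline_prototroph_rate <- base
  points$feasible <- points$mean_secretion_rate >= points$feed_rate &
    points$growth_rate > base
  points
}
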