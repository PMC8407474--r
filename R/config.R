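#' Gene-expression parameters
#'
#' Parameters of the stochastic burst-expression machinery shared by the `n`
#' enzymes of each biosynthetic operon.  All times are in seconds (the
#' interface convention of 4 min / 2.4 min burst durations corresponds to the
#' defaults 240 s and 144 s).
#'
#' @param mean_t_on mean duration of a transcription burst (s).
#' @param mean_t_off mean waiting time between bursts (s).
#' @param mrna_rate_on transcript initiation rate while the burst is ON (1/s).
#' @param mean_mrna_lifetime mean exponential mRNA lifetime (s).
#' @param mean_protein_lifetime mean exponential protein lifetime (s).
#' @param txn_elongation_time time for RNA polymerase to complete one
#'   transcript (s); transcripts unfinished at burst end are discarded.
#' @param tln_time_per_protein time for the single ribosome on an mRNA to
#'   complete one protein (s); a part-finished protein is lost when the mRNA
#'   decays.
#' @return an object of class `expression_params`.
#' @export
expression_params <- function(mean_t_on = 240, mean_t_off = 144,
                              mrna_rate_on = 1 / 240,
                              mean_mrna_lifetime = 120,
                              mean_protein_lifetime = 1800,
                              txn_elongation_time = 20,
                              tln_time_per_protein = 20) {
  x <- list(mean_t_on = mean_t_on, mean_t_off = mean_t_off,
            mrna_rate_on = mrna_rate_on,
            mean_mrna_lifetime = mean_mrna_lifetime,
            mean_protein_lifetime = mean_protein_lifetime,
            txn_elongation_time = txn_elongation_time,
            tln_time_per_protein = tln_time_per_protein)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("expression parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(x, class = "expression_params")
}

#' Pathway kinetic parameters
#'
#' The cell carries `p` parallel linear biosynthetic pathways of `n`
#' equivalent Michaelis-Menten enzyme steps, all fed by a common substrate
#' supplied at `s_in` molecules per second per pathway (total inflow
#' `p * s_in`).  Quantities are absolute molecule numbers for a cell of
#' volume 1 um^3.
#'
#' @param p number of bottleneck pathways (>= 1).
#' @param n enzyme steps per pathway (>= 1).
#' @param s_in substrate supply rate per pathway (molecules/s); a scalar, or a
#'   length-`p` vector for unequal supplies (total inflow is always the sum).
#' @param kcat catalytic constant per enzyme (1/s).
#' @param km half-saturation constant (molecules).
#' @param kcat_multiplier per-pathway multiplier on `kcat` (overexpression of
#'   a pathway doubles it); scalar or length `p`.
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(p = 3, n = 3, s_in = 9000, kcat = 300, km = 6e4,
                           kcat_multiplier = 1) {
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p))
    stop("p must be a positive integer", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  p <- as.integer(p); n <- as.integer(n)
  if (length(s_in) == 1L) s_in <- rep(s_in, p)
  if (length(s_in) != p || any(!is.finite(s_in)) || any(s_in < 0))
    stop("s_in must be non-negative, length 1 or p", call. = FALSE)
  if (!is.numeric(kcat) || length(kcat) != 1L || kcat <= 0)
    stop("kcat must be a single positive number", call. = FALSE)
  if (!is.numeric(km) || length(km) != 1L || km <= 0)
    stop("km must be a single positive number", call. = FALSE)
  if (length(kcat_multiplier) == 1L) kcat_multiplier <- rep(kcat_multiplier, p)
  if (length(kcat_multiplier) != p || any(kcat_multiplier <= 0))
    stop("kcat_multiplier must be positive, length 1 or p", call. = FALSE)
  structure(list(p = p, n = n, s_in = s_in, kcat = kcat, km = km,
                 kcat_multiplier = kcat_multiplier),
            class = "kinetic_params")
}

#' Metabolite exchange parameters
#'
#' Per-pathway secretion, import, and knockout flags.  Secretion exports the
#' fraction `secretion_ratio` of the final step's instantaneous production;
#' import adds a constant `feed_rate` to the final pool.  A knocked-out
#' pathway expresses no enzymes and produces nothing internally, but keeps
#' its division requirement, so it must be fed.  Total substrate inflow is
#' unchanged by knockouts (the flux is redistributed over the remaining
#' pathways).
#'
#' @param p number of pathways (must match the kinetic parameters).
#' @param secretion_ratio fraction of final-step production secreted, in
#'   `[0, 1)`; scalar or length `p`.
#' @param feed_rate constant import rate (molecules/s, >= 0); scalar or
#'   length `p`.
#' @param knockout logical; scalar or length `p`.
#' @return an object of class `exchange_params`.
#' @export
exchange_params <- function(p = 3, secretion_ratio = 0, feed_rate = 0,
                            knockout = FALSE) {
  p <- as.integer(p)
  if (length(secretion_ratio) == 1L) secretion_ratio <- rep(secretion_ratio, p)
  if (length(feed_rate) == 1L) feed_rate <- rep(feed_rate, p)
  if (length(knockout) == 1L) knockout <- rep(knockout, p)
  if (length(secretion_ratio) != p || any(secretion_ratio < 0) ||
      any(secretion_ratio >= 1))
    stop("secretion_ratio must lie in [0, 1), length 1 or p", call. = FALSE)
  if (length(feed_rate) != p || any(feed_rate < 0) || any(!is.finite(feed_rate)))
    stop("feed_rate must be non-negative, length 1 or p", call. = FALSE)
  if (length(knockout) != p || !is.logical(knockout))
    stop("knockout must be logical, length 1 or p", call. = FALSE)
  structure(list(p = p, secretion_ratio = secretion_ratio,
                 feed_rate = feed_rate, knockout = knockout),
            class = "exchange_params")
}

#' Metabolic division rule
#'
#' Under the metabolic Adder, division requires producing a fixed amount
#' (`threshold`) of each limiting metabolite on top of whatever was
#' inherited; under the metabolic Sizer, each final pool must reach the
#' absolute level `threshold`.
#'
#' @param kind `"sizer"` or `"adder"`.
#' @param threshold molecules of each limiting metabolite; defaults to 2e7
#'   for the Sizer and 1e7 for the Adder.  Scalar or per-pathway vector.
#' @return an object of class `division_rule`.
#' @export
division_rule <- function(kind = c("sizer", "adder"), threshold = NULL) {
  kind <- match.arg(kind)
  if (is.null(threshold)) threshold <- if (kind == "sizer") 2e7 else 1e7
  if (!is.numeric(threshold) || any(threshold <= 0) || any(!is.finite(threshold)))
    stop("threshold must be positive", call. = FALSE)
  structure(list(kind = kind, threshold = threshold), class = "division_rule")
}

#' Simulation plan
#'
#' @param burn_in_generations single-lineage generations simulated before any
#'   data are recorded, so the cell reaches steady cycling from the all-zero
#'   start (default 100).
#' @param tree_generations depth of the full binary lineage tree recorded
#'   after burn-in; yields `2^g - 1` cells (default 13, i.e. 8191 cells).
#' @param replicates independent runs with distinct seed streams (default 3).
#' @param max_cycle_time hard cap (s) on a single cell cycle, after which the
#'   cell is flagged non-dividing; `NULL` = 50x the deterministic-limit cycle
#'   time of the configuration.
#' @param initial_horizon initial expression horizon (s) per cycle; extended
#'   (the burst schedule is continued, not regenerated) until division or
#'   `max_cycle_time`.  `NULL` = 2.5x the deterministic-limit cycle time.
#' @return an object of class `simulation_plan`.
#' @export
simulation_plan <- function(burn_in_generations = 100, tree_generations = 13,
                            replicates = 3, max_cycle_time = NULL,
                            initial_horizon = NULL) {
  if (burn_in_generations < 0) stop("burn_in_generations must be >= 0", call. = FALSE)
  if (tree_generations < 1) stop("tree_generations must be >= 1", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(burn_in_generations = as.integer(burn_in_generations),
                 tree_generations = as.integer(tree_generations),
                 replicates = as.integer(replicates),
                 max_cycle_time = max_cycle_time,
                 initial_horizon = initial_horizon),
            class = "simulation_plan")
}

#' Assemble a full simulation configuration
#'
#' Bundles expression, kinetic, exchange, division-rule and plan parameters
#' with the master seed.  All cross-field consistency checks happen here.
#'
#' @param expression an [expression_params()] object.
#' @param kinetics a [kinetic_params()] object.
#' @param exchange an [exchange_params()] object, or `NULL` for no exchange.
#' @param rule a [division_rule()] object.
#' @param plan a [simulation_plan()] object.
#' @param seed master seed (integer); every cell cycle derives its own stream
#'   from it, so results do not depend on traversal order.
#' @param constant_enzymes `NULL` for stochastic expression, or a scalar /
#'   `p x n` matrix of fixed enzyme counts for a deterministic cell (used for
#'   fixtures and closed-form checks).
#' @return an object of class `growth_config`.
#' @export
growth_config <- function(expression = expression_params(),
                          kinetics = kinetic_params(),
                          exchange = NULL,
                          rule = division_rule(),
                          plan = simulation_plan(),
                          seed = 1L,
                          constant_enzymes = NULL) {
  stopifnot(inherits(expression, "expression_params"),
            inherits(kinetics, "kinetic_params"),
            inherits(rule, "division_rule"),
            inherits(plan, "simulation_plan"))
  p <- kinetics$p; n <- kinetics$n
  if (is.null(exchange)) exchange <- exchange_params(p)
  stopifnot(inherits(exchange, "exchange_params"))
  if (exchange$p != p)
    stop("exchange parameters are for p = ", exchange$p,
         " but kinetics have p = ", p, call. = FALSE)
  thr <- rule$threshold
  if (!length(thr) %in% c(1L, p))
    stop("rule threshold must be scalar or length p", call. = FALSE)
  if (!is.null(constant_enzymes)) {
    if (length(constant_enzymes) == 1L)
      constant_enzymes <- matrix(constant_enzymes, p, n)
    constant_enzymes <- as.matrix(constant_enzymes)
    if (!all(dim(constant_enzymes) == c(p, n)) || any(constant_enzymes < 0))
      stop("constant_enzymes must be a non-negative scalar or p x n matrix",
           call. = FALSE)
    constant_enzymes[exchange$knockout, ] <- 0
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer", call. = FALSE)
  cfg <- structure(list(expression = expression, kinetics = kinetics,
                        exchange = exchange, rule = rule, plan = plan,
                        seed = as.integer(seed),
                        constant_enzymes = constant_enzymes),
                   class = "growth_config")
  # fail early on configurations that can never divide
  rates <- .limit_rates(cfg)
  if (any(rates <= 0))
    stop("pathway ", which(rates <= 0)[1],
         " has no substrate supply and no feed: the cell can never divide ",
         "(a knocked-out pathway under the Sizer must be fed)", call. = FALSE)
  cfg
}

# per-pathway thresholds recycled to length p
.thresholds <- function(cfg) {
  rep(cfg$rule$threshold, length.out = cfg$kinetics$p)
}

# best-case (deterministic-limit) supply rate per pathway: active pathways
# share the total inflow, knocked-out pathways rely on their feed alone
.limit_rates <- function(cfg) {
  p <- cfg$kinetics$p
  active <- !cfg$exchange$knockout
  total_in <- sum(cfg$kinetics$s_in)
  rates <- cfg$exchange$feed_rate
  if (any(active))
    rates[active] <- rates[active] + total_in / sum(active)
  rates
}

# deterministic-limit cycle time: longest per-pathway time to produce a full
# threshold at the best-case supply rate
.limit_cycle_time <- function(cfg) {
  max(.thresholds(cfg) / .limit_rates(cfg))
}

.max_cycle_time <- function(cfg) {
  mct <- cfg$plan$max_cycle_time
  if (is.null(mct)) mct <- 50 * .limit_cycle_time(cfg)
  mct
}

.initial_horizon <- function(cfg) {
  h <- cfg$plan$initial_horizon
  if (is.null(h)) h <- 2.5 * .limit_cycle_time(cfg)
  min(h, .max_cycle_time(cfg))
}

#' @export
print.growth_config <- function(x, ...) {
  k <- x$kinetics
  cat("<growth_config>\n")
  cat(sprintf("  pathways p = %d, steps n = %d, S_in = %s molecules/s\n",
              k$p, k$n, paste(format(k$s_in), collapse = ", ")))
  cat(sprintf("  kcat = %g /s (multipliers %s), Km = %g molecules\n",
              k$kcat, paste(k$kcat_multiplier, collapse = ", "), k$km))
  cat(sprintf("  rule: %s, threshold %s\n", x$rule$kind,
              paste(format(x$rule$threshold), collapse = ", ")))
  cat(sprintf("  burst: t_ON %g s, t_OFF %g s\n",
              x$expression$mean_t_on, x$expression$mean_t_off))
  ex <- x$exchange
  if (any(ex$secretion_ratio > 0) || any(ex$feed_rate > 0) || any(ex$knockout))
    cat(sprintf("  exchange: sigma = %s, feed = %s, knockout = %s\n",
                paste(ex$secretion_ratio, collapse = ","),
                paste(ex$feed_rate, collapse = ","),
                paste(as.integer(ex$knockout), collapse = ",")))
  cat(sprintf("  plan: burn-in %d, tree %d generations, %d replicate(s), seed %d\n",
              x$plan$burn_in_generations, x$plan$tree_generations,
              x$plan$replicates, x$seed))
  if (!is.null(x$constant_enzymes))
    cat("  deterministic cell: constant enzyme counts\n")
  invisible(x)
}

# ---- file I/O -------------------------------------------------------------

.config_sections <- c("expression", "kinetics", "exchange", "rule", "plan",
                      "seed", "constant_enzymes")

#' Load a configuration from a JSON file
#'
#' The file holds a nested object with any of the sections `expression`,
#' `kinetics`, `exchange`, `rule`, `plan`, plus `seed` and
#' `constant_enzymes`; omitted fields take the package defaults.  Unknown
#' keys are rejected by name.
#'
#' @param path path to a JSON configuration file.
#' @return a [growth_config()] object.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  config_from_list(raw)
}

# JSON has no NULL scalar inside objects: empty lists read back from a
# config echo stand for absent values
.drop_empty <- function(x) {
  if (is.null(x)) return(NULL)
  x[!vapply(x, function(a) is.list(a) && !length(a), logical(1))]
}

#' @rdname load_config
#' @param x a nested list with the same structure as the JSON file.
#' @export
config_from_list <- function(x) {
  bad <- setdiff(names(x), .config_sections)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  build <- function(section, fun) {
    args <- .drop_empty(x[[section]])
    if (is.null(args) || !length(args)) return(fun())
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad))
      stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    do.call(fun, as.list(args))
  }
  kin <- build("kinetics", kinetic_params)
  exch <- if (!length(.drop_empty(x$exchange))) NULL else {
    args <- .drop_empty(x$exchange)
    bad <- setdiff(names(args), names(formals(exchange_params)))
    if (length(bad))
      stop("unknown key(s) in 'exchange': ", paste(bad, collapse = ", "),
           call. = FALSE)
    args$p <- kin$p
    do.call(exchange_params, as.list(args))
  }
  growth_config(expression = build("expression", expression_params),
                kinetics = kin, exchange = exch,
                rule = build("rule", division_rule),
                plan = build("plan", simulation_plan),
                seed = if (is.null(x$seed)) 1L else x$seed,
                constant_enzymes = if (length(x$constant_enzymes))
                  x$constant_enzymes else NULL)
}

#' @rdname load_config
#' @param cfg a `growth_config` object.
#' @export
config_to_list <- function(cfg) {
  lapply(unclass(cfg), function(f) if (is.list(f)) unclass(f) else f)
}

#' Write simulation outputs
#'
#' Writes `lineage.csv` (fixed header, UTF-8, '.' decimal), `summary.json`
#' and `run_meta.json` (seed, full config echo, package version) into
#' `outdir`.  Existing files are overwritten with a warning.
#'
#' @param lineage a lineage table from [simulate_lineage()].
#' @param summaries a named list of summary results (coerced to JSON).
#' @param outdir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(lineage, summaries, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("lineage.csv", "summary.json", "run_meta.json"))
  if (any(file.exists(paths)))
    warning("overwriting existing output files in ", outdir, call. = FALSE)
  write_lineage(lineage, paths[1])
  jsonlite::write_json(summaries, paths[2], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  meta <- list(seed = attr(lineage, "seed"),
               config = config_to_list(attr(lineage, "config")),
               package_version = as.character(utils::packageVersion("stogrow")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  # 17 significant digits so the config echo replays bit-exactly
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(paths)
}

#' Read and write lineage tables
#'
#' @param lineage a lineage data frame.
#' @param path a CSV path.
#' @return `read_lineage` returns the lineage data frame.
#' @export
write_lineage <- function(lineage, path) {
  utils::write.csv(as.data.frame(lineage), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lineage
#' @export
read_lineage <- function(path) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  class(x) <- c("lineage", "data.frame")
  x
}
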