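#' Population growth rate from sorted birth events
#'
#' Treats each birth as a unit increment to the population: with births
#' sorted ascending, the cumulative count N(t) is exponential during the
#' early expansion, so the slope of a least-squares line of `ln N` against
#' `t` over the first `window_fraction` of events estimates the population
#' growth rate (the later part of a finite tree saturates and is excluded).
#' To use the whole data set, the fit is repeated over `n_resamples`
#' bootstrap resamples of the cells and the slopes averaged.
#'
#' @param x a `lineage` data frame or a numeric vector of birth times (s).
#'   A multi-replicate lineage is estimated per replicate and averaged.
#' @param window_fraction fraction of the sorted birth events fitted
#'   (default 0.4).
#' @param n_resamples number of bootstrap resamples (default 100).
#' @return an object of class `growth_estimate` with the mean `rate` (1/s),
#'   the point estimate, the resample rates and the fit R-squared.
#' @export
growth_rate <- function(x, window_fraction = 0.4, n_resamples = 100) {
  if (inherits(x, "lineage") || is.data.frame(x)) {
    reps <- split(birth_times(x, drop_na = FALSE)[!is.na(x$division_time_s)],
                  x$replicate[!is.na(x$division_time_s)])
    ests <- lapply(reps, growth_rate, window_fraction = window_fraction,
                   n_resamples = n_resamples)
    rate <- mean(vapply(ests, `[[`, numeric(1), "rate"))
    out <- ests[[1]]
    out$rate <- rate
    out$per_replicate <- vapply(ests, `[[`, numeric(1), "rate")
    return(out)
  }
  t <- as.numeric(x)
  if (length(t) < 20) stop("need at least 20 birth events", call. = FALSE)
  fit_one <- function(tt) {
    tt <- sort(tt)
    m <- ceiling(window_fraction * length(tt))
    tw <- tt[seq_len(m)]
    if (stats::var(tw) == 0)
      stop("degenerate birth times: no spread within the fitting window",
           call. = FALSE)
    lnN <- log(seq_len(m))
    f <- stats::lm.fit(cbind(1, tw), lnN)
    list(slope = f$coefficients[2],
         r2 = 1 - sum(f$residuals^2) / sum((lnN - mean(lnN))^2))
  }
  point <- fit_one(t)
  slopes <- vapply(seq_len(n_resamples), function(b)
    fit_one(sample(t, replace = TRUE))$slope, numeric(1))
  structure(list(rate = mean(slopes), rate_point = unname(point$slope),
                 rate_sd = stats::sd(slopes), resample_rates = slopes,
                 r_squared = point$r2, window_fraction = window_fraction,
                 n_events = length(t)),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("Population growth rate: %.4g /s (%.4g /h)\n",
              x$rate, x$rate * 3600))
  cat(sprintf("  point estimate %.4g /s, bootstrap sd %.2g, R^2 %.4f, %d births\n",
              x$rate_point, x$rate_sd, x$r_squared, x$n_events))
  invisible(x)
}

#' @export
coef.growth_estimate <- function(object, ...) c(rate = object$rate)

# ---- generalized extreme value distribution -------------------------------

#' Generalized extreme value distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the GEV distribution with location `loc`, scale `scale` and shape
#' `shape`.  The shape convention is the one in which `shape < 0` is the
#' type III (reversed-Weibull, bounded upper tail) family and `shape > 0`
#' type II (Frechet); `shape = 0` is the Gumbel limit.
#'
#' @param x,q,p quantiles / probabilities.
#' @param n number of draws.
#' @param loc,scale,shape GEV parameters; `scale > 0`.
#' @param log return log-density.
#' @return numeric vector.
#' @name gev
NULL

#' @rdname gev
#' @export
dgev <- function(x, loc = 0, scale = 1, shape = 0, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - loc) / scale
  if (abs(shape) < 1e-9) {
    logd <- -z - exp(-z) - base::log(scale)
  } else {
    t <- 1 + shape * z
    logd <- ifelse(t > 0,
                   -(1 / shape + 1) * base::log(pmax(t, 1e-300)) -
                     pmax(t, 1e-300)^(-1 / shape) - base::log(scale),
                   -Inf)
  }
  if (log) logd else exp(logd)
}

#' @rdname gev
#' @export
pgev <- function(q, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0)
  z <- (q - loc) / scale
  if (abs(shape) < 1e-9) return(exp(-exp(-z)))
  t <- 1 + shape * z
  ifelse(t > 0, exp(-t^(-1 / shape)),
         if (shape > 0) 0 else 1)
}

#' @rdname gev
#' @export
qgev <- function(p, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0, all(p > 0 & p < 1))
  if (abs(shape) < 1e-9) return(loc - scale * base::log(-base::log(p)))
  loc + scale * ((-base::log(p))^(-shape) - 1) / shape
}

#' @rdname gev
#' @export
rgev <- function(n, loc = 0, scale = 1, shape = 0) {
  qgev(stats::runif(n), loc, scale, shape)
}

# Hosking probability-weighted-moment starting values.  Hosking's k equals
# -shape in the convention used here.
.gev_pwm <- function(y) {
  y <- sort(y)
  n <- length(y)
  j <- seq_len(n)
  b0 <- mean(y)
  b1 <- sum((j - 1) / (n - 1) * y) / n
  b2 <- sum((j - 1) * (j - 2) / ((n - 1) * (n - 2)) * y) / n
  c <- (2 * b1 - b0) / (3 * b2 - b0) - base::log(2) / base::log(3)
  k <- 7.8590 * c + 2.9554 * c^2
  g <- gamma(1 + k)
  scale <- (2 * b1 - b0) * k / (g * (1 - 2^(-k)))
  loc <- b0 + scale * (g - 1) / k
  if (!is.finite(scale) || scale <= 0) {
    scale <- stats::sd(y) * sqrt(6) / pi
    loc <- mean(y) - 0.5772 * scale
    k <- 1e-4
  }
  c(loc = loc, scale = scale, shape = -k)
}

#' Fit a GEV distribution to log-transformed generation times
#'
#' Maximum-likelihood GEV fit to `ln(times)` ("log GEV": the log of the
#' variable is GEV-distributed).  Starting values come from
#' probability-weighted moments; the likelihood is maximised over
#' (location, log scale, shape) by Nelder-Mead with a BFGS polish.  A
#' negative fitted shape denotes the type III (bounded-tail) family.
#'
#' @param x a `lineage` data frame or a numeric vector of generation times
#'   (all positive, at least 100 values).
#' @param transform set to `FALSE` to fit the GEV to `x` as-is, without the
#'   log transform.
#' @return an object of class `gev_fit` with components `par`
#'   (`loc`, `scale`, `shape` on the log scale), `loglik`, `n`, and the
#'   shape-sign convention in `convention`.
#' @export
fit_log_gev <- function(x, transform = TRUE) {
  if (inherits(x, "lineage") || is.data.frame(x)) x <- generation_times(x)
  x <- as.numeric(x)
  if (length(x) < 100) stop("need at least 100 generation times", call. = FALSE)
  if (any(x <= 0)) stop("generation times must be positive", call. = FALSE)
  y <- if (transform) base::log(x) else x
  if (stats::sd(y) == 0)
    stop("degenerate sample: all values identical", call. = FALSE)
  start <- .gev_pwm(y)
  nll <- function(par) {
    s <- exp(par[2])
    ll <- dgev(y, par[1], s, par[3], log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  p0 <- c(start[1], base::log(start[2]), start[3])
  opt <- stats::optim(p0, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt2 <- tryCatch(stats::optim(opt$par, nll, method = "BFGS",
                                control = list(maxit = 500)),
                   error = function(e) opt)
  if (opt2$value <= opt$value) opt <- opt2
  par <- c(loc = unname(opt$par[1]), scale = exp(unname(opt$par[2])),
           shape = unname(opt$par[3]))
  structure(list(par = par, loglik = -opt$value, n = length(y),
                 transform = transform, convergence = opt$convergence,
                 convention = "shape < 0 = type III (bounded upper tail)",
                 data = y),
            class = "gev_fit")
}

#' @export
print.gev_fit <- function(x, ...) {
  cat(sprintf("GEV fit%s (n = %d)\n",
              if (x$transform) " to log-transformed data" else "", x$n))
  cat(sprintf("  location %.4f, scale %.4f, shape %.4f  [%s]\n",
              x$par["loc"], x$par["scale"], x$par["shape"], x$convention))
  cat(sprintf("  log-likelihood %.2f\n", x$loglik))
  invisible(x)
}

#' @export
coef.gev_fit <- function(object, ...) object$par

#' @export
logLik.gev_fit <- function(object, ...) {
  structure(object$loglik, df = 3, nobs = object$n, class = "logLik")
}

#' @export
simulate.gev_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  y <- rgev(nsim * object$n, object$par["loc"], object$par["scale"],
            object$par["shape"])
  m <- matrix(y, object$n, nsim)
  if (object$transform) exp(m) else m
}

#' @export
plot.gev_fit <- function(x, breaks = "FD", ...) {
  h <- graphics::hist(x$data, breaks = breaks, plot = FALSE)
  graphics::plot(h, freq = FALSE,
                 xlab = if (x$transform) "ln generation time" else "value",
                 main = "GEV fit", ...)
  xs <- seq(min(x$data), max(x$data), length.out = 400)
  graphics::lines(xs, dgev(xs, x$par["loc"], x$par["scale"], x$par["shape"]),
                  col = 2, lwd = 2)
  invisible(x)
}

# ---- distribution moments -------------------------------------------------

#' Moments of a generation-time distribution
#'
#' Mean, coefficient of variation, sample skewness and excess kurtosis.  A
#' degenerate (zero-variance) sample reports CV, skewness and kurtosis of 0
#' with `degenerate = TRUE`.
#'
#' @param x a `lineage` data frame or numeric vector of generation times
#'   (at least 2 values).
#' @return a list with `mean`, `cv`, `skewness`, `kurtosis`, `n`,
#'   `degenerate`.
#' @export
summarize_generation_times <- function(x) {
  if (inherits(x, "lineage") || is.data.frame(x)) x <- generation_times(x)
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0)
    return(list(mean = mean(x), cv = 0, skewness = 0, kurtosis = 0,
                n = length(x), degenerate = TRUE))
  list(mean = mean(x), cv = s / mean(x),
       skewness = e1071::skewness(x),
       kurtosis = e1071::kurtosis(x),  # excess kurtosis
       n = length(x), degenerate = FALSE)
}

# ---- Monod fit ------------------------------------------------------------

#' Fit a Monod curve to growth rate versus substrate supply
#'
#' Nonlinear least squares of `mu = mu_max * S / (K_s + S)`, the hyperbolic
#' dependence of growth rate on substrate availability.  Starting values
#' come from a Lineweaver-Burk linearisation; fitting uses [stats::nls()]
#' (port algorithm, positivity bounds) with a Levenberg-Marquardt fallback.
#'
#' @param s_in substrate supply rates (at least 4 distinct values).
#' @param rates matching growth rates (1/s).
#' @return an object of class `monod_fit` with `mu_max`, `K_s`, `r_squared`
#'   and the underlying `nls` object.
#' @export
fit_monod <- function(s_in, rates) {
  s_in <- as.numeric(s_in); rates <- as.numeric(rates)
  stopifnot(length(s_in) == length(rates))
  if (length(unique(s_in)) < 4)
    stop("need at least 4 distinct substrate supply values", call. = FALSE)
  if (any(rates <= 0) || any(s_in <= 0))
    stop("supplies and rates must be positive for the Monod fit", call. = FALSE)
  lb <- stats::lm(I(1 / rates) ~ I(1 / s_in))
  mu0 <- unname(1 / stats::coef(lb)[1])
  ks0 <- unname(stats::coef(lb)[2] * mu0)
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- 1.2 * max(rates)
  if (!is.finite(ks0) || ks0 <= 0) ks0 <- stats::median(s_in)
  df <- data.frame(s = s_in, mu = rates)
  fit <- tryCatch(
    stats::nls(mu ~ mu_max * s / (K_s + s), data = df,
               start = list(mu_max = mu0, K_s = ks0),
               lower = c(mu_max = 1e-300, K_s = 1e-300),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      minpack.lm::nlsLM(mu ~ mu_max * s / (K_s + s), data = df,
                        start = list(mu_max = mu0, K_s = ks0),
                        lower = c(1e-300, 1e-300)),
      error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
  } else {
    # data far from hyperbolic (e.g. decreasing): direct least squares so a
    # poor fit is still reported rather than silently failing
    ss <- function(lp) sum((df$mu - exp(lp[1]) * df$s /
                              (exp(lp[2]) + df$s))^2)
    opt <- stats::optim(c(log(mu0), log(ks0)), ss, method = "Nelder-Mead",
                        control = list(maxit = 2000))
    co <- c(mu_max = exp(opt$par[1]), K_s = exp(opt$par[2]))
  }
  pred <- co["mu_max"] * df$s / (co["K_s"] + df$s)
  r2 <- 1 - sum((df$mu - pred)^2) / sum((df$mu - mean(df$mu))^2)
  out <- structure(list(mu_max = unname(co["mu_max"]),
                        K_s = unname(co["K_s"]),
                        r_squared = r2, fit = fit, data = df),
                   class = "monod_fit")
  if (r2 < 0.9)
    warning("Monod fit is poor (R^2 = ", signif(r2, 3),
            "): the rate-supply relation may not be hyperbolic",
            call. = FALSE)
  out
}

#' @export
print.monod_fit <- function(x, ...) {
  cat(sprintf("Monod fit: mu_max = %.4g /s, K_s = %.4g molecules/s, R^2 = %.4f\n",
              x$mu_max, x$K_s, x$r_squared))
  if (x$r_squared < 0.9)
    cat("  warning: poor fit (R^2 < 0.9); the relationship may not be hyperbolic\n")
  invisible(x)
}

#' @export
coef.monod_fit <- function(object, ...) {
  c(mu_max = object$mu_max, K_s = object$K_s)
}

#' @export
predict.monod_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$s else
    if (is.data.frame(newdata)) newdata$s else as.numeric(newdata)
  object$mu_max * s / (object$K_s + s)
}

#' @export
residuals.monod_fit <- function(object, ...) {
  object$data$mu - predict(object)
}

#' @export
plot.monod_fit <- function(x, ...) {
  graphics::plot(x$data$s, x$data$mu, xlab = "substrate supply S_in (molecules/s)",
                 ylab = "growth rate (1/s)", main = "Monod fit", ...)
  ss <- seq(0, max(x$data$s) * 1.05, length.out = 200)
  graphics::lines(ss, x$mu_max * ss / (x$K_s + ss), col = 2, lwd = 2)
  invisible(x)
}
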