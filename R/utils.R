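#' @useDynLib kisssync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov median quantile rbinom rgamma rlnorm rnorm rpois runif
#'   runmed sd spline t.test var.test pnorm setNames
#' @importFrom utils read.csv write.csv head tail combn
#' @importFrom graphics plot points lines
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop_input(sprintf("'%s' must be a single finite number in [%s, %s]",
                       name, format(min), format(max)))
  as.numeric(x)
}

# Derive a reproducible sub-stream seed from a master seed and a component
# name, so adding a component to a simulator does not shuffle the draws of the
# others.  Kept below 2^31 - 1 (R integers are 32-bit).
component_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

with_component_seed <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(component_seed(seed, component))
  expr
}

#' Specify a univariate sampling distribution
#'
#' Lightweight distribution specifications used throughout the simulators for
#' event amplitudes, response amplitudes and inter-event intervals.  Supported
#' families: `"normal"` (mean, sd), `"lognormal"` (meanlog, sdlog),
#' `"gamma"` (mean, shape), `"constant"` (value).  Optional `min`/`max`
#' truncate by resampling.
#'
#' @param dist family name.
#' @param ... family parameters (see Details).
#' @return an object of class `dist_spec`.
#' @examples
#' draw_spec(dist_spec("normal", mean = 15, sd = 2, min = 10), 5)
#' @export
dist_spec <- function(dist = c("normal", "lognormal", "gamma", "constant"),
                      ...) {
  dist <- match.arg(dist)
  pars <- list(...)
  spec <- c(list(dist = dist), pars)
  need <- switch(dist,
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    gamma = c("mean", "shape"),
    constant = "value")
  missing <- setdiff(need, names(pars))
  if (length(missing))
    stop_input("dist_spec('", dist, "') requires parameter(s): ",
               paste(missing, collapse = ", "))
  structure(spec, class = "dist_spec")
}

as_dist_spec <- function(x, name = "distribution") {
  if (inherits(x, "dist_spec")) return(x)
  if (is.list(x) && !is.null(x$dist))
    return(do.call(dist_spec, x))
  if (is.numeric(x) && length(x) == 1L)
    return(dist_spec("constant", value = x))
  stop_input("'", name, "' is not a valid distribution specification")
}

#' @rdname dist_spec
#' @param spec a `dist_spec`.
#' @param n number of draws.
#' @export
draw_spec <- function(spec, n) {
  spec <- as_dist_spec(spec)
  if (n == 0L) return(numeric(0))
  draw <- function(m) switch(spec$dist,
    normal = rnorm(m, spec$mean, spec$sd),
    lognormal = rlnorm(m, spec$meanlog, spec$sdlog),
    gamma = rgamma(m, shape = spec$shape, scale = spec$mean / spec$shape),
    constant = rep(spec$value, m))
  x <- draw(n)
  lo <- spec$min %||% -Inf
  hi <- spec$max %||% Inf
  for (i in 1:100) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) break
    if (spec$dist == "constant")
      stop_input("constant dist_spec value outside its own truncation bounds")
    x[bad] <- draw(length(bad))
  }
  if (any(x < lo | x > hi)) x <- pmin(pmax(x, lo), hi)
  x
}

#' Percent reduction between two rates
#'
#' `100 * (before - after) / before`, the convention used for event, mSE and
#' firing-rate suppression summaries.
#'
#' @param before,after non-negative rates (before must be > 0).
#' @return percent reduction (positive when `after < before`).
#' @examples
#' percent_reduction(22.9, 5.3)  # 77 (rounded)
#' @export
percent_reduction <- function(before, after) {
  if (any(before <= 0)) stop_input("'before' must be > 0")
  100 * (before - after) / before
}

# difference-of-exponentials calcium transient kernel, unit peak, with its
# maximum shifted to lag 0 so planted event times coincide with kernel peaks
calcium_kernel <- function(dt, rise, decay, length_s = NULL) {
  if (rise >= decay) stop_input("kernel rise time must be < decay time")
  length_s <- length_s %||% (decay * 6)
  tt <- seq(0, length_s, by = dt)
  k <- exp(-tt / decay) - exp(-tt / rise)
  tpk <- log(decay / rise) * rise * decay / (decay - rise)
  kpk <- exp(-tpk / decay) - exp(-tpk / rise)
  k <- k / kpk
  list(k = k, peak_lag = tt[which.max(k)])
}

# place kernel-shaped transients of given amplitudes at given times on a
# regular grid starting at t0 with step dt
add_transients <- function(n, t0, dt, times, amps, kernel) {
  sig <- numeric(n)
  if (!length(times)) return(sig)
  klen <- length(kernel$k)
  shift <- round(kernel$peak_lag / dt)
  for (j in seq_along(times)) {
    i0 <- round((times[j] - t0) / dt) - shift + 1L
    idx <- i0:(i0 + klen - 1L)
    keep <- idx >= 1L & idx <= n
    if (any(keep)) sig[idx[keep]] <- sig[idx[keep]] + amps[j] * kernel$k[keep]
  }
  sig
}
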