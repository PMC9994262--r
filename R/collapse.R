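# Collapse-pressure analysis: normalisation of OD500 series, least-squares
# fit of the collapse sigmoid OD = 1/(1 + exp(k (p - p0))), and n-of-n
# bootstrap uncertainty of the midpoint p0.

#' Normalise an optical-density series to [0, 1]
#'
#' `(od - min) / (max - min)` per measurement, the standard normalisation
#' before sigmoid fitting.
#'
#' @param od Numeric vector of OD500 values.
#' @return Normalised vector in `[0, 1]`.
#' @export
normalize_od <- function(od) {
  stopifnot(is.numeric(od), length(od) >= 2)
  rng <- range(od)
  if (diff(rng) <= 0)
    stop("constant series cannot be normalised", call. = FALSE)
  (od - rng[1]) / diff(rng)
}

sigmoid_model <- function(p, p0, k) 1 / (1 + exp(k * (p - p0)))

# initialisation: p0 from the first downward 0.5 crossing (linear
# interpolation), k from 4 / (span between the 0.75 and 0.25 crossings)
sigmoid_init <- function(p, od) {
  cross <- function(level) {
    below <- which(od <= level)
    if (!length(below) || below[1] == 1L) return(NA_real_)
    i <- below[1]
    p[i - 1] + (od[i - 1] - level) / (od[i - 1] - od[i]) * (p[i] - p[i - 1])
  }
  p0 <- cross(0.5)
  if (!is.finite(p0)) p0 <- stats::median(p)
  span <- cross(0.25) - cross(0.75)
  k <- if (is.finite(span) && span > 0) 4 / span else 1
  c(p0 = p0, k = k)
}

#' Fit the collapse sigmoid
#'
#' Least-squares fit of `OD = 1/(1 + exp(k (p - p0)))` to a normalised
#' series, with optional inverse-variance weights (e.g. from replicate
#' standard deviations). Bounded optimisation keeps `k > 0`; the
#' initialisation rule (midpoint from the first 0.5 crossing, width from
#' the 0.75/0.25 crossing span) makes the fit deterministic.
#'
#' @param pressures Pressures in bar (strictly increasing, n >= 4).
#' @param od_norm Normalised OD values (same length).
#' @param weights Optional non-negative weights (e.g. `1/sd^2`).
#' @return An object of class `sigmoid_fit`: `p0` (bar), `k` (1/bar),
#'   `rss`, `fitted`, `converged`, `init`.
#' @examples
#' cc <- make_collapse_curve(5.2, 2, noise_sd = 0)
#' fit_sigmoid(cc$pressure[cc$replicate == 1],
#'             normalize_od(cc$od500[cc$replicate == 1]))
#' @export
fit_sigmoid <- function(pressures, od_norm, weights = NULL) {
  stopifnot(is.numeric(pressures), is.numeric(od_norm),
            length(pressures) == length(od_norm))
  if (length(pressures) < 4) stop("need at least 4 points", call. = FALSE)
  if (is.unsorted(pressures, strictly = FALSE))
    stop("pressures must be sorted increasing", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(pressures))
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  init <- sigmoid_init(pressures, od_norm)
  obj <- function(par)
    sum(weights * (od_norm - sigmoid_model(pressures, par[1], par[2]))^2)
  opt <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(-Inf, 1e-8), upper = c(Inf, Inf),
                      control = list(maxit = 500L))
  if (opt$convergence != 0)
    stop("sigmoid fit did not converge: ", opt$message, call. = FALSE)
  # damped Gauss-Newton polish to machine precision (L-BFGS-B stops early)
  par <- opt$par; rss <- opt$value
  for (it in seq_len(50L)) {
    e <- exp(par[2] * (pressures - par[1]))
    f <- 1 / (1 + e)
    d <- e * f^2                       # -df/dx at x = k (p - p0)
    J <- cbind(par[2] * d, -(pressures - par[1]) * d)
    r <- od_norm - f
    sw <- sqrt(weights)
    step <- tryCatch(stats::lm.fit(J * sw, r * sw)$coefficients,
                     error = function(err) c(0, 0))
    step[!is.finite(step)] <- 0
    if (all(step == 0)) break
    lambda <- 1
    repeat {
      cand <- par + lambda * step
      cand[2] <- max(cand[2], 1e-8)
      new_rss <- obj(cand)
      if (new_rss <= rss || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (new_rss >= rss - 1e-16 * (1 + rss)) { if (new_rss < rss) { par <- cand; rss <- new_rss }; break }
    par <- cand; rss <- new_rss
  }
  structure(list(p0 = unname(par[1]), k = unname(par[2]),
                 rss = rss,
                 fitted = sigmoid_model(pressures, opt$par[1], opt$par[2]),
                 converged = TRUE, init = init),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Collapse sigmoid fit: p0 = %.3f bar, k = %.3f 1/bar (RSS %.3g)\n",
              x$p0, x$k, x$rss))
  if (!is.null(x$boot_mean))
    cat(sprintf("  bootstrap p0: %.3f +/- %.3f bar (%d resamples, %d failed)\n",
                x$boot_mean, x$boot_sd, x$n_boot, x$n_failed))
  invisible(x)
}

#' Bootstrap uncertainty of the collapse midpoint
#'
#' n-of-n resampling with replacement at the (pressure, od) pair level;
#' the fit is repeated on each resample and the midpoint uncertainty is
#' the mean and SD of p0 over the successful refits (default 50).
#'
#' @inheritParams fit_sigmoid
#' @param n_boot Number of bootstrap resamples (default 50).
#' @param seed RNG seed (default 0); results are bit-identical for a
#'   fixed seed.
#' @return A list with `mean`, `sd`, `p0s` (successful refits), `n_failed`.
#' @export
bootstrap_p0 <- function(pressures, od_norm, weights = NULL, n_boot = 50,
                         seed = 0) {
  stopifnot(n_boot >= 2)
  fit_sigmoid(pressures, od_norm, weights)  # must be fittable on full data
  n <- length(pressures)
  p0s <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sort(sample.int(n, n, replace = TRUE))
      w <- if (is.null(weights)) NULL else weights[idx]
      tryCatch(fit_sigmoid(pressures[idx], od_norm[idx], w)$p0,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(p0s))
  if (n_failed > n_boot / 2)
    stop("bootstrap failed: more than half of the refits did not converge",
         call. = FALSE)
  ok <- p0s[!is.na(p0s)]
  list(mean = mean(ok), sd = stats::sd(ok), p0s = ok, n_failed = n_failed)
}

#' Fit a collapse curve table with replicate handling
#'
#' Computes per-pressure means over replicates, uses the replicate
#' standard deviations as inverse-variance weights when at least two
#' replicates exist (`weighted = TRUE`), normalises, fits the sigmoid and
#' attaches the bootstrap uncertainty of p0.
#'
#' @param curve A data.frame with columns `pressure`, `od500` and
#'   optionally `replicate` (e.g. from [make_collapse_curve()] or
#'   [read_collapse_table()]).
#' @param weighted Use inverse-variance weighting from replicate SDs
#'   (default TRUE; ignored without replicates).
#' @param n_boot,seed Passed to [bootstrap_p0()].
#' @return A `sigmoid_fit` with bootstrap fields `boot_mean`, `boot_sd`,
#'   `n_boot`, `n_failed`.
#' @export
fit_collapse_curve <- function(curve, weighted = TRUE, n_boot = 50, seed = 0) {
  stopifnot(is.data.frame(curve),
            all(c("pressure", "od500") %in% names(curve)))
  p <- sort(unique(curve$pressure))
  m <- tapply(curve$od500, curve$pressure, mean)[as.character(p)]
  s <- tapply(curve$od500, curve$pressure, stats::sd)[as.character(p)]
  nrep <- tapply(curve$od500, curve$pressure, length)[as.character(p)]
  odn <- normalize_od(as.numeric(m))
  w <- NULL
  if (weighted && all(nrep >= 2) && all(is.finite(s)) && all(s > 0)) {
    # sds are on the raw scale; weights only need to be proportional
    w <- 1 / as.numeric(s)^2
    w <- w / mean(w)
  }
  fit <- fit_sigmoid(p, odn, w)
  bt <- bootstrap_p0(p, odn, w, n_boot = n_boot, seed = seed)
  fit$boot_mean <- bt$mean
  fit$boot_sd <- bt$sd
  fit$n_boot <- n_boot
  fit$n_failed <- bt$n_failed
  fit
}

#' Read a collapse-pressure table
#'
#' Delimited text with columns `pressure` (bar), `od500` and optionally
#' `replicate`.
#'
#' @param path File path (tab/whitespace/comma delimited, with header).
#' @return A data.frame of class `collapse_curve`.
#' @export
read_collapse_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           comment.char = "#")
  if (ncol(tab) == 1L) tab <- utils::read.csv(path, comment.char = "#")
  if (!all(c("pressure", "od500") %in% names(tab)))
    stop("need columns `pressure` and `od500`", call. = FALSE)
  class(tab) <- c("collapse_curve", "data.frame")
  tab
}
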