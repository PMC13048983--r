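#' Extract ON and OFF dwell times from a state sequence
#'
#' Maximal runs of constant state become dwells of length
#' `(run length in bins) * delta`. The input can be a fitted model (its
#' per-bin ON marginal is binarized at the 0.5 threshold; a marginal of
#' exactly 0.5 resolves to OFF), an integer label vector (1 = ON, 2 = OFF)
#' or a numeric marginal in `[0, 1]`. Runs touching either end of the trace
#' are truncated by the observation window; they are kept under
#' `boundary = "include"` (the default) and dropped under `"censor"`.
#'
#' @param x A `"blink_hmm"` fit, integer labels, or a numeric ON marginal.
#' @param delta Bin width in seconds (taken from the fit when available).
#' @param boundary `"include"` or `"censor"` boundary runs.
#' @return List with components `on` and `off`, each a `"dwell_set"`.
#' @export
#' @examples
#' d <- extract_dwells(c(1, 1, 2, 1, 1, 1), delta = 5e-4)
#' d$on$durations # 1.0 ms and 1.5 ms
extract_dwells <- function(x, delta = NULL, boundary = c("include", "censor")) {
  boundary <- match.arg(boundary)
  if (inherits(x, "blink_hmm")) {
    if (is.null(delta)) delta <- x$trace$delta
    x <- x$state_marginal
  }
  if (is.null(delta)) stop("delta is required")
  labels <- if (is.integer(x) || any(x > 1)) {
    if (!all(x %in% c(1, 2))) stop("label sequences must contain only 1 (ON) and 2 (OFF)")
    as.integer(x)
  } else {
    stopifnot(all(x >= 0 & x <= 1))
    ifelse(x > 0.5, 1L, 2L) # ties at exactly 0.5 resolve to OFF
  }
  if (!length(labels)) stop("empty state sequence")
  r <- rle(labels)
  keep <- rep(TRUE, length(r$lengths))
  if (boundary == "censor") {
    keep[1] <- FALSE
    keep[length(keep)] <- FALSE
  }
  mk <- function(state_label, state_name) {
    sel <- keep & r$values == state_label
    dwell_set(r$lengths[sel] * delta, state = state_name,
              delta = delta, boundary_policy = boundary)
  }
  list(on = mk(1L, "on"), off = mk(2L, "off"))
}

#' Construct a dwell-time set
#'
#' @param durations Dwell times in seconds (positive multiples of `delta`).
#' @param state `"on"` or `"off"`.
#' @param delta Bin width that produced the dwells (seconds).
#' @param boundary_policy `"include"` or `"censor"` (metadata).
#' @return Object of class `"dwell_set"`.
#' @export
dwell_set <- function(durations, state = c("on", "off"), delta,
                      boundary_policy = "include") {
  state <- match.arg(state)
  stopifnot(is.numeric(durations), all(durations > 0), delta > 0)
  k <- durations / delta
  if (any(abs(k - round(k)) > 1e-6))
    stop("durations must be positive integer multiples of delta")
  structure(list(durations = as.numeric(durations), state = state,
                 n_events = length(durations), delta = delta,
                 boundary_policy = boundary_policy),
            class = "dwell_set")
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf("%s dwells: %d events, mean %.3f ms (boundary runs %sd)\n",
              toupper(x$state), x$n_events,
              if (x$n_events) 1e3 * mean(x$durations) else NA_real_,
              x$boundary_policy))
  invisible(x)
}

#' Pool dwell sets across molecules
#'
#' Concatenates dwell sets of the same state and bin width; event counts are
#' additive.
#'
#' @param dwell_sets A list of `"dwell_set"` objects.
#' @return A single `"dwell_set"`.
#' @export
pool_dwells <- function(dwell_sets) {
  stopifnot(length(dwell_sets) >= 1,
            all(vapply(dwell_sets, inherits, logical(1), "dwell_set")))
  states <- vapply(dwell_sets, `[[`, character(1), "state")
  deltas <- vapply(dwell_sets, `[[`, numeric(1), "delta")
  if (length(unique(states)) != 1)
    stop("cannot pool dwell sets with mixed state labels: ",
         paste(unique(states), collapse = ", "))
  if (diff(range(deltas)) > 1e-12)
    stop("cannot pool dwell sets with different bin widths")
  dwell_set(unlist(lapply(dwell_sets, `[[`, "durations")),
            state = states[1], delta = deltas[1],
            boundary_policy = dwell_sets[[1]]$boundary_policy)
}

#' Dwell-time probability density (blinking plot)
#'
#' Histogram-type density on the grid `tau_k = k * dtau`: bin `k` counts
#' events with `tau_{k-1} <= tau < tau_k` and the density is
#' `p(tau_k) = n_k / (N_e * dtau)`, so `sum_k p(tau_k) * dtau = 1` exactly.
#'
#' @param d A `"dwell_set"`.
#' @param dtau Grid spacing in seconds (default 1 ms).
#' @return Object of class `"dwell_pdf"`: list with `grid` (bin upper edges
#'   `tau_k`), `counts`, `density`, `dtau`, `n_events`, `state`.
#' @export
#' @examples
#' d <- dwell_set(c(1, 1, 2, 3) * 1e-3, "on", delta = 1e-3)
#' dwell_pdf(d, dtau = 1e-3)$density # 0, 500, 250, 250 per second
dwell_pdf <- function(d, dtau = 1e-3) {
  stopifnot(inherits(d, "dwell_set"), dtau > 0)
  if (d$n_events == 0) stop("empty dwell set")
  # a duration exactly on a grid point tau_k belongs to bin k + 1
  idx <- as.integer(floor(d$durations / dtau + 1e-9)) + 1L
  n_tau <- max(idx)
  counts <- tabulate(idx, nbins = n_tau)
  structure(list(grid = seq_len(n_tau) * dtau, counts = counts,
                 density = counts / (d$n_events * dtau), dtau = dtau,
                 n_events = d$n_events, state = d$state),
            class = "dwell_pdf")
}

#' @export
print.dwell_pdf <- function(x, ...) {
  cat(sprintf("%s dwell-time density: %d events on %d grid cells of %.3g ms\n",
              toupper(x$state), x$n_events, length(x$grid), 1e3 * x$dtau))
  invisible(x)
}

#' @export
plot.dwell_pdf <- function(x, fit = NULL, ...) {
  graphics::barplot(x$density, names.arg = sprintf("%.0f", 1e3 * x$grid),
                    xlab = "duration (ms)", ylab = "probability density (1/s)",
                    main = paste(toupper(x$state), "dwell-time density"),
                    col = "mediumpurple", border = NA, ...)
  invisible(x)
}

#' Fit an exponential dwell-time density
#'
#' Fits `p(tau) = (1/s) exp(-tau/s)` to a dwell set. Under `method = "mle"`
#' the estimate is the sample mean (the maximum-likelihood estimator of the
#' exponential scale) with standard error `s / sqrt(N_e)`. Under
#' `method = "histogram_lsq"` the scale minimizes the squared deviation
#' between the model density and the [dwell_pdf()] histogram on its grid
#' (the model is evaluated at bin midpoints to limit discretization bias).
#'
#' @param d A `"dwell_set"`.
#' @param method `"mle"` or `"histogram_lsq"`.
#' @param dtau Histogram grid spacing for `"histogram_lsq"`.
#' @return Object of class `"exp_fit"`: list with `s` (seconds), `method`,
#'   `stderr`, `n_events`, `state`.
#' @export
#' @examples
#' d <- dwell_set(c(2, 4, 6) * 1e-3, "on", delta = 1e-3)
#' fit_exponential(d)$s # 0.004
fit_exponential <- function(d, method = c("mle", "histogram_lsq"),
                            dtau = 1e-3) {
  method <- match.arg(method)
  stopifnot(inherits(d, "dwell_set"))
  if (d$n_events == 0) stop("empty dwell set")
  if (d$n_events < 10)
    warning("only ", d$n_events, " dwell events; the fitted decay constant ",
            "will be noisy")
  if (method == "mle") {
    s <- mean(d$durations)
    stderr <- s / sqrt(d$n_events)
  } else {
    pdf <- dwell_pdf(d, dtau = dtau)
    mid <- pdf$grid - dtau / 2
    obj <- function(log_s) {
      s <- exp(log_s)
      sum((pdf$density - exp(-mid / s) / s)^2)
    }
    opt <- optimize(obj, interval = log(c(dtau / 20, 100 * max(d$durations))))
    s <- exp(opt$minimum)
    stderr <- NA_real_
  }
  structure(list(s = s, method = method, stderr = stderr,
                 n_events = d$n_events, state = d$state),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential dwell fit (%s, %s): s = %.3f ms",
              toupper(x$state), x$method, 1e3 * x$s))
  if (is.finite(x$stderr)) cat(sprintf(" +/- %.3f ms", 1e3 * x$stderr))
  cat(sprintf(" (N_e = %d)\n", x$n_events))
  invisible(x)
}

#' Relaxation times from an averaged transition matrix
#'
#' Inverts the first-order dwell discretization: a self-transition
#' probability `A_kk` per bin of width `delta` corresponds to a geometric
#' dwell with mean `delta / (1 - A_kk)`. Applied to the posterior-mean
#' transition matrix this gives the ON and OFF relaxation times.
#'
#' @param A_bar Averaged transition matrix (diagonal entries in `[0, 1]`).
#' @param delta Bin width in seconds.
#' @return Named numeric vector of relaxation times in seconds (`Inf` with a
#'   warning where `A_kk = 1`).
#' @export
#' @examples
#' relaxation_from_transition(matrix(c(0.9, 0.1, 0.05, 0.95), 2), 5e-4)
relaxation_from_transition <- function(A_bar, delta) {
  stopifnot(is.matrix(A_bar), nrow(A_bar) == ncol(A_bar), delta > 0)
  d <- diag(A_bar)
  if (any(d < 0 | d > 1))
    stop("diagonal entries of A must lie in [0, 1]")
  tau <- ifelse(d == 1, Inf, delta / (1 - d))
  if (any(is.infinite(tau)))
    warning("A_kk = 1 for state(s) ", paste(which(d == 1), collapse = ", "),
            ": infinite dwell reported")
  K <- nrow(A_bar)
  names(tau) <- c("on", "off", if (K > 2) paste0("state", 3:K))[seq_len(K)]
  tau
}
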