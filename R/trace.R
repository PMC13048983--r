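#' Construct a photon-count trace
#'
#' The observed data container: one nonnegative integer photon count per
#' fixed-width time bin.
#'
#' @param counts Nonnegative integer vector (length at least 2).
#' @param delta Bin width in seconds.
#' @param molecule_id Text label identifying the molecule/record.
#' @return An object of class `"photon_trace"`.
#' @export
#' @examples
#' photon_trace(c(18, 22, 1, 0, 19), delta = 5e-4)
photon_trace <- function(counts, delta, molecule_id = "mol") {
  if (!is.numeric(counts) || length(counts) < 2)
    stop("counts must be a numeric vector of length >= 2")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be nonnegative integers")
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("delta must be a single positive number (seconds)")
  structure(list(counts = as.integer(round(counts)), delta = delta,
                 molecule_id = as.character(molecule_id)),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("Photon trace '%s': %d bins of %.4g ms (%.4g s), mean %.2f counts/bin\n",
              x$molecule_id, length(x$counts), 1e3 * x$delta,
              length(x$counts) * x$delta, mean(x$counts)))
  invisible(x)
}

#' Standardize a trace to zero mean and unit variance
#'
#' Uses the population standard deviation (divisor `N`) so that the realized
#' series has exactly unit variance. The returned `center` and `scale` allow
#' fitted emission parameters to be mapped back to counts/bin:
#' `mu_raw = mu * scale + center`, `sigma2_raw = scale^2 / lambda`.
#'
#' @param trace A [photon_trace()] or numeric vector.
#' @return List with `z` (standardized values), `center`, `scale`.
#' @export
#' @examples
#' standardize(photon_trace(c(0, 10, 20), 1e-3))$z
standardize <- function(trace) {
  x <- if (inherits(trace, "photon_trace")) trace$counts else trace
  stopifnot(is.numeric(x), length(x) >= 2)
  center <- mean(x)
  scale <- sqrt(mean((x - center)^2))
  if (scale <= 0)
    stop("trace has zero spread (all counts identical); standardization is undefined")
  list(z = (x - center) / scale, center = center, scale = scale)
}

#' Map standardized emission parameters back to counts/bin
#'
#' @param mu,lam Emission means and precisions on the standardized scale.
#' @param std The list returned by [standardize()].
#' @return List with `mu` (counts/bin) and `sigma2` (counts^2/bin).
#' @export
destandardize_params <- function(mu, lam, std) {
  stopifnot(all(lam > 0))
  list(mu = mu * std$scale + std$center, sigma2 = std$scale^2 / lam)
}

#' Photon-count histogram of a trace
#'
#' Exact tally `h(n)` of the integer counts over the support `0..max(count)`.
#'
#' @param trace A [photon_trace()].
#' @return Object of class `"count_histogram"`: list with `support`, `h`,
#'   `n_events` (= trace length), `delta`.
#' @export
count_histogram <- function(trace) {
  stopifnot(inherits(trace, "photon_trace"))
  support <- 0:max(trace$counts)
  h <- tabulate(trace$counts + 1L, nbins = length(support))
  structure(list(support = support, h = h, n_events = length(trace$counts),
                 delta = trace$delta),
            class = "count_histogram")
}

#' @export
print.count_histogram <- function(x, ...) {
  cat(sprintf("Photon-count histogram: %d events, support 0..%d, mode at n = %d\n",
              x$n_events, max(x$support), x$support[which.max(x$h)]))
  invisible(x)
}

#' Rebin a trace or arrival record to a new bin width
#'
#' From a count trace, `new_delta` must be an integer multiple of the current
#' bin width; consecutive windows are summed and a trailing partial window is
#' dropped (so all bins stay identically distributed). From raw photon
#' arrival times any `new_delta > 0` works. Total photons are conserved up to
#' the dropped remainder.
#'
#' @param x A [photon_trace()] or `"photon_arrivals"` record.
#' @param new_delta Target bin width in seconds.
#' @param ... Unused.
#' @return A [photon_trace()] at the new bin width.
#' @export
#' @examples
#' tr <- photon_trace(c(1, 2, 3, 4), 1e-3)
#' rebin(tr, 2e-3)$counts # 3, 7
rebin <- function(x, new_delta, ...) UseMethod("rebin")

#' @rdname rebin
#' @export
rebin.photon_trace <- function(x, new_delta, ...) {
  stopifnot(new_delta > 0)
  ratio <- new_delta / x$delta
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("new_delta must be an integer multiple of the trace bin width; ",
         "rebin the raw arrival record for arbitrary bin widths")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(x)
  n_full <- length(x$counts) %/% ratio
  if (n_full < 2) stop("rebinned trace would have fewer than 2 bins")
  counts <- colSums(matrix(x$counts[seq_len(n_full * ratio)], nrow = ratio))
  photon_trace(counts, delta = new_delta, molecule_id = x$molecule_id)
}

#' @rdname rebin
#' @export
rebin.photon_arrivals <- function(x, new_delta, ...) {
  stopifnot(new_delta > 0)
  nb <- as.integer(floor(x$duration / new_delta + 1e-9))
  if (nb < 2) stop("rebinned trace would have fewer than 2 bins")
  t <- x$times[x$times < nb * new_delta]
  counts <- tabulate(pmin(as.integer(floor(t / new_delta)) + 1L, nb), nbins = nb)
  photon_trace(counts, delta = new_delta, molecule_id = "arrivals")
}
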