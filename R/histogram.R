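#' Two-Gaussian model of the photon-count histogram
#'
#' Evaluates the mixture model of the count histogram implied by a fit: the
#' two de-standardized emission Gaussians weighted by the posterior ON/OFF
#' occupancies and scaled to the total number of counting events,
#' `h_model(n) = N_eve * (w_on N(n | mu_on, sigma2_on) +
#' w_off N(n | mu_off, sigma2_off))`.
#'
#' @param fit A `"blink_hmm"` fit.
#' @param hist Optional [count_histogram()]; defaults to the histogram of the
#'   fitted trace.
#' @return Object of class `"model_histogram"`: list with `support`, `h`
#'   (observed counts), `h_model`, `w_on`, `w_off`, `mu`, `sigma2`,
#'   `n_events`.
#' @export
model_histogram <- function(fit, hist = NULL) {
  stopifnot(inherits(fit, "blink_hmm"))
  if (is.null(hist)) hist <- count_histogram(fit$trace)
  stopifnot(inherits(hist, "count_histogram"))
  p <- fit$posterior
  w <- p$w
  if (abs(sum(w) - 1) > 1e-9)
    stop("occupancy weights do not sum to 1")
  hm <- hist$n_events *
    (w["on"] * dnorm(hist$support, p$mu["on"], sqrt(p$sigma2["on"])) +
     w["off"] * dnorm(hist$support, p$mu["off"], sqrt(p$sigma2["off"])))
  structure(list(support = hist$support, h = hist$h, h_model = unname(hm),
                 w_on = unname(w["on"]), w_off = unname(w["off"]),
                 mu = p$mu, sigma2 = p$sigma2, n_events = hist$n_events),
            class = "model_histogram")
}

#' @export
print.model_histogram <- function(x, ...) {
  mis <- sum(abs(x$h - x$h_model)) / x$n_events
  cat(sprintf("Two-Gaussian histogram model: w_on = %.3f, misfit sum|h - h_model|/N = %.3f\n",
              x$w_on, mis))
  invisible(x)
}

#' @export
plot.model_histogram <- function(x, ...) {
  plot(x$support, x$h, type = "h", col = "mediumpurple", lwd = 2,
       xlab = "photon count per bin", ylab = "occurrences h(n)",
       main = "Photon-count histogram", ...)
  lines(x$support, x$h_model, col = "forestgreen", lwd = 2)
  legend("topright", legend = c("observed", "model"),
         col = c("mediumpurple", "forestgreen"), lty = 1, bty = "n")
  invisible(x)
}

#' Classify the modality of the emission mixture
#'
#' Quantifies how separated the fitted ON and OFF emission components are by
#' the separation score `d = (mu_on - mu_off) / (sd_on + sd_off)` and
#' classifies the histogram shape: `"bimodal"` for `d >= 1` (boundary
#' inclusive), `"shoulder"` for `0.5 <= d < 1`, `"unimodal"` for `d < 0.5`.
#' The thresholds are a reproducible stand-in for the visual judgement of
#' histogram shape: well-separated mixtures read as two peaks, partially
#' overlapping ones as a shoulder.
#'
#' @param x A `"model_histogram"`, a `"blink_hmm"` fit, or a list with `mu`
#'   (ON, OFF) and `sigma2` (ON, OFF).
#' @return List with `separation` (the score `d`) and `class`.
#' @export
#' @examples
#' bimodality_report(list(mu = c(20, 2), sigma2 = c(20, 2)))
bimodality_report <- function(x) {
  if (inherits(x, "blink_hmm")) x <- x$posterior
  if (inherits(x, "model_histogram")) x <- list(mu = x$mu, sigma2 = x$sigma2)
  mu <- unname(x$mu); sigma2 <- unname(x$sigma2)
  stopifnot(length(mu) >= 2, all(sigma2 > 0))
  if (mu[1] < mu[2]) stop("components must be ordered mu_on > mu_off")
  d <- (mu[1] - mu[2]) / (sqrt(sigma2[1]) + sqrt(sigma2[2]))
  cls <- if (d >= 1) "bimodal" else if (d >= 0.5) "shoulder" else "unimodal"
  list(separation = d, class = cls)
}

#' Trajectory quality-control flag
#'
#' Flags a fit whose histogram classification is unimodal (the ON/OFF
#' emission levels are not distinguishable, so the inferred state sequence is
#' dominated by the identifiability limit) or whose post-burn-in mean
#' surrogate log-likelihood falls below the `-1.4189` emission baseline.
#' Flags are reported, never auto-dropped.
#'
#' @param fit A `"blink_hmm"` fit.
#' @return List with `flagged`, `reasons`, `separation`, `class`,
#'   `objective_mean`.
#' @export
qc_flag <- function(fit) {
  stopifnot(inherits(fit, "blink_hmm"))
  bi <- bimodality_report(fit)
  keep <- (fit$burn_in + 1):fit$n_iter
  L_mean <- mean(fit$objective$L[keep])
  baseline <- -(1 + log(2 * pi)) / 2
  reasons <- character(0)
  if (bi$class == "unimodal")
    reasons <- c(reasons, sprintf("unimodal emission mixture (d = %.2f)",
                                  bi$separation))
  if (L_mean < baseline)
    reasons <- c(reasons, sprintf("mean objective %.3f below baseline %.4f",
                                  L_mean, baseline))
  list(flagged = length(reasons) > 0, reasons = reasons,
       separation = bi$separation, class = bi$class,
       objective_mean = L_mean)
}

#' Mean-variance table across molecules
#'
#' One row per molecule per state with the de-standardized emission mean and
#' variance and the Poisson-deviation ratio `sigma2 / mu`. For shot-noise
#' dominated photon counting the ratio should sit near 1; rows with a ratio
#' outside `[0.5, 2]` or a nonpositive mean are flagged (never dropped).
#'
#' @param fits A list of `"blink_hmm"` fits (or a single fit).
#' @return A `data.frame` with columns `molecule_id`, `state`, `mu`, `var`,
#'   `ratio`, `flag`.
#' @export
mean_variance_table <- function(fits) {
  if (inherits(fits, "blink_hmm")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "blink_hmm")))
  rows <- lapply(fits, function(f) {
    p <- f$posterior
    data.frame(molecule_id = f$trace$molecule_id,
               state = c("on", "off"),
               mu = unname(p$mu[c("on", "off")]),
               var = unname(p$sigma2[c("on", "off")]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ratio <- ifelse(out$mu > 0, out$var / out$mu, NA_real_)
  out$flag <- out$mu <= 0 | is.na(out$ratio) | out$ratio < 0.5 | out$ratio > 2
  rownames(out) <- NULL
  out
}
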