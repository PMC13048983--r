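#' Write a photon-count trace to CSV
#'
#' Self-describing single-file format: comment lines starting with `#` carry
#' metadata (`# delta_s=`, `# molecule_id=`, optionally `# seed=`), followed
#' by a `bin,count` header and one row per bin.
#'
#' @param trace A [photon_trace()].
#' @param path Output file path.
#' @param seed Optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, seed = NULL) {
  stopifnot(inherits(trace, "photon_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# delta_s=%.12g", trace$delta),
               sprintf("# molecule_id=%s", trace$molecule_id),
               if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)),
               "bin,count"), con)
  writeLines(sprintf("%d,%d", seq_along(trace$counts) - 1L, trace$counts), con)
  invisible(path)
}

#' Write photon arrival times to a text file
#'
#' One arrival time (seconds) per line; `#`-prefixed metadata header with the
#' detector resolution and record duration.
#'
#' @param arrivals A `"photon_arrivals"` record.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_arrivals <- function(arrivals, path) {
  stopifnot(inherits(arrivals, "photon_arrivals"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# resolution_s=%.12g", arrivals$resolution),
               sprintf("# duration_s=%.12g", arrivals$duration)), con)
  writeLines(sprintf("%.12g", arrivals$times), con)
  invisible(path)
}

parse_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([A-Za-z_]+)=(.*)$", meta_lines))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- m[3]
  out
}

#' Read a photon-count trace or arrival record from disk
#'
#' `format = "counts_csv"` reads the [write_trace()] format; a `delta`
#' argument overrides the header value (the override is messaged).
#' `format = "arrivals_txt"` reads one arrival time per line and bins it at
#' `delta` via [rebin()].
#'
#' @param path Input file path.
#' @param format `"counts_csv"` or `"arrivals_txt"`.
#' @param delta Bin width in seconds (required for arrivals; optional
#'   override for counts).
#' @return A [photon_trace()].
#' @export
read_trace <- function(path, format = c("counts_csv", "arrivals_txt"),
                       delta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta <- parse_meta(lines)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (format == "counts_csv") {
    header_at <- which(body == "bin,count")
    if (length(header_at) != 1)
      stop("counts_csv file must contain a 'bin,count' header line")
    rows <- body[-seq_len(header_at)]
    parts <- strsplit(rows, ",", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != 2 |
                   is.na(suppressWarnings(
                     vapply(parts, function(p) as.numeric(p[2]), numeric(1)))))
    if (length(bad))
      stop("malformed count row at data line ", bad[1], ": '", rows[bad[1]], "'")
    counts <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9)) {
      bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-9)[1]
      stop("negative or non-integer count at data line ", bad,
           ": '", rows[bad], "'")
    }
    header_delta <- if (!is.null(meta$delta_s)) as.numeric(meta$delta_s) else NULL
    if (is.null(delta)) delta <- header_delta
    if (is.null(delta))
      stop("bin width missing: no '# delta_s=' header and no delta argument")
    if (!is.null(header_delta) && !is.null(delta) &&
        abs(header_delta - delta) > 1e-15)
      message("delta argument (", delta, " s) overrides header value (",
              header_delta, " s)")
    photon_trace(counts, delta = delta,
                 molecule_id = meta$molecule_id %||% basename(path))
  } else {
    if (is.null(delta)) stop("delta is required to bin an arrival record")
    times <- suppressWarnings(as.numeric(body))
    if (anyNA(times))
      stop("malformed arrival time at data line ", which(is.na(times))[1],
           ": '", body[which(is.na(times))[1]], "'")
    duration <- if (!is.null(meta$duration_s)) as.numeric(meta$duration_s)
      else ceiling(max(times) / delta) * delta
    arr <- structure(list(times = sort(times),
                          resolution = as.numeric(meta$resolution_s %||% 0),
                          duration = duration),
                     class = "photon_arrivals")
    tr <- rebin(arr, delta)
    tr$molecule_id <- meta$molecule_id %||% basename(path)
    tr
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dwell set as one duration per line
#'
#' @param d A `"dwell_set"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dwells <- function(d, path) {
  stopifnot(inherits(d, "dwell_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# state=%s", d$state),
               sprintf("# delta_s=%.12g", d$delta),
               sprintf("# boundary_policy=%s", d$boundary_policy),
               sprintf("# n_events=%d", d$n_events)), con)
  writeLines(sprintf("%.12g", d$durations), con)
  invisible(path)
}

#' Write a dwell-time density as CSV
#'
#' Columns `tau_s`, `count`, `density`.
#'
#' @param pdf A `"dwell_pdf"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dwell_pdf <- function(pdf, path) {
  stopifnot(inherits(pdf, "dwell_pdf"))
  df <- data.frame(tau_s = pdf$grid, count = pdf$counts,
                   density = pdf$density)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an observed + model photon-count histogram as CSV
#'
#' Columns `n`, `h`, `h_model`.
#'
#' @param mh A `"model_histogram"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(mh, path) {
  stopifnot(inherits(mh, "model_histogram"))
  df <- data.frame(n = mh$support, h = mh$h, h_model = mh$h_model)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_to_list <- function(fit) {
  s <- summary(fit)
  p <- fit$posterior
  list(molecule_id = fit$trace$molecule_id,
       n_bins = length(fit$trace$counts),
       delta_s = fit$trace$delta,
       mu = as.list(p$mu), sigma2 = as.list(p$sigma2),
       mu_std = as.list(p$mu_std), lam_std = as.list(p$lam_std),
       A = list(on = as.list(p$A[, "on"]), off = as.list(p$A[, "off"])),
       pi = as.list(p$pi), w = as.list(p$w),
       n_on_mean = p$n_on_mean, n_off_mean = p$n_off_mean,
       standardized = list(center = fit$std$center, scale = fit$std$scale),
       relaxation_ms = as.list(1e3 * s$relaxation),
       objective_mean = s$objective_mean,
       convergence_sweep = s$convergence_sweep,
       qc = s$qc[c("flagged", "reasons", "separation", "class")])
}

#' Run the full blinking analysis pipeline
#'
#' Ties simulate/read, fit, dwell extraction and reporting into one
#' reproducible run: every molecule is fitted with [blink_hmm()] (seeded
#' deterministically from `seed`), dwells are extracted and pooled across
#' QC-passing molecules, dwell-time densities and exponential fits are
#' computed for both states, transition-matrix relaxation times are reported
#' as across-molecule mean +/- sd, and per-molecule histograms, objective
#' traces and QC flags are written to `out_dir`.
#'
#' @param config A list with entries:
#'   \describe{
#'     \item{inputs}{character vector of trace file paths (counts CSV), or}
#'     \item{traces}{a list of [photon_trace()] objects (alternative to
#'       `inputs`);}
#'     \item{delta}{bin width in seconds (for files without a header);}
#'     \item{n_iter, burn_in, seed}{sampler settings (defaults 1000 / 100 /
#'       1);}
#'     \item{prior}{a [blink_prior()] (default `blink_prior()`);}
#'     \item{boundary}{dwell boundary policy, `"include"` or `"censor"`;}
#'     \item{dtau}{dwell-histogram grid spacing in seconds (default 1 ms);}
#'     \item{out_dir}{output directory (created if missing).}
#'   }
#' @return The report (also written to `report.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  n_iter <- config$n_iter %||% 1000
  burn_in <- config$burn_in %||% 100
  seed <- config$seed %||% 1
  prior <- config$prior %||% blink_prior()
  boundary <- config$boundary %||% "include"
  dtau <- config$dtau %||% 1e-3
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  traces <- if (!is.null(config$traces)) {
    config$traces
  } else if (!is.null(config$inputs)) {
    missing <- config$inputs[!file.exists(config$inputs)]
    if (length(missing)) stop("missing input file(s): ",
                              paste(missing, collapse = ", "))
    lapply(config$inputs, read_trace, format = "counts_csv",
           delta = config$delta)
  } else stop("config needs either 'inputs' (paths) or 'traces' (objects)")

  # fingerprint the analysis settings (not the output location or in-memory
  # trace objects)
  cfg_desc <- paste(deparse(config[setdiff(names(config),
                                           c("traces", "out_dir"))]),
                    collapse = "")
  stamp <- list(seed = seed,
                package_version = as.character(packageVersion("blinkHMM")),
                config_hash = fnv1a(cfg_desc))

  fits <- vector("list", length(traces))
  per_mol <- vector("list", length(traces))
  log_lines <- character(0)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    fit <- tryCatch(
      blink_hmm(tr, prior = prior, n_iter = n_iter, burn_in = burn_in,
                seed = seed + i),
      error = function(e) stop("stage 'fit' failed for molecule '",
                               tr$molecule_id, "': ", conditionMessage(e)))
    fits[[i]] <- fit
    info <- fit_to_list(fit)
    jsonlite::write_json(
      c(stamp, info),
      file.path(out_dir, sprintf("fit_%s.json", tr$molecule_id)),
      auto_unbox = TRUE, digits = 10, pretty = TRUE)
    utils::write.csv(fit$objective,
                     file.path(out_dir,
                               sprintf("objective_%s.csv", tr$molecule_id)),
                     row.names = FALSE, quote = FALSE)
    write_histogram(model_histogram(fit),
                    file.path(out_dir,
                              sprintf("histogram_%s.csv", tr$molecule_id)))
    per_mol[[i]] <- info
    log_lines <- c(log_lines, sprintf(
      "molecule %s: %d bins, objective %.4f, convergence sweep %s, QC %s",
      tr$molecule_id, info$n_bins, info$objective_mean,
      format(info$convergence_sweep),
      if (info$qc$flagged) "FLAGGED" else "pass"))
  }

  pass <- !vapply(per_mol, function(m) isTRUE(m$qc$flagged), logical(1))
  report <- c(stamp, list(
    n_molecules = length(traces),
    n_qc_pass = sum(pass),
    molecules = per_mol))

  if (any(pass)) {
    dw <- lapply(fits[pass], extract_dwells, boundary = boundary)
    pooled_on <- pool_dwells(lapply(dw, `[[`, "on"))
    pooled_off <- pool_dwells(lapply(dw, `[[`, "off"))
    write_dwells(pooled_on, file.path(out_dir, "dwells_on.txt"))
    write_dwells(pooled_off, file.path(out_dir, "dwells_off.txt"))
    write_dwell_pdf(dwell_pdf(pooled_on, dtau),
                    file.path(out_dir, "dwell_pdf_on.csv"))
    write_dwell_pdf(dwell_pdf(pooled_off, dtau),
                    file.path(out_dir, "dwell_pdf_off.csv"))
    fe <- function(d, m) suppressWarnings(fit_exponential(d, m, dtau = dtau))
    tau_mat <- vapply(fits[pass], function(f)
      relaxation_from_transition(f$posterior$A, f$trace$delta),
      numeric(2))
    report$dwell_analysis <- list(
      n_events = list(on = pooled_on$n_events, off = pooled_off$n_events),
      s_mle_ms = list(on = 1e3 * fe(pooled_on, "mle")$s,
                      off = 1e3 * fe(pooled_off, "mle")$s),
      s_lsq_ms = list(on = 1e3 * fe(pooled_on, "histogram_lsq")$s,
                      off = 1e3 * fe(pooled_off, "histogram_lsq")$s),
      tau_transition_ms = list(
        on = list(mean = 1e3 * mean(tau_mat[1, ]),
                  sd = 1e3 * stats::sd(tau_mat[1, ])),
        off = list(mean = 1e3 * mean(tau_mat[2, ]),
                   sd = 1e3 * stats::sd(tau_mat[2, ]))))
  }

  mv <- mean_variance_table(fits)
  utils::write.csv(mv, file.path(out_dir, "mean_variance.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}
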