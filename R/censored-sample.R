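#' Type-I censored samples
#'
#' Container for a life test terminated at a fixed censoring time `T`:
#' `n_total` identical units go on test, the `m` failure times observed
#' before `T` are recorded in increasing order, and the remaining
#' `n_total - m` units are known only to survive past `T`.  A complete
#' sample is the degenerate case `censor_time = Inf`, `m = n_total`.
#'
#' @param times vector of positive observed failure times (sorted
#'   internally); may be empty when `n_total = 0` (a "no data" object used
#'   by prior-only posterior sampling).
#' @param n_total total number of units on test (default: `length(times)`,
#'   i.e. a complete sample).
#' @param censor_time the fixed termination time `T`; `Inf` for complete
#'   sampling.
#' @return An object of class `"censored_sample"`: the sorted times with
#'   attributes `n_total` and `censor_time`.
#' @examples
#' censored_sample(c(3, 1, 2), n_total = 5, censor_time = 4)
#' @export
censored_sample <- function(times, n_total = length(times), censor_time = Inf) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("'times' contains NA/NaN", call. = FALSE)
  if (length(times) && any(times <= 0))
    stop("'times' must be strictly positive", call. = FALSE)
  if (length(censor_time) != 1L || is.na(censor_time) || censor_time <= 0)
    stop("'censor_time' must be a positive time or Inf", call. = FALSE)
  if (n_total < length(times))
    stop("'n_total' must be at least the number of observed failures", call. = FALSE)
  if (length(times) && max(times) > censor_time)
    stop("observed failure times must not exceed 'censor_time'", call. = FALSE)
  structure(sort(times), n_total = as.integer(n_total),
            censor_time = censor_time, class = "censored_sample")
}

#' @export
print.censored_sample <- function(x, ...) {
  m <- length(x); n <- attr(x, "n_total"); Tc <- attr(x, "censor_time")
  if (is.finite(Tc))
    cat(sprintf("Type-I censored sample: m = %d failures of n = %d units, T = %g\n",
                m, n, Tc))
  else
    cat(sprintf("Complete sample: n = %d failures\n", n))
  if (m) print(as.numeric(x), ...)
  invisible(x)
}

as_censored_sample <- function(x, n_total = NULL, censor_time = Inf) {
  if (inherits(x, "censored_sample")) return(x)
  if (is.null(n_total)) n_total <- length(x)
  censored_sample(x, n_total = n_total, censor_time = censor_time)
}

#' Simulate a Type-I censored NEXF sample
#'
#' Draws `n` lifetimes by inverse-transform sampling and records only the
#' failures at or before the censoring time.
#'
#' @param theta numeric vector `c(alpha, beta, lambda)` of true parameters.
#' @param n number of units on test.
#' @param censor_time termination time `T` (default `Inf`: complete sample).
#' @param seed optional integer seed for reproducibility.
#' @return a [censored_sample] object.
#' @examples
#' s <- generate_censored_sample(c(0.5, 0.5, 0.5), 50, censor_time = 1.5, seed = 1)
#' @export
generate_censored_sample <- function(theta, n, censor_time = Inf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnexf(n, theta[1], theta[2], theta[3])
  censored_sample(x[x <= censor_time], n_total = n, censor_time = censor_time)
}

#' Read failure times from a single-column text file
#'
#' Accepts one positive number per row; a single non-numeric header line
#' (e.g. `time`) is tolerated.
#'
#' @param path path to a CSV/plain-text file.
#' @return sorted numeric vector of failure times; the count is reported
#'   via `message()`.
#' @export
read_times <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  if (!length(raw)) stop("empty input file: ", path, call. = FALSE)
  first <- suppressWarnings(as.numeric(raw[1]))
  if (is.na(first)) raw <- raw[-1]          # header line
  if (!length(raw)) stop("no data rows in: ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) | !is.finite(vals) | vals <= 0)
  if (length(bad))
    stop("nonpositive or non-numeric failure time at data row ", bad[1],
         " of ", path, call. = FALSE)
  message(length(vals), " failure times read from ", path)
  sort(vals)
}

#' Write a synthetic Type-I censored fixture with a truth sidecar
#'
#' Simulates a censored NEXF sample and writes it as a one-column CSV plus a
#' plain-text sidecar (`<path>.meta`) recording the generating parameters,
#' `n`, `m`, `T` and the seed, so downstream runs are self-describing.  The
#' defaults mirror a leukemia remission-time trial shape: 40 patients under a
#' heavy right censoring at day 205, with parameters at which roughly half
#' the cohort fails before termination.  The fixture is synthetic stand-in
#' data, not a published dataset.
#'
#' @param path output CSV path.
#' @param theta generating parameters `c(alpha, beta, lambda)`.
#' @param n number of units on test.
#' @param censor_time termination time.
#' @param seed integer seed.
#' @return (invisibly) the generated [censored_sample].
#' @export
make_fixture <- function(path, theta = c(14933.1, 120.539, 0.37816),
                         n = 40, censor_time = 205, seed = 101) {
  s <- generate_censored_sample(theta, n, censor_time, seed = seed)
  utils::write.table(data.frame(time = as.numeric(s)), path,
                     row.names = FALSE, col.names = TRUE, sep = ",",
                     quote = FALSE)
  meta <- c(sprintf("alpha: %.10g", theta[1]),
            sprintf("beta: %.10g", theta[2]),
            sprintf("lambda: %.10g", theta[3]),
            sprintf("n_total: %d", n),
            sprintf("m: %d", length(s)),
            sprintf("censor_time: %.10g", censor_time),
            sprintf("seed: %d", seed),
            "note: synthetic sample simulated from the recorded parameters")
  writeLines(meta, paste0(path, ".meta"))
  invisible(s)
}
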