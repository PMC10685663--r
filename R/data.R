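#' Individual-level right-censored survival data
#'
#' @param time Non-negative survival or censoring times.
#' @param event Event indicator: 1 = event observed, 0 = right-censored.
#' @param covariates Optional data.frame of numeric covariate values, one
#'   row per individual.
#'
#' @return A data.frame of class `"individual_data"` with columns `time`,
#'   `event` and any covariates.
#' @export
individual_data <- function(time, event, covariates = NULL) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  bad <- which(time < 0 | is.na(time))
  if (length(bad)) stop("negative or missing time in row ", bad[1])
  bad <- which(!event %in% c(0, 1))
  if (length(bad)) stop("event must be 0 or 1; offending row ", bad[1])
  out <- data.frame(time = time, event = event)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(time)) stop("covariate rows != data rows")
    out <- cbind(out, covariates)
  }
  class(out) <- c("individual_data", "data.frame")
  out
}

#' External aggregate survival data
#'
#' Each row states that out of `n` people alive at time `u` (with covariate
#' values `covariates`), `r` survived to time `v`. Counts may be
#' real-valued, as arises when the row encodes an elicited Beta judgement
#' (see [elicitation_to_counts()]); the likelihood uses the continuous
#' binomial kernel.
#'
#' @param u,v Interval start and end times, `0 <= u < v`.
#' @param n Number (possibly non-integer) alive at `u`; positive.
#' @param r Number surviving to `v`; `0 <= r <= n`.
#' @param covariates Optional data.frame of covariate values per row.
#' @return A data.frame of class `"external_data"`.
#' @export
external_data <- function(u, v, n, r, covariates = NULL) {
  u <- as.numeric(u); v <- as.numeric(v); n <- as.numeric(n); r <- as.numeric(r)
  len <- length(u)
  if (!all(lengths(list(v, n, r)) == len)) stop("u, v, n, r lengths differ")
  bad <- which(u < 0 | v <= u)
  if (length(bad)) stop("need 0 <= u < v; offending row ", bad[1])
  bad <- which(n < 1 | r < 0 | r > n)
  if (length(bad)) stop("need 0 <= r <= n and n >= 1; offending row ", bad[1])
  out <- data.frame(u = u, v = v, n = n, r = r)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != len) stop("covariate rows != data rows")
    out <- cbind(out, covariates)
  }
  class(out) <- c("external_data", "data.frame")
  out
}

#' Known piecewise-constant background hazard
#'
#' Defines a background (e.g. general-population) mortality rate as a step
#' function of time: rate `rates[i]` applies on
#' `[breakpoints[i], breakpoints[i+1])`, and the final rate extends to
#' infinity.
#'
#' @param breakpoints Strictly increasing times starting at 0; one per rate.
#' @param rates Non-negative hazard rates (events per unit time).
#' @return An object of class `"background_hazard"`.
#' @export
background_hazard <- function(breakpoints, rates) {
  breakpoints <- as.numeric(breakpoints); rates <- as.numeric(rates)
  if (length(breakpoints) != length(rates)) stop("breakpoints and rates lengths differ")
  if (!length(rates)) stop("at least one rate required")
  if (breakpoints[1] != 0) stop("breakpoints must start at 0")
  if (is.unsorted(breakpoints, strictly = TRUE)) stop("breakpoints must be strictly increasing")
  if (any(rates < 0)) stop("rates must be non-negative")
  structure(list(breakpoints = breakpoints, rates = rates),
            class = "background_hazard")
}

#' @export
print.background_hazard <- function(x, ...) {
  cat("Piecewise-constant background hazard,", length(x$rates), "intervals\n")
  ends <- c(x$breakpoints[-1], Inf)
  print(data.frame(start = x$breakpoints, stop = ends, rate = x$rates))
  invisible(x)
}

## Exact background hazard and cumulative hazard (piecewise-linear H_b)
bg_hazard_at <- function(bg, t) {
  idx <- findInterval(t, bg$breakpoints)
  bg$rates[pmax(idx, 1L)]
}

bg_cumhaz_at <- function(bg, t) {
  ends <- c(bg$breakpoints[-1], Inf)
  H <- numeric(length(t))
  for (i in seq_along(bg$rates)) {
    overlap <- pmax(0, pmin(t, ends[i]) - bg$breakpoints[i])
    H <- H + bg$rates[i] * overlap
  }
  H
}

#' Elicited Beta judgement about a survival probability
#'
#' Represents an expert's Beta(a, b) distribution for the probability of
#' surviving from time `u` to time `v`.
#'
#' @param a,b Positive Beta shape parameters.
#' @param u,v Interval the judged probability refers to, `0 <= u < v`.
#' @param covariates Optional single-row data.frame of covariate values.
#' @return An object of class `"elicitation"`.
#' @export
elicitation <- function(a, b, u, v, covariates = NULL) {
  if (a <= 0 || b <= 0) stop("Beta shapes must be positive")
  if (u < 0 || v <= u) stop("need 0 <= u < v")
  structure(list(a = a, b = b, u = u, v = v, covariates = covariates),
            class = "elicitation")
}

#' Convert an elicited Beta judgement to equivalent survivor counts
#'
#' A Beta(a, b) judgement about the survival probability over an interval
#' is interpreted as the posterior from a vague Beta(0, 0) prior updated
#' with `r = a` survivors out of `n = a + b` at risk, giving an external
#' data row carrying the same information. Shapes need not be integers.
#'
#' @param e An [elicitation()] object.
#' @return A one-row [external_data()] table with `r = a`, `n = a + b`.
#' @export
elicitation_to_counts <- function(e) {
  stopifnot(inherits(e, "elicitation"))
  external_data(u = e$u, v = e$v, n = e$a + e$b, r = e$a,
                covariates = e$covariates)
}

#' Central credible interval of a Beta distribution
#'
#' Reports what an elicited Beta judgement implies: the equal-tailed
#' interval of the stated level.
#'
#' @param a,b Positive Beta shapes.
#' @param level Interval level in (0, 1), default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
beta_interval <- function(a, b, level = 0.95) {
  if (a <= 0 || b <= 0) stop("Beta shapes must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- (1 - level) / 2
  stats::qbeta(c(alpha, 1 - alpha), a, b)
}

## ---- CSV readers/writers -------------------------------------------------

read_checked <- function(path, required) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df
}

#' Read and write the three data roles as CSV
#'
#' Individual data use columns `time,event[,covariates]`; external data
#' `start,stop,n,r[,covariates]`; background hazard `start,stop,rate` with
#' contiguous intervals starting at 0 (the final `stop` may be empty or
#' `Inf`). All files are comma-separated with a header row. Validation
#' errors name the offending row.
#'
#' @param path File path.
#' @return The corresponding validated object.
#' @export
read_individual <- function(path) {
  df <- read_checked(path, c("time", "event"))
  covs <- df[setdiff(names(df), c("time", "event"))]
  individual_data(df$time, df$event, if (ncol(covs)) covs else NULL)
}

#' @rdname read_individual
#' @export
read_external <- function(path) {
  df <- read_checked(path, c("start", "stop", "n", "r"))
  covs <- df[setdiff(names(df), c("start", "stop", "n", "r"))]
  external_data(df$start, df$stop, df$n, df$r, if (ncol(covs)) covs else NULL)
}

#' @rdname read_individual
#' @export
read_background <- function(path) {
  df <- read_checked(path, c("start", "stop", "rate"))
  background_hazard(df$start, df$rate)
}

#' @rdname read_individual
#' @param x Object to write.
#' @export
write_individual <- function(x, path) {
  stopifnot(inherits(x, "individual_data"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_individual
#' @export
write_external <- function(x, path) {
  stopifnot(inherits(x, "external_data"))
  df <- as.data.frame(x)
  names(df)[match(c("u", "v"), names(df))] <- c("start", "stop")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_individual
#' @export
write_background <- function(x, path) {
  stopifnot(inherits(x, "background_hazard"))
  df <- data.frame(start = x$breakpoints,
                   stop = c(x$breakpoints[-1], Inf),
                   rate = x$rates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## covariate columns of a data role (everything beyond the structural ones)
cov_columns <- function(data) {
  structural <- c("time", "event", "u", "v", "n", "r")
  setdiff(names(data), structural)
}
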