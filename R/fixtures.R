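#' Synthetic optical-density growth curve
#'
#' Generates an exponential-growth OD time series `od0 * exp(b * t)` with
#' `b = gr_per_h * ln(2)` (so `gr_per_h` is in doublings per hour),
#' multiplied by lognormal noise of coefficient of variation `noise_cv`.
#' The generating parameters are stored so fitting routines can be tested
#' against ground truth.
#'
#' @param gr_per_h Growth rate in doublings per hour.
#' @param od0 Initial OD.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param times Sampling times in hours (strictly increasing).
#' @param seed Optional RNG seed.
#' @return A data frame with columns `time_h`, `value` and an attribute
#'   `truth` (list of the generating parameters).
#' @export
synthetic_od_curve <- function(gr_per_h, od0 = 0.1, noise_cv = 0,
                               times = seq(0, 18, by = 0.25), seed = NULL) {
  stopifnot(gr_per_h > 0, od0 > 0, noise_cv >= 0, all(diff(times) > 0))
  if (!is.null(seed)) set.seed(seed)
  b <- gr_per_h * log(2)
  values <- od0 * exp(b * times)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    values <- values * stats::rlnorm(length(times), -sdlog^2 / 2, sdlog)
  }
  out <- data.frame(time_h = times, value = values)
  attr(out, "truth") <- list(gr_per_h = gr_per_h, od0 = od0,
                             noise_cv = noise_cv)
  out
}

#' Synthetic lag/linear/saturation area curve
#'
#' Builds a colony-area curve with an initial exponential lag, an exactly
#' linear middle regime of known slope, and a saturating tail — the shape
#' that area curves of expanding colonies take — for testing the
#' linear-regime detection of [expansion_rate()].
#'
#' @param slope Linear-regime slope in um^2/h.
#' @param lag_h,linear_h,sat_h Durations of the three regimes (hours).
#' @param area0 Area at the start of the linear regime (um^2).
#' @param dt_h Sampling interval.
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param seed Optional RNG seed.
#' @return A data frame `time_h`, `area_um2`, with a `truth` attribute.
#' @export
synthetic_area_curve <- function(slope, lag_h = 6, linear_h = 24, sat_h = 12,
                                 area0 = 5e5, dt_h = 0.5, noise_cv = 0,
                                 seed = NULL) {
  stopifnot(slope > 0, lag_h >= 0, linear_h > 0, sat_h >= 0)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, lag_h + linear_h + sat_h, by = dt_h)
  area <- numeric(length(times))
  # lag: exponential approach ending tangentially at (lag_h, area0)
  lag_rate <- slope / area0
  in_lag <- times < lag_h
  area[in_lag] <- area0 * exp(lag_rate * (times[in_lag] - lag_h))
  in_lin <- times >= lag_h & times <= lag_h + linear_h
  area[in_lin] <- area0 + slope * (times[in_lin] - lag_h)
  a_end <- area0 + slope * linear_h
  in_sat <- times > lag_h + linear_h
  tau <- max(sat_h / 3, dt_h)
  area[in_sat] <- a_end + slope * tau *
    (1 - exp(-(times[in_sat] - lag_h - linear_h) / tau))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    area <- area * stats::rlnorm(length(times), -sdlog^2 / 2, sdlog)
  }
  out <- data.frame(time_h = times, area_um2 = area)
  attr(out, "truth") <- list(slope = slope, lag_h = lag_h,
                             linear_h = linear_h)
  out
}

#' Synthetic regression tables with planted effects
#'
#' Draws a design matrix matching the variables of the outcome models
#' (categorical inducer level or switching rate, edge-cluster count,
#' initial spatial metrics, initial-condition label), computes the response
#' from the supplied linear form plus Gaussian noise, and stores the truth.
#' For a balanced orthogonal design the analytic sequential eta-squared
#' decomposition equals each term's share of the generated variance.
#'
#' @param n Number of rows.
#' @param betas Named list of coefficients. Continuous predictors get a
#'   single coefficient; categorical predictors a vector of per-level
#'   effects (contrasts are applied as given). Interactions are named
#'   `"a:b"` and multiply the two (numeric or effect-coded) columns.
#' @param design Named list describing each predictor: either
#'   `list(type = "continuous")` (standard normal draw) or
#'   `list(type = "categorical", levels = k)` (balanced random levels).
#' @param noise_sd Residual standard deviation.
#' @param seed Optional RNG seed.
#' @return A data frame with the predictors and response `y`; attribute
#'   `truth` holds the betas and per-term expected variance contributions.
#' @export
synthetic_regression_table <- function(n, betas, design, noise_sd = 1,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  main <- names(design)
  bad <- setdiff(setdiff(names(betas), main),
                 unlist(lapply(strsplit(names(betas), ":"), function(p)
                   if (length(p) == 2 && all(p %in% main)) paste(p, collapse = ":")
                   else character(0))))
  if (length(bad)) stop("betas refer to unknown terms: ",
                        paste(bad, collapse = ", "))
  tab <- data.frame(row.names = seq_len(n))
  numcol <- list()
  for (v in main) {
    d <- design[[v]]
    if (identical(d$type, "categorical")) {
      k <- d$levels
      lev <- rep_len(seq_len(k), n)[sample.int(n)] # balanced, shuffled
      tab[[v]] <- factor(lev)
      eff <- betas[[v]] %||% rep(0, k)
      if (length(eff) != k) stop("effect length mismatch for ", v)
      numcol[[v]] <- eff[lev]
    } else {
      tab[[v]] <- stats::rnorm(n)
      numcol[[v]] <- (betas[[v]] %||% 0) * tab[[v]]
    }
  }
  y <- 0
  contrib <- list()
  for (term in names(betas)) {
    parts <- strsplit(term, ":")[[1]]
    if (length(parts) == 1) {
      contrib[[term]] <- numcol[[term]]
    } else {
      a <- if (is.factor(tab[[parts[1]]])) numcol[[parts[1]]] else tab[[parts[1]]]
      b <- if (is.factor(tab[[parts[2]]])) numcol[[parts[2]]] else tab[[parts[2]]]
      contrib[[term]] <- betas[[term]] * a * b
    }
    y <- y + contrib[[term]]
  }
  y <- y + stats::rnorm(n, sd = noise_sd)
  tab$y <- y
  attr(tab, "truth") <- list(betas = betas, noise_sd = noise_sd,
                             contrib_var = vapply(contrib, stats::var,
                                                  numeric(1)))
  tab
}
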