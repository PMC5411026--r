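#' Spatial initial-condition metrics
#'
#' For a lattice state at time zero, computes the number of initial C cells
#' `n_c0`, the norm of the mean C position vector relative to the colony
#' centroid `r_c0` (the centre-of-mass formula), and the spread of C cells
#' `d_c0`, the mean Euclidean distance of C cells from their own centre of
#' mass. All distances are physical (micrometres). The colony centre is the
#' centroid of all occupied sites.
#'
#' The literal reading of the spread formula, the norm of the mean deviation
#' vector, is identically zero; it is available under `literal = TRUE` for
#' audit. Similarly `radial = TRUE` returns the mean radial distance of C
#' cells from the colony centre instead of the centre-of-mass norm.
#'
#' @param state A [lattice_state()] at time 0 with at least one C cell.
#' @param literal Return the literal (identically zero) spread formula.
#' @param radial Return mean radial distance instead of the centre-of-mass
#'   norm for `r_c0`.
#' @return A list with `n_c0`, `r_c0`, `d_c0`, and `positions` (matrix of C
#'   positions in micrometres relative to the colony centre).
#' @export
initial_spatial_metrics <- function(state, literal = FALSE, radial = FALSE) {
  g <- state$grid
  occ <- which(g != SITE_STATES[["AGAR"]], arr.ind = TRUE)
  if (nrow(occ) == 0) stop("empty lattice")
  cc <- which(g == SITE_STATES[["C"]], arr.ind = TRUE)
  if (nrow(cc) == 0) stop("no C cells in the initial state")
  center <- colMeans(occ)
  rel <- sweep(cc, 2, center) * state$pixel_um
  mean_vec <- colMeans(rel)
  r_c0 <- if (radial) mean(sqrt(rowSums(rel^2))) else sqrt(sum(mean_vec^2))
  dev <- sweep(rel, 2, mean_vec)
  d_c0 <- if (literal) sqrt(sum(colMeans(dev)^2)) else
    mean(sqrt(rowSums(dev^2)))
  list(n_c0 = nrow(cc), r_c0 = r_c0, d_c0 = d_c0, positions = unname(rel))
}

# igraph connected components of a logical mask.
# connectivity: 8 (Moore) for cell clusters, 4 for the agar background.
mask_components <- function(mask, connectivity = 8) {
  n <- nrow(mask)
  idx <- which(mask)
  comp <- integer(length(mask))
  if (length(idx) == 0) return(list(labels = comp, n = 0L))
  pos <- match(seq_along(mask), idx) # site index -> vertex id (NA outside)
  shifts <- if (connectivity == 8) {
    list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  } else {
    list(c(1, 0), c(0, 1))
  }
  i <- (idx - 1L) %% n + 1L
  j <- (idx - 1L) %/% n + 1L
  edges <- integer(0)
  for (s in shifts) {
    ii <- i + s[1]
    jj <- j + s[2]
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n
    nidx <- (jj - 1L) * n + ii
    ok[ok] <- mask[nidx[ok]]
    if (any(ok)) edges <- c(edges, rbind(pos[idx[ok]], pos[nidx[ok]]))
  }
  gr <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  memb <- igraph::components(gr)$membership
  comp[idx] <- memb
  list(labels = comp, n = max(memb))
}

#' Count viable C clusters at the colony edge
#'
#' Counts the 8-connected components of C-lineage sites (states C and C_on)
#' that contain at least one reproducing C site (viability) and touch the
#' colony edge — an occupied site with at least one Moore neighbour in the
#' colony's external agar background, where the background is the set of
#' agar sites 4-connected to the lattice border. Evaluated on the snapshot
#' recorded at the end of the first competition phase (12 h by default in
#' [colony_metrics()]).
#'
#' @param state A [lattice_state()].
#' @return Integer cluster count.
#' @export
count_edge_clusters <- function(state) {
  g <- state$grid
  n <- nrow(g)
  if (all(g == SITE_STATES[["AGAR"]])) stop("empty colony")
  c_mask <- g == SITE_STATES[["C"]] | g == SITE_STATES[["C_ON"]]
  if (!any(c_mask)) return(0L)

  agar <- g == SITE_STATES[["AGAR"]]
  bg <- mask_components(agar, connectivity = 4)
  border_sites <- unique(c(seq_len(n), (n - 1L) * n + seq_len(n),
                           (seq_len(n) - 1L) * n + 1L, (seq_len(n) - 1L) * n + n))
  ext_labels <- setdiff(unique(bg$labels[border_sites]), 0L)
  external <- matrix(bg$labels %in% ext_labels, n, n)

  # occupied sites with an external-agar Moore neighbour
  edge <- matrix(FALSE, n, n)
  occ <- g != SITE_STATES[["AGAR"]]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    src <- external
    shifted <- matrix(FALSE, n, n)
    ri <- seq_len(n) + di
    rj <- seq_len(n) + dj
    ok_i <- ri >= 1 & ri <= n
    ok_j <- rj >= 1 & rj <= n
    shifted[ok_i, ok_j] <- src[ri[ok_i], rj[ok_j]]
    edge <- edge | (occ & shifted)
  }

  cl <- mask_components(c_mask, connectivity = 8)
  if (cl$n == 0) return(0L)
  lab <- matrix(cl$labels, n, n)
  viable <- unique(lab[g == SITE_STATES[["C"]]])
  at_edge <- unique(lab[edge & c_mask])
  length(setdiff(intersect(viable, at_edge), 0L))
}

#' Final C-strain fraction of a trajectory
#'
#' The C-lineage share (C + C_on) of the occupied colony area (C + C_on +
#' X + X_stop) at the final recording; 0 for an empty colony.
#'
#' @param traj A `competition_trajectory`.
#' @return A fraction in `[0, 1]`.
#' @export
final_fraction <- function(traj) {
  a <- traj$areas[nrow(traj$areas), ]
  tot <- a$n_c + a$n_con + a$n_x + a$n_xstop
  if (tot == 0) return(0)
  (a$n_c + a$n_con) / tot
}

#' Classify a competition outcome
#'
#' Extinction (total occupied area below 1e6 um^2) is checked first; then
#' C domination (`f_c > 0.9`), S domination (`f_c < 0.1`), else coexistence.
#' A tiny all-C colony is therefore classified as extinction.
#'
#' @param f_c Final C fraction.
#' @param total_area_um2 Final occupied colony area in um^2.
#' @return One of `"extinction"`, `"c_domination"`, `"s_domination"`,
#'   `"coexistence"`.
#' @export
#' @examples
#' classify_outcome(0.95, 5e6)  # c_domination
#' classify_outcome(0.5, 9e5)   # extinction
classify_outcome <- function(f_c, total_area_um2) {
  stopifnot(is.finite(f_c), is.finite(total_area_um2))
  if (total_area_um2 < 1e6) return("extinction")
  if (f_c > 0.9) return("c_domination")
  if (f_c < 0.1) return("s_domination")
  "coexistence"
}

#' Transition time of a competition trajectory
#'
#' The first recorded time at which the C lineage holds more than half of
#' the colonized area and keeps doing so for the next two recorded points
#' (a sustained-crossing rule that suppresses single-snapshot noise).
#'
#' @param traj A `competition_trajectory`, or a data frame with columns
#'   `time_h` and a C fraction column `frac_c`.
#' @return Time in hours, or `NA` if C never captures half the colony.
#' @export
transition_time <- function(traj) {
  if (inherits(traj, "competition_trajectory")) {
    a <- traj$areas
    tot <- a$n_c + a$n_con + a$n_x + a$n_xstop
    frac <- ifelse(tot > 0, (a$n_c + a$n_con) / tot, 0)
    times <- a$time_h
  } else {
    frac <- traj$frac_c
    times <- traj$time_h
  }
  above <- frac > 0.5
  nn <- length(above)
  for (k in seq_len(max(0, nn - 2))) {
    if (above[k] && above[k + 1] && above[k + 2]) return(times[k])
  }
  NA_real_
}

# Window (>= max(min_pts, 25% of the series)) maximising the linear-fit
# R^2; near-ties (within 1e-6) resolve to the longer window, so an exactly
# linear regime is returned whole. NULL when no window reaches r2_min.
best_linear_window <- function(x, y, r2_min = 0.98, min_pts = 6) {
  n <- length(x)
  min_len <- max(min_pts, ceiling(0.25 * n))
  if (n < min_len) return(NULL)
  best <- NULL
  for (len in n:min_len) { # longest first: ties keep the longer window
    for (start in 1:(n - len + 1)) {
      xs <- x[start:(start + len - 1)]
      ys <- y[start:(start + len - 1)]
      if (stats::var(ys) == 0) {
        r2 <- 1
        slope <- 0
      } else {
        fit <- stats::lm.fit(cbind(1, xs), ys)
        ssr <- sum(fit$residuals^2)
        sst <- sum((ys - mean(ys))^2)
        r2 <- 1 - ssr / sst
        slope <- fit$coefficients[2]
      }
      if (is.null(best) || r2 > best$r2 + 1e-6) {
        best <- list(start = start, end = start + len - 1, slope = slope,
                     r2 = r2, n = len)
      }
    }
  }
  if (is.null(best) || best$r2 < r2_min) return(NULL)
  best
}

#' Colony expansion rate from an area curve
#'
#' Identifies the linear growth regime as the longest window (at least 25%
#' of the series and 6 points) whose linear fit reaches R^2 >= 0.98 and
#' returns the fitted slope in um^2/h. Signals an error when no window
#' qualifies (e.g. for a purely exponential curve).
#'
#' @param curve A `competition_trajectory`, or a data frame with columns
#'   `time_h` and `area_um2`.
#' @param r2_min Minimum R^2 for an acceptable window.
#' @return A list: `rate_um2_per_h`, `window` (time range used), `r2`.
#' @export
expansion_rate <- function(curve, r2_min = 0.98) {
  if (inherits(curve, "competition_trajectory")) {
    curve <- data.frame(time_h = curve$areas$time_h,
                        area_um2 = curve$areas$area_um2_total)
  }
  stopifnot(all(c("time_h", "area_um2") %in% names(curve)))
  w <- best_linear_window(curve$time_h, curve$area_um2, r2_min = r2_min)
  if (is.null(w))
    stop("no linear regime found: no window of >= 25% of the series reaches R^2 >= ",
         r2_min)
  list(rate_um2_per_h = unname(w$slope),
       window = c(curve$time_h[w$start], curve$time_h[w$end]),
       r2 = w$r2)
}

#' Producer fraction of the C population
#'
#' `C_on / (C + C_on)` per recorded time point of a trajectory, or for a
#' single lattice state. Time points with no C-lineage cells give `NA`.
#'
#' @param x A `competition_trajectory` or a `lattice_state`.
#' @return For a trajectory, a data frame `time_h`, `producer_fraction`;
#'   for a state, a single number (or `NA`).
#' @export
producer_fraction <- function(x) {
  if (inherits(x, "lattice_state")) {
    tb <- state_counts(x)
    tot <- tb[["C"]] + tb[["C_ON"]]
    return(if (tot == 0) NA_real_ else tb[["C_ON"]] / tot)
  }
  a <- x$areas
  tot <- a$n_c + a$n_con
  data.frame(time_h = a$time_h,
             producer_fraction = ifelse(tot > 0, a$n_con / tot, NA_real_))
}

#' Population growth rate from an optical-density curve
#'
#' Fits the natural logarithm of the OD values in the exponential-phase
#' window (detected with the same longest-high-R^2-window rule as
#' [expansion_rate()]) and returns the growth rate GR = b / ln(2) in
#' doublings per hour, with `b` the fitted slope.
#'
#' @param curve A data frame (or [synthetic_od_curve()] fixture) with
#'   columns `time_h` and `value`.
#' @param r2_min Minimum R^2 for the exponential-phase window.
#' @return A list: `gr_doublings_per_h`, `slope`, `window`, `r2`.
#' @export
#' @examples
#' crv <- synthetic_od_curve(gr_per_h = 1, od0 = 0.1, noise_cv = 0,
#'                           times = seq(0, 5, by = 0.25))
#' growth_rate_from_od(crv)$gr_doublings_per_h
growth_rate_from_od <- function(curve, r2_min = 0.98) {
  stopifnot(all(c("time_h", "value") %in% names(curve)))
  if (any(curve$value <= 0)) stop("OD values must be positive")
  w <- best_linear_window(curve$time_h, log(curve$value), r2_min = r2_min)
  if (is.null(w)) stop("no exponential-phase window reaches R^2 >= ", r2_min)
  list(gr_doublings_per_h = unname(w$slope) / log(2),
       slope = unname(w$slope),
       window = c(curve$time_h[w$start], curve$time_h[w$end]),
       r2 = w$r2)
}

#' All per-run colony metrics in one row
#'
#' Computes the full per-run statistics table from a trajectory: initial
#' spatial metrics (from the stored initial state when available), the
#' edge-cluster count at the phase-1 boundary, final fraction, outcome
#' class, transition time and expansion rate.
#'
#' @param traj A `competition_trajectory` with a snapshot at `edge_time`.
#' @param init Optional initial [lattice_state()] for the spatial metrics
#'   (skipped when absent).
#' @param edge_time Phase-1 boundary in hours (snapshot at which edge
#'   clusters are counted).
#' @return A one-row data frame.
#' @export
colony_metrics <- function(traj, init = NULL, edge_time = 12) {
  a <- traj$areas[nrow(traj$areas), ]
  f_c <- final_fraction(traj)
  out <- classify_outcome(f_c, a$area_um2_total)
  snap_name <- sprintf("t%g", edge_time)
  n_edge <- if (snap_name %in% names(traj$snapshots))
    count_edge_clusters(traj$snapshots[[snap_name]]) else NA_integer_
  er <- tryCatch(expansion_rate(traj)$rate_um2_per_h, error = function(e) NA_real_)
  row <- data.frame(
    s_c = traj$params$s_c, sigma_x = traj$params$sigma_x,
    scenario = traj$scenario$mode,
    n_c0 = NA_integer_, r_c0_um = NA_real_, d_c0_um = NA_real_,
    n_c_edge = n_edge, f_c = f_c, outcome = out,
    total_area_um2 = a$area_um2_total,
    transition_time_h = transition_time(traj),
    expansion_rate_um2_per_h = er,
    seed = traj$seed %||% NA_integer_)
  if (!is.null(init)) {
    sm <- initial_spatial_metrics(init)
    row$n_c0 <- sm$n_c0
    row$r_c0_um <- sm$r_c0
    row$d_c0_um <- sm$d_c0
  }
  row
}
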