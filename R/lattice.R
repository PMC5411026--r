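#' Site state codes
#'
#' Integer codes used on the lattice: `AGAR = 0` (empty), `C = 1`
#' (reproducing producer-strain cell), `C_ON = 2` (toxin-producing cell),
#' `X = 3` (living competitor cell), `X_STOP = 4` (growth-inhibited,
#' permanently occupying competitor cell).
#'
#' @format A named integer vector of length 5.
#' @export
SITE_STATES <- c(AGAR = 0L, C = 1L, C_ON = 2L, X = 3L, X_STOP = 4L)

#' Construct a lattice state
#'
#' A lattice state holds the per-site agent grid, the cumulative toxin
#' field, the zoom bookkeeping (physical pixel size grows by a factor of 5
#' at each coarse-graining event) and the simulation clock.
#'
#' @param grid Integer matrix of site states (see [SITE_STATES]).
#' @param toxin Numeric matrix of cumulative toxin, same shape as `grid`;
#'   defaults to all zero.
#' @param zoom_level Non-negative integer count of coarse-graining events.
#' @param base_pixel_um Physical pixel size at zoom 0 (micrometres).
#' @param time Simulation time in hours.
#' @return An object of class `lattice_state`.
#' @export
lattice_state <- function(grid, toxin = NULL, zoom_level = 0L,
                          base_pixel_um = 2, time = 0) {
  stopifnot(is.matrix(grid), nrow(grid) == ncol(grid))
  storage.mode(grid) <- "integer"
  if (!all(grid %in% SITE_STATES)) stop("grid contains unknown site states")
  if (is.null(toxin)) toxin <- matrix(0, nrow(grid), ncol(grid))
  stopifnot(is.matrix(toxin), all(dim(toxin) == dim(grid)), all(toxin >= 0))
  stopifnot(zoom_level >= 0, base_pixel_um > 0, time >= 0)
  structure(list(grid = grid, toxin = toxin,
                 zoom_level = as.integer(zoom_level),
                 base_pixel_um = base_pixel_um,
                 pixel_um = base_pixel_um * 5^zoom_level,
                 time = time),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  tb <- state_counts(x)
  cat(sprintf("lattice_state %d x %d, zoom %d (%g um/pixel), t = %.2f h\n",
              nrow(x$grid), ncol(x$grid), x$zoom_level, x$pixel_um, x$time))
  cat("  sites:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Per-state site counts of a lattice state
#'
#' @param state A `lattice_state`.
#' @return Named integer vector with counts for AGAR, C, C_ON, X, X_STOP.
#' @export
state_counts <- function(state) {
  tb <- tabulate(state$grid + 1L, nbins = 5L)
  names(tb) <- names(SITE_STATES)
  tb
}

# TRUE when any occupied site lies on the lattice border (the coarse-grain
# trigger condition).
touches_boundary <- function(grid) {
  n <- nrow(grid)
  any(grid[1, ] != 0L) || any(grid[n, ] != 0L) ||
    any(grid[, 1] != 0L) || any(grid[, n] != 0L)
}

#' Deposit an exponential toxin profile
#'
#' Adds `n_tox * exp(-d * pixel_um / lambda_tox)` to every site, where `d`
#' is the Euclidean lattice distance to `origin`. Deposition is additive
#' across lysis events; contributions below `cutoff` are truncated.
#'
#' @param toxin Numeric matrix (the current toxin field).
#' @param origin Integer vector `c(row, col)` of the lysing cell.
#' @param n_tox Toxin amount released (value added at the origin itself).
#' @param lambda_tox Decay length in micrometres.
#' @param pixel_um Physical pixel size in micrometres.
#' @param cutoff Truncation threshold in toxin units (0 = no truncation).
#' @return The updated toxin matrix.
#' @export
#' @examples
#' f <- deposit_toxin(matrix(0, 11, 11), c(6, 6), n_tox = 1,
#'                    lambda_tox = 10, pixel_um = 2)
#' f[6, 6] # == 1
deposit_toxin <- function(toxin, origin, n_tox, lambda_tox, pixel_um,
                          cutoff = 0) {
  stopifnot(is.matrix(toxin), length(origin) == 2,
            origin[1] >= 1, origin[1] <= nrow(toxin),
            origin[2] >= 1, origin[2] <= ncol(toxin),
            n_tox > 0, lambda_tox > 0, pixel_um > 0)
  cpp_deposit_toxin(toxin, as.integer(origin[1]), as.integer(origin[2]),
                    n_tox, lambda_tox / pixel_um, cutoff)
}

#' Coarse-grain a lattice state by a factor of five
#'
#' When the expanding colony touches the lattice border, each 5 x 5 block
#' is mapped to one site of a 50 x 50 lattice (for the default 250 x 250
#' grid) that is re-centred in a fresh all-agar lattice. A block becomes
#' AGAR when fewer than 13 of its 25 sites are occupied, otherwise it takes
#' the plurality occupied state (ties broken by the fixed precedence
#' C_ON > C > X_STOP > X). Toxin is block-averaged and re-centred in the
#' same way. The zoom level increments, the pixel size grows by 5 and the
#' agent reaction rates (replication, switching, lysis) are divided by 5:
#' this preserves the physical front speed in um/h, the producer fraction
#' s_c/(s_c + d_con) and the switching cost per replication opportunity
#' s_c/r across zoom events. The toxin response sigma_x is untouched.
#'
#' @param state A `lattice_state` whose occupied region touches the border.
#' @param params The current `colicin_params`.
#' @param force Skip the border-contact check (used in tests).
#' @return A list with elements `state` and `params`.
#' @export
coarse_grain <- function(state, params, force = FALSE) {
  g <- state$grid
  n <- nrow(g)
  if (n %% 5 != 0) stop("lattice size must be divisible by 5")
  if (!force && !touches_boundary(g))
    stop("coarse_grain called before the colony reached the lattice border")
  nb <- n %/% 5

  blocks <- array(g, dim = c(5, nb, 5, nb))
  counts <- vapply(1:4, function(s) {
    apply(blocks == s, c(2, 4), sum)
  }, matrix(0, nb, nb)) # nb x nb x 4 (C, C_ON, X, X_STOP)
  occupied <- counts[, , 1] + counts[, , 2] + counts[, , 3] + counts[, , 4]

  # plurality with precedence C_ON > C > X_STOP > X on ties
  prec <- c(2, 3, 0, 1) # indexed by state code 1..4 (C, C_ON, X, X_STOP)
  score <- vapply(1:4, function(s) counts[, , s] * 4 + prec[s],
                  matrix(0, nb, nb))
  winner <- apply(score, c(1, 2), which.max)
  small <- matrix(as.integer(winner), nb, nb)
  small[occupied < 13] <- 0L

  tox_blocks <- array(state$toxin, dim = c(5, nb, 5, nb))
  tox_small <- apply(tox_blocks, c(2, 4), mean)

  off <- (n - nb) %/% 2
  new_grid <- matrix(0L, n, n)
  new_tox <- matrix(0, n, n)
  new_grid[off + seq_len(nb), off + seq_len(nb)] <- small
  new_tox[off + seq_len(nb), off + seq_len(nb)] <- tox_small

  params$r_c <- params$r_c / 5
  params$r_x <- params$r_x / 5
  params$s_c <- params$s_c / 5
  params$d_con <- params$d_con / 5
  list(state = lattice_state(new_grid, new_tox,
                             zoom_level = state$zoom_level + 1L,
                             base_pixel_um = state$base_pixel_um,
                             time = state$time),
       params = params)
}
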