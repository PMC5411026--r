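#' Inoculum specification
#'
#' Describes the spotted founder community: about 150 cells placed uniformly
#' at random (without site collisions) inside a centred disc of about 450 um
#' diameter, each cell being a producer (C) with probability 1/101 so the
#' C:X ratio is approximately 1:100, resampled until at least one C cell is
#' present. Density-variation experiments multiply the cell number by 2, 4
#' or 8 within the same disc.
#'
#' @param n_cells_total Cells at density multiplier 1 (default 150).
#' @param ratio_c_to_x Length-2 numeric, relative C and X weights
#'   (default `c(1, 100)`); `c(0, 1)` gives a single-strain X inoculum and
#'   `c(1, 0)` a pure C inoculum.
#' @param spot_diameter_um Diameter of the spotting disc in micrometres.
#' @param density_multiplier One of 1, 2, 4, 8.
#' @param require_min_one_c Resample until at least one C cell is present.
#' @return An object of class `inoculum_spec`.
#' @export
inoculum_spec <- function(n_cells_total = 150, ratio_c_to_x = c(1, 100),
                          spot_diameter_um = 450, density_multiplier = 1,
                          require_min_one_c = TRUE) {
  stopifnot(n_cells_total >= 1, length(ratio_c_to_x) == 2,
            all(ratio_c_to_x >= 0), sum(ratio_c_to_x) > 0,
            spot_diameter_um > 0, density_multiplier %in% c(1, 2, 4, 8))
  p_c <- ratio_c_to_x[1] / sum(ratio_c_to_x)
  if (require_min_one_c && p_c == 0)
    stop("cannot require a C cell when the C weight is zero")
  structure(list(n_cells_total = n_cells_total, ratio_c_to_x = ratio_c_to_x,
                 p_c = p_c, spot_diameter_um = spot_diameter_um,
                 density_multiplier = density_multiplier,
                 require_min_one_c = require_min_one_c),
            class = "inoculum_spec")
}

#' Generate a random inoculum lattice
#'
#' Places `n_cells_total * density_multiplier` cells uniformly at random on
#' distinct sites within the centred spotting disc; each cell is C with
#' probability given by the C:X ratio, and the layout is resampled until at
#' least one C cell is present when the spec requires it. The toxin field is
#' zero and the clock starts at zero. The function draws from R's global
#' RNG; call `set.seed()` (or pass `seed`) for reproducible layouts.
#'
#' @param spec An [inoculum_spec()].
#' @param base_pixel_um Physical pixel size at zoom 0 (micrometres).
#' @param lattice_size Lattice side length in pixels.
#' @param seed Optional integer seed applied before sampling.
#' @return A [lattice_state()] at time 0.
#' @export
#' @examples
#' init <- generate_inoculum(inoculum_spec(), seed = 1)
#' state_counts(init)
generate_inoculum <- function(spec, base_pixel_um = 2, lattice_size = 250L,
                              seed = NULL) {
  stopifnot(inherits(spec, "inoculum_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(lattice_size)
  n_cells <- spec$n_cells_total * spec$density_multiplier
  radius_px <- spec$spot_diameter_um / 2 / base_pixel_um
  if (2 * radius_px > n)
    stop("spotting disc does not fit in the lattice at this pixel size")
  ctr <- (n + 1) / 2
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  in_disc <- (ij$i - ctr)^2 + (ij$j - ctr)^2 <= radius_px^2
  disc_idx <- which(in_disc)
  if (length(disc_idx) < n_cells)
    stop("spotting disc has fewer sites than cells to place")

  repeat {
    sites <- sample(disc_idx, n_cells)
    is_c <- stats::runif(n_cells) < spec$p_c
    if (!spec$require_min_one_c || any(is_c)) break
  }
  grid <- matrix(0L, n, n)
  grid[sites[is_c]] <- SITE_STATES[["C"]]
  grid[sites[!is_c]] <- SITE_STATES[["X"]]
  lattice_state(grid, base_pixel_um = base_pixel_um)
}

#' Replication design with frozen initial conditions
#'
#' Builds the run manifest for the fixed-initial-condition campaign: `n_ic`
#' frozen inoculum layouts (identified by a deterministic inoculum seed),
#' each paired with `reps` distinct simulation seeds for every switching
#' rate in `s_c_values`. The default 16 x 30 x 17 design yields 8,160 runs.
#'
#' @param n_ic Number of frozen initial conditions.
#' @param reps Replicates per (IC, s_c) cell.
#' @param s_c_values Switching rates to scan.
#' @param master_seed Master seed from which all layout and run seeds are
#'   derived via [derive_seed()].
#' @return A data frame with columns `run_id`, `ic`, `rep`, `s_c`,
#'   `ic_seed`, `run_seed`.
#' @export
#' @examples
#' nrow(make_fixed_ic_design(2, 3, c(0.01, 0.02), master_seed = 1))
make_fixed_ic_design <- function(n_ic = 16, reps = 30,
                                 s_c_values = default_s_c_values(),
                                 master_seed = 1L) {
  stopifnot(n_ic >= 1, reps >= 1, length(s_c_values) >= 1,
            all(s_c_values >= 0))
  des <- expand.grid(rep = seq_len(reps), s_c_index = seq_along(s_c_values),
                     ic = seq_len(n_ic))
  des$s_c <- s_c_values[des$s_c_index]
  des$ic_seed <- vapply(des$ic, function(ic) derive_seed(master_seed, 0L, ic),
                        integer(1))
  des$run_seed <- mapply(function(ic, si, r) derive_seed(master_seed, ic, si, r),
                         des$ic, des$s_c_index, des$rep)
  des$run_id <- seq_len(nrow(des))
  des[, c("run_id", "ic", "rep", "s_c", "ic_seed", "run_seed")]
}

#' Default switching-rate scan
#'
#' Seventeen switching rates, log-spaced over 0.06-9.3 per hour. With the
#' default lysis rate (1.2 per hour) these cover producer fractions from
#' about 5 percent to about 89 percent, bracketing the C-success optimum
#' near 50 percent.
#'
#' @return Numeric vector of length 17.
#' @export
default_s_c_values <- function() {
  exp(seq(log(0.06), log(9.3), length.out = 17))
}
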