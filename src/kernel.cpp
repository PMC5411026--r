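#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Site states. Must stay in sync with the R-side constants in R/lattice.R.
#define ST_AGAR 0
#define ST_C 1
#define ST_CON 2
#define ST_X 3
#define ST_XSTOP 4

// Scenario codes (R/params.R): 0 stochastic (all-OFF is s_c = 0),
// 1 synchronous grow/pause/collective release, 2 non-lysing all-ON
// (toxin deposited at every C replication, no switching, no lysis).
#define MODE_STOCH 0
#define MODE_SYNC 1
#define MODE_NONLYSING 2

static const int DI[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DJ[8] = {0, 0, -1, 1, -1, 1, -1, 1};
static const bool DIAG[8] = {false, false, false, false, true, true, true, true};

// Exponential colicin profile, tabulated by squared lattice distance so each
// lysis event is additions only. Entries beyond the cutoff radius are 0.
static std::vector<double> make_exp_table(int n, double lambda_px,
                                          double n_tox, double cutoff) {
  double d2max = 2.0 * (double)(n - 1) * (double)(n - 1);
  double rcut = R_PosInf;
  if (cutoff > 0.0 && n_tox > 0.0)
    rcut = lambda_px * std::log(n_tox / cutoff);
  int len = (int)d2max + 1;
  std::vector<double> tab(len, 0.0);
  double r2cut = rcut * rcut;
  for (int d2 = 0; d2 < len; ++d2) {
    if ((double)d2 <= r2cut)
      tab[d2] = std::exp(-std::sqrt((double)d2) / lambda_px);
  }
  return tab;
}

static inline void deposit(double *tox, int n, int oi, int oj, double n_tox,
                           double lambda_px, const std::vector<double> &tab,
                           double cutoff) {
  double rcut = R_PosInf;
  if (cutoff > 0.0 && n_tox > 0.0)
    rcut = lambda_px * std::log(n_tox / cutoff);
  int r = (rcut < (double)(2 * n)) ? (int)std::ceil(rcut) : 2 * n;
  int ilo = std::max(0, oi - r), ihi = std::min(n - 1, oi + r);
  int jlo = std::max(0, oj - r), jhi = std::min(n - 1, oj + r);
  for (int j = jlo; j <= jhi; ++j) {
    int dj = j - oj;
    double *col = tox + (size_t)n * j;
    for (int i = ilo; i <= ihi; ++i) {
      int di = i - oi;
      col[i] += n_tox * tab[di * di + dj * dj];
    }
  }
}

//' @noRd
// [[Rcpp::export(name = "cpp_deposit_toxin")]]
NumericMatrix cpp_deposit_toxin(NumericMatrix toxin, int origin_i, int origin_j,
                                double n_tox, double lambda_px, double cutoff) {
  NumericMatrix out = clone(toxin);
  int n = out.nrow();
  std::vector<double> tab = make_exp_table(n, lambda_px, n_tox, cutoff);
  deposit(REAL(out), n, origin_i - 1, origin_j - 1, n_tox, lambda_px, tab,
          cutoff);
  return out;
}

static inline bool on_border(int i, int j, int n) {
  return i == 0 || j == 0 || i == n - 1 || j == n - 1;
}

// Advance the lattice by up to n_steps fixed-dt kinetic Monte Carlo steps,
// modifying grid and toxin IN PLACE (the R wrapper owns the copies).
// Stops after the step during which the colony first touches the border so
// the caller can coarse-grain. Returns steps completed and status flags.
//' @noRd
// [[Rcpp::export(name = "cpp_advance")]]
List cpp_advance(IntegerMatrix grid, NumericMatrix toxin, double dt,
                 int n_steps, double r_c, double r_x, double diag_factor,
                 double s_c, double d_con, double sigma_x, double n_tox,
                 double lambda_px, double tox_cutoff, int mode, double t0,
                 double t_grow_end, double t_release, bool released) {
  int n = grid.nrow();
  if (grid.ncol() != n || toxin.nrow() != n || toxin.ncol() != n)
    stop("grid and toxin must be square matrices of identical size");
  double pmax = std::max(std::max(r_c, r_x), std::max(s_c, d_con)) * dt;
  if (pmax > 1.0)
    stop("dt * max rate exceeds 1: single-step event probability overflow");
  int *g = INTEGER(grid);
  double *tox = REAL(toxin);
  std::vector<double> tab = make_exp_table(n, lambda_px, n_tox, tox_cutoff);

  // active sites: anything that can still act (C, C_on, living X)
  std::vector<int> act;
  act.reserve(4096);
  bool boundary_hit = false;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      int s = g[i + (size_t)n * j];
      if (s == ST_C || s == ST_CON || s == ST_X) {
        act.push_back(i + n * j);
        if (on_border(i, j, n)) boundary_hit = true;
      } else if (s == ST_XSTOP && on_border(i, j, n)) {
        boundary_hit = true;
      }
    }
  if (boundary_hit)
    return List::create(_["steps_done"] = 0, _["boundary_hit"] = true,
                        _["released"] = released);

  double p_sw = s_c * dt, p_ly = d_con * dt;
  int steps_done = 0;
  int nbr[8];

  for (int step = 0; step < n_steps; ++step) {
    double t = t0 + step * dt;

    // synchronous collective toxin release
    if (mode == MODE_SYNC && !released && t >= t_release - 1e-9) {
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
          int idx = i + n * j;
          if (g[idx] == ST_C || g[idx] == ST_CON) {
            g[idx] = ST_AGAR;
            deposit(tox, n, i, j, n_tox, lambda_px, tab, tox_cutoff);
          }
        }
      released = true;
    }

    // drop stale entries, then fresh random order (Fisher-Yates)
    size_t m = 0;
    for (size_t k = 0; k < act.size(); ++k) {
      int s = g[act[k]];
      if (s == ST_C || s == ST_CON || s == ST_X) act[m++] = act[k];
    }
    act.resize(m);
    for (size_t k = m; k > 1; --k) {
      size_t r = (size_t)(unif_rand() * k);
      if (r >= k) r = k - 1;
      std::swap(act[k - 1], act[r]);
    }

    for (size_t k = 0; k < m; ++k) {
      int idx = act[k];
      int s = g[idx];
      int i = idx % n, j = idx / n;

      if (s == ST_C) {
        if (mode == MODE_STOCH && p_sw > 0.0 && unif_rand() < p_sw) {
          g[idx] = ST_CON;
          continue;
        }
        if (mode == MODE_SYNC && t >= t_grow_end - 1e-9) continue;
        // replication into a uniformly chosen empty Moore neighbour;
        // diagonal neighbours enter the rate at diag_factor
        int na = 0;
        double w = 0.0;
        for (int d = 0; d < 8; ++d) {
          int ii = i + DI[d], jj = j + DJ[d];
          if (ii < 0 || jj < 0 || ii >= n || jj >= n) continue;
          int nidx = ii + n * jj;
          if (g[nidx] == ST_AGAR) {
            nbr[na] = nidx;
            w += DIAG[d] ? diag_factor : 1.0;
            ++na;
          }
        }
        if (na == 0) continue;
        if (unif_rand() < r_c * dt * w) {
          int pick = (int)(unif_rand() * na);
          if (pick >= na) pick = na - 1;
          int tgt = nbr[pick];
          g[tgt] = ST_C;
          act.push_back(tgt);
          if (on_border(tgt % n, tgt / n, n)) boundary_hit = true;
          if (mode == MODE_NONLYSING)
            deposit(tox, n, i, j, n_tox, lambda_px, tab, tox_cutoff);
        }
      } else if (s == ST_CON) {
        if (p_ly > 0.0 && unif_rand() < p_ly) {
          g[idx] = ST_AGAR;
          deposit(tox, n, i, j, n_tox, lambda_px, tab, tox_cutoff);
        }
      } else { // living X
        double h = sigma_x * tox[idx] * dt;
        if (h > 0.0 && unif_rand() < -std::expm1(-h)) {
          g[idx] = ST_XSTOP;
          continue;
        }
        int na = 0;
        double w = 0.0;
        for (int d = 0; d < 8; ++d) {
          int ii = i + DI[d], jj = j + DJ[d];
          if (ii < 0 || jj < 0 || ii >= n || jj >= n) continue;
          int nidx = ii + n * jj;
          if (g[nidx] == ST_AGAR) {
            nbr[na] = nidx;
            w += DIAG[d] ? diag_factor : 1.0;
            ++na;
          }
        }
        if (na == 0) continue;
        if (unif_rand() < r_x * dt * w) {
          int pick = (int)(unif_rand() * na);
          if (pick >= na) pick = na - 1;
          int tgt = nbr[pick];
          g[tgt] = ST_X;
          act.push_back(tgt);
          if (on_border(tgt % n, tgt / n, n)) boundary_hit = true;
        }
      }
    }
    ++steps_done;
    if (boundary_hit) break;
  }
  return List::create(_["steps_done"] = steps_done,
                      _["boundary_hit"] = boundary_hit,
                      _["released"] = released);
}
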