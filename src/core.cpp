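// Compiled kernels: per-shot migration march, DAS pixel/element loop, and
// the two-way channel-data reference simulator. The R implementations in
// R/asm.R and R/migration.R are the documented references; tests assert the
// two routes agree.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// phase integral of the radial propagator: Phi(u) = sqrt(u^2-1) - atan(...)
// for propagating u > 1, else 0 (phase accumulates only over the
// propagating portion of the path).
static inline double phi_prop(double u) {
  if (u <= 1.0) return 0.0;
  double s = std::sqrt(u * u - 1.0);
  return s - std::atan(s);
}

// fill Phi(|k|, f; r, c) for all spectrum bins
static void fill_phi(mat& Phi, const vec& absk, const vec& freqs,
                     double r, double c) {
  const uword nk = absk.n_elem, nf = freqs.n_elem;
  for (uword j = 0; j < nf; ++j) {
    double fr_c = freqs[j] * r / c;
    for (uword i = 0; i < nk; ++i) {
      double ak = absk[i];
      Phi(i, j) = (ak > 0.0) ? phi_prop(fr_c / ak) : 0.0;
    }
  }
}

// one fused pass: the branch "-" propagator from the cached Phi at r1 and
// the fresh Phi at r2 (stored into Phi2 for reuse as the next step's Phi1)
static void fill_H(cx_mat& H, const mat& Phi1, mat& Phi2,
                   const vec& absk, const vec& freqs,
                   double r2, double c, double dr) {
  const uword nk = absk.n_elem, nf = freqs.n_elem;
  const double twopi = 2.0 * M_PI;
  for (uword j = 0; j < nf; ++j) {
    double fr2_c = freqs[j] * r2 / c;
    double ph0 = -twopi * freqs[j] * dr / c;      // k_theta = 0 limit
    const double* p1 = Phi1.colptr(j);
    double* p2 = Phi2.colptr(j);
    cx_double* h = H.colptr(j);
    for (uword i = 0; i < nk; ++i) {
      double ak = absk[i];
      if (ak == 0.0) {
        p2[i] = 0.0;
        h[i] = std::polar(1.0, ph0);
        continue;
      }
      double u2 = fr2_c / ak;
      if (u2 <= 1.0) {
        p2[i] = 0.0;
        h[i] = (dr != 0.0) ? cx_double(0.0, 0.0) : cx_double(1.0, 0.0);
      } else {
        double s = std::sqrt(u2 * u2 - 1.0);
        p2[i] = s - std::atan(s);
        h[i] = std::polar(1.0, -twopi * ak * (p2[i] - p1[i]));
      }
    }
  }
}

// [[Rcpp::export]]
arma::cx_mat migrate_shot_cpp(const arma::cx_mat& tx0, const arma::cx_mat& rx0,
                              const arma::vec& ktheta, const arma::vec& freqs,
                              const arma::vec& r_shells, const arma::vec& c_int,
                              const arma::vec& window, const arma::vec& band,
                              double f_number) {
  const uword nth = tx0.n_rows, nf = tx0.n_cols, nr = r_shells.n_elem;
  vec absk = abs(ktheta);
  cx_vec wcx = conv_to<cx_vec>::from(window);
  cx_vec bcx = conv_to<cx_vec>::from(band);
  double sinacc = (f_number > 0.0)
    ? std::sin(std::atan(1.0 / (2.0 * f_number))) : 0.0;

  cx_mat tx = tx0, rx = rx0;
  cx_mat image(nth, nr, fill::zeros);
  mat Phi1(nth, nf), Phi2(nth, nf);
  cx_mat H(nth, nf);
  double phi_c = -1.0;   // sound speed Phi1 was computed with

  for (uword i = 0; i < nr; ++i) {
    cx_mat RXs;
    bool have_RXs = false;
    cx_mat rx_img;
    if (f_number > 0.0) {
      RXs = fft(rx);
      have_RXs = true;
      double c_here = c_int.n_elem ? c_int[std::min<uword>(i, c_int.n_elem - 1)] : 1540.0;
      cx_mat RXw = RXs;
      for (uword j = 0; j < nf; ++j) {
        double kc = freqs[j] * r_shells[i] / c_here * sinacc;
        for (uword k = 0; k < nth; ++k) {
          double ak = absk[k];
          double w;
          if (ak == 0.0) w = 1.0;
          else if (kc <= 0.0) w = 0.0;
          else {
            double q = ak / kc;
            if (q <= 0.9) w = 1.0;
            else if (q <= 1.0) w = 0.5 * (1.0 + std::cos(M_PI * (q - 0.9) / 0.1));
            else w = 0.0;
          }
          RXw(k, j) *= w;
        }
      }
      rx_img = ifft(RXw);
    } else {
      rx_img = rx;
    }
    image.col(i) = (conj(tx) % rx_img) * bcx;

    if (i + 1 < nr) {
      double c = c_int[std::min<uword>(i, c_int.n_elem - 1)];
      if (phi_c != c) {
        fill_phi(Phi1, absk, freqs, r_shells[i], c);
        phi_c = c;
      }
      fill_H(H, Phi1, Phi2, absk, freqs, r_shells[i + 1], c,
             r_shells[i + 1] - r_shells[i]);
      cx_mat TXs = fft(tx);
      if (!have_RXs) RXs = fft(rx);
      tx = ifft(TXs % H);
      rx = ifft(RXs % conj(H));
      tx.each_col() %= wcx;
      rx.each_col() %= wcx;
      std::swap(Phi1, Phi2);
    }
  }
  return image;
}

// [[Rcpp::export]]
arma::cx_vec das_shot_cpp(const arma::cx_mat& traces, double fs, double t0,
                          const arma::vec& el_x, const arma::vec& el_z,
                          const arma::vec& el_nx, const arma::vec& el_nz,
                          const arma::vec& px, const arma::vec& pz,
                          const arma::vec& t_tx, double c, double f_number) {
  const uword n_t = traces.n_rows, n_el = traces.n_cols, np = px.n_elem;
  cx_vec out(np, fill::zeros);
  for (uword p = 0; p < np; ++p) {
    cx_double acc(0.0, 0.0);
    for (uword e = 0; e < n_el; ++e) {
      double dx = px[p] - el_x[e], dz = pz[p] - el_z[e];
      double d = std::sqrt(dx * dx + dz * dz);
      if (d < 1e-9) continue;
      double w = 1.0;
      if (f_number > 0.0) {
        double cosA = (dx * el_nx[e] + dz * el_nz[e]) / d;
        if (cosA <= 0.0) continue;
        double tanA = std::sqrt(std::max(0.0, 1.0 - cosA * cosA)) / cosA;
        double q = tanA * 2.0 * f_number;
        if (q > 1.0) continue;
        if (q > 0.9) w = 0.5 * (1.0 + std::cos(M_PI * (q - 0.9) / 0.1));
      }
      double s = (t_tx[p] + d / c - t0) * fs;
      if (s < 0.0 || s >= (double)(n_t - 1)) continue;   // outside the record
      uword i0 = (uword)s;
      double fr = s - (double)i0;
      acc += w * (traces(i0, e) * (1.0 - fr) + traces(i0 + 1, e) * fr);
    }
    out[p] = acc;
  }
  return out;
}

// Direct per-pair evaluation of the two-way Born sum (no intermediate
// waveform grid): exactly symmetric under exchange of transmit and receive
// elements. Cost grows with tx*rx pair count; the two-stage fast route
// below is preferred for large simulations.
// [[Rcpp::export]]
arma::mat simulate_event_exact_cpp(const arma::vec& sx, const arma::vec& sz,
                                   const arma::vec& amp,
                                   const arma::mat& tx_subx, const arma::mat& tx_subz,
                                   const arma::vec& tx_delay, const arma::vec& tx_apod,
                                   const arma::mat& rx_subx, const arma::mat& rx_subz,
                                   double c, double fs, double t0, int n_t,
                                   const arma::vec& pulse_tab, double pulse_dt,
                                   double pulse_tstart) {
  const uword ns = sx.n_elem;
  const uword n_txel = tx_subx.n_rows, n_sub_tx = tx_subx.n_cols;
  const uword n_rxel = rx_subx.n_rows, n_sub_rx = rx_subx.n_cols;
  const double pulse_dur = (pulse_tab.n_elem - 1) * pulse_dt;
  mat traces((uword)n_t, n_rxel, fill::zeros);
  for (uword s = 0; s < ns; ++s) {
    for (uword e = 0; e < n_txel; ++e) {
      double a0 = tx_apod[e] / (double)(n_sub_tx * n_sub_rx);
      if (a0 == 0.0) continue;
      for (uword q = 0; q < n_sub_tx; ++q) {
        double dx = sx[s] - tx_subx(e, q), dz = sz[s] - tx_subz(e, q);
        double dtxv = std::sqrt(dx * dx + dz * dz);
        double lead = tx_delay[e] + dtxv / c;
        for (uword e2 = 0; e2 < n_rxel; ++e2)
          for (uword q2 = 0; q2 < n_sub_rx; ++q2) {
            double rx_ = sx[s] - rx_subx(e2, q2), rz = sz[s] - rx_subz(e2, q2);
            double drxv = std::sqrt(rx_ * rx_ + rz * rz);
            double base = lead + drxv / c + pulse_tstart;
            double g = amp[s] * a0 / (dtxv * drxv);
            long n0 = (long)std::ceil((base - t0) * fs);
            long n1 = (long)std::floor((base + pulse_dur - t0) * fs);
            if (n0 < 0) n0 = 0;
            if (n1 >= n_t) n1 = n_t - 1;
            for (long n = n0; n <= n1; ++n) {
              double idx = (t0 + n / fs - base) / pulse_dt;
              uword i0 = (uword)idx;
              double frv = idx - (double)i0;
              if (i0 + 1 < pulse_tab.n_elem)
                traces(n, e2) += g * (pulse_tab[i0] * (1.0 - frv) +
                                      pulse_tab[i0 + 1] * frv);
            }
          }
      }
    }
  }
  return traces;
}

static inline double table_interp(const vec& tab, double idx) {
  if (idx < 0.0 || idx >= (double)(tab.n_elem - 1)) return 0.0;
  uword i0 = (uword)idx;
  double fr = idx - (double)i0;
  return tab[i0] * (1.0 - fr) + tab[i0 + 1] * fr;
}

// Two-way Born channel data for one transmit event. For each scatterer the
// transmit waveform (all active elements' delayed, apodized, sub-divided
// contributions, 1/d spreading) is accumulated on a fine local time grid,
// then spread to every receive element/sub-source with its own delay and
// 1/d factor. Exact reordering of the per-pair double sum.
// [[Rcpp::export]]
arma::mat simulate_event_cpp(const arma::vec& sx, const arma::vec& sz,
                             const arma::vec& amp,
                             const arma::mat& tx_subx, const arma::mat& tx_subz,
                             const arma::vec& tx_delay, const arma::vec& tx_apod,
                             const arma::mat& rx_subx, const arma::mat& rx_subz,
                             double c, double fs, double t0, int n_t,
                             const arma::vec& pulse_tab, double pulse_dt,
                             double pulse_tstart, int osr) {
  const uword ns = sx.n_elem;
  const uword n_txel = tx_subx.n_rows, n_sub_tx = tx_subx.n_cols;
  const uword n_rxel = rx_subx.n_rows, n_sub_rx = rx_subx.n_cols;
  const double pulse_dur = (pulse_tab.n_elem - 1) * pulse_dt;
  const double dtw = 1.0 / (osr * fs);
  mat traces((uword)n_t, n_rxel, fill::zeros);

  std::vector<double> dtx(n_txel * n_sub_tx);
  for (uword s = 0; s < ns; ++s) {
    // transmit-leg arrival window
    double bmin = datum::inf, bmax = -datum::inf;
    for (uword e = 0; e < n_txel; ++e)
      for (uword q = 0; q < n_sub_tx; ++q) {
        double dx = sx[s] - tx_subx(e, q), dz = sz[s] - tx_subz(e, q);
        double d = std::sqrt(dx * dx + dz * dz);
        dtx[e * n_sub_tx + q] = d;
        double b = tx_delay[e] + d / c;
        if (b < bmin) bmin = b;
        if (b > bmax) bmax = b;
      }
    double tmin = bmin + pulse_tstart;
    double tmax = bmax + pulse_tstart + pulse_dur;
    uword Lw = (uword)std::ceil((tmax - tmin) / dtw) + 2;
    vec w(Lw, fill::zeros);
    const long n_tab = (long)pulse_tab.n_elem;
    const double* tabp = pulse_tab.memptr();
    double* wp = w.memptr();
    const double didx_tx = dtw / pulse_dt;
    for (uword e = 0; e < n_txel; ++e) {
      double a = tx_apod[e] / (double)n_sub_tx;
      if (a == 0.0) continue;
      for (uword q = 0; q < n_sub_tx; ++q) {
        double d = dtx[e * n_sub_tx + q];
        double base = tx_delay[e] + d / c + pulse_tstart;   // table-time origin
        long j0 = (long)std::ceil((base - tmin) / dtw);
        long j1 = (long)std::floor((base + pulse_dur - tmin) / dtw);
        if (j0 < 0) j0 = 0;
        if (j1 >= (long)Lw) j1 = Lw - 1;
        double ainv = a / d;
        double idx = (tmin + j0 * dtw - base) / pulse_dt;
        for (long j = j0; j <= j1; ++j, idx += didx_tx) {
          long i0 = (long)idx;
          if (i0 >= 0 && i0 + 1 < n_tab) {
            double frv = idx - (double)i0;
            wp[j] += ainv * (tabp[i0] * (1.0 - frv) + tabp[i0 + 1] * frv);
          }
        }
      }
    }
    // receive leg; Catmull-Rom interpolation of the local waveform keeps
    // the resampling error far below the linear order at this grid rate
    const double didx_rx = 1.0 / (fs * dtw);
    const long Lw2 = (long)Lw - 2;
    for (uword e = 0; e < n_rxel; ++e) {
      double* trp = traces.colptr(e);
      for (uword q = 0; q < n_sub_rx; ++q) {
        double dx = sx[s] - rx_subx(e, q), dz = sz[s] - rx_subz(e, q);
        double d = std::sqrt(dx * dx + dz * dz);
        double shift = d / c;
        double g = amp[s] / (d * (double)n_sub_rx);
        long n0 = (long)std::ceil((tmin + shift - t0) * fs);
        long n1 = (long)std::floor((tmax + shift - t0) * fs);
        if (n0 < 0) n0 = 0;
        if (n1 >= n_t) n1 = n_t - 1;
        double idx = (t0 + n0 / fs - shift - tmin) / dtw;
        for (long n = n0; n <= n1; ++n, idx += didx_rx) {
          long i0 = (long)idx;
          if (i0 >= 1 && i0 < Lw2) {
            double tq = idx - (double)i0;
            double w0 = wp[i0 - 1], w1 = wp[i0], w2 = wp[i0 + 1], w3 = wp[i0 + 2];
            double v = w1 + 0.5 * tq * (w2 - w0 +
                        tq * (2.0 * w0 - 5.0 * w1 + 4.0 * w2 - w3 +
                              tq * (3.0 * (w1 - w2) + w3 - w0)));
            trp[n] += g * v;
          } else if (i0 >= 0 && i0 < (long)Lw - 1) {
            double frv = idx - (double)i0;
            trp[n] += g * (wp[i0] * (1.0 - frv) + wp[i0 + 1] * frv);
          }
        }
      }
    }
  }
  return traces;
}
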