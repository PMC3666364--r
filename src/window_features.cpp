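#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-voxel sliding-window descriptors on a reflect-padded volume.
//
// For every requested voxel the w x w x w window centred on it is visited
// once per co-occurrence direction; pair counts are accumulated into a dense
// levels x levels buffer with a touched-cell list, so only the <= 2*w^2*(w-1)
// nonzero cells are reset between directions. Haralick statistics use the
// symmetric, normalised co-occurrence probabilities with gray levels indexed
// 0..levels-1. Definitions (p = normalised symmetric GLCM, mu = row-marginal
// mean, equal to the column mean by symmetry):
//   energy          sum p^2
//   entropy         -sum p log2 p            (0 log 0 := 0)
//   correlation     (sum ij p - mu_x mu_y) / (sd_x sd_y), 0 if sd = 0
//   contrast        sum (i-j)^2 p
//   homogeneity     sum p / (1 + (i-j)^2)
//   variance        sum (i-mu)^2 p
//   sum average     sum (i+j) p
//   dissimilarity   sum |i-j| p
//   cluster shade   sum (i+j-mu_x-mu_y)^3 p
//   cluster tendency sum (i+j-mu_x-mu_y)^2 p
//   maximum probability  max p
//   difference variance  var of p_{x-y} = contrast - dissimilarity^2
//   inverse variance (extra) sum_{i!=j} p / (1 + (i-j)^2)
//
// Local-histogram moments use the normalised level histogram h of the window:
// mean, variance, energy sum h^2, entropy, skewness and (plain) kurtosis of
// the standardised level, both 0 for zero-variance windows, and the mode
// (lowest level on ties). First-order features use the raw intensities.

static const int N_HARALICK = 13;  // 12 canonical + inverse variance
static const int N_HIST = 7;
static const int N_FIRST = 3;

// [[Rcpp::export]]
List cpp_window_features(IntegerVector q, NumericVector raw,
                         IntegerVector pdim, int r,
                         IntegerMatrix vox, IntegerMatrix offs,
                         int levels,
                         bool do_haralick, bool do_first, bool do_hist) {
  const int V = vox.nrow(), D = offs.nrow();
  const int px = pdim[0], py = pdim[1];
  const int w = 2 * r + 1;
  const double wn = (double)(w * w * w);

  NumericMatrix har, fo, lh;
  if (do_haralick) har = NumericMatrix(V, N_HARALICK);
  if (do_first) fo = NumericMatrix(V, N_FIRST);
  if (do_hist) lh = NumericMatrix(V, N_HIST);

  std::vector<double> buf((size_t)levels * levels, 0.0);
  std::vector<int> touched;
  touched.reserve(4 * w * w * (w - 1));
  std::vector<double> hist(levels, 0.0);
  std::vector<double> feat(N_HARALICK, 0.0);

  for (int v = 0; v < V; ++v) {
    // centre in padded coordinates
    const int cx = vox(v, 0) + r, cy = vox(v, 1) + r, cz = vox(v, 2) + r;

    if (do_haralick) {
      std::fill(feat.begin(), feat.end(), 0.0);
      for (int d = 0; d < D; ++d) {
        const int dx = offs(d, 0), dy = offs(d, 1), dz = offs(d, 2);
        // base offsets (relative to centre) with base and base+d in window
        const int x0 = std::max(-r, -r - dx), x1 = std::min(r, r - dx);
        const int y0 = std::max(-r, -r - dy), y1 = std::min(r, r - dy);
        const int z0 = std::max(-r, -r - dz), z1 = std::min(r, r - dz);
        touched.clear();
        int npairs = 0;
        for (int z = z0; z <= z1; ++z)
          for (int y = y0; y <= y1; ++y)
            for (int x = x0; x <= x1; ++x) {
              const long b = (cx + x) + (long)px * ((cy + y) +
                             (long)py * (cz + z));
              const long b2 = (cx + x + dx) + (long)px * ((cy + y + dy) +
                              (long)py * (cz + z + dz));
              const int i = q[b], j = q[b2];
              const int c1 = i * levels + j, c2 = j * levels + i;
              if (buf[c1] == 0.0) touched.push_back(c1);
              buf[c1] += 1.0;
              if (c2 != c1 && buf[c2] == 0.0) touched.push_back(c2);
              buf[c2] += 1.0;  // symmetric accumulation G_d + G_d^T
              ++npairs;
            }
        if (npairs == 0) continue;  // offset exceeds window: empty GLCM
        const double tot = 2.0 * npairs;
        double energy = 0, ent = 0, contrast = 0, homog = 0, dissim = 0,
               maxp = 0, mux = 0, muy = 0, sij = 0, sumavg = 0, invv = 0;
        for (size_t t = 0; t < touched.size(); ++t) {
          const int c = touched[t];
          const double p = buf[c] / tot;
          const int i = c / levels, j = c % levels, df = i - j;
          energy += p * p;
          ent -= p * std::log2(p);
          contrast += (double)(df * df) * p;
          homog += p / (1.0 + df * df);
          dissim += std::abs(df) * p;
          if (p > maxp) maxp = p;
          mux += i * p; muy += j * p;
          sij += (double)i * j * p;
          sumavg += (double)(i + j) * p;
          if (df != 0) invv += p / (1.0 + df * df);
        }
        double varx = 0, vary = 0, cshade = 0, ctend = 0;
        for (size_t t = 0; t < touched.size(); ++t) {
          const int c = touched[t];
          const double p = buf[c] / tot;
          const int i = c / levels, j = c % levels;
          varx += (i - mux) * (i - mux) * p;
          vary += (j - muy) * (j - muy) * p;
          const double s = i + j - mux - muy;
          cshade += s * s * s * p;
          ctend += s * s * p;
          buf[c] = 0.0;  // reset for next direction
        }
        const double sdx = std::sqrt(varx), sdy = std::sqrt(vary);
        const double corr = (sdx > 1e-12 && sdy > 1e-12)
                                ? (sij - mux * muy) / (sdx * sdy) : 0.0;
        feat[0] += energy;   feat[1] += ent;     feat[2] += corr;
        feat[3] += contrast; feat[4] += homog;   feat[5] += varx;
        feat[6] += sumavg;   feat[7] += dissim;  feat[8] += cshade;
        feat[9] += ctend;    feat[10] += maxp;
        feat[11] += contrast - dissim * dissim;
        feat[12] += invv;
      }
      for (int f = 0; f < N_HARALICK; ++f) har(v, f) = feat[f] / D;
    }

    if (do_hist) {
      std::fill(hist.begin(), hist.end(), 0.0);
      for (int z = -r; z <= r; ++z)
        for (int y = -r; y <= r; ++y)
          for (int x = -r; x <= r; ++x) {
            const long b = (cx + x) + (long)px * ((cy + y) +
                           (long)py * (cz + z));
            hist[q[b]] += 1.0;
          }
      double mean = 0, energy = 0, ent = 0;
      int mode = 0;
      double hmax = -1.0;
      for (int l = 0; l < levels; ++l) {
        const double h = hist[l] / wn;
        mean += l * h;
        energy += h * h;
        if (h > 0) ent -= h * std::log2(h);
        if (h > hmax) { hmax = h; mode = l; }
      }
      double var = 0, m3 = 0, m4 = 0;
      for (int l = 0; l < levels; ++l) {
        const double h = hist[l] / wn, dlv = l - mean;
        var += dlv * dlv * h;
        m3 += dlv * dlv * dlv * h;
        m4 += dlv * dlv * dlv * dlv * h;
      }
      double skew = 0, kurt = 0;
      if (var > 1e-12) {
        const double sd = std::sqrt(var);
        skew = m3 / (sd * sd * sd);
        kurt = m4 / (var * var);
      }
      lh(v, 0) = mean; lh(v, 1) = var; lh(v, 2) = energy; lh(v, 3) = ent;
      lh(v, 4) = skew; lh(v, 5) = kurt; lh(v, 6) = mode;
    }

    if (do_first) {
      double s = 0, s2 = 0;
      for (int z = -r; z <= r; ++z)
        for (int y = -r; y <= r; ++y)
          for (int x = -r; x <= r; ++x) {
            const long b = (cx + x) + (long)px * ((cy + y) +
                           (long)py * (cz + z));
            const double val = raw[b];
            s += val; s2 += val * val;
          }
      const double mean = s / wn;
      fo(v, 0) = raw[cx + (long)px * (cy + (long)py * cz)];
      fo(v, 1) = mean;
      fo(v, 2) = std::max(0.0, s2 / wn - mean * mean);
    }
  }

  List out;
  if (do_haralick) out["haralick"] = har;
  if (do_first) out["first_order"] = fo;
  if (do_hist) out["local_hist"] = lh;
  return out;
}
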