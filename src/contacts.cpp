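#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement along one axis.
static inline double min_image(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

static inline double pair_dist2(const double* x, int i, int j, int n,
                                const double* L) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = min_image(x[i + n * k] - x[j + n * k], L[k]);
    s += d * d;
  }
  return s;
}

// Molecular contact counting: an unordered molecule pair (a,b), a != b, is in
// contact if ANY bead of a lies within `cutoff` of ANY bead of b under the
// minimum-image convention. Returns an S x S symmetric count matrix aggregated
// by the species of each molecule. `mol` and `sp_mol` are 0-based.
// [[Rcpp::export]]
IntegerMatrix contact_counts_cpp(NumericMatrix coords, IntegerVector mol,
                                 IntegerVector sp_mol, int n_species,
                                 NumericVector box, double cutoff,
                                 bool cell_list) {
  const int n = coords.nrow();
  const double* x = coords.begin();
  const double L[3] = {box[0], box[1], box[2]};
  const double cut2 = cutoff * cutoff;
  const int n_mol = sp_mol.size();

  std::unordered_set<long long> pairs;
  pairs.reserve(64 + n);

  auto record = [&](int bi, int bj) {
    int ma = mol[bi], mb = mol[bj];
    if (ma == mb) return;
    long long lo = ma < mb ? ma : mb, hi = ma < mb ? mb : ma;
    pairs.insert(lo * (long long)n_mol + hi);
  };

  if (!cell_list) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (pair_dist2(x, i, j, n, L) < cut2) record(i, j);
  } else {
    // Linked-cell grid; cell edge >= cutoff so only 27 neighbour cells matter.
    int nc[3];
    for (int k = 0; k < 3; ++k) {
      nc[k] = std::max(1, (int)std::floor(L[k] / cutoff));
      if (nc[k] > 50) nc[k] = 50; // cap memory for very large boxes
    }
    const int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(n, -1);
    auto cell_of = [&](int i) {
      int c[3];
      for (int k = 0; k < 3; ++k) {
        double w = x[i + n * k] / L[k];
        w -= std::floor(w);
        c[k] = std::min(nc[k] - 1, (int)(w * nc[k]));
      }
      return (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    };
    for (int i = 0; i < n; ++i) {
      int c = cell_of(i);
      nxt[i] = head[c];
      head[c] = i;
    }
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c = (cz * nc[1] + cy) * nc[0] + cx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ex = (cx + dx + nc[0]) % nc[0];
                int ey = (cy + dy + nc[1]) % nc[1];
                int ez = (cz + dz + nc[2]) % nc[2];
                int c2 = (ez * nc[1] + ey) * nc[0] + ex;
                if (c2 < c) continue; // visit each cell pair once
                for (int i = head[c]; i >= 0; i = nxt[i]) {
                  int jstart = (c2 == c) ? nxt[i] : head[c2];
                  for (int j = jstart; j >= 0; j = nxt[j])
                    if (pair_dist2(x, i, j, n, L) < cut2) record(i, j);
                }
              }
        }
  }

  IntegerMatrix counts(n_species, n_species);
  for (long long key : pairs) {
    int ma = (int)(key / n_mol), mb = (int)(key % n_mol);
    int sa = sp_mol[ma], sb = sp_mol[mb];
    if (sa > sb) std::swap(sa, sb);
    counts(sa, sb) += 1;
  }
  for (int a = 0; a < n_species; ++a)
    for (int b = a + 1; b < n_species; ++b) counts(b, a) = counts(a, b);
  return counts;
}

// Bead-pair variant: counts every bead pair (on distinct molecules) within
// cutoff, aggregated by bead species.
// [[Rcpp::export]]
IntegerMatrix bead_contact_counts_cpp(NumericMatrix coords, IntegerVector mol,
                                      IntegerVector sp_bead, int n_species,
                                      NumericVector box, double cutoff) {
  const int n = coords.nrow();
  const double* x = coords.begin();
  const double L[3] = {box[0], box[1], box[2]};
  const double cut2 = cutoff * cutoff;
  IntegerMatrix counts(n_species, n_species);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (mol[i] == mol[j]) continue;
      if (pair_dist2(x, i, j, n, L) < cut2) {
        int sa = sp_bead[i], sb = sp_bead[j];
        if (sa > sb) std::swap(sa, sb);
        counts(sa, sb) += 1;
      }
    }
  for (int a = 0; a < n_species; ++a)
    for (int b = a + 1; b < n_species; ++b) counts(b, a) = counts(a, b);
  return counts;
}

// Per-centre neighbour census: counts, for every molecule centre, how many
// centres of each species lie within `radius` (self excluded).
// [[Rcpp::export]]
IntegerMatrix neighbor_species_counts_cpp(NumericMatrix centers,
                                          IntegerVector sp, int n_species,
                                          NumericVector box, double radius) {
  const int n = centers.nrow();
  const double* x = centers.begin();
  const double L[3] = {box[0], box[1], box[2]};
  const double r2 = radius * radius;
  IntegerMatrix counts(n, n_species);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (pair_dist2(x, i, j, n, L) < r2) {
        counts(i, sp[j]) += 1;
        counts(j, sp[i]) += 1;
      }
  return counts;
}

// Raw pair-distance histogram between two index sets (possibly identical)
// with bins [k*dr, (k+1)*dr). Each unordered pair counted once when
// same = TRUE, all cross pairs when same = FALSE.
// [[Rcpp::export]]
NumericVector pair_dist_hist_cpp(NumericMatrix coords, IntegerVector idx_a,
                                 IntegerVector idx_b, bool same,
                                 NumericVector box, double r_max, double dr) {
  const int n = coords.nrow();
  const double* x = coords.begin();
  const double L[3] = {box[0], box[1], box[2]};
  const int nbin = (int)std::ceil(r_max / dr);
  NumericVector hist(nbin);
  const double r2max = r_max * r_max;
  if (same) {
    const int na = idx_a.size();
    for (int a = 0; a < na; ++a)
      for (int b = a + 1; b < na; ++b) {
        double d2 = pair_dist2(x, idx_a[a], idx_a[b], n, L);
        if (d2 < r2max) {
          int k = (int)(std::sqrt(d2) / dr);
          if (k < nbin) hist[k] += 1.0;
        }
      }
  } else {
    const int na = idx_a.size(), nb = idx_b.size();
    for (int a = 0; a < na; ++a)
      for (int b = 0; b < nb; ++b) {
        double d2 = pair_dist2(x, idx_a[a], idx_b[b], n, L);
        if (d2 < r2max) {
          int k = (int)(std::sqrt(d2) / dr);
          if (k < nbin) hist[k] += 1.0;
        }
      }
  }
  return hist;
}
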