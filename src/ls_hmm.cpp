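#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Diploid Li-Stephens forward-backward.
//
// Hidden state at a marker = ordered pair (i, m) of reference haplotypes
// (H^2 states). Each chromosome switches template independently over an
// interval of genetic length d with probability r = 1 - exp(-rho * d); on a
// switch the new template is uniform over all H haplotypes (including the
// current one). Because the transition kernel is (1-r) I + (r/H) J, the
// pair update factorizes to O(H^2) per marker via row/column sums.
//
// Emission at a typed marker with observed genotype g in {0,1,2}: the two
// observed alleles are independent per-allele readings of the template
// alleles, each flipped with probability err[l] (per-marker error rates,
// so observations of different provenance - e.g. array genotypes versus
// hard calls from an earlier imputation step - can carry their own noise
// level). Untyped markers (NA) emit with probability 1.
//
// Returns a 3 x L matrix of posterior P(AA), P(AB), P(BB) for the template
// genotype at every marker.

// [[Rcpp::export(name = ".ls_diploid_fb")]]
NumericMatrix ls_diploid_fb(const IntegerMatrix& ref, const IntegerVector& gt,
                            const NumericVector& dmorgan, double rho,
                            const NumericVector& err) {
  const int H = ref.nrow();
  const int L = ref.ncol();
  if (H < 2) stop("need at least 2 reference haplotypes");
  if (L < 1) stop("need at least 1 marker");
  if (dmorgan.size() != L - 1) stop("dmorgan must have length L - 1");
  if (err.size() != L) stop("err must have length L");
  const size_t HH = (size_t)H * H;

  // per-marker emission tables:
  // Etab[l][s][g] = P(observed genotype g | template allele sum s)
  std::vector<double> Etab((size_t)L * 9);
  for (int l = 0; l < L; ++l) {
    double e = err[l];
    if (!(e > 0.0 && e < 0.5)) stop("error rates must lie in (0, 0.5)");
    for (int s = 0; s < 3; ++s) {
      double p1 = (s >= 1) ? 1.0 - e : e;  // P(first observed allele = 1)
      double p2 = (s == 2) ? 1.0 - e : e;  // P(second observed allele = 1)
      double* E = &Etab[(size_t)l * 9 + (size_t)s * 3];
      E[0] = (1.0 - p1) * (1.0 - p2);
      E[1] = p1 * (1.0 - p2) + (1.0 - p1) * p2;
      E[2] = p1 * p2;
    }
  }

  // copy alleles column-wise for fast access
  std::vector<int> al((size_t)H * L);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < H; ++i) {
      int a = ref(i, l);
      if (a != 0 && a != 1) stop("reference alleles must be 0/1");
      al[(size_t)l * H + i] = a;
    }

  std::vector<double> F(HH * (size_t)L);
  std::vector<double> RS(H), CS(H);

  // ---- forward, scaled per marker ----
  {
    double* F0 = &F[0];
    const int* a0 = &al[0];
    const double* E0 = &Etab[0];
    int g = gt[0];
    bool typed = (g != NA_INTEGER);
    double z = 0.0;
    for (int i = 0; i < H; ++i)
      for (int m = 0; m < H; ++m) {
        double v = typed ? E0[(a0[i] + a0[m]) * 3 + g] : 1.0;
        F0[(size_t)i * H + m] = v;
        z += v;
      }
    if (z <= 0) stop("zero forward mass at marker 1");
    for (size_t k = 0; k < HH; ++k) F0[k] /= z;
  }
  for (int l = 1; l < L; ++l) {
    const double r = 1.0 - std::exp(-rho * dmorgan[l - 1]);
    const double a = 1.0 - r;
    const double s = r / H;
    const double* Fp = &F[HH * (size_t)(l - 1)];
    double* Fc = &F[HH * (size_t)l];
    std::fill(RS.begin(), RS.end(), 0.0);
    std::fill(CS.begin(), CS.end(), 0.0);
    double tot = 0.0;
    for (int i = 0; i < H; ++i) {
      const double* row = Fp + (size_t)i * H;
      for (int m = 0; m < H; ++m) {
        RS[i] += row[m];
        CS[m] += row[m];
        tot += row[m];
      }
    }
    const int* acol = &al[(size_t)l * H];
    const double* El = &Etab[(size_t)l * 9];
    int g = gt[l];
    bool typed = (g != NA_INTEGER);
    double z = 0.0;
    for (int i = 0; i < H; ++i) {
      const double* prow = Fp + (size_t)i * H;
      double* crow = Fc + (size_t)i * H;
      const double aa = a * a;
      const double as_ri = a * s * RS[i];
      const int ai = acol[i];
      for (int m = 0; m < H; ++m) {
        double v = aa * prow[m] + as_ri + a * s * CS[m] + s * s * tot;
        if (typed) v *= El[(ai + acol[m]) * 3 + g];
        crow[m] = v;
        z += v;
      }
    }
    if (z <= 0) stop("zero forward mass at marker %d", l + 1);
    for (size_t k = 0; k < HH; ++k) Fc[k] /= z;
  }

  // ---- backward + posterior genotype probabilities ----
  NumericMatrix out(3, L);
  std::vector<double> B(HH, 1.0), G(HH);
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1) {
      // fold emission at l+1 into B, transit back across interval [l, l+1]
      const int* anx = &al[(size_t)(l + 1) * H];
      const double* En = &Etab[(size_t)(l + 1) * 9];
      int g = gt[l + 1];
      bool typed = (g != NA_INTEGER);
      for (int i = 0; i < H; ++i) {
        const int ai = anx[i];
        for (int m = 0; m < H; ++m) {
          double v = B[(size_t)i * H + m];
          if (typed) v *= En[(ai + anx[m]) * 3 + g];
          G[(size_t)i * H + m] = v;
        }
      }
      const double r = 1.0 - std::exp(-rho * dmorgan[l]);
      const double a = 1.0 - r;
      const double s = r / H;
      std::fill(RS.begin(), RS.end(), 0.0);
      std::fill(CS.begin(), CS.end(), 0.0);
      double tot = 0.0;
      for (int i = 0; i < H; ++i)
        for (int m = 0; m < H; ++m) {
          double v = G[(size_t)i * H + m];
          RS[i] += v;
          CS[m] += v;
          tot += v;
        }
      double z = 0.0;
      for (int i = 0; i < H; ++i) {
        const double aa = a * a;
        const double as_ri = a * s * RS[i];
        for (int m = 0; m < H; ++m) {
          double v = aa * G[(size_t)i * H + m] + as_ri + a * s * CS[m] +
                     s * s * tot;
          B[(size_t)i * H + m] = v;
          z += v;
        }
      }
      if (z <= 0) stop("zero backward mass at marker %d", l + 1);
      for (size_t k = 0; k < HH; ++k) B[k] /= z;
    }
    const double* Fl = &F[HH * (size_t)l];
    const int* acol = &al[(size_t)l * H];
    double z = 0.0;
    for (size_t k = 0; k < HH; ++k) z += Fl[k] * B[k];
    if (z <= 0) stop("zero posterior mass at marker %d", l + 1);
    double p0 = 0.0, p1 = 0.0, p2 = 0.0;
    for (int i = 0; i < H; ++i) {
      double t = 0.0, w = 0.0;  // t: mass on partner allele 1, w: row mass
      const double* frow = Fl + (size_t)i * H;
      const double* brow = &B[(size_t)i * H];
      for (int m = 0; m < H; ++m) {
        double v = frow[m] * brow[m];
        w += v;
        if (acol[m] == 1) t += v;
      }
      if (acol[i] == 1) {
        p2 += t;
        p1 += w - t;
      } else {
        p1 += t;
        p0 += w - t;
      }
    }
    double tot3 = p0 + p1 + p2;
    out(0, l) = p0 / tot3;
    out(1, l) = p1 / tot3;
    out(2, l) = p2 / tot3;
  }
  return out;
}
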