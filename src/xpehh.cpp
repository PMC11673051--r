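#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Homozygosity of a grouping restricted to a set of rows:
// sum over groups of k*(k-1) / (n*(n-1)).
static double ehh_of(const std::vector<int>& grp, int from, int to) {
  std::map<int, int> counts;
  for (int i = from; i < to; ++i) counts[grp[i]]++;
  double n = to - from;
  if (n < 2) return 0.0;
  double s = 0.0;
  for (std::map<int, int>::iterator it = counts.begin(); it != counts.end();
       ++it)
    s += (double)it->second * (it->second - 1);
  return s / (n * (n - 1.0));
}

// Refine group ids by the allele at site j (NA -> own allele class 2).
static void refine(std::vector<int>& grp, const IntegerMatrix& ha,
                   const IntegerMatrix& hb, int j) {
  int na = ha.nrow(), nb = hb.nrow();
  std::map<std::pair<int, int>, int> remap;
  int next = 0;
  for (int i = 0; i < na + nb; ++i) {
    int a = (i < na) ? ha(i, j) : hb(i - na, j);
    if (a == NA_INTEGER) a = 2;
    std::pair<int, int> key(grp[i], a);
    std::map<std::pair<int, int>, int>::iterator it = remap.find(key);
    if (it == remap.end()) {
      remap[key] = next;
      grp[i] = next++;
    } else {
      grp[i] = it->second;
    }
  }
}

// Unstandardized XP-EHH: per core SNP, extend EHH both directions until the
// pooled-sample EHH drops below `cutoff` (or extension/gap caps hit),
// integrate each population's EHH over bp by the trapezoid rule, and return
// ln(iHH_A / iHH_B). NA where either integral is zero.
// [[Rcpp::export]]
NumericVector xpehh_raw_cpp(IntegerMatrix ha, IntegerMatrix hb,
                            NumericVector pos, IntegerVector cores,
                            double cutoff, double max_extend,
                            double max_gap) {
  int na = ha.nrow(), nb = hb.nrow(), k = pos.size();
  int n = na + nb;
  NumericVector out(cores.size(), NA_REAL);
  for (int ci = 0; ci < cores.size(); ++ci) {
    int c = cores[ci];
    double ihh_a = 0.0, ihh_b = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      std::vector<int> grp(n, 0);
      refine(grp, ha, hb, c);
      double ea = ehh_of(grp, 0, na);
      double eb = ehh_of(grp, na, n);
      double ep = ehh_of(grp, 0, n);
      double prev_pos = pos[c];
      int j = c + dir;
      while (j >= 0 && j < k) {
        double gap = (pos[j] > prev_pos) ? pos[j] - prev_pos
                                         : prev_pos - pos[j];
        double ext = (pos[j] > pos[c]) ? pos[j] - pos[c] : pos[c] - pos[j];
        if (gap > max_gap || ext > max_extend) break;
        refine(grp, ha, hb, j);
        double ea2 = ehh_of(grp, 0, na);
        double eb2 = ehh_of(grp, na, n);
        double ep2 = ehh_of(grp, 0, n);
        ihh_a += 0.5 * (ea + ea2) * gap;
        ihh_b += 0.5 * (eb + eb2) * gap;
        ea = ea2; eb = eb2; ep = ep2;
        prev_pos = pos[j];
        if (ep < cutoff) break;
        j += dir;
      }
    }
    if (ihh_a > 0.0 && ihh_b > 0.0) out[ci] = std::log(ihh_a / ihh_b);
  }
  return out;
}
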