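// Gene-dropping through a pedigree: founder chromosomes carry unique
// haplotype labels; each transmission is a recombinant of the parent's two
// haplotypes with crossovers placed as a Poisson process (rate 1 / 100 cM,
// Haldane, no interference) and a random start phase. All randomness goes
// through R's RNG so set.seed() in R makes drops reproducible.
//
// A haplotype mosaic on one chromosome is stored as segment end positions
// (cM, half-open [start, end) tiling [0, L)) plus integer founder-haplotype
// labels.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Hap {
  std::vector<double> ends;
  std::vector<int> labs;
};

inline void push_seg(Hap& h, double end, int lab) {
  if (!h.ends.empty() && h.labs.back() == lab) {
    h.ends.back() = end;
  } else {
    h.ends.push_back(end);
    h.labs.push_back(lab);
  }
}

Hap meiosis(const Hap& h1, const Hap& h2, double L) {
  int k = static_cast<int>(R::rpois(L / 100.0));
  std::vector<double> cx(k);
  for (int i = 0; i < k; ++i) cx[i] = R::runif(0.0, L);
  std::sort(cx.begin(), cx.end());
  int cur = (R::unif_rand() < 0.5) ? 0 : 1;
  const Hap* H[2] = { &h1, &h2 };
  Hap out;
  double pos = 0.0;
  size_t ci = 0;
  while (pos < L) {
    double stop = (ci < cx.size()) ? cx[ci] : L;
    if (stop > pos) {
      const Hap& h = *H[cur];
      size_t j = std::upper_bound(h.ends.begin(), h.ends.end(), pos) - h.ends.begin();
      double p = pos;
      while (p < stop && j < h.ends.size()) {
        double e = std::min(h.ends[j], stop);
        if (e > p) push_seg(out, e, h.labs[j]);
        p = e;
        ++j;
      }
      pos = stop;
    }
    cur ^= 1;
    ++ci;
    if (ci > cx.size()) break;
  }
  return out;
}

Hap whole_chrom(double L, int lab) {
  Hap h;
  h.ends.push_back(L);
  h.labs.push_back(lab);
  return h;
}

List hap_to_R(const Hap& h) {
  return List::create(_["end"] = NumericVector(h.ends.begin(), h.ends.end()),
                      _["lab"] = IntegerVector(h.labs.begin(), h.labs.end()));
}

Hap hap_from_R(const List& l) {
  NumericVector e = l["end"];
  IntegerVector lb = l["lab"];
  Hap h;
  h.ends.assign(e.begin(), e.end());
  h.labs.assign(lb.begin(), lb.end());
  return h;
}

// matching intervals of two label step-functions on one chromosome
void match_intervals(const Hap& a, const Hap& b,
                     std::vector<double>& starts, std::vector<double>& ends) {
  size_t i = 0, j = 0;
  double pos = 0.0;
  double open = -1.0;
  while (i < a.ends.size() && j < b.ends.size()) {
    double e = std::min(a.ends[i], b.ends[j]);
    bool eq = a.labs[i] == b.labs[j];
    if (eq) {
      if (open < 0.0) open = pos;
    } else if (open >= 0.0) {
      starts.push_back(open); ends.push_back(pos); open = -1.0;
    }
    pos = e;
    if (a.ends[i] <= e) ++i;
    if (b.ends[j] <= e) ++j;
  }
  if (open >= 0.0) { starts.push_back(open); ends.push_back(pos); }
}

} // namespace

// fa, mo: 1-based parent row indices (0 unknown); ord: rows in
// parents-before-children order; keep: rows whose mosaics are returned.
// Returns list parallel to `keep`; element = list(h1, h2), each a list over
// chromosomes of list(end, lab). Labels: founder row r contributes 2r-1, 2r;
// phantom founders (single known parent) get fresh labels beyond 2n.
// [[Rcpp::export(name = ".gene_drop_cpp")]]
List gene_drop_cpp(IntegerVector fa, IntegerVector mo, IntegerVector ord,
                   NumericVector chrlen, IntegerVector keep) {
  const int n = fa.size();
  const int nchr = chrlen.size();
  // mosaics[row][hap][chr]
  std::vector<std::vector<std::vector<Hap> > > mos(
      n + 1, std::vector<std::vector<Hap> >(2, std::vector<Hap>(nchr)));
  std::vector<bool> done(n + 1, false);
  int next_phantom = 2 * n + 1;

  for (int t = 0; t < ord.size(); ++t) {
    int r = ord[t];
    int f = fa[r - 1], m = mo[r - 1];
    for (int side = 0; side < 2; ++side) {
      int par = side == 0 ? f : m;
      if (par == 0) {
        // phantom founder side: unique labels, no recombination needed
        int lab = next_phantom++;
        for (int c = 0; c < nchr; ++c)
          mos[r][side][c] = whole_chrom(chrlen[c], lab);
      } else {
        if (!done[par]) stop("gene drop order violates parents-before-children");
        for (int c = 0; c < nchr; ++c)
          mos[r][side][c] = meiosis(mos[par][0][c], mos[par][1][c], chrlen[c]);
      }
    }
    if (f == 0 && m == 0) {
      // true founder: overwrite with its canonical labels
      for (int side = 0; side < 2; ++side)
        for (int c = 0; c < nchr; ++c)
          mos[r][side][c] = whole_chrom(chrlen[c], 2 * (r - 1) + side + 1);
    }
    done[r] = true;
  }

  List out(keep.size());
  for (int i = 0; i < keep.size(); ++i) {
    int r = keep[i];
    if (!done[r]) stop("requested mosaic for a row not covered by the drop order");
    List h1(nchr), h2(nchr);
    for (int c = 0; c < nchr; ++c) {
      h1[c] = hap_to_R(mos[r][0][c]);
      h2[c] = hap_to_R(mos[r][1][c]);
    }
    out[i] = List::create(_["h1"] = h1, _["h2"] = h2);
  }
  return out;
}

// IBD intervals between two individuals' mosaics.
// mode 0: per-pairing intervals (pairing 1..4 = a1b1, a1b2, a2b1, a2b2)
// mode 1: union over the 4 pairings, merged, per chromosome
// Returns matrix with columns chrom (1-based), start, end, pairing (0 = union)
// [[Rcpp::export(name = ".pair_ibd_cpp")]]
NumericMatrix pair_ibd_cpp(List mosA, List mosB, NumericVector chrlen,
                           double min_cM, int mode) {
  const int nchr = chrlen.size();
  List a1 = mosA["h1"], a2 = mosA["h2"], b1 = mosB["h1"], b2 = mosB["h2"];
  std::vector<double> rc, rs, re, rp;
  for (int c = 0; c < nchr; ++c) {
    Hap A[2] = { hap_from_R(a1[c]), hap_from_R(a2[c]) };
    Hap B[2] = { hap_from_R(b1[c]), hap_from_R(b2[c]) };
    if (mode == 0) {
      int pairing = 0;
      for (int i = 0; i < 2; ++i) for (int j = 0; j < 2; ++j) {
        ++pairing;
        std::vector<double> s, e;
        match_intervals(A[i], B[j], s, e);
        for (size_t k = 0; k < s.size(); ++k) {
          if (e[k] - s[k] >= min_cM) {
            rc.push_back(c + 1); rs.push_back(s[k]); re.push_back(e[k]);
            rp.push_back(pairing);
          }
        }
      }
    } else {
      std::vector<double> s, e;
      for (int i = 0; i < 2; ++i) for (int j = 0; j < 2; ++j)
        match_intervals(A[i], B[j], s, e);
      // union-merge
      std::vector<size_t> idx(s.size());
      for (size_t k = 0; k < idx.size(); ++k) idx[k] = k;
      std::sort(idx.begin(), idx.end(),
                [&](size_t x, size_t y) { return s[x] < s[y]; });
      double cs = -1.0, ce = -1.0;
      for (size_t q = 0; q <= idx.size(); ++q) {
        if (q < idx.size() && s[idx[q]] <= ce) {
          ce = std::max(ce, e[idx[q]]);
        } else {
          if (cs >= 0.0 && ce - cs >= min_cM) {
            rc.push_back(c + 1); rs.push_back(cs); re.push_back(ce);
            rp.push_back(0);
          }
          if (q < idx.size()) { cs = s[idx[q]]; ce = e[idx[q]]; }
        }
      }
    }
  }
  NumericMatrix out(rc.size(), 4);
  for (size_t k = 0; k < rc.size(); ++k) {
    out(k, 0) = rc[k]; out(k, 1) = rs[k]; out(k, 2) = re[k]; out(k, 3) = rp[k];
  }
  colnames(out) = CharacterVector::create("chrom", "start", "end", "pairing");
  return out;
}
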