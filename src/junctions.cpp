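#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Junction (ancestry-block) representation: a homolog on one chromosome is a
// pair of parallel vectors pos/lab; segment j covers [pos[j], pos[j+1]) (last
// segment runs to the chromosome end) and carries founder-haplotype label
// lab[j].  pos[0] == 0 always; labels of adjacent segments differ.
//
// All randomness uses R's RNG stream (RNGScope via Rcpp attributes), with a
// draw order matching the pure-R reference engine exactly:
//   k ~ rpois(1, morgans); xs ~ runif(k, 0, L); coin ~ runif(1)

struct Homolog {
  std::vector<double> pos;
  std::vector<int> lab;
};

static void append_seg(Homolog &g, double p, int l) {
  if (!g.lab.empty() && g.lab.back() == l) return; // merge equal labels
  g.pos.push_back(p);
  g.lab.push_back(l);
}

// copy segments of parental homolog (pos,lab) overlapping [a,b) into gamete
static void copy_window(const double *pos, const int *lab, int n,
                        double a, double b, Homolog &out) {
  // first segment j with pos[j] <= a < pos[j+1]
  int j = int(std::upper_bound(pos, pos + n, a) - pos) - 1;
  if (j < 0) j = 0;
  for (; j < n && pos[j] < b; ++j) {
    double s = pos[j] > a ? pos[j] : a;
    append_seg(out, s, lab[j]);
  }
}

static Homolog gamete_core(const NumericVector &p1, const IntegerVector &l1,
                           const NumericVector &p2, const IntegerVector &l2,
                           double L, double morgans) {
  int k = int(R::rpois(morgans));
  std::vector<double> xs(k);
  for (int i = 0; i < k; ++i) xs[i] = unif_rand() * L;
  std::sort(xs.begin(), xs.end());
  bool first = unif_rand() < 0.5; // start on homolog 1?
  Homolog out;
  out.pos.reserve(p1.size() + p2.size() + k);
  out.lab.reserve(p1.size() + p2.size() + k);
  double a = 0.0;
  bool cur = first;
  for (int i = 0; i <= k; ++i) {
    double b = (i == k) ? L : xs[i];
    if (b > a) {
      if (cur)
        copy_window(REAL(p1), INTEGER(l1), p1.size(), a, b, out);
      else
        copy_window(REAL(p2), INTEGER(l2), p2.size(), a, b, out);
      a = b;
    }
    cur = !cur;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_gamete(List chrom, double L, double morgans) {
  Homolog g = gamete_core(chrom["p1"], chrom["l1"], chrom["p2"], chrom["l2"],
                          L, morgans);
  return List::create(_["pos"] = wrap(g.pos), _["lab"] = wrap(g.lab));
}

// Drop one full generation: for each offspring i, one gamete from its sire
// and one from its dam, chromosome by chromosome.  sire/dam are 1-based
// indices into `pop` (list of individuals; individual = list of chromosomes;
// chromosome = list(p1, l1, p2, l2)).
// [[Rcpp::export]]
List cpp_make_offspring(List pop, IntegerVector sire, IntegerVector dam,
                        NumericVector chrom_bp, NumericVector chrom_m) {
  int n_off = sire.size(), n_chr = chrom_bp.size();
  List out(n_off);
  for (int i = 0; i < n_off; ++i) {
    List sg = pop[sire[i] - 1], dg = pop[dam[i] - 1];
    List ind(n_chr);
    for (int c = 0; c < n_chr; ++c) {
      List sc = sg[c], dc = dg[c];
      Homolog g1 = gamete_core(sc[0], sc[1], sc[2], sc[3],
                               chrom_bp[c], chrom_m[c]);
      Homolog g2 = gamete_core(dc[0], dc[1], dc[2], dc[3],
                               chrom_bp[c], chrom_m[c]);
      ind[c] = List::create(_["p1"] = wrap(g1.pos), _["l1"] = wrap(g1.lab),
                            _["p2"] = wrap(g2.pos), _["l2"] = wrap(g2.lab));
    }
    out[i] = ind;
  }
  return out;
}

// sum of per-locus effects covered by one homolog, using per-label cumulative
// sums: cum(h, j) = sum of effects of label h at grid loci 1..j (0-based col
// j; column 0 is 0).  Grid positions gpos are sorted.
static double homolog_value(const double *pos, const int *lab, int n, double L,
                            const NumericVector &gpos,
                            const NumericMatrix &cum) {
  double v = 0.0;
  const double *gb = gpos.begin(), *ge = gpos.end();
  for (int j = 0; j < n; ++j) {
    double s = pos[j];
    double e = (j + 1 < n) ? pos[j + 1] : L;
    int i1 = int(std::lower_bound(gb, ge, s) - gb); // first grid >= s
    int i2 = int(std::lower_bound(gb, ge, e) - gb); // first grid >= e
    if (i2 > i1) v += cum(lab[j] - 1, i2) - cum(lab[j] - 1, i1);
  }
  return v;
}

// Breeding values of a whole population, summed over one or more
// effect-grid sets (e.g. the infinitesimal grid and the discrete-locus
// grid).  grid_sets: list of grid sets; each is a list per chromosome of
// list(gpos = positions, cum = labels x (L+1) cumulative effect matrix).
// Chromosome lists are accessed positionally: (p1, l1, p2, l2).
// [[Rcpp::export]]
NumericVector cpp_breeding_values(List pop, List grid_sets,
                                  NumericVector chrom_bp) {
  int n = pop.size(), n_chr = chrom_bp.size(), n_set = grid_sets.size();
  // hoist all grid vectors/matrices out of the individual loop
  std::vector<std::vector<NumericVector> > gpos(n_set);
  std::vector<std::vector<NumericMatrix> > cum(n_set);
  for (int s = 0; s < n_set; ++s) {
    List grids = grid_sets[s];
    for (int c = 0; c < n_chr; ++c) {
      List gr = grids[c];
      gpos[s].push_back(as<NumericVector>(gr["gpos"]));
      cum[s].push_back(as<NumericMatrix>(gr["cum"]));
    }
  }
  NumericVector bv(n);
  for (int i = 0; i < n; ++i) {
    List ind = pop[i];
    double v = 0.0;
    for (int c = 0; c < n_chr; ++c) {
      List chr = ind[c];
      NumericVector p1 = chr[0], p2 = chr[2];
      IntegerVector l1 = chr[1], l2 = chr[3];
      for (int s = 0; s < n_set; ++s) {
        if (gpos[s][c].size() == 0) continue;
        v += homolog_value(REAL(p1), INTEGER(l1), p1.size(), chrom_bp[c],
                           gpos[s][c], cum[s][c]);
        v += homolog_value(REAL(p2), INTEGER(l2), p2.size(), chrom_bp[c],
                           gpos[s][c], cum[s][c]);
      }
    }
    bv[i] = v;
  }
  return bv;
}

// Per-individual inbreeding coefficient: fraction of the genome where the two
// homologs carry the same founder-haplotype label.
// [[Rcpp::export]]
NumericVector cpp_ibd_fraction(List pop, NumericVector chrom_bp) {
  int n = pop.size(), n_chr = chrom_bp.size();
  double total = 0.0;
  for (int c = 0; c < n_chr; ++c) total += chrom_bp[c];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    List ind = pop[i];
    double shared = 0.0;
    for (int c = 0; c < n_chr; ++c) {
      List chr = ind[c];
      NumericVector p1 = chr[0], p2 = chr[2];
      IntegerVector l1 = chr[1], l2 = chr[3];
      int n1 = p1.size(), n2 = p2.size();
      int j1 = 0, j2 = 0;
      double a = 0.0, L = chrom_bp[c];
      while (a < L) {
        double e1 = (j1 + 1 < n1) ? p1[j1 + 1] : L;
        double e2 = (j2 + 1 < n2) ? p2[j2 + 1] : L;
        double b = e1 < e2 ? e1 : e2;
        if (b > L) b = L;
        if (l1[j1] == l2[j2]) shared += b - a;
        if (e1 <= b && j1 + 1 < n1) ++j1;
        if (e2 <= b && j2 + 1 < n2) ++j2;
        if (b <= a) break; // safety, cannot happen on valid input
        a = b;
      }
    }
    out[i] = shared / total;
  }
  return out;
}
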