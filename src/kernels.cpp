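#include <Rcpp.h>
using namespace Rcpp;

// Gamete dropping. `hap` holds haplotypes as a loci x (2 * nAnimals) raw
// matrix, columns 2i-1 and 2i (1-based) being the maternal/paternal
// haplotypes of animal i. For each requested parent one recombined gamete is
// produced: crossovers per chromosome ~ Poisson(length in Morgan), breakpoint
// positions uniform, no interference (Haldane); recurrent bidirectional
// mutation flips alleles with probability `mutRate` per locus. Uses R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export]]
RawMatrix cpp_drop_gametes(RawMatrix hap, IntegerVector parent,
                           IntegerVector chrStart, IntegerVector chrEnd,
                           NumericVector posM, NumericVector chrLenM,
                           double mutRate) {
  const int L = hap.nrow();
  const int K = parent.size();
  const int nChr = chrStart.size();
  if (posM.size() != L)
    stop("positions do not match haplotype rows");
  RawMatrix out(L, K);
  RNGScope scope;
  std::vector<double> bp;
  for (int k = 0; k < K; ++k) {
    const int p = parent[k] - 1;
    if (p < 0 || 2 * p + 1 >= hap.ncol())
      stop("parent index out of range");
    const Rbyte *h0 = &hap(0, 2 * p);
    const Rbyte *h1 = &hap(0, 2 * p + 1);
    Rbyte *g = &out(0, k);
    for (int c = 0; c < nChr; ++c) {
      const int lo = chrStart[c] - 1, hi = chrEnd[c] - 1;
      int ncx = (chrLenM[c] > 0.0) ? (int) R::rpois(chrLenM[c]) : 0;
      int src = (unif_rand() < 0.5) ? 0 : 1;
      if (ncx == 0) {
        const Rbyte *h = src ? h1 : h0;
        for (int i = lo; i <= hi; ++i) g[i] = h[i];
      } else {
        bp.clear();
        for (int x = 0; x < ncx; ++x) bp.push_back(unif_rand() * chrLenM[c]);
        std::sort(bp.begin(), bp.end());
        size_t b = 0;
        for (int i = lo; i <= hi; ++i) {
          while (b < bp.size() && posM[i] >= bp[b]) { src ^= 1; ++b; }
          g[i] = src ? h1[i] : h0[i];
        }
      }
    }
    if (mutRate > 0.0) {
      int nmut = (int) R::rbinom((double) L, mutRate);
      for (int x = 0; x < nmut; ++x) {
        int i = (int) (unif_rand() * L);
        if (i >= L) i = L - 1;
        g[i] = g[i] ? (Rbyte) 0 : (Rbyte) 1;
      }
    }
  }
  return out;
}

// Generalized Meuwissen & Luo recursion: diagonal of the (gamma-augmented)
// numerator relationship matrix and Mendelian sampling variances m_i.
// Pedigree must be topologically ordered; sire/dam are 1-based row indices or
// 0 when unknown. Founder rows (both parents 0) either belong to a
// metafounder group (`group` in 1..m, with founder covariances taken from
// `Gamma`) or are classical unrelated founders (group 0, self-relationship
// 1). A missing parent of a non-founder contributes as an unrelated
// non-inbred phantom founder. Mendelian variances are reported as NA for
// founder rows (they carry no Mendelian term).
// [[Rcpp::export]]
List cpp_ml_mendelian(IntegerVector sire, IntegerVector dam,
                      IntegerVector group, NumericMatrix Gamma) {
  const int n = sire.size();
  const int m = Gamma.nrow();
  NumericVector diag(n), mend(n);
  std::vector<double> buf(n, 0.0);
  std::vector<double> gcoef(m > 0 ? m : 1, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s > i || d > i)
      stop("pedigree not topologically ordered at row %d", i + 1);
    if (s == 0 && d == 0) {
      const int g = group[i];
      mend[i] = NA_REAL;
      diag[i] = (g > 0) ? Gamma(g - 1, g - 1) : 1.0;
      continue;
    }
    const double ds = (s > 0) ? diag[s - 1] : 1.0;
    const double dd = (d > 0) ? diag[d - 1] : 1.0;
    mend[i] = 1.0 - 0.25 * (ds + dd);
    if (m > 0) std::fill(gcoef.begin(), gcoef.end(), 0.0);
    buf[i] = 1.0;
    int lowest = i;
    double a = 0.0;
    for (int j = i; j >= lowest; --j) {
      const double c = buf[j];
      if (c == 0.0) continue;
      buf[j] = 0.0;
      const int js = sire[j], jd = dam[j];
      if (js == 0 && jd == 0) {
        const int g = group[j];
        if (g > 0) gcoef[g - 1] += c;
        else a += c * c;
        continue;
      }
      a += c * c * mend[j];
      if (js > 0) { buf[js - 1] += 0.5 * c; if (js - 1 < lowest) lowest = js - 1; }
      else a += 0.25 * c * c;
      if (jd > 0) { buf[jd - 1] += 0.5 * c; if (jd - 1 < lowest) lowest = jd - 1; }
      else a += 0.25 * c * c;
    }
    if (m > 0) {
      for (int g1 = 0; g1 < m; ++g1) {
        if (gcoef[g1] == 0.0) continue;
        for (int g2 = 0; g2 < m; ++g2)
          if (gcoef[g2] != 0.0) a += gcoef[g1] * gcoef[g2] * Gamma(g1, g2);
      }
    }
    diag[i] = a;
  }
  return List::create(_["diag"] = diag, _["mendelian"] = mend);
}
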