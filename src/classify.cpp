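#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// Does the sequence contain any 12-mer present in the context table?
// Rolling 24-bit encoding; windows containing non-ACGT restart.
static bool seed_hit(const std::string &s, const std::vector<bool> &tab) {
  const int W = 12;
  int n = (int) s.size();
  if (n < W) return false;
  unsigned int h = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[(size_t) i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (unsigned) c) & 0xFFFFFFu;
    if (++run >= W && tab[h]) return true;
  }
  return false;
}

// Best ungapped alignment of each read (both orientations) at every offset
// against every 2k-nt junction context. A candidate is valid iff the aligned
// span crosses the context midpoint (index k) with >= m nt on both sides and
// its mismatch rate over the aligned span is <= max_rate. Best = fewest
// mismatches, then longest overlap; a residual tie across different context
// indices is flagged (the caller reports AMBIGUOUS).
//
// A lossless seed prefilter skips orientations that cannot hold a valid
// candidate: any aligned span of >= 2m nt (m >= 6) at <= max_rate < 0.2
// mismatch rate contains an exact run of >= ceil((2m - floor(2m*rate))/
// (floor(2m*rate)+1)) matches; for the permitted parameter ranges this is
// always >= 12, so a valid read must share an exact 12-mer with a context.
// [[Rcpp::export]]
DataFrame classify_reads_cpp(CharacterVector reads, CharacterVector contexts,
                             int k, int m, double max_rate) {
  int nr = reads.size(), nc = contexts.size();
  std::vector<std::string> ctx(nc);
  for (int j = 0; j < nc; ++j) ctx[j] = as<std::string>(contexts[j]);
  // pigeonhole guarantee: a valid span of ov nt with b = floor(ov*rate)
  // mismatches contains an exact run of >= ceil((ov - b)/(b + 1)) matches;
  // the filter is lossless iff that bound is >= 12 for every permitted ov.
  int min_run = INT_MAX;
  for (int ov = 2 * m; ov <= 2 * k; ++ov) {
    int b = (int) (max_rate * ov + 1e-9);
    int run = (ov - b + b) / (b + 1);  // ceil((ov - b)/(b + 1))
    if (run < min_run) min_run = run;
  }
  bool use_seed = min_run >= 12;
  std::vector<bool> tab;
  if (use_seed) {
    tab.assign(1u << 24, false);
    const int W = 12;
    for (int j = 0; j < nc; ++j) {
      const std::string &cx = ctx[j];
      int n = (int) cx.size();
      unsigned int h = 0;
      int run = 0;
      for (int i = 0; i < n; ++i) {
        int c = base_code(cx[(size_t) i]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (unsigned) c) & 0xFFFFFFu;
        if (++run >= W) tab[h] = true;
      }
    }
  }
  IntegerVector best_idx(nr), best_mm(nr), left_ov(nr), right_ov(nr);
  LogicalVector tie(nr);
  CharacterVector strand(nr);
  const int w = 2 * k;
  for (int i = 0; i < nr; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp_str(fwd);
    int rlen = (int) fwd.size();
    int bmm = INT_MAX, bov = -1, bidx = -1;
    bool btie = false;
    char bstr = '+';
    for (int ori = 0; ori < 2; ++ori) {
      const std::string &rd = ori == 0 ? fwd : rev;
      if (use_seed && !seed_hit(rd, tab)) continue;
      for (int j = 0; j < nc; ++j) {
        const std::string &cx = ctx[j];
        if ((int) cx.size() != w) continue;
        // offset o: context index t aligns to read index t + o
        int olo = m - k, ohi = rlen - k - m;
        for (int o = olo; o <= ohi; ++o) {
          int a = o < 0 ? -o : 0;
          int b = w < rlen - o ? w : rlen - o;
          int ov = b - a;
          if (ov < 2 * m) continue;
          int budget = (int) (max_rate * ov + 1e-9);
          int mm = 0;
          for (int t = a; t < b; ++t) {
            if (rd[(size_t)(t + o)] != cx[(size_t) t]) {
              if (++mm > budget) break;
            }
          }
          if (mm > budget) continue;
          if (mm < bmm || (mm == bmm && ov > bov)) {
            bmm = mm; bov = ov; bidx = j; btie = false;
            bstr = ori == 0 ? '+' : '-';
            left_ov[i] = k - a; right_ov[i] = b - k;
          } else if (mm == bmm && ov == bov && j != bidx) {
            btie = true;
          }
        }
      }
    }
    if (bidx < 0) {
      best_idx[i] = 0; best_mm[i] = NA_INTEGER; tie[i] = false;
      left_ov[i] = 0; right_ov[i] = 0; strand[i] = NA_STRING;
    } else {
      best_idx[i] = bidx + 1; best_mm[i] = bmm; tie[i] = btie;
      strand[i] = std::string(1, bstr);
    }
  }
  return DataFrame::create(_["best_idx"] = best_idx,
                           _["mismatches"] = best_mm,
                           _["left_overlap"] = left_ov,
                           _["right_overlap"] = right_ov,
                           _["tie"] = tie, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Full-length ungapped placement of each read on a (circular) genome, both
// strands, allowing a mismatch rate <= max_rate. Returns the best placement
// (0-based position of the read's leftmost genome-forward coordinate) or
// idx 0 when none. Positions are deduplicated modulo the genome length.
// [[Rcpp::export]]
DataFrame place_reads_cpp(CharacterVector reads, std::string genome,
                          bool circular, double max_rate) {
  int L = (int) genome.size();
  std::string g = circular ? genome + genome : genome;
  int nr = reads.size();
  IntegerVector pos(nr), mm_out(nr);
  CharacterVector strand(nr);
  LogicalVector found(nr), tie(nr);
  for (int i = 0; i < nr; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp_str(fwd);
    int rlen = (int) fwd.size();
    int budget = (int) (max_rate * rlen + 1e-9);
    int bmm = INT_MAX, bpos = -1;
    bool btie = false;
    char bstr = '+';
    int maxstart = circular ? L - 1 : L - rlen;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string &rd = ori == 0 ? fwd : rev;
      for (int p = 0; p <= maxstart; ++p) {
        if (p + rlen > (int) g.size()) break;
        int mm = 0;
        for (int t = 0; t < rlen; ++t) {
          if (rd[(size_t) t] != g[(size_t)(p + t)]) {
            if (++mm > budget) break;
          }
        }
        if (mm > budget) continue;
        char cstr = ori == 0 ? '+' : '-';
        if (mm < bmm) {
          bmm = mm; bpos = p; btie = false; bstr = cstr;
        } else if (mm == bmm && !(p == bpos && cstr == bstr)) {
          btie = true;
        }
      }
    }
    if (bpos < 0) {
      found[i] = false; pos[i] = NA_INTEGER; mm_out[i] = NA_INTEGER;
      strand[i] = NA_STRING; tie[i] = false;
    } else {
      found[i] = true; pos[i] = bpos % L; mm_out[i] = bmm;
      strand[i] = std::string(1, bstr); tie[i] = btie;
    }
  }
  return DataFrame::create(_["found"] = found, _["pos"] = pos,
                           _["mismatches"] = mm_out, _["strand"] = strand,
                           _["tie"] = tie, _["stringsAsFactors"] = false);
}
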