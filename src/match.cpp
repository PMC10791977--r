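#include <Rcpp.h>
using namespace Rcpp;

// A position matches only when both bases are equal AND unambiguous (ACGT);
// any other symbol (N, IUPAC codes, lowercase) mismatches everything,
// including itself.
static inline bool base_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

static inline int hamming_capped(const char* a, const char* b, int len,
                                 int cap) {
  int d = 0;
  for (int i = 0; i < len; ++i) {
    if (!base_match(a[i], b[i])) {
      if (++d > cap) return d;
    }
  }
  return d;
}

// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size())
    stop("sequences must have equal length (%d vs %d)", (int)a.size(),
         (int)b.size());
  return hamming_capped(a.c_str(), b.c_str(), (int)a.size(), (int)a.size());
}

// Minimum pairwise Hamming distance among equal-length strings.
// [[Rcpp::export]]
int min_hamming_cpp(CharacterVector seqs) {
  int n = seqs.size();
  if (n < 2) stop("need at least two sequences");
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  int len = (int)s[0].size();
  int best = len;
  for (int i = 0; i < n; ++i) {
    if ((int)s[i].size() != len) stop("sequences must have equal length");
    for (int j = i + 1; j < n; ++j) {
      int d = hamming_capped(s[i].c_str(), s[j].c_str(), len, best);
      if (d < best) best = d;
      if (best == 0) return 0;
    }
  }
  return best;
}

// Assign each read to its best-matching cassette pattern.
//
// Every pattern is evaluated at every valid offset of the read (and of its
// reverse complement when supplied). Among all (pattern, offset) pairs with
// mismatch count <= max_mm, the minimal distance d* is found. If no pair
// qualifies the read is unassigned; if all minimal pairs share one pattern it
// is assigned at the leftmost minimal offset; if two or more distinct
// patterns attain d* the read is discarded as ambiguous.
//
// status: 0 = unassigned, 1 = assigned, 2 = ambiguous.
// [[Rcpp::export]]
List match_reads_cpp(CharacterVector reads, CharacterVector cassettes,
                     int max_mm, Nullable<CharacterVector> reads_rc_ =
                         R_NilValue) {
  int n_reads = reads.size();
  int n_pat = cassettes.size();
  std::vector<std::string> pats(n_pat);
  for (int j = 0; j < n_pat; ++j) pats[j] = as<std::string>(cassettes[j]);

  bool use_rc = reads_rc_.isNotNull();
  CharacterVector reads_rc;
  if (use_rc) reads_rc = reads_rc_.get();

  IntegerVector status(n_reads), pat_idx(n_reads), offset(n_reads),
      mism(n_reads);

  for (int r = 0; r < n_reads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int n_strands = use_rc ? 2 : 1;
    int best_d = max_mm + 1;
    int best_j = -1, best_off = -1;
    bool tie_other_id = false;
    for (int strand = 0; strand < n_strands; ++strand) {
      std::string rd =
          strand == 0 ? fwd : as<std::string>(reads_rc[r]);
      int rl = (int)rd.size();
      for (int j = 0; j < n_pat; ++j) {
        int cl = (int)pats[j].size();
        for (int o = 0; o + cl <= rl; ++o) {
          int d = hamming_capped(rd.c_str() + o, pats[j].c_str(), cl, best_d);
          if (d < best_d) {
            best_d = d;
            best_j = j;
            best_off = (strand == 0) ? o : -1;  // offset on fwd strand only
            tie_other_id = false;
          } else if (d == best_d && best_d <= max_mm && j != best_j) {
            tie_other_id = true;
          }
        }
      }
    }
    if (best_d > max_mm) {
      status[r] = 0;
      pat_idx[r] = NA_INTEGER;
      offset[r] = NA_INTEGER;
      mism[r] = NA_INTEGER;
    } else if (tie_other_id) {
      status[r] = 2;
      pat_idx[r] = NA_INTEGER;
      offset[r] = NA_INTEGER;
      mism[r] = best_d;
    } else {
      status[r] = 1;
      pat_idx[r] = best_j + 1;  // 1-based for R
      offset[r] = best_off;     // 0-based; -1 if on reverse strand
      mism[r] = best_d;
    }
  }
  return List::create(_["status"] = status, _["pattern"] = pat_idx,
                      _["offset"] = offset, _["mismatches"] = mism);
}
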