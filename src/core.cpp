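// Hot loops of the pipeline: seeded ungapped mapping and DUST scoring.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp(c);
  return out;
}

// Exact k-mer index of the reference: 2-bit encoded k-mer -> start positions.
static void build_index(const std::string& ref, int k,
                        std::unordered_map<uint64_t, std::vector<int>>& idx) {
  int n = (int)ref.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(ref[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++valid >= k) idx[kmer].push_back(i - k + 1);
  }
}

static inline int hamming(const std::string& ref, int pos, const std::string& q,
                          int stop_at) {
  int mm = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    if (ref[pos + i] != q[i] && ++mm > stop_at) return mm;
  }
  return mm;
}

// Best ungapped placement of each read: both strands, exact 16-mer seeding
// at every query offset, full-length Hamming extension, mismatch-rate cap.
// Ties: fewest mismatches, then lowest ref_start, then + strand.
// [[Rcpp::export]]
List map_reads_cpp(std::string reference, CharacterVector seqs,
                   int k, double max_mismatch_rate) {
  int refn = (int)reference.size();
  std::unordered_map<uint64_t, std::vector<int>> idx;
  build_index(reference, k, idx);
  int n = seqs.size();
  IntegerVector start(n), mism(n);
  CharacterVector strand(n);
  LogicalVector mapped(n);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(seqs[r]);
    int len = (int)fwd.size();
    int best_mm = (int)(max_mismatch_rate * len);  // floor: reject if mm > cap
    int bb_mm = best_mm + 1, bb_pos = -1, bb_strand = 0;
    if (len >= k && len <= refn) {
      std::string rev = revcomp_str(fwd);
      for (int s = 0; s < 2; ++s) {
        const std::string& q = (s == 0) ? fwd : rev;
        std::vector<char> tried(refn, 0);
        uint64_t kmer = 0; int valid = 0;
        for (int i = 0; i < len; ++i) {
          int b = base2bit(q[i]);
          if (b < 0) { valid = 0; kmer = 0; continue; }
          kmer = ((kmer << 2) | (uint64_t)b) & mask;
          if (++valid < k) continue;
          int off = i - k + 1;
          auto it = idx.find(kmer);
          if (it == idx.end()) continue;
          for (int hit : it->second) {
            int pos = hit - off;
            if (pos < 0 || pos + len > refn) continue;
            if (tried[pos]) continue;
            tried[pos] = 1;
            int mm = hamming(reference, pos, q, bb_mm);
            bool better = mm < bb_mm ||
              (mm == bb_mm && bb_pos >= 0 &&
               (pos < bb_pos || (pos == bb_pos && s < bb_strand)));
            if (mm <= best_mm && better) {
              bb_mm = mm; bb_pos = pos; bb_strand = s;
            }
          }
        }
      }
    }
    if (bb_pos >= 0) {
      mapped[r] = true; start[r] = bb_pos; mism[r] = bb_mm;
      strand[r] = (bb_strand == 0) ? "+" : "-";
    } else {
      mapped[r] = false; start[r] = NA_INTEGER; mism[r] = NA_INTEGER;
      strand[r] = NA_STRING;
    }
  }
  return List::create(_["mapped"] = mapped, _["start"] = start,
                      _["strand"] = strand, _["n_mismatches"] = mism);
}

// Morgulis-style windowed DUST: max over 64-bp sliding windows of
// sum c_t(c_t - 1)/2 / (w - 1), c_t the count of each overlapping 3-mer
// among the window's w valid (non-N) triplets.
// [[Rcpp::export]]
NumericVector dust_score_cpp(CharacterVector seqs, int window) {
  int n = seqs.size();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int len = (int)s.size();
    if (len < 3) { out[r] = NA_REAL; continue; }
    // triplet code at each start (-1 if any base invalid)
    std::vector<int> tri(len - 2, -1);
    for (int i = 0; i + 2 < len; ++i) {
      int a = base2bit(s[i]), b = base2bit(s[i + 1]), c = base2bit(s[i + 2]);
      if (a >= 0 && b >= 0 && c >= 0) tri[i] = (a << 4) | (b << 2) | c;
    }
    double best = 0.0;
    int nwin = std::max(1, len - window + 1);
    std::vector<int> cnt(64, 0);
    for (int w0 = 0; w0 < nwin; ++w0) {
      int wend = std::min(len, w0 + window);  // window [w0, wend) in bp
      std::fill(cnt.begin(), cnt.end(), 0);
      int wtri = 0;
      double sum = 0.0;
      for (int i = w0; i + 2 < wend; ++i) {
        if (tri[i] < 0) continue;
        sum += cnt[tri[i]];  // adding the (c+1)-th copy adds c pairs
        ++cnt[tri[i]];
        ++wtri;
      }
      if (wtri >= 2) {
        double score = sum / (double)(wtri - 1);
        if (score > best) best = score;
      }
    }
    out[r] = best;
  }
  return out;
}
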