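#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Two independent routes to the same placement set:
//  - cpp_seeded_scan: exact k-mer seeding (pigeonhole) + Hamming verification
//  - cpp_brute_scan:  naive enumeration of every (substring, window) placement
// They deliberately share no traversal logic; only the trivial base encoding
// convention (A=0 C=1 G=2 T=3, anything else = 4, which never matches) is
// common to both.

struct Placement {
  int guide;         // 1-based guide index
  int ref;           // 1-based reference index
  int strand;        // 0 = '+', 1 = '-'
  int ref_start;     // 0-based on the forward reference
  int guide_offset;  // 0-based offset of the matched substring in the guide
  int len;           // aligned length
  int mm;            // mismatches
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<int> encode_seq(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int> revcomp_codes(const std::vector<int> &v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int c = v[v.size() - 1 - i];
    r[i] = (c <= 3) ? 3 - c : 4;
  }
  return r;
}

static int min_aligned(int L, double min_cov) {
  return (int)std::ceil(min_cov * L - 1e-9);
}

static DataFrame placements_to_df(const std::vector<Placement> &hits) {
  int n = hits.size();
  IntegerVector guide(n), ref(n), start(n), off(n), len(n), mm(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    guide[i] = hits[i].guide;
    ref[i] = hits[i].ref;
    strand[i] = hits[i].strand ? "-" : "+";
    start[i] = hits[i].ref_start;
    off[i] = hits[i].guide_offset;
    len[i] = hits[i].len;
    mm[i] = hits[i].mm;
  }
  return DataFrame::create(
    _["guide_idx"] = guide, _["ref_idx"] = ref, _["strand"] = strand,
    _["ref_start"] = start, _["guide_offset"] = off,
    _["aligned_length"] = len, _["mismatches"] = mm,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------- seeded scan

// [[Rcpp::export]]
DataFrame cpp_seeded_scan(CharacterVector references, CharacterVector guides,
                          int k, int max_mm, double min_cov, bool both_strands) {
  std::vector<Placement> hits;
  int n_ref = references.size(), n_guide = guides.size();

  std::vector<std::vector<int>> guide_fwd(n_guide), guide_rc(n_guide);
  for (int gi = 0; gi < n_guide; ++gi) {
    guide_fwd[gi] = encode_seq(as<std::string>(guides[gi]));
    if (both_strands) guide_rc[gi] = revcomp_codes(guide_fwd[gi]);
  }

  for (int ri = 0; ri < n_ref; ++ri) {
    std::string refs = as<std::string>(references[ri]);
    std::vector<int> ref = encode_seq(refs);
    int N = (int)ref.size();
    if (N < k) continue;

    // exact k-mer index of the forward reference (k-mers containing
    // ambiguity codes are unseedable and skipped)
    std::unordered_map<uint64_t, std::vector<int>> index;
    index.reserve(N);
    uint64_t code = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (int i = 0; i < N; ++i) {
      if (ref[i] > 3) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)ref[i]) & mask;
      if (++valid >= k) index[code].push_back(i - k + 1);
    }

    for (int gi = 0; gi < n_guide; ++gi) {
      int L = (int)guide_fwd[gi].size();
      int lmin = min_aligned(L, min_cov);
      if (N < lmin || L < k) continue;
      for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
        const std::vector<int> &g = strand ? guide_rc[gi] : guide_fwd[gi];
        // candidate diagonals from exact seed matches
        std::vector<int> diags;
        uint64_t gcode = 0;
        int gvalid = 0;
        for (int o = 0; o < L; ++o) {
          if (g[o] > 3) { gvalid = 0; gcode = 0; continue; }
          gcode = ((gcode << 2) | (uint64_t)g[o]) & mask;
          if (++gvalid < k) continue;
          int off = o - k + 1;
          auto it = index.find(gcode);
          if (it == index.end()) continue;
          for (int p : it->second) diags.push_back(p - off);
        }
        std::sort(diags.begin(), diags.end());
        diags.erase(std::unique(diags.begin(), diags.end()), diags.end());

        for (int d : diags) {
          for (int len = lmin; len <= L; ++len) {
            for (int o = 0; o + len <= L; ++o) {
              int r = d + o;
              if (r < 0 || r + len > N) continue;
              int mm = 0;
              for (int t = 0; t < len; ++t) {
                if (g[o + t] != ref[r + t] || g[o + t] > 3) {
                  if (++mm > max_mm) break;
                }
              }
              if (mm <= max_mm) {
                // map the matched substring back onto the given guide
                int goff = strand ? (L - o - len) : o;
                hits.push_back({gi + 1, ri + 1, strand, r, goff, len, mm});
              }
            }
          }
        }
      }
    }
  }
  return placements_to_df(hits);
}

// ----------------------------------------------------------------- brute force

// [[Rcpp::export]]
DataFrame cpp_brute_scan(CharacterVector references, CharacterVector guides,
                         int max_mm, double min_cov, bool both_strands) {
  std::vector<Placement> hits;
  int n_ref = references.size(), n_guide = guides.size();

  for (int gi = 0; gi < n_guide; ++gi) {
    std::vector<int> gf = encode_seq(as<std::string>(guides[gi]));
    int L = (int)gf.size();
    int lmin = min_aligned(L, min_cov);
    std::vector<int> gr;
    if (both_strands) gr = revcomp_codes(gf);

    for (int ri = 0; ri < n_ref; ++ri) {
      std::string refs = as<std::string>(references[ri]);
      std::vector<int> ref = encode_seq(refs);
      int N = (int)ref.size();
      if (N < lmin) continue;  // reference shorter than any qualifying placement

      for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
        const std::vector<int> &g = strand ? gr : gf;
        // every placement (o, len, r) lies on the diagonal d = r - o; walk
        // each diagonal once, take mismatch prefix sums, and evaluate every
        // in-bounds window — a full enumeration without any seeding
        std::vector<int> prefix(L + 1);
        for (int d = -(L - lmin); d <= N - lmin; ++d) {
          prefix[0] = 0;
          for (int j = 0; j < L; ++j) {
            int rp = d + j;
            int mis = (rp < 0 || rp >= N) ? 0
                      : (g[j] != ref[rp] || g[j] > 3) ? 1 : 0;
            prefix[j + 1] = prefix[j] + mis;
          }
          for (int len = lmin; len <= L; ++len) {
            for (int o = 0; o + len <= L; ++o) {
              int r = d + o;
              if (r < 0 || r + len > N) continue;
              int mm = prefix[o + len] - prefix[o];
              if (mm <= max_mm) {
                int goff = strand ? (L - o - len) : o;
                hits.push_back({gi + 1, ri + 1, strand, r, goff, len, mm});
              }
            }
          }
        }
      }
    }
  }
  return placements_to_df(hits);
}
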