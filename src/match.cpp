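#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Ungapped mismatch-tolerant read matching: slide the read along the
// reference (forward strand and the read's reverse complement) and accept
// any placement whose Hamming distance is <= max_mismatches. Positions
// only match on identical A/C/G/T; N (or any other code) never matches.

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    case 'a': return 'T'; case 't': return 'A';
    case 'c': return 'G'; case 'g': return 'C';
    default:  return 'N';
  }
}

static inline bool base_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

static bool scan_one(const std::string &read, const std::string &ref,
                     int max_mm) {
  const int m = (int)read.size(), n = (int)ref.size();
  if (m == 0 || m > n) return false;
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0;
    for (int k = 0; k < m; ++k) {
      if (!base_match(read[k], ref[s + k]) && ++mm > max_mm) break;
    }
    if (mm <= max_mm) return true;
  }
  return false;
}

static std::string upper(const std::string &s) {
  std::string r(s);
  for (char &c : r) c = (char)toupper((unsigned char)c);
  return r;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) c = comp(c);
  return r;
}

// [[Rcpp::export]]
bool cpp_read_matches(std::string read, std::string reference, int max_mismatches) {
  std::string rd = upper(read), rf = upper(reference);
  if (scan_one(rd, rf, max_mismatches)) return true;
  return scan_one(revcomp(rd), rf, max_mismatches);
}

// [[Rcpp::export]]
int cpp_count_matches(CharacterVector reads, std::string reference, int max_mismatches) {
  std::string rf = upper(reference);
  int count = 0;
  for (int i = 0; i < reads.size(); ++i) {
    std::string rd = upper(as<std::string>(reads[i]));
    if (scan_one(rd, rf, max_mismatches) ||
        scan_one(revcomp(rd), rf, max_mismatches)) ++count;
  }
  return count;
}
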