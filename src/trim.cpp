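#include <Rcpp.h>
#include <zlib.h>
#include <cctype>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// Match bonus: log10(4), the information content of one confirmed base.
// Mismatch penalty: q/10, i.e. -log10 of the base-call error probability
// scale, so the printed clip thresholds (10 ~ 17 perfect matches, 30 ~ 50)
// keep their conventional meaning.
static const double LOG10_4 = 0.6020599913279624;

static inline char upbase(char c) {
  return static_cast<char>(std::toupper(static_cast<unsigned char>(c)));
}

static inline bool base_match(char a, char b) {
  a = upbase(a);
  b = upbase(b);
  if (a == 'N' || b == 'N') return false; // N matches nothing
  return a == b;
}

// ---- sliding-window quality trimming -------------------------------------

// Returns the kept prefix length (0 => read dropped).
// Window means are compared exactly: mean < q  <=>  sum < q * w.
// [[Rcpp::export(name = ".sliding_window_keep")]]
int sliding_window_keep(IntegerVector quals, int w, int q) {
  const int n = quals.size();
  if (n == 0) return 0;
  if (n < w) {
    // the whole read is a single window
    long long sum = 0;
    for (int i = 0; i < n; ++i) sum += quals[i];
    return (sum < static_cast<long long>(q) * n) ? 0 : n;
  }
  long long sum = 0;
  for (int i = 0; i < w; ++i) sum += quals[i];
  const long long lim = static_cast<long long>(q) * w;
  int cut = -1;
  for (int i = 0; i + w <= n; ++i) {
    if (i > 0) sum += quals[i + w - 1] - quals[i - 1];
    if (sum < lim) { cut = i; break; }
  }
  if (cut < 0) return n; // no failing window: read untouched
  int keep = cut;
  while (keep > 0 && quals[keep - 1] < q) --keep; // 3' cleanup after the cut
  return keep;
}

// ---- information-maximizing trimming --------------------------------------

static inline double flen_term(double x) {
  // ln(1 / (1 + e^x)) = -log1p(e^x), stable for large x
  if (x > 35.0) return -x;
  return -std::log1p(std::exp(x));
}

// Returns the kept prefix length L* maximizing
//   score(L) = ln(1/(1+e^(T-1-L))) + (1-s) ln(L) + s * sum_{i<L} ln(1-10^(-q_i/10))
// with q_i = 0 treated as 1; ties broken toward larger L; n == 0 => 0.
// [[Rcpp::export(name = ".maxinfo_keep")]]
int maxinfo_keep(IntegerVector quals, int target, double strictness) {
  const int n = quals.size();
  if (n == 0) return 0;
  double best = R_NegInf;
  int best_l = 0;
  double err_sum = 0.0;
  for (int L = 1; L <= n; ++L) {
    int q = quals[L - 1];
    if (q < 1) q = 1;
    err_sum += std::log(1.0 - std::pow(10.0, -q / 10.0));
    double score = flen_term(static_cast<double>(target) - 1.0 - L) +
                   (1.0 - strictness) * std::log(static_cast<double>(L)) +
                   strictness * err_sum;
    if (score >= best) { best = score; best_l = L; }
  }
  return best_l;
}

// ---- adapter alignment -----------------------------------------------------

// Score one gap-free alignment window: +log10(4) per match, -q/10 per
// mismatch, q taken from read_quals.
// [[Rcpp::export(name = ".alignment_score")]]
double alignment_score_cpp(std::string read_bases, IntegerVector read_quals,
                           std::string adapter_bases) {
  const size_t n = read_bases.size();
  if (n != static_cast<size_t>(read_quals.size()) || n != adapter_bases.size())
    stop("alignment windows must have equal length");
  double score = 0.0;
  for (size_t i = 0; i < n; ++i) {
    if (base_match(read_bases[i], adapter_bases[i])) score += LOG10_4;
    else score -= read_quals[i] / 10.0;
  }
  return score;
}

// Earliest read offset at which the adapter aligns above threshold, or -1.
// Offsets are scanned 5'->3'; at each offset the overlap is the adapter
// prefix that fits in the read. Overlaps shorter than min_adapter_len are
// considered only while a perfect overlap could still reach the threshold.
// Seed test: <= seed_mismatches in the first min(16, overlap) columns.
// [[Rcpp::export(name = ".simple_clip_offset")]]
int simple_clip_offset(std::string bases, IntegerVector quals,
                       std::string adapter, int seed_mismatches,
                       double threshold, int min_adapter_len) {
  const int n = bases.size();
  const int m = adapter.size();
  for (int o = 0; o < n; ++o) {
    int ov = std::min(m, n - o);
    if (ov < 1) continue;
    if (ov < min_adapter_len &&
        ov * LOG10_4 < threshold) continue; // short and cannot reach threshold
    if (ov * LOG10_4 < threshold) continue; // cannot reach threshold anyway
    int seed = std::min(16, ov);
    int mism = 0;
    for (int i = 0; i < seed; ++i)
      if (!base_match(bases[o + i], adapter[i]) && ++mism > seed_mismatches)
        break;
    if (mism > seed_mismatches) continue;
    double score = 0.0;
    for (int i = 0; i < ov; ++i) {
      if (base_match(bases[o + i], adapter[i])) score += LOG10_4;
      else score -= quals[o + i] / 10.0;
    }
    if (score >= threshold) return o;
  }
  return -1;
}

static inline char comp(char c) {
  switch (upbase(c)) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// Palindrome (read-through) detection across a pair.
//
// Conceptually each mate is extended 5' with its ligated adapter prefix
// (prefix1 onto fwd, prefix2 onto rev; extension columns carry quality 40),
// and the extended forward read is aligned against the reverse complement
// of the extended reverse read at every implied fragment length
// L in 1 .. min(len_fwd, len_rev) - 1. Each candidate passes a 16-column
// seed test, then a full-overlap score (mismatch penalty uses the smaller
// of the two column qualities). The best score >= threshold wins; ties go
// to the shorter fragment. Returns the fragment length, or -1.
// [[Rcpp::export(name = ".palindrome_fragment")]]
int palindrome_fragment(std::string fwd_bases, IntegerVector fwd_quals,
                        std::string rev_bases, IntegerVector rev_quals,
                        std::string prefix1, std::string prefix2,
                        int seed_mismatches, double threshold) {
  const int n1 = fwd_bases.size();
  const int n2 = rev_bases.size();
  const int a1 = prefix1.size();
  const int a2 = prefix2.size();
  if (n1 == 0 || n2 == 0) return -1;

  // ext1 = prefix1 + fwd
  const int len1 = a1 + n1;
  std::string e1(len1, 'N');
  std::vector<int> q1(len1, 40);
  for (int i = 0; i < a1; ++i) e1[i] = upbase(prefix1[i]);
  for (int i = 0; i < n1; ++i) {
    e1[a1 + i] = upbase(fwd_bases[i]);
    q1[a1 + i] = fwd_quals[i];
  }

  // rc2 = revcomp(prefix2 + rev) = revcomp(rev) + revcomp(prefix2)
  const int len2 = n2 + a2;
  std::string e2(len2, 'N');
  std::vector<int> q2(len2, 40);
  for (int i = 0; i < n2; ++i) {
    e2[i] = comp(rev_bases[n2 - 1 - i]);
    q2[i] = rev_quals[n2 - 1 - i];
  }
  for (int i = 0; i < a2; ++i) e2[n2 + i] = comp(prefix2[a2 - 1 - i]);

  double best = R_NegInf;
  int best_l = -1;
  const int lmax = std::min(n1, n2) - 1;
  for (int L = 1; L <= lmax; ++L) {
    // column i of ext1 aligns with column i + d of rc2
    const int d = (n2 - L) - a1;
    const int i0 = std::max(0, -d);
    const int i1 = std::min(len1, len2 - d);
    const int ov = i1 - i0;
    if (ov < 1 || ov * LOG10_4 < threshold) continue;
    int seed = std::min(16, ov);
    int mism = 0;
    for (int i = i0; i < i0 + seed; ++i)
      if (!base_match(e1[i], e2[i + d]) && ++mism > seed_mismatches) break;
    if (mism > seed_mismatches) continue;
    double score = 0.0;
    for (int i = i0; i < i1; ++i) {
      if (base_match(e1[i], e2[i + d])) score += LOG10_4;
      else score -= std::min(q1[i], q2[i + d]) / 10.0;
    }
    if (score >= threshold && score > best) { best = score; best_l = L; }
  }
  return best_l;
}

// ---- GZIP member compression ----------------------------------------------

// Compress a buffer into one complete RFC 1952 GZIP member (fresh
// dictionary), so that concatenated members form a valid multi-member
// stream readable by any standard decompressor.
// [[Rcpp::export(name = ".gzip_compress_member")]]
RawVector gzip_compress_member(RawVector data, int level = 6) {
  z_stream strm;
  std::memset(&strm, 0, sizeof(strm));
  // windowBits 15 + 16 selects the GZIP wrapper
  if (deflateInit2(&strm, level, Z_DEFLATED, 15 + 16, 8,
                   Z_DEFAULT_STRATEGY) != Z_OK)
    stop("deflateInit2 failed");
  uLong bound = deflateBound(&strm, data.size());
  std::vector<unsigned char> out(bound + 32);
  strm.next_in = data.size() ? reinterpret_cast<Bytef*>(RAW(data)) : Z_NULL;
  strm.avail_in = data.size();
  strm.next_out = out.data();
  strm.avail_out = out.size();
  int ret = deflate(&strm, Z_FINISH);
  if (ret != Z_STREAM_END) {
    deflateEnd(&strm);
    stop("deflate failed (code %d)", ret);
  }
  size_t produced = out.size() - strm.avail_out;
  deflateEnd(&strm);
  RawVector res(produced);
  std::memcpy(RAW(res), out.data(), produced);
  return res;
}
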