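#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// ---------------------------------------------------------------------------
// banded global identity
// scoring: match +1, mismatch -1, internal gap -2 per base, terminal gap -1
// per base.  identity = matches / aligned columns, where columns lying in a
// terminal overhang (before both sequences have started, or after one has
// ended) are excluded.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_banded_identity(std::string a, std::string b, double band_frac) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int minlen = std::min(n, m);
  int W = (int)std::ceil(band_frac * minlen) + std::abs(n - m);
  if (W < 1) W = 1;

  // dp over (n+1) x (2W+1) band centred on j = i
  const int bw = 2 * W + 1;
  std::vector<double> dp((size_t)(n + 1) * bw, NEG_INF);
  std::vector<signed char> mv((size_t)(n + 1) * bw, 0); // 1=diag 2=up 3=left 0=origin
  auto idx = [&](int i, int j) { return (size_t)i * bw + (j - i + W); };
  auto inband = [&](int i, int j) { return j >= 0 && j <= m && std::abs(j - i) <= W; };

  dp[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m && j <= W; ++j) { dp[idx(0, j)] = -1.0 * j; mv[idx(0, j)] = 3; }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i - W), jhi = std::min(m, i + W);
    for (int j = jlo; j <= jhi; ++j) {
      double best = NEG_INF; signed char how = 0;
      if (i > 0 && j == 0) { best = -1.0 * i; how = 2; } // leading terminal gap in b
      if (i > 0 && j > 0 && inband(i - 1, j - 1)) {
        double s = dp[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 1.0 : -1.0);
        if (s > best) { best = s; how = 1; }
      }
      if (i > 0 && inband(i - 1, j)) { // gap in b (consume a)
        double g = (j == m) ? -1.0 : -2.0; // trailing terminal vs internal
        double s = dp[idx(i - 1, j)] + g;
        if (s > best) { best = s; how = 2; }
      }
      if (j > 0 && inband(i, j - 1)) { // gap in a (consume b)
        double g = (i == n || i == 0) ? -1.0 : -2.0;
        double s = dp[idx(i, j - 1)] + g;
        if (s > best) { best = s; how = 3; }
      }
      if (how != 0 || (i == 0 && j == 0)) { dp[idx(i, j)] = best; mv[idx(i, j)] = how; }
    }
  }
  if (dp[idx(n, m)] <= NEG_INF / 2) stop("band too narrow for these sequences");

  // traceback, counting matches and aligned (non-terminal) columns
  int i = n, j = m;
  long matches = 0, cols = 0;
  // trailing overhang: moves while i==n (left) or j==m (up) at the very end
  bool in_tail = true;
  while (i > 0 || j > 0) {
    signed char how = mv[idx(i, j)];
    if (how == 1) {
      in_tail = false;
      if (a[i - 1] == b[j - 1]) ++matches;
      ++cols; --i; --j;
    } else if (how == 2) {
      bool terminal = (j == m && in_tail) || j == 0;
      if (!terminal) ++cols;
      --i;
    } else if (how == 3) {
      bool terminal = (i == n && in_tail) || i == 0;
      if (!terminal) ++cols;
      --j;
    } else {
      break;
    }
  }
  if (cols == 0) return 0.0;
  return (double)matches / (double)cols;
}

// ---------------------------------------------------------------------------
// sequence utilities
// ---------------------------------------------------------------------------

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = revcomp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}

// Hamming distance of `pattern` against every window of `seq`.
// [[Rcpp::export]]
IntegerVector cpp_hamming_windows(std::string seq, std::string pattern) {
  const int n = seq.size(), k = pattern.size();
  if (k > n) return IntegerVector(0);
  IntegerVector out(n - k + 1);
  for (int s = 0; s <= n - k; ++s) {
    int mm = 0;
    for (int j = 0; j < k; ++j) if (seq[s + j] != pattern[j]) ++mm;
    out[s] = mm;
  }
  return out;
}

// substitute single bases in place: seqs[read_idx][pos] <- base (1-based idx)
// [[Rcpp::export]]
CharacterVector cpp_mutate_bases(CharacterVector seqs, IntegerVector read_idx,
                                 IntegerVector pos, CharacterVector base) {
  std::vector<std::string> s(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) s[i] = as<std::string>(seqs[i]);
  for (R_xlen_t i = 0; i < read_idx.size(); ++i) {
    int r = read_idx[i] - 1, p = pos[i] - 1;
    if (r < 0 || r >= (int)s.size() || p < 0 || p >= (int)s[r].size())
      stop("mutation index out of range");
    s[r][p] = as<std::string>(base[i])[0];
  }
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) out[i] = s[i];
  return out;
}

// ---------------------------------------------------------------------------
// seed-and-extend gapless paired mapper
// ---------------------------------------------------------------------------

static inline int base2bit(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map; // kmer -> (cand,pos)
};

static void index_candidates(const std::vector<std::string> &cands, int k, SeedIndex &ix) {
  ix.k = k;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int c = 0; c < (int)cands.size(); ++c) {
    const std::string &s = cands[c];
    if ((int)s.size() < k) continue;
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) ix.map[h].push_back({c, i - k + 1});
    }
  }
}

// per-base error prob from phred+33 char, capped
static inline double eps_of(char q, double cap) {
  double e = std::pow(10.0, -((double)q - 33.0) / 10.0);
  return std::min(e, cap);
}

// gapless verification of `read` (already oriented) at candidate position s.
// returns mismatches, or -1 if out of bounds / above cap; fills loglik.
static int verify(const std::string &cand, const std::string &read,
                  const std::string &qual, bool qual_reversed, int s,
                  int max_mm, double eps_cap, double &loglik) {
  const int L = read.size();
  if (s < 0 || s + L > (int)cand.size()) return -1;
  int mm = 0; double ll = 0.0;
  for (int j = 0; j < L; ++j) {
    char q = qual_reversed ? qual[L - 1 - j] : qual[j];
    double e = eps_of(q, eps_cap);
    if (read[j] == cand[s + j]) ll += std::log1p(-e);
    else { if (++mm > max_mm) return -1; ll += std::log(e / 3.0); }
  }
  loglik = ll;
  return mm;
}

static void seed_starts(const SeedIndex &ix, const std::string &read,
                        std::unordered_map<int, std::vector<int>> &out) {
  const int k = ix.k, L = read.size();
  if (L < k) return;
  int offs[3] = {0, (L - k) / 2, L - k};
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int oi = 0; oi < 3; ++oi) {
    int o = offs[oi];
    if (oi > 0 && o == offs[oi - 1]) continue;
    uint64_t h = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bit(read[o + j]);
      if (b < 0) { ok = false; break; }
      h = (h << 2) | (uint64_t)b;
    }
    if (!ok) continue;
    h &= mask;
    auto it = ix.map.find(h);
    if (it == ix.map.end()) continue;
    for (auto &cp : it->second) {
      int start = cp.second - o;
      auto &v = out[cp.first];
      if (std::find(v.begin(), v.end(), start) == v.end()) v.push_back(start);
    }
  }
}

// Map read pairs against candidate sequences.  For each candidate keep the
// single best placement (highest pair log-likelihood; ties -> leftmost
// forward start, then leftmost reverse start, then orientation with mate 1
// forward).  Gapless, both mates required, insert within [insert_min,
// insert_max].  rc_mate reports which mate aligned as reverse complement.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector cand_seqs, CharacterVector r1, CharacterVector r2,
                        CharacterVector q1, CharacterVector q2, double max_mm_rate,
                        int insert_min, int insert_max, int seed_len, double eps_cap) {
  const int nc = cand_seqs.size(), np = r1.size();
  std::vector<std::string> cands(nc);
  for (int c = 0; c < nc; ++c) cands[c] = as<std::string>(cand_seqs[c]);
  SeedIndex ix; index_candidates(cands, seed_len, ix);

  std::vector<int> o_pair, o_cand, o_s1, o_s2, o_rc, o_mm, o_ins;
  std::vector<double> o_ll;

  for (int p = 0; p < np; ++p) {
    std::string m1 = as<std::string>(r1[p]), m2 = as<std::string>(r2[p]);
    std::string u1 = as<std::string>(q1[p]), u2 = as<std::string>(q2[p]);
    std::string m1r = revcomp(m1), m2r = revcomp(m2);

    // best hit per candidate across both orientations
    std::unordered_map<int, std::tuple<double,int,int,int,int,int>> best; // ll,s1,s2,rc,mm,ins

    for (int ori = 0; ori < 2; ++ori) {
      // ori 0: mate1 forward, mate2 reverse-complemented
      const std::string &F  = (ori == 0) ? m1  : m2;
      const std::string &Fq = (ori == 0) ? u1  : u2;
      const std::string &R  = (ori == 0) ? m2r : m1r;
      const std::string &Rq = (ori == 0) ? u2  : u1;
      const int rc_mate = (ori == 0) ? 2 : 1;
      const int maxmmF = (int)std::floor(max_mm_rate * F.size());
      const int maxmmR = (int)std::floor(max_mm_rate * R.size());

      std::unordered_map<int, std::vector<int>> hf, hr;
      seed_starts(ix, F, hf);
      seed_starts(ix, R, hr);
      for (auto &cf : hf) {
        auto itr = hr.find(cf.first);
        if (itr == hr.end()) continue;
        std::sort(cf.second.begin(), cf.second.end());
        std::sort(itr->second.begin(), itr->second.end());
        for (int sf : cf.second) {
          double llF;
          int mmF = verify(cands[cf.first], F, Fq, false, sf, maxmmF, eps_cap, llF);
          if (mmF < 0) continue;
          for (int sr : itr->second) {
            if (sr < sf) continue;
            int ins = sr + (int)R.size() - sf;
            if (ins < insert_min || ins > insert_max) continue;
            double llR;
            int mmR = verify(cands[cf.first], R, Rq, true, sr, maxmmR, eps_cap, llR);
            if (mmR < 0) continue;
            double ll = llF + llR;
            auto itb = best.find(cf.first);
            if (itb == best.end() || ll > std::get<0>(itb->second) + 1e-12) {
              best[cf.first] = std::make_tuple(ll, sf, sr, rc_mate, mmF + mmR, ins);
            }
          }
        }
      }
    }
    for (auto &kb : best) {
      o_pair.push_back(p + 1); o_cand.push_back(kb.first + 1);
      o_ll.push_back(std::get<0>(kb.second));
      o_s1.push_back(std::get<1>(kb.second)); o_s2.push_back(std::get<2>(kb.second));
      o_rc.push_back(std::get<3>(kb.second)); o_mm.push_back(std::get<4>(kb.second));
      o_ins.push_back(std::get<5>(kb.second));
    }
  }
  return DataFrame::create(_["pair"] = o_pair, _["cand"] = o_cand,
                           _["start_fwd"] = o_s1, _["start_rc"] = o_s2,
                           _["rc_mate"] = o_rc, _["mismatches"] = o_mm,
                           _["insert"] = o_ins, _["loglik"] = o_ll,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// posterior-weighted base counts for one candidate
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_base_weights(int cand_len, CharacterVector r1, CharacterVector r2,
                               CharacterVector q1, CharacterVector q2,
                               IntegerVector pair, IntegerVector start_fwd,
                               IntegerVector start_rc, IntegerVector rc_mate,
                               NumericVector post, double eps_cap) {
  NumericMatrix W(4, cand_len);
  const int nh = pair.size();
  for (int h = 0; h < nh; ++h) {
    int p = pair[h] - 1;
    double w = post[h];
    if (w <= 0) continue;
    std::string F  = (rc_mate[h] == 2) ? as<std::string>(r1[p]) : as<std::string>(r2[p]);
    std::string Fq = (rc_mate[h] == 2) ? as<std::string>(q1[p]) : as<std::string>(q2[p]);
    std::string R  = (rc_mate[h] == 2) ? revcomp(as<std::string>(r2[p]))
                                       : revcomp(as<std::string>(r1[p]));
    std::string Rq = (rc_mate[h] == 2) ? as<std::string>(q2[p]) : as<std::string>(q1[p]);
    int sf = start_fwd[h], sr = start_rc[h];
    for (int j = 0; j < (int)F.size(); ++j) {
      int b = base2bit(F[j]);
      int pos = sf + j;
      if (b < 0 || pos < 0 || pos >= cand_len) continue;
      W(b, pos) += w * (1.0 - eps_of(Fq[j], eps_cap));
    }
    int LR = R.size();
    for (int j = 0; j < LR; ++j) {
      int b = base2bit(R[j]);
      int pos = sr + j;
      if (b < 0 || pos < 0 || pos >= cand_len) continue;
      W(b, pos) += w * (1.0 - eps_of(Rq[LR - 1 - j], eps_cap));
    }
  }
  return W;
}
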