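#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit base encoding; anything non-ACGT breaks a k-mer run
static inline int b2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char revcomp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = revcomp_base(r[i]);
  return r;
}

// k-mer -> list of (target << 32 | pos)
typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerIndex;

static void index_targets(const std::vector<std::string> &tgt, int k, KmerIndex &idx) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t t = 0; t < tgt.size(); ++t) {
    const std::string &s = tgt[t];
    if ((int)s.size() < k) continue;
    uint64_t key = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = b2(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k)
        idx[key].push_back(((uint64_t)t << 32) | (uint64_t)(i + 1 - k));
    }
  }
}

// mismatches of read placed at offset `off` on target, early abort beyond `limit`
static int count_mm(const std::string &read, const std::string &tgt, long off, int limit) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    if (read[i] != tgt[off + i] && ++mm > limit) return mm;
  }
  return mm;
}

// Seed-and-extend ungapped alignment of short reads against a small target set.
// status: 0 = unaligned, 1 = aligned (unique best), 2 = multimapped (tied best)
// [[Rcpp::export(name = ".align_reads_cpp")]]
List align_reads_cpp(CharacterVector reads, CharacterVector targets,
                     int k, int max_mismatch, bool both_strands) {
  std::vector<std::string> tgt(targets.size());
  for (int i = 0; i < targets.size(); ++i) tgt[i] = as<std::string>(targets[i]);
  KmerIndex idx;
  index_targets(tgt, k, idx);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  int n = reads.size();
  IntegerVector out_target(n, NA_INTEGER), out_start(n, NA_INTEGER),
      out_mm(n, NA_INTEGER), out_status(n, 0);
  CharacterVector out_strand(n, NA_STRING);

  std::unordered_set<uint64_t> seen;
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int rl = (int)fwd.size();
    if (rl < k) continue;
    int best_mm = max_mismatch + 1;
    long best_t = -1, best_off = -1;
    int best_strand = 0; // 0 = "+", 1 = "-"
    int n_best = 0;
    seen.clear();

    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string read = (strand == 0) ? fwd : revcomp(fwd);
      // seed offsets: every k bases plus the final window
      std::vector<int> seeds;
      for (int s = 0; s + k <= rl; s += k) seeds.push_back(s);
      if (rl - k > 0 && (seeds.empty() || seeds.back() != rl - k))
        seeds.push_back(rl - k);
      for (size_t si = 0; si < seeds.size(); ++si) {
        int s = seeds[si];
        uint64_t key = 0;
        bool ok = true;
        for (int i = 0; i < k; ++i) {
          int b = b2(read[s + i]);
          if (b < 0) { ok = false; break; }
          key = ((key << 2) | (uint64_t)b) & mask;
        }
        if (!ok) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        const std::vector<uint64_t> &occ = it->second;
        for (size_t oi = 0; oi < occ.size(); ++oi) {
          long t = (long)(occ[oi] >> 32);
          long pos = (long)(occ[oi] & 0xFFFFFFFFULL);
          long off = pos - s;
          if (off < 0 || off + rl > (long)tgt[t].size()) continue;
          uint64_t enc = ((uint64_t)t << 33) | ((uint64_t)off << 1) | (uint64_t)strand;
          if (!seen.insert(enc).second) continue; // candidate already evaluated
          int mm = count_mm(read, tgt[t], off, std::min(max_mismatch, best_mm));
          if (mm > max_mismatch || mm > best_mm) continue;
          if (mm < best_mm) {
            best_mm = mm; best_t = t; best_off = off; best_strand = strand;
            n_best = 1;
          } else {
            ++n_best;
          }
        }
      }
    }
    if (n_best == 1) {
      out_target[r] = (int)best_t + 1;
      out_start[r] = (int)best_off;
      out_strand[r] = (best_strand == 0) ? "+" : "-";
      out_mm[r] = best_mm;
      out_status[r] = 1;
    } else if (n_best > 1) {
      out_status[r] = 2;
    }
  }
  return List::create(_["target"] = out_target, _["start"] = out_start,
                      _["strand"] = out_strand, _["mismatches"] = out_mm,
                      _["status"] = out_status);
}

// Shared-k-mer matched bases per (query, target) pair on the best single
// diagonal (ungapped chain): union length of k-mer match intervals.
// [[Rcpp::export(name = ".kmer_matched_bases_cpp")]]
DataFrame kmer_matched_bases_cpp(CharacterVector queries, CharacterVector targets, int k) {
  std::vector<std::string> tgt(targets.size());
  for (int i = 0; i < targets.size(); ++i) tgt[i] = as<std::string>(targets[i]);
  KmerIndex idx;
  index_targets(tgt, k, idx);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::vector<int> out_q, out_t, out_m;
  for (int q = 0; q < queries.size(); ++q) {
    std::string qs = as<std::string>(queries[q]);
    int ql = (int)qs.size();
    if (ql < k) continue;
    // (target << 32 | diag + ql) -> query positions of matching k-mers
    std::unordered_map<uint64_t, std::vector<int> > diag_hits;
    uint64_t key = 0;
    int run = 0;
    for (int i = 0; i < ql; ++i) {
      int b = b2(qs[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      int qpos = i + 1 - k;
      KmerIndex::const_iterator it = idx.find(key);
      if (it == idx.end()) continue;
      const std::vector<uint64_t> &occ = it->second;
      for (size_t oi = 0; oi < occ.size(); ++oi) {
        long t = (long)(occ[oi] >> 32);
        long pos = (long)(occ[oi] & 0xFFFFFFFFULL);
        uint64_t dkey = ((uint64_t)t << 32) | (uint64_t)(uint32_t)(pos - qpos + ql);
        diag_hits[dkey].push_back(qpos);
      }
    }
    // best diagonal per target by covered bases
    std::unordered_map<long, int> best;
    for (std::unordered_map<uint64_t, std::vector<int> >::iterator it = diag_hits.begin();
         it != diag_hits.end(); ++it) {
      long t = (long)(it->first >> 32);
      std::vector<int> &pos = it->second;
      std::sort(pos.begin(), pos.end());
      int covered = 0;
      long cur_start = -1, cur_end = -1;
      for (size_t i = 0; i < pos.size(); ++i) {
        long a = pos[i], b = pos[i] + k;
        if (a > cur_end) {
          covered += (int)(cur_end - cur_start);
          cur_start = a; cur_end = b;
        } else if (b > cur_end) {
          cur_end = b;
        }
      }
      covered += (int)(cur_end - cur_start);
      std::unordered_map<long, int>::iterator bi = best.find(t);
      if (bi == best.end() || covered > bi->second) best[t] = covered;
    }
    for (std::unordered_map<long, int>::iterator it = best.begin(); it != best.end(); ++it) {
      out_q.push_back(q + 1);
      out_t.push_back((int)it->first + 1);
      out_m.push_back(it->second);
    }
  }
  return DataFrame::create(_["query"] = out_q, _["target"] = out_t,
                           _["matched"] = out_m);
}
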