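// Short-read alignment core: seed-and-extend mapper, exhaustive DP oracle,
// and reference pileup.  Scoring is local (Smith-Waterman) with linear gap
// costs; read ends are free (soft clips).  An alignment is acceptable iff
//   n_match / columns            >= similarity_fraction   and
//   (n_match+n_mismatch+n_ins) / read_length >= length_fraction.
// Among acceptable placements the maximal score wins; ties are broken by
// (ref_start asc, strand '+' first, ref_end asc, read_start asc, cigar).
// The same comparator and traceback preference (diagonal > deletion >
// insertion) are used by the seeded mapper and the exhaustive oracle so the
// two can be compared cell-for-cell in tests.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct MapParams {
  double sim_frac;
  double len_frac;
  double match_reward;
  double mismatch_cost;
  double ins_cost;
  double del_cost;
  int    seed_kmer;
  bool   random_policy;
  uint64_t rng_seed;
};

struct Aln {
  bool mapped = false;
  int  strand = 0;            // 0 = '+', 1 = '-'
  long ref_start = 0, ref_end = 0;
  int  read_start = 0, read_end = 0;
  int  n_match = 0, n_mismatch = 0, n_ins = 0, n_del = 0;
  double score = 0.0;
  std::string cigar;
};

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

inline bool base_match(char a, char b) {
  // N never matches anything (conservative mismatch rule)
  return a == b && a != 'N';
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return r;
}

int columns(const Aln& a) {
  return a.n_match + a.n_mismatch + a.n_ins + a.n_del;
}

bool acceptable(const Aln& a, const MapParams& P, int read_len) {
  int cols = columns(a);
  if (cols == 0) return false;
  double sim = (double)a.n_match / (double)cols;
  double lfrac = (double)(a.n_match + a.n_mismatch + a.n_ins) / (double)read_len;
  return sim >= P.sim_frac && lfrac >= P.len_frac;
}

// total order: best first
bool aln_before(const Aln& a, const Aln& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.ref_start != b.ref_start) return a.ref_start < b.ref_start;
  if (a.strand != b.strand) return a.strand < b.strand;
  if (a.ref_end != b.ref_end) return a.ref_end < b.ref_end;
  if (a.read_start != b.read_start) return a.read_start < b.read_start;
  if (a.read_end != b.read_end) return a.read_end < b.read_end;
  return a.cigar < b.cigar;
}

bool aln_same_placement(const Aln& a, const Aln& b) {
  return a.strand == b.strand && a.ref_start == b.ref_start &&
         a.ref_end == b.ref_end && a.read_start == b.read_start &&
         a.read_end == b.read_end && a.cigar == b.cigar;
}

void push_cigar(std::string& cig, long n, char op) {
  if (n > 0) { cig += std::to_string(n); cig += op; }
}

// Smith-Waterman over genome region [lo, hi); collects every acceptable
// candidate alignment at the highest score level at which any candidate in
// this region is acceptable.  Candidates are derived by preference-ordered
// traceback from each end cell, scanned in descending score order.
void region_candidates(const std::string& q, const std::string& g,
                       long lo, long hi, const MapParams& P, int strand,
                       std::vector<Aln>& out) {
  const int n = (int)q.size();
  const long m = hi - lo;
  if (m <= 0 || n == 0) return;

  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  auto at = [&](int i, long j) -> double& { return H[(size_t)i * (m + 1) + j]; };

  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    for (long j = 1; j <= m; ++j) {
      const char gc = g[lo + j - 1];
      double diag = at(i - 1, j - 1) +
        (base_match(qc, gc) ? P.match_reward : -P.mismatch_cost);
      double del = at(i, j - 1) - P.del_cost;   // gap in read, consumes ref
      double ins = at(i - 1, j) - P.ins_cost;   // gap in ref, consumes read
      double best = diag;
      if (del > best) best = del;
      if (ins > best) best = ins;
      if (best < 0.0) best = 0.0;
      at(i, j) = best;
    }
  }

  // conservative lower bound on the score of any acceptable alignment
  double maxc = std::max(P.mismatch_cost, std::max(P.ins_cost, P.del_cost));
  double prune = std::max(1e-9,
    P.len_frac * n * (P.sim_frac * (P.match_reward + maxc) - maxc));

  struct Cell { double h; int i; long j; };
  std::vector<Cell> cells;
  for (int i = 1; i <= n; ++i)
    for (long j = 1; j <= m; ++j)
      if (at(i, j) >= prune) cells.push_back({at(i, j), i, j});
  std::sort(cells.begin(), cells.end(), [](const Cell& a, const Cell& b) {
    if (a.h != b.h) return a.h > b.h;
    if (a.j != b.j) return a.j < b.j;
    return a.i < b.i;
  });

  double level = -1.0;
  for (const Cell& c : cells) {
    if (level >= 0.0 && c.h < level) break;
    // traceback with fixed preference: diagonal > deletion > insertion
    int i = c.i; long j = c.j;
    std::vector<std::pair<long, char>> ops;  // reversed
    while (i > 0 && j > 0 && at(i, j) > 0.0) {
      double h = at(i, j);
      double sub = base_match(q[i - 1], g[lo + j - 1]) ? P.match_reward
                                                       : -P.mismatch_cost;
      if (at(i - 1, j - 1) + sub == h) {
        ops.push_back({1, base_match(q[i - 1], g[lo + j - 1]) ? '=' : 'X'});
        --i; --j;
      } else if (at(i, j - 1) - P.del_cost == h) {
        ops.push_back({1, 'D'}); --j;
      } else if (at(i - 1, j) - P.ins_cost == h) {
        ops.push_back({1, 'I'}); --i;
      } else {
        break;  // unreachable for a consistent matrix
      }
    }
    Aln a;
    a.mapped = true;
    a.strand = strand;
    a.read_start = i;
    a.read_end = c.i;
    a.ref_start = lo + j;
    a.ref_end = lo + c.j;
    a.score = c.h;
    std::string cig;
    push_cigar(cig, a.read_start, 'S');
    // run-length encode (merge = and X into M for the CIGAR)
    long run = 0; char cur = 0;
    for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
      char op = it->second;
      if (op == '=') a.n_match++;
      else if (op == 'X') a.n_mismatch++;
      else if (op == 'I') a.n_ins++;
      else if (op == 'D') a.n_del++;
      char emit = (op == '=' || op == 'X') ? 'M' : op;
      if (emit == cur) run++;
      else { push_cigar(cig, run, cur ? cur : 'M'); cur = emit; run = 1; }
    }
    push_cigar(cig, run, cur ? cur : 'M');
    push_cigar(cig, (long)n - a.read_end, 'S');
    a.cigar = cig;
    if (acceptable(a, P, n)) {
      if (level < 0.0) level = c.h;
      if (c.h == level) out.push_back(a);
    }
  }
}

// ---- k-mer index ----------------------------------------------------------

struct KIndex {
  int k = 0;
  std::unordered_map<uint64_t, std::vector<long>> pos;
};

inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}

void build_index(const std::string& g, int k, KIndex& idx) {
  idx.k = k;
  idx.pos.clear();
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0; int have = 0;
  for (long p = 0; p < (long)g.size(); ++p) {
    int b = base_code(g[p]);
    if (b < 0) { have = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++have >= k) idx.pos[key].push_back(p - k + 1);
  }
}

void seed_diagonals(const std::string& q, const KIndex& idx,
                    std::vector<long>& diags) {
  const int k = idx.k;
  const int L = (int)q.size();
  if (L < k) return;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0; int have = 0;
  for (int o = 0; o < L; ++o) {
    int b = base_code(q[o]);
    if (b < 0) { have = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (have + 1 >= k) {
      auto it = idx.pos.find(key);
      if (it != idx.pos.end())
        for (long p : it->second) diags.push_back(p - (o - k + 1));
    }
    ++have;
  }
}

// cluster sorted diagonals (gap <= 32) into windows; keep clusters with at
// least min_hits seed hits
void diag_windows(std::vector<long>& diags, long G, int read_len, int min_hits,
                  std::vector<std::pair<long, long>>& wins) {
  if (diags.empty()) return;
  std::sort(diags.begin(), diags.end());
  const long pad = read_len / 2 + 16;
  size_t s = 0;
  for (size_t i = 1; i <= diags.size(); ++i) {
    if (i == diags.size() || diags[i] - diags[i - 1] > 32) {
      if ((int)(i - s) >= min_hits) {
        long lo = std::max(0L, diags[s] - pad);
        long hi = std::min(G, diags[i - 1] + (long)read_len + pad);
        if (hi > lo) wins.push_back({lo, hi});
      }
      s = i;
    }
  }
  // merge overlapping windows
  std::sort(wins.begin(), wins.end());
  std::vector<std::pair<long, long>> merged;
  for (auto& w : wins) {
    if (!merged.empty() && w.first <= merged.back().second)
      merged.back().second = std::max(merged.back().second, w.second);
    else
      merged.push_back(w);
  }
  wins.swap(merged);
}

// collapse candidate pool to distinct placements at the maximal score
void finalize_pool(std::vector<Aln>& pool) {
  if (pool.empty()) return;
  double best = pool[0].score;
  for (const Aln& a : pool) best = std::max(best, a.score);
  std::vector<Aln> keep;
  for (const Aln& a : pool) if (a.score == best) keep.push_back(a);
  std::sort(keep.begin(), keep.end(), aln_before);
  std::vector<Aln> uniq;
  for (const Aln& a : keep)
    if (uniq.empty() || !aln_same_placement(uniq.back(), a)) uniq.push_back(a);
  pool.swap(uniq);
}

MapParams params_from_list(List p) {
  MapParams P;
  P.sim_frac      = as<double>(p["similarity_fraction"]);
  P.len_frac      = as<double>(p["length_fraction"]);
  P.match_reward  = as<double>(p["match_reward"]);
  P.mismatch_cost = as<double>(p["mismatch_cost"]);
  P.ins_cost      = as<double>(p["insertion_cost"]);
  P.del_cost      = as<double>(p["deletion_cost"]);
  P.seed_kmer     = as<int>(p["seed_kmer"]);
  std::string pol = as<std::string>(p["ambiguous_policy"]);
  P.random_policy = (pol == "random");
  P.rng_seed      = (uint64_t)as<double>(p["rng_seed"]);
  return P;
}

// seed-and-extend mapping of one oriented read pair (q, qrc) with layered
// re-seeding: primary k, then k-6 (needing 2 clustered hits on large
// genomes), then k=7 on small genomes.  Deterministic.
void map_one(const std::string& q, const std::string& qrc,
             const std::string& g,
             std::unordered_map<int, KIndex>& cache,
             const MapParams& P, std::vector<Aln>& pool) {
  const long G = (long)g.size();
  const int L = (int)q.size();
  struct Tier { int k; int min_hits; };
  std::vector<Tier> tiers;
  tiers.push_back({P.seed_kmer, 1});
  int k2 = std::max(7, P.seed_kmer - 6);
  if (k2 < P.seed_kmer)
    tiers.push_back({k2, G <= 16384 ? 1 : 2});
  if (G <= 16384 && k2 > 7) tiers.push_back({7, 1});

  for (const Tier& t : tiers) {
    if (t.k > L) continue;
    auto ins = cache.find(t.k);
    if (ins == cache.end()) {
      build_index(g, t.k, cache[t.k]);
      ins = cache.find(t.k);
    }
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& qq = strand == 0 ? q : qrc;
      std::vector<long> diags;
      seed_diagonals(qq, ins->second, diags);
      std::vector<std::pair<long, long>> wins;
      diag_windows(diags, G, L, t.min_hits, wins);
      for (auto& w : wins)
        region_candidates(qq, g, w.first, w.second, P, strand, pool);
    }
    finalize_pool(pool);
    if (!pool.empty()) return;
  }
}

DataFrame alns_to_df(const std::vector<Aln>& res,
                     const std::vector<int>& nbest,
                     const CharacterVector& ids, int read_len_known,
                     const std::vector<int>& read_lens) {
  int n = (int)res.size();
  LogicalVector mapped(n);
  CharacterVector strand(n), cigar(n);
  NumericVector ref_start(n), ref_end(n), score(n), similarity(n), alnfrac(n);
  IntegerVector read_start(n), read_end(n), n_match(n), n_mismatch(n),
      n_ins(n), n_del(n), n_best(n);
  for (int i = 0; i < n; ++i) {
    const Aln& a = res[i];
    mapped[i] = a.mapped;
    if (a.mapped) {
      strand[i] = a.strand == 0 ? "+" : "-";
      cigar[i] = a.cigar;
      ref_start[i] = (double)a.ref_start;
      ref_end[i] = (double)a.ref_end;
      score[i] = a.score;
      int cols = columns(a);
      similarity[i] = (double)a.n_match / cols;
      alnfrac[i] = (double)(a.n_match + a.n_mismatch + a.n_ins) / read_lens[i];
      read_start[i] = a.read_start; read_end[i] = a.read_end;
      n_match[i] = a.n_match; n_mismatch[i] = a.n_mismatch;
      n_ins[i] = a.n_ins; n_del[i] = a.n_del;
      n_best[i] = nbest[i];
    } else {
      strand[i] = NA_STRING; cigar[i] = NA_STRING;
      ref_start[i] = NA_REAL; ref_end[i] = NA_REAL; score[i] = NA_REAL;
      similarity[i] = NA_REAL; alnfrac[i] = NA_REAL;
      read_start[i] = NA_INTEGER; read_end[i] = NA_INTEGER;
      n_match[i] = NA_INTEGER; n_mismatch[i] = NA_INTEGER;
      n_ins[i] = NA_INTEGER; n_del[i] = NA_INTEGER; n_best[i] = NA_INTEGER;
    }
  }
  return DataFrame::create(
      _["read_id"] = ids, _["mapped"] = mapped, _["strand"] = strand,
      _["ref_start"] = ref_start, _["ref_end"] = ref_end,
      _["read_start"] = read_start, _["read_end"] = read_end,
      _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
      _["n_ins"] = n_ins, _["n_del"] = n_del, _["score"] = score,
      _["similarity"] = similarity, _["aligned_read_fraction"] = alnfrac,
      _["cigar"] = cigar, _["n_best"] = n_best,
      _["stringsAsFactors"] = false);
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector read_ids,
                        std::string genome, List params) {
  MapParams P = params_from_list(params);
  std::unordered_map<int, KIndex> cache;
  int n = reads.size();
  std::vector<Aln> res(n);
  std::vector<int> nbest(n, 0);
  std::vector<int> read_lens(n, 0);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(reads[i]);
    read_lens[i] = (int)q.size();
    if ((int)q.size() < P.seed_kmer)
      stop("read '%s' is shorter than seed_kmer (%d)",
           as<std::string>(read_ids[i]).c_str(), P.seed_kmer);
    std::string qrc = revcomp(q);
    std::vector<Aln> pool;
    map_one(q, qrc, genome, cache, P, pool);
    if (!pool.empty()) {
      size_t pick = 0;
      if (P.random_policy && pool.size() > 1) {
        uint64_t z = splitmix64(P.rng_seed ^ splitmix64((uint64_t)(i + 1)));
        pick = (size_t)(z % pool.size());
      }
      res[i] = pool[pick];
      nbest[i] = (int)pool.size();
    }
  }
  return alns_to_df(res, nbest, read_ids, 0, read_lens);
}

// [[Rcpp::export]]
DataFrame cpp_oracle_map(CharacterVector reads, CharacterVector read_ids,
                         std::string genome, List params) {
  if (genome.size() > 10000)
    stop("oracle_map refuses genomes longer than 10 kb (got %d bp)",
         (int)genome.size());
  MapParams P = params_from_list(params);
  int n = reads.size();
  std::vector<Aln> res(n);
  std::vector<int> nbest(n, 0);
  std::vector<int> read_lens(n, 0);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(reads[i]);
    read_lens[i] = (int)q.size();
    std::string qrc = revcomp(q);
    std::vector<Aln> pool;
    region_candidates(q, genome, 0, (long)genome.size(), P, 0, pool);
    region_candidates(qrc, genome, 0, (long)genome.size(), P, 1, pool);
    finalize_pool(pool);
    if (!pool.empty()) {
      size_t pick = 0;
      if (P.random_policy && pool.size() > 1) {
        uint64_t z = splitmix64(P.rng_seed ^ splitmix64((uint64_t)(i + 1)));
        pick = (size_t)(z % pool.size());
      }
      res[i] = pool[pick];
      nbest[i] = (int)pool.size();
    }
  }
  return alns_to_df(res, nbest, read_ids, 0, read_lens);
}

// Reference-frame pileup: per-position read depth (M and D columns) and
// A/C/G/T base counts (M columns only).  Sequences must be given in the
// orientation in which they were aligned.
// [[Rcpp::export]]
List cpp_pileup(int genome_length, NumericVector ref_start,
                CharacterVector cigar, CharacterVector seq) {
  IntegerVector depth(genome_length);
  IntegerMatrix counts(4, genome_length);
  for (int r = 0; r < ref_start.size(); ++r) {
    long pos = (long)ref_start[r];
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    size_t qi = 0;
    long num = 0;
    for (char c : cg) {
      if (c >= '0' && c <= '9') { num = num * 10 + (c - '0'); continue; }
      switch (c) {
        case 'M': case '=': case 'X':
          for (long t = 0; t < num; ++t) {
            if (pos >= 0 && pos < genome_length) {
              depth[pos]++;
              int b = base_code(sq[qi]);
              if (b >= 0) counts(b, pos)++;
            }
            ++pos; ++qi;
          }
          break;
        case 'I': case 'S': qi += num; break;
        case 'D':
          for (long t = 0; t < num; ++t) {
            if (pos >= 0 && pos < genome_length) depth[pos]++;
            ++pos;
          }
          break;
        default:
          stop("unsupported CIGAR op '%c'", c);
      }
      num = 0;
    }
  }
  return List::create(_["depth"] = depth, _["base_counts"] = counts);
}
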