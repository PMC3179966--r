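// Seed-and-extend ungapped read mapper.
//
// Exact seed words (default 32-mers) are indexed over every genome position
// whose word is unmasked A/C/G/T only (soft-mask seeding: seeds never start
// in masked sequence, mirroring masked-database seeding in BLAST). Hits are
// extended ungapped in both directions with an X-drop stop and trimmed back
// to the maximum-scoring extent. Extension never crosses an N, so N-masked
// repeats truncate matches, while lowercase-masked sequence is extended
// through (its masked overlap is filtered downstream). All qualifying
// matches of a read are reported: multi-mapping is the signal that makes
// collapsed duplications visible as excess depth.

#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline bool is_masked(char c) { return c >= 'a' && c <= 'z'; }

struct SeedEntry {
  uint64_t key;
  uint32_t chrom;
  uint32_t pos;
};

static bool seed_less(const SeedEntry &a, const SeedEntry &b) {
  return a.key < b.key;
}

// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector read_id, CharacterVector read_seq,
                        CharacterVector chrom_name, CharacterVector chrom_seq,
                        int seed_len = 32, int stride = 16, int min_len = 301,
                        double min_identity = 93.0, int match = 1,
                        int mismatch = 2, int xdrop = 20) {
  if (seed_len < 4 || seed_len > 32) stop("seed_len must be in [4, 32]");
  const int nc = chrom_seq.size();
  std::vector<std::string> genome(nc);
  for (int i = 0; i < nc; ++i) genome[i] = as<std::string>(chrom_seq[i]);

  // Build seed index
  std::vector<SeedEntry> index;
  {
    size_t total = 0;
    for (int c = 0; c < nc; ++c) total += genome[c].size();
    index.reserve(total);
  }
  const uint64_t mask_key =
      (seed_len == 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * seed_len)) - 1);
  for (int c = 0; c < nc; ++c) {
    const std::string &g = genome[c];
    const int n = (int)g.size();
    uint64_t key = 0;
    int valid = 0;  // number of consecutive valid (unmasked ACGT) bases ending here
    for (int i = 0; i < n; ++i) {
      int b = base_code(g[i]);
      if (b == 4 || is_masked(g[i])) {
        valid = 0;
        key = 0;
        continue;
      }
      key = ((key << 2) | (uint64_t)b) & mask_key;
      if (++valid >= seed_len) {
        index.push_back({key, (uint32_t)c, (uint32_t)(i - seed_len + 1)});
      }
    }
  }
  std::sort(index.begin(), index.end(), seed_less);

  const int nr = read_seq.size();
  std::vector<int> out_read;
  std::vector<int> out_chrom;
  std::vector<int> out_start, out_end, out_mm;
  std::vector<double> out_ident;
  std::vector<char> out_strand;

  std::string rc;
  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(read_seq[r]);
    const int qlen = (int)fwd.size();
    if (qlen < seed_len) continue;
    rc.resize(qlen);
    for (int i = 0; i < qlen; ++i) {
      char c = fwd[qlen - 1 - i];
      switch (c) {
        case 'A': case 'a': rc[i] = 'T'; break;
        case 'C': case 'c': rc[i] = 'G'; break;
        case 'G': case 'g': rc[i] = 'C'; break;
        case 'T': case 't': rc[i] = 'A'; break;
        default: rc[i] = 'N';
      }
    }
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &s = strand == 0 ? fwd : rc;
      // per (chrom, diagonal) extents already examined
      std::unordered_map<int64_t, std::vector<std::pair<int, int>>> seen;
      std::vector<int> offsets;
      for (int q = 0; q + seed_len <= qlen; q += stride) offsets.push_back(q);
      if (offsets.empty() || offsets.back() != qlen - seed_len)
        offsets.push_back(qlen - seed_len);
      for (int qo : offsets) {
        uint64_t key = 0;
        bool ok = true;
        for (int i = 0; i < seed_len; ++i) {
          int b = base_code(s[qo + i]);
          if (b == 4) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        {
          SeedEntry probe{key & mask_key, 0, 0};
          auto lo = std::lower_bound(index.begin(), index.end(), probe, seed_less);
          for (auto it = lo; it != index.end() && it->key == (key & mask_key); ++it) {
            const int c = (int)it->chrom;
            const int gp = (int)it->pos;
            const std::string &g = genome[c];
            const int glen = (int)g.size();
            int64_t diag = ((int64_t)c << 34) + ((int64_t)gp - (int64_t)qo);
            bool done = false;
            auto &v = seen[diag];
            for (auto &iv : v) {
              if (gp >= iv.first && gp < iv.second) { done = true; break; }
            }
            if (done) continue;

            // extend right from end of seed
            int score = seed_len * match, best = score;
            int i = qo + seed_len, j = gp + seed_len;
            int bi = i, bj = j, mm = 0, bmm_r = 0;
            while (i < qlen && j < glen) {
              int rb = base_code(s[i]);
              int gb = base_code(g[j]);
              if (rb == 4 || gb == 4) break;
              if (rb == gb) score += match; else { score -= mismatch; ++mm; }
              ++i; ++j;
              if (score > best) { best = score; bi = i; bj = j; bmm_r = mm; }
              else if (best - score > xdrop) break;
            }
            // extend left from start of seed
            score = best;
            i = qo - 1; j = gp - 1;
            int ai = qo, aj = gp, bmm_l = 0;
            mm = 0;
            while (i >= 0 && j >= 0) {
              int rb = base_code(s[i]);
              int gb = base_code(g[j]);
              if (rb == 4 || gb == 4) break;
              if (rb == gb) score += match; else { score -= mismatch; ++mm; }
              if (score > best) { best = score; ai = i; aj = j; bmm_l = mm; }
              else if (best - score > xdrop) { break; }
              --i; --j;
            }
            const int gs = aj, ge = bj;
            const int len = ge - gs;
            const int mism = bmm_l + bmm_r;
            v.push_back(std::make_pair(gs, ge));
            if (len < min_len) continue;
            double ident = 100.0 * (len - mism) / len;
            if (ident < min_identity) continue;
            out_read.push_back(r + 1);
            out_chrom.push_back(c + 1);
            out_start.push_back(gs);
            out_end.push_back(ge);
            out_mm.push_back(mism);
            out_ident.push_back(ident);
            out_strand.push_back(strand == 0 ? '+' : '-');
          }
        }
      }
    }
  }

  const int no = (int)out_read.size();
  CharacterVector rid(no), chn(no), strd(no);
  IntegerVector len(no);
  for (int i = 0; i < no; ++i) {
    rid[i] = read_id[out_read[i] - 1];
    chn[i] = chrom_name[out_chrom[i] - 1];
    strd[i] = std::string(1, out_strand[i]);
    len[i] = out_end[i] - out_start[i];
  }
  return DataFrame::create(
      _["read_id"] = rid, _["chrom"] = chn,
      _["start"] = IntegerVector(out_start.begin(), out_start.end()),
      _["end"] = IntegerVector(out_end.begin(), out_end.end()),
      _["length"] = len,
      _["strand"] = strd,
      _["identity"] = NumericVector(out_ident.begin(), out_ident.end()),
      _["mismatches"] = IntegerVector(out_mm.begin(), out_mm.end()),
      _["stringsAsFactors"] = false);
}

// Mutate sequences by independent substitutions at `rate` (recycled over
// sequences), using R's RNG so results are reproducible under set.seed().
// Positions with non-ACGT characters are left untouched.
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, NumericVector rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const int n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const double r = rate[i % rate.size()];
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base_code(s[j]);
      if (b == 4) continue;
      if (unif_rand() < r) {
        int nb = (b + 1 + (int)(unif_rand() * 3)) % 4;
        if (nb == b) nb = (b + 1) % 4;
        s[j] = bases[nb];
      }
    }
    out[i] = s;
  }
  return out;
}
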