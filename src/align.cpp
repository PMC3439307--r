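#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// A=0 C=1 G=2 T=3, anything else (incl. N) = -1 and never scores a match.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

struct Aln {
  int score, qs, qe, ss, se, nmatch, alen;
};

// Affine-gap local alignment (Gotoh) with full traceback.
// Gap of length L costs gap_open + L * gap_extend.
static Aln sw_core(const std::string& q, const std::string& s,
                   int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)q.size(), n = (int)s.size();
  const int NEG = -1073741824;
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), Fv(n + 1, NEG);
  // traceback byte per cell: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F),
  // bit 2: E extended from E (else opened from H), bit 3: same for F.
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    int Ev = NEG;
    Hc[0] = 0;
    const int cq = base_code(q[i - 1]);
    uint8_t* tbrow = &tb[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      uint8_t t = 0;
      const int e_open = Hc[j - 1] - gap_open - gap_extend;
      const int e_ext = Ev - gap_extend;
      if (e_open >= e_ext) Ev = e_open; else { Ev = e_ext; t |= 4; }
      const int f_open = Hp[j] - gap_open - gap_extend;
      const int f_ext = Fv[j] - gap_extend;
      if (f_open >= f_ext) Fv[j] = f_open; else { Fv[j] = f_ext; t |= 8; }
      const int cs = base_code(s[j - 1]);
      const int diag = Hp[j - 1] + ((cq >= 0 && cq == cs) ? match : mismatch);
      int h = 0;
      uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (Ev > h) { h = Ev; src = 2; }
      if (Fv[j] > h) { h = Fv[j]; src = 3; }
      t |= src;
      tbrow[j] = t;
      Hc[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc);
  }

  Aln a{best, bi, bi, bj, bj, 0, 0};
  if (best <= 0) { a = Aln{0, 0, 0, 0, 0, 0, 0}; return a; }
  // traceback from the best cell
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    const uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      const uint8_t src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        a.alen++;
        const int cq = base_code(q[i - 1]);
        if (cq >= 0 && cq == base_code(s[j - 1])) a.nmatch++;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {      // gap in query, consume s[j-1]
      a.alen++;
      const bool ext = (t & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else {                      // gap in subject, consume q[i-1]
      a.alen++;
      const bool ext = (t & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  a.qs = i; a.ss = j;
  return a;
}

// [[Rcpp::export(name = ".ft_sw")]]
List ft_sw(std::string query, std::string subject,
           int match, int mismatch, int gap_open, int gap_extend) {
  Aln a = sw_core(query, subject, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = a.score,
                      _["q_start"] = a.qs, _["q_end"] = a.qe,
                      _["s_start"] = a.ss, _["s_end"] = a.se,
                      _["n_match"] = a.nmatch, _["aln_len"] = a.alen);
}

// ---------------- seeded search ----------------

struct SeedIndex {
  std::vector<std::string> seqs;
  int word;
  long long total_length;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> pos;
};

// [[Rcpp::export(name = ".ft_build_index")]]
SEXP ft_build_index(CharacterVector seqs, int word) {
  if (word < 4 || word > 31) stop("word size must be in [4, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->word = word;
  idx->total_length = 0;
  const uint64_t mask = (word == 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
  for (int si = 0; si < seqs.size(); ++si) {
    idx->seqs.push_back(as<std::string>(seqs[si]));
    const std::string& s = idx->seqs.back();
    idx->total_length += (long long)s.size();
    uint64_t kmer = 0;
    int valid = 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      const int c = base_code(s[j]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++valid >= word) idx->pos[kmer].push_back({si, j - word + 1});
    }
  }
  return XPtr<SeedIndex>(idx, true);
}

// [[Rcpp::export(name = ".ft_ptr_valid")]]
bool ft_ptr_valid(SEXP p) {
  return TYPEOF(p) == EXTPTRSXP && R_ExternalPtrAddr(p) != NULL;
}

// [[Rcpp::export(name = ".ft_index_info")]]
List ft_index_info(SEXP idxp) {
  XPtr<SeedIndex> idx(idxp);
  long long npos = 0;
  for (auto& kv : idx->pos) npos += (long long)kv.second.size();
  return List::create(_["n_kmers"] = (double)idx->pos.size(),
                      _["n_positions"] = (double)npos,
                      _["word_size"] = idx->word,
                      _["total_length"] = (double)idx->total_length);
}

// [[Rcpp::export(name = ".ft_index_lookup")]]
IntegerMatrix ft_index_lookup(SEXP idxp, std::string kmer) {
  XPtr<SeedIndex> idx(idxp);
  if ((int)kmer.size() != idx->word) stop("kmer length must equal the index word size");
  uint64_t key = 0;
  for (char c : kmer) {
    const int b = base_code(c);
    if (b < 0) return IntegerMatrix(0, 2);
    key = (key << 2) | (uint64_t)b;
  }
  auto it = idx->pos.find(key);
  if (it == idx->pos.end()) return IntegerMatrix(0, 2);
  IntegerMatrix out((int)it->second.size(), 2);
  for (int i = 0; i < (int)it->second.size(); ++i) {
    out(i, 0) = it->second[i].first + 1;   // subject index, 1-based
    out(i, 1) = it->second[i].second;      // 0-based position
  }
  return out;
}

struct Seed { int subj, diag, spos; };

// Seeded search of one query strand against the index: seeds are clustered by
// (subject, diagonal band), each cluster resolved by exact local DP on a
// subject window spanning the cluster.
// [[Rcpp::export(name = ".ft_search")]]
DataFrame ft_search(std::string query, SEXP idxp,
                    int match, int mismatch, int gap_open, int gap_extend,
                    int max_window = 20000) {
  XPtr<SeedIndex> idx(idxp);
  const int word = idx->word;
  const int qlen = (int)query.size();
  std::vector<Seed> seeds;
  if (qlen >= word) {
    const uint64_t mask = (1ULL << (2 * word)) - 1;
    uint64_t kmer = 0;
    int valid = 0;
    for (int j = 0; j < qlen; ++j) {
      const int c = base_code(query[j]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++valid >= word) {
        auto it = idx->pos.find(kmer);
        if (it != idx->pos.end()) {
          const int qpos = j - word + 1;
          for (auto& p : it->second)
            seeds.push_back({p.first, p.second - qpos, p.second});
        }
      }
    }
  }
  std::vector<int> osubj; std::vector<int> oqs, oqe, oss, ose, oscore, onm, olen;
  if (!seeds.empty()) {
    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
      if (a.subj != b.subj) return a.subj < b.subj;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.spos < b.spos;
    });
    const int diag_band = 50;
    size_t k = 0;
    while (k < seeds.size()) {
      // diagonal-band cluster
      size_t k2 = k + 1;
      while (k2 < seeds.size() && seeds[k2].subj == seeds[k].subj &&
             seeds[k2].diag - seeds[k2 - 1].diag <= diag_band) ++k2;
      // split on subject-position gaps within the band
      std::vector<int> sp;
      for (size_t t = k; t < k2; ++t) sp.push_back(seeds[t].spos);
      std::sort(sp.begin(), sp.end());
      size_t a = 0;
      const std::string& subj = idx->seqs[seeds[k].subj];
      const int slen = (int)subj.size();
      while (a < sp.size()) {
        size_t b = a + 1;
        while (b < sp.size() && sp[b] - sp[b - 1] <= qlen + 200) ++b;
        int lo = sp[a] - qlen - 32;
        int hi = sp[b - 1] + word + qlen + 32;
        if (lo < 0) lo = 0;
        if (hi > slen) hi = slen;
        if (hi - lo > max_window) {
          const int mid = (sp[a] + sp[b - 1] + word) / 2;
          lo = std::max(0, mid - max_window / 2);
          hi = std::min(slen, lo + max_window);
        }
        Aln al = sw_core(query, subj.substr(lo, hi - lo),
                         match, mismatch, gap_open, gap_extend);
        if (al.score > 0) {
          osubj.push_back(seeds[k].subj + 1);
          oqs.push_back(al.qs); oqe.push_back(al.qe);
          oss.push_back(al.ss + lo); ose.push_back(al.se + lo);
          oscore.push_back(al.score); onm.push_back(al.nmatch);
          olen.push_back(al.alen);
        }
        a = b;
      }
      k = k2;
    }
  }
  return DataFrame::create(_["subject"] = osubj,
                           _["q_start"] = oqs, _["q_end"] = oqe,
                           _["s_start"] = oss, _["s_end"] = ose,
                           _["score"] = oscore, _["n_match"] = onm,
                           _["aln_len"] = olen);
}
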