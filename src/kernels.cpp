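#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; -1 for anything not A/C/G/T
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

struct KmerIndex {
  int k;
  std::string ref;
  std::unordered_map<uint64_t, std::vector<int>> pos; // 1-based kmer starts
};

static bool encode_kmer(const char *s, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_index_reference(std::string ref, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  if ((int)ref.size() < k) stop("k exceeds reference length");
  XPtr<KmerIndex> idx(new KmerIndex(), true);
  idx->k = k;
  idx->ref = ref;
  const char *s = idx->ref.c_str();
  int n = (int)ref.size() - k + 1;
  for (int i = 0; i < n; ++i) {
    uint64_t key;
    if (encode_kmer(s + i, k, key)) idx->pos[key].push_back(i + 1);
  }
  return idx;
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal k");
  uint64_t key;
  if (!encode_kmer(kmer.c_str(), idx->k, key)) return IntegerVector(0);
  auto it = idx->pos.find(key);
  if (it == idx->pos.end()) return IntegerVector(0);
  return wrap(it->second);
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["n_kmers"] = (double)idx->pos.size(),
                      _["ref_length"] = (double)idx->ref.size());
}

static void revcomp_inplace(std::string &s) {
  int n = (int)s.size();
  for (int i = 0, j = n - 1; i <= j; ++i, --j) {
    char a = s[i], b = s[j];
    auto comp = [](char c) -> char {
      switch (c) {
      case 'A': return 'T'; case 'C': return 'G';
      case 'G': return 'C'; case 'T': return 'A';
      case 'a': return 't'; case 'c': return 'g';
      case 'g': return 'c'; case 't': return 'a';
      default: return 'N';
      }
    };
    s[i] = comp(b);
    s[j] = comp(a);
  }
}

// Count mismatches of read (already oriented) against ref at 1-based start;
// bail out early once > cap.
static int mismatches_at(const std::string &ref, const std::string &read,
                         int start, int cap) {
  const char *r = ref.c_str() + (start - 1);
  const char *q = read.c_str();
  int m = (int)read.size(), mm = 0;
  for (int i = 0; i < m; ++i) {
    if (r[i] != q[i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Seed-and-extend ungapped mapping of many reads against an indexed reference.
// Ties broken by mismatch count, then smallest start, then + strand; a tie on
// mismatch count between distinct best placements gives mapq 0.
// [[Rcpp::export]]
List cpp_map_reads(SEXP xp, CharacterVector reads, int step,
                   double max_mismatch_frac) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  const std::string &ref = idx->ref;
  const int L = (int)ref.size();
  int n = reads.size();
  IntegerVector out_start(n), out_nm(n), out_mapq(n);
  LogicalVector out_mapped(n);
  CharacterVector out_strand(n);
  std::vector<std::pair<int, int>> cands; // (start, strand 0=+,1=-)

  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int m = (int)fwd.size();
    out_mapped[r] = false;
    out_start[r] = NA_INTEGER;
    out_nm[r] = NA_INTEGER;
    out_mapq[r] = 0;
    out_strand[r] = NA_STRING;
    if (m < k) continue;
    std::string rev = fwd;
    revcomp_inplace(rev);
    int mm_limit = (int)std::floor(max_mismatch_frac * m);

    cands.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &oriented = strand == 0 ? fwd : rev;
      const char *s = oriented.c_str();
      for (int o = 0; o <= m - k; o += step) {
        int off = o;
        uint64_t key;
        if (!encode_kmer(s + off, k, key)) continue;
        auto it = idx->pos.find(key);
        if (it == idx->pos.end()) continue;
        for (int p : it->second) {
          int st = p - off;
          if (st >= 1 && st + m - 1 <= L) cands.push_back({st, strand});
        }
        if (o + step > m - k && o != m - k) { // ensure terminal seed
          o = m - k - step;
        }
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best_mm = mm_limit + 1, best_start = -1, best_strand = 0;
    int second_mm = INT_MAX;
    for (auto &c : cands) {
      int cap = std::max(best_mm, mm_limit); // need exact counts up to current best for ties
      int mm = mismatches_at(ref, c.second == 0 ? fwd : rev, c.first, cap);
      if (mm < best_mm) {
        if (best_start >= 0) second_mm = best_mm;
        best_mm = mm;
        best_start = c.first;
        best_strand = c.second;
      } else if (mm < second_mm &&
                 !(c.first == best_start && c.second == best_strand)) {
        second_mm = mm;
      }
    }
    if (best_start < 0 || best_mm > mm_limit) continue;
    out_mapped[r] = true;
    out_start[r] = best_start;
    out_nm[r] = best_mm;
    out_strand[r] = best_strand == 0 ? "+" : "-";
    if (second_mm == INT_MAX) out_mapq[r] = 60;
    else out_mapq[r] = std::min(60, 10 * (second_mm - best_mm));
  }
  return List::create(_["mapped"] = out_mapped, _["start"] = out_start,
                      _["strand"] = out_strand, _["nm"] = out_nm,
                      _["mapq"] = out_mapq);
}

// i.i.d. substitution errors using R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, double rate) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < rate) {
        int c = base_code(s[j]);
        if (c < 0) continue;
        int shift = 1 + (int)(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        s[j] = CODE2BASE[(c + shift) & 3];
      }
    }
    out[i] = s;
  }
  return out;
}

// Resolve one fragment's base at an absolute position given one or two reads.
// Returns code 0..3, or -1 if uncovered / below quality. Reads i and (optionally)
// j are 0-based indices into the vectors.
struct ReadView {
  const char *seq;
  const char *qual;
  int start;
  int len;
  bool plus;
};

static inline bool covers(const ReadView &rv, int pos) {
  return pos >= rv.start && pos <= rv.start + rv.len - 1;
}

// winner: 0 none, 1 first read, 2 second read
static inline int resolve_base(const ReadView &a, const ReadView *b, int pos,
                               int min_q, int &code, int &qual, bool &plus) {
  bool ca = covers(a, pos);
  bool cb = b && covers(*b, pos);
  int winner = 0;
  const ReadView *w = nullptr;
  if (ca && cb) {
    int qa = a.qual[pos - a.start] - 33;
    int qb = b->qual[pos - b->start] - 33;
    w = (qb > qa) ? b : &a; // tie -> first mate
    winner = (qb > qa) ? 2 : 1;
  } else if (ca) {
    w = &a; winner = 1;
  } else if (cb) {
    w = b; winner = 2;
  }
  if (!w) return 0;
  int q = w->qual[pos - w->start] - 33;
  int c = base_code(w->seq[pos - w->start]);
  if (q < min_q || c < 0) return 0;
  code = c;
  qual = q;
  plus = w->plus;
  return winner;
}

// Build a pileup over reference length L. Reads must be ordered so mates are
// adjacent (same frag id). seq/qual are reference-oriented.
// [[Rcpp::export]]
List cpp_build_pileup(int L, IntegerVector start, CharacterVector seq,
                      CharacterVector qual, CharacterVector strand,
                      IntegerVector frag, int min_base_q) {
  int n = start.size();
  IntegerMatrix counts_fwd(L, 4), counts_rev(L, 4);
  NumericMatrix qualsum(L, 4);
  std::vector<std::string> seqs(n), quals(n);
  std::vector<ReadView> views(n);
  for (int i = 0; i < n; ++i) {
    seqs[i] = as<std::string>(seq[i]);
    quals[i] = as<std::string>(qual[i]);
    if ((int)seqs[i].size() != (int)quals[i].size())
      stop("sequence/quality length mismatch at read %d", i + 1);
    views[i] = {seqs[i].c_str(), quals[i].c_str(), start[i],
                (int)seqs[i].size(), as<std::string>(strand[i]) == "+"};
    if (start[i] < 1 || start[i] + views[i].len - 1 > L)
      stop("read %d exceeds reference bounds", i + 1);
  }
  int i = 0;
  while (i < n) {
    bool paired = (i + 1 < n) && frag[i + 1] == frag[i];
    const ReadView &a = views[i];
    const ReadView *b = paired ? &views[i + 1] : nullptr;
    int lo = a.start, hi = a.start + a.len - 1;
    if (b) {
      lo = std::min(lo, b->start);
      hi = std::max(hi, b->start + b->len - 1);
    }
    for (int pos = lo; pos <= hi; ++pos) {
      int code, q;
      bool plus;
      if (resolve_base(a, b, pos, min_base_q, code, q, plus)) {
        if (plus) counts_fwd(pos - 1, code)++;
        else counts_rev(pos - 1, code)++;
        qualsum(pos - 1, code) += q;
      }
    }
    i += paired ? 2 : 1;
  }
  return List::create(_["counts_fwd"] = counts_fwd, _["counts_rev"] = counts_rev,
                      _["qualsum"] = qualsum);
}

// Per-fragment resolved base codes at a set of sites (columns). -1 = uncovered
// or below min quality. Rows follow the fragment order of the input (mates
// adjacent, same frag id).
// [[Rcpp::export]]
List cpp_fragment_bases(IntegerVector start, CharacterVector seq,
                        CharacterVector qual, CharacterVector strand,
                        IntegerVector frag, IntegerVector sites,
                        int min_base_q) {
  int n = start.size(), ns = sites.size();
  std::vector<std::string> seqs(n), quals(n);
  std::vector<ReadView> views(n);
  for (int i = 0; i < n; ++i) {
    seqs[i] = as<std::string>(seq[i]);
    quals[i] = as<std::string>(qual[i]);
    views[i] = {seqs[i].c_str(), quals[i].c_str(), start[i],
                (int)seqs[i].size(), as<std::string>(strand[i]) == "+"};
  }
  std::vector<int> frag_row;
  std::vector<std::vector<int>> rows;
  int i = 0;
  while (i < n) {
    bool paired = (i + 1 < n) && frag[i + 1] == frag[i];
    const ReadView &a = views[i];
    const ReadView *b = paired ? &views[i + 1] : nullptr;
    std::vector<int> row(ns, -1);
    for (int s = 0; s < ns; ++s) {
      int code, q;
      bool plus;
      if (resolve_base(a, b, sites[s], min_base_q, code, q, plus))
        row[s] = code;
    }
    rows.push_back(std::move(row));
    frag_row.push_back(frag[i]);
    i += paired ? 2 : 1;
  }
  int nf = (int)rows.size();
  IntegerMatrix m(nf, ns);
  for (int r = 0; r < nf; ++r)
    for (int s = 0; s < ns; ++s) m(r, s) = rows[r][s];
  return List::create(_["codes"] = m, _["frag"] = wrap(frag_row));
}
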