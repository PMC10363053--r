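// Local alignment core: affine-gap Smith-Waterman with deterministic
// traceback, a k-mer index for seeded (seed-and-extend) search on both
// strands, an end-to-end mismatch-bounded matcher (host subtraction),
// and a gapless sliding expectation-score scan (target prediction).

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

const int NEG_INF = INT_MIN / 4;

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct Aln {
  int score = 0;
  // 0-based half-open spans; empty when score == 0
  int qstart = 0, qend = 0, sstart = 0, send = 0;
  int matches = 0, length = 0, gaps = 0;
};

// Optimal local alignment with affine gaps (gap of length L costs
// gap_open + L * gap_extend). Traceback ties prefer diagonal, then up
// (gap in subject), then left (gap in query); the best cell is the first
// maximum in row-major order.
Aln sw_core(const std::string& q, const std::string& s, int match,
            int mismatch, int gap_open, int gap_extend) {
  const int m = static_cast<int>(q.size());
  const int n = static_cast<int>(s.size());
  const double cells = (static_cast<double>(m) + 1.0) * (n + 1.0);
  if (cells > 2.5e7)
    stop("sequences too long for full dynamic programming (%d x %d)", m, n);

  const size_t ncol = static_cast<size_t>(n) + 1;
  std::vector<int> H((m + 1) * ncol, 0);
  std::vector<int> E((m + 1) * ncol, NEG_INF);
  std::vector<int> F((m + 1) * ncol, NEG_INF);
  const int gop = gap_open + gap_extend;

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t row = i * ncol, prev = (i - 1) * ncol;
    for (int j = 1; j <= n; ++j) {
      const int e = std::max(H[row + j - 1] - gop, E[row + j - 1] - gap_extend);
      const int f = std::max(H[prev + j] - gop, F[prev + j] - gap_extend);
      const int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      int h = H[prev + j - 1] + sub;
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0) h = 0;
      E[row + j] = e;
      F[row + j] = f;
      H[row + j] = h;
      if (h > best) {
        best = h;
        bi = i;
        bj = j;
      }
    }
  }

  Aln a;
  a.score = best;
  if (best == 0) return a;

  int i = bi, j = bj;
  char state = 'H';
  while (true) {
    if (state == 'H') {
      const int h = H[i * ncol + j];
      if (h == 0) break;
      const int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      if (h == H[(i - 1) * ncol + (j - 1)] + sub) {
        a.length++;
        if (q[i - 1] == s[j - 1]) a.matches++;
        --i;
        --j;
      } else if (h == F[i * ncol + j]) {
        state = 'F';
      } else if (h == E[i * ncol + j]) {
        state = 'E';
      } else {
        stop("internal error: inconsistent traceback");
      }
    } else if (state == 'F') {  // gap in subject, consume query base
      a.length++;
      a.gaps++;
      const bool open = (F[i * ncol + j] == H[(i - 1) * ncol + j] - gop);
      --i;
      if (open) state = 'H';
    } else {  // 'E': gap in query, consume subject base
      a.length++;
      a.gaps++;
      const bool open = (E[i * ncol + j] == H[i * ncol + (j - 1)] - gop);
      --j;
      if (open) state = 'H';
    }
  }
  a.qstart = i;
  a.qend = bi;
  a.sstart = j;
  a.send = bj;
  return a;
}

struct SeqIndex {
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  int word = 0;
  // k-mer code -> (sequence index, 0-based position); insertion order is
  // the deterministic build scan order
  std::unordered_map<uint64_t, std::vector<std::pair<uint32_t, uint32_t>>> kmap;
};

bool encode_kmer(const std::string& s, size_t pos, int w, uint64_t& out) {
  uint64_t v = 0;
  for (int k = 0; k < w; ++k) {
    const int c = base_code(s[pos + k]);
    if (c < 0) return false;
    v = (v << 2) | static_cast<uint64_t>(c);
  }
  out = v;
  return true;
}

struct Hit {
  int qidx = 0;   // 0-based query index
  int sidx = 0;   // 0-based subject index
  char strand = '+';
  Aln a;
};

void search_one_strand(const SeqIndex& idx, const std::string& qq, char strand,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int qidx, std::vector<Hit>& out) {
  const int w = idx.word;
  const int qlen = static_cast<int>(qq.size());
  if (qlen < w) return;

  std::vector<std::pair<uint32_t, std::pair<int, int>>> cand;  // (sidx, window)
  for (int qp = 0; qp + w <= qlen; ++qp) {
    uint64_t code;
    if (!encode_kmer(qq, qp, w, code)) continue;
    auto it = idx.kmap.find(code);
    if (it == idx.kmap.end()) continue;
    for (size_t h = 0; h < it->second.size(); ++h) {
      const uint32_t si = it->second[h].first;
      const int sp = static_cast<int>(it->second[h].second);
      const int slen = static_cast<int>(idx.seqs[si].size());
      int lo = sp - qp - qlen;
      int hi = sp + (qlen - qp) + qlen;
      if (lo < 0) lo = 0;
      if (hi > slen) hi = slen;
      cand.push_back({si, {lo, hi}});
    }
  }
  if (cand.empty()) return;
  std::sort(cand.begin(), cand.end());

  size_t k = 0;
  while (k < cand.size()) {
    const uint32_t si = cand[k].first;
    int lo = cand[k].second.first, hi = cand[k].second.second;
    size_t k2 = k + 1;
    while (k2 < cand.size() && cand[k2].first == si &&
           cand[k2].second.first <= hi) {
      hi = std::max(hi, cand[k2].second.second);
      ++k2;
    }
    Aln a = sw_core(qq, idx.seqs[si].substr(lo, hi - lo), match, mismatch,
                    gap_open, gap_extend);
    if (a.score > 0) {
      a.sstart += lo;
      a.send += lo;
      if (strand == '-') {  // report spans on the original (forward) query
        const int qs = a.qstart, qe = a.qend;
        a.qstart = qlen - qe;
        a.qend = qlen - qs;
      }
      Hit hit;
      hit.qidx = qidx;
      hit.sidx = static_cast<int>(si);
      hit.strand = strand;
      hit.a = a;
      out.push_back(hit);
    }
    k = k2;
  }
}

DataFrame hits_to_df(const std::vector<Hit>& hits) {
  const int n = static_cast<int>(hits.size());
  IntegerVector query(n), subject(n), score(n), qstart(n), qend(n), sstart(n),
      send(n), matches(n), length(n), gaps(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    query[i] = hits[i].qidx + 1;
    subject[i] = hits[i].sidx + 1;
    strand[i] = std::string(1, hits[i].strand);
    score[i] = hits[i].a.score;
    qstart[i] = hits[i].a.qstart;
    qend[i] = hits[i].a.qend;
    sstart[i] = hits[i].a.sstart;
    send[i] = hits[i].a.send;
    matches[i] = hits[i].a.matches;
    length[i] = hits[i].a.length;
    gaps[i] = hits[i].a.gaps;
  }
  return DataFrame::create(
      Named("query") = query, Named("subject") = subject,
      Named("strand") = strand, Named("score") = score,
      Named("qstart") = qstart, Named("qend") = qend,
      Named("sstart") = sstart, Named("send") = send,
      Named("matches") = matches, Named("length") = length,
      Named("gaps") = gaps);
}

// deterministic hit order / best-hit preference:
// score desc, identity desc, subject name asc, sstart asc, '+' before '-'
bool hit_better(const Hit& x, const Hit& y, const SeqIndex& idx) {
  if (x.a.score != y.a.score) return x.a.score > y.a.score;
  const double ix = x.a.length ? (double)x.a.matches / x.a.length : 0.0;
  const double iy = y.a.length ? (double)y.a.matches / y.a.length : 0.0;
  if (ix != iy) return ix > iy;
  const std::string& nx = idx.names[x.sidx];
  const std::string& ny = idx.names[y.sidx];
  if (nx != ny) return nx < ny;
  if (x.a.sstart != y.a.sstart) return x.a.sstart < y.a.sstart;
  return x.strand == '+' && y.strand == '-';
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, CharacterVector names, int word) {
  if (word < 4 || word > 31) stop("word size must be between 4 and 31");
  XPtr<SeqIndex> p(new SeqIndex(), true);
  p->word = word;
  const int ns = seqs.size();
  for (int i = 0; i < ns; ++i) {
    p->seqs.push_back(as<std::string>(seqs[i]));
    p->names.push_back(as<std::string>(names[i]));
  }
  for (uint32_t si = 0; si < p->seqs.size(); ++si) {
    const std::string& s = p->seqs[si];
    if (static_cast<int>(s.size()) < word) continue;
    for (size_t pos = 0; pos + word <= s.size(); ++pos) {
      uint64_t code;
      if (!encode_kmer(s, pos, word, code)) continue;
      p->kmap[code].push_back({si, static_cast<uint32_t>(pos)});
    }
  }
  return p;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP ptr) {
  XPtr<SeqIndex> p(ptr);
  double total = 0;
  for (size_t i = 0; i < p->seqs.size(); ++i) total += p->seqs[i].size();
  return List::create(Named("n_sequences") = (int)p->seqs.size(),
                      Named("total_bases") = total,
                      Named("word_size") = p->word,
                      Named("names") = wrap(p->names));
}

// [[Rcpp::export]]
DataFrame cpp_search_local(SEXP ptr, CharacterVector queries, int match,
                           int mismatch, int gap_open, int gap_extend,
                           bool best_only) {
  XPtr<SeqIndex> p(ptr);
  std::vector<Hit> all;
  for (int qi = 0; qi < queries.size(); ++qi) {
    const std::string q = as<std::string>(queries[qi]);
    std::vector<Hit> hits;
    search_one_strand(*p, q, '+', match, mismatch, gap_open, gap_extend, qi,
                      hits);
    search_one_strand(*p, revcomp_str(q), '-', match, mismatch, gap_open,
                      gap_extend, qi, hits);
    if (hits.empty()) continue;
    std::sort(hits.begin(), hits.end(), [&](const Hit& x, const Hit& y) {
      return hit_better(x, y, *p);
    });
    if (best_only) {
      all.push_back(hits[0]);
    } else {
      for (size_t h = 0; h < hits.size(); ++h) all.push_back(hits[h]);
    }
  }
  return hits_to_df(all);
}

// [[Rcpp::export]]
List cpp_sw(std::string q, std::string s, int match, int mismatch,
            int gap_open, int gap_extend) {
  const Aln a = sw_core(q, s, match, mismatch, gap_open, gap_extend);
  return List::create(Named("score") = a.score, Named("qstart") = a.qstart,
                      Named("qend") = a.qend, Named("sstart") = a.sstart,
                      Named("send") = a.send, Named("matches") = a.matches,
                      Named("length") = a.length, Named("gaps") = a.gaps);
}

// End-to-end (gapless, full query length) matching with at most max_mm
// substitutions, both strands. Complete via pigeonhole seeding over
// max_mm + 1 blocks; falls back to exhaustive scanning when the blocks are
// shorter than the index word.
// [[Rcpp::export]]
List cpp_search_endtoend(SEXP ptr, CharacterVector queries, int max_mm) {
  XPtr<SeqIndex> p(ptr);
  const int w = p->word;
  const int nq = queries.size();
  LogicalVector matched(nq, false);
  IntegerVector mismatches(nq, NA_INTEGER), subject(nq, NA_INTEGER),
      pos(nq, NA_INTEGER);
  CharacterVector strand(nq, NA_STRING);

  for (int qi = 0; qi < nq; ++qi) {
    const std::string q0 = as<std::string>(queries[qi]);
    const int L = static_cast<int>(q0.size());
    if (L < 1) continue;
    bool done = false;
    for (int st = 0; st < 2 && !done; ++st) {
      const std::string qq = (st == 0) ? q0 : revcomp_str(q0);
      const int nb = max_mm + 1;
      const int bl = L / nb;
      if (bl >= w) {
        for (int b = 0; b < nb && !done; ++b) {
          const int o = b * bl;
          uint64_t code;
          if (!encode_kmer(qq, o, w, code)) continue;
          auto it = p->kmap.find(code);
          if (it == p->kmap.end()) continue;
          for (size_t h = 0; h < it->second.size() && !done; ++h) {
            const uint32_t si = it->second[h].first;
            const int sp = static_cast<int>(it->second[h].second);
            const int start = sp - o;
            const std::string& s = p->seqs[si];
            if (start < 0 || start + L > static_cast<int>(s.size())) continue;
            int mm = 0;
            for (int k = 0; k < L; ++k) {
              if (qq[k] != s[start + k] && ++mm > max_mm) break;
            }
            if (mm <= max_mm) {
              matched[qi] = true;
              mismatches[qi] = mm;
              subject[qi] = static_cast<int>(si) + 1;
              pos[qi] = start;
              strand[qi] = (st == 0) ? "+" : "-";
              done = true;
            }
          }
        }
      } else {  // exhaustive fallback for very permissive settings
        for (size_t si = 0; si < p->seqs.size() && !done; ++si) {
          const std::string& s = p->seqs[si];
          const int slen = static_cast<int>(s.size());
          for (int start = 0; start + L <= slen && !done; ++start) {
            int mm = 0;
            for (int k = 0; k < L; ++k) {
              if (qq[k] != s[start + k] && ++mm > max_mm) break;
            }
            if (mm <= max_mm) {
              matched[qi] = true;
              mismatches[qi] = mm;
              subject[qi] = static_cast<int>(si) + 1;
              pos[qi] = start;
              strand[qi] = (st == 0) ? "+" : "-";
              done = true;
            }
          }
        }
      }
    }
  }
  return List::create(Named("matched") = matched,
                      Named("mismatches") = mismatches,
                      Named("subject") = subject, Named("pos") = pos,
                      Named("strand") = strand);
}

// Gapless sliding expectation score of a miRNA against every window of a
// transcript (antiparallel pairing: miRNA position i from the 5' end pairs
// with window position L - i + 1). Returns windows with score <= cutoff.
// [[Rcpp::export]]
DataFrame cpp_target_scan(std::string mirna, std::string tx, double mm_pen,
                          double gu_pen, int seed_lo, int seed_hi,
                          double seed_mult, double cutoff) {
  const int L = static_cast<int>(mirna.size());
  const int n = static_cast<int>(tx.size());
  std::vector<int> positions;
  std::vector<double> scores;
  for (int start = 0; start + L <= n; ++start) {
    double sc = 0.0;
    for (int i = 1; i <= L; ++i) {
      const char b = mirna[i - 1];
      const char t = tx[start + L - i];
      double pen;
      if (t == comp_base(b)) {
        pen = 0.0;
      } else if ((b == 'G' && t == 'T') || (b == 'T' && t == 'G')) {
        pen = gu_pen;
      } else {
        pen = mm_pen;
      }
      if (i >= seed_lo && i <= seed_hi) pen *= seed_mult;
      sc += pen;
      if (sc > cutoff) break;
    }
    if (sc <= cutoff) {
      positions.push_back(start);
      scores.push_back(sc);
    }
  }
  return DataFrame::create(Named("position") = wrap(positions),
                           Named("expectation") = wrap(scores));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    out[i] = revcomp_str(as<std::string>(x[i]));
  }
  return out;
}
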