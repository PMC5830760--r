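// Low-level kernels for radasm: Hamming distances, sequential catalog
// merging, weighted consensus calling, substitution-error injection,
// suffix-prefix overlap discovery, greedy OLC assembly and a k-mer seeded
// ungapped read mapper.  All randomness goes through R's RNG so results
// are reproducible under set.seed().
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int ham_limited(const char* a, const char* b, int n, int limit) {
  // Hamming distance with early abort once the count exceeds `limit`.
  int d = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) { if (++d > limit) return d; }
  }
  return d;
}

// [[Rcpp::export(name = ".hamming_cpp")]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size())
    stop("hamming distance requires equal-length sequences");
  return ham_limited(a.c_str(), b.c_str(), (int)a.size(), (int)a.size());
}

// All pairs (i < j) at Hamming distance <= m.  Returns a 3-column matrix
// (i, j, d), 1-based.
// [[Rcpp::export(name = ".hamming_edges_cpp")]]
IntegerMatrix hamming_edges_cpp(CharacterVector seqs, int m) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 1; i < n; ++i)
    if (s[i].size() != s[0].size()) stop("sequences must share one length");
  std::vector<int> ei, ej, ed;
  int L = n ? (int)s[0].size() : 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = ham_limited(s[i].c_str(), s[j].c_str(), L, m);
      if (d <= m) { ei.push_back(i + 1); ej.push_back(j + 1); ed.push_back(d); }
    }
  }
  IntegerMatrix out(ei.size(), 3);
  for (size_t k = 0; k < ei.size(); ++k) {
    out(k, 0) = ei[k]; out(k, 1) = ej[k]; out(k, 2) = ed[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "d");
  return out;
}

// For each query: number of refs within m mismatches and the (1-based)
// index of the first such ref (0 when none).  Queries and refs must share
// one length.
// [[Rcpp::export(name = ".hamming_hits_cpp")]]
IntegerMatrix hamming_hits_cpp(CharacterVector queries, CharacterVector refs, int m) {
  int nq = queries.size(), nr = refs.size();
  std::vector<std::string> q(nq), r(nr);
  for (int i = 0; i < nq; ++i) q[i] = as<std::string>(queries[i]);
  for (int i = 0; i < nr; ++i) r[i] = as<std::string>(refs[i]);
  IntegerMatrix out(nq, 2);
  for (int i = 0; i < nq; ++i) {
    int hits = 0, first = 0;
    int L = (int)q[i].size();
    for (int j = 0; j < nr; ++j) {
      if ((int)r[j].size() != L) continue;
      int d = ham_limited(q[i].c_str(), r[j].c_str(), L, m);
      if (d <= m) { if (++hits == 1) first = j + 1; }
    }
    out(i, 0) = hits; out(i, 1) = first;
  }
  colnames(out) = CharacterVector::create("n_hits", "first");
  return out;
}

// Sequential catalog merge: loci arrive grouped by individual (group is a
// non-decreasing integer vector).  Each locus is compared against catalog
// entries founded by *previous* individuals only; the first entry (lowest
// cat id) within n mismatches absorbs it, otherwise the locus founds a new
// entry whose consensus is its own.  Returns 1-based cat ids per locus.
// [[Rcpp::export(name = ".catalog_merge_cpp")]]
IntegerVector catalog_merge_cpp(CharacterVector consensi, IntegerVector group, int n) {
  int N = consensi.size();
  if (group.size() != N) stop("group length mismatch");
  std::vector<std::string> s(N);
  for (int i = 0; i < N; ++i) s[i] = as<std::string>(consensi[i]);
  std::vector<std::string> cat;        // catalog consensi (founder sequences)
  std::vector<int> cat_group;          // founding individual of each entry
  IntegerVector assign(N);
  for (int i = 0; i < N; ++i) {
    int g = group[i], hit = -1;
    int L = (int)s[i].size();
    for (size_t j = 0; j < cat.size(); ++j) {
      if (cat_group[j] >= g) break;    // entries from this pass not eligible
      if ((int)cat[j].size() != L) continue;
      if (ham_limited(s[i].c_str(), cat[j].c_str(), L, n) <= n) { hit = (int)j; break; }
    }
    if (hit < 0) {
      cat.push_back(s[i]); cat_group.push_back(g);
      assign[i] = (int)cat.size();
    } else assign[i] = hit + 1;
  }
  return assign;
}

// Per-column weighted majority over equal-length sequences.  Only A,C,G,T
// vote; ties break to the alphabetically smallest base; a column with no
// votes yields 'N'.
// [[Rcpp::export(name = ".consensus_cpp")]]
std::string consensus_cpp(CharacterVector seqs, NumericVector w) {
  int n = seqs.size();
  if (n == 0) stop("no sequences");
  if (w.size() != n) stop("weight length mismatch");
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  int L = (int)s[0].size();
  for (int i = 1; i < n; ++i)
    if ((int)s[i].size() != L) stop("sequences must share one length");
  std::string cons(L, 'N');
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int c = 0; c < L; ++c) {
    double cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      switch (s[i][c]) {
        case 'A': cnt[0] += w[i]; break;
        case 'C': cnt[1] += w[i]; break;
        case 'G': cnt[2] += w[i]; break;
        case 'T': cnt[3] += w[i]; break;
        default: break;
      }
    }
    int best = -1; double bv = 0;
    for (int b = 0; b < 4; ++b)
      if (cnt[b] > bv) { bv = cnt[b]; best = b; }  // strict > keeps smallest base on ties
    if (best >= 0) cons[c] = bases[best];
  }
  return cons;
}

// Substitute each base independently with probability err to a uniformly
// chosen different base.  Uses R's RNG.
// [[Rcpp::export(name = ".inject_errors_cpp")]]
CharacterVector inject_errors_cpp(CharacterVector seqs, double err) {
  int n = seqs.size();
  CharacterVector out(n);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < err) {
        char cur = s[j];
        char alt[3]; int k = 0;
        for (int b = 0; b < 4; ++b) if (bases[b] != cur) alt[k++] = bases[b];
        if (k == 3) s[j] = alt[(int)(unif_rand() * 3) % 3];
      }
    }
    out[i] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Overlap discovery and greedy OLC assembly
// ---------------------------------------------------------------------------

struct Ov {
  // type: 0 none, 1 a-left dovetail (suffix of a overlaps prefix of b),
  //       2 b-left dovetail, 3 b contained in a, 4 a contained in b
  int type = 0;
  int len = 0, mism = 0, off = 0;  // off: b's start in a's frame (types 1,3) or a's start in b's frame (types 2,4)
  long score = -1;
};

static inline long ov_score(int len, int mism, int penalty) {
  return (long)(len - mism) - (long)penalty * mism;
}

// Best dovetail a->b over overlap lengths in [min_ov, min(la,lb)-1].
static void best_dovetail(const std::string& a, const std::string& b,
                          int min_ov, double rate, int penalty,
                          int type, Ov& best) {
  int la = (int)a.size(), lb = (int)b.size();
  int Lmax = std::min(la, lb) - 1;
  for (int L = Lmax; L >= min_ov; --L) {
    int budget = (int)(rate * L + 1e-9);
    int d = ham_limited(a.c_str() + (la - L), b.c_str(), L, budget);
    if (d > budget) continue;
    long sc = ov_score(L, d, penalty);
    if (sc > best.score || (sc == best.score && (L > best.len ||
        (L == best.len && d < best.mism)))) {
      best.type = type; best.len = L; best.mism = d;
      best.off = la - L; best.score = sc;
    }
  }
}

// Best containment of shorter `b` inside `a` (la >= lb): any offset.
static void best_containment(const std::string& a, const std::string& b,
                             double rate, int penalty, int type, Ov& best) {
  int la = (int)a.size(), lb = (int)b.size();
  int budget = (int)(rate * lb + 1e-9);
  for (int o = 0; o + lb <= la; ++o) {
    int d = ham_limited(a.c_str() + o, b.c_str(), lb, budget);
    if (d > budget) continue;
    long sc = ov_score(lb, d, penalty);
    if (sc > best.score || (sc == best.score && (lb > best.len ||
        (lb == best.len && d < best.mism)))) {
      best.type = type; best.len = lb; best.mism = d;
      best.off = o; best.score = sc;
    }
  }
}

static Ov best_overlap(const std::string& a, const std::string& b,
                       int min_ov, double rate, int penalty) {
  Ov best;
  best_dovetail(a, b, min_ov, rate, penalty, 1, best);
  best_dovetail(b, a, min_ov, rate, penalty, 2, best);
  if (b.size() <= a.size()) best_containment(a, b, rate, penalty, 3, best);
  if (a.size() <  b.size()) best_containment(b, a, rate, penalty, 4, best);
  return best;
}

// All qualifying overlaps between pairs of sequences: for each ordered pair
// the best suffix-prefix dovetail, plus the best containment per unordered
// pair.  1-based indices; `a` is the left/containing sequence.
// [[Rcpp::export(name = ".find_overlaps_cpp")]]
DataFrame find_overlaps_cpp(CharacterVector seqs, int min_overlap,
                            double max_mismatch_rate, int mismatch_penalty) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  std::vector<int> ra, rb, rlen, rmis, roff;
  std::vector<bool> rcont;
  std::vector<double> rsc;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      Ov d1; best_dovetail(s[i], s[j], min_overlap, max_mismatch_rate, mismatch_penalty, 1, d1);
      if (d1.type) {
        ra.push_back(i + 1); rb.push_back(j + 1); rlen.push_back(d1.len);
        rmis.push_back(d1.mism); roff.push_back(d1.off);
        rcont.push_back(false); rsc.push_back((double)d1.score);
      }
      Ov d2; best_dovetail(s[j], s[i], min_overlap, max_mismatch_rate, mismatch_penalty, 1, d2);
      if (d2.type) {
        ra.push_back(j + 1); rb.push_back(i + 1); rlen.push_back(d2.len);
        rmis.push_back(d2.mism); roff.push_back(d2.off);
        rcont.push_back(false); rsc.push_back((double)d2.score);
      }
      Ov ct;
      if (s[j].size() <= s[i].size())
        best_containment(s[i], s[j], max_mismatch_rate, mismatch_penalty, 3, ct);
      else
        best_containment(s[j], s[i], max_mismatch_rate, mismatch_penalty, 3, ct);
      if (ct.type) {
        bool j_in_i = s[j].size() <= s[i].size();
        ra.push_back(j_in_i ? i + 1 : j + 1);
        rb.push_back(j_in_i ? j + 1 : i + 1);
        rlen.push_back(ct.len); rmis.push_back(ct.mism); roff.push_back(ct.off);
        rcont.push_back(true); rsc.push_back((double)ct.score);
      }
    }
  }
  return DataFrame::create(_["a"] = ra, _["b"] = rb, _["length"] = rlen,
                           _["mismatches"] = rmis, _["offset"] = roff,
                           _["contained"] = LogicalVector(rcont.begin(), rcont.end()),
                           _["score"] = rsc);
}

struct Member { int uid; int off; double w; };
struct Contig {
  int id = 0;                 // smallest founding unique-read index
  bool alive = false;
  std::string cons;
  std::vector<Member> mem;
};

static std::string contig_consensus(const Contig& c, const std::vector<std::string>& useq) {
  int L = 0;
  for (const Member& m : c.mem)
    L = std::max(L, m.off + (int)useq[m.uid].size());
  std::vector<double> cnt(4L * L, 0.0);
  for (const Member& m : c.mem) {
    const std::string& s = useq[m.uid];
    for (int j = 0; j < (int)s.size(); ++j) {
      int b;
      switch (s[j]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
      }
      if (b >= 0) cnt[4L * (m.off + j) + b] += m.w;
    }
  }
  std::string cons(L, 'N');
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int c2 = 0; c2 < L; ++c2) {
    int best = -1; double bv = 0;
    for (int b = 0; b < 4; ++b)
      if (cnt[4L * c2 + b] > bv) { bv = cnt[4L * c2 + b]; best = b; }
    if (best >= 0) cons[c2] = bases[best];
  }
  return cons;
}

// Greedy overlap-layout-consensus assembly.  Exact duplicate input reads
// are collapsed to one weighted member first.  Returns contigs sorted by
// length (desc, ties by founding id asc) and the 1-based contig assignment
// of every input sequence.
// [[Rcpp::export(name = ".greedy_assemble_cpp")]]
List greedy_assemble_cpp(CharacterVector seqs, int min_overlap,
                         double max_mismatch_rate, int mismatch_penalty) {
  int N = seqs.size();
  if (N == 0) stop("no sequences to assemble");
  std::vector<std::string> in(N);
  for (int i = 0; i < N; ++i) in[i] = as<std::string>(seqs[i]);

  // collapse exact duplicates, preserving first-occurrence order
  std::unordered_map<std::string, int> seen;
  std::vector<std::string> useq;
  std::vector<double> uw;
  std::vector<int> rep(N);
  for (int i = 0; i < N; ++i) {
    auto it = seen.find(in[i]);
    if (it == seen.end()) {
      seen[in[i]] = (int)useq.size();
      rep[i] = (int)useq.size();
      useq.push_back(in[i]); uw.push_back(1.0);
    } else { rep[i] = it->second; uw[it->second] += 1.0; }
  }
  int n = (int)useq.size();

  std::vector<Contig> ctg(n);
  std::vector<int> uid2slot(n);
  for (int i = 0; i < n; ++i) {
    ctg[i].id = i; ctg[i].alive = true; ctg[i].cons = useq[i];
    ctg[i].mem.push_back({i, 0, uw[i]});
    uid2slot[i] = i;
  }

  // pairwise best overlaps, upper-triangular storage by slot pair
  std::vector<Ov> pbest((size_t)n * n);
  auto P = [&](int i, int j) -> Ov& { return pbest[(size_t)std::min(i, j) * n + std::max(i, j)]; };
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      P(i, j) = best_overlap(ctg[i].cons, ctg[j].cons, min_overlap,
                             max_mismatch_rate, mismatch_penalty);

  while (true) {
    // pick the globally best eligible overlap
    int bi = -1, bj = -1; Ov bo;
    for (int i = 0; i < n; ++i) {
      if (!ctg[i].alive) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!ctg[j].alive) continue;
        const Ov& o = P(i, j);
        if (!o.type) continue;
        bool better = false;
        if (bi < 0) better = true;
        else if (o.score != bo.score) better = o.score > bo.score;
        else if (o.len != bo.len) better = o.len > bo.len;
        else if (o.mism != bo.mism) better = o.mism < bo.mism;
        else {
          int ci1 = std::min(ctg[i].id, ctg[j].id), cj1 = std::max(ctg[i].id, ctg[j].id);
          int ci2 = std::min(ctg[bi].id, ctg[bj].id), cj2 = std::max(ctg[bi].id, ctg[bj].id);
          better = (ci1 < ci2) || (ci1 == ci2 && cj1 < cj2);
        }
        if (better) { bi = i; bj = j; bo = o; }
      }
    }
    if (bi < 0) break;

    // merge bj into bi (bi keeps its slot); compute shifts per overlap type
    Contig& A = ctg[bi];
    Contig& B = ctg[bj];
    int shiftA = 0, shiftB = 0;
    switch (bo.type) {
      case 1: shiftB = bo.off; break;                          // A left
      case 2: shiftA = bo.off; break;                          // B left
      case 3: shiftB = bo.off; break;                          // B inside A
      case 4: shiftA = bo.off; break;                          // A inside B
    }
    for (Member& m : A.mem) m.off += shiftA;
    for (Member& m : B.mem) { m.off += shiftB; A.mem.push_back(m); }
    for (const Member& m : B.mem) uid2slot[m.uid] = bi;
    A.id = std::min(A.id, B.id);
    B.alive = false; B.mem.clear();
    std::string old_cons = A.cons;
    A.cons = contig_consensus(A, useq);
    if (A.cons == old_cons && shiftA == 0) continue;  // absorbed without change: existing overlaps stay valid
    for (int j = 0; j < n; ++j) {
      if (j == bi || !ctg[j].alive) continue;
      P(bi, j) = best_overlap(bi < j ? A.cons : ctg[j].cons,
                              bi < j ? ctg[j].cons : A.cons,
                              min_overlap, max_mismatch_rate, mismatch_penalty);
      // best_overlap(a,b) is orientation-complete, but keep (min,max) argument
      // order consistent with storage so types 1/2 mean the same thing.
    }
  }

  // collect and sort surviving contigs
  std::vector<int> order;
  for (int i = 0; i < n; ++i) if (ctg[i].alive) order.push_back(i);
  std::sort(order.begin(), order.end(), [&](int x, int y) {
    if (ctg[x].cons.size() != ctg[y].cons.size())
      return ctg[x].cons.size() > ctg[y].cons.size();
    return ctg[x].id < ctg[y].id;
  });
  std::vector<int> slot2out(n, 0);
  CharacterVector cons_out(order.size());
  IntegerVector nreads(order.size());
  for (size_t k = 0; k < order.size(); ++k) {
    slot2out[order[k]] = (int)k + 1;
    cons_out[k] = ctg[order[k]].cons;
    double tot = 0; for (const Member& m : ctg[order[k]].mem) tot += m.w;
    nreads[k] = (int)(tot + 0.5);
  }
  IntegerVector assign(N);
  for (int i = 0; i < N; ++i) assign[i] = slot2out[uid2slot[rep[i]]];
  return List::create(_["contigs"] = cons_out, _["assignment"] = assign,
                      _["n_reads"] = nreads);
}

// ---------------------------------------------------------------------------
// k-mer seeded ungapped read mapper
// ---------------------------------------------------------------------------

static inline int base2bits(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Map each read to its best contig location (either strand) by exact k-mer
// seeding followed by full-length ungapped identity.  Columns (per read):
// contig (1-based, 0 = unmapped), start (1-based leftmost contig coordinate,
// may be < 1 if the read overhangs), strand (1 fwd, -1 rev), identity
// (fraction over the full read length; overhanging and N columns count as
// mismatches).  Ties: identity desc, contig asc, start asc, fwd before rev.
// [[Rcpp::export(name = ".map_reads_cpp")]]
NumericMatrix map_reads_cpp(CharacterVector reads, CharacterVector contigs,
                            int k, double min_identity) {
  int nc = contigs.size(), nr = reads.size();
  std::vector<std::string> C(nc);
  for (int i = 0; i < nc; ++i) C[i] = as<std::string>(contigs[i]);

  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int ci = 0; ci < nc; ++ci) {
    const std::string& s = C[ci];
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx[h].push_back({ci, p - k + 1});
    }
  }

  NumericMatrix out(nr, 4);
  colnames(out) = CharacterVector::create("contig", "start", "strand", "identity");
  for (int ri = 0; ri < nr; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = (int)fwd.size();
    double best_id = -1; int best_c = -1, best_start = 0, best_strand = 0;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? fwd : revcomp_str(fwd);
      if ((int)q.size() < k) continue;
      // candidate (contig, diagonal) set from seed hits
      std::vector<std::pair<int, int>> cand;
      uint64_t h = 0; int run = 0;
      for (int p = 0; p < L; ++p) {
        int b = base2bits(q[p]);
        if (b < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          auto it = idx.find(h);
          if (it == idx.end()) continue;
          int qpos = p - k + 1;
          for (const auto& hit : it->second)
            cand.push_back({hit.first, hit.second - qpos});
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (const auto& cd : cand) {
        const std::string& s = C[cd.first];
        int diag = cd.second;  // contig coordinate of read position 0
        int match = 0;
        for (int p = 0; p < L; ++p) {
          int cp = diag + p;
          if (cp < 0 || cp >= (int)s.size()) continue;
          if (s[cp] == q[p] && q[p] != 'N') ++match;
        }
        double id = (double)match / L;
        bool better = false;
        if (id > best_id) better = true;
        else if (id == best_id) {
          if (cd.first < best_c) better = true;
          else if (cd.first == best_c) {
            if (diag + 1 < best_start) better = true;
            else if (diag + 1 == best_start && strand == 0 && best_strand < 0) better = true;
          }
        }
        if (better) {
          best_id = id; best_c = cd.first; best_start = diag + 1;
          best_strand = strand == 0 ? 1 : -1;
        }
      }
    }
    if (best_id >= min_identity) {
      out(ri, 0) = best_c + 1; out(ri, 1) = best_start;
      out(ri, 2) = best_strand; out(ri, 3) = best_id;
    } else {
      out(ri, 0) = 0; out(ri, 1) = NA_REAL; out(ri, 2) = 0;
      out(ri, 3) = best_id < 0 ? NA_REAL : best_id;
    }
  }
  return out;
}
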