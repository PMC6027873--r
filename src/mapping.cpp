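// Hot paths of the consensus pipeline: tandem-repeat period detection and
// rotation-aware fragment mapping. Bases are coded A=1, C=2, G=3, T=4;
// masked/absent positions are NA (R) and arrive here as NA_INTEGER.
// K-mers over {1..4} pack two bits per base into a uint64, so seeds up to
// 31-mers need no string hashing.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

struct SeedIndex {
  int k;
  int k_rescue;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > map_k;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > map_r;
  std::vector<std::vector<int> > tx; // transcript codes, 1..4
};

static bool pack_kmer(const int* v, int k, uint64_t& key) {
  uint64_t x = 0;
  for (int i = 0; i < k; ++i) {
    int b = v[i];
    if (b == NA_INTEGER || b < 1 || b > 4) return false;
    x = (x << 2) | (uint64_t)(b - 1);
  }
  key = x;
  return true;
}

static void index_tier(
    std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >& m,
    const std::vector<std::vector<int> >& tx, int k) {
  for (size_t t = 0; t < tx.size(); ++t) {
    const std::vector<int>& s = tx[t];
    int n = (int)s.size() - k + 1;
    for (int i = 0; i < n; ++i) {
      uint64_t key;
      if (pack_kmer(&s[i], k, key))
        m[key].push_back(std::make_pair((int)t, i)); // 0-based ref pos
    }
  }
}

// [[Rcpp::export]]
SEXP build_index_cpp(List tx_codes, int k, int k_rescue) {
  XPtr<SeedIndex> idx(new SeedIndex(), true);
  idx->k = k;
  idx->k_rescue = k_rescue;
  idx->tx.resize(tx_codes.size());
  for (int t = 0; t < tx_codes.size(); ++t) {
    IntegerVector v = tx_codes[t];
    idx->tx[t].assign(v.begin(), v.end());
  }
  index_tier(idx->map_k, idx->tx, k);
  if (k_rescue > 0) index_tier(idx->map_r, idx->tx, k_rescue);
  return idx;
}

// Period detection: for each read (rows of an int matrix, NA allowed),
// return the period in [min_p, max_p] maximizing mean identity between
// positions i and i+p, or NA if identity < min_ident or the read is
// shorter than two minimum-length repeats.
// [[Rcpp::export]]
IntegerVector detect_periods_cpp(IntegerMatrix M, int min_p, int max_p,
                                 double min_ident) {
  int n = M.nrow(), W = M.ncol();
  IntegerVector out(n, NA_INTEGER);
  std::vector<int> row(W);
  for (int r = 0; r < n; ++r) {
    int width = 0;
    for (int j = 0; j < W; ++j) {
      row[j] = M(r, j);
      if (row[j] != NA_INTEGER) ++width;
    }
    if (width < 2 * min_p) continue;
    double best_id = -1.0;
    int best_p = NA_INTEGER;
    for (int p = min_p; p <= max_p; ++p) {
      int ncmp = 0, neq = 0;
      for (int j = 0; j + p < W; ++j) {
        int a = row[j], b = row[j + p];
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        ++ncmp;
        if (a == b) ++neq;
      }
      if (ncmp < p) continue; // need at least one full second copy
      double ident = (double)neq / ncmp;
      if (ident > best_id) {
        best_id = ident;
        best_p = p;
      }
    }
    if (best_id >= min_ident) out[r] = best_p;
  }
  return out;
}

struct RotFit {
  long score;
  int j;       // junction, 1..p+1 (R convention)
  int s;       // 1-based window start
  int config;  // 0 = B, 1 = C
  int d0;
  int t;       // transcript (0-based)
  std::vector<int> optB, optC; // equally-scoring junction placements
};

// cons: codes with 0 = masked. R transcript codes. d0 such that branch A
// maps consensus i (1-based) to reference d0 + i (1-based).
static bool score_rotation_cpp(const std::vector<int>& cons,
                               const std::vector<int>& R, int d0, int p,
                               RotFit& fit) {
  int Lr = (int)R.size();
  std::vector<long> SA(p + 1, 0), SB(p + 1, 0), SC(p + 1, 0);
  for (int i = 1; i <= p; ++i) {
    int c = cons[i - 1];
    int mA = 0, mB = 0, mC = 0;
    if (c > 0) {
      int iA = d0 + i, iB = iA - p, iC = iA + p;
      if (iA >= 1 && iA <= Lr && R[iA - 1] == c) mA = 1;
      if (iB >= 1 && iB <= Lr && R[iB - 1] == c) mB = 1;
      if (iC >= 1 && iC <= Lr && R[iC - 1] == c) mC = 1;
    }
    SA[i] = SA[i - 1] + mA;
    SB[i] = SB[i - 1] + mB;
    SC[i] = SC[i - 1] + mC;
  }
  // config B: prefix branch A, suffix branch B; s = d0 + j - p
  // config C: prefix branch C, suffix branch A; s = d0 + j
  // Tie-break as in the reference semantics: smallest j within a config,
  // config B preferred over C on equal scores.
  long bestB = -1, bestC = -1;
  int jB = -1, jC = -1;
  for (int j = 1; j <= p + 1; ++j) {
    int sB = d0 + j - p;
    if (sB >= 1 && sB + p - 1 <= Lr) {
      long sc = SA[j - 1] + (SB[p] - SB[j - 1]);
      if (sc > bestB) { bestB = sc; jB = j; }
    }
    int sC = d0 + j;
    if (sC >= 1 && sC + p - 1 <= Lr) {
      long sc = SC[j - 1] + (SA[p] - SA[j - 1]);
      if (sc > bestC) { bestC = sc; jC = j; }
    }
  }
  if (bestB < 0 && bestC < 0) return false;
  long best;
  int bj, bcfg;
  if (bestB >= bestC) { best = bestB; bj = jB; bcfg = 0; }
  else { best = bestC; bj = jC; bcfg = 1; }
  fit.score = best;
  fit.j = bj;
  fit.config = bcfg;
  fit.s = (bcfg == 0) ? d0 + bj - p : d0 + bj;
  fit.d0 = d0;
  fit.optB.clear();
  fit.optC.clear();
  for (int j = 1; j <= p + 1; ++j) {
    int sB = d0 + j - p;
    if (sB >= 1 && sB + p - 1 <= Lr &&
        SA[j - 1] + (SB[p] - SB[j - 1]) == best)
      fit.optB.push_back(j);
    int sC = d0 + j;
    if (sC >= 1 && sC + p - 1 <= Lr &&
        SC[j - 1] + (SA[p] - SA[j - 1]) == best)
      fit.optC.push_back(j);
  }
  return true;
}

static inline int rot_refidx(int config, int j, int d0, int p, int i) {
  if (config == 0) return (i < j) ? d0 + i : d0 + i - p;
  return (i < j) ? d0 + i + p : d0 + i;
}

// any k mismatches within a window of `win` consensus positions?
static bool mismatch_cluster_cpp(const std::vector<int>& pos, int win, int k) {
  int n = (int)pos.size();
  if (n < k) return false;
  for (int i = 0; i + k - 1 < n; ++i)
    if (pos[i + k - 1] - pos[i] < win) return true;
  return false;
}

struct GapFit {
  long score;
  int type; // 0 = del, 1 = ins
  int g;
  int s;
  bool found;
};

// single-base-gap scan of U (codes, 0 = masked) against R near start s0;
// mirrors the R implementation including its index guards
static void score_gapped_cpp(const std::vector<int>& U,
                             const std::vector<int>& R, int s0, int p,
                             GapFit& best) {
  int Lr = (int)R.size();
  for (int ds = -1; ds <= 1; ++ds) {
    int s = s0 + ds;
    // deletion: U[1..g] ~ R[s-1+i], deleted base R[s+g], U[g+1..p] ~ R[s+i]
    if (s >= 1 && s + p <= Lr) {
      std::vector<long> S1(p + 1, 0), S2(p + 1, 0);
      for (int i = 1; i <= p; ++i) {
        int u = U[i - 1];
        S1[i] = S1[i - 1] + ((u > 0 && R[s - 1 + i - 1] == u) ? 1 : 0);
        S2[i] = S2[i - 1] + ((u > 0 && R[s + i - 1] == u) ? 1 : 0);
      }
      for (int g = 1; g <= p - 1; ++g) {
        long sc = S1[g] + (S2[p] - S2[g]);
        if (!best.found || sc > best.score) {
          best.found = true;
          best.score = sc;
          best.type = 0;
          best.g = g;
          best.s = s;
        }
      }
    }
    // insertion: U[g] extra; U[i<g] ~ R[s-1+i], U[i>g] ~ R[s-2+i]
    if (s >= 1 && s + p - 2 <= Lr) {
      std::vector<long> S1(p + 1, 0), S2(p + 1, 0);
      for (int i = 1; i <= p; ++i) {
        int u = U[i - 1];
        int i1 = s - 1 + i, i2 = s - 2 + i;
        S1[i] = S1[i - 1] +
          ((u > 0 && i1 >= 1 && i1 <= Lr && R[i1 - 1] == u) ? 1 : 0);
        S2[i] = S2[i - 1] +
          ((u > 0 && i2 >= 1 && i2 <= Lr && R[i2 - 1] == u) ? 1 : 0);
      }
      for (int g = 2; g <= p - 1; ++g) {
        long sc = S1[g - 1] + (S2[p] - S2[g]);
        if (!best.found || sc > best.score) {
          best.found = true;
          best.score = sc;
          best.type = 1;
          best.g = g;
          best.s = s;
        }
      }
    }
  }
}

// status codes
enum MapStatus { ST_OK = 0, ST_TOO_SHORT = 1, ST_UNMAPPED = 2,
                 ST_AMBIGUOUS = 3, ST_DISCARDED_INDEL = 4 };

struct MapResult {
  int status;
  int t;
  std::vector<int> refidx;   // 1-based, 0 where none
  std::vector<bool> compared;
  std::vector<bool> match;
  bool has_indel;
  int indel_type; // 0 del, 1 ins
  int indel_refpos; // 1-based
  int indel_base;   // 0 if none
};

static const std::vector<std::pair<int, int> >* lookup(
    const std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >& m,
    uint64_t key) {
  std::unordered_map<uint64_t,
                     std::vector<std::pair<int, int> > >::const_iterator it =
    m.find(key);
  return (it == m.end()) ? 0 : &it->second;
}

static void map_one(const std::vector<int>& cons, const SeedIndex& idx,
                    int max_mm, int min_called, MapResult& out) {
  int p = (int)cons.size();
  int n_called = 0;
  for (int i = 0; i < p; ++i)
    if (cons[i] > 0) ++n_called;
  if (n_called < min_called || p < idx.k) {
    out.status = ST_TOO_SHORT;
    return;
  }
  // circular seed scan over the doubled consensus
  std::vector<int> D(cons);
  D.insert(D.end(), cons.begin(),
           cons.begin() + std::min(p, idx.k - 1));
  const std::vector<std::pair<int, int> >* hits = 0;
  int seed_off = 0;
  for (int o = 1; o <= p; ++o) {
    if (o + idx.k - 1 > (int)D.size()) break;
    uint64_t key;
    if (!pack_kmer(&D[o - 1], idx.k, key)) continue;
    hits = lookup(idx.map_k, key);
    if (hits) { seed_off = o; break; }
  }
  if (!hits && idx.k_rescue > 0) {
    for (int o = 1; o <= p; ++o) {
      if (o + idx.k_rescue - 1 > (int)D.size()) break;
      uint64_t key;
      if (!pack_kmer(&D[o - 1], idx.k_rescue, key)) continue;
      hits = lookup(idx.map_r, key);
      if (hits) { seed_off = o; break; }
    }
  }
  if (!hits) {
    out.status = ST_UNMAPPED;
    return;
  }
  RotFit best;
  bool have = false;
  long second = -1;
  for (size_t h = 0; h < hits->size(); ++h) {
    int t = (*hits)[h].first;
    int q = (*hits)[h].second + 1; // 1-based
    RotFit fit;
    if (!score_rotation_cpp(cons, idx.tx[t], q - seed_off, p, fit)) continue;
    fit.t = t;
    if (!have || fit.score > best.score) {
      if (have) second = best.score;
      best = fit;
      have = true;
    } else if (fit.score > second) {
      second = fit.score;
    }
  }
  if (!have) {
    out.status = ST_UNMAPPED;
    return;
  }
  if (second == best.score) {
    out.status = ST_AMBIGUOUS;
    return;
  }
  const std::vector<int>& R = idx.tx[best.t];
  long mm = n_called - best.score;

  bool have_ungapped = false;
  MapResult ung;
  if (mm <= max_mm) {
    ung.status = ST_OK;
    ung.t = best.t;
    ung.refidx.assign(p, 0);
    ung.compared.assign(p, false);
    ung.match.assign(p, false);
    ung.has_indel = false;
    for (int i = 1; i <= p; ++i) {
      int ri = rot_refidx(best.config, best.j, best.d0, p, i);
      ung.refidx[i - 1] = ri;
      bool called = cons[i - 1] > 0;
      ung.compared[i - 1] = called;
      ung.match[i - 1] = called && ri >= 1 && ri <= (int)R.size() &&
        R[ri - 1] == cons[i - 1];
    }
    // mask mismatches whose coordinate differs among tied junctions
    if (best.optB.size() + best.optC.size() > 1) {
      for (int i = 1; i <= p; ++i) {
        if (!(ung.compared[i - 1] && !ung.match[i - 1])) continue;
        bool amb = false;
        for (size_t a = 0; a < best.optB.size() && !amb; ++a)
          if (rot_refidx(0, best.optB[a], best.d0, p, i) != ung.refidx[i - 1])
            amb = true;
        for (size_t a = 0; a < best.optC.size() && !amb; ++a)
          if (rot_refidx(1, best.optC[a], best.d0, p, i) != ung.refidx[i - 1])
            amb = true;
        if (amb) ung.compared[i - 1] = false;
      }
    }
    std::vector<int> mis;
    for (int i = 0; i < p; ++i)
      if (ung.compared[i] && !ung.match[i]) mis.push_back(i + 1);
    if (!mismatch_cluster_cpp(mis, 10, 3)) have_ungapped = true;
    if (have_ungapped && mm < 2) {
      out = ung;
      return;
    }
  }

  // gapped retry over every candidate junction and both block orders
  GapFit gap;
  gap.found = false;
  std::vector<int> best_ord;
  for (int j2 = 1; j2 <= p + 1; ++j2) {
    for (int cfg = 0; cfg <= 1; ++cfg) {
      if (cfg == 1 && j2 == 1) continue; // duplicate of (B, p+1)
      int s0 = (cfg == 0) ? best.d0 + j2 - p : best.d0 + j2;
      if (s0 + p < 1 || s0 > (int)R.size()) continue;
      std::vector<int> ord;
      ord.reserve(p);
      if (j2 <= p) {
        for (int i = j2; i <= p; ++i) ord.push_back(i);
        for (int i = 1; i < j2; ++i) ord.push_back(i);
      } else {
        for (int i = 1; i <= p; ++i) ord.push_back(i);
      }
      std::vector<int> U(p);
      for (int i = 0; i < p; ++i) U[i] = cons[ord[i] - 1];
      GapFit cand;
      cand.found = false;
      score_gapped_cpp(U, R, s0, p, cand);
      if (cand.found && (!gap.found || cand.score > gap.score)) {
        gap = cand;
        best_ord = ord;
      }
    }
  }
  if (!gap.found) {
    if (have_ungapped) out = ung; else out.status = ST_DISCARDED_INDEL;
    return;
  }
  std::vector<int> U(p);
  for (int i = 0; i < p; ++i) U[i] = cons[best_ord[i] - 1];
  std::vector<int> refidx_u(p, 0);
  std::vector<bool> compared_u(p, false), match_u(p, false);
  int indel_refpos = 0, indel_base = 0;
  if (gap.type == 0) { // deletion
    for (int i = 1; i <= p; ++i)
      refidx_u[i - 1] = (i <= gap.g) ? gap.s - 1 + i : gap.s + i;
    for (int i = 0; i < p; ++i) compared_u[i] = U[i] > 0;
    indel_refpos = gap.s + gap.g;
  } else { // insertion
    for (int i = 1; i <= p; ++i)
      refidx_u[i - 1] = (i < gap.g) ? gap.s - 1 + i : gap.s - 2 + i;
    refidx_u[gap.g - 1] = 0;
    for (int i = 0; i < p; ++i)
      compared_u[i] = U[i] > 0 && (i + 1) != gap.g;
    if (U[gap.g - 1] <= 0) {
      if (have_ungapped) out = ung; else out.status = ST_DISCARDED_INDEL;
      return;
    }
    indel_refpos = gap.s - 1 + gap.g;
    indel_base = U[gap.g - 1];
  }
  long mm2 = 0;
  std::vector<int> mis2;
  for (int i = 0; i < p; ++i) {
    if (!compared_u[i]) continue;
    int ri = refidx_u[i];
    if (ri < 1 || ri > (int)R.size()) {
      compared_u[i] = false;
      continue;
    }
    match_u[i] = R[ri - 1] == U[i];
    if (!match_u[i]) {
      ++mm2;
      mis2.push_back(i + 1);
    }
  }
  if (mm2 > max_mm || mm2 > mm - 3 || mismatch_cluster_cpp(mis2, 10, 3)) {
    if (have_ungapped) out = ung; else out.status = ST_DISCARDED_INDEL;
    return;
  }
  // translate back to consensus coordinates
  out.status = ST_OK;
  out.t = best.t;
  out.refidx.assign(p, 0);
  out.compared.assign(p, false);
  out.match.assign(p, false);
  for (int u = 0; u < p; ++u) {
    int ci = best_ord[u]; // consensus index (1-based)
    out.refidx[ci - 1] = refidx_u[u];
    out.compared[ci - 1] = compared_u[u];
    out.match[ci - 1] = match_u[u];
  }
  out.has_indel = true;
  out.indel_type = gap.type;
  out.indel_refpos = indel_refpos;
  out.indel_base = indel_base;
}

// Map a batch of consensus fragments and accumulate events/denominators.
// cons_list: list of integer vectors (codes, NA = masked).
// Returns list(status, counts, events (vectors), n_b, dinuc, coverage).
// [[Rcpp::export]]
List map_fragments_cpp(List cons_list, SEXP index_ptr, int max_mm,
                       int min_called) {
  XPtr<SeedIndex> idx(index_ptr);
  int nf = cons_list.size();
  IntegerVector status(nf);
  // accumulators
  std::vector<double> n_b(4, 0.0);
  std::vector<double> dinuc(16, 0.0); // [prev + 4*(focal-1)] 0-based
  std::vector<std::vector<int> > cov(idx->tx.size());
  for (size_t t = 0; t < idx->tx.size(); ++t)
    cov[t].assign(idx->tx[t].size(), 0);
  std::vector<int> ev_frag, ev_t, ev_pos, ev_ref, ev_obs;
  std::vector<int> ev_type; // 0 sub, 1 ins, 2 del

  std::vector<int> cons;
  for (int f = 0; f < nf; ++f) {
    IntegerVector cv = cons_list[f];
    cons.assign(cv.size(), 0);
    for (int i = 0; i < cv.size(); ++i)
      cons[i] = (cv[i] == NA_INTEGER) ? 0 : cv[i];
    MapResult res;
    map_one(cons, *idx, max_mm, min_called, res);
    status[f] = res.status;
    if (res.status != ST_OK) continue;
    const std::vector<int>& R = idx->tx[res.t];
    int p = (int)cons.size();
    for (int i = 0; i < p; ++i) {
      if (!res.compared[i]) continue;
      int ri = res.refidx[i];
      int rb = R[ri - 1];
      n_b[rb - 1] += 1.0;
      cov[res.t][ri - 1] += 1;
      if (ri >= 2) dinuc[(R[ri - 2] - 1) + 4 * (rb - 1)] += 1.0;
      if (!res.match[i]) {
        ev_frag.push_back(f + 1);
        ev_t.push_back(res.t + 1);
        ev_pos.push_back(ri - 1); // 0-based
        ev_ref.push_back(rb);
        ev_obs.push_back(cons[i]);
        ev_type.push_back(0);
      }
    }
    if (res.has_indel) {
      ev_frag.push_back(f + 1);
      ev_t.push_back(res.t + 1);
      if (res.indel_type == 0) { // deletion
        ev_pos.push_back(res.indel_refpos - 1);
        ev_ref.push_back(R[res.indel_refpos - 1]);
        ev_obs.push_back(NA_INTEGER);
        ev_type.push_back(2);
      } else {
        // 0-based reference position immediately 3' of the inserted base
        ev_pos.push_back(res.indel_refpos - 1);
        ev_ref.push_back(res.indel_refpos >= 1 &&
                         res.indel_refpos <= (int)R.size()
                         ? R[res.indel_refpos - 1] : NA_INTEGER);
        ev_obs.push_back(res.indel_base);
        ev_type.push_back(1);
      }
    }
  }
  List coverage(idx->tx.size());
  for (size_t t = 0; t < idx->tx.size(); ++t)
    coverage[t] = IntegerVector(cov[t].begin(), cov[t].end());
  return List::create(
    _["status"] = status,
    _["ev_frag"] = IntegerVector(ev_frag.begin(), ev_frag.end()),
    _["ev_t"] = IntegerVector(ev_t.begin(), ev_t.end()),
    _["ev_pos"] = IntegerVector(ev_pos.begin(), ev_pos.end()),
    _["ev_ref"] = IntegerVector(ev_ref.begin(), ev_ref.end()),
    _["ev_obs"] = IntegerVector(ev_obs.begin(), ev_obs.end()),
    _["ev_type"] = IntegerVector(ev_type.begin(), ev_type.end()),
    _["n_b"] = NumericVector(n_b.begin(), n_b.end()),
    _["dinuc"] = NumericVector(dinuc.begin(), dinuc.end()),
    _["coverage"] = coverage);
}
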