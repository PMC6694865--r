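#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <cmath>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// A base matches only itself, and only for the four unambiguous bases:
// N (and any stray IUPAC code) on the read side matches nothing, not even N.
static inline bool base_match(char a, char b) {
    switch (a) {
    case 'A': case 'C': case 'G': case 'T': break;
    default: return false;
    }
    return a == b;
}

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    }
    return -1;
}

// IUPAC nucleotide code -> 4-bit base set (A=1, C=2, G=4, T=8).
static inline int iupac_bits(char c) {
    switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;  case 'W': return 9;
    case 'K': return 12; case 'M': return 3;  case 'B': return 14; case 'D': return 13;
    case 'H': return 11; case 'V': return 7;  case 'N': return 15;
    }
    return 0;
}

// ---------------------------------------------------------------------------
// Global alignment, unit mismatch/gap costs.  Among minimum-cost alignments
// the one with the most matched identical positions is taken; the pair
// (cost, matches) is returned.  Two-row DP, no traceback needed.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_global_cost_matches(std::string a, std::string b) {
    const int la = a.size(), lb = b.size();
    if (la < 2047 && lb < 2047) {
        // Lexicographic (cost asc, matches desc) collapses onto the single
        // additive key K = 2048*cost - matches (|matches delta| < 2048), so
        // the DP is a plain 3-way min.
        const int GAP = 2048, MISM = 2048, MATCH = -1;
        std::vector<int> prev(lb + 1), cur(lb + 1);
        for (int j = 0; j <= lb; ++j) prev[j] = j * GAP;
        for (int i = 1; i <= la; ++i) {
            cur[0] = i * GAP;
            const char ai = a[i - 1];
            for (int j = 1; j <= lb; ++j) {
                int d = prev[j - 1] + (base_match(ai, b[j - 1]) ? MATCH : MISM);
                int u = prev[j] + GAP;
                int l = cur[j - 1] + GAP;
                int v = d < u ? d : u;
                cur[j] = v < l ? v : l;
            }
            std::swap(prev, cur);
        }
        int K = prev[lb];
        int cost = (K + 2047) >> 11;
        int matches = 2048 * cost - K;
        return IntegerVector::create(_["cost"] = cost, _["matches"] = matches);
    }
    std::vector<int> pc(lb + 1), pm(lb + 1), cc(lb + 1), cm(lb + 1);
    for (int j = 0; j <= lb; ++j) { pc[j] = j; pm[j] = 0; }
    for (int i = 1; i <= la; ++i) {
        cc[0] = i; cm[0] = 0;
        for (int j = 1; j <= lb; ++j) {
            bool mt = base_match(a[i - 1], b[j - 1]);
            int c = pc[j - 1] + (mt ? 0 : 1), m = pm[j - 1] + (mt ? 1 : 0);
            int cu = pc[j] + 1, mu = pm[j];
            if (cu < c || (cu == c && mu > m)) { c = cu; m = mu; }
            int cl = cc[j - 1] + 1, ml = cm[j - 1];
            if (cl < c || (cl == c && ml > m)) { c = cl; m = ml; }
            cc[j] = c; cm[j] = m;
        }
        std::swap(pc, cc); std::swap(pm, cm);
    }
    return IntegerVector::create(_["cost"] = pc[lb], _["matches"] = pm[lb]);
}

// ---------------------------------------------------------------------------
// Myers/Hyyro bit-parallel global edit distance (block version, as in edlib's
// column recurrence).  Used as a prescreen bound in clustering: on a minimum-
// cost unit alignment, matches <= (|a| + |b| - distance) / 2.
// ---------------------------------------------------------------------------

static int myers_distance(const std::string& P, const std::string& T) {
    const int m = (int)P.size(), n = (int)T.size();
    if (m == 0) return n;
    if (n == 0) return m;
    const int W = (m + 63) / 64;
    std::vector<uint64_t> Peq(4 * W, 0), Pv(W, ~0ULL), Mv(W, 0);
    for (int i = 0; i < m; ++i) {
        int c = base_code(P[i]);
        if (c >= 0) Peq[(size_t)c * W + i / 64] |= 1ULL << (i % 64);
    }
    const int last = W - 1;
    const uint64_t mbit = 1ULL << ((m - 1) % 64);
    int score = m;
    for (int j = 0; j < n; ++j) {
        const int tc = base_code(T[j]);
        int hin = 1;  // global alignment: top row of the matrix increases by 1 per column
        for (int w = 0; w < W; ++w) {
            uint64_t Eq = (tc >= 0) ? Peq[(size_t)tc * W + w] : 0ULL;
            uint64_t Xv = Eq | Mv[w];
            if (hin < 0) Eq |= 1ULL;
            uint64_t Xh = (((Eq & Pv[w]) + Pv[w]) ^ Pv[w]) | Eq;
            uint64_t Ph = Mv[w] | ~(Xh | Pv[w]);
            uint64_t Mh = Pv[w] & Xh;
            if (w == last) {
                if (Ph & mbit) ++score;
                else if (Mh & mbit) --score;
            }
            int hout = 0;
            if (Ph & 0x8000000000000000ULL) hout = 1;
            else if (Mh & 0x8000000000000000ULL) hout = -1;
            Ph <<= 1; Mh <<= 1;
            if (hin < 0) Mh |= 1ULL;
            else if (hin > 0) Ph |= 1ULL;
            Pv[w] = Mh | ~(Xv | Ph);
            Mv[w] = Ph & Xv;
            hin = hout;
        }
    }
    return score;
}

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
    return myers_distance(a, b);
}

// Percent identity of `s` to each representative; identity is
// 100 * matches / min(length).  With `prescreen` on, representatives whose
// identity provably cannot reach `threshold` are skipped and the (sub-
// threshold) upper bound is reported in place of the exact value.
// [[Rcpp::export]]
NumericVector cpp_identity_to_reps(std::string s, CharacterVector reps,
                                   double threshold, bool prescreen) {
    int n = reps.size();
    NumericVector out(n);
    int ls = s.size();
    for (int k = 0; k < n; ++k) {
        std::string r = as<std::string>(reps[k]);
        int lr = r.size();
        int shorter = std::min(ls, lr);
        if (shorter == 0) { out[k] = 0.0; continue; }
        if (prescreen) {
            int e = myers_distance(s, r);
            double ub = 100.0 * std::min((double)shorter, (ls + lr - e) / 2.0) / shorter;
            if (ub < threshold) { out[k] = ub; continue; }
        }
        IntegerVector cm = cpp_global_cost_matches(s, r);
        out[k] = 100.0 * cm[1] / shorter;
    }
    return out;
}

// Best representative for greedy clustering.  Identity of a read to a
// representative is taken over both read strands (the clusterer is
// strand-aware, as the downstream orientation-adjustment step presumes).
// Returns the (1-based) index of the representative with the highest
// identity >= threshold (ties: lowest index) and that identity, or index 0
// when none qualifies.  The Myers bound is used to skip strand/representative
// combinations that provably cannot beat the current best (or reach the
// threshold); the outcome is identical to an exhaustive scan.
// [[Rcpp::export]]
NumericVector cpp_best_rep(std::string s, std::string s_rc, CharacterVector reps,
                           double threshold, bool prescreen) {
    const int n = reps.size();
    const int ls = (int)s.size();
    const std::string* strands[2] = { &s, &s_rc };
    std::vector<std::string> rs(n);
    std::vector<double> ub(2 * n);      // candidate c = 2*k + strand
    std::vector<int> ord;
    ord.reserve(2 * n);
    for (int k = 0; k < n; ++k) {
        rs[k] = as<std::string>(reps[k]);
        int shorter = std::min(ls, (int)rs[k].size());
        for (int st = 0; st < 2; ++st) {
            int c = 2 * k + st;
            if (shorter == 0) { ub[c] = -1.0; continue; }
            if (prescreen) {
                int e = myers_distance(*strands[st], rs[k]);
                ub[c] = 100.0 * std::min((double)shorter,
                                         (ls + (double)rs[k].size() - e) / 2.0) / shorter;
            } else {
                ub[c] = 200.0;  // no bound: every candidate is examined
            }
            ord.push_back(c);
        }
    }
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        if (ub[a] != ub[b]) return ub[a] > ub[b];
        return a < b;
    });
    double best_ident = -1.0;
    int best_k = -1;
    for (size_t idx = 0; idx < ord.size(); ++idx) {
        int c = ord[idx], k = c / 2, st = c % 2;
        if (ub[c] < threshold) continue;
        if (best_k >= 0) {
            if (ub[c] < best_ident) continue;
            if (ub[c] == best_ident && k >= best_k) continue;
        }
        IntegerVector cm = cpp_global_cost_matches(*strands[st], rs[k]);
        int shorter = std::min(ls, (int)rs[k].size());
        double ident = 100.0 * cm[1] / shorter;
        if (ident < threshold) continue;
        if (ident > best_ident || (ident == best_ident && k < best_k)) {
            best_ident = ident;
            best_k = k;
        }
    }
    if (best_k < 0) return NumericVector::create(0, NA_REAL);
    return NumericVector::create(best_k + 1, best_ident);
}

// ---------------------------------------------------------------------------
// Error-tolerant primer matching: semi-global edit-distance search of an
// IUPAC primer in a read.  Free read ends; the primer may overhang a read
// end, in which case only the in-read part counts toward the matched length.
// Hit choice: fewest edits, then leftmost read start, then longest matched
// primer stretch, then smallest read end.  Per-cell state is the
// lexicographic minimum of (cost, start_col, start_row), which is composable
// along paths because cost is additive and the tie keys are start properties.
// ---------------------------------------------------------------------------

struct PrimerHitC {
    bool found;
    int edits, start, end, prim_start, prim_end;
};

// Candidate selection order: fewest edits, leftmost read start, longest
// matched primer stretch; remaining exact ties resolve to the largest read
// end, then the leftmost primer window.
static void primer_consider(PrimerHitC& best, double max_error_rate,
                            int min_overlap, int cost, int s, int e,
                            int a, int b) {
    int matched = b - a;
    if (matched < min_overlap) return;
    if (e - s < min_overlap) return;  // the overlap must exist read-side too
    if (cost > (int)std::floor(max_error_rate * matched)) return;
    if (!best.found) {
        best.found = true;
        best.edits = cost; best.start = s; best.end = e;
        best.prim_start = a; best.prim_end = b;
        return;
    }
    int mlbest = best.prim_end - best.prim_start;
    bool better =
        cost < best.edits ||
        (cost == best.edits && (s < best.start ||
         (s == best.start && (matched > mlbest ||
          (matched == mlbest && (e > best.end ||
           (e == best.end && a < best.prim_start)))))));
    if (better) {
        best.edits = cost; best.start = s; best.end = e;
        best.prim_start = a; best.prim_end = b;
    }
}

// Semi-global DP with the primer anchored at row 0 (no 5' primer overhang):
// per cell only (cost, leftmost start) is needed, because the matched
// length is fixed by the end cell.  Reports candidates ending at the last
// primer row (full primer window) and, optionally, at the last text column
// (primer 3' end overhanging the text).
static void primer_dp_anchored(const std::vector<int>& pbits,
                               const std::vector<int>& tbits,
                               bool report_text_end,
                               std::vector<int>& end_cost_row,   // (m,j) j=0..n
                               std::vector<int>& end_sc_row,
                               std::vector<int>& end_cost_col,   // (i,n) i=0..m
                               std::vector<int>& end_sc_col) {
    const int m = (int)pbits.size(), n = (int)tbits.size();
    std::vector<int> pc(n + 1), ps(n + 1), cc(n + 1), cs(n + 1);
    for (int j = 0; j <= n; ++j) { pc[j] = 0; ps[j] = j; }
    end_cost_col.assign(m + 1, INT_MAX); end_sc_col.assign(m + 1, 0);
    if (report_text_end) { end_cost_col[0] = pc[n]; end_sc_col[0] = ps[n]; }
    for (int i = 1; i <= m; ++i) {
        cc[0] = i; cs[0] = 0;
        for (int j = 1; j <= n; ++j) {
            bool mt = (pbits[i - 1] & tbits[j - 1]) != 0;
            int c = pc[j - 1] + (mt ? 0 : 1), s = ps[j - 1];
            int cu = pc[j] + 1;
            if (cu < c || (cu == c && ps[j] < s)) { c = cu; s = ps[j]; }
            int cl = cc[j - 1] + 1;
            if (cl < c || (cl == c && cs[j - 1] < s)) { c = cl; s = cs[j - 1]; }
            cc[j] = c; cs[j] = s;
        }
        if (report_text_end) { end_cost_col[i] = cc[n]; end_sc_col[i] = cs[n]; }
        std::swap(pc, cc); std::swap(ps, cs);
    }
    end_cost_row = pc; end_sc_row = ps;
}

static PrimerHitC find_primer_one(const std::string& text, const std::string& primer,
                                  double max_error_rate, int min_overlap) {
    const int m = (int)primer.size(), n = (int)text.size();
    std::vector<int> pbits(m), tbits(n);
    for (int i = 0; i < m; ++i) pbits[i] = iupac_bits(primer[i]);
    for (int j = 0; j < n; ++j) {
        char c = text[j];
        tbits[j] = (c == 'A' || c == 'C' || c == 'G' || c == 'T') ? iupac_bits(c) : 0;
    }
    PrimerHitC best; best.found = false;
    best.edits = INT_MAX; best.start = INT_MAX; best.end = -1;
    best.prim_start = 0; best.prim_end = 0;

    std::vector<int> er, es, ec, esc;
    // forward pass: primer windows starting at its 5' end (a = 0)
    primer_dp_anchored(pbits, tbits, true, er, es, ec, esc);
    for (int j = 0; j <= n; ++j) {
        primer_consider(best, max_error_rate, min_overlap, er[j], es[j], j, 0, m);
    }
    for (int i = min_overlap; i < m; ++i) {  // 3' overhang: b = i, e = n
        primer_consider(best, max_error_rate, min_overlap, ec[i], esc[i], n, 0, i);
    }
    // reversed pass: primer windows ending at its 3' end (b = m, a > 0, s = 0)
    std::vector<int> rp(pbits.rbegin(), pbits.rend());
    std::vector<int> rt(tbits.rbegin(), tbits.rend());
    primer_dp_anchored(rp, rt, true, er, es, ec, esc);
    for (int i = min_overlap; i < m; ++i) {
        // reversed (i, n) candidate: original a = m - i, b = m, s = 0, e = n - sc'
        primer_consider(best, max_error_rate, min_overlap, ec[i], 0, n - esc[i],
                        m - i, m);
    }
    // both-end overhang (a > 0 and b < m, so s = 0 and e = n): only possible
    // when the whole text is shorter than the primer window plus its budget
    if (n < m + (int)std::floor(max_error_rate * m)) {
        for (int a = 1; a < m; ++a) {
            std::vector<int> sub(pbits.begin() + a, pbits.end());
            std::vector<int> c2r, c2s, c2c, c2sc;
            // anchored at row 0 of the sub-primer, text start fixed at 0:
            // run the DP with a "text window = whole text" and read the
            // (r, n) cells; starts other than 0 are excluded afterwards.
            const int ms = (int)sub.size();
            std::vector<int> pc(n + 1), cc(n + 1);
            for (int j = 0; j <= n; ++j) pc[j] = j;  // s = 0: leading text costs
            std::vector<std::vector<int>> colcost(ms + 1);
            colcost[0] = pc;
            for (int r = 1; r <= ms; ++r) {
                cc[0] = r;
                for (int j = 1; j <= n; ++j) {
                    bool mt = (sub[r - 1] & tbits[j - 1]) != 0;
                    int c = pc[j - 1] + (mt ? 0 : 1);
                    c = std::min(c, pc[j] + 1);
                    c = std::min(c, cc[j - 1] + 1);
                    cc[j] = c;
                }
                std::swap(pc, cc);
                colcost[r] = pc;
            }
            for (int r = min_overlap; r < ms; ++r) {  // b = a + r < m
                primer_consider(best, max_error_rate, min_overlap,
                                colcost[r][n], 0, n, a, a + r);
            }
        }
    }
    return best;
}

// [[Rcpp::export]]
List cpp_find_primer(std::string text, std::string primer,
                     double max_error_rate, int min_overlap) {
    PrimerHitC h = find_primer_one(text, primer, max_error_rate, min_overlap);
    if (!h.found) return List::create(_["found"] = false);
    return List::create(_["found"] = true, _["edits"] = h.edits,
                        _["read_start"] = h.start, _["read_end"] = h.end,
                        _["primer_start"] = h.prim_start, _["primer_end"] = h.prim_end,
                        _["matched_len"] = h.prim_end - h.prim_start);
}

// One row per text; columns: found, edits, read_start, read_end,
// primer_start, primer_end, matched_len.
// [[Rcpp::export]]
IntegerMatrix cpp_find_primer_batch(CharacterVector texts, std::string primer,
                                    double max_error_rate, int min_overlap) {
    int n = texts.size();
    IntegerMatrix out(n, 7);
    for (int k = 0; k < n; ++k) {
        PrimerHitC h = find_primer_one(as<std::string>(texts[k]), primer,
                                       max_error_rate, min_overlap);
        out(k, 0) = h.found ? 1 : 0;
        out(k, 1) = h.found ? h.edits : NA_INTEGER;
        out(k, 2) = h.found ? h.start : NA_INTEGER;
        out(k, 3) = h.found ? h.end : NA_INTEGER;
        out(k, 4) = h.found ? h.prim_start : NA_INTEGER;
        out(k, 5) = h.found ? h.prim_end : NA_INTEGER;
        out(k, 6) = h.found ? h.prim_end - h.prim_start : NA_INTEGER;
    }
    colnames(out) = CharacterVector::create("found", "edits", "read_start", "read_end",
                                            "primer_start", "primer_end", "matched_len");
    return out;
}

// ---------------------------------------------------------------------------
// Global unit-cost alignment with traceback to a gapped string pair
// (used for center-star MSA construction).  Traceback prefers diagonal,
// then a gap in `b`, then a gap in `a` among cost ties.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pair_align_strings(std::string a, std::string b) {
    const int la = (int)a.size(), lb = (int)b.size();
    std::vector<uint16_t> cost((size_t)(la + 1) * (lb + 1));
    auto at = [lb](int i, int j) { return (size_t)i * (lb + 1) + j; };
    for (int j = 0; j <= lb; ++j) cost[at(0, j)] = j;
    for (int i = 1; i <= la; ++i) {
        cost[at(i, 0)] = i;
        for (int j = 1; j <= lb; ++j) {
            int c = cost[at(i - 1, j - 1)] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
            c = std::min(c, cost[at(i - 1, j)] + 1);
            c = std::min(c, cost[at(i, j - 1)] + 1);
            cost[at(i, j)] = (uint16_t)c;
        }
    }
    std::string ga, gb;
    ga.reserve(la + lb); gb.reserve(la + lb);
    int i = la, j = lb;
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            cost[at(i, j)] == cost[at(i - 1, j - 1)] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1)) {
            ga.push_back(a[i - 1]); gb.push_back(b[j - 1]); --i; --j;
        } else if (i > 0 && cost[at(i, j)] == cost[at(i - 1, j)] + 1) {
            ga.push_back(a[i - 1]); gb.push_back('-'); --i;
        } else {
            ga.push_back('-'); gb.push_back(b[j - 1]); --j;
        }
    }
    std::reverse(ga.begin(), ga.end());
    std::reverse(gb.begin(), gb.end());
    return List::create(_["a"] = ga, _["b"] = gb);
}

// ---------------------------------------------------------------------------
// Unit-cost global alignment error counts.  Minimizes cost = mismatches +
// gapped positions; among cost ties, fewest gaps.  The counts follow from
// (cost, gaps) alone: mismatches = cost - gaps, and the query/target length
// difference splits gaps into insertions and deletions.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_unit_cost_counts(std::string query, std::string target) {
    const int lq = (int)query.size(), lt = (int)target.size();
    std::vector<int> pc(lt + 1), pg(lt + 1), cc(lt + 1), cg(lt + 1);
    for (int j = 0; j <= lt; ++j) { pc[j] = j; pg[j] = j; }
    for (int i = 1; i <= lq; ++i) {
        cc[0] = i; cg[0] = i;
        for (int j = 1; j <= lt; ++j) {
            bool mt = base_match(query[i - 1], target[j - 1]);
            int c = pc[j - 1] + (mt ? 0 : 1), g = pg[j - 1];
            int cu = pc[j] + 1, gu = pg[j] + 1;
            if (cu < c || (cu == c && gu < g)) { c = cu; g = gu; }
            int cl = cc[j - 1] + 1, gl = cg[j - 1] + 1;
            if (cl < c || (cl == c && gl < g)) { c = cl; g = gl; }
            cc[j] = c; cg[j] = g;
        }
        std::swap(pc, cc); std::swap(pg, cg);
    }
    int cost = pc[lt], gaps = pg[lt];
    int mism = cost - gaps;
    int ins = (gaps + (lq - lt)) / 2;  // query bases absent from target
    int del = (gaps - (lq - lt)) / 2;  // target bases absent from query
    return IntegerVector::create(_["cost"] = cost, _["gaps"] = gaps,
                                 _["mismatches"] = mism,
                                 _["insertions"] = ins, _["deletions"] = del);
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment, linear gap penalty.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_local_align(std::string q, std::string s,
                     int match = 1, int mismatch = -2, int gap = -2) {
    const int lq = (int)q.size(), ls = (int)s.size();
    std::vector<int> H((size_t)(lq + 1) * (ls + 1), 0);
    auto at = [ls](int i, int j) { return (size_t)i * (ls + 1) + j; };
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= lq; ++i) {
        for (int j = 1; j <= ls; ++j) {
            int sc = base_match(q[i - 1], s[j - 1]) ? match : mismatch;
            int v = H[at(i - 1, j - 1)] + sc;
            v = std::max(v, H[at(i - 1, j)] + gap);
            v = std::max(v, H[at(i, j - 1)] + gap);
            v = std::max(v, 0);
            H[at(i, j)] = v;
            if (v > best) { best = v; bi = i; bj = j; }
        }
    }
    if (best == 0) {
        return List::create(_["score"] = 0, _["matches"] = 0, _["columns"] = 0,
                            _["q_start"] = 0, _["q_end"] = 0,
                            _["s_start"] = 0, _["s_end"] = 0);
    }
    int i = bi, j = bj, matches = 0, columns = 0;
    while (i > 0 && j > 0 && H[at(i, j)] > 0) {
        int sc = base_match(q[i - 1], s[j - 1]) ? match : mismatch;
        if (H[at(i, j)] == H[at(i - 1, j - 1)] + sc) {
            if (sc == match) ++matches;
            ++columns; --i; --j;
        } else if (H[at(i, j)] == H[at(i - 1, j)] + gap) {
            ++columns; --i;
        } else {
            ++columns; --j;
        }
    }
    return List::create(_["score"] = best, _["matches"] = matches, _["columns"] = columns,
                        _["q_start"] = i, _["q_end"] = bi,
                        _["s_start"] = j, _["s_end"] = bj);
}

// ---------------------------------------------------------------------------
// Reverse complement (IUPAC-aware).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
    static char comp[256];
    static bool init = false;
    if (!init) {
        for (int i = 0; i < 256; ++i) comp[i] = (char)i;
        const char* from = "ACGTRYSWKMBDHVNacgtryswkmbdhvn";
        const char* to   = "TGCAYRSWMKVHDBNtgcayrswmkvhdbn";
        for (int i = 0; from[i]; ++i) comp[(unsigned char)from[i]] = to[i];
        init = true;
    }
    int n = x.size();
    CharacterVector out(n);
    for (int k = 0; k < n; ++k) {
        std::string s = as<std::string>(x[k]);
        std::string r(s.rbegin(), s.rend());
        for (auto& c : r) c = comp[(unsigned char)c];
        out[k] = r;
    }
    return out;
}
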