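#include <Rcpp.h>
#include <climits>
#include <unordered_map>
#include <array>
using namespace Rcpp;

// Sentinel low score; kept far from INT_MIN so additions cannot wrap.
static const int NEG_INF = INT_MIN / 4;

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    case 'N': return 'N';
    case 'n': return 'n';
    default:  return 'N';
    }
}

// [[Rcpp::export]]
CharacterVector rc_cpp(CharacterVector x) {
    R_xlen_t n = x.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
        std::string s = as<std::string>(x[i]);
        std::string r(s.size(), 'N');
        for (size_t j = 0; j < s.size(); ++j)
            r[j] = comp(s[s.size() - 1 - j]);
        out[i] = r;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Canonical k-mer index: one hash table over all unitig k-mers, queried per
// read. Entries record (node, offset, strand) of the canonical form.

struct KEntry { int node, off, strand; };
typedef std::unordered_map<std::string, KEntry> KIndex;

static inline bool rc_into(const std::string &s, std::string &r) {
    r.resize(s.size());
    for (size_t j = 0; j < s.size(); ++j) {
        char c = comp(s[s.size() - 1 - j]);
        if (c == 'N') return false;
        r[j] = c;
    }
    return true;
}

// [[Rcpp::export]]
SEXP build_kindex_cpp(CharacterVector seqs, int k) {
    XPtr<KIndex> idx(new KIndex(), true);
    std::string rc;
    for (int u = 0; u < seqs.size(); ++u) {
        std::string s = as<std::string>(seqs[u]);
        int n = (int) s.size();
        for (int o = 0; o + k <= n; ++o) {
            std::string km = s.substr(o, k);
            if (!rc_into(km, rc)) stop("non-ACGT character in unitig sequence");
            bool fwd = km <= rc;
            const std::string &canon = fwd ? km : rc;
            KEntry e = {u + 1, o, fwd ? 1 : -1};
            auto ins = idx->emplace(canon, e);
            if (!ins.second) stop("duplicate k-mer across unitigs: invalid graph");
        }
    }
    return idx;
}

// [[Rcpp::export]]
int kindex_size_cpp(SEXP ptr) {
    XPtr<KIndex> idx(ptr);
    return (int) idx->size();
}

// Look up one k-mer (either strand). Returns integer(0) on a miss, else
// (signed node, oriented offset, strand of query w.r.t. stored sequence).
// [[Rcpp::export]]
IntegerVector lookup_kmer_cpp(SEXP ptr, std::string kmer, IntegerVector node_len) {
    XPtr<KIndex> idx(ptr);
    std::string rc;
    if (!rc_into(kmer, rc)) return IntegerVector(0);
    bool fwd = kmer <= rc;
    const std::string &canon = fwd ? kmer : rc;
    auto it = idx->find(canon);
    if (it == idx->end()) return IntegerVector(0);
    int k = (int) kmer.size();
    int ta = (fwd ? 1 : -1) * it->second.strand;
    int node = ta * it->second.node;
    int off = ta > 0 ? it->second.off
                     : node_len[it->second.node - 1] - k - it->second.off;
    return IntegerVector::create(node, off, ta);
}

// All k-mer seed hits of a read, merged into maximal runs that are
// contiguous in both the read and one oriented unitig. Returns a 4-column
// matrix: read_start (0-based), signed node, oriented offset, length.
// [[Rcpp::export]]
IntegerMatrix seed_runs_cpp(SEXP ptr, std::string read, IntegerVector node_len,
                            int k) {
    XPtr<KIndex> idx(ptr);
    int L = (int) read.size();
    std::vector<std::array<int, 4>> runs;
    int cur_node = 0, cur_off = 0, cur_start = 0, cur_len = 0;
    std::string km, rc;
    for (int i = 0; i + k <= L; ++i) {
        km = read.substr(i, k);
        int node = 0, off = 0;
        if (rc_into(km, rc)) {
            bool fwd = km <= rc;
            auto it = idx->find(fwd ? km : rc);
            if (it != idx->end()) {
                int ta = (fwd ? 1 : -1) * it->second.strand;
                node = ta * it->second.node;
                off = ta > 0 ? it->second.off
                             : node_len[it->second.node - 1] - k - it->second.off;
            }
        }
        if (node != 0 && cur_len > 0 && node == cur_node &&
            off == cur_off + cur_len) {
            ++cur_len;                      // extends the current run
        } else {
            if (cur_len > 0)
                runs.push_back({cur_start, cur_node, cur_off, cur_len + k - 1});
            if (node != 0) {
                cur_node = node; cur_off = off; cur_start = i; cur_len = 1;
            } else cur_len = 0;
        }
    }
    if (cur_len > 0)
        runs.push_back({cur_start, cur_node, cur_off, cur_len + k - 1});
    IntegerMatrix out((int) runs.size(), 4);
    for (size_t r = 0; r < runs.size(); ++r)
        for (int c = 0; c < 4; ++c) out(r, c) = runs[r][c];
    return out;
}

// Row 0 of the prefix DP: empty graph path against every prefix of the read,
// i.e. D[0][n] = gap * n.
// [[Rcpp::export]]
IntegerVector dp_init_row(int L, int gap) {
    IntegerVector row(L + 1);
    for (int n = 0; n <= L; ++n) row[n] = gap * n;
    return row;
}

// Extend the DP by the characters of `chunk` (appended graph-path sequence)
// against read `s`. `row` is the last DP row of the path so far:
// row[n] = best global score of path-so-far vs s[1..n].
// Returns:
//   row       -- final DP row after consuming chunk
//   best_col  -- max over the newly added rows p of D[p][L] (candidate
//                complete alignments ending inside this chunk); NEG_INF if
//                chunk is empty
//   best_col_row -- 1-based row index within chunk attaining best_col
//   prio      -- max_n of final row (best prefix-alignment score)
//   prefix_end-- largest n attaining prio
//   bound     -- max_n (finalRow[n] + match * (L - n)), the admissible
//                upper bound on any completed extension of this path
// [[Rcpp::export]]
List dp_extend_row(IntegerVector row, std::string chunk, std::string s,
                   int match, int mismatch, int gap) {
    int L = (int) s.size();
    if ((int) row.size() != L + 1) stop("row length must be nchar(s) + 1");
    std::vector<int> cur(row.begin(), row.end());
    std::vector<int> nxt(L + 1);
    int best_col = NEG_INF, best_col_row = NA_INTEGER;
    for (size_t p = 0; p < chunk.size(); ++p) {
        char c = chunk[p];
        nxt[0] = cur[0] + gap;
        for (int n = 1; n <= L; ++n) {
            int diag = cur[n - 1] + (s[n - 1] == c ? match : mismatch);
            int up   = cur[n] + gap;
            int left = nxt[n - 1] + gap;
            int v = diag > up ? diag : up;
            if (left > v) v = left;
            nxt[n] = v;
        }
        if (nxt[L] > best_col) { best_col = nxt[L]; best_col_row = (int) p + 1; }
        std::swap(cur, nxt);
    }
    int prio = NEG_INF, prefix_end = 0, bound = NEG_INF;
    for (int n = 0; n <= L; ++n) {
        if (cur[n] >= prio) { prio = cur[n]; prefix_end = n; }
        int b = cur[n] + match * (L - n);
        if (b > bound) bound = b;
    }
    IntegerVector out_row(cur.begin(), cur.end());
    return List::create(_["row"] = out_row,
                        _["best_col"] = best_col,
                        _["best_col_row"] = best_col_row,
                        _["prio"] = prio,
                        _["prefix_end"] = prefix_end,
                        _["bound"] = bound);
}

// Global Needleman-Wunsch alignment of a vs b with linear gaps. Alongside the
// score, the number of matched bases and the number of alignment columns on
// one optimal path are tracked (ties resolved diagonal > up > left) so that
// identity = matches / columns can be reported without a traceback.
// [[Rcpp::export]]
List nw_stats_cpp(std::string a, std::string b, int match, int mismatch, int gap) {
    int A = (int) a.size(), B = (int) b.size();
    std::vector<int> sc(B + 1), mt(B + 1), cl(B + 1);
    std::vector<int> sc2(B + 1), mt2(B + 1), cl2(B + 1);
    for (int j = 0; j <= B; ++j) { sc[j] = gap * j; mt[j] = 0; cl[j] = j; }
    for (int i = 1; i <= A; ++i) {
        sc2[0] = gap * i; mt2[0] = 0; cl2[0] = i;
        for (int j = 1; j <= B; ++j) {
            bool eq = a[i - 1] == b[j - 1];
            int diag = sc[j - 1] + (eq ? match : mismatch);
            int up   = sc[j] + gap;
            int left = sc2[j - 1] + gap;
            if (diag >= up && diag >= left) {
                sc2[j] = diag;
                mt2[j] = mt[j - 1] + (eq ? 1 : 0);
                cl2[j] = cl[j - 1] + 1;
            } else if (up >= left) {
                sc2[j] = up;
                mt2[j] = mt[j];
                cl2[j] = cl[j] + 1;
            } else {
                sc2[j] = left;
                mt2[j] = mt2[j - 1];
                cl2[j] = cl2[j - 1] + 1;
            }
        }
        std::swap(sc, sc2); std::swap(mt, mt2); std::swap(cl, cl2);
    }
    return List::create(_["score"] = sc[B],
                        _["matches"] = mt[B],
                        _["columns"] = cl[B]);
}
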