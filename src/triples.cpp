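#include <Rcpp.h>
#include <map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Enumerate candidate three-SNP combinations target-first: every valid
// triple must be a 3-subset of some target cell's SNP set, so we iterate
// over per-cell 3-subsets instead of all C(V, 3) triples, deduplicating
// with a hash on the (sorted) variant index triple. Uniqueness against the
// comparison scope is then a three-way sorted-intersection test on the
// inverted index variant -> scope cells.

static inline uint64_t key3(int a, int b, int c) {
    // a < b < c, each < 2^21
    return (static_cast<uint64_t>(a) << 42) |
           (static_cast<uint64_t>(b) << 21) |
            static_cast<uint64_t>(c);
}

static bool intersect3_nonempty(const IntegerVector& x,
                                const IntegerVector& y,
                                const IntegerVector& z) {
    R_xlen_t i = 0, j = 0, k = 0;
    while (i < x.size() && j < y.size() && k < z.size()) {
        int a = x[i], b = y[j], c = z[k];
        if (a == b && b == c) return true;
        int m = std::max(a, std::max(b, c));
        if (a < m) ++i;
        if (b < m) ++j;
        if (c < m) ++k;
    }
    return false;
}

// target_vars: list of sorted 1-based variant index vectors, one per target
//   cell. scope_cells: list over ALL variants of sorted scope-cell indices
//   carrying that variant. Returns valid triples (support >= min_support,
//   empty scope intersection) with per-triple supporting target cells.
// [[Rcpp::export(name = ".enumerate_triples_cpp")]]
List enumerate_triples_cpp(List target_vars, List scope_cells,
                           int min_support) {
    std::map<uint64_t, std::vector<int> > cand;  // triple -> target cells
    int n_target = target_vars.size();
    for (int cell = 0; cell < n_target; ++cell) {
        IntegerVector v = target_vars[cell];
        int n = v.size();
        if (n < 3) continue;
        for (int i = 0; i < n - 2; ++i)
            for (int j = i + 1; j < n - 1; ++j)
                for (int k = j + 1; k < n; ++k)
                    cand[key3(v[i], v[j], v[k])].push_back(cell + 1);
    }
    std::vector<int> v1, v2, v3, support;
    std::vector<std::vector<int> > cells;
    for (std::map<uint64_t, std::vector<int> >::const_iterator it =
             cand.begin(); it != cand.end(); ++it) {
        if (static_cast<int>(it->second.size()) < min_support) continue;
        int a = static_cast<int>(it->first >> 42) & 0x1FFFFF;
        int b = static_cast<int>(it->first >> 21) & 0x1FFFFF;
        int c = static_cast<int>(it->first) & 0x1FFFFF;
        IntegerVector sa = scope_cells[a - 1];
        IntegerVector sb = scope_cells[b - 1];
        IntegerVector sc = scope_cells[c - 1];
        if (sa.size() && sb.size() && sc.size() &&
            intersect3_nonempty(sa, sb, sc))
            continue;
        v1.push_back(a); v2.push_back(b); v3.push_back(c);
        support.push_back(static_cast<int>(it->second.size()));
        cells.push_back(it->second);
    }
    List cell_list(cells.size());
    for (size_t i = 0; i < cells.size(); ++i)
        cell_list[i] = wrap(cells[i]);
    return List::create(_["v1"] = wrap(v1), _["v2"] = wrap(v2),
                        _["v3"] = wrap(v3), _["support"] = wrap(support),
                        _["target_cells"] = cell_list);
}
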