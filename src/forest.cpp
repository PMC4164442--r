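#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Deterministic PRNG independent of R's RNG so that forests are
// bit-identical across platforms and runs. splitmix64 seeds an
// xorshift64* stream; each tree (and each permutation stream in the
// importance computation) gets its own stream derived from the root
// seed by fixed offsets, so growing more trees never reshuffles the
// earlier ones.
static inline uint64_t splitmix64_step(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

struct XRng {
    uint64_t s;
    explicit XRng(uint64_t seed) {
        uint64_t x = seed;
        s = splitmix64_step(x);
        if (s == 0) s = 0x9E3779B97F4A7C15ULL;
    }
    uint64_t next() {
        s ^= s >> 12;
        s ^= s << 25;
        s ^= s >> 27;
        return s * 0x2545F4914F6CDD1DULL;
    }
    // uniform in [0, 1)
    double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
    // uniform integer in [0, n)
    int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline uint64_t mix2(uint64_t a, uint64_t b) {
    uint64_t x = a * 0x9E3779B97F4A7C15ULL + b;
    return splitmix64_step(x);
}

struct TreeBuf {
    std::vector<int> feature;      // -1 for leaf
    std::vector<double> threshold; // NA for leaf
    std::vector<int> left, right;  // 0-based node ids, -1 for leaf
    std::vector<double> value;     // node mean response
    std::vector<int> count;        // rows reaching the node
};

// Best split on one feature within a node: maximise the decrease in
// within-node sum of squared deviations, which for a fixed parent
// reduces to maximising sumL^2/nL + sumR^2/nR. Thresholds are the
// midpoints between consecutive distinct sorted values.
struct SplitResult {
    bool found = false;
    double gain = -1.0;
    double threshold = 0.0;
};

static SplitResult best_split_on_feature(const std::vector<double> &v,
                                         const std::vector<double> &yv) {
    const int n = (int)v.size();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return v[a] < v[b]; });
    SplitResult res;
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += yv[i];
    double sumL = 0.0;
    for (int k = 1; k < n; ++k) {
        sumL += yv[ord[k - 1]];
        double lo = v[ord[k - 1]], hi = v[ord[k]];
        if (hi <= lo) continue; // not a distinct boundary
        double sumR = total - sumL;
        double gain = sumL * sumL / k + sumR * sumR / (n - k);
        if (!res.found || gain > res.gain) {
            res.found = true;
            res.gain = gain;
            res.threshold = lo + (hi - lo) / 2.0;
        }
    }
    return res;
}

static int grow_node(TreeBuf &tb, const NumericMatrix &X, const NumericVector &y,
                     std::vector<int> &rows, int m_try, int node_cutoff,
                     XRng &rng) {
    const int p = X.ncol();
    const int n = (int)rows.size();
    double sum = 0.0, sum2 = 0.0;
    for (int i = 0; i < n; ++i) {
        sum += y[rows[i]];
        sum2 += y[rows[i]] * y[rows[i]];
    }
    const double mean = sum / n;
    const double sse = sum2 - sum * mean;

    int node = (int)tb.feature.size();
    tb.feature.push_back(-1);
    tb.threshold.push_back(NA_REAL);
    tb.left.push_back(-1);
    tb.right.push_back(-1);
    tb.value.push_back(mean);
    tb.count.push_back(n);

    // a node with fewer rows than the cutoff is never split
    if (n < node_cutoff || sse <= 1e-12) return node;

    // draw m_try distinct candidate features (partial Fisher-Yates),
    // then examine them in ascending index order so that equal-gain
    // ties resolve to the lowest feature index
    std::vector<int> pool(p);
    for (int j = 0; j < p; ++j) pool[j] = j;
    int m = std::min(m_try, p);
    for (int j = 0; j < m; ++j) {
        int k = j + rng.below(p - j);
        std::swap(pool[j], pool[k]);
    }
    std::vector<int> cand(pool.begin(), pool.begin() + m);
    std::sort(cand.begin(), cand.end());

    int best_feat = -1;
    double best_gain = -1.0, best_thr = 0.0;
    std::vector<double> v(n), yv(n);
    for (int ci = 0; ci < m; ++ci) {
        int f = cand[ci];
        for (int i = 0; i < n; ++i) {
            v[i] = X(rows[i], f);
            yv[i] = y[rows[i]];
        }
        SplitResult s = best_split_on_feature(v, yv);
        if (s.found && s.gain > best_gain) { // strict > keeps lowest index/threshold
            best_gain = s.gain;
            best_feat = f;
            best_thr = s.threshold;
        }
    }
    if (best_feat < 0) return node; // all candidate features constant

    std::vector<int> lrows, rrows;
    lrows.reserve(n);
    rrows.reserve(n);
    for (int i = 0; i < n; ++i) {
        if (X(rows[i], best_feat) <= best_thr) lrows.push_back(rows[i]);
        else rrows.push_back(rows[i]);
    }
    if (lrows.empty() || rrows.empty()) return node; // cannot happen for midpoints

    tb.feature[node] = best_feat;
    tb.threshold[node] = best_thr;
    int li = grow_node(tb, X, y, lrows, m_try, node_cutoff, rng);
    tb.left[node] = li;
    int ri = grow_node(tb, X, y, rrows, m_try, node_cutoff, rng);
    tb.right[node] = ri;
    return node;
}

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_tree, int m_try,
                int node_cutoff, double seed, bool bootstrap) {
    const int n = X.nrow();
    List trees(n_tree);
    const uint64_t root = (uint64_t)seed;
    for (int t = 0; t < n_tree; ++t) {
        XRng rng(mix2(root, (uint64_t)(t + 1)));
        std::vector<int> rows;
        std::vector<char> inbag(n, 0);
        rows.reserve(n);
        if (bootstrap) {
            for (int i = 0; i < n; ++i) {
                int k = rng.below(n);
                rows.push_back(k);
                inbag[k] = 1;
            }
        } else {
            for (int i = 0; i < n; ++i) {
                rows.push_back(i);
                inbag[i] = 1;
            }
        }
        TreeBuf tb;
        grow_node(tb, X, y, rows, m_try, node_cutoff, rng);
        std::vector<int> oob;
        for (int i = 0; i < n; ++i)
            if (!inbag[i]) oob.push_back(i + 1); // 1-based for R
        IntegerVector boot(rows.size());
        for (size_t i = 0; i < rows.size(); ++i) boot[i] = rows[i] + 1;
        trees[t] = List::create(
            _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
            _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
            _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
            _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
            _["value"] = NumericVector(tb.value.begin(), tb.value.end()),
            _["count"] = IntegerVector(tb.count.begin(), tb.count.end()),
            _["oob"] = IntegerVector(oob.begin(), oob.end()),
            _["bootstrap"] = boot);
    }
    return trees;
}

static inline double tree_predict_row(const IntegerVector &feature,
                                      const NumericVector &threshold,
                                      const IntegerVector &left,
                                      const IntegerVector &right,
                                      const NumericVector &value,
                                      const NumericMatrix &X, int row) {
    int node = 0;
    while (feature[node] >= 0) {
        node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                          : right[node];
    }
    return value[node];
}

// Per-tree predictions: n x n_tree matrix (column t = tree t).
// [[Rcpp::export(name = ".rf_predict_mat")]]
NumericMatrix rf_predict_mat_cpp(List trees, NumericMatrix X) {
    const int n = X.nrow(), T = trees.size();
    NumericMatrix out(n, T);
    for (int t = 0; t < T; ++t) {
        List tr = trees[t];
        IntegerVector feature = tr["feature"];
        NumericVector threshold = tr["threshold"];
        IntegerVector left = tr["left"], right = tr["right"];
        NumericVector value = tr["value"];
        for (int i = 0; i < n; ++i)
            out(i, t) = tree_predict_row(feature, threshold, left, right,
                                         value, X, i);
    }
    return out;
}

// OOB error and raw permutation importance. For every tree the OOB
// MSE is computed, then each feature in turn is permuted among the
// tree's OOB rows and the MSE recomputed; the raw importance of a
// feature is the mean increase over trees with a nonempty OOB set.
// [[Rcpp::export(name = ".rf_oob_stats")]]
List rf_oob_stats_cpp(List trees, NumericMatrix X, NumericVector y,
                      double seed) {
    const int n = X.nrow(), p = X.ncol(), T = trees.size();
    const uint64_t root = (uint64_t)seed;
    std::vector<double> imp(p, 0.0);
    std::vector<double> oob_sum(n, 0.0);
    std::vector<int> oob_cnt(n, 0);
    int used = 0, skipped = 0;
    double err_acc = 0.0;
    NumericMatrix Xp(clone(X)); // scratch copy for permutations
    for (int t = 0; t < T; ++t) {
        List tr = trees[t];
        IntegerVector oob = tr["oob"];
        const int m = oob.size();
        if (m == 0) { ++skipped; continue; }
        ++used;
        IntegerVector feature = tr["feature"];
        NumericVector threshold = tr["threshold"];
        IntegerVector left = tr["left"], right = tr["right"];
        NumericVector value = tr["value"];
        double err = 0.0;
        for (int k = 0; k < m; ++k) {
            int i = oob[k] - 1;
            double pr = tree_predict_row(feature, threshold, left, right,
                                         value, X, i);
            oob_sum[i] += pr;
            oob_cnt[i] += 1;
            double d = pr - y[i];
            err += d * d;
        }
        err /= m;
        err_acc += err;
        for (int j = 0; j < p; ++j) {
            XRng rng(mix2(mix2(root, (uint64_t)(t + 1)), (uint64_t)(j + 101)));
            // permute column j among the OOB rows (Fisher-Yates)
            std::vector<int> idx(m);
            for (int k = 0; k < m; ++k) idx[k] = oob[k] - 1;
            for (int k = m - 1; k > 0; --k) {
                int q = rng.below(k + 1);
                std::swap(idx[k], idx[q]);
            }
            for (int k = 0; k < m; ++k) Xp(oob[k] - 1, j) = X(idx[k], j);
            double errp = 0.0;
            for (int k = 0; k < m; ++k) {
                int i = oob[k] - 1;
                double pr = tree_predict_row(feature, threshold, left, right,
                                             value, Xp, i);
                double d = pr - y[i];
                errp += d * d;
            }
            errp /= m;
            imp[j] += errp - err;
            for (int k = 0; k < m; ++k) Xp(oob[k] - 1, j) = X(oob[k] - 1, j);
        }
    }
    NumericVector importance(p);
    for (int j = 0; j < p; ++j)
        importance[j] = used > 0 ? imp[j] / used : NA_REAL;
    NumericVector oob_pred(n);
    double mse = 0.0;
    int n_oob = 0;
    for (int i = 0; i < n; ++i) {
        if (oob_cnt[i] > 0) {
            oob_pred[i] = oob_sum[i] / oob_cnt[i];
            double d = oob_pred[i] - y[i];
            mse += d * d;
            ++n_oob;
        } else {
            oob_pred[i] = NA_REAL;
        }
    }
    return List::create(
        _["oob_error"] = n_oob > 0 ? mse / n_oob : NA_REAL,
        _["per_tree_oob_error"] = used > 0 ? err_acc / used : NA_REAL,
        _["importance"] = importance,
        _["oob_predictions"] = oob_pred,
        _["trees_used"] = used,
        _["trees_skipped"] = skipped);
}

// Shrake-Rupley solvent-accessible surface area per atom.
// A deterministic golden-section spiral point set of size n_points is
// placed on the expanded sphere (vdW + probe) of every atom; a point
// is accessible when it lies outside the expanded sphere of every
// other atom. Area = accessible fraction x 4 pi R^2.
// [[Rcpp::export(name = ".sasa_atoms")]]
NumericVector sasa_atoms_cpp(NumericMatrix coords, NumericVector radii,
                             double probe, int n_points) {
    const int n = coords.nrow();
    NumericVector out(n);
    std::vector<double> cx(n), cy(n), cz(n), R(n);
    for (int i = 0; i < n; ++i) {
        cx[i] = coords(i, 0);
        cy[i] = coords(i, 1);
        cz[i] = coords(i, 2);
        R[i] = radii[i] + probe;
    }
    // golden-section spiral on the unit sphere
    std::vector<double> px(n_points), py(n_points), pz(n_points);
    const double golden = M_PI * (3.0 - std::sqrt(5.0));
    for (int k = 0; k < n_points; ++k) {
        double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
        double r = std::sqrt(std::max(0.0, 1.0 - zk * zk));
        double th = golden * k;
        px[k] = r * std::cos(th);
        py[k] = r * std::sin(th);
        pz[k] = zk;
    }
    std::vector<double> nx, ny, nz, nr2;
    for (int i = 0; i < n; ++i) {
        const double Ri = R[i];
        // neighbours whose expanded spheres can occlude atom i
        nx.clear(); ny.clear(); nz.clear(); nr2.clear();
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            double dx = cx[j] - cx[i], dy = cy[j] - cy[i],
                   dz = cz[j] - cz[i];
            double lim = Ri + R[j];
            if (dx * dx + dy * dy + dz * dz < lim * lim) {
                nx.push_back(cx[j]);
                ny.push_back(cy[j]);
                nz.push_back(cz[j]);
                nr2.push_back(R[j] * R[j]);
            }
        }
        const int m = (int)nx.size();
        int acc = 0;
        for (int k = 0; k < n_points; ++k) {
            double x = cx[i] + Ri * px[k];
            double y = cy[i] + Ri * py[k];
            double z = cz[i] + Ri * pz[k];
            bool free_pt = true;
            for (int q = 0; q < m; ++q) {
                double dx = x - nx[q], dy = y - ny[q], dz = z - nz[q];
                if (dx * dx + dy * dy + dz * dz < nr2[q]) {
                    free_pt = false;
                    break;
                }
            }
            if (free_pt) ++acc;
        }
        out[i] = 4.0 * M_PI * Ri * Ri * ((double)acc / n_points);
    }
    return out;
}
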