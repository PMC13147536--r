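#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Incremental sweep over the local trees of a succinct tree sequence.
//
// The branch GRM is B = Z Sigma_A Z^T where columns of Z index sub-edges
// (maximal edge fragments with a constant descendant sample set) and
// Sigma_A holds sub-edge areas (span x branch length).  Sub-edges are never
// materialized: the sweep walks edge insertions/removals along the genome
// and accrues each node's contribution lazily over the genomic interval
// since its state (parent or weight below) last changed.  Those intervals
// are exactly the sub-edges.
//
// State per node u:
//   parent[u] : current parent (-1 if none)
//   w[u,]     : k-vector, sum of input weights over sample nodes at or
//               below u in the current tree
//   v[u,]     : k-vector of accrued output, interpreted through the
//               invariant below
//   last[u]   : genome position at which u's contribution was last accrued
//
// Invariant maintained by every operation: for any sample s, the output
// accumulated so far equals sum of v[a,] over a on the path from s to its
// current root, plus pending rate terms (x - last[a]) * len(a) * w[a,].
// Detaching child c adds the path sum above c into v[c,]; attaching c
// subtracts the new path sum, so contributions accrued while c was
// elsewhere never leak into (or out of) its subtree.

struct Sweep {
    int n_nodes, n_edges, k;
    const double *time;
    const double *left, *right;
    const int *eparent, *echild;
    double L;

    std::vector<int> parent;
    std::vector<double> w, v;   // n_nodes x k, row-major
    std::vector<double> last;
    std::vector<int> ins, rem;  // edge processing orders
    std::vector<double> ps;     // reusable path-sum buffer

    // mode flags
    bool do_rate;      // accrue dx * len * w (matvec mode)
    bool do_sim;       // accrue Gaussian sub-edge effects (Algorithm T)
    double tau2;

    Sweep(const NumericVector &node_time,
          const NumericVector &edge_left, const NumericVector &edge_right,
          const IntegerVector &edge_parent, const IntegerVector &edge_child,
          double seq_len, int k_)
        : n_nodes(node_time.size()), n_edges(edge_left.size()), k(k_),
          time(node_time.begin()), left(edge_left.begin()),
          right(edge_right.begin()), eparent(edge_parent.begin()),
          echild(edge_child.begin()), L(seq_len),
          parent(n_nodes, -1), w((size_t) n_nodes * k, 0.0),
          v((size_t) n_nodes * k, 0.0), last(n_nodes, 0.0),
          ps(k, 0.0), do_rate(false), do_sim(false), tau2(0.0)
    {
        ins.resize(n_edges);
        rem.resize(n_edges);
        for (int e = 0; e < n_edges; e++) ins[e] = rem[e] = e;
        const double *t = time;
        const int *ep = eparent;
        const double *lf = left, *rt = right;
        // insert bottom-up: by left, then parent time ascending
        std::sort(ins.begin(), ins.end(), [t, ep, lf](int a, int b) {
            if (lf[a] != lf[b]) return lf[a] < lf[b];
            if (t[ep[a]] != t[ep[b]]) return t[ep[a]] < t[ep[b]];
            return a < b;
        });
        // remove top-down: by right, then parent time descending
        std::sort(rem.begin(), rem.end(), [t, ep, rt](int a, int b) {
            if (rt[a] != rt[b]) return rt[a] < rt[b];
            if (t[ep[a]] != t[ep[b]]) return t[ep[a]] > t[ep[b]];
            return a < b;
        });
    }

    inline double *wrow(int u) { return &w[(size_t) u * k]; }
    inline double *vrow(int u) { return &v[(size_t) u * k]; }

    // Accrue node u's pending contribution over [last[u], x).
    inline void flush(int u, double x) {
        int p = parent[u];
        if (p >= 0) {
            double dx = x - last[u];
            if (dx > 0) {
                double len = time[p] - time[u];
                if (do_rate && len != 0) {
                    double c = dx * len;
                    double *wv = wrow(u), *vv = vrow(u);
                    for (int t_ = 0; t_ < k; t_++) vv[t_] += c * wv[t_];
                }
                if (do_sim && len > 0) {
                    // one Gaussian per maximal constant interval; splitting a
                    // sub-edge across draws leaves the law of Zu unchanged
                    vrow(u)[0] += norm_rand() * std::sqrt(tau2 * dx * len);
                }
            }
        }
        last[u] = x;
    }

    void remove_edge(int e, double x) {
        int p = eparent[e], c = echild[e];
        flush(c, x);
        std::fill(ps.begin(), ps.end(), 0.0);
        double *wc = wrow(c);
        for (int a = p; a >= 0; a = parent[a]) {
            flush(a, x);
            double *va = vrow(a), *wa = wrow(a);
            for (int t_ = 0; t_ < k; t_++) {
                ps[t_] += va[t_];
                wa[t_] -= wc[t_];
            }
        }
        double *vc = vrow(c);
        for (int t_ = 0; t_ < k; t_++) vc[t_] += ps[t_];
        parent[c] = -1;
    }

    void insert_edge(int e, double x) {
        int p = eparent[e], c = echild[e];
        flush(c, x);
        std::fill(ps.begin(), ps.end(), 0.0);
        double *wc = wrow(c);
        for (int a = p; a >= 0; a = parent[a]) {
            flush(a, x);
            double *va = vrow(a), *wa = wrow(a);
            for (int t_ = 0; t_ < k; t_++) {
                ps[t_] += va[t_];
                wa[t_] += wc[t_];
            }
        }
        double *vc = vrow(c);
        for (int t_ = 0; t_ < k; t_++) vc[t_] -= ps[t_];
        parent[c] = p;
    }

    // Run the sweep; 'visit' is called for each tree interval [x, xn).
    template <class F> void run(F visit) {
        int j = 0, r = 0;
        double x = 0.0;
        while (true) {
            while (r < n_edges && right[rem[r]] == x) remove_edge(rem[r++], x);
            while (j < n_edges && left[ins[j]] == x) insert_edge(ins[j++], x);
            double xn = L;
            if (j < n_edges && left[ins[j]] < xn) xn = left[ins[j]];
            if (r < n_edges && right[rem[r]] < xn) xn = right[rem[r]];
            visit(x, xn);
            if (xn >= L) break;
            x = xn;
        }
        for (int u = 0; u < n_nodes; u++) flush(u, L);
    }

    // Collect per-sample results: path sums of v in the final forest.
    NumericMatrix gather(const IntegerVector &sample_nodes) {
        int n = sample_nodes.size();
        NumericMatrix out(n, k);
        for (int i = 0; i < n; i++) {
            for (int a = sample_nodes[i]; a >= 0; a = parent[a]) {
                double *va = vrow(a);
                for (int t_ = 0; t_ < k; t_++) out(i, t_) += va[t_];
            }
        }
        return out;
    }
};

// [[Rcpp::export(name = ".cpp_grm_matvec")]]
NumericMatrix cpp_grm_matvec(NumericVector node_time,
                             NumericVector edge_left, NumericVector edge_right,
                             IntegerVector edge_parent, IntegerVector edge_child,
                             double sequence_length,
                             IntegerVector sample_nodes,
                             NumericMatrix W) {
    int k = W.ncol(), n = sample_nodes.size();
    if (W.nrow() != n) stop("weight matrix must have one row per sample node");
    Sweep s(node_time, edge_left, edge_right, edge_parent, edge_child,
            sequence_length, k);
    s.do_rate = true;
    for (int i = 0; i < n; i++) {
        double *wv = s.wrow(sample_nodes[i]);
        for (int t_ = 0; t_ < k; t_++) wv[t_] = W(i, t_);
    }
    s.run([](double, double) {});
    return s.gather(sample_nodes);
}

// [[Rcpp::export(name = ".cpp_simulate_values")]]
NumericVector cpp_simulate_values(NumericVector node_time,
                                  NumericVector edge_left, NumericVector edge_right,
                                  IntegerVector edge_parent, IntegerVector edge_child,
                                  double sequence_length,
                                  IntegerVector sample_nodes,
                                  double tau2) {
    Sweep s(node_time, edge_left, edge_right, edge_parent, edge_child,
            sequence_length, 1);
    s.do_sim = true;
    s.tau2 = tau2;
    RNGScope scope;
    s.run([](double, double) {});
    NumericMatrix out = s.gather(sample_nodes);
    return NumericVector(out.begin(), out.end());
}

// Sum, over samples, of effects of mutations carried: a mutation at
// (pos, node) is inherited by every sample below 'node' in the local tree
// at 'pos'.  Mutations must be sorted by position.
// [[Rcpp::export(name = ".cpp_mutation_values")]]
NumericVector cpp_mutation_values(NumericVector node_time,
                                  NumericVector edge_left, NumericVector edge_right,
                                  IntegerVector edge_parent, IntegerVector edge_child,
                                  double sequence_length,
                                  IntegerVector sample_nodes,
                                  NumericVector mut_pos, IntegerVector mut_node,
                                  NumericVector mut_effect) {
    Sweep s(node_time, edge_left, edge_right, edge_parent, edge_child,
            sequence_length, 1);
    int m = mut_pos.size(), i = 0;
    s.run([&](double x, double xn) {
        while (i < m && mut_pos[i] < xn) {
            if (mut_pos[i] >= x) s.vrow(mut_node[i])[0] += mut_effect[i];
            i++;
        }
    });
    NumericMatrix out = s.gather(sample_nodes);
    return NumericVector(out.begin(), out.end());
}

// Total root area (sum over local trees of span x root time, over every
// root subtending at least one sample) and the number of local trees.
// [[Rcpp::export(name = ".cpp_root_area")]]
List cpp_root_area(NumericVector node_time,
                   NumericVector edge_left, NumericVector edge_right,
                   IntegerVector edge_parent, IntegerVector edge_child,
                   double sequence_length,
                   IntegerVector sample_nodes) {
    Sweep s(node_time, edge_left, edge_right, edge_parent, edge_child,
            sequence_length, 1);
    for (int i = 0; i < sample_nodes.size(); i++)
        s.wrow(sample_nodes[i])[0] = 1.0;
    double area = 0.0;
    int n_trees = 0;
    s.run([&](double x, double xn) {
        if (xn > x) {
            n_trees++;
            double r = 0.0;
            for (int u = 0; u < s.n_nodes; u++)
                if (s.parent[u] < 0 && s.wrow(u)[0] > 0) r += s.time[u];
            area += (xn - x) * r;
        }
    });
    return List::create(Named("area") = area, Named("n_trees") = n_trees);
}
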