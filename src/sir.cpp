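#include <Rcpp.h>
using namespace Rcpp;

// Synchronous discrete-time SIR on a CSR adjacency.
// status: 0 = susceptible, 1 = infected, 2 = recovered.
// Newly infected nodes become infectious at the next step; infected nodes
// recover after exactly one infectious step (recovery probability 1), which
// maps the final recovered set exactly onto bond percolation with bond
// probability beta.
//
// Events (scheduled interventions) are applied at the start of step t when
// ev_time <= t: type 0 sets beta, type 1 deactivates an edge set, type 2
// reactivates one. Edge ids index the undirected edge list (0-based).
//
// Returns the last executed step; fills i_counts with the infected count at
// steps 0..t. rec_step[v] is the step at which v recovered (-1 if never;
// nodes still infected at max_steps keep status 1 and rec_step -1).
// `parent`, when non-null, records each node's infector.
static int sir_dynamics(const int* off, const int* nbr, const int* eid,
                        int n, int origin, double beta, int max_steps,
                        std::vector<char>& active, bool use_active,
                        const int* ev_time, const int* ev_type,
                        const double* ev_beta, const List* ev_edges, int n_ev,
                        std::vector<signed char>& status,
                        std::vector<int>& rec_step, bool record,
                        std::vector<int>* parent,
                        std::vector<int>& i_counts, bool& hit_max)
{
    std::vector<int> frontier, nxt;
    frontier.push_back(origin);
    status[origin] = 1;
    i_counts.clear();
    i_counts.push_back(1);
    double b = beta;
    int t = 0, ev_i = 0;
    while (!frontier.empty() && t < max_steps) {
        ++t;
        while (ev_i < n_ev && ev_time[ev_i] <= t) {
            if (ev_type[ev_i] == 0) {
                b = ev_beta[ev_i];
            } else {
                IntegerVector ed = (*ev_edges)[ev_i];
                char val = (ev_type[ev_i] == 1) ? 0 : 1;
                for (int k = 0; k < ed.size(); ++k) active[ed[k]] = val;
            }
            ++ev_i;
        }
        nxt.clear();
        for (size_t fi = 0; fi < frontier.size(); ++fi) {
            int u = frontier[fi];
            for (int j = off[u]; j < off[u + 1]; ++j) {
                if (use_active && !active[eid[j]]) continue;
                int v = nbr[j];
                if (status[v] == 0 && unif_rand() < b) {
                    status[v] = 1;
                    if (parent) (*parent)[v] = u;
                    nxt.push_back(v);
                }
            }
        }
        for (size_t fi = 0; fi < frontier.size(); ++fi) {
            status[frontier[fi]] = 2;
            if (record) rec_step[frontier[fi]] = t;
        }
        frontier.swap(nxt);
        i_counts.push_back((int)frontier.size());
    }
    hit_max = !frontier.empty();
    return t;
}

// [[Rcpp::export]]
List sir_run_cpp(IntegerVector off, IntegerVector nbr, IntegerVector eid,
                 int n_edges, int origin, double beta, int max_steps,
                 IntegerVector ev_time, IntegerVector ev_type,
                 NumericVector ev_beta, List ev_edges,
                 IntegerVector coord_x, IntegerVector coord_y, int L)
{
    int n = off.size() - 1;
    std::vector<char> active((size_t)std::max(n_edges, 1), 1);
    std::vector<signed char> status((size_t)n, 0);
    std::vector<int> rec_step((size_t)n, -1);
    std::vector<int> parent((size_t)n, -1);
    std::vector<int> i_counts;
    bool hit_max = false;
    int n_ev = ev_time.size();
    int t = sir_dynamics(off.begin(), nbr.begin(), eid.begin(), n, origin,
                         beta, max_steps, active, true,
                         n_ev ? ev_time.begin() : (int*)0,
                         n_ev ? ev_type.begin() : (int*)0,
                         n_ev ? ev_beta.begin() : (double*)0,
                         &ev_edges, n_ev,
                         status, rec_step, true, &parent, i_counts, hit_max);

    List out = List::create(
        _["steps"] = t,
        _["rec_step"] = IntegerVector(rec_step.begin(), rec_step.end()),
        _["i_counts"] = IntegerVector(i_counts.begin(), i_counts.end()),
        _["hit_max"] = hit_max);

    // Unwrapped displacement from the origin, accumulated along the
    // infection tree: a node's displacement is its infector's plus the
    // minimal-image step between them. Unlike the minimal-image distance it
    // keeps growing when the front winds around the torus. Computed in
    // infection order (a parent is always infected strictly earlier).
    if (coord_x.size() == n && L > 0) {
        std::vector<double> dx((size_t)n, 0.0), dy((size_t)n, 0.0);
        std::vector<int> touched;
        for (int v = 0; v < n; ++v)
            if (rec_step[v] >= 0 || status[v] == 1) touched.push_back(v);
        std::sort(touched.begin(), touched.end(), [&](int a, int b) {
            int ra = rec_step[a] < 0 ? max_steps + 1 : rec_step[a];
            int rb = rec_step[b] < 0 ? max_steps + 1 : rec_step[b];
            return ra < rb;
        });
        for (size_t i = 0; i < touched.size(); ++i) {
            int v = touched[i], u = parent[v];
            if (u < 0) continue; // origin
            double sx = coord_x[v] - coord_x[u];
            double sy = coord_y[v] - coord_y[u];
            if (sx > L / 2.0) sx -= L; else if (sx < -L / 2.0) sx += L;
            if (sy > L / 2.0) sy -= L; else if (sy < -L / 2.0) sy += L;
            dx[v] = dx[u] + sx;
            dy[v] = dy[u] + sy;
        }
        out["disp_x"] = NumericVector(dx.begin(), dx.end());
        out["disp_y"] = NumericVector(dy.begin(), dy.end());
    }
    return out;
}

// Monte-Carlo distribution of the final recovered set on a small graph
// (n <= 16 nodes): tallies the recovered-set bitmask over `reps`
// realizations, sharing sir_dynamics() with sir_run_cpp().
// [[Rcpp::export]]
IntegerVector sir_reach_mc_cpp(IntegerVector off, IntegerVector nbr,
                               int origin, double beta, int reps)
{
    int n = off.size() - 1;
    if (n > 16) stop("sir_reach_mc_cpp: at most 16 nodes supported");
    IntegerVector counts(1 << n, 0);
    std::vector<char> active(1, 1);
    std::vector<signed char> status((size_t)n, 0);
    std::vector<int> rec_step, i_counts;
    for (int r = 0; r < reps; ++r) {
        std::fill(status.begin(), status.end(), 0);
        bool hit_max = false;
        sir_dynamics(off.begin(), nbr.begin(), (int*)0, n, origin, beta,
                     2 * n + 2, active, false, (int*)0, (int*)0, (double*)0,
                     (List*)0, 0, status, rec_step, false, (std::vector<int>*)0,
                     i_counts, hit_max);
        int mask = 0;
        for (int v = 0; v < n; ++v)
            if (status[v] == 2) mask |= (1 << v);
        counts[mask]++;
    }
    return counts;
}
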