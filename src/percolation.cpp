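#include <Rcpp.h>
using namespace Rcpp;

// Bond percolation on the periodic L x L square lattice with wrapping
// detection via union-find with relative displacements: each node stores its
// lattice offset to its parent; a bond that closes a cycle with a nonzero
// net displacement has wound around the torus in that axis.
struct UF {
    std::vector<int> par, ox, oy, sz;
    UF(int n) : par(n), ox(n, 0), oy(n, 0), sz(n, 1) {
        for (int i = 0; i < n; ++i) par[i] = i;
    }
    // find with path compression, updating offsets to point at the root
    int find(int u) {
        int r = u, cx = 0, cy = 0;
        while (par[r] != r) { cx += ox[r]; cy += oy[r]; r = par[r]; }
        int cur = u, sx = 0, sy = 0;
        while (par[cur] != cur && par[cur] != r) {
            int nxt = par[cur], tox = ox[cur], toy = oy[cur];
            ox[cur] = cx - sx; oy[cur] = cy - sy;
            par[cur] = r;
            sx += tox; sy += toy;
            cur = nxt;
        }
        if (par[cur] == r && cur != r) { ox[cur] = cx - sx; oy[cur] = cy - sy; }
        return r;
    }
};

static void perc_one(int size, double p, bool& wrap_x, bool& wrap_y,
                     double& largest_frac)
{
    int n = size * size;
    UF uf(n);
    wrap_x = wrap_y = false;
    for (int yy = 0; yy < size; ++yy) {
        for (int xx = 0; xx < size; ++xx) {
            int u = yy * size + xx;
            // right and down bonds (periodic)
            for (int d = 0; d < 2; ++d) {
                if (unif_rand() >= p) continue;
                int dx = (d == 0) ? 1 : 0, dy = (d == 0) ? 0 : 1;
                int v = ((yy + dy) % size) * size + (xx + dx) % size;
                int ru = uf.find(u), rv = uf.find(v);
                if (ru != rv) {
                    uf.par[rv] = ru;
                    uf.ox[rv] = uf.ox[u] + dx - uf.ox[v];
                    uf.oy[rv] = uf.oy[u] + dy - uf.oy[v];
                    uf.sz[ru] += uf.sz[rv];
                } else {
                    if (uf.ox[u] + dx - uf.ox[v] != 0) wrap_x = true;
                    if (uf.oy[u] + dy - uf.oy[v] != 0) wrap_y = true;
                }
            }
        }
    }
    int best = 1;
    for (int i = 0; i < n; ++i)
        if (uf.par[i] == i && uf.sz[i] > best) best = uf.sz[i];
    largest_frac = (double)best / n;
}

// [[Rcpp::export]]
List perc_trial_cpp(int size, double p)
{
    bool wx, wy; double lf;
    perc_one(size, p, wx, wy, lf);
    return List::create(_["wraps_x"] = wx, _["wraps_y"] = wy,
                        _["wraps"] = (wx || wy), _["largest_frac"] = lf);
}

// Wrapping frequencies over `reps` independent trials at bond probability p.
// [[Rcpp::export]]
List perc_wrap_freq_cpp(int size, double p, int reps)
{
    int cx = 0, cy = 0, cany = 0;
    double lf_sum = 0.0;
    for (int r = 0; r < reps; ++r) {
        bool wx, wy; double lf;
        perc_one(size, p, wx, wy, lf);
        if (wx) ++cx;
        if (wy) ++cy;
        if (wx || wy) ++cany;
        lf_sum += lf;
    }
    return List::create(_["freq_x"] = (double)cx / reps,
                        _["freq_y"] = (double)cy / reps,
                        _["freq_any"] = (double)cany / reps,
                        _["mean_largest_frac"] = lf_sum / reps);
}
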