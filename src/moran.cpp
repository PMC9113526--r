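#include <Rcpp.h>
using namespace Rcpp;

// Discrete Moran-type death-birth process for one host community.
//
// The local community holds `local_size` individuals. Each event kills one
// uniformly chosen individual; with probability `m` the replacement is an
// immigrant drawn from the metacommunity weights, otherwise it is a copy of
// a uniformly chosen surviving local individual. `generations * local_size`
// events are run in total.
//
// Immigration weights are `meta[j]`, except that taxa listed in `sel_idx`
// (0-based) have their weight multiplied by `sel_weight[k]` while their
// current local count is strictly below `sel_target[k]` (host-mediated
// top-up recruitment). Selected taxa additionally occupy a protected host
// niche of fixed carrying capacity: their individuals are exempt from death
// while the taxon's count is at or below its target quota, and replacements
// that would push the count above the quota are redrawn, so the host
// maintains them at a small, stable abundance (exactly the quota at
// stationarity). Taxa banned from this host must arrive with
// meta[j] == 0 and absent from `init`; they can then never appear.
//
// Uses R's RNG (unif_rand) so results are reproducible via set.seed().

static int search_cdf(const std::vector<double> &cdf, double u) {
    // first index with cdf[i] > u
    int lo = 0, hi = (int)cdf.size() - 1;
    while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cdf[mid] > u) hi = mid; else lo = mid + 1;
    }
    return lo;
}

// [[Rcpp::export]]
IntegerVector moran_host_cpp(IntegerVector init, NumericVector meta,
                             double m, int generations,
                             IntegerVector sel_idx, NumericVector sel_weight,
                             IntegerVector sel_target) {
    const int n_taxa = meta.size();
    if (init.size() != n_taxa)
        stop("init and meta must have the same length");
    const int n_sel = sel_idx.size();

    std::vector<int> counts(n_taxa);
    long local_size = 0;
    for (int j = 0; j < n_taxa; ++j) {
        counts[j] = init[j];
        local_size += init[j];
    }
    if (local_size < 1) stop("empty initial community");
    const int N = (int)local_size;

    // individuals vector: O(1) uniform choice of victims / parents
    std::vector<int> ind(N);
    for (int j = 0, k = 0; j < n_taxa; ++j)
        for (int c = 0; c < counts[j]; ++c) ind[k++] = j;

    // base CDF over non-selected taxa; selected taxa handled separately
    std::vector<bool> is_sel(n_taxa, false);
    std::vector<int> quota(n_taxa, -1);   // protected niche size; -1 = none
    for (int k = 0; k < n_sel; ++k) {
        int j = sel_idx[k];
        if (j < 0 || j >= n_taxa) stop("selected taxon index out of range");
        is_sel[j] = true;
        quota[j] = sel_target[k];
    }
    long n_protected_max = 0;
    for (int k = 0; k < n_sel; ++k) n_protected_max += sel_target[k];
    if (n_protected_max >= N)
        stop("protected niche quotas must total less than local_size");
    std::vector<double> base_cdf(n_taxa);
    double acc = 0.0;
    for (int j = 0; j < n_taxa; ++j) {
        if (!is_sel[j]) acc += meta[j];
        base_cdf[j] = acc;
    }
    const double w_base = acc;

    // current immigration weight of each selected taxon
    std::vector<double> sel_w(n_sel);
    for (int k = 0; k < n_sel; ++k) {
        int j = sel_idx[k];
        sel_w[k] = (counts[j] < sel_target[k]) ? meta[j] * sel_weight[k]
                                               : meta[j];
    }

    const long n_events = (long)generations * (long)N;
    for (long e = 0; e < n_events; ++e) {
        int i, victim;
        do {   // redraw while the chosen individual sits in a protected niche
            i = (int)(unif_rand() * N);
            if (i == N) i = N - 1;
            victim = ind[i];
        } while (quota[victim] >= 0 && counts[victim] <= quota[victim]);
        counts[victim]--;

        int newcomer;
      redraw_replacement:
        if (unif_rand() < m) {
            double w_sel = 0.0;
            for (int k = 0; k < n_sel; ++k) w_sel += sel_w[k];
            double u = unif_rand() * (w_base + w_sel);
            if (u < w_base || n_sel == 0) {
                newcomer = search_cdf(base_cdf, u);
            } else {
                u -= w_base;
                int k = 0;
                while (k < n_sel - 1 && u >= sel_w[k]) { u -= sel_w[k]; ++k; }
                newcomer = sel_idx[k];
            }
        } else {
            int j = (int)(unif_rand() * (N - 1));
            if (j >= N - 1) j = N - 2;
            if (j >= i) ++j;            // skip the dead individual
            newcomer = ind[j];
        }
        // a full protected niche accepts no further individuals
        if (quota[newcomer] >= 0 && counts[newcomer] >= quota[newcomer])
            goto redraw_replacement;
        ind[i] = newcomer;
        counts[newcomer]++;

        if (n_sel > 0) {
            // refresh weights of the (at most two) selected taxa touched
            for (int k = 0; k < n_sel; ++k) {
                int j = sel_idx[k];
                if (j == victim || j == newcomer)
                    sel_w[k] = (counts[j] < sel_target[k])
                                   ? meta[j] * sel_weight[k]
                                   : meta[j];
            }
        }
    }

    IntegerVector out(n_taxa);
    for (int j = 0; j < n_taxa; ++j) out[j] = counts[j];
    return out;
}
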