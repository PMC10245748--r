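#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Two-pass union-find labeling of a logical matrix, 8-connectivity.
// Returns an integer matrix of labels (0 = background, labels 1..k dense).

static int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask) {
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> parent;
    parent.push_back(0); // label 0 unused

    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (!mask(r, c)) continue;
            // previously visited 8-neighbours in column-major scan order:
            // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
            int neigh[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
            int lmin = 0;
            for (int k = 0; k < 4; ++k) {
                int rr = neigh[k][0], cc = neigh[k][1];
                if (rr < 0 || rr >= nr || cc < 0) continue;
                int l = lab(rr, cc);
                if (l > 0) lmin = (lmin == 0) ? l : std::min(lmin, l);
            }
            if (lmin == 0) {
                int fresh = (int) parent.size();
                parent.push_back(fresh);
                lab(r, c) = fresh;
            } else {
                lab(r, c) = lmin;
                for (int k = 0; k < 4; ++k) {
                    int rr = neigh[k][0], cc = neigh[k][1];
                    if (rr < 0 || rr >= nr || cc < 0) continue;
                    int l = lab(rr, cc);
                    if (l > 0) uf_union(parent, l, lmin);
                }
            }
        }
    }

    // flatten and relabel densely
    std::vector<int> dense(parent.size(), 0);
    int k = 0;
    for (size_t i = 1; i < parent.size(); ++i) {
        int root = uf_find(parent, (int) i);
        if (dense[root] == 0) dense[root] = ++k;
        dense[i] = dense[root];
    }
    for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
            if (lab(r, c) > 0) lab(r, c) = dense[lab(r, c)];
    return lab;
}

// Grayscale erosion (min) or dilation (max) over a structuring element
// given as a two-column matrix of (drow, dcol) offsets; out-of-image
// neighbours are ignored (equivalent to edge replication for min/max).

// [[Rcpp::export(name = ".gray_morph_cpp")]]
NumericMatrix gray_morph_cpp(NumericMatrix img, IntegerMatrix offsets,
                             bool erode) {
    int nr = img.nrow(), nc = img.ncol(), no = offsets.nrow();
    NumericMatrix out(nr, nc);
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            double v = img(r, c);
            for (int k = 0; k < no; ++k) {
                int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
                if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
                double x = img(rr, cc);
                if (erode ? (x < v) : (x > v)) v = x;
            }
            out(r, c) = v;
        }
    }
    return out;
}

// Translate every labelled object to an independent uniform position with
// the object's bounding box kept inside the image (so shapes, count and
// area are preserved exactly), rejecting positions that would make it
// touch (8-adjacency) an already placed object. Objects are placed
// largest-first; after max_tries rejections an overlapping position is
// accepted (only reachable for pathologically crowded masks). Uses R's RNG.

// [[Rcpp::export(name = ".randomize_objects_cpp")]]
LogicalMatrix randomize_objects_cpp(IntegerMatrix lab, int n_obj,
                                    int max_tries) {
    int nr = lab.nrow(), nc = lab.ncol();
    std::vector<std::vector<int>> rows(n_obj), cols(n_obj);
    std::vector<int> rmin(n_obj, nr), rmax(n_obj, -1);
    std::vector<int> cmin(n_obj, nc), cmax(n_obj, -1);
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            int l = lab(r, c);
            if (l > 0) {
                rows[l - 1].push_back(r);
                cols[l - 1].push_back(c);
                if (r < rmin[l - 1]) rmin[l - 1] = r;
                if (r > rmax[l - 1]) rmax[l - 1] = r;
                if (c < cmin[l - 1]) cmin[l - 1] = c;
                if (c > cmax[l - 1]) cmax[l - 1] = c;
            }
        }
    }
    std::vector<int> order(n_obj);
    for (int i = 0; i < n_obj; ++i) order[i] = i;
    std::sort(order.begin(), order.end(), [&](int a, int b) {
        return rows[a].size() > rows[b].size();
    });
    LogicalMatrix out(nr, nc);
    std::vector<char> blocked((size_t) nr * nc, 0);
    std::vector<int> rr, cc;
    for (int oi = 0; oi < n_obj; ++oi) {
        int o = order[oi];
        size_t npx = rows[o].size();
        int hspan = nr - (rmax[o] - rmin[o]);   // valid top positions
        int wspan = nc - (cmax[o] - cmin[o]);
        rr.resize(npx);
        cc.resize(npx);
        bool placed = false;
        for (int t = 0; t <= max_tries && !placed; ++t) {
            int r0 = (int) (unif_rand() * hspan);
            int c0 = (int) (unif_rand() * wspan);
            if (r0 >= hspan) r0 = hspan - 1;
            if (c0 >= wspan) c0 = wspan - 1;
            int dr = r0 - rmin[o], dc = c0 - cmin[o];
            bool ok = true;
            for (size_t k = 0; k < npx; ++k) {
                rr[k] = rows[o][k] + dr;
                cc[k] = cols[o][k] + dc;
                if (blocked[(size_t) cc[k] * nr + rr[k]]) {
                    ok = false;
                    break;
                }
            }
            // the final attempt is accepted even if it overlaps
            if (ok || t == max_tries) {
                if (!ok) {
                    for (size_t k = 0; k < npx; ++k) {
                        rr[k] = rows[o][k] + dr;
                        cc[k] = cols[o][k] + dc;
                    }
                }
                placed = true;
            }
        }
        for (size_t k = 0; k < npx; ++k) {
            out(rr[k], cc[k]) = TRUE;
            for (int d8r = -1; d8r <= 1; ++d8r) {
                for (int d8c = -1; d8c <= 1; ++d8c) {
                    int br = rr[k] + d8r, bc = cc[k] + d8c;
                    if (br < 0 || br >= nr || bc < 0 || bc >= nc) continue;
                    blocked[(size_t) bc * nr + br] = 1;
                }
            }
        }
    }
    return out;
}

// Square-window median filter with edge replication. size must be odd.

// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix img, int size) {
    int nr = img.nrow(), nc = img.ncol();
    int h = size / 2;
    NumericMatrix out(nr, nc);
    std::vector<double> win(size * size);
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            int n = 0;
            for (int dc = -h; dc <= h; ++dc) {
                int cc = std::min(std::max(c + dc, 0), nc - 1);
                for (int dr = -h; dr <= h; ++dr) {
                    int rr = std::min(std::max(r + dr, 0), nr - 1);
                    win[n++] = img(rr, cc);
                }
            }
            std::nth_element(win.begin(), win.begin() + n / 2, win.begin() + n);
            out(r, c) = win[n / 2];
        }
    }
    return out;
}
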