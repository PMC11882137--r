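#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Column-major linear index, 0-based: x + X*(y + Y*z)
static inline int lin(int x, int y, int z, int X, int Y) {
    return x + X * (y + Y * z);
}

// Trilinear resampling onto a target grid covering the same physical extent
// (half-voxel-centre convention: target voxel j maps to source coordinate
// (j+0.5)*S/T - 0.5 in source voxel units).
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector src, IntegerVector sdim,
                                     IntegerVector tdim) {
    const int X = sdim[0], Y = sdim[1], Z = sdim[2];
    const int TX = tdim[0], TY = tdim[1], TZ = tdim[2];
    NumericVector out(static_cast<R_xlen_t>(TX) * TY * TZ);
    const double fx = (double)X / TX, fy = (double)Y / TY, fz = (double)Z / TZ;
    for (int k = 0; k < TZ; ++k) {
        double zc = (k + 0.5) * fz - 0.5;
        if (zc < 0) zc = 0; if (zc > Z - 1) zc = Z - 1;
        int z0 = (int)std::floor(zc), z1 = std::min(z0 + 1, Z - 1);
        double wz = zc - z0;
        for (int j = 0; j < TY; ++j) {
            double yc = (j + 0.5) * fy - 0.5;
            if (yc < 0) yc = 0; if (yc > Y - 1) yc = Y - 1;
            int y0 = (int)std::floor(yc), y1 = std::min(y0 + 1, Y - 1);
            double wy = yc - y0;
            for (int i = 0; i < TX; ++i) {
                double xc = (i + 0.5) * fx - 0.5;
                if (xc < 0) xc = 0; if (xc > X - 1) xc = X - 1;
                int x0 = (int)std::floor(xc), x1 = std::min(x0 + 1, X - 1);
                double wx = xc - x0;
                double v000 = src[lin(x0, y0, z0, X, Y)], v100 = src[lin(x1, y0, z0, X, Y)];
                double v010 = src[lin(x0, y1, z0, X, Y)], v110 = src[lin(x1, y1, z0, X, Y)];
                double v001 = src[lin(x0, y0, z1, X, Y)], v101 = src[lin(x1, y0, z1, X, Y)];
                double v011 = src[lin(x0, y1, z1, X, Y)], v111 = src[lin(x1, y1, z1, X, Y)];
                double v0 = (v000 * (1 - wx) + v100 * wx) * (1 - wy) + (v010 * (1 - wx) + v110 * wx) * wy;
                double v1 = (v001 * (1 - wx) + v101 * wx) * (1 - wy) + (v011 * (1 - wx) + v111 * wx) * wy;
                out[lin(i, j, k, TX, TY)] = v0 * (1 - wz) + v1 * wz;
            }
        }
    }
    return out;
}

// Nearest-neighbour resampling (label mode): preserves the value set exactly.
// [[Rcpp::export]]
NumericVector cpp_resample_nearest(NumericVector src, IntegerVector sdim,
                                   IntegerVector tdim) {
    const int X = sdim[0], Y = sdim[1], Z = sdim[2];
    const int TX = tdim[0], TY = tdim[1], TZ = tdim[2];
    NumericVector out(static_cast<R_xlen_t>(TX) * TY * TZ);
    const double fx = (double)X / TX, fy = (double)Y / TY, fz = (double)Z / TZ;
    for (int k = 0; k < TZ; ++k) {
        int zs = (int)std::lround((k + 0.5) * fz - 0.5);
        zs = std::max(0, std::min(zs, Z - 1));
        for (int j = 0; j < TY; ++j) {
            int ys = (int)std::lround((j + 0.5) * fy - 0.5);
            ys = std::max(0, std::min(ys, Y - 1));
            for (int i = 0; i < TX; ++i) {
                int xs = (int)std::lround((i + 0.5) * fx - 0.5);
                xs = std::max(0, std::min(xs, X - 1));
                out[lin(i, j, k, TX, TY)] = src[lin(xs, ys, zs, X, Y)];
            }
        }
    }
    return out;
}

static std::vector<std::array<int, 3> > ball_offsets(double radius) {
    std::vector<std::array<int, 3> > off;
    int r = (int)std::floor(radius);
    for (int dz = -r; dz <= r; ++dz)
        for (int dy = -r; dy <= r; ++dy)
            for (int dx = -r; dx <= r; ++dx)
                if (dx * dx + dy * dy + dz * dz <= radius * radius)
                    off.push_back({dx, dy, dz});
    return off;
}

// Binary dilation with a Euclidean ball of the given radius (voxel units).
// [[Rcpp::export]]
IntegerVector cpp_dilate(IntegerVector mask, IntegerVector dim, double radius) {
    const int X = dim[0], Y = dim[1], Z = dim[2];
    IntegerVector out(mask.size());
    std::vector<std::array<int, 3> > off = ball_offsets(radius);
    for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
            for (int x = 0; x < X; ++x) {
                if (!mask[lin(x, y, z, X, Y)]) continue;
                for (size_t t = 0; t < off.size(); ++t) {
                    int nx = x + off[t][0], ny = y + off[t][1], nz = z + off[t][2];
                    if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
                    out[lin(nx, ny, nz, X, Y)] = 1;
                }
            }
    return out;
}

// Binary erosion (outside the grid counts as background).
// [[Rcpp::export]]
IntegerVector cpp_erode(IntegerVector mask, IntegerVector dim, double radius) {
    const int X = dim[0], Y = dim[1], Z = dim[2];
    IntegerVector out(mask.size());
    std::vector<std::array<int, 3> > off = ball_offsets(radius);
    for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
            for (int x = 0; x < X; ++x) {
                if (!mask[lin(x, y, z, X, Y)]) continue;
                bool keep = true;
                for (size_t t = 0; t < off.size() && keep; ++t) {
                    int nx = x + off[t][0], ny = y + off[t][1], nz = z + off[t][2];
                    if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z ||
                        !mask[lin(nx, ny, nz, X, Y)])
                        keep = false;
                }
                if (keep) out[lin(x, y, z, X, Y)] = 1;
            }
    return out;
}

// Connected-component labelling; connectivity 6 or 26. Labels 1..K by
// decreasing first-voxel order; 0 is background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim, int conn) {
    const int X = dim[0], Y = dim[1], Z = dim[2];
    IntegerVector lab(mask.size());
    std::vector<std::array<int, 3> > off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (conn == 6 && manh != 1) continue;
                off.push_back({dx, dy, dz});
            }
    int next = 0;
    std::vector<int> stack;
    for (R_xlen_t s = 0; s < mask.size(); ++s) {
        if (!mask[s] || lab[s]) continue;
        ++next;
        stack.push_back((int)s);
        lab[s] = next;
        while (!stack.empty()) {
            int v = stack.back();
            stack.pop_back();
            int x = v % X, y = (v / X) % Y, z = v / (X * Y);
            for (size_t t = 0; t < off.size(); ++t) {
                int nx = x + off[t][0], ny = y + off[t][1], nz = z + off[t][2];
                if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
                int n = lin(nx, ny, nz, X, Y);
                if (mask[n] && !lab[n]) {
                    lab[n] = next;
                    stack.push_back(n);
                }
            }
        }
    }
    return lab;
}

// Surface voxels: mask voxels with at least one neighbour (given connectivity)
// outside the mask; the grid edge counts as outside.
// [[Rcpp::export]]
IntegerVector cpp_boundary(IntegerVector mask, IntegerVector dim, int conn) {
    const int X = dim[0], Y = dim[1], Z = dim[2];
    IntegerVector out(mask.size());
    for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
            for (int x = 0; x < X; ++x) {
                if (!mask[lin(x, y, z, X, Y)]) continue;
                bool bd = false;
                for (int dz = -1; dz <= 1 && !bd; ++dz)
                    for (int dy = -1; dy <= 1 && !bd; ++dy)
                        for (int dx = -1; dx <= 1 && !bd; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
                            if (conn == 6 && manh != 1) continue;
                            int nx = x + dx, ny = y + dy, nz = z + dz;
                            if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y ||
                                nz >= Z || !mask[lin(nx, ny, nz, X, Y)])
                                bd = true;
                        }
                if (bd) out[lin(x, y, z, X, Y)] = 1;
            }
    return out;
}

// Directed Hausdorff distance in mm between two point sets (0-based voxel
// coordinates, n x 3), using anisotropic spacing. Returns max_a min_b ||a-b||.
// [[Rcpp::export]]
double cpp_directed_hausdorff(NumericMatrix a, NumericMatrix b, NumericVector sp) {
    double worst = 0.0;
    for (int i = 0; i < a.nrow(); ++i) {
        double best = R_PosInf;
        double ax = a(i, 0) * sp[0], ay = a(i, 1) * sp[1], az = a(i, 2) * sp[2];
        for (int j = 0; j < b.nrow(); ++j) {
            double dx = ax - b(j, 0) * sp[0];
            double dy = ay - b(j, 1) * sp[1];
            double dz = az - b(j, 2) * sp[2];
            double d = dx * dx + dy * dy + dz * dz;
            if (d < best) best = d;
        }
        if (best > worst) worst = best;
    }
    return std::sqrt(worst);
}

typedef std::pair<double, int> KeyedVoxel; // (random key, linear index)

// Face-connected accretion: add n_add voxels to the mask, always choosing the
// frontier voxel with the smallest key (keys supplied by the caller's RNG so
// growth is reproducible). Growth is confined to `allowed`. Returns the grown
// mask and the number of voxels actually added.
// [[Rcpp::export]]
List cpp_grow_mask(IntegerVector mask, IntegerVector dim, int n_add,
                   IntegerVector allowed, NumericVector keys) {
    const int X = dim[0], Y = dim[1], Z = dim[2];
    IntegerVector out = clone(mask);
    std::priority_queue<KeyedVoxel, std::vector<KeyedVoxel>, std::greater<KeyedVoxel> > pq;
    std::vector<char> queued(out.size(), 0);
    const int dxs[6] = {1, -1, 0, 0, 0, 0};
    const int dys[6] = {0, 0, 1, -1, 0, 0};
    const int dzs[6] = {0, 0, 0, 0, 1, -1};
    for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
            for (int x = 0; x < X; ++x) {
                int v = lin(x, y, z, X, Y);
                if (out[v] || !allowed[v]) continue;
                for (int t = 0; t < 6; ++t) {
                    int nx = x + dxs[t], ny = y + dys[t], nz = z + dzs[t];
                    if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
                    if (out[lin(nx, ny, nz, X, Y)]) {
                        pq.push(KeyedVoxel(keys[v], v));
                        queued[v] = 1;
                        break;
                    }
                }
            }
    int added = 0;
    while (added < n_add && !pq.empty()) {
        KeyedVoxel kv = pq.top();
        pq.pop();
        int v = kv.second;
        if (out[v]) continue;
        out[v] = 1;
        ++added;
        int x = v % X, y = (v / X) % Y, z = v / (X * Y);
        for (int t = 0; t < 6; ++t) {
            int nx = x + dxs[t], ny = y + dys[t], nz = z + dzs[t];
            if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
            int n = lin(nx, ny, nz, X, Y);
            if (!out[n] && allowed[n] && !queued[n]) {
                pq.push(KeyedVoxel(keys[n], n));
                queued[n] = 1;
            }
        }
    }
    return List::create(_["mask"] = out, _["added"] = added);
}

// Boundary peeling: remove n_remove voxels, always choosing the current
// surface voxel with the smallest key.
// [[Rcpp::export]]
List cpp_shrink_mask(IntegerVector mask, IntegerVector dim, int n_remove,
                     NumericVector keys) {
    const int X = dim[0], Y = dim[1], Z = dim[2];
    IntegerVector out = clone(mask);
    std::priority_queue<KeyedVoxel, std::vector<KeyedVoxel>, std::greater<KeyedVoxel> > pq;
    std::vector<char> queued(out.size(), 0);
    const int dxs[6] = {1, -1, 0, 0, 0, 0};
    const int dys[6] = {0, 0, 1, -1, 0, 0};
    const int dzs[6] = {0, 0, 0, 0, 1, -1};
    for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
            for (int x = 0; x < X; ++x) {
                int v = lin(x, y, z, X, Y);
                if (!out[v]) continue;
                bool bd = false;
                for (int t = 0; t < 6 && !bd; ++t) {
                    int nx = x + dxs[t], ny = y + dys[t], nz = z + dzs[t];
                    if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z ||
                        !out[lin(nx, ny, nz, X, Y)])
                        bd = true;
                }
                if (bd) {
                    pq.push(KeyedVoxel(keys[v], v));
                    queued[v] = 1;
                }
            }
    int removed = 0;
    while (removed < n_remove && !pq.empty()) {
        KeyedVoxel kv = pq.top();
        pq.pop();
        int v = kv.second;
        if (!out[v]) continue;
        out[v] = 0;
        ++removed;
        int x = v % X, y = (v / X) % Y, z = v / (X * Y);
        for (int t = 0; t < 6; ++t) {
            int nx = x + dxs[t], ny = y + dys[t], nz = z + dzs[t];
            if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
            int n = lin(nx, ny, nz, X, Y);
            if (out[n] && !queued[n]) {
                pq.push(KeyedVoxel(keys[n], n));
                queued[n] = 1;
            }
        }
    }
    return List::create(_["mask"] = out, _["removed"] = removed);
}

// For each point in `a`, the distance (mm) to its nearest point in `b`.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b, NumericVector sp) {
    NumericVector out(a.nrow());
    for (int i = 0; i < a.nrow(); ++i) {
        double best = R_PosInf;
        double ax = a(i, 0) * sp[0], ay = a(i, 1) * sp[1], az = a(i, 2) * sp[2];
        for (int j = 0; j < b.nrow(); ++j) {
            double dx = ax - b(j, 0) * sp[0];
            double dy = ay - b(j, 1) * sp[1];
            double dz = az - b(j, 2) * sp[2];
            double d = dx * dx + dy * dy + dz * dz;
            if (d < best) best = d;
        }
        out[i] = std::sqrt(best);
    }
    return out;
}
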