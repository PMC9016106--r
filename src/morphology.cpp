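#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

// Neighbor displacement table for 6/18/26 connectivity.
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
    int limit;
    switch (connectivity) {
    case 6:  limit = 1; break;
    case 18: limit = 2; break;
    case 26: limit = 3; break;
    default: stop("connectivity must be 6, 18 or 26");
    }
    std::vector<std::array<int, 3>> offs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (s > 0 && s <= limit)
                    offs.push_back({dx, dy, dz});
            }
    return offs;
}

// Connected component of a 3D logical mask containing the given seed
// (1-based linear index). BFS touching only the component itself.
// [[Rcpp::export(name = ".seed_component3d")]]
LogicalVector seed_component3d(LogicalVector mask, IntegerVector dim,
                               int seed, int connectivity) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dim");
    if (seed < 1 || seed > n) stop("seed index out of range");
    if (!mask[seed - 1]) stop("seed voxel is not set in the mask");

    std::vector<std::array<int, 3>> offs = neighbor_offsets(connectivity);
    LogicalVector out(n);
    std::vector<R_xlen_t> queue;
    queue.reserve(1024);
    out[seed - 1] = TRUE;
    queue.push_back(seed - 1);
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    size_t head = 0;
    while (head < queue.size()) {
        R_xlen_t cur = queue[head++];
        int z = (int)(cur / nxy);
        int rem = (int)(cur % nxy);
        int y = rem / nx;
        int x = rem % nx;
        for (size_t o = 0; o < offs.size(); ++o) {
            int X = x + offs[o][0], Y = y + offs[o][1], Z = z + offs[o][2];
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
            R_xlen_t idx = X + (R_xlen_t)nx * Y + nxy * Z;
            if (mask[idx] && !out[idx]) {
                out[idx] = TRUE;
                queue.push_back(idx);
            }
        }
    }
    return out;
}

// Fill fully enclosed 3D cavities: flood the background 6-connected from all
// border voxels; anything neither foreground nor reached is a cavity.
// [[Rcpp::export(name = ".fill_holes3d")]]
LogicalVector fill_holes3d(LogicalVector mask, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dim");
    const R_xlen_t nxy = (R_xlen_t)nx * ny;

    std::vector<char> reached(n, 0);
    std::vector<R_xlen_t> queue;
    queue.reserve(4096);
    // seed the flood from every background voxel on the image border
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                if (x > 0 && x < nx - 1 && y > 0 && y < ny - 1 &&
                    z > 0 && z < nz - 1)
                    continue;
                R_xlen_t idx = x + (R_xlen_t)nx * y + nxy * z;
                if (!mask[idx] && !reached[idx]) {
                    reached[idx] = 1;
                    queue.push_back(idx);
                }
            }
    const int offs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    size_t head = 0;
    while (head < queue.size()) {
        R_xlen_t cur = queue[head++];
        int z = (int)(cur / nxy);
        int rem = (int)(cur % nxy);
        int y = rem / nx;
        int x = rem % nx;
        for (int o = 0; o < 6; ++o) {
            int X = x + offs[o][0], Y = y + offs[o][1], Z = z + offs[o][2];
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
            R_xlen_t idx = X + (R_xlen_t)nx * Y + nxy * Z;
            if (!mask[idx] && !reached[idx]) {
                reached[idx] = 1;
                queue.push_back(idx);
            }
        }
    }
    LogicalVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = mask[i] || !reached[i];
    return out;
}
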