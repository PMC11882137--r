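// Minimal 3-D convolution primitives (im2col + GEMM) for the desk-scale
// networks. Kernel is fixed at 3x3x3 with zero padding 1; stride 1 or 2.
// Layout: volumes are column-major R arrays dim (X, Y, Z, C); weights are
// matrices of shape (27*Cin, Cout) with row index cin*27 + kz*9 + ky*3 + kx.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outdim(int n, int stride) { return (n - 1) / stride + 1; }

static arma::mat im2col3(const double* x, int X, int Y, int Z, int C, int stride) {
    const int XO = outdim(X, stride), YO = outdim(Y, stride), ZO = outdim(Z, stride);
    const arma::uword nout = (arma::uword)XO * YO * ZO;
    arma::mat col(nout, (arma::uword)27 * C, arma::fill::zeros);
    const R_xlen_t plane = (R_xlen_t)X * Y;
    const R_xlen_t chan = plane * Z;
    for (int c = 0; c < C; ++c) {
        for (int kz = 0; kz < 3; ++kz)
            for (int ky = 0; ky < 3; ++ky)
                for (int kx = 0; kx < 3; ++kx) {
                    arma::uword ccol = (arma::uword)c * 27 + kz * 9 + ky * 3 + kx;
                    double* dst = col.colptr(ccol);
                    for (int oz = 0; oz < ZO; ++oz) {
                        int iz = oz * stride + kz - 1;
                        if (iz < 0 || iz >= Z) continue;
                        for (int oy = 0; oy < YO; ++oy) {
                            int iy = oy * stride + ky - 1;
                            if (iy < 0 || iy >= Y) continue;
                            const double* src = x + (R_xlen_t)c * chan + (R_xlen_t)iz * plane + (R_xlen_t)iy * X;
                            double* d = dst + (arma::uword)oz * XO * YO + (arma::uword)oy * XO;
                            for (int ox = 0; ox < XO; ++ox) {
                                int ix = ox * stride + kx - 1;
                                if (ix >= 0 && ix < X) d[ox] = src[ix];
                            }
                        }
                    }
                }
    }
    return col;
}

static void col2im3(const arma::mat& col, double* gx, int X, int Y, int Z, int C, int stride) {
    const int XO = outdim(X, stride), YO = outdim(Y, stride), ZO = outdim(Z, stride);
    const R_xlen_t plane = (R_xlen_t)X * Y;
    const R_xlen_t chan = plane * Z;
    for (int c = 0; c < C; ++c) {
        for (int kz = 0; kz < 3; ++kz)
            for (int ky = 0; ky < 3; ++ky)
                for (int kx = 0; kx < 3; ++kx) {
                    arma::uword ccol = (arma::uword)c * 27 + kz * 9 + ky * 3 + kx;
                    const double* src = col.colptr(ccol);
                    for (int oz = 0; oz < ZO; ++oz) {
                        int iz = oz * stride + kz - 1;
                        if (iz < 0 || iz >= Z) continue;
                        for (int oy = 0; oy < YO; ++oy) {
                            int iy = oy * stride + ky - 1;
                            if (iy < 0 || iy >= Y) continue;
                            double* dst = gx + (R_xlen_t)c * chan + (R_xlen_t)iz * plane + (R_xlen_t)iy * X;
                            const double* s = src + (arma::uword)oz * XO * YO + (arma::uword)oy * XO;
                            for (int ox = 0; ox < XO; ++ox) {
                                int ix = ox * stride + kx - 1;
                                if (ix >= 0 && ix < X) dst[ix] += s[ox];
                            }
                        }
                    }
                }
    }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector dim,
                            const arma::mat& w, NumericVector bias, int stride) {
    const int X = dim[0], Y = dim[1], Z = dim[2], C = dim[3];
    const int XO = outdim(X, stride), YO = outdim(Y, stride), ZO = outdim(Z, stride);
    const int CO = (int)w.n_cols;
    arma::mat col = im2col3(x.begin(), X, Y, Z, C, stride);
    arma::mat y = col * w;
    y.each_row() += arma::rowvec(bias.begin(), CO);
    NumericVector out(y.memptr(), y.memptr() + y.n_elem);
    out.attr("dim") = IntegerVector::create(XO, YO, ZO, CO);
    return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, IntegerVector dim, const arma::mat& w,
                   NumericVector gy, int stride) {
    const int X = dim[0], Y = dim[1], Z = dim[2], C = dim[3];
    const int XO = outdim(X, stride), YO = outdim(Y, stride), ZO = outdim(Z, stride);
    const int CO = (int)w.n_cols;
    const arma::uword nout = (arma::uword)XO * YO * ZO;
    arma::mat col = im2col3(x.begin(), X, Y, Z, C, stride);
    arma::mat gym(gy.begin(), nout, CO, false);
    arma::mat gw = col.t() * gym;
    arma::rowvec gb = arma::sum(gym, 0);
    arma::mat gcol = gym * w.t();
    NumericVector gx(x.size());
    col2im3(gcol, gx.begin(), X, Y, Z, C, stride);
    gx.attr("dim") = dim;
    return List::create(_["gx"] = gx, _["gw"] = gw,
                        _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Nearest-neighbour 2x upsampling along the three spatial axes.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, IntegerVector dim) {
    const int X = dim[0], Y = dim[1], Z = dim[2], C = dim[3];
    const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
    NumericVector out((R_xlen_t)X2 * Y2 * Z2 * C);
    for (int c = 0; c < C; ++c)
        for (int z = 0; z < Z2; ++z)
            for (int y = 0; y < Y2; ++y)
                for (int x2 = 0; x2 < X2; ++x2) {
                    R_xlen_t src = (R_xlen_t)(x2 / 2) + (R_xlen_t)X * ((y / 2) + (R_xlen_t)Y * ((z / 2) + (R_xlen_t)Z * c));
                    R_xlen_t dst = (R_xlen_t)x2 + (R_xlen_t)X2 * (y + (R_xlen_t)Y2 * (z + (R_xlen_t)Z2 * c));
                    out[dst] = x[src];
                }
    out.attr("dim") = IntegerVector::create(X2, Y2, Z2, C);
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy, IntegerVector dim_in) {
    const int X = dim_in[0], Y = dim_in[1], Z = dim_in[2], C = dim_in[3];
    const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
    NumericVector gx((R_xlen_t)X * Y * Z * C);
    for (int c = 0; c < C; ++c)
        for (int z = 0; z < Z2; ++z)
            for (int y = 0; y < Y2; ++y)
                for (int x2 = 0; x2 < X2; ++x2) {
                    R_xlen_t src = (R_xlen_t)(x2 / 2) + (R_xlen_t)X * ((y / 2) + (R_xlen_t)Y * ((z / 2) + (R_xlen_t)Z * c));
                    R_xlen_t dst = (R_xlen_t)x2 + (R_xlen_t)X2 * (y + (R_xlen_t)Y2 * (z + (R_xlen_t)Z2 * c));
                    gx[src] += gy[dst];
                }
    gx.attr("dim") = dim_in;
    return gx;
}
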