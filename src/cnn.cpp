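// Fast path of the convolutional engine. Mirrors the reference R
// implementation in R/cnn.R layer for layer (same activation layout, same
// patch-offset ordering), so the two can be cross-checked exactly; the R
// version remains the oracle in the test suite.
//
// Activation layout ("feature format"): C x (npos * B), positions
// depth-fastest column-major within each sample, samples consecutive.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::umat;

// [[Rcpp::export]]
List cpp_net_forward(List layers, arma::mat X, bool keep) {
  const int n = layers.size();
  const int B = X.n_cols;

  List first = layers[0];
  int cin1 = as<int>(first["cin"]);
  mat A;
  if (cin1 == 1) {
    A = mat(X.memptr(), 1, X.n_elem);
  } else {
    int hw = X.n_rows / cin1;
    A.set_size(cin1, (size_t)hw * B);
    for (int s = 0; s < B; ++s)
      for (int c = 0; c < cin1; ++c)
        for (int p = 0; p < hw; ++p)
          A(c, (size_t)s * hw + p) = X((size_t)c * hw + p, s);
  }

  List caches(n);
  for (int i = 0; i < n; ++i) {
    List ly = layers[i];
    std::string type = as<std::string>(ly["type"]);
    if (type == "conv") {
      int cin = ly["cin"], hin = ly["hin"], hout = ly["hout"], wout = ly["wout"];
      mat W = ly["W"];
      arma::vec b = ly["b"];
      int npos_in = hin * as<int>(ly["win"]);
      int npos2 = hout * wout;
      mat P(9 * cin, (size_t)npos2 * B);
      const double *Ap = A.memptr();
      double *Pp = P.memptr();
      const size_t prow = 9 * (size_t)cin;
      int k = 0;
      for (int dx = 0; dx < 3; ++dx) for (int dz = 0; dz < 3; ++dz) {
        for (int s = 0; s < B; ++s) {
          size_t off_in = (size_t)s * npos_in;
          size_t off_out = (size_t)s * npos2;
          for (int xo = 0; xo < wout; ++xo) {
            size_t src0 = off_in + (size_t)(xo + dx) * hin + dz;
            size_t dst0 = off_out + (size_t)xo * hout;
            for (int zo = 0; zo < hout; ++zo)
              memcpy(Pp + (dst0 + zo) * prow + (size_t)k * cin,
                     Ap + (src0 + zo) * cin, cin * sizeof(double));
          }
        }
        ++k;
      }
      mat Z = W * P;
      Z.each_col() += b;
      if (keep) caches[i] = List::create(_["P"] = P, _["B"] = B);
      A = Z;
    } else if (type == "relu") {
      mat mask = arma::conv_to<mat>::from(A > 0);
      A = A % mask;
      if (keep) caches[i] = List::create(_["mask"] = mask, _["A"] = A);
    } else if (type == "pool") {
      int cc = ly["c"], hin = ly["hin"], hout = ly["hout"], wout = ly["wout"];
      int npos_in = hin * as<int>(ly["win"]);
      int npos2 = hout * wout;
      mat out(cc, (size_t)npos2 * B);
      umat ch(cc, (size_t)npos2 * B);
      const double *Ap = A.memptr();
      double *Op = out.memptr();
      arma::uword *Cp = ch.memptr();
      for (int s = 0; s < B; ++s) {
        size_t off_in = (size_t)s * npos_in;
        size_t off_out = (size_t)s * npos2;
        for (int xo = 0; xo < wout; ++xo) {
          for (int zo = 0; zo < hout; ++zo) {
            size_t dst = off_out + (size_t)xo * hout + zo;
            // same offset order as the R reference: k over (dx, dz)
            const size_t q[4] = {
              off_in + (size_t)(2 * xo) * hin + 2 * zo,
              off_in + (size_t)(2 * xo) * hin + 2 * zo + 1,
              off_in + (size_t)(2 * xo + 1) * hin + 2 * zo,
              off_in + (size_t)(2 * xo + 1) * hin + 2 * zo + 1
            };
            for (int c = 0; c < cc; ++c) {
              double best = Ap[q[0] * cc + c];
              int bk = 0;
              for (int k = 1; k < 4; ++k) {
                double v = Ap[q[k] * cc + c];
                if (v > best) { best = v; bk = k; }
              }
              Op[dst * cc + c] = best;
              Cp[dst * cc + c] = bk;
            }
          }
        }
      }
      if (keep) caches[i] = List::create(_["ch"] = ch, _["B"] = B);
      A = out;
    } else if (type == "apool") {
      int cc = ly["c"], hin = ly["hin"], hout = ly["hout"], wout = ly["wout"];
      int npos_in = hin * as<int>(ly["win"]);
      int npos2 = hout * wout;
      mat out(cc, (size_t)npos2 * B);
      const double *Ap = A.memptr();
      double *Op = out.memptr();
      for (int s = 0; s < B; ++s) {
        size_t off_in = (size_t)s * npos_in;
        size_t off_out = (size_t)s * npos2;
        for (int xo = 0; xo < wout; ++xo) {
          for (int zo = 0; zo < hout; ++zo) {
            size_t dst = off_out + (size_t)xo * hout + zo;
            const size_t q[4] = {
              off_in + (size_t)(2 * xo) * hin + 2 * zo,
              off_in + (size_t)(2 * xo) * hin + 2 * zo + 1,
              off_in + (size_t)(2 * xo + 1) * hin + 2 * zo,
              off_in + (size_t)(2 * xo + 1) * hin + 2 * zo + 1
            };
            for (int c = 0; c < cc; ++c)
              Op[dst * cc + c] = 0.25 * (Ap[q[0] * cc + c] + Ap[q[1] * cc + c] +
                                         Ap[q[2] * cc + c] + Ap[q[3] * cc + c]);
          }
        }
      }
      if (keep) caches[i] = List::create(_["B"] = B);
      A = out;
    } else if (type == "gap") {
      int cc = ly["c"], npos = ly["npos"];
      mat out(cc, B);
      for (int s = 0; s < B; ++s)
        out.col(s) = arma::mean(A.cols((size_t)s * npos,
                                       (size_t)(s + 1) * npos - 1), 1);
      if (keep) caches[i] = List::create(_["B"] = B);
      A = out;
    } else if (type == "dense") {
      int din = ly["din"];
      mat W = ly["W"];
      arma::vec b = ly["b"];
      std::string head = ly.containsElementNamed("head") ?
        as<std::string>(ly["head"]) : "flatten";
      mat Xf = (head == "gap") ? A : mat(A.memptr(), din, B);
      mat Z = W * Xf;
      Z.each_col() += b;
      if (keep) caches[i] = List::create(_["Xf"] = Xf, _["B"] = B);
      A = Z;
    }
  }
  return List::create(_["out"] = A, _["caches"] = caches);
}

// stop_at: 1-based layer index (0 = none); returns the gradient at the
// output of layer stop_at without descending further
// [[Rcpp::export]]
List cpp_net_backward(List layers, List caches, arma::mat dZ, int stop_at) {
  const int n = layers.size();
  List grads(n);
  mat G = dZ;
  bool haveG = true;
  for (int i = n - 1; i >= 0; --i) {
    List ly = layers[i];
    List cc = caches[i];
    std::string type = as<std::string>(ly["type"]);
    if (type == "dense") {
      mat Xf = cc["Xf"];
      mat W = ly["W"];
      grads[i] = List::create(_["W"] = mat(G * Xf.t()),
                              _["b"] = arma::vec(arma::sum(G, 1)));
      G = W.t() * G;
      std::string head = ly.containsElementNamed("head") ?
        as<std::string>(ly["head"]) : "flatten";
      if (head == "flatten") {
        int c = ly["c"];
        int B = cc["B"];
        G.reshape(c, G.n_elem / c);
        (void)B;
      }
    } else if (type == "gap") {
      int cc_ = ly["c"], npos = ly["npos"];
      int B = cc["B"];
      mat Gin(cc_, (size_t)npos * B);
      for (int s = 0; s < B; ++s) {
        for (int p = 0; p < npos; ++p)
          Gin.col((size_t)s * npos + p) = G.col(s) / npos;
      }
      G = Gin;
    } else if (type == "apool") {
      int cc_ = ly["c"], hin = ly["hin"], hout = ly["hout"], wout = ly["wout"];
      int npos_in = hin * as<int>(ly["win"]);
      int npos2 = hout * wout;
      int B = cc["B"];
      mat Gin(cc_, (size_t)npos_in * B, arma::fill::zeros);
      const double *Gp = G.memptr();
      double *Ip = Gin.memptr();
      for (int s = 0; s < B; ++s) {
        size_t off_in = (size_t)s * npos_in;
        size_t off_out = (size_t)s * npos2;
        for (int xo = 0; xo < wout; ++xo) {
          for (int zo = 0; zo < hout; ++zo) {
            size_t dst = off_out + (size_t)xo * hout + zo;
            const size_t q[4] = {
              off_in + (size_t)(2 * xo) * hin + 2 * zo,
              off_in + (size_t)(2 * xo) * hin + 2 * zo + 1,
              off_in + (size_t)(2 * xo + 1) * hin + 2 * zo,
              off_in + (size_t)(2 * xo + 1) * hin + 2 * zo + 1
            };
            for (int c = 0; c < cc_; ++c) {
              double g = 0.25 * Gp[dst * cc_ + c];
              Ip[q[0] * cc_ + c] = g;
              Ip[q[1] * cc_ + c] = g;
              Ip[q[2] * cc_ + c] = g;
              Ip[q[3] * cc_ + c] = g;
            }
          }
        }
      }
      G = Gin;
    } else if (type == "pool") {
      int cc_ = ly["c"], hin = ly["hin"], hout = ly["hout"], wout = ly["wout"];
      int npos_in = hin * as<int>(ly["win"]);
      int npos2 = hout * wout;
      int B = cc["B"];
      umat ch = cc["ch"];
      mat Gin(cc_, (size_t)npos_in * B, arma::fill::zeros);
      const double *Gp = G.memptr();
      double *Ip = Gin.memptr();
      const arma::uword *Cp = ch.memptr();
      for (int s = 0; s < B; ++s) {
        size_t off_in = (size_t)s * npos_in;
        size_t off_out = (size_t)s * npos2;
        for (int xo = 0; xo < wout; ++xo) {
          for (int zo = 0; zo < hout; ++zo) {
            size_t dst = off_out + (size_t)xo * hout + zo;
            const size_t q[4] = {
              off_in + (size_t)(2 * xo) * hin + 2 * zo,
              off_in + (size_t)(2 * xo) * hin + 2 * zo + 1,
              off_in + (size_t)(2 * xo + 1) * hin + 2 * zo,
              off_in + (size_t)(2 * xo + 1) * hin + 2 * zo + 1
            };
            for (int c = 0; c < cc_; ++c)
              Ip[q[Cp[dst * cc_ + c]] * cc_ + c] = Gp[dst * cc_ + c];
          }
        }
      }
      G = Gin;
    } else if (type == "relu") {
      mat mask = cc["mask"];
      G = G % mask;
    } else if (type == "conv") {
      int cin = ly["cin"], hin = ly["hin"], hout = ly["hout"], wout = ly["wout"];
      int npos_in = hin * as<int>(ly["win"]);
      int npos2 = hout * wout;
      mat P = cc["P"];
      mat W = ly["W"];
      int B = cc["B"];
      grads[i] = List::create(_["W"] = mat(G * P.t()),
                              _["b"] = arma::vec(arma::sum(G, 1)));
      bool need_input = ((i + 1) > stop_at + 1) && (i > 0);
      if (need_input) {
        mat dP = W.t() * G;
        mat Gin(cin, (size_t)npos_in * B, arma::fill::zeros);
        const double *Dp = dP.memptr();
        double *Ip = Gin.memptr();
        const size_t prow = 9 * (size_t)cin;
        int k = 0;
        for (int dx = 0; dx < 3; ++dx) for (int dz = 0; dz < 3; ++dz) {
          for (int s = 0; s < B; ++s) {
            size_t off_in = (size_t)s * npos_in;
            size_t off_out = (size_t)s * npos2;
            for (int xo = 0; xo < wout; ++xo) {
              size_t src0 = off_in + (size_t)(xo + dx) * hin + dz;
              size_t dst0 = off_out + (size_t)xo * hout;
              for (int zo = 0; zo < hout; ++zo) {
                const double *dsrc = Dp + (dst0 + zo) * prow + (size_t)k * cin;
                double *idst = Ip + (src0 + zo) * cin;
                for (int c = 0; c < cin; ++c) idst[c] += dsrc[c];
              }
            }
          }
          ++k;
        }
        G = Gin;
      } else {
        haveG = false;
      }
    }
    if (i + 1 == stop_at + 1) {
      return List::create(_["grads"] = grads,
                          _["G_stop"] = haveG ? wrap(G) : R_NilValue);
    }
    if (!haveG && i > 0) {
      return List::create(_["grads"] = grads, _["G_stop"] = R_NilValue);
    }
  }
  return List::create(_["grads"] = grads,
                      _["G_stop"] = haveG ? wrap(G) : R_NilValue);
}
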