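// Multi-branch fully connected network engine with forward propagation of
// spatial derivatives (value, d/dx, d/dy and optionally the three unique
// second derivatives) and a hand-derived reverse pass returning parameter
// gradients. Channels are stacked row-wise ([val; dx; dy; dxx; dxy; dyy],
// each block N rows) so every linear layer is a single GEMM per pass.
//
// Instantiated in double (used by the finite-difference verification tests)
// and float (the training hot path, matching the single precision of
// mainstream deep-learning stacks).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;

struct BranchSpec {
  int parent;                 // -1 = features, else 0-based branch index
  std::vector<int> widths;    // hidden layer widths
  int out;                    // output dim; 0 = trunk (output = last hidden activation)
};

class EngineBase {
public:
  virtual ~EngineBase() {}
  virtual List forward(const NumericVector& params) = 0;
  virtual NumericVector backward(const List& seeds) = 0;
  virtual int n_params() const = 0;
};

template <typename eT>
class Engine : public EngineBase {
  typedef arma::Mat<eT> Mat;
  typedef arma::Col<eT> Col;

  int N;        // points
  int C;        // channels (3 or 6)
  int order;    // 1 or 2
  int nb;
  int nparams_;
  std::vector<BranchSpec> spec;
  Mat feats;    // C*N x f

  struct Layer {
    Mat W; Col b;     // current parameters
    Mat Z;            // stacked preactivation (C*N x w)
    Mat A;            // stacked activation (hidden) or linear output
    Mat S;            // sigmoid of value-channel preactivation (N x w)
    bool is_output;
  };
  std::vector<std::vector<Layer> > layers;   // per branch
  std::vector<Mat> trunkAdj;                 // adjoint of trunk outputs

  arma::span ch(int c) const { return arma::span(c * N, (c + 1) * N - 1); }

  const Mat& branch_input(int b) const {
    int p = spec[b].parent;
    if (p < 0) return feats;
    return layers[p].back().A;
  }

public:
  Engine(const IntegerVector& parents, const List& widths,
         const IntegerVector& outs, const NumericMatrix& feats_stacked,
         int N_, int order_)
    : N(N_), order(order_) {
    C = (order == 2) ? 6 : 3;
    nb = parents.size();
    feats = arma::conv_to<Mat>::from(
      Rcpp::as<arma::mat>(feats_stacked));
    if ((int)feats.n_rows != C * N)
      Rcpp::stop("feature matrix must have C*N rows");
    nparams_ = 0;
    for (int b = 0; b < nb; ++b) {
      BranchSpec s;
      s.parent = parents[b];
      IntegerVector w = widths[b];
      s.widths = std::vector<int>(w.begin(), w.end());
      s.out = outs[b];
      int in_dim = (s.parent < 0) ? feats.n_cols
                                  : spec[s.parent].widths.back();
      std::vector<Layer> ls;
      int prev = in_dim;
      for (size_t l = 0; l < s.widths.size(); ++l) {
        Layer L; L.is_output = false;
        L.W.set_size(s.widths[l], prev); L.b.set_size(s.widths[l]);
        nparams_ += s.widths[l] * prev + s.widths[l];
        prev = s.widths[l];
        ls.push_back(L);
      }
      if (s.out > 0) {
        Layer L; L.is_output = true;
        L.W.set_size(s.out, prev); L.b.set_size(s.out);
        nparams_ += s.out * prev + s.out;
        ls.push_back(L);
      }
      spec.push_back(s);
      layers.push_back(ls);
    }
    trunkAdj.resize(nb);
  }

  int n_params() const { return nparams_; }

  void unpack(const NumericVector& params) {
    if ((int)params.size() != nparams_)
      Rcpp::stop("parameter vector has wrong length");
    const double* p = params.begin();
    for (int b = 0; b < nb; ++b)
      for (size_t l = 0; l < layers[b].size(); ++l) {
        Layer& L = layers[b][l];
        for (arma::uword k = 0; k < L.W.n_elem; ++k) L.W(k) = (eT)p[k];
        p += L.W.n_elem;
        for (arma::uword k = 0; k < L.b.n_elem; ++k) L.b(k) = (eT)p[k];
        p += L.b.n_elem;
      }
  }

  List forward(const NumericVector& params) {
    unpack(params);
    List out(nb);
    for (int b = 0; b < nb; ++b) {
      const Mat* Ain = &branch_input(b);
      for (size_t l = 0; l < layers[b].size(); ++l) {
        Layer& L = layers[b][l];
        L.Z = (*Ain) * L.W.t();
        L.Z(ch(0), arma::span::all).each_row() += L.b.t();
        if (L.is_output) {
          L.A = L.Z;
        } else {
          swish_forward(L);
        }
        Ain = &L.A;
      }
      const Layer& last = layers[b].back();
      if (spec[b].out > 0)
        out[b] = Rcpp::wrap(arma::conv_to<arma::mat>::from(last.A));
      else
        out[b] = R_NilValue;
    }
    return out;
  }

  // Swish activation with derivative-channel mixing.
  void swish_forward(Layer& L) {
    const Mat Zv = L.Z(ch(0), arma::span::all);
    L.S = 1.0 / (1.0 + arma::exp(-Zv));
    Mat p1 = L.S % (1.0 + Zv % (1.0 - L.S));       // swish'(z)
    L.A.set_size(L.Z.n_rows, L.Z.n_cols);
    L.A(ch(0), arma::span::all) = Zv % L.S;
    if (order == 1) {
      L.A(ch(1), arma::span::all) = p1 % L.Z(ch(1), arma::span::all);
      L.A(ch(2), arma::span::all) = p1 % L.Z(ch(2), arma::span::all);
    } else {
      Mat sp = L.S % (1.0 - L.S);
      Mat p2 = 2.0 * sp + Zv % sp % (1.0 - 2.0 * L.S);   // swish''(z)
      const Mat Zx = L.Z(ch(1), arma::span::all);
      const Mat Zy = L.Z(ch(2), arma::span::all);
      L.A(ch(1), arma::span::all) = p1 % Zx;
      L.A(ch(2), arma::span::all) = p1 % Zy;
      L.A(ch(3), arma::span::all) = p1 % L.Z(ch(3), arma::span::all) + p2 % Zx % Zx;
      L.A(ch(4), arma::span::all) = p1 % L.Z(ch(4), arma::span::all) + p2 % Zx % Zy;
      L.A(ch(5), arma::span::all) = p1 % L.Z(ch(5), arma::span::all) + p2 % Zy % Zy;
    }
  }

  // Reverse pass. seeds: per branch either NULL (trunk) or a C*N x out
  // numeric matrix of adjoints of the branch output channels.
  NumericVector backward(const List& seeds) {
    NumericVector grad(nparams_);
    for (int b = 0; b < nb; ++b) trunkAdj[b].reset();

    // gradient slot offsets per branch/layer
    std::vector<std::vector<size_t> > offs(nb);
    size_t off = 0;
    for (int b = 0; b < nb; ++b)
      for (size_t l = 0; l < layers[b].size(); ++l) {
        offs[b].push_back(off);
        off += layers[b][l].W.n_elem + layers[b][l].b.n_elem;
      }

    for (int b = nb - 1; b >= 0; --b) {
      Mat Abar;
      if (spec[b].out > 0) {
        if (Rf_isNull(seeds[b]))
          Rcpp::stop("missing seed for output branch");
        Abar = arma::conv_to<Mat>::from(Rcpp::as<arma::mat>(seeds[b]));
      } else {
        if (trunkAdj[b].n_elem == 0)
          Abar.zeros(C * N, spec[b].widths.back());
        else Abar = trunkAdj[b];
      }
      for (int l = (int)layers[b].size() - 1; l >= 0; --l) {
        Layer& L = layers[b][l];
        Mat Zbar;
        if (L.is_output) Zbar = Abar;
        else swish_backward(L, Abar, Zbar);
        const Mat& Ain = (l == 0) ? branch_input(b) : layers[b][l - 1].A;
        // weight/bias gradients
        Mat Wg = Zbar.t() * Ain;
        Col bg = arma::sum(Zbar(ch(0), arma::span::all), 0).t();
        double* gp = grad.begin() + offs[b][l];
        for (arma::uword k = 0; k < Wg.n_elem; ++k) gp[k] += (double)Wg(k);
        gp += Wg.n_elem;
        for (arma::uword k = 0; k < bg.n_elem; ++k) gp[k] += (double)bg(k);
        Abar = Zbar * L.W;
      }
      int p = spec[b].parent;
      if (p >= 0) {
        if (trunkAdj[p].n_elem == 0) trunkAdj[p] = Abar;
        else trunkAdj[p] += Abar;
      }
    }
    return grad;
  }

  // Adjoint of swish_forward: given Abar (C*N x w), produce Zbar.
  void swish_backward(const Layer& L, const Mat& Abar, Mat& Zbar) {
    const Mat Zv = L.Z(ch(0), arma::span::all);
    const Mat& S = L.S;
    Mat sp = S % (1.0 - S);
    Mat p1 = S + Zv % sp;                          // swish'
    Mat spp = sp % (1.0 - 2.0 * S);                // sigma''
    Mat p2 = 2.0 * sp + Zv % spp;                  // swish''
    Zbar.set_size(L.Z.n_rows, L.Z.n_cols);
    const Mat Av = Abar(ch(0), arma::span::all);
    const Mat Ax = Abar(ch(1), arma::span::all);
    const Mat Ay = Abar(ch(2), arma::span::all);
    const Mat Zx = L.Z(ch(1), arma::span::all);
    const Mat Zy = L.Z(ch(2), arma::span::all);
    if (order == 1) {
      Zbar(ch(1), arma::span::all) = p1 % Ax;
      Zbar(ch(2), arma::span::all) = p1 % Ay;
      Zbar(ch(0), arma::span::all) = p1 % Av + p2 % (Zx % Ax + Zy % Ay);
    } else {
      Mat sppp = spp % (1.0 - 2.0 * S) - 2.0 * sp % sp;  // sigma'''
      Mat p3 = 3.0 * spp + Zv % sppp;                    // swish'''
      const Mat Axx = Abar(ch(3), arma::span::all);
      const Mat Axy = Abar(ch(4), arma::span::all);
      const Mat Ayy = Abar(ch(5), arma::span::all);
      const Mat Zxx = L.Z(ch(3), arma::span::all);
      const Mat Zxy = L.Z(ch(4), arma::span::all);
      const Mat Zyy = L.Z(ch(5), arma::span::all);
      Zbar(ch(3), arma::span::all) = p1 % Axx;
      Zbar(ch(4), arma::span::all) = p1 % Axy;
      Zbar(ch(5), arma::span::all) = p1 % Ayy;
      Zbar(ch(1), arma::span::all) = p1 % Ax +
        p2 % (2.0 * Zx % Axx + Zy % Axy);
      Zbar(ch(2), arma::span::all) = p1 % Ay +
        p2 % (2.0 * Zy % Ayy + Zx % Axy);
      Zbar(ch(0), arma::span::all) = p1 % Av +
        p2 % (Zx % Ax + Zy % Ay) +
        Axx % (p2 % Zxx + p3 % Zx % Zx) +
        Axy % (p2 % Zxy + p3 % Zx % Zy) +
        Ayy % (p2 % Zyy + p3 % Zy % Zy);
    }
  }
};

typedef Rcpp::XPtr<EngineBase> EnginePtr;

// [[Rcpp::export]]
SEXP mlp_engine_new(IntegerVector parents, List widths, IntegerVector outs,
                    NumericMatrix feats_stacked, int n_points, int order,
                    bool single_precision) {
  EngineBase* e;
  if (single_precision)
    e = new Engine<float>(parents, widths, outs, feats_stacked, n_points, order);
  else
    e = new Engine<double>(parents, widths, outs, feats_stacked, n_points, order);
  return EnginePtr(e, true);
}

// [[Rcpp::export]]
List mlp_engine_forward(SEXP ptr, NumericVector params) {
  EnginePtr e(ptr);
  return e->forward(params);
}

// [[Rcpp::export]]
NumericVector mlp_engine_backward(SEXP ptr, List seeds) {
  EnginePtr e(ptr);
  return e->backward(seeds);
}

// [[Rcpp::export]]
int mlp_engine_n_params(SEXP ptr) {
  EnginePtr e(ptr);
  return e->n_params();
}
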