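// 1-D convolutional network kernels for photobleaching-trace classification.
// The network is small (one or more conv->ReLU->maxpool blocks followed by
// dense layers and softmax) and is trained with weighted cross-entropy;
// forward, backward and inference passes live here, the optimizer loop in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct Block { int kernel, filters, pool; };

static std::vector<Block> parseBlocks(const List& arch) {
  List bl = arch["blocks"];
  std::vector<Block> out;
  for (int i = 0; i < bl.size(); ++i) {
    List b = bl[i];
    Block bb;
    bb.kernel = as<int>(b["kernel"]);
    bb.filters = as<int>(b["filters"]);
    bb.pool = as<int>(b["pool"]);
    out.push_back(bb);
  }
  return out;
}

// im2col for one sample: A (Lin x Fin) -> M (Lout x k*Fin)
static mat im2col(const mat& A, int k) {
  const int Lin = A.n_rows, Fin = A.n_cols, Lout = Lin - k + 1;
  mat M(Lout, k * Fin);
  for (int fi = 0; fi < Fin; ++fi)
    for (int j = 0; j < k; ++j)
      M.col(fi * k + j) = A.col(fi).subvec(j, j + Lout - 1);
  return M;
}

static void col2imAdd(mat& dA, const mat& dM, int k) {
  const int Fin = dA.n_cols, Lout = dM.n_rows;
  for (int fi = 0; fi < Fin; ++fi)
    for (int j = 0; j < k; ++j)
      dA.col(fi).subvec(j, j + Lout - 1) += dM.col(fi * k + j);
}

// conv -> ReLU applied in place on the im2col product
static mat convRelu(const mat& M, const mat& W, const rowvec& b) {
  mat C = M * W;
  C.each_row() += b;
  return clamp(C, 0.0, datum::inf);
}

// non-overlapping max pool along rows; records argmax row offsets
static mat maxPool(const mat& Z, int pool, umat& idx) {
  const int Lp = Z.n_rows / pool, F = Z.n_cols;
  mat P(Lp, F);
  idx.set_size(Lp, F);
  for (int f = 0; f < F; ++f) {
    for (int l = 0; l < Lp; ++l) {
      uword rel = Z.col(f).subvec(l * pool, l * pool + pool - 1).index_max();
      idx(l, f) = l * pool + rel;
      P(l, f) = Z(idx(l, f), f);
    }
  }
  return P;
}

static mat softmaxRows(mat S) {
  S.each_col() -= max(S, 1);
  S = exp(S);
  S.each_col() /= sum(S, 1);
  return S;
}

// Forward + (optionally) backward pass over one minibatch.
// X: B x L traces; y: 0-based labels (length 0 => inference only);
// params: list W1,b1,...(conv blocks) then W,b per dense layer (the last
// dense layer maps to the classes); classw: per-class loss weights.
// [[Rcpp::export]]
List cnnBatch(const arma::mat& X, const arma::ivec& y, List params, List arch,
              const arma::vec& classw, bool wantGrad) {
  const int B = X.n_rows;
  std::vector<Block> blocks = parseBlocks(arch);
  const int nb = blocks.size();
  const int nClasses = as<int>(arch["nClasses"]);
  IntegerVector denseWidths = arch["dense"];
  const int nd = denseWidths.size() + 1;   // hidden layers + output layer

  std::vector<mat> Wc(nb);
  std::vector<rowvec> bc(nb);
  std::vector<mat> Wd(nd);
  std::vector<rowvec> bd(nd);
  int p = 0;
  for (int i = 0; i < nb; ++i) {
    Wc[i] = as<mat>(params[p++]);
    bc[i] = as<rowvec>(params[p++]);
  }
  for (int j = 0; j < nd; ++j) {
    Wd[j] = as<mat>(params[p++]);
    bd[j] = as<rowvec>(params[p++]);
  }

  // ---- convolutional stage ----
  std::vector<cube> Mcache(nb), Zcache(nb);
  std::vector<ucube> Pidx(nb);
  std::vector<cube> A(nb + 1);
  A[0].set_size(X.n_cols, 1, B);
  for (int b = 0; b < B; ++b) A[0].slice(b).col(0) = X.row(b).t();

  for (int i = 0; i < nb; ++i) {
    const int Lin = A[i].n_rows, Fin = A[i].n_cols;
    const int Lout = Lin - blocks[i].kernel + 1;
    const int Lp = Lout / blocks[i].pool;
    if (Lout < 1 || Lp < 1) stop("architecture collapses the trace length");
    Mcache[i].set_size(Lout, blocks[i].kernel * Fin, B);
    Zcache[i].set_size(Lout, blocks[i].filters, B);
    Pidx[i].set_size(Lp, blocks[i].filters, B);
    A[i + 1].set_size(Lp, blocks[i].filters, B);
    for (int b = 0; b < B; ++b) {
      Mcache[i].slice(b) = im2col(A[i].slice(b), blocks[i].kernel);
      Zcache[i].slice(b) = convRelu(Mcache[i].slice(b), Wc[i], bc[i]);
      umat idx;
      A[i + 1].slice(b) = maxPool(Zcache[i].slice(b), blocks[i].pool, idx);
      Pidx[i].slice(b) = idx;
    }
  }

  // ---- dense stage ----
  const int flat = A[nb].n_rows * A[nb].n_cols;
  std::vector<mat> H(nd);           // input to each dense layer
  H[0].set_size(B, flat);
  for (int b = 0; b < B; ++b)
    H[0].row(b) = vectorise(A[nb].slice(b)).t();
  mat S;
  for (int j = 0; j < nd; ++j) {
    S = H[j] * Wd[j];
    S.each_row() += bd[j];
    if (j < nd - 1) H[j + 1] = clamp(S, 0.0, datum::inf);
  }
  mat P = softmaxRows(S);

  double loss = NA_REAL;
  const bool haveY = y.n_elem == (uword)B;
  double wsum = 0.0;
  if (haveY) {
    loss = 0.0;
    for (int b = 0; b < B; ++b) {
      const double w = classw(y(b));
      loss -= w * std::log(std::max(P(b, y(b)), 1e-12));
      wsum += w;
    }
    loss /= wsum;
  }

  List out = List::create(_["probs"] = P, _["loss"] = loss);
  if (!wantGrad || !haveY) return out;

  // ---- backward ----
  mat dS = P;
  for (int b = 0; b < B; ++b) {
    dS(b, y(b)) -= 1.0;
    dS.row(b) *= classw(y(b)) / wsum;
  }
  std::vector<mat> dWd(nd);
  std::vector<rowvec> dbd(nd);
  for (int j = nd - 1; j >= 0; --j) {
    dWd[j] = H[j].t() * dS;
    dbd[j] = sum(dS, 0);
    if (j > 0) {
      dS = dS * Wd[j].t();
      dS %= conv_to<mat>::from(H[j] > 0);
    } else {
      dS = dS * Wd[j].t();   // gradient w.r.t. the flattened conv output
    }
  }

  std::vector<mat> dWc(nb);
  std::vector<rowvec> dbc(nb);
  for (int i = 0; i < nb; ++i) {
    dWc[i].zeros(Wc[i].n_rows, Wc[i].n_cols);
    dbc[i].zeros(bc[i].n_elem);
  }
  // per-sample gradient flowing into the pooled activations of block i
  std::vector<mat> dA(B);
  for (int b = 0; b < B; ++b)
    dA[b] = reshape(dS.row(b).t(), A[nb].n_rows, A[nb].n_cols);

  for (int i = nb - 1; i >= 0; --i) {
    const int Lout = Zcache[i].n_rows;
    for (int b = 0; b < B; ++b) {
      mat dZ(Lout, blocks[i].filters, fill::zeros);
      const mat& dP = dA[b];
      for (uword f = 0; f < dP.n_cols; ++f)
        for (uword l = 0; l < dP.n_rows; ++l)
          dZ(Pidx[i](l, f, b), f) += dP(l, f);
      dZ %= conv_to<mat>::from(Zcache[i].slice(b) > 0);
      dWc[i] += Mcache[i].slice(b).t() * dZ;
      dbc[i] += sum(dZ, 0);
      if (i > 0) {
        mat dM = dZ * Wc[i].t();
        mat dAprev(A[i].n_rows, A[i].n_cols, fill::zeros);
        col2imAdd(dAprev, dM, blocks[i].kernel);
        dA[b] = dAprev;
      }
    }
  }

  List grads(params.size());
  p = 0;
  for (int i = 0; i < nb; ++i) {
    grads[p++] = wrap(dWc[i]);
    grads[p++] = wrap(dbc[i]);
  }
  for (int j = 0; j < nd; ++j) {
    grads[p++] = wrap(dWd[j]);
    grads[p++] = wrap(dbd[j]);
  }
  out["grads"] = grads;
  return out;
}

// Lean inference pass (no caches): X -> class probabilities.
// [[Rcpp::export]]
arma::mat cnnPredict(const arma::mat& X, List params, List arch) {
  const int B = X.n_rows;
  std::vector<Block> blocks = parseBlocks(arch);
  const int nb = blocks.size();
  IntegerVector denseWidths = arch["dense"];
  const int nd = denseWidths.size() + 1;
  const int nClasses = as<int>(arch["nClasses"]);

  std::vector<mat> Wc(nb);
  std::vector<rowvec> bc(nb);
  std::vector<mat> Wd(nd);
  std::vector<rowvec> bd(nd);
  int p = 0;
  for (int i = 0; i < nb; ++i) {
    Wc[i] = as<mat>(params[p++]);
    bc[i] = as<rowvec>(params[p++]);
  }
  for (int j = 0; j < nd; ++j) {
    Wd[j] = as<mat>(params[p++]);
    bd[j] = as<rowvec>(params[p++]);
  }

  mat out(B, nClasses);
  for (int b = 0; b < B; ++b) {
    mat Acur(X.n_cols, 1);
    Acur.col(0) = X.row(b).t();
    for (int i = 0; i < nb; ++i) {
      mat Z = convRelu(im2col(Acur, blocks[i].kernel), Wc[i], bc[i]);
      umat idx;
      Acur = maxPool(Z, blocks[i].pool, idx);
    }
    rowvec h = vectorise(Acur).t();
    for (int j = 0; j < nd; ++j) {
      h = h * Wd[j] + bd[j];
      if (j < nd - 1) h = clamp(h, 0.0, datum::inf);
    }
    out.row(b) = h;
  }
  return softmaxRows(out);
}
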