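// Convolutional per-label-attention multi-label coder.
//
// Architecture: word embeddings -> one 1-d convolution (tanh) -> per-label
// attention over positions -> per-label linear output -> sigmoid.
// Trained with per-document Adagrad on binary cross-entropy; the dev-set
// mean average precision is recorded after every epoch and the parameters
// from the best epoch are returned. All randomness comes from a private
// mt19937 stream so training is bit-reproducible for a given seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat E;        // V x d embeddings
  mat Wc;       // (k*d) x dc convolution weights
  rowvec bc;    // dc
  mat U;        // dc x L attention
  mat B;        // dc x L output weights
  vec b;        // L output bias
};

// Build the unfolded convolution input: row i holds the k-window of
// embeddings centred at position i, zero-padded at the edges.
mat unfold(const mat& X, int k) {
  const int n = X.n_rows, d = X.n_cols, h = k / 2;
  mat Z(n, k * d, fill::zeros);
  for (int off = -h; off <= h; ++off) {
    int c0 = (off + h) * d;
    for (int i = 0; i < n; ++i) {
      int j = i + off;
      if (j >= 0 && j < n) Z.submat(i, c0, i, c0 + d - 1) = X.row(j);
    }
  }
  return Z;
}

// Column-wise softmax (over positions, one column per label), mixed with a
// small uniform component. The smoothing keeps gradient flowing to every
// position, preventing the attention of rarely-updated labels from
// collapsing onto an uninformative token early in training.
const double kAttnSmooth = 0.1;

mat colsoftmax(const mat& S) {
  mat A = S;
  A.each_row() -= max(A, 0);
  A = exp(A);
  A.each_row() /= sum(A, 0);
  A = (1.0 - kAttnSmooth) * A + kAttnSmooth / S.n_rows;
  return A;
}

vec forward_doc(const std::vector<int>& toks, const Params& p, int k,
                mat* Zout, mat* Hout, mat* Aout, mat* Vout) {
  const int L = p.b.n_elem;
  if (toks.empty()) {
    vec y = 1.0 / (1.0 + exp(-p.b));
    return y;
  }
  mat X(toks.size(), p.E.n_cols);
  for (size_t i = 0; i < toks.size(); ++i) X.row(i) = p.E.row(toks[i]);
  mat Z = unfold(X, k);
  mat H = tanh(Z * p.Wc + repmat(p.bc, Z.n_rows, 1));
  mat A = colsoftmax(H * p.U);          // n x L
  mat V = H.t() * A;                    // dc x L
  vec lin(L);
  for (int l = 0; l < L; ++l) lin(l) = dot(V.col(l), p.B.col(l)) + p.b(l);
  if (Zout) { *Zout = std::move(Z); *Hout = std::move(H);
              *Aout = std::move(A); *Vout = std::move(V); }
  return 1.0 / (1.0 + exp(-lin));
}

double average_precision(const vec& scores, const uvec& pos_mask) {
  // stable sort by decreasing score (ties keep document order)
  uvec ord = stable_sort_index(scores, "descend");
  double hits = 0.0, ap = 0.0;
  const double npos = accu(pos_mask);
  for (size_t r = 0; r < ord.n_elem; ++r) {
    if (pos_mask(ord(r))) {
      hits += 1.0;
      ap += hits / (r + 1.0);
    }
  }
  return npos > 0 ? ap / npos : NA_REAL;
}

double macro_map(const mat& scores, const std::vector<std::vector<int>>& gold,
                 int L) {
  const int n = scores.n_rows;
  double sum = 0.0;
  int used = 0;
  for (int l = 0; l < L; ++l) {
    uvec pos(n, fill::zeros);
    bool any = false;
    for (int i = 0; i < n; ++i) {
      for (int g : gold[i]) if (g == l) { pos(i) = 1; any = true; }
    }
    if (!any) continue;
    sum += average_precision(scores.col(l), pos);
    ++used;
  }
  return used > 0 ? sum / used : NA_REAL;
}

std::vector<std::vector<int>> as_int_lists(const Rcpp::List& x) {
  std::vector<std::vector<int>> out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    Rcpp::IntegerVector v = x[i];
    out[i].assign(v.begin(), v.end());
    for (int& t : out[i]) t -= 1;  // 0-based
  }
  return out;
}

mat score_all(const std::vector<std::vector<int>>& docs, const Params& p,
              int k) {
  mat S(docs.size(), p.b.n_elem);
  for (size_t i = 0; i < docs.size(); ++i) {
    S.row(i) = forward_doc(docs[i], p, k, nullptr, nullptr, nullptr,
                           nullptr).t();
  }
  return S;
}

struct Ada {
  mat E, Wc, U, B;
  rowvec bc;
  vec b;
  void init(const Params& p) {
    E = mat(size(p.E), fill::zeros); Wc = mat(size(p.Wc), fill::zeros);
    U = mat(size(p.U), fill::zeros); B = mat(size(p.B), fill::zeros);
    bc = rowvec(p.bc.n_elem, fill::zeros); b = vec(p.b.n_elem, fill::zeros);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List caml_fit(Rcpp::List docs_r, Rcpp::List labels_r,
                    Rcpp::List dev_docs_r, Rcpp::List dev_labels_r,
                    int n_vocab, int n_labels, int emb_dim, int conv_dim,
                    int kernel, int epochs, double lr, int seed) {
  auto docs = as_int_lists(docs_r);
  auto labels = as_int_lists(labels_r);
  auto dev_docs = as_int_lists(dev_docs_r);
  auto dev_labels = as_int_lists(dev_labels_r);
  const int n = docs.size(), L = n_labels, k = kernel;
  const double eps = 1e-8;

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  auto init_mat = [&](int r, int c, double scale) {
    mat M(r, c);
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < c; ++j) M(i, j) = scale * unif(rng);
    return M;
  };

  Params p;
  p.E = init_mat(n_vocab, emb_dim, 0.01);
  p.Wc = init_mat(k * emb_dim, conv_dim,
                  std::sqrt(6.0 / (k * emb_dim + conv_dim)));
  p.bc = rowvec(conv_dim, fill::zeros);
  p.U = init_mat(conv_dim, L, std::sqrt(6.0 / (conv_dim + L)));
  p.B = init_mat(conv_dim, L, std::sqrt(6.0 / (conv_dim + L)));
  p.b = vec(L, fill::zeros);

  Ada g; g.init(p);
  Params best = p;
  vec dev_map(epochs, fill::zeros);
  double best_map = -1.0;
  int best_epoch = 1;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int idx : order) {
      const auto& toks = docs[idx];
      vec t(L, fill::zeros);
      for (int l : labels[idx]) t(l) = 1.0;
      if (toks.empty()) {
        vec y = 1.0 / (1.0 + exp(-p.b));
        vec dy = y - t;
        g.b += dy % dy;
        p.b -= lr * dy / sqrt(g.b + eps);
        continue;
      }
      mat Z, H, A, V;
      vec y = forward_doc(toks, p, k, &Z, &H, &A, &V);
      if (!y.is_finite()) Rcpp::stop("divergence: non-finite model output");
      vec dy = y - t;                               // L
      vec db = dy;
      mat dB(size(p.B)), dV(size(V));
      for (int l = 0; l < L; ++l) {
        dB.col(l) = dy(l) * V.col(l);
        dV.col(l) = dy(l) * p.B.col(l);
      }
      mat dA = (1.0 - kAttnSmooth) * (H * dV);      // n x L, softmax part
      mat Asoft = (A - kAttnSmooth / A.n_rows) / (1.0 - kAttnSmooth);
      mat dS(size(dA));
      for (int l = 0; l < L; ++l) {
        double s = dot(Asoft.col(l), dA.col(l));
        dS.col(l) = Asoft.col(l) % (dA.col(l) - s);
      }
      mat dU = H.t() * dS;                          // dc x L
      mat dH = A * dV.t() + dS * p.U.t();           // n x dc
      mat dHpre = dH % (1.0 - H % H);
      mat dWc = Z.t() * dHpre;
      rowvec dbc = sum(dHpre, 0);
      mat dZ = dHpre * p.Wc.t();                    // n x k*d

      // parameter updates (Adagrad)
      g.B += dB % dB;   p.B -= lr * dB / sqrt(g.B + eps);
      g.b += db % db;   p.b -= lr * db / sqrt(g.b + eps);
      g.U += dU % dU;   p.U -= lr * dU / sqrt(g.U + eps);
      g.Wc += dWc % dWc; p.Wc -= lr * dWc / sqrt(g.Wc + eps);
      g.bc += dbc % dbc; p.bc -= lr * dbc / sqrt(g.bc + eps);

      // scatter dZ back into the touched embedding rows
      const int d = emb_dim, h = k / 2, nn = (int)toks.size();
      for (int off = -h; off <= h; ++off) {
        int c0 = (off + h) * d;
        for (int i = 0; i < nn; ++i) {
          int j = i + off;
          if (j < 0 || j >= nn) continue;
          int row = toks[j];
          rowvec gE = dZ.submat(i, c0, i, c0 + d - 1);
          g.E.row(row) += gE % gE;
          p.E.row(row) -= lr * gE / sqrt(g.E.row(row) + eps);
        }
      }
    }
    double m = dev_docs.empty() ? 0.0
      : macro_map(score_all(dev_docs, p, k), dev_labels, L);
    dev_map(ep) = m;
    if (m > best_map) { best_map = m; best_epoch = ep + 1; best = p; }
  }

  return Rcpp::List::create(
    Rcpp::Named("E") = best.E, Rcpp::Named("Wc") = best.Wc,
    Rcpp::Named("bc") = Rcpp::NumericVector(best.bc.begin(), best.bc.end()),
    Rcpp::Named("U") = best.U, Rcpp::Named("B") = best.B,
    Rcpp::Named("b") = Rcpp::NumericVector(best.b.begin(), best.b.end()),
    Rcpp::Named("dev_map") = Rcpp::NumericVector(dev_map.begin(), dev_map.end()),
    Rcpp::Named("selected_epoch") = best_epoch);
}

// [[Rcpp::export]]
arma::mat caml_score(Rcpp::List docs_r, Rcpp::List params, int kernel) {
  auto docs = as_int_lists(docs_r);
  Params p;
  p.E = Rcpp::as<mat>(params["E"]);
  p.Wc = Rcpp::as<mat>(params["Wc"]);
  p.bc = Rcpp::as<rowvec>(params["bc"]);
  p.U = Rcpp::as<mat>(params["U"]);
  p.B = Rcpp::as<mat>(params["B"]);
  p.b = Rcpp::as<vec>(params["b"]);
  return score_all(docs, p, kernel);
}
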