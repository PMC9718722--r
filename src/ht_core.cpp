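// Hierarchical Tucker core arithmetic.
//
// A tensor is stored node-wise on a binary dimension tree: leaves carry an
// n_i x r_t frame, inner nodes an r_t1 x r_t2 x r_t transfer cube (root has
// r_root = 1).  Nodes are ordered root-first (parent index < child index),
// so forward loops run root-to-leaves and reverse loops leaves-to-root.
// All indices arriving from R are 1-based; 0 marks "no child".
//
// Layout convention: transfer entry B(a, b, k) couples rank index a of the
// left child with b of the right child; matricizations flatten (a, b) with
// a fastest, which matches both Armadillo's and R's array memory order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;

namespace {

struct HtData {
  int nnodes;
  arma::ivec left, right, parent;   // 0-based, -1 = none
  std::vector<mat> frames;          // leaves only
  std::vector<cube> transfers;      // inner nodes only

  bool is_leaf(int t) const { return left[t] < 0; }
  int rank(int t) const {
    return is_leaf(t) ? (int)frames[t].n_cols : (int)transfers[t].n_slices;
  }
};

HtData unpack(const List& tree, const List& data) {
  HtData h;
  IntegerVector l = tree["left"], r = tree["right"], p = tree["parent"];
  h.nnodes = l.size();
  h.left.set_size(h.nnodes); h.right.set_size(h.nnodes);
  h.parent.set_size(h.nnodes);
  for (int t = 0; t < h.nnodes; ++t) {
    h.left[t] = l[t] - 1; h.right[t] = r[t] - 1; h.parent[t] = p[t] - 1;
  }
  h.frames.resize(h.nnodes);
  h.transfers.resize(h.nnodes);
  for (int t = 0; t < h.nnodes; ++t) {
    if (h.left[t] < 0) {
      h.frames[t] = as<mat>(data[t]);
    } else {
      // as<cube> borrows the R array's memory; deep-copy so that no
      // in-place arithmetic can write back into the caller's object
      cube borrowed = as<cube>(data[t]);
      h.transfers[t] = cube(borrowed.memptr(), borrowed.n_rows,
                            borrowed.n_cols, borrowed.n_slices, true);
    }
  }
  return h;
}

List pack(const HtData& h) {
  List out(h.nnodes);
  for (int t = 0; t < h.nnodes; ++t) {
    if (h.is_leaf(t)) {
      out[t] = wrap(h.frames[t]);
    } else {
      out[t] = wrap(h.transfers[t]);
    }
  }
  return out;
}

mat matricize_transfer(const cube& B) {
  // (a, b) x k with a fastest -- same memory, no copy semantics needed
  return mat(const_cast<double*>(B.memptr()), B.n_rows * B.n_cols,
             B.n_slices, true);
}

// Leaves-to-root QR orthogonalization.  Afterwards every non-root frame and
// transfer matricization has orthonormal columns and the whole tensor's
// Euclidean norm equals the Frobenius norm of the root transfer.
void orthogonalize_inplace(HtData& h) {
  for (int t = h.nnodes - 1; t >= 1; --t) {
    mat M;
    if (h.is_leaf(t)) M = h.frames[t];
    else M = matricize_transfer(h.transfers[t]);
    mat Q, R;
    arma::qr_econ(Q, R, M);
    int rnew = Q.n_cols;
    if (h.is_leaf(t)) {
      h.frames[t] = Q;
    } else {
      h.transfers[t] = cube(Q.memptr(), h.transfers[t].n_rows,
                            h.transfers[t].n_cols, rnew, true);
    }
    int p = h.parent[t];
    cube& Bp = h.transfers[p];
    if (h.left[p] == t) {
      cube nb(rnew, Bp.n_cols, Bp.n_slices);
      for (arma::uword k = 0; k < Bp.n_slices; ++k)
        nb.slice(k) = R * Bp.slice(k);
      Bp = nb;
    } else {
      cube nb(Bp.n_rows, rnew, Bp.n_slices);
      for (arma::uword k = 0; k < Bp.n_slices; ++k)
        nb.slice(k) = Bp.slice(k) * R.t();
      Bp = nb;
    }
  }
}

// Reduced Gramians of an orthogonalized tensor, root to leaves.  For node t,
// the matricization satisfies B^(t) = U_t V_t' with orthonormal U_t, and
// G_t = V_t' V_t; its eigenvalues are the squared node singular values.
std::vector<mat> gramians(const HtData& h) {
  std::vector<mat> G(h.nnodes);
  G[0] = mat(1, 1, arma::fill::ones);  // norm enters through the root transfer
  for (int t = 0; t < h.nnodes; ++t) {
    if (h.is_leaf(t)) continue;
    const cube& B = h.transfers[t];
    const mat& Gt = G[t];
    int r = B.n_slices;
    cube W(B.n_rows, B.n_cols, r, arma::fill::zeros);
    for (int kp = 0; kp < r; ++kp)
      for (int k = 0; k < r; ++k)
        if (Gt(k, kp) != 0.0) W.slice(kp) += Gt(k, kp) * B.slice(k);
    mat G1(B.n_rows, B.n_rows, arma::fill::zeros);
    mat G2(B.n_cols, B.n_cols, arma::fill::zeros);
    for (int kp = 0; kp < r; ++kp) {
      G1 += W.slice(kp) * B.slice(kp).t();
      G2 += W.slice(kp).t() * B.slice(kp);
    }
    G[h.left[t]] = G1;
    G[h.right[t]] = G2;
  }
  return G;
}

double root_norm(const HtData& h) {
  return std::sqrt(arma::accu(arma::square(h.transfers[0])));
}

// Rank-revealing projections from the Gramians; keeps at node t the
// eigenvectors of G_t whose discarded eigenvalue mass stays within
// budget2, never fewer than one and never more than max_rank (if > 0).
std::vector<mat> projections(const HtData& h, const std::vector<mat>& G,
                             double budget2, int max_rank) {
  std::vector<mat> P(h.nnodes);
  P[0] = mat(1, 1, arma::fill::ones);
  for (int t = 1; t < h.nnodes; ++t) {
    vec eval;
    mat evec;
    arma::eig_sym(eval, evec, arma::symmatu(G[t]));  // ascending
    int r = eval.n_elem;
    vec ev = arma::clamp(eval, 0.0, arma::datum::inf);
    double s = 0.0;
    int disc = 0;
    for (int i = 0; i < r - 1; ++i) {
      s += ev(i);
      if (s <= budget2) disc = i + 1; else break;
    }
    int keep = r - disc;
    if (max_rank > 0 && keep > max_rank) keep = max_rank;
    if (keep < 1) keep = 1;
    P[t] = arma::fliplr(evec.cols(r - keep, r - 1));
  }
  return P;
}

void project_inplace(HtData& h, const std::vector<mat>& P) {
  for (int t = 0; t < h.nnodes; ++t) {
    if (h.is_leaf(t)) {
      h.frames[t] = h.frames[t] * P[t];
    } else {
      const cube& B = h.transfers[t];
      const mat& P1 = P[h.left[t]];
      const mat& P2 = P[h.right[t]];
      const mat& Pt = P[t];
      cube C(P1.n_cols, P2.n_cols, B.n_slices);
      for (arma::uword k = 0; k < B.n_slices; ++k)
        C.slice(k) = P1.t() * B.slice(k) * P2;
      cube Bn(P1.n_cols, P2.n_cols, Pt.n_cols, arma::fill::zeros);
      for (arma::uword kp = 0; kp < Pt.n_cols; ++kp)
        for (arma::uword k = 0; k < B.n_slices; ++k)
          if (Pt(k, kp) != 0.0) Bn.slice(kp) += Pt(k, kp) * C.slice(k);
      h.transfers[t] = Bn;
    }
  }
}

void truncate_inplace(HtData& h, double eps_rel, int max_rank) {
  orthogonalize_inplace(h);
  if (h.nnodes == 1) return;
  double nrm = root_norm(h);
  if (nrm == 0.0) return;
  std::vector<mat> G = gramians(h);
  double budget2 = (eps_rel * nrm) * (eps_rel * nrm) / (h.nnodes - 1);
  std::vector<mat> P = projections(h, G, budget2, max_rank);
  project_inplace(h, P);
}

HtData add(const HtData& x, const HtData& y, double a, double b) {
  HtData z;
  z.nnodes = x.nnodes;
  z.left = x.left; z.right = x.right; z.parent = x.parent;
  z.frames.resize(z.nnodes);
  z.transfers.resize(z.nnodes);
  for (int t = 0; t < z.nnodes; ++t) {
    if (x.is_leaf(t)) {
      z.frames[t] = arma::join_rows(x.frames[t], y.frames[t]);
    } else {
      const cube& Bx = x.transfers[t];
      const cube& By = y.transfers[t];
      if (t == 0) {
        cube Bz(Bx.n_rows + By.n_rows, Bx.n_cols + By.n_cols, 1,
                arma::fill::zeros);
        Bz.slice(0).submat(0, 0, Bx.n_rows - 1, Bx.n_cols - 1) =
            a * Bx.slice(0);
        Bz.slice(0).submat(Bx.n_rows, Bx.n_cols,
                           Bx.n_rows + By.n_rows - 1,
                           Bx.n_cols + By.n_cols - 1) = b * By.slice(0);
        z.transfers[t] = Bz;
      } else {
        cube Bz(Bx.n_rows + By.n_rows, Bx.n_cols + By.n_cols,
                Bx.n_slices + By.n_slices, arma::fill::zeros);
        Bz.subcube(0, 0, 0, Bx.n_rows - 1, Bx.n_cols - 1, Bx.n_slices - 1) =
            Bx;
        Bz.subcube(Bx.n_rows, Bx.n_cols, Bx.n_slices,
                   Bx.n_rows + By.n_rows - 1, Bx.n_cols + By.n_cols - 1,
                   Bx.n_slices + By.n_slices - 1) = By;
        z.transfers[t] = Bz;
      }
    }
  }
  return z;
}

double inner(const HtData& x, const HtData& y) {
  std::vector<mat> M(x.nnodes);
  for (int t = x.nnodes - 1; t >= 0; --t) {
    if (x.is_leaf(t)) {
      M[t] = x.frames[t].t() * y.frames[t];
    } else {
      const cube& Bx = x.transfers[t];
      const cube& By = y.transfers[t];
      const mat& M1 = M[x.left[t]];
      const mat& M2 = M[x.right[t]];
      mat Mt(Bx.n_slices, By.n_slices);
      for (arma::uword k = 0; k < Bx.n_slices; ++k) {
        mat E = M1.t() * Bx.slice(k) * M2;
        for (arma::uword kp = 0; kp < By.n_slices; ++kp)
          Mt(k, kp) = arma::accu(E % By.slice(kp));
      }
      M[t] = Mt;
    }
  }
  return M[0](0, 0);
}

// Multiply the leaf frames by a CP term's factor matrices; empty matrices
// mark identity factors.
HtData apply_term(const HtData& x, const List& factors,
                  const IntegerVector& leaf_mode) {
  HtData z = x;
  for (int t = 0; t < z.nnodes; ++t) {
    if (!z.is_leaf(t)) continue;
    int j = leaf_mode[t] - 1;
    RObject f = factors[j];
    if (f.isNULL()) continue;
    z.frames[t] = as<mat>(f) * z.frames[t];
  }
  return z;
}

}  // namespace

// [[Rcpp::export]]
List cpp_ht_orthogonalize(List tree, List data) {
  HtData h = unpack(tree, data);
  orthogonalize_inplace(h);
  return pack(h);
}

// [[Rcpp::export]]
List cpp_ht_truncate(List tree, List data, double eps_rel, int max_rank) {
  HtData h = unpack(tree, data);
  truncate_inplace(h, eps_rel, max_rank);
  return pack(h);
}

// [[Rcpp::export]]
List cpp_ht_node_svals(List tree, List data) {
  HtData h = unpack(tree, data);
  orthogonalize_inplace(h);
  double nrm = root_norm(h);
  std::vector<mat> G = gramians(h);
  List out(h.nnodes);
  out[0] = NumericVector::create(nrm);
  for (int t = 1; t < h.nnodes; ++t) {
    vec eval = arma::eig_sym(arma::symmatu(G[t]));
    vec sv = arma::sqrt(arma::clamp(arma::reverse(eval), 0.0,
                                    arma::datum::inf));
    out[t] = wrap(sv);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_ht_inner(List tree, List datax, List datay) {
  HtData x = unpack(tree, datax);
  HtData y = unpack(tree, datay);
  return inner(x, y);
}

// [[Rcpp::export]]
List cpp_ht_add(List tree, List datax, List datay, double a, double b) {
  HtData x = unpack(tree, datax);
  HtData y = unpack(tree, datay);
  return pack(add(x, y, a, b));
}

// Apply a CP operator sum_i coef_i * T_i to x.  In incremental mode the
// running sum is truncated after every added term (keeping intermediate
// ranks near the working rank); in batch mode all terms are accumulated
// exactly and truncated once at the end.  eps_rel < 0 disables truncation.
// [[Rcpp::export]]
List cpp_ht_apply_cp(List tree, List terms, NumericVector coefs, List datax,
                     double eps_rel, int max_rank, bool incremental) {
  HtData x = unpack(tree, datax);
  IntegerVector leaf_mode = tree["leaf_mode"];
  int r = terms.size();
  HtData acc = apply_term(x, terms[0], leaf_mode);
  acc.transfers[0] *= coefs[0];
  for (int i = 1; i < r; ++i) {
    HtData zi = apply_term(x, terms[i], leaf_mode);
    acc = add(acc, zi, 1.0, coefs[i]);
    if (incremental && eps_rel >= 0) truncate_inplace(acc, eps_rel, max_rank);
  }
  if (!incremental && eps_rel >= 0) truncate_inplace(acc, eps_rel, max_rank);
  return pack(acc);
}
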