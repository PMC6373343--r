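// Compiled kernels for streaming and batch EM estimation of the linear
// multilevel model y_ij = x'beta + z'b_j + e_ij, b_j ~ MVN(0, Phi),
// e_ij ~ N(0, sigma2).  All per-individual state lives in parallel arrays
// (cubes indexed by a 0-based individual slot), so a data stream touches
// O(J (p^2 + p r + r^2)) memory independent of n.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::stop;

// Inverse of Phi with an eigenvalue floor at floorRel * tr(Phi)/r; early in a
// stream Phi can be numerically singular and Eq.-style E-steps need Phi^{-1}.
static mat phiInverse(const mat& phi, double floorRel) {
  vec eval;
  mat evec;
  eig_sym(eval, evec, symmatu(phi));
  double tr = trace(phi);
  double fl = floorRel * std::max(tr, 1e-4) / (double) phi.n_rows;
  if (!(fl > 0.0)) fl = 1e-12;
  eval = clamp(eval, fl, datum::inf);
  return evec * diagmat(1.0 / eval) * evec.t();
}

// E-step for one individual from its stored cross-products:
//   C_j    = Z_j'Z_j + sigma2 Phi^{-1}
//   bhat_j = C_j^{-1} (Z_j'y_j - Z_j'X_j beta)
//   t1_j   = X_j'Z_j bhat_j
//   T2_j   = bhat_j bhat_j' + sigma2 C_j^{-1}
//   t3_j   = E[e_j'e_j | y]  via the cross-product expansion plus
//            sigma2 tr(C_j^{-1} Z_j'Z_j).
static void estepOne(const mat& ZtZ, const mat& XtZ, const vec& Zty,
                     const mat& XtXj, const vec& Xtyj, double yty,
                     const vec& beta, const mat& phiInv, double sigma2,
                     vec& bhat, mat& Cinv, vec& t1j, mat& T2j, double& t3j) {
  mat C = symmatu(ZtZ + sigma2 * phiInv);
  if (!inv_sympd(Cinv, C)) {
    Cinv = pinv(C);
  }
  Cinv = symmatu(Cinv);
  bhat = Cinv * (Zty - XtZ.t() * beta);
  t1j = XtZ * bhat;
  T2j = symmatu(bhat * bhat.t() + sigma2 * Cinv);
  t3j = yty
      + as_scalar(beta.t() * XtXj * beta)
      + as_scalar(bhat.t() * ZtZ * bhat)
      - 2.0 * dot(Xtyj, beta)
      - 2.0 * dot(Zty, bhat)
      + 2.0 * as_scalar(beta.t() * XtZ * bhat)
      + sigma2 * trace(Cinv * ZtZ);
}

// Accumulate per-individual and global cross-products from raw rows.
// id is 0-based and must be < Jmax.
// [[Rcpp::export]]
List cppBuildSuff(const arma::mat& X, const arma::mat& Z, const arma::vec& y,
                  const IntegerVector& id, int Jmax) {
  const int n = X.n_rows, p = X.n_cols, r = Z.n_cols;
  if ((int) Z.n_rows != n || (int) y.n_elem != n || id.size() != n)
    stop("row counts of X, Z, y, id differ");
  cube ZtZ(r, r, Jmax, fill::zeros), XtZ(p, r, Jmax, fill::zeros),
       XtXj(p, p, Jmax, fill::zeros);
  mat Zty(r, Jmax, fill::zeros), Xtyj(p, Jmax, fill::zeros);
  vec yty(Jmax, fill::zeros);
  ivec nj(Jmax, fill::zeros);
  mat XtX(p, p, fill::zeros);
  vec Xty(p, fill::zeros);
  for (int t = 0; t < n; ++t) {
    int j = id[t];
    if (j < 0 || j >= Jmax) stop("individual index out of range at row %d", t + 1);
    vec x = X.row(t).t(), z = Z.row(t).t();
    double yt = y(t);
    ZtZ.slice(j) += z * z.t();
    XtZ.slice(j) += x * z.t();
    XtXj.slice(j) += x * x.t();
    Zty.col(j) += z * yt;
    Xtyj.col(j) += x * yt;
    yty(j) += yt * yt;
    nj(j) += 1;
    XtX += x * x.t();
    Xty += x * yt;
  }
  return List::create(
    Named("ZtZ") = ZtZ, Named("XtZ") = XtZ, Named("XtXj") = XtXj,
    Named("Zty") = Zty, Named("Xtyj") = Xtyj, Named("yty") = yty,
    Named("nj") = IntegerVector(nj.begin(), nj.end()),
    Named("XtX") = XtX, Named("Xty") = Xty,
    Named("n") = n, Named("p") = p, Named("r") = r, Named("Jmax") = Jmax);
}

// Offline E-step over all individuals with nj > 0 (from cross-products).
// [[Rcpp::export]]
List cppEStep(const List& suff, const arma::vec& beta, const arma::mat& phi,
              double sigma2, double phiFloorRel) {
  cube ZtZ = suff["ZtZ"], XtZ = suff["XtZ"], XtXj = suff["XtXj"];
  mat Zty = suff["Zty"], Xtyj = suff["Xtyj"];
  vec yty = suff["yty"];
  IntegerVector nj = suff["nj"];
  const int Jmax = ZtZ.n_slices, p = XtZ.n_rows, r = ZtZ.n_rows;
  mat phiInv = phiInverse(phi, phiFloorRel);
  vec t1(p, fill::zeros);
  mat T2(r, r, fill::zeros), sumCinv(r, r, fill::zeros);
  double t3 = 0.0;
  mat bhat(r, Jmax, fill::zeros);
  cube Cinv(r, r, Jmax, fill::zeros);
  vec bj(r), t1j(p);
  mat Cj(r, r), T2j(r, r);
  double t3j;
  int J = 0;
  for (int j = 0; j < Jmax; ++j) {
    if (nj[j] <= 0) continue;
    ++J;
    estepOne(ZtZ.slice(j), XtZ.slice(j), Zty.col(j), XtXj.slice(j),
             Xtyj.col(j), yty(j), beta, phiInv, sigma2,
             bj, Cj, t1j, T2j, t3j);
    bhat.col(j) = bj;
    Cinv.slice(j) = Cj;
    t1 += t1j;
    T2 += T2j;
    t3 += t3j;
    sumCinv += Cj;
  }
  return List::create(
    Named("t1") = t1, Named("T2") = T2, Named("t3") = t3,
    Named("sumCinv") = sumCinv, Named("bhat") = bhat, Named("Cinv") = Cinv,
    Named("J") = J);
}

static rowvec packParams(const vec& beta, const mat& phi, double sigma2) {
  const int p = beta.n_elem, r = phi.n_rows;
  rowvec out(p + r * (r + 1) / 2 + 1);
  int k = 0;
  for (int i = 0; i < p; ++i) out(k++) = beta(i);
  for (int c = 0; c < r; ++c)
    for (int rw = c; rw < r; ++rw) out(k++) = phi(rw, c);
  out(k) = sigma2;
  return out;
}

// Batch EM: alternate cppEStep / closed-form M-step until the largest absolute
// parameter change drops below tol or maxIter is hit.
// [[Rcpp::export]]
List cppEmFit(const List& suff, const arma::vec& beta0, const arma::mat& phi0,
              double sigma20, double tol, int maxIter, double phiFloorRel) {
  mat XtX = suff["XtX"];
  vec Xty = suff["Xty"];
  int n = suff["n"];
  IntegerVector njv = suff["nj"];
  int J = 0;
  for (int j = 0; j < njv.size(); ++j) if (njv[j] > 0) ++J;
  if (J < 1 || n < 1) stop("empty data");
  mat XtXinv;
  if (!inv_sympd(XtXinv, symmatu(XtX)))
    stop("X'X is rank deficient (deficiency %d)",
         (int) (XtX.n_rows - arma::rank(XtX)));
  vec beta = beta0;
  mat phi = phi0;
  double sigma2 = sigma20;
  rowvec prev = packParams(beta, phi, sigma2);
  mat trace_(maxIter, prev.n_elem, fill::zeros);
  int it = 0;
  bool converged = false;
  for (it = 0; it < maxIter; ++it) {
    List es = cppEStep(suff, beta, phi, sigma2, phiFloorRel);
    vec t1 = es["t1"];
    mat T2 = es["T2"];
    double t3 = es["t3"];
    beta = XtXinv * (Xty - t1);
    phi = symmatu(T2 / (double) J);
    sigma2 = std::max(t3 / (double) n, 1e-10);
    if (!beta.is_finite() || !phi.is_finite() || !std::isfinite(sigma2))
      stop("EM diverged to non-finite parameters at iteration %d", it + 1);
    rowvec cur = packParams(beta, phi, sigma2);
    trace_.row(it) = cur;
    double delta = abs(cur - prev).max();
    prev = cur;
    if (delta < tol) { converged = true; ++it; break; }
  }
  return List::create(
    Named("beta") = beta, Named("phi") = phi, Named("sigma2") = sigma2,
    Named("trace") = trace_.rows(0, std::max(it - 1, 0)),
    Named("iterations") = it, Named("converged") = converged);
}

// Assemble a full streaming state from raw rows at the supplied parameters:
// cross-products, a direct inversion of X'X, per-individual posteriors and
// CDSS contributions, and the running CDSS totals.
// [[Rcpp::export]]
List cppBuildState(const arma::mat& X, const arma::mat& Z, const arma::vec& y,
                   const IntegerVector& id, int Jmax, const arma::vec& beta,
                   const arma::mat& phi, double sigma2, double phiFloorRel) {
  List suff = cppBuildSuff(X, Z, y, id, Jmax);
  const int p = X.n_cols, r = Z.n_cols;
  mat XtX = suff["XtX"];
  mat XtXinv;
  if (!inv_sympd(XtXinv, symmatu(XtX)))
    stop("X'X from the warm-up data is rank deficient; supply a larger training set");
  List es = cppEStep(suff, beta, phi, sigma2, phiFloorRel);
  IntegerVector nj = suff["nj"];
  cube ZtZ = suff["ZtZ"], XtZ = suff["XtZ"], XtXj = suff["XtXj"];
  mat Zty = suff["Zty"], Xtyj = suff["Xtyj"];
  vec yty = suff["yty"];
  mat bhat = es["bhat"];
  cube Cinv = es["Cinv"];
  // store per-individual contributions so the online subtract-then-add works
  mat t1j(p, Jmax, fill::zeros);
  cube T2j(r, r, Jmax, fill::zeros);
  vec t3j(Jmax, fill::zeros);
  mat phiInv = phiInverse(phi, phiFloorRel);
  IntegerVector seen(Jmax);
  int J = 0;
  vec bj(r), t1v(p);
  mat Cj(r, r), T2v(r, r);
  double t3v;
  for (int j = 0; j < Jmax; ++j) {
    if (nj[j] <= 0) continue;
    seen[j] = 1;
    ++J;
    estepOne(ZtZ.slice(j), XtZ.slice(j), Zty.col(j), XtXj.slice(j),
             Xtyj.col(j), yty(j), beta, phiInv, sigma2,
             bj, Cj, t1v, T2v, t3v);
    t1j.col(j) = t1v;
    T2j.slice(j) = T2v;
    t3j(j) = t3v;
  }
  vec t1 = es["t1"];
  mat T2 = es["T2"];
  double t3 = es["t3"];
  return List::create(
    Named("n") = (int) suff["n"], Named("J") = J,
    Named("p") = p, Named("r") = r,
    Named("XtX") = XtX, Named("XtXinv") = XtXinv, Named("xy") = (vec) suff["Xty"],
    Named("t1") = t1, Named("T2") = T2, Named("t3") = t3,
    Named("beta") = beta, Named("phi") = phi, Named("sigma2") = sigma2,
    Named("nj") = nj, Named("seen") = seen,
    Named("ZtZ") = ZtZ, Named("XtZ") = XtZ, Named("XtXj") = XtXj,
    Named("Zty") = Zty, Named("Xtyj") = Xtyj, Named("yty") = yty,
    Named("bhat") = bhat, Named("Cinv") = Cinv,
    Named("t1j") = t1j, Named("T2j") = T2j, Named("t3j") = t3j);
}

// SEMA streaming loop: for each data point emit the prequential prediction,
// ingest the rank-one updates, redo the E-step for that individual only
// (subtract-then-add on the CDSS totals), and run the closed-form M-step.
// sweepEvery > 0 additionally re-runs the E-step for every stored individual
// at that cadence (the "update" variant) followed by one M-step.
// [[Rcpp::export]]
List cppSemaStream(const List& state, const arma::mat& X, const arma::mat& Z,
                   const arma::vec& y, const IntegerVector& id,
                   int sweepEvery, int reinvertEvery, double phiFloorRel,
                   const IntegerVector& checkpointAt) {
  const int T = X.n_rows, p = X.n_cols, r = Z.n_cols;
  int n = state["n"], J = state["J"];
  mat XtX = state["XtX"], XtXinv = state["XtXinv"];
  vec xy = state["xy"], t1 = state["t1"];
  mat T2 = state["T2"];
  double t3 = state["t3"];
  vec beta = state["beta"];
  mat phi = state["phi"];
  double sigma2 = state["sigma2"];
  IntegerVector nj = Rcpp::clone((IntegerVector) state["nj"]);
  IntegerVector seen = Rcpp::clone((IntegerVector) state["seen"]);
  cube ZtZ = state["ZtZ"], XtZ = state["XtZ"], XtXj = state["XtXj"];
  mat Zty = state["Zty"], Xtyj = state["Xtyj"];
  vec yty = state["yty"];
  mat bhat = state["bhat"];
  cube Cinv = state["Cinv"];
  mat t1j = state["t1j"];
  cube T2j = state["T2j"];
  vec t3j = state["t3j"];
  const int Jmax = ZtZ.n_slices;
  mat phiInv = phiInverse(phi, phiFloorRel);
  vec preds(T);
  const int nCp = checkpointAt.size();
  mat cpParams(nCp, p + r * (r + 1) / 2 + 1, fill::value(datum::nan));
  int sinceInvert = 0;
  vec bj(r), t1v(p);
  mat Cj(r, r), T2v(r, r);
  double t3v;

  for (int t = 0; t < T; ++t) {
    int j = id[t];
    if (j < 0 || j >= Jmax) stop("individual index out of range at stream position %d", t + 1);
    vec x = X.row(t).t(), z = Z.row(t).t();
    double yt = y(t);
    // prequential prediction, before any update
    preds(t) = dot(x, beta) + (seen[j] ? dot(z, bhat.col(j)) : 0.0);
    if (!seen[j]) { seen[j] = 1; ++J; }
    // ingest: exact rank-one accumulator updates
    ZtZ.slice(j) += z * z.t();
    XtZ.slice(j) += x * z.t();
    XtXj.slice(j) += x * x.t();
    Zty.col(j) += z * yt;
    Xtyj.col(j) += x * yt;
    yty(j) += yt * yt;
    nj[j] += 1;
    ++n;
    XtX += x * x.t();
    xy += x * yt;
    vec Ax = XtXinv * x;
    double denom = 1.0 + dot(x, Ax);
    if (denom > 1e-12) {
      XtXinv -= (Ax * Ax.t()) / denom;
    } else if (!inv_sympd(XtXinv, symmatu(XtX))) {
      stop("X'X became numerically singular at stream position %d", t + 1);
    }
    if (reinvertEvery > 0 && ++sinceInvert >= reinvertEvery) {
      sinceInvert = 0;
      mat fresh;
      if (inv_sympd(fresh, symmatu(XtX))) XtXinv = fresh;
    }
    // online E-step for this individual only
    estepOne(ZtZ.slice(j), XtZ.slice(j), Zty.col(j), XtXj.slice(j),
             Xtyj.col(j), yty(j), beta, phiInv, sigma2,
             bj, Cj, t1v, T2v, t3v);
    t1 += t1v - t1j.col(j);
    T2 += T2v - T2j.slice(j);
    t3 += t3v - t3j(j);
    bhat.col(j) = bj;
    Cinv.slice(j) = Cj;
    t1j.col(j) = t1v;
    T2j.slice(j) = T2v;
    t3j(j) = t3v;
    // online M-step
    beta = XtXinv * (xy - t1);
    phi = symmatu(T2) / (double) J;
    sigma2 = std::max(t3 / (double) n, 1e-10);
    phiInv = phiInverse(phi, phiFloorRel);
    // periodic sweep through every stored individual (no raw data revisited)
    if (sweepEvery > 0 && (t + 1) % sweepEvery == 0) {
      t1.zeros(); T2.zeros(); t3 = 0.0;
      for (int j2 = 0; j2 < Jmax; ++j2) {
        if (!seen[j2]) continue;
        estepOne(ZtZ.slice(j2), XtZ.slice(j2), Zty.col(j2), XtXj.slice(j2),
                 Xtyj.col(j2), yty(j2), beta, phiInv, sigma2,
                 bj, Cj, t1v, T2v, t3v);
        bhat.col(j2) = bj;
        Cinv.slice(j2) = Cj;
        t1j.col(j2) = t1v;
        T2j.slice(j2) = T2v;
        t3j(j2) = t3v;
        t1 += t1v; T2 += T2v; t3 += t3v;
      }
      beta = XtXinv * (xy - t1);
      phi = symmatu(T2) / (double) J;
      sigma2 = std::max(t3 / (double) n, 1e-10);
      phiInv = phiInverse(phi, phiFloorRel);
    }
    for (int k = 0; k < nCp; ++k)
      if (checkpointAt[k] == n) cpParams.row(k) = packParams(beta, phi, sigma2);
  }

  List out = List::create(
    Named("n") = n, Named("J") = J, Named("p") = p, Named("r") = r,
    Named("XtX") = XtX, Named("XtXinv") = XtXinv, Named("xy") = xy,
    Named("t1") = t1, Named("T2") = T2, Named("t3") = t3,
    Named("beta") = beta, Named("phi") = phi, Named("sigma2") = sigma2,
    Named("nj") = nj, Named("seen") = seen,
    Named("ZtZ") = ZtZ, Named("XtZ") = XtZ, Named("XtXj") = XtXj,
    Named("Zty") = Zty, Named("Xtyj") = Xtyj, Named("yty") = yty);
  // List::create tops out at 20 elements; append the rest
  out["bhat"] = bhat;
  out["Cinv"] = Cinv;
  out["t1j"] = t1j;
  out["T2j"] = T2j;
  out["t3j"] = t3j;
  return List::create(Named("state") = out, Named("predictions") = preds,
                      Named("checkpointParams") = cpParams);
}

// Windowed / incremental-batch EM streamer shared by the batched-EM and
// sliding-window comparators.  m == 0 keeps all data (cumulative batches);
// m > 0 keeps only the m most recent points (FIFO eviction).  Predictions are
// prequential: last-refit parameters with bhat_j recomputed on demand from the
// currently held cross-products.
// [[Rcpp::export]]
List cppWindowStream(const arma::mat& X, const arma::mat& Z, const arma::vec& y,
                     const IntegerVector& id, int Jmax, int trainN, int m,
                     int refitEvery, int refitMaxIter, double tol,
                     const arma::vec& beta0, const arma::mat& phi0,
                     double sigma20, double phiFloorRel,
                     const IntegerVector& checkpointAt,
                     bool finalConverge, int finalMaxIter) {
  const int T = X.n_rows, p = X.n_cols, r = Z.n_cols;
  cube ZtZ(r, r, Jmax, fill::zeros), XtZ(p, r, Jmax, fill::zeros),
       XtXj(p, p, Jmax, fill::zeros);
  mat Zty(r, Jmax, fill::zeros), Xtyj(p, Jmax, fill::zeros);
  vec yty(Jmax, fill::zeros);
  ivec nj(Jmax, fill::zeros);
  mat XtX(p, p, fill::zeros);
  vec Xty(p, fill::zeros);
  int nWin = 0;
  // circular row buffer for eviction
  int cap = (m > 0) ? m : 1;
  mat Xbuf(p, cap), Zbuf(r, cap);
  vec ybuf(cap);
  ivec idbuf(cap);
  int head = 0;

  vec beta = beta0;
  mat phi = phi0;
  double sigma2 = sigma20;
  mat phiInv = phiInverse(phi, phiFloorRel);
  vec preds(std::max(T - trainN, 0));
  const int nCp = checkpointAt.size();
  mat cpParams(nCp, p + r * (r + 1) / 2 + 1, fill::value(datum::nan));
  vec bj(r);
  mat Cj(r, r);

  auto addRow = [&](int t) {
    int j = id[t];
    vec x = X.row(t).t(), z = Z.row(t).t();
    double yt = y(t);
    if (m > 0 && nWin == m) { // evict oldest first
      vec xo = Xbuf.col(head), zo = Zbuf.col(head);
      double yo = ybuf(head);
      int jo = idbuf(head);
      ZtZ.slice(jo) -= zo * zo.t();
      XtZ.slice(jo) -= xo * zo.t();
      XtXj.slice(jo) -= xo * xo.t();
      Zty.col(jo) -= zo * yo;
      Xtyj.col(jo) -= xo * yo;
      yty(jo) -= yo * yo;
      nj(jo) -= 1;
      XtX -= xo * xo.t();
      Xty -= xo * yo;
      --nWin;
    }
    ZtZ.slice(j) += z * z.t();
    XtZ.slice(j) += x * z.t();
    XtXj.slice(j) += x * x.t();
    Zty.col(j) += z * yt;
    Xtyj.col(j) += x * yt;
    yty(j) += yt * yt;
    nj(j) += 1;
    XtX += x * x.t();
    Xty += x * yt;
    ++nWin;
    if (m > 0) {
      Xbuf.col(head) = x;
      Zbuf.col(head) = z;
      ybuf(head) = yt;
      idbuf(head) = j;
      head = (head + 1) % m;
    }
  };

  auto refit = [&](int maxIter, double tolUse) {
    int Jw = 0;
    for (int j = 0; j < Jmax; ++j) if (nj(j) > 0) ++Jw;
    if (Jw < 1 || nWin < p) return;
    mat XtXinv;
    if (!inv_sympd(XtXinv, symmatu(XtX))) return; // keep previous estimates
    rowvec prev = packParams(beta, phi, sigma2);
    vec t1v(p), bv(r);
    mat Cv(r, r), T2v(r, r);
    double t3v;
    for (int it = 0; it < maxIter; ++it) {
      vec t1(p, fill::zeros);
      mat T2(r, r, fill::zeros);
      double t3 = 0.0;
      for (int j = 0; j < Jmax; ++j) {
        if (nj(j) <= 0) continue;
        estepOne(ZtZ.slice(j), XtZ.slice(j), Zty.col(j), XtXj.slice(j),
                 Xtyj.col(j), yty(j), beta, phiInv, sigma2,
                 bv, Cv, t1v, T2v, t3v);
        t1 += t1v; T2 += T2v; t3 += t3v;
      }
      beta = XtXinv * (Xty - t1);
      phi = symmatu(T2 / (double) Jw);
      sigma2 = std::max(t3 / (double) nWin, 1e-10);
      phiInv = phiInverse(phi, phiFloorRel);
      rowvec cur = packParams(beta, phi, sigma2);
      double delta = abs(cur - prev).max();
      prev = cur;
      if (delta < tolUse) break;
    }
  };

  for (int t = 0; t < trainN && t < T; ++t) addRow(t);
  int sinceRefit = 0;
  for (int t = trainN; t < T; ++t) {
    int j = id[t];
    if (j < 0 || j >= Jmax) stop("individual index out of range at stream position %d", t + 1);
    vec x = X.row(t).t(), z = Z.row(t).t();
    double bhatz = 0.0;
    if (nj(j) > 0) { // posterior mean from currently held data, else 0
      mat C = symmatu(ZtZ.slice(j) + sigma2 * phiInv);
      if (!inv_sympd(Cj, C)) Cj = pinv(C);
      bj = Cj * (Zty.col(j) - XtZ.slice(j).t() * beta);
      bhatz = dot(z, bj);
    }
    preds(t - trainN) = dot(x, beta) + bhatz;
    addRow(t);
    if (++sinceRefit >= refitEvery) {
      sinceRefit = 0;
      refit(refitMaxIter, tol);
    }
    for (int k = 0; k < nCp; ++k)
      if (checkpointAt[k] == t + 1) cpParams.row(k) = packParams(beta, phi, sigma2);
  }
  if (finalConverge) refit(finalMaxIter, tol);

  return List::create(
    Named("beta") = beta, Named("phi") = phi, Named("sigma2") = sigma2,
    Named("predictions") = preds, Named("checkpointParams") = cpParams,
    Named("nWindow") = nWin);
}
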