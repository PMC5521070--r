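// GY94-style codon substitution model over the 61 sense codons:
// q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous] for codon pairs
// differing at exactly one position, normalized to one expected
// substitution per codon per unit time, with branch lengths from the input
// tree multiplied by one free global scale. Likelihood by Felsenstein
// pruning with gapped/ambiguous codons as missing data. The free-omega fit
// profiles the scale and omega by alternating golden-section searches.

#include <RcppArmadillo.h>
#include <functional>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct CodonModel {
  arma::vec pi;        // stationary codon frequencies (61)
  arma::vec sqp;       // sqrt(pi)
  arma::vec eigval;
  arma::mat eigvec;    // of the symmetrized rate matrix
};

// type(i,j): 0 = multi-nt change, 1 syn transversion, 2 syn transition,
// 3 nonsyn transversion, 4 nonsyn transition
static CodonModel build_model(const arma::vec& pi, const arma::imat& type,
                              double kappa, double omega) {
  int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      int t = type(i, j);
      if (t == 0) continue;
      double r = pi(j);
      if (t == 2 || t == 4) r *= kappa;
      if (t >= 3) r *= omega;
      Q(i, j) = r;
    }
  }
  arma::vec rs = arma::sum(Q, 1);
  Q.diag() = -rs;
  double mu = arma::dot(pi, rs);  // mean rate
  if (mu > 0) Q /= mu;
  CodonModel m;
  m.pi = pi;
  m.sqp = arma::sqrt(pi);
  arma::mat A = Q;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      A(i, j) = Q(i, j) * m.sqp(i) / m.sqp(j);
  A = 0.5 * (A + A.t());  // symmetrize numerical noise
  arma::eig_sym(m.eigval, m.eigvec, A);
  return m;
}

static arma::mat pmat(const CodonModel& m, double t) {
  arma::vec e = arma::exp(m.eigval * t);
  arma::mat P = m.eigvec * arma::diagmat(e) * m.eigvec.t();
  int n = m.pi.n_elem;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = P(i, j) * m.sqp(j) / m.sqp(i);
      P(i, j) = v > 0 ? v : 0.0;
    }
  return P;
}

// states: ntaxa x nsites, 0-based codon index, -1 missing.
// edge: nedge x 2 (1-based ape node ids, postorder), edge_len parallel.
static double loglik(const CodonModel& m, const arma::imat& states,
                     const arma::imat& edge, const arma::vec& edge_len,
                     int ntaxa, double scale) {
  int nsites = states.n_cols;
  int nstate = m.pi.n_elem;
  int nnode = edge.max();
  std::vector<arma::mat> partial(nnode + 1);
  // many trees reuse a handful of distinct branch lengths; cache P by t
  std::map<double, arma::mat> pcache;
  // tips
  for (int tip = 1; tip <= ntaxa; ++tip) {
    arma::mat L(nstate, nsites, arma::fill::zeros);
    for (int s = 0; s < nsites; ++s) {
      int st = states(tip - 1, s);
      if (st < 0) L.col(s).ones();
      else L(st, s) = 1.0;
    }
    partial[tip] = L;
  }
  std::vector<double> logscale(nsites, 0.0);
  for (unsigned int e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0), child = edge(e, 1);
    if (partial[par].n_elem == 0)
      partial[par] = arma::mat(nstate, nsites, arma::fill::ones);
    double t = scale * edge_len(e);
    auto it = pcache.find(t);
    if (it == pcache.end()) it = pcache.emplace(t, pmat(m, t)).first;
    partial[par] %= it->second * partial[child];
    // rescale to avoid underflow
    arma::rowvec mx = arma::max(partial[par], 0);
    for (int s = 0; s < nsites; ++s) {
      if (mx(s) > 0 && mx(s) < 1e-100) {
        partial[par].col(s) /= mx(s);
        logscale[s] += std::log(mx(s));
      }
    }
  }
  int root = edge(edge.n_rows - 1, 0);
  arma::rowvec site = m.pi.t() * partial[root];
  double ll = 0.0;
  for (int s = 0; s < nsites; ++s) {
    double v = site(s);
    ll += (v > 0 ? std::log(v) : -745.0) + logscale[s];
  }
  return ll;
}

// golden-section maximization on [lo, hi]
static double golden(const std::function<double(double)>& f, double lo,
                     double hi, double tol, double* fbest) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = f(x1), f2 = f(x2);
  while (b - a > tol) {
    if (f1 < f2) { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = f(x2); }
    else { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = f(x1); }
  }
  double x = (f1 > f2) ? x1 : x2;
  if (fbest) *fbest = std::max(f1, f2);
  return x;
}

// [[Rcpp::export]]
double cpp_codon_loglik(IntegerMatrix states_, NumericVector pi_,
                        IntegerMatrix type_, double kappa, double omega,
                        double scale, IntegerMatrix edge_,
                        NumericVector edge_len_, int ntaxa) {
  arma::imat states = as<arma::imat>(states_);
  arma::vec pi = as<arma::vec>(pi_);
  arma::imat type = as<arma::imat>(type_);
  arma::imat edge = as<arma::imat>(edge_);
  arma::vec edge_len = as<arma::vec>(edge_len_);
  CodonModel m = build_model(pi, type, kappa, omega);
  return loglik(m, states, edge, edge_len, ntaxa, scale);
}

// [[Rcpp::export]]
NumericMatrix cpp_codon_pmat(NumericVector pi_, IntegerMatrix type_,
                             double kappa, double omega, double t) {
  arma::vec pi = as<arma::vec>(pi_);
  arma::imat type = as<arma::imat>(type_);
  CodonModel m = build_model(pi, type, kappa, omega);
  return wrap(pmat(m, t));
}

// one eigendecomposition, many branch lengths
// [[Rcpp::export]]
List cpp_codon_pmats(NumericVector pi_, IntegerMatrix type_, double kappa,
                     double omega, NumericVector ts) {
  arma::vec pi = as<arma::vec>(pi_);
  arma::imat type = as<arma::imat>(type_);
  CodonModel m = build_model(pi, type, kappa, omega);
  List out(ts.size());
  for (int i = 0; i < ts.size(); ++i) out[i] = wrap(pmat(m, ts[i]));
  return out;
}

// [[Rcpp::export]]
List cpp_codon_lrt(IntegerMatrix states_, NumericVector pi_,
                   IntegerMatrix type_, double kappa, IntegerMatrix edge_,
                   NumericVector edge_len_, int ntaxa,
                   double omega_min = 1e-4, double omega_max = 20.0,
                   double scale_min = 1e-4, double scale_max = 100.0,
                   double tol = 0.05) {
  arma::imat states = as<arma::imat>(states_);
  arma::vec pi = as<arma::vec>(pi_);
  arma::imat type = as<arma::imat>(type_);
  arma::imat edge = as<arma::imat>(edge_);
  arma::vec edge_len = as<arma::vec>(edge_len_);

  auto lik_os = [&](double omega, double scale) {
    CodonModel m = build_model(pi, type, kappa, omega);
    return loglik(m, states, edge, edge_len, ntaxa, scale);
  };
  auto opt_scale = [&](double omega, double* fbest) {
    CodonModel m = build_model(pi, type, kappa, omega);
    auto f = [&](double ls) {
      return loglik(m, states, edge, edge_len, ntaxa, std::exp(ls));
    };
    double ls = golden(f, std::log(scale_min), std::log(scale_max), tol, fbest);
    return std::exp(ls);
  };

  // fixed model: omega = 1, scale profiled
  double lnl_fixed;
  double s_fixed = opt_scale(1.0, &lnl_fixed);

  // free model: alternate omega and scale searches
  double s = s_fixed;
  double lnl_free = lnl_fixed, omega_hat = 1.0;
  for (int round = 0; round < 2; ++round) {
    double before = lnl_free;
    double fw;
    auto fo = [&](double lw) { return lik_os(std::exp(lw), s); };
    double lw = golden(fo, std::log(omega_min), std::log(omega_max), tol, &fw);
    double w = std::exp(lw);
    if (fw > lnl_free) { lnl_free = fw; omega_hat = w; }
    // when the omega pass barely improves on omega = 1 the scale profile
    // is already converged; skip the re-optimization
    if (lnl_free - before < 0.1) break;
    double fs;
    double s_new = opt_scale(w, &fs);
    if (fs > lnl_free) { lnl_free = fs; omega_hat = w; s = s_new; }
    // a second alternation round only pays off when the first one moved
    if (lnl_free - before < 0.5) break;
  }
  if (lnl_free < lnl_fixed) { lnl_free = lnl_fixed; }
  return List::create(
    _["lnl_fixed"] = lnl_fixed, _["lnl_free"] = lnl_free,
    _["omega_hat"] = omega_hat, _["scale_fixed"] = s_fixed,
    _["scale_free"] = s);
}
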