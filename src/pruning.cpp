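// Felsenstein pruning over compressed codon site patterns.
// Nodes follow the ape convention: tips 1..ntip, root ntip+1, internal
// nodes above; edges must arrive in postorder (children before parents).
// Per-branch transition matrices are built here from the eigensystem of
// the (reversible) class generator: P(t) = A diag(exp(vals t)) B.
// Tip children contribute single columns of P (their state is observed),
// so the full matrix product is only needed for internal children.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
double pruneLoglikC(const arma::imat &edges, const arma::vec &lengths,
                    const arma::ivec &classFg,
                    const arma::mat &Abg, const arma::vec &valsBg,
                    const arma::mat &Bbg,
                    const arma::mat &Afg, const arma::vec &valsFg,
                    const arma::mat &Bfg,
                    const arma::imat &tipPatterns,
                    const arma::vec &weights, const arma::vec &pi,
                    int nnode) {
    const int ntip = tipPatterns.n_rows;
    const int npat = tipPatterns.n_cols;
    const int ns = pi.n_elem;
    const int ntot = ntip + nnode;

    std::vector<arma::mat> L(ntot);
    std::vector<bool> seen(ntot, false);
    arma::rowvec logscale(npat, arma::fill::zeros);

    const int ne = edges.n_rows;
    for (int e = 0; e < ne; ++e) {
        int par = edges(e, 0) - 1, ch = edges(e, 1) - 1;
        const bool fg = classFg(e) != 0;
        const arma::mat &A = fg ? Afg : Abg;
        const arma::mat &B = fg ? Bfg : Bbg;
        const arma::vec &v = fg ? valsFg : valsBg;
        arma::mat P = A * (arma::diagmat(arma::exp(v * lengths(e))) * B);
        P.transform([](double x) { return x < 0 ? 0.0 : x; });
        arma::mat contrib(ns, npat);
        if (ch < ntip) {
            arma::vec rs = arma::sum(P, 1);   // missing state: sum_j P_ij
            for (int p = 0; p < npat; ++p) {
                int st = tipPatterns(ch, p);
                if (st == 0) contrib.col(p) = rs;
                else contrib.col(p) = P.col(st - 1);
            }
        } else {
            contrib = P * L[ch];
        }
        if (!seen[par]) { L[par] = std::move(contrib); seen[par] = true; }
        else            L[par] %= contrib;
        // rescale columns to guard against underflow
        arma::rowvec mx = arma::max(L[par], 0);
        for (int p = 0; p < npat; ++p) {
            if (mx(p) > 0 && mx(p) < 1e-200) {
                L[par].col(p) /= mx(p);
                logscale(p) += std::log(mx(p));
            }
        }
    }

    const arma::mat &root = L[ntip];   // ape root index = ntip + 1
    double ll = 0.0;
    for (int p = 0; p < npat; ++p) {
        double lik = arma::dot(pi, root.col(p));
        if (lik <= 0) return -std::numeric_limits<double>::infinity();
        ll += weights(p) * (std::log(lik) + logscale(p));
    }
    return ll;
}
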