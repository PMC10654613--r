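// Registration glue for the compiled NMF kernel.
#include <RcppArmadillo.h>
#include <Rcpp.h>

using namespace Rcpp;

Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol);

RcppExport SEXP _epistrat_nmf_kl_cpp(SEXP VSEXP, SEXP WSEXP, SEXP HSEXP,
                                     SEXP max_iterSEXP, SEXP tolSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter<const arma::mat&>::type V(VSEXP);
    Rcpp::traits::input_parameter<arma::mat>::type W(WSEXP);
    Rcpp::traits::input_parameter<arma::mat>::type H(HSEXP);
    Rcpp::traits::input_parameter<int>::type max_iter(max_iterSEXP);
    Rcpp::traits::input_parameter<double>::type tol(tolSEXP);
    rcpp_result_gen = Rcpp::wrap(nmf_kl_cpp(V, W, H, max_iter, tol));
    return rcpp_result_gen;
END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
    {"_epistrat_nmf_kl_cpp", (DL_FUNC) &_epistrat_nmf_kl_cpp, 5},
    {NULL, NULL, 0}
};

RcppExport void R_init_epistrat(DllInfo *dll) {
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
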