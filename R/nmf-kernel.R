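# Wrapper for the compiled KL-NMF multiplicative-update kernel.
.nmf_kl_cpp <- function(V, W, H, max_iter, tol) {
  .Call("_epistrat_nmf_kl_cpp", V, W, H, max_iter, tol,
        PACKAGE = "epistrat")
}
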