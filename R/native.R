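# Glue to the compiled Metropolis-within-Gibbs sampler (src/ar1_poisson.cpp).
ar1_poisson_chain <- function(O, Y, n_draws, n_warmup, prior_var) {
  .Call("_synsurv_ar1_poisson_chain", as.numeric(O), as.numeric(Y),
        as.integer(n_draws), as.integer(n_warmup), as.numeric(prior_var),
        PACKAGE = "synsurv")
}
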