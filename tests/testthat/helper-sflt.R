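# Shared fixtures: the packaged reference parameter set (ensemble medians
# for HUVEC sFLT1 secretion) and small helpers used across test files.

ref <- reference_params()
m2 <- sflt_model("M2")
m1 <- sflt_model("M1")

# reference params recast for the no-delay model
ref_m1 <- local({
  v <- unclass(ref)
  v["tau"] <- 0
  do.call(sflt_params, as.list(v))
})

# noiseless synthetic study set emulating the three experimental designs
noiseless_designs <- function() {
  list(synthetic_design("hornig_like", noise_cv = 0),
       synthetic_design("kinghorn_like", noise_cv = 0),
       synthetic_design("jung_like", noise_cv = 0))
}

noiseless_datasets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(noiseless_designs(),
                       function(d) generate_dataset(ref, d, m2))
    }
    cache
  }
})

rel_err <- function(x, y) abs(x - y) / abs(y)
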