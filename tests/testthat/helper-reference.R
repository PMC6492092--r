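# The shared reference simulation (shipped default configuration, fixed
# seed), computed once per test session and reused by every block that
# interrogates it.

ref_run <- function() {
  memo("ref_run", run_pipeline(default_config(), seed = 1))
}

# same acquisition, non-rigid GMD reconstruction with ground-truth
# deformation fields (validation mode)
ref_run_true <- function() {
  memo("ref_run_true",
       run_pipeline(default_config(), seed = 1,
                    variants = c("uncorrected", "nonrigid"),
                    use_true_fields = TRUE))
}

nrmse_of <- function(res, parity, variant) {
  tab <- res$metrics$nrmse
  tab$nrmse[tab$parity == parity & tab$variant == variant]
}
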