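# Cached scaled replication runs shared by several test files: the case-1
# study at the package's scaled problem sizes. Computed on first use.
.harness_cache <- new.env(parent = emptyenv())

case1_replication <- function(n, M) {
  key <- sprintf("case1_n%d_M%d", n, M)
  if (!exists(key, envir = .harness_cache)) {
    res <- cscp_replicate(1, n, M, models = "deep-cp",
                          control = harness_control(), base_seed = 1L)
    assign(key, res, envir = .harness_cache)
  }
  get(key, envir = .harness_cache)
}
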