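# Small shared fixtures, built once per test run.

small_genome <- function(seed = 11) {
  generate_genome(n_genes = 600, n_chromosomes = 8,
                  complex_fraction = 0.33, seed = seed)
}

# memoised default study used by several files (4,800 genes, 12 strains)
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_disome_study(seed = 42)
    cache
  }
})

small_study <- function(seed = 7, ...) {
  generate_disome_study(genome = small_genome(seed), n_aps = 20,
                        seed = seed, ...)
}

# planted-label lookup: is (gene, strain) attenuated in the truth?
planted_attenuated <- function(study, calls_df) {
  mapply(function(g, s) g %in% study$truths[[s]]$attenuated_genes,
         calls_df$gene, calls_df$strain, USE.NAMES = FALSE)
}

# independent brute-force hypergeometric upper tail via bitmask
# enumeration of every n-subset of an N-element universe
enumerate_hyper_p <- function(N, K, n, k) {
  masks <- 0:(2^N - 1)
  bits <- sapply(0:(N - 1), function(b) bitwAnd(masks, 2^b) > 0)
  popcount <- rowSums(bits)
  overlap <- if (K > 0) rowSums(bits[, seq_len(K), drop = FALSE]) else 0
  subs <- popcount == n   # first K elements form the target set
  sum(subs & overlap >= k) / sum(subs)
}
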