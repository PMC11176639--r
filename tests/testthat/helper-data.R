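# small programmatic fixtures

make_counts <- function(m, samples = sprintf("S%d", seq_len(nrow(m))),
                        taxa = sprintf("T%d", seq_len(ncol(m))),
                        kind = "counts") {
  dimnames(m) <- list(samples, taxa)
  comm_table(m, kind)
}

random_counts <- function(n, t, depth = 500, seed = 1) {
  set.seed(seed)
  m <- t(stats::rmultinom(n, depth, stats::rlnorm(t)))
  make_counts(m)
}
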