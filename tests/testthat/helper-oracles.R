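# Independent brute-force evaluations of the index formulas, used as oracles
# against the vectorized implementations.

aci_brute <- function(mat, frames_per_chunk) {
  total <- 0
  n_chunks <- ceiling(ncol(mat) / frames_per_chunk)
  for (b in seq_len(nrow(mat))) {
    for (cchunk in seq_len(n_chunks)) {
      cols <- ((cchunk - 1) * frames_per_chunk + 1):
        min(cchunk * frames_per_chunk, ncol(mat))
      if (length(cols) < 2) next
      v <- mat[b, cols]
      d <- 0
      for (k in seq_len(length(v) - 1)) d <- d + abs(v[k + 1] - v[k])
      if (sum(v) > 0) total <- total + d / sum(v)
    }
  }
  total
}

entropy_brute <- function(p) {
  p <- p / sum(p)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}
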