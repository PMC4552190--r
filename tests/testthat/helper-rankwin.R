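# shared fixture builders and independent oracles

# tiny two-condition, two-replicate table built in code
tiny_table <- function(n = 6, lengths = NULL, counts = NULL,
                       descriptions = NULL) {
  ids <- sprintf("e%02d", seq_len(n))
  if (is.null(lengths)) lengths <- rep(1000L, n)
  samples <- c("NR_1", "NR_2", "ND_1", "ND_2")
  if (is.null(counts))
    counts <- matrix(100L, n, 4, dimnames = list(ids, samples))
  else dimnames(counts) <- list(ids, samples)
  ests <- data.frame(est_id = ids, length_bp = lengths,
                     stringsAsFactors = FALSE)
  if (!is.null(descriptions)) ests$description <- descriptions
  est_table(ests, .tiny_design(), counts = counts)
}

.tiny_design <- function() {
  data.frame(sample_id = c("NR_1", "NR_2", "ND_1", "ND_2"),
             condition = rep(c("N_replete", "N_depleted"), each = 2),
             replicate = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE)
}

# a ranking over ids r1..rN in that order (rank 1 = r1)
fixed_ranking <- function(N) {
  ids <- sprintf("r%04d", seq_len(N))
  structure(data.frame(rank = seq_len(N), est_id = ids,
                       key = rev(seq_len(N)), stringsAsFactors = FALSE),
            mode = "by_level", class = c("est_ranking", "data.frame"))
}

# independent binomial upper tail: explicit sum of choose() terms
binom_tail_oracle <- function(x, n, p) {
  if (x <= 0) return(1)
  k <- x:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# brute-force windows: slide a start index until the window no longer fits
windows_oracle <- function(N, w, s) {
  starts <- integer(0)
  st <- 1L
  while (st + w - 1L <= N) {
    starts <- c(starts, st)
    st <- st + as.integer(s)
  }
  starts
}

# brute-force overlap tail by enumerating all draws of size a from the
# universe, against a fixed reference set of size b (N_u <= 12 only)
overlap_tail_oracle <- function(N_u, a, b, k) {
  draws <- utils::combn(N_u, a)
  mean(apply(draws, 2, function(d) sum(d <= b) >= k))
}
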