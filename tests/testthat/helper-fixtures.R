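# Shared fixtures, built in code at test time.

toy_proteins <- function() {
  tibble::tibble(
    id = c("P1", "P2"),
    sequence = c("MASTYKLMNPQRSTVWYACDEFGHIKLMNPQRSTV",
                 "MKKRRSTAYWVLMNPQRSTVWYACDEFGHIKLMNP")
  )
}

# one protein long enough for interior 31-windows
long_protein <- function(seed = 1) {
  rng <- phosppi:::rng_local(seed)
  tibble::tibble(
    id = "LONG1",
    sequence = paste(rng$sample_vec(phosppi:::AA_LETTERS, 120, replace = TRUE),
                     collapse = "")
  )
}

# brute-force single-head attention oracle: explicit loops, no shared code
attention_oracle <- function(Q, K, V) {
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) {
      s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(Q))
    }
    w <- exp(s) / sum(exp(s))
    for (j in seq_len(nrow(K))) {
      out[i, ] <- out[i, ] + w[j] * V[j, ]
    }
  }
  out
}

# O(n^2) pair-counting AUROC oracle
auroc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
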