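# Independent oracles used across tests.

# Brute-force two-pass Pearson correlation.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Full-enumeration conditional NB split test: normalized pmf over all
# splits of the total, summing probabilities as small or smaller than the
# observed split's.
nb_exact_oracle <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  k <- 0:t
  pr <- if (phi == 0) {
    dbinom(k, t, na / (na + nb))
  } else {
    ra <- na / phi; rb <- nb / phi
    lp <- lchoose(k + ra - 1, k) + lchoose(t - k + rb - 1, t - k)
    v <- exp(lp - max(lp))
    v / sum(v)
  }
  sum(pr[pr <= pr[ya + 1] * (1 + 1e-9)])
}

# Quick NB count matrix with optional per-gene means.
rand_counts <- function(n_genes, n_samples, mu = 100, phi = 0.2,
                        prefix = "g") {
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / phi),
              nrow = n_genes,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "double"
  m
}

# Study-shaped sample table: 6 AI / 6 NB / 5 non-pregnant, one year.
study_samples <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:17),
    outcome = factor(rep(c("AI_PREG", "NB_PREG", "NON_PREG"), c(6, 6, 5)),
                     levels = c("AI_PREG", "NB_PREG", "NON_PREG")),
    year = 1L, stringsAsFactors = FALSE)
}
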