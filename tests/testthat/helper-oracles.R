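# Independent brute-force oracles, deliberately naive: the implementations
# under test must agree with these on small inputs.

# Co-occurrence matrix by explicit double loop over every pixel and offset.
oracle_glcm <- function(levelled, dr, dc, G, symmetric) {
  m <- matrix(0, G, G)
  h <- nrow(levelled); w <- ncol(levelled)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      i <- levelled[r, c]; j <- levelled[r2, c2]
      if (is.na(i) || is.na(j)) next
      m[i + 1, j + 1] <- m[i + 1, j + 1] + 1
      if (symmetric) m[j + 1, i + 1] <- m[j + 1, i + 1] + 1
    }
  }
  if (sum(m) == 0) return(NULL)
  m / sum(m)
}

# Exact two-tailed Mann-Whitney p by full enumeration of the
# choose(na+nb, na) assignments of pooled ranks to group a (tie-free data).
oracle_mwu_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(idx) sum(sort(rk)[idx]) - na * (na + 1) / 2)
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  min(1, 2 * min(lower, upper))
}
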