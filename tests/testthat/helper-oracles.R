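# Independent oracles used to cross-check the implementation.

# Exhaustive O(n*m) proximity computation: outer loop over T cells, inner
# (vectorized) over Tregs, distances kept in Treg-index order.
brute_proximity <- function(tcells, tregs, radius, mode = "pairwise") {
  d_all <- numeric(0)
  for (i in seq_len(nrow(tcells))) {
    d <- sqrt((tcells$x_um[i] - tregs$x_um)^2 +
                (tcells$y_um[i] - tregs$y_um)^2)
    if (mode == "pairwise") {
      d_all <- c(d_all, d[d <= radius])
    } else {
      if (length(d) > 0L && min(d) <= radius) d_all <- c(d_all, min(d))
    }
  }
  list(n_pairs = length(d_all),
       mean_distance_um = if (length(d_all)) mean(d_all) else NA_real_,
       distances = d_all)
}

# Exhaustive window oracle for novel 9-mer enumeration from a single
# substitution at position p of a length-L toy protein.
brute_missense_9mers <- function(wildtype, p, alt_aa, k = 9) {
  mutant <- wildtype
  substr(mutant, p, p) <- alt_aa
  L <- nchar(mutant)
  if (L < k) return(character(0))
  peps <- character(0)
  for (s in 1:(L - k + 1)) {
    if (p >= s && p <= s + k - 1) peps <- c(peps, substr(mutant, s, s + k - 1))
  }
  wt <- character(0)
  for (s in 1:(nchar(wildtype) - k + 1)) {
    wt <- c(wt, substr(wildtype, s, s + k - 1))
  }
  unique(peps[!peps %in% wt])
}

# Exact two-sided Mann-Whitney p by complete enumeration of group labelings
# (small n only).
enum_mannwhitney_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
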