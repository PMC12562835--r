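# Independent brute-force oracles. These re-derive expected values by
# exhaustive enumeration and deliberately share no code with the package's
# implementations.

# all permutations of 1..n by the insertion method
oraclePerms <- function(n) {
  out <- list(integer(0))
  for (k in seq_len(n)) {
    nxt <- list()
    for (p in out)
      for (pos in 0:(k - 1))
        nxt[[length(nxt) + 1L]] <- append(p, k, after = pos)
    out <- nxt
  }
  out
}

# minimal number of mutation events explaining allele multisets A vs B at a
# marker with `expected` copies: enumerates every copy-assignment scenario
# (all injections of the smaller multiset into the larger, both homoallelic
# readings of a single peak when expected == 2), charging |step difference|
# per matched same-microvariant pair, 1 per microvariant mismatch, and 1 per
# unmatched (gained/lost) copy.
oracleMinEvents <- function(A, B, expected = 2L) {
  if (all(is.na(A)) && all(is.na(B))) return(0L)
  if (anyNA(A) || anyNA(B)) return(1L)
  pairCost <- function(a, b) {
    da <- round(a * 10); db <- round(b * 10)
    if (da == db) 0L
    else if (da %% 10 != db %% 10) 1L
    else as.integer(abs(da - db) %/% 10)
  }
  readings <- function(X) {
    r <- list(X)
    if (length(X) == 1L && expected == 2L) r <- c(r, list(c(X, X)))
    r
  }
  best <- Inf
  for (Ai in readings(A)) for (Bi in readings(B)) {
    sm <- if (length(Ai) <= length(Bi)) Ai else Bi
    lg <- if (length(Ai) <= length(Bi)) Bi else Ai
    for (p in oraclePerms(length(lg))) {
      cost <- length(lg) - length(sm)
      for (i in seq_along(sm)) cost <- cost + pairCost(sm[i], lg[p[i]])
      best <- min(best, cost)
    }
  }
  as.integer(best)
}

# all multisets of the given sizes with repeats drawn from `values`
oracleMultisets <- function(values, sizes = 1:3) {
  out <- list()
  for (s in sizes) {
    cmb <- utils::combn(length(values) + s - 1, s)
    for (j in seq_len(ncol(cmb))) {
      idx <- cmb[, j] - seq_len(s) + 1L   # combinations with repetition
      out[[length(out) + 1L]] <- values[idx]
    }
  }
  out
}

# two-sided Fisher exact p-values for every x1 at fixed margins, by direct
# binomial-coefficient enumeration (sorting + cumulative sums); returns a
# vector indexed by x1 over the support.
oracleFisherAll <- function(n1, n2, k) {
  supp <- max(0L, k - n2):min(k, n1)
  logp <- lchoose(n1, supp) + lchoose(n2, k - supp) - lchoose(n1 + n2, k)
  pr <- exp(logp)
  # p(x) = total probability of tables no more likely than x (with the
  # customary relative tolerance for floating-point ties)
  p <- vapply(seq_along(supp), function(i) {
    sum(pr[pr <= pr[i] * (1 + 1e-7)])
  }, numeric(1))
  names(p) <- supp
  pmin(p, 1)
}
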