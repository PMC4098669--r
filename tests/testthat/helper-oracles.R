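# Independent oracles used across the suite. These deliberately use
# different algorithms/arithmetic than the package implementation.

# Compatible child dosages by enumerating transmitted alleles.
oracle_compatible_child <- function(gf, gm) {
  trans <- function(g) {
    if (is.na(g)) return(0:1)
    switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
  }
  sort(unique(as.vector(outer(trans(gf), trans(gm), "+"))))
}

# Informativeness by enumerating consistent (paternal, maternal)
# transmitted-allele pairs for a trio genotype combination.
oracle_informative <- function(gc, gf, gm) {
  if (is.na(gc)) return(c(paternal = FALSE, maternal = FALSE))
  trans <- function(g) if (is.na(g)) 0:1 else
    switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
  pairs <- expand.grid(tf = trans(gf), tm = trans(gm))
  pairs <- pairs[pairs$tf + pairs$tm == gc, , drop = FALSE]
  if (nrow(pairs) == 0L) return(c(paternal = FALSE, maternal = FALSE))
  c(paternal = length(unique(pairs$tf)) == 1L,
    maternal = length(unique(pairs$tm)) == 1L)
}

# Window-based shared-segment oracle: is the marker window [i, j]
# shareable by `subset` (some chromosome choice per member is consistent
# at every marker), and with how many fully witnessed markers?
oracle_window_ok <- function(phased, subset, idx) {
  k <- length(subset)
  choices <- expand.grid(rep(list(c("pat", "mat")), k),
                         stringsAsFactors = FALSE)
  for (r in seq_len(nrow(choices))) {
    H <- t(vapply(seq_len(k), function(i)
      phased[[choices[r, i]]][subset[i], idx], numeric(length(idx))))
    ok <- TRUE
    wit <- 0L
    for (j in seq_along(idx)) {
      vals <- H[, j][!is.na(H[, j])]
      if (length(vals) && length(unique(vals)) > 1L) { ok <- FALSE; break }
      if (length(vals) == k) wit <- wit + 1L
    }
    if (ok) return(list(ok = TRUE, witnessed = wit, choice = choices[r, ]))
  }
  list(ok = FALSE, witnessed = 0L)
}

# Exhaustive two-sided Fisher p by lchoose arithmetic (sum of point
# probabilities <= observed).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  lp <- vapply(lo:hi, function(x)
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1), numeric(1))
  p <- exp(lp)
  p_obs <- p[a - lo + 1L]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# HWE exact p by enumerating genotype configurations with choose()
# pairing counts (conditional on allele counts).
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0) return(1)
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  w <- vapply(hets, function(h) {
    naa <- (na - h) / 2; nbb <- (nb - h) / 2
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb)
        + h * log(2))
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Apply a (pos, ref, alt) edit to a sequence string.
apply_edit <- function(seqs, chrom, pos, ref, alt) {
  s <- seqs[[chrom]]
  stopifnot(substr(s, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(s, 1, pos - 1), alt, substr(s, pos + nchar(ref), nchar(s)))
}

# Reciprocal overlap of two 1-based inclusive intervals.
reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  min(inter / (e1 - s1 + 1), inter / (e2 - s2 + 1))
}
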