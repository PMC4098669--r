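#' Greedy LD pruning in a moving window
#'
#' Slides a window of `window` SNPs (advancing by `step`) and, scanning
#' pairs left to right, removes the later SNP of any retained pair whose
#' squared genotype correlation reaches `r2_max`. After pruning, all
#' retained pairs within any window satisfy r-squared < `r2_max`.
#'
#' @param geno individuals x SNPs dosage matrix (0/1/2, NA allowed);
#'   colnames are SNP ids.
#' @param r2_max maximum allowed pairwise r-squared (default 0.25).
#' @param window window size in SNPs (default 50).
#' @param step window advance in SNPs (default 1).
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(geno, r2_max = 0.25, window = 50, step = 1) {
  stopifnot(window >= 2, step >= 1)
  M <- ncol(geno)
  if (M == 0L) return(character(0))
  removed <- rep(FALSE, M)
  starts <- seq(1L, max(M - 1L, 1L), by = step)
  for (s in starts) {
    e <- min(s + window - 1L, M)
    if (e <= s) next
    idx <- s:e
    for (a in seq_along(idx)[-length(idx)]) {
      i <- idx[a]
      if (removed[i]) next
      for (b in (a + 1):length(idx)) {
        j <- idx[b]
        if (removed[j]) next
        r <- suppressWarnings(stats::cor(geno[, i], geno[, j],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 >= r2_max) removed[j] <- TRUE
      }
    }
  }
  colnames(geno)[!removed]
}

#' SNP filters ahead of principal-component analysis
#'
#' Applies the stratification-analysis filter set: autosomes only, call
#' rate above `call_rate`, minor allele frequency above `maf`, and LD
#' pruning at `r2_max` within a moving window of `window` SNPs.
#'
#' @param geno individuals x SNPs dosage matrix.
#' @param chrom chromosome label per SNP.
#' @param call_rate,maf,r2_max,window filter thresholds (defaults 0.95,
#'   0.05, 0.25, 50).
#' @return the filtered dosage matrix.
#' @export
pca_snp_filter <- function(geno, chrom, call_rate = 0.95, maf = 0.05,
                           r2_max = 0.25, window = 50) {
  auto <- !grepl("^(chr)?[XY]$", chrom, ignore.case = TRUE)
  cr <- colMeans(!is.na(geno)) > call_rate
  p <- colMeans(geno, na.rm = TRUE) / 2
  mafv <- pmin(p, 1 - p)
  keep <- auto & cr & !is.na(mafv) & mafv > maf
  g <- geno[, keep, drop = FALSE]
  g[, ld_prune(g, r2_max = r2_max, window = window), drop = FALSE]
}

#' Principal-component scores from genotype dosages
#'
#' Dosages are mean-imputed, centered and scaled to unit variance per SNP,
#' then decomposed; SNPs with zero variance are dropped. Components are
#' ordered by variance explained.
#'
#' @param geno filtered individuals x SNPs dosage matrix
#'   (see [pca_snp_filter()]).
#' @param n_components number of components returned (default 10).
#' @return matrix of per-sample scores (individuals x components), rownames
#'   preserved.
#' @export
pca_scores <- function(geno, n_components = 10) {
  if (n_components > nrow(geno))
    stop("more components requested than samples")
  g <- apply(geno, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  v <- apply(g, 2, stats::var)
  g <- g[, v > 0, drop = FALSE]
  pc <- stats::prcomp(g, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(geno)
  scores
}

#' Ancestry outliers by distance from the median centroid
#'
#' Computes each sample's Euclidean distance from the coordinate-wise
#' median of the first two principal components and flags samples whose
#' distance exceeds `Q3 + 1.5 * IQR` of the distance distribution.
#'
#' @param pc1,pc2 numeric score vectors (named by sample id when
#'   available).
#' @param quantile_type quantile estimator passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return list with `outliers` (ids or indices), `threshold`, `q3`,
#'   `iqr`, `distance` (per-sample).
#' @export
ancestry_outliers <- function(pc1, pc2, quantile_type = 7) {
  stopifnot(length(pc1) == length(pc2), length(pc1) >= 4)
  centroid <- c(stats::median(pc1), stats::median(pc2))
  d <- sqrt((pc1 - centroid[1])^2 + (pc2 - centroid[2])^2)
  q <- stats::quantile(d, c(0.25, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[2] - q[1]
  thr <- q[2] + 1.5 * iqr
  ids <- names(pc1) %||% seq_along(pc1)
  list(outliers = ids[d > thr], threshold = thr, q3 = q[2], iqr = iqr,
       distance = stats::setNames(d, ids))
}

#' Relatedness pruning: one subject per family
#'
#' Retains, from every family, the member closest to the median centroid
#' of the first two principal components (ties broken by sample-id sort
#' order). Singletons are their own family and always retained.
#'
#' @param families named character vector: sample id -> family id.
#' @param pc1,pc2 score vectors named by sample id.
#' @return character vector of retained sample ids (one per family).
#' @export
relatedness_prune <- function(families, pc1, pc2) {
  ids <- names(families)
  stopifnot(!is.null(ids), all(ids %in% names(pc1)), all(ids %in% names(pc2)))
  centroid <- c(stats::median(pc1[ids]), stats::median(pc2[ids]))
  d <- sqrt((pc1[ids] - centroid[1])^2 + (pc2[ids] - centroid[2])^2)
  keep <- vapply(split(ids, families[ids]), function(mem) {
    mem <- mem[order(mem)]
    mem[which.min(d[mem])]
  }, character(1))
  unname(keep)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, computes the probability of
#' each possible heterozygote count and sums the probabilities of
#' configurations no more likely than the observed one (two-sided exact
#' test, no mid-p correction). A chi-squared alternative (1 df, no
#' continuity correction) is available.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom, het, hom).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-value; 1 for a monomorphic marker.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) stop("no genotypes")
  na <- 2L * n_aa + n_ab         # copies of allele a
  nb <- 2L * n_bb + n_ab
  if (na == 0L || nb == 0L) return(1)
  rare <- min(na, nb)
  if (method == "chisq") {
    p <- na / (2 * n)
    e <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    o <- c(n_aa, n_ab, n_bb)
    x2 <- sum((o - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # possible het counts share the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  logp <- lgamma(n + 1) - lgamma((na - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((nb - hets) / 2 + 1) + hets * log(2) +
    lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}
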