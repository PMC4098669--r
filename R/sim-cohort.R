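#' Simulation settings for a case/control cohort
#'
#' @param n_cases,n_controls cohort sizes (defaults 1541 and 5785, the
#'   scale of a large SNP-array association cohort).
#' @param variants data frame with columns `maf` (control minor-allele
#'   frequency, in (0, 0.5]) and `or` (true allelic odds ratio, > 0); one
#'   row per rare variant.
#' @param n_common number of common SNPs generated for ancestry analyses
#'   (default 0).
#' @param common_maf range of common-SNP allele frequencies.
#' @param clusters optional ancestry structure: list with `n_outliers`
#'   (samples drawn from a diverged subpopulation) and `fst`
#'   (Balding-Nichols divergence of their allele frequencies).
#' @param families optional relatedness structure: list with `n_families`,
#'   `sizes` (vector of family sizes to sample from) and optionally
#'   `correlation` (probability that a relative's common-SNP genotype is
#'   copied from the family's first member; default 0.5); remaining
#'   samples are singletons.
#' @return list of class `SimCohortSpec`.
#' @export
sim_cohort_spec <- function(n_cases = 1541, n_controls = 5785,
                            variants = data.frame(maf = 0.005, or = 2),
                            n_common = 0, common_maf = c(0.1, 0.5),
                            clusters = NULL, families = NULL) {
  stopifnot(all(variants$maf > 0), all(variants$maf <= 0.5),
            all(variants$or > 0))
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 variants = variants, n_common = n_common,
                 common_maf = common_maf, clusters = clusters,
                 families = families),
            class = "SimCohortSpec")
}

# case allele frequency giving allelic odds ratio `or` against control
# frequency p0
.case_freq <- function(p0, or) {
  odds <- or * p0 / (1 - p0)
  p1 <- odds / (1 + odds)
  if (p1 <= 0 || p1 >= 1) stop("case allele frequency outside (0, 1)")
  p1
}

#' Simulate a case/control cohort
#'
#' Rare variants are drawn so that the expected allelic odds ratio equals
#' the specified one: the case allele frequency is solved from the control
#' frequency and the odds ratio, and genotypes are formed under
#' Hardy-Weinberg equilibrium within each group. Common SNPs (for PCA)
#' are drawn at uniform frequencies; designated ancestry outliers use
#' frequencies diverged by a Balding-Nichols model at the given Fst.
#' Family blocks replicate a founder member's genotypes with the given
#' within-family correlation.
#'
#' @param spec a [sim_cohort_spec()].
#' @param seed integer seed.
#' @return list with `counts` (per-variant genotype count table in the
#'   [association_table()] layout), `geno_variants` (samples x variants
#'   dosages), `common` (samples x common SNPs dosages or NULL),
#'   `phenotype` (named "case"/"control"), `cluster` (named;
#'   "main"/"outlier"), `families` (named sample -> family map).
#' @export
simulate_cohort <- function(spec, seed = 1) {
  set.seed(seed)
  n <- spec$n_cases + spec$n_controls
  ids <- sprintf("s%05d", seq_len(n))
  pheno <- stats::setNames(rep(c("case", "control"),
                               c(spec$n_cases, spec$n_controls)), ids)

  nv <- nrow(spec$variants)
  gv <- matrix(0L, n, nv, dimnames = list(ids, sprintf("var%03d", seq_len(nv))))
  for (j in seq_len(nv)) {
    p0 <- spec$variants$maf[j]
    p1 <- .case_freq(p0, spec$variants$or[j])
    p <- ifelse(pheno == "case", p1, p0)
    gv[, j] <- stats::rbinom(n, 1L, p) + stats::rbinom(n, 1L, p)
  }

  counts <- data.frame(variant = colnames(gv))
  case <- pheno == "case"
  counts$het_cases <- colSums(gv[case, , drop = FALSE] == 1L)
  counts$hom_cases <- colSums(gv[case, , drop = FALSE] == 2L)
  counts$wt_cases <- colSums(gv[case, , drop = FALSE] == 0L)
  counts$het_controls <- colSums(gv[!case, , drop = FALSE] == 1L)
  counts$hom_controls <- colSums(gv[!case, , drop = FALSE] == 2L)
  counts$wt_controls <- colSums(gv[!case, , drop = FALSE] == 0L)

  cluster <- stats::setNames(rep("main", n), ids)
  common <- NULL
  if (spec$n_common > 0) {
    p <- stats::runif(spec$n_common, spec$common_maf[1], spec$common_maf[2])
    if (!is.null(spec$clusters) && spec$clusters$n_outliers > 0) {
      out_idx <- sample(n, spec$clusters$n_outliers)
      cluster[out_idx] <- "outlier"
      fst <- spec$clusters$fst
      p_out <- stats::rbeta(spec$n_common,
                            p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
    }
    common <- matrix(0L, n, spec$n_common,
                     dimnames = list(ids, sprintf("snp%04d",
                                                  seq_len(spec$n_common))))
    for (j in seq_len(spec$n_common)) {
      pj <- rep(p[j], n)
      if (any(cluster == "outlier")) pj[cluster == "outlier"] <- p_out[j]
      common[, j] <- stats::rbinom(n, 2L, pj)
    }
  }

  fam <- stats::setNames(paste0("fam_", ids), ids)
  if (!is.null(spec$families) && spec$families$n_families > 0) {
    sizes <- sample(spec$families$sizes, spec$families$n_families,
                    replace = TRUE)
    pool <- sample(ids)
    used <- 0L
    rho <- spec$families$correlation %||% 0.5
    for (f in seq_len(spec$families$n_families)) {
      take <- pool[(used + 1L):min(used + sizes[f], n)]
      fam[take] <- sprintf("family%03d", f)
      if (!is.null(common) && length(take) > 1L && rho > 0) {
        for (mem in take[-1]) {
          cp <- stats::runif(ncol(common)) < rho
          common[mem, cp] <- common[take[1], cp]
        }
      }
      used <- used + length(take)
      if (used >= n) break
    }
  }

  list(counts = counts, geno_variants = gv, common = common,
       phenotype = pheno, cluster = cluster, families = fam)
}
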