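test_that("LD pruning removes correlated SNPs and the retained set passes a
           brute-force pairwise check", {
  set.seed(8)
  n <- 200
  base <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
  # make SNPs 2, 12, 22 near-copies of their left neighbours
  geno <- base
  for (j in c(2, 12, 22)) geno[, j] <- base[, j - 1]
  colnames(geno) <- sprintf("snp%02d", 1:40)
  kept <- ld_prune(geno, r2_max = 0.25, window = 10)
  expect_false(any(c("snp02", "snp12", "snp22") %in% kept))
  expect_true("snp01" %in% kept)
  # brute force: every retained pair within any 10-SNP window has r2 < 0.25
  idx <- match(kept, colnames(geno))
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (b <= a) next
    if (idx[b] - idx[a] >= 10) next
    r2 <- cor(geno[, idx[a]], geno[, idx[b]])^2
    expect_lt(r2, 0.25)
  }
  # independent SNPs are retained
  indep <- matrix(rbinom(n * 20, 2, 0.4), n, 20)
  colnames(indep) <- sprintf("i%02d", 1:20)
  expect_equal(ld_prune(indep, 0.25, 10), colnames(indep))
})

test_that("PCA separates simulated populations and scores are uncorrelated", {
  spec <- sim_cohort_spec(n_cases = 100, n_controls = 100, n_common = 300,
                          clusters = list(n_outliers = 40, fst = 0.15))
  sim <- simulate_cohort(spec, seed = 4)
  sc <- pca_scores(sim$common, n_components = 4)
  lab <- sim$cluster[rownames(sc)]
  # silhouette of the two groups on PC1
  s <- vapply(seq_along(lab), function(i) {
    same <- which(lab == lab[i]); same <- same[same != i]
    own <- mean(abs(sc[i, 1] - sc[same, 1]))
    oth <- mean(abs(sc[i, 1] - sc[lab != lab[i], 1]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(s), 0.8)
  cv <- cov(sc)
  expect_lt(max(abs(cv[upper.tri(cv)])) / max(diag(cv)), 1e-8)
})

test_that("ancestry outlier rule matches hand-computed quartiles", {
  pc1 <- c(-1, -1, -1, 1, 1, 1, 1, 100)
  pc2 <- rep(0, 8)
  names(pc1) <- names(pc2) <- paste0("s", 1:8)
  res <- ancestry_outliers(pc1, pc2)
  # centroid (1, 0); distances 2,2,2,0,0,0,0,99; type-7: Q3 = 2, Q1 = 0
  expect_equal(unname(res$q3), 2)
  expect_equal(unname(res$iqr), 2)
  expect_equal(unname(res$threshold), 5)
  expect_equal(res$outliers, "s8")

  same <- ancestry_outliers(rep(1, 6), rep(2, 6))
  expect_length(same$outliers, 0)
})

test_that("a planted divergent cluster is flagged with few false positives", {
  spec <- sim_cohort_spec(n_cases = 500, n_controls = 500, n_common = 400,
                          clusters = list(n_outliers = 50, fst = 0.2))
  sim <- simulate_cohort(spec, seed = 19)
  sc <- pca_scores(sim$common, n_components = 2)
  res <- ancestry_outliers(sc[, 1], sc[, 2])
  out <- rownames(sc) %in% res$outliers
  planted <- sim$cluster[rownames(sc)] == "outlier"
  expect_gte(mean(out[planted]), 0.9)
  expect_lte(mean(out[!planted]), 0.02)
})

test_that("relatedness pruning keeps exactly the per-family centroid-nearest
           member", {
  spec <- sim_cohort_spec(n_cases = 150, n_controls = 150, n_common = 200,
                          families = list(n_families = 100, sizes = 1:5))
  sim <- simulate_cohort(spec, seed = 23)
  sc <- pca_scores(sim$common, n_components = 2)
  pc1 <- sc[, 1]; pc2 <- sc[, 2]
  fam <- sim$families
  kept <- relatedness_prune(fam, pc1, pc2)
  expect_equal(length(kept), length(unique(fam)))
  expect_equal(length(kept), length(unique(fam[kept])))
  cen <- c(median(pc1[names(fam)]), median(pc2[names(fam)]))
  d <- sqrt((pc1 - cen[1])^2 + (pc2 - cen[2])^2)
  for (k in kept) {
    members <- names(fam)[fam == fam[k]]
    expect_equal(unname(d[k]), min(d[members]), info = fam[k])
  }
  # singletons all retained
  solo <- relatedness_prune(setNames(c("a", "b", "c"), c("x", "y", "z")),
                            setNames(1:3, c("x", "y", "z")),
                            setNames(1:3, c("x", "y", "z")))
  expect_setequal(solo, c("x", "y", "z"))
})

test_that("HWE exact test equals enumeration and behaves at equilibrium", {
  expect_equal(hwe_test(0, 50, 0), oracle_hwe(0, 50, 0))
  expect_lt(hwe_test(0, 50, 0), 1e-6)
  expect_equal(hwe_test(10, 0, 10), oracle_hwe(10, 0, 10))
  expect_lt(hwe_test(10, 0, 10), 1e-4)
  expect_equal(hwe_test(25, 50, 25), oracle_hwe(25, 50, 25))
  expect_gt(hwe_test(25, 50, 25), 0.5)
  expect_equal(hwe_test(30, 0, 0), 1)     # monomorphic
  set.seed(6)
  for (i in 1:25) {
    cts <- as.vector(rmultinom(1, sample(5:80, 1), prob = runif(3)))
    expect_equal(hwe_test(cts[1], cts[2], cts[3]),
                 oracle_hwe(cts[1], cts[2], cts[3]),
                 info = paste(cts, collapse = "/"))
  }
})

test_that("association statistics reproduce the published candidate table", {
  # 28 het cases / 65 het controls in 1,541 cases and 5,785 controls
  r <- allelic_association(28, 1513, 65, 5720)
  expect_equal(round(r$odds_ratio, 2), 1.62)
  expect_equal(round(r$ci_low, 2), 1.04)
  expect_equal(round(r$ci_high, 2), 2.53)
  expect_equal(signif(r$chisq_p, 3), 3.13e-2)
  expect_equal(signif(r$fisher_p, 3), 4.02e-2)

  singleton <- allelic_association(1, 1540, 0, 5785)
  expect_equal(singleton$odds_ratio, Inf)
  expect_true(is.na(singleton$ci_low) && is.na(singleton$ci_high))
  expect_equal(signif(singleton$fisher_p, 3), 2.10e-1)
  expect_equal(signif(singleton$chisq_p, 3), 5.27e-2)

  akap9 <- allelic_association(4, 1537, 4, 5781)
  expect_equal(round(akap9$odds_ratio, 2), 3.76)
  expect_equal(round(akap9$ci_low, 2), 0.94)
  expect_equal(round(akap9$ci_high, 2), 15.03)

  balanced <- allelic_association(10, 100, 10, 100)
  expect_equal(balanced$odds_ratio, 1)
})

test_that("OR inverts under label swap, Fisher p does not; chi-squared
           matches the closed form", {
  set.seed(12)
  for (i in 1:20) {
    het_ca <- sample(0:30, 1); het_co <- sample(0:30, 1)
    wt_ca <- sample(100:2000, 1); wt_co <- sample(100:2000, 1)
    if (het_ca + het_co == 0) het_ca <- 1
    r <- allelic_association(het_ca, wt_ca, het_co, wt_co)
    sw <- allelic_association(het_co, wt_co, het_ca, wt_ca)
    if (is.finite(r$odds_ratio) && r$odds_ratio > 0)
      expect_equal(sw$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
    expect_equal(sw$fisher_p, r$fisher_p, tolerance = 1e-12)
  }
  r <- allelic_association(1, 1540, 0, 5785)
  a <- 1; b <- 2 * 1541 - 1; c <- 0; d <- 2 * 5785
  N <- a + b + c + d
  x2 <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(r$chisq_p, pchisq(x2, 1, lower.tail = FALSE))
})

test_that("Fisher p equals fisher.test and the lchoose enumeration oracle", {
  set.seed(33)
  for (i in 1:40) {
    tot <- sample(10:200, 1)
    cells <- as.vector(rmultinom(1, tot, runif(4, 0.05, 1)))
    p_pkg <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    p_or <- oracle_fisher(cells[1], cells[2], cells[3], cells[4])
    p_ft <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, p_or, tolerance = 1e-10)
    expect_equal(p_pkg, p_ft, tolerance = 1e-7)
  }
})

test_that("prioritization flags case-unique variants and OR strictly above
           the cutoff", {
  counts <- candidate_counts()
  res <- association_table(counts)
  res$variant <- counts$variant
  pr <- prioritize(res)
  expect_equal(nrow(pr$candidates), 11)

  # OR exactly at the cutoff is not flagged
  exact <- data.frame(variant = "at_cutoff", case_minor = 30,
                      control_minor = 20, odds_ratio = 1.5)
  expect_equal(nrow(prioritize(exact)$candidates), 0)

  fam <- data.frame(variant = c("famonly", "shared"), carriers = c(3, 2))
  res2 <- data.frame(variant = c("shared", "famonly"),
                     case_minor = c(5, 0), control_minor = c(2, 0),
                     odds_ratio = c(2.0, NaN))
  pr2 <- prioritize(res2, fam)
  expect_equal(pr2$family_only$variant, "famonly")
})
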