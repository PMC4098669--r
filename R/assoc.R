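#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Point-probability summation over the hypergeometric distribution with
#' the table's margins fixed: the p-value is the sum of probabilities of
#' all tables no more probable than the observed one (with the
#' conventional `1 + 1e-7` relative guard against floating-point ties).
#'
#' @param a,b,c_,d_ cell counts (rows: group 1/2, columns: outcome 1/2).
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c_, d_) {
  m <- a + c_      # column-1 total
  n <- b + d_      # column-2 total
  k <- a + b       # row-1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- stats::dhyper(x, m, n, k)
  p_obs <- pr[match(a, x)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Allelic case/control association for one variant
#'
#' Builds the 2x2 allele-count table (minor/major x case/control) from
#' genotype counts, with the minor allele defined in the combined
#' case+control cohort, and computes: the minor-allele odds ratio
#' `(a*d)/(b*c)` (a = case minor, b = case major, c = control minor,
#' d = control major; infinite with an undefined CI when `b*c = 0` and
#' `a*d > 0`), the Woolf 95% confidence interval
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`, the two-sided
#' Fisher exact p-value, and the Pearson chi-squared p-value on the allele
#' table without continuity correction.
#'
#' @param het_cases,hom_cases,wt_cases genotype counts in cases
#'   (heterozygous, homozygous non-reference, wild-type).
#' @param het_controls,hom_controls,wt_controls the same in controls.
#' @return list of class `AssociationResult` with `odds_ratio`, `ci_low`,
#'   `ci_high`, `fisher_p`, `chisq_p`, `case_minor`, `control_minor`,
#'   `case_unique`, `table` (the 2x2 allele table).
#' @export
allelic_association <- function(het_cases, wt_cases, het_controls,
                                wt_controls, hom_cases = 0,
                                hom_controls = 0) {
  n_cases <- het_cases + hom_cases + wt_cases
  n_controls <- het_controls + hom_controls + wt_controls
  if (n_cases == 0 || n_controls == 0) stop("a group has zero total")

  alt_cases <- het_cases + 2 * hom_cases
  alt_controls <- het_controls + 2 * hom_controls
  alt_total <- alt_cases + alt_controls
  all_total <- 2 * (n_cases + n_controls)
  # minor allele in the combined cohort
  minor_is_alt <- alt_total <= all_total - alt_total
  a <- if (minor_is_alt) alt_cases else 2 * n_cases - alt_cases
  b <- 2 * n_cases - a
  c_ <- if (minor_is_alt) alt_controls else 2 * n_controls - alt_controls
  d_ <- 2 * n_controls - c_

  if (b * c_ == 0 && a * d_ > 0) {
    or <- Inf; ci <- c(NA_real_, NA_real_)
  } else if (a * d_ == 0 && b * c_ == 0) {
    or <- NaN; ci <- c(NA_real_, NA_real_)
  } else {
    or <- (a * d_) / (b * c_)
    if (min(a, b, c_, d_) > 0) {
      se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d_)
      ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
    } else ci <- c(NA_real_, NA_real_)
  }

  tab <- matrix(c(a, c_, b, d_), 2, 2,
                dimnames = list(c("case", "control"), c("minor", "major")))
  fisher_p <- fisher_exact_2x2(a, b, c_, d_)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq_p <- if (any(e == 0)) NA_real_ else
    stats::pchisq(sum((tab - e)^2 / e), df = 1, lower.tail = FALSE)

  structure(list(odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
                 fisher_p = fisher_p, chisq_p = chisq_p,
                 case_minor = a, control_minor = c_,
                 case_unique = (c_ == 0 && a > 0), table = tab),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("AssociationResult: OR(minor) = %s, 95%% CI (%s, %s)\n",
              format(x$odds_ratio, digits = 3),
              format(x$ci_low, digits = 3), format(x$ci_high, digits = 3)))
  cat(sprintf("  Fisher p = %.3g, chi-squared p = %.3g\n",
              x$fisher_p, x$chisq_p))
  invisible(x)
}

#' Association results for a table of variant counts
#'
#' @param counts data frame with one row per variant and columns
#'   `het_cases`, `wt_cases`, `het_controls`, `wt_controls` and optionally
#'   `hom_cases`, `hom_controls` (default 0) plus any annotation columns,
#'   which are carried through.
#' @return the input with appended columns `odds_ratio`, `ci_low`,
#'   `ci_high`, `fisher_p`, `chisq_p`, `case_minor`, `control_minor`,
#'   `case_unique`.
#' @export
association_table <- function(counts) {
  hc <- counts$hom_cases %||% rep(0, nrow(counts))
  ho <- counts$hom_controls %||% rep(0, nrow(counts))
  res <- lapply(seq_len(nrow(counts)), function(i)
    allelic_association(counts$het_cases[i], counts$wt_cases[i],
                        counts$het_controls[i], counts$wt_controls[i],
                        hc[i], ho[i]))
  add <- function(f) vapply(res, function(r) r[[f]], numeric(1))
  counts$odds_ratio <- add("odds_ratio")
  counts$ci_low <- add("ci_low")
  counts$ci_high <- add("ci_high")
  counts$fisher_p <- add("fisher_p")
  counts$chisq_p <- add("chisq_p")
  counts$case_minor <- add("case_minor")
  counts$control_minor <- add("control_minor")
  counts$case_unique <- vapply(res, function(r) r$case_unique, logical(1))
  counts
}

#' Prioritize variants from association results
#'
#' Candidate variants are those unique to cases (minor allele present in
#' cases, absent from controls) or with a minor-allele odds ratio strictly
#' greater than `or_cutoff`. Variants absent from both cases and controls
#' but carried in the discovery families are reported separately as
#' family-only.
#'
#' @param results an [association_table()] result (or any data frame with
#'   `case_minor`, `control_minor`, `odds_ratio` and an id column named
#'   `variant`).
#' @param family_carriers optional data frame with columns `variant`
#'   and `carriers` (>= 1 family carriers) for variants assayed in the
#'   families.
#' @param or_cutoff odds-ratio cutoff, strict inequality (default 1.5).
#' @return list with `candidates` (rows of `results`) and `family_only`.
#' @export
prioritize <- function(results, family_carriers = NULL, or_cutoff = 1.5) {
  case_unique <- results$control_minor == 0 & results$case_minor > 0
  high_or <- !is.na(results$odds_ratio) & results$odds_ratio > or_cutoff
  candidates <- results[case_unique | high_or, , drop = FALSE]

  family_only <- NULL
  if (!is.null(family_carriers)) {
    absent <- results$variant[results$case_minor == 0 &
                              results$control_minor == 0]
    fam <- family_carriers[family_carriers$carriers >= 1, , drop = FALSE]
    family_only <- fam[fam$variant %in% absent |
                       !(fam$variant %in% results$variant), , drop = FALSE]
  }
  list(candidates = candidates, family_only = family_only)
}
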