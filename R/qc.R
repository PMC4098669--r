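#' Filter markers by call rate
#'
#' Retains markers whose fraction of non-missing genotypes is at least
#' `threshold` (the SNP-array convention is 0.99). Applying the filter
#' twice is the same as applying it once.
#'
#' @param gm a [GenotypeMatrix()].
#' @param threshold required call rate in (0, 1].
#' @return list with `gm` (filtered matrix) and `report`, a `QCReport`
#'   list holding per-marker call rates, removed marker ids and per-sample
#'   call rates.
#' @export
marker_call_rate_filter <- function(gm, threshold = 0.99) {
  if (ncol(gm$geno) == 0L || nrow(gm$geno) == 0L)
    stop("empty genotype matrix")
  stopifnot(threshold > 0, threshold <= 1)
  cr <- call_rates(gm)
  keep <- cr$marker >= threshold
  report <- structure(list(threshold = threshold,
                           marker_call_rate = cr$marker,
                           sample_call_rate = cr$sample,
                           removed = colnames(gm$geno)[!keep],
                           retained = colnames(gm$geno)[keep]),
                      class = "QCReport")
  list(gm = subset_markers(gm, which(keep)), report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: call-rate threshold %.3f; %d retained, %d removed\n",
              x$threshold, length(x$retained), length(x$removed)))
  invisible(x)
}

# Vectorized Mendelian incompatibility over dosage vectors; NA constrains
# nothing. Returns the error kind per marker ("" = consistent).
.mendel_error_kind <- function(gc, gf, gm_) {
  kind <- rep("", length(gc))
  opp <- (!is.na(gf) & ((gf == 0L & gc == 2L) | (gf == 2L & gc == 0L))) |
         (!is.na(gm_) & ((gm_ == 0L & gc == 2L) | (gm_ == 2L & gc == 0L)))
  kind[opp] <- "hom_parent_opposite_allele_in_child"
  both <- !is.na(gf) & !is.na(gm_)
  hh <- both & ((gf == 0L & gm_ == 0L & gc != 0L) |
                (gf == 2L & gm_ == 2L & gc != 2L))
  kind[hh & kind == ""] <- "both_parents_hom_child_differs"
  cross <- both & (((gf == 0L & gm_ == 2L) | (gf == 2L & gm_ == 0L)) & gc != 1L)
  kind[cross & kind == ""] <- "opposite_hom_parents_non_het_child"
  kind[is.na(gc)] <- ""
  kind
}

#' Nuclear-family Mendelian-consistency check
#'
#' Flags every (marker, trio) where the child genotype is impossible given
#' the non-missing parent genotypes — e.g. two homozygous-reference parents
#' with a heterozygous child. Missing genotypes are never flagged. Sex
#' chromosomes (chrom X/Y, case-insensitive, with or without "chr" prefix)
#' are skipped.
#'
#' @param ped a [Pedigree()].
#' @param gm a [GenotypeMatrix()] covering the pedigree members.
#' @return data frame with columns `marker`, `child`, `father`, `mother`,
#'   `error_kind`; zero rows when the data are Mendelian-consistent.
#' @export
mendelian_check <- function(ped, gm) {
  trios <- .trios(ped)
  auto <- !grepl("^(chr)?[XY]$", gm$map$chrom, ignore.case = TRUE)
  res <- list()
  geno <- gm$geno
  ids <- rownames(geno)
  for (t in seq_len(nrow(trios))) {
    ic <- match(ped$id[trios$child[t]], ids)
    i_f <- match(ped$id[trios$father[t]], ids)
    i_m <- match(ped$id[trios$mother[t]], ids)
    if (is.na(ic)) next
    gc <- geno[ic, ]
    gf <- if (is.na(i_f)) rep(NA_integer_, ncol(geno)) else geno[i_f, ]
    gmo <- if (is.na(i_m)) rep(NA_integer_, ncol(geno)) else geno[i_m, ]
    kind <- .mendel_error_kind(gc, gf, gmo)
    kind[!auto] <- ""
    hit <- which(kind != "")
    if (length(hit))
      res[[length(res) + 1L]] <- data.frame(
        marker = colnames(geno)[hit],
        child = ped$id[trios$child[t]],
        father = ped$id[trios$father[t]],
        mother = ped$id[trios$mother[t]],
        error_kind = kind[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(marker = character(0), child = character(0),
                      father = character(0), mother = character(0),
                      error_kind = character(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Exclude markers showing any Mendelian error
#'
#' A marker flagged in any trio is removed for the whole dataset.
#'
#' @inheritParams mendelian_check
#' @return list with `gm` (filtered) and `errors` (the flag table).
#' @export
mendelian_filter <- function(ped, gm) {
  err <- mendelian_check(ped, gm)
  bad <- unique(err$marker)
  keep <- setdiff(colnames(gm$geno), bad)
  list(gm = subset_markers(gm, keep), errors = err)
}
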