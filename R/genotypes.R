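#' Genotype matrix over biallelic markers
#'
#' Genotypes are stored as the dosage of the marker's second allele
#' (`a2`): 0 = homozygous `a1`, 1 = heterozygous, 2 = homozygous `a2`,
#' `NA` = missing. Missingness is always the `NA` sentinel, never a third
#' allele code. Rows are individuals, columns markers; the marker order
#' matches the accompanying map.
#'
#' @param geno integer matrix (individuals x markers) with values 0/1/2/NA;
#'   rownames are individual ids, colnames marker ids.
#' @param alleles data frame with columns `marker`, `a1`, `a2` giving the
#'   allele labels per marker (single bases or "1"/"2" codes).
#' @param map a [marker_map()] aligned with the columns of `geno`.
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `geno`, `alleles`, `map`.
#' @export
GenotypeMatrix <- function(geno, alleles, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("geno must carry individual ids as rownames and marker ids as colnames")
  if (!identical(colnames(geno), map$marker))
    stop("marker order of geno and map disagree")
  if (!identical(alleles$marker, map$marker))
    stop("marker order of alleles and map disagree")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  structure(list(geno = geno, alleles = alleles, map = map),
            class = "GenotypeMatrix")
}

#' Marker map
#'
#' @param marker character marker ids (unique).
#' @param chrom character chromosome labels.
#' @param pos_bp integer 1-based physical positions, strictly increasing
#'   within chromosome.
#' @param pos_cm optional genetic positions in centimorgans (defaults to
#'   1 cM/Mb when absent).
#' @return data frame of class `MarkerMap`.
#' @export
marker_map <- function(marker, chrom, pos_bp, pos_cm = NULL) {
  marker <- as.character(marker); chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  if (anyDuplicated(marker)) stop("marker ids must be unique")
  if (is.null(pos_cm)) pos_cm <- pos_bp / 1e6
  m <- data.frame(marker = marker, chrom = chrom, pos_bp = pos_bp,
                  pos_cm = as.numeric(pos_cm), stringsAsFactors = FALSE)
  for (ch in unique(m$chrom)) {
    p <- m$pos_bp[m$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(m) <- c("MarkerMap", "data.frame")
  m
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$geno)

# Subset a GenotypeMatrix by marker index or id, keeping map/alleles aligned.
subset_markers <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, colnames(gm$geno))
  GenotypeMatrix(gm$geno[, keep, drop = FALSE],
                 gm$alleles[keep, , drop = FALSE],
                 {m <- gm$map[keep, , drop = FALSE]; class(m) <- class(gm$map); m})
}

#' Per-marker and per-sample call rates
#' @param gm a `GenotypeMatrix`.
#' @return list with `marker` and `sample` named numeric vectors in \[0, 1\].
#' @export
call_rates <- function(gm) {
  list(marker = colMeans(!is.na(gm$geno)),
       sample = rowMeans(!is.na(gm$geno)))
}
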