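#' Informative markers per parent-child transmission
#'
#' A marker is informative for a given parental transmission when the
#' transmitted allele can be assigned unambiguously from the trio
#' genotypes: the child is homozygous, the parent is homozygous, or the
#' child is heterozygous and the *other* parent is homozygous. A marker
#' that is Mendelian-inconsistent in the trio is not informative.
#'
#' @param ped a [Pedigree()].
#' @param gm a [GenotypeMatrix()] (QC-passed).
#' @return named list (one element per child with two known parents), each
#'   a list with logical vectors `paternal` and `maternal` over markers.
#' @export
informative_markers <- function(ped, gm) {
  trios <- .trios(ped)
  geno <- gm$geno
  ids <- rownames(geno)
  out <- list()
  for (t in seq_len(nrow(trios))) {
    child <- ped$id[trios$child[t]]
    gc <- geno[match(child, ids), ]
    gf <- .row_or_na(geno, ped$id[trios$father[t]])
    gmo <- .row_or_na(geno, ped$id[trios$mother[t]])
    consistent <- .mendel_error_kind(gc, gf, gmo) == ""
    hom <- function(g) !is.na(g) & g != 1L
    child_hom <- hom(gc)
    het <- !is.na(gc) & gc == 1L
    inf_f <- consistent & (child_hom | (het & (hom(gf) | hom(gmo))))
    inf_m <- consistent & (child_hom | (het & (hom(gmo) | hom(gf))))
    inf_f[is.na(gc)] <- FALSE; inf_m[is.na(gc)] <- FALSE
    out[[child]] <- list(paternal = unname(inf_f), maternal = unname(inf_m))
  }
  out
}

.row_or_na <- function(geno, id) {
  i <- match(id, rownames(geno))
  if (is.na(i)) rep(NA_integer_, ncol(geno)) else geno[i, ]
}

#' Phase a pedigree by Mendelian inheritance
#'
#' Assigns, for every individual and marker where the trio genotypes force
#' it, the allele inherited from the father (paternal haplotype) and from
#' the mother (maternal haplotype). Homozygous genotypes phase trivially;
#' a heterozygous child is resolved when at least one parent is homozygous.
#' Entries that Mendelian logic cannot force stay `NA`; founders are phased
#' only at their homozygous markers. Alleles are coded as in the genotype
#' matrix: 0 = first allele, 1 = second allele.
#'
#' @param ped a [Pedigree()].
#' @param gm a Mendelian-consistent [GenotypeMatrix()].
#' @return object of class `PhasedHaplotypes`: list with integer matrices
#'   `pat` and `mat` (individuals x markers, entries 0/1/NA) and the
#'   marker `map`.
#' @export
phase_pedigree <- function(ped, gm) {
  geno <- gm$geno
  n <- nrow(geno); M <- ncol(geno)
  pat <- matrix(NA_integer_, n, M, dimnames = dimnames(geno))
  mat <- matrix(NA_integer_, n, M, dimnames = dimnames(geno))

  hom0 <- !is.na(geno) & geno == 0L
  hom2 <- !is.na(geno) & geno == 2L
  pat[hom0] <- 0L; mat[hom0] <- 0L
  pat[hom2] <- 1L; mat[hom2] <- 1L

  trios <- .trios(ped)
  ids <- rownames(geno)
  for (t in seq_len(nrow(trios))) {
    child <- ped$id[trios$child[t]]
    ic <- match(child, ids)
    if (is.na(ic)) next
    gc <- geno[ic, ]
    gf <- .row_or_na(geno, ped$id[trios$father[t]])
    gmo <- .row_or_na(geno, ped$id[trios$mother[t]])
    kind <- .mendel_error_kind(gc, gf, gmo)
    if (any(kind != "")) {
      j <- which(kind != "")[1]
      stop("Mendelian inconsistency at marker ", colnames(geno)[j],
           " in trio (child ", child, ", father ", ped$id[trios$father[t]],
           ", mother ", ped$id[trios$mother[t]], ")")
    }
    het <- !is.na(gc) & gc == 1L
    f_hom <- !is.na(gf) & gf != 1L
    m_hom <- !is.na(gmo) & gmo != 1L
    j <- het & f_hom
    pat[ic, j] <- as.integer(gf[j] / 2L)
    mat[ic, j] <- 1L - pat[ic, j]
    j <- het & !f_hom & m_hom
    mat[ic, j] <- as.integer(gmo[j] / 2L)
    pat[ic, j] <- 1L - mat[ic, j]
  }
  structure(list(pat = pat, mat = mat, map = gm$map),
            class = "PhasedHaplotypes")
}

#' @export
print.PhasedHaplotypes <- function(x, ...) {
  res <- mean(!is.na(x$pat) & !is.na(x$mat))
  cat(sprintf("PhasedHaplotypes: %d individuals x %d markers (%.1f%% fully resolved)\n",
              nrow(x$pat), ncol(x$pat), 100 * res))
  invisible(x)
}
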