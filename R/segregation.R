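#' Carrier tabulation of a variant in a pedigree
#'
#' Counts tested (genotyped) affected members and how many of them carry
#' at least one copy of the variant allele. Members with missing genotype
#' (no DNA available) are excluded from the denominators; members with
#' unknown affection status are not counted as tested affecteds.
#'
#' @param ped a [Pedigree()].
#' @param genotypes named integer vector: individual id -> variant dosage
#'   (0/1/2, NA = not genotyped). Ids absent from the vector are treated
#'   as not genotyped.
#' @return list of class `SegregationReport` with `tested_affected`,
#'   `affected_carriers`, `unaffected_carriers`, `carrier_ids`,
#'   `full_cosegregation`.
#' @export
carrier_table <- function(ped, genotypes) {
  g <- genotypes[match(ped$id, names(genotypes))]
  tested <- !is.na(g)
  carrier <- tested & g >= 1L
  aff <- ped$affected == "affected"
  unaff <- ped$affected == "unaffected"
  tested_affected <- sum(tested & aff)
  affected_carriers <- sum(carrier & aff)
  structure(list(tested_affected = tested_affected,
                 affected_carriers = affected_carriers,
                 unaffected_carriers = sum(carrier & unaff),
                 carrier_ids = ped$id[carrier],
                 full_cosegregation = tested_affected > 0 &&
                   affected_carriers == tested_affected),
            class = "SegregationReport")
}

#' @export
print.SegregationReport <- function(x, ...) {
  cat(sprintf("SegregationReport: %d of %d tested affecteds carry the variant%s\n",
              x$affected_carriers, x$tested_affected,
              if (x$full_cosegregation) " (full co-segregation)" else ""))
  invisible(x)
}

#' Parental origin of a carried variant
#'
#' Maternal when the genotyped mother carries the variant and the
#' genotyped father does not; paternal symmetrically. When neither
#' genotyped parent carries it, or a parent is ungenotyped (so paternal
#' origin cannot be separated from a de novo event), the call is
#' `"de_novo_or_unknown"`.
#'
#' @param ped a [Pedigree()].
#' @param genotypes named dosage vector as in [carrier_table()].
#' @param individual id of a carrier.
#' @return one of `"maternal"`, `"paternal"`, `"de_novo_or_unknown"`.
#' @export
parental_origin <- function(ped, genotypes, individual) {
  i <- match(individual, ped$id)
  if (is.na(i)) stop("individual ", individual, " not in pedigree")
  gi <- genotypes[individual]
  if (is.na(gi) || gi < 1L) stop(individual, " is not a carrier")
  gof <- function(id) if (is.na(id)) NA_integer_ else
    unname(genotypes[match(id, names(genotypes))])
  gf <- gof(ped$father[i]); gm <- gof(ped$mother[i])
  f_car <- !is.na(gf) && gf >= 1L
  m_car <- !is.na(gm) && gm >= 1L
  if (m_car && !is.na(gf) && gf == 0L) return("maternal")
  if (f_car && !is.na(gm) && gm == 0L) return("paternal")
  "de_novo_or_unknown"
}

#' Segregation report across pedigrees and variants
#'
#' @param peds named list of [Pedigree()] objects.
#' @param variant_genotypes named list: variant id -> named dosage vector
#'   over individuals (across all pedigrees).
#' @return data frame with one row per (variant, pedigree): tested
#'   affecteds, affected/unaffected carriers, full co-segregation flag.
#' @export
segregation_report <- function(peds, variant_genotypes) {
  rows <- list()
  for (v in names(variant_genotypes)) {
    for (p in names(peds)) {
      ct <- carrier_table(peds[[p]], variant_genotypes[[v]])
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, pedigree = p,
        tested_affected = ct$tested_affected,
        affected_carriers = ct$affected_carriers,
        unaffected_carriers = ct$unaffected_carriers,
        full_cosegregation = ct$full_cosegregation,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
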