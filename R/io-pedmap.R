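#' Read a PLINK-style text PED/MAP pair
#'
#' The PED file carries six leading columns (family, individual, father,
#' mother, sex, phenotype) followed by two allele columns per marker;
#' alleles may be bases (A/C/G/T) or 1/2 codes, with 0 meaning missing.
#' The MAP file has four columns (chromosome, marker id, genetic position
#' in cM, physical position in bp). Markers with no physical map location
#' (position <= 0) are dropped, and the number dropped is reported via a
#' message and the `dropped_markers` attribute of the returned map.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return list with elements `ped` ([Pedigree()]), `gm`
#'   ([GenotypeMatrix()]) and `map` (the retained [marker_map()]).
#' @export
read_ped_map <- function(ped_path, map_path) {
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "marker", "pos_cm", "pos_bp"))
  n_markers_all <- nrow(mp)
  unmapped <- is.na(mp$pos_bp) | mp$pos_bp <= 0
  if (any(unmapped))
    message(sum(unmapped), " marker(s) with no map location dropped")
  keep_mk <- which(!unmapped)
  mp_keep <- mp[keep_mk, , drop = FALSE]

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n_expect <- 6L + 2L * n_markers_all
  widths <- lengths(toks)
  if (any(widths != n_expect))
    stop("PED line(s) ", paste(which(widths != n_expect), collapse = ","),
         " have ", paste(unique(widths[widths != n_expect]), collapse = "/"),
         " fields, expected ", n_expect)
  tab <- do.call(rbind, toks)

  sex <- c("1" = "male", "2" = "female")[tab[, 5]]
  sex[is.na(sex)] <- "unknown"
  aff <- c("1" = "unaffected", "2" = "affected")[tab[, 6]]
  aff[is.na(aff)] <- "unknown"
  ped <- Pedigree(data.frame(fid = tab[, 1], id = tab[, 2],
                             father = tab[, 3], mother = tab[, 4],
                             sex = sex, affected = aff,
                             stringsAsFactors = FALSE))

  a1col <- 6L + 2L * seq_len(n_markers_all) - 1L
  A1 <- tab[, a1col, drop = FALSE]
  A2 <- tab[, a1col + 1L, drop = FALSE]
  A1[A1 == "0"] <- NA; A2[A2 == "0"] <- NA
  A1 <- A1[, keep_mk, drop = FALSE]; A2 <- A2[, keep_mk, drop = FALSE]

  n_ind <- nrow(tab); n_mk <- length(keep_mk)
  geno <- matrix(NA_integer_, n_ind, n_mk,
                 dimnames = list(ped$id, mp_keep$marker))
  alleles <- data.frame(marker = mp_keep$marker,
                        a1 = NA_character_, a2 = NA_character_,
                        stringsAsFactors = FALSE)
  for (j in seq_len(n_mk)) {
    obs <- c(A1[, j], A2[, j])
    labs <- sort(unique(obs[!is.na(obs)]))
    if (length(labs) > 2L)
      stop("marker ", mp_keep$marker[j], " has >2 alleles: ",
           paste(labs, collapse = ","))
    if (length(labs) == 0L) labs <- c("1", "2")
    if (length(labs) == 1L) labs <- c(labs, NA)
    alleles$a1[j] <- labs[1]; alleles$a2[j] <- labs[2]
    d <- (!is.na(A1[, j]) & !is.na(labs[2]) & A1[, j] == labs[2]) +
         (!is.na(A2[, j]) & !is.na(labs[2]) & A2[, j] == labs[2])
    d[is.na(A1[, j]) | is.na(A2[, j])] <- NA
    geno[, j] <- as.integer(d)
  }

  map <- marker_map(mp_keep$marker, as.character(mp_keep$chrom),
                    mp_keep$pos_bp, mp_keep$pos_cm)
  attr(map, "dropped_markers") <- sum(unmapped)
  list(ped = ped, gm = GenotypeMatrix(geno, alleles, map), map = map)
}

#' Write a PED/MAP pair
#'
#' Inverse of [read_ped_map()] on its retained markers: missing genotypes
#' are written as `0 0`, sex and affection use the usual 1/2 codes with 0
#' for unknown.
#'
#' @param ped a [Pedigree()].
#' @param gm a [GenotypeMatrix()] whose rows cover `ped$id`.
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(ped, gm, ped_path, map_path) {
  map <- gm$map
  utils::write.table(
    data.frame(map$chrom, map$marker, map$pos_cm, map$pos_bp),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)

  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  aff_code <- c(unaffected = "1", affected = "2", unknown = "0")[ped$affected]
  geno <- gm$geno[ped$id, , drop = FALSE]
  lines <- vapply(seq_len(nrow(ped)), function(i) {
    g <- geno[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, gm$alleles$a2, gm$alleles$a1))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, gm$alleles$a2, gm$alleles$a1))
    paste(c(ped$fid[i], ped$id[i],
            ifelse(is.na(ped$father[i]), "0", ped$father[i]),
            ifelse(is.na(ped$mother[i]), "0", ped$mother[i]),
            sex_code[i], aff_code[i],
            as.vector(rbind(a1, a2))), collapse = "\t")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(NULL)
}
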