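#' Physicochemical amino-acid classes
#'
#' Grouping used to call a missense change conservative (within-class) or
#' non-conservative (across classes): aliphatic (A, V, L, I, M), aromatic
#' (F, W, Y), polar uncharged (S, T, N, Q, C), positively charged
#' (K, R, H), negatively charged (D, E), and special (G, P). Replaceable
#' via the `aa_classes` argument of [classify_variant()].
#'
#' @format named character vector mapping one-letter amino-acid codes to a
#'   class label.
#' @export
aa_class_table <- c(
  A = "aliphatic", V = "aliphatic", L = "aliphatic", I = "aliphatic",
  M = "aliphatic",
  F = "aromatic", W = "aromatic", Y = "aromatic",
  S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative",
  G = "special", P = "special")

# CDS coordinate (1 = first coding base) of genomic position `pos`, or NA
.cds_coord <- function(tx, pos) {
  parts <- .cds_exon_parts(tx)
  if (nrow(parts) == 0L) return(NA_integer_)
  if (tx$strand == "+") {
    off <- 0L
    for (i in seq_len(nrow(parts))) {
      if (pos >= parts$start[i] && pos <= parts$end[i])
        return(off + pos - parts$start[i] + 1L)
      off <- off + parts$end[i] - parts$start[i] + 1L
    }
  } else {
    off <- 0L
    for (i in rev(seq_len(nrow(parts)))) {
      if (pos >= parts$start[i] && pos <= parts$end[i])
        return(off + parts$end[i] - pos + 1L)
      off <- off + parts$end[i] - parts$start[i] + 1L
    }
  }
  NA_integer_
}

# spliced CDS sequence (coding strand)
.cds_seq <- function(tx, reference) {
  parts <- .cds_exon_parts(tx)
  pieces <- vapply(seq_len(nrow(parts)), function(i)
    .ref_seq(reference, tx$chrom, parts$start[i], parts$end[i]), character(1))
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

.translate1 <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

.revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[toupper(b)]]

# splice-junction context of a position: distances to internal exon edges
.splice_flags <- function(tx, pos, splice_intron, splice_exon) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) return(c(intronic = FALSE, exonic = FALSE))
  don <- ex$end[-n]      # last exonic base before each intron
  acc <- ex$start[-1]    # first exonic base after each intron
  intronic <- any(pos >= don + 1L & pos <= don + splice_intron) ||
              any(pos <= acc - 1L & pos >= acc - splice_intron)
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  exonic <- in_exon &&
    (any(pos <= don & pos >= don - splice_exon + 1L) ||
     any(pos >= acc & pos <= acc + splice_exon - 1L))
  c(intronic = intronic, exonic = exonic)
}

#' Classify a variant against a transcript
#'
#' Assigns one or more functional categories: `synonymous`,
#' `conservative_missense`, `nonconservative_missense`, `nonsense`,
#' `frameshift`, `splice_site`, `other`. Coding SNVs are classified by
#' translating the reference and alternate codons with the standard
#' genetic code; coding indels whose length change is not a multiple of 3
#' are frameshifts. Variants in the first `splice_intron` intronic bases
#' of a junction are splice-site changes; exonic positions within
#' `splice_exon` bases of an internal junction receive `splice_site` in
#' addition to their coding label. Protein notation is emitted as
#' `RefPosAlt` with `X` for a stop codon (e.g. `"Q22X"`).
#'
#' @param chrom,pos,ref,alt the (normalized) variant.
#' @param tx a [Transcript()].
#' @param reference named `DNAStringSet` or character vector.
#' @param splice_intron intronic splice window (default 2, the canonical
#'   donor/acceptor dinucleotides).
#' @param splice_exon exonic bases near a junction that flag possible
#'   splicing effects (default 3).
#' @param aa_classes class table for the conservative/non-conservative
#'   call (default [aa_class_table]).
#' @return list of class `VariantEffect` with `categories` (character
#'   vector) and `protein` (notation or NA).
#' @export
classify_variant <- function(chrom, pos, ref, alt, tx, reference,
                             splice_intron = 2, splice_exon = 3,
                             aa_classes = aa_class_table) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (chrom != tx$chrom)
    stop("variant chromosome ", chrom, " does not match transcript ", tx$chrom)
  categories <- character(0)
  protein <- NA_character_

  sp <- .splice_flags(tx, pos, splice_intron, splice_exon)
  if (sp[["intronic"]]) categories <- c(categories, "splice_site")

  has_cds <- !is.na(tx$cds_start)
  cdspos <- if (has_cds) .cds_coord(tx, pos) else NA_integer_
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L

  if (!is.na(cdspos) && is_snv) {
    cds <- .cds_seq(tx, reference)
    cp <- if (tx$strand == "+") cdspos else cdspos  # already strand-resolved
    codon_i <- (cp - 1L) %/% 3L
    within <- (cp - 1L) %% 3L
    codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_c <- if (tx$strand == "+") alt else .revcomp_base(alt)
    new_codon <- codon
    substr(new_codon, within + 1L, within + 1L) <- alt_c
    aa_ref <- .translate1(codon)
    aa_alt <- .translate1(new_codon)
    aa_pos <- codon_i + 1L
    disp <- function(a) if (a == "*") "X" else a
    protein <- paste0(disp(aa_ref), aa_pos, disp(aa_alt))
    if (aa_ref == aa_alt) {
      categories <- c(categories, "synonymous")
    } else if (aa_alt == "*") {
      categories <- c(categories, "nonsense")
    } else if (aa_ref == "*") {
      categories <- c(categories, "other")
    } else {
      same <- !is.na(aa_classes[aa_ref]) && !is.na(aa_classes[aa_alt]) &&
        aa_classes[[aa_ref]] == aa_classes[[aa_alt]]
      categories <- c(categories,
                      if (same) "conservative_missense" else
                        "nonconservative_missense")
    }
    if (sp[["exonic"]]) categories <- c(categories, "splice_site")
  } else if (!is.na(cdspos) && !is_snv) {
    shift <- abs(nchar(ref) - nchar(alt))
    categories <- c(categories,
                    if (shift %% 3L != 0L) "frameshift" else "other")
    if (sp[["exonic"]]) categories <- c(categories, "splice_site")
  }

  if (!length(categories)) categories <- "other"
  structure(list(categories = unique(categories), protein = protein),
            class = "VariantEffect")
}

#' @export
print.VariantEffect <- function(x, ...) {
  cat("VariantEffect:", paste(x$categories, collapse = " + "),
      if (!is.na(x$protein)) paste0("(", x$protein, ")") else "", "\n")
  invisible(x)
}
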