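# Fetch reference bases [start, end] for a chromosome; `reference` is a
# named Biostrings::DNAStringSet or a named character vector.
.ref_seq <- function(reference, chrom, start, end) {
  if (start < 1) stop("reference coordinate below 1")
  if (methods::is(reference, "DNAStringSet")) {
    if (!chrom %in% names(reference)) stop("chromosome ", chrom, " not in reference")
    if (end > Biostrings::width(reference[[chrom]]))
      stop("coordinate past end of ", chrom)
    return(toupper(as.character(Biostrings::subseq(reference[[chrom]], start, end))))
  }
  seqc <- reference[[chrom]]
  if (is.null(seqc) || is.na(seqc)) stop("chromosome ", chrom, " not in reference")
  if (end > nchar(seqc)) stop("coordinate past end of ", chrom)
  toupper(substr(seqc, start, end))
}

#' Normalize a variant to its left-aligned minimal representation
#'
#' Implements the standard normalization used for cross-caller matching:
#' shared trailing bases are trimmed (extending left with reference
#' sequence when an allele would become empty), then shared leading bases
#' are trimmed. SNVs and already-minimal records pass through unchanged;
#' the operation is idempotent and preserves the edited sequence.
#'
#' @param chrom,pos,ref,alt the variant (1-based `pos`).
#' @param reference named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @return list with `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) == 0L || nchar(alt) == 0L) stop("empty allele")
  obs <- .ref_seq(reference, chrom, pos, pos + nchar(ref) - 1L)
  if (obs != ref)
    stop("REF allele ", ref, " does not match reference ", obs,
         " at ", chrom, ":", pos)
  last <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    while (nchar(ref) > 1L && nchar(alt) > 1L && last(ref) == last(alt)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    if (nchar(ref) != nchar(alt) && last(ref) == last(alt) && pos > 1L) {
      base <- .ref_seq(reference, chrom, pos - 1L, pos - 1L)
      ref <- paste0(base, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(base, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) stop("ref and alt identical after normalization")
  list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

#' Consensus of multiple variant call sets
#'
#' Keeps a variant when its (chrom, pos, ref, alt) key appears in at least
#' `min_support` of the supplied call sets — the "called by at least two
#' of three methods" rule. Call sets are assumed normalized; the result is
#' invariant to their order and records which callers support each kept
#' variant.
#'
#' @param callsets named list of `VariantTable` data frames.
#' @param min_support minimum number of supporting call sets (default 2).
#' @return `VariantTable` with an extra `callers` column
#'   (comma-separated caller names, alphabetical).
#' @export
consensus_calls <- function(callsets, min_support = 2) {
  if (min_support > length(callsets))
    stop("min_support exceeds the number of call sets")
  if (is.null(names(callsets)))
    names(callsets) <- paste0("caller", seq_along(callsets))
  key <- function(tab) paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  support <- list()
  recs <- list()
  for (cl in names(callsets)) {
    tab <- callsets[[cl]]
    for (i in seq_len(nrow(tab))) {
      k <- key(tab)[i]
      support[[k]] <- sort(unique(c(support[[k]], cl)))
      if (is.null(recs[[k]])) recs[[k]] <- tab[i, c("chrom", "pos", "ref", "alt")]
    }
  }
  keep <- names(support)[lengths(support) >= min_support]
  keep <- sort(keep)
  if (!length(keep)) {
    out <- variant_table(character(0), integer(0), character(0), character(0))
    out$callers <- character(0)
    return(out)
  }
  tab <- do.call(rbind, recs[keep])
  out <- variant_table(tab$chrom, tab$pos, tab$ref, tab$alt)
  out$callers <- vapply(support[keep], paste, character(1), collapse = ",")
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("VariantTable", "data.frame")
  out
}
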