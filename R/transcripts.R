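#' Transcript model
#'
#' @param id transcript id.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with 1-based inclusive `start`, `end`, ordered
#'   and non-overlapping.
#' @param cds_start,cds_end genomic CDS bounds (inclusive); NA for a
#'   non-coding transcript. The CDS must lie within the exon union and its
#'   spliced length must be a multiple of 3.
#' @return object of class `Transcript`.
#' @export
Transcript <- function(id, chrom, strand, exons, cds_start = NA, cds_end = NA) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon with end < start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap or touch")
  tx <- structure(list(id = id, chrom = chrom, strand = strand,
                       exons = exons, cds_start = cds_start,
                       cds_end = cds_end),
                  class = "Transcript")
  if (!is.na(cds_start)) {
    cds <- .cds_exon_parts(tx)
    if (nrow(cds) == 0L) stop("CDS outside exon union")
    len <- sum(cds$end - cds$start + 1L)
    if (len %% 3L != 0L)
      stop("CDS length ", len, " not divisible by 3")
  }
  tx
}

# exonic pieces of the CDS, in genomic order
.cds_exon_parts <- function(tx) {
  s <- pmax(tx$exons$start, tx$cds_start)
  e <- pmin(tx$exons$end, tx$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

#' Read transcript models from a GFF3 file
#'
#' Uses rtracklayer to parse the GFF3; transcripts are assembled from
#' `exon` and `CDS` features grouped by their `Parent` attribute (or
#' `transcript_id` when present).
#'
#' @param path GFF3 file.
#' @return named list of [Transcript()] objects.
#' @export
read_transcripts_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(g)
  parent <- if (!is.null(md$Parent))
    vapply(as.list(md$Parent), function(x)
      if (length(x)) as.character(x)[1] else NA_character_, character(1))
  else as.character(md$transcript_id)
  type <- as.character(md$type)
  out <- list()
  for (tid in unique(parent[type %in% c("exon", "CDS")])) {
    sel <- parent == tid & !is.na(parent)
    ex <- g[sel & type == "exon"]
    cds <- g[sel & type == "CDS"]
    if (length(ex) == 0L) next
    out[[tid]] <- Transcript(
      id = tid,
      chrom = as.character(GenomicRanges::seqnames(ex))[1],
      strand = as.character(GenomicRanges::strand(ex))[1],
      exons = data.frame(start = GenomicRanges::start(ex),
                         end = GenomicRanges::end(ex)),
      cds_start = if (length(cds)) min(GenomicRanges::start(cds)) else NA,
      cds_end = if (length(cds)) max(GenomicRanges::end(cds)) else NA)
  }
  out
}

#' Capture regions for targeted sequencing
#'
#' For each transcript takes the promoter (`upstream_bp` bases upstream of
#' the transcription start site, strand-aware), every exon, and
#' `boundary_pad` intronic bases on each side of every splice junction,
#' then merges overlapping intervals per chromosome. Intervals running off
#' the contig start are truncated at 1.
#'
#' @param transcripts list of [Transcript()] objects.
#' @param upstream_bp promoter length (default 2000).
#' @param boundary_pad intronic pad at each exon-intron boundary
#'   (default 10).
#' @return data frame with `chrom`, `start_bp`, `end_bp` (1-based
#'   inclusive), sorted.
#' @export
build_capture_regions <- function(transcripts, upstream_bp = 2000,
                                  boundary_pad = 10) {
  stopifnot(upstream_bp >= 0)
  rows <- list()
  for (tx in transcripts) {
    ex <- tx$exons
    tss <- if (tx$strand == "+") min(ex$start) else max(ex$end)
    if (upstream_bp > 0) {
      prom <- if (tx$strand == "+")
        c(tss - upstream_bp, tss - 1L) else c(tss + 1L, tss + upstream_bp)
      rows[[length(rows) + 1L]] <- data.frame(chrom = tx$chrom,
                                              start = max(prom[1], 1L),
                                              end = prom[2])
    }
    rows[[length(rows) + 1L]] <- data.frame(chrom = tx$chrom,
                                            start = ex$start, end = ex$end)
    if (nrow(ex) > 1 && boundary_pad > 0) {
      don <- data.frame(chrom = tx$chrom,
                        start = ex$end[-nrow(ex)] + 1L,
                        end = ex$end[-nrow(ex)] + boundary_pad)
      acc <- data.frame(chrom = tx$chrom,
                        start = pmax(ex$start[-1] - boundary_pad, 1L),
                        end = ex$start[-1] - 1L)
      rows[[length(rows) + 1L]] <- rbind(don, acc)
    }
  }
  all <- do.call(rbind, rows)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    all$chrom, IRanges::IRanges(all$start, all$end)))
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}
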