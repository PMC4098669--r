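#' Read variant records from a VCF file
#'
#' Parses a VCF 4.x file (via vcfR) into a variant table. Multiallelic rows
#' are split into one biallelic record per ALT allele; per-sample genotypes,
#' when present, are recoded as the dosage of that record's ALT allele.
#' Coordinates stay 1-based as in the VCF.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return data frame of class `VariantTable` with columns `chrom`, `pos`,
#'   `id`, `ref`, `alt`; if the VCF has genotypes, an attribute `gt` holds a
#'   variants x samples integer dosage matrix aligned with the rows.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) return(variant_table(character(0), integer(0),
                                                            character(0), character(0)))
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | is.na(fix[, "REF"]) | fix[, "REF"] == "" |
               is.na(fix[, "ALT"]) | fix[, "ALT"] == "" |
               grepl("[^ACGTNacgtn,*<>0-9_]", fix[, "ALT"]))
  if (length(bad))
    stop("malformed VCF record at data line ", bad[1],
         " (", fix[bad[1], "CHROM"], ":", fix[bad[1], "POS"], ")")

  has_gt <- ncol(v@gt %||% matrix(nrow = 0, ncol = 0)) > 1L
  gt_alleles <- NULL
  if (has_gt) {
    raw <- v@gt[, -1, drop = FALSE]
    fmt <- v@gt[, 1]
    gt_idx <- vapply(strsplit(fmt, ":"), function(f) match("GT", f), integer(1))
    gt_alleles <- matrix(NA_character_, nrow(fix), ncol(raw),
                         dimnames = list(NULL, colnames(raw)))
    for (j in seq_len(ncol(raw))) {
      fields <- strsplit(raw[, j], ":")
      gt_alleles[, j] <- vapply(seq_along(fields), function(i) {
        k <- gt_idx[i]
        if (is.na(k) || length(fields[[i]]) < k) NA_character_ else fields[[i]][k]
      }, character(1))
    }
  }

  out <- list(); gts <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = pos[i],
        id = ifelse(is.na(fix[i, "ID"]), ".", fix[i, "ID"]),
        ref = fix[i, "REF"], alt = alts[ai], stringsAsFactors = FALSE)
      if (has_gt)
        gts[[length(gts) + 1L]] <- .gt_dosage(gt_alleles[i, ], ai)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("VariantTable", "data.frame")
  if (has_gt) {
    gt <- do.call(rbind, gts)
    rownames(gt) <- NULL
    attr(tab, "gt") <- gt
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dosage of allele index `ai` (1 = first ALT) from GT strings like "0/1", "1|2"
.gt_dosage <- function(gt, ai) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(as.integer(al) == ai)
  }, integer(1), USE.NAMES = FALSE)
}

#' Construct a variant table directly
#' @param chrom,pos,ref,alt vectors describing biallelic records.
#' @param id optional record ids (default ".").
#' @param gt optional variants x samples dosage matrix.
#' @return a `VariantTable` data frame.
#' @export
variant_table <- function(chrom, pos, ref, alt, id = NULL, gt = NULL) {
  tab <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    id = if (is.null(id)) rep(".", length(chrom)) else as.character(id),
                    ref = as.character(ref), alt = as.character(alt),
                    stringsAsFactors = FALSE)
  class(tab) <- c("VariantTable", "data.frame")
  if (!is.null(gt)) attr(tab, "gt") <- gt
  tab
}

#' Write a variant table as minimal VCF 4.2 text
#'
#' @param tab a `VariantTable`; when it carries a `gt` attribute the dosages
#'   are written back as unphased GT fields.
#' @param path output path.
#' @export
write_vcf <- function(tab, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  gt <- attr(tab, "gt")
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(gt)) hdr <- c(hdr, "FORMAT", colnames(gt))
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(tab)) {
    body <- paste(tab$chrom, tab$pos, tab$id, tab$ref, tab$alt,
                  ".", "PASS", ".", sep = "\t")
    if (!is.null(gt)) {
      code <- c("0/0", "0/1", "1/1")
      gs <- apply(gt, 1, function(r)
        paste(ifelse(is.na(r), "./.", code[r + 1L]), collapse = "\t"))
      body <- paste(body, "GT", gs, sep = "\t")
    }
    writeLines(body, con)
  }
  invisible(NULL)
}
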