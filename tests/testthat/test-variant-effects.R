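test_that("promoter intervals are strand-aware and truncated at the contig start", {
  tx_plus <- Transcript("p", "chr1", "+",
                        exons = data.frame(start = 10000, end = 10500))
  reg <- build_capture_regions(list(tx_plus), upstream_bp = 2000,
                               boundary_pad = 0)
  expect_equal(reg$start_bp, 8000)
  expect_equal(reg$end_bp, 10500)

  tx_minus <- Transcript("m", "chr1", "-",
                         exons = data.frame(start = 10000, end = 10500))
  reg <- build_capture_regions(list(tx_minus), upstream_bp = 2000,
                               boundary_pad = 0)
  expect_equal(reg$start_bp, 10000)
  expect_equal(reg$end_bp, 12500)

  tx_edge <- Transcript("e", "chr1", "+",
                        exons = data.frame(start = 500, end = 900))
  reg <- build_capture_regions(list(tx_edge), upstream_bp = 2000,
                               boundary_pad = 0)
  expect_equal(reg$start_bp, 1)
})

test_that("capture regions of overlapping transcripts equal the brute-force union", {
  txs <- list(
    Transcript("a", "chr1", "+",
               exons = data.frame(start = c(5000, 6000), end = c(5200, 6300))),
    Transcript("b", "chr1", "+",
               exons = data.frame(start = c(5100, 7000), end = c(5900, 7100))))
  reg <- build_capture_regions(txs, upstream_bp = 100, boundary_pad = 10)
  # brute force: mark every covered base
  covered <- rep(FALSE, 10000)
  mark <- function(s, e) covered[max(s, 1):e] <<- TRUE
  for (tx in txs) {
    ex <- tx$exons
    mark(min(ex$start) - 100, min(ex$start) - 1)
    for (i in seq_len(nrow(ex))) mark(ex$start[i], ex$end[i])
    if (nrow(ex) > 1) for (i in seq_len(nrow(ex) - 1)) {
      mark(ex$end[i] + 1, ex$end[i] + 10)
      mark(ex$start[i + 1] - 10, ex$start[i + 1] - 1)
    }
  }
  runs <- rle(covered)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  expect_equal(reg$start_bp, starts[runs$values])
  expect_equal(reg$end_bp, ends[runs$values])
})

test_that("normalization left-aligns indels to the representation an
           exhaustive shift search finds", {
  ref <- c(chr1 = "GGTGCAAATAGGCCTTAAC")
  #         123456789012345678 9
  # insertion of A within the A-run (pos 6-8): CA -> CAA at pos 5
  v <- normalize_variant("chr1", 5, "CA", "CAA", ref)
  # oracle: try every anchored single-A insertion, keep those whose edit
  # reproduces the same sequence, take the leftmost
  target <- apply_edit(ref, "chr1", 5, "CA", "CAA")
  hits <- list()
  for (p in 1:18) {
    base <- substr(ref[["chr1"]], p, p)
    cand <- list(chrom = "chr1", pos = p, ref = base,
                 alt = paste0(base, "A"))
    ok <- tryCatch(apply_edit(ref, "chr1", p, cand$ref, cand$alt) == target,
                   error = function(e) FALSE)
    if (ok) hits[[length(hits) + 1L]] <- cand
  }
  leftmost <- hits[[which.min(vapply(hits, `[[`, numeric(1), "pos"))]]
  expect_equal(v$pos, leftmost$pos)
  expect_equal(v$ref, leftmost$ref)
  expect_equal(v$alt, leftmost$alt)
  # apply-edit equivalence
  expect_equal(apply_edit(ref, "chr1", v$pos, v$ref, v$alt), target)
})

test_that("normalization is idempotent and leaves SNVs untouched", {
  ref <- c(chr1 = "GGTGCAAATAGGCCTTAAC")
  snv <- normalize_variant("chr1", 11, "G", "T", ref)
  expect_equal(snv, list(chrom = "chr1", pos = 11L, ref = "G", alt = "T"))
  del <- normalize_variant("chr1", 12, "GC", "G", ref)
  again <- normalize_variant(del$chrom, del$pos, del$ref, del$alt, ref)
  expect_equal(again, del)
  expect_error(normalize_variant("chr1", 11, "C", "T", ref), "does not match")
})

test_that("consensus keeps variants in >= 2 of 3 call sets, order-invariantly", {
  mk <- function(pos) variant_table("chr1", pos, "A", "G")
  cs <- list(m1 = rbind(mk(10), mk(20)),
             m2 = rbind(mk(20), mk(30)),
             m3 = rbind(mk(10), mk(40)))
  out <- consensus_calls(cs, min_support = 2)
  expect_setequal(out$pos, c(10L, 20L))
  expect_equal(out$callers[out$pos == 10], "m1,m3")
  out_rev <- consensus_calls(rev(cs), min_support = 2)
  expect_equal(out_rev[order(out_rev$pos), ]$pos, out[order(out$pos), ]$pos)

  dropped <- consensus_calls(list(m1 = mk(99), m2 = mk(1), m3 = mk(2)), 2)
  expect_false(99 %in% dropped$pos)

  same <- consensus_calls(list(a = mk(5), b = mk(5), c = mk(5)), 2)
  expect_equal(nrow(same), 1)
  expect_error(consensus_calls(cs, min_support = 4), "min_support")
})

test_that("every single-base change of a lysine codon classifies per the
           genetic code", {
  g <- toy_gene()   # codon 5 = AAA (K) at CDS 13-15, well inside exon 1
  code <- Biostrings::GENETIC_CODE
  classes <- aa_class_table
  for (b in 1:3) for (alt in c("C", "G", "T")) {
    pos <- toy_codon_pos(5, b)
    eff <- classify_variant("chrT", pos, "A", alt, g$tx, g$ref)
    new_codon <- "AAA"; substr(new_codon, b, b) <- alt
    aa <- code[[new_codon]]
    want <- if (aa == "K") "synonymous"
      else if (aa == "*") "nonsense"
      else if (classes[[aa]] == classes[["K"]]) "conservative_missense"
      else "nonconservative_missense"
    expect_equal(eff$categories, want, info = paste(b, alt))
    if (aa == "*") expect_equal(eff$protein, "K5X")
  }
})

test_that("a stop-gain is reported with X notation at the right residue", {
  # make codon 22 CAG (Q); G>A at third base on a plus strand is
  # synonymous, so instead use C->T at base 1: CAG -> TAG (stop)
  g <- toy_gene(list(`22` = "CAG"))
  pos <- toy_codon_pos(22, 1)
  eff <- classify_variant("chrT", pos, "C", "T", g$tx, g$ref)
  expect_equal(eff$categories, "nonsense")
  expect_equal(eff$protein, "Q22X")
})

test_that("proline-to-leucine is a non-conservative missense change", {
  g <- toy_gene(list(`30` = "CCG"))   # P at codon 30
  pos <- toy_codon_pos(30, 2)
  eff <- classify_variant("chrT", pos, "C", "T", g$tx, g$ref)  # CCG -> CTG (L)
  expect_equal(eff$categories, "nonconservative_missense")
  expect_equal(eff$protein, "P30L")
})

test_that("an exon-edge coding change carries a splice-site double label", {
  # CDS position 61 is the first base of exon 2 (codon 21, base 1)
  g <- toy_gene(list(`21` = "TTT"))   # F at codon 21
  pos <- toy_codon_pos(21, 1)
  expect_equal(pos, 221)              # first base of exon 2
  eff <- classify_variant("chrT", pos, "T", "C", g$tx, g$ref)  # TTT -> CTT (L)
  expect_setequal(eff$categories, c("nonconservative_missense", "splice_site"))
  expect_equal(eff$protein, "F21L")
})

test_that("canonical intronic splice positions are splice-site, CDS indels
           frameshift by length", {
  g <- toy_gene()
  # intron is 181-220; donor +1/+2 = 181/182, acceptor -1/-2 = 219/220
  for (pos in c(181, 182, 219, 220)) {
    eff <- classify_variant("chrT", pos, "G", "A", g$tx, g$ref)
    expect_equal(eff$categories, "splice_site", info = pos)
  }
  # exonic base 3 bp inside the donor also gets the extra splice flag
  near <- classify_variant("chrT", 178, "A", "G", g$tx, g$ref)
  expect_setequal(near$categories,
                  c("nonconservative_missense", "splice_site"))
  # 2 bp deletion inside CDS -> frameshift; 3 bp -> in-frame "other"
  p <- toy_codon_pos(10, 1)
  fs <- classify_variant("chrT", p - 1, "AAA", "A", g$tx, g$ref)
  expect_true("frameshift" %in% fs$categories)
  inframe <- classify_variant("chrT", p - 1, "AAAA", "A", g$tx, g$ref)
  expect_false("frameshift" %in% inframe$categories)
})

test_that("GFF3 transcripts round-trip through rtracklayer", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chrT\ttest\tgene\t101\t300\t.\t+\t.\tID=gene1",
    "chrT\ttest\tmRNA\t101\t300\t.\t+\t.\tID=tx1;Parent=gene1",
    "chrT\ttest\texon\t101\t180\t.\t+\t.\tParent=tx1",
    "chrT\ttest\texon\t221\t300\t.\t+\t.\tParent=tx1",
    "chrT\ttest\tCDS\t121\t180\t.\t+\t0\tParent=tx1",
    "chrT\ttest\tCDS\t221\t280\t.\t+\t0\tParent=tx1"), gff)
  txs <- read_transcripts_gff3(gff)
  expect_equal(names(txs), "tx1")
  expect_equal(txs$tx1$exons$start, c(101, 221))
  expect_equal(txs$tx1$cds_start, 121)
  expect_equal(txs$tx1$cds_end, 280)
  expect_equal(txs$tx1$strand, "+")
})
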