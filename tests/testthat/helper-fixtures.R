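# Fixtures built in code.

trio_pedigree <- function() {
  Pedigree(data.frame(
    id = c("dad", "mom", "kid"),
    father = c(NA, NA, "dad"), mother = c(NA, NA, "mom"),
    sex = c("male", "female", "male"),
    affected = c("unaffected", "unaffected", "affected")))
}

# GenotypeMatrix from a plain dosage matrix on a uniform map
gm_from <- function(geno, chrom = "1") {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("m%04d", seq_len(ncol(geno)))
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("i%02d", seq_len(nrow(geno)))
  map <- marker_map(colnames(geno), rep(chrom, ncol(geno)),
                    seq_len(ncol(geno)) * 1e5)
  alleles <- data.frame(marker = colnames(geno), a1 = "A", a2 = "B",
                        stringsAsFactors = FALSE)
  GenotypeMatrix(geno, alleles, map)
}

# Published case/control genotype counts for the 11 candidate variants
# (heterozygote and wild-type counts in 1,541 cases / 5,785 controls).
candidate_counts <- function() {
  read.delim(system.file("extdata", "casecontrol_counts.tsv",
                         package = "famvar"), stringsAsFactors = FALSE)
}

# Two-generation pedigree: mother carries a variant transmitted to all
# three affected sons but not to the unaffected daughter.
pedigree_rab11fip5 <- function() {
  ped <- Pedigree(data.frame(
    id = c("father", "mother", "son1", "son2", "son3", "daughter"),
    father = c(NA, NA, "father", "father", "father", "father"),
    mother = c(NA, NA, "mother", "mother", "mother", "mother"),
    sex = c("male", "female", "male", "male", "male", "female"),
    affected = c("unaffected", "unaffected", "affected", "affected",
                 "affected", "unaffected")))
  geno <- c(father = 0L, mother = 1L, son1 = 1L, son2 = 1L, son3 = 1L,
            daughter = 0L)
  list(ped = ped, geno = geno)
}

# Two-generation pedigree with five affected sons, four inheriting a
# maternal variant.
pedigree_klhl6 <- function() {
  ped <- Pedigree(data.frame(
    id = c("father", "mother", paste0("son", 1:5)),
    father = c(NA, NA, rep("father", 5)),
    mother = c(NA, NA, rep("mother", 5)),
    sex = c("male", "female", rep("male", 5)),
    affected = c("unaffected", "unaffected", rep("affected", 5))))
  geno <- c(father = 0L, mother = 1L, son1 = 1L, son2 = 1L, son3 = 1L,
            son4 = 1L, son5 = 0L)
  list(ped = ped, geno = geno)
}

# Plus-strand two-exon gene on a 400 bp chromosome built from explicit
# codons so expected amino acids are known by construction.
# Exon 1: 101-180, exon 2: 221-300; CDS: 121-180 + 221-280 (120 bp = 40
# codons). Codons are all "AAA" (lysine) except where a test edits them.
toy_gene <- function(codon_overrides = list()) {
  codons <- rep("AAA", 40)
  for (i in seq_along(codon_overrides))
    codons[as.integer(names(codon_overrides)[i])] <- codon_overrides[[i]]
  cds <- paste(codons, collapse = "")
  pad <- function(n) paste(rep("G", n), collapse = "")
  # 1-100 pad, 101-120 5'UTR (exonic), 121-180 CDS part 1 (codons 1-20),
  # 181-220 intron, 221-280 CDS part 2 (codons 21-40), 281-300 3'UTR,
  # 301-400 pad
  chrom_seq <- paste0(pad(100), paste(rep("C", 20), collapse = ""),
                      substr(cds, 1, 60), pad(40),
                      substr(cds, 61, 120),
                      paste(rep("C", 20), collapse = ""), pad(100))
  stopifnot(nchar(chrom_seq) == 400)
  tx <- Transcript("tx1", "chrT", "+",
                   exons = data.frame(start = c(101, 221),
                                      end = c(180, 300)),
                   cds_start = 121, cds_end = 280)
  list(ref = c(chrT = chrom_seq), tx = tx)
}

# genomic position of base `b` (1-3) of codon `i` (1-40) in toy_gene
toy_codon_pos <- function(i, b) {
  cp <- (i - 1) * 3 + b         # CDS coordinate
  if (cp <= 60) 120 + cp else 220 + (cp - 60)
}
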