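# Building transcript-oriented acceptor contexts from a genome and exon
# annotations, and enumerating/applying first-nucleotide variants.

test_that("plus-strand context slices the acceptor window directly", {
  g <- toy_gene(paste0(random_dna(44), "TTTCAG"), paste0("G", random_dna(39)))
  ctx <- build_context(g$middle, g$genome)
  expect_s3_class(ctx, "AcceptorContext")
  expect_identical(nchar(ctx$intronic3), 50L)
  expect_identical(substr(ctx$intronic3, 49, 50), "AG")
  expect_identical(ctx$ref_first_base, "G")
  expect_identical(ctx$exon_length, 40L)
  expect_identical(nchar(ctx$donor9), 9L)
  # coordinate round-trip: Ex+1 maps back to exon_start on the plus strand
  expect_equal(ctx$coord$pos, g$middle$exon_start)
})

test_that("minus-strand contexts equal their plus-strand mirror base for base", {
  intron <- paste0(random_dna(44), "TTACAG")
  exon <- paste0("G", random_dna(30))
  plus <- toy_gene(intron, exon)
  ctx_plus <- build_context(plus$middle, plus$genome)
  # mirror: reverse-complement the whole chromosome, flip the annotation
  L <- length(plus$genome[[1]])
  rc <- Biostrings::reverseComplement(plus$genome)
  ann <- plus$annotation
  mirror <- data.frame(
    transcript_id = ann$transcript_id, chrom = ann$chrom, strand = "-",
    exon_start = L + 1 - ann$exon_end, exon_end = L + 1 - ann$exon_start,
    exon_index = ann$exon_index, n_exons = ann$n_exons)
  ctx_minus <- build_context(mirror[2, ], rc)
  for (f in c("intronic3", "exonic", "donor9", "exon_length",
              "ref_first_base")) {
    expect_identical(ctx_minus[[f]], ctx_plus[[f]])
  }
  # the genomic sense strand holds C where the transcript reads G
  expect_identical(as.character(Biostrings::subseq(
    rc[[1]], mirror$exon_end[2], mirror$exon_end[2])), "C")
  # coordinate round-trip on the minus strand: Ex+1 is exon_end
  expect_equal(ctx_minus$coord$pos, mirror$exon_end[2])
})

test_that("terminal exons are rejected and bad windows error", {
  g <- toy_gene(paste0(random_dna(44), "TTTCAG"), paste0("G", random_dna(39)))
  expect_error(build_context(g$annotation[1, ], g$genome), "terminal exon")
  expect_error(build_context(g$annotation[3, ], g$genome), "terminal exon")
  # window beyond chromosome bounds
  short <- data.frame(transcript_id = "T", chrom = "chrT", strand = "+",
                      exon_start = 20, exon_end = 45, exon_index = 2,
                      n_exons = 3)
  expect_error(build_context(short, g$genome), "exceeds bounds")
  # ambiguity base in a required window is a hard error naming the position
  gn <- g$genome
  seq_n <- as.character(gn[[1]])
  substr(seq_n, g$middle$exon_start - 10, g$middle$exon_start - 10) <- "N"
  gn2 <- Biostrings::DNAStringSet(setNames(seq_n, "chrT"))
  expect_error(build_context(g$middle, gn2), "non-ACGT.*position")
})

test_that("a non-AG acceptor warns but still builds", {
  g <- toy_gene(paste0(random_dna(44), "TTTCAC"), paste0("G", random_dna(20)))
  expect_warning(build_context(g$middle, g$genome), "does not end in AG")
})

test_that("variant enumeration yields exactly G>A, G>C, G>T in order", {
  g <- toy_gene(paste0(random_dna(44), "TTTCAG"), paste0("G", random_dna(39)))
  ctx <- build_context(g$middle, g$genome)
  vars <- enumerate_fex_variants(ctx)
  expect_length(vars, 3)
  expect_identical(vapply(vars, `[[`, "", "alt"), c("A", "C", "T"))
  # round-trip: applying each variant then reading Ex+1 yields its alt
  for (v in vars) {
    applied <- apply_variant(v)
    expect_identical(substr(applied$exonic, 1, 1), v$alt)
    expect_identical(applied$intronic3, ctx$intronic3)
    expect_identical(substr(applied$exonic, 2, nchar(applied$exonic)),
                     substr(ctx$exonic, 2, nchar(ctx$exonic)))
  }
  # contexts whose first base is not G are refused
  g2 <- toy_gene(paste0(random_dna(44), "TTTCAG"), paste0("A", random_dna(39)))
  ctx2 <- build_context(g2$middle, g2$genome)
  expect_error(enumerate_fex_variants(ctx2), "not G")
})

test_that("variants in very short exons propagate into the donor window", {
  g <- toy_gene(paste0(random_dna(44), "TTTCAG"), "GAT",
                intron2 = paste0("GTAAGT", random_dna(24)))
  ctx <- build_context(g$middle, g$genome)
  expect_identical(substr(ctx$donor9, 1, 3), "GAT")
  v <- fex_variant(ctx, "T")
  applied <- apply_variant(v)
  expect_identical(substr(applied$donor9, 1, 1), "T")
  expect_identical(substr(applied$donor9, 4, 9), "GTAAGT")
})

test_that("context building is deterministic", {
  g <- toy_gene(paste0(random_dna(44), "TTCCAG"), paste0("G", random_dna(50)))
  expect_identical(build_context(g$middle, g$genome),
                   build_context(g$middle, g$genome))
})

test_that("exons_at_first_base finds internal exons on both strands", {
  ds <- generate_dataset(synth_params(n_variants = 12, seed = 7))
  for (i in seq_len(nrow(ds$snvs))) {
    hits <- exons_at_first_base(ds$annotation, ds$snvs$chrom[i],
                                ds$snvs$pos[i])
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$exon_index, 2L)
  }
})
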