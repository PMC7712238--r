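test_that("FASTA reading enforces record contracts", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT"), fa)
  set <- readFasta(fa)
  expect_equal(names(set), "s1")
  expect_equal(as.character(set[["s1"]]), "ACGT")

  writeLines(c(">s1", "ACGT", ">s1", "GGTT"), fa)
  expect_error(readFasta(fa), "s1")

  file.create(fa)
  expect_error(readFasta(fa), "no FASTA records")
})

test_that("random FASTA records round-trip write -> read identically", {
  set.seed(11)
  n <- 100L
  seqs <- vapply(seq_len(n), function(i)
    randDna(sample(30:200, 1L)), character(1))
  names(seqs) <- sprintf("rec%03d", seq_len(n))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeFasta(Biostrings::DNAStringSet(seqs), fa)
  back <- readFasta(fa)
  expect_equal(names(back), names(seqs))
  expect_equal(as.character(back), seqs)
})

test_that("GFF3 CDS features become 1-based sorted gene models", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "scf1\t.\tgene\t101\t260\t.\t+\t.\tID=g1",
    "scf1\t.\tmRNA\t101\t260\t.\t+\t.\tID=g1.t1;Parent=g1",
    "scf1\t.\tCDS\t201\t260\t.\t+\t0\tID=c2;Parent=g1.t1",
    "scf1\t.\tCDS\t101\t130\t.\t+\t0\tID=c1;Parent=g1.t1"), gff)
  models <- readGeneModels(gff)
  expect_length(models, 1L)
  gm <- models[["g1.t1"]]
  expect_equal(geneID(gm), "g1")
  expect_equal(scaffoldName(gm), "scf1")
  # CDS lines were out of order in the file; model is sorted
  expect_equal(IRanges::start(cdsRanges(gm)), c(101L, 201L))
  expect_equal(IRanges::end(cdsRanges(gm)), c(130L, 260L))
  expect_equal(totalCdsLength(gm), 90L)
})

test_that("mixed-strand CDS under one parent is rejected", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "scf1\t.\tCDS\t101\t130\t.\t+\t0\tParent=t1",
    "scf1\t.\tCDS\t201\t260\t.\t-\t0\tParent=t1"), gff)
  expect_error(readGeneModels(gff), "mixed strands")
})

test_that("annotated phases disagreeing with coordinates raise a warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "scf1\t.\tCDS\t101\t130\t.\t+\t0\tParent=t1",
    "scf1\t.\tCDS\t201\t260\t.\t+\t1\tParent=t1"), gff)
  expect_warning(readGeneModels(gff), "phase disagrees")
})

test_that("transcript selection policies are deterministic", {
  mk <- function(tx, gene, from, to)
    GeneModel(gene, tx, "s", "+", IRanges::IRanges(from, to))
  models <- list(mk("gA.t2", "gA", 1, 60), mk("gA.t1", "gA", 1, 30),
                 mk("gB.t1", "gB", 100, 120))
  longest <- selectTranscripts(models, "longest")
  expect_equal(names(longest), c("gA.t2", "gB.t1"))
  firstId <- selectTranscripts(models, "first-id")
  expect_equal(names(firstId), c("gA.t1", "gB.t1"))
  expect_length(selectTranscripts(models, "all"), 3L)
})

test_that("spliced CDS respects strand and reports introns in transcription order", {
  genome <- Biostrings::DNAStringSet(c(scf = paste0(
    "AAAA", "ATGGTT", "GTAAG", "CCTTAA", "TTTT")))
  # exons at 5..10 and 16..21 (1-based)
  gmPlus <- GeneModel("gp", "gp.t", "scf", "+",
                      IRanges::IRanges(c(5, 16), c(10, 21)))
  sp <- splicedCds(gmPlus, genome)
  expect_equal(sp$cds, "ATGGTTCCTTAA")
  expect_equal(sp$introns$start, 11L)
  expect_equal(sp$introns$end, 15L)

  gmMinus <- GeneModel("gm", "gm.t", "scf", "-",
                       IRanges::IRanges(c(5, 16), c(10, 21)))
  sm <- splicedCds(gmMinus, genome)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(sm$cds, rc("ATGGTTCCTTAA"))
  # same genomic gap, still one intron
  expect_equal(nrow(sm$introns), 1L)

  bad <- GeneModel("gb", "gb.t", "scf", "+", IRanges::IRanges(20, 40))
  expect_error(splicedCds(bad, genome), "bounds")
})

test_that("re-inserting introns into the spliced CDS reconstructs the genomic span", {
  set.seed(21)
  for (rep in 1:25) {
    scafSeq <- randDna(2000)
    genome <- Biostrings::DNAStringSet(c(scf = scafSeq))
    # random 5-exon plus-strand gene
    cuts <- sort(sample(seq(120, 1800, by = 3), 10L))
    starts <- cuts[c(1, 3, 5, 7, 9)]
    ends <- cuts[c(2, 4, 6, 8, 10)] - 1L
    gm <- GeneModel("g", "g.t", "scf", "+",
                    IRanges::IRanges(starts, ends))
    sp <- splicedCds(gm, genome)
    expect_equal(nchar(sp$cds), totalCdsLength(gm))
    # splice the introns back between the exon pieces
    w <- IRanges::width(cdsRanges(gm))
    offsets <- cumsum(w)
    rebuilt <- substr(sp$cds, 1, offsets[1])
    for (i in seq_len(nrow(sp$introns))) {
      rebuilt <- paste0(rebuilt,
                        substr(scafSeq, sp$introns$start[i],
                               sp$introns$end[i]),
                        substr(sp$cds, offsets[i] + 1, offsets[i + 1]))
    }
    expect_equal(rebuilt, substr(scafSeq, min(starts), max(ends)))
  }
})

test_that("translation follows the standard code with stop handling", {
  expect_equal(translateCds("ATGGCCTAA"), "MA")
  expect_error(translateCds("ATGTAAGCC"), "codon 2")
  expect_warning(out <- translateCds("ATGGCCTAAGCC",
                                     on_internal_stop = "truncate"),
                 "truncating")
  expect_equal(out, "MA")
  expect_warning(translateCds("ATGGCCTAAG"), "incomplete codon")
  # ambiguity codes pass through as X
  expect_equal(translateCds("ATGANT"), "MX")
  expect_error(translateCds("AT"), "shorter")
})

test_that("translation matches an independent codon-table oracle", {
  set.seed(31)
  for (rep in 1:200) {
    nCodon <- sample(2:60, 1L)
    cds <- paste(vapply(seq_len(nCodon), function(i) {
      repeat {
        cod <- randDna(3)
        if (!Biostrings::GENETIC_CODE[[cod]] == "*") return(cod)
      }
    }, character(1)), collapse = "")
    expect_equal(translateCds(cds), oracleTranslate(cds))
  }
})

test_that("flank extraction obeys orientation and truncation contracts", {
  seq <- randDna(3000)
  genome <- Biostrings::DNAStringSet(c(scf = seq))
  gm <- GeneModel("g", "g.t", "scf", "+",
                  IRanges::IRanges(401, 700))
  fl <- extractFlanks(gm, genome, 1000L)
  expect_equal(nchar(fl$five_prime), 400L)
  expect_true(fl$five_prime_truncated)
  expect_equal(fl$five_prime, substr(seq, 1, 400))
  expect_equal(fl$three_prime, substr(seq, 701, 1700))
  expect_false(fl$three_prime_truncated)

  gmM <- GeneModel("g2", "g2.t", "scf", "-",
                   IRanges::IRanges(401, 700))
  flM <- extractFlanks(gmM, genome, 300L)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  # minus-strand 5' flank is the reverse complement of the right side
  expect_equal(flM$five_prime, rc(substr(seq, 701, 1000)))
  expect_equal(flM$three_prime, rc(substr(seq, 101, 400)))
})
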