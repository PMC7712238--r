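# build a plus-strand two-exon model whose first exon has `off` coding nt
twoExonModel <- function(off, strand = "+", scafLen = 4000L,
                         cdsLen = 900L) {
  gStart <- 1001L
  ex1 <- IRanges::IRanges(gStart, gStart + off - 1L)
  intronLen <- 50L
  ex2Start <- gStart + off + intronLen
  ex2 <- IRanges::IRanges(ex2Start, ex2Start + (cdsLen - off) - 1L)
  GeneModel("g", "g.t", "scf", strand, c(ex1, ex2))
}

test_that("intron codon index and phase derive from the spliced-CDS offset", {
  m30 <- mapIntronsToProtein(twoExonModel(30L))
  expect_equal(m30$codon_index, 10L)
  expect_equal(m30$phase, 0L)
  m31 <- mapIntronsToProtein(twoExonModel(31L))
  expect_equal(m31$codon_index, 10L)
  expect_equal(m31$phase, 1L)
  m32 <- mapIntronsToProtein(twoExonModel(32L))
  expect_equal(m32$phase, 2L)
  expect_equal(nrow(mapIntronsToProtein(
    GeneModel("g", "g.t", "s", "+", IRanges::IRanges(1, 30)))), 0L)
})

test_that("cds offsets reconstruct intron genomic positions on random multi-exon genes", {
  set.seed(201)
  for (rep in 1:40) {
    nEx <- sample(2:6, 1L)
    cuts <- sort(sample(seq(100, 3000, by = 1), 2L * nEx))
    starts <- cuts[seq(1, 2 * nEx, by = 2)]
    ends <- cuts[seq(2, 2 * nEx, by = 2)]
    strand <- sample(c("+", "-"), 1L)
    gm <- GeneModel("g", "g.t", "scf", strand,
                    IRanges::IRanges(starts, ends))
    introns <- mapIntronsToProtein(gm)
    w <- IRanges::width(cdsRanges(gm))
    expect_equal(nrow(introns), nEx - 1L)
    # invert: walking cds_offset through the exon chain in transcription
    # order must land exactly on the recorded donor boundary
    for (i in seq_len(nrow(introns))) {
      off <- introns$cds_offset[i]
      expect_equal(off, 3L * introns$codon_index[i] + introns$phase[i])
      if (strand == "+") {
        cum <- cumsum(w)
        k <- match(off, cum)
        expect_false(is.na(k))
        expect_equal(introns$start[i], IRanges::end(cdsRanges(gm))[k] + 1L)
      } else {
        cum <- cumsum(rev(w))
        k <- match(off, cum)
        expect_false(is.na(k))
        revIdx <- length(w) - k + 1L
        expect_equal(introns$end[i],
                     IRanges::start(cdsRanges(gm))[revIdx] - 1L)
      }
    }
  }
})

test_that("landmark offsets reproduce the conserved intron descriptors", {
  # intron between the 20th and 21st codons after C4 (at residue 65)
  d <- landmarkOffset(codon_index = 85L, phase = 0L, landmark_pos = 65L,
                      landmark = "C4")
  expect_equal(d$codon_offset, 20L)
  expect_equal(d$phase, 0L)
  expect_false(d$non_canonical)
  # intron 1 bp after the codon for C3 (at residue 47)
  d2 <- landmarkOffset(codon_index = 47L, phase = 1L, landmark_pos = 47L,
                       landmark = "C3")
  expect_equal(d2$codon_offset, 1L)
  expect_equal(d2$phase, 1L)
  # intron 8 codons after C4
  d3 <- landmarkOffset(codon_index = 59L, phase = 0L, landmark_pos = 51L,
                       landmark = "C4")
  expect_equal(d3$codon_offset, 8L)
  # intron 5' of the landmark: negative offset, flagged
  d4 <- landmarkOffset(codon_index = 10L, phase = 0L, landmark_pos = 47L,
                       landmark = "C3")
  expect_true(d4$non_canonical)
  expect_lt(d4$codon_offset, 0L)
})

test_that("plant-and-recover round-trips random landmark descriptors exactly", {
  set.seed(202)
  p <- 50L  # landmark residue
  for (rep in 1:60) {
    k <- sample(1:60, 1L)
    ph <- sample(0:2, 1L)
    off <- if (ph == 0L) 3L * (p + k) else 3L * p + 3L * (k - 1L) + ph
    gm <- twoExonModel(off)
    site <- mapIntronsToProtein(gm)
    d <- landmarkOffset(site$codon_index, site$phase, p, "C4")
    expect_equal(d$codon_offset, k)
    expect_equal(d$phase, ph)
    expect_false(d$non_canonical)
  }
})

test_that("landmark descriptors are invariant under strand re-embedding", {
  genome1 <- Biostrings::DNAStringSet(c(scf = randDna(4000)))
  gmP <- twoExonModel(255L, "+")
  # re-embed the same gene on the minus strand of a mirrored scaffold
  L <- 4000L
  cds <- cdsRanges(gmP)
  mirrored <- IRanges::IRanges(L - IRanges::end(cds) + 1L,
                               L - IRanges::start(cds) + 1L)
  gmM <- GeneModel("g", "g.t", "scf", "-", mirrored)
  fingers <- data.frame(kind = "gata_canonical", c1 = 41, c2 = 44,
                        c3 = 62, c4 = 65)
  dP <- landmarkDescriptors(mapIntronsToProtein(gmP), fingers)
  dM <- landmarkDescriptors(mapIntronsToProtein(gmM), fingers)
  expect_equal(dP[, c("landmark", "codon_offset", "phase")],
               dM[, c("landmark", "codon_offset", "phase")])
})

test_that("signature flags equal a set-membership oracle on random descriptor sets", {
  set.seed(203)
  flagSpecs <- list(has_N_basic_intron = c("C4", 20, 0),
                    has_C_basic_intron = c("C4", 8, 0),
                    has_zf_intron = c("C3", 1, 1))
  for (rep in 1:100) {
    n <- sample(0:6, 1L)
    d <- data.frame(
      intron = seq_len(n),
      finger = rep(1L, n),
      finger_kind = rep("gata_canonical", n),
      landmark = sample(c("C3", "C4"), n, replace = TRUE),
      codon_offset = sample(c(0:2, 8L, 20L), n, replace = TRUE),
      phase = sample(0:2, n, replace = TRUE),
      non_canonical = rep(FALSE, n),
      stringsAsFactors = FALSE)
    sig <- intronSignature(d, n)
    for (fl in names(flagSpecs)) {
      spec <- flagSpecs[[fl]]
      expect_equal(sig[[fl]],
                   any(d$landmark == spec[1] &
                         d$codon_offset == as.integer(spec[2]) &
                         d$phase == as.integer(spec[3])))
    }
    expect_equal(sig$intronless, n == 0L)
  }
  # an ELT-1-type descriptor pair sets both basic-domain flags
  d1 <- data.frame(intron = 1:2, finger = 1:2,
                   finger_kind = "gata_canonical",
                   landmark = "C4", codon_offset = c(20L, 8L),
                   phase = 0L, non_canonical = FALSE,
                   stringsAsFactors = FALSE)
  sig1 <- intronSignature(d1, 2L)
  expect_true(sig1$has_N_basic_intron)
  expect_true(sig1$has_C_basic_intron)
  expect_false(sig1$has_zf_intron)
  expect_equal(sig1$extra_introns, 0L)
})
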