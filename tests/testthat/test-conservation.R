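canonicalDbd <- function() {
  lib <- consensusLibrary()
  lib[["ELT5"]]
}

dbdTableFor <- function(seqs, nterm = 0L) {
  data.frame(seq_id = names(seqs), c1 = nterm + 1L, c2 = nterm + 4L,
             c3 = nterm + 22L, c4 = nterm + 25L,
             stringsAsFactors = FALSE)
}

test_that("identical canonical DBDs anchor into identical gapless rows", {
  seqs <- c(a = canonicalDbd(), b = canonicalDbd())
  aln <- anchorAlign(dbdTableFor(seqs), seqs)
  expect_equal(nchar(aln$rows), c(a = 55L, b = 55L))
  expect_identical(aln$rows[["a"]], aln$rows[["b"]])
  expect_false(grepl("-", aln$rows[["a"]]))
  expect_equal(nrow(aln$insertions), 0L)
  # cysteine columns
  for (col in c(1, 4, 22, 25))
    expect_equal(substr(aln$rows[["a"]], col, col), "C")
})

test_that("short loops are center-padded and long spacers center-trimmed", {
  # loop of 16: single gap just right of the loop center (column 13)
  p16 <- paste0("C", "AA", "C", strrep("A", 8), strrep("G", 8),
                "C", "AA", "C", strrep("K", 30))
  tab <- data.frame(seq_id = "x", c1 = 1L, c2 = 4L, c3 = 21L, c4 = 24L)
  aln <- anchorAlign(tab, c(x = p16))
  row <- aln$rows[["x"]]
  expect_equal(nchar(row), 55L)
  expect_equal(substr(row, 13, 13), "-")
  expect_equal(substr(row, 5, 12), strrep("A", 8))
  expect_equal(substr(row, 14, 21), strrep("G", 8))

  # CSNSNC variant: the 4-residue spacer keeps its outer 2 residues and
  # records the middle 2 as an insertion
  pv <- paste0("CSNSNC", strrep("A", 17), "C", "AA", "C",
               strrep("K", 30))
  tabv <- data.frame(seq_id = "v", c1 = 1L, c2 = 6L, c3 = 24L, c4 = 27L)
  alnv <- anchorAlign(tabv, c(v = pv))
  expect_equal(substr(alnv$rows[["v"]], 1, 4), "CSNC")
  expect_equal(alnv$insertions$region, "first_spacer")
  expect_equal(alnv$insertions$seq, "NS")

  # truncated basic domain is gap-padded on the right
  pt <- paste0("C", "AA", "C", strrep("A", 17), "C", "AA", "C",
               strrep("K", 13))
  tabt <- data.frame(seq_id = "t", c1 = 1L, c2 = 4L, c3 = 22L, c4 = 25L)
  alnt <- anchorAlign(tabt, c(t = pt))
  expect_equal(substr(alnt$rows[["t"]], 39, 55), strrep("-", 17))
})

test_that("consensus case encodes absolute vs majority conservation", {
  rows <- rep(canonicalDbd(), 3)
  names(rows) <- paste0("r", 1:3)
  aln <- anchorAlign(dbdTableFor(rows), rows)
  cons <- consensusString55(aln)
  expect_equal(cons, canonicalDbd())  # all uppercase, identical rows
  expect_equal(conservationCount(aln, "absolute")$k, 55L)

  # {A, A, G, G} column yields '.'
  r4 <- c("AAAA", "AAAA", "GAAA", "GAAA")
  expect_equal(substr(oracleConsensus(r4), 1, 1), ".")

  # fuzzed alignments match the per-column counting oracle
  set.seed(401)
  for (rep in 1:150) {
    n <- sample(2:8, 1L)
    rows <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "G", "K", "-"), 55, replace = TRUE),
            collapse = ""), character(1))
    expect_equal(consensusString55(rows), oracleConsensus(rows))
    cc <- consensusString55(rows)
    ch <- strsplit(cc, "")[[1]]
    expect_equal(conservationCount(rows, "absolute")$k,
                 sum(ch %in% LETTERS))
    expect_equal(conservationCount(rows, "majority")$k,
                 sum(ch != "."))
    expect_gte(conservationCount(rows, "majority")$k,
               conservationCount(rows, "absolute")$k)
  }
})

test_that("conservation counting matches the constructed two-row example", {
  a <- canonicalDbd()
  b <- a
  # mutate 5 non-cysteine columns
  for (col in c(6, 10, 30, 40, 50))
    substr(b, col, col) <- if (substr(a, col, col) == "A") "G" else "A"
  cc <- conservationCount(c(a, b), "absolute")
  expect_equal(cc$k, 50L)
  expect_equal(cc$n, 55L)
})

test_that("consensus is idempotent on case-stripped content", {
  set.seed(402)
  rows <- vapply(1:5, function(i)
    paste(sample(c("A", "G", "K"), 55, replace = TRUE), collapse = ""),
    character(1))
  cons <- consensusString55(rows)
  again <- consensusString55(toupper(gsub("\\.", "-", cons)))
  # a single-row alignment conserves every non-gap column absolutely
  expect_equal(tolower(gsub("\\.", "-", again)),
               tolower(gsub("\\.", "-", cons)))
})

test_that("contact-position variability counts disagreeing class consensi", {
  contacts <- contactPositions()
  expect_length(contacts, 18L)
  same <- c(A = canonicalDbd(), B = canonicalDbd())
  expect_equal(contactVariability(same, contacts)$varied, 0L)
  other <- canonicalDbd()
  changed <- intersect(contacts, c(8, 9, 11))
  for (col in changed)
    substr(other, col, col) <- "W"
  expect_equal(contactVariability(c(A = canonicalDbd(), B = other),
                                  contacts)$varied, length(changed))
  # lowercase (majority-only) consensus counts as varied even when equal
  lowered <- tolower(canonicalDbd())
  expect_equal(contactVariability(c(A = lowered, B = lowered),
                                  contacts)$varied, 18L)
})

test_that("alignment export round-trips and preserves the 55-column width", {
  seqs <- c(a = canonicalDbd(), b = canonicalDbd())
  aln <- anchorAlign(dbdTableFor(seqs), seqs)
  out <- withr::local_tempfile(fileext = ".fasta")
  exportAlignment(aln, out)
  back <- readFasta(out, "AA")
  expect_equal(names(back), c("a", "b"))
  expect_equal(unique(Biostrings::width(back)), 55L)
  expect_equal(as.character(back[["a"]]), aln$rows[["a"]])
  golden <- readLines(test_path("fixtures", "alignment_golden.fasta"))
  expect_identical(readLines(out), golden)
})
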