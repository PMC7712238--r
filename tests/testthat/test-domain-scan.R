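test_that("canonical and variant C4 fingers are detected with exact geometry", {
  p <- paste0("M", "C", "AA", "C", strrep("A", 17), "C", "AA", "C",
              strrep("K", 30))
  f <- findGataFingers(p)
  expect_equal(nrow(f), 1L)
  expect_equal(f$kind, "gata_canonical")
  expect_equal(unlist(f[, c("c1", "c2", "c3", "c4")], use.names = FALSE),
               c(2L, 5L, 23L, 26L))
  expect_equal(f$first_spacer, 2L)
  expect_equal(f$loop_len, 17L)

  # CSNSNC-style variant spacer (4 residues between the first cysteines)
  v <- paste0("CSNSNC", strrep("A", 17), "C", "AA", "C", strrep("K", 30))
  fv <- findGataFingers(v)
  expect_equal(nrow(fv), 1L)
  expect_equal(fv$kind, "gata_variant")
  expect_equal(fv$first_spacer, 4L)

  # loop lengths outside the configured range do not match
  short <- paste0("C", "AA", "C", strrep("A", 15), "C", "AA", "C")
  expect_equal(nrow(findGataFingers(short)), 0L)
})

test_that("finger scan equals brute-force quadruple enumeration on fuzzed proteins", {
  set.seed(101)
  cfg <- scanConfig()
  for (rep in 1:120) {
    p <- randProtein(sample(80:400, 1L), cProb = 0.08)
    got <- findGataFingers(p, cfg)
    exp <- oracleC4(p, cfg$first_spacer_range, cfg$loop_range)
    asInt <- function(m) matrix(as.integer(unlist(m)), ncol = 4L)
    expect_equal(asInt(got[, c("c1", "c2", "c3", "c4")]),
                 asInt(exp))
    # every reported cysteine index is literally C
    ch <- strsplit(p, "")[[1]]
    for (col in c("c1", "c2", "c3", "c4"))
      expect_true(all(ch[got[[col]]] == "C"))
  }
})

test_that("scan is deterministic and case-insensitive, X never matches C", {
  p <- paste0("xc", "aa", "c", strrep("a", 17), "c", "aa", "c",
              strrep("k", 12))
  f1 <- findGataFingers(p)
  expect_equal(nrow(f1), 1L)
  expect_identical(f1, findGataFingers(p))
  pX <- sub("^xc", "xX", p)
  expect_equal(nrow(findGataFingers(pX)), 0L)
})

test_that("basic domain fraction and truncation follow the 30-residue window", {
  p <- paste0("C", "AA", "C", strrep("A", 17), "C", "AA", "C",
              strrep("K", 30), "AAA")
  b <- findBasicDomain(p, 25L)
  expect_equal(b$observed_len, 30L)
  expect_equal(b$basic_fraction, 1.0)
  expect_false(b$truncated)

  # protein ends 13 residues after C4
  pT <- paste0("C", "AA", "C", strrep("A", 17), "C", "AA", "C",
               strrep("K", 13))
  bT <- findBasicDomain(pT, 25L)
  expect_equal(bT$observed_len, 13L)
  expect_true(bT$truncated)

  set.seed(102)
  for (rep in 1:50) {
    p <- randProtein(80, cProb = 0)
    b <- findBasicDomain(p, 20L)
    win <- strsplit(substr(p, 21, 50), "")[[1]]
    expect_equal(b$basic_fraction, mean(win %in% c("K", "R")))
  }
})

test_that("degenerate fingers require the upstream-of-DBD context", {
  dbd <- paste0("C", "AA", "C", strrep("A", 17), "C", "AA", "C",
                strrep("K", 30))
  deg <- paste0("C", "AA", "C", strrep("A", 12), "C", "AA", "C")
  up <- paste0("M", deg, strrep("G", 60), dbd)
  fingers <- findGataFingers(up)
  d <- findDegenerateFingers(up, fingers)
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "degenerate")
  expect_equal(d$loop_len, 12L)
  expect_equal(d$upstream_gap, 60L)

  # same motif downstream of the only GATA finger: orphan, not a hit
  down <- paste0("M", dbd, strrep("G", 60), deg)
  fingers2 <- findGataFingers(down)
  d2 <- findDegenerateFingers(down, fingers2)
  expect_equal(nrow(d2), 0L)
  expect_equal(nrow(attr(d2, "orphans")), 1L)

  # beyond the maximum upstream gap: rejected
  far <- paste0("M", deg, strrep("G", 230), dbd)
  d3 <- findDegenerateFingers(far, findGataFingers(far))
  expect_equal(nrow(d3), 0L)
})

test_that("degenerate loop bounds 9 and 20 are accepted, 8 and 21 rejected", {
  dbd <- paste0("C", "AA", "C", strrep("A", 17), "C", "AA", "C",
                strrep("K", 30))
  for (n in c(9L, 20L)) {
    p <- paste0("M", "C", "AA", "C", strrep("A", n), "C", "AA", "C",
                strrep("G", 50), dbd)
    d <- findDegenerateFingers(p, findGataFingers(p))
    expect_equal(nrow(d), 1L)
    expect_equal(d$loop_len, n)
  }
  for (n in c(8L, 21L)) {
    p <- paste0("M", "C", "AA", "C", strrep("A", n), "C", "AA", "C",
                strrep("G", 50), dbd)
    d <- findDegenerateFingers(p, findGataFingers(p))
    expect_equal(nrow(d), 0L)
  }
})

test_that("hexapeptide search returns the first literal T-X-[LA]-W-R-R match", {
  p <- paste0(strrep("G", 10), "TTAWRR", strrep("G", 10))
  hx <- findHexapeptide(p, 1L, nchar(p))
  expect_equal(hx$seq, "TTAWRR")
  expect_equal(hx$offset, 11L)
  # the final arginine is required
  expect_null(findHexapeptide(paste0(strrep("G", 4), "TPLWRA"), 1L, 10L))
  # regex-family oracle on random windows
  set.seed(103)
  for (rep in 1:200) {
    w <- randProtein(40, cProb = 0.02)
    got <- findHexapeptide(w, 1L, 40L)
    m <- regexpr("T[A-Z][LA]WRR", w, perl = TRUE)
    if (m == -1L) expect_null(got)
    else expect_equal(got$offset, as.integer(m))
  }
})

test_that("poly-serine segments are merged unions of qualifying windows", {
  seg <- findPolyS("AAAAASSSSSSAAAAA")
  expect_equal(nrow(seg), 1L)
  # 1-based closed [2, 15]: the union of qualifying windows starting 2..6
  expect_equal(seg$start, 2L)
  expect_equal(seg$end, 15L)
  expect_equal(seg$ser_count, 6L)

  expect_equal(nrow(findPolyS(paste0("SSSSS", strrep("A", 20)))), 0L)
})

test_that("poly-serine scan equals window-enumeration oracle on fuzzed input", {
  set.seed(104)
  for (rep in 1:200) {
    p <- randProtein(sample(20:150, 1L), cProb = 0.02, sProb = 0.3)
    got <- findPolyS(p)
    exp <- oraclePolyS(p)
    asInt <- function(m) matrix(as.integer(unlist(m)), ncol = 3L)
    expect_equal(asInt(got), asInt(exp))
    # segments never overlap
    if (nrow(got) > 1L)
      expect_true(all(got$start[-1L] > got$end[-nrow(got)]))
  }
})
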