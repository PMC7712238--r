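# Independent brute-force oracles. Each re-derives the expected result
# from first principles (exhaustive enumeration / direct counting) and is
# deliberately implemented differently from the package code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randProtein <- function(n, cProb = 0.06, sProb = 0.05) {
  other <- setdiff(AA20, c("C", "S"))
  paste(sample(c("C", "S", other), n, replace = TRUE,
               prob = c(cProb, sProb,
                        rep((1 - cProb - sProb) / length(other),
                            length(other)))),
        collapse = "")
}

randDna <- function(n, pyr = 0.5) {
  paste(sample(c("A", "G", "C", "T"), n, replace = TRUE,
               prob = c((1 - pyr) / 2, (1 - pyr) / 2, pyr / 2, pyr / 2)),
        collapse = "")
}

# exhaustive C4-motif enumeration over all cysteine quadruples, followed
# by the same published overlap rule (leftmost span first, then longest)
oracleC4 <- function(protein, spacer1, loop) {
  ch <- strsplit(toupper(protein), "")[[1]]
  cpos <- which(ch == "C")
  cand <- list()
  if (length(cpos) >= 4L) {
    quads <- utils::combn(cpos, 4L)
    for (q in seq_len(ncol(quads))) {
      c1 <- quads[1L, q]; c2 <- quads[2L, q]
      c3 <- quads[3L, q]; c4 <- quads[4L, q]
      if ((c2 - c1 - 1L) %in% spacer1 && (c3 - c2 - 1L) %in% loop &&
          (c4 - c3 - 1L) == 2L)
        cand[[length(cand) + 1L]] <- c(c1, c2, c3, c4)
    }
  }
  if (!length(cand)) return(matrix(integer(0), ncol = 4L))
  m <- do.call(rbind, cand)
  m <- m[order(m[, 1L], -(m[, 4L] - m[, 1L])), , drop = FALSE]
  taken <- rep(FALSE, nchar(protein))
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    span <- m[i, 1L]:m[i, 4L]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  m[keep, , drop = FALSE]
}

# poly-serine segments via a window coverage vector
oraclePolyS <- function(protein, w = 10L, k = 6L) {
  ch <- strsplit(toupper(protein), "")[[1]]
  n <- length(ch)
  if (n < w) return(matrix(integer(0), ncol = 3L))
  cov <- logical(n)
  for (s in 1:(n - w + 1L)) {
    win <- ch[s:(s + w - 1L)]
    if (sum(win == "S") >= k) cov[s:(s + w - 1L)] <- TRUE
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(segs)) return(matrix(integer(0), ncol = 3L))
  cbind(segs, apply(segs, 1L, function(se)
    sum(ch[se[1L]:se[2L]] == "S")))
}

HGATAR_PLUS <- as.vector(outer(c("A", "C", "T"),
                               paste0("GATA", c("A", "G")), paste0))

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# HGATAR hits by checking every 6-mer window against the enumerated set
oracleHgatar <- function(seq) {
  up <- toupper(seq)
  n <- nchar(up)
  hits <- list()
  if (n >= 6L) {
    for (s in 1:(n - 5L)) {
      win <- substr(up, s, s + 5L)
      if (win %in% HGATAR_PLUS)
        hits[[length(hits) + 1L]] <- data.frame(start = s, strand = "+")
      if (revcomp(win) %in% HGATAR_PLUS)
        hits[[length(hits) + 1L]] <- data.frame(start = s, strand = "-")
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), strand = character(0)))
  do.call(rbind, hits)
}

oracleDoubleGata <- function(seq, maxSpacer = 20L) {
  h <- oracleHgatar(seq)
  out <- list()
  for (p in h$start[h$strand == "+"]) {
    for (m in h$start[h$strand == "-"]) {
      sp <- m - (p + 6L)
      if (sp >= 0L && sp <= maxSpacer)
        out[[length(out) + 1L]] <- c(p, m + 5L, sp)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3L))
  m <- do.call(rbind, out)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

oraclePolypyrimidine <- function(seq, minLen = 12L, minFrac = 0.9) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n < minLen) return(matrix(integer(0), ncol = 2L))
  cov <- logical(n)
  for (s in 1:(n - minLen + 1L)) {
    win <- ch[s:(s + minLen - 1L)]
    if (mean(win %in% c("C", "T")) >= minFrac)
      cov[s:(s + minLen - 1L)] <- TRUE
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# per-column consensus by direct counting
oracleConsensus <- function(rows) {
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  paste(vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    counts <- table(col[col != "-"])
    if (length(counts) == 1L && sum(counts) == length(col))
      return(names(counts))
    if (length(counts) && max(counts) * 2L > length(col))
      return(tolower(names(counts)[which.max(counts)]))
    "."
  }, character(1)), collapse = "")
}

# codon-by-codon translation through the standard-code lookup table
oracleTranslate <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3L
  aa <- vapply(seq_len(n), function(i)
    unname(gc[substr(toupper(cds), 3L * i - 2L, 3L * i)]),
    character(1))
  paste(aa, collapse = "")
}

# pairwise paralog geometry by direct interval reasoning
oraclePair <- function(sA, eA, strA, sB, eB, strB) {
  overlap <- !(eA < sB || eB < sA)
  sep <- if (overlap) 0L else max(sB - eA, sA - eB) - 1L
  orient <- if (strA == strB) "same_direction"
  else {
    leftPlus <- if (sA <= sB) strA == "+" else strB == "+"
    if (leftPlus) "convergent" else "divergent"
  }
  list(sep = sep, orient = orient)
}

# a protein assembled from the shipped class templates, for classifier
# and conservation tests
templateProtein <- function(class, nterm = 20L, tail = 15L) {
  lib <- consensusLibrary()
  neutral <- setdiff(AA20, c("C", "S"))
  rand <- function(n) paste(sample(neutral, n, replace = TRUE),
                            collapse = "")
  if (class == "ELT1") {
    paste0(rand(nterm), substr(lib[["ELT1_N"]], 1, 25), rand(29),
           lib[["ELT1_C"]], rand(tail))
  } else if (class == "ELT2") {
    paste0(rand(nterm), "CLEC", rand(12), "CGAC", rand(60),
           lib[["ELT2"]], rand(tail))
  } else {
    paste0(rand(nterm), lib[[class]], rand(tail))
  }
}
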