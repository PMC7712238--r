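#' Scan for HGATAR GATA-binding sites
#'
#' Reports every occurrence of the GATA core `HGATAR` (`H` = A/C/T, `R` =
#' A/G) on the given strand, and of its reverse complement
#' (`[CT]TATC[AGT]`) as minus-strand hits at forward coordinates.
#' Overlapping occurrences are all reported.
#'
#' @param seq nucleotide string.
#' @return data.frame `kind` (`"hgatar"`), `start`, `end` (1-based
#'   closed, length-6 spans), `strand`, `detail` (`NA`).
#' @examples
#' scanHgatar("AGATAA")   # one plus-strand hit
#' scanHgatar("TTATCT")   # one minus-strand hit
#' @export
scanHgatar <- function(seq) {
  up <- toupper(seq)
  plus <- .allMatches(up, "(?=[ACT]GATA[AG])")
  minus <- .allMatches(up, "(?=[CT]TATC[AGT])")
  out <- data.frame(
    kind = rep("hgatar", length(plus) + length(minus)),
    start = c(plus, minus),
    end = c(plus, minus) + 5L,
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    detail = rep(NA_real_, length(plus) + length(minus)),
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all (possibly overlapping) match starts of a lookahead pattern
.allMatches <- function(x, pattern) {
  m <- gregexpr(pattern, x, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Find inverted-convergent double-GATA arrangements
#'
#' Pairs of HGATAR sites facing each other — a plus-strand site 5' of a
#' minus-strand site — separated by at most `max_spacer` bp. All
#' qualifying pairs are reported (no greedy consumption), each as one hit
#' spanning both sites with the spacer length in `detail`.
#'
#' @param seq nucleotide string.
#' @param max_spacer maximum bp between the two sites (default 20).
#' @return data.frame `kind` (`"double_gata"`), `start`, `end`, `strand`
#'   (`"both"`), `detail` (spacer).
#' @examples
#' findDoubleGata(paste0("AGATAA", "GGG", "TTATCA"))  # spacer 3
#' @export
findDoubleGata <- function(seq, max_spacer = 20L) {
  h <- scanHgatar(seq)
  plus <- h$start[h$strand == "+"]
  minus <- h$start[h$strand == "-"]
  rows <- list()
  for (p in plus) {
    for (m in minus) {
      spacer <- m - (p + 6L)
      if (spacer >= 0L && spacer <= max_spacer)
        rows[[length(rows) + 1L]] <- c(p, m, spacer)
    }
  }
  if (!length(rows))
    return(.emptyDf(kind = "character", start = "integer",
                    end = "integer", strand = "character",
                    detail = "numeric"))
  mt <- do.call(rbind, rows)
  out <- data.frame(kind = "double_gata", start = mt[, 1L],
                    end = mt[, 2L] + 5L, strand = "both",
                    detail = as.numeric(mt[, 3L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find polypyrimidine tracts
#'
#' Marks every window of length `min_len` whose C/T fraction is at least
#' `min_frac` and merges overlapping or adjacent qualifying windows into
#' maximal segments; `detail` is the pyrimidine fraction over the merged
#' span.
#'
#' @param seq nucleotide string.
#' @param min_len window length (default 12).
#' @param min_frac minimum C/T fraction per window (default 0.9).
#' @return data.frame `kind` (`"polypyrimidine"`), `start`, `end`,
#'   `strand` (`"+"`), `detail`.
#' @export
findPolypyrimidine <- function(seq, min_len = 12L, min_frac = 0.9) {
  ch <- .chars(seq)
  n <- length(ch)
  empty <- .emptyDf(kind = "character", start = "integer",
                    end = "integer", strand = "character",
                    detail = "numeric")
  if (n < min_len) return(empty)
  isPy <- ch %in% c("C", "T")
  cs <- c(0L, cumsum(isPy))
  need <- ceiling(min_frac * min_len)
  starts <- which((cs[(min_len + 1L):(n + 1L)] -
                     cs[1L:(n - min_len + 1L)]) >= need)
  if (!length(starts)) return(empty)
  segs <- list()
  curS <- starts[1L]; curE <- starts[1L] + min_len - 1L
  for (s in starts[-1L]) {
    if (s <= curE + 1L) curE <- s + min_len - 1L
    else { segs[[length(segs) + 1L]] <- c(curS, curE)
           curS <- s; curE <- s + min_len - 1L }
  }
  segs[[length(segs) + 1L]] <- c(curS, curE)
  m <- do.call(rbind, segs)
  data.frame(kind = "polypyrimidine", start = m[, 1L], end = m[, 2L],
             strand = "+",
             detail = (cs[m[, 2L] + 1L] - cs[m[, 1L]]) /
               (m[, 2L] - m[, 1L] + 1L),
             stringsAsFactors = FALSE)
}

#' Scan one flank for all three motif families
#'
#' @param seq nucleotide string (a flank in gene orientation).
#' @param max_spacer,min_len,min_frac passed through to the individual
#'   scanners.
#' @return combined data.frame of [scanHgatar()], [findDoubleGata()] and
#'   [findPolypyrimidine()] hits.
#' @export
scanFlankMotifs <- function(seq, max_spacer = 20L, min_len = 12L,
                            min_frac = 0.9) {
  rbind(scanHgatar(seq),
        findDoubleGata(seq, max_spacer),
        findPolypyrimidine(seq, min_len, min_frac))
}
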