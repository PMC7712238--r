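#' Scanner configuration
#'
#' Tunable parameters of the protein-domain scanners. The GATA-type C4
#' finger is `C-X(f)-C-X(L)-C-X2-C`: `f` (first spacer) defaults to 2-4
#' residues to admit the rare CSNSNC-style variant spacer, `L` (loop)
#' defaults to 16-19 with the strict canonical label reserved for exactly
#' (f = 2, L = 17). The degenerate upstream finger is `C-X2-C-X(9..20)-C-X2-C`
#' and must sit within `max_upstream_gap` residues upstream of a GATA
#' finger. Poly-serine segments are unions of length-`polyS_window`
#' windows containing at least `polyS_min_ser` serines.
#'
#' @param first_spacer_range integer vector of admissible first-spacer
#'   lengths.
#' @param loop_range integer vector of admissible loop lengths
#'   (C2-C3 interior).
#' @param canonical_spacer,canonical_loop the (spacer, loop) pair labelled
#'   `gata_canonical`.
#' @param degenerate_loop_range loop lengths of the degenerate finger.
#' @param max_upstream_gap maximum residues between a degenerate finger's
#'   last cysteine and a GATA finger's first cysteine (default 200).
#' @param hexapeptide_pattern regular expression for the diagnostic
#'   hexapeptide family (TPLWRR / TTLWRR / TSLWRR / TTAWRR ...).
#' @param polyS_window,polyS_min_ser poly-serine window length and minimum
#'   serine count.
#' @return a list with class `"ScanConfig"`.
#' @export
scanConfig <- function(first_spacer_range = 2:4,
                       loop_range = 16:19,
                       canonical_spacer = 2L,
                       canonical_loop = 17L,
                       degenerate_loop_range = 9:20,
                       max_upstream_gap = 200L,
                       hexapeptide_pattern = "T[A-Z][LA]WRR",
                       polyS_window = 10L,
                       polyS_min_ser = 6L) {
  structure(list(first_spacer_range = as.integer(first_spacer_range),
                 loop_range = as.integer(loop_range),
                 canonical_spacer = as.integer(canonical_spacer),
                 canonical_loop = as.integer(canonical_loop),
                 degenerate_loop_range = as.integer(degenerate_loop_range),
                 max_upstream_gap = as.integer(max_upstream_gap),
                 hexapeptide_pattern = hexapeptide_pattern,
                 polyS_window = as.integer(polyS_window),
                 polyS_min_ser = as.integer(polyS_min_ser)),
            class = "ScanConfig")
}

# enumerate all C-X(f)-C-X(L)-C-X2-C candidates; positions 1-based
.c4Candidates <- function(isC, spacer1Range, loopRange) {
  n <- length(isC)
  cpos <- which(isC)
  out <- vector("list", 0L)
  for (c1 in cpos) {
    for (f in spacer1Range) {
      c2 <- c1 + f + 1L
      if (c2 > n || !isC[c2]) next
      for (L in loopRange) {
        c3 <- c2 + L + 1L
        c4 <- c3 + 3L
        if (c4 > n) next
        if (isC[c3] && isC[c4])
          out[[length(out) + 1L]] <- c(c1, c2, c3, c4, f, L)
      }
    }
  }
  if (!length(out))
    return(.emptyDf(c1 = "integer", c2 = "integer", c3 = "integer",
                    c4 = "integer", first_spacer = "integer",
                    loop_len = "integer"))
  m <- do.call(rbind, out)
  data.frame(c1 = m[, 1L], c2 = m[, 2L], c3 = m[, 3L], c4 = m[, 4L],
             first_spacer = m[, 5L], loop_len = m[, 6L])
}

# leftmost-then-longest greedy resolution of overlapping candidate spans
.resolveOverlaps <- function(df) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$c1, -(df$c4 - df$c1)), , drop = FALSE]
  keep <- logical(nrow(df))
  lastEnd <- -1L
  for (i in seq_len(nrow(df))) {
    if (df$c1[i] > lastEnd) {
      keep[i] <- TRUE
      lastEnd <- df$c4[i]
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find GATA-type C4 zinc fingers
#'
#' Scans a protein for all non-overlapping matches of
#' `C-X(f)-C-X(L)-C-X2-C` with `f` in `cfg$first_spacer_range` and `L` in
#' `cfg$loop_range`. Overlapping candidates are resolved leftmost-first,
#' then longest. Matches at exactly the canonical geometry (spacer 2,
#' loop 17) are labelled `gata_canonical`, all others `gata_variant`.
#' Comparison is case-insensitive; `X` never matches `C`.
#'
#' @param protein amino-acid string.
#' @param cfg a [scanConfig()].
#' @return data.frame with columns `kind`, `c1`..`c4` (1-based cysteine
#'   positions), `first_spacer`, `loop_len`, `start`, `end` (closed span
#'   C1..C4).
#' @examples
#' p <- paste0("M", "C", "AA", "C", strrep("A", 17), "C", "AA", "C",
#'             strrep("K", 30))
#' findGataFingers(p)
#' @export
findGataFingers <- function(protein, cfg = scanConfig()) {
  isC <- .chars(protein) == "C"
  df <- .c4Candidates(isC, cfg$first_spacer_range, cfg$loop_range)
  df <- .resolveOverlaps(df)
  df$kind <- ifelse(df$first_spacer == cfg$canonical_spacer &
                      df$loop_len == cfg$canonical_loop,
                    "gata_canonical", "gata_variant")
  df$start <- df$c1
  df$end <- df$c4
  df[, c("kind", "c1", "c2", "c3", "c4", "first_spacer", "loop_len",
         "start", "end")]
}

#' Basic domain following a zinc finger
#'
#' The basic domain is the window of up to 30 residues immediately after
#' the fourth cysteine; it is reported truncated when the protein ends
#' sooner. `basic_fraction` is the K+R fraction over the observed
#' residues.
#'
#' @param protein amino-acid string.
#' @param c4 1-based position of the finger's fourth cysteine.
#' @return list `start`, `end` (closed; `end < start` when the protein
#'   ends at C4), `observed_len`, `basic_fraction`, `truncated`.
#' @export
findBasicDomain <- function(protein, c4) {
  n <- nchar(protein)
  start <- c4 + 1L
  end <- min(n, c4 + 30L)
  obs <- max(0L, end - start + 1L)
  frac <- if (obs > 0L) {
    w <- .chars(substr(protein, start, end))
    mean(w %in% c("K", "R"))
  } else NA_real_
  list(start = start, end = end, observed_len = obs,
       basic_fraction = frac, truncated = obs < 30L)
}

#' Find degenerate upstream C4 fingers
#'
#' Matches of `C-X2-C-X(9..20)-C-X2-C` that (a) do not overlap any GATA
#' finger and (b) lie upstream of a GATA finger with at most
#' `cfg$max_upstream_gap` residues between the candidate's fourth cysteine
#' and the GATA finger's first. Candidates overlapping each other are
#' resolved leftmost-then-longest before the upstream test. Free-standing
#' degenerate motifs with no downstream GATA finger are returned in the
#' `"orphans"` attribute, not the main result.
#'
#' @param protein amino-acid string.
#' @param gataFingers result of [findGataFingers()] on the same protein.
#' @param cfg a [scanConfig()].
#' @return data.frame like [findGataFingers()] with `kind =
#'   "degenerate"`, plus an `upstream_gap` column (residues to the nearest
#'   downstream GATA finger); orphans in `attr(, "orphans")`.
#' @export
findDegenerateFingers <- function(protein, gataFingers,
                                  cfg = scanConfig()) {
  isC <- .chars(protein) == "C"
  df <- .c4Candidates(isC, 2L, cfg$degenerate_loop_range)
  if (nrow(df) && nrow(gataFingers)) {
    clash <- vapply(seq_len(nrow(df)), function(i)
      any(df$c1[i] <= gataFingers$c4 & df$c4[i] >= gataFingers$c1),
      logical(1))
    df <- df[!clash, , drop = FALSE]
  }
  df <- .resolveOverlaps(df)
  df$kind <- rep("degenerate", nrow(df))
  df$start <- df$c1
  df$end <- df$c4
  df$upstream_gap <- rep(NA_integer_, nrow(df))
  ok <- logical(nrow(df))
  if (nrow(df) && nrow(gataFingers)) {
    for (i in seq_len(nrow(df))) {
      gaps <- gataFingers$c1 - df$c4[i] - 1L
      gaps <- gaps[gaps >= 0L]
      if (length(gaps) && min(gaps) <= cfg$max_upstream_gap) {
        ok[i] <- TRUE
        df$upstream_gap[i] <- min(gaps)
      }
    }
  }
  cols <- c("kind", "c1", "c2", "c3", "c4", "first_spacer", "loop_len",
            "start", "end", "upstream_gap")
  res <- df[ok, cols, drop = FALSE]
  rownames(res) <- NULL
  orphans <- df[!ok, cols, drop = FALSE]
  rownames(orphans) <- NULL
  attr(res, "orphans") <- orphans
  res
}

#' Find the diagnostic hexapeptide in a DBD window
#'
#' First match of the `T-X-[LA]-W-R-R` family (TPLWRR, TTLWRR, TSLWRR,
#' TTAWRR, ...) within a window of the protein.
#'
#' @param protein amino-acid string.
#' @param start,end 1-based closed window (typically finger start to end
#'   of basic domain).
#' @param cfg a [scanConfig()].
#' @return `NULL` or list `seq` (the literal matched hexapeptide) and
#'   `offset` (1-based position in the protein).
#' @export
findHexapeptide <- function(protein, start, end, cfg = scanConfig()) {
  window <- toupper(substr(protein, start, end))
  m <- regexpr(cfg$hexapeptide_pattern, window, perl = TRUE)
  if (m == -1L) return(NULL)
  list(seq = substr(window, m, m + attr(m, "match.length") - 1L),
       offset = start + as.integer(m) - 1L)
}

#' Find poly-serine segments
#'
#' Marks every length-`polyS_window` window containing at least
#' `polyS_min_ser` serines and merges overlapping or adjacent qualifying
#' windows into maximal segments.
#'
#' @param protein amino-acid string.
#' @param cfg a [scanConfig()].
#' @return data.frame `start`, `end` (1-based closed), `ser_count`
#'   (serines over the merged span).
#' @examples
#' findPolyS("AAAAASSSSSSAAAAA")  # one segment, residues 2..15
#' @export
findPolyS <- function(protein, cfg = scanConfig()) {
  w <- cfg$polyS_window
  k <- cfg$polyS_min_ser
  ch <- .chars(protein)
  n <- length(ch)
  empty <- .emptyDf(start = "integer", end = "integer",
                    ser_count = "integer")
  if (n < w) return(empty)
  isS <- ch == "S"
  cs <- c(0L, cumsum(isS))
  starts <- which((cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) >= k)
  if (!length(starts)) return(empty)
  # merge windows [s, s+w-1] that overlap or touch
  segs <- list()
  curS <- starts[1L]; curE <- starts[1L] + w - 1L
  for (s in starts[-1L]) {
    if (s <= curE + 1L) curE <- s + w - 1L
    else { segs[[length(segs) + 1L]] <- c(curS, curE); curS <- s; curE <- s + w - 1L }
  }
  segs[[length(segs) + 1L]] <- c(curS, curE)
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1L], end = m[, 2L],
             ser_count = cs[m[, 2L] + 1L] - cs[m[, 1L]])
}

#' Assemble the DBD table of a protein
#'
#' For every GATA finger: attach the basic domain and search the finger
#' span plus basic domain for the diagnostic hexapeptide.
#'
#' @param protein amino-acid string.
#' @param cfg a [scanConfig()].
#' @return data.frame, one row per GATA DBD.
#' @export
buildDbdTable <- function(protein, cfg = scanConfig()) {
  fingers <- findGataFingers(protein, cfg)
  n <- nrow(fingers)
  fingers$basic_start <- integer(n)
  fingers$basic_end <- integer(n)
  fingers$basic_observed <- integer(n)
  fingers$basic_fraction <- numeric(n)
  fingers$basic_truncated <- logical(n)
  fingers$hexapeptide <- rep(NA_character_, n)
  fingers$hexapeptide_offset <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    b <- findBasicDomain(protein, fingers$c4[i])
    fingers$basic_start[i] <- b$start
    fingers$basic_end[i] <- b$end
    fingers$basic_observed[i] <- b$observed_len
    fingers$basic_fraction[i] <- b$basic_fraction
    fingers$basic_truncated[i] <- b$truncated
    hx <- findHexapeptide(protein, fingers$c1[i],
                          max(fingers$c4[i], b$end), cfg)
    if (!is.null(hx)) {
      fingers$hexapeptide[i] <- hx$seq
      fingers$hexapeptide_offset[i] <- hx$offset
    }
  }
  fingers
}
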