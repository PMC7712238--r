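# fixed 55-column layout: C1, spacer x2, C2, loop x17, C3, spacer x2, C4,
# basic x30
.COL_C <- c(1L, 4L, 22L, 25L)

# fit a residue block into `width` columns: shorter blocks are
# center-padded with gaps (extra gap right of center), longer blocks are
# center-trimmed with the removed residues recorded as an insertion
.fitBlock <- function(res, width) {
  L <- length(res)
  if (L == width) return(list(cols = res, insertion = ""))
  if (L < width) {
    left <- ceiling(L / 2)
    cols <- c(res[seq_len(left)], rep("-", width - L),
              if (left < L) res[(left + 1L):L])
    return(list(cols = cols, insertion = ""))
  }
  keepL <- ceiling(width / 2)
  keepR <- width - keepL
  list(cols = c(res[seq_len(keepL)], res[(L - keepR + 1L):L]),
       insertion = .collapse(res[(keepL + 1L):(L - keepR)]))
}

#' Build a landmark-anchored 55-column DBD alignment
#'
#' Places each DBD's residues by landmark rather than by progressive
#' alignment: the four cysteines go to fixed columns (1, 4, 22, 25), the
#' first spacer occupies 2 columns and the loop 17, center-padded with
#' gaps when shorter than canonical and center-trimmed (removed residues
#' recorded per row as an insertion) when longer; the basic domain is
#' left-aligned into 30 columns and gap-padded when truncated.
#'
#' @param dbdTable data.frame with columns `seq_id`, `c1`, `c2`, `c3`,
#'   `c4` (1-based cysteine positions per row).
#' @param proteins named character vector (or `AAStringSet`) supplying
#'   each `seq_id`'s sequence.
#' @return an object of class `"AnchoredAlignment"`: list with `rows`
#'   (named character vector of 55-character strings) and `insertions`
#'   (data.frame `seq_id`, `region`, `seq` for trimmed residues).
#' @export
anchorAlign <- function(dbdTable, proteins) {
  if (!is.character(proteins)) proteins <- as.character(proteins)
  rows <- character(nrow(dbdTable))
  ins <- list()
  for (i in seq_len(nrow(dbdTable))) {
    id <- dbdTable$seq_id[i]
    p <- proteins[[id]]
    c1 <- dbdTable$c1[i]; c2 <- dbdTable$c2[i]
    c3 <- dbdTable$c3[i]; c4 <- dbdTable$c4[i]
    ch <- .chars(p)
    if (any(ch[c(c1, c2, c3, c4)] != "C"))
      stop("landmark positions of ", id, " are not all cysteine")
    sp1 <- .fitBlock(ch[seq2(c1 + 1L, c2 - 1L)], 2L)
    loop <- .fitBlock(ch[seq2(c2 + 1L, c3 - 1L)], 17L)
    sp2 <- ch[seq2(c3 + 1L, c4 - 1L)]
    if (length(sp2) != 2L)
      stop("second spacer of ", id, " is not 2 residues")
    basic <- ch[seq2(c4 + 1L, min(length(ch), c4 + 30L))]
    basic <- c(basic, rep("-", 30L - length(basic)))
    rows[i] <- .collapse(c("C", sp1$cols, "C", loop$cols, "C", sp2, "C",
                           basic))
    for (reg in c("first_spacer", "loop")) {
      insSeq <- if (reg == "first_spacer") sp1$insertion else loop$insertion
      if (nzchar(insSeq))
        ins[[length(ins) + 1L]] <- data.frame(
          seq_id = id, region = reg, seq = insSeq,
          stringsAsFactors = FALSE)
    }
  }
  names(rows) <- dbdTable$seq_id
  structure(list(rows = rows,
                 insertions = if (length(ins)) do.call(rbind, ins)
                 else .emptyDf(seq_id = "character", region = "character",
                               seq = "character")),
            class = "AnchoredAlignment")
}

# seq() that returns integer(0) instead of descending when from > to
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' @export
print.AnchoredAlignment <- function(x, ...) {
  cat(sprintf("AnchoredAlignment: %d row(s) x 55 columns, %d insertion(s)\n",
              length(x$rows), nrow(x$insertions)))
  invisible(x)
}

.alnMatrix <- function(aln) {
  rows <- if (inherits(aln, "AnchoredAlignment")) aln$rows else aln
  stopifnot(all(nchar(rows) == 55L))
  do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
}

#' Consensus string with case-encoded conservation
#'
#' Per column: an uppercase residue when every row carries the same
#' residue with no gaps (absolute conservation); a lowercase residue when
#' one residue holds a strict majority (> 50% of rows); `'.'` otherwise
#' (ties and pluralities included).
#'
#' @param aln an `AnchoredAlignment` or character vector of equal-length
#'   rows.
#' @return a single consensus string.
#' @export
consensusString55 <- function(aln) {
  m <- .alnMatrix(aln)
  n <- nrow(m)
  out <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) == n && length(unique(res)) == 1L)
      return(res[1L])
    if (length(res)) {
      tab <- table(res)
      top <- names(tab)[which.max(tab)]
      if (max(tab) > n / 2) return(tolower(top))
    }
    "."
  }, character(1))
  .collapse(out)
}

#' Count conserved columns
#'
#' @param aln an `AnchoredAlignment` (or row vector).
#' @param mode `"majority"` (column has an absolute or majority-conserved
#'   residue) or `"absolute"` (uppercase only).
#' @return list `k`, `n` (55), `fraction`.
#' @export
conservationCount <- function(aln, mode = c("majority", "absolute")) {
  mode <- match.arg(mode)
  cons <- .chars2(consensusString55(aln))
  k <- switch(mode,
    absolute = sum(cons %in% LETTERS),
    majority = sum(cons != "."))
  list(k = as.integer(k), n = 55L, fraction = k / 55)
}

# case-preserving character split
.chars2 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Variability at DNA-contact positions across class consensi
#'
#' A contact position counts as varied unless every class consensus shows
#' the same absolutely conserved (uppercase) residue at that column.
#'
#' @param consensusByClass named character vector of 55-character
#'   consensus strings (one per class).
#' @param contacts integer vector of contact columns (1-based), e.g.
#'   [contactPositions()].
#' @return list `varied`, `n`, `fraction`.
#' @export
contactVariability <- function(consensusByClass, contacts) {
  stopifnot(length(consensusByClass) >= 2L)
  varied <- vapply(contacts, function(j) {
    ch <- substr(consensusByClass, j, j)
    !(length(unique(ch)) == 1L && ch[1L] %in% LETTERS)
  }, logical(1))
  list(varied = as.integer(sum(varied)), n = length(contacts),
       fraction = sum(varied) / length(contacts))
}

#' Export an anchored alignment as aligned FASTA
#'
#' @param aln an `AnchoredAlignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportAlignment <- function(aln, path) {
  writeFasta(Biostrings::AAStringSet(aln$rows), path, width = 60L)
  invisible(path)
}

#' The default DNA-contact position set
#'
#' Eighteen 1-based columns of the 55-column DBD layout designated as
#' directly contacting DNA bases, shipped as a plain-text fixture. The
#' shipped set is a synthetic stand-in modelled on the distribution of
#' base-contacting residues in the chicken GATA1 solution structure
#' (loop and proximal basic domain); substitute your own via `path`.
#'
#' @param path optional path to a one-column TSV of positions.
#' @return integer vector of column indices.
#' @export
contactPositions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "contact_positions_synthetic.tsv",
                        package = "nemaGATA", mustWork = TRUE)
  as.integer(read.table(path, header = TRUE)$column)
}
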