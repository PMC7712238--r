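#' Read a FASTA file with uniqueness checks
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()]: record ids are the first whitespace
#' token of each header, the remainder is kept as a `description` metadata
#' column. Errors on empty files and duplicate ids (naming the offender).
#'
#' @param path path to a FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] named
#'   by record id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "ACGT"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- switch(type,
    DNA = Biostrings::readDNAStringSet(path),
    AA  = Biostrings::readAAStringSet(path))
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  names(set) <- ids
  S4Vectors::mcols(set)$description <- desc
  set
}

#' Write sequences to FASTA
#'
#' @param set an `XStringSet` (or named character vector).
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(set, path, width = 60L) {
  if (is.character(set)) set <- Biostrings::BStringSet(set)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file via [rtracklayer::import()], groups CDS features by
#' their `Parent` transcript and returns one [GeneModel-class] per
#' transcript, CDS segments sorted ascending. All transcripts of a gene
#' are retained; use [selectTranscripts()] to pick one per gene.
#'
#' Annotated CDS phases, when present, are validated against the phases
#' implied by the segment coordinates; disagreement raises a warning
#' (a model-quality flag, never auto-repaired).
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates, CDS
#'   features carrying `Parent` attributes).
#' @return a named list of `GeneModel` objects (names are transcript ids).
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  parents <- cds$Parent
  if (is.null(parents) || any(lengths(parents) == 0L))
    stop("CDS features without Parent attribute in ", path)
  # map transcript -> gene via mRNA/transcript features when available
  tx <- gr[tolower(as.character(gr$type)) %in%
             c("mrna", "transcript") & !is.na(gr$ID)]
  txGene <- setNames(
    vapply(seq_along(tx), function(i) {
      p <- tx$Parent[[i]]
      if (length(p)) p[[1L]] else tx$ID[[i]]
    }, character(1)),
    tx$ID)
  idx <- rep(seq_along(cds), lengths(parents))
  flat <- data.frame(i = idx, parent = unlist(parents),
                     stringsAsFactors = FALSE)
  byParent <- split(flat$i, flat$parent)
  models <- Map(function(parent, ii) {
    sub <- cds[ii]
    scaf <- unique(as.character(GenomicRanges::seqnames(sub)))
    strd <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(scaf) > 1L)
      stop("CDS segments of ", parent, " span multiple scaffolds")
    if (length(strd) > 1L)
      stop("CDS segments of ", parent, " are on mixed strands")
    o <- order(GenomicRanges::start(sub))
    sub <- sub[o]
    ph <- sub$phase
    if (is.null(ph)) ph <- rep(NA_integer_, length(sub))
    GeneModel(
      geneID = if (parent %in% names(txGene)) txGene[[parent]] else parent,
      txID = parent,
      scaffold = scaf,
      strand = if (strd %in% c("+", "-")) strd else "+",
      cds = IRanges::IRanges(GenomicRanges::start(sub),
                             GenomicRanges::end(sub)),
      phase = as.integer(ph))
  }, names(byParent), byParent)
  for (gm in models) .checkPhases(gm)
  models
}

# compare annotated GFF3 phases to phases implied by coordinates
.checkPhases <- function(gm) {
  ph <- gm@phase
  if (all(is.na(ph))) return(invisible(TRUE))
  w <- IRanges::width(gm@cds)
  ord <- if (gm@strand == "-") rev(seq_along(w)) else seq_along(w)
  prior <- c(0L, cumsum(w[ord]))[seq_along(w)]
  expected <- (3L - prior %% 3L) %% 3L
  annotated <- ph[ord]
  bad <- which(!is.na(annotated) & annotated != expected)
  if (length(bad))
    warning("annotated CDS phase disagrees with coordinates for ",
            gm@txID, " (segment ", paste(bad, collapse = ","),
            "); coordinates win", call. = FALSE)
  invisible(length(bad) == 0L)
}

#' Pick one transcript per gene
#'
#' @param models list of [GeneModel-class] objects.
#' @param policy `"longest"` (largest total CDS, ties broken by smallest
#'   transcript id), `"first-id"` (lexicographically smallest transcript
#'   id) or `"all"`.
#' @return filtered list of `GeneModel` objects.
#' @export
selectTranscripts <- function(models,
                              policy = c("longest", "first-id", "all")) {
  policy <- match.arg(policy)
  if (policy == "all") return(models)
  byGene <- split(models, vapply(models, geneID, character(1)))
  out <- lapply(byGene, function(ms) {
    ids <- vapply(ms, txID, character(1))
    if (policy == "first-id") return(ms[[order(ids)[1L]]])
    lens <- vapply(ms, totalCdsLength, integer(1))
    ms[[order(-lens, ids)[1L]]]
  })
  out <- out[order(names(out))]
  setNames(out, vapply(out, txID, character(1)))
}

#' Assemble the spliced CDS and coding introns of a gene model
#'
#' Concatenates CDS segments in transcription order (reverse-complementing
#' for minus-strand genes) and reports the inter-segment gaps as introns,
#' also in transcription order.
#'
#' @param gm a [GeneModel-class].
#' @param genome a named [Biostrings::DNAStringSet] of scaffolds.
#' @return list with `cds` (character spliced CDS) and `introns`
#'   (data.frame `scaffold`, `start`, `end`, 1-based closed genomic intron
#'   spans in transcription order).
#' @export
splicedCds <- function(gm, genome) {
  scaf <- scaffoldName(gm)
  if (!scaf %in% names(genome)) stop("scaffold not in genome: ", scaf)
  seq <- genome[[scaf]]
  cds <- cdsRanges(gm)
  if (min(IRanges::start(cds)) < 1L || max(IRanges::end(cds)) > length(seq))
    stop("CDS segment out of scaffold bounds for ", txID(gm))
  pieces <- as.character(Biostrings::extractAt(seq, cds))
  cat_fwd <- paste(pieces, collapse = "")
  k <- length(cds)
  introns <- if (k > 1L) {
    data.frame(scaffold = scaf,
               start = IRanges::end(cds)[-k] + 1L,
               end = IRanges::start(cds)[-1L] - 1L,
               stringsAsFactors = FALSE)
  } else .emptyDf(scaffold = "character", start = "integer", end = "integer")
  if (geneStrand(gm) == "-") {
    cat_fwd <- .revcompChr(cat_fwd)
    if (nrow(introns)) introns <- introns[rev(seq_len(nrow(introns))), ,
                                          drop = FALSE]
    rownames(introns) <- NULL
  }
  list(cds = cat_fwd, introns = introns)
}

#' Translate a coding sequence
#'
#' Standard genetic code via [Biostrings::translate()]. A trailing
#' incomplete codon is dropped with a warning; a terminal stop is removed;
#' codons containing ambiguity codes translate to `X`.
#'
#' @param cds nucleotide string, length >= 3.
#' @param on_internal_stop `"error"` (default; names the offending codon,
#'   1-based) or `"truncate"` (keep the sequence up to the stop, with a
#'   warning) for gene models whose predicted splicing is suspect.
#' @return amino-acid string.
#' @examples
#' translateCds("ATGGCCTAA")
#' @export
translateCds <- function(cds, on_internal_stop = c("error", "truncate")) {
  on_internal_stop <- match.arg(on_internal_stop)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  rem <- n %% 3L
  if (rem) {
    warning("dropping trailing incomplete codon (", rem, " nt)",
            call. = FALSE)
    cds <- substr(cds, 1L, n - rem)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "solve",
                                           no.init.codon = TRUE))
  stars <- which(.chars(aa) == "*")
  if (length(stars)) {
    last <- nchar(aa)
    internal <- stars[stars < last]
    if (length(internal)) {
      if (on_internal_stop == "error")
        stop("internal stop codon at codon ", internal[1L])
      warning("internal stop codon at codon ", internal[1L],
              "; truncating", call. = FALSE)
      return(substr(aa, 1L, internal[1L] - 1L))
    }
    aa <- substr(aa, 1L, last - 1L)
  }
  aa
}

#' Extract 5' and 3' flanking sequence in gene orientation
#'
#' The 5' flank is up to `n` bp immediately upstream of the first CDS base
#' in transcription orientation, the 3' flank up to `n` bp downstream of
#' the last; both are reverse-complemented for minus-strand genes so that
#' they read in gene orientation. Truncation at scaffold ends sets a flag
#' and is not an error.
#'
#' @param gm a [GeneModel-class].
#' @param genome named [Biostrings::DNAStringSet].
#' @param n requested flank length (default 1000).
#' @return list `gene_id`, `five_prime`, `three_prime`,
#'   `five_prime_truncated`, `three_prime_truncated`.
#' @export
extractFlanks <- function(gm, genome, n = 1000L) {
  stopifnot(n >= 1L)
  seq <- genome[[scaffoldName(gm)]]
  L <- length(seq)
  s <- min(IRanges::start(cdsRanges(gm)))
  e <- max(IRanges::end(cdsRanges(gm)))
  left <- if (s > 1L)
    as.character(Biostrings::subseq(seq, max(1L, s - n), s - 1L)) else ""
  right <- if (e < L)
    as.character(Biostrings::subseq(seq, e + 1L, min(L, e + n))) else ""
  if (geneStrand(gm) == "+") {
    five <- left; three <- right
  } else {
    five <- .revcompChr(right); three <- .revcompChr(left)
  }
  list(gene_id = geneID(gm),
       five_prime = five, three_prime = three,
       five_prime_truncated = nchar(five) < n,
       three_prime_truncated = nchar(three) < n)
}
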