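#' GeneModel: a transcript's CDS footprint on a scaffold
#'
#' A `GeneModel` holds the CDS segments of one transcript on one scaffold,
#' stored 1-based closed as an [IRanges::IRanges] in ascending scaffold
#' order. The spliced CDS, protein, coding introns and flanking regions all
#' derive from it.
#'
#' @slot geneID character(1), gene identifier.
#' @slot txID character(1), transcript identifier (may equal `geneID`).
#' @slot scaffold character(1), scaffold/sequence name.
#' @slot strand character(1), `"+"` or `"-"`.
#' @slot cds [IRanges::IRanges] of CDS segments, ascending, non-overlapping.
#' @slot phase integer vector of annotated GFF3 phases per segment
#'   (`NA` when not annotated); validated, never used for splicing.
#'
#' @examples
#' gm <- GeneModel("g1", "g1.t1", "scf1", "+",
#'                 IRanges::IRanges(start = c(101, 201), end = c(130, 260)))
#' totalCdsLength(gm)
#' @export
setClass("GeneModel",
  representation(geneID = "character", txID = "character",
                 scaffold = "character", strand = "character",
                 cds = "IRanges", phase = "integer"))

setValidity("GeneModel", function(object) {
  msgs <- character(0)
  if (length(object@geneID) != 1L || !nzchar(object@geneID))
    msgs <- c(msgs, "geneID must be a single non-empty string")
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  cds <- object@cds
  if (length(cds) < 1L)
    msgs <- c(msgs, "at least one CDS segment required")
  else {
    if (any(IRanges::width(cds) < 1L))
      msgs <- c(msgs, "CDS segments must have positive width")
    if (is.unsorted(IRanges::start(cds)))
      msgs <- c(msgs, "CDS segments must be sorted ascending")
    if (length(cds) > 1L &&
        any(IRanges::start(cds)[-1L] <= IRanges::end(cds)[-length(cds)]))
      msgs <- c(msgs, "CDS segments must not overlap")
    if (sum(IRanges::width(cds)) < 3L)
      msgs <- c(msgs, "total CDS length must be >= 3")
  }
  if (length(object@phase) != length(cds))
    msgs <- c(msgs, "phase must have one entry per CDS segment")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneModel
#'
#' @param geneID,txID,scaffold,strand,cds,phase see slots of
#'   [GeneModel-class].
#' @return a `GeneModel`.
#' @export
GeneModel <- function(geneID, txID = geneID, scaffold, strand, cds,
                      phase = rep(NA_integer_, length(cds))) {
  cds <- cds[order(IRanges::start(cds))]
  new("GeneModel", geneID = geneID, txID = txID, scaffold = scaffold,
      strand = strand, cds = cds, phase = as.integer(phase))
}

#' @describeIn GeneModel-class gene identifier
#' @param object,x a `GeneModel`
#' @export
setGeneric("geneID", function(object) standardGeneric("geneID"))
#' @rdname GeneModel-class
#' @export
setMethod("geneID", "GeneModel", function(object) object@geneID)

#' @describeIn GeneModel-class transcript identifier
#' @export
setGeneric("txID", function(object) standardGeneric("txID"))
#' @rdname GeneModel-class
#' @export
setMethod("txID", "GeneModel", function(object) object@txID)

#' @describeIn GeneModel-class scaffold name
#' @export
setGeneric("scaffoldName", function(object) standardGeneric("scaffoldName"))
#' @rdname GeneModel-class
#' @export
setMethod("scaffoldName", "GeneModel", function(object) object@scaffold)

#' @describeIn GeneModel-class CDS segments as an IRanges
#' @export
setGeneric("cdsRanges", function(object) standardGeneric("cdsRanges"))
#' @rdname GeneModel-class
#' @export
setMethod("cdsRanges", "GeneModel", function(object) object@cds)

#' @describeIn GeneModel-class transcription strand
#' @export
setGeneric("geneStrand", function(object) standardGeneric("geneStrand"))
#' @rdname GeneModel-class
#' @export
setMethod("geneStrand", "GeneModel", function(object) object@strand)

#' @describeIn GeneModel-class summed CDS segment length in nucleotides
#' @export
setGeneric("totalCdsLength", function(object) standardGeneric("totalCdsLength"))
#' @rdname GeneModel-class
#' @export
setMethod("totalCdsLength", "GeneModel",
          function(object) sum(IRanges::width(object@cds)))

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (tx %s) on %s(%s): %d CDS segment(s), %d nt\n",
              object@geneID, object@txID, object@scaffold, object@strand,
              length(object@cds), totalCdsLength(object)))
})

#' GataFactor: an annotated GATA transcription factor
#'
#' Bundles one protein with every structural feature the scanners detect:
#' GATA-type DNA-binding domains (zinc finger + basic domain +
#' hexapeptide), upstream degenerate C4 fingers, poly-serine segments,
#' coding introns with landmark descriptors, and the intron signature used
#' by classification.
#'
#' @slot proteinID,geneID character identifiers.
#' @slot protein character(1), the amino-acid sequence.
#' @slot dbds data.frame of GATA DBDs (one row per finger): `kind`,
#'   `c1..c4`, `first_spacer`, `loop_len`, `start`, `end`, `basic_start`,
#'   `basic_end`, `basic_observed`, `basic_fraction`, `basic_truncated`,
#'   `hexapeptide`, `hexapeptide_offset`.
#' @slot degenerate data.frame of upstream degenerate fingers.
#' @slot polyS data.frame of poly-serine segments.
#' @slot introns data.frame of coding introns in protein coordinates.
#' @slot descriptors data.frame of cysteine-landmark descriptors.
#' @slot signature list of intron-signature flags (see [intronSignature()]).
#' @export
setClass("GataFactor",
  representation(proteinID = "character", geneID = "character",
                 protein = "character", dbds = "data.frame",
                 degenerate = "data.frame", polyS = "data.frame",
                 introns = "data.frame", descriptors = "data.frame",
                 signature = "list"))

setValidity("GataFactor", function(object) {
  if (nrow(object@dbds) < 1L)
    return("a GataFactor must carry at least one GATA DBD")
  if (is.unsorted(object@dbds$c1))
    return("DBDs must be ordered by position")
  TRUE
})

#' @describeIn GataFactor-class number of GATA DBDs
#' @param object a `GataFactor`
#' @export
setGeneric("nDbds", function(object) standardGeneric("nDbds"))
#' @rdname GataFactor-class
#' @export
setMethod("nDbds", "GataFactor", function(object) nrow(object@dbds))

#' @describeIn GataFactor-class the DBD table
#' @export
setGeneric("dbds", function(object) standardGeneric("dbds"))
#' @rdname GataFactor-class
#' @export
setMethod("dbds", "GataFactor", function(object) object@dbds)

#' @describeIn GataFactor-class protein sequence
#' @export
setGeneric("proteinSeq", function(object) standardGeneric("proteinSeq"))
#' @rdname GataFactor-class
#' @export
setMethod("proteinSeq", "GataFactor", function(object) object@protein)

#' @describeIn GataFactor-class intron signature flags
#' @export
setGeneric("signatureFlags", function(object) standardGeneric("signatureFlags"))
#' @rdname GataFactor-class
#' @export
setMethod("signatureFlags", "GataFactor", function(object) object@signature)

setMethod("show", "GataFactor", function(object) {
  sig <- object@signature
  flags <- names(sig)[vapply(sig, isTRUE, logical(1))]
  cat(sprintf(paste0("GataFactor %s (%d aa): %d DBD(s), %d degenerate",
                     " finger(s), %d poly-S segment(s), %d intron(s)\n"),
              object@proteinID, nchar(object@protein), nrow(object@dbds),
              nrow(object@degenerate), nrow(object@polyS),
              nrow(object@introns)))
  if (length(flags))
    cat("  signature:", paste(flags, collapse = ", "), "\n")
})
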