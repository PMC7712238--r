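#' Map coding introns into protein codon coordinates
#'
#' Each gap between consecutive CDS segments (in transcription order)
#' becomes one intron with `cds_offset` = number of spliced-CDS
#' nucleotides 5' of it, `codon_index` = complete codons 5' of it
#' (`cds_offset %/% 3`), and `phase` = nucleotides of the interrupted
#' codon lying 5' (`cds_offset %% 3`; 0 means the intron falls between
#' codons).
#'
#' @param gm a [GeneModel-class].
#' @return data.frame `intron`, `scaffold`, `start`, `end` (genomic,
#'   1-based closed), `cds_offset`, `codon_index`, `phase`, in
#'   transcription order.
#' @export
mapIntronsToProtein <- function(gm) {
  cds <- cdsRanges(gm)
  k <- length(cds)
  empty <- .emptyDf(intron = "integer", scaffold = "character",
                    start = "integer", end = "integer",
                    cds_offset = "integer", codon_index = "integer",
                    phase = "integer")
  if (k < 2L) return(empty)
  w <- IRanges::width(cds)
  gapStart <- IRanges::end(cds)[-k] + 1L
  gapEnd <- IRanges::start(cds)[-1L] - 1L
  if (geneStrand(gm) == "+") {
    off <- cumsum(w)[-k]
    ord <- seq_len(k - 1L)
  } else {
    off <- cumsum(rev(w))[-k]
    ord <- rev(seq_len(k - 1L))
  }
  data.frame(intron = seq_len(k - 1L),
             scaffold = scaffoldName(gm),
             start = gapStart[ord], end = gapEnd[ord],
             cds_offset = as.integer(off),
             codon_index = as.integer(off %/% 3L),
             phase = as.integer(off %% 3L),
             stringsAsFactors = FALSE)
}

#' Express an intron relative to a cysteine landmark
#'
#' Converts an intron at (`codon_index`, `phase`) into a descriptor
#' relative to a landmark cysteine at 1-based protein position
#' `landmark_pos`: with `nt_after` = nucleotides between the end of the
#' landmark's codon and the intron, `codon_offset = ceiling(nt_after/3)`
#' and the phase is unchanged. Thus an intron exactly between the Nth and
#' (N+1)th codons after the landmark yields (N, phase 0), and one 1 bp
#' into the codon following the landmark's yields (1, phase 1) — the two
#' conventions used for the conserved basic-domain and zinc-finger
#' introns. Introns 5' of the landmark get a negative offset and are
#' flagged non-canonical rather than discarded.
#'
#' @param codon_index,phase intron position (see
#'   [mapIntronsToProtein()]).
#' @param landmark_pos 1-based protein position of the landmark cysteine.
#' @param landmark `"C3"` or `"C4"`.
#' @return list `landmark`, `codon_offset`, `phase`, `non_canonical`.
#' @export
landmarkOffset <- function(codon_index, phase, landmark_pos,
                           landmark = c("C4", "C3")) {
  landmark <- match.arg(landmark)
  nt_after <- 3L * codon_index + phase - 3L * landmark_pos
  list(landmark = landmark,
       codon_offset = as.integer(ceiling(nt_after / 3)),
       phase = as.integer(phase),
       non_canonical = nt_after < 0L)
}

#' Landmark descriptors of every intron against every finger
#'
#' @param introns data.frame from [mapIntronsToProtein()].
#' @param fingers data.frame of fingers (needs `c3`, `c4`, optionally
#'   `kind`); descriptors are computed against each finger's C3 and C4.
#' @return data.frame `intron`, `finger`, `finger_kind`, `landmark`,
#'   `codon_offset`, `phase`, `non_canonical`.
#' @export
landmarkDescriptors <- function(introns, fingers) {
  empty <- .emptyDf(intron = "integer", finger = "integer",
                    finger_kind = "character", landmark = "character",
                    codon_offset = "integer", phase = "integer",
                    non_canonical = "logical")
  if (!nrow(introns) || !nrow(fingers)) return(empty)
  rows <- list()
  for (i in seq_len(nrow(introns))) {
    for (j in seq_len(nrow(fingers))) {
      for (lm in c("C3", "C4")) {
        pos <- if (lm == "C3") fingers$c3[j] else fingers$c4[j]
        d <- landmarkOffset(introns$codon_index[i], introns$phase[i],
                            pos, lm)
        rows[[length(rows) + 1L]] <- data.frame(
          intron = introns$intron[i], finger = j,
          finger_kind = if ("kind" %in% names(fingers))
            fingers$kind[j] else NA_character_,
          landmark = lm, codon_offset = d$codon_offset,
          phase = d$phase, non_canonical = d$non_canonical,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# the three conserved intron positions, as (landmark, offset, phase)
.SIGNATURE_FLAGS <- list(
  has_N_basic_intron = c("C4", 20L, 0L),
  has_C_basic_intron = c("C4", 8L, 0L),
  has_zf_intron      = c("C3", 1L, 1L))

#' Intron signature of a factor
#'
#' Sets the three conserved-intron flags by exact (landmark,
#' codon_offset, phase) match among the descriptors computed against
#' GATA-kind fingers: the amino basic-domain intron (C4 + 20 codons,
#' phase 0), the carboxyl basic-domain intron (C4 + 8, phase 0) and the
#' zinc-finger intron (C3 + 1 codon, phase 1). `intronless` is true when
#' the gene has no coding introns; `extra_introns` counts introns not
#' matched by any flag.
#'
#' @param descriptors data.frame from [landmarkDescriptors()].
#' @param n_introns total number of coding introns.
#' @return list of flags `has_N_basic_intron`, `has_C_basic_intron`,
#'   `has_zf_intron`, `intronless`, `extra_introns`.
#' @export
intronSignature <- function(descriptors, n_introns) {
  d <- descriptors
  if (nrow(d) && "finger_kind" %in% names(d) &&
      !all(is.na(d$finger_kind)))
    d <- d[is.na(d$finger_kind) | grepl("^gata", d$finger_kind), ,
           drop = FALSE]
  matched <- integer(0)
  flags <- lapply(.SIGNATURE_FLAGS, function(spec) {
    hit <- nrow(d) > 0 & d$landmark == spec[[1L]] &
      d$codon_offset == as.integer(spec[[2L]]) &
      d$phase == as.integer(spec[[3L]])
    if (any(hit)) matched <<- c(matched, d$intron[hit])
    any(hit)
  })
  c(flags,
    list(intronless = n_introns == 0L,
         extra_introns = as.integer(n_introns -
                                      length(unique(matched)))))
}
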