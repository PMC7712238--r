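#' Synthetic corpus configuration
#'
#' Defines the study conditions the generator emulates: multi-scaffold
#' genomes carrying planted GATA genes of each structural class with
#' class-typical finger architecture, conserved introns at
#' cysteine-relative landmarks, poly-serine segments, linked paralog
#' pairs, and flanks with planted HGATAR / double-GATA / polypyrimidine
#' motifs. Defaults follow the observed corpus structure: ELT1 carries
#' two tandem DBDs 29 residues apart with basic-domain introns at C4+20
#' and C4+8 (phase 0); ELT2 carries one DBD, a degenerate upstream C4
#' finger 34-152 residues away, and the zinc-finger intron at C3+1
#' (phase 1); ELT3 is short-tailed with the zinc-finger intron; ELT5 has
#' a 38-126 residue tail and the C4+8 basic-domain intron; ELTX is a
#' diverged intronless single-DBD factor. Poly-serine frequencies per
#' class follow the reported 26/32, 11/30, 2/22, 3/26 proportions (ELTX
#' set to 1/3).
#'
#' @param seed integer seed; identical seed + config give byte-identical
#'   corpora.
#' @param genes_per_class named integer vector over
#'   ELT1/ELT2/ELT3/ELT5/ELTX.
#' @param mutation_rate per-residue substitution probability applied to
#'   each template protein.
#' @param protect_landmarks protect cysteines and diagnostic
#'   hexapeptides from mutation.
#' @param polyS_prob named per-class probability of planting a
#'   poly-serine run.
#' @param degenerate_gap_range residues between the degenerate finger's
#'   C4 and the DBD's C1 (sampled uniformly).
#' @param degenerate_loop_choices loop lengths sampled for the
#'   degenerate finger. Lengths 16-19 are excluded by default: they are
#'   structurally identical to the canonical GATA finger and undecidable
#'   without cross-species conservation; the extremes 9 and 20 are kept.
#' @param elt5_tail_range residues after the ELT5 basic domain.
#' @param paralog_plan data.frame `class`, `separation`, `orientation`
#'   of linked pairs to plant (consumes the first two genes of the
#'   class; separations must exceed twice the flank length plus 100).
#' @param flank_len flank length generated and motif-cleaned per gene.
#' @param gc_background GC fraction of intergenic background.
#' @param pad plain background padding at scaffold/unit edges.
#' @return list with class `"SynthConfig"`.
#' @export
synthConfig <- function(seed = 1L,
                        genes_per_class = c(ELT1 = 10L, ELT2 = 10L,
                                            ELT3 = 10L, ELT5 = 10L,
                                            ELTX = 10L),
                        mutation_rate = 0,
                        protect_landmarks = TRUE,
                        polyS_prob = c(ELT1 = 26 / 32, ELT2 = 11 / 30,
                                       ELT3 = 2 / 22, ELT5 = 3 / 26,
                                       ELTX = 1 / 3),
                        degenerate_gap_range = c(34L, 152L),
                        degenerate_loop_choices = c(9:15, 20L),
                        elt5_tail_range = c(38L, 126L),
                        paralog_plan = data.frame(
                          class = c("ELT1", "ELT2", "ELT3", "ELT5"),
                          separation = c(2600L, 6000L, 12000L, 26000L),
                          orientation = c("same_direction",
                                          "same_direction", "convergent",
                                          "same_direction"),
                          stringsAsFactors = FALSE),
                        flank_len = 1000L,
                        gc_background = 0.42,
                        pad = 500L) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            all(genes_per_class >= 0L),
            all(polyS_prob >= 0), all(polyS_prob <= 1))
  structure(list(seed = as.integer(seed),
                 genes_per_class = genes_per_class,
                 mutation_rate = mutation_rate,
                 protect_landmarks = protect_landmarks,
                 polyS_prob = polyS_prob,
                 degenerate_gap_range = degenerate_gap_range,
                 degenerate_loop_choices = degenerate_loop_choices,
                 elt5_tail_range = elt5_tail_range,
                 paralog_plan = paralog_plan,
                 flank_len = as.integer(flank_len),
                 gc_background = gc_background,
                 pad = as.integer(pad)),
            class = "SynthConfig")
}

#' Mutate a protein at a per-residue rate
#'
#' Each unprotected position is independently substituted, with
#' probability `rate`, by a uniformly chosen different residue from the
#' 20-letter alphabet.
#'
#' @param seq amino-acid string.
#' @param rate substitution probability in \[0, 1\].
#' @param protected integer vector of 1-based immune positions.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return mutated string.
#' @export
mutateProtein <- function(seq, rate, protected = integer(0),
                          seed = NULL) {
  run <- function() {
    ch <- .chars(seq)
    n <- length(ch)
    hit <- runif(n) < rate
    if (length(protected)) hit[protected] <- FALSE
    for (i in which(hit))
      ch[i] <- sample(setdiff(.AA, ch[i]), 1L)
    .collapse(ch)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

.randAa <- function(n, alphabet = .AA_NEUTRAL) {
  .collapse(sample(alphabet, n, replace = TRUE))
}

.randDna <- function(n, gc = 0.42) {
  .collapse(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
}

# inverse genetic code for uniform synonymous reverse translation
.REV_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.reverseTranslate <- function(protein) {
  ch <- .chars(protein)
  codons <- vapply(ch, function(a) {
    opts <- .REV_CODON[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  .collapse(codons)
}

# ---- per-class protein construction ---------------------------------------

# positions of the four cysteines within a 55-residue template
.TPL_C <- c(1L, 4L, 22L, 25L)

# build the rate-0 protein and truth features of one gene
.buildClassProtein <- function(class, lib, cfg) {
  plantPolyS <- runif(1) < cfg$polyS_prob[[class]]
  ntermLen <- switch(class, ELT1 = 40L, ELT2 = 30L, 26L)
  nterm <- .chars(.randAa(ntermLen))
  polyS <- NULL
  if (plantPolyS) {
    r <- 11L
    nterm[r:(r + 9L)] <- "S"
    polyS <- data.frame(start = r - 4L, end = r + 13L, ser_count = 10L,
                        stringsAsFactors = FALSE)
  }
  deg <- NULL
  fingerStarts <- integer(0)
  if (class == "ELT1") {
    fingerN <- .chars(substr(lib[["ELT1_N"]], 1L, 25L))
    inter <- .chars(.randAa(29L))
    body <- c(fingerN, inter, .chars(lib[["ELT1_C"]]))
    tail <- .chars(.randAa(20L))
    fingerStarts <- c(ntermLen + 1L, ntermLen + 25L + 29L + 1L)
  } else if (class == "ELT2") {
    degLoop <- sample(cfg$degenerate_loop_choices, 1L)
    degSeq <- c("C", "L", "E", "C", .chars(.randAa(degLoop)),
                "C", "G", "A", "C")
    gap <- sample(seq(cfg$degenerate_gap_range[1L],
                      cfg$degenerate_gap_range[2L]), 1L)
    body <- c(degSeq, .chars(.randAa(gap)), .chars(lib[["ELT2"]]))
    tail <- .chars(.randAa(40L))
    degC1 <- ntermLen + 1L
    deg <- data.frame(c1 = degC1, c2 = degC1 + 3L,
                      c3 = degC1 + 3L + degLoop + 1L,
                      c4 = degC1 + 3L + degLoop + 4L,
                      loop_len = degLoop, stringsAsFactors = FALSE)
    fingerStarts <- ntermLen + length(degSeq) + gap + 1L
  } else {
    tmpl <- switch(class, ELT3 = "ELT3", ELT5 = "ELT5", ELTX = "ELTX")
    tailLen <- switch(class,
      ELT3 = 8L,
      ELT5 = sample(seq(cfg$elt5_tail_range[1L],
                        cfg$elt5_tail_range[2L]), 1L),
      ELTX = 25L)
    body <- .chars(lib[[tmpl]])
    tail <- .chars(.randAa(tailLen))
    fingerStarts <- ntermLen + 1L
  }
  protein <- .collapse(c(nterm, body, tail))
  fingers <- data.frame(
    kind = "gata_canonical",
    c1 = fingerStarts + .TPL_C[1L] - 1L,
    c2 = fingerStarts + .TPL_C[2L] - 1L,
    c3 = fingerStarts + .TPL_C[3L] - 1L,
    c4 = fingerStarts + .TPL_C[4L] - 1L,
    stringsAsFactors = FALSE)
  fingers$start <- fingers$c1
  fingers$end <- fingers$c4
  # intron plan: conserved landmark introns plus one plain intron in the
  # N-terminal region for the intron-bearing classes
  introns <- list()
  addIntron <- function(cds_offset, landmark, offset, phase) {
    introns[[length(introns) + 1L]] <<- data.frame(
      cds_offset = as.integer(cds_offset), landmark = landmark,
      codon_offset = as.integer(offset), phase = as.integer(phase),
      stringsAsFactors = FALSE)
  }
  if (class == "ELT1") {
    addIntron(3L * (fingers$c4[1L] + 20L), "C4", 20L, 0L)
    addIntron(3L * (fingers$c4[2L] + 8L), "C4", 8L, 0L)
  } else if (class %in% c("ELT2", "ELT3")) {
    addIntron(3L * fingers$c3[1L] + 1L, "C3", 1L, 1L)
  } else if (class == "ELT5") {
    addIntron(3L * (fingers$c4[1L] + 8L), "C4", 8L, 0L)
  }
  if (class != "ELTX") {
    ci <- sample(3:(ntermLen - 5L), 1L)
    ph <- sample(0:2, 1L)
    addIntron(3L * ci + ph, NA_character_, NA_integer_, ph)
  }
  introns <- if (length(introns)) do.call(rbind, introns)
  else .emptyDf(cds_offset = "integer", landmark = "character",
                codon_offset = "integer", phase = "integer")
  introns <- introns[order(introns$cds_offset), , drop = FALSE]
  list(protein = protein, fingers = fingers, degenerate = deg,
       polyS = polyS, introns = introns)
}

# protected positions: every planted cysteine + diagnostic hexapeptides
.protectedPositions <- function(protein, fingers, deg) {
  pos <- c(fingers$c1, fingers$c2, fingers$c3, fingers$c4)
  if (!is.null(deg)) pos <- c(pos, deg$c1, deg$c2, deg$c3, deg$c4)
  m <- gregexpr("T[A-Z][LA]WRR", protein, perl = TRUE)[[1L]]
  if (m[1L] != -1L)
    pos <- c(pos, unlist(lapply(as.integer(m), function(s) s:(s + 5L))))
  sort(unique(pos))
}

# ---- flank construction ---------------------------------------------------

# plant motifs into a background flank, then scrub chance motifs so that
# recovery scoring is unambiguous: planted features are the only hits
.makeFlank <- function(len, plan, gc) {
  ch <- .chars(.randDna(len, gc))
  protected <- logical(len)
  expected <- list()  # closed spans inside which hits are intended
  truth <- list()
  plant <- function(s, txt) {
    stopifnot(s >= 1L, s + nchar(txt) - 1L <= len)
    ch[s:(s + nchar(txt) - 1L)] <<- .chars(txt)
    protected[s:(s + nchar(txt) - 1L)] <<- TRUE
  }
  for (p in plan) {
    if (p$kind == "hgatar") {
      plant(p$at, "AGATAA")
      expected[[length(expected) + 1L]] <- c(p$at, p$at + 5L)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "hgatar", start = p$at, end = p$at + 5L, strand = "+",
        detail = NA_real_, stringsAsFactors = FALSE)
    } else if (p$kind == "double_gata") {
      mStart <- p$at + 6L + p$spacer
      plant(p$at, "AGATAA")
      plant(mStart, "TTATCA")
      expected[[length(expected) + 1L]] <- c(p$at, mStart + 5L)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = c("hgatar", "hgatar", "double_gata"),
        start = c(p$at, mStart, p$at),
        end = c(p$at + 5L, mStart + 5L, mStart + 5L),
        strand = c("+", "-", "both"),
        detail = c(NA_real_, NA_real_, p$spacer),
        stringsAsFactors = FALSE)
    } else if (p$kind == "polypyrimidine") {
      tract <- "TCTCTTTCCTCTTC"  # 14 pyrimidines
      plant(p$at - 1L, "A")      # purine guards delimit the segment
      plant(p$at, tract)
      plant(p$at + 14L, "A")
      expected[[length(expected) + 1L]] <- c(p$at - 1L, p$at + 14L)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "polypyrimidine", start = p$at - 1L, end = p$at + 14L,
        strand = "+", detail = 14 / 16, stringsAsFactors = FALSE)
    }
  }
  inExpected <- function(s, e) {
    for (sp in expected) if (s >= sp[1L] && e <= sp[2L]) return(TRUE)
    FALSE
  }
  for (iter in 1:100) {
    seq <- .collapse(ch)
    h <- scanHgatar(seq)
    spans <- Map(c, h$start, h$end)
    pyStarts <- .pyWindows(ch)
    spans <- c(spans, lapply(pyStarts, function(s) c(s, s + 11L)))
    bad <- Filter(function(sp) !inExpected(sp[1L], sp[2L]), spans)
    if (!length(bad)) break
    for (sp in bad) {
      fix <- setdiff(sp[1L]:sp[2L], which(protected))
      ch[fix] <- sample(c("A", "G"), length(fix), replace = TRUE)
    }
  }
  truthDf <- if (length(truth)) do.call(rbind, truth)
  else .emptyDf(kind = "character", start = "integer", end = "integer",
                strand = "character", detail = "numeric")
  list(seq = .collapse(ch), truth = truthDf)
}

# starts of length-12 windows with >= 11 pyrimidines
.pyWindows <- function(ch) {
  n <- length(ch)
  if (n < 12L) return(integer(0))
  cs <- c(0L, cumsum(ch %in% c("C", "T")))
  which((cs[13L:(n + 1L)] - cs[1L:(n - 11L)]) >= 11L)
}

.flankPlan5 <- function(class) {
  plan <- list(list(kind = "hgatar", at = 150L))
  if (class == "ELT2")
    plan[[length(plan) + 1L]] <- list(kind = "double_gata", at = 400L,
                                      spacer = 5L)
  if (class %in% c("ELT1", "ELT5"))
    plan[[length(plan) + 1L]] <- list(kind = "polypyrimidine", at = 600L)
  plan
}

.flankPlan3 <- function(class) {
  if (class %in% c("ELT1", "ELT5"))
    list(list(kind = "polypyrimidine", at = 300L))
  else list()
}

# ---- gene -> nucleotide layout --------------------------------------------

# returns gene sequence (coding orientation) and local exon ranges
.layoutGene <- function(protein, intronOffsets) {
  cds <- paste0(.reverseTranslate(protein),
                c("TAA", "TAG", "TGA")[sample.int(3L, 1L)])
  offs <- sort(intronOffsets)
  stopifnot(all(offs > 0L), all(offs < nchar(cds)))
  bounds <- c(0L, offs, nchar(cds))
  pieces <- character(0)
  exonLocal <- matrix(0L, nrow = length(bounds) - 1L, ncol = 2L)
  at <- 0L
  for (i in seq_len(length(bounds) - 1L)) {
    ex <- substr(cds, bounds[i] + 1L, bounds[i + 1L])
    exonLocal[i, ] <- c(at + 1L, at + nchar(ex))
    at <- at + nchar(ex)
    pieces <- c(pieces, ex)
    if (i < length(bounds) - 1L) {
      ilen <- sample(40:60, 1L)
      intron <- paste0("GT", .randDna(ilen - 4L), "AG")
      pieces <- c(pieces, intron)
      at <- at + ilen
    }
  }
  list(seq = .collapse(pieces), exons = exonLocal, cdsLen = nchar(cds))
}

# ---- corpus assembly ------------------------------------------------------

#' Generate a synthetic genome corpus with truth manifest
#'
#' Builds proteins from the class consensus templates, mutates them at
#' `mutation_rate` (landmarks optionally protected), reverse-translates
#' with uniform synonymous codons, inserts introns at the planned
#' landmark descriptors, embeds the genes on scaffolds at the planned
#' paralog separations and orientations, plants flank motifs, and
#' records everything in a truth manifest. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [synthConfig()].
#' @return list `genome` ([Biostrings::DNAStringSet]), `models` (list of
#'   [GeneModel-class]), `gff` ([GenomicRanges::GRanges] ready for GFF3
#'   export) and `truth` (list of data.frames: `genes`, `fingers`,
#'   `polyS`, `introns`, `pairs`, `motifs`).
#' @export
generateCorpus <- function(cfg = synthConfig()) {
  withSeed(cfg$seed, .generateCorpusImpl(cfg))
}

.generateCorpusImpl <- function(cfg) {
  lib <- consensusLibrary()
  classes <- names(cfg$genes_per_class)
  genesT <- list(); fingersT <- list(); polysT <- list()
  intronsT <- list(); motifsT <- list(); pairsT <- list()
  units <- list()   # each: list of gene entries to place together
  for (class in classes) {
    nGenes <- cfg$genes_per_class[[class]]
    if (nGenes == 0L) next
    plan <- cfg$paralog_plan
    pair <- plan[plan$class == class, , drop = FALSE]
    entries <- lapply(seq_len(nGenes), function(i) {
      gid <- sprintf("%s_g%02d", tolower(class), i)
      built <- .buildClassProtein(class, lib, cfg)
      prot <- built$protein
      if (cfg$mutation_rate > 0) {
        protected <- if (cfg$protect_landmarks)
          .protectedPositions(prot, built$fingers, built$degenerate)
        else integer(0)
        prot <- mutateProtein(prot, cfg$mutation_rate, protected)
      }
      lay <- .layoutGene(prot, built$introns$cds_offset)
      f5 <- .makeFlank(cfg$flank_len, .flankPlan5(class),
                       cfg$gc_background)
      f3 <- .makeFlank(cfg$flank_len, .flankPlan3(class),
                       cfg$gc_background)
      list(gid = gid, class = class, protein = prot, built = built,
           layout = lay, flank5 = f5, flank3 = f3)
    })
    if (nrow(pair) == 1L && nGenes >= 2L) {
      units[[length(units) + 1L]] <- list(
        genes = entries[1:2], separation = pair$separation[1L],
        orientation = pair$orientation[1L])
      pairsT[[length(pairsT) + 1L]] <- data.frame(
        class = class, gene_a = entries[[1L]]$gid,
        gene_b = entries[[2L]]$gid,
        separation_bp = pair$separation[1L],
        orientation = pair$orientation[1L], stringsAsFactors = FALSE)
      entries <- entries[-(1:2)]
    }
    for (k in seq_along(entries))
      units[[length(units) + 1L]] <- list(
        genes = entries[k],
        strand = if (k %% 2L == 1L) "+" else "-")
  }
  scaffolds <- character(length(units))
  names(scaffolds) <- sprintf("scf%03d", seq_along(units))
  models <- list()
  for (u in seq_along(units)) {
    unit <- units[[u]]
    scafName <- names(scaffolds)[u]
    placed <- .placeUnit(unit, cfg)
    scaffolds[u] <- placed$seq
    for (g in placed$genes) {
      e <- g$entry
      gm <- GeneModel(geneID = e$gid, txID = paste0(e$gid, ".t1"),
                      scaffold = scafName, strand = g$strand,
                      cds = IRanges::IRanges(g$exons[, 1L],
                                             g$exons[, 2L]))
      models[[txID(gm)]] <- gm
      genesT[[length(genesT) + 1L]] <- data.frame(
        gene_id = e$gid, class = e$class, scaffold = scafName,
        strand = g$strand, start = min(g$exons[, 1L]),
        end = max(g$exons[, 2L]), protein = e$protein,
        length = nchar(e$protein), stringsAsFactors = FALSE)
      fg <- e$built$fingers
      fg <- data.frame(gene_id = e$gid, kind = "gata", fg[, -1L],
                       stringsAsFactors = FALSE)
      fingersT[[length(fingersT) + 1L]] <- fg
      if (!is.null(e$built$degenerate)) {
        d <- e$built$degenerate
        fingersT[[length(fingersT) + 1L]] <- data.frame(
          gene_id = e$gid, kind = "degenerate", c1 = d$c1, c2 = d$c2,
          c3 = d$c3, c4 = d$c4, start = d$c1, end = d$c4,
          stringsAsFactors = FALSE)
      }
      if (!is.null(e$built$polyS))
        polysT[[length(polysT) + 1L]] <- data.frame(
          gene_id = e$gid, e$built$polyS, stringsAsFactors = FALSE)
      if (nrow(e$built$introns))
        intronsT[[length(intronsT) + 1L]] <- data.frame(
          gene_id = e$gid, e$built$introns,
          codon_index = e$built$introns$cds_offset %/% 3L,
          stringsAsFactors = FALSE)
      for (side in c("5", "3")) {
        tf <- if (side == "5") e$flank5$truth else e$flank3$truth
        if (nrow(tf))
          motifsT[[length(motifsT) + 1L]] <- data.frame(
            gene_id = e$gid, flank = side, tf, stringsAsFactors = FALSE)
      }
    }
  }
  genome <- Biostrings::DNAStringSet(scaffolds)
  bindOr <- function(lst, ...) if (length(lst)) do.call(rbind, lst)
    else .emptyDf(...)
  truth <- list(
    seed = cfg$seed,
    genes = bindOr(genesT, gene_id = "character", class = "character",
                   scaffold = "character", strand = "character",
                   start = "integer", end = "integer",
                   protein = "character", length = "integer"),
    fingers = bindOr(fingersT, gene_id = "character", kind = "character",
                     c1 = "integer", c2 = "integer", c3 = "integer",
                     c4 = "integer", start = "integer", end = "integer"),
    polyS = bindOr(polysT, gene_id = "character", start = "integer",
                   end = "integer", ser_count = "integer"),
    introns = bindOr(intronsT, gene_id = "character",
                     cds_offset = "integer", landmark = "character",
                     codon_offset = "integer", phase = "integer",
                     codon_index = "integer"),
    pairs = bindOr(pairsT, class = "character", gene_a = "character",
                   gene_b = "character", separation_bp = "integer",
                   orientation = "character"),
    motifs = bindOr(motifsT, gene_id = "character", flank = "character",
                    kind = "character", start = "integer",
                    end = "integer", strand = "character",
                    detail = "numeric"))
  list(genome = genome, models = models, gff = .modelsToGff(models),
       truth = truth)
}

# place one unit (a single gene or a linked pair) on a fresh scaffold,
# returning the scaffold sequence and genomic exon coordinates
.placeUnit <- function(unit, cfg) {
  rc <- .revcompChr
  pad <- function() .randDna(cfg$pad, cfg$gc_background)
  toGenomic <- function(entry, strand, at) {
    # at = bases before the gene sequence on the scaffold
    G <- nchar(entry$layout$seq)
    ex <- entry$layout$exons
    if (strand == "+") ex <- cbind(at + ex[, 1L], at + ex[, 2L])
    else ex <- cbind(at + G - ex[, 2L] + 1L, at + G - ex[, 1L] + 1L)
    ex[order(ex[, 1L]), , drop = FALSE]
  }
  if (length(unit$genes) == 1L) {
    e <- unit$genes[[1L]]
    strand <- unit$strand
    g <- e$layout$seq
    if (strand == "+") {
      parts <- c(pad(), e$flank5$seq, g, e$flank3$seq, pad())
      at <- cfg$pad + cfg$flank_len
    } else {
      parts <- c(pad(), rc(e$flank3$seq), rc(g), rc(e$flank5$seq), pad())
      at <- cfg$pad + cfg$flank_len
    }
    return(list(seq = .collapse(parts),
                genes = list(list(entry = e, strand = strand,
                                  exons = toGenomic(e, strand, at)))))
  }
  a <- unit$genes[[1L]]; b <- unit$genes[[2L]]
  sep <- unit$separation
  fl <- cfg$flank_len
  if (sep < 2L * fl + 100L)
    stop("infeasible paralog separation: ", sep,
         " (needs > twice the flank length)")
  filler <- .randDna(sep - 2L * fl, cfg$gc_background)
  ga <- a$layout$seq; gb <- b$layout$seq
  orient <- unit$orientation
  if (orient == "same_direction") {
    strands <- c("+", "+")
    parts <- c(pad(), a$flank5$seq, ga, a$flank3$seq, filler,
               b$flank5$seq, gb, b$flank3$seq, pad())
  } else if (orient == "convergent") {
    strands <- c("+", "-")
    parts <- c(pad(), a$flank5$seq, ga, a$flank3$seq, filler,
               rc(b$flank3$seq), rc(gb), rc(b$flank5$seq), pad())
  } else if (orient == "divergent") {
    strands <- c("-", "+")
    parts <- c(pad(), rc(a$flank3$seq), rc(ga), rc(a$flank5$seq), filler,
               b$flank5$seq, gb, b$flank3$seq, pad())
  } else stop("unknown orientation: ", orient)
  atA <- cfg$pad + fl
  atB <- cfg$pad + fl + nchar(ga) + sep  # the gap holds both inner flanks
  list(seq = .collapse(parts),
       genes = list(
         list(entry = a, strand = strands[1L],
              exons = toGenomic(a, strands[1L], atA)),
         list(entry = b, strand = strands[2L],
              exons = toGenomic(b, strands[2L], atB))))
}

# GRanges (gene/mRNA/CDS with Parent links) ready for GFF3 export
.modelsToGff <- function(models) {
  rows <- list()
  for (gm in models) {
    cds <- cdsRanges(gm)
    span <- range(cds)
    w <- IRanges::width(cds)
    ord <- if (geneStrand(gm) == "-") rev(seq_along(w)) else seq_along(w)
    prior <- integer(length(w))
    prior[ord] <- c(0L, cumsum(w[ord]))[seq_along(w)]
    phase <- (3L - prior %% 3L) %% 3L
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = scaffoldName(gm),
      start = c(IRanges::start(span), IRanges::start(span),
                IRanges::start(cds)),
      end = c(IRanges::end(span), IRanges::end(span), IRanges::end(cds)),
      strand = geneStrand(gm),
      type = c("gene", "mRNA", rep("CDS", length(cds))),
      ID = c(geneID(gm), txID(gm), rep(NA_character_, length(cds))),
      parent = c(NA_character_, geneID(gm),
                 rep(txID(gm), length(cds))),
      phase = c(NA_integer_, NA_integer_, phase),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(
    lapply(df$parent, function(p) if (is.na(p)) character(0) else p))
  gr$phase <- df$phase
  gr
}

#' Write a corpus to disk
#'
#' Emits `genome.fa`, `genes.gff3` and `truth.json` into `dir`.
#'
#' @param corpus result of [generateCorpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(corpus$genome, file.path(dir, "genome.fa"),
                              width = 70L)
  rtracklayer::export(corpus$gff, file.path(dir, "genes.gff3"),
                      format = "gff3")
  jsonlite::write_json(corpus$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
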