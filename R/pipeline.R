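#' Build a GataFactor from a protein and its intron table
#'
#' Runs every protein-level scanner (GATA fingers + basic domains +
#' hexapeptides, degenerate upstream fingers, poly-serine segments),
#' attaches the intron table, computes landmark descriptors against all
#' fingers and the intron signature. Returns `NULL` when the protein
#' carries no GATA finger.
#'
#' @param protein amino-acid string.
#' @param introns data.frame from [mapIntronsToProtein()], or `NULL`
#'   when the gene structure is unknown or intronless.
#' @param proteinID,geneID identifiers.
#' @param scanCfg a [scanConfig()].
#' @return a [GataFactor-class] or `NULL`.
#' @export
buildGataFactor <- function(protein, introns = NULL,
                            proteinID = "protein", geneID = proteinID,
                            scanCfg = scanConfig()) {
  if (is.null(introns))
    introns <- .emptyDf(intron = "integer", scaffold = "character",
                        start = "integer", end = "integer",
                        cds_offset = "integer", codon_index = "integer",
                        phase = "integer")
  dbdTab <- buildDbdTable(protein, scanCfg)
  if (nrow(dbdTab) == 0L) return(NULL)
  deg <- findDegenerateFingers(protein, dbdTab, scanCfg)
  polyS <- findPolyS(protein, scanCfg)
  allFingers <- rbind(
    dbdTab[, c("kind", "c1", "c2", "c3", "c4")],
    if (nrow(deg)) deg[, c("kind", "c1", "c2", "c3", "c4")])
  desc <- landmarkDescriptors(introns, allFingers)
  sig <- intronSignature(desc, nrow(introns))
  new("GataFactor", proteinID = proteinID, geneID = geneID,
      protein = protein, dbds = dbdTab, degenerate = deg,
      polyS = polyS, introns = introns, descriptors = desc,
      signature = sig)
}

#' Annotate every gene model of a genome
#'
#' Runs the full analysis in memory: splice and translate each gene
#' model, scan for GATA fingers, basic domains, hexapeptides, degenerate
#' upstream fingers and poly-serine segments, map introns to
#' cysteine-landmark descriptors, build the intron signature, classify,
#' extract flanks and scan them for motifs, and measure paralog pairs.
#' Genes whose protein carries no GATA finger are skipped.
#'
#' @param genome named [Biostrings::DNAStringSet] of scaffolds.
#' @param models list of [GeneModel-class] (one transcript per gene; see
#'   [selectTranscripts()]).
#' @param scanCfg a [scanConfig()].
#' @param classifyCfg a [classifyConfig()].
#' @param lib a [consensusLibrary()].
#' @param species species label attached to every factor.
#' @param flank flank length for motif scanning (default 1000).
#' @return list with data.frames `factors`, `domains`, `introns`,
#'   `motifs`, `pairs`, a `tally` table, the `calls` list, the
#'   [GataFactor-class] objects in `objects`, and per-class
#'   `AnchoredAlignment`s plus consensus/conservation reports in
#'   `conservation`.
#' @export
annotateGenome <- function(genome, models, scanCfg = scanConfig(),
                           classifyCfg = classifyConfig(),
                           lib = consensusLibrary(),
                           species = "sample", flank = 1000L) {
  factors <- list(); domains <- list(); intronRows <- list()
  motifRows <- list(); objects <- list(); calls <- list()
  geneRows <- list()
  for (gm in models) {
    sp <- splicedCds(gm, genome)
    protein <- translateCds(sp$cds, on_internal_stop = "truncate")
    introns <- mapIntronsToProtein(gm)
    factor <- buildGataFactor(protein, introns, proteinID = txID(gm),
                              geneID = geneID(gm), scanCfg = scanCfg)
    if (is.null(factor)) next
    dbdTab <- dbds(factor)
    deg <- factor@degenerate
    polyS <- factor@polyS
    desc <- factor@descriptors
    sig <- factor@signature
    call <- assignClass(factor, lib, classifyCfg)
    objects[[txID(gm)]] <- factor
    calls[[txID(gm)]] <- call
    if (flank >= 1L) {
      fl <- extractFlanks(gm, genome, flank)
      for (side in c("5", "3")) {
        seq <- if (side == "5") fl$five_prime else fl$three_prime
        if (!nzchar(seq)) next
        hits <- scanFlankMotifs(seq)
        if (nrow(hits))
          motifRows[[length(motifRows) + 1L]] <-
            data.frame(gene_id = geneID(gm), flank = side, hits,
                       stringsAsFactors = FALSE)
      }
    }
    factors[[length(factors) + 1L]] <- data.frame(
      protein_id = txID(gm), gene_id = geneID(gm), species = species,
      class = call$label, score = call$score, n_dbds = nrow(dbdTab),
      n_degenerate = nrow(deg), n_polyS = nrow(polyS),
      n_introns = nrow(introns),
      intronless = sig$intronless,
      has_N_basic_intron = sig$has_N_basic_intron,
      has_C_basic_intron = sig$has_C_basic_intron,
      has_zf_intron = sig$has_zf_intron,
      hexapeptide = paste(stats::na.omit(dbdTab$hexapeptide),
                          collapse = ","),
      length = nchar(protein),
      evidence = paste(call$evidence, collapse = ";"),
      stringsAsFactors = FALSE)
    dd <- rbind(
      data.frame(kind = dbdTab$kind, c1 = dbdTab$c1, c2 = dbdTab$c2,
                 c3 = dbdTab$c3, c4 = dbdTab$c4, start = dbdTab$start,
                 end = dbdTab$end, stringsAsFactors = FALSE),
      if (nrow(deg)) deg[, c("kind", "c1", "c2", "c3", "c4", "start",
                             "end")],
      if (nrow(polyS)) data.frame(kind = "polyS", c1 = NA_integer_,
                                  c2 = NA_integer_, c3 = NA_integer_,
                                  c4 = NA_integer_, start = polyS$start,
                                  end = polyS$end,
                                  stringsAsFactors = FALSE))
    domains[[length(domains) + 1L]] <-
      data.frame(gene_id = geneID(gm), dd, stringsAsFactors = FALSE)
    if (nrow(introns)) {
      di <- merge(introns, desc, by = "intron", sort = TRUE)
      intronRows[[length(intronRows) + 1L]] <-
        data.frame(gene_id = geneID(gm), di, stringsAsFactors = FALSE)
    }
    span <- range(cdsRanges(gm))
    geneRows[[length(geneRows) + 1L]] <- data.frame(
      gene_id = geneID(gm), species = species, class = call$label,
      scaffold = scaffoldName(gm), strand = geneStrand(gm),
      start = IRanges::start(span), end = IRanges::end(span),
      stringsAsFactors = FALSE)
  }
  bindOr <- function(lst) if (length(lst)) {
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  } else NULL
  factorsDf <- bindOr(factors)
  geneTable <- bindOr(geneRows)
  pairs <- if (!is.null(geneTable)) findParalogPairs(geneTable)
  else findParalogPairs(.emptyDf(gene_id = "character",
                                 species = "character",
                                 class = "character",
                                 scaffold = "character",
                                 strand = "character",
                                 start = "integer", end = "integer"))
  conservation <- .classConservation(objects, calls)
  list(factors = factorsDf,
       domains = bindOr(domains),
       introns = bindOr(intronRows),
       motifs = bindOr(motifRows),
       pairs = pairs,
       tally = if (!is.null(factorsDf))
         tallyByClass(factorsDf$class, factorsDf$species)
       else tallyByClass(character(0), character(0)),
       conservation = conservation,
       calls = calls, objects = objects)
}

# per-class anchored alignments, consensus strings and conservation;
# multi-DBD factors contribute one alignment block per finger position
# (amino and carboxyl DBDs are aligned separately, as their conservation
# patterns differ)
.classConservation <- function(objects, calls) {
  if (!length(objects)) return(list())
  labels <- vapply(calls, `[[`, character(1), "label")
  out <- list()
  for (cl in sort(unique(labels))) {
    ids <- names(labels)[labels == cl]
    maxDbds <- max(vapply(ids, function(id) nDbds(objects[[id]]),
                          integer(1)))
    for (pos in seq_len(maxDbds)) {
      rows <- list()
      prots <- character(0)
      for (id in ids) {
        d <- dbds(objects[[id]])
        if (pos > nrow(d)) next
        rid <- sprintf("%s_dbd%d", id, pos)
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = rid, c1 = d$c1[pos], c2 = d$c2[pos], c3 = d$c3[pos],
          c4 = d$c4[pos], stringsAsFactors = FALSE)
        prots[rid] <- proteinSeq(objects[[id]])
      }
      if (!length(rows)) next
      tab <- do.call(rbind, rows)
      aln <- anchorAlign(tab, prots)
      entry <- list(alignment = aln, n_rows = length(aln$rows))
      if (length(aln$rows) >= 2L) {
        entry$consensus <- consensusString55(aln)
        entry$absolute <- conservationCount(aln, "absolute")
        entry$majority <- conservationCount(aln, "majority")
      }
      name <- if (maxDbds == 1L) cl else sprintf("%s_dbd%d", cl, pos)
      out[[name]] <- entry
    }
  }
  out
}

.writeTsv <- function(df, path) {
  if (is.null(df)) df <- data.frame()
  df[] <- lapply(df, function(col) {
    if (is.character(col)) ifelse(is.na(col) | col == "", ".", col)
    else col
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Run the annotation pipeline on files and write a report bundle
#'
#' Reads a genome FASTA and GFF3 gene models, picks one transcript per
#' gene, annotates (see [annotateGenome()]) and writes the output bundle
#' into `outDir`: `factors.tsv`, `domains.tsv`, `introns.tsv`,
#' `motifs.tsv`, `pairs.tsv`, `summary.json`, one aligned DBD FASTA per
#' class, and optionally one SVG structure diagram per factor. When a
#' protein FASTA is also supplied, its sequences are cross-checked
#' against the genome-derived translations; mismatches are logged and
#' the genome-derived translation wins.
#'
#' @param genomeFile,gffFile,proteinsFile input paths (`proteinsFile`
#'   optional).
#' @param outDir output directory.
#' @param flank flank length (default 1000).
#' @param transcriptPolicy passed to [selectTranscripts()].
#' @param scanCfg,classifyCfg,lib,species see [annotateGenome()].
#' @param diagrams also write per-factor SVG diagrams.
#' @return the [annotateGenome()] result, invisibly.
#' @export
runAnnotate <- function(genomeFile, gffFile, proteinsFile = NULL,
                        outDir, flank = 1000L,
                        transcriptPolicy = "longest",
                        scanCfg = scanConfig(),
                        classifyCfg = classifyConfig(),
                        lib = consensusLibrary(),
                        species = "sample", diagrams = FALSE) {
  if (missing(genomeFile) || missing(gffFile))
    stop("a genome FASTA and a GFF3 file are required")
  genome <- readFasta(genomeFile, "DNA")
  models <- selectTranscripts(readGeneModels(gffFile), transcriptPolicy)
  if (!is.null(proteinsFile)) {
    prots <- readFasta(proteinsFile, "AA")
    for (gm in models) {
      if (!txID(gm) %in% names(prots)) next
      derived <- translateCds(splicedCds(gm, genome)$cds,
                              on_internal_stop = "truncate")
      if (toupper(as.character(prots[[txID(gm)]])) != toupper(derived))
        message("note: supplied protein for ", txID(gm),
                " differs from genome-derived translation; using the ",
                "genome-derived sequence")
    }
  }
  ann <- annotateGenome(genome, models, scanCfg, classifyCfg, lib,
                        species, flank)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(ann$factors, file.path(outDir, "factors.tsv"))
  .writeTsv(ann$domains, file.path(outDir, "domains.tsv"))
  .writeTsv(ann$introns, file.path(outDir, "introns.tsv"))
  .writeTsv(ann$motifs, file.path(outDir, "motifs.tsv"))
  .writeTsv(ann$pairs, file.path(outDir, "pairs.tsv"))
  for (cl in names(ann$conservation))
    exportAlignment(ann$conservation[[cl]]$alignment,
                    file.path(outDir, sprintf("dbd_%s.aln.fasta", cl)))
  summary <- list(
    schema_version = "1.0",
    n_factors = if (is.null(ann$factors)) 0L else nrow(ann$factors),
    tally = ann$tally,
    conservation = lapply(ann$conservation, function(e) {
      e$alignment <- NULL; e
    }))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (isTRUE(diagrams)) {
    for (id in names(ann$objects))
      renderDiagram(ann$objects[[id]],
                    file.path(outDir, sprintf("diagram_%s.svg", id)))
  }
  if (is.null(ann$factors))
    message("note: zero GATA factors found; tables are empty")
  invisible(ann)
}

#' Render a to-scale protein structure diagram as SVG
#'
#' Horizontal bar for the protein with shaded DNA-binding domains
#' (finger + basic domain), the degenerate C4 finger, poly-serine
#' segments, inverted triangles marking intron positions at their codon
#' indices, and the total length label.
#'
#' @param factor a [GataFactor-class].
#' @param path optional output path; when `NULL` the SVG text is
#'   returned.
#' @param width diagram width in pixels (bar drawn to scale within it).
#' @return the SVG document as a character scalar (invisibly when
#'   written to `path`).
#' @export
renderDiagram <- function(factor, path = NULL, width = 600) {
  n <- nchar(proteinSeq(factor))
  barX <- 40; barY <- 60; barH <- 14
  barW <- width - 2 * barX
  px <- function(pos) barX + barW * (pos - 1) / max(1L, n - 1L)
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="120" viewBox="0 0 %d 120">'),
                   width, width),
           sprintf(paste0('<rect x="%.1f" y="%d" width="%.1f" ',
                          'height="%d" fill="#dddddd" stroke="#333333"/>'),
                   barX, barY, barW, barH))
  box <- function(s, e, fill, label) {
    sprintf(paste0('<rect class="%s" x="%.1f" y="%d" width="%.1f" ',
                   'height="%d" fill="%s" stroke="#333333"/>'),
            label, px(s), barY, px(e) - px(s), barH, fill)
  }
  d <- dbds(factor)
  for (i in seq_len(nrow(d)))
    out <- c(out, box(d$c1[i], min(n, d$basic_end[i]), "#2b6cb0", "dbd"))
  dg <- factor@degenerate
  for (i in seq_len(nrow(dg)))
    out <- c(out, box(dg$c1[i], dg$c4[i], "#b07c2b", "degenerate"))
  ps <- factor@polyS
  for (i in seq_len(nrow(ps)))
    out <- c(out, box(ps$start[i], ps$end[i], "#2bb06c", "polyS"))
  it <- factor@introns
  for (i in seq_len(nrow(it))) {
    x <- px(min(n, it$codon_index[i] + 1L))
    out <- c(out, sprintf(paste0('<polygon class="intron" points=',
                                 '"%.1f,%d %.1f,%d %.1f,%d" ',
                                 'fill="#555555"/>'),
                          x - 5, barY - 12, x + 5, barY - 12, x, barY - 2))
  }
  out <- c(out,
           sprintf(paste0('<text x="%.1f" y="%d" font-size="12" ',
                          'font-family="sans-serif">%s (%d aa)</text>'),
                   barX, barY + barH + 20, factor@proteinID, n),
           "</svg>")
  svg <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path)
    return(invisible(svg))
  }
  svg
}
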