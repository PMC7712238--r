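# greedy one-to-one matching of predicted vs truth spans at >= 80%
# reciprocal overlap; returns c(tp, npred, ntruth)
.matchSpans <- function(pred, truth, minOverlap = 0.8) {
  used <- logical(nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(pred))) {
    best <- 0; bestJ <- 0L
    for (j in seq_len(nrow(truth))) {
      if (used[j]) next
      ro <- .reciprocalOverlap(pred$start[i], pred$end[i],
                               truth$start[j], truth$end[j])
      if (ro > best) { best <- ro; bestJ <- j }
    }
    if (bestJ > 0L && best >= minOverlap) {
      used[bestJ] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, npred = nrow(pred), ntruth = nrow(truth))
}

.prStats <- function(counts) {
  tp <- sum(counts["tp", ]); np <- sum(counts["npred", ])
  nt <- sum(counts["ntruth", ])
  list(tp = tp, n_predicted = np, n_truth = nt,
       precision = if (np > 0L) tp / np else NA_real_,
       recall = if (nt > 0L) tp / nt else NA_real_)
}

#' Score pipeline output against a synthetic truth manifest
#'
#' Computes per-feature precision and recall plus the class confusion
#' matrix. A predicted finger, poly-serine segment or motif matches
#' truth when their spans overlap at least 80% reciprocally (within the
#' same gene, feature group and — for motifs — flank and kind); intron
#' positions match exactly on (codon_index, phase); classes match by
#' label.
#'
#' @param ann result of [annotateGenome()] on a corpus.
#' @param truth the `truth` element of [generateCorpus()].
#' @return list with elements `fingers`, `polyS`, `introns`, `motifs`
#'   (each `tp`, `n_predicted`, `n_truth`, `precision`, `recall`),
#'   `confusion` (truth class x predicted class matrix), `accuracy`, and
#'   `pairs` (planted linked pairs recovered with exact separation and
#'   orientation).
#' @export
scoreRecovery <- function(ann, truth) {
  knownGenes <- truth$genes$gene_id
  predGenes <- if (is.null(ann$factors)) character(0)
  else ann$factors$gene_id
  unknown <- setdiff(predGenes, knownGenes)
  if (length(unknown))
    stop("pipeline output names unknown gene id(s): ",
         paste(unknown, collapse = ", "))
  domains <- if (is.null(ann$domains))
    .emptyDf(gene_id = "character", kind = "character",
             start = "integer", end = "integer")
  else ann$domains
  domains$group <- ifelse(domains$kind %in%
                            c("gata_canonical", "gata_variant"),
                          "gata", domains$kind)
  truthF <- truth$fingers
  perGene <- function(predDf, truthDf, keys) {
    allKeys <- unique(rbind(predDf[keys], truthDf[keys]))
    counts <- vapply(seq_len(nrow(allKeys)), function(r) {
      selP <- rep(TRUE, nrow(predDf)); selT <- rep(TRUE, nrow(truthDf))
      for (k in keys) {
        selP <- selP & predDf[[k]] == allKeys[[k]][r]
        selT <- selT & truthDf[[k]] == allKeys[[k]][r]
      }
      .matchSpans(predDf[selP, , drop = FALSE],
                  truthDf[selT, , drop = FALSE])
    }, c(tp = 0L, npred = 0L, ntruth = 0L))
    if (!is.matrix(counts))
      counts <- matrix(integer(0), nrow = 3L,
                       dimnames = list(c("tp", "npred", "ntruth")))
    .prStats(counts)
  }
  # group-aware finger matching: gata and degenerate scored separately
  fingerStats <- {
    predF <- domains[domains$group %in% c("gata", "degenerate"),
                     c("gene_id", "group", "start", "end")]
    names(predF)[2L] <- "kind"
    perGene(predF, truthF, c("gene_id", "kind"))
  }
  polyStats <- perGene(
    domains[domains$group == "polyS", c("gene_id", "start", "end")],
    truth$polyS, "gene_id")
  # introns: exact (codon_index, phase) multiset match per gene
  predI <- if (is.null(ann$introns))
    .emptyDf(gene_id = "character", codon_index = "integer",
             phase = "integer")
  else unique(ann$introns[, c("gene_id", "intron", "codon_index",
                              "phase.x")])
  if ("phase.x" %in% names(predI)) names(predI)[4L] <- "phase"
  truthI <- truth$introns
  ikey <- function(df) paste(df$gene_id, df$codon_index, df$phase)
  tp <- 0L
  remaining <- ikey(truthI)
  for (k in ikey(predI)) {
    hit <- match(k, remaining)
    if (!is.na(hit)) { tp <- tp + 1L; remaining <- remaining[-hit] }
  }
  intronStats <- list(tp = tp, n_predicted = nrow(predI),
                      n_truth = nrow(truthI),
                      precision = if (nrow(predI)) tp / nrow(predI)
                      else NA_real_,
                      recall = if (nrow(truthI)) tp / nrow(truthI)
                      else NA_real_)
  motifPred <- if (is.null(ann$motifs))
    .emptyDf(gene_id = "character", flank = "character",
             kind = "character", start = "integer", end = "integer")
  else ann$motifs
  motifStats <- perGene(motifPred, truth$motifs,
                        c("gene_id", "flank", "kind"))
  # class confusion
  lev <- c("ELT1", "ELT2", "ELT3", "ELT5", "ELTX", "missed")
  predClass <- setNames(rep("missed", nrow(truth$genes)),
                        truth$genes$gene_id)
  if (!is.null(ann$factors))
    predClass[ann$factors$gene_id] <- ann$factors$class
  confusion <- table(truth = factor(truth$genes$class,
                                    levels = lev[1:5]),
                     predicted = factor(predClass, levels = lev))
  accuracy <- mean(predClass == truth$genes$class)
  # planted linked pairs: recovered with exact separation + orientation
  pairHits <- 0L
  if (nrow(truth$pairs)) {
    for (r in seq_len(nrow(truth$pairs))) {
      tp_ <- truth$pairs[r, ]
      sel <- ann$pairs$gene_a == tp_$gene_a &
        ann$pairs$gene_b == tp_$gene_b &
        ann$pairs$same_scaffold &
        ann$pairs$separation_bp == tp_$separation_bp &
        ann$pairs$orientation == tp_$orientation
      if (any(sel)) pairHits <- pairHits + 1L
    }
  }
  list(fingers = fingerStats, polyS = polyStats, introns = intronStats,
       motifs = motifStats, confusion = confusion, accuracy = accuracy,
       pairs = list(recovered = pairHits, n_truth = nrow(truth$pairs)))
}
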