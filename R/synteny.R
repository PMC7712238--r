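#' Paralogous gene pairs: proximity and orientation
#'
#' Emits every within-species, within-class gene pair once (lexicographic
#' id order). The gene span is the min/max over CDS segments. Separation
#' is the number of base pairs between the facing ends of the two spans
#' (0 when they overlap); orientation is `same_direction` for equal
#' strands, `convergent` when opposite strands face 3'-to-3',
#' `divergent` when they face 5'-to-5', and `n/a` across scaffolds.
#'
#' @param geneTable data.frame with columns `gene_id`, `species`,
#'   `class`, `scaffold`, `strand`, `start`, `end`.
#' @param nearby_threshold separation (bp) under which a same-scaffold
#'   pair is flagged `nearby` in the output (default 50000, spanning the
#'   2.6-35 kbp band typical of linked GATA duplicates with margin).
#' @return data.frame `species`, `class`, `gene_a`, `gene_b`,
#'   `scaffold_a`, `scaffold_b`, `same_scaffold`, `separation_bp`,
#'   `orientation`, `nearby`.
#' @export
findParalogPairs <- function(geneTable, nearby_threshold = 50000L) {
  empty <- .emptyDf(species = "character", class = "character",
                    gene_a = "character", gene_b = "character",
                    scaffold_a = "character", scaffold_b = "character",
                    same_scaffold = "logical", separation_bp = "integer",
                    orientation = "character", nearby = "logical")
  if (!nrow(geneTable)) return(empty)
  rows <- list()
  for (grp in split(geneTable,
                    paste(geneTable$species, geneTable$class, sep = "\r"))) {
    if (nrow(grp) < 2L) next
    grp <- grp[order(grp$gene_id), , drop = FALSE]
    for (i in seq_len(nrow(grp) - 1L)) {
      for (j in (i + 1L):nrow(grp)) {
        a <- grp[i, ]; b <- grp[j, ]
        sameScaf <- a$scaffold == b$scaffold
        if (sameScaf) {
          left <- if (a$start <= b$start) a else b
          right <- if (a$start <= b$start) b else a
          sep <- max(0L, right$start - left$end - 1L)
          orient <- if (a$strand == b$strand) "same_direction"
          else if (left$strand == "+") "convergent" else "divergent"
        } else {
          sep <- NA_integer_
          orient <- "n/a"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          species = a$species, class = a$class,
          gene_a = a$gene_id, gene_b = b$gene_id,
          scaffold_a = a$scaffold, scaffold_b = b$scaffold,
          same_scaffold = sameScaf,
          separation_bp = sep, orientation = orient,
          nearby = sameScaf && sep <= nearby_threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$class, out$gene_a, out$gene_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
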