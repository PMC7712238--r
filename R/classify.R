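#' Load the class consensus DBD library
#'
#' A named character vector of 55-residue class consensus DBD strings
#' following the anchored layout of [anchorAlign()]. The shipped default
#' is a synthetic stand-in library carrying the structural hallmarks of
#' each class (canonical C4 geometry; TPLWRR in ELT1_N, TTLWRR in
#' ELT1_C/ELT2, TSLWRR in ELT3, TTAWRR in ELT5; a diverged
#' hexapeptide-free ELTX); it doubles as the template set for the
#' synthetic-genome generator so classifier and generator share one
#' source of truth.
#'
#' @param path optional path to an alternative FASTA of 55-residue
#'   consensus strings.
#' @return named character vector.
#' @export
consensusLibrary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "consensus_dbd_synthetic.fasta",
                        package = "nemaGATA", mustWork = TRUE)
  set <- readFasta(path, type = "AA")
  out <- setNames(as.character(set), names(set))
  stopifnot(all(nchar(out) == 55L))
  out
}

#' Classification configuration
#'
#' @param tandem_gap maximum residues from one finger's C4 to the next
#'   finger's C1 for the pair to count as tandem (ELT-1-style); default
#'   50, splitting the ~29-residue tandem regime from the 100+ residue
#'   spacings seen in widely separated double-DBD factors.
#' @param min_identity minimum anchored-window identity to a single-finger
#'   class consensus for an ELT-3/ELT-5 call; below it the factor falls
#'   to the ELT-X catch-all. Default 0.60.
#' @param single_finger_classes names of the consensus-library entries
#'   competed over for single-DBD factors.
#' @return list with class `"ClassifyConfig"`.
#' @export
classifyConfig <- function(tandem_gap = 50L, min_identity = 0.60,
                           single_finger_classes = c("ELT3", "ELT5")) {
  structure(list(tandem_gap = as.integer(tandem_gap),
                 min_identity = min_identity,
                 single_finger_classes = single_finger_classes),
            class = "ClassifyConfig")
}

#' Identity of an anchored DBD row to a consensus string
#'
#' Case-insensitive positional identity over the 55 columns; gaps and
#' consensus `'.'` columns count as mismatches.
#'
#' @param row,consensus 55-character strings.
#' @return fraction in \[0, 1\].
#' @export
dbdIdentity <- function(row, consensus) {
  a <- .chars(row)
  b <- .chars(consensus)
  stopifnot(length(a) == 55L, length(b) == 55L)
  mean(a == b & a != "-" & b != ".")
}

# anchored row for one DBD of a factor
.dbdRow <- function(factor, i) {
  tab <- dbds(factor)[i, , drop = FALSE]
  tab$seq_id <- "x"
  anchorAlign(tab, c(x = proteinSeq(factor)))$rows[[1L]]
}

# rule 3: best single-finger class by consensus identity, with
# hexapeptide then intron-flag tie-breaks
.singleFingerCall <- function(factor, i, lib, cfg) {
  row <- .dbdRow(factor, i)
  ids <- vapply(cfg$single_finger_classes,
                function(cl) dbdIdentity(row, lib[[cl]]), numeric(1))
  best <- max(ids)
  evidence <- sprintf("identity_%s=%.3f", names(ids), ids)
  if (best < cfg$min_identity)
    return(list(label = "ELTX", score = best,
                evidence = c(evidence, "below_min_identity")))
  winners <- names(ids)[ids == best]
  if (length(winners) > 1L) {
    hx <- dbds(factor)$hexapeptide[i]
    if (!is.na(hx) && hx == "TTAWRR" && "ELT5" %in% winners) {
      winners <- "ELT5"
      evidence <- c(evidence, "tie_break=hexapeptide_TTAWRR")
    } else {
      sig <- signatureFlags(factor)
      if (isTRUE(sig$has_zf_intron) && "ELT3" %in% winners) {
        winners <- "ELT3"
        evidence <- c(evidence, "tie_break=zf_intron")
      } else if (isTRUE(sig$has_C_basic_intron) && "ELT5" %in% winners) {
        winners <- "ELT5"
        evidence <- c(evidence, "tie_break=C_basic_intron")
      } else {
        return(list(label = "ELTX", score = best,
                    evidence = c(evidence, "unresolved_tie")))
      }
    }
  }
  list(label = winners[1L], score = best, evidence = evidence)
}

#' Assign a GATA factor to one of the five structural classes
#'
#' Decision sequence: (1) two or more GATA DBDs with an adjacent pair
#' (C4-to-C1 gap at most `tandem_gap`) is ELT1 — a purely structural
#' call; (2) a single GATA DBD plus at least one upstream degenerate
#' finger is ELT2; (3) a single GATA DBD is scored by anchored-window
#' identity against each single-finger class consensus, taking the argmax
#' when it reaches `min_identity` (ties broken by the TTAWRR hexapeptide,
#' then by the conserved intron flags), otherwise ELTX; (4) two or more
#' widely spaced DBDs are each scored by rule 3, agreeing labels win,
#' disagreement falls to ELTX.
#'
#' @param factor a [GataFactor-class].
#' @param lib a [consensusLibrary()].
#' @param cfg a [classifyConfig()].
#' @return list with class `"ClassCall"`: `label`, `score` (identity to
#'   the winning consensus; `NA` for structural ELT1/ELT2 calls),
#'   `evidence` (character vector of rule firings).
#' @export
assignClass <- function(factor, lib = consensusLibrary(),
                        cfg = classifyConfig()) {
  d <- dbds(factor)
  if (nrow(d) == 0L) stop("factor has no DBDs")
  call <- if (nrow(d) >= 2L) {
    gaps <- d$c1[-1L] - d$c4[-nrow(d)] - 1L
    if (any(gaps <= cfg$tandem_gap)) {
      list(label = "ELT1", score = NA_real_,
           evidence = sprintf("tandem_dbds_gap=%d", min(gaps)))
    } else {
      sub <- lapply(seq_len(nrow(d)), function(i)
        .singleFingerCall(factor, i, lib, cfg))
      labels <- vapply(sub, `[[`, character(1), "label")
      ev <- c(sprintf("widely_spaced_dbds_gap=%d", min(gaps)),
              sprintf("dbd%d=%s", seq_along(labels), labels))
      if (length(unique(labels)) == 1L)
        list(label = labels[1L],
             score = max(vapply(sub, `[[`, numeric(1), "score")),
             evidence = ev)
      else
        list(label = "ELTX", score = NA_real_,
             evidence = c(ev, "dbd_labels_disagree"))
    }
  } else if (nrow(factor@degenerate) >= 1L) {
    list(label = "ELT2", score = NA_real_,
         evidence = sprintf("degenerate_upstream_finger_gap=%d",
                            factor@degenerate$upstream_gap[1L]))
  } else {
    .singleFingerCall(factor, 1L, lib, cfg)
  }
  structure(call, class = "ClassCall")
}

#' @export
print.ClassCall <- function(x, ...) {
  cat(sprintf("ClassCall: %s (score %s)\n  evidence: %s\n", x$label,
              ifelse(is.na(x$score), "-", sprintf("%.3f", x$score)),
              paste(x$evidence, collapse = "; ")))
  invisible(x)
}

#' Per-species tally of class calls
#'
#' @param labels character vector of class labels.
#' @param species character vector, one per label.
#' @return data.frame: one row per species, columns ELT1, ELT2, ELT3,
#'   ELT5, ELTX, total, rows sorted by species.
#' @export
tallyByClass <- function(labels, species = rep("all", length(labels))) {
  lev <- c("ELT1", "ELT2", "ELT3", "ELT5", "ELTX")
  sp <- sort(unique(species))
  if (!length(labels))
    return(data.frame(species = character(0),
                      setNames(as.data.frame(matrix(integer(0), 0, 5)),
                               lev),
                      total = integer(0)))
  tab <- table(factor(species, levels = sp),
               factor(labels, levels = lev))
  out <- data.frame(species = rownames(tab),
                    as.data.frame.matrix(tab),
                    stringsAsFactors = FALSE)
  out$total <- rowSums(tab)
  rownames(out) <- NULL
  out
}
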