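#' @import methods
#' @importFrom stats median runif setNames
#' @importFrom utils write.table read.table
NULL

# 20-letter amino-acid alphabet used throughout
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residues drawn for synthetic linkers: no C (would seed spurious fingers),
# no S (would seed spurious poly-serine windows)
.AA_NEUTRAL <- setdiff(.AA, c("C", "S"))

.chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

.collapse <- function(x) paste(x, collapse = "")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# reciprocal-overlap match between two closed intervals
.reciprocalOverlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  if (ov <= 0L) return(0)
  min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
}

.emptyDf <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(t) vector(t, 0L)),
                stringsAsFactors = FALSE)
}
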