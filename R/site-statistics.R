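# Occurrence and propensity tables over the X1/X2/X3 positions of the
# unique-sequence motif set.

.std_aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Residue occurrence table at the variable motif positions
#'
#' Counts each standard residue at positions X1, X2, X3 (motif positions
#' 2, 3, 5) over a deduplicated motif set.  Nonstandard residues are
#' counted under "other" with a warning.
#'
#' @param motifs list of \code{zt_motif}, deduplicated by sequence, or a
#'   character vector of 5-letter sequences
#' @return matrix (21 x 3, rows the 20 standard residues plus "other"),
#'   with attribute \code{total_sequences}
#' @export
occurrence_table <- function(motifs) {
  seqs <- if (is.character(motifs)) motifs
  else vapply(motifs, function(m) m$sequence, character(1))
  counts <- matrix(0L, nrow = length(.std_aa) + 1L, ncol = 3,
                   dimnames = list(c(.std_aa, "other"),
                                   c("X1", "X2", "X3")))
  for (sq in seqs) {
    letters5 <- strsplit(sq, "")[[1]]
    xs <- letters5[c(2, 3, 5)]
    for (k in 1:3) {
      r <- xs[k]
      if (!(r %in% .std_aa)) {
        warning("nonstandard residue '", r, "' counted under 'other'")
        r <- "other"
      }
      counts[r, k] <- counts[r, k] + 1L
    }
  }
  attr(counts, "total_sequences") <- length(seqs)
  counts
}

#' Load the bundled background amino-acid composition
#'
#' Standard average composition of the UniProtKB/Swiss-Prot database,
#' used as the default reference for propensity calculation.  The source
#' label travels with the result so outputs always state which background
#' was used.
#'
#' @return named numeric vector of frequencies summing to 1, with
#'   attribute \code{source}
#' @export
background_composition <- function() {
  tab <- read.delim(system.file("extdata", "aa_background_swissprot.tsv",
                                package = "zincturn"),
                    stringsAsFactors = FALSE)
  bg <- setNames(tab$frequency, tab$residue)
  bg <- bg / sum(bg)
  attr(bg, "source") <- "swissprot_average"
  bg
}

#' Position-wise residue propensities
#'
#' propensity(r, pos) = (count / total) / background(r); a zero count
#' gives propensity 0.
#'
#' @param occ occurrence matrix from \code{\link{occurrence_table}} (or
#'   any residue x position count matrix with attribute
#'   \code{total_sequences}, falling back to column sums)
#' @param bg named background frequencies (default the bundled
#'   composition); must cover every counted residue
#' @return numeric matrix of propensities with attribute
#'   \code{background_source}
#' @export
propensity_table <- function(occ, bg = background_composition()) {
  rows <- rownames(occ)
  rows <- rows[rows != "other"]
  occ <- occ[rows, , drop = FALSE]
  total <- attr(occ, "total_sequences")
  if (is.null(total)) total <- sum(occ[, 1])
  if (total <= 0) stop("propensity_table: empty occurrence table")
  missing_bg <- setdiff(rows, names(bg))
  if (length(missing_bg))
    stop("propensity_table: background lacks residues: ",
         paste(missing_bg, collapse = ", "))
  prop <- sweep(occ / total, 1, bg[rows], `/`)
  prop[occ == 0] <- 0
  attr(prop, "background_source") <- attr(bg, "source")
  prop
}

#' Bundled reference occurrence table
#'
#' The published position-wise residue occurrences over the non-redundant
#' set of 44 unique zinc-bound CXXHX alpha-turn sequences, as a count
#' matrix compatible with \code{\link{propensity_table}}.
#'
#' @return integer matrix (20 x 3) with attribute \code{total_sequences}
#' @export
reference_occurrences <- function() {
  tab <- read.delim(system.file("extdata", "cxxhx_position_occurrences.tsv",
                                package = "zincturn"),
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, c("X1", "X2", "X3")])
  rownames(m) <- tab$residue
  attr(m, "total_sequences") <- sum(m[, "X1"])
  m
}

#' Reconstruct a sequence set realizing an occurrence table
#'
#' Builds a deterministic set of C-X1-X2-H-X3 sequences whose column-wise
#' residue counts reproduce the given occurrence table: the per-position
#' residue multisets are permuted under a fixed internal seed sequence
#' until all triples are distinct.  Used to exercise the statistics stage
#' when only the marginal counts are published.
#'
#' @param occ count matrix as from \code{\link{reference_occurrences}}
#' @return character vector of distinct 5-letter sequences
#' @export
sequences_from_occurrences <- function(occ) {
  expand <- function(col) rep(rownames(occ), times = occ[, col])
  x1 <- expand("X1"); x2 <- expand("X2"); x3 <- expand("X3")
  n <- length(x1)
  stopifnot(length(x2) == n, length(x3) == n)
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
  for (trial in 1:500) {
    set.seed(trial)
    seqs <- paste0("C", x1, sample(x2), "H", sample(x3))
    if (!anyDuplicated(seqs)) return(sort(seqs))
  }
  stop("sequences_from_occurrences: could not realize distinct sequences")
}
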