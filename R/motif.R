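#' Build a marked reference transposase
#'
#' A reference peptide with the coordinates of its catalytic residues —
#' the DDE triad (two aspartates and a glutamate) plus the conserved
#' arginine and tryptophan of hAT transposases — marked explicitly.
#' Positions are 0-based, strictly increasing in the order
#' D1 < D2 < E, and the sequence letters at the marked positions must be
#' `D, D, E, R, W`.
#'
#' @param seq Amino-acid string.
#' @param positions Named integer vector with names `D1, D2, E, R, W`
#'   (0-based coordinates into `seq`).
#' @param id Reference identifier.
#' @return An object of class `transposase_reference`.
#' @export
transposase_reference <- function(seq, positions, id = "reference") {
  need <- c("D1", "D2", "E", "R", "W")
  if (!all(need %in% names(positions))) {
    stop("reference must mark positions D1, D2, E, R, W")
  }
  positions <- vapply(need, function(k) as.integer(positions[[k]]), integer(1))
  if (any(positions < 0L | positions >= nchar(seq))) {
    stop("marked positions outside reference sequence")
  }
  if (!(positions[["D1"]] < positions[["D2"]] &&
        positions[["D2"]] < positions[["E"]])) {
    stop("catalytic triad must satisfy D1 < D2 < E")
  }
  expected <- c(D1 = "D", D2 = "D", E = "E", R = "R", W = "W")
  got <- substring(seq, positions + 1L, positions + 1L)
  if (!all(got == expected[need])) {
    stop("reference letters at marked positions must be D, D, E, R, W (got ",
         paste(got, collapse = ""), ")")
  }
  structure(list(id = id, seq = toupper(seq), positions = positions),
            class = "transposase_reference")
}

#' Packaged synthetic marked reference transposase
#'
#' A deterministic 600-aa synthetic peptide (it is not a natural hAT
#' transposase) carrying a marked DDE triad and RW pair with hAT-like
#' spacing.  It anchors [scan_catalytic_residues()] out of the box; for
#' real curation supply your own marked reference (e.g. a Charlie/hAT
#' transposase) via [transposase_reference()].
#'
#' @param length_aa Peptide length (default 600).
#' @return A [transposase_reference()].
#' @export
synthetic_reference_transposase <- function(length_aa = 600L) {
  stopifnot(length_aa >= 60L)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ## fixed internal stream so the packaged reference is a constant
  s <- with_local_seed(20260101L, {
    paste0(sample(aa20, length_aa, replace = TRUE), collapse = "")
  })
  pos <- round(length_aa * c(D1 = 0.30, D2 = 0.42, E = 0.63,
                             R = 0.72, W = 0.85))
  pos <- as.integer(pos)
  names(pos) <- c("D1", "D2", "E", "R", "W")
  for (k in names(pos)) {
    letter <- c(D1 = "D", D2 = "D", E = "E", R = "R", W = "W")[[k]]
    substr(s, pos[[k]] + 1L, pos[[k]] + 1L) <- letter
  }
  transposase_reference(s, pos, id = sprintf("synthetic_hAT_ref_%daa", length_aa))
}

#' Locate DDE/RW catalytic residues by alignment anchoring
#'
#' Globally aligns a query protein to a marked reference transposase
#' (affine gaps, BLOSUM62) and maps each marked reference column onto the
#' query.  A residue is *found* iff the aligned query letter equals the
#' expected letter (D, D, E, R or W).  Anchoring to a reference makes the
#' search deterministic, in contrast to pattern heuristics.
#'
#' @param protein Query amino-acid string.
#' @param reference A [transposase_reference()].
#' @param gap_opening,gap_extension Affine gap penalties (defaults 10, 0.5).
#' @return List with `positions` (named integer vector, 0-based query
#'   coordinate or `NA` when not found), `found` (named logical),
#'   `n_found`, `reference_id`, `alignment_score`.
#' @export
scan_catalytic_residues <- function(protein, reference,
                                    gap_opening = 10, gap_extension = 0.5) {
  if (!is(reference, "transposase_reference")) {
    stop("reference must be a transposase_reference with marked positions")
  }
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  mat <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein), Biostrings::AAString(reference$seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  expected <- c(D1 = "D", D2 = "D", E = "E", R = "R", W = "W")
  positions <- setNames(rep(NA_integer_, 5L), names(expected))
  found <- setNames(rep(FALSE, 5L), names(expected))
  qi <- 0L; si <- 0L
  want <- reference$positions            # 0-based reference coords
  for (col in seq_along(qa)) {
    if (qa[col] != "-") qi <- qi + 1L
    if (sa[col] != "-") {
      si <- si + 1L
      hit <- names(want)[want == si - 1L]
      if (length(hit)) {
        for (k in hit) {
          if (qa[col] != "-" && qa[col] == expected[[k]]) {
            positions[[k]] <- qi - 1L
            found[[k]] <- TRUE
          }
        }
      }
    }
  }
  list(positions = positions, found = found, n_found = sum(found),
       reference_id = reference$id, alignment_score = Biostrings::score(pa))
}

## BLOSUM62 from Biostrings, loaded once per session.
get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
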