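## Deterministic semi-global sequence alignment: the model sequence is
## aligned in full, end gaps on the reference are free. Replaces a
## heuristic database search for reference-sequence matching at archive
## scale, where there is one candidate reference per chain and the question
## is "do these match, and over which region?".

#' AlignmentResult: outcome of a semi-global alignment
#'
#' @slot score optimal alignment score under the supplied scoring scheme
#' @slot identity_percent 100 * matches / (matches + mismatches + gaps)
#' @slot model_begin,model_end aligned span on the model sequence (always
#'   the full sequence for semi-global alignment)
#' @slot ref_begin,ref_end aligned span on the reference sequence
#' @slot n_matches,n_mismatches,n_gaps aligned-column counts
#' @slot aligned_model,aligned_ref gapped alignment strings (`-` for gaps)
#' @export
setClass("AlignmentResult",
  representation(score = "numeric", identity_percent = "numeric",
                 model_begin = "integer", model_end = "integer",
                 ref_begin = "integer", ref_end = "integer",
                 n_matches = "integer", n_mismatches = "integer",
                 n_gaps = "integer", aligned_model = "character",
                 aligned_ref = "character"))

setValidity("AlignmentResult", function(object) {
  tot <- object@n_matches + object@n_mismatches + object@n_gaps
  idOk <- tot == 0 ||
    abs(object@identity_percent - 100 * object@n_matches / tot) < 1e-9
  if (!idOk) return("identity_percent inconsistent with aligned-column counts")
  TRUE
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: score %g, identity %.1f%% (%dm/%dx/%dg), model %d-%d, ref %d-%d\n",
              object@score, object@identity_percent, object@n_matches,
              object@n_mismatches, object@n_gaps, object@model_begin,
              object@model_end, object@ref_begin, object@ref_end))
  cat(" ", object@aligned_model, "\n ", object@aligned_ref, "\n")
})

#' Align a model sequence to a reference sequence
#'
#' Optimal semi-global dynamic programming: the model sequence is aligned in
#' full (internal and terminal gaps in the model are penalized), while
#' unaligned reference overhangs are free. Linear gap penalty. Tie-breaking
#' is deterministic: among equal-scoring reference end columns the smallest
#' is chosen, and traceback prefers diagonal, then up (gap in reference),
#' then left (gap in model) moves.
#'
#' @param modelSeq one-letter model sequence (string, A-Z)
#' @param refSeq one-letter reference sequence (string, A-Z)
#' @param scoring list with `match`, `mismatch` and `gap` scores
#' @return an [AlignmentResult-class]
#' @examples
#' alignToReference("CDE", "ABCDEFG")
#' @export
alignToReference <- function(modelSeq, refSeq,
                             scoring = list(match = 1, mismatch = -1, gap = -2)) {
  if (!nzchar(modelSeq) || !nzchar(refSeq))
    stop("sequences must be non-empty", call. = FALSE)
  if (grepl("[^A-Za-z]", modelSeq) || grepl("[^A-Za-z]", refSeq))
    stop("sequences must use the A-Z alphabet", call. = FALSE)
  a <- strsplit(toupper(modelSeq), "")[[1]]
  b <- strsplit(toupper(refSeq), "")[[1]]
  m <- length(a); n <- length(b)
  gap <- scoring$gap
  M <- matrix(0, m + 1L, n + 1L)
  M[, 1L] <- (0:m) * gap      # gaps in the model column are penalized
  M[1L, ] <- 0                # free reference prefix
  for (i in seq_len(m)) {
    s <- ifelse(b == a[[i]], scoring$match, scoring$mismatch)
    diag <- M[i, 1:n] + s
    up <- M[i, 2:(n + 1L)] + gap
    best <- pmax(diag, up)
    left <- M[i + 1L, 1L]
    for (j in seq_len(n)) {     # left moves depend on the current row
      left <- max(best[[j]], left + gap)
      M[i + 1L, j + 1L] <- left
    }
  }
  jEnd <- which.max(M[m + 1L, ]) - 1L   # smallest maximizing column
  score <- M[m + 1L, jEnd + 1L]

  ## traceback, diagonal > up > left
  i <- m; j <- jEnd
  nm <- 0L; nx <- 0L; ng <- 0L
  am <- character(0); ar <- character(0)
  while (i > 0L) {
    here <- M[i + 1L, j + 1L]
    s <- if (j > 0L) (if (a[[i]] == b[[j]]) scoring$match else scoring$mismatch) else NA
    if (j > 0L && here == M[i, j] + s) {
      if (a[[i]] == b[[j]]) nm <- nm + 1L else nx <- nx + 1L
      am <- c(a[[i]], am); ar <- c(b[[j]], ar)
      i <- i - 1L; j <- j - 1L
    } else if (here == M[i, j + 1L] + gap) {
      ng <- ng + 1L
      am <- c(a[[i]], am); ar <- c("-", ar)
      i <- i - 1L
    } else {
      ng <- ng + 1L
      am <- c("-", am); ar <- c(b[[j]], ar)
      j <- j - 1L
    }
  }
  refBegin <- j + 1L
  tot <- nm + nx + ng
  new("AlignmentResult", score = score,
      identity_percent = if (tot) 100 * nm / tot else 0,
      model_begin = 1L, model_end = m,
      ref_begin = if (jEnd >= refBegin) refBegin else 0L,
      ref_end = jEnd,
      n_matches = nm, n_mismatches = nx, n_gaps = ng,
      aligned_model = paste(am, collapse = ""),
      aligned_ref = paste(ar, collapse = ""))
}
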