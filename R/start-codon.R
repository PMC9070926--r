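## Start-codon selection. Every in-frame ATG/GTG/TTG of an ORF is scored
## by (rbs_score + coupling_score) * type_score: RBS potential from a
## weight-matrix scan aggregated under a 9-position triangle centred 7
## bases upstream of the start (tvaGGAGnnnnnnnATG), down-weighted where
## several potential starts compete for the same RBS (ATG triplets are
## depleted next to true starts); translational coupling from the offset
## of the start against an upstream stop codon; and a codon-type weight
## of 16/4/1 for ATG/GTG/TTG.

#' Codon type score
#'
#' Fixed weights reflecting relative start-codon usage without overfitting:
#' ATG 16, GTG 4, TTG 1 (normalised shares 76.2% / 19.0% / 4.8%).
#'
#' @param codon character vector over `ATG`, `GTG`, `TTG`.
#' @return numeric scores.
#' @export
codon_type_score <- function(codon) {
  if (!all(codon %in% names(START_TYPE_SCORES)))
    stopf("not a start codon: %s",
          paste(setdiff(codon, names(START_TYPE_SCORES)), collapse = ", "))
  unname(START_TYPE_SCORES[codon])
}

#' Load an RBS weight matrix
#'
#' TSV with columns `A`, `C`, `G`, `T`, one row per motif position;
#' `# threshold` and `# ramp` comment headers override the defaults. A
#' synthetic matrix with consensus `tvaGGag` ships in
#' `inst/extdata/rbs_matrix_synthetic.tsv`; any matrix of matching shape
#' may be supplied.
#'
#' @param path TSV path; default the bundled synthetic matrix.
#' @param threshold raw score at/above which RBS potential is 1.
#' @param ramp width of the linear ramp below `threshold`.
#' @return an `RbsMatrix`: list of `weights` (positions x ACGT),
#'   `threshold`, `ramp`, `width`.
#' @export
read_rbs_matrix <- function(path = system.file("extdata",
                                               "rbs_matrix_synthetic.tsv",
                                               package = "genoprof"),
                            threshold = NULL, ramp = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    hit <- grep(paste0("^#\\s*", key), hdr, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^#\\s*", key, "\\s+"), "",
                                    hit[1])) else NULL
  }
  if (is.null(threshold)) threshold <- get_hdr("threshold")
  if (is.null(ramp)) ramp <- get_hdr("ramp")
  if (is.null(threshold)) threshold <- 2.54
  if (is.null(ramp)) ramp <- 0.4
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  w <- as.matrix(tab[, c("A", "C", "G", "T")])
  rbs_matrix(w, threshold, ramp)
}

#' @rdname read_rbs_matrix
#' @param weights numeric matrix, positions x columns `A,C,G,T`.
#' @export
rbs_matrix <- function(weights, threshold = 2.54, ramp = 0.4) {
  weights <- as.matrix(weights)
  if (!identical(colnames(weights), c("A", "C", "G", "T")))
    stopf("weight matrix needs columns A, C, G, T")
  if (nrow(weights) < 6L) stopf("motif width must be >= 6")
  if (ramp <= 0) stopf("ramp must be positive")
  structure(list(weights = weights, threshold = threshold, ramp = ramp,
                 width = nrow(weights)),
            class = "RbsMatrix")
}

#' Scan a sequence for RBS potential
#'
#' Slides the weight matrix along the sequence; a raw score at or above
#' the threshold maps to potential 1, scores within `ramp` below it fall
#' linearly to 0, anything lower is 0. Ambiguous bases take the minimum
#' column weight (counted and reported via attribute `n_ambiguous`).
#'
#' @param sequence single character string over ACGT (case-insensitive).
#' @param matrix an [rbs_matrix()].
#' @return numeric vector of potentials, one per placement (position i
#'   covers bases `i .. i+width-1`); raw scores in attribute `raw`.
#' @export
scan_rbs <- function(sequence, matrix) {
  stopifnot(inherits(matrix, "RbsMatrix"))
  s <- toupper(sequence)
  n <- nchar(s)
  w <- matrix$width
  if (n < w) {
    out <- numeric(0); attr(out, "raw") <- numeric(0)
    return(out)
  }
  base_idx <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  n_amb <- sum(is.na(base_idx))
  min_w <- apply(matrix$weights, 1, min)
  raw <- numeric(n - w + 1L)
  for (j in seq_len(w)) {
    idx <- base_idx[seq.int(j, n - w + j)]
    col <- unname(matrix$weights[j, ][idx])
    col[is.na(idx)] <- min_w[j]
    raw <- raw + col
  }
  pot <- clamp((raw - (matrix$threshold - matrix$ramp)) / matrix$ramp, 0, 1)
  attr(pot, "raw") <- raw
  attr(pot, "n_ambiguous") <- n_amb
  pot
}

#' Aggregate RBS potential for one start candidate
#'
#' Weighted sum of per-placement potentials under the 9-position triangle
#' centred at a 7-base gap between motif end and the start codon. Each
#' placement's contribution is multiplied by this start's share of the
#' weighted sum (codon type x triangle weight) over all candidate starts
#' visible to that placement — the ATG-depletion down-weighting.
#'
#' @param potentials vector from [scan_rbs()] on the same sequence.
#' @param start_pos 1-based position of the candidate's first base.
#' @param starts data.frame of all candidate starts of the ORF, columns
#'   `pos`, `codon`.
#' @param width motif width of the matrix used for `potentials`.
#' @return rbs score in `[0, 1]`.
#' @export
aggregate_rbs <- function(potentials, start_pos, starts, width) {
  type <- codon_type_score(starts$codon)
  own_type <- type[match(start_pos, starts$pos)]
  if (is.na(own_type)) stopf("start_pos is not among the candidate starts")
  score <- 0
  for (k in seq_along(TRIANGLE_GAPS)) {
    g <- TRIANGLE_GAPS[k]
    p <- start_pos - g - width           # placement: motif at [p, p+width-1]
    if (p < 1L || p > length(potentials)) next
    if (potentials[p] == 0) next
    gaps_all <- starts$pos - (p + width)
    vis <- gaps_all >= min(TRIANGLE_GAPS) & gaps_all <= max(TRIANGLE_GAPS)
    denom <- sum(type[vis] * TRIANGLE_W[match(gaps_all[vis], TRIANGLE_GAPS)])
    share <- (own_type * TRIANGLE_W[k]) / denom
    score <- score + potentials[p] * TRIANGLE_W[k] * share
  }
  score
}

#' Translational coupling score
#'
#' Scores the offset of a start codon relative to the end of an upstream
#' gene's stop codon (offset 0 = start immediately follows the stop;
#' offset -4 = the last two bases of the start overlap the stop). The
#' curve peaks at 1 at offset -4, falls linearly to 8/22 at -7 and on to
#' 0 at -25; downstream it falls linearly to 8/22 at -1 and then decays
#' exponentially with a halving distance of 100 bases. `NA` offsets (no
#' upstream gene in range) score 0.
#'
#' @param offset integer vector of signed offsets.
#' @return scores in `[0, 1]`.
#' @examples
#' coupling_score(c(-4, -7, -25, 99))
#' @export
coupling_score <- function(offset) {
  out <- numeric(length(offset))
  na <- is.na(offset)
  o <- offset[!na]
  s <- numeric(length(o))
  k <- 8 / 22
  up <- o <= -7 & o > -25
  s[up] <- k * (o[up] + 25) / 18
  mid <- o > -7 & o < -4
  s[mid] <- k + (1 - k) * (o[mid] + 7) / 3
  s[o == -4] <- 1
  dn <- o > -4 & o < -1
  s[dn] <- 1 - (1 - k) * (o[dn] + 4) / 3
  tail <- o >= -1
  s[tail] <- k * 2^(-(o[tail] + 1) / 100)
  out[!na] <- s
  out
}

#' Score all start candidates of one ORF
#'
#' @param sequence strand-local sequence (the ORF's own strand, 5'->3')
#'   containing the candidates and their upstream context.
#' @param candidates data.frame with `pos` (1-based first base of the
#'   codon), `codon`, and optional `coupling_offset` (signed offset versus
#'   an upstream stop, `NA` when absent) and `review_only` (logical:
#'   candidate lies more than 10 codons inside the first homology hit, so
#'   it is recorded but never auto-selected).
#' @param matrix an [rbs_matrix()].
#' @return the candidates with `rbs_score`, `coupling`, `type_score` and
#'   `combined = (rbs_score + coupling) * type_score` columns.
#' @export
score_start_candidates <- function(sequence, candidates,
                                   matrix = read_rbs_matrix()) {
  pot <- scan_rbs(sequence, matrix)
  if (is.null(candidates$coupling_offset))
    candidates$coupling_offset <- NA_integer_
  if (is.null(candidates$review_only)) candidates$review_only <- FALSE
  candidates$rbs_score <- vapply(candidates$pos, function(p) {
    aggregate_rbs(pot, p, candidates, matrix$width)
  }, numeric(1))
  candidates$coupling <- coupling_score(candidates$coupling_offset)
  candidates$type_score <- codon_type_score(candidates$codon)
  candidates$combined <-
    (candidates$rbs_score + candidates$coupling) * candidates$type_score
  candidates
}

#' Select the best start codon
#'
#' Picks the highest-combined-score candidate among those not flagged
#' review-only; ties go to the most upstream candidate. The confidence
#' ratio is the best score divided by the next best (`Inf` when only one
#' candidate exists or the runner-up scores 0).
#'
#' @param scored output of [score_start_candidates()].
#' @return list: `chosen` (row of `scored`, or `NULL` when no candidate is
#'   eligible), `confidence_ratio`, `flagged` (TRUE when nothing was
#'   eligible), and `review` (review-only candidates outscoring the
#'   chosen one).
#' @export
select_start <- function(scored) {
  elig <- scored[!scored$review_only, , drop = FALSE]
  if (!nrow(elig))
    return(list(chosen = NULL, confidence_ratio = NA_real_, flagged = TRUE,
                review = scored))
  ord <- order(-elig$combined, elig$pos)
  chosen <- elig[ord[1], , drop = FALSE]
  ratio <- if (nrow(elig) == 1L) Inf else {
    second <- elig$combined[ord[2]]
    if (second <= 0) Inf else chosen$combined / second
  }
  review <- scored[scored$review_only &
                     scored$combined > chosen$combined, , drop = FALSE]
  list(chosen = chosen, confidence_ratio = ratio, flagged = FALSE,
       review = review)
}
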