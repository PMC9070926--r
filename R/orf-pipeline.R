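## ORF enumeration, reciprocal-best-hit orthology, RNA-overlap trimming
## and the iterative suspicion-score filter. ORFs are maximal stop-to-stop
## frame segments on either strand holding at least one in-frame
## ATG/GTG/TTG; the suspicion score (0-8, four 0/1/2 components) removes
## implausible ORFs by iteratively lowering the permitted maximum to 5,
## re-scoring after each removal because overlap points relax as
## neighbours disappear.

## map a strand-local 1-based inclusive interval to a genome 0-based
## half-open span; L = genome length
local_span <- function(strand, L, lo, hi) {
  if (strand == "forward") c(lo - 1L, hi)
  else c(L - hi, L - lo + 1L)
}

#' Enumerate open reading frames
#'
#' Scans all six frames for maximal stop-bounded segments containing at
#' least one candidate start (in-frame ATG/GTG/TTG) and at least
#' `min_length` nucleotides from the first candidate start through the
#' stop codon. Segments lacking a terminating stop (running off the
#' sequence end) are not reported.
#'
#' @param sequence genome as a single ACGT string.
#' @param min_length minimum ORF length in nt (start through stop),
#'   default 90.
#' @return an `OrfSet`: list with `orfs` (data.frame: `id`, `strand`,
#'   `frame`, `local_stop`, `current_start` (strand-local, 1-based),
#'   `length`, `span_start`/`span_end` (genome, 0-based half-open),
#'   `n_starts`) and `starts` (data.frame: `orf_id`, `pos`
#'   (strand-local), `codon`).
#' @export
enumerate_orfs <- function(sequence, min_length = 90L) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  seqs <- list(forward = sequence, reverse = revcomp(sequence))
  orfs <- list(); starts <- list(); n <- 0L
  for (strand in names(seqs)) {
    s <- seqs[[strand]]
    for (frame in 0:2) {
      cod_pos <- seq.int(frame + 1L, L - 2L, by = 3L)
      if (!length(cod_pos)) next
      codons <- substring(s, cod_pos, cod_pos + 2L)
      is_stop <- codons %in% STOP_CODONS
      is_start <- codons %in% names(START_TYPE_SCORES)
      stop_idx <- which(is_stop)
      seg_begin <- 1L
      for (si in stop_idx) {
        cand <- which(is_start[seg_begin:(si - 1L)]) + seg_begin - 1L
        if (si > seg_begin && length(cand)) {
          first <- cod_pos[cand[1]]
          len <- cod_pos[si] + 2L - first + 1L
          if (len >= min_length) {
            n <- n + 1L
            id <- sprintf("orf%04d", n)
            span <- local_span(strand, L, first, cod_pos[si] + 2L)
            orfs[[n]] <- data.frame(
              id = id, strand = strand, frame = frame,
              local_stop = cod_pos[si], current_start = first,
              length = len, span_start = span[1], span_end = span[2],
              n_starts = length(cand), stringsAsFactors = FALSE)
            starts[[n]] <- data.frame(
              orf_id = id, pos = cod_pos[cand], codon = codons[cand],
              stringsAsFactors = FALSE)
          }
        }
        seg_begin <- si + 1L
      }
    }
  }
  out <- list(
    orfs = if (n) do.call(rbind, orfs) else
      data.frame(id = character(), strand = character(), frame = integer(),
                 local_stop = integer(), current_start = integer(),
                 length = integer(), span_start = integer(),
                 span_end = integer(), n_starts = integer()),
    starts = if (n) do.call(rbind, starts) else
      data.frame(orf_id = character(), pos = integer(), codon = character()),
    genome_length = L)
  class(out) <- "OrfSet"
  out
}

#' @export
print.OrfSet <- function(x, ...) {
  cat(sprintf("OrfSet: %d ORFs (%d candidate starts) on %d bp\n",
              nrow(x$orfs), nrow(x$starts), x$genome_length))
  invisible(x)
}

## best hit per query: highest bitscore, then lower e-value when present,
## then lexicographic subject id
best_hits <- function(hits) {
  ev <- if ("evalue" %in% names(hits)) hits$evalue else
    rep(0, nrow(hits))
  ord <- order(hits$query_id, -hits$bitscore, ev, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Reciprocal best hits
#'
#' A pair (q, r) is reported iff r is q's single best hit in the reference
#' and q is r's single best hit back. Duplicate query/subject rows are
#' reduced to their best before pairing.
#'
#' @param hits_q_to_ref,hits_ref_to_q data.frames with columns `query_id`,
#'   `subject_id`, `bitscore` and optionally `evalue` (BLAST outfmt-6
#'   naming; see [read_blast_tab()]).
#' @return data.frame with columns `query_id`, `subject_id`, `bitscore`.
#' @export
reciprocal_best_hits <- function(hits_q_to_ref, hits_ref_to_q) {
  bq <- best_hits(hits_q_to_ref)
  br <- best_hits(hits_ref_to_q)
  back <- br$subject_id[match(bq$subject_id, br$query_id)]
  keep <- !is.na(back) & back == bq$query_id
  bq[keep, c("query_id", "subject_id", "bitscore"), drop = FALSE]
}

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Standard 12 columns; only query, subject, e-value, bitscore and the
#' aligned query range are retained.
#'
#' @param path TSV path.
#' @return data.frame: `query_id`, `subject_id`, `identity`, `qstart`,
#'   `qend`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stopf("outfmt-6 needs 12 columns, found %d", ncol(tab))
  data.frame(query_id = tab[[1]], subject_id = tab[[2]],
             identity = tab[[3]], qstart = tab[[7]], qend = tab[[8]],
             evalue = tab[[11]], bitscore = tab[[12]],
             stringsAsFactors = FALSE)
}

orf_overlaps <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start))
}

## recompute an ORF's span after moving its current start
update_span <- function(orf_set, i) {
  o <- orf_set$orfs[i, ]
  span <- local_span(o$strand, orf_set$genome_length, o$current_start,
                     o$local_stop + 2L)
  orf_set$orfs$span_start[i] <- span[1]
  orf_set$orfs$span_end[i] <- span[2]
  orf_set$orfs$length[i] <- o$local_stop + 2L - o$current_start + 1L
  orf_set
}

#' Trim or discard ORFs overlapping RNA (or orthology-backed) features
#'
#' Applies only to ORFs without RBH evidence: an overlapping ORF is
#' trimmed by advancing to its next in-frame candidate start clear of the
#' feature; when no clear start exists, or the remnant is shorter than
#' `remnant_min`, the ORF is discarded.
#'
#' @param orf_set an [enumerate_orfs()] result.
#' @param features data.frame with `start`, `end` (genome, 0-based
#'   half-open) of RNA features and RBH-backed genes.
#' @param has_rbh logical vector (or character vector of exempt ids)
#'   marking ORFs exempt from the rule.
#' @param remnant_min minimum surviving length in nt (default 90).
#' @return the `OrfSet` with trimmed spans; discarded ORFs are dropped and
#'   listed in attribute `discarded`.
#' @export
resolve_rna_overlaps <- function(orf_set, features, has_rbh = character(),
                                 remnant_min = 90L) {
  if (is.logical(has_rbh)) has_rbh <- orf_set$orfs$id[has_rbh]
  drop <- character()
  for (i in seq_len(nrow(orf_set$orfs))) {
    o <- orf_set$orfs[i, ]
    if (o$id %in% has_rbh) next
    overl <- function(span) any(orf_overlaps(span[1], span[2],
                                             features$start,
                                             features$end) > 0L)
    span <- c(o$span_start, o$span_end)
    if (!nrow(features) || !overl(span)) next
    cand <- orf_set$starts$pos[orf_set$starts$orf_id == o$id]
    cand <- sort(cand[cand >= o$current_start])
    ok <- NA_integer_
    for (p in cand) {
      sp <- local_span(o$strand, orf_set$genome_length, p, o$local_stop + 2L)
      if (!overl(sp)) { ok <- p; break }
    }
    if (is.na(ok) || (o$local_stop + 2L - ok + 1L) < remnant_min) {
      drop <- c(drop, o$id)
    } else {
      orf_set$orfs$current_start[i] <- ok
      orf_set <- update_span(orf_set, i)
    }
  }
  keep <- !(orf_set$orfs$id %in% drop)
  orf_set$orfs <- orf_set$orfs[keep, , drop = FALSE]
  orf_set$starts <- orf_set$starts[orf_set$starts$orf_id %in%
                                     orf_set$orfs$id, , drop = FALSE]
  attr(orf_set, "discarded") <- drop
  orf_set
}

#' Suspicion score thresholds
#'
#' The four 0/1/2 components and their double cut-offs. These defaults
#' are declared package defaults (the original cut-offs were empirical
#' and unpublished): start strength scores 0 when the confidence ratio is
#' at least `start_ratio_ok` and the combined score is above the genome
#' median, 2 below the `start_weak_quantile` quantile; length scores 0 at
#' `length_ok` nt or more, 2 under `length_bad`; the same-strand to
#' antisense depth ratio scores 0 at `strand_ok` or more, 2 at
#' `strand_bad` or less; overlap scores 0 when absent, 1 under
#' `overlap_minor` nt, 2 otherwise.
#'
#' @param start_ratio_ok,start_weak_quantile,length_ok,length_bad,strand_ok,strand_bad,overlap_minor cut-offs as described.
#' @return a `SuspicionConfig` list.
#' @export
suspicion_config <- function(start_ratio_ok = 2, start_weak_quantile = 0.10,
                             length_ok = 300L, length_bad = 150L,
                             strand_ok = 2, strand_bad = 0.5,
                             overlap_minor = 30L) {
  structure(list(start_ratio_ok = start_ratio_ok,
                 start_weak_quantile = start_weak_quantile,
                 length_ok = length_ok, length_bad = length_bad,
                 strand_ok = strand_ok, strand_bad = strand_bad,
                 overlap_minor = overlap_minor),
            class = "SuspicionConfig")
}

#' Reference quantiles for the start-strength suspicion component
#'
#' @param orfs ORF table with a `combined` column.
#' @param config a [suspicion_config()].
#' @return list with `median` and `p10` of the combined start scores.
#' @export
suspicion_reference <- function(orfs, config = suspicion_config()) {
  list(median = stats::median(orfs$combined),
       p10 = stats::quantile(orfs$combined, config$start_weak_quantile,
                             type = 7, names = FALSE))
}

#' Suspicion score of ORFs
#'
#' Zero, one or two points for each of start-codon strength, ORF length,
#' RNAseq forward:reverse depth ratio and overlap with other features; the
#' higher the total (0-8) the less assurance the ORF is a real gene.
#'
#' @param orfs data.frame with columns `id`, `span_start`, `span_end`,
#'   `length`, `combined` (start score), `confidence_ratio`, and
#'   `strand_ratio` (same-strand over antisense normalised depth; `NA`
#'   when RNAseq is unavailable, which scores a neutral 1 and sets the
#'   `strand_flagged` column).
#' @param fixed_features optional data.frame (`start`, `end`) of
#'   annotations that count towards overlap but are never removed.
#' @param config a [suspicion_config()].
#' @param ref reference quantiles for the start-strength component, from
#'   [suspicion_reference()]; defaults to quantiles of `orfs` itself.
#' @return `orfs` with the four point columns, `total` and
#'   `strand_flagged`.
#' @export
suspicion_score <- function(orfs, fixed_features = NULL,
                            config = suspicion_config(), ref = NULL) {
  ## start-strength cut-offs are relative to a fixed reference population
  ## (the genome-wide ORF set), so that removing ORFs during iterative
  ## filtering cannot raise the start points of the survivors
  if (is.null(ref)) ref <- suspicion_reference(orfs, config)
  med <- ref$median
  p10 <- ref$p10
  pts_start <- ifelse(
    orfs$combined < p10, 2L,
    ifelse(orfs$confidence_ratio >= config$start_ratio_ok &
             orfs$combined > med, 0L, 1L))
  pts_len <- ifelse(orfs$length >= config$length_ok, 0L,
                    ifelse(orfs$length < config$length_bad, 2L, 1L))
  sr <- orfs$strand_ratio
  pts_strand <- ifelse(is.na(sr), 1L,
                       ifelse(sr >= config$strand_ok, 0L,
                              ifelse(sr <= config$strand_bad, 2L, 1L)))
  ov <- vapply(seq_len(nrow(orfs)), function(i) {
    others <- orfs[-i, , drop = FALSE]
    o1 <- if (nrow(others))
      max(orf_overlaps(orfs$span_start[i], orfs$span_end[i],
                       others$span_start, others$span_end)) else 0L
    o2 <- if (!is.null(fixed_features) && nrow(fixed_features))
      max(orf_overlaps(orfs$span_start[i], orfs$span_end[i],
                       fixed_features$start, fixed_features$end)) else 0L
    max(o1, o2)
  }, integer(1))
  pts_overlap <- ifelse(ov == 0L, 0L,
                        ifelse(ov < config$overlap_minor, 1L, 2L))
  orfs$points_start <- pts_start
  orfs$points_length <- pts_len
  orfs$points_strand_ratio <- pts_strand
  orfs$points_overlap <- pts_overlap
  orfs$strand_flagged <- is.na(sr)
  orfs$total <- pts_start + pts_len + pts_strand + pts_overlap
  orfs
}

#' Iteratively remove the most suspicious ORFs
#'
#' Starting at a permitted maximum of 8 and lowering it one point per
#' round down to `max_score_final`, removes ORFs whose total exceeds the
#' current cut-off, one at a time from the highest score (ties broken by
#' coordinate), re-scoring after every removal because the overlap
#' component of previously overlapping ORFs relaxes. Removals only ever
#' lower other ORFs' totals, so the process terminates.
#'
#' @param orfs as for [suspicion_score()] (point columns are recomputed).
#' @param fixed_features,config passed through to [suspicion_score()].
#' @param max_score_final final permitted maximum total (default 5).
#' @return list: `orfs` (survivors with final scores), `removed`
#'   (data.frame id/total/cutoff in removal order).
#' @export
iterative_filter <- function(orfs, fixed_features = NULL,
                             config = suspicion_config(),
                             max_score_final = 5L) {
  log <- data.frame(id = character(), total = integer(),
                    cutoff = integer(), stringsAsFactors = FALSE)
  ref <- suspicion_reference(orfs, config)
  for (cutoff in seq.int(8L, max_score_final, by = -1L)) {
    repeat {
      if (!nrow(orfs)) break
      sc <- suspicion_score(orfs, fixed_features, config, ref)
      bad <- which(sc$total > cutoff)
      if (!length(bad)) { orfs <- sc; break }
      pick <- bad[order(-sc$total[bad], sc$span_start[bad],
                        sc$span_end[bad])][1]
      log <- rbind(log, data.frame(id = sc$id[pick],
                                   total = sc$total[pick],
                                   cutoff = cutoff))
      orfs <- orfs[-pick, , drop = FALSE]
    }
  }
  if (nrow(orfs)) orfs <- suspicion_score(orfs, fixed_features, config, ref)
  list(orfs = orfs, removed = log)
}

#' Report unannotated gaps
#'
#' BED-style data.frame of genome stretches longer than `min_gap` covered
#' by no feature, for end-of-pipeline manual review (completely novel
#' genes would surface here).
#'
#' @param features data.frame with `start`, `end` (0-based half-open).
#' @param genome_length total length.
#' @param min_gap minimum reported gap width (default 300 nt).
#' @return data.frame `start`, `end` (0-based half-open).
#' @export
gap_report <- function(features, genome_length, min_gap = 300L) {
  if (!nrow(features)) {
    gaps <- data.frame(start = 0L, end = as.integer(genome_length))
  } else {
    f <- features[order(features$start, features$end), , drop = FALSE]
    cov_end <- cummax(f$end)
    gaps <- data.frame(start = c(0L, cov_end),
                       end = c(f$start, as.integer(genome_length)))
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
  }
  gaps <- gaps[gaps$end - gaps$start >= min_gap, , drop = FALSE]
  rownames(gaps) <- NULL
  gaps
}
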