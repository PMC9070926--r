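## Pileup-based error correction. A samtools-mpileup text column is
## reduced to per-allele counts; a difference is called only when one
## non-reference allele is unambiguous (>= min_fraction of counted
## alleles at >= min_depth), everything else lands in an ambiguous-site
## report for manual review. Only substitutions and single-base indels
## are callable — the error classes of homopolymer-troubled long-read
## assemblies — and indels are left-normalised within homopolymer runs.

#' Parse samtools mpileup text
#'
#' Handles match/mismatch symbols, `^X`/`$` read markers, `*` deletion
#' placeholders, `>`/`<` reference skips and `+n`/`-n` indel strings;
#' strand case is folded. A malformed indel length is a hard error naming
#' the position.
#'
#' @param input path to an mpileup file, or a character vector of its
#'   lines.
#' @return a `Pileup`: list of columns, each with `chrom`, `pos`, `ref`,
#'   `depth` and `counts` (named integer vector: `ref`, base letters,
#'   `+SEQ`, `-SEQ`).
#' @export
parse_pileup <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  cols <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stopf("malformed pileup line: %s", ln)
    pos <- as.integer(f[2])
    structure(list(chrom = f[1], pos = pos, ref = toupper(f[3]),
                   depth = as.integer(f[4]),
                   counts = parse_base_string(f[5], pos)),
              class = "PileupColumn")
  })
  structure(cols, class = "Pileup")
}

parse_base_string <- function(bs, pos) {
  ## fast path: pure-match column
  if (grepl("^[.,]*$", bs))
    return(stats::setNames(as.integer(nchar(bs)), "ref")[nchar(bs) > 0])
  ch <- strsplit(bs, "", fixed = TRUE)[[1]]
  counts <- c(ref = 0L)
  add <- function(key) {
    counts[key] <<- (if (key %in% names(counts)) counts[[key]] else 0L) + 1L
  }
  i <- 1L; n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") { i <- i + 2L; next }
    if (c0 == "$" || c0 == ">" || c0 == "<" || c0 == "*") { i <- i + 1L; next }
    if (c0 == "." || c0 == ",") { add("ref"); i <- i + 1L; next }
    if (c0 %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", ch[j])) j <- j + 1L
      if (j == i + 1L) stopf("malformed indel length at position %d", pos)
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) stopf("malformed indel length at position %d", pos)
      seq <- toupper(paste(ch[j:(j + len - 1L)], collapse = ""))
      add(paste0(c0, seq))
      i <- j + len
      next
    }
    if (toupper(c0) %in% c("A", "C", "G", "T", "N")) {
      add(toupper(c0)); i <- i + 1L; next
    }
    stopf("unrecognised pileup symbol '%s' at position %d", c0, pos)
  }
  counts[counts > 0L]
}

## leftmost position of the homopolymer run of `base` containing
## position q (1-based) in `genome`
run_left <- function(genome, q, base) {
  while (q > 1L && substr(genome, q - 1L, q - 1L) == base) q <- q - 1L
  q
}

#' Call unambiguous differences from a pileup
#'
#' A call is emitted iff the top non-reference allele accounts for at
#' least `min_fraction` of the counted alleles at a column with at least
#' `min_depth` counted alleles. Columns with material non-reference
#' support (above `1 - min_fraction`) that fail either test are reported
#' as ambiguous, never auto-called; indels longer than one base likewise.
#' When `genome` is supplied, indels are left-normalised to the canonical
#' leftmost position of their homopolymer run.
#'
#' @param pileup a [parse_pileup()] result.
#' @param min_depth minimum counted alleles (default 10).
#' @param min_fraction minimum allele support fraction (default 0.9).
#' @param genome reference sequence string (for indel normalisation and
#'   reference checks); optional.
#' @return list: `calls` (data.frame: `position`, `kind`, `ref_allele`,
#'   `alt_allele`, `support_fraction`, `depth`) and `ambiguous`
#'   (data.frame: `position`, `allele`, `support_fraction`, `depth`,
#'   `reason`).
#' @export
call_differences <- function(pileup, min_depth = 10L, min_fraction = 0.9,
                             genome = NULL) {
  calls <- list(); amb <- list()
  for (col in pileup) {
    ## indel symbols ride on a base symbol of the same read, so the
    ## denominator is the base-level read count, not the sum of all
    ## allele counts
    is_indel <- grepl("^[+-]", names(col$counts))
    total <- sum(col$counts[!is_indel])
    if (total == 0L) total <- sum(col$counts)
    if (total == 0L) next
    alt <- col$counts[names(col$counts) != "ref"]
    if (!length(alt)) next
    top_i <- which.max(alt)
    allele <- names(alt)[top_i]
    frac <- min(1, alt[[top_i]] / total)
    if (frac < (1 - min_fraction)) next   # clearly reference
    long_indel <- grepl("^[+-]", allele) && nchar(allele) > 2L
    if (frac >= min_fraction && total >= min_depth && !long_indel) {
      kind <- if (startsWith(allele, "-")) "deletion_1bp"
      else if (startsWith(allele, "+")) "insertion_1bp"
      else "substitution"
      if (kind == "substitution") {
        position <- col$pos; ref <- col$ref; altb <- allele
      } else if (kind == "deletion_1bp") {
        base <- substr(allele, 2L, 2L)
        position <- col$pos + 1L          # the deleted base itself
        if (!is.null(genome)) position <- run_left(genome, position, base)
        ref <- base; altb <- "-"
      } else {
        base <- substr(allele, 2L, 2L)
        position <- col$pos               # insert after this base
        if (!is.null(genome)) {
          while (position > 1L &&
                 substr(genome, position, position) == base)
            position <- position - 1L
        }
        ref <- if (is.null(genome)) col$ref else
          substr(genome, position, position)
        altb <- base
      }
      calls[[length(calls) + 1L]] <- data.frame(
        position = position, kind = kind, ref_allele = ref,
        alt_allele = altb, support_fraction = unname(frac),
        depth = total, stringsAsFactors = FALSE)
    } else {
      reason <- if (long_indel) "multi-base indel"
      else if (total < min_depth) "low depth" else "mixed support"
      amb[[length(amb) + 1L]] <- data.frame(
        position = col$pos, allele = allele,
        support_fraction = unname(frac), depth = total, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  empty_calls <- data.frame(position = integer(), kind = character(),
                            ref_allele = character(),
                            alt_allele = character(),
                            support_fraction = numeric(),
                            depth = integer())
  empty_amb <- data.frame(position = integer(), allele = character(),
                          support_fraction = numeric(), depth = integer(),
                          reason = character())
  list(calls = if (length(calls)) do.call(rbind, calls) else empty_calls,
       ambiguous = if (length(amb)) do.call(rbind, amb) else empty_amb)
}

#' Apply difference calls to a genome
#'
#' Calls are applied right to left so earlier coordinates stay valid; the
#' audit trail records every edit with its cumulative coordinate shift so
#' [reverse_corrections()] can restore the input byte-exactly. Two calls
#' touching the same position are a hard error.
#'
#' @param genome sequence as a single string.
#' @param calls data.frame as returned in `call_differences()$calls`.
#' @return list: `genome` (corrected string), `audit` (data.frame:
#'   `position`, `kind`, `ref_allele`, `alt_allele`, `new_position`).
#' @export
apply_corrections <- function(genome, calls) {
  if (!nrow(calls))
    return(list(genome = genome,
                audit = data.frame(position = integer(), kind = character(),
                                   ref_allele = character(),
                                   alt_allele = character(),
                                   new_position = integer())))
  if (any(calls$position < 1L | calls$position > nchar(genome)))
    stopf("call position outside the genome")
  dup <- calls$position[duplicated(calls$position)]
  if (length(dup))
    stopf("overlapping calls at position(s): %s",
          paste(unique(dup), collapse = ", "))
  ord <- order(-calls$position)
  g <- genome
  for (i in ord) {
    p <- calls$position[i]
    kind <- calls$kind[i]
    if (kind == "substitution") {
      if (substr(g, p, p) != calls$ref_allele[i])
        stopf("reference mismatch at %d: expected %s", p,
              calls$ref_allele[i])
      substr(g, p, p) <- calls$alt_allele[i]
    } else if (kind == "deletion_1bp") {
      g <- paste0(substr(g, 1L, p - 1L), substr(g, p + 1L, nchar(g)))
    } else if (kind == "insertion_1bp") {
      g <- paste0(substr(g, 1L, p), calls$alt_allele[i],
                  substr(g, p + 1L, nchar(g)))
    } else stopf("unknown call kind: %s", kind)
  }
  asc <- calls[order(calls$position), , drop = FALSE]
  shift <- cumsum(ifelse(asc$kind == "insertion_1bp", 1L,
                         ifelse(asc$kind == "deletion_1bp", -1L, 0L)))
  audit <- data.frame(position = asc$position, kind = asc$kind,
                      ref_allele = asc$ref_allele,
                      alt_allele = asc$alt_allele,
                      new_position = asc$position +
                        c(0L, shift[-length(shift)]),
                      stringsAsFactors = FALSE)
  list(genome = g, audit = audit)
}

#' Undo corrections using the audit trail
#'
#' @param genome corrected sequence.
#' @param audit audit data.frame from [apply_corrections()].
#' @return the original sequence.
#' @export
reverse_corrections <- function(genome, audit) {
  g <- genome
  for (i in rev(seq_len(nrow(audit)))) {
    p <- audit$new_position[i]
    kind <- audit$kind[i]
    if (kind == "substitution") {
      substr(g, p, p) <- audit$ref_allele[i]
    } else if (kind == "deletion_1bp") {        # re-insert the base
      g <- paste0(substr(g, 1L, p - 1L), audit$ref_allele[i],
                  substr(g, p, nchar(g)))
    } else if (kind == "insertion_1bp") {       # remove the inserted base
      g <- paste0(substr(g, 1L, p), substr(g, p + 2L, nchar(g)))
    }
  }
  g
}

#' Write calls as minimal VCF 4.2
#'
#' Indels are emitted with the conventional anchor base (the call's
#' left-normalised coordinates), substitutions directly.
#'
#' @param calls calls data.frame.
#' @param path output path.
#' @param genome reference sequence (needed for indel anchor bases).
#' @param sequence_id CHROM value.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, genome, sequence_id = "seq") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", sequence_id,
                   nchar(genome)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    p <- calls$position[i]
    if (calls$kind[i] == "substitution") {
      pos <- p; ref <- calls$ref_allele[i]; alt <- calls$alt_allele[i]
    } else if (calls$kind[i] == "deletion_1bp") {
      pos <- p - 1L
      anchor <- substr(genome, pos, pos)
      ref <- paste0(anchor, calls$ref_allele[i]); alt <- anchor
    } else {
      pos <- p
      anchor <- substr(genome, p, p)
      ref <- anchor; alt <- paste0(anchor, calls$alt_allele[i])
    }
    rows[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", sequence_id, pos,
                       ref, alt)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
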