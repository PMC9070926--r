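## Tiling of per-base depth into fixed-width strand-separated tiles.
## Internal coordinates are 0-based half-open; tile i covers
## [i*tile_size, min((i+1)*tile_size, length)). Input TSV positions are
## 1-based (samtools depth dialect) unless read as bedGraph.

#' Describe the coordinate axis of one replicon
#'
#' A `GenomeAxis` fixes the sequence label, its length and the tile width
#' shared by every depth matrix derived from it. The number of tiles per
#' strand is `ceiling(length / tile_size)`; the final tile may be short and
#' is flagged in [tile_depth_matrix()] objects so downstream steps can
#' exclude it.
#'
#' @param sequence_id single character label of the replicon.
#' @param length genome length in bases (positive integer).
#' @param tile_size tile width in bases; default 100.
#' @return an object of class `GenomeAxis`.
#' @examples
#' genome_axis("chr", 6300000)
#' @export
genome_axis <- function(sequence_id, length, tile_size = 100L) {
  if (!is.character(sequence_id) || length(sequence_id) != 1L)
    stopf("sequence_id must be a single string")
  if (!is_count(length)) stopf("length must be a positive integer")
  if (!is_count(tile_size)) stopf("tile_size must be a positive integer")
  structure(
    list(sequence_id = sequence_id,
         length = as.integer(length),
         tile_size = as.integer(tile_size),
         n_tiles = as.integer(ceiling(length / tile_size))),
    class = "GenomeAxis")
}

#' @export
print.GenomeAxis <- function(x, ...) {
  cat(sprintf("GenomeAxis %s: %d bp, %d tiles of %d bp\n",
              x$sequence_id, x$length, x$n_tiles, x$tile_size))
  invisible(x)
}

axis_identical <- function(a, b) {
  identical(a$sequence_id, b$sequence_id) &&
    identical(a$length, b$length) && identical(a$tile_size, b$tile_size)
}

#' Construct a strand-separated tile depth matrix
#'
#' The container shared by the normaliser and the colour encoder: one
#' non-negative depth value per (library, strand, tile), with tiles in
#' genome coordinate order.
#'
#' @param axis a [genome_axis()].
#' @param forward,reverse numeric matrices, `n_tiles x n_libraries`,
#'   with identical column names (the library labels).
#' @return an object of class `TileDepthMatrix` with elements `axis`,
#'   `libraries`, `depth` (list of `forward`/`reverse` matrices) and
#'   `short_final` (TRUE when the last tile is shorter than `tile_size`).
#' @export
tile_depth_matrix <- function(axis, forward, reverse) {
  stopifnot(inherits(axis, "GenomeAxis"))
  forward <- as.matrix(forward); reverse <- as.matrix(reverse)
  if (nrow(forward) != axis$n_tiles || nrow(reverse) != axis$n_tiles)
    stopf("depth matrices must have %d rows (tiles)", axis$n_tiles)
  if (!identical(colnames(forward), colnames(reverse)) ||
      is.null(colnames(forward)))
    stopf("forward and reverse matrices must share library column names")
  if (anyDuplicated(colnames(forward)))
    stopf("duplicate library label: %s",
          colnames(forward)[duplicated(colnames(forward))][1])
  if (any(forward < 0) || any(reverse < 0))
    stopf("tile depths must be non-negative")
  structure(
    list(axis = axis,
         libraries = colnames(forward),
         depth = list(forward = forward, reverse = reverse),
         short_final = (axis$length %% axis$tile_size) != 0L),
    class = "TileDepthMatrix")
}

#' @export
print.TileDepthMatrix <- function(x, ...) {
  cat(sprintf("TileDepthMatrix: %d libraries x 2 strands x %d tiles (%s)\n",
              length(x$libraries), x$axis$n_tiles, x$axis$sequence_id))
  cat(" libraries:", paste(x$libraries, collapse = ", "), "\n")
  invisible(x)
}

#' Per-library raw aligned sizes
#'
#' The raw aligned-read size of a library is the sum of its tile depths over
#' both strands; it seeds the preliminary normalisation factors.
#'
#' @param matrix a [tile_depth_matrix()].
#' @return named numeric vector, one total per library.
#' @export
library_sizes <- function(matrix) {
  stopifnot(inherits(matrix, "TileDepthMatrix"))
  colSums(matrix$depth$forward) + colSums(matrix$depth$reverse)
}

#' Reduce a per-base depth stream to tile depths
#'
#' Each tile's depth is the sum of per-base depths at positions falling in
#' the tile's half-open interval; positions absent from the input contribute
#' zero. Input positions are 1-based (the samtools `depth` convention).
#' Out-of-range records are dropped with one summary warning; a negative
#' depth is a hard error.
#'
#' @param records data.frame with columns `position` (1-based), `strand`
#'   (`"forward"`/`"reverse"` or `"+"/"-"`), `depth` (non-negative).
#' @param axis a [genome_axis()].
#' @param library single library label for the resulting matrix.
#' @return single-library [tile_depth_matrix()].
#' @examples
#' ax <- genome_axis("c", 200, 100)
#' rec <- data.frame(position = 1:100, strand = "forward", depth = 5)
#' compute_tile_depths(rec, ax, "lib1")
#' @export
compute_tile_depths <- function(records, axis, library = "lib1") {
  stopifnot(inherits(axis, "GenomeAxis"))
  if (nrow(records) == 0L) {
    z <- matrix(0, axis$n_tiles, 1, dimnames = list(NULL, library))
    return(tile_depth_matrix(axis, z, z))
  }
  if (!all(c("position", "strand", "depth") %in% names(records)))
    stopf("records need columns position, strand, depth")
  if (any(records$depth < 0)) stopf("negative depth in input records")
  strand <- norm_strand(records$strand)
  bad <- records$position < 1L | records$position > axis$length
  if (any(bad)) {
    warnf("%d record(s) outside [1, %d] rejected", sum(bad), axis$length)
    records <- records[!bad, , drop = FALSE]
    strand <- strand[!bad]
  }
  one <- function(which) {
    keep <- strand == which
    v <- numeric(axis$n_tiles)
    if (any(keep)) {
      idx <- (records$position[keep] - 1L) %/% axis$tile_size + 1L
      acc <- rowsum(records$depth[keep], idx)
      v[as.integer(rownames(acc))] <- acc[, 1]
    }
    matrix(v, ncol = 1, dimnames = list(NULL, library))
  }
  tile_depth_matrix(axis, one("forward"), one("reverse"))
}

norm_strand <- function(s) {
  out <- ifelse(s %in% c("forward", "+", "fwd"), "forward",
                ifelse(s %in% c("reverse", "-", "rev"), "reverse", NA))
  if (anyNA(out)) stopf("unrecognised strand value: %s",
                        paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

#' Combine single-library matrices into one multi-library matrix
#'
#' @param matrices list of [tile_depth_matrix()] objects sharing one axis.
#' @return multi-library `TileDepthMatrix`, libraries in input order.
#' @export
collate_libraries <- function(matrices) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "TileDepthMatrix")))
  ax <- matrices[[1]]$axis
  for (m in matrices[-1])
    if (!axis_identical(ax, m$axis)) stopf("matrices have mismatched axes")
  fwd <- do.call(cbind, lapply(matrices, function(m) m$depth$forward))
  rev <- do.call(cbind, lapply(matrices, function(m) m$depth$reverse))
  tile_depth_matrix(ax, fwd, rev)
}

#' Read a per-base depth table or bedGraph into tile depths
#'
#' `depth-tsv` is the three-column `samtools depth` output (chrom, 1-based
#' position, depth); `bedgraph` is 0-based half-open (chrom, start, end,
#' value) where the value is a per-base depth applying to every base of the
#' interval. The format is never guessed. gzip input is read transparently.
#'
#' @param path file path (optionally `.gz`).
#' @param axis a [genome_axis()].
#' @param strand strand this file measures, `"forward"` or `"reverse"`.
#' @param format `"depth-tsv"` or `"bedgraph"`.
#' @param library library label.
#' @return single-library, single-strand populated [tile_depth_matrix()]
#'   (the other strand is zero).
#' @export
read_depth_file <- function(path, axis, strand,
                            format = c("depth-tsv", "bedgraph"),
                            library = sub("\\.(tsv|bedgraph|bg)(\\.gz)?$", "",
                                          basename(path))) {
  format <- match.arg(format)
  strand <- norm_strand(strand)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (format == "depth-tsv") {
    if (ncol(tab) < 3L) stopf("depth-tsv needs 3 columns, found %d", ncol(tab))
    rec <- data.frame(position = tab[[2]], strand = strand, depth = tab[[3]])
    return(compute_tile_depths(rec, axis, library))
  }
  ## bedGraph: accumulate interval overlap with each tile analytically
  if (ncol(tab) < 4L) stopf("bedGraph needs 4 columns, found %d", ncol(tab))
  v <- numeric(axis$n_tiles)
  ts <- axis$tile_size
  start <- pmax(tab[[2]], 0L); end <- pmin(tab[[3]], axis$length)
  val <- tab[[4]]
  if (any(val < 0)) stopf("negative depth in bedGraph")
  for (i in seq_along(start)) {
    if (end[i] <= start[i]) next
    t0 <- start[i] %/% ts
    t1 <- (end[i] - 1L) %/% ts
    for (tt in t0:t1) {
      lo <- max(start[i], tt * ts); hi <- min(end[i], (tt + 1) * ts)
      v[tt + 1L] <- v[tt + 1L] + (hi - lo) * val[i]
    }
  }
  m <- matrix(v, ncol = 1, dimnames = list(NULL, library))
  z <- matrix(0, axis$n_tiles, 1, dimnames = list(NULL, library))
  if (strand == "forward") tile_depth_matrix(axis, m, z)
  else tile_depth_matrix(axis, z, m)
}

#' Per-base depth from a SAM/BAM alignment
#'
#' Convenience ingestion for alignments: computes per-base coverage per
#' strand. Strand assignment follows the library protocol: for
#' `strand_mode = "reverse"` (dUTP-style, the default) a read aligned to
#' the minus strand reports *forward*-strand transcription.
#'
#' @param path SAM or BAM file.
#' @param axis a [genome_axis()].
#' @param library library label.
#' @param strand_mode `"reverse"`, `"forward"` (read strand = transcript
#'   strand), or `"unstranded"` (all depth assigned to forward).
#' @return single-library [tile_depth_matrix()].
#' @export
read_depth_sam <- function(path, axis, library = basename(path),
                           strand_mode = c("reverse", "forward",
                                           "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  aln <- GenomicAlignments::readGAlignments(bam)
  cov_for_strand <- function(read_strand) {
    sel <- aln[S4Vectors::decode(GenomicAlignments::strand(aln)) ==
                 read_strand]
    cov <- GenomicAlignments::coverage(sel)
    if (!axis$sequence_id %in% names(cov)) return(numeric(axis$length))
    v <- as.numeric(cov[[axis$sequence_id]])
    length(v) <- axis$length
    v[is.na(v)] <- 0
    v
  }
  plus <- cov_for_strand("+"); minus <- cov_for_strand("-")
  tx <- switch(strand_mode,
               reverse    = list(forward = minus, reverse = plus),
               forward    = list(forward = plus, reverse = minus),
               unstranded = list(forward = plus + minus,
                                 reverse = numeric(axis$length)))
  rec <- data.frame(
    position = rep(seq_len(axis$length), 2L),
    strand = rep(c("forward", "reverse"), each = axis$length),
    depth = c(tx$forward, tx$reverse))
  rec <- rec[rec$depth > 0, , drop = FALSE]
  compute_tile_depths(rec, axis, library)
}

#' Write / read the collated tile depth CSV
#'
#' The on-disk interchange format between tiling and normalisation: columns
#' `sequence_id, strand, tile_start` (0-based) then one column per library.
#' Values are written with enough digits that `read_tile_csv(write_tile_csv(m))`
#' reproduces `m` exactly. Rows out of coordinate order on read are sorted
#' back to genome order. gzip paths are handled transparently.
#'
#' @param matrix a [tile_depth_matrix()].
#' @param path output CSV path.
#' @return `write_tile_csv` returns `path` invisibly; `read_tile_csv`
#'   returns a `TileDepthMatrix`.
#' @export
write_tile_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "TileDepthMatrix"))
  ax <- matrix$axis
  starts <- (seq_len(ax$n_tiles) - 1L) * ax$tile_size
  head <- data.frame(
    sequence_id = ax$sequence_id,
    strand = rep(c("forward", "reverse"), each = ax$n_tiles),
    tile_start = c(starts, starts))
  dep <- rbind(matrix$depth$forward, matrix$depth$reverse)
  dep_chr <- as.data.frame(apply(dep, 2, fmt_num), optional = TRUE)
  names(dep_chr) <- matrix$libraries
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(cbind(head, dep_chr), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_tile_csv
#' @param genome_length true axis length; when `NULL` it is inferred as
#'   `max(tile_start) + tile_size` (an exact multiple; supply the length to
#'   preserve a short final tile).
#' @export
read_tile_csv <- function(path, genome_length = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("sequence_id", "strand", "tile_start")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("tile CSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  libs <- setdiff(names(tab), need)
  if (!length(libs)) stopf("tile CSV has no library columns")
  for (lb in libs) {
    v <- tab[[lb]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stopf("non-numeric depth in column '%s' at data row %d", lb, bad)
    }
    if (any(v < 0)) stopf("negative depth in column '%s'", lb)
  }
  tab <- tab[order(tab$sequence_id, tab$strand, tab$tile_start), ,
             drop = FALSE]
  starts <- sort(unique(tab$tile_start))
  ts <- if (length(starts) > 1L) as.integer(min(diff(starts))) else
    as.integer(max(starts) + 1L)
  glen <- if (is.null(genome_length)) as.integer(max(starts) + ts) else
    as.integer(genome_length)
  ax <- genome_axis(tab$sequence_id[1], glen, ts)
  get_strand <- function(s) {
    sub <- tab[tab$strand == s, , drop = FALSE]
    if (nrow(sub) != ax$n_tiles)
      stopf("strand %s has %d tiles, expected %d", s, nrow(sub), ax$n_tiles)
    as.matrix(sub[, libs, drop = FALSE])
  }
  fwd <- get_strand("forward"); rev <- get_strand("reverse")
  rownames(fwd) <- rownames(rev) <- NULL
  tile_depth_matrix(ax, fwd, rev)
}
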