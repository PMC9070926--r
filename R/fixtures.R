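## Deterministic synthetic-data generators: random genomes with planted
## genes (RBS at the canonical 7-base spacing, optional translationally
## coupled pairs at offset -4), stranded multi-library tile depths with
## known scale factors and a controllable differentially expressed tile
## fraction, and homopolymer single-base deletion errors with a matching
## mpileup. All randomness flows from one integer seed; depth and pileup
## structures, not reads, are the simulation unit because they are what
## the toolkit consumes.

#' Synthesise a genome with planted genes
#'
#' Plants `n_genes` non-overlapping genes (ATG start, stop-free body, TAA
#' stop) on random strands, each preceded by the RBS consensus `TAAGGAG`
#' ending exactly 7 bases upstream of the start. With
#' `coupled_pairs > 0`, that many extra genes are appended immediately
#' after an existing gene's stop at offset -4 (their start's last two
#' bases overlap the stop), the canonical translational-coupling
#' arrangement.
#'
#' @param genome_length total length in bases (default 20000).
#' @param n_genes planted gene count (default 10).
#' @param gene_length_range nt range for gene bodies (rounded to codons).
#' @param gc_fraction background GC content (default 0.60, a
#'   *Pseudomonas*-like value).
#' @param coupled_pairs number of coupled downstream partners.
#' @param seed RNG seed.
#' @return list: `sequence` (string), `genes` (data.frame: `id`, `strand`,
#'   `start`, `end` 0-based half-open genome span of start..stop,
#'   `local_start`, `local_stop` strand-local 1-based, `coupled`).
#' @export
synth_genome <- function(genome_length = 20000L, n_genes = 10L,
                         gene_length_range = c(300L, 900L),
                         gc_fraction = 0.60, coupled_pairs = 0L,
                         seed = 1L) {
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  base <- sample(names(p), genome_length, replace = TRUE, prob = p)
  seq <- paste(base, collapse = "")

  total <- n_genes + coupled_pairs
  lens <- 3L * round(stats::runif(total, gene_length_range[1],
                                  gene_length_range[2]) / 3)
  ## one genome-space slot per primary gene (reverse-strand genes live in
  ## the same genome interval; their strand-local coordinates are mirrored)
  margin <- 60L
  rbs_len <- 14L
  slot_w <- genome_length %/% n_genes
  reserve <- rbs_len + max(lens) +
    (if (coupled_pairs > 0L) max(lens) else 0L)
  if (slot_w < reserve + 2L * margin)
    stopf("cannot pack %d genes of up to %d nt into %d bp", total,
          max(lens), genome_length)
  genes <- list()
  for (i in seq_len(n_genes)) {
    strand <- sample(c("forward", "reverse"), 1)
    partner_room <- if (i <= coupled_pairs) max(lens) else 0L
    need <- rbs_len + lens[i] + partner_room
    off <- margin + sample.int(slot_w - need - 2L * margin, 1)
    g0 <- (i - 1L) * slot_w + off            # cassette genome start, 0-based
    ## strand-local 1-based position of the cassette's first base
    cas_lo <- if (strand == "forward") g0 + 1L else
      genome_length - (g0 + need) + 1L
    local_start <- cas_lo + rbs_len   # partner room sits 3' of the gene
    body_cod <- sample(NON_STOP_CODONS, lens[i] / 3 - 2L, replace = TRUE)
    gene_seq <- paste0("ATG", paste(body_cod, collapse = ""), "TAA")
    rbs_block <- paste0("TAAGGAG",
                        paste(sample(c("A", "C", "G", "T"), 7,
                                     replace = TRUE), collapse = ""))
    seq <- plant(seq, paste0(rbs_block, gene_seq), cas_lo, strand,
                 genome_length)
    genes[[i]] <- data.frame(
      id = sprintf("gene%02d", i), strand = strand,
      local_start = local_start,
      local_stop = local_start + nchar(gene_seq) - 3L,
      length = nchar(gene_seq), coupled = FALSE,
      stringsAsFactors = FALSE)
  }
  ## coupled partners: start at offset -4 from an upstream gene's stop end
  for (j in seq_len(coupled_pairs)) {
    up <- genes[[j]]
    stop_end <- up$local_stop + 2L
    local_start <- stop_end + 1L - 4L          # offset -4
    body_cod <- sample(NON_STOP_CODONS, lens[n_genes + j] / 3 - 2L,
                       replace = TRUE)
    ## the partner's 4th base is the upstream stop's last base (TAA ->
    ## TGA under the ATGA overlap), so the first body codon must begin A
    a_codons <- grep("^A", NON_STOP_CODONS, value = TRUE)
    body_cod[1] <- sample(a_codons, 1)
    gene_seq <- paste0("ATG", paste(body_cod, collapse = ""), "TAA")
    seq <- plant(seq, gene_seq, local_start, up$strand, genome_length)
    genes[[n_genes + j]] <- data.frame(
      id = sprintf("gene%02dc", j), strand = up$strand,
      local_start = local_start,
      local_stop = local_start + nchar(gene_seq) - 3L,
      length = nchar(gene_seq), coupled = TRUE, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  span <- t(mapply(function(s, a, b) local_span(s, genome_length, a, b),
                   genes$strand, genes$local_start, genes$local_stop + 2L))
  genes$start <- as.integer(span[, 1]); genes$end <- as.integer(span[, 2])
  list(sequence = seq, genes = genes)
}

## write a strand-local cassette into the genome string
plant <- function(seq, cassette, local_start, strand, L) {
  if (strand == "forward") {
    a <- local_start
    substr(seq, a, a + nchar(cassette) - 1L) <- cassette
  } else {
    rc <- revcomp(cassette)
    b <- L - local_start + 1L            # genome pos of cassette start base
    a <- b - nchar(cassette) + 1L
    substr(seq, a, b) <- rc
  }
  seq
}

#' Write planted genes as GFF3
#' @param genes `genes` data.frame from [synth_genome()].
#' @param path output path.
#' @param sequence_id sequence name.
#' @export
write_genes_gff <- function(genes, path, sequence_id = "synthetic") {
  gr <- GenomicRanges::GRanges(
    seqnames = sequence_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = ifelse(genes$strand == "reverse", "-", "+"))
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Synthesise stranded multi-library tile depths with known truth
#'
#' Tile depth for library `l` is
#' `scale_factors[l] * (background + gene signal) * lognormal noise`,
#' with the gene signal of a tile the sum over planted genes covering it
#' of that gene's per-library expression. A `de_fraction` of the
#' gene-covered tiles is additionally multiplied by `de_fold` in the
#' first half of the libraries (the differential-expression
#' contamination the normaliser must resist).
#'
#' @param axis a [genome_axis()].
#' @param genes data.frame with `strand`, `start`, `end` (0-based
#'   half-open), e.g. from [synth_genome()].
#' @param expression matrix, genes x libraries: mean expression depth per
#'   tile for each library (before scaling); column names are the library
#'   labels.
#' @param scale_factors named per-library true scale factors.
#' @param de_fraction fraction of gene-covered tiles made differential.
#' @param de_fold fold change applied to DE tiles.
#' @param noise_sigma lognormal sigma of multiplicative noise (0 = none).
#' @param background_depth mean background depth per tile, both strands.
#' @param seed RNG seed.
#' @return list: `matrix` (a [tile_depth_matrix()]), `truth` (list:
#'   `scale_factors`, `de_tiles` data.frame, `expression`).
#' @export
synth_depth_libraries <- function(axis, genes, expression, scale_factors,
                                  de_fraction = 0.10, de_fold = 5,
                                  noise_sigma = 0.10,
                                  background_depth = 20, seed = 1L) {
  set.seed(seed)
  libs <- colnames(expression)
  stopifnot(identical(sort(libs), sort(names(scale_factors))),
            nrow(expression) == nrow(genes))
  nt <- axis$n_tiles
  signal <- list(forward = matrix(0, nt, length(libs),
                                  dimnames = list(NULL, libs)),
                 reverse = matrix(0, nt, length(libs),
                                  dimnames = list(NULL, libs)))
  for (g in seq_len(nrow(genes))) {
    tiles <- seq.int(genes$start[g] %/% axis$tile_size,
                     (genes$end[g] - 1L) %/% axis$tile_size) + 1L
    signal[[genes$strand[g]]][tiles, ] <-
      signal[[genes$strand[g]]][tiles, ] +
      rep(expression[g, ], each = length(tiles))
  }
  ## DE contamination: tiles with signal, first half of the libraries
  cov_tiles <- which(rowSums(signal$forward) + rowSums(signal$reverse) > 0)
  n_de <- floor(length(cov_tiles) * de_fraction)
  de_tiles <- sort(sample(cov_tiles, n_de))
  de_libs <- libs[seq_len(length(libs) %/% 2)]
  build <- function(strand) {
    m <- signal[[strand]] + background_depth
    if (n_de) {
      de_rows <- de_tiles[de_tiles %in%
                            which(rowSums(signal[[strand]]) > 0)]
      m[de_rows, de_libs] <- m[de_rows, de_libs] * de_fold
    }
    m <- sweep(m, 2, scale_factors[libs], `*`)
    if (noise_sigma > 0)
      m <- m * matrix(stats::rlnorm(length(m), -noise_sigma^2 / 2,
                                    noise_sigma), nrow(m))
    m
  }
  mat <- tile_depth_matrix(axis, build("forward"), build("reverse"))
  list(matrix = mat,
       truth = list(scale_factors = scale_factors,
                    de_tiles = data.frame(tile = de_tiles),
                    de_libraries = de_libs,
                    expression = expression))
}

#' Smooth unimodal time-course expression profiles
#'
#' One Gaussian-bump profile per gene over ordered time points: peak times
#' and widths are drawn per gene, amplitudes lognormal. Emulates genes
#' switching on at different culture phases.
#'
#' @param n_genes,n_timepoints dimensions.
#' @param amplitude_meanlog,amplitude_sdlog lognormal amplitude (depth
#'   units).
#' @param seed RNG seed.
#' @return matrix genes x timepoints.
#' @export
synth_profiles <- function(n_genes, n_timepoints = 7L,
                           amplitude_meanlog = log(200),
                           amplitude_sdlog = 0.8, seed = 1L) {
  set.seed(seed)
  t <- seq_len(n_timepoints)
  amp <- stats::rlnorm(n_genes, amplitude_meanlog, amplitude_sdlog)
  peak <- stats::runif(n_genes, 1, n_timepoints)
  width <- stats::runif(n_genes, 0.8, 2.5)
  out <- t(vapply(seq_len(n_genes), function(g) {
    amp[g] * exp(-(t - peak[g])^2 / (2 * width[g]^2))
  }, numeric(n_timepoints)))
  colnames(out) <- sprintf("t%d", t)
  out
}

#' Implant homopolymer deletions (and one substitution) into a genome
#'
#' Deletes one base from each of `n_deletions` distinct homopolymer runs
#' of at least `min_run` bases — the residual error class of long-read
#' assemblies — and optionally substitutes one base outside any chosen
#' run. Event coordinates are reported both against the original genome
#' (`truth`) and against the mutated genome (`events`), the latter being
#' exactly what an aligner of error-free reads from the original genome
#' observes against the mutated reference.
#'
#' @param genome sequence string.
#' @param n_deletions number of single-base deletions (default 50).
#' @param substitution add one substitution (default TRUE).
#' @param min_run minimum homopolymer run length used (default 4).
#' @param seed RNG seed.
#' @return list: `mutated` (string), `truth` (data.frame in original
#'   coordinates), `events` (data.frame in mutated coordinates: `position`,
#'   `kind` in `insertion_after`/`substitution`, `base`).
#' @export
implant_errors <- function(genome, n_deletions = 50L, substitution = TRUE,
                           min_run = 4L, seed = 1L) {
  set.seed(seed)
  ch <- strsplit(genome, "", fixed = TRUE)[[1]]
  r <- rle(ch)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  eligible <- which(r$lengths >= min_run)
  if (length(eligible) < n_deletions)
    stopf("only %d homopolymer runs of >= %d bp; need %d",
          length(eligible), min_run, n_deletions)
  runs <- sort(sample(eligible, n_deletions))
  del_pos <- run_start[runs]                  # canonical leftmost base
  truth <- data.frame(position = del_pos,
                      kind = rep("deletion_1bp", length(del_pos)),
                      base = r$values[runs], stringsAsFactors = FALSE)
  sub_row <- NULL
  if (substitution) {
    in_run <- unlist(mapply(seq, run_start[runs], run_end[runs]))
    ok <- setdiff(seq_along(ch), in_run)
    ## avoid adjacency to a chosen run so events stay independent
    ok <- setdiff(ok, c(del_pos - 1L, run_end[runs] + 1L))
    sp <- sample(ok, 1)
    old <- ch[sp]
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    sub_row <- data.frame(position = sp, kind = "substitution",
                          base = new, ref = old, stringsAsFactors = FALSE)
  }
  ## apply deletions right-to-left; track mutated coordinates
  mut <- ch
  for (p in rev(del_pos)) mut <- mut[-p]
  shift_at <- function(p) sum(del_pos < p)    # bases removed before p
  events <- data.frame(
    position = del_pos - 1L -
      vapply(del_pos, shift_at, integer(1)),
    kind = rep("insertion_after", length(del_pos)),
    base = r$values[runs], stringsAsFactors = FALSE)
  if (!is.null(sub_row)) {
    mp <- sub_row$position - shift_at(sub_row$position)
    mut[mp] <- sub_row$base
    events <- rbind(events,
                    data.frame(position = mp, kind = "substitution",
                               base = strsplit(genome, "")[[1]][sub_row$position],
                               stringsAsFactors = FALSE))
    truth <- rbind(truth, sub_row[, c("position", "kind", "base")])
  }
  list(mutated = paste(mut, collapse = ""), truth = truth,
       events = events[order(events$position), ])
}

#' Build mpileup text from a reference and a set of observed events
#'
#' Writes one column per reference position at uniform depth: pure
#' matches everywhere except the event columns, where every read carries
#' the insertion (`.+1B`) or the substituted base. Read-start (`^]`) and
#' read-end (`$`) markers are included at the fixture edges so parsers
#' must handle them.
#'
#' @param reference sequence the reads are aligned against.
#' @param events data.frame (`position`, `kind`, `base`) in reference
#'   coordinates; `kind` in `insertion_after`, `substitution`.
#' @param depth uniform read depth (default 30).
#' @param sequence_id CHROM column value.
#' @return character vector of mpileup lines.
#' @export
pileup_from_events <- function(reference, events, depth = 30L,
                               sequence_id = "seq") {
  L <- nchar(reference)
  ref <- strsplit(reference, "", fixed = TRUE)[[1]]
  bases <- rep(strrep(".", depth), L)
  if (nrow(events)) {
    ins <- events[events$kind == "insertion_after", , drop = FALSE]
    bases[ins$position] <- strrep(paste0(".+1", ins$base), depth)
    sub <- events[events$kind == "substitution", , drop = FALSE]
    ## reads observe the true (pre-mutation) base, mixed case
    for (i in seq_len(nrow(sub))) {
      b <- sub$base[i]
      bases[sub$position[i]] <-
        paste(rep(c(b, tolower(b)), length.out = depth), collapse = "")
    }
  }
  bases[1] <- paste0("^]", bases[1])
  bases[L] <- paste0(bases[L], "$")
  sprintf("%s\t%d\t%s\t%d\t%s\t%s", sequence_id, seq_len(L), ref, depth,
          bases, strrep("I", depth))
}
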