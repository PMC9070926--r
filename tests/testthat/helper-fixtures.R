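# shared helpers: small in-code fixtures and independent oracles

# build a TileDepthMatrix from forward/reverse tile x library values
make_tdm <- function(fwd, rev = fwd * 0, tile_size = 100L, seq_id = "t",
                     libs = NULL) {
  fwd <- as.matrix(fwd); rev <- as.matrix(rev)
  if (is.null(libs)) libs <- paste0("L", seq_len(ncol(fwd)))
  colnames(fwd) <- colnames(rev) <- libs
  ax <- genome_axis(seq_id, nrow(fwd) * tile_size, tile_size)
  tile_depth_matrix(ax, fwd, rev)
}

# independent six-frame ORF oracle: plain per-codon loop, no shared code
# with enumerate_orfs beyond the alphabet
oracle_orfs <- function(seq, min_length) {
  seq <- toupper(seq)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "GTG", "TTG")
  out <- list()
  for (strand in c("forward", "reverse")) {
    s <- if (strand == "forward") seq else rc
    L <- nchar(s)
    for (f in 0:2) {
      first_start <- NA
      n_starts <- 0L
      p <- f + 1L
      while (p + 2L <= L) {
        cod <- substr(s, p, p + 2L)
        if (cod %in% stops) {
          if (!is.na(first_start) && (p + 2L - first_start + 1L) >=
              min_length) {
            out[[length(out) + 1L]] <-
              c(strand, first_start, p, n_starts)
          }
          first_start <- NA; n_starts <- 0L
        } else if (cod %in% starts) {
          if (is.na(first_start)) first_start <- p
          n_starts <- n_starts + 1L
        }
        p <- p + 3L
      }
    }
  }
  keys <- vapply(out, paste, character(1), collapse = ":")
  sort(keys)
}

orf_keys <- function(orf_set) {
  o <- orf_set$orfs
  sort(sprintf("%s:%d:%d:%d", o$strand, o$current_start, o$local_stop,
               o$n_starts))
}

# exhaustive double-argmax RBH oracle over full score matrices
oracle_rbh <- function(score_qr, score_rq) {
  pairs <- character()
  for (q in rownames(score_qr)) {
    r <- colnames(score_qr)[which.max(score_qr[q, ])]
    q_back <- rownames(score_qr)[which.max(score_rq[r, ])]
    if (identical(q_back, q)) pairs <- c(pairs, paste(q, r))
  }
  sort(pairs)
}

# second, independent minimal mpileup base-string parser (regex based)
oracle_base_counts <- function(bs) {
  bs <- gsub("\\^.", "", bs)
  bs <- gsub("\\$", "", bs)
  counts <- integer(0)
  bump <- function(counts, key, n = 1L) {
    counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0L) + n
    counts
  }
  m <- gregexpr("[+-][0-9]+", bs)[[1]]
  while (m[1] != -1) {
    len <- as.integer(regmatches(bs, gregexpr("[0-9]+", bs))[[1]][1])
    tok <- substr(bs, m[1], m[1] + attr(m, "match.length")[1] - 1L + len)
    key <- paste0(substr(tok, 1, 1),
                  toupper(substr(tok, nchar(tok) - len + 1L, nchar(tok))))
    counts <- bump(counts, key)
    bs <- sub(tok, "", bs, fixed = TRUE)
    m <- gregexpr("[+-][0-9]+", bs)[[1]]
  }
  ch <- strsplit(bs, "")[[1]]
  for (c0 in ch) {
    if (c0 %in% c(".", ",")) counts <- bump(counts, "ref")
    else if (toupper(c0) %in% c("A", "C", "G", "T", "N"))
      counts <- bump(counts, toupper(c0))
  }
  counts
}

# geometric-mean-1 rescale of true scale factors into expected factors
expected_factors <- function(scale_factors) {
  f <- 1 / scale_factors
  f / exp(mean(log(f)))
}
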