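## Rendering of expression colours as genome-browser features. Artemis
## renders misc_feature annotations carrying /colour=R G B qualifiers in
## two strips along the sequence, one per orientation, so a whole
## time-course collapses to a colour bar per strand. Internal feature
## coordinates are 0-based half-open; EMBL locations are written 1-based
## inclusive (reverse strand as complement(a..b)).

#' Build a coloured feature table
#'
#' @param kind one of `"tile"`, `"cds"`, `"rna"` (recycled).
#' @param strand `"forward"`/`"reverse"` (recycled).
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param rgb integer matrix (n x 3) or vector of 3, channels in 0..255.
#' @param label optional feature labels.
#' @return data.frame of class `ColouredFeatures`.
#' @export
coloured_features <- function(kind, strand, start, end, rgb,
                              label = NA_character_) {
  rgb <- matrix(as.integer(rgb), ncol = 3)
  n <- max(length(start), nrow(rgb))
  df <- data.frame(kind = rep_len(kind, n),
                   strand = norm_strand(rep_len(strand, n)),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   R = rep_len(rgb[, 1], n), G = rep_len(rgb[, 2], n),
                   B = rep_len(rgb[, 3], n),
                   label = rep_len(label, n),
                   stringsAsFactors = FALSE)
  if (!all(df$kind %in% names(FEATURE_KINDS)))
    stopf("kind must be one of: %s", paste(names(FEATURE_KINDS),
                                           collapse = ", "))
  if (any(df$start >= df$end)) stopf("feature start must be < end")
  if (any(df$R < 0 | df$R > 255 | df$G < 0 | df$G > 255 |
          df$B < 0 | df$B > 255))
    stopf("colour channels must lie in [0, 255]")
  class(df) <- c("ColouredFeatures", "data.frame")
  df
}

#' One coloured misc_feature per tile per strand
#'
#' @param matrix a [tile_depth_matrix()] giving the axis.
#' @param colours data.frame from [encode_matrix()] (one row per
#'   (strand, tile)).
#' @param merge merge runs of adjacent same-colour tiles into single
#'   features (off by default: bit-faithful to the per-tile model).
#' @return a [coloured_features()] table.
#' @export
render_tiles <- function(matrix, colours, merge = FALSE) {
  stopifnot(inherits(matrix, "TileDepthMatrix"))
  ax <- matrix$axis
  if (nrow(colours) != 2L * ax$n_tiles)
    stopf("expected %d colour rows, found %d", 2L * ax$n_tiles,
          nrow(colours))
  out <- lapply(c("forward", "reverse"), function(s) {
    cc <- colours[colours$strand == s, , drop = FALSE]
    cc <- cc[order(cc$tile), , drop = FALSE]
    start <- (cc$tile - 1L) * ax$tile_size
    end <- pmin(cc$tile * ax$tile_size, ax$length)
    if (merge) {
      key <- paste(cc$R, cc$G, cc$B)
      run <- cumsum(c(TRUE, key[-1] != key[-length(key)] |
                        start[-1] != end[-length(start)]))
      start <- tapply(start, run, min)
      end <- tapply(end, run, max)
      first <- !duplicated(run)
      cc <- cc[first, , drop = FALSE]
    }
    coloured_features("tile", s, start, end,
                      cbind(cc$R, cc$G, cc$B))
  })
  out <- rbind(out[[1]], out[[2]])
  class(out) <- c("ColouredFeatures", "data.frame")
  out
}

#' Colour annotated genes by their averaged tile profile
#'
#' Each CDS (or RNA feature) receives the colour of the profile obtained
#' by averaging, per sample point, the same-strand tiles its span covers;
#' RNA features carry `kind = "rna"` so renderers can draw them in-line
#' with CDS boxes but without a border.
#'
#' @param annotation data.frame with columns `id`, `kind` (`"cds"`/
#'   `"rna"`), `strand`, `start`, `end` (0-based half-open).
#' @param matrix normalised, replicate-merged [tile_depth_matrix()].
#' @param params an [encoding_params()]; default derived from `matrix`.
#' @return a [coloured_features()] table with one row per annotation, plus
#'   columns `H`, `S`, `L` and `id`.
#' @export
render_genes <- function(annotation, matrix, params = NULL) {
  stopifnot(inherits(matrix, "TileDepthMatrix"))
  ax <- matrix$axis
  if (is.null(params)) {
    params <- encoding_params(length(matrix$libraries),
                              background = estimate_background(matrix),
                              upper_clamp = upper_clamp_value(matrix))
  }
  if (any(annotation$start < 0L | annotation$end > ax$length))
    stopf("feature outside genome bounds")
  strand <- norm_strand(annotation$strand)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    tiles <- seq.int(annotation$start[i] %/% ax$tile_size,
                     (annotation$end[i] - 1L) %/% ax$tile_size) + 1L
    profile <- colMeans(matrix$depth[[strand[i]]][tiles, , drop = FALSE])
    hsl <- encode_profile(profile, params)
    c(hsl$hue, hsl$saturation, hsl$lightness, hsl_to_rgb(hsl))
  })
  rows <- do.call(rbind, rows)
  out <- coloured_features(annotation$kind, strand, annotation$start,
                           annotation$end, rows[, 4:6],
                           label = annotation$id)
  out$id <- annotation$id
  out$H <- rows[, 1]; out$S <- rows[, 2]; out$L <- rows[, 3]
  out
}

embl_location <- function(strand, start, end) {
  loc <- sprintf("%d..%d", start + 1L, end)      # 1-based inclusive
  strand <- rep_len(strand, length(loc))
  ifelse(strand == "reverse", sprintf("complement(%s)", loc), loc)
}

#' Write features as an Artemis-readable EMBL feature table
#'
#' Emits the exact `/colour=R G B` qualifier dialect Artemis renders.
#' Features are sorted by coordinate before writing.
#'
#' @param features a [coloured_features()] table.
#' @param path output path.
#' @param sequence_id,length identify the entry (ID/SQ header framing).
#' @return `path`, invisibly.
#' @export
write_embl_colour <- function(features, path, sequence_id = "seq",
                              length = max(features$end)) {
  f <- features[order(features$start, features$end), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ID   %s; SV 1; linear; genomic DNA; STD; PRO; %d BP.",
            sequence_id, as.integer(length)),
    "FH   Key             Location/Qualifiers",
    "FH"), con)
  key <- FEATURE_KINDS[f$kind]
  loc <- embl_location(f$strand, f$start, f$end)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("FT   %-16s%s", key[i], loc[i]), con)
    writeLines(sprintf("FT                   /colour=%d %d %d",
                       f$R[i], f$G[i], f$B[i]), con)
    if (!is.na(f$label[i]))
      writeLines(sprintf("FT                   /label=%s", f$label[i]), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read back a colour-qualified EMBL feature table
#'
#' Strict re-reader for the dialect emitted by [write_embl_colour()];
#' serves as the round-trip check and as a lenient Artemis-style parser
#' for the feature lines.
#'
#' @param path EMBL file path.
#' @return a [coloured_features()] table.
#' @export
read_embl_colour <- function(path) {
  lines <- readLines(path)
  ft <- grep("^FT   \\S", lines)
  kinds <- stats::setNames(names(FEATURE_KINDS), FEATURE_KINDS)
  rec <- list()
  for (i in ft) {
    m <- regmatches(lines[i],
                    regexec("^FT   (\\S+)\\s+(complement\\()?(\\d+)\\.\\.(\\d+)",
                            lines[i]))[[1]]
    if (length(m) == 0L) stopf("unparseable FT line: %s", lines[i])
    j <- i + 1L
    colour <- NULL; label <- NA_character_
    while (j <= length(lines) && grepl("^FT {19}/", lines[j])) {
      q <- sub("^FT {19}/", "", lines[j])
      if (startsWith(q, "colour="))
        colour <- as.integer(strsplit(sub("colour=", "", q), " ")[[1]])
      if (startsWith(q, "label=")) label <- sub("label=", "", q)
      j <- j + 1L
    }
    if (is.null(colour)) stopf("feature without /colour at line %d", i)
    rec[[length(rec) + 1L]] <- data.frame(
      kind = unname(kinds[m[2]]),
      strand = if (nzchar(m[3])) "reverse" else "forward",
      start = as.integer(m[4]) - 1L, end = as.integer(m[5]),
      R = colour[1], G = colour[2], B = colour[3], label = label,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rec)
  class(out) <- c("ColouredFeatures", "data.frame")
  out
}

#' Write / read features as GFF3 with a colour attribute
#'
#' Uses `rtracklayer` for the GFF3 serialisation; the colour travels as a
#' `colour=R G B` attribute and the feature kind as the GFF type.
#'
#' @param features a [coloured_features()] table.
#' @param path output path.
#' @param sequence_id sequence name for column 1.
#' @return `path` invisibly / a [coloured_features()] table.
#' @export
write_gff_colour <- function(features, path, sequence_id = "seq") {
  f <- features[order(features$start, features$end), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = sequence_id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = ifelse(f$strand == "reverse", "-", "+"))
  S4Vectors::mcols(gr)$type <- unname(FEATURE_KINDS[f$kind])
  S4Vectors::mcols(gr)$phase <- ifelse(f$kind == "cds", 0L, NA_integer_)
  S4Vectors::mcols(gr)$colour <- sprintf("%d %d %d", f$R, f$G, f$B)
  if (any(!is.na(f$label))) S4Vectors::mcols(gr)$Name <- f$label
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff_colour
#' @export
read_gff_colour <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  kinds <- stats::setNames(names(FEATURE_KINDS), FEATURE_KINDS)
  colour <- do.call(rbind, lapply(strsplit(S4Vectors::mcols(gr)$colour, " "),
                                  as.integer))
  md <- S4Vectors::mcols(gr)
  label <- if ("Name" %in% names(md)) as.character(md$Name) else
    NA_character_
  coloured_features(
    unname(kinds[as.character(md$type)]),
    ifelse(as.character(GenomicRanges::strand(gr)) == "-", "reverse",
           "forward"),
    GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
    colour, label = label)
}

#' Whole-genome overview raster
#'
#' Deterministic PNG: the genome is wrapped over rows; each row shows the
#' two tile strips either side of the DNA line, CDS boxes offset from the
#' line and RNA boxes adjacent to it, plus a key panel relating lightness
#' to intensity, saturation to range ratio and hue to peak time.
#'
#' @param matrix a [tile_depth_matrix()] (axis source).
#' @param colours data.frame from [encode_matrix()].
#' @param annotation optional [render_genes()] output to draw as boxes.
#' @param path output PNG path.
#' @param row_bp bases per row (layout, not contract).
#' @param width,height image size in pixels.
#' @param params an [encoding_params()] used for the key panel; optional.
#' @return `path`, invisibly.
#' @export
render_overview <- function(matrix, colours, annotation = NULL, path,
                            row_bp = NULL, width = 1000, height = 700,
                            params = NULL) {
  stopifnot(inherits(matrix, "TileDepthMatrix"))
  ax <- matrix$axis
  if (is.null(row_bp)) row_bp <- ceiling(ax$length / 8 / ax$tile_size) *
      ax$tile_size
  n_rows <- ceiling(ax$length / row_bp)
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 1, 1))
  graphics::plot(NULL, xlim = c(0, row_bp), ylim = c(0, n_rows + 1.2),
                 axes = FALSE, xlab = "", ylab = "", xaxs = "i",
                 yaxs = "i")
  for (s in c("forward", "reverse")) {
    cc <- colours[colours$strand == s, , drop = FALSE]
    x0 <- (cc$tile - 1) * ax$tile_size
    row <- x0 %/% row_bp
    x_in <- x0 %% row_bp
    y0 <- n_rows - row - if (s == "forward") 0.32 else 0.68
    graphics::rect(x_in, y0, x_in + ax$tile_size, y0 + 0.22,
                   col = grDevices::rgb(cc$R, cc$G, cc$B, max = 255),
                   border = NA)
  }
  yline <- n_rows - (seq_len(n_rows) - 1) - 0.5
  graphics::segments(0, yline, row_bp, yline, col = "black")
  if (!is.null(annotation) && nrow(annotation)) {
    for (i in seq_len(nrow(annotation))) {
      a <- annotation[i, ]
      row <- a$start %/% row_bp
      x0 <- a$start %% row_bp
      x1 <- min(x0 + (a$end - a$start), row_bp)
      base <- n_rows - row - 0.5
      off <- if (a$kind == "rna") 0.03 else 0.12
      y0 <- if (a$strand == "forward") base + off else base - off - 0.08
      graphics::rect(x0, y0, x1, y0 + 0.08,
                     col = grDevices::rgb(a$R, a$G, a$B, max = 255),
                     border = if (a$kind == "rna") NA else "black")
    }
  }
  draw_key_panel(params, y = n_rows + 0.3)
  invisible(path)
}

## key: lightness vs intensity (x), saturation vs range ratio (y), hue bar
draw_key_panel <- function(params, y) {
  if (is.null(params)) return(invisible(NULL))
  usr <- graphics::par("usr")
  w <- usr[2] - usr[1]
  nx <- 24; ny <- 6
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    l <- 1 - (1 - params$lightness_floor) * (ix - 1) / (nx - 1)
    s <- ((iy - 1) / (ny - 1))^2
    rgb <- hsl_to_rgb(list(hue = 0, saturation = s, lightness = l))
    graphics::rect(usr[1] + (ix - 1) / nx * w * 0.4,
                   y + (iy - 1) / ny * 0.6,
                   usr[1] + ix / nx * w * 0.4, y + iy / ny * 0.6,
                   col = grDevices::rgb(rgb[1], rgb[2], rgb[3], max = 255),
                   border = NA)
  }
  for (ih in seq_len(nx)) {
    h <- (ih - 1) / (nx - 1) * params$hue_span_degrees
    rgb <- hsl_to_rgb(list(hue = h, saturation = 1,
                           lightness = params$lightness_floor))
    graphics::rect(usr[1] + w * 0.5 + (ih - 1) / nx * w * 0.4, y,
                   usr[1] + w * 0.5 + ih / nx * w * 0.4, y + 0.6,
                   col = grDevices::rgb(rgb[1], rgb[2], rgb[3], max = 255),
                   border = NA)
  }
  invisible(NULL)
}
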