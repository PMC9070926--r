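small_colours <- function(m) {
  p <- encoding_params(length(m$libraries), background = 0.5,
                       upper_clamp = 1000)
  encode_matrix(m, p)
}

test_that("render_tiles emits one feature per tile with correct spans", {
  m <- make_tdm(matrix(1:6, 3, 2) * 50, matrix(1, 3, 2))
  cc <- small_colours(m)
  ft <- render_tiles(m, cc)
  expect_equal(nrow(ft), 6L)
  fwd <- ft[ft$strand == "forward", ]
  expect_equal(fwd$start, c(0L, 100L, 200L))
  expect_equal(fwd$end, c(100L, 200L, 300L))
  expect_error(render_tiles(m, cc[1:3, ]), "colour rows")
})

test_that("adjacent same-colour tiles merge only when asked", {
  m <- make_tdm(cbind(c(5, 5, 500), c(5, 5, 500)), matrix(1, 3, 2))
  cc <- small_colours(m)
  plain <- render_tiles(m, cc)
  merged <- render_tiles(m, cc, merge = TRUE)
  expect_equal(nrow(plain), 6L)
  # tiles 1-2 share a colour (identical values), tile 3 differs;
  # reverse strand is uniform and merges to one feature
  mf <- merged[merged$strand == "forward", ]
  expect_equal(nrow(mf), 2L)
  expect_equal(mf$start[1], 0L)
  expect_equal(mf$end[1], 200L)
  expect_equal(nrow(merged[merged$strand == "reverse", ]), 1L)
})

test_that("render_genes averages same-strand tile profiles", {
  fwd <- rbind(c(10, 80, 10), c(10, 80, 10), c(60, 5, 5))
  m <- make_tdm(fwd, matrix(1, 3, 3))
  p <- encoding_params(3, background = 0.5, upper_clamp = 500)
  ann <- data.frame(id = c("one", "two"), kind = "cds",
                    strand = "forward",
                    start = c(0L, 50L), end = c(100L, 250L))
  g <- render_genes(ann, m, p)
  # single-tile CDS equals that tile's colour
  cc <- encode_matrix(m, p)
  t1 <- cc[cc$strand == "forward" & cc$tile == 1, ]
  expect_equal(g$H[1], t1$H)
  expect_equal(g$L[1], t1$L)
  # multi-tile CDS equals the hand-averaged profile
  avg <- colMeans(fwd)
  want <- encode_profile(avg, p)
  expect_equal(g$H[2], want$hue)
  expect_equal(g$S[2], want$saturation)
  expect_equal(g$L[2], want$lightness)
  # two tiles with equal profiles -> same colour as either
  m2 <- make_tdm(rbind(c(5, 9, 2), c(5, 9, 2)), matrix(1, 2, 3))
  g2 <- render_genes(data.frame(id = "x", kind = "cds",
                                strand = "forward", start = 0L,
                                end = 200L), m2, p)
  cc2 <- encode_matrix(m2, p)
  expect_equal(g2$H, cc2$H[1])
  expect_error(render_genes(data.frame(id = "y", kind = "cds",
                                       strand = "forward", start = 0L,
                                       end = 999L), m2, p), "bounds")
})

test_that("EMBL colour dialect round-trips and uses complement()", {
  ft <- coloured_features(
    kind = c("tile", "cds", "rna"),
    strand = c("forward", "reverse", "forward"),
    start = c(0L, 100L, 300L), end = c(100L, 250L, 420L),
    rgb = rbind(c(255L, 0L, 0L), c(0L, 128L, 64L), c(10L, 20L, 30L)),
    label = c(NA, "geneA", NA))
  path <- withr::local_tempfile(fileext = ".embl")
  write_embl_colour(ft, path, "chr", 1000L)
  lines <- readLines(path)
  expect_true(any(grepl("/colour=255 0 0", lines, fixed = TRUE)))
  expect_true(any(grepl("complement(101..250)", lines, fixed = TRUE)))
  back <- read_embl_colour(path)
  ord <- order(back$start)
  expect_equal(back$start[ord], ft$start[order(ft$start)])
  expect_equal(back$end[ord], ft$end[order(ft$start)])
  expect_equal(back[ord, c("R", "G", "B")],
               ft[order(ft$start), c("R", "G", "B")],
               ignore_attr = TRUE)
  expect_equal(back$kind[ord], ft$kind[order(ft$start)])
})

test_that("GFF3 colour output round-trips through rtracklayer", {
  ft <- coloured_features(
    kind = c("tile", "cds"), strand = c("forward", "reverse"),
    start = c(0L, 500L), end = c(100L, 800L),
    rgb = rbind(c(1L, 2L, 3L), c(200L, 100L, 50L)),
    label = c(NA, "g1"))
  path <- withr::local_tempfile(fileext = ".gff3")
  suppressWarnings(write_gff_colour(ft, path, "chr"))
  back <- read_gff_colour(path)
  ord <- order(back$start)
  expect_equal(back$start[ord], ft$start)
  expect_equal(back$end[ord], ft$end)
  expect_equal(back$strand[ord], ft$strand)
  expect_equal(unlist(back[ord, c("R", "G", "B")], use.names = FALSE),
               unlist(ft[, c("R", "G", "B")], use.names = FALSE))
})

test_that("coordinate conversions are mutually inverse", {
  set.seed(2)
  start <- sort(sample(0:5000, 20)); end <- start + sample(50:500, 20)
  loc_f <- genoprof:::embl_location("forward", start, end)
  parts <- strsplit(loc_f, "..", fixed = TRUE)
  got_start <- vapply(parts, function(x) as.integer(x[1]), integer(1)) - 1L
  got_end <- vapply(parts, function(x) as.integer(x[2]), integer(1))
  expect_equal(got_start, start)
  expect_equal(got_end, end)
})

test_that("strand fidelity: asymmetric colours stay in their strip", {
  fwd <- matrix(c(1000, 1000, 1000), 3, 2)
  rev <- matrix(c(1, 1, 1), 3, 2)
  m <- make_tdm(fwd, rev)
  cc <- small_colours(m)
  ft <- render_tiles(m, cc)
  f_cols <- unique(paste(ft$R[ft$strand == "forward"],
                         ft$G[ft$strand == "forward"],
                         ft$B[ft$strand == "forward"]))
  r_cols <- unique(paste(ft$R[ft$strand == "reverse"],
                         ft$G[ft$strand == "reverse"],
                         ft$B[ft$strand == "reverse"]))
  expect_length(intersect(f_cols, r_cols), 0L)
})

test_that("render_overview writes a deterministic raster", {
  set.seed(6)
  m <- make_tdm(matrix(rlnorm(60, 4), 20, 3), matrix(1, 20, 3))
  p <- encoding_params(3, background = estimate_background(m),
                       upper_clamp = upper_clamp_value(m))
  cc <- encode_matrix(m, p)
  ann <- render_genes(data.frame(id = "g", kind = "cds",
                                 strand = "forward", start = 100L,
                                 end = 600L), m, p)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_overview(m, cc, ann, f1, params = p)
  render_overview(m, cc, ann, f2, params = p)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # empty annotation still renders
  f3 <- withr::local_tempfile(fileext = ".png")
  render_overview(m, cc, NULL, f3, params = p)
  expect_true(file.size(f3) > 0)
})
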