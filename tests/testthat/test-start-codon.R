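# a minimal matrix where exact raw scores are easy to construct: only
# position 1 discriminates (A=2.54, C=2.34, G=2.14, T=0)
ramp_matrix <- function() {
  w <- matrix(0, 7, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  w[1, ] <- c(2.54, 2.34, 2.14, 0)
  rbs_matrix(w, threshold = 2.54, ramp = 0.4)
}

test_that("RBS ramp maps raw scores to potentials", {
  m <- ramp_matrix()
  pot <- scan_rbs("ACGTTTTTTT", m)
  raw <- attr(pot, "raw")
  expect_equal(raw[1:4], c(2.54, 2.34, 2.14, 0))
  expect_equal(pot[1:4], c(1, 0.5, 0, 0))
  # above threshold clamps at 1
  w2 <- m$weights; w2[1, "A"] <- 5
  expect_equal(scan_rbs("ATTTTTTT", rbs_matrix(w2, 2.54, 0.4))[1], 1)
})

test_that("scan_rbs scores ambiguous bases at the column minimum", {
  m <- read_rbs_matrix()
  s1 <- paste0("TAAGGAG", strrep("T", 7))
  s2 <- paste0("NAAGGAG", strrep("T", 7))
  p1 <- scan_rbs(s1, m); p2 <- scan_rbs(s2, m)
  expect_equal(attr(p2, "raw")[1],
               unname(attr(p1, "raw")[1] - m$weights[1, "T"] +
                        min(m$weights[1, ])))
  expect_equal(attr(p2, "n_ambiguous"), 1L)
})

test_that("aggregate_rbs applies the triangle and the visibility share", {
  m <- read_rbs_matrix()
  # perfect RBS at the canonical 7-base gap, single start: only the
  # centre placement has potential 1 -> score = centre weight 5/25
  s <- paste0(strrep("C", 20), "TAAGGAG", strrep("C", 7), "ATGAAA")
  pot <- scan_rbs(s, m)
  start <- data.frame(pos = 35L, codon = "ATG")
  expect_equal(pot[21], 1)
  got <- aggregate_rbs(pot, 35L, start, m$width)
  manual <- sum(vapply(3:11, function(g) {
    p <- 35L - g - m$width
    w <- c(1:5, 4:1)[g - 2] / 25
    if (p >= 1 && p <= length(pot)) pot[p] * w else 0
  }, numeric(1)))
  expect_equal(got, manual)
  expect_gte(got, 5 / 25)

  # no upstream potential -> 0
  expect_equal(aggregate_rbs(rep(0, 40), 35L, start, m$width), 0)

  # two identical equally-visible ATGs halve each other's contribution
  pot1 <- rep(0, 40); pot1[21] <- 1
  two <- data.frame(pos = c(35L, 35L + 9L), codon = c("ATG", "ATG"))
  solo <- aggregate_rbs(pot1, 35L, two[1, ], m$width)
  # place the twin so both see placement 21 with equal triangle weight:
  # gaps 7 and 16 are not equal, so construct symmetric gaps 6 and 8
  two_sym <- data.frame(pos = c(34L, 36L), codon = c("ATG", "ATG"))
  a <- aggregate_rbs(pot1, 34L, two_sym, m$width)
  solo_a <- aggregate_rbs(pot1, 34L, two_sym[1, , drop = FALSE], m$width)
  expect_equal(a, solo_a / 2)

  # down-weighting conservation: contributions across all visible starts
  # never exceed the standalone potential-weighted sum
  set.seed(5)
  for (rep_i in 1:20) {
    pos <- sort(sample(30:60, 3))
    starts <- data.frame(pos = pos,
                         codon = sample(c("ATG", "GTG", "TTG"), 3, TRUE))
    potr <- runif(60)
    tot <- sum(vapply(pos, function(p)
      aggregate_rbs(potr, p, starts, m$width), numeric(1)))
    standalone <- sum(vapply(pos, function(p)
      aggregate_rbs(potr, p, starts[starts$pos == p, , drop = FALSE],
                    m$width), numeric(1)))
    expect_lte(tot, standalone + 1e-12)
  }
})

test_that("coupling score reproduces the knots and interpolation", {
  expect_equal(coupling_score(-4), 1)
  expect_equal(coupling_score(-7), 8 / 22)
  expect_equal(coupling_score(-25), 0)
  expect_equal(coupling_score(-30), 0)
  expect_equal(coupling_score(-16), 4 / 22)   # midpoint of -25..-7
  expect_equal(coupling_score(-1), 8 / 22)
  expect_equal(coupling_score(99), 4 / 22)    # one halving past -1
  expect_equal(coupling_score(199), 2 / 22)
  expect_equal(coupling_score(NA), 0)
  # continuity at every knot
  eps <- 1e-9
  for (k in c(-25, -7, -4, -1))
    expect_equal(coupling_score(k),
                 mean(coupling_score(c(k - eps, k + eps))),
                 tolerance = 1e-6)
  # monotone rise then fall around the optimum
  up <- coupling_score(seq(-25, -4, by = 1))
  expect_true(all(diff(up) >= 0))
  dn <- coupling_score(seq(-4, 300, by = 1))
  expect_true(all(diff(dn) <= 0))
})

test_that("codon type scores and their normalised shares", {
  expect_equal(codon_type_score(c("ATG", "GTG", "TTG")), c(16, 4, 1))
  expect_error(codon_type_score("CTG"), "not a start codon")
  shares <- codon_type_score(c("ATG", "GTG", "TTG")) / 21 * 100
  expect_equal(round(shares, 1), c(76.2, 19.0, 4.8))
})

test_that("combined score and selection follow the contract", {
  m <- read_rbs_matrix()
  seqs <- paste0(strrep("C", 20), "TAAGGAG", strrep("C", 7),
                 "ATGAAAATTGGCTAA")
  cand <- data.frame(pos = c(35L, 41L), codon = c("ATG", "TTG"),
                     coupling_offset = c(NA, -4L))
  sc <- score_start_candidates(seqs, cand, m)
  expect_equal(sc$combined, (sc$rbs_score + sc$coupling) * sc$type_score)
  # ATG with RBS: (r+0)*16; TTG with perfect coupling: (~0+1)*1;
  # ATG wins iff 16*r > 1 -- here r ~ 0.2 so ATG wins
  sel <- select_start(sc)
  expect_equal(sel$chosen$codon, "ATG")
  expect_equal(sel$confidence_ratio,
               max(sc$combined) / sort(sc$combined, TRUE)[2])

  # flip the boundary: remove the RBS so ATG scores ~0
  sc2 <- sc; sc2$rbs_score <- c(0.03, 0)
  sc2$combined <- (sc2$rbs_score + sc2$coupling) * sc2$type_score
  expect_equal(select_start(sc2)$chosen$codon, "TTG")

  # scores (8, 2) -> ratio 4; single candidate -> Inf
  s3 <- data.frame(pos = c(1L, 10L), codon = "ATG", review_only = FALSE,
                   combined = c(8, 2))
  expect_equal(select_start(s3)$confidence_ratio, 4)
  expect_equal(select_start(s3[1, ])$confidence_ratio, Inf)

  # ties go to the most upstream; review-only never auto-selected
  s4 <- data.frame(pos = c(10L, 4L), codon = "ATG", review_only = FALSE,
                   combined = c(5, 5))
  expect_equal(select_start(s4)$chosen$pos, 4L)
  s5 <- data.frame(pos = c(4L, 10L), codon = "ATG",
                   review_only = c(TRUE, FALSE), combined = c(9, 5))
  r5 <- select_start(s5)
  expect_equal(r5$chosen$pos, 10L)
  expect_equal(nrow(r5$review), 1L)
  r6 <- select_start(s5[s5$review_only, , drop = FALSE])
  expect_true(r6$flagged)
})

test_that("selection is invariant under uniform score scaling and
           monotone in evidence", {
  m <- read_rbs_matrix()
  set.seed(8)
  base <- data.frame(pos = c(5L, 20L, 35L), codon = c("GTG", "ATG", "TTG"),
                     review_only = FALSE,
                     combined = c(3.2, 7.7, 0.4))
  pick0 <- select_start(base)$chosen$pos
  for (k in c(0.01, 12)) {
    b <- base; b$combined <- b$combined * k
    expect_equal(select_start(b)$chosen$pos, pick0)
  }
  # improving rbs or coupling never lowers the combined score
  cand <- data.frame(pos = 35L, codon = "ATG", coupling_offset = 50L)
  s <- paste0(strrep("C", 20), "TAAGGAG", strrep("C", 7), "ATGAAA")
  sc <- score_start_candidates(s, cand, m)
  worse <- score_start_candidates(gsub("TAAGGAG", "TTTTTTT", s), cand, m)
  expect_gte(sc$combined, worse$combined)
})

test_that("the bundled matrix loads with its declared threshold", {
  m <- read_rbs_matrix()
  expect_s3_class(m, "RbsMatrix")
  expect_equal(m$threshold, 2.54)
  expect_equal(m$ramp, 0.4)
  expect_equal(m$width, 7L)
  # consensus scores above threshold
  expect_equal(scan_rbs(paste0("TAAGGAG"), m)[1], 1)
})
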