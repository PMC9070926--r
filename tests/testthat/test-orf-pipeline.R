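test_that("enumerate_orfs finds minimal genes and nothing in poly-A", {
  r <- enumerate_orfs("ATGAAATAA", min_length = 9)
  expect_equal(nrow(r$orfs), 1L)
  expect_equal(r$orfs$current_start, 1L)
  expect_equal(r$orfs$length, 9L)
  expect_equal(r$orfs$n_starts, 1L)
  expect_equal(nrow(enumerate_orfs(strrep("A", 300))$orfs), 0L)
})

test_that("enumerate_orfs equals the naive six-frame oracle", {
  set.seed(21)
  for (i in 1:12) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE,
                      prob = c(.2, .3, .3, .2)), collapse = "")
    expect_identical(orf_keys(enumerate_orfs(s, 90)), oracle_orfs(s, 90))
  }
  # planted genes are all recovered with their exact stop
  g <- synth_genome(genome_length = 12000, n_genes = 5, seed = 4)
  r <- enumerate_orfs(g$sequence, 150)
  for (i in seq_len(nrow(g$genes))) {
    hit <- r$orfs$strand == g$genes$strand[i] &
      r$orfs$local_stop == g$genes$local_stop[i]
    expect_true(any(hit), label = g$genes$id[i])
    cand <- r$starts$pos[r$starts$orf_id == r$orfs$id[hit]]
    expect_true(g$genes$local_start[i] %in% cand)
  }
})

test_that("reciprocal_best_hits equals the double-argmax oracle", {
  set.seed(33)
  for (i in 1:10) {
    nq <- sample(5:20, 1); nr <- sample(5:20, 1)
    qs <- paste0("q", seq_len(nq)); rs <- paste0("r", seq_len(nr))
    sc_qr <- matrix(round(runif(nq * nr, 30, 200), 1), nq,
                    dimnames = list(qs, rs))
    sc_rq <- matrix(round(runif(nq * nr, 30, 200), 1), nr,
                    dimnames = list(rs, qs))
    long <- function(m) data.frame(
      query_id = rep(rownames(m), ncol(m)),
      subject_id = rep(colnames(m), each = nrow(m)),
      bitscore = as.vector(m))
    got <- reciprocal_best_hits(long(sc_qr), long(sc_rq))
    expect_identical(sort(paste(got$query_id, got$subject_id)),
                     oracle_rbh(sc_qr, sc_rq))
  }
})

test_that("RBH handles the spec's small cases and is symmetric", {
  q2r <- data.frame(query_id = "q1", subject_id = "r1", bitscore = 50)
  r2q <- data.frame(query_id = "r1", subject_id = "q1", bitscore = 50)
  expect_equal(nrow(reciprocal_best_hits(q2r, r2q)), 1L)
  # asymmetry: r1's best points elsewhere
  r2q2 <- data.frame(query_id = "r1", subject_id = "q2", bitscore = 60)
  expect_equal(nrow(reciprocal_best_hits(q2r, r2q2)), 0L)
  # duplicates reduce to the best row before pairing
  q2r3 <- data.frame(query_id = c("q1", "q1"),
                     subject_id = c("r1", "r2"), bitscore = c(10, 90))
  r2q3 <- data.frame(query_id = c("r1", "r2"),
                     subject_id = c("q1", "q1"), bitscore = c(5, 80))
  expect_equal(reciprocal_best_hits(q2r3, r2q3)$subject_id, "r2")
  # symmetry under table swap
  swap <- reciprocal_best_hits(r2q3, q2r3)
  expect_equal(swap$query_id, "r2")
})

test_that("RNA overlap rule trims to a clear start or discards", {
  # one forward gene with two candidate starts 150 nt apart
  body <- paste(rep("AAA", 120), collapse = "")
  s <- paste0(strrep("C", 30), "ATG", substr(body, 1, 147), "ATG",
              substr(body, 151, 360), "TAATTT")
  r <- enumerate_orfs(s, 90)
  o <- r$orfs[which.max(r$orfs$length), ]
  # rRNA overlapping only the first start
  rna <- data.frame(start = 20L, end = 40L)
  tr <- resolve_rna_overlaps(r, rna, remnant_min = 90)
  expect_false(o$id %in% attr(tr, "discarded"))
  expect_gt(tr$orfs$current_start[tr$orfs$id == o$id], 40L)
  # RBH-exempt ORFs are untouched
  tr2 <- resolve_rna_overlaps(r, rna, has_rbh = o$id)
  expect_equal(tr2$orfs$current_start[tr2$orfs$id == o$id],
               o$current_start)
  # feature covering the whole ORF -> discarded
  all_cover <- data.frame(start = 0L, end = nchar(s))
  tr3 <- resolve_rna_overlaps(r, all_cover)
  expect_true(o$id %in% attr(tr3, "discarded"))
  # remnant below the minimum -> discarded
  tr4 <- resolve_rna_overlaps(r, rna, remnant_min = 5000L)
  expect_true(o$id %in% attr(tr4, "discarded"))
})

sus_orfs <- function() {
  data.frame(
    id = c("good", "bad", "mid"),
    span_start = c(0L, 2000L, 2010L),
    span_end = c(1000L, 2140L, 2500L),
    length = c(1000L, 140L, 290L),
    combined = c(50, 0.1, 10),
    confidence_ratio = c(5, 1, 1.5),
    strand_ratio = c(10, 0.2, 1),
    stringsAsFactors = FALSE)
}

test_that("suspicion components flip at the documented cut-offs", {
  sc <- suspicion_score(sus_orfs())
  good <- sc[sc$id == "good", ]
  expect_equal(good$total, 0L)
  bad <- sc[sc$id == "bad", ]
  expect_equal(unname(unlist(
    bad[c("points_start", "points_length", "points_strand_ratio",
          "points_overlap")])), c(2L, 2L, 2L, 2L))
  expect_equal(bad$total, 8L)
  mid <- sc[sc$id == "mid", ]
  expect_equal(mid$points_length, 1L)       # 150 <= 290 < 300
  expect_equal(mid$points_strand_ratio, 1L) # 0.5 < 1 < 2

  # boundary checks on length and strand-ratio thresholds
  o <- sus_orfs()[1, ]; o$span_start <- 5000L; o$span_end <- 5300L
  for (len in c(300L, 299L, 149L)) {
    o$length <- len
    pts <- suspicion_score(o)$points_length
    expect_equal(pts, c(`300` = 0L, `299` = 1L, `149` = 2L)[[as.character(len)]])
  }
  for (sr in c(2, 1.99, 0.5)) {
    o$strand_ratio <- sr
    expect_equal(suspicion_score(o)$points_strand_ratio,
                 if (sr >= 2) 0L else if (sr <= 0.5) 2L else 1L)
  }
  # missing RNAseq -> neutral 1 and flagged
  o$strand_ratio <- NA
  s1 <- suspicion_score(o)
  expect_equal(s1$points_strand_ratio, 1L)
  expect_true(s1$strand_flagged)
})

test_that("iterative_filter relaxes overlaps and matches a brute force", {
  # two mutually overlapping weak ORFs: removing the weaker must drop the
  # stronger below the cut-off
  orfs <- data.frame(
    id = c("a", "b"),
    span_start = c(100L, 150L), span_end = c(400L, 430L),
    length = c(300L, 280L),
    combined = c(10, 0.01), confidence_ratio = c(3, 1),
    strand_ratio = c(3, 0.2), stringsAsFactors = FALSE)
  r <- iterative_filter(orfs, max_score_final = 5L)
  expect_equal(r$orfs$id, "a")
  expect_equal(r$removed$id, "b")
  expect_equal(r$orfs$points_overlap, 0L)

  # nothing above the cut-off -> identity
  lone <- sus_orfs()[1, ]
  r0 <- iterative_filter(lone)
  expect_equal(r0$orfs$id, "good")
  expect_equal(nrow(r0$removed), 0L)

  # chain of three overlapping ORFs vs an exhaustive schedule simulation
  chain <- data.frame(
    id = c("x", "y", "z"),
    span_start = c(0L, 200L, 420L), span_end = c(290L, 460L, 700L),
    length = c(290L, 260L, 280L),
    combined = c(0.5, 30, 0.4), confidence_ratio = c(1, 4, 1),
    strand_ratio = c(0.4, 5, 0.3), stringsAsFactors = FALSE)
  got <- iterative_filter(chain)
  sim <- chain
  ref0 <- suspicion_reference(chain)
  removed_sim <- character()
  for (cutoff in 8:5) repeat {
    sc <- suspicion_score(sim, ref = ref0)
    bad <- sc[sc$total > cutoff, ]
    if (!nrow(bad)) break
    pick <- bad$id[order(-bad$total, bad$span_start)][1]
    removed_sim <- c(removed_sim, pick)
    sim <- sim[sim$id != pick, , drop = FALSE]
  }
  expect_equal(got$removed$id, removed_sim)
  expect_setequal(got$orfs$id, sim$id)

  # removal monotonicity: dropping any ORF never raises another's total
  # (start-strength quantiles held at the full-set reference)
  full <- suspicion_score(chain, ref = ref0)
  for (drop_id in chain$id) {
    rest <- suspicion_score(chain[chain$id != drop_id, , drop = FALSE],
                            ref = ref0)
    before <- full$total[match(rest$id, full$id)]
    expect_true(all(rest$total <= before))
  }
})

test_that("gap_report finds uncovered stretches", {
  f <- data.frame(start = c(100L, 900L), end = c(500L, 1200L))
  g <- gap_report(f, 2000L, min_gap = 150L)
  expect_equal(g$start, c(500L, 1200L))
  expect_equal(g$end, c(900L, 2000L))
  expect_equal(nrow(gap_report(f, 2000L, min_gap = 5000L)), 0L)
  g2 <- gap_report(f[0, ], 700L, min_gap = 100L)
  expect_equal(unlist(g2, use.names = FALSE), c(0L, 700L))
})
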