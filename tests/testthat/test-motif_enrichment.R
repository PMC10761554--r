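test_that("new_pwm validates rows and background", {
  expect_error(new_pwm(matrix(c(0.5, 0.5, 0.1, 0.1), nrow = 1)), "sum to 1")
  expect_error(new_pwm(matrix(0.25, 1, 4), background = c(1, 1, 1, 1)),
               "background")
  p <- new_pwm(matrix(0.25, 3, 4))
  expect_identical(p$width, 3L)
})

test_that("pwm_logodds is zero for an uninformative motif and finite always", {
  uni <- new_pwm(matrix(0.25, 4, 4))
  expect_equal(pwm_logodds(uni), matrix(0, 4, 4),
               ignore_attr = TRUE)
  # prob -> 1 at pseudocount -> 0 approaches log2(4) = 2
  peak <- new_pwm(matrix(c(1, 0, 0, 0), nrow = 1))
  lo <- pwm_logodds(peak, pseudocount = 1e-9)
  expect_equal(unname(lo[1, "A"]), 2, tolerance = 1e-6)
  expect_true(all(is.finite(pwm_logodds(peak)))) # zero probs stay finite
  bad <- new_pwm(matrix(0.25, 1, 4))
  bad$background <- c(A = 0, C = 0.5, G = 0.25, T = 0.25)
  expect_error(pwm_logodds(bad), "background")
})

test_that("score_threshold admits only the top base at p_cut 0.3 (w = 1)", {
  p <- new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 1))
  lo <- pwm_logodds(p)
  thr <- score_threshold(lo, p$background, p_cut = 0.3)
  admitted <- which(lo[1, ] >= thr - 1e-9)
  expect_identical(names(admitted), "A")
  # p_cut = 1 -> threshold at (or below) the minimum possible score
  thr_all <- score_threshold(lo, p$background, p_cut = 1)
  expect_lte(thr_all, min(lo) + 1e-3)
  expect_error(score_threshold(matrix(0, 30, 4), rep(0.25, 4)), "width")
})

test_that("convolution tail matches exhaustive 4^w enumeration (w <= 6)", {
  set.seed(14)
  for (w in c(2, 4, 6)) {
    probs <- matrix(stats::rgamma(w * 4, 1), nrow = w)
    probs <- probs / rowSums(probs)
    bg <- c(0.2, 0.3, 0.3, 0.2)
    pwm <- new_pwm(probs, background = bg)
    lo <- pwm_logodds(pwm)
    q <- round(lo / 1e-3) # same discretization as the convolution
    # enumerate every sequence of length w with its background probability
    grids <- do.call(expand.grid, rep(list(1:4), w))
    scores <- as.matrix(grids)
    seq_score <- rowSums(matrix(q[cbind(rep(1:w, each = nrow(grids)),
                                        as.vector(scores))],
                                nrow = nrow(grids)))
    seq_prob <- apply(grids, 1, function(r) prod(bg[as.integer(r)]))
    for (p_cut in c(1e-3, 0.05, 0.5)) {
      thr <- score_threshold(lo, bg, p_cut = p_cut)
      thr_bins <- round(thr / 1e-3)
      tail_at_thr <- sum(seq_prob[seq_score >= thr_bins])
      expect_lte(tail_at_thr, p_cut + 1e-9)
      # one bin lower must exceed p_cut (threshold is the smallest score)
      tail_below <- sum(seq_prob[seq_score >= thr_bins - 1L])
      if (tail_below <= p_cut) {
        # only allowed if nothing scores in between (empty bin)
        expect_identical(tail_below, tail_at_thr)
      }
    }
  }
})

test_that("scan_sequence matches hand-scanned GG example", {
  gg <- gg_motif()
  lo <- pwm_logodds(gg)
  thr <- score_threshold(lo, gg$background, p_cut = 0.0625)
  hits <- scan_sequence("AGGA", lo, thr)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$position, 1L)
  expect_identical(hits$strand, "+")
  # zero-information motif with positive threshold: no hits
  uni <- pwm_logodds(new_pwm(matrix(0.25, 2, 4)))
  expect_identical(nrow(scan_sequence("AGGA", uni, 0.5)), 0L)
  # shorter than the motif -> empty with warning
  expect_warning(none <- scan_sequence("A", lo, thr), "shorter")
  expect_identical(nrow(none), 0L)
})

test_that("scan_sequence equals the naive rescoring oracle", {
  set.seed(19)
  gg <- gg_motif()
  lo <- pwm_logodds(gg)
  thr <- score_threshold(lo, gg$background, p_cut = 0.1)
  for (s in random_dna(50, 60)) {
    got <- scan_sequence(s, lo, thr)
    want <- naive_scan(s, lo, thr)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
  # N-containing windows are skipped
  withN <- scan_sequence("AGNGA", lo, thr)
  expect_identical(nrow(withN), 0L)
})

test_that("reverse-complementing the sequence mirrors the hit set", {
  set.seed(23)
  gg <- gg_motif()
  lo <- pwm_logodds(gg)
  thr <- score_threshold(lo, gg$background, p_cut = 0.1)
  for (s in random_dna(20, 40)) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    h1 <- scan_sequence(s, lo, thr)
    h2 <- scan_sequence(rc, lo, thr)
    w <- gg$width
    # hit at position p on strand + <-> hit at L - w - p on strand - of rc
    mirrored <- data.frame(
      position = nchar(s) - w - h1$position,
      strand = as.character(ifelse(h1$strand == "+", "-", "+")),
      score = h1$score)
    mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
    expect_equal(h2$position, mirrored$position)
    expect_equal(h2$strand, mirrored$strand)
    expect_equal(h2$score, mirrored$score, tolerance = 1e-9)
  }
})

test_that("occurrence_ratio counts promoters with >= 1 hit", {
  gg <- gg_motif()
  lo <- pwm_logodds(gg)
  thr <- score_threshold(lo, gg$background, p_cut = 0.0625)
  expect_equal(occurrence_ratio(c("AGGA", "TTTT"), lo, thr), 0.5)
  expect_equal(occurrence_ratio(c("AGGA", "GGGG"), lo, thr), 1.0)
  # threshold above the maximum attainable score
  expect_equal(occurrence_ratio(c("AGGA", "GGGG"), lo, 1e6), 0.0)
  expect_error(occurrence_ratio(character(0), lo, thr), "empty")
})

test_that("permutation_test handles degenerate bounds", {
  gg <- gg_motif()
  universe <- c(p1 = "AGGA", p2 = "AGGA", p3 = "TTTT")
  # observed ratio 0 -> every null ratio >= 0 -> p = 1
  r0 <- permutation_test(c("p3"), universe, gg, n_iter = 50, seed = 1,
                         p_cut = 0.0625)
  expect_equal(r0$observed_ratio, 0)
  expect_equal(r0$p_empirical, 1)
  # all promoters contain the motif -> observed = null = 1 -> p = 1
  all_hit <- c(a = "AGGA", b = "GGGG", c = "CCCC")
  r1 <- permutation_test(c("a", "b"), all_hit, gg, n_iter = 50, seed = 1,
                         p_cut = 0.0625)
  expect_equal(r1$observed_ratio, 1)
  expect_equal(r1$p_empirical, 1)
  expect_error(permutation_test("zz", universe, gg), "not all present")
  expect_error(permutation_test(character(0), universe, gg), "empty")
  # default iteration count is 1000
  expect_identical(formals(permutation_test)$n_iter, 1000)
})

test_that("zero exceedances report p = 0 with upper bound 1/n_iter", {
  hits <- setNames(c(TRUE, rep(FALSE, 30)), paste0("p", 0:30))
  r <- permutation_test_hits(hits, "p0", n_iter = 40, seed = 3)
  # singleton target with the only motif promoter: null sets of size 1
  # almost never contain it; allow either outcome but check the contract
  if (r$p_empirical == 0) {
    expect_equal(r$p_upper, 1 / 40)
  } else {
    expect_equal(r$p_upper, r$p_empirical)
  }
})

test_that("permutation p converges to the exhaustive subset value", {
  # universe of 5, 3 motif-bearing; target = 2 motif-bearing promoters;
  # exhaustive C(5,2) enumeration gives P(null ratio >= 1) = 3/10
  hits <- setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE), paste0("p", 1:5))
  combos <- utils::combn(5, 2)
  exact <- mean(colSums(matrix(hits[combos], nrow = 2)) == 2)
  expect_equal(exact, 0.3)
  r <- permutation_test_hits(hits, c("p1", "p2"), n_iter = 10000, seed = 5)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(r$p_empirical - 0.3), 3 * se)
})

test_that("GC-matched sampling preserves the target bin composition", {
  set.seed(30)
  hits <- setNames(runif(100) < 0.4, paste0("p", 1:100))
  gc <- setNames(runif(100, 0.3, 0.7), names(hits))
  r <- permutation_test_hits(hits, names(hits)[1:10], n_iter = 100,
                             seed = 2, match_gc = gc)
  expect_length(r$null_ratios, 100)
  expect_true(all(r$null_ratios >= 0 & r$null_ratios <= 1))
})

test_that("motif file readers round-trip a matrix", {
  dir <- withr::local_tempdir()
  pfm <- file.path(dir, "m.tsv")
  write.table(data.frame(A = c(8, 1), C = c(1, 1), G = c(0, 7), T = c(1, 1)),
              pfm, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- read_pfm(pfm)
  expect_equal(unname(p$probs[1, "A"]), 0.8)
  expect_equal(unname(p$probs[2, "G"]), 0.7)
  meme <- file.path(dir, "m.meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF TEST_MOTIF",
    "letter-probability matrix: alength= 4 w= 2 nsites= 10 E= 0",
    " 0.900000 0.033333 0.033333 0.033334",
    " 0.033333 0.033333 0.900000 0.033334"
  ), meme)
  m <- read_meme(meme)
  expect_identical(m$name, "TEST_MOTIF")
  expect_identical(m$width, 2L)
  expect_equal(unname(m$background), c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(m$probs[1, "A"]), 0.9, tolerance = 1e-6)
})
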