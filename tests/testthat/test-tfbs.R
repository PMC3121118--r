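toy_pwm <- function(cons = "ACGTACGT", sharp = 97) {
  v <- strsplit(cons, "")[[1]]
  counts <- matrix(1, 4, length(v), dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(v, rownames(counts)), seq_along(v))] <- sharp
  make_pwm("TOY", counts)
}

toy_regions <- function(seqs, prefix = "r") {
  data.frame(region_id = paste0(prefix, seq_along(seqs)), source = "s",
             chrom = "chr1", start = 0L, end = nchar(seqs), kind = "x",
             extended = FALSE, truncated = FALSE, seq = seqs,
             stringsAsFactors = FALSE)
}

test_that("log-odds conversion matches the stated formula", {
  # uniform column scores 0 everywhere under a uniform background
  counts <- matrix(5, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  lom <- pwm_to_log_odds(make_pwm("U", counts))
  expect_equal(unname(lom$mat), matrix(0, 4, 2))

  # single-base column, count 10, pseudocount 0.8, bg 0.25:
  # log2((10 + 0.2) / 10.8 / 0.25) = log2(3.7778) ~ 1.9175
  counts <- matrix(0, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["G", 1] <- 10
  lom <- pwm_to_log_odds(make_pwm("S", counts))
  expect_equal(unname(lom$mat["G", 1]), log2((10 + 0.2) / 10.8 / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(lom$mat["G", 1]), 1.91754, tolerance = 1e-4)

  # max score is the sum of per-column maxima
  p <- toy_pwm("AC")
  lom <- pwm_to_log_odds(p)
  expect_equal(lom$max_score, sum(apply(lom$mat, 2, max)))
  expect_equal(lom$min_score, sum(apply(lom$mat, 2, min)))
})

test_that("scanning finds planted consensus on both strands at max score", {
  set.seed(51)
  p <- toy_pwm("ACGGTCAAGT")
  lom <- pwm_to_log_odds(p)
  bg <- strsplit(random_dna(60, gc = 0.2), "")[[1]]

  fwd <- bg
  fwd[8:17] <- strsplit(pwm_consensus(p), "")[[1]]
  hits <- scan_sequence(paste(fwd, collapse = ""), lom)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$offset == 7 & abs(plus$score - lom$max_score) < 1e-9))

  rev <- bg
  rev[4:13] <- strsplit(revcomp(pwm_consensus(p)), "")[[1]]
  hits <- scan_sequence(paste(rev, collapse = ""), lom)
  minus <- hits[hits$strand == "-", ]
  expect_true(any(minus$offset == 3 & abs(minus$score - lom$max_score) < 1e-9))

  # all-N never hits; short sequence gives an empty frame
  expect_equal(nrow(scan_sequence(strrep("N", 50), lom)), 0)
  expect_equal(nrow(scan_sequence("ACG", lom)), 0)
})

test_that("scanning matches the per-offset brute-force oracle", {
  set.seed(53)
  motifs <- lapply(c("ACGGTCAAGT", "TTGACA", "GCGCGATATA"), toy_pwm)
  for (m in motifs) {
    lom <- pwm_to_log_odds(m)
    for (i in 1:12) {
      s <- random_dna(sample(30:300, 1), gc = runif(1, 0.3, 0.7))
      for (f in c(0.6, 0.8, 1.0)) {
        expect_equal(scan_sequence(s, lom, f), scan_oracle(s, lom, f))
      }
    }
  }
})

test_that("hit counts are monotone in the threshold and complete over strands", {
  set.seed(55)
  lom <- pwm_to_log_odds(toy_pwm("ACGGTCAA", sharp = 5))
  for (i in 1:10) {
    s <- random_dna(500, gc = 0.5)
    n6 <- nrow(scan_sequence(s, lom, 0.6))
    n8 <- nrow(scan_sequence(s, lom, 0.8))
    n10 <- nrow(scan_sequence(s, lom, 1.0))
    expect_gte(n6, n8)
    expect_gte(n8, n10)

    # scanning the reverse complement flips strands and mirrors offsets
    h <- scan_sequence(s, lom, 0.7)
    hr <- scan_sequence(revcomp(s), lom, 0.7)
    mirrored <- data.frame(offset = nchar(s) - hr$offset - lom$width,
                           strand = as.character(ifelse(hr$strand == "+", "-", "+")),
                           score = hr$score)
    mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
    rownames(mirrored) <- NULL
    expect_equal(h, mirrored)
  }
})

test_that("normalization and fold classification pin the stated boundaries", {
  reg <- toy_regions(strrep("A", 2500))
  reg <- rbind(reg, toy_regions(strrep("A", 2500), prefix = "q"))
  expect_equal(normalized_count(10, reg), 2.0)
  expect_equal(normalized_count(0, reg), 0.0)

  expect_equal(classify_fold(10, 2)$category, "over-represented")
  expect_equal(classify_fold(10, 2)$fold, 5)
  expect_equal(classify_fold(1, 1)$category, "shared")
  expect_equal(classify_fold(0.4, 1)$category, "under-represented")
  # boundary exactness
  expect_equal(classify_fold(2, 1)$category, "over-represented")
  expect_equal(classify_fold(1, 2)$category, "under-represented")
  expect_equal(classify_fold(1, 0)$fold, Inf)
  expect_equal(classify_fold(1, 0)$category, "over-represented")
  bz <- classify_fold(0, 0)
  expect_equal(bz$category, "shared")
  expect_true(bz$both_zero)
  expect_error(classify_fold(-1, 1))
})

test_that("enrichment table recovers planted rate differences", {
  set.seed(57)
  p1 <- toy_pwm("ACGGTCAAGTCC"); p1$id <- "OVER"; p1$name <- "over"
  p2 <- toy_pwm("TTGACAGGCATG"); p2$id <- "EQ"; p2$name <- "eq"
  # plant OVER at n_over copies per region and EQ at two fixed offsets
  plant_region <- function(n_over) {
    v <- strsplit(random_dna(1000, gc = 0.4), "")[[1]]
    for (k in seq_len(n_over)) {
      off <- 1 + (k - 1) * 150
      v[off:(off + 11)] <- strsplit(pwm_consensus(p1), "")[[1]]
    }
    v[801:812] <- strsplit(pwm_consensus(p2), "")[[1]]
    v[901:912] <- strsplit(revcomp(pwm_consensus(p2)), "")[[1]]
    paste(v, collapse = "")
  }
  bid <- toy_regions(vapply(1:10, function(i) plant_region(5), ""), prefix = "b")
  uni <- toy_regions(vapply(1:10, function(i) plant_region(1), ""), prefix = "u")
  tab <- enrichment_table(bid, uni, list(p1, p2))
  expect_equal(tab$category[tab$motif_id == "OVER"], "over-represented")
  expect_equal(tab$category[tab$motif_id == "EQ"], "shared")
  expect_true(all(diff(tab$fold) <= 0))  # sorted by fold descending

  # the same collection passed twice overlaps on its over-represented set
  expect_equal(overrepresented_overlap(tab, tab),
               sort(tolower(tab$name[tab$category == "over-represented"])))

  # a PWM wider than every promoter yields zero counts, flagged
  wide <- make_pwm("WIDE", matrix(1, 4, 1200,
                                  dimnames = list(c("A", "C", "G", "T"), NULL)))
  tabw <- enrichment_table(bid, uni, list(wide))
  expect_true(tabw$too_wide)
  expect_true(tabw$both_zero)
})
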