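test_that("trend classification applies the buffer-zone rule", {
  res <- data.frame(event_id = c("e1", "e2", "e3", "e4", "e5"),
                    tested = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    p = c(1e-6, 1e-6, 0.7, 0.1, NA),
                    q = c(0.01, 0.01, 0.3, 0.3, NA),
                    perm_fraction = c(0, 0, 0.5, 0.2, NA),
                    beta_age = c(0.01, -0.02, 0.001, 0.004, NA))
  res <- call_significant(res)
  cls <- classify_trend(res)
  expect_equal(unname(cls), c("up", "down", "stable", NA, NA))
})

test_that("IUPAC counting matches direct inspection and the naive scanner", {
  expect_equal(count_iupac("ACGTACGT", "ACGT"), 2L)
  expect_equal(count_iupac("CTCTCT", "CT"), 3L)
  expect_equal(count_iupac("CCCC", "CC"), 3L)      # overlapping matches
  expect_equal(count_iupac("ACNT", "ACGT"), 0L)    # N never matches
  expect_equal(count_iupac("TCAT", "YCAY"), 1L)
  expect_error(count_iupac("ACGT", "ACXGT"), "IUPAC")
  expect_error(count_iupac("ACGT", ""), "empty")

  mot <- list(motif_id = "m", consensus = "YCAY")
  regions <- c(upstream_exon_3p = "TCATTCAC", cassette_exon = "GGGG")
  cnt <- count_motif_occurrences(regions, mot)
  expect_equal(cnt, c(upstream_exon_3p = 2L, cassette_exon = 0L))

  # fuzz against the position-by-position oracle
  set.seed(50)
  alphabet <- c("A", "C", "G", "T", "N")
  motifs <- c("YCAY", "TGCATG", "RNYK", "ACGT", "WWSS")
  for (rep in 1:40) {
    s <- paste(sample(alphabet, 60, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    m <- sample(motifs, 1)
    expect_identical(count_iupac(s, m), naive_motif_count(s, m))
  }
})

test_that("rank-sum enrichment p-values match exact enumeration", {
  # {1,2,3} vs {4,5,6}: the most extreme assignment; exact two-sided p
  expect_equal(wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value,
               ranksum_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(ranksum_oracle(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(51)
  for (rep in 1:25) {
    x <- sample(1000, sample(3:5, 1))   # distinct values, exact test valid
    y <- sample(2000:3000, sample(3:5, 1))
    expect_equal(wilcox.test(x, y, exact = TRUE)$p.value,
                 ranksum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("motif enrichment scan flags planted signal and respects guards", {
  set.seed(52)
  events <- sprintf("e%03d", 1:60)
  classes <- setNames(rep(c("up", "stable", "down"), each = 20), events)
  mk_counts <- function(lambda_up) {
    rbind(
      data.frame(event_id = events, region = "cassette_exon", motif_id = "hit",
                 count = rpois(60, ifelse(classes == "up", lambda_up, 1))),
      data.frame(event_id = events, region = "cassette_exon",
                 motif_id = "decoy", count = rpois(60, 1)))
  }
  enr <- motif_enrichment_scan(mk_counts(6), classes, fdr = 0.1)
  hit_row <- enr[enr$motif_id == "hit" & enr$comparison == "up-vs-stable", ]
  expect_true(hit_row$significant)
  expect_equal(hit_row$direction, 1L)
  expect_false(any(enr$significant[enr$motif_id == "decoy"]))
  # identical distributions are never significant
  enr0 <- motif_enrichment_scan(mk_counts(1), classes, fdr = 0.1)
  expect_gt(min(enr0$p[enr0$motif_id == "hit"]), 0.001)
  # class-size guard
  expect_error(motif_enrichment_scan(mk_counts(6), classes[1:25], fdr = 0.1),
               "need >=")
})

test_that("driver calls require both enrichment and SF age association", {
  w <- small_world(seed = 53, n = 120, n_events = 200, frac = 0.3,
                   noise_sd = 0.3, effect_size = 0.03)
  rs <- simulate_regions_and_sf(w$truth, w$cohort, w$cfg)
  # use true trend classes to isolate the driver logic from the scan
  ev <- w$truth$events[w$truth$events$type == "SE", ]
  classes <- setNames(ev$trend_class, ev$event_id)
  counts <- count_motif_table(rs$regions, w$cfg$motif_set)
  enr <- motif_enrichment_scan(counts, classes, fdr = 0.1)
  drv <- identify_drivers(enr, rs$sf_expr, w$cohort, w$cfg$motif_set)
  expect_equal(drv$sf_gene, "PTBP1")
  expect_lt(drv$sf_beta_age, 0)
  expect_match(drv$mechanism, "repressor losing activity")

  # no enrichments -> empty calls
  none <- enr; none$q <- 1
  expect_equal(nrow(identify_drivers(none, rs$sf_expr, w$cohort,
                                     w$cfg$motif_set)), 0)
  # enriched motif but SF not age-associated -> no call
  flat_sf <- rs$sf_expr
  set.seed(1); flat_sf["PTBP1", ] <- exp(rnorm(ncol(flat_sf), 3, 0.2))
  drv2 <- identify_drivers(enr, flat_sf, w$cohort, w$cfg$motif_set)
  expect_false("PTBP1" %in% drv2$sf_gene)
  # SF absent from the matrix -> untestable note, not an error
  drv3 <- identify_drivers(enr, rs$sf_expr[-match("PTBP1",
                                                  rownames(rs$sf_expr)), ],
                           w$cohort, w$cfg$motif_set)
  expect_match(drv3$mechanism[drv3$sf_gene == "PTBP1"], "untestable")
})

test_that("target overlap test matches the hypergeometric oracle", {
  bg <- sprintf("g%02d", 1:20)
  pipe <- bg[1:10]; ext <- c(bg[1:8], bg[11])
  res <- target_overlap_test(pipe, ext, bg)
  expect_equal(unname(res$table[1, 1]), 8)
  expect_equal(res$p_value, fisher_oracle(res$table), tolerance = 1e-12)
  expect_gt(res$odds_ratio, 1)

  # degenerate table: both sets equal the background
  deg <- target_overlap_test(bg, bg, bg)
  expect_equal(deg$odds_ratio, Inf)
  expect_match(deg$note, "degenerate")

  expect_error(target_overlap_test(pipe, ext, character(0)), "empty")
  expect_error(target_overlap_test(c(pipe, "zzz"), ext, bg), "subsets")

  # type-I calibration of the overlap test on independent random sets
  # (reduced from 1000 to 300 seeds for runtime)
  ps <- vapply(1:300, function(s) {
    set.seed(s)
    u <- sprintf("u%03d", 1:60)
    target_overlap_test(sample(u, 20), sample(u, 20), u)$p_value
  }, numeric(1))
  expect_lt(mean(ps <= 0.05), 0.08)   # Fisher is conservative; never above
})
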