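test_that("8-state secondary structure collapses to helix/strand/coil", {
  expect_equal(simplify_ss("HGIEBTS "), "HHHEECCC")
  expect_equal(simplify_ss(""), "")
  expect_equal(simplify_ss("TTSS--"), "CCCCCC")
  expect_equal(simplify_ss("HEC"), "HEC")
  expect_error(simplify_ss("HEX"), "unknown")
})

test_that("DSSP residue tables parse from the fixed-column format", {
  f <- tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M  H  >S+     0   0  132",
    "    2    2 A K  G 3<5S+     0   0   85",
    "    3    3 A V  E     -A   25   0A  11",
    "    4        !*             0   0    0",
    "    5    4 B L  T  <        0   0   90"), f)
  d <- read_dssp(f)
  expect_equal(d$resno, c(1, 2, 3, 4))
  expect_equal(d$ss8, c("H", "G", "E", "T"))
  expect_equal(d$ss3, "HHEC")
  dA <- read_dssp(f, chain = "A")
  expect_equal(dA$ss3, "HHE")
  expect_error(read_dssp(tempfile()), "not found")
})

test_that("divergence windows follow the 15-residue / 50% rule exactly", {
  same <- strrep("HECCH", 10)
  expect_equal(nrow(find_divergent_regions(same, same)), 0)
  # 15 all-H vs all-E residues: a single span covering them
  a <- paste0(strrep("C", 5), strrep("H", 15), strrep("C", 5))
  b <- paste0(strrep("C", 5), strrep("E", 15), strrep("C", 5))
  div <- find_divergent_regions(a, b)
  expect_equal(div, data.frame(start = 6L, end = 20L))
  # symmetric in its arguments
  expect_equal(find_divergent_regions(b, a), div)
  expect_error(find_divergent_regions(a, paste0(b, "C")), "length")
})

test_that("the call flips between 7/15 and 8/15 alpha-beta differences", {
  mk <- function(ndiff) {
    a <- rep("H", 15)
    b <- rep("H", 15)
    b[seq_len(ndiff) * 2 - 1] <- "E"   # spread differences out
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
  }
  s7 <- mk(7)
  s8 <- mk(8)
  expect_equal(nrow(find_divergent_regions(s7$a, s7$b)), 0)
  expect_gt(nrow(find_divergent_regions(s8$a, s8$b)), 0)
  # agreement with a brute-force window scan on random strings
  set.seed(61)
  for (rep in 1:10) {
    ra <- paste(sample(c("H", "E", "C"), 60, TRUE), collapse = "")
    rb <- paste(sample(c("H", "E", "C"), 60, TRUE), collapse = "")
    expect_equal(find_divergent_regions(ra, rb),
                 brute_divergence_spans(ra, rb, 15, 0.5))
  }
})

test_that("corroboration requires clusters on a structure's unique contacts", {
  ca <- as_contact_sets(data.frame(i = c(10, 10, 10), j = c(30, 31, 32)),
                        L = 60, id = "a")
  cb <- as_contact_sets(data.frame(i = c(40, 40, 40), j = c(50, 51, 52)),
                        L = 60, id = "b")
  # clusters on a's uniques only
  f1 <- dbscan_filter(data.frame(i = c(10, 10, 10), j = c(30, 31, 32)),
                      eps = 2, min_samples = 3)
  co1 <- corroborate(ca, cb, f1)
  expect_true(co1$corroborated_a)
  expect_false(co1$corroborated_b)
  # identical predicted structures: unique sets empty, never corroborated
  co2 <- corroborate(ca, ca, f1)
  expect_false(co2$corroborated_a)
  expect_false(co2$corroborated_b)
  # planted clusters on both unique sets corroborate both
  f3 <- dbscan_filter(data.frame(i = c(10, 10, 10, 40, 40, 40),
                                 j = c(30, 31, 32, 50, 51, 52)),
                      eps = 2, min_samples = 3)
  co3 <- corroborate(ca, cb, f3)
  expect_true(co3$corroborated_a && co3$corroborated_b)
})

test_that("blind categories follow the divergence/corroboration rules", {
  ca <- as_contact_sets(data.frame(i = c(10, 10, 10), j = c(30, 31, 32)),
                        L = 60, id = "a")
  cb <- as_contact_sets(data.frame(i = c(40, 40, 40), j = c(50, 51, 52)),
                        L = 60, id = "b")
  div_a <- paste0(strrep("C", 10), strrep("H", 20), strrep("C", 30))
  div_b <- paste0(strrep("C", 10), strrep("E", 20), strrep("C", 30))
  same <- div_a
  f_both <- dbscan_filter(data.frame(i = c(10, 10, 10, 40, 40, 40),
                                     j = c(30, 31, 32, 50, 51, 52)),
                          eps = 2, min_samples = 3)
  co_both <- corroborate(ca, cb, f_both)
  call1 <- classify_blind(div_a, div_b, co_both)
  expect_equal(call1$category, "category1")
  expect_length(call1$flags, 0)

  # divergence with single-sided corroboration: flagged category1
  f_one <- dbscan_filter(data.frame(i = c(10, 10, 10), j = c(30, 31, 32)),
                         eps = 2, min_samples = 3)
  co_one <- corroborate(ca, cb, f_one)
  call_one <- classify_blind(div_a, div_b, co_one)
  expect_equal(call_one$category, "category1")
  expect_true("low_confidence_partial_corroboration" %in% call_one$flags)

  # no divergence, no unexplained clusters -> single fold
  call2 <- classify_blind(same, same, co_both, list())
  expect_equal(call2$category, "single_fold")

  # no divergence but a planted unexplained 6-contact cluster
  preds <- data.frame(i = c(10, 10, 10, rep(20, 6)),
                      j = c(30, 31, 32, 45:50))
  f_alt <- dbscan_filter(preds, eps = 2, min_samples = 3)
  alt <- alternative_signal_clusters(f_alt, ca, cb)
  expect_length(alt, 1)
  expect_equal(nrow(alt[[1]]), 6)
  call3 <- classify_blind(same, same, corroborate(ca, cb, f_alt), alt)
  expect_equal(call3$category, "category2")
  expect_true("multimer_ambiguity" %in% call3$flags)

  # divergence without any corroboration stays a single-fold call
  co_none <- corroborate(ca, cb,
                         dbscan_filter(data.frame(i = 1, j = 20), eps = 2))
  call4 <- classify_blind(div_a, div_b, co_none)
  expect_equal(call4$category, "single_fold")
})

test_that("unexplained clusters respect size, separation and overlap gates", {
  ca <- as_contact_sets(data.frame(i = 10, j = 30), L = 60, id = "a")
  cb <- as_contact_sets(data.frame(i = 11, j = 31), L = 60, id = "b")
  # size 4 < 5: not a signal
  f4 <- dbscan_filter(data.frame(i = rep(20, 4), j = 45:48), eps = 2,
                      min_samples = 3)
  expect_length(alternative_signal_clusters(f4, ca, cb), 0)
  # touching a structure contact within the box: not a signal
  f5 <- dbscan_filter(data.frame(i = rep(11, 5), j = 29:33), eps = 2,
                      min_samples = 3)
  expect_length(alternative_signal_clusters(f5, ca, cb), 0)
  # short-range cluster (mean separation < 6): not a signal
  f6 <- dbscan_filter(data.frame(i = 40:44, j = 43:47), eps = 2,
                      min_samples = 3)
  expect_length(alternative_signal_clusters(f6, ca, cb), 0)
})

test_that("dominant-only positions exclude anything with alternative pairs", {
  dm <- toy_dualmap12()
  dm$dominant_id <- "a"
  # predictions: dominant pairs (1,5) and (2,6); alternative pair (2,10)
  preds <- data.frame(i = c(1, 2, 2), j = c(5, 6, 10))
  cats <- categorize_predictions(preds, dm, tol = 0)
  expect_equal(dominant_only_positions(cats), c(1, 5, 6))
  # all-dominant predictions return every touched position
  cats2 <- categorize_predictions(preds[1:2, ], dm, tol = 0)
  expect_equal(dominant_only_positions(cats2), c(1, 2, 5, 6))
  # hand-labelled 12-residue toy with common and unobserved pairs mixed in
  preds3 <- data.frame(i = c(1, 2, 3, 8), j = c(5, 10, 9, 12))
  cats3 <- categorize_predictions(preds3, dm, tol = 0)
  expect_equal(dominant_only_positions(cats3), c(1, 5))
})
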