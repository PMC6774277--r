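test_that("coverage equals the sum of the ten strand/base counts in both
           published excerpts (25/25 rows)", {
  for (prof in list(candidates_profile(), buffer_series_profile())) {
    counts <- prof[, c("A", "G", "T", "C", "N", "a", "g", "t", "c", "n")]
    expect_equal(rowSums(counts), as.numeric(prof$cov))
  }
})

test_that("mismatch_rate reproduces every printed mismatch cell to 5 decimals", {
  for (prof in list(candidates_profile(), buffer_series_profile())) {
    mm <- mismatch_rate(prof, prof$refbase)
    expect_equal(round(mm, 5), prof$mismatch, tolerance = 1e-9)
  }
})

test_that("the spanning-read jump denominator is integer-consistent with the
           published rates", {
  # rows with nonzero jump rates: the implied deletion counts under
  # span = cov + direct + double must be integers and reproduce the printed
  # rates to all 5 decimals
  check_row <- function(cov, direct_rate, delayed_rate, double_rate) {
    # solve span from cov = span * (1 - direct_rate - double_rate)
    span <- round(cov / (1 - direct_rate - double_rate))
    direct <- direct_rate * span
    delayed <- delayed_rate * span
    double <- double_rate * span
    # implied counts are integers (to printed 5-decimal precision)
    expect_lt(abs(direct - round(direct)), 0.05)
    expect_lt(abs(delayed - round(delayed)), 0.05)
    expect_lt(abs(double - round(double)), 0.05)
    jr <- jump_rates(cov, round(direct), round(delayed), round(double))
    expect_equal(round(jr$single_jump_direct, 5), direct_rate)
    expect_equal(round(jr$single_jump_delayed, 5), delayed_rate)
    expect_equal(round(jr$double_jump, 5), double_rate)
    jr$span
  }
  cand <- candidates_profile()
  thr1 <- cand[cand$pos == 58 & grepl("Thr\\|AGT", cand$ref_seg), ][1, ]
  expect_equal(check_row(thr1$cov, thr1$single_jump_direct,
                         thr1$single_jump_delayed, thr1$double_jump), 451)
  thr2 <- cand[cand$pos == 58 & grepl("Thr\\|AGT", cand$ref_seg), ][2, ]
  expect_equal(check_row(thr2$cov, thr2$single_jump_direct,
                         thr2$single_jump_delayed, thr2$double_jump), 688)
  buf <- buffer_series_profile()
  refrow <- buf[buf$pos == 59 & grepl("Reference", buf$ref_seg), ]
  expect_equal(check_row(refrow$cov, refrow$single_jump_direct,
                         refrow$single_jump_delayed, refrow$double_jump), 6585)
})

test_that("the arrest formula reproduces the published reference-buffer value
           from implied spanning-read counts", {
  buf <- buffer_series_profile()
  span59 <- 6585   # cov 6311 + 274 double-jump reads (integer-consistency)
  r60 <- buf[buf$pos == 60 & grepl("Reference", buf$ref_seg), ]
  span60 <- r60$cov  # no deletions at pos 60 in the reference buffer
  expect_equal(span60, 42890L)
  expect_equal(round(arrest_rate(span59, span60), 5), 0.84647)
})

test_that("arrest_rate clamps and handles missing neighbors", {
  expect_equal(arrest_rate(100, 100), 0)
  expect_equal(arrest_rate(150, 100), 0)        # coverage rising toward 5'
  expect_equal(arrest_rate(50, 100), 0.5)
  expect_equal(arrest_rate(50, NA), 0)          # pos+1 absent
  expect_equal(arrest_rate(50, 0), 0)
})

test_that("jump_rates returns zeros when nothing spans", {
  jr <- jump_rates(0, 0, 0, 0)
  expect_equal(unlist(jr[c("single_jump_direct", "single_jump_delayed",
                           "double_jump")]), c(single_jump_direct = 0,
                                               single_jump_delayed = 0,
                                               double_jump = 0))
})

test_that("a simple homogeneous column counts correctly", {
  pf <- withr::local_tempfile()
  writeLines(c("r1\t1\tA\t10\t^I.^I.^I.^I.^I.^I.^I.^I.^I.^I.\tIIIIIIIIII",
               "r1\t2\tC\t10\t.$.$.$.$.$.$.$.$.$.$\tIIIIIIIIII"), pf)
  p <- read_pileup(pf)
  ref <- structure(c(r1 = "AC"), class = "reference_set")
  prof <- compute_profile(p, ref)
  expect_equal(prof$A[1], 10L)
  expect_equal(sum(prof[1, c("G", "T", "C", "N", "a", "g", "t", "c", "n")]), 0)
  expect_equal(prof$mismatch, c(0, 0))
})

test_that("deletion placeholders are excluded from cov and counted as jumps", {
  ref <- structure(c(r1 = "ACGTACGT"), class = "reference_set")
  reads <- list(
    info = data.frame(ref_name = "r1", start = c(1L, 1L, 1L), strand = "+",
                      stringsAsFactors = FALSE),
    ops = list(strsplit("ACGTACGT", "")[[1]],
               c("A", "C", "*", "T", "A", "C", "G", "T"),
               c("A", "C", "*", "T", "A", "C", "G", "T")),
    ins = list(NULL, NULL, NULL))
  p <- rtsig:::reads_to_pileup(reads, ref)
  prof <- compute_profile(p, ref)
  r3 <- prof[prof$pos == 3, ]
  expect_equal(r3$cov, 1L)
  expect_equal(r3$single_jump_direct, 2 / 3)   # span = 1 + 2 direct
  r4 <- prof[prof$pos == 4, ]
  expect_equal(r4$cov, 3L)
  expect_equal(r4$single_jump_delayed, 2 / 3)  # len-1 deletion at pos-1
})

test_that("prebase is the 3'-neighbor reference base, '-' at the terminus", {
  ref <- structure(c(r1 = "GATTC"), class = "reference_set")
  sim <- simulate_pileup(ref, NULL, depth = 5, seed = 3)
  prof <- compute_profile(sim$pileup, ref)
  expect_equal(prof$prebase, c("A", "T", "T", "C", "-"))
  expect_equal(prof$refbase, c("G", "A", "T", "T", "C"))
})

test_that("unmodified simulated data yields all-zero rates", {
  ref <- simulate_reference(1, 76, seed = 55)
  sim <- simulate_pileup(ref, NULL, depth = 400, seed = 56)
  prof <- compute_profile(sim$pileup, ref)
  expect_equal(nrow(prof), 76L)
  for (col in c("mismatch", "single_jump_direct", "single_jump_delayed",
                "double_jump", "arrest")) {
    expect_equal(prof[[col]], rep(0, 76))
  }
})

test_that("profile rates recover planted site parameters at depth 5000", {
  ref <- simulate_reference(1, 60, seed = 61)
  site <- mod_site("sim_ref_1", 30, p_arrest = 0.3, p_mismatch = 0.4,
                   p_jump1 = 0.03, p_jump2 = 0.05)
  sim <- simulate_pileup(ref, site, depth = 5000, seed = 62)
  prof <- compute_profile(sim$pileup, ref)
  row <- prof[prof$pos == 30, ]
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(row$mismatch - 0.4), 3 * se(0.4, row$cov))
  # span counts the non-arrested reads, among which each jump has its plain
  # per-read probability
  span30 <- row$cov / (1 - row$single_jump_direct - row$double_jump)
  expect_lt(abs(row$arrest - 0.3), 3 * se(0.3, 5000))
  expect_lt(abs(row$single_jump_direct - 0.03), 3 * se(0.03, span30))
  expect_lt(abs(row$double_jump - 0.05), 3 * se(0.05, span30))
})

test_that("rows below min_cov are suppressed", {
  ref <- simulate_reference(1, 40, seed = 71)
  sim <- simulate_pileup(ref, mod_site("sim_ref_1", 20, p_arrest = 0.9),
                         depth = 100, seed = 72)
  prof_all <- compute_profile(sim$pileup, ref)
  prof_cut <- compute_profile(sim$pileup, ref, min_cov = 50)
  expect_true(all(prof_cut$cov >= 50))
  expect_lt(nrow(prof_cut), nrow(prof_all))
})

test_that("a pileup reference missing from the FASTA is a hard error", {
  ref <- simulate_reference(1, 30, seed = 81)
  sim <- simulate_pileup(ref, NULL, depth = 10, seed = 82)
  other <- structure(c(zz = "ACGT"), class = "reference_set")
  expect_error(compute_profile(sim$pileup, other), "sim_ref_1")
})

test_that("increasing planted arrest probability never decreases the
           estimated arrest rate", {
  ref <- simulate_reference(1, 40, seed = 91)
  levels <- c(0.05, 0.2, 0.4, 0.6, 0.8)
  means <- vapply(levels, function(pa) {
    est <- vapply(1:5, function(s) {
      sim <- simulate_pileup(ref, mod_site("sim_ref_1", 20, p_arrest = pa),
                             depth = 10000, seed = 900 + s)
      prof <- compute_profile(sim$pileup, ref)
      prof$arrest[prof$pos == 20]
    }, numeric(1))
    mean(est)
  }, numeric(1))
  expect_false(is.unsorted(means))
})
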