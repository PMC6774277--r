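# shared fixtures built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# published per-position signature excerpts shipped with the package:
# 13 m1A candidate rows (AlkB demethylation screen) and the Asn(GTT)
# buffer-series rows (positions 58-60 under four RT buffers)
candidates_profile <- function() {
  read_profile(system.file("extdata", "yeast_trna_m1A_candidates.profile",
                           package = "rtsig"))
}

buffer_series_profile <- function() {
  read_profile(system.file("extdata", "asn_gtt_rt_buffer_series.profile",
                           package = "rtsig"))
}

# minimal single-reference set without any C (or G) so that every injected
# C-tail (or reverse-strand G-tail) overhang base mismatches the reference
reference_without <- function(bases_excluded, length = 60L, seed = 101L) {
  set.seed(seed)
  alphabet <- setdiff(c("A", "C", "G", "T"), bases_excluded)
  s <- paste(sample(alphabet, length, replace = TRUE), collapse = "")
  structure(stats::setNames(s, "r1"), class = "reference_set")
}

# build a one-row profile data.frame from explicit fields (counts default 0)
profile_row <- function(ref_seg, pos, refbase, cov, prebase = "-",
                        mismatch = 0, A = 0, G = 0, T = 0, C = 0, N = 0,
                        a = 0, g = 0, t = 0, c = 0, n = 0,
                        single_jump_direct = 0, single_jump_delayed = 0,
                        double_jump = 0, arrest = 0) {
  df <- data.frame(ref_seg = ref_seg, pos = as.integer(pos),
                   refbase = refbase, cov = as.integer(cov),
                   prebase = prebase, mismatch = mismatch,
                   A = A, G = G, T = T, C = C, N = N,
                   a = a, g = g, t = t, c = c, n = n,
                   single_jump_direct = single_jump_direct,
                   single_jump_delayed = single_jump_delayed,
                   double_jump = double_jump, arrest = arrest,
                   stringsAsFactors = FALSE)
  class(df) <- c("rt_profile", "data.frame")
  df
}

# random synthetic profile for property tests: n rows over one reference,
# counts drawn so cov == sum of counts holds by construction
random_profile <- function(n, seed, ref_seg = "rp") {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    counts <- as.integer(stats::rpois(10, lambda = sample(c(5, 40, 120), 1)))
    names(counts) <- c("A", "G", "T", "C", "N", "a", "g", "t", "c", "n")
    rb <- sample(c("A", "C", "G", "T"), 1)
    cov <- sum(counts)
    mm <- if (cov > 0) mismatch_rate(as.data.frame(t(counts)), rb) else 0
    profile_row(ref_seg, i, rb, cov, prebase = sample(c("A", "C", "G", "T"), 1),
                mismatch = mm,
                A = counts[["A"]], G = counts[["G"]], T = counts[["T"]],
                C = counts[["C"]], N = counts[["N"]],
                a = counts[["a"]], g = counts[["g"]], t = counts[["t"]],
                c = counts[["c"]], n = counts[["n"]],
                arrest = stats::runif(1))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rt_profile", "data.frame")
  out
}

expect_pileup_equal <- function(a, b) {
  expect_equal(a$columns, b$columns)
  expect_equal(a$events, b$events)
}
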