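#' Single-sample threshold filter: likely modified vs likely unmodified
#'
#' Splits the positions of one profile whose reference base equals the
#' nucleobase of interest into "likely modified" (coverage, mismatch and
#' arrest all reach their thresholds) and "likely unmodified" (the rest).
#' For m1A, mismatch and arrest thresholds alone usually separate modified
#' adenosines well. Rows with other reference bases are dropped.
#'
#' @param profile An `rt_profile` data.frame.
#' @param base Nucleobase of interest (default `"A"`).
#' @param min_mismatch,min_arrest Minimum rates in `[0,1]`.
#' @param min_cov Minimum coverage.
#' @return A list with `likely_modified` and `likely_unmodified`, both
#'   `rt_profile` data.frames.
#' @export
threshold_filter <- function(profile, base = "A", min_mismatch = 0,
                             min_arrest = 0, min_cov = 0L) {
  profile <- as.data.frame(profile)
  stopifnot(min_mismatch >= 0, min_mismatch <= 1,
            min_arrest >= 0, min_arrest <= 1, min_cov >= 0)
  base <- toupper(base)
  of_base <- profile[toupper(profile$refbase) == base, , drop = FALSE]
  pass <- of_base$cov >= min_cov &
    of_base$mismatch >= min_mismatch &
    of_base$arrest >= min_arrest
  mk <- function(df) {
    rownames(df) <- NULL
    class(df) <- c("rt_profile", "data.frame")
    df
  }
  list(likely_modified = mk(of_base[pass, , drop = FALSE]),
       likely_unmodified = mk(of_base[!pass, , drop = FALSE]))
}

#' Two-sample demethylation relative-change filter
#'
#' Compares the mismatch rate of each shared position between a reference
#' (e.g. untreated) and a treated sample (e.g. AlkB demethylated, which
#' "repairs" m1A and erases its RT signature, lowering the mismatch rate).
#' For every shared position whose reference base is the nucleobase of
#' interest, the absolute change is `m_ref - m_treated` and the relative
#' change is `abs_change / m_ref`. A position passes when both changes and
#' the coverage requirement reach their thresholds; the output contains the
#' treated sample's rows for the passing positions.
#'
#' Positions present in only one profile are skipped, as are positions where
#' the reference-sample mismatch is 0 (relative change undefined); skip
#' counts are attached as the `"skip_report"` attribute.
#'
#' @param reference_profile,treated_profile `rt_profile` data.frames indexed
#'   by (`ref_seg`, `pos`).
#' @param base Nucleobase of interest (default `"A"`).
#' @param min_rel_change Minimum relative mismatch-rate change (default 0.5).
#' @param min_abs_change Minimum absolute mismatch-rate change (default 0.3).
#' @param min_cov Minimum coverage (default 250).
#' @param cov_scope Apply `min_cov` to `"both"` samples (default) or to
#'   `"either"` (at least one sample).
#' @return The treated sample's passing rows as an `rt_profile`, with a
#'   `"skip_report"` attribute (named integer vector).
#' @examples
#' # a strong m1A signature (mismatch 0.845) erased down to 0.163 passes:
#' # abs change 0.682 >= 0.3, relative change 0.807 >= 0.5
#' @export
demeth_change_filter <- function(reference_profile, treated_profile,
                                 base = "A", min_rel_change = 0.5,
                                 min_abs_change = 0.3, min_cov = 250L,
                                 cov_scope = c("both", "either")) {
  cov_scope <- match.arg(cov_scope)
  stopifnot(min_rel_change >= 0, min_rel_change <= 1,
            min_abs_change >= 0, min_abs_change <= 1, min_cov >= 0)
  rp <- as.data.frame(reference_profile)
  tp <- as.data.frame(treated_profile)
  base <- toupper(base)

  key_r <- paste(rp$ref_seg, rp$pos, sep = "\r")
  key_t <- paste(tp$ref_seg, tp$pos, sep = "\r")
  if (anyDuplicated(key_r) || anyDuplicated(key_t)) {
    stop("duplicated (ref_seg, pos) rows in a profile")
  }
  idx_r <- match(key_t, key_r)
  shared <- !is.na(idx_r)
  of_base <- shared & toupper(tp$refbase) == base

  m_ref <- rp$mismatch[idx_r[of_base]]
  m_trt <- tp$mismatch[of_base]
  cov_r <- rp$cov[idx_r[of_base]]
  cov_t <- tp$cov[of_base]

  undef <- m_ref <= 0
  abs_change <- m_ref - m_trt
  rel_change <- ifelse(undef, NA_real_, abs_change / m_ref)
  cov_ok <- if (cov_scope == "both") {
    cov_r >= min_cov & cov_t >= min_cov
  } else {
    cov_r >= min_cov | cov_t >= min_cov
  }
  pass <- !undef & abs_change >= min_abs_change &
    rel_change >= min_rel_change & cov_ok

  out <- tp[which(of_base)[pass], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rt_profile", "data.frame")
  attr(out, "skip_report") <- c(
    treated_only = sum(!shared),
    reference_only = nrow(rp) - length(unique(idx_r[shared])),
    zero_reference_mismatch = sum(undef))
  out
}
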