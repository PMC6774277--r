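#' @title RT-signature profiles
#'
#' @description A profile is the per-position record of reverse-transcription
#' signature statistics: strand-split base counts, coverage, the 3'-adjacent
#' reference base (`prebase` — the base the RT enzyme encounters immediately
#' before the position of interest, reading 3' to 5'), and five rates:
#' `mismatch`, three jump rates (`single_jump_direct`, `single_jump_delayed`,
#' `double_jump`) and `arrest`. It is stored as a data.frame with the exact
#' column set below and serialized as a tab-separated table.
#'
#' Columns: `ref_seg, pos, refbase, cov, prebase, mismatch, A, G, T, C, N, a,
#' g, t, c, n, single_jump_direct, single_jump_delayed, double_jump, arrest`.
#' Uppercase count columns are forward-strand, lowercase reverse-strand;
#' `cov` counts aligned bases only (deletion placeholders excluded) and always
#' equals the sum of the ten count columns.
#'
#' @name rt_profile
NULL

profile_cols <- c("ref_seg", "pos", "refbase", "cov", "prebase", "mismatch",
                  "A", "G", "T", "C", "N", "a", "g", "t", "c", "n",
                  "single_jump_direct", "single_jump_delayed", "double_jump",
                  "arrest")
count_cols <- c("A", "G", "T", "C", "N", "a", "g", "t", "c", "n")
rate_cols <- c("mismatch", "single_jump_direct", "single_jump_delayed",
               "double_jump", "arrest")

#' Mismatch rate from strand-split base counts
#'
#' The mismatch rate at a position is 1 minus the fraction of aligned bases
#' (both strands) that match the reference base: reads misincorporated during
#' reverse transcription at a modified residue inflate it.
#'
#' @param counts A data.frame (or coercible) with the ten count columns
#'   `A,G,T,C,N` (forward strand) and `a,g,t,c,n` (reverse strand); one row
#'   per position.
#' @param refbase Character vector of reference bases (recycled to rows).
#' @return Numeric vector of rates in `[0,1]`; `NA` where coverage is 0.
#' @examples
#' mismatch_rate(data.frame(A = 493, G = 8, T = 2, C = 94, N = 0,
#'                          a = 0, g = 5, t = 5, c = 92, n = 0), "A")
#' @export
mismatch_rate <- function(counts, refbase) {
  counts <- as.data.frame(counts)
  stopifnot(all(count_cols %in% names(counts)))
  refbase <- rep_len(toupper(refbase), nrow(counts))
  cm <- as.matrix(counts[count_cols])
  cov <- rowSums(cm)
  i <- seq_len(nrow(cm))
  m <- cm[cbind(i, match(refbase, count_cols))] +
    cm[cbind(i, match(tolower(refbase), count_cols))]
  ifelse(cov > 0, 1 - as.numeric(m) / cov, NA_real_)
}

#' Jump rates from spanning-read counts
#'
#' Jumps are template nucleotides skipped by the reverse transcriptase,
#' observed as alignment deletions: length-1 exactly at the position
#' (*single jump direct*), length-1 at the -1 neighbor (*single jump
#' delayed*; these reads do align a base at the position itself), and
#' length-2 covering the position and its -1 neighbor (*double jump*). Each
#' rate is the respective read count divided by the number of reads spanning
#' the position, `span = cov + direct + double` (delayed-jump reads already
#' contribute an aligned base to `cov`).
#'
#' @param cov Aligned-base counts at the position.
#' @param direct,delayed,double Deletion read counts as defined above.
#' @return A data.frame with `single_jump_direct`, `single_jump_delayed`,
#'   `double_jump` and the `span` denominator; rates are 0 where span is 0.
#' @export
jump_rates <- function(cov, direct, delayed, double) {
  span <- cov + direct + double
  safe <- function(x) ifelse(span > 0, x / span, 0)
  data.frame(single_jump_direct = safe(direct),
             single_jump_delayed = safe(delayed),
             double_jump = safe(double),
             span = span)
}

#' Arrest rate from spanning-read counts at a position and its 3' neighbor
#'
#' Reverse transcription proceeds 3' to 5' along the template, so the
#' position 3' of a site (pos + 1) is reached first; cDNA synthesis aborting
#' at the site appears as a coverage drop relative to that neighbor. The rate
#' is `1 - span(pos) / span(pos + 1)`, clamped to `[0,1]`; it is 0 when the
#' neighbor is absent or has zero span.
#'
#' @param span_pos Spanning-read count at the position.
#' @param span_next Spanning-read count at pos + 1 (NA if absent).
#' @return Numeric vector of arrest rates in `[0,1]`.
#' @export
arrest_rate <- function(span_pos, span_next) {
  out <- ifelse(!is.na(span_next) & span_next > 0,
                1 - span_pos / span_next, 0)
  pmin(pmax(out, 0), 1)
}

#' Compute the per-position RT-signature profile from a pileup
#'
#' Tallies strand-split base counts, jump counts and spanning reads for every
#' covered reference position and derives the five signature rates. Deletion
#' placeholders are excluded from `cov`; deletion runs are located via the
#' `-N` annotations carried by the event preceding each run. `prebase` is the
#' reference base at pos + 1 (`"-"` at the reference 3' terminus).
#'
#' @param p A [pileup] object (normally overhang-trimmed first; see
#'   [trim_overhangs()]).
#' @param ref A reference set from [read_fasta()]; every reference named in
#'   the pileup must be present.
#' @param min_cov Minimum coverage for a row to be emitted (default 1;
#'   zero-coverage positions are always suppressed, their rates being
#'   undefined).
#' @param arrest_mode `"span"` (default): arrest uses spanning-read counts
#'   (`cov` + direct + double jumps) at the position and its 3' neighbor.
#'   `"simple"`: plain coverage ratio `1 - cov(pos)/cov(pos+1)`.
#' @return A data.frame of class `rt_profile` with the standard column set
#'   (see [rt_profile]).
#' @export
compute_profile <- function(p, ref, min_cov = 1L,
                            arrest_mode = c("span", "simple")) {
  stopifnot(inherits(p, "pileup"))
  arrest_mode <- match.arg(arrest_mode)
  cols <- p$columns
  ev <- p$events
  missing_ref <- setdiff(unique(cols$ref_name), names(ref))
  if (length(missing_ref) > 0L) {
    stop("reference(s) in pileup absent from the FASTA: ",
         paste(missing_ref, collapse = ", "))
  }
  out <- vector("list", length(unique(cols$ref_name)))
  names(out) <- unique(cols$ref_name)
  for (rn in unique(cols$ref_name)) {
    ci <- which(cols$ref_name == rn)
    pos <- cols$pos[ci]
    npos <- length(pos)
    colmap <- match(ev$col, ci)          # index into pos, NA for other refs
    here <- !is.na(colmap)

    counts <- matrix(0L, nrow = npos, ncol = 10L,
                     dimnames = list(NULL, count_cols))
    isb <- here & ev$kind == "base"
    for (b in c("A", "G", "T", "C", "N")) {
      counts[, b] <- tabulate(colmap[isb & ev$base == b & ev$strand == "+"],
                              npos)
      counts[, tolower(b)] <-
        tabulate(colmap[isb & ev$base == b & ev$strand == "-"], npos)
    }
    cov <- as.integer(rowSums(counts))

    # deletion runs: annotation at column q with length L spans q+1 .. q+L
    isdel <- here & !is.na(ev$indel_op) & ev$indel_op == "del"
    dstart <- cols$pos[ev$col[isdel]] + 1L
    dlen <- ev$indel_len[isdel]
    cnt_at <- function(run_pos) tabulate(match(run_pos, pos), npos)
    direct <- cnt_at(dstart[dlen == 1L])
    delayed_src <- cnt_at(dstart[dlen == 1L] + 1L)  # len-1 run at pos-1
    double <- cnt_at(dstart[dlen == 2L] + 1L)       # len-2 run at pos-1,pos

    jr <- jump_rates(cov, direct, delayed_src, double)
    span <- jr$span
    nxt <- match(pos + 1L, pos)
    if (arrest_mode == "span") {
      arrest <- arrest_rate(span, span[nxt])
    } else {
      arrest <- arrest_rate(cov, cov[nxt])
    }

    refbase <- ref_base_at(ref, rn, pos)
    prebase <- ref_base_at(ref, rn, pos + 1L)
    prebase[prebase == ""] <- "-"
    mm <- mismatch_rate(as.data.frame(counts), refbase)
    mm[is.na(mm)] <- 0

    df <- data.frame(ref_seg = rn, pos = pos, refbase = refbase, cov = cov,
                     prebase = prebase, mismatch = mm,
                     as.data.frame(counts),
                     single_jump_direct = jr$single_jump_direct,
                     single_jump_delayed = jr$single_jump_delayed,
                     double_jump = jr$double_jump,
                     arrest = arrest,
                     stringsAsFactors = FALSE, check.names = FALSE)
    out[[rn]] <- df[df$cov >= max(as.integer(min_cov), 1L), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rt_profile", "data.frame")
  res
}

#' Write a profile as a tab-separated table
#'
#' Serializes with the standard header and rates formatted to 5 decimal
#' places; counts and positions are written as integers.
#'
#' @param profile An `rt_profile` data.frame (see [rt_profile]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  profile <- as.data.frame(profile)
  stopifnot(all(profile_cols %in% names(profile)))
  profile <- profile[profile_cols]
  for (rc in rate_cols) {
    profile[[rc]] <- sprintf("%.5f", profile[[rc]])
  }
  lines <- c(paste(profile_cols, collapse = "\t"),
             if (nrow(profile) > 0L) {
               do.call(paste, c(unname(as.list(profile)), sep = "\t"))
             })
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-separated profile
#'
#' The header must contain every mandatory column (order-insensitive; extra
#' columns are tolerated with a warning and dropped). The coverage identity
#' `cov == A+G+T+C+N+a+g+t+c+n` is checked for every row; violations are
#' reported per row as warnings.
#'
#' @param path Path to a profile TSV.
#' @return An `rt_profile` data.frame with the standard columns.
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  missing <- setdiff(profile_cols, names(df))
  if (length(missing) > 0L) {
    stop("profile is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), profile_cols)
  if (length(extra) > 0L) {
    warning("ignoring extra profile column(s): ", paste(extra, collapse = ", "))
  }
  df <- df[profile_cols]
  df$pos <- as.integer(df$pos)
  df$cov <- as.integer(df$cov)
  for (cc in count_cols) df[[cc]] <- as.integer(df[[cc]])
  for (rc in rate_cols) df[[rc]] <- as.numeric(df[[rc]])
  csum <- rowSums(df[count_cols])
  bad <- which(df$cov != csum)
  if (length(bad) > 0L) {
    warning("cov differs from the sum of base counts at: ",
            paste(paste0(df$ref_seg[bad], ":", df$pos[bad]), collapse = ", "))
  }
  class(df) <- c("rt_profile", "data.frame")
  df
}
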