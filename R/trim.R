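#' Trim residual C-tail overhang bases from read termini
#'
#' Library-preparation protocols that C-tail the cDNA 3' end can leave a few
#' untemplated tailing bases on reads even after adapter trimming. Once
#' aligned, these overhang bases corrupt the terminal pileup columns and mimic
#' modification signatures. This post-alignment step reconstructs per-read
#' linkage from the pileup (read slot order is preserved across consecutive
#' columns; `^` inserts a slot, `$` removes it) and then, for each selected
#' read terminus, repeatedly removes the terminal base while it mismatches the
#' reference at its position, up to `max_iterations` bases per terminus.
#'
#' A genuine modification-induced mismatch that happens to sit exactly at a
#' read terminus is indistinguishable from an overhang base and is removed as
#' well (at most `max_iterations` bases); this collateral damage is inherent
#' to the method. Matching terminal bases stop the iteration, so damage is
#' bounded.
#'
#' @param p A [pileup] object sorted by (reference, position).
#' @param ref A reference set from [read_fasta()] (or a named character
#'   vector of uppercase sequences).
#' @param max_iterations Maximum number of bases removed per read terminus
#'   (default 10).
#' @param ends Which alignment ends to trim: `"both"` (default; paired-end
#'   mates map in both orientations, so the cDNA 3' terminus may be either
#'   alignment end), `"left"` or `"right"`.
#' @param enabled If `FALSE`, return the input unchanged.
#' @return A [pileup] object; still valid pileup, with depths and event lists
#'   updated consistently. Columns whose events are all removed disappear.
#' @examples
#' ref <- structure(c(r1 = "ACGTT"), class = "reference_set")
#' sim <- simulate_pileup(ref, depth = 5, seed = 1)
#' trimmed <- trim_overhangs(sim$pileup, ref)
#' @export
trim_overhangs <- function(p, ref, max_iterations = 10L,
                           ends = c("both", "left", "right"),
                           enabled = TRUE) {
  stopifnot(inherits(p, "pileup"))
  ends <- match.arg(ends)
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L) {
    stop("max_iterations must be a positive integer")
  }
  if (!enabled) {
    return(p)
  }
  missing_ref <- setdiff(unique(p$columns$ref_name), names(ref))
  if (length(missing_ref) > 0L) {
    stop("reference(s) absent from the reference set: ",
         paste(missing_ref, collapse = ", "))
  }
  reads <- pileup_to_reads(p)
  reads <- normalize_reads(reads)

  for (i in seq_along(reads$ops)) {
    o <- reads$ops[[i]]
    rn <- reads$info$ref_name[i]
    start <- reads$info$start[i]
    rs <- ref[[rn]]

    if (ends %in% c("both", "left")) {
      removed <- 0L
      repeat {
        while (length(o) > 0L && o[1L] == "*") {  # terminal deletion: drop
          o <- o[-1L]; start <- start + 1L
        }
        if (length(o) == 0L || removed >= max_iterations) break
        if (o[1L] == substring(rs, start, start)) break
        o <- o[-1L]; start <- start + 1L; removed <- removed + 1L
        if (!is.null(reads$ins[[i]])) {
          a <- reads$ins[[i]]
          a$idx <- a$idx - 1L
          a <- a[a$idx >= 1L, , drop = FALSE]
          reads$ins[[i]] <- if (nrow(a)) a else NULL
        }
      }
    }
    if (ends %in% c("both", "right")) {
      removed <- 0L
      repeat {
        while (length(o) > 0L && o[length(o)] == "*") {
          o <- o[-length(o)]
        }
        if (length(o) == 0L || removed >= max_iterations) break
        endpos <- start + length(o) - 1L
        if (o[length(o)] == substring(rs, endpos, endpos)) break
        o <- o[-length(o)]; removed <- removed + 1L
        if (!is.null(reads$ins[[i]])) {
          a <- reads$ins[[i]]
          a <- a[a$idx <= length(o), , drop = FALSE]
          reads$ins[[i]] <- if (nrow(a)) a else NULL
        }
      }
    }
    reads$ops[[i]] <- o
    reads$info$start[i] <- start
  }
  reads_to_pileup(reads, ref)
}
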