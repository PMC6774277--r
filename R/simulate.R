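#' Simulate a random reference set
#'
#' Generates uniform-random nucleotide references (tRNA-scale by default),
#' deterministically for a given seed.
#'
#' @param n_refs Number of references.
#' @param ref_length Length of each reference (recycled).
#' @param seed Integer seed (mandatory; no wall-clock seeding).
#' @return A `reference_set` named character vector
#'   (`sim_ref_1`, `sim_ref_2`, ...).
#' @export
simulate_reference <- function(n_refs = 1L, ref_length = 76L, seed) {
  stopifnot(n_refs >= 1L, all(ref_length >= 1L))
  set.seed(seed)
  ref_length <- rep_len(as.integer(ref_length), n_refs)
  seqs <- vapply(ref_length, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- paste0("sim_ref_", seq_len(n_refs))
  structure(seqs, class = "reference_set")
}

#' Specify a modified site for the simulator
#'
#' One row of the site table consumed by [simulate_pileup()]: the
#' probabilities with which the simulated reverse transcriptase, upon
#' reaching the site (reading 3' to 5'), arrests (the read's 5'-most base
#' becomes pos + 1), skips one template nucleotide (length-1 deletion at the
#' site), skips two (length-2 deletion covering the site and its -1
#' neighbor), or misincorporates (the aligned base is drawn from
#' `misread` over the three non-reference bases).
#'
#' @param ref_name Reference name.
#' @param pos 1-based site position.
#' @param p_arrest,p_mismatch,p_jump1,p_jump2 Event probabilities in `[0,1]`;
#'   `p_jump1 + p_jump2` must not exceed 1.
#' @param misread Probabilities over the three non-reference bases in
#'   alphabetical order (default uniform); must sum to 1.
#' @return A one-row data.frame; rows can be `rbind`-ed into a site table.
#' @export
mod_site <- function(ref_name, pos, p_arrest = 0, p_mismatch = 0,
                     p_jump1 = 0, p_jump2 = 0, misread = rep(1 / 3, 3)) {
  stopifnot(all(c(p_arrest, p_mismatch, p_jump1, p_jump2) >= 0),
            all(c(p_arrest, p_mismatch, p_jump1, p_jump2) <= 1),
            length(misread) == 3L, abs(sum(misread) - 1) < 1e-8)
  if (p_jump1 + p_jump2 > 1) {
    stop("site probability mass > 1: p_jump1 + p_jump2 = ", p_jump1 + p_jump2)
  }
  data.frame(ref_name = ref_name, pos = as.integer(pos), p_arrest = p_arrest,
             p_mismatch = p_mismatch, p_jump1 = p_jump1, p_jump2 = p_jump2,
             mis1 = misread[1L], mis2 = misread[2L], mis3 = misread[3L],
             stringsAsFactors = FALSE)
}

#' Simulate reads over a reference and emit them as a pileup
#'
#' Models the phenomenology of reverse-transcription signatures: cDNA
#' synthesis proceeds 3' to 5' along each template, so every read starts at
#' the reference 3' end (the highest position) and extends toward position 1
#' unless the enzyme arrests at a modified site, truncating coverage 5' of
#' it. At each site, surviving reads may skip one or two template nucleotides
#' (length-1/length-2 alignment deletions) or misincorporate. Optionally, a
#' C-tailing overhang is appended past the genuine cDNA 3' terminus (the
#' read's 5'-most aligned position): `k` extra bases (geometric length,
#' capped), `C` on forward-strand alignments and `G` (its complement) on
#' reverse-strand alignments. Reads are split into forward/reverse
#' populations and encoded as valid pileup text with `^`/`$`/`-N`/`*`
#' markers.
#'
#' @param ref A `reference_set`.
#' @param sites Site table from [mod_site()] (rbind rows), or `NULL`.
#' @param depth Reads per reference.
#' @param strand_fraction Fraction of reads on the forward strand.
#' @param overhang_prob Per-read probability of a residual overhang.
#' @param overhang_mean_len Mean of the geometric overhang-length model.
#' @param overhang_max_len Hard cap on overhang length.
#' @param error_rate Optional uniform per-base misread probability away from
#'   sites (default 0: background is clean).
#' @param seed Integer seed (mandatory).
#' @return A list with `pileup` (a [pileup] object), `truth` (per-site
#'   realized event counts next to the generative parameters, plus overhang
#'   injection counts) and `reads` (the internal read representation).
#' @export
simulate_pileup <- function(ref, sites = NULL, depth = 1000L,
                            strand_fraction = 0.5, overhang_prob = 0,
                            overhang_mean_len = 2, overhang_max_len = 5L,
                            error_rate = 0, seed) {
  stopifnot(inherits(ref, "reference_set") || !is.null(names(ref)),
            depth >= 1L, strand_fraction >= 0, strand_fraction <= 1,
            overhang_prob >= 0, overhang_prob <= 1, error_rate >= 0,
            error_rate < 1)
  if (!is.null(sites)) {
    stopifnot(all(c("ref_name", "pos", "p_arrest", "p_mismatch", "p_jump1",
                    "p_jump2") %in% names(sites)))
    if (any(sites$p_jump1 + sites$p_jump2 > 1)) {
      stop("site probability mass > 1 at ",
           paste(sites$ref_name[sites$p_jump1 + sites$p_jump2 > 1],
                 collapse = ", "))
    }
    bad <- !sites$ref_name %in% names(ref) |
      sites$pos < 1L | sites$pos > nchar(ref)[match(sites$ref_name, names(ref))]
    if (any(bad)) {
      stop("site position outside its reference: ",
           paste(paste0(sites$ref_name[bad], ":", sites$pos[bad]),
                 collapse = ", "))
    }
    if (!all(c("mis1", "mis2", "mis3") %in% names(sites))) {
      sites$mis1 <- sites$mis2 <- sites$mis3 <- 1 / 3
    }
  }
  set.seed(seed)
  depth <- as.integer(rep_len(depth, length(ref)))

  info_ref <- character(0); info_start <- integer(0); info_strand <- character(0)
  ops_all <- list()
  truth_rows <- list()
  oh_total <- 0L; oh_mismatching <- 0L; oh_reads <- 0L

  bases4 <- c("A", "C", "G", "T")
  for (ri in seq_along(ref)) {
    rn <- names(ref)[ri]
    L <- nchar(ref[[rn]])
    D <- depth[ri]
    ref_chars <- strsplit(ref[[rn]], "", fixed = TRUE)[[1]]
    strand <- ifelse(stats::runif(D) < strand_fraction, "+", "-")

    M <- matrix(ref_chars, nrow = D, ncol = L, byrow = TRUE)
    if (error_rate > 0) {
      flip <- which(matrix(stats::runif(D * L) < error_rate, D, L))
      if (length(flip) > 0L) {
        cur <- M[flip]
        M[flip] <- vapply(cur, function(b) sample(setdiff(bases4, b), 1L), "")
      }
    }

    s <- rep(1L, D)            # final 5'-most aligned position
    alive <- rep(TRUE, D)      # synthesis still running at current scan point
    st <- if (is.null(sites)) NULL else
      sites[sites$ref_name == rn, , drop = FALSE]
    if (!is.null(st) && nrow(st) > 0L) {
      st <- st[order(-st$pos), , drop = FALSE]
      for (si in seq_len(nrow(st))) {
        p <- st$pos[si]
        arr <- alive & stats::runif(D) < st$p_arrest[si]
        s[arr] <- p + 1L
        alive[arr] <- FALSE
        cover <- alive
        u <- stats::runif(D)
        j2 <- cover & u < st$p_jump2[si] & p > 1L
        j1 <- cover & !j2 & u < st$p_jump2[si] + st$p_jump1[si]
        base_ev <- cover & !j1 & !j2
        mis <- base_ev & stats::runif(D) < st$p_mismatch[si]
        others <- setdiff(bases4, ref_chars[p])
        if (any(mis)) {
          M[which(mis), p] <- sample(others, sum(mis), replace = TRUE,
                                     prob = unlist(st[si, c("mis1", "mis2", "mis3")]))
        }
        if (any(j1)) M[which(j1), p] <- "*"
        if (any(j2)) {
          M[which(j2), p] <- "*"
          M[which(j2), p - 1L] <- "*"
        }
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          ref_name = rn, pos = p,
          p_arrest = st$p_arrest[si], p_mismatch = st$p_mismatch[si],
          p_jump1 = st$p_jump1[si], p_jump2 = st$p_jump2[si],
          n_reaching = sum(arr) + sum(cover),
          n_arrested = sum(arr), n_jump1 = sum(j1), n_jump2 = sum(j2),
          n_base = sum(base_ev), n_mismatch = sum(mis),
          stringsAsFactors = FALSE)
      }
    }

    # C-tail overhang past the cDNA 3' terminus (5'-most aligned position)
    if (overhang_prob > 0) {
      oh <- stats::runif(D) < overhang_prob & s > 1L
      k <- integer(D)
      if (any(oh)) {
        k[oh] <- pmin(stats::rgeom(sum(oh), prob = 1 / overhang_mean_len) + 1L,
                      as.integer(overhang_max_len), s[oh] - 1L)
        tail_base <- ifelse(strand == "+", "C", "G")
        for (i in which(oh)) {
          cols <- (s[i] - k[i]):(s[i] - 1L)
          oh_mismatching <- oh_mismatching +
            sum(ref_chars[cols] != tail_base[i])
          M[i, cols] <- tail_base[i]
        }
        oh_total <- oh_total + sum(k[oh])
        oh_reads <- oh_reads + sum(oh)
        s <- s - k
      }
    }

    ops <- lapply(seq_len(D), function(i) M[i, s[i]:L])
    info_ref <- c(info_ref, rep(rn, D))
    info_start <- c(info_start, s)
    info_strand <- c(info_strand, strand)
    ops_all <- c(ops_all, ops)
  }

  reads <- list(info = data.frame(ref_name = info_ref, start = info_start,
                                  strand = info_strand,
                                  stringsAsFactors = FALSE),
                ops = ops_all,
                ins = vector("list", length(ops_all)))
  p <- reads_to_pileup(reads, ref)
  truth <- list(
    sites = if (length(truth_rows)) do.call(rbind, truth_rows) else NULL,
    overhang = c(reads_with_overhang = oh_reads,
                 bases_injected = oh_total,
                 mismatching_bases_injected = oh_mismatching))
  list(pileup = p, truth = truth, reads = reads)
}

#' Simulate a labelled training dataset
#'
#' Plants modified sites with parameters drawn from realistic m1A-like
#' ranges at adenosine positions of simulated references, profiles the
#' resulting pileup, and returns the profile together with positive labels
#' (the planted sites) and negative labels (all other adenosine positions
#' present in the profile). The 1:1 class balancing is left to
#' [train_caller()].
#'
#' @param n_refs,ref_length,depth Passed to the simulators.
#' @param sites_per_ref Planted sites per reference (default 1).
#' @param p_mismatch_range,p_arrest_range,p_jump1_range,p_jump2_range
#'   Uniform sampling ranges for the site parameters.
#' @param seed Integer seed.
#' @return A list with `profile`, `positives`, `negatives` (data.frames with
#'   `ref_seg`/`pos`), `ref` and `truth`.
#' @export
make_labeled_dataset <- function(n_refs = 4L, ref_length = 76L, depth = 1000L,
                                 sites_per_ref = 1L,
                                 p_mismatch_range = c(0.3, 0.9),
                                 p_arrest_range = c(0.2, 0.7),
                                 p_jump1_range = c(0, 0.03),
                                 p_jump2_range = c(0, 0.05),
                                 seed = 1L) {
  ref <- simulate_reference(n_refs, ref_length, seed = seed)
  set.seed((seed + 104729L) %% .Machine$integer.max)
  site_rows <- list()
  for (rn in names(ref)) {
    chars <- strsplit(ref[[rn]], "", fixed = TRUE)[[1]]
    L <- length(chars)
    inner <- which(chars == "A")
    inner <- inner[inner > 5L & inner < L - 5L]
    if (length(inner) == 0L) next
    picked <- sample(inner, min(sites_per_ref, length(inner)))
    for (p in picked) {
      site_rows[[length(site_rows) + 1L]] <- mod_site(
        rn, p,
        p_arrest = stats::runif(1, p_arrest_range[1], p_arrest_range[2]),
        p_mismatch = stats::runif(1, p_mismatch_range[1], p_mismatch_range[2]),
        p_jump1 = stats::runif(1, p_jump1_range[1], p_jump1_range[2]),
        p_jump2 = stats::runif(1, p_jump2_range[1], p_jump2_range[2]))
    }
  }
  sites <- do.call(rbind, site_rows)
  sim <- simulate_pileup(ref, sites, depth = depth,
                         seed = (seed + 15485863L) %% .Machine$integer.max)
  prof <- compute_profile(sim$pileup, ref)
  positives <- data.frame(ref_seg = sites$ref_name, pos = sites$pos,
                          stringsAsFactors = FALSE)
  key_pos <- paste(positives$ref_seg, positives$pos)
  is_a <- toupper(prof$refbase) == "A"
  key_all <- paste(prof$ref_seg, prof$pos)
  neg <- prof[is_a & !(key_all %in% key_pos), c("ref_seg", "pos")]
  rownames(neg) <- NULL
  list(profile = prof, positives = positives, negatives = neg,
       ref = ref, truth = sim$truth)
}
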