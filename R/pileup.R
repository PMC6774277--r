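#' @title Pileup columns: the per-position representation of aligned reads
#'
#' @description A `pileup` object holds the parsed content of samtools-style
#' 6-column pileup text (reference name, 1-based position, reference base,
#' depth, base string, qualities). The base string is fully tokenized into
#' per-read events so that downstream steps (overhang trimming, signature
#' profiling) can reason about individual reads.
#'
#' Structure: a list with
#' \describe{
#'   \item{columns}{data.frame with `ref_name`, `pos`, `ref_base`, `depth`
#'     (depth as reported by / consistent with the token count).}
#'   \item{events}{data.frame with one row per read event, in the order they
#'     appear on the line: `col` (index into `columns`), `kind`
#'     (`"base"` or `"del"` for a deletion placeholder), `base` (`NA` for
#'     placeholders), `strand` (`"+"`/`"-"`), `is_start`, `is_end`,
#'     `indel_op` (`NA`, `"ins"` or `"del"`), `indel_len`, `indel_seq`.}
#' }
#'
#' Conventions follow samtools mpileup: `.`/`,` are reference matches on the
#' forward/reverse strand, letter case encodes strand, `^X` starts a read
#' (consuming the mapping-quality character `X`), `$` ends a read, `+N`/`-N`
#' plus `N` sequence characters annotate an indel after the preceding event,
#' and `*` is a deleted-base placeholder (`#` for a reverse-strand deletion,
#' the samtools `--reverse-del` convention; plain `*` parses as forward).
#' Base qualities are read and discarded; no quality filtering is applied.
#'
#' @name pileup
NULL

new_pileup <- function(columns, events) {
  rownames(columns) <- NULL
  rownames(events) <- NULL
  structure(list(columns = columns, events = events), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup:", nrow(x$columns), "columns over",
      length(unique(x$columns$ref_name)), "reference(s),",
      nrow(x$events), "read events\n")
  invisible(x)
}

empty_events <- function(n = 0L) {
  data.frame(col = integer(n), kind = character(n), base = character(n),
             strand = character(n), is_start = logical(n), is_end = logical(n),
             indel_op = rep(NA_character_, n), indel_len = rep(NA_integer_, n),
             indel_seq = rep(NA_character_, n), stringsAsFactors = FALSE)
}

# Tokenize one pileup base string. Returns a list of parallel vectors
# (kind, base, strand, is_start, is_end, indel_op, indel_len, indel_seq).
tokenize_bases <- function(s, ref_base, line = NA) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  kind <- character(n); base <- rep(NA_character_, n); strand <- character(n)
  is_start <- logical(n); is_end <- logical(n)
  indel_op <- rep(NA_character_, n); indel_len <- rep(NA_integer_, n)
  indel_seq <- rep(NA_character_, n)
  ref_base <- toupper(ref_base)
  k <- 0L
  i <- 1L
  pending_start <- FALSE
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      # '^' starts a read; the next character is the mapping quality, which
      # may be any printable character and is discarded.
      if (i + 1L > n) stop("dangling '^' at end of base string (line ", line, ")")
      pending_start <- TRUE
      i <- i + 2L
    } else if (ch == "$") {
      if (k == 0L) stop("'$' with no preceding event (line ", line, ")")
      is_end[k] <- TRUE
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] >= "0" && chars[j] <= "9") j <- j + 1L
      if (j == i + 1L) {
        stop("malformed indel: '", ch, "' not followed by a length (line ",
             line, ")")
      }
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (is.na(len) || len < 1L || j + len - 1L > n) {
        stop("malformed indel length ", len, " (line ", line, ")")
      }
      if (k == 0L) stop("indel with no preceding event (line ", line, ")")
      indel_op[k] <- if (ch == "+") "ins" else "del"
      indel_len[k] <- len
      indel_seq[k] <- paste(chars[j:(j + len - 1L)], collapse = "")
      i <- j + len
    } else {
      k <- k + 1L
      if (ch == "*" || ch == "#") {
        kind[k] <- "del"
        strand[k] <- if (ch == "*") "+" else "-"
      } else if (ch == ".") {
        kind[k] <- "base"; base[k] <- ref_base; strand[k] <- "+"
      } else if (ch == ",") {
        kind[k] <- "base"; base[k] <- ref_base; strand[k] <- "-"
      } else if (ch %in% c("A", "C", "G", "T", "N")) {
        kind[k] <- "base"; base[k] <- ch; strand[k] <- "+"
      } else if (ch %in% c("a", "c", "g", "t", "n")) {
        kind[k] <- "base"; base[k] <- toupper(ch); strand[k] <- "-"
      } else {
        stop("unsupported pileup character '", ch, "' (line ", line, ")")
      }
      if (pending_start) {
        is_start[k] <- TRUE
        pending_start <- FALSE
      }
      i <- i + 1L
    }
  }
  idx <- seq_len(k)
  list(kind = kind[idx], base = base[idx], strand = strand[idx],
       is_start = is_start[idx], is_end = is_end[idx],
       indel_op = indel_op[idx], indel_len = indel_len[idx],
       indel_seq = indel_seq[idx])
}

#' Read samtools-style pileup text
#'
#' Parses a 6-column pileup file (reference name, 1-based position, reference
#' base, depth, base string, base qualities) into a [pileup] object. The base
#' string is fully tokenized; the quality column is discarded. If the reported
#' depth disagrees with the number of parsed read events, a warning is issued
#' and the token count is trusted.
#'
#' @param path Path to a pileup text file.
#' @return A [pileup] object.
#' @seealso [write_pileup()], [trim_overhangs()], [compute_profile()]
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_pileup(
      data.frame(ref_name = character(), pos = integer(),
                 ref_base = character(), depth = integer(),
                 stringsAsFactors = FALSE),
      empty_events()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop("pileup line ", which(nf < 5L)[1L], " has fewer than 5 columns")
  }
  ref_name <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  if (anyNA(pos) || any(pos < 1L)) {
    stop("non-positive or non-integer position at line ",
         which(is.na(pos) | pos < 1L)[1L])
  }
  ref_base <- toupper(vapply(fields, `[[`, "", 3L))
  depth <- as.integer(vapply(fields, `[[`, "", 4L))
  bases <- vapply(fields, `[[`, "", 5L)

  toks <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    toks[[i]] <- tokenize_bases(bases[i], ref_base[i], line = i)
  }
  nev <- vapply(toks, function(t) length(t$kind), integer(1))
  bad <- which(!is.na(depth) & depth != nev)
  if (length(bad) > 0L) {
    warning("depth column disagrees with parsed event count on ",
            length(bad), " line(s) (first at line ", bad[1L],
            "); trusting the parsed events")
  }
  depth <- nev

  events <- data.frame(
    col = rep(seq_along(lines), nev),
    kind = unlist(lapply(toks, `[[`, "kind"), use.names = FALSE),
    base = unlist(lapply(toks, `[[`, "base"), use.names = FALSE),
    strand = unlist(lapply(toks, `[[`, "strand"), use.names = FALSE),
    is_start = unlist(lapply(toks, `[[`, "is_start"), use.names = FALSE),
    is_end = unlist(lapply(toks, `[[`, "is_end"), use.names = FALSE),
    indel_op = unlist(lapply(toks, `[[`, "indel_op"), use.names = FALSE),
    indel_len = unlist(lapply(toks, `[[`, "indel_len"), use.names = FALSE),
    indel_seq = unlist(lapply(toks, `[[`, "indel_seq"), use.names = FALSE),
    stringsAsFactors = FALSE)
  columns <- data.frame(ref_name = ref_name, pos = pos, ref_base = ref_base,
                        depth = depth, stringsAsFactors = FALSE)
  new_pileup(columns, events)
}

#' Write a pileup object as samtools-style text
#'
#' Serializes a [pileup] back to 6-column text. Reverse-strand deletion
#' placeholders are written as `#` (samtools `--reverse-del` convention) so
#' that strand information survives a round trip; qualities are written as a
#' constant `I` per event.
#'
#' @param p A [pileup] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(p, path) {
  stopifnot(inherits(p, "pileup"))
  ev <- p$events
  chr <- character(nrow(ev))
  is_del <- ev$kind == "del"
  fwd <- ev$strand == "+"
  ref_for_ev <- p$columns$ref_base[ev$col]
  match <- !is_del & ev$base == ref_for_ev
  chr[is_del & fwd] <- "*"
  chr[is_del & !fwd] <- "#"
  chr[match & fwd] <- "."
  chr[match & !fwd] <- ","
  other <- !is_del & !match
  chr[other & fwd] <- ev$base[other & fwd]
  chr[other & !fwd] <- tolower(ev$base[other & !fwd])

  tok <- paste0(ifelse(ev$is_start, "^I", ""), chr,
                ifelse(is.na(ev$indel_op), "",
                       paste0(ifelse(ev$indel_op == "ins", "+", "-"),
                              ev$indel_len,
                              ifelse(is.na(ev$indel_seq), "", ev$indel_seq))),
                ifelse(ev$is_end, "$", ""))
  base_str <- vapply(split(tok, factor(ev$col, levels = seq_len(nrow(p$columns)))),
                     paste, "", collapse = "")
  cols <- p$columns
  lines <- paste(cols$ref_name, cols$pos, cols$ref_base, cols$depth,
                 base_str, strrep("I", cols$depth), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---- read-linkage codec -----------------------------------------------------
#
# A valid pileup preserves read slot order across consecutive columns: '^'
# inserts a slot at its place in the event order, '$' removes it afterwards.
# This makes per-read linkage reconstructable from pileup text alone, which is
# what the overhang trimmer relies on.
#
# Internal reads representation: list(
#   info = data.frame(ref_name, start, strand),
#   ops  = list of character vectors over {A,C,G,T,N,"*"} (one per covered
#          reference position; "*" = deleted base),
#   ins  = list of NULL or data.frame(idx, seq) insertion annotations)

pileup_to_reads <- function(p) {
  stopifnot(inherits(p, "pileup"))
  cols <- p$columns
  ev <- p$events
  ev_by_col <- split(seq_len(nrow(ev)), factor(ev$col, levels = seq_len(nrow(cols))))

  info_ref <- character(0); info_start <- integer(0); info_strand <- character(0)
  ops <- list(); ins <- list()
  n_reads <- 0L

  open <- integer(0)  # read ids of slots continuing into the next column
  prev_ref <- NULL; prev_pos <- NULL

  for (ci in seq_len(nrow(cols))) {
    rn <- cols$ref_name[ci]; pp <- cols$pos[ci]
    contiguous <- !is.null(prev_ref) && prev_ref == rn && prev_pos + 1L == pp
    if (!is.null(prev_ref) && prev_ref == rn && pp <= prev_pos) {
      stop("pileup positions not strictly increasing at ", rn, ":", pp)
    }
    if (!contiguous && length(open) > 0L) {
      stop("read linkage broken: ", length(open), " read(s) open at ",
           prev_ref, ":", prev_pos, " but next column is ", rn, ":", pp)
    }
    rows <- ev_by_col[[ci]]
    nxt <- integer(length(rows))
    ended <- logical(length(rows))
    oi <- 1L
    for (j in seq_along(rows)) {
      r <- rows[j]
      if (ev$is_start[r]) {
        n_reads <- n_reads + 1L
        id <- n_reads
        info_ref[id] <- rn; info_start[id] <- pp; info_strand[id] <- ev$strand[r]
        ops[[id]] <- character(0); ins[id] <- list(NULL)
      } else {
        if (oi > length(open)) {
          stop("read linkage ambiguity at ", rn, ":", pp,
               ": more continuing events than open reads")
        }
        id <- open[oi]
        oi <- oi + 1L
      }
      op <- if (ev$kind[r] == "del") "*" else ev$base[r]
      ops[[id]] <- c(ops[[id]], op)
      if (!is.na(ev$indel_op[r]) && ev$indel_op[r] == "ins") {
        rec <- data.frame(idx = length(ops[[id]]), seq = ev$indel_seq[r],
                          stringsAsFactors = FALSE)
        ins[[id]] <- if (is.null(ins[[id]])) rec else rbind(ins[[id]], rec)
      }
      nxt[j] <- id
      ended[j] <- ev$is_end[r]
    }
    if (oi <= length(open)) {
      stop("read linkage ambiguity at ", rn, ":", pp,
           ": fewer continuing events than open reads")
    }
    open <- nxt[!ended]
    prev_ref <- rn; prev_pos <- pp
  }
  # reads still open after the final column end there (truncated pileup)
  list(info = data.frame(ref_name = info_ref, start = info_start,
                         strand = info_strand, stringsAsFactors = FALSE),
       ops = ops, ins = ins)
}

# Drop leading/trailing deletion placeholders (a read cannot start or end on a
# deletion in pileup), adjusting start and insertion indices; drop empty reads.
normalize_reads <- function(reads) {
  keep <- logical(length(reads$ops))
  for (i in seq_along(reads$ops)) {
    o <- reads$ops[[i]]
    nb <- which(o != "*")
    if (length(nb) == 0L) {
      keep[i] <- FALSE
      next
    }
    keep[i] <- TRUE
    lo <- nb[1L]; hi <- nb[length(nb)]
    if (lo > 1L || hi < length(o)) {
      reads$ops[[i]] <- o[lo:hi]
      reads$info$start[i] <- reads$info$start[i] + lo - 1L
      if (!is.null(reads$ins[[i]])) {
        a <- reads$ins[[i]]
        a$idx <- a$idx - (lo - 1L)
        a <- a[a$idx >= 1L & a$idx <= hi - lo + 1L, , drop = FALSE]
        reads$ins[[i]] <- if (nrow(a)) a else NULL
      }
    }
  }
  list(info = reads$info[keep, , drop = FALSE],
       ops = reads$ops[keep], ins = reads$ins[keep])
}

reads_to_pileup <- function(reads, ref) {
  reads <- normalize_reads(reads)
  info <- reads$info
  if (nrow(info) == 0L) {
    return(new_pileup(
      data.frame(ref_name = character(), pos = integer(),
                 ref_base = character(), depth = integer(),
                 stringsAsFactors = FALSE),
      empty_events()))
  }
  out_cols <- list(); out_ev <- list(); col_off <- 0L
  for (rn in unique(info$ref_name)) {
    sel <- which(info$ref_name == rn)
    ord <- sel[order(info$start[sel], sel)]
    lens <- lengths(reads$ops[ord])
    rid <- rep(seq_along(ord), lens)             # rank of read in column order
    offs <- sequence(lens) - 1L
    pos <- info$start[ord][rid] + offs
    op <- unlist(reads$ops[ord], use.names = FALSE)
    strand <- info$strand[ord][rid]
    at_start <- offs == 0L
    at_end <- sequence(lens) == lens[rid]

    # deletion-run annotations: the base event before a run of '*' carries
    # '-L' plus the deleted reference sequence
    is_star <- op == "*"
    nxt_star <- c(is_star[-1L], FALSE)
    nxt_same <- c(rid[-1L] == rid[-length(rid)], FALSE)
    run_after <- !is_star & nxt_star & nxt_same
    del_len <- integer(length(op))
    if (any(run_after)) {
      r <- rle(ifelse(is_star, rid, -1L))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (q in which(r$values >= 0L)) {
        s <- starts[q]
        if (s > 1L && !is_star[s - 1L] && rid[s - 1L] == rid[s]) {
          del_len[s - 1L] <- r$lengths[q]
        }
      }
    }
    refseq <- ref[[rn]]
    del_seq <- rep(NA_character_, length(op))
    has_del <- del_len > 0L
    if (any(has_del)) {
      dstart <- pos[has_del] + 1L
      dend <- dstart + del_len[has_del] - 1L
      seqs <- substring(refseq, dstart, dend)
      rev_del <- strand[has_del] == "-"
      seqs[rev_del] <- tolower(seqs[rev_del])
      del_seq[has_del] <- seqs
    }
    indel_op <- ifelse(has_del, "del", NA_character_)
    indel_len <- ifelse(has_del, del_len, NA_integer_)
    indel_seq <- del_seq
    # insertion annotations override/extend
    for (k in seq_along(ord)) {
      a <- reads$ins[[ord[k]]]
      if (!is.null(a)) {
        for (q in seq_len(nrow(a))) {
          gi <- which(rid == k)[a$idx[q]]
          indel_op[gi] <- "ins"
          indel_len[gi] <- nchar(a$seq[q])
          indel_seq[gi] <- a$seq[q]
        }
      }
    }

    o <- order(pos, rid)
    upos <- sort(unique(pos))
    if (any(upos > nchar(refseq))) {
      stop("read extends past the end of reference '", rn, "'")
    }
    colidx <- match(pos[o], upos) + col_off
    out_cols[[length(out_cols) + 1L]] <- data.frame(
      ref_name = rn, pos = upos,
      ref_base = substring(refseq, upos, upos),
      depth = as.integer(tabulate(match(pos, upos), length(upos))),
      stringsAsFactors = FALSE)
    out_ev[[length(out_ev) + 1L]] <- data.frame(
      col = colidx,
      kind = ifelse(is_star[o], "del", "base"),
      base = ifelse(is_star[o], NA_character_, op[o]),
      strand = strand[o],
      is_start = at_start[o], is_end = at_end[o],
      indel_op = indel_op[o], indel_len = indel_len[o],
      indel_seq = indel_seq[o],
      stringsAsFactors = FALSE)
    col_off <- col_off + length(upos)
  }
  new_pileup(do.call(rbind, out_cols), do.call(rbind, out_ev))
}
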