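#' Enumerate candidate Cas9 targets within an ORF
#'
#' Scans both the sense strand of the ORF and its reverse complement for
#' every position where a full 20 nt spacer followed by an NGG PAM lies
#' entirely inside the ORF (the PAM may not overhang the ORF boundary, so
#' the cut site is always intragenic). Output order is deterministic: sense
#' candidates 5'->3', then antisense candidates 5'->3'. Spacers containing
#' a non-ACGT base are kept but marked `discarded_reason = "ambiguous_base"`.
#'
#' @param locus A `Locus` from [extract_locus()].
#' @return A data.frame of candidates with columns `spacer`, `pam`,
#'   `locus_name`, `strand_vs_orf` (+/- relative to the ORF sense strand),
#'   `chrom`, `start`, `end` (0-based half-open genomic interval of the
#'   23 nt spacer+PAM), `genome_strand`, `discarded_reason` (NA when live)
#'   and internal filter flags.
#' @export
enumerate_candidates <- function(locus) {
  stopifnot(inherits(locus, "Locus"))
  f <- locus$feature
  orf <- locus$orf_seq
  L <- nchar(orf)
  rows <- list()
  scan_strand <- function(seq, strand_vs_orf) {
    n <- nchar(seq)
    if (n < 23L) return(NULL)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    # offset j (0-based) of the spacer start; PAM at j+20..j+22
    j <- which(ch[22:(n - 1L)] == "G" & ch[23:n] == "G") - 1L
    j <- j[j <= n - 23L]
    if (!length(j)) return(NULL)
    spacer <- substring(seq, j + 1L, j + 20L)
    pam <- substring(seq, j + 21L, j + 23L)
    keep <- !grepl("[^ACGT]", pam)  # PAM N-slot must be a called base
    j <- j[keep]; spacer <- spacer[keep]; pam <- pam[keep]
    if (!length(j)) return(NULL)
    data.frame(offset = j, spacer = spacer, pam = pam,
               strand_vs_orf = strand_vs_orf, stringsAsFactors = FALSE)
  }
  sense <- scan_strand(orf, "+")
  anti <- scan_strand(revcomp(orf), "-")
  cand <- rbind(sense, anti)
  if (is.null(cand) || nrow(cand) == 0L) return(empty_candidates())

  # map ORF offsets (counted from the ORF 5' end on the scanned strand)
  # to genomic plus-strand coordinates of the 23 nt window
  off <- cand$offset
  start <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    same <- (cand$strand_vs_orf[i] == "+")
    if (f$strand == "+") {
      start[i] <- if (same) f$start + off[i] else f$start + (L - off[i] - 23L)
    } else {
      start[i] <- if (same) f$start + (L - off[i] - 23L) else f$start + off[i]
    }
  }
  gstrand <- ifelse((cand$strand_vs_orf == "+") == (f$strand == "+"), "+", "-")
  out <- data.frame(
    spacer = cand$spacer, pam = cand$pam,
    locus_name = f$systematic_name,
    strand_vs_orf = cand$strand_vs_orf,
    chrom = f$chrom, start = as.integer(start),
    end = as.integer(start) + 23L,
    genome_strand = gstrand,
    flag_ambiguous = grepl("[^ACGT]", cand$spacer),
    flag_polyT = FALSE, flag_offtarget = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  update_discard_reason(out)
}

empty_candidates <- function() {
  update_discard_reason(data.frame(
    spacer = character(), pam = character(), locus_name = character(),
    strand_vs_orf = character(), chrom = character(), start = integer(),
    end = integer(), genome_strand = character(),
    flag_ambiguous = logical(), flag_polyT = logical(),
    flag_offtarget = logical(), stringsAsFactors = FALSE))
}

# discard reason derived from flags under a fixed priority, so the filter
# operations are idempotent and commute
update_discard_reason <- function(cand) {
  reason <- rep(NA_character_, nrow(cand))
  reason[cand$flag_offtarget] <- "offtarget"
  reason[cand$flag_polyT] <- "polyT"
  reason[cand$flag_ambiguous] <- "ambiguous_base"
  cand$discarded_reason <- reason
  cand
}

#' Discard spacers containing a poly-T Pol III terminator
#'
#' A run of six or more consecutive T within the 20 nt spacer (as written on
#' the protospacer strand; the PAM is not part of the run check) can
#' terminate RNA polymerase III transcription of the gRNA, so such
#' candidates are marked `discarded_reason = "polyT"`. Total T count is
#' irrelevant; only the longest run matters.
#'
#' @param candidates Candidate data.frame from [enumerate_candidates()].
#' @return The data.frame with poly-T candidates marked; idempotent.
#' @export
filter_polyT <- function(candidates) {
  candidates$flag_polyT <- grepl("TTTTTT", candidates$spacer, fixed = TRUE)
  update_discard_reason(candidates)
}

pam_class_plus <- function(p1, p2, p3) {
  ifelse(p1 %in% c("A", "C", "G", "T") & p3 == "G",
         ifelse(p2 == "G", "NGG", ifelse(p2 == "A", "NAG", NA_character_)),
         NA_character_)
}

#' Find genome-wide off-target sites of spacers
#'
#' Reports every genomic site, on both strands, where a 20-mer lies within
#' Hamming distance `max_mismatch` (default 3, i.e. >= 17/20 identity) of a
#' spacer and is immediately followed (3', same strand) by an NGG or NAG
#' PAM. N in the genome counts as a mismatch and never completes a PAM.
#'
#' The scan is seed-and-extend by pigeonhole: the 20-mer is split into four
#' disjoint 5-mer seeds, so any site within 3 mismatches matches at least
#' one seed exactly. A 5-mer position index of the genome is built once per
#' call, seed lookups collect candidate alignments for all spacers and both
#' strands, and every candidate is verified by exact Hamming recount and
#' the NGG/NAG PAM gate. For `max_mismatch > 3` the pigeonhole guarantee
#' needs more than four seeds and the scan delegates to
#' [find_offtargets_exhaustive()].
#'
#' `find_offtargets_batch` scans many spacers at once and returns one hit
#' table per spacer; [find_offtargets()] is the single-spacer convenience
#' wrapper.
#'
#' @param spacers Character vector of 20 nt ACGT-only spacers.
#' @param genome A `Genome`.
#' @param max_mismatch Maximum Hamming distance (default 3).
#' @return For `find_offtargets_batch`, an unnamed list parallel to
#'   `spacers`; each element is a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open interval of the 20 nt match), `strand`,
#'   `mismatches`, `pam_class`, `is_on_target` (all FALSE here; set by
#'   [apply_uniqueness()]).
#' @export
find_offtargets_batch <- function(spacers, genome, max_mismatch = 3L) {
  stopifnot(length(spacers) >= 1L, all(nchar(spacers) == 20L),
            !any(grepl("[^ACGT]", spacers)))
  if (max_mismatch > 3L)
    return(lapply(spacers, find_offtargets_exhaustive, genome = genome,
                  max_mismatch = max_mismatch))
  uniq <- unique(spacers)
  n <- length(uniq)
  seed_offsets <- c(0L, 5L, 10L, 15L)   # four disjoint 5-mer seeds
  # candidate sites per unique spacer and strand, as "chrom:start" keys
  plus_starts <- rep(list(character()), n)
  minus_starts <- rep(list(character()), n)
  rc_uniq <- revcomp(uniq)
  for (chrom in names(genome$chroms)) {
    idx <- kmer_index(genome$chroms[[chrom]], 5L)
    if (is.null(idx)) next
    Ls <- nchar(genome$chroms[[chrom]]) - 19L  # last valid 20-mer start
    for (k in seq_len(n)) {
      for (pat in list(list(uniq[k], "plus"), list(rc_uniq[k], "minus"))) {
        cand <- integer()
        for (o in seed_offsets) {
          seed <- substr(pat[[1]], o + 1L, o + 5L)
          hit <- idx$index[[seed]]
          if (!is.null(hit)) cand <- c(cand, hit - o)
        }
        cand <- unique(cand[cand >= 1L & cand <= Ls])
        if (!length(cand)) next
        keys <- paste0(chrom, ":", sort(cand))
        if (pat[[2]] == "plus")
          plus_starts[[k]] <- c(plus_starts[[k]], keys)
        else
          minus_starts[[k]] <- c(minus_starts[[k]], keys)
      }
    }
  }
  verify <- function(spacer, keys, strand) {
    if (!length(keys)) return(NULL)
    keys <- unique(keys)
    parts <- strsplit(keys, ":", fixed = TRUE)
    chroms <- vapply(parts, `[`, character(1), 1L)
    s0 <- as.integer(vapply(parts, `[`, character(1), 2L)) - 1L
    out <- NULL
    for (cn in unique(chroms)) {
      seq <- genome$chroms[[cn]]
      Lc <- nchar(seq)
      s <- sort(s0[chroms == cn])
      if (strand == "+") {
        s <- s[s + 23L <= Lc]
        if (!length(s)) next
        win <- substring(seq, s + 1L, s + 20L)
        p <- substring(seq, s + 21L, s + 23L)
        pc <- pam_class_plus(substr(p, 1, 1), substr(p, 2, 2),
                             substr(p, 3, 3))
      } else {
        s <- s[s >= 3L]
        if (!length(s)) next
        win <- revcomp(substring(seq, s + 1L, s + 20L))
        # PAM on the minus strand: 3 nt genomically 5' of the match
        p <- revcomp(substring(seq, s - 2L, s))
        pc <- pam_class_plus(substr(p, 1, 1), substr(p, 2, 2),
                             substr(p, 3, 3))
      }
      mm <- hamming_vec(spacer, win)
      keep <- !is.na(pc) & mm <= max_mismatch
      if (any(keep))
        out <- rbind(out, data.frame(
          chrom = cn, start = s[keep], end = s[keep] + 20L,
          strand = strand, mismatches = mm[keep], pam_class = pc[keep],
          stringsAsFactors = FALSE))
    }
    out
  }
  per_uniq <- lapply(seq_len(n), function(k) {
    out <- rbind(verify(uniq[k], plus_starts[[k]], "+"),
                 verify(uniq[k], minus_starts[[k]], "-"))
    if (is.null(out))
      out <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        mismatches = integer(), pam_class = character(),
                        stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start, out$strand, method = "radix"), ,
               drop = FALSE]
    out$is_on_target <- logical(nrow(out))
    rownames(out) <- NULL
    out
  })
  unname(per_uniq[match(spacers, uniq)])
}

#' @rdname find_offtargets_batch
#' @param spacer A single 20 nt ACGT-only spacer.
#' @return For `find_offtargets`, the hit data.frame for one spacer.
#' @export
find_offtargets <- function(spacer, genome, max_mismatch = 3L) {
  find_offtargets_batch(spacer, genome, max_mismatch)[[1L]]
}

# 5-mer position index of a chromosome: k-mer string -> sorted 1-based
# start positions. k-mers containing N are not indexed (an N can never sit
# inside a mismatch-free seed).
kmer_index <- function(seq, k = 5L) {
  L <- nchar(seq)
  if (L < 23L) return(NULL)
  kmers <- substring(seq, 1L:(L - k + 1L), k:L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  list(index = split(seq_len(L - k + 1L)[ok], kmers[ok]))
}

# exact Hamming distances between one pattern and equal-length strings;
# any non-identical character pair (including N) is a mismatch
hamming_vec <- function(pattern, strings) {
  if (!length(strings)) return(integer())
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  vapply(strsplit(strings, "", fixed = TRUE),
         function(ch) sum(ch != p), integer(1))
}

#' Exhaustive position-by-position off-target scan
#'
#' Independent reference scanner: slides over every position of every
#' chromosome on both strands, computes the exact Hamming distance of the
#' 20-mer to the spacer, and applies the same NGG/NAG PAM gate as
#' [find_offtargets()]. Shares no matching code with the production
#' scanner; used as its oracle and for collision screening when building
#' synthetic genomes.
#'
#' @inheritParams find_offtargets
#' @return Same shape as [find_offtargets()].
#' @export
find_offtargets_exhaustive <- function(spacer, genome, max_mismatch = 3L) {
  stopifnot(nchar(spacer) == 20L, !grepl("[^ACGT]", spacer))
  p <- strsplit(spacer, "", fixed = TRUE)[[1]]
  hits <- list()
  for (chrom in names(genome$chroms)) {
    ch <- strsplit(genome$chroms[[chrom]], "", fixed = TRUE)[[1]]
    Lc <- length(ch)
    if (Lc < 23L) next
    n <- Lc - 19L  # candidate 20-mer start positions (1-based)
    mm_plus <- integer(n)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    ch_comp <- unname(comp[ch]); ch_comp[is.na(ch_comp)] <- "N"
    mm_minus <- integer(n)
    for (k in 1:20) {
      win <- ch[k:(k + n - 1L)]
      mm_plus <- mm_plus + (win != p[k])
      # minus-strand 20-mer starting at i (plus coords) read 3'->5' is
      # complement reversed: position k of the spacer aligns to plus
      # position i + 20 - k
      win2 <- ch_comp[(21L - k):(21L - k + n - 1L)]
      mm_minus <- mm_minus + (win2 != p[k])
    }
    for (i in which(mm_plus <= max_mismatch)) {
      if (i + 22L > Lc) next
      pc <- pam_class_plus(ch[i + 20L], ch[i + 21L], ch[i + 22L])
      if (!is.na(pc))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = i - 1L, end = i + 19L, strand = "+",
          mismatches = mm_plus[i], pam_class = pc, stringsAsFactors = FALSE)
    }
    for (i in which(mm_minus <= max_mismatch)) {
      if (i < 4L) next
      # PAM on minus strand: complement of plus positions i-1, i-2, i-3
      p1 <- ch_comp[i - 1L]; p2 <- ch_comp[i - 2L]; p3 <- ch_comp[i - 3L]
      pc <- pam_class_plus(p1, p2, p3)
      if (!is.na(pc))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = i - 1L, end = i + 19L, strand = "-",
          mismatches = mm_minus[i], pam_class = pc, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), mismatches = integer(),
               pam_class = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand, method = "radix"), ,
             drop = FALSE]
  out$is_on_target <- logical(nrow(out))
  rownames(out) <- NULL
  out
}

# spacer interval (20-mer) of a candidate in genome coordinates
candidate_spacer_interval <- function(cand_row) {
  if (cand_row$genome_strand == "+") {
    c(cand_row$start, cand_row$start + 20L)
  } else {
    c(cand_row$start + 3L, cand_row$end)
  }
}

#' Discard candidates with genome-wide off-targets
#'
#' Scans the full genome for sites within 3 mismatches of each live
#' candidate's spacer carrying an NGG or NAG PAM. The hit at the
#' candidate's own protospacer location (interval + strand equality) is the
#' on-target; any other hit — including a perfect duplicate elsewhere —
#' marks the candidate `discarded_reason = "offtarget"`. A candidate whose
#' own site is not recovered indicates a candidate/genome mismatch and is a
#' hard error.
#'
#' @param candidates Candidate data.frame (one or more rows).
#' @param genome The `Genome` the candidates were enumerated from.
#' @param scanner Off-target scan function (default [find_offtargets()]).
#' @return The candidates with off-target flags set; attribute `"hits"`
#'   holds the per-candidate hit tables (list, is_on_target filled in).
#' @export
apply_uniqueness <- function(candidates, genome, scanner = find_offtargets) {
  hit_list <- vector("list", nrow(candidates))
  scannable <- which(!candidates$flag_ambiguous)
  batch <- NULL
  if (identical(scanner, find_offtargets) && length(scannable)) {
    # one batched pigeonhole scan for all candidates of the locus
    batch <- find_offtargets_batch(candidates$spacer[scannable], genome)
    names(batch) <- NULL
  }
  for (i in seq_len(nrow(candidates))) {
    if (candidates$flag_ambiguous[i]) next  # cannot scan non-ACGT spacer
    h <- if (!is.null(batch)) batch[[match(i, scannable)]] else
      scanner(candidates$spacer[i], genome)
    iv <- candidate_spacer_interval(candidates[i, ])
    on <- h$chrom == candidates$chrom[i] & h$start == iv[1] &
      h$end == iv[2] & h$strand == candidates$genome_strand[i]
    if (sum(on) == 0L)
      stop("candidate '", candidates$spacer[i],
           "' not found at its own site: candidate/genome mismatch")
    h$is_on_target <- on
    hit_list[[i]] <- h
    candidates$flag_offtarget[i] <- any(!on)
  }
  candidates <- update_discard_reason(candidates)
  attr(candidates, "hits") <- hit_list
  candidates
}

#' Write an off-target hit table as TSV
#'
#' Coordinates are converted to 1-based inclusive for output.
#'
#' @param hits Hit data.frame from [find_offtargets()]/[apply_uniqueness()].
#' @param path Output file path.
#' @export
write_offtarget_tsv <- function(hits, path) {
  out <- data.frame(chrom = hits$chrom, start = hits$start + 1L,
                    end = hits$end, strand = hits$strand,
                    mismatches = hits$mismatches, pam_class = hits$pam_class,
                    on_target = hits$is_on_target)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
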