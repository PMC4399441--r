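#' Backbone configuration for plasmid construction
#'
#' The plasmid backbone sequences around the spacer slot are configuration,
#' not constants: the single- and double-gRNA plasmid series are deposited
#' externally, so the fixed flanks are supplied by the user (or generated
#' synthetically for testing).
#'
#' @param flank5 50 nt backbone sequence immediately 5' of the spacer slot.
#' @param flank3 50 nt backbone sequence immediately 3' of the slot.
#' @param double_homology 50 nt shared end of the single-primer-linearized
#'   double-gRNA backbone.
#' @param two_micron_anneal Primer 3' annealing sequence on the 2 micron
#'   fragment (>= 18 nt; default designs use 20 nt).
#' @param backbone_seq Optional full plasmid sequence.
#' @return A `BackboneConfig` list.
#' @export
backbone_config <- function(flank5, flank3, double_homology,
                            two_micron_anneal, backbone_seq = NULL) {
  chk <- function(x, len, nm, exact = TRUE) {
    if (grepl("[^ACGT]", x)) stop(nm, " must be ACGT-only")
    if (exact && nchar(x) != len)
      stop(nm, " must be exactly ", len, " nt, got ", nchar(x))
    if (!exact && nchar(x) < len)
      stop(nm, " must be at least ", len, " nt, got ", nchar(x))
  }
  chk(flank5, 50L, "flank5"); chk(flank3, 50L, "flank3")
  chk(double_homology, 50L, "double_homology")
  chk(two_micron_anneal, 18L, "two_micron_anneal", exact = FALSE)
  structure(list(flank5 = flank5, flank3 = flank3,
                 double_homology = double_homology,
                 two_micron_anneal = two_micron_anneal,
                 backbone_seq = backbone_seq),
            class = "BackboneConfig")
}

#' Read a backbone configuration from JSON
#'
#' @param path JSON file with keys `flank5`, `flank3`, `double_homology`,
#'   `two_micron_anneal` and optionally `backbone_seq`.
#' @return A `BackboneConfig`.
#' @export
read_backbone_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("flank5", "flank3", "double_homology", "two_micron_anneal")
  if (!all(need %in% names(x)))
    stop("backbone config missing keys: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  backbone_config(x$flank5, x$flank3, x$double_homology,
                  x$two_micron_anneal, x$backbone_seq)
}

#' Write a backbone configuration to JSON
#' @param config A `BackboneConfig`.
#' @param path Output path.
#' @export
write_backbone_config <- function(config, path) {
  jsonlite::write_json(unclass(config)[!vapply(config, is.null, logical(1))],
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# double-stranded oligo: bottom strand is the exact reverse complement and
# the anatomy segments tile the top strand without gaps
oligo_pair <- function(name, top, roles, lengths) {
  stopifnot(sum(lengths) == nchar(top), length(roles) == length(lengths))
  end <- cumsum(lengths)
  anatomy <- data.frame(role = roles, start = c(0L, end[-length(end)]),
                        end = end, stringsAsFactors = FALSE)
  structure(list(name = name, top = top, bottom = revcomp(top),
                 anatomy = anatomy), class = "OligoPair")
}

#' @export
print.OligoPair <- function(x, ...) {
  cat("OligoPair", x$name, sprintf("(%d nt)\n", nchar(x$top)))
  cat("  top:   ", x$top, "\n  roles: ",
      paste(sprintf("%s[%d-%d]", x$anatomy$role, x$anatomy$start,
                    x$anatomy$end), collapse = " "), "\n")
  invisible(x)
}

#' Design the single-gRNA plasmid insert oligos
#'
#' The insert carries the 20 nt spacer flanked by 50 bp sequences identical
#' to each side of the linearized plasmid backbone, so that the yeast HR
#' machinery assembles the gRNA plasmid in vivo. Emitted as two
#' complementary 120 nt single strands to be annealed.
#'
#' @param spacer 20 nt spacer that survived filtering.
#' @param backbone A `BackboneConfig`.
#' @param name Record name (default `"gRNA_insert"`).
#' @return An `OligoPair`; `top = flank5 + spacer + flank3`.
#' @export
design_single_insert <- function(spacer, backbone, name = "gRNA_insert") {
  stopifnot(inherits(backbone, "BackboneConfig"))
  if (nchar(spacer) != 20L || grepl("[^ACGT]", spacer))
    stop("spacer must be a 20 nt ACGT string")
  oligo_pair(name, paste0(backbone$flank5, spacer, backbone$flank3),
             c("flank5", "spacer", "flank3"), c(50L, 20L, 50L))
}

#' Design the 120 bp scarless-deletion repair fragment
#'
#' Two complementary 120 nt strands whose top strand fuses the 60 nt
#' immediately upstream of the ORF to the 60 nt immediately downstream:
#' homologous recombination across the Cas9 break with this fragment
#' removes the entire ORF and leaves no scar.
#'
#' @param locus A `Locus` with at least 60 nt of flank on each side.
#' @param name Record name.
#' @return A `RepairFragment`: list with `oligo` (`OligoPair`), `arm5`,
#'   `arm3` and `edit` (NULL for deletions).
#' @export
design_deletion_repair <- function(locus, name = NULL) {
  stopifnot(inherits(locus, "Locus"))
  if (is.null(name))
    name <- paste0(locus$feature$systematic_name, "_del_repair")
  up <- nchar(locus$upstream); dn <- nchar(locus$downstream)
  if (up < 60L) stop("insufficient upstream flank: need 60 nt, have ", up)
  if (dn < 60L) stop("insufficient downstream flank: need 60 nt, have ", dn)
  arm5 <- substr(locus$upstream, up - 59L, up)
  arm3 <- substr(locus$downstream, 1L, 60L)
  structure(list(
    oligo = oligo_pair(name, paste0(arm5, arm3),
                       c("arm5", "arm3"), c(60L, 60L)),
    arm5 = arm5, arm3 = arm3, edit = NULL), class = "RepairFragment")
}

#' Design a 120 bp mutagenic repair fragment for a single-nucleotide edit
#'
#' The fragment is the genomic plus-strand 120-mer centered on the edited
#' base (60 nt each side) with the single substitution applied. When
#' `protect_spacer` (the 23 nt spacer+PAM of the guide used to cut) is
#' given, the fragment is checked for Cas9 re-cut protection: if the edit
#' does not destroy the spacer+PAM match a warning is issued — re-cutting
#' can still occur while the gRNA is expressed, so resequencing after
#' plasmid removal is advised.
#'
#' @param genome A `Genome`.
#' @param chrom Chromosome name.
#' @param pos 0-based position of the base to edit.
#' @param alt Replacement base (must differ from the reference base).
#' @param protect_spacer Optional 23 nt spacer+PAM string.
#' @param name Record name.
#' @return A `RepairFragment` with `edit = list(position, ref_base,
#'   alt_base)` (position 0-based genomic).
#' @export
design_mutation_repair <- function(genome, chrom, pos, alt,
                                   protect_spacer = NULL,
                                   name = "snv_repair") {
  stopifnot(inherits(genome, "Genome"), chrom %in% names(genome$chroms))
  L <- nchar(genome$chroms[[chrom]])
  if (pos < 60L || pos + 60L > L)
    stop("position ", pos + 1L, " is within 60 nt of the end of ", chrom)
  if (!alt %in% c("A", "C", "G", "T")) stop("alt must be A/C/G/T")
  ref <- genome_subseq(genome, chrom, pos, pos + 1L)
  if (ref == alt) stop("reference base at ", chrom, ":", pos + 1L,
                       " is already ", alt)
  frag <- genome_subseq(genome, chrom, pos - 60L, pos + 60L)
  substr(frag, 61L, 61L) <- alt
  if (!is.null(protect_spacer)) {
    if (grepl(protect_spacer, frag, fixed = TRUE) ||
        grepl(revcomp(protect_spacer), frag, fixed = TRUE))
      warning("edit does not destroy the spacer+PAM '", protect_spacer,
              "': Cas9 may re-cut the repaired site")
  }
  structure(list(
    oligo = oligo_pair(name, frag, c("arm5", "edit", "arm3"),
                       c(60L, 1L, 59L)),
    arm5 = substr(frag, 1L, 60L), arm3 = substr(frag, 61L, 120L),
    edit = list(position = pos, ref_base = ref, alt_base = alt)),
    class = "RepairFragment")
}

#' Design the tailed primers of the double-gRNA method
#'
#' Each primer anneals on the 2 micron fragment and carries a 5' tail made
#' of the 50 bp backbone homology (identical for both primers, since the
#' double-gRNA backbone is linearized with a single primer) followed by the
#' 20 bp spacer.
#'
#' @param spacerA,spacerB 20 nt spacers for the two loci (distinct; a
#'   warning is issued when identical, as digest verification then cannot
#'   distinguish assembly orientations).
#' @param backbone A `BackboneConfig`.
#' @return Named list of two `OligoPair`-like records `primerA`, `primerB`
#'   (single-stranded primers: `bottom` omitted, anatomy recorded).
#' @export
design_double_primers <- function(spacerA, spacerB, backbone) {
  stopifnot(inherits(backbone, "BackboneConfig"))
  for (s in c(spacerA, spacerB))
    if (nchar(s) != 20L || grepl("[^ACGT]", s))
      stop("spacers must be 20 nt ACGT strings")
  if (spacerA == spacerB)
    warning("identical spacers: assembly verification cannot distinguish ",
            "the two orientations")
  mk <- function(spacer, name) {
    top <- paste0(backbone$double_homology, spacer, backbone$two_micron_anneal)
    end <- cumsum(c(50L, 20L, nchar(backbone$two_micron_anneal)))
    list(name = name, top = top,
         anatomy = data.frame(role = c("homology", "spacer", "anneal"),
                              start = c(0L, end[-3]), end = end,
                              stringsAsFactors = FALSE))
  }
  list(primerA = mk(spacerA, "double_gRNA_primer_A"),
       primerB = mk(spacerB, "double_gRNA_primer_B"))
}

#' Design 60 bp homology tails for multigene integration
#'
#' Replaces the ORF of `locus` with an ordered set of cassettes assembled
#' in vivo by HR: the first fragment's 5' tail is the 60 nt immediately
#' upstream of the ORF, the last fragment's 3' tail the 60 nt immediately
#' downstream, and each internal junction carries a tail equal to the
#' terminal 60 nt of the neighboring cassette, so consecutive fragments
#' overlap by 60 bp.
#'
#' @param cassettes Ordered character vector of cassette sequences
#'   (each >= 60 nt).
#' @param locus Target `Locus` (flanks >= 60 nt).
#' @return data.frame with columns `fragment` (1-based index), `end`
#'   (`"5prime"`/`"3prime"`) and `tail` (60 nt).
#' @export
design_integration_tails <- function(cassettes, locus) {
  stopifnot(inherits(locus, "Locus"), length(cassettes) >= 1L)
  if (any(nchar(cassettes) < 60L))
    stop("cassette ", which(nchar(cassettes) < 60L)[1],
         " is shorter than 60 nt")
  up <- nchar(locus$upstream); dn <- nchar(locus$downstream)
  if (up < 60L || dn < 60L)
    stop("locus flanks must be >= 60 nt (have ", up, "/", dn, ")")
  n <- length(cassettes)
  rows <- list(data.frame(fragment = 1L, end = "5prime",
                          tail = substr(locus$upstream, up - 59L, up),
                          stringsAsFactors = FALSE))
  if (n > 1L) for (i in seq_len(n - 1L)) {
    # fragment i's 3' tail copies the start of the next cassette
    rows[[length(rows) + 1L]] <- data.frame(
      fragment = i, end = "3prime",
      tail = substr(cassettes[i + 1L], 1L, 60L), stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    fragment = n, end = "3prime",
    tail = substr(locus$downstream, 1L, 60L), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$fragment, out$end, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate HR stitching of tailed integration fragments
#'
#' Builds each amplicon as `5' tail + cassette + 3' tail` (tails absent
#' where not designed), then merges consecutive amplicons across their
#' 60 bp overlaps. The result is the integrated allele as it would appear
#' between the genomic junctions: `upstream60 + cassette1 + ... +
#' cassetteN + downstream60`.
#'
#' @param cassettes Ordered cassette sequences.
#' @param tails Output of [design_integration_tails()].
#' @return The stitched allele (character).
#' @export
stitch_integration <- function(cassettes, tails) {
  n <- length(cassettes)
  get_tail <- function(i, e) {
    t <- tails$tail[tails$fragment == i & tails$end == e]
    if (length(t)) t else ""
  }
  allele <- paste0(get_tail(1L, "5prime"), cassettes[1])
  if (n > 1L) for (i in 2:n) {
    amp <- paste0(get_tail(i, "5prime"), cassettes[i])
    # overlap: previous amplicon ends with the first 60 nt of cassette i
    prev_tail <- get_tail(i - 1L, "3prime")
    if (nzchar(prev_tail)) {
      if (prev_tail != substr(cassettes[i], 1L, 60L))
        stop("junction ", i - 1L, "/", i, " tails do not overlap")
      # overlap region appears once: allele so far ends at cassette i-1
      allele <- paste0(allele, cassettes[i])
    } else {
      allele <- paste0(allele, amp)
    }
  }
  paste0(allele, get_tail(n, "3prime"))
}

# deterministic stand-in cores for the externally deposited plasmid parts
default_two_micron_core <- function() strrep("GATCCA", 50L)
default_backbone_core <- function() strrep("CTGGAT", 60L)

#' Enumerate double-gRNA assembly outcomes
#'
#' The 2 micron template carries the primer-annealing sequence at both ends
#' in opposite orientations, so each tailed primer can prime either end:
#' the four end assignments (A,A), (A,B), (B,A), (B,B) are equally likely.
#' For each assignment the circular plasmid is built (backbone joined to
#' the amplified fragment through the shared 50 bp homology) and the copies
#' of each spacer are counted by exact substring scan on both strands with
#' circular wrap-around. An assembly is correct when it contains exactly
#' one copy of each spacer — the case for the two mixed assignments, hence
#' a 50% expected correct fraction.
#'
#' @param spacerA,spacerB 20 nt spacers.
#' @param backbone A `BackboneConfig`.
#' @param two_micron_core,backbone_core Internal template sequences
#'   (deterministic synthetic defaults).
#' @return data.frame with `description`, `sequence` (circular, as a
#'   linear string), `copies_A`, `copies_B`, `correct`.
#' @export
simulate_double_assembly <- function(spacerA, spacerB, backbone,
                                     two_micron_core = default_two_micron_core(),
                                     backbone_core = default_backbone_core()) {
  stopifnot(inherits(backbone, "BackboneConfig"))
  D <- backbone$double_homology
  A <- backbone$two_micron_anneal
  amplify <- function(spL, spR) {
    # left primer extends through the template; right primer appears as
    # its reverse complement at the far end
    paste0(D, spL, A, two_micron_core, revcomp(A), revcomp(spR), revcomp(D))
  }
  count_circular <- function(circle, spacer) {
    doubled <- paste0(circle, circle)
    n_top <- count_starts(doubled, spacer, nchar(circle))
    n_bot <- count_starts(doubled, revcomp(spacer), nchar(circle))
    n_top + n_bot
  }
  assignments <- list(c("A", "A"), c("A", "B"), c("B", "A"), c("B", "B"))
  sp <- c(A = spacerA, B = spacerB)
  out <- lapply(assignments, function(ab) {
    frag <- amplify(sp[[ab[1]]], sp[[ab[2]]])
    # Gibson: each homology end present once in the circle
    circle <- paste0(frag, backbone_core)
    cA <- count_circular(circle, spacerA)
    cB <- count_circular(circle, spacerB)
    data.frame(description = paste0("left=", ab[1], ",right=", ab[2]),
               sequence = circle, copies_A = cA, copies_B = cB,
               correct = (cA == 1L && cB == 1L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# number of occurrences of `pattern` (plain ACGT string) starting in the
# first `limit` positions of `text`; overlapping occurrences counted
count_starts <- function(text, pattern, limit) {
  pos <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1]]
  if (pos[1] == -1L) return(0L)
  sum(pos <= limit)
}

#' Restriction digest of a circular plasmid
#'
#' Finds every recognition site on both strands with circular wrap-around
#' (cut coordinates taken at the site start; fragment lengths depend only
#' on inter-site distances) and returns the sorted fragment lengths per
#' enzyme. Fragment lengths always sum to the plasmid length; an enzyme
#' with no site yields an empty vector (uncut).
#'
#' @param plasmid Circular plasmid sequence (linear representation).
#' @param enzymes Enzyme data.frame (`name`, `site`).
#' @return Named list: enzyme name -> sorted integer fragment lengths.
#' @export
digest_check <- function(plasmid, enzymes = default_enzymes()) {
  stopifnot(nzchar(plasmid))
  L <- nchar(plasmid)
  doubled <- paste0(plasmid, plasmid)
  res <- lapply(seq_len(nrow(enzymes)), function(i) {
    site <- enzymes$site[i]
    cuts <- integer()
    for (s in unique(c(site, revcomp(site)))) {
      re <- paste0("(?=", iupac_to_regex(s), ")")
      pos <- gregexpr(re, doubled, perl = TRUE)[[1]]
      if (pos[1] != -1L)
        cuts <- c(cuts, (pos[pos <= L] - 1L) %% L)
    }
    cuts <- sort(unique(cuts))
    if (!length(cuts)) return(integer())
    if (length(cuts) == 1L) return(L)
    sort(as.integer(c(diff(cuts), L - cuts[length(cuts)] + cuts[1])))
  })
  names(res) <- enzymes$name
  res
}

#' Write designed oligos as FASTA and TSV
#'
#' One FASTA record per strand with the segment anatomy in the description
#' line; the TSV lists name, sequence, length and role.
#'
#' @param oligos Named list of `OligoPair` / primer records.
#' @param fasta_path,tsv_path Output paths (NULL to skip either).
#' @export
write_oligos <- function(oligos, fasta_path = NULL, tsv_path = NULL) {
  recs <- list()
  for (o in oligos) {
    anat <- paste(sprintf("%s:%d-%d", o$anatomy$role, o$anatomy$start + 1L,
                          o$anatomy$end), collapse = ";")
    recs[[length(recs) + 1L]] <- c(paste0(o$name, "_top anatomy=", anat),
                                   o$top, paste0(o$name, "_top"))
    if (!is.null(o$bottom))
      recs[[length(recs) + 1L]] <- c(paste0(o$name, "_bottom revcomp_of=",
                                            o$name, "_top"),
                                     o$bottom, paste0(o$name, "_bottom"))
  }
  if (!is.null(fasta_path)) {
    lines <- as.character(unlist(lapply(recs, function(r)
      c(paste0(">", r[1]), r[2]))))
    writeLines(lines, fasta_path)
  }
  if (!is.null(tsv_path)) {
    df <- do.call(rbind, lapply(recs, function(r)
      data.frame(name = r[3], sequence = r[2], length = nchar(r[2]),
                 role = sub(" .*$", "", r[1]), stringsAsFactors = FALSE)))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  }
  invisible(length(recs))
}
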