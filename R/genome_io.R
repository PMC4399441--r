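#' Reverse complement of a DNA string
#'
#' Complements per the IUPAC table (ambiguity codes accepted) and reverses.
#' `revcomp` is an involution: `revcomp(revcomp(x)) == x`.
#'
#' @param seq Character vector of DNA strings (A/C/G/T/N and IUPAC codes).
#' @return Character vector of reverse complements, same length as `seq`.
#' @examples
#' revcomp("AAGTC")   # "GACTT"
#' revcomp("GGATCC")  # palindrome
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTNRYSWKMBDHVacgtnryswkmbdhv-]", seq)
  if (any(bad)) {
    stop("non-IUPAC character in sequence: ",
         substr(seq[bad][1], 1, 40))
  }
  comp <- chartr("ACGTNRYSWKMBDHVacgtnryswkmbdhv",
                 "TGCANYRSWMKVHDBtgcanyrswmkvhdb", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

#' Read a genome from FASTA and GFF3 into a `Genome` object
#'
#' Chromosome sequences are upper-cased; IUPAC ambiguity codes other than
#' A/C/G/T are collapsed to N (downstream stages treat N as matching
#' nothing). Gene features are taken from GFF3 records of type `gene`
#' (falling back to `CDS` grouped by `Parent` when a file carries no `gene`
#' records); introns are not spliced out — a feature is its genomic span.
#' GFF3 1-based inclusive coordinates are converted to internal 0-based
#' half-open; all user-facing output is converted back to 1-based inclusive.
#'
#' @param fasta_path Path to a (multi-record) FASTA file.
#' @param gff_path Path to a GFF3 file whose `ID=` (and optional
#'   `gene=`/`Name=`) attributes name the genes.
#' @return An object of class `Genome`: a list with `chroms` (named
#'   character vector of sequences) and `features` (data.frame with columns
#'   `systematic_name`, `standard_name`, `chrom`, `start`, `end`, `strand`;
#'   `start`/`end` 0-based half-open).
#' @export
read_genome <- function(fasta_path, gff_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                   error = function(e) stop("malformed FASTA '", fasta_path,
                                            "': ", conditionMessage(e)))
  chroms <- toupper(as.character(seqs))
  # FASTA description lines may carry extra tokens after the name
  names(chroms) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(chroms)))
    stop("duplicate chromosome name in FASTA: ",
         names(chroms)[duplicated(names(chroms))][1])
  if (any(!nzchar(names(chroms)))) stop("empty chromosome name in FASTA")
  chroms <- vapply(chroms, function(s)
    gsub("[^ACGTN]", "N", s), character(1))

  gr <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", gff_path,
                                          "': ", conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  feat <- df[df$type == "gene", , drop = FALSE]
  if (nrow(feat) == 0L && any(df$type == "CDS")) {
    cds <- df[df$type == "CDS", , drop = FALSE]
    parent <- vapply(cds$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
    cds$ID <- ifelse(is.na(parent), cds$ID, parent)
    # one feature per parent: the full genomic span of its CDS parts
    feat <- do.call(rbind, lapply(split(cds, cds$ID), function(g) {
      g1 <- g[1, , drop = FALSE]
      g1$start <- min(g$start); g1$end <- max(g$end)
      g1
    }))
  }
  if (nrow(feat) == 0L) stop("no gene or CDS features in GFF3: ", gff_path)

  std <- rep(NA_character_, nrow(feat))
  for (col in c("gene", "Name")) {
    if (col %in% names(feat)) {
      v <- as.character(feat[[col]])
      std <- ifelse(is.na(std) & !is.na(v) & nzchar(v), v, std)
    }
  }
  features <- data.frame(
    systematic_name = as.character(feat$ID),
    standard_name = std,
    chrom = as.character(feat$seqnames),
    start = as.integer(feat$start) - 1L,  # 1-based incl -> 0-based half-open
    end = as.integer(feat$end),
    strand = as.character(feat$strand),
    stringsAsFactors = FALSE
  )
  rownames(features) <- NULL
  if (any(is.na(features$systematic_name)) || any(!nzchar(features$systematic_name)))
    stop("GFF3 gene feature without an ID attribute in ", gff_path)
  if (anyDuplicated(features$systematic_name))
    stop("duplicate gene ID in GFF3: ",
         features$systematic_name[duplicated(features$systematic_name)][1])
  if (!all(features$strand %in% c("+", "-")))
    stop("gene feature without +/- strand: ",
         features$systematic_name[!features$strand %in% c("+", "-")][1])
  missing_chr <- setdiff(features$chrom, names(chroms))
  if (length(missing_chr)) {
    f <- features$systematic_name[features$chrom %in% missing_chr][1]
    stop("feature '", f, "' refers to chromosome '",
         features$chrom[features$systematic_name == f][1],
         "' absent from the FASTA")
  }
  lens <- nchar(chroms)[features$chrom]
  bad <- features$start < 0L | features$start >= features$end |
    features$end > lens
  if (any(bad))
    stop("feature '", features$systematic_name[bad][1],
         "' has coordinates outside its chromosome")
  structure(list(chroms = chroms, features = features), class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome:", length(x$chroms), "chromosome(s),",
      nrow(x$features), "gene feature(s)\n")
  cat("  total length:", sum(nchar(x$chroms)), "bp\n")
  invisible(x)
}

# 0-based half-open substring of a chromosome
genome_subseq <- function(genome, chrom, start, end) {
  s <- genome$chroms[[chrom]]
  stopifnot(start >= 0L, end <= nchar(s), start <= end)
  substr(s, start + 1L, end)
}

#' Resolve a gene query to its feature
#'
#' Matches case-insensitively against systematic names first, then standard
#' names. A query matching several standard names is rejected with a request
#' for the systematic name.
#'
#' @param genome A `Genome` from [read_genome()].
#' @param query Gene name, systematic (e.g. `"YDL054C"`) or standard
#'   (e.g. `"MCH1"`); case-insensitive.
#' @return The matching feature as a one-row data.frame.
#' @export
resolve_gene <- function(genome, query) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query))
  feats <- genome$features
  q <- toupper(query)
  hit <- which(toupper(feats$systematic_name) == q)
  if (length(hit) == 1L) return(feats[hit, , drop = FALSE])
  hit <- which(!is.na(feats$standard_name) &
                 toupper(feats$standard_name) == q)
  if (length(hit) == 1L) return(feats[hit, , drop = FALSE])
  if (length(hit) > 1L)
    stop("standard name '", query, "' is ambiguous (",
         paste(feats$systematic_name[hit], collapse = ", "),
         "); use a systematic name")
  known <- unique(c(feats$systematic_name,
                    feats$standard_name[!is.na(feats$standard_name)]))
  d <- utils::adist(q, toupper(known))
  near <- known[order(d)][seq_len(min(3L, length(known)))]
  stop("unknown gene '", query, "'; nearest names: ",
       paste(near, collapse = ", "))
}

#' Extract a gene locus with flanking sequence
#'
#' Returns the sense-strand ORF sequence plus up to 1 kb of immediately
#' flanking sequence on each side, also sense-oriented (upstream is 5' of
#' the start codon). For minus-strand genes all three sequences are reverse
#' complements of the corresponding genomic plus-strand slices. Flanks are
#' shorter than `flank` only at chromosome ends.
#'
#' @param genome A `Genome`.
#' @param feature A one-row feature data.frame from [resolve_gene()] (or a
#'   character gene query, resolved internally).
#' @param flank Maximum flank length in nt (default 1000).
#' @return An object of class `Locus`: list with `feature`, `orf_seq`,
#'   `upstream`, `downstream`.
#' @export
extract_locus <- function(genome, feature, flank = 1000L) {
  if (is.character(feature)) feature <- resolve_gene(genome, feature)
  stopifnot(is.data.frame(feature), nrow(feature) == 1L)
  if (!feature$systematic_name %in% genome$features$systematic_name)
    stop("feature '", feature$systematic_name,
         "' does not belong to this genome")
  L <- nchar(genome$chroms[[feature$chrom]])
  orf <- genome_subseq(genome, feature$chrom, feature$start, feature$end)
  left <- genome_subseq(genome, feature$chrom,
                        max(0L, feature$start - flank), feature$start)
  right <- genome_subseq(genome, feature$chrom, feature$end,
                         min(L, feature$end + flank))
  if (feature$strand == "+") {
    locus <- list(feature = feature, orf_seq = orf,
                  upstream = left, downstream = right)
  } else {
    locus <- list(feature = feature, orf_seq = revcomp(orf),
                  upstream = revcomp(right), downstream = revcomp(left))
  }
  structure(locus, class = "Locus")
}

#' @export
print.Locus <- function(x, ...) {
  f <- x$feature
  cat(sprintf("Locus %s (%s) %s:%d-%d [%s], ORF %d nt, flanks %d/%d nt\n",
              f$systematic_name,
              ifelse(is.na(f$standard_name), "-", f$standard_name),
              f$chrom, f$start + 1L, f$end, f$strand, nchar(x$orf_seq),
              nchar(x$upstream), nchar(x$downstream)))
  invisible(x)
}
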