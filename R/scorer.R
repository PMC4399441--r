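#' Default restriction-enzyme list
#'
#' Minimal set of common 6-cutters used for plasmid-assembly verification.
#' Extend or replace via [read_enzyme_list()].
#'
#' @return data.frame with columns `name`, `site` (IUPAC recognition site).
#' @export
default_enzymes <- function() {
  data.frame(
    name = c("PvuI", "EcoRV", "DraI", "EcoRI", "KpnI", "BamHI", "PvuII"),
    site = c("CGATCG", "GATATC", "TTTAAA", "GAATTC", "GGTACC", "GGATCC",
             "CAGCTG"),
    stringsAsFactors = FALSE
  )
}

#' Read a restriction-enzyme list from TSV
#'
#' @param path TSV file with columns `name` and `site` (IUPAC codes).
#' @return data.frame with columns `name`, `site`.
#' @export
read_enzyme_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "site") %in% names(df)))
    stop("enzyme list must have columns 'name' and 'site': ", path)
  df$site <- toupper(df$site)
  bad <- grepl("[^ACGTNRYSWKMBDHV]", df$site) | nchar(df$site) < 4L
  if (any(bad))
    stop("invalid IUPAC site for enzyme ", df$name[bad][1])
  df[, c("name", "site")]
}

#' Scoring configuration
#'
#' @param enabled_components Subset of `c("AT", "RNA", "restriction")`;
#'   the rank sum adds only the enabled components.
#' @param enzyme_list Enzyme data.frame (default [default_enzymes()]).
#' @param fold_backend `"MEA-thermodynamic"` (ViennaRNA `RNAfold`, maximum
#'   expected accuracy) or `"basepair-max-fallback"` (bundled base-pair
#'   maximization).
#' @param fold_temperature Folding temperature in Celsius (default 30).
#' @param fold_molecule `"spacer_only"` folds the 20 nt spacer as RNA;
#'   `"spacer_plus_scaffold"` appends `scaffold_seq` 3' of the spacer.
#' @param scaffold_seq Optional scaffold RNA/DNA string (required when
#'   `fold_molecule = "spacer_plus_scaffold"`).
#' @return A `ScoreConfig` list.
#' @export
score_config <- function(enabled_components = c("AT", "RNA", "restriction"),
                         enzyme_list = default_enzymes(),
                         fold_backend = c("MEA-thermodynamic",
                                          "basepair-max-fallback"),
                         fold_temperature = 30,
                         fold_molecule = c("spacer_only",
                                           "spacer_plus_scaffold"),
                         scaffold_seq = NULL) {
  enabled_components <- match.arg(enabled_components,
                                  c("AT", "RNA", "restriction"),
                                  several.ok = TRUE)
  if (!length(enabled_components)) stop("no scoring components enabled")
  fold_molecule <- match.arg(fold_molecule)
  if (fold_molecule == "spacer_plus_scaffold" && is.null(scaffold_seq))
    stop("scaffold_seq required for spacer_plus_scaffold folding")
  structure(list(enabled_components = enabled_components,
                 enzyme_list = enzyme_list,
                 fold_backend = match.arg(fold_backend),
                 fold_temperature = fold_temperature,
                 fold_molecule = fold_molecule,
                 scaffold_seq = scaffold_seq),
            class = "ScoreConfig")
}

#' AT fraction of a spacer
#'
#' @param spacer 20 nt ACGT-only spacer; the PAM is never included.
#' @return (#A + #T) / 20, exact.
#' @examples
#' at_fraction("TATTGGCAATAAACATCTCG")  # 0.65
#' @export
at_fraction <- function(spacer) {
  stopifnot(is.character(spacer), length(spacer) == 1L)
  if (nchar(spacer) != 20L) stop("spacer must be 20 nt, got ", nchar(spacer))
  if (grepl("[^ACGT]", spacer)) stop("spacer must be ACGT-only")
  ch <- strsplit(spacer, "", fixed = TRUE)[[1]]
  sum(ch %in% c("A", "T")) / 20
}

#' Predicted secondary-structure pairing of a spacer
#'
#' Transcribes the spacer to RNA, folds the configured molecule and counts
#' the spacer nucleotides engaged in base pairs (non-dot characters of the
#' dot-bracket string over the first 20 positions). The default backend is
#' ViennaRNA's `RNAfold` maximum expected accuracy structure with lonely
#' pairs disallowed at 30 degrees C; when `RNAfold` is not on the PATH the
#' bundled base-pair-maximization folder (Watson-Crick + GU wobble pairs,
#' minimum hairpin loop 3) is used with a warning.
#'
#' @param spacer 20 nt ACGT-only spacer.
#' @param config A `ScoreConfig`.
#' @return list with `dot_bracket` (structure of the folded molecule) and
#'   `paired_count` (integer 0-20, spacer portion only).
#' @export
fold_paired_count <- function(spacer, config = score_config()) {
  stopifnot(nchar(spacer) == 20L, !grepl("[^ACGT]", spacer))
  mol <- if (config$fold_molecule == "spacer_plus_scaffold")
    paste0(spacer, config$scaffold_seq) else spacer
  rna <- chartr("Tt", "Uu", toupper(mol))
  backend <- config$fold_backend
  if (backend == "MEA-thermodynamic" && !nzchar(Sys.which("RNAfold"))) {
    warning("RNAfold not found; falling back to base-pair maximization")
    backend <- "basepair-max-fallback"
  }
  db <- if (backend == "MEA-thermodynamic")
    rnafold_mea(rna, config$fold_temperature) else nussinov_fold(rna)
  paired <- sum(strsplit(substr(db, 1L, 20L), "", fixed = TRUE)[[1]] != ".")
  list(dot_bracket = db, paired_count = paired)
}

# MEA structure via the RNAfold CLI; returns the dot-bracket string
rnafold_mea <- function(rna, temp) {
  owd <- setwd(tempdir()); on.exit(setwd(owd))
  out <- suppressWarnings(system2(
    "RNAfold", c("--MEA", "--noLP", "--noPS", paste0("--temp=", temp)),
    input = rna, stdout = TRUE, stderr = FALSE))
  mea_line <- grep("MEA=", out, value = TRUE, fixed = TRUE)
  if (!length(mea_line)) stop("could not parse RNAfold MEA output")
  db <- sub("\\s.*$", "", mea_line[1])
  if (nchar(db) != nchar(rna)) stop("RNAfold structure length mismatch")
  db
}

# Watson-Crick + GU wobble pairing, on integer codes A=1 C=2 G=3 U=4
rna_pair_matrix <- local({
  m <- matrix(FALSE, 4L, 4L)
  m[1, 4] <- m[4, 1] <- TRUE   # A:U
  m[2, 3] <- m[3, 2] <- TRUE   # C:G
  m[3, 4] <- m[4, 3] <- TRUE   # G:U
  m
})

# Base-pair maximization (Nussinov-style DP, min hairpin loop 3,
# Watson-Crick + GU) with traceback to dot-bracket.
nussinov_fold <- function(rna) {
  ch <- strsplit(rna, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 5L) return(strrep(".", n))
  code <- match(ch, c("A", "C", "G", "U"))   # NA never pairs
  D <- matrix(0L, n, n)
  pairable <- function(k, j)
    !is.na(code[k]) & !is.na(code[j]) & rna_pair_matrix[cbind(code[k],
                                                              code[j])]
  for (span in 4:(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- D[i, j - 1]                      # j unpaired
      ks <- (i:(j - 4L))[pairable(i:(j - 4L), j)]  # j pairs with k
      if (length(ks)) {
        left <- integer(length(ks))
        sel <- ks > i
        left[sel] <- D[i, ks[sel] - 1L]
        vals <- 1L + left + D[cbind(ks + 1L, j - 1L)]
        best <- max(best, vals)
      }
      D[i, j] <- best
    }
  }
  struct <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i < 4L) next
    if (D[i, j] == D[i, j - 1]) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    for (k in i:(j - 4)) {
      if (pairable(k, j)) {
        v <- 1L + (if (k > i) D[i, k - 1] else 0L) + D[k + 1, j - 1]
        if (v == D[i, j]) {
          struct[k] <- "("; struct[j] <- ")"
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          break
        }
      }
    }
  }
  paste(struct, collapse = "")
}

iupac_regex_map <- c(A = "A", C = "C", G = "G", T = "T",
                     R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                     K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                     H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_to_regex <- function(site) {
  paste(iupac_regex_map[strsplit(site, "", fixed = TRUE)[[1]]],
        collapse = "")
}

#' Restriction sites within a spacer
#'
#' Scans the 20 nt spacer and its reverse complement for each enzyme's
#' IUPAC recognition site (the PAM is excluded: only the spacer is carried
#' into the verification plasmid). A genome N never satisfies an ambiguity
#' code. Duplicate reports (e.g. palindromic sites found on both strands)
#' are collapsed.
#'
#' @param spacer 20 nt spacer.
#' @param enzymes Enzyme data.frame (`name`, `site`).
#' @return Character vector of enzyme names with at least one site.
#' @export
restriction_hits <- function(spacer, enzymes = default_enzymes()) {
  rc <- revcomp(spacer)
  hit <- vapply(enzymes$site, function(site) {
    re <- iupac_to_regex(site)
    grepl(re, spacer) || grepl(re, rc)
  }, logical(1))
  unique(enzymes$name[hit])
}

#' Score surviving candidates of a locus
#'
#' Computes the raw components for every candidate not yet discarded:
#' AT fraction, folded paired count and restriction hits.
#'
#' @param candidates Candidate data.frame after filtering.
#' @param config A `ScoreConfig`.
#' @return data.frame of raw scores (one row per surviving candidate) ready
#'   for [normalize_and_rank()].
#' @export
score_targets <- function(candidates, config = score_config()) {
  live <- candidates[is.na(candidates$discarded_reason), , drop = FALSE]
  if (nrow(live) == 0L) {
    return(data.frame(locus_name = character(), spacer = character(),
                      pam = character(), strand_vs_orf = character(),
                      chrom = character(), start = integer(), end = integer(),
                      genome_strand = character(), at_fraction = numeric(),
                      paired_count = integer(),
                      enzymes_hit = character(), stringsAsFactors = FALSE))
  }
  live$at_fraction <- vapply(live$spacer, at_fraction, numeric(1))
  live$paired_count <- vapply(live$spacer, function(s)
    fold_paired_count(s, config)$paired_count, numeric(1))
  live$enzymes_hit <- vapply(live$spacer, function(s)
    paste(restriction_hits(s, config$enzyme_list), collapse = ","),
    character(1))
  rownames(live) <- NULL
  live[, c("locus_name", "spacer", "pam", "strand_vs_orf", "chrom",
           "start", "end", "genome_strand", "at_fraction", "paired_count",
           "enzymes_hit")]
}

#' Normalize scores per locus and rank candidates
#'
#' Within one locus: `at_norm = (at - min) / (max - min)` (1 = highest AT
#' content), `rna_norm = (max_paired - paired) / (max_paired - min_paired)`
#' (1 = least paired), `restriction_score` = 1 when any enzyme cuts the
#' spacer else 0. When a component's range is degenerate (max == min) it is
#' set to 0.5 for every candidate, which is neutral for the ordering. The
#' rank sum adds the enabled components only; candidates are sorted by
#' descending rank sum with deterministic tie-breaking (higher raw AT
#' fraction, then smaller genomic start, then "+" strand first) and ranks
#' 1..n assigned. Scores order targets within a single locus only and are
#' not comparable across loci.
#'
#' @param scored Output of [score_targets()] for a single locus.
#' @param config A `ScoreConfig`.
#' @return The scored data.frame with `at_norm`, `rna_norm`,
#'   `restriction_score`, `rank_sum`, `rank` columns, sorted by rank.
#' @export
normalize_and_rank <- function(scored, config = score_config()) {
  if (nrow(scored) == 0L) {
    scored$at_norm <- numeric(); scored$rna_norm <- numeric()
    scored$restriction_score <- numeric(); scored$rank_sum <- numeric()
    scored$rank <- integer()
    return(scored)
  }
  if (length(unique(scored$locus_name)) != 1L)
    stop("normalize_and_rank expects candidates from a single locus")
  rng_norm <- function(x, invert = FALSE) {
    lo <- min(x); hi <- max(x)
    if (hi == lo) return(rep(0.5, length(x)))
    v <- (x - lo) / (hi - lo)
    if (invert) 1 - v else v
  }
  scored$at_norm <- rng_norm(scored$at_fraction)
  scored$rna_norm <- rng_norm(scored$paired_count, invert = TRUE)
  scored$restriction_score <- as.numeric(nzchar(scored$enzymes_hit))
  comp <- config$enabled_components
  scored$rank_sum <- (if ("AT" %in% comp) scored$at_norm else 0) +
    (if ("RNA" %in% comp) scored$rna_norm else 0) +
    (if ("restriction" %in% comp) scored$restriction_score else 0)
  ord <- order(-scored$rank_sum, -scored$at_fraction, scored$start,
               scored$genome_strand, method = "radix")
  scored <- scored[ord, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  scored
}

#' Write a target score table as TSV
#'
#' Coordinates are 1-based inclusive in the output.
#'
#' @param scored Ranked score data.frame from [normalize_and_rank()]
#'   (several loci may be row-bound).
#' @param path Output file path.
#' @export
write_score_tsv <- function(scored, path) {
  out <- data.frame(
    locus = scored$locus_name, spacer = scored$spacer, pam = scored$pam,
    strand = scored$strand_vs_orf, chrom = scored$chrom,
    start = scored$start + 1L, end = scored$end,
    genome_strand = scored$genome_strand,
    at_fraction = scored$at_fraction, paired_count = scored$paired_count,
    enzymes = scored$enzymes_hit, at_norm = scored$at_norm,
    rna_norm = scored$rna_norm,
    restriction_score = scored$restriction_score,
    rank_sum = scored$rank_sum, rank = scored$rank)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
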