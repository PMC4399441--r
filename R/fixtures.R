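# run code under a temporary RNG state so fixture generation is
# deterministic without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# spacer variant at exactly `m` mismatches (positions and substitutions
# drawn from the current RNG stream)
mutate_spacer <- function(spacer, m) {
  ch <- strsplit(spacer, "", fixed = TRUE)[[1]]
  if (m > 0L) for (i in sample(seq_along(ch), m)) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Specification of a synthetic test genome
#'
#' @param chromosome_lengths Integer vector of chromosome lengths;
#'   chromosomes are named `chr1`, `chr2`, ...
#' @param genes data.frame with columns `name`, `chrom`, `start` (0-based),
#'   `strand`, `orf_length`; optional `standard_name`.
#' @param planted_targets data.frame with columns `gene`, `offset` (0-based
#'   offset of the spacer within the ORF sense strand), `spacer` (20 nt),
#'   `pam` (3 nt NGG).
#' @param decoys data.frame with columns `spacer` (the reference spacer to
#'   degrade), `mismatches` (0-20; only decoys within 3 are visible to the
#'   off-target scanner), `pam` (3 nt), `chrom`, `position`
#'   (0-based plus-strand position of the planted 20-mer).
#' @param seed Integer seed; the same spec yields byte-identical output.
#' @return A `SyntheticGenomeSpec` list.
#' @export
synthetic_genome_spec <- function(chromosome_lengths, genes,
                                  planted_targets = NULL, decoys = NULL,
                                  seed = 1L) {
  structure(list(chromosome_lengths = as.integer(chromosome_lengths),
                 genes = genes, planted_targets = planted_targets,
                 decoys = decoys, seed = as.integer(seed)),
            class = "SyntheticGenomeSpec")
}

#' Generate a deterministic synthetic genome with planted targets
#'
#' Samples background sequence from the seeded generator, plants target
#' spacer+PAM sequences inside genes and decoy 20-mers (exact-mismatch
#' variants of a reference spacer, followed by a chosen PAM) elsewhere.
#' The background is screened with the exhaustive off-target scanner
#' ([find_offtargets_exhaustive()], independent of the production scanner)
#' for accidental <=3-mismatch NGG/NAG neighbors of any planted spacer and
#' re-sampled on collision, so every off-target present is one that was
#' planted. Genes are plain sequence spans without start/stop-codon
#' realism.
#'
#' @param spec A `SyntheticGenomeSpec`.
#' @param max_retries Background re-sampling attempts before giving up.
#' @return list with `genome` (a `Genome`), `fasta` (FASTA text),
#'   `gff` (GFF3 text), and `decoys` (the realized decoy table with the
#'   planted sequences).
#' @export
make_genome <- function(spec, max_retries = 25L) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  lens <- spec$chromosome_lengths
  chrom_names <- paste0("chr", seq_along(lens))
  genes <- spec$genes
  stopifnot(all(genes$chrom %in% chrom_names),
            all(genes$start >= 0L),
            all(genes$start + genes$orf_length <= lens[match(genes$chrom, chrom_names)]))

  # planned insertions: (chrom, start0, sequence)
  plant <- list()
  realized_decoys <- NULL
  with_local_seed(spec$seed, {
    if (!is.null(spec$planted_targets) && nrow(spec$planted_targets)) {
      for (i in seq_len(nrow(spec$planted_targets))) {
        p <- spec$planted_targets[i, ]
        g <- genes[genes$name == p$gene, ]
        stopifnot(nrow(g) == 1L, nchar(p$spacer) == 20L, nchar(p$pam) == 3L)
        # offset is on the ORF sense strand; convert to plus-strand coords
        seq23 <- paste0(p$spacer, p$pam)
        if (g$strand == "+") {
          s0 <- g$start + p$offset
        } else {
          s0 <- g$start + g$orf_length - p$offset - 23L
          seq23 <- revcomp(seq23)
        }
        plant[[length(plant) + 1L]] <- list(chrom = g$chrom, start = s0,
                                            seq = seq23)
      }
    }
    if (!is.null(spec$decoys) && nrow(spec$decoys)) {
      dec <- spec$decoys
      dec$planted_seq <- NA_character_
      for (i in seq_len(nrow(dec))) {
        d <- dec[i, ]
        stopifnot(d$mismatches >= 0L, d$mismatches <= 20L)
        variant <- mutate_spacer(d$spacer, d$mismatches)
        dec$planted_seq[i] <- variant
        plant[[length(plant) + 1L]] <- list(chrom = d$chrom,
                                            start = d$position,
                                            seq = paste0(variant, d$pam))
      }
      realized_decoys <- dec
    }
    # planted intervals must be pairwise disjoint
    if (length(plant) > 1L) {
      iv <- do.call(rbind, lapply(plant, function(p)
        data.frame(chrom = p$chrom, s = p$start,
                   e = p$start + nchar(p$seq))))
      for (cn in unique(iv$chrom)) {
        sub <- iv[iv$chrom == cn, ]
        sub <- sub[order(sub$s), ]
        if (nrow(sub) > 1L && any(sub$s[-1] < sub$e[-nrow(sub)]))
          stop("planted intervals overlap on ", cn)
      }
    }

    spacers <- unique(c(
      if (!is.null(spec$planted_targets)) spec$planted_targets$spacer,
      if (!is.null(realized_decoys)) realized_decoys$spacer))
    intended_hits <- function(genome) {
      # every <=3-mismatch NGG/NAG site must be a planted one
      planted_starts <- vapply(plant, function(p)
        paste0(p$chrom, ":", p$start), character(1))
      for (sp in spacers) {
        h <- find_offtargets_exhaustive(sp, genome)
        if (!nrow(h)) next
        key <- paste0(h$chrom, ":", ifelse(h$strand == "+", h$start,
                                           h$start))
        # a hit is expected iff its 20-mer lies inside a planted interval
        ok <- vapply(seq_len(nrow(h)), function(k) {
          any(vapply(plant, function(p)
            h$chrom[k] == p$chrom & h$start[k] >= p$start - 3L &
              h$end[k] <= p$start + nchar(p$seq) + 3L, logical(1)))
        }, logical(1))
        if (!all(ok)) return(FALSE)
      }
      TRUE
    }

    genome <- NULL
    for (attempt in seq_len(max_retries)) {
      chroms <- vapply(lens, random_dna, character(1))
      names(chroms) <- chrom_names
      for (p in plant) {
        substr(chroms[[p$chrom]], p$start + 1L,
               p$start + nchar(p$seq)) <- p$seq
      }
      features <- data.frame(
        systematic_name = genes$name,
        standard_name = if ("standard_name" %in% names(genes))
          genes$standard_name else NA_character_,
        chrom = genes$chrom, start = as.integer(genes$start),
        end = as.integer(genes$start + genes$orf_length),
        strand = genes$strand, stringsAsFactors = FALSE)
      cand <- structure(list(chroms = chroms, features = features),
                        class = "Genome")
      if (!length(spacers) || intended_hits(cand)) { genome <- cand; break }
    }
    if (is.null(genome))
      stop("could not generate a collision-free background after ",
           max_retries, " attempts; spec may be unsatisfiable")

    fasta <- unlist(lapply(chrom_names, function(cn)
      c(paste0(">", cn), genome$chroms[[cn]])))
    gff <- c("##gff-version 3",
             vapply(seq_len(nrow(genome$features)), function(i) {
               f <- genome$features[i, ]
               attrs <- paste0("ID=", f$systematic_name)
               if (!is.na(f$standard_name))
                 attrs <- paste0(attrs, ";gene=", f$standard_name)
               paste(f$chrom, "guidecraft", "gene", f$start + 1L, f$end,
                     ".", f$strand, ".", attrs, sep = "\t")
             }, character(1)))
    list(genome = genome, fasta = paste(fasta, collapse = "\n"),
         gff = paste(gff, collapse = "\n"), decoys = realized_decoys)
  })
}

#' Write a synthetic genome to FASTA and GFF3 files
#'
#' @param made Output of [make_genome()].
#' @param dir Directory to write into (created if absent).
#' @return Named list with `fasta` and `gff` paths.
#' @export
write_genome_fixture <- function(made, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genes.gff3")
  writeLines(made$fasta, fasta)
  writeLines(made$gff, gff)
  list(fasta = fasta, gff = gff)
}

#' Generate a random backbone configuration
#'
#' Random ACGT flanks of the exact required lengths (50/50/50/20),
#' deterministic per seed.
#'
#' @param seed Integer seed.
#' @return A `BackboneConfig`.
#' @export
make_backbone_config <- function(seed = 1L) {
  with_local_seed(seed, {
    backbone_config(flank5 = random_dna(50L), flank3 = random_dna(50L),
                    double_homology = random_dna(50L),
                    two_micron_anneal = random_dna(20L))
  })
}
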