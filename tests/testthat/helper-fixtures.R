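# shared fixtures and independent oracles

# touch the sequence and annotation machinery once so per-test timings
# reflect the algorithms, not first-use package initialization
invisible(guidecraft::revcomp("ACGT"))
local({
  d <- tempfile("warmup")
  dir.create(d)
  writeLines(c(">chrW", strrep("ACGT", 20)), file.path(d, "w.fasta"))
  writeLines(c("##gff-version 3",
               "chrW\tx\tgene\t5\t60\t.\t+\t.\tID=WARM1"),
             file.path(d, "w.gff3"))
  invisible(guidecraft::read_genome(file.path(d, "w.fasta"),
                                    file.path(d, "w.gff3")))
  unlink(d, recursive = TRUE)
})

# the ten published target spacers (20 nt, PAM stripped) with their printed
# AT scores and restriction-enzyme assignments
published_targets <- data.frame(
  locus = c("MCH1", "MCH2", "MCH5", "AQY1", "ITR1", "PDR12", "NAT1",
            "GET4", "ACS1", "ACS2"),
  spacer = c("TATTGGCAATAAACATCTCG", "ATCTCGATCGAGGTGCCTGA",
             "ACTCTTCCGTTTTAGATATC", "ACCATCGCTTTAAAATCTCT",
             "ATACATCAACGAATTCCAAC", "GCATTTTCGGTACCTAACTC",
             "AAAGGAATTGGATCCTGCGT", "GGGCTCGCTAGGATCCAATT",
             "TTCTTCACAGCTGGAGACAT", "TCCTTGCCGTTAAATCACCA"),
  pam = c("AGG", "TGG", "TGG", "AGG", "CGG", "CGG", "AGG", "CGG", "TGG",
          "TGG"),
  at_score = c(0.65, 0.45, 0.65, 0.65, 0.65, 0.55, 0.55, 0.45, 0.55, 0.55),
  enzyme = c(NA, "PvuI", "EcoRV", "DraI", "EcoRI", "KpnI", "BamHI",
             "BamHI", "PvuII", NA),
  stringsAsFactors = FALSE)

# deterministic random DNA for tests
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small one-gene genome with one planted unique target
simple_fixture <- function(seed = 42L, strand = "+", spacer = NULL,
                           decoys = NULL, chrom_lens = c(5000L, 3000L)) {
  if (is.null(spacer)) spacer <- "TATTGGCAATAAACATCTCG"
  genes <- data.frame(name = "YGN001", standard_name = "MCH1",
                      chrom = "chr1", start = 1200L, strand = strand,
                      orf_length = 600L, stringsAsFactors = FALSE)
  pt <- data.frame(gene = "YGN001", offset = 100L, spacer = spacer,
                   pam = "AGG", stringsAsFactors = FALSE)
  make_genome(synthetic_genome_spec(chrom_lens, genes, pt, decoys,
                                    seed = seed))
}

# brute-force candidate enumeration by regex over both strands of the ORF
oracle_enumerate <- function(orf) {
  scan <- function(seq, strand) {
    hits <- list()
    n <- nchar(seq)
    if (n < 23L) return(NULL)
    for (j in 0:(n - 23L)) {
      pam <- substr(seq, j + 21L, j + 23L)
      if (substr(pam, 2, 3) == "GG" &&
          substr(pam, 1, 1) %in% c("A", "C", "G", "T"))
        hits[[length(hits) + 1L]] <- data.frame(
          offset = j, spacer = substr(seq, j + 1L, j + 20L), pam = pam,
          strand_vs_orf = strand, stringsAsFactors = FALSE)
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }
  rbind(scan(orf, "+"), scan(guidecraft::revcomp(orf), "-"))
}

# exhaustive enumeration of all valid secondary structures (WC + GU pairs,
# min hairpin loop 3); returns the maximum number of base pairs
oracle_max_pairs <- function(rna) {
  ch <- strsplit(chartr("T", "U", rna), "", fixed = TRUE)[[1]]
  can_pair <- function(a, b)
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  best <- function(i, j) {
    if (j - i < 4L) return(0L)
    b <- best(i, j - 1L)                  # j unpaired
    for (k in i:(j - 4L)) {
      if (can_pair(ch[k], ch[j])) {
        left <- if (k > i) best(i, k - 1L) else 0L
        b <- max(b, 1L + left + best(k + 1L, j - 1L))
      }
    }
    b
  }
  if (length(ch) < 5L) return(0L)
  best(1L, length(ch))
}

# two-gene fixture for the pipeline tests; writes FASTA/GFF3/backbone to a
# temp dir scoped to the calling test
pipeline_fixture <- function(seed = 101L) {
  genes <- data.frame(
    name = c("YAA001", "YBB002"),
    standard_name = c("AAA1", "BBB2"),
    chrom = c("chr1", "chr1"), start = c(1200L, 3500L),
    strand = c("+", "-"), orf_length = c(600L, 450L),
    stringsAsFactors = FALSE)
  pt <- data.frame(gene = c("YAA001", "YBB002"), offset = c(100L, 80L),
                   spacer = c("TATTGGCAATAAACATCTCG",
                              "ATCTCGATCGAGGTGCCTGA"),
                   pam = c("AGG", "TGG"), stringsAsFactors = FALSE)
  made <- make_genome(synthetic_genome_spec(c(6000L, 3000L), genes, pt,
                                            seed = seed))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_genome_fixture(made, dir)
  bbpath <- file.path(dir, "backbone.json")
  write_backbone_config(make_backbone_config(17L), bbpath)
  c(paths, list(backbone = bbpath, dir = dir))
}

fast_cfg <- function() score_config(fold_backend = "basepair-max-fallback")

# longest run of a character in a string
longest_run <- function(s, char = "T") {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  runs <- r$lengths[r$values == char]
  if (length(runs)) max(runs) else 0L
}
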