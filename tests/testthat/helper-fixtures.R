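# Shared fixtures and independent oracles, built in code at test time.

# A tiny cohort with known structure: `signal` genes separate the risk
# strata deterministically, `noise` genes are N(0, 1).
toy_cohort <- function(n_low = 6, n_high = 6, n_signal = 1, n_noise = 9,
                       effect = 5, seed = 42) {
  set.seed(seed)
  subtype <- c(rep("RA", n_low), rep("RAEB2", n_high))
  n <- n_low + n_high
  m <- matrix(rnorm(n * (n_signal + n_noise)), nrow = n_signal + n_noise)
  if (n_signal > 0) {
    m[seq_len(n_signal), subtype == "RAEB2"] <-
      m[seq_len(n_signal), subtype == "RAEB2"] + effect
  }
  rownames(m) <- c(sprintf("SIG%d", seq_len(n_signal)),
                   sprintf("NOISE%d", seq_len(n_noise)))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  expression_cohort(m, subtype)
}

# Hand-built two-exon gene with an all-C intron body (GT..AG ends) and a
# stop-free CDS; insertion of the intron's 5' fragment at a codon boundary
# keeps in-frame retentions stop-free.
flat_gene <- function(strand = "+") {
  exon1 <- paste0("ATG", strrep("C", 27))                 # 30 nt
  intron <- paste0("GT", strrep("C", 206), "AG")          # 210 nt
  exon2 <- paste0(strrep("C", 27), "TAA", "TAACTAGCTGAC") # 42 nt
  tx <- paste0(exon1, intron, exon2)
  G <- nchar(tx)
  if (strand == "+") {
    genome <- c(chrT = tx)
    exons <- tibble::tibble(start = c(1, 241), end = c(30, 279 + 3))
  } else {
    genome <- c(chrT = as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(tx))))
    exons <- tibble::tibble(start = G - c(30, 282) + 1, end = G - c(1, 241) + 1)
  }
  model <- gene_model("flatGene", "chrT", strand, exons, cds_tx = c(1, 60))
  list(model = model, genome = genome)
}

# Independent junction-classification oracle: label every genomic position
# of a gene as exon k / intron k by direct lookup, then classify a
# (donor, acceptor) pair from first principles in transcription orientation.
oracle_classify <- function(donor, acceptor, model) {
  span <- gene_span(model)
  if (donor < span["start"] || acceptor > span["end"]) return("other")
  ex <- model$exons
  intr <- introns(model)
  feature_of <- function(pos) {
    e <- which(pos >= ex$start & pos <= ex$end)
    if (length(e) == 1) return(c("exon", e))
    i <- which(pos >= pmin(intr$start, intr$end) &
                 pos <= pmax(intr$start, intr$end))
    if (length(i) == 1) return(c("intron", i))
    c("none", NA)
  }
  fd <- feature_of(donor); fa <- feature_of(acceptor)
  # transcription orientation: on '-', the genomic-right endpoint is upstream
  if (model$strand == "+") {
    up <- list(pos = donor, f = fd, boundary_ok = fd[1] == "exon" &&
                 donor == ex$end[as.integer(fd[2])])
    dn <- list(pos = acceptor, f = fa, boundary_ok = fa[1] == "exon" &&
                 acceptor == ex$start[as.integer(fa[2])])
  } else {
    up <- list(pos = acceptor, f = fa, boundary_ok = fa[1] == "exon" &&
                 acceptor == ex$end[as.integer(fa[2])])
    dn <- list(pos = donor, f = fd, boundary_ok = fd[1] == "exon" &&
                 donor == ex$start[as.integer(fd[2])])
  }
  # note: for '-' genes ex$end is the genomic high end = transcription start
  if (model$strand == "-") {
    up$boundary_ok <- up$f[1] == "exon" &&
      up$pos == ex$start[as.integer(up$f[2])]
    dn$boundary_ok <- dn$f[1] == "exon" &&
      dn$pos == ex$end[as.integer(dn$f[2])]
  }
  up_exon <- if (up$boundary_ok) as.integer(up$f[2]) else NA
  dn_exon <- if (dn$boundary_ok) as.integer(dn$f[2]) else NA
  if (!is.na(up_exon) && !is.na(dn_exon)) {
    if (dn_exon == up_exon + 1) return("annotated")
    if (dn_exon > up_exon + 1) return("exon_skip")
    return("other")
  }
  if (up$f[1] == "intron" && dn$f[1] == "intron" && up$f[2] == dn$f[2]) {
    return("intronic")
  }
  if (!is.na(up_exon) && dn$f[1] == "intron" &&
      as.integer(dn$f[2]) == up_exon) {
    return("partial_retention_3prime")
  }
  if (!is.na(dn_exon) && up$f[1] == "intron" &&
      as.integer(up$f[2]) == dn_exon - 1) {
    return("partial_retention_5prime")
  }
  "other"
}

# Exhaustive global-alignment oracle (match +1, mismatch 0, gap -1) for
# short sequences: enumerate every alignment, return the identity
# percentages achievable at the optimal score.
oracle_identities <- function(x, y) {
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  best <- new.env(); best$score <- -Inf; best$ids <- numeric()
  rec <- function(i, j, score, matches, cols) {
    if (i > length(xs) && j > length(ys)) {
      if (score > best$score) {
        best$score <- score; best$ids <- 100 * matches / cols
      } else if (score == best$score) {
        best$ids <- c(best$ids, 100 * matches / cols)
      }
      return(invisible())
    }
    if (i <= length(xs) && j <= length(ys)) {
      rec(i + 1, j + 1, score + (xs[i] == ys[j]),
          matches + (xs[i] == ys[j]), cols + 1)
    }
    if (i <= length(xs)) rec(i + 1, j, score - 1, matches, cols + 1)
    if (j <= length(ys)) rec(i, j + 1, score - 1, matches, cols + 1)
  }
  rec(1, 1, 0, 0, 0)
  unique(best$ids)
}

NON_STOP_CODONS_TEST <- local({
  b <- c("A", "C", "G", "T")
  setdiff(as.vector(outer(outer(b, b, paste0), b, paste0)),
          c("TAA", "TAG", "TGA"))
})

# plain row-subset used where a test needs the panel submatrix without
# going through the function under test
panel_submatrix_for_test <- function(coh, panel) {
  coh$expr <- coh$expr[intersect(panel$genes, rownames(coh$expr)), ,
                       drop = FALSE]
  coh
}
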