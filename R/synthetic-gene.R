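#' Specify a synthetic gene locus
#'
#' Parameters for [simulate_gene_model()], which generates a toy multi-exon
#' gene and its genomic sequence as a stand-in for a real locus when testing
#' the retention-detection pipeline.
#'
#' @param exon_lengths Integer vector of exon lengths (nt), >= 2 exons.
#' @param intron_lengths Integer vector of intron lengths, one fewer than
#'   exons; each >= 4 (room for the canonical GT..AG dinucleotides).
#' @param strand `"+"` or `"-"`.
#' @param cds_start_offset Nucleotides into the first exon at which the CDS
#'   starts (0 = first base).
#' @param gc_fraction GC content of the non-coding sequence, in \[0, 1\].
#' @return An object of class `toy_gene_spec`.
#' @export
toy_gene_spec <- function(exon_lengths, intron_lengths, strand = "+",
                          cds_start_offset = 0, gc_fraction = 0.5) {
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (length(exon_lengths) < 2L) abort("Need at least 2 exons.")
  if (length(intron_lengths) != length(exon_lengths) - 1L) {
    abort("Need exactly one intron fewer than exons.")
  }
  if (any(exon_lengths < 1L)) abort("All exon lengths must be >= 1.")
  if (any(intron_lengths < 4L)) {
    abort("Intron lengths must be >= 4 to carry GT..AG splice dinucleotides.")
  }
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'.")
  if (cds_start_offset < 0 || cds_start_offset >= exon_lengths[1]) {
    abort("`cds_start_offset` must fall inside the first exon.")
  }
  if (gc_fraction < 0 || gc_fraction > 1) abort("`gc_fraction` must be in [0, 1].")
  structure(list(exon_lengths = exon_lengths, intron_lengths = intron_lengths,
                 strand = strand, cds_start_offset = as.integer(cds_start_offset),
                 gc_fraction = gc_fraction),
            class = "toy_gene_spec")
}

#' Synthetic PIGN-like locus preset
#'
#' A [toy_gene_spec()] sized like the PIGN locus for end-to-end runs of the
#' retention pipeline without reference downloads: 18 exons, a 931-codon
#' CDS, and the clinically relevant intron between exons 14 and 15 landing
#' at codon 408, so partial retentions there truncate the product near 45%
#' of its length. The generated sequence is synthetic, not the real PIGN
#' reference.
#'
#' @return A [toy_gene_spec()].
#' @export
pign_like_gene_spec <- function() {
  toy_gene_spec(
    exon_lengths = c(rep(91L, 14), 400L, 400L, 400L, 372L),
    intron_lengths = rep(300L, 17),
    strand = "+",
    cds_start_offset = 50
  )
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

NON_STOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

#' Simulate a gene model and its genomic sequence
#'
#' Generates a random genomic sequence for the locus described by a
#' [toy_gene_spec()]: canonical GT..AG dinucleotides at every intron
#' boundary, and a CDS annotated from `cds_start_offset` (ATG) to a
#' generated in-frame stop codon placed in the last exon, with no internal
#' stop codon. Minus-strand genes report exon coordinates on the forward
#' sequence with the strand flag set.
#'
#' @param spec A [toy_gene_spec()].
#' @param seed Integer seed.
#' @param gene_id,chrom Identifiers for the generated locus.
#' @return List with elements `model` (a [gene_model()]) and `genome`
#'   (named character vector, forward-strand sequence).
#' @export
#' @examples
#' g <- simulate_gene_model(toy_gene_spec(c(30, 30), 60), seed = 1)
#' g$model
simulate_gene_model <- function(spec, seed, gene_id = "toyGene",
                                chrom = "chrT") {
  stopifnot(inherits(spec, "toy_gene_spec"))
  L <- sum(spec$exon_lengths)
  cds_start <- spec$cds_start_offset + 1L
  # largest in-frame CDS end whose stop codon sits fully in the last exon
  cds_end <- L - ((L - cds_start + 1L) %% 3L)
  last_exon_start_tx <- L - spec$exon_lengths[length(spec$exon_lengths)] + 1L
  n_codons <- (cds_end - cds_start + 1L) %/% 3L
  if (cds_end - 2L < last_exon_start_tx || n_codons < 3L) {
    abort("CDS cannot be placed: exons too short for start + body + in-frame stop in the last exon.")
  }

  with_seed(seed, {
    exonic <- strsplit(random_dna(L, spec$gc_fraction), "")[[1]]
    codons <- c("ATG",
                sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
                sample(c("TAA", "TAG", "TGA"), 1L))
    exonic[cds_start:cds_end] <- strsplit(paste(codons, collapse = ""), "")[[1]]
    exonic <- paste(exonic, collapse = "")

    exon_seqs <- character(length(spec$exon_lengths))
    off <- 0L
    for (i in seq_along(spec$exon_lengths)) {
      exon_seqs[i] <- substr(exonic, off + 1L, off + spec$exon_lengths[i])
      off <- off + spec$exon_lengths[i]
    }
    intron_seqs <- vapply(spec$intron_lengths, function(n) {
      paste0("GT", random_dna(n - 4L, spec$gc_fraction), "AG")
    }, character(1))

    tx_genomic <- paste0(
      paste0(exon_seqs[-length(exon_seqs)], intron_seqs, collapse = ""),
      exon_seqs[length(exon_seqs)]
    )
    G <- nchar(tx_genomic)

    # exon coordinates in transcription orientation
    starts_tx <- cumsum(c(1L, head(spec$exon_lengths, -1L) +
                            spec$intron_lengths))
    ends_tx <- starts_tx + spec$exon_lengths - 1L
    if (spec$strand == "+") {
      fwd <- tx_genomic
      ex <- tibble(start = starts_tx, end = ends_tx)
    } else {
      fwd <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tx_genomic)))
      ex <- tibble(start = G - ends_tx + 1L, end = G - starts_tx + 1L)
    }
    model <- gene_model(gene_id = gene_id, chrom = chrom,
                        strand = spec$strand, exons = ex,
                        cds_tx = c(cds_start, cds_end))
    list(model = model, genome = setNames(fwd, chrom))
  })
}

#' Describe a partial intron-retention event
#'
#' A partial retention keeps a fragment of an intron adjacent to one of its
#' splice sites: `"5prime"` retains the fragment abutting the upstream exon
#' (in transcription orientation), `"3prime"` the fragment abutting the
#' downstream exon.
#'
#' @param intron_index 1-based intron index in transcription order.
#' @param fragment_length Retained fragment length (nt), >= 1 and strictly
#'   less than the intron length.
#' @param retained_end `"5prime"` or `"3prime"`.
#' @param supporting_reads Junction read count attached to the event.
#' @return One-row tibble of class `retention_event`.
#' @export
retention_event <- function(intron_index, fragment_length,
                            retained_end = c("5prime", "3prime"),
                            supporting_reads = NA_integer_) {
  retained_end <- match.arg(retained_end)
  if (fragment_length < 1L) abort("`fragment_length` must be >= 1.")
  out <- tibble(intron_index = as.integer(intron_index),
                retained_end = retained_end,
                fragment_length = as.integer(fragment_length),
                supporting_reads = as.integer(supporting_reads))
  class(out) <- c("retention_event", class(out))
  out
}

# genomic (donor, acceptor) of the novel junction created by a retention
retention_junction_coords <- function(model, intron_index, retained_end,
                                      fragment_length) {
  intr <- introns(model)
  if (!intron_index %in% intr$index) {
    abort(paste0("Intron ", intron_index, " does not exist in the model."))
  }
  lo <- intr$start[intr$index == intron_index]
  hi <- intr$end[intr$index == intron_index]
  if (fragment_length >= hi - lo + 1L) {
    abort("`fragment_length` must be strictly less than the intron length.")
  }
  five_at_low <- (model$strand == "+") == (retained_end == "5prime")
  if (five_at_low) {
    c(donor = lo + fragment_length - 1L, acceptor = hi + 1L)
  } else {
    c(donor = lo - 1L, acceptor = hi - fragment_length + 1L)
  }
}

#' Simulate a splice-junction file for a gene model
#'
#' Emits the annotated exon-exon junctions (optionally) plus one novel
#' junction per retention event, whose intron-internal endpoint lies
#' `fragment_length` nt inside the retained intron.
#'
#' @param model A [gene_model()].
#' @param events A tibble of [retention_event()]s (or `NULL`).
#' @param reads_per_event Read count for each novel retention junction.
#' @param include_annotated Emit the annotated junctions as well?
#' @param annotated_reads Read count for annotated junctions.
#' @return A junction tibble (`chrom`, `donor`, `acceptor`, `strand`,
#'   `unique_reads`), coordinates in the internal convention: donor/acceptor
#'   are the flanking exonic bases, 1-based.
#' @seealso [write_junctions()], [call_retentions()]
#' @export
simulate_junctions <- function(model, events = NULL, reads_per_event = 10L,
                               include_annotated = TRUE,
                               annotated_reads = 50L) {
  stopifnot(inherits(model, "gene_model"))
  out <- list()
  if (include_annotated) {
    intr <- introns(model)
    out$annotated <- tibble(chrom = model$chrom,
                            donor = pmin(intr$start, intr$end) - 1L,
                            acceptor = pmax(intr$start, intr$end) + 1L,
                            strand = model$strand,
                            unique_reads = as.integer(annotated_reads))
  }
  if (!is.null(events) && nrow(events) > 0L) {
    ev <- lapply(seq_len(nrow(events)), function(i) {
      reads <- events$supporting_reads[i]
      if (is.na(reads)) reads <- reads_per_event
      da <- retention_junction_coords(model, events$intron_index[i],
                                      events$retained_end[i],
                                      events$fragment_length[i])
      tibble(chrom = model$chrom, donor = unname(da["donor"]),
             acceptor = unname(da["acceptor"]), strand = model$strand,
             unique_reads = as.integer(reads))
    })
    out$novel <- bind_rows(ev)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(chrom = character(), donor = integer(), acceptor = integer(),
                  strand = character(), unique_reads = integer())
  }
  arrange(res, .data$donor, .data$acceptor)
}
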