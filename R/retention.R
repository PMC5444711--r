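#' Classify a splice junction against a gene model
#'
#' Classes (defined in transcription orientation; minus-strand genes are
#' mirrored):
#' * `annotated` — donor/acceptor equal an annotated exon end / next exon
#'   start pair;
#' * `partial_retention_5prime` — the acceptor-side splice site is annotated
#'   and the other endpoint lies strictly inside the immediately preceding
#'   intron, so the transcript retains the intron's 5' fragment;
#' * `partial_retention_3prime` — symmetric, retaining the 3' fragment;
#' * `exon_skip` — both ends annotated but on non-adjacent exons;
#' * `intronic` — both ends inside one intron;
#' * `other` — anything else (junctions outside the gene span are classified
#'   `other` with a warning).
#'
#' @param junctions Junction tibble (see [read_junctions()]); must be on the
#'   model's chromosome and strand (unstranded records are accepted).
#' @param model A [gene_model()].
#' @return The junction tibble with columns `class`, `intron_index`,
#'   `retained_end`, `fragment_length` added.
#' @export
classify_junction <- function(junctions, model) {
  stopifnot(inherits(model, "gene_model"))
  j <- as_tibble(junctions)
  if (nrow(j) == 0L) {
    return(mutate(j, class = character(), intron_index = integer(),
                  retained_end = character(), fragment_length = integer()))
  }
  if (any(j$chrom != model$chrom)) {
    abort("Junction chromosome does not match the gene model.")
  }
  if (any(!j$strand %in% c(model$strand, "*", "0", NA))) {
    abort("Junction strand does not match the gene model.")
  }
  intr <- introns(model)
  # genomic order of introns (tx order for '+', reversed for '-')
  span <- gene_span(model)
  n_ex <- nrow(model$exons)

  classify_one <- function(donor, acceptor) {
    if (donor < span["start"] || acceptor > span["end"]) {
      warn("Junction outside the gene span; classified 'other'.")
      return(list(class = "other", intron_index = NA_integer_,
                  retained_end = NA_character_, fragment_length = NA_integer_))
    }
    d_intr <- intr$index[intr$start - 1L == donor]      # donor is annotated 5' ss of this intron (genomic)
    a_intr <- intr$index[intr$end + 1L == acceptor]     # acceptor is annotated 3' ss of this intron
    d_in <- intr$index[donor >= intr$start & donor <= intr$end]
    a_in <- intr$index[acceptor >= intr$start & acceptor <= intr$end]
    d_ok <- length(d_intr) == 1L
    a_ok <- length(a_intr) == 1L
    if (d_ok && a_ok) {
      if (d_intr == a_intr) {
        return(list(class = "annotated", intron_index = d_intr,
                    retained_end = NA_character_, fragment_length = NA_integer_))
      }
      return(list(class = "exon_skip", intron_index = NA_integer_,
                  retained_end = NA_character_, fragment_length = NA_integer_))
    }
    if (length(d_in) == 1L && length(a_in) == 1L && d_in == a_in) {
      return(list(class = "intronic", intron_index = d_in,
                  retained_end = NA_character_, fragment_length = NA_integer_))
    }
    if (a_ok && length(d_in) == 1L && d_in == a_intr) {
      # internal endpoint at the genomic-low end of the intron
      i <- d_in
      lo <- intr$start[intr$index == i]
      frag <- donor - lo + 1L
      end <- if (model$strand == "+") "5prime" else "3prime"
      return(list(class = paste0("partial_retention_", end),
                  intron_index = i, retained_end = end,
                  fragment_length = frag))
    }
    if (d_ok && length(a_in) == 1L && a_in == d_intr) {
      i <- a_in
      hi <- intr$end[intr$index == i]
      frag <- hi - acceptor + 1L
      end <- if (model$strand == "+") "3prime" else "5prime"
      return(list(class = paste0("partial_retention_", end),
                  intron_index = i, retained_end = end,
                  fragment_length = frag))
    }
    list(class = "other", intron_index = NA_integer_,
         retained_end = NA_character_, fragment_length = NA_integer_)
  }

  res <- purrr::map2(j$donor, j$acceptor, classify_one)
  j$class <- purrr::map_chr(res, "class")
  j$intron_index <- purrr::map_int(res, "intron_index")
  j$retained_end <- purrr::map_chr(res, "retained_end")
  j$fragment_length <- purrr::map_int(res, "fragment_length")
  j
}

#' Call partial intron-retention events from junction evidence
#'
#' Every junction classified as a partial retention with at least
#' `min_reads` unique reads and a fragment length within
#' `[min_len, max_len]` yields one event. Duplicate junctions (same
#' coordinates) are merged with summed read counts; events are sorted by
#' intron index, then fragment length.
#'
#' @inheritParams classify_junction
#' @param min_reads Minimum unique read support (default 2).
#' @param min_len,max_len Fragment length bounds (defaults 1 and intron
#'   length - 1).
#' @return Tibble of retention events (`intron_index`, `retained_end`,
#'   `fragment_length`, `fragment_start`, `fragment_end`,
#'   `supporting_reads`), genomic fragment coordinates 1-based inclusive.
#' @export
call_retentions <- function(junctions, model, min_reads = 2L, min_len = 1L,
                            max_len = Inf) {
  cl <- classify_junction(junctions, model)
  cl <- filter(cl, startsWith(.data$class, "partial_retention"))
  if (nrow(cl) > 0L) {
    cl <- cl %>%
      group_by(.data$chrom, .data$donor, .data$acceptor, .data$strand,
               .data$class, .data$intron_index, .data$retained_end,
               .data$fragment_length) %>%
      summarise(unique_reads = sum(.data$unique_reads), .groups = "drop")
  }
  cl <- filter(cl, .data$unique_reads >= min_reads,
               .data$fragment_length >= min_len,
               .data$fragment_length <= max_len)
  if (nrow(cl) == 0L) {
    return(tibble(intron_index = integer(), retained_end = character(),
                  fragment_length = integer(), fragment_start = integer(),
                  fragment_end = integer(), supporting_reads = integer()))
  }
  intr <- introns(model)
  cl %>%
    left_join(intr, by = c(intron_index = "index")) %>%
    mutate(
      fragment_start = dplyr::if_else(
        (model$strand == "+") == (.data$retained_end == "5prime"),
        .data$start, .data$end - .data$fragment_length + 1L),
      fragment_end = .data$fragment_start + .data$fragment_length - 1L
    ) %>%
    select("intron_index", "retained_end", "fragment_length",
           "fragment_start", "fragment_end",
           supporting_reads = "unique_reads") %>%
    arrange(.data$intron_index, .data$fragment_length)
}

#' Reconstruct the aberrant transcript of a retention event
#'
#' Splices the gene's exons with the retained intronic fragment inserted at
#' the corresponding exon/intron boundary. Minus-strand genes are
#' reverse-complemented; the coordinate map records the genomic origin of
#' every transcript base.
#'
#' @param model A [gene_model()].
#' @param genome Genome sequence covering the gene span.
#' @param event One event: a [retention_event()] or one row of
#'   [call_retentions()] output.
#' @return List: `seq` (character), `map` (tibble `tx_pos`, `genomic_pos`),
#'   `cds_offset` (first CDS base in aberrant-transcript coordinates),
#'   `last_junction_pos` (last exon-exon junction, transcript coordinates),
#'   `inserted_nt`.
#' @export
aberrant_transcript <- function(model, genome, event) {
  stopifnot(inherits(model, "gene_model"))
  event <- as_tibble(event)
  if (nrow(event) != 1L) abort("`event` must be a single retention event.")
  i <- event$intron_index
  n_frag <- event$fragment_length
  end5 <- event$retained_end == "5prime"
  intr <- introns(model)
  if (!i %in% intr$index) abort("Event intron does not exist in the model.")
  if (n_frag < 1L) abort("`fragment_length` must be >= 1.")
  if (n_frag >= intr$length[intr$index == i]) {
    abort("Retained fragment must be shorter than the intron.")
  }

  # merge the retained fragment into the exon it abuts (transcription order)
  blocks <- model$exons
  plus <- model$strand == "+"
  if (plus && end5) blocks$end[i] <- blocks$end[i] + n_frag
  if (plus && !end5) blocks$start[i + 1L] <- blocks$start[i + 1L] - n_frag
  if (!plus && end5) blocks$start[i] <- blocks$start[i] - n_frag
  if (!plus && !end5) blocks$end[i + 1L] <- blocks$end[i + 1L] + n_frag

  dna <- chrom_seq(genome, model$chrom)
  seq <- splice_blocks(blocks, model$strand, dna)
  map <- tx_map_blocks(blocks, model$strand)
  lens <- blocks$end - blocks$start + 1L
  last_junction_pos <- sum(lens) - lens[length(lens)]
  cds_start_genomic <- tx_map(model)$genomic_pos[model$cds_tx[1]]
  cds_offset <- map$tx_pos[map$genomic_pos == cds_start_genomic]
  list(seq = seq, map = map, cds_offset = cds_offset,
       last_junction_pos = last_junction_pos, inserted_nt = as.integer(n_frag))
}

#' Predict the coding consequence of an insertion-bearing transcript
#'
#' Translates the transcript from `cds_offset` to the first in-frame stop
#' codon and reports: the frameshift flag (`inserted_nt` not a multiple of
#' 3), the first premature termination codon (PTC) if the stop falls at a
#' codon index earlier than the annotated stop, the truncated protein length
#' and mass, and NMD sensitivity under the 50-nt rule (a PTC ending more
#' than 50 nt upstream of the last exon-exon junction is predicted to
#' trigger nonsense-mediated decay; the flag is advisory).
#'
#' @param transcript Transcript sequence (character).
#' @param cds_offset 1-based transcript position of the first CDS base.
#' @param last_junction_pos Transcript position of the last exon-exon
#'   junction (last base before the final exon).
#' @param inserted_nt Number of inserted nucleotides.
#' @param normal_protein Normal (annotated) protein sequence, used for the
#'   annotated stop-codon index and the full mass.
#' @return One-row tibble: `frameshift`, `inserted_nt`, `ptc_codon_index`,
#'   `truncated_protein_length`, `truncated_mass_kda`, `full_mass_kda`,
#'   `nmd_sensitive`, `nonstop`.
#' @export
predict_consequence <- function(transcript, cds_offset, last_junction_pos,
                                inserted_nt, normal_protein) {
  if (cds_offset < 1L || cds_offset > nchar(transcript)) {
    abort("`cds_offset` must fall within the transcript.")
  }
  frameshift <- (inserted_nt %% 3L) != 0L
  tail_seq <- substr(transcript, cds_offset, nchar(transcript))
  n_codons <- nchar(tail_seq) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(tail_seq, 1L, n_codons * 3L)),
    no.init.codon = TRUE))
  stop_idx <- regexpr("*", aa, fixed = TRUE)[1]
  nonstop <- stop_idx < 0L

  normal_len <- nchar(normal_protein)
  annotated_stop_codon <- normal_len + 1L
  expected_stop <- annotated_stop_codon + inserted_nt %/% 3L

  if (nonstop) {
    warn("No stop codon before the transcript end ('non-stop' prediction).")
    trunc_len <- n_codons
    ptc_codon_index <- NA_integer_
    nmd <- FALSE
  } else {
    trunc_len <- stop_idx - 1L
    is_ptc <- stop_idx < expected_stop
    ptc_codon_index <- if (is_ptc) as.integer(stop_idx) else NA_integer_
    if (is_ptc) {
      ptc_end_nt <- cds_offset + 3L * stop_idx - 1L
      nmd <- (last_junction_pos - ptc_end_nt) > 50L
    } else {
      nmd <- FALSE
    }
  }
  truncated_seq <- substr(aa, 1L, trunc_len)
  tibble(
    frameshift = frameshift,
    inserted_nt = as.integer(inserted_nt),
    ptc_codon_index = ptc_codon_index,
    truncated_protein_length = as.integer(trunc_len),
    truncated_mass_kda = if (trunc_len > 0L) protein_mw(truncated_seq) else 0,
    full_mass_kda = protein_mw(normal_protein),
    nmd_sensitive = nmd,
    nonstop = nonstop
  )
}

#' Predict the consequence of a retention event directly from a gene model
#'
#' Convenience wrapper: reconstructs the aberrant transcript with
#' [aberrant_transcript()] and feeds [predict_consequence()] with the
#' model's annotated protein.
#'
#' @inheritParams aberrant_transcript
#' @return As [predict_consequence()], with `intron_index`, `retained_end`
#'   and `fragment_length` prepended.
#' @export
predict_retention_consequence <- function(model, genome, event) {
  ab <- aberrant_transcript(model, genome, event)
  res <- predict_consequence(ab$seq, ab$cds_offset, ab$last_junction_pos,
                             ab$inserted_nt,
                             normal_protein(model, genome))
  event <- as_tibble(event)
  dplyr::bind_cols(event[, c("intron_index", "retained_end", "fragment_length")],
                   res)
}

# average (not monoisotopic) residue masses in Da; the kDa values reported
# by gels are average-mass estimates
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0513, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da), in kDa.
#'
#' @param aa_sequence Amino-acid sequence over the 20 standard residues.
#' @return Mass in kDa.
#' @export
#' @examples
#' protein_mw("G")  # 75.0666 Da = 0.0750666 kDa
protein_mw <- function(aa_sequence) {
  if (!is.character(aa_sequence) || length(aa_sequence) != 1L ||
      nchar(aa_sequence) == 0L) {
    abort("`aa_sequence` must be a non-empty amino-acid string.")
  }
  res <- strsplit(toupper(aa_sequence), "")[[1]]
  unknown <- setdiff(unique(res), names(AA_AVG_MASS))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown residue(s): ", paste(unknown, collapse = ", ")))
  }
  (sum(AA_AVG_MASS[res]) + WATER_MASS) / 1000
}

#' Write retention events as BED6
#'
#' Fragment intervals in 0-based half-open BED coordinates; name =
#' `intron<i>/<length>nt`, score = supporting reads.
#'
#' @param events Output of [call_retentions()].
#' @param model The [gene_model()] the events were called against.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_retention_bed <- function(events, model, path) {
  lines <- sprintf("%s\t%d\t%d\tintron%d/%dnt\t%d\t%s",
                   model$chrom, events$fragment_start - 1L,
                   events$fragment_end, events$intron_index,
                   events$fragment_length, events$supporting_reads,
                   model$strand)
  readr::write_lines(lines, path)
  invisible(path)
}
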