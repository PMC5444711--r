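#' Construct a gene model
#'
#' Exon/CDS structure of a single transcript, with genomic coordinates
#' 1-based inclusive on the forward strand of `chrom`. Exons are stored in
#' transcription order (for minus-strand genes, decreasing genomic
#' coordinates); introns are derived as the gaps between consecutive exons.
#' The CDS is recorded in spliced-transcript coordinates (`cds_tx`, covering
#' the start codon through the stop codon).
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble/data frame with columns `start`, `end` (1-based
#'   inclusive), one row per exon in transcription order.
#' @param cds_tx Length-2 integer vector: first and last CDS base in spliced
#'   transcript coordinates (1-based, stop codon included).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_tx,
                       transcript_id = paste0(gene_id, ".t1")) {
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'.")
  exons <- as_tibble(exons)[, c("start", "end")]
  if (nrow(exons) < 2L) abort("A gene model needs at least 2 exons.")
  if (any(exons$end < exons$start)) abort("Exon end < start.")
  g_start <- if (strand == "+") exons$start else rev(exons$start)
  g_end <- if (strand == "+") exons$end else rev(exons$end)
  # in genomic order exons must be strictly separated by >= 1 intronic base
  if (any(diff(g_start) <= 0) || any(g_start[-1] - g_end[-length(g_end)] < 2)) {
    abort("Exons must be non-overlapping, in transcription order, separated by introns.")
  }
  tx_len <- sum(exons$end - exons$start + 1)
  cds_tx <- as.integer(cds_tx)
  if (length(cds_tx) != 2L || cds_tx[1] < 1L || cds_tx[2] > tx_len ||
      cds_tx[2] <= cds_tx[1]) {
    abort("`cds_tx` must lie within the spliced transcript.")
  }
  if ((cds_tx[2] - cds_tx[1] + 1) %% 3 != 0) {
    abort("CDS length (including the stop codon) must be a multiple of 3.")
  }
  exons$index <- seq_len(nrow(exons))
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand,
                 exons = exons[, c("index", "start", "end")],
                 cds_tx = cds_tx),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " (", x$strand, ") ", x$chrom, ": ",
      nrow(x$exons), " exons, transcript ", tx_length(x), " nt, CDS ",
      x$cds_tx[1], "-", x$cds_tx[2], "\n", sep = "")
  invisible(x)
}

#' Derived intron coordinates of a gene model
#'
#' @param model A [gene_model()].
#' @return Tibble (`index`, `start`, `end`, `length`) in transcription order;
#'   `start`/`end` are genomic 1-based inclusive (first/last intronic base).
#' @export
introns <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  n <- nrow(ex)
  out <- if (model$strand == "+") {
    tibble(index = seq_len(n - 1L),
           start = ex$end[-n] + 1L, end = ex$start[-1] - 1L)
  } else {
    tibble(index = seq_len(n - 1L),
           start = ex$end[-1] + 1L, end = ex$start[-n] - 1L)
  }
  mutate(out, length = .data$end - .data$start + 1L)
}

#' @rdname introns
#' @export
tx_length <- function(model) sum(model$exons$end - model$exons$start + 1L)

#' @rdname introns
#' @export
gene_span <- function(model) {
  c(start = min(model$exons$start), end = max(model$exons$end))
}

# genomic position of every transcript base, in transcription order
tx_map_blocks <- function(blocks, strand) {
  pos <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    if (strand == "+") blocks$start[i]:blocks$end[i]
    else blocks$end[i]:blocks$start[i]
  }))
  tibble(tx_pos = seq_along(pos), genomic_pos = as.integer(pos))
}

#' Transcript-to-genome coordinate map
#'
#' @param model A [gene_model()].
#' @return Tibble (`tx_pos`, `genomic_pos`) for the normal spliced
#'   transcript, in transcription order.
#' @export
tx_map <- function(model) tx_map_blocks(model$exons, model$strand)

# Resolve the chromosome sequence from a genome given as DNAStringSet,
# DNAString or (named) character.
chrom_seq <- function(genome, chrom) {
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) abort(paste0("Genome lacks sequence '", chrom, "'."))
    return(genome[[chrom]])
  }
  if (inherits(genome, "DNAString")) return(genome)
  if (is.character(genome)) {
    s <- if (!is.null(names(genome)) && chrom %in% names(genome)) {
      genome[[chrom]]
    } else if (length(genome) == 1L) {
      genome[[1]]
    } else {
      abort(paste0("Genome lacks sequence '", chrom, "'."))
    }
    return(Biostrings::DNAString(s))
  }
  abort("`genome` must be a DNAStringSet, DNAString or character sequence.")
}

# Extract and splice a set of genomic blocks (tx order) into one sequence.
splice_blocks <- function(blocks, strand, chrom_dna) {
  if (max(blocks$end) > length(chrom_dna)) {
    abort("Genome sequence does not cover the gene span.")
  }
  parts <- lapply(seq_len(nrow(blocks)), function(i) {
    s <- Biostrings::subseq(chrom_dna, blocks$start[i], blocks$end[i])
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    s
  })
  as.character(do.call(Biostrings::xscat, parts))
}

#' Normal spliced transcript of a gene model
#'
#' @param model A [gene_model()].
#' @param genome Genome sequence covering the gene span (DNAStringSet,
#'   DNAString or character).
#' @return List: `seq` (character), `map` (tibble `tx_pos`, `genomic_pos`),
#'   `cds_offset` (first CDS base, transcript coords),
#'   `last_junction_pos` (transcript position of the last base before the
#'   final exon, used by the NMD rule).
#' @export
spliced_transcript <- function(model, genome) {
  dna <- chrom_seq(genome, model$chrom)
  lens <- model$exons$end - model$exons$start + 1L
  list(seq = splice_blocks(model$exons, model$strand, dna),
       map = tx_map(model),
       cds_offset = model$cds_tx[1],
       last_junction_pos = sum(lens) - lens[length(lens)])
}

#' Translate the annotated CDS of a gene model
#'
#' @inheritParams spliced_transcript
#' @return Character amino-acid sequence (stop codon not included).
#' @export
normal_protein <- function(model, genome) {
  txp <- spliced_transcript(model, genome)
  cds <- substr(txp$seq, model$cds_tx[1], model$cds_tx[2])
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  if (substr(aa, nchar(aa), nchar(aa)) != "*") {
    abort("Annotated CDS does not end at a stop codon.")
  }
  body <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", body, fixed = TRUE)) {
    abort("Annotated CDS contains an internal stop codon.")
  }
  body
}

#' Write / read a gene model as GFF3
#'
#' Writes gene, mRNA, exon and CDS features (1-based inclusive, CDS phase
#' computed per piece). `read_gene_model_gff3()` reconstructs the model from
#' such a file (one transcript).
#'
#' @param model A [gene_model()].
#' @param path File path.
#' @return `write_gene_model_gff3()`: `path`, invisibly.
#' @export
write_gene_model_gff3 <- function(model, path) {
  span <- gene_span(model)
  ex <- model$exons
  # map CDS transcript range onto genomic pieces (runs within exons)
  m <- tx_map(model)
  cds_pos <- m$genomic_pos[model$cds_tx[1]:model$cds_tx[2]]
  brk <- c(0L, which(abs(diff(cds_pos)) != 1L), length(cds_pos))
  pieces <- lapply(seq_len(length(brk) - 1L), function(i) {
    p <- cds_pos[(brk[i] + 1L):brk[i + 1L]]
    tibble(start = min(p), end = max(p), tx_order = i, len = length(p))
  }) %>% bind_rows()
  pieces$phase <- (3L - (cumsum(c(0L, pieces$len))[seq_len(nrow(pieces))] %% 3L)) %% 3L

  line <- function(type, start, end, phase = ".", attrs) {
    paste(model$chrom, "gpinstab", type, start, end, ".", model$strand,
          phase, attrs, sep = "\t")
  }
  gid <- model$gene_id
  tid <- model$transcript_id
  lines <- c(
    "##gff-version 3",
    line("gene", span["start"], span["end"], ".", paste0("ID=", gid)),
    line("mRNA", span["start"], span["end"], ".",
         paste0("ID=", tid, ";Parent=", gid)),
    vapply(seq_len(nrow(ex)), function(i) {
      line("exon", ex$start[i], ex$end[i], ".",
           paste0("ID=", tid, ".exon", i, ";Parent=", tid))
    }, character(1)),
    vapply(seq_len(nrow(pieces)), function(i) {
      line("CDS", pieces$start[i], pieces$end[i], pieces$phase[i],
           paste0("ID=", tid, ".cds;Parent=", tid))
    }, character(1))
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_gene_model_gff3
#' @export
read_gene_model_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  gene <- gr[typ == "gene"]
  mrna <- gr[typ == "mRNA"]
  if (length(mrna) != 1L) abort("Expected exactly one mRNA feature.")
  strand <- as.character(BiocGenerics::strand(mrna))
  exon <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  if (length(exon) < 2L || length(cds) < 1L) {
    abort("GFF3 must contain >= 2 exon features and a CDS.")
  }
  ex <- tibble(start = BiocGenerics::start(exon), end = BiocGenerics::end(exon))
  ex <- if (strand == "+") arrange(ex, .data$start) else arrange(ex, -.data$start)
  # CDS genomic extent -> transcript coordinates
  blocks <- mutate(ex, index = dplyr::row_number())
  m <- tx_map_blocks(blocks, strand)
  cds_g <- sort(c(BiocGenerics::start(cds), BiocGenerics::end(cds)))
  cds_gmin <- min(cds_g); cds_gmax <- max(cds_g)
  cds_tx_pos <- m$tx_pos[m$genomic_pos >= cds_gmin & m$genomic_pos <= cds_gmax]
  gid <- if (length(gene) == 1L && !is.null(gene$ID)) gene$ID else "gene1"
  tid <- if (!is.null(mrna$ID)) mrna$ID else paste0(gid, ".t1")
  gene_model(gene_id = gid, chrom = as.character(GenomicRanges::seqnames(mrna)),
             strand = strand, exons = ex,
             cds_tx = c(min(cds_tx_pos), max(cds_tx_pos)),
             transcript_id = tid)
}

#' Write a genome sequence as FASTA
#'
#' @param genome Named character vector or DNAStringSet.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)
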