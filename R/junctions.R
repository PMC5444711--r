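#' Read splice junctions
#'
#' Parses a junction file into the internal convention: `donor` = last
#' exonic base of the upstream (genomic-left) side, `acceptor` = first
#' exonic base of the downstream side, both 1-based.
#'
#' Dialects:
#' * `sj_tab` — the STAR `SJ.out.tab` layout (tab-separated, no header):
#'   chrom, first and last intronic base (1-based), strand code (0/1/2),
#'   intron motif, annotated flag, unique reads, multi-mapping reads,
#'   overhang. An intron `i..j` maps to donor `i - 1`, acceptor `j + 1`.
#' * `bed12` —12-column BED; each pair of adjacent blocks encodes one
#'   junction (0-based half-open block coordinates converted internally).
#'
#' @param path File path.
#' @param dialect `"sj_tab"` or `"bed12"`.
#' @return Junction tibble (`chrom`, `donor`, `acceptor`, `strand`,
#'   `unique_reads`, `dialect`).
#' @export
read_junctions <- function(path, dialect = c("sj_tab", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "sj_tab") {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      return(empty_junctions(dialect))
    }
    recs <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 7L || anyNA(suppressWarnings(as.integer(f[2:3])))) {
        abort(paste0("Malformed SJ.out.tab line ", i, ": '", lines[i], "'"))
      }
      istart <- as.integer(f[2]); iend <- as.integer(f[3])
      if (iend < istart) abort(paste0("Malformed SJ.out.tab line ", i,
                                      ": intron end < start"))
      tibble(chrom = f[1], donor = istart - 1L, acceptor = iend + 1L,
             strand = unname(c("0" = "*", "1" = "+", "2" = "-")[f[4]]),
             unique_reads = as.integer(f[7]))
    })
    out <- bind_rows(recs)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) return(empty_junctions(dialect))
    if (is.null(gr$blocks)) abort("BED12 input lacks block definitions.")
    recs <- lapply(seq_along(gr), function(i) {
      bl <- gr$blocks[[i]]
      if (length(bl) < 2L) {
        abort(paste0("BED12 record ", i, " has fewer than 2 blocks."))
      }
      off <- BiocGenerics::start(gr[i]) - 1L  # absolute 1-based offset
      abs_start <- off + BiocGenerics::start(bl)
      abs_end <- off + BiocGenerics::end(bl)
      k <- seq_len(length(bl) - 1L)
      tibble(chrom = as.character(GenomicRanges::seqnames(gr[i])),
             donor = abs_end[k], acceptor = abs_start[k + 1L],
             strand = as.character(BiocGenerics::strand(gr[i])),
             unique_reads = as.integer(gr$score[i]))
    })
    out <- bind_rows(recs)
  }
  if (any(out$donor >= out$acceptor)) abort("Junction donor must be < acceptor.")
  mutate(out, dialect = dialect)
}

empty_junctions <- function(dialect) {
  tibble(chrom = character(), donor = integer(), acceptor = integer(),
         strand = character(), unique_reads = integer(), dialect = dialect)
}

#' Write splice junctions
#'
#' Inverse of [read_junctions()] for both dialects. For `bed12`, each
#' junction is written as a 2-block record with `anchor`-nt flanks (clipped
#' at position 1).
#'
#' @param junctions Junction tibble (`chrom`, `donor`, `acceptor`, `strand`,
#'   `unique_reads`).
#' @param path Output path.
#' @param dialect `"sj_tab"` or `"bed12"`.
#' @param anchor Flank length for BED12 blocks.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path, dialect = c("sj_tab", "bed12"),
                            anchor = 20L) {
  dialect <- match.arg(dialect)
  j <- junctions
  if (dialect == "sj_tab") {
    strand_code <- c("+" = 1L, "-" = 2L)[j$strand]
    strand_code[is.na(strand_code)] <- 0L
    lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                     j$chrom, j$donor + 1L, j$acceptor - 1L, strand_code,
                     0L, 0L, j$unique_reads, 0L, anchor)
    readr::write_lines(lines, path)
  } else {
    if (nrow(j) == 0L) {
      readr::write_lines(character(), path)
      return(invisible(path))
    }
    left <- pmin(anchor, j$donor)
    start <- j$donor - left + 1L
    end <- j$acceptor + anchor - 1L
    gr <- GenomicRanges::GRanges(
      seqnames = j$chrom,
      ranges = IRanges::IRanges(start = start, end = end),
      strand = ifelse(j$strand %in% c("+", "-"), j$strand, "*")
    )
    gr$name <- sprintf("junc%d", seq_len(nrow(j)))
    gr$score <- j$unique_reads
    gr$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(j)), function(i) {
      IRanges::IRanges(start = c(1L, j$acceptor[i] - start[i] + 1L),
                       width = c(left[i], anchor))
    }))
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}
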