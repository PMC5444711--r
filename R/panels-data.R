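#' Construct a gene panel
#'
#' A gene panel is a named, ordered list of gene symbols used for per-sample
#' panel scoring ([panel_pc1()]), heat maps and importance ranking.
#'
#' @param name Panel name.
#' @param genes Character vector of gene symbols; must be non-empty with no
#'   duplicates.
#' @return An object of class `gene_panel`.
#' @export
#' @examples
#' gene_panel("toy", c("A", "B", "C"))
gene_panel <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) abort("A gene panel must contain at least one gene.")
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicate gene symbols in panel '", name, "': ",
                 paste(unique(dup), collapse = ", ")))
  }
  structure(list(name = as.character(name), genes = genes),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_panel <- function(x) length(x$genes)

#' Read a gene panel from a file
#'
#' Panel files carry one gene symbol per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path Path to the panel file.
#' @param name Panel name; defaults to the file name without extension.
#' @return A [gene_panel()].
#' @export
read_panel <- function(path, name = NULL) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_panel(name, lines)
}

#' Packaged chromosomal-instability (CIN70) signature panel
#'
#' The 70-gene chromosomal-instability expression signature used as a
#' genomic-instability readout in expression cohorts. The packaged list is a
#' reconstruction of the published signature with current HGNC symbols where
#' probe-era aliases have been renamed; membership is configurable by
#' supplying your own file to [read_panel()].
#'
#' @return A [gene_panel()] with exactly 70 symbols.
#' @export
cin70_panel <- function() {
  read_panel(system.file("extdata", "cin70_genes.txt", package = "gpinstab"),
             name = "CIN70")
}

#' Packaged GPI-anchor biosynthesis panel
#'
#' Genes of the glycosylphosphatidylinositol (GPI) anchor biosynthesis and
#' remodeling pathway: the PIG family plus GPAA1 and the PGAP remodeling
#' genes. The pathway membership used in the original cohort analysis was
#' never enumerated, so this list is a reconstruction; swap in an alternative
#' with [read_panel()].
#'
#' @return A [gene_panel()] (25 symbols, including PIGN).
#' @export
gpi_panel <- function() {
  read_panel(system.file("extdata", "gpi_panel_genes.txt", package = "gpinstab"),
             name = "GPI")
}
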