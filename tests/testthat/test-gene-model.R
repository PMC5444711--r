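test_that("simulated gene geometry matches a cumulative-sum oracle", {
  g <- simulate_gene_model(toy_gene_spec(c(30, 30), 60), seed = 1)
  expect_equal(nchar(g$genome[[1]]), 120)
  expect_equal(introns(g$model)$start, 31L)
  expect_equal(introns(g$model)$end, 90L)

  spec <- toy_gene_spec(c(25, 40, 33), c(50, 70), cds_start_offset = 4)
  g3 <- simulate_gene_model(spec, seed = 2)
  # oracle: exon starts/ends from cumulative sums of interleaved lengths
  starts <- cumsum(c(1, head(spec$exon_lengths, -1) + spec$intron_lengths))
  ends <- starts + spec$exon_lengths - 1
  expect_equal(g3$model$exons$start, as.integer(starts))
  expect_equal(g3$model$exons$end, as.integer(ends))
  expect_equal(nchar(g3$genome[[1]]), sum(spec$exon_lengths, spec$intron_lengths))
})

test_that("generated CDS translates without internal stops and ends in stop", {
  for (s in 1:5) {
    g <- simulate_gene_model(toy_gene_spec(c(40, 80, 60), c(44, 91),
                                           strand = sample(c("+", "-"), 1),
                                           gc_fraction = runif(1, 0.3, 0.7)),
                             seed = s)
    aa <- normal_protein(g$model, g$genome)   # errors on internal stop
    expect_gt(nchar(aa), 0)
    expect_equal(substr(aa, 1, 1), "M")
  }
})

test_that("splice-site dinucleotides are canonical GT..AG", {
  g <- simulate_gene_model(toy_gene_spec(c(30, 30, 30), c(60, 60)), seed = 3)
  dna <- g$genome[[1]]
  for (i in seq_len(nrow(introns(g$model)))) {
    intr <- introns(g$model)[i, ]
    expect_equal(substr(dna, intr$start, intr$start + 1), "GT")
    expect_equal(substr(dna, intr$end - 1, intr$end), "AG")
  }
  # minus strand: dinucleotides are canonical in transcription orientation
  gm <- simulate_gene_model(toy_gene_spec(c(30, 30), 60, strand = "-"), seed = 3)
  intr <- introns(gm$model)[1, ]
  seg <- Biostrings::reverseComplement(Biostrings::DNAString(
    substr(gm$genome[[1]], intr$start, intr$end)))
  expect_equal(as.character(Biostrings::subseq(seg, 1, 2)), "GT")
  expect_equal(as.character(Biostrings::subseq(seg, length(seg) - 1)), "AG")
})

test_that("impossible CDS placement and invalid specs error", {
  expect_error(simulate_gene_model(toy_gene_spec(c(4, 3), 60), seed = 1),
               "CDS cannot be placed")
  expect_error(toy_gene_spec(c(30), integer()), "at least 2 exons")
  expect_error(toy_gene_spec(c(30, 30), c(60, 60)), "one intron fewer")
  expect_error(toy_gene_spec(c(30, 30), 3), ">= 4")
  expect_error(toy_gene_spec(c(30, 30), 60, cds_start_offset = 30),
               "inside the first exon")
})

test_that("gene models survive a GFF3 + FASTA round trip", {
  for (strand in c("+", "-")) {
    g <- simulate_gene_model(toy_gene_spec(c(30, 45, 60), c(50, 80),
                                           strand = strand,
                                           cds_start_offset = 6), seed = 4)
    gff <- withr::local_tempfile(fileext = ".gff3")
    fa <- withr::local_tempfile(fileext = ".fa")
    write_gene_model_gff3(g$model, gff)
    write_genome_fasta(g$genome, fa)
    m2 <- read_gene_model_gff3(gff)
    genome2 <- read_genome_fasta(fa)
    expect_equal(m2$exons, g$model$exons)
    expect_equal(m2$cds_tx, g$model$cds_tx)
    expect_equal(m2$strand, g$model$strand)
    expect_equal(normal_protein(m2, genome2), normal_protein(g$model, g$genome))
  }
})

test_that("junction files round-trip through both dialects", {
  g <- simulate_gene_model(toy_gene_spec(c(30, 30, 30), c(60, 80)), seed = 5)
  ev <- dplyr::bind_rows(retention_event(1, 11, "5prime"),
                         retention_event(2, 38, "3prime"))
  j <- simulate_junctions(g$model, ev, reads_per_event = 7)
  for (d in c("sj_tab", "bed12")) {
    f <- withr::local_tempfile()
    write_junctions(j, f, d)
    j2 <- read_junctions(f, d)
    expect_equal(j2$donor, j$donor)
    expect_equal(j2$acceptor, j$acceptor)
    expect_equal(j2$unique_reads, j$unique_reads)
    expect_equal(j2$chrom, j$chrom)
  }
})

test_that("dialect conventions map intron coordinates to exonic endpoints", {
  sj <- withr::local_tempfile()
  writeLines("chr1\t101\t160\t1\t0\t0\t5\t0\t20", sj)
  j <- read_junctions(sj, "sj_tab")
  expect_equal(j$donor, 100L)
  expect_equal(j$acceptor, 161L)
  expect_equal(j$strand, "+")
  expect_equal(j$unique_reads, 5L)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t200\tj1\t5\t+\t0\t200\t0\t2\t100,40,\t0,160,", bed)
  jb <- read_junctions(bed, "bed12")
  expect_equal(jb$donor, 100L)
  expect_equal(jb$acceptor, 161L)

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_equal(nrow(read_junctions(empty, "sj_tab")), 0)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t101\t160\t1\t0\t0\t5\t0\t20", "chr1\toops"), bad)
  expect_error(read_junctions(bad, "sj_tab"), "line 2")
})

test_that("generated junctions place retention endpoints inside the intron", {
  g <- simulate_gene_model(toy_gene_spec(c(30, 30), 60), seed = 6)
  # no events + annotated: one junction per intron
  j0 <- simulate_junctions(g$model, NULL, include_annotated = TRUE)
  expect_equal(nrow(j0), 1)
  expect_equal(j0$donor, 30L)
  expect_equal(j0$acceptor, 91L)
  # a 38-nt 5' retention: donor = intron start + 37
  j <- simulate_junctions(g$model, retention_event(1, 38, "5prime"),
                          include_annotated = FALSE)
  expect_equal(j$donor, 31L + 37L)
  expect_equal(j$acceptor, 91L)
  # fragment length >= intron length is rejected
  expect_error(simulate_junctions(g$model, retention_event(1, 60, "5prime")),
               "strictly less")
})
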