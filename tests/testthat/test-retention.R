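test_that("classification agrees with an enumeration oracle on a 4-exon gene", {
  for (strand in c("+", "-")) {
    g <- simulate_gene_model(toy_gene_spec(c(20, 25, 30, 22), c(40, 50, 60),
                                           strand = strand), seed = 7)
    model <- g$model
    boundaries <- sort(unique(c(model$exons$start, model$exons$end,
                                introns(model)$start, introns(model)$end)))
    cand <- sort(unique(as.vector(outer(boundaries, -2:2, `+`))))
    span <- gene_span(model)
    cand <- cand[cand >= span["start"] & cand <= span["end"]]
    pairs <- expand.grid(donor = cand, acceptor = cand)
    pairs <- pairs[pairs$donor < pairs$acceptor, ]
    j <- tibble::tibble(chrom = model$chrom, donor = as.integer(pairs$donor),
                        acceptor = as.integer(pairs$acceptor),
                        strand = model$strand, unique_reads = 5L)
    got <- classify_junction(j, model)
    want <- mapply(oracle_classify, pairs$donor, pairs$acceptor,
                   MoreArgs = list(model = model))
    expect_equal(got$class, unname(want))
  }
})

test_that("junctions outside the gene span warn and classify as 'other'", {
  g <- simulate_gene_model(toy_gene_spec(c(30, 30), 60), seed = 8)
  j <- tibble::tibble(chrom = "chrT", donor = 90L, acceptor = 500L,
                      strand = "+", unique_reads = 3L)
  expect_warning(cl <- classify_junction(j, g$model), "outside")
  expect_equal(cl$class, "other")
  jj <- tibble::tibble(chrom = "chrX", donor = 10L, acceptor = 50L,
                       strand = "+", unique_reads = 3L)
  expect_error(classify_junction(jj, g$model), "chromosome")
})

test_that("retention calling round-trips generated events exactly", {
  g <- simulate_gene_model(toy_gene_spec(c(60, 60, 60), c(200, 250)), seed = 9)
  for (strand_gene in list(g)) {
    for (N in c(11, 38, 142)) {
      for (end in c("5prime", "3prime")) {
        ev <- retention_event(2, N, end, supporting_reads = 4)
        j <- simulate_junctions(g$model, ev, include_annotated = TRUE)
        calls <- call_retentions(j, g$model, min_reads = 1)
        expect_equal(nrow(calls), 1)
        expect_equal(calls$fragment_length, N)
        expect_equal(calls$intron_index, 2L)
        expect_equal(calls$retained_end, end)
        expect_equal(calls$supporting_reads, 4L)
      }
    }
  }
})

test_that("read-count and length filters apply; duplicates merge", {
  g <- simulate_gene_model(toy_gene_spec(c(60, 60), 200), seed = 10)
  j1 <- simulate_junctions(g$model, retention_event(1, 30, "5prime",
                                                    supporting_reads = 1),
                           include_annotated = FALSE)
  expect_equal(nrow(call_retentions(j1, g$model, min_reads = 2)), 0)
  expect_equal(nrow(call_retentions(j1, g$model, min_reads = 1)), 1)
  # annotated-only input yields nothing
  j2 <- simulate_junctions(g$model, NULL, include_annotated = TRUE)
  expect_equal(nrow(call_retentions(j2, g$model, min_reads = 1)), 0)
  # duplicate junction rows merge with summed reads
  j3 <- dplyr::bind_rows(j1, j1)
  merged <- call_retentions(j3, g$model, min_reads = 2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$supporting_reads, 2L)
  # length window
  expect_equal(nrow(call_retentions(j1, g$model, min_reads = 1,
                                    min_len = 31)), 0)
  expect_equal(nrow(call_retentions(j1, g$model, min_reads = 1,
                                    max_len = 29)), 0)
})

test_that("aberrant transcripts insert the fragment at the boundary", {
  fg <- flat_gene("+")
  ev <- retention_event(1, 4, "5prime")
  j <- simulate_junctions(fg$model, ev, include_annotated = FALSE)
  calls <- call_retentions(j, fg$model, min_reads = 1)
  ab <- aberrant_transcript(fg$model, fg$genome, calls[1, ])
  normal <- spliced_transcript(fg$model, fg$genome)
  expect_equal(nchar(ab$seq), nchar(normal$seq) + 4)
  # inserted bases are the first 4 intronic bases, after exon 1
  expect_equal(substr(ab$seq, 31, 34), "GTCC")
  expect_equal(substr(ab$seq, 1, 30), substr(normal$seq, 1, 30))
  expect_equal(substr(ab$seq, 35, nchar(ab$seq)),
               substr(normal$seq, 31, nchar(normal$seq)))
  # coordinate map covers every base once, in genomic origin
  expect_equal(nrow(ab$map), nchar(ab$seq))
  expect_equal(ab$map$genomic_pos[31:34], 31:34)
})

test_that("strand mirror image gives identical transcripts and consequences", {
  fp <- flat_gene("+"); fm <- flat_gene("-")
  expect_equal(spliced_transcript(fp$model, fp$genome)$seq,
               spliced_transcript(fm$model, fm$genome)$seq)
  for (N in c(4, 5, 6, 38)) {
    evp <- call_retentions(
      simulate_junctions(fp$model, retention_event(1, N, "5prime")),
      fp$model, min_reads = 1)
    evm <- call_retentions(
      simulate_junctions(fm$model, retention_event(1, N, "5prime")),
      fm$model, min_reads = 1)
    abp <- aberrant_transcript(fp$model, fp$genome, evp[1, ])
    abm <- aberrant_transcript(fm$model, fm$genome, evm[1, ])
    expect_equal(abp$seq, abm$seq)
    expect_equal(abp$cds_offset, abm$cds_offset)
    expect_equal(abp$last_junction_pos, abm$last_junction_pos)
  }
})

test_that("frameshift iff insertion size is not a multiple of 3", {
  fg <- flat_gene("+")
  np <- normal_protein(fg$model, fg$genome)
  for (N in 1:45) {
    calls <- call_retentions(
      simulate_junctions(fg$model, retention_event(1, N, "5prime")),
      fg$model, min_reads = 1)
    cons <- suppressWarnings(
      predict_retention_consequence(fg$model, fg$genome, calls[1, ]))
    expect_equal(cons$frameshift, N %% 3 != 0)
    if (N %% 3 == 0) {
      # stop-free in-frame insertion extends the protein by N/3 residues
      expect_true(is.na(cons$ptc_codon_index))
      expect_equal(cons$truncated_protein_length, nchar(np) + N / 3)
    }
  }
})

test_that("premature stops are detected with the NMD 50-nt rule", {
  # handcrafted transcript: CDS starts at 1, annotated protein 'MKKKK' (5 aa)
  # insertion of TAA-bearing fragment creates an early stop
  tx <- paste0("ATG", "TAA", strrep("AAA", 40), "TAA")
  # inserted 3 nt 'TAA' right after codon 1 -> stop at codon 2
  res <- predict_consequence(tx, cds_offset = 1,
                             last_junction_pos = 100,
                             inserted_nt = 3,
                             normal_protein = paste(rep("K", 41), collapse = ""))
  expect_false(res$frameshift)
  expect_equal(res$ptc_codon_index, 2L)
  expect_equal(res$truncated_protein_length, 1L)
  expect_true(res$nmd_sensitive)   # stop ends at nt 6, junction at 100
  # same stop with the last junction close by: not NMD-sensitive
  res2 <- predict_consequence(tx, 1, 20, 3, paste(rep("K", 41), collapse = ""))
  expect_false(res2$nmd_sensitive)
  # brute-force translation oracle for the stop position
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(tx, 1, 3 * (nchar(tx) %/% 3)))))
  expect_equal(res$ptc_codon_index, as.integer(regexpr("\\*", aa)))
})

test_that("transcripts without any stop are flagged non-stop", {
  tx <- strrep("AAA", 20)
  expect_warning(res <- predict_consequence(tx, 1, 10, 1, "MKK"), "non-stop")
  expect_true(res$nonstop)
  expect_equal(res$truncated_protein_length, 20L)
})

test_that("protein masses follow the average-mass table and are additive", {
  expect_equal(protein_mw("G"), 0.0750666, tolerance = 1e-6)
  expect_error(protein_mw(""), "non-empty")
  expect_error(protein_mw("GX"), "X")
  set.seed(5)
  aas <- c("MKWVTFISLLFLFSSAYS", "GG", "PEPTIDE" , "W")
  for (i in 1:4) {
    s1 <- aas[i]; s2 <- rev(aas)[i]
    expect_equal(protein_mw(paste0(s1, s2)),
                 protein_mw(s1) + protein_mw(s2) - 0.0180153,
                 tolerance = 1e-9)
  }
})

test_that("a PIGN-like synthetic locus yields a truncated product under half mass", {
  g <- simulate_gene_model(pign_like_gene_spec(), seed = 20)
  np <- normal_protein(g$model, g$genome)
  expect_equal(nchar(np), 931)
  full <- protein_mw(np)
  expect_gt(full, 90); expect_lt(full, 115)
  calls <- call_retentions(
    simulate_junctions(g$model, retention_event(14, 38, "5prime",
                                                supporting_reads = 6)),
    g$model, min_reads = 2)
  cons <- predict_retention_consequence(g$model, g$genome, calls[1, ])
  expect_true(cons$frameshift)
  expect_false(is.na(cons$ptc_codon_index))
  expect_lt(cons$truncated_mass_kda, full / 2)
  expect_true(cons$nmd_sensitive)
})
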