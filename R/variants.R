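#' Construct a variant table
#'
#' Validates a tibble of single-sequence alterations (Sanger-derived point
#' events): substitutions or single-base deletions (`alt = "-"`).
#'
#' @param position 1-based positions on the reference.
#' @param ref,alt Reference and alternate bases (`alt` may be the deletion
#'   symbol `"-"`).
#' @param region `"intron"` or `"exon"`.
#' @param exon_number Optional exon numbers.
#' @param type Optional consequence type (`synonymous`, `non-synonymous`,
#'   `frameshift_deletion`, `frameshift_insertion`, `intronic`).
#' @param aa_change Optional protein change (e.g. `p.S9N`).
#' @param sift Optional pass-through impact annotation (never computed here).
#' @return A validated variant tibble.
#' @export
variant_table <- function(position, ref, alt, region = "exon",
                          exon_number = NA_integer_, type = NA_character_,
                          aa_change = NA_character_, sift = NA_character_) {
  v <- tibble(position = as.integer(position), ref = as.character(ref),
              alt = as.character(alt), region = region,
              exon_number = as.integer(exon_number), type = type,
              aa_change = aa_change, sift = sift)
  if (any(v$position < 1L)) abort("Variant positions must be >= 1.")
  if (any(v$ref == v$alt)) abort("`ref` must differ from `alt`.")
  if (anyDuplicated(v$position)) {
    abort(paste0("Duplicate position(s) within one profile: ",
                 paste(unique(v$position[duplicated(v$position)]),
                       collapse = ", ")))
  }
  v
}

#' Packaged conserved TP53 alterations
#'
#' The three sequence alterations verified as conserved between the paired
#' leukemic and non-leukemic populations (a frameshift deletion and two
#' missense changes), transcribed as a fixture; positions are on the TP53
#' reference used for the Sanger comparison. The SIFT column is a
#' pass-through annotation.
#'
#' @return Variant tibble with 3 rows.
#' @export
tp53_conserved_variants <- function() {
  readr::read_csv(system.file("extdata", "tp53_conserved_variants.csv",
                              package = "gpinstab"),
                  show_col_types = FALSE,
                  col_types = readr::cols(
                    position = readr::col_integer(),
                    exon_number = readr::col_integer(),
                    .default = readr::col_character()))
}

#' Simulate paired variant profiles
#'
#' Builds two variant profiles sharing a conserved core: profile A = shared
#' + private_a, profile B = shared + private_b. Used to emulate paired
#' tumor/normal Sanger comparisons.
#'
#' @param shared Variant tibble of conserved alterations (default: the
#'   packaged conserved TP53 set).
#' @param n_private_a,n_private_b Number of private alterations to draw for
#'   each profile.
#' @param region_length_bp Length of the sequenced region; all positions
#'   must fall within it.
#' @param seed Integer seed.
#' @return List of two variant tibbles, `a` and `b`.
#' @export
simulate_variant_profiles <- function(shared = tp53_conserved_variants(),
                                      n_private_a = 5, n_private_b = 5,
                                      region_length_bp = 15000, seed) {
  shared <- as_tibble(shared)
  if (nrow(shared) > 0 && any(shared$position > region_length_bp)) {
    abort("Shared variant positions exceed `region_length_bp`.")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    draw_private <- function(n, taken) {
      if (n == 0L) {
        return(variant_table(integer(), character(), character())[0, ])
      }
      pos <- sample(setdiff(seq_len(region_length_bp), taken), n)
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      variant_table(pos, ref, alt, region = "intron", type = "intronic")
    }
    pa <- draw_private(n_private_a, shared$position)
    pb <- draw_private(n_private_b, c(shared$position, pa$position))
    list(a = arrange(bind_rows(shared, pa), .data$position),
         b = arrange(bind_rows(shared, pb), .data$position))
  })
}

#' Percent sequence identity from global alignment
#'
#' Global (Needleman-Wunsch) pairwise alignment with match +1, mismatch 0
#' and linear gap penalty -1 (alignment only); identity = matches /
#' alignment columns x 100, gaps counting as non-matches.
#'
#' @param query,reference Non-empty DNA sequences (character or DNAString).
#' @return Identity percentage in \[0, 100\].
#' @export
#' @examples
#' sequence_identity("ACGT", "AGT")  # 75
sequence_identity <- function(query, reference) {
  q <- as.character(query); r <- as.character(reference)
  if (nchar(q) == 0L || nchar(r) == 0L) abort("Sequences must be non-empty.")
  al <- Biostrings::pairwiseAlignment(
    q, r, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = 0, baseOnly = TRUE),
    gapOpening = 0, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  matches <- sum(p == s & p != "-")
  100 * matches / length(p)
}

#' Mutation rate per kilobase
#'
#' @param n_alterations Total alteration count over the sequenced region.
#' @param region_length_bp Region length in bp (> 0).
#' @return `1000 * n_alterations / region_length_bp`.
#' @export
mutation_rate_per_kbp <- function(n_alterations, region_length_bp) {
  if (any(region_length_bp <= 0)) abort("`region_length_bp` must be > 0.")
  1000 * n_alterations / region_length_bp
}

#' Intersect two variant profiles
#'
#' Conserved alterations: records matching exactly on (position, ref, alt).
#' No fuzzy matching across indel representations is attempted.
#'
#' @param a,b Variant tibbles with columns `position`, `ref`, `alt` (no
#'   duplicate positions within a profile).
#' @return The matching records of `a` (with `a`'s annotations), sorted by
#'   position.
#' @export
intersect_profiles <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  for (p in list(a, b)) {
    if (anyDuplicated(p$position)) {
      abort("Duplicate positions within one profile.")
    }
  }
  inner_join(a, b[, c("position", "ref", "alt")],
             by = c("position", "ref", "alt")) %>%
    arrange(.data$position)
}

#' Classify the coding consequence of a variant
#'
#' For a substitution, compares the translation of the reference and
#' mutated codons (`p.<ref><codon#><alt>` or synonymous); a single-base
#' deletion is a frameshift, reported as `p.<ref><codon#>fs`. Codon number =
#' `ceiling(cds_position / 3)`. Positions outside the CDS are classified
#' `intronic`.
#'
#' @param v One-row variant tibble (`position`, `ref`, `alt`).
#' @param cds_sequence The spliced CDS sequence (character).
#' @param cds_map Tibble mapping `genomic_pos` to `cds_pos` (1-based).
#' @return One-row tibble: `type`, `aa_change`, `note`.
#' @export
classify_coding_change <- function(v, cds_sequence, cds_map) {
  v <- as_tibble(v)
  if (nrow(v) != 1L) abort("`v` must be a single variant record.")
  hit <- cds_map$cds_pos[cds_map$genomic_pos == v$position]
  if (length(hit) != 1L) {
    return(tibble(type = "intronic", aa_change = NA_character_,
                  note = "position outside the CDS"))
  }
  cds_pos <- hit
  ref_at <- substr(cds_sequence, cds_pos, cds_pos)
  if (!identical(ref_at, v$ref)) {
    abort(paste0("Reference mismatch at CDS position ", cds_pos, ": CDS has '",
                 ref_at, "', variant says '", v$ref, "'."))
  }
  codon_number <- ceiling(cds_pos / 3)
  codon_start <- 3L * (codon_number - 1L) + 1L
  ref_codon <- substr(cds_sequence, codon_start, codon_start + 2L)
  ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(ref_codon),
                                               no.init.codon = TRUE))
  if (v$alt == "-") {
    return(tibble(type = "frameshift_deletion",
                  aa_change = paste0("p.", ref_aa, codon_number, "fs"),
                  note = NA_character_))
  }
  alt_codon <- ref_codon
  substr(alt_codon, cds_pos - codon_start + 1L, cds_pos - codon_start + 1L) <- v$alt
  alt_aa <- as.character(Biostrings::translate(Biostrings::DNAString(alt_codon),
                                               no.init.codon = TRUE))
  if (identical(ref_aa, alt_aa)) {
    tibble(type = "synonymous", aa_change = NA_character_, note = NA_character_)
  } else {
    tibble(type = "non-synonymous",
           aa_change = paste0("p.", ref_aa, codon_number, alt_aa),
           note = NA_character_)
  }
}

#' Compare per-sample mutation rates between two groups
#'
#' Two-sample Student's t-test with pooled variance, two-sided.
#'
#' @param group_a,group_b Numeric vectors of per-sample rates, each n >= 2.
#' @return One-row tibble: `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
compare_rates <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("Each group needs at least 2 values.")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(tibble(t = 0, p = 1,
                    df = length(group_a) + length(group_b) - 2,
                    mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    abort("Zero pooled variance with unequal means: t statistic undefined.")
  }
  tt <- t.test(group_a, group_b, var.equal = TRUE,
               alternative = "two.sided")
  tibble(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter),
         mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Summarize a variant profile
#'
#' @param profile Variant tibble.
#' @param region_length_bp Sequenced region length (bp).
#' @return One-row tibble: `n_alterations_total`, `n_coding`,
#'   `region_length_bp`, `rate_per_kbp`.
#' @export
profile_summary <- function(profile, region_length_bp) {
  profile <- as_tibble(profile)
  n <- nrow(profile)
  n_coding <- sum(profile$region == "exon", na.rm = TRUE)
  tibble(n_alterations_total = n, n_coding = n_coding,
         region_length_bp = as.integer(region_length_bp),
         rate_per_kbp = mutation_rate_per_kbp(n, region_length_bp))
}
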