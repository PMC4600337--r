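#' Thresholds of the rule-based pileup variant caller
#'
#' Variant observations are accepted when supported by at least
#' `min_unique_reads` unique reads, seen at least `min_first25` times within
#' the first 25 bases of a read (the most accurately aligned, highest-quality
#' part of a read), with raw coverage of at least `min_coverage`, mean
#' supporting base quality of at least `min_base_quality` (phred) and a
#' non-reference allele fraction of at least `min_alt_fraction`.  All five
#' comparisons are inclusive.
#'
#' @param min_unique_reads,min_first25,min_coverage,min_base_quality,min_alt_fraction
#'   rule thresholds; defaults 3, 1, 10, 20 and 0.15.
#' @return A list of class `caller_thresholds`.
#' @export
caller_thresholds <- function(min_unique_reads = 3, min_first25 = 1,
                              min_coverage = 10, min_base_quality = 20,
                              min_alt_fraction = 0.15) {
  vals <- list(
    min_unique_reads = min_unique_reads, min_first25 = min_first25,
    min_coverage = min_coverage, min_base_quality = min_base_quality,
    min_alt_fraction = min_alt_fraction
  )
  if (any(unlist(vals) < 0)) abort("caller thresholds must be non-negative.")
  structure(vals, class = "caller_thresholds")
}

#' Apply the five caller rules to pileup sites
#'
#' Evaluates each rule with an inclusive (>=) comparison per pileup record
#' and adds one logical column per rule plus the overall `pass` flag
#' (conjunction of all five).
#'
#' @param pileup tibble of pileup records with columns
#'   `unique_read_support`, `first25_support`, `raw_coverage`,
#'   `base_quality`, `alt_fraction` (e.g. from [simulate_pileups()]).
#' @param thresholds a [caller_thresholds()] object.
#' @return `pileup` with columns `pass_unique_reads`, `pass_first25`,
#'   `pass_coverage`, `pass_base_quality`, `pass_alt_fraction`, `pass`.
#' @export
filter_pileup_sites <- function(pileup, thresholds = caller_thresholds()) {
  need <- c(
    "unique_read_support", "first25_support", "raw_coverage",
    "base_quality", "alt_fraction"
  )
  if (!all(need %in% names(pileup))) {
    abort(paste0("`pileup` must have columns: ", paste(need, collapse = ", ")))
  }
  dplyr::mutate(
    pileup,
    pass_unique_reads = .data$unique_read_support >= thresholds$min_unique_reads,
    pass_first25 = .data$first25_support >= thresholds$min_first25,
    pass_coverage = .data$raw_coverage >= thresholds$min_coverage,
    pass_base_quality = .data$base_quality >= thresholds$min_base_quality,
    pass_alt_fraction = .data$alt_fraction >= thresholds$min_alt_fraction,
    pass = .data$pass_unique_reads & .data$pass_first25 & .data$pass_coverage &
      .data$pass_base_quality & .data$pass_alt_fraction
  )
}

#' Genotype a sample from its pileup record
#'
#' Classifies the alternative-allele fraction into homozygous reference
#' (below the band), heterozygous (inside the band, bounds inclusive) or
#' homozygous alternative (above).  A record with coverage below
#' `min_coverage` is not callable (`nocall`).  The discovery-level decision
#' whether a variant exists at the site at all is [filter_pileup_sites()]'s;
#' this function only assigns per-sample genotypes at discovered sites.
#'
#' @param pileup tibble of pileup records.
#' @param het_band length-2 numeric, the inclusive heterozygote band of the
#'   alt fraction (default `c(0.15, 0.85)`).
#' @param min_coverage minimum coverage to call any genotype (default 10).
#' @return `pileup` with a `genotype` column in
#'   `c("homref", "het", "homalt", "nocall")`.
#' @export
genotype_from_pileup <- function(pileup, het_band = c(0.15, 0.85),
                                 min_coverage = 10) {
  if (length(het_band) != 2 || het_band[1] > het_band[2]) {
    abort("`het_band` must be (lower, upper) with lower <= upper.")
  }
  dplyr::mutate(
    pileup,
    genotype = dplyr::case_when(
      .data$raw_coverage < min_coverage ~ "nocall",
      .data$alt_fraction < het_band[1] ~ "homref",
      .data$alt_fraction <= het_band[2] ~ "het",
      TRUE ~ "homalt"
    )
  )
}

#' Call variants from multi-sample pileups
#'
#' Runs the full caller: per-record rule filtering, site-level variant
#' discovery (a site is a variant iff at least one sample passes all five
#' rules) and per-sample genotyping at discovered sites.
#'
#' @param pileup multi-sample pileup tibble (one row per sample x site).
#' @param thresholds a [caller_thresholds()] object.
#' @param het_band inclusive heterozygote alt-fraction band.
#' @return Tibble of per-sample calls at discovered sites: site key columns
#'   (`chromosome`, `position_bp`, `ref_base`, `alt_base`), `sample_id`,
#'   `genotype`, the per-rule flags and `pass`.
#' @export
call_variants <- function(pileup, thresholds = caller_thresholds(),
                          het_band = c(0.15, 0.85)) {
  flt <- filter_pileup_sites(pileup, thresholds)
  flt <- genotype_from_pileup(flt, het_band, thresholds$min_coverage)
  discovered <- dplyr::filter(
    dplyr::summarise(
      dplyr::group_by(flt, .data$chromosome, .data$position_bp,
                      .data$ref_base, .data$alt_base),
      any_pass = any(.data$pass), .groups = "drop"
    ),
    .data$any_pass
  )
  dplyr::inner_join(
    flt,
    discovered[, c("chromosome", "position_bp", "ref_base", "alt_base")],
    by = c("chromosome", "position_bp", "ref_base", "alt_base")
  )
}

#' Recessive case/control concordance of called variants
#'
#' A variant fits a fully penetrant recessive model iff every case is
#' homozygous for the alternative allele and no control is; controls may be
#' heterozygous (carriers).  A case without a callable genotype fails
#' concordance (conservative), with its own reason code.
#'
#' @param calls per-sample call tibble (e.g. from [call_variants()]) with
#'   columns `chromosome`, `position_bp`, `ref_base`, `alt_base`,
#'   `sample_id`, `genotype`.
#' @param case_ids,control_ids sample ids of the cases and controls.
#' @return One row per site: site key, `concordant` flag and `reason`, one
#'   of `"concordant"`, `"case_nocall"`, `"case_not_homalt"`,
#'   `"control_homalt"`.
#' @export
recessive_concordance <- function(calls, case_ids, control_ids) {
  per_site <- function(d) {
    g <- stats::setNames(d$genotype, d$sample_id)
    gc <- g[case_ids]
    gt <- g[control_ids]
    gc[is.na(gc)] <- "nocall"
    reason <- if (any(gc == "nocall")) {
      "case_nocall"
    } else if (any(gc != "homalt")) {
      "case_not_homalt"
    } else if (any(gt == "homalt", na.rm = TRUE)) {
      "control_homalt"
    } else {
      "concordant"
    }
    tibble::tibble(concordant = reason == "concordant", reason = reason)
  }
  out <- dplyr::group_modify(
    dplyr::group_by(calls, .data$chromosome, .data$position_bp,
                    .data$ref_base, .data$alt_base),
    ~ per_site(.x)
  )
  dplyr::ungroup(out)
}

#' Codon number of a coding-sequence position
#'
#' @param cds_position 1-based position within the coding sequence.
#' @return 1-based codon index, `ceiling(cds_position / 3)`.
#' @export
#' @examples
#' codon_index(1423) # 475
codon_index <- function(cds_position) {
  if (any(cds_position < 1)) abort("`cds_position` must be >= 1.")
  ((as.integer(cds_position) - 1L) %/% 3L) + 1L
}

#' Annotate a coding substitution
#'
#' Extracts the affected codon from the coding sequence, applies the
#' substitution, translates both codons with the standard genetic code and
#' classifies the consequence.  For a stop-gain, the truncation length is
#' `protein_length - codon_index + 1` residues (the mutated codon and
#' everything downstream).
#'
#' @param cds_sequence coding sequence (character or
#'   [Biostrings::DNAString]); length must be a multiple of 3.
#' @param cds_position 1-based substituted position; the reference base
#'   there must equal `ref_base`.
#' @param ref_base,alt_base single upper-case nucleotides.
#' @param protein_length protein length in residues; defaults to
#'   `nchar(cds_sequence)/3 - 1` (coding sequence including the terminal
#'   stop codon).
#' @return One-row tibble: `cds_position`, `ref_base`, `alt_base`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `consequence` (`synonymous`, `missense`, `stop_gain`, `stop_loss`),
#'   `truncation_aa` (NA unless stop-gain).
#' @export
#' @examples
#' annotate_cds(paste0("ATG", "CAG", "TGA"), 4, "C", "T") # Gln2* stop gain
annotate_cds <- function(cds_sequence, cds_position, ref_base, alt_base,
                         protein_length = NULL) {
  seq <- toupper(as.character(cds_sequence))
  n <- nchar(seq)
  if (n %% 3 != 0) abort("`cds_sequence` length must be a multiple of 3.")
  if (cds_position < 1 || cds_position > n) {
    abort("`cds_position` outside the coding sequence.")
  }
  observed <- substr(seq, cds_position, cds_position)
  if (observed != toupper(ref_base)) {
    abort(sprintf(
      "reference mismatch at CDS position %d: sequence has %s, expected %s.",
      cds_position, observed, ref_base
    ))
  }
  ci <- codon_index(cds_position)
  codon_start <- (ci - 1L) * 3L + 1L
  ref_codon <- substr(seq, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cds_position - codon_start + 1L, cds_position - codon_start + 1L) <-
    toupper(alt_base)
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  if (is.na(ref_aa) || is.na(alt_aa)) abort("codon contains a non-ACGT base.")
  consequence <- dplyr::case_when(
    ref_aa == alt_aa ~ "synonymous",
    alt_aa == "*" ~ "stop_gain",
    ref_aa == "*" ~ "stop_loss",
    TRUE ~ "missense"
  )
  protein_length <- protein_length %||% (n / 3 - 1)
  tibble::tibble(
    cds_position = as.integer(cds_position),
    ref_base = toupper(ref_base), alt_base = toupper(alt_base),
    codon_index = ci, ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence,
    truncation_aa = if (consequence == "stop_gain") {
      as.integer(protein_length - ci + 1L)
    } else {
      NA_integer_
    }
  )
}
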