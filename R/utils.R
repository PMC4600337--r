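# Shared internal helpers for genotype tables.
#
# A genotype table is a tibble with one row per sample: `sample_id`,
# `phenotype` (one of "case", "control", "obligate_carrier"), then one
# integer column per marker holding dosage codes 0 (homozygous
# reference-like), 1 (heterozygous), 2 (homozygous alternative), NA missing.
# The marker map travels alongside as a tibble with `marker_id`,
# `chromosome`, `position_bp` (1-based), `allele_ref`, `allele_alt`.

PHENOTYPE_LEVELS <- c("case", "control", "obligate_carrier")

#' Round half away from zero at a fixed number of decimals
#'
#' Plain `round()` rounds half to even; reported percentages and frequencies
#' use the conventional half-up rule instead.  Applied only when formatting
#' report values, never to intermediate quantities.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(13.35, 1)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  trunc(x * f + 0.5 + sign(x) * 1e-9) / f
}

marker_cols <- function(geno) {
  setdiff(names(geno), c("sample_id", "phenotype"))
}

# samples x markers integer matrix view of a genotype table
geno_matrix <- function(geno) {
  mk <- marker_cols(geno)
  m <- as.matrix(geno[, mk, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- geno$sample_id
  m
}

as_geno_tibble <- function(mat, sample_ids, phenotypes) {
  stopifnot(nrow(mat) == length(sample_ids), length(sample_ids) == length(phenotypes))
  out <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
  dplyr::bind_cols(
    tibble::tibble(sample_id = sample_ids, phenotype = phenotypes),
    out
  )
}

check_geno_map <- function(geno, map, call = rlang::caller_env()) {
  if (!all(c("sample_id", "phenotype") %in% names(geno))) {
    abort("`genotypes` must have `sample_id` and `phenotype` columns.", call = call)
  }
  mk <- marker_cols(geno)
  if (!identical(mk, map$marker_id)) {
    abort("marker columns of `genotypes` must match `map$marker_id` (same order).",
      call = call
    )
  }
  ord <- order(map$chromosome, map$position_bp)
  if (is.unsorted(ord) && !identical(ord, seq_len(nrow(map)))) {
    abort("`map` must be ordered by (chromosome, position_bp).", call = call)
  }
  invisible(TRUE)
}

check_probability <- function(x, name, call = rlang::caller_env()) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name), call = call)
  }
  invisible(TRUE)
}
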