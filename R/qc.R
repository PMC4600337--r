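#' Minor allele frequency of one marker
#'
#' With dosage codes 0/1/2 counting alternative alleles, the alternative
#' allele frequency over non-missing samples is
#' f = (n1 + 2 n2) / (2 n), and the MAF is min(f, 1 - f).
#'
#' @param genotypes integer vector of dosage codes (0/1/2, NA missing).
#' @return MAF in \[0, 0.5\].  Errors if all genotypes are missing.
#' @export
#' @examples
#' compute_maf(c(0, 1, 1, 2))
compute_maf <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0) abort("MAF is uncomputable: all genotypes missing.")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Call rate of a marker or sample
#'
#' @param genotypes vector of dosage codes with NA for missing.
#' @return Fraction of non-missing entries in \[0, 1\].
#' @export
call_rate <- function(genotypes) {
  if (length(genotypes) == 0) abort("empty genotype vector.")
  mean(!is.na(genotypes))
}

# vectorized per-marker stats on a samples x markers matrix
marker_mafs <- function(G) {
  nn <- colSums(!is.na(G))
  f <- colSums(G, na.rm = TRUE) / (2 * nn)
  maf <- pmin(f, 1 - f)
  maf[nn == 0] <- NA_real_
  maf
}

#' Apply marker and sample quality control
#'
#' Replicates standard SNP-array QC: markers with minor allele frequency
#' below `maf_min` or call rate below `marker_cr_min` are discarded (both
#' comparisons strict, so a marker at exactly the threshold passes), then
#' samples with call rate below `sample_cr_min` over the retained markers are
#' removed.  Marker statistics are computed over all phenotype classes
#' jointly.
#'
#' @param genotypes genotype tibble (see [simulate_population()] for the
#'   layout).
#' @param map marker map tibble matching `genotypes`.
#' @param maf_min,marker_cr_min,sample_cr_min filter thresholds; defaults
#'   MAF 0.05 and call rate 0.90 for both markers and samples.
#' @return A list of class `qc_result`: `genotypes` and `map` (filtered,
#'   original order preserved), `report` (one-row tibble: `n_markers_in`,
#'   `n_markers_out`, `fraction_retained`, `pct_retained`, `n_failed_maf`,
#'   `n_failed_callrate`, `fraction_discarded_low_maf`,
#'   `pct_discarded_low_maf`, `n_samples_in`, `n_samples_removed`),
#'   `marker_stats` (per input marker: `maf`, `call_rate`, `kept`, failure
#'   flags) and `sample_call_rates` (per input sample, on retained markers).
#'   Percentages are rounded half-up to 1 decimal; fractions are exact.
#' @export
#' @examples
#' sim <- simulate_population(sim_config(n_markers = 60, disease_locus_marker = 30))
#' qc <- apply_qc(sim$genotypes, sim$map)
#' glance(qc)
apply_qc <- function(genotypes, map, maf_min = 0.05, marker_cr_min = 0.90,
                     sample_cr_min = 0.90) {
  check_geno_map(genotypes, map)
  check_probability(maf_min, "maf_min")
  check_probability(marker_cr_min, "marker_cr_min")
  check_probability(sample_cr_min, "sample_cr_min")
  G <- geno_matrix(genotypes)

  maf <- marker_mafs(G)
  cr <- colMeans(!is.na(G))
  fail_maf <- !is.na(maf) & maf < maf_min
  fail_cr <- cr < marker_cr_min | is.na(maf) # all-missing markers fail call rate
  keep_marker <- !fail_maf & !fail_cr
  if (!any(keep_marker)) abort("QC removed every marker; nothing to analyse.")

  Gk <- G[, keep_marker, drop = FALSE]
  sample_cr <- rowMeans(!is.na(Gk))
  keep_sample <- sample_cr >= sample_cr_min
  if (!any(keep_sample)) abort("QC removed every sample; nothing to analyse.")

  n_in <- ncol(G)
  n_out <- sum(keep_marker)
  n_disc <- n_in - n_out
  report <- tibble::tibble(
    n_markers_in = n_in,
    n_markers_out = n_out,
    fraction_retained = n_out / n_in,
    pct_retained = round_half_up(100 * n_out / n_in, 1),
    n_failed_maf = sum(fail_maf),
    n_failed_callrate = sum(fail_cr),
    fraction_discarded_low_maf = if (n_disc > 0) sum(fail_maf) / n_disc else NA_real_,
    pct_discarded_low_maf = if (n_disc > 0) {
      round_half_up(100 * sum(fail_maf) / n_disc, 1)
    } else {
      NA_real_
    },
    n_samples_in = nrow(G),
    n_samples_removed = sum(!keep_sample)
  )

  structure(
    list(
      genotypes = genotypes[keep_sample, c("sample_id", "phenotype", map$marker_id[keep_marker])],
      map = map[keep_marker, ],
      report = report,
      marker_stats = tibble::tibble(
        marker_id = map$marker_id,
        maf = maf,
        call_rate = cr,
        failed_maf = fail_maf,
        failed_callrate = fail_cr,
        kept = keep_marker
      ),
      sample_call_rates = tibble::tibble(
        sample_id = genotypes$sample_id,
        call_rate = sample_cr,
        kept = keep_sample
      ),
      thresholds = list(
        maf_min = maf_min, marker_cr_min = marker_cr_min,
        sample_cr_min = sample_cr_min
      )
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<qc_result> markers %d -> %d (%.1f%% retained); samples %d -> %d\n",
    r$n_markers_in, r$n_markers_out, r$pct_retained,
    r$n_samples_in, r$n_samples_in - r$n_samples_removed
  ))
  invisible(x)
}

#' @rdname apply_qc
#' @param x a `qc_result`.
#' @param ... unused.
#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) x$marker_stats

#' @rdname apply_qc
#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) x$report
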