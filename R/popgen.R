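#' Two-locus linkage disequilibrium r-squared
#'
#' Estimates r² between two biallelic loci from unphased dosage codes.  The
#' default `"em"` method estimates the four haplotype frequencies by
#' expectation-maximization over the double-heterozygote phase ambiguity
#' (initialized at linkage equilibrium, iterated until the largest relative
#' frequency change is below 1e-8 or 1000 iterations), then computes
#' r² = D² / (pA(1-pA) pB(1-pB)) with D the haplotype-frequency departure
#' from independence.  The `"genotype_correlation"` method is the fast
#' cross-check: the squared Pearson correlation of the dosage vectors.
#'
#' @param genotypes_a,genotypes_b equal-length integer dosage vectors
#'   (0/1/2, NA missing); at least 2 jointly non-missing samples, and both
#'   loci must be polymorphic.
#' @param method `"em"` (default) or `"genotype_correlation"`.
#' @return One-row tibble of class `ld_result`: `r2`, `method`, `n`
#'   (jointly non-missing samples), alt-allele frequencies `freq_alt_a`,
#'   `freq_alt_b`, and (EM only) haplotype frequencies `hap_rr`, `hap_ra`,
#'   `hap_ar`, `hap_aa` (reference/alternative at locus a then b) and `d`
#'   (the disequilibrium coefficient).
#' @export
#' @examples
#' a <- c(0, 1, 2, 2, 0, 1)
#' ld_r2(a, a)$r2 # 1
ld_r2 <- function(genotypes_a, genotypes_b,
                  method = c("em", "genotype_correlation")) {
  method <- match.arg(method)
  if (length(genotypes_a) != length(genotypes_b)) {
    abort("genotype vectors must have equal length.")
  }
  ok <- !is.na(genotypes_a) & !is.na(genotypes_b)
  a <- as.integer(genotypes_a[ok])
  b <- as.integer(genotypes_b[ok])
  n <- length(a)
  if (n < 2) abort("need at least 2 samples with both genotypes non-missing.")
  if (var(a) == 0 || var(b) == 0) {
    abort("r-squared is undefined for a monomorphic locus.")
  }

  if (method == "genotype_correlation") {
    r2 <- min(1, max(0, cor(a, b)^2))
    return(structure(
      tibble::tibble(
        r2 = r2, method = method, n = n,
        freq_alt_a = sum(a) / (2 * n), freq_alt_b = sum(b) / (2 * n)
      ),
      class = c("ld_result", class(tibble::tibble()))
    ))
  }

  # 3x3 genotype cell counts, alt-dosage indexed
  C <- matrix(0, 3, 3)
  for (i in seq_len(n)) C[a[i] + 1L, b[i] + 1L] <- C[a[i] + 1L, b[i] + 1L] + 1
  pa <- sum(a) / (2 * n)
  pb <- sum(b) / (2 * n)
  # haplotype frequencies: p[1]=ref-ref, p[2]=ref-alt, p[3]=alt-ref, p[4]=alt-alt
  p <- c((1 - pa) * (1 - pb), (1 - pa) * pb, pa * (1 - pb), pa * pb)
  for (iter in seq_len(1000)) {
    h <- numeric(4)
    # deterministic cells (alt-allele counts per locus 0/1/2)
    h[1] <- 2 * C[1, 1] + C[1, 2] + C[2, 1]
    h[2] <- 2 * C[1, 3] + C[1, 2] + C[2, 3]
    h[3] <- 2 * C[3, 1] + C[2, 1] + C[3, 2]
    h[4] <- 2 * C[3, 3] + C[3, 2] + C[2, 3]
    dh <- C[2, 2]
    if (dh > 0) {
      denom <- p[4] * p[1] + p[2] * p[3]
      w <- if (denom > 0) p[4] * p[1] / denom else 0.5
      h[1] <- h[1] + w * dh
      h[4] <- h[4] + w * dh
      h[2] <- h[2] + (1 - w) * dh
      h[3] <- h[3] + (1 - w) * dh
    }
    p_new <- h / (2 * n)
    delta <- max(abs(p_new - p) / pmax(p, 1e-12))
    p <- p_new
    if (delta < 1e-8) break
  }
  pa_hat <- p[3] + p[4]
  pb_hat <- p[2] + p[4]
  D <- p[4] - pa_hat * pb_hat
  denom <- pa_hat * (1 - pa_hat) * pb_hat * (1 - pb_hat)
  r2 <- if (denom > 0) min(1, max(0, D^2 / denom)) else NA_real_
  structure(
    tibble::tibble(
      r2 = r2, method = method, n = n,
      freq_alt_a = pa_hat, freq_alt_b = pb_hat,
      hap_rr = p[1], hap_ra = p[2], hap_ar = p[3], hap_aa = p[4], d = D
    ),
    class = c("ld_result", class(tibble::tibble()))
  )
}

check_screen_counts <- function(counts, call = rlang::caller_env()) {
  need <- c("n_homref", "n_het", "n_homalt")
  if (!all(need %in% names(counts))) {
    abort("screen counts need columns n_homref, n_het, n_homalt.", call = call)
  }
  if (any(unlist(counts[need]) < 0)) abort("screen counts must be non-negative.", call = call)
  invisible(TRUE)
}

#' Allele frequency from carrier-screen genotype counts
#'
#' Direct allele-counting estimator
#' (n_het + 2 n_homalt) / (2 n_total); rows of `counts` (e.g. screening
#' strata such as stallions and broodmares) are pooled.
#'
#' @param counts data frame with columns `n_homref`, `n_het`, `n_homalt`
#'   (one row per stratum).
#' @return Estimated alternative-allele frequency.
#' @export
#' @examples
#' allele_frequency_from_screen(
#'   data.frame(n_homref = 718, n_het = 147, n_homalt = 0)
#' ) # 0.085
allele_frequency_from_screen <- function(counts) {
  check_screen_counts(counts)
  total <- sum(counts$n_homref) + sum(counts$n_het) + sum(counts$n_homalt)
  if (total == 0) abort("screen is empty: total count is zero.")
  (sum(counts$n_het) + 2 * sum(counts$n_homalt)) / (2 * total)
}

#' Carrier percentage in a screen
#'
#' Percentage of heterozygous carriers per stratum, rounded half-up to one
#' decimal (reporting convention).
#'
#' @param counts data frame with columns `n_homref`, `n_het`, `n_homalt`.
#' @return Numeric vector, one percentage per row of `counts`.
#' @export
#' @examples
#' carrier_percentage(data.frame(n_homref = 52, n_het = 8, n_homalt = 0)) # 13.3
carrier_percentage <- function(counts) {
  check_screen_counts(counts)
  total <- counts$n_homref + counts$n_het + counts$n_homalt
  if (any(total == 0)) abort("screen stratum with zero total.")
  round_half_up(100 * counts$n_het / total, 1)
}

#' Summarise a screening stratum table
#'
#' Convenience wrapper adding per-stratum carrier percentages and the pooled
#' allele-frequency estimate to a screen-count table.
#'
#' @param counts data frame with columns `n_homref`, `n_het`, `n_homalt`
#'   and optionally a stratum label column.
#' @return List with `strata` (input plus `n_total`, `carrier_pct`) and
#'   `allele_frequency` (pooled, rounded half-up to 3 decimals) plus
#'   `allele_frequency_raw`.
#' @export
screen_summary <- function(counts) {
  check_screen_counts(counts)
  strata <- dplyr::mutate(
    tibble::as_tibble(counts),
    n_total = .data$n_homref + .data$n_het + .data$n_homalt,
    carrier_pct = carrier_percentage(counts)
  )
  f <- allele_frequency_from_screen(counts)
  list(
    strata = strata,
    allele_frequency = round_half_up(f, 3),
    allele_frequency_raw = f
  )
}

#' Concordance of a candidate variant with the recessive model
#'
#' Cross-tabulates validation genotypes at one variant by phenotype class
#' and checks the three hallmarks of a fully penetrant recessive lethal:
#' all cases homozygous alternative, no control homozygous alternative, all
#' obligate carriers heterozygous.
#'
#' @param validation data frame with columns `phenotype` (`case`,
#'   `control`, `obligate_carrier`) and `genotype` (`homref`, `het`,
#'   `homalt`).
#' @return List of class `validation_summary`: `counts` (phenotype x
#'   genotype tibble) and `flags` (one-row tibble `all_cases_homalt`,
#'   `no_control_homalt`, `all_carriers_het`; a flag is NA when its
#'   phenotype class is absent).
#' @export
validation_summary <- function(validation) {
  if (nrow(validation) == 0) {
    return(structure(
      list(
        counts = tibble::tibble(
          phenotype = character(), genotype = character(), n = integer()
        ),
        flags = tibble::tibble(
          all_cases_homalt = NA, no_control_homalt = NA, all_carriers_het = NA
        )
      ),
      class = "validation_summary"
    ))
  }
  counts <- dplyr::count(
    tibble::as_tibble(validation), .data$phenotype, .data$genotype
  )
  gen_of <- function(ph) validation$genotype[validation$phenotype == ph]
  flag <- function(ph, pred) {
    g <- gen_of(ph)
    if (length(g) == 0) NA else pred(g)
  }
  structure(
    list(
      counts = counts,
      flags = tibble::tibble(
        all_cases_homalt = flag("case", function(g) all(g == "homalt")),
        no_control_homalt = flag("control", function(g) !any(g == "homalt")),
        all_carriers_het = flag("obligate_carrier", function(g) all(g == "het"))
      )
    ),
    class = "validation_summary"
  )
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("<validation_summary>\n")
  print(x$counts)
  print(x$flags)
  invisible(x)
}
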