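#' Case/control genotype counts for one marker
#'
#' Builds the 2x3 genotypic contingency table (rows case, control; columns
#' dosage 0, 1, 2) used by the association scan.  Missing genotypes are
#' excluded; obligate carriers are not part of the case/control contrast.
#'
#' @param genotypes genotype tibble.
#' @param map marker map matching `genotypes`.
#' @param marker_id marker to tabulate.
#' @return 2x3 integer matrix with dimnames
#'   `list(c("case", "control"), c("0", "1", "2"))`.
#' @export
genotype_counts <- function(genotypes, map, marker_id) {
  check_geno_map(genotypes, map)
  if (!marker_id %in% map$marker_id) {
    abort(sprintf("marker `%s` not found in map.", marker_id))
  }
  g <- genotypes[[marker_id]]
  out <- matrix(0L, 2, 3, dimnames = list(c("case", "control"), c("0", "1", "2")))
  for (grp in c("case", "control")) {
    gg <- g[genotypes$phenotype == grp]
    out[grp, ] <- tabulate(gg[!is.na(gg)] + 1L, nbins = 3)
  }
  if (sum(out) == 0) abort(sprintf("marker `%s`: all case/control genotypes missing.", marker_id))
  out
}

#' Pearson chi-square test on a 2x3 genotypic table
#'
#' Computes the Pearson statistic over cells with positive expected count.
#' Genotype columns with zero total are dropped and the degrees of freedom
#' reduced accordingly (df = number of non-empty columns minus 1).  A table
#' with at most one non-empty column carries no information: it is flagged
#' degenerate with statistic 0, df 0 and p = 1.
#'
#' @param table 2x3 matrix of non-negative counts (rows case/control,
#'   columns dosages 0/1/2), e.g. from [genotype_counts()].
#' @return One-row tibble: `chi2_stat`, `df`, `p_value`, `degenerate`.
#' @export
#' @examples
#' chisq_2x3(rbind(c(13, 0, 0), c(0, 35, 34)))
chisq_2x3 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 3)) || any(tab < 0)) {
    abort("`table` must be a 2x3 matrix of non-negative counts.")
  }
  N <- sum(tab)
  if (N == 0) abort("empty table: grand total is zero.")
  col_tot <- colSums(tab)
  keep <- col_tot > 0
  if (sum(keep) <= 1) {
    return(tibble::tibble(chi2_stat = 0, df = 0L, p_value = 1, degenerate = TRUE))
  }
  O <- tab[, keep, drop = FALSE]
  E <- outer(rowSums(tab), col_tot[keep]) / N
  stat <- sum(ifelse(E > 0, (O - E)^2 / E, 0))
  df <- sum(keep) - 1L
  tibble::tibble(
    chi2_stat = stat, df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE),
    degenerate = FALSE
  )
}

#' Exact test on a 2x3 genotypic table
#'
#' Two-sided exact p-value by the probability-ordering criterion: with both
#' margins fixed, table probabilities follow the multivariate hypergeometric
#' distribution, and p is the sum of the probabilities of all tables no more
#' probable than the observed one.  The full outcome space is enumerated,
#' which is feasible for the cohort sizes this test targets (grand total up
#' to 500); larger tables should use [chisq_2x3()].
#'
#' @param table 2x3 matrix of non-negative counts.
#' @return Exact p-value in (0, 1\].
#' @export
#' @examples
#' fisher_2x3(rbind(c(4, 0, 0), c(0, 3, 3)))
fisher_2x3 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 3)) || any(tab < 0)) {
    abort("`table` must be a 2x3 matrix of non-negative counts.")
  }
  N <- sum(tab)
  if (N == 0) abort("empty table: grand total is zero.")
  if (N > 500) {
    abort("grand total exceeds the enumeration bound (500); use chisq_2x3() instead.")
  }
  n1 <- sum(tab[1, ])
  ct <- colSums(tab)
  log_denom <- lchoose(N, n1)
  logp_obs <- sum(lchoose(ct, tab[1, ])) - log_denom

  logp <- c()
  for (a in 0:min(n1, ct[1])) {
    b_max <- min(n1 - a, ct[2])
    b <- 0:b_max
    cc <- n1 - a - b
    ok <- cc <= ct[3]
    if (!any(ok)) next
    logp <- c(
      logp,
      lchoose(ct[1], a) + lchoose(ct[2], b[ok]) + lchoose(ct[3], cc[ok]) - log_denom
    )
  }
  min(1, sum(exp(logp[logp <= logp_obs + 1e-7])))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha desired family-wise significance level.
#' @param n_tests number of tests (markers).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 29720) # 1.68e-6
bonferroni_threshold <- function(alpha, n_tests) {
  check_probability(alpha, "alpha")
  if (n_tests < 1) abort("`n_tests` must be at least 1.")
  alpha / n_tests
}

#' Is a 2x3 table consistent with a fully penetrant recessive locus?
#'
#' TRUE iff all non-missing cases fall in a single homozygote column and no
#' control falls in that column.  Controls may be heterozygous.
#'
#' @param table 2x3 matrix (rows case/control, columns dosages 0/1/2).
#' @return Logical flag.
#' @export
recessive_pattern <- function(table) {
  tab <- as.matrix(table)
  n_case <- sum(tab[1, ])
  if (n_case == 0) {
    return(FALSE)
  }
  (tab[1, 1] == n_case && tab[2, 1] == 0) ||
    (tab[1, 3] == n_case && tab[2, 3] == 0)
}

#' Genome-wide genotypic association scan
#'
#' For every marker, tabulates case/control genotype counts (missing
#' excluded, obligate carriers excluded), computes the genotypic Pearson
#' chi-square test with zero-column df reduction, flags significance against
#' the Bonferroni threshold `alpha / n_markers`, and screens each table for
#' the fully penetrant recessive pattern.  Optionally adds the exact
#' (probability-ordering) p-value, the remedy for the zero cells that a
#' recessive locus produces.
#'
#' @param genotypes QC'd genotype tibble.
#' @param map marker map matching `genotypes`.
#' @param alpha family-wise significance level (default 0.05).
#' @param test `"chi2"` (default), `"fisher"`, or `"both"`.
#' @return Tibble of class `assoc_scan`, one row per marker in genome order:
#'   marker/map columns, the six table counts (`case_0` ... `control_2`),
#'   `chi2_stat`, `df`, `p_chi2`, `degenerate`, optionally `p_fisher`,
#'   `neg_log10_p`, `significant`, `recessive_consistent`.  Attributes
#'   `alpha`, `threshold` and `n_tests` record the multiple-testing
#'   correction.
#' @export
#' @examples
#' sim <- simulate_population(sim_config(n_markers = 60, disease_locus_marker = 30))
#' scan <- assoc_scan(sim$genotypes, sim$map)
#' dplyr::slice_min(scan, p_chi2, n = 3)
assoc_scan <- function(genotypes, map, alpha = 0.05,
                       test = c("chi2", "fisher", "both")) {
  test <- match.arg(test)
  check_geno_map(genotypes, map)
  check_probability(alpha, "alpha")
  cc <- genotypes$phenotype %in% c("case", "control")
  G <- geno_matrix(genotypes)[cc, , drop = FALSE]
  is_case <- genotypes$phenotype[cc] == "case"

  cnt <- function(rows, g) colSums(G[rows, , drop = FALSE] == g, na.rm = TRUE)
  a0 <- cnt(is_case, 0L); a1 <- cnt(is_case, 1L); a2 <- cnt(is_case, 2L)
  b0 <- cnt(!is_case, 0L); b1 <- cnt(!is_case, 1L); b2 <- cnt(!is_case, 2L)
  c0 <- a0 + b0; c1 <- a1 + b1; c2 <- a2 + b2
  r1 <- a0 + a1 + a2; r2 <- b0 + b1 + b2
  N <- r1 + r2

  cell <- function(o, r, ctot) {
    e <- r * ctot / N
    ifelse(ctot > 0 & N > 0 & e > 0, (o - e)^2 / e, 0)
  }
  stat <- cell(a0, r1, c0) + cell(a1, r1, c1) + cell(a2, r1, c2) +
    cell(b0, r2, c0) + cell(b1, r2, c1) + cell(b2, r2, c2)
  df <- pmax((c0 > 0) + (c1 > 0) + (c2 > 0) - 1L, 0L)
  degenerate <- df == 0L | N == 0
  p <- ifelse(degenerate, 1, pchisq(stat, pmax(df, 1L), lower.tail = FALSE))
  stat[degenerate] <- 0

  threshold <- bonferroni_threshold(alpha, nrow(map))
  res <- dplyr::bind_cols(
    map,
    tibble::tibble(
      case_0 = a0, case_1 = a1, case_2 = a2,
      control_0 = b0, control_1 = b1, control_2 = b2,
      chi2_stat = stat, df = df, p_chi2 = p, degenerate = degenerate
    )
  )
  if (test %in% c("fisher", "both")) {
    res$p_fisher <- purrr::pmap_dbl(
      res[, c("case_0", "case_1", "case_2", "control_0", "control_1", "control_2")],
      function(case_0, case_1, case_2, control_0, control_1, control_2) {
        tot <- case_0 + case_1 + case_2 + control_0 + control_1 + control_2
        if (tot == 0) return(NA_real_)
        fisher_2x3(rbind(
          c(case_0, case_1, case_2),
          c(control_0, control_1, control_2)
        ))
      }
    )
  }
  p_used <- if (test == "fisher") res$p_fisher else res$p_chi2
  res$neg_log10_p <- -log10(pmax(p_used, 1e-300))
  res$significant <- !is.na(p_used) & p_used < threshold
  res$recessive_consistent <- (a0 == r1 & r1 > 0 & b0 == 0) |
    (a2 == r1 & r1 > 0 & b2 == 0)

  structure(res,
    class = c("assoc_scan", class(res)),
    alpha = alpha, threshold = threshold, n_tests = nrow(map), test = test
  )
}

#' @rdname assoc_scan
#' @param x an `assoc_scan` result.
#' @param ... unused.
#' @method tidy assoc_scan
#' @export
tidy.assoc_scan <- function(x, ...) {
  tibble::as_tibble(x)[, c(
    "marker_id", "chromosome", "position_bp", "chi2_stat", "df",
    intersect(c("p_chi2", "p_fisher"), names(x)),
    "neg_log10_p", "significant", "recessive_consistent"
  )]
}

#' @rdname assoc_scan
#' @method glance assoc_scan
#' @export
glance.assoc_scan <- function(x, ...) {
  tibble::tibble(
    n_markers = attr(x, "n_tests"),
    alpha = attr(x, "alpha"),
    threshold = attr(x, "threshold"),
    n_significant = sum(x$significant, na.rm = TRUE),
    min_p = min(x$p_chi2, na.rm = TRUE),
    top_marker = x$marker_id[which.min(x$p_chi2)]
  )
}

#' Manhattan plot of an association scan
#'
#' @param object an [assoc_scan()] result.
#' @param ... unused.
#' @return A ggplot: -log10 p by genome position, with the Bonferroni
#'   threshold as a horizontal line.
#' @method autoplot assoc_scan
#' @export
autoplot.assoc_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$position_bp / 1e6, y = .data$neg_log10_p,
                 colour = .data$chromosome)
  ) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "position (Mb)", y = expression(-log[10](italic(p))),
      title = "Genotypic association scan"
    ) +
    ggplot2::theme_minimal()
}
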