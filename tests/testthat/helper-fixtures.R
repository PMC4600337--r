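# Fixtures and independent oracles shared across test files.

# small genotype tibble from an explicit samples x markers matrix
make_geno <- function(codes, phenotypes, chromosome = "1", spacing = 1000) {
  m <- as.matrix(codes)
  storage.mode(m) <- "integer"
  nm <- ncol(m)
  map <- tibble::tibble(
    marker_id = sprintf("T%03d", seq_len(nm)),
    chromosome = chromosome,
    position_bp = (seq_len(nm) - 1) * spacing + 1,
    allele_ref = rep(c("A", "C", "G", "T"), length.out = nm),
    allele_alt = rep(c("G", "T", "A", "C"), length.out = nm)
  )
  colnames(m) <- map$marker_id
  geno <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(nrow(m))),
      phenotype = phenotypes
    ),
    tibble::as_tibble(as.data.frame(m))
  )
  list(genotypes = geno, map = map)
}

# textbook Pearson chi-square on a 2xk table, written independently of the
# package implementation (explicit loops over cells)
oracle_chisq <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  N <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / N
      if (e > 0) stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# exhaustive window-enumeration oracle for shared homozygous regions on one
# chromosome: a window [i, j] is a region iff it is "shareable" at every
# marker, its end markers have a defined consensus, and it is maximal.
oracle_shared_regions <- function(G_cases, positions, min_markers = 3) {
  nm <- ncol(G_cases)
  consensus <- rep(NA_integer_, nm)
  shareable <- rep(FALSE, nm)
  for (j in seq_len(nm)) {
    v <- G_cases[, j]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      shareable[j] <- TRUE # all missing: tolerated inside
    } else if (all(v == 0L)) {
      shareable[j] <- TRUE
      consensus[j] <- 0L
    } else if (all(v == 2L)) {
      shareable[j] <- TRUE
      consensus[j] <- 2L
    }
  }
  out <- list()
  for (i in seq_len(nm)) {
    for (j in i:nm) {
      if (!all(shareable[i:j])) next
      if (is.na(consensus[i]) || is.na(consensus[j])) next
      if (sum(!is.na(consensus[i:j])) < min_markers) next
      left_ext <- i > 1 && shareable[i - 1]
      right_ext <- j < nm && shareable[j + 1]
      # maximal after trimming: extensions by gap markers do not count
      if (left_ext && any(!is.na(consensus[1:(i - 1)])
      & sapply(1:(i - 1), function(k) all(shareable[k:j])))) {
        next
      }
      if (right_ext && any(!is.na(consensus[(j + 1):nm])
      & sapply((j + 1):nm, function(k) all(shareable[i:k])))) {
        next
      }
      out[[length(out) + 1]] <- c(start = positions[i], end = positions[j])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start_bp = numeric(), end_bp = numeric()))
  }
  res <- tibble::as_tibble(do.call(rbind, out))
  names(res) <- c("start_bp", "end_bp")
  dplyr::distinct(dplyr::arrange(res, start_bp))
}

# direct re-application of the five caller rules, one comparison at a time
oracle_filter <- function(row, t) {
  row$unique_read_support >= t$min_unique_reads &&
    row$first25_support >= t$min_first25 &&
    row$raw_coverage >= t$min_coverage &&
    row$base_quality >= t$min_base_quality &&
    row$alt_fraction >= t$min_alt_fraction
}

# phased two-locus haplotype sample with known disequilibrium D
sample_phased_pair <- function(n, pa, pb, D) {
  p <- c((1 - pa) * (1 - pb) + D, (1 - pa) * pb - D, pa * (1 - pb) - D, pa * pb + D)
  stopifnot(all(p >= -1e-12))
  p <- pmax(p, 0)
  h1 <- sample(1:4, n, TRUE, p)
  h2 <- sample(1:4, n, TRUE, p)
  alt_a <- c(0L, 0L, 1L, 1L)
  alt_b <- c(0L, 1L, 0L, 1L)
  hc <- tabulate(c(h1, h2), 4) / (2 * n)
  paa <- hc[3] + hc[4]
  pbb <- hc[2] + hc[4]
  r2_phased <- if (paa %in% c(0, 1) || pbb %in% c(0, 1)) {
    NA_real_
  } else {
    (hc[4] - paa * pbb)^2 / (paa * (1 - paa) * pbb * (1 - pbb))
  }
  list(
    a = alt_a[h1] + alt_a[h2],
    b = alt_b[h1] + alt_b[h2],
    r2_phased = r2_phased
  )
}
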