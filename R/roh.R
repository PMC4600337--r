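#' Runs of homozygosity per sample
#'
#' A run is a maximal stretch of consecutive markers (in map order, per
#' chromosome) at which the sample is homozygous (dosage 0 or 2, either
#' allele).  A heterozygous marker terminates a run; missing genotypes are
#' tolerated inside a run but cannot be its first or last marker.  Runs with
#' fewer than `min_markers` homozygous markers are discarded.  Boundaries are
#' the positions of the first and last homozygous markers.
#'
#' @param genotypes genotype tibble.
#' @param map marker map matching `genotypes`.
#' @param min_markers minimum number of homozygous markers per run
#'   (default 3).
#' @return Tibble: `sample_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_markers` (homozygous markers in the run), `start_marker`,
#'   `end_marker`.
#' @export
homozygous_runs <- function(genotypes, map, min_markers = 3) {
  check_geno_map(genotypes, map)
  G <- geno_matrix(genotypes)
  out <- vector("list", 0)
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    pos <- map$position_bp[idx]
    ids <- map$marker_id[idx]
    for (s in seq_len(nrow(G))) {
      runs <- hom_runs_one(G[s, idx])
      for (r in runs) {
        if (length(r$hom) < min_markers) next
        out[[length(out) + 1]] <- tibble::tibble(
          sample_id = genotypes$sample_id[s],
          chromosome = chr,
          start_bp = pos[r$hom[1]],
          end_bp = pos[r$hom[length(r$hom)]],
          n_markers = length(r$hom),
          start_marker = ids[r$hom[1]],
          end_marker = ids[r$hom[length(r$hom)]]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      sample_id = character(), chromosome = character(),
      start_bp = numeric(), end_bp = numeric(), length_bp = numeric(),
      n_markers = integer(), start_marker = character(), end_marker = character()
    ))
  }
  dplyr::mutate(
    dplyr::bind_rows(out),
    length_bp = .data$end_bp - .data$start_bp + 1, .after = "end_bp"
  )
}

# split one sample's code vector at heterozygous markers; each block keeps the
# indices (relative to the vector) of its homozygous (non-NA) markers
hom_runs_one <- function(codes) {
  het <- !is.na(codes) & codes == 1L
  grp <- cumsum(het)
  keep <- !het
  idx_by_block <- split(which(keep), grp[keep])
  lapply(idx_by_block, function(ix) list(hom = ix[!is.na(codes[ix])]))
}

#' Regions shared homozygous identical-by-state across all cases
#'
#' Finds maximal stretches of consecutive markers at which every case is
#' homozygous for the identical allele (identical-by-state; opposite
#' homozygotes break sharing, as does any heterozygous case).  Missing case
#' genotypes are tolerated: a marker's shared allele is the consensus of the
#' non-missing case homozygotes, and markers where all cases are missing may
#' sit inside a region but not at its ends.  For every region, controls
#' sharing it are counted: a control shares iff it is homozygous for the
#' consensus allele at every consensus marker of the region (a missing
#' genotype disqualifies).
#'
#' @param genotypes genotype tibble containing cases and controls.
#' @param map marker map matching `genotypes`.
#' @param min_markers minimum number of consensus markers per region
#'   (default 3).
#' @param region optional list `list(chromosome =, start_bp =, end_bp =)`
#'   restricting the search to a window of interest.
#' @return Tibble of class `shared_regions`, one row per region in genome
#'   order: `chromosome`, `start_bp`, `end_bp`, `length_bp`, `length_mb`,
#'   `n_markers`, `n_cases_sharing`, `n_controls_sharing`, plus list-columns
#'   `marker_ids` and `shared_codes` (consensus dosage, 0 or 2, per consensus
#'   marker).  Empty tibble when no region is shared.
#' @export
shared_homozygous_regions <- function(genotypes, map, min_markers = 3,
                                      region = NULL) {
  check_geno_map(genotypes, map)
  if (sum(genotypes$phenotype == "case") < 2) {
    abort("shared-homozygosity mapping needs at least 2 cases.")
  }
  sel <- rep(TRUE, nrow(map))
  if (!is.null(region)) {
    sel <- map$chromosome == region$chromosome &
      map$position_bp >= region$start_bp & map$position_bp <= region$end_bp
  }
  out <- vector("list", 0)
  G <- geno_matrix(genotypes)
  is_case <- genotypes$phenotype == "case"
  is_control <- genotypes$phenotype == "control"

  for (chr in unique(map$chromosome[sel])) {
    idx <- which(sel & map$chromosome == chr)
    Gc <- G[is_case, idx, drop = FALSE]
    # per-marker state: consensus hom code, NA = all cases missing (gap),
    # -1 = sharing broken (het case or conflicting homozygotes)
    n0 <- colSums(Gc == 0L, na.rm = TRUE)
    n1 <- colSums(Gc == 1L, na.rm = TRUE)
    n2 <- colSums(Gc == 2L, na.rm = TRUE)
    nn <- n0 + n1 + n2
    state <- rep(-1L, length(idx))
    state[nn == 0] <- NA_integer_
    state[n1 == 0 & n2 == 0 & n0 > 0] <- 0L
    state[n1 == 0 & n0 == 0 & n2 > 0] <- 2L

    blocks <- split(seq_along(idx), cumsum(!is.na(state) & state == -1L))
    for (b in blocks) {
      b <- b[is.na(state[b]) | state[b] != -1L]
      cons <- b[!is.na(state[b])]
      if (length(cons) < min_markers) next
      b <- b[b >= cons[1] & b <= cons[length(cons)]] # trim gap ends
      mk <- idx[cons]
      codes <- state[cons]
      Gctrl <- G[is_control, mk, drop = FALSE]
      sharing <- colSums(
        t(Gctrl) == codes & !is.na(t(Gctrl))
      ) == length(codes)
      out[[length(out) + 1]] <- tibble::tibble(
        chromosome = chr,
        start_bp = map$position_bp[mk[1]],
        end_bp = map$position_bp[mk[length(mk)]],
        n_markers = length(cons),
        n_cases_sharing = sum(is_case),
        n_controls_sharing = sum(sharing),
        marker_ids = list(map$marker_id[idx[b]]),
        shared_codes = list(stats::setNames(codes, map$marker_id[mk]))
      )
    }
  }
  if (length(out) == 0) {
    res <- tibble::tibble(
      chromosome = character(), start_bp = numeric(), end_bp = numeric(),
      length_bp = numeric(), length_mb = numeric(), n_markers = integer(),
      n_cases_sharing = integer(), n_controls_sharing = integer(),
      marker_ids = list(), shared_codes = list()
    )
  } else {
    res <- dplyr::mutate(
      dplyr::arrange(dplyr::bind_rows(out), .data$chromosome, .data$start_bp),
      length_bp = .data$end_bp - .data$start_bp + 1,
      length_mb = region_length_mb(.data$start_bp, .data$end_bp),
      .after = "end_bp"
    )
  }
  structure(res, class = c("shared_regions", class(res)))
}

#' Rank candidate shared regions
#'
#' Orders regions the way a mapping study reads them: most cases sharing
#' first, then fewest controls sharing, then longest; ties broken by start
#' coordinate so the order is deterministic.
#'
#' @param regions tibble of regions (e.g. from
#'   [shared_homozygous_regions()]) with columns `n_cases_sharing`,
#'   `n_controls_sharing`, `length_bp`, `start_bp`.
#' @return The same tibble, reordered.
#' @export
rank_regions <- function(regions) {
  dplyr::arrange(
    regions,
    dplyr::desc(.data$n_cases_sharing),
    .data$n_controls_sharing,
    dplyr::desc(.data$length_bp),
    .data$start_bp
  )
}

#' Region length in megabases
#'
#' Length of a 1-based inclusive interval, in Mb, rounded half-up to two
#' decimals (reporting convention).
#'
#' @param start_bp,end_bp 1-based inclusive interval bounds.
#' @return `(end_bp - start_bp + 1) / 1e6`, rounded to 2 decimals.
#' @export
#' @examples
#' region_length_mb(74897451, 76370694) # 1.47
region_length_mb <- function(start_bp, end_bp) {
  if (any(end_bp < start_bp)) abort("`end_bp` must be >= `start_bp`.")
  round_half_up((end_bp - start_bp + 1) / 1e6, 2)
}

#' Colour-coded genotypes over a candidate region
#'
#' Classifies every sample's genotype at each consensus marker of a shared
#' region against the disease-associated allele (the allele homozygous in
#' cases): `associated_hom`, `het`, `normal_hom` or `missing`.  The long
#' table feeds a tile plot of the region (cases red, carriers yellow in the
#' classical display) or TSV export.
#'
#' @param genotypes genotype tibble.
#' @param map marker map matching `genotypes`.
#' @param region one row of a [shared_homozygous_regions()] result (or any
#'   list with a `shared_codes` named vector of consensus dosages).
#' @return Tibble of class `region_codes`: `sample_id`, `phenotype`,
#'   `marker_id`, `position_bp`, `state`.
#' @export
genotype_region_codes <- function(genotypes, map, region) {
  check_geno_map(genotypes, map)
  codes <- region$shared_codes
  if (is.list(codes)) codes <- codes[[1]]
  mk <- names(codes)
  long <- tidyr::pivot_longer(
    genotypes[, c("sample_id", "phenotype", mk)],
    cols = dplyr::all_of(mk), names_to = "marker_id", values_to = "dosage"
  )
  long$position_bp <- map$position_bp[match(long$marker_id, map$marker_id)]
  assoc <- codes[long$marker_id]
  long$state <- dplyr::case_when(
    is.na(long$dosage) ~ "missing",
    long$dosage == 1L ~ "het",
    long$dosage == assoc ~ "associated_hom",
    TRUE ~ "normal_hom"
  )
  out <- long[, c("sample_id", "phenotype", "marker_id", "position_bp", "state")]
  structure(out, class = c("region_codes", class(out)))
}

#' @rdname genotype_region_codes
#' @param object a `region_codes` tibble.
#' @param ... unused.
#' @method autoplot region_codes
#' @export
autoplot.region_codes <- function(object, ...) {
  d <- dplyr::arrange(tibble::as_tibble(object), .data$phenotype, .data$sample_id)
  d$sample_id <- factor(d$sample_id, levels = unique(d$sample_id))
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$sample_id, y = factor(.data$position_bp),
                 fill = .data$state)
  ) +
    ggplot2::geom_tile(colour = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(
      associated_hom = "#c0392b", het = "#f1c40f",
      normal_hom = "#27ae60", missing = "black"
    )) +
    ggplot2::labs(x = NULL, y = "marker position (bp)", fill = "genotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
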