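#' Configuration for the founder-population simulator
#'
#' Bundles the parameters of [simulate_population()].  Defaults emulate the
#' discovery cohort of a lethal congenital defect in a closed, inbred horse
#' population: 13 genotyped cases, 69 controls and 17 obligate-carrier dams
#' typed on a dense SNP array, with every case autozygous for a multi-Mb
#' founder haplotype around the disease locus.
#'
#' @param n_cases,n_controls,n_obligate_carriers sample sizes per phenotype
#'   class.  Obligate carriers (dams of affected offspring) carry exactly one
#'   copy of the founder haplotype.
#' @param n_markers number of SNP markers on the simulated chromosome
#'   (at least 10).
#' @param marker_spacing_bp distance between adjacent markers, bp.
#' @param chromosome chromosome label written to the marker map.
#' @param disease_locus_marker 1-based index of the marker carrying the
#'   causal allele.
#' @param carrier_frequency probability that a non-case haplotype is the
#'   founder (disease) haplotype; equals the population frequency of the
#'   disease allele.  Must be < 1.
#' @param case_ibd_length_mean_bp mean length, in bp, of the
#'   homozygous-by-descent (autozygous) segment of a case around the disease
#'   locus.  Each haplotype's founder segment extends left and right of the
#'   locus by independent exponential lengths with mean equal to this value,
#'   so the intersected autozygous segment of a case has mean length equal to
#'   it as well.
#' @param genotyping_error_rate per-genotype probability of a single-step
#'   error (homozygote mis-typed as heterozygote; heterozygote as either
#'   homozygote with equal probability).
#' @param missing_rate per-genotype probability of a no-call.
#' @param seed integer seed; simulation output is a pure function of the
#'   configuration.
#' @return A list of class `sim_config`.
#' @seealso [simulate_population()]
#' @export
sim_config <- function(n_cases = 13, n_controls = 69, n_obligate_carriers = 17,
                       n_markers = 1200, marker_spacing_bp = 50000,
                       chromosome = "1", disease_locus_marker = 600,
                       carrier_frequency = 0.085,
                       case_ibd_length_mean_bp = 10.5e6,
                       genotyping_error_rate = 0.001,
                       missing_rate = 0.004, seed = 1L) {
  if (n_markers < 10) abort("`n_markers` must be at least 10.")
  if (disease_locus_marker < 1 || disease_locus_marker > n_markers) {
    abort("`disease_locus_marker` must be a 1-based index within `n_markers`.")
  }
  check_probability(carrier_frequency, "carrier_frequency")
  check_probability(genotyping_error_rate, "genotyping_error_rate")
  check_probability(missing_rate, "missing_rate")
  if (carrier_frequency >= 1) {
    abort("`carrier_frequency` must be < 1: controls free of the founder homozygote would be impossible.")
  }
  if (case_ibd_length_mean_bp <= 0) abort("`case_ibd_length_mean_bp` must be positive.")
  if (n_cases < 1 || n_controls < 1) abort("need at least one case and one control.")
  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      n_obligate_carriers = as.integer(n_obligate_carriers),
      n_markers = as.integer(n_markers),
      marker_spacing_bp = as.numeric(marker_spacing_bp),
      chromosome = as.character(chromosome),
      disease_locus_marker = as.integer(disease_locus_marker),
      carrier_frequency = carrier_frequency,
      case_ibd_length_mean_bp = case_ibd_length_mean_bp,
      genotyping_error_rate = genotyping_error_rate,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a founder population segregating a recessive lethal haplotype
#'
#' Generates SNP-array genotypes for cases, controls and obligate carriers on
#' one chromosome.  A single founder haplotype carries the alternative
#' (disease) allele at the disease locus; outside the founder haplotype the
#' disease allele does not occur, as expected for a recent mutation.  Every
#' case inherits the founder haplotype on both chromosomes over an interval
#' containing the locus (independent exponential extents on each side of the
#' locus per haplotype, intersected and snapped to marker positions), so the
#' shared autozygous region shrinks as cases accumulate.  Control haplotypes
#' are founder with probability `carrier_frequency`, but a control is never
#' homozygous founder at the disease locus; obligate carriers carry exactly
#' one founder haplotype.  Marker alternative-allele frequencies are drawn
#' uniformly on \[0.05, 0.5\] so unlinked markers pass a 5 % MAF filter by
#' design.  Genotyping error (symmetric single-step flips) and missingness
#' are applied last.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `founder_sim` with elements
#'   \describe{
#'     \item{genotypes}{tibble, one row per sample: `sample_id`, `phenotype`,
#'       then one integer dosage column (0/1/2/NA) per marker.}
#'     \item{map}{marker map tibble: `marker_id`, `chromosome`,
#'       `position_bp`, `allele_ref`, `allele_alt`.}
#'     \item{truth}{list of class `truth_record`: `disease_marker_index`,
#'       `disease_marker_id`, `disease_position_bp`, `founder_haplotype`
#'       (0/1 allele vector over markers), `case_ibd` (tibble `sample_id`,
#'       `start_bp`, `end_bp` of each case's autozygous segment, marker
#'       snapped), `true_genotypes` (genotype tibble before error and
#'       missingness), and the `config`.}
#'   }
#' @export
#' @examples
#' sim <- simulate_population(sim_config(n_markers = 50, disease_locus_marker = 25))
#' dim(sim$genotypes)
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a `sim_config` object.")
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  nm <- config$n_markers
  positions <- (seq_len(nm) - 1) * config$marker_spacing_bp + 1
  locus <- config$disease_locus_marker
  locus_pos <- positions[locus]
  L <- config$case_ibd_length_mean_bp

  # population alt-allele frequencies; the disease allele exists only on the
  # founder haplotype
  p_alt <- runif(nm, 0.05, 0.5)
  founder <- rbinom(nm, 1, p_alt)
  founder[locus] <- 1L
  p_alt[locus] <- 0

  random_hap <- function() rbinom(nm, 1, p_alt)

  # founder-descent haplotype: founder alleles over an interval containing
  # the locus, random population alleles elsewhere
  founder_hap <- function() {
    ext <- rexp(2, rate = 1 / L)
    lo <- locus_pos - ext[1]
    hi <- locus_pos + ext[2]
    hap <- random_hap()
    inside <- positions >= lo & positions <= hi
    hap[inside] <- founder[inside]
    list(hap = hap, lo = lo, hi = hi)
  }

  ids <- c(
    sprintf("case_%02d", seq_len(config$n_cases)),
    sprintf("control_%02d", seq_len(config$n_controls)),
    if (config$n_obligate_carriers > 0) {
      sprintf("carrier_%02d", seq_len(config$n_obligate_carriers))
    }
  )
  phen <- rep(
    PHENOTYPE_LEVELS,
    c(config$n_cases, config$n_controls, config$n_obligate_carriers)
  )

  G <- matrix(0L, nrow = length(ids), ncol = nm)
  ibd <- vector("list", config$n_cases)

  for (i in seq_len(config$n_cases)) {
    h1 <- founder_hap()
    h2 <- founder_hap()
    G[i, ] <- h1$hap + h2$hap
    lo <- max(h1$lo, h2$lo)
    hi <- min(h1$hi, h2$hi)
    inside <- which(positions >= lo & positions <= hi)
    ibd[[i]] <- c(positions[inside[1]], positions[inside[length(inside)]])
  }
  for (i in seq_len(config$n_controls)) {
    f1 <- runif(1) < config$carrier_frequency
    f2 <- runif(1) < config$carrier_frequency
    if (f1 && f2) f2 <- FALSE # a founder homozygote would be an (unviable) case
    h1 <- if (f1) founder_hap()$hap else random_hap()
    h2 <- if (f2) founder_hap()$hap else random_hap()
    G[config$n_cases + i, ] <- h1 + h2
  }
  if (config$n_obligate_carriers > 0) {
    for (i in seq_len(config$n_obligate_carriers)) {
      G[config$n_cases + config$n_controls + i, ] <-
        founder_hap()$hap + random_hap()
    }
  }

  marker_ids <- sprintf("M%05d", seq_len(nm))
  base_pairs <- matrix(
    replicate(nm, sample(c("A", "C", "G", "T"), 2, replace = FALSE)),
    nrow = 2
  )
  map <- tibble::tibble(
    marker_id = marker_ids,
    chromosome = config$chromosome,
    position_bp = positions,
    allele_ref = base_pairs[1, ],
    allele_alt = base_pairs[2, ]
  )
  colnames(G) <- marker_ids
  true_geno <- as_geno_tibble(G, ids, phen)

  # symmetric single-step genotyping errors, then independent missingness
  Gobs <- G
  if (config$genotyping_error_rate > 0) {
    err <- matrix(runif(length(G)) < config$genotyping_error_rate, nrow = nrow(G))
    hom <- err & (G != 1L)
    het <- err & (G == 1L)
    Gobs[hom] <- 1L
    Gobs[het] <- 2L * (runif(sum(het)) < 0.5)
  }
  if (config$missing_rate > 0) {
    Gobs[matrix(runif(length(G)) < config$missing_rate, nrow = nrow(G))] <- NA_integer_
  }
  genotypes <- as_geno_tibble(Gobs, ids, phen)

  truth <- structure(
    list(
      disease_marker_index = locus,
      disease_marker_id = marker_ids[locus],
      disease_position_bp = locus_pos,
      founder_haplotype = founder,
      case_ibd = tibble::tibble(
        sample_id = ids[seq_len(config$n_cases)],
        start_bp = vapply(ibd, `[`, numeric(1), 1),
        end_bp = vapply(ibd, `[`, numeric(1), 2)
      ),
      true_genotypes = true_geno,
      config = config
    ),
    class = "truth_record"
  )
  structure(
    list(genotypes = genotypes, map = map, truth = truth),
    class = "founder_sim"
  )
}

#' @export
print.founder_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "<founder_sim> %d cases, %d controls, %d obligate carriers x %d markers (chr %s)\n",
    cfg$n_cases, cfg$n_controls, cfg$n_obligate_carriers, cfg$n_markers,
    cfg$chromosome
  ))
  cat(sprintf(
    "  disease locus: %s at %s bp (marker %d); seed %d\n",
    x$truth$disease_marker_id, format(x$truth$disease_position_bp, big.mark = ","),
    x$truth$disease_marker_index, cfg$seed
  ))
  invisible(x)
}

#' Simulate per-sample read pileups at variant sites
#'
#' Emulates targeted-resequencing pileup summaries consistent with the
#' underlying genotypes: per sample and site, read depth is
#' Poisson(`mean_depth`) and the alternative-supporting read count is
#' Binomial(depth, f) with f equal to `base_error_rate`, 0.5 and
#' 1 - `base_error_rate` for dosages 0, 1 and 2.  Supporting observations
#' fall within the first 25 read bases with probability 25/`read_length`,
#' and the site-level mean base quality of supporting bases is drawn around
#' 30 on the phred scale.
#'
#' @param genotypes genotype tibble (typically `truth$true_genotypes` from
#'   [simulate_population()]); genotypes at the selected sites must be
#'   non-missing.
#' @param map marker map matching `genotypes`.
#' @param sites marker ids at which to generate pileups (default: all).
#' @param mean_depth mean read depth per sample and site (must be > 0);
#'   default 216, a typical deep targeted-capture coverage.
#' @param base_error_rate per-read probability of a miscalled base.
#' @param seed integer seed.
#' @param read_length read length in bp, used for the first-25-base model.
#' @return Tibble with one row per sample x site: `sample_id`, `chromosome`,
#'   `position_bp`, `ref_base`, `alt_base`, `unique_read_support`,
#'   `first25_support`, `raw_coverage`, `base_quality`, `alt_fraction`.
#' @export
simulate_pileups <- function(genotypes, map, sites = NULL, mean_depth = 216,
                             base_error_rate = 0.001, seed = 1L,
                             read_length = 50) {
  if (mean_depth <= 0) abort("`mean_depth` must be positive.")
  check_probability(base_error_rate, "base_error_rate")
  check_geno_map(genotypes, map)
  sites <- sites %||% map$marker_id
  if (!all(sites %in% map$marker_id)) {
    abort("all `sites` must be marker ids present in `map`.")
  }
  sub <- map[match(sites, map$marker_id), ]
  G <- geno_matrix(genotypes)[, sites, drop = FALSE]
  if (anyNA(G)) abort("genotypes at pileup sites must be non-missing.")

  withr::with_seed(seed, {
    n <- length(G)
    code <- as.vector(G) # sample-major within site columns
    f <- c(base_error_rate, 0.5, 1 - base_error_rate)[code + 1L]
    cov <- rpois(n, mean_depth)
    alt <- rbinom(n, cov, f)
    first25 <- rbinom(n, alt, min(1, 25 / read_length))
    qual <- pmin(41, pmax(2, round(rnorm(n, 30, 3))))
    tibble::tibble(
      sample_id = rep(genotypes$sample_id, times = length(sites)),
      chromosome = rep(sub$chromosome, each = nrow(G)),
      position_bp = rep(sub$position_bp, each = nrow(G)),
      ref_base = rep(sub$allele_ref, each = nrow(G)),
      alt_base = rep(sub$allele_alt, each = nrow(G)),
      unique_read_support = alt,
      first25_support = first25,
      raw_coverage = cov,
      base_quality = as.numeric(qual),
      alt_fraction = ifelse(cov > 0, alt / cov, 0)
    )
  })
}
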