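#' Configuration of the end-to-end mapping pipeline
#'
#' @param sim a [sim_config()] describing the simulated cohort, or NULL to
#'   read genotypes from `ped_path`/`map_path` (variant-calling stages then
#'   require a `pileup` table).
#' @param ped_path,map_path PLINK-dialect text inputs, used when `sim` is
#'   NULL.
#' @param maf_min,marker_cr_min,sample_cr_min QC thresholds.
#' @param alpha family-wise significance level for the scan.
#' @param min_roh_markers minimum consensus markers per shared region.
#' @param thresholds a [caller_thresholds()] object.
#' @param het_band heterozygote alt-fraction band for genotyping.
#' @param mean_depth,base_error_rate pileup simulation parameters (simulated
#'   runs only).
#' @param seed integer seed for the pileup stage.
#' @param out_dir output directory for per-stage TSVs, or NULL to skip
#'   writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), ped_path = NULL, map_path = NULL,
                            maf_min = 0.05, marker_cr_min = 0.90,
                            sample_cr_min = 0.90, alpha = 0.05,
                            min_roh_markers = 3,
                            thresholds = caller_thresholds(),
                            het_band = c(0.15, 0.85),
                            mean_depth = 216, base_error_rate = 0.001,
                            seed = 1L, out_dir = NULL) {
  check_probability(alpha, "alpha")
  structure(
    list(
      sim = sim, ped_path = ped_path, map_path = map_path,
      maf_min = maf_min, marker_cr_min = marker_cr_min,
      sample_cr_min = sample_cr_min, alpha = alpha,
      min_roh_markers = min_roh_markers, thresholds = thresholds,
      het_band = het_band, mean_depth = mean_depth,
      base_error_rate = base_error_rate, seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full recessive-mapping workflow
#'
#' Executes the stages in discovery order: (simulated or file) genotypes ->
#' quality control -> genotypic chi-square scan -> shared-homozygosity
#' mapping and ranking -> pileup variant calling over the top-ranked region
#' -> recessive case/control concordance -> LD between the surviving
#' variants and the region's markers.  Per-stage tables are written to
#' `config$out_dir` (when set) with provenance headers recording seed and
#' thresholds.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result`: `qc`, `scan`, `regions`
#'   (ranked), `top_region`, `calls`, `concordance`, `concordant_sites`,
#'   `ld` (LD of each concordant site with the region's markers),
#'   `summary` (one-row tibble) and `success` (TRUE iff at least one
#'   concordant variant survived).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  meta <- list(
    seed = config$seed, alpha = config$alpha, maf_min = config$maf_min,
    marker_cr_min = config$marker_cr_min, sample_cr_min = config$sample_cr_min,
    caller = unlist(unclass(config$thresholds))
  )
  emit <- function(x, file, extra = list()) {
    if (!is.null(config$out_dir)) {
      if (!dir.exists(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE)
      }
      write_report_tsv(x, file.path(config$out_dir, file), c(meta, extra))
    }
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_population(config$sim))
    genotypes <- sim$genotypes
    map <- sim$map
    truth <- sim$truth
  } else {
    inp <- stage("read", read_ped_map(config$ped_path, config$map_path))
    genotypes <- inp$genotypes
    map <- inp$map
  }

  qc <- stage("qc", apply_qc(
    genotypes, map, config$maf_min, config$marker_cr_min, config$sample_cr_min
  ))
  emit(qc$report, "qc_report.tsv")

  scan <- stage("gwas", assoc_scan(qc$genotypes, qc$map, alpha = config$alpha))
  emit(tidy(scan), "association.tsv", list(threshold = attr(scan, "threshold")))

  regions <- stage("roh", rank_regions(shared_homozygous_regions(
    qc$genotypes, qc$map, min_markers = config$min_roh_markers
  )))
  emit(regions, "shared_regions.tsv")
  top_region <- if (nrow(regions) > 0) regions[1, ] else NULL

  calls <- concord <- concordant_sites <- ld <- NULL
  if (!is.null(top_region) && !is.null(truth)) {
    sites <- top_region$marker_ids[[1]]
    sites <- intersect(sites, names(top_region$shared_codes[[1]]))
    pile <- stage("pileup", simulate_pileups(
      truth$true_genotypes, map, sites = sites,
      mean_depth = config$mean_depth, base_error_rate = config$base_error_rate,
      seed = config$seed
    ))
    calls <- stage("call", call_variants(pile, config$thresholds, config$het_band))
    case_ids <- genotypes$sample_id[genotypes$phenotype == "case"]
    control_ids <- genotypes$sample_id[genotypes$phenotype == "control"]
    concord <- stage(
      "concordance",
      recessive_concordance(calls, case_ids, control_ids)
    )
    concordant_sites <- dplyr::filter(concord, .data$concordant)
    emit(concord, "concordance.tsv")

    if (nrow(concordant_sites) > 0) {
      region_markers <- names(top_region$shared_codes[[1]])
      G <- qc$genotypes
      ld <- dplyr::bind_rows(lapply(seq_len(nrow(concordant_sites)), function(i) {
        site_marker <- map$marker_id[
          map$position_bp == concordant_sites$position_bp[i] &
            map$chromosome == concordant_sites$chromosome[i]
        ][1]
        others <- setdiff(intersect(region_markers, names(G)), site_marker)
        if (is.na(site_marker) || !site_marker %in% names(G)) {
          return(NULL)
        }
        dplyr::bind_rows(lapply(others, function(m) {
          res <- tryCatch(
            ld_r2(G[[site_marker]], G[[m]]),
            error = function(e) NULL
          )
          if (is.null(res)) {
            return(NULL)
          }
          tibble::tibble(
            locus_a = site_marker, locus_b = m,
            r2 = res$r2, method = res$method
          )
        }))
      }))
      if (!is.null(ld) && nrow(ld) > 0) emit(ld, "ld.tsv")
    }
  }

  summary <- tibble::tibble(
    n_markers_post_qc = qc$report$n_markers_out,
    n_significant = sum(scan$significant),
    top_marker = glance(scan)$top_marker,
    n_regions = nrow(regions),
    top_region_chr = if (is.null(top_region)) NA_character_ else top_region$chromosome,
    top_region_start_bp = if (is.null(top_region)) NA_real_ else top_region$start_bp,
    top_region_end_bp = if (is.null(top_region)) NA_real_ else top_region$end_bp,
    top_region_length_mb = if (is.null(top_region)) NA_real_ else top_region$length_mb,
    top_region_controls_sharing = if (is.null(top_region)) NA_integer_ else top_region$n_controls_sharing,
    n_concordant = if (is.null(concordant_sites)) 0L else nrow(concordant_sites)
  )
  emit(summary, "summary.tsv")

  structure(
    list(
      qc = qc, scan = scan, regions = regions, top_region = top_region,
      calls = calls, concordance = concord,
      concordant_sites = concordant_sites, ld = ld,
      truth = truth, summary = summary,
      success = summary$n_concordant > 0
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf(
    "  markers post-QC: %d; significant: %d; top marker: %s\n",
    s$n_markers_post_qc, s$n_significant, s$top_marker
  ))
  if (!is.na(s$top_region_chr)) {
    cat(sprintf(
      "  top shared region: chr%s:%s-%s (%.2f Mb, %d controls sharing)\n",
      s$top_region_chr, format(s$top_region_start_bp, big.mark = ","),
      format(s$top_region_end_bp, big.mark = ","), s$top_region_length_mb,
      s$top_region_controls_sharing
    ))
  }
  cat(sprintf("  concordant variants surviving: %d\n", s$n_concordant))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) x$summary
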