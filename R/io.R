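# Text-format readers and writers: PLINK-dialect PED/MAP, VCF v4.2, and
# provenance-stamped TSV reports.  All coordinates are 1-based.

ped_phenotype_code <- c(case = "2", control = "1", obligate_carrier = "0")

#' Write genotypes as PLINK-dialect text PED/MAP
#'
#' PED: one row per sample with family id, sample id, paternal and maternal
#' ids (0), sex (0), phenotype (2 = case, 1 = control, 0 = obligate
#' carrier/unknown) and one allele pair per marker (missing written `0 0`).
#' MAP: chromosome, marker id, 0 (genetic distance placeholder), position
#' in bp.
#'
#' @param genotypes genotype tibble.
#' @param map marker map with allele columns (`allele_ref`, `allele_alt`).
#' @param ped_path,map_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(genotypes, map, ped_path, map_path) {
  check_geno_map(genotypes, map)
  G <- geno_matrix(genotypes)
  pair <- function(code, ref, alt) {
    dplyr::case_when(
      is.na(code) ~ "0 0",
      code == 0L ~ paste(ref, ref),
      code == 1L ~ paste(ref, alt),
      code == 2L ~ paste(alt, alt)
    )
  }
  allele_txt <- vapply(seq_len(nrow(G)), function(i) {
    paste(pair(G[i, ], map$allele_ref, map$allele_alt), collapse = " ")
  }, character(1))
  ped <- paste(
    genotypes$sample_id, genotypes$sample_id, 0, 0, 0,
    ped_phenotype_code[genotypes$phenotype], allele_txt
  )
  writeLines(ped, ped_path)
  readr::write_tsv(
    tibble::tibble(
      chromosome = map$chromosome, marker_id = map$marker_id,
      cm = 0, position_bp = format(map$position_bp, scientific = FALSE, trim = TRUE)
    ),
    map_path,
    col_names = FALSE
  )
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK-dialect text PED/MAP into a genotype table
#'
#' Allele pairs are recoded to dosages 0/1/2 (`0 0` is missing, the PLINK
#' convention).  Unless an allele-orientation sidecar is given, the minor
#' allele at each marker becomes the alternative allele (code 2 homozygote);
#' on a frequency tie the alphabetically later allele is alternative, so the
#' coding is deterministic.  Phenotype column 2/1/0 maps to
#' case/control/obligate_carrier.
#'
#' @param ped_path,map_path input file paths.
#' @param alleles optional tibble (`marker_id`, `allele_ref`, `allele_alt`)
#'   fixing the allele orientation, e.g. the map written by
#'   [write_ped_map()]; with it, read is the exact inverse of write.
#' @return List with `genotypes` and `map` (including the ref/alt alleles
#'   used for coding; NA alt for monomorphic markers).
#' @export
read_ped_map <- function(ped_path, map_path, alleles = NULL) {
  map_raw <- utils::read.table(
    map_path,
    col.names = c("chromosome", "marker_id", "cm", "position_bp"),
    colClasses = c("character", "character", "character", "numeric")
  )
  nm <- nrow(map_raw)
  for (chr in unique(map_raw$chromosome)) {
    if (is.unsorted(map_raw$position_bp[map_raw$chromosome == chr])) {
      abort(sprintf("MAP positions on chromosome %s are not sorted; sort the input.", chr))
    }
  }

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ids <- character(n)
  phen <- character(n)
  A1 <- matrix(NA_character_, n, nm)
  A2 <- matrix(NA_character_, n, nm)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * nm) {
      abort(sprintf(
        "PED line %d: %d genotype tokens found, expected %d (marker-count mismatch with MAP).",
        i, max(0, length(tok) - 6), 2 * nm
      ))
    }
    ids[i] <- tok[2]
    phen[i] <- c(`2` = "case", `1` = "control", `0` = "obligate_carrier")[tok[6]]
    if (is.na(phen[i])) {
      abort(sprintf("PED line %d: unrecognised phenotype code `%s`.", i, tok[6]))
    }
    al <- tok[-(1:6)]
    bad <- !al %in% c("A", "C", "G", "T", "0")
    if (any(bad)) {
      abort(sprintf(
        "PED line %d: malformed genotype token `%s`.", i, al[which(bad)[1]]
      ))
    }
    A1[i, ] <- al[seq(1, 2 * nm, by = 2)]
    A2[i, ] <- al[seq(2, 2 * nm, by = 2)]
  }
  A1[A1 == "0"] <- NA
  A2[A2 == "0"] <- NA
  if (any(is.na(A1) != is.na(A2))) {
    abort("half-missing genotype (one allele `0`): malformed PED.")
  }

  ref <- alt <- character(nm)
  if (!is.null(alleles)) {
    ix <- match(map_raw$marker_id, alleles$marker_id)
    if (anyNA(ix)) abort("allele sidecar does not cover every MAP marker.")
    ref <- alleles$allele_ref[ix]
    alt <- alleles$allele_alt[ix]
  } else {
    for (j in seq_len(nm)) {
      tab <- sort(table(c(A1[, j], A2[, j])), decreasing = TRUE)
      obs <- names(tab)
      if (length(obs) > 2) {
        abort(sprintf("marker %s has more than two alleles.", map_raw$marker_id[j]))
      }
      if (length(obs) == 0) {
        ref[j] <- NA; alt[j] <- NA
      } else if (length(obs) == 1) {
        ref[j] <- obs; alt[j] <- NA
      } else {
        # minor allele is alternative; alphabetical tie-break
        if (tab[1] == tab[2]) obs <- sort(obs)
        ref[j] <- obs[1]; alt[j] <- obs[2]
      }
    }
  }

  G <- matrix(NA_integer_, n, nm)
  for (j in seq_len(nm)) {
    G[, j] <- (A1[, j] == alt[j]) + (A2[, j] == alt[j])
    if (!is.na(ref[j])) {
      known <- !is.na(A1[, j])
      legal <- A1[, j] %in% c(ref[j], alt[j]) & A2[, j] %in% c(ref[j], alt[j])
      if (any(known & !legal)) {
        abort(sprintf(
          "marker %s: allele outside {%s, %s}.", map_raw$marker_id[j],
          ref[j], alt[j]
        ))
      }
      G[known & is.na(G[, j]), j] <- 0L # monomorphic: all ref
    }
  }
  colnames(G) <- map_raw$marker_id
  list(
    genotypes = as_geno_tibble(G, ids, phen),
    map = tibble::tibble(
      marker_id = map_raw$marker_id, chromosome = map_raw$chromosome,
      position_bp = map_raw$position_bp, allele_ref = ref, allele_alt = alt
    )
  )
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file of CDS sequences.
#' @return Named character vector of upper-case sequences.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write per-sample variant calls as VCF v4.2
#'
#' One record per discovered site, with the caller's rule outcomes as FILTER
#' (PASS when at least one sample passed every rule, otherwise the
#' semicolon-joined failed rules), recessive concordance in INFO and
#' per-sample genotypes as GT.
#'
#' @param calls per-sample call tibble from [call_variants()].
#' @param path output path.
#' @param concordance optional result of [recessive_concordance()] on the
#'   same calls; concordant sites gain `RECESSIVE_CONCORDANT` in INFO.
#' @param sample_order order of sample columns (default: first appearance).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(calls, path, concordance = NULL, sample_order = NULL) {
  samples <- sample_order %||% unique(calls$sample_id)
  gt_code <- c(homref = "0/0", het = "0/1", homalt = "1/1", nocall = "./.")
  rules <- c(
    "pass_unique_reads", "pass_first25", "pass_coverage",
    "pass_base_quality", "pass_alt_fraction"
  )
  fail_names <- c(
    pass_unique_reads = "unique_reads", pass_first25 = "first25",
    pass_coverage = "coverage", pass_base_quality = "base_quality",
    pass_alt_fraction = "alt_fraction"
  )

  sites <- dplyr::group_split(
    dplyr::group_by(calls, .data$chromosome, .data$position_bp,
                    .data$ref_base, .data$alt_base)
  )
  recs <- vapply(sites, function(d) {
    key <- d[1, c("chromosome", "position_bp", "ref_base", "alt_base")]
    filt <- if (any(d$pass)) {
      "PASS"
    } else {
      failed <- rules[!vapply(rules, function(r) any(d[[r]]), logical(1))]
      paste(fail_names[failed], collapse = ";")
    }
    info <- "."
    if (!is.null(concordance)) {
      m <- concordance$chromosome == key$chromosome &
        concordance$position_bp == key$position_bp &
        concordance$ref_base == key$ref_base &
        concordance$alt_base == key$alt_base
      if (any(m) && concordance$concordant[m][1]) info <- "RECESSIVE_CONCORDANT"
    }
    g <- stats::setNames(d$genotype, d$sample_id)[samples]
    g[is.na(g)] <- "nocall"
    paste(
      key$chromosome, format(key$position_bp, scientific = FALSE),
      ".", key$ref_base, key$alt_base, ".", filt, info, "GT",
      paste(gt_code[g], collapse = "\t"),
      sep = "\t"
    )
  }, character(1))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=recmapr",
    sprintf(
      "##FILTER=<ID=%s,Description=\"No sample passed the %s rule\">",
      unname(fail_names), unname(fail_names)
    ),
    "##INFO=<ID=RECESSIVE_CONCORDANT,Number=0,Type=Flag,Description=\"All cases homozygous alternative and no control homozygous alternative\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(
      c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
      collapse = "\t"
    )
  )
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Write a tibble as TSV with a provenance header
#'
#' Prepends `#`-prefixed comment lines recording the package version, the
#' seed and the thresholds in force, so every stage output is reproducible
#' from its own header.
#'
#' @param x data frame to write.
#' @param path output path.
#' @param meta named list of provenance values (seed, thresholds, ...).
#' @return Invisibly, `path`.
#' @export
write_report_tsv <- function(x, path, meta = list()) {
  meta <- c(
    list(package = paste0("recmapr ", as.character(utils::packageVersion("recmapr")))),
    meta
  )
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, function(v) {
    paste(format(unlist(v), trim = TRUE, scientific = FALSE), collapse = ",")
  }, character(1)))
  writeLines(hdr, path)
  # drop list-columns (marker lists etc.) from flat-file export
  flat <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  suppressWarnings(
    readr::write_tsv(flat, path, append = TRUE, col_names = TRUE)
  )
  invisible(path)
}

#' Parse the provenance header of a report TSV
#'
#' @param path file written by [write_report_tsv()].
#' @return Named character vector of the header fields.
#' @export
read_report_meta <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  stats::setNames(
    vapply(kv, `[`, character(1), 3),
    vapply(kv, `[`, character(1), 2)
  )
}
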