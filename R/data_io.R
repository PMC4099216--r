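#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom data.table fread fwrite data.table as.data.table :=
#' @importFrom stats median coef lm lm.fit pchisq pt fisher.test p.adjust
#'   quantile qnorm rnorm runif rbinom rlnorm sd setNames complete.cases
#' @importFrom utils head modifyList
NULL

REGION_CLASSES <- c("intergenic", "genic", "protein_coding")
PEAK_MARKS <- c("H3K27ac", "H3K4me1")

#' Read genomic regions from a BED file
#'
#' Regions are stored on disk as BED (0-based, half-open) with the name
#' column carrying the region id and an optional fifth column carrying the
#' region class (`intergenic`, `genic` or `protein_coding`). In memory they
#' are returned as a [GenomicRanges::GRanges] (1-based, closed), so the
#' 1-based inclusive span of a region equals `BED start + 1` to `BED end`.
#'
#' @param path Path to a BED3+ file (tab-separated, no header).
#' @return A `GRanges` with metadata columns `region_id` and `region_class`.
#' @export
read_regions <- function(path) {
  fields <- read_bed_lines(path, min_fields = 4L)
  n <- length(fields)
  if (n == 0L) {
    gr <- GRanges()
    mcols(gr)$region_id <- character(0)
    mcols(gr)$region_class <- character(0)
    return(gr)
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- bed_int(fields, 2L, path)
  end0 <- bed_int(fields, 3L, path)
  region_id <- vapply(fields, `[`, character(1), 4L)
  region_class <- vapply(fields, function(f) {
    if (length(f) >= 5L) f[5L] else "intergenic"
  }, character(1))
  bad <- which(start0 >= end0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d: start >= end (%d >= %d)",
                 path, bad[1L], start0[bad[1L]], end0[bad[1L]]))
  }
  if (anyDuplicated(region_id)) {
    stop(sprintf("%s: duplicate region ids: %s", path,
                 paste(unique(region_id[duplicated(region_id)]), collapse = ", ")))
  }
  unknown <- setdiff(unique(region_class), REGION_CLASSES)
  if (length(unknown) > 0L) {
    stop(sprintf("%s: unknown region class: %s", path,
                 paste(unknown, collapse = ", ")))
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  mcols(gr)$region_id <- region_id
  mcols(gr)$region_class <- region_class
  gr
}

#' Write genomic regions to a BED file
#'
#' Inverse of [read_regions()]; start coordinates are shifted back to the
#' 0-based BED convention so that a read/write cycle is byte-identical.
#'
#' @param regions A `GRanges` with `region_id` and `region_class` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  dt <- data.table(
    chrom = as.character(seqnames(regions)),
    start = start(regions) - 1L,
    end = end(regions),
    name = mcols(regions)$region_id,
    class = mcols(regions)$region_class
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read ChIP-seq peaks from a BED file
#'
#' Peak files are BED3 plus three typed columns: histone mark
#' (`H3K27ac`/`H3K4me1`), replicate id, and the peak-calling p-value.
#'
#' @param path Path to the peak BED file.
#' @return A `GRanges` with metadata columns `mark`, `replicate_id`, `peak_p`.
#' @export
read_peaks <- function(path) {
  fields <- read_bed_lines(path, min_fields = 6L)
  n <- length(fields)
  if (n == 0L) {
    gr <- GRanges()
    mcols(gr)$mark <- character(0)
    mcols(gr)$replicate_id <- character(0)
    mcols(gr)$peak_p <- numeric(0)
    return(gr)
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- bed_int(fields, 2L, path)
  end0 <- bed_int(fields, 3L, path)
  mark <- vapply(fields, `[`, character(1), 4L)
  replicate_id <- vapply(fields, `[`, character(1), 5L)
  peak_p <- as.numeric(vapply(fields, `[`, character(1), 6L))
  bad <- which(start0 >= end0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d: start >= end", path, bad[1L]))
  }
  if (any(is.na(peak_p)) || any(peak_p <= 0) || any(peak_p > 1)) {
    stop(sprintf("%s: peak p-values must lie in (0, 1]", path))
  }
  unknown <- setdiff(unique(mark), PEAK_MARKS)
  if (length(unknown) > 0L) {
    stop(sprintf("%s: unknown mark: %s", path, paste(unknown, collapse = ", ")))
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  mcols(gr)$mark <- mark
  mcols(gr)$replicate_id <- replicate_id
  mcols(gr)$peak_p <- peak_p
  gr
}

#' Write peaks to a BED file
#' @param peaks A `GRanges` as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  dt <- data.table(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    mark = mcols(peaks)$mark,
    replicate_id = mcols(peaks)$replicate_id,
    peak_p = format(mcols(peaks)$peak_p, trim = TRUE)
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read the SNP panel
#'
#' The panel TSV has columns `snp_id`, `chrom`, `pos` (1-based), `allele_a`,
#' `allele_b`. SNP ids must be unique and the two alleles must differ; the
#' allele labels are treated as abstract (no strand flipping is ever done).
#'
#' @param path Path to the panel TSV.
#' @return A `data.frame` with one row per SNP.
#' @export
read_snp_panel <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("snp_id", "chrom", "allele_a", "allele_b"),
    integer = "pos"
  ))
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(dt))) {
    stop(sprintf("%s: panel must have columns %s", path,
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(dt$snp_id)) {
    stop(sprintf("%s: duplicate snp ids", path))
  }
  if (any(dt$pos < 1L)) stop(sprintf("%s: positions must be >= 1", path))
  if (any(dt$allele_a == dt$allele_b)) {
    stop(sprintf("%s: allele_a must differ from allele_b", path))
  }
  as.data.frame(dt)
}

#' Write the SNP panel
#' @param panel A panel `data.frame` (see [read_snp_panel()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_panel <- function(panel, path) {
  fwrite(as.data.table(panel), path, sep = "\t")
  invisible(path)
}

#' Read a sample-by-SNP matrix from TSV
#'
#' The header row carries SNP ids and the first column sample ids. Missing
#' cells are written as `NA` (never 0 -- a zero is a legal intensity).
#'
#' @param path Path to the TSV.
#' @param panel Optional SNP panel; when given, every column id must be a
#'   panel SNP id and the call errors listing any offenders.
#' @param numeric Coerce cells to numeric (`TRUE`, intensities) or leave as
#'   character (`FALSE`, genotype calls / phased haplotypes).
#' @return A matrix with sample-id rownames and SNP-id colnames.
#' @export
read_matrix <- function(path, panel = NULL, numeric = TRUE) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = "NA")
  if (ncol(dt) < 1L) stop(sprintf("%s: empty matrix file", path))
  sample_ids <- dt[[1L]]
  snp_ids <- names(dt)[-1L]
  if (!is.null(panel)) {
    missing_ids <- setdiff(snp_ids, panel$snp_id)
    if (length(missing_ids) > 0L) {
      stop(sprintf("%s: SNP ids absent from panel: %s", path,
                   paste(missing_ids, collapse = ", ")))
    }
  }
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (numeric) {
    storage.mode(m) <- "numeric"
  }
  dimnames(m) <- list(sample_ids, snp_ids)
  m
}

#' Write a sample-by-SNP matrix to TSV
#' @param m Matrix with sample rownames and SNP colnames.
#' @param path Output path.
#' @param id_col Name for the sample-id column (first header field).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "sample_id") {
  dt <- data.table(rownames(m))
  setnames_dt(dt, 1L, id_col)
  for (j in seq_len(ncol(m))) {
    dt[[colnames(m)[j]]] <- m[, j]
  }
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read phased haplotypes
#'
#' Phased genotypes are stored as a sample-by-SNP matrix of `"a|b"` strings,
#' where `a` is the allele on haplotype 1 and `b` on haplotype 2, each coded
#' 0 (allele A) or 1 (allele B). Orientation is taken as given; no
#' re-phasing is performed.
#'
#' @param path Path to the phased TSV.
#' @param panel Optional SNP panel for id validation.
#' @return A list with integer 0/1 matrices `hap1` and `hap2` (NA = missing).
#' @export
read_phased <- function(path, panel = NULL) {
  m <- read_matrix(path, panel = panel, numeric = FALSE)
  split_phased(m)
}

split_phased <- function(m) {
  parse_one <- function(v, which) {
    out <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    parts <- strsplit(v[ok], "|", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed phased genotype (expected 'a|b')")
    out[ok] <- as.integer(vapply(parts, `[`, character(1), which))
    out
  }
  hap1 <- matrix(parse_one(as.vector(m), 1L), nrow(m), ncol(m), dimnames = dimnames(m))
  hap2 <- matrix(parse_one(as.vector(m), 2L), nrow(m), ncol(m), dimnames = dimnames(m))
  stopifnot(all(hap1 %in% c(0L, 1L, NA)), all(hap2 %in% c(0L, 1L, NA)))
  list(hap1 = hap1, hap2 = hap2)
}

#' Write phased haplotypes
#' @param phased List with matrices `hap1`, `hap2`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased <- function(phased, path) {
  m <- matrix(NA_character_, nrow(phased$hap1), ncol(phased$hap1),
              dimnames = dimnames(phased$hap1))
  ok <- !is.na(phased$hap1) & !is.na(phased$hap2)
  m[ok] <- paste0(phased$hap1[ok], "|", phased$hap2[ok])
  write_matrix(m, path)
}

#' Read a GWAS-catalog-like table
#'
#' Columns: `snp_id`, `trait`, `immune_related` (TRUE/FALSE). The
#' immune-trait labels are an input column, not inferred.
#'
#' @param path Path to the catalog TSV.
#' @return A `data.frame`; `(snp_id, trait)` pairs are unique.
#' @export
read_gwas_catalog <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("snp_id", "trait"),
                                logical = "immune_related"))
  need <- c("snp_id", "trait", "immune_related")
  if (!all(need %in% names(dt))) {
    stop(sprintf("%s: catalog must have columns %s", path,
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(dt[, c("snp_id", "trait")])) {
    stop(sprintf("%s: duplicate (snp_id, trait) pairs", path))
  }
  as.data.frame(dt)
}

#' Write a GWAS-catalog-like table
#' @param catalog A catalog `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_catalog <- function(catalog, path) {
  fwrite(as.data.table(catalog), path, sep = "\t")
  invisible(path)
}

#' Default run configuration
#'
#' Flat key-value configuration holding every pipeline threshold, with the
#' published analysis values as defaults. All keys can be overridden from a
#' YAML file ([read_config()]) or programmatically.
#'
#' @return A named list of thresholds.
#' @export
default_config <- function() {
  list(
    norm.n_bins = 100L,
    qc.snp_call_rate = 0.99,
    qc.sample_call_rate = 0.98,
    qc.hwe_p = 1e-6,
    qc.contamination_call_rate = 0.40,
    ase.min_informative_snps = 3L,
    ase.expression_threshold = 1000,
    assoc.window_bp = 250000L,
    assoc.p_thresh = 1e-6,
    assoc.slope_thresh = 0.05,
    assoc.min_per_class = 4L,
    enrich.min_support = 2L,
    enrich.min_overlap = 0.5,
    enrich.peak_p_thresh = 1e-5,
    enrich.flank_bp = 2500L,
    coexpr.fdr_q = 0.10,
    coexpr.ase_p_thresh = 1e-6,
    coexpr.max_gene_distance_bp = 250000L,
    gwas.r2_thresh = 0.8
  )
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override [default_config()]; unknown keys are an
#' error so typos cannot silently leave a threshold at its default.
#'
#' @param path Path to a flat YAML file, or `NULL` for pure defaults.
#' @return A named list of thresholds.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("%s: unknown config keys: %s", path,
                 paste(unknown, collapse = ", ")))
  }
  modifyList(cfg, user)
}

#' Write a run configuration to YAML
#' @param config Named list of thresholds.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

# Split a BED-like file into fields, with line-numbered errors.
read_bed_lines <- function(path, min_fields) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < min_fields)
  if (length(short) > 0L) {
    stop(sprintf("%s: line %d: expected >= %d tab-separated fields, got %d",
                 path, short[1L], min_fields, length(fields[[short[1L]]])))
  }
  fields
}

bed_int <- function(fields, idx, path) {
  v <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), idx)))
  bad <- which(is.na(v))
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d: field %d is not an integer", path, bad[1L], idx))
  }
  v
}

setnames_dt <- function(dt, idx, nm) {
  data.table::setnames(dt, idx, nm)
}
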