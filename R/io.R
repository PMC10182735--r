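#' Write a phased panel as VCF v4.2
#'
#' Haplotypes of the same sample are paired into phased diploid GT fields
#' (`a|b`); a sample with a single haplotype is written haploid.
#'
#' @param panel A [phased_panel()].
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  haps <- panel$haplotypes
  samples <- unique(haps$sample)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hsrscan",
    sprintf("##contig=<ID=%s,length=%d>", names(panel$chrom_lengths),
            as.integer(panel$chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_cols <- vapply(samples, function(sm) {
    rows <- which(haps$sample == sm)
    rows <- rows[order(haps$phase[rows])]
    g <- panel$geno[rows, , drop = FALSE]
    if (nrow(g) == 2) paste(g[1, ], g[2, ], sep = "|") else as.character(g[1, ])
  }, character(ncol(panel$geno)))
  body <- paste(
    panel$sites$chrom, panel$sites$pos + 1L, ".",
    panel$sites$ref, panel$sites$alt, ".", "PASS", ".", "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased biallelic SNPs from a VCF into a panel
#'
#' Only biallelic SNP records in which every requested sample has a fully
#' phased, non-missing genotype are kept; skipped records are counted and
#' reported (attribute `"skipped"` and a message).
#'
#' @param path VCF file (v4.x, plain or gzipped).
#' @param group_assignment Mapping of sample name to panel group
#'   (`query`/`ref_A`/`ref_B`): either a named character vector or a
#'   data frame with columns `sample` and `group`.
#' @return A [phased_panel()].
#' @export
read_phased_vcf <- function(path, group_assignment) {
  abort_if(!file.exists(path), sprintf("VCF not found: %s", path))
  if (is.data.frame(group_assignment)) {
    group_assignment <- setNames(group_assignment$group,
                                 group_assignment$sample)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- names(group_assignment)
  missing_samples <- setdiff(samples, colnames(gt))
  abort_if(length(missing_samples) > 0,
           sprintf("sample(s) not in VCF: %s",
                   paste(missing_samples, collapse = ", ")))
  gt <- gt[, samples, drop = FALSE]
  snp <- fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  phased <- !apply(gt, 1, function(r) {
    any(is.na(r)) || any(grepl("/", r, fixed = TRUE)) ||
      any(grepl(".", r, fixed = TRUE)) ||
      any(!r %in% c("0|0", "0|1", "1|0", "1|1", "0", "1"))
  })
  keep <- snp & phased
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("read_phased_vcf: skipped %d record(s) (%d non-SNP, %d unphased/missing)",
                    n_skipped, sum(!snp), sum(snp & !phased)))
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  hap_rows <- list()
  hap_meta <- list()
  for (sm in samples) {
    alleles <- strsplit(gt[, sm], "|", fixed = TRUE)
    n_al <- length(alleles[[1]])
    for (ph in seq_len(n_al)) {
      hap_rows[[length(hap_rows) + 1L]] <-
        as.integer(vapply(alleles, `[`, character(1), ph))
      hap_meta[[length(hap_meta) + 1L]] <- tibble(
        hap_id = if (n_al == 1) sm else sprintf("%s_h%d", sm, ph),
        sample = sm, phase = ph,
        group = unname(group_assignment[[sm]])
      )
    }
  }
  chrom_lengths <- vcf_contig_lengths(vcf)
  panel <- phased_panel(
    do.call(rbind, hap_rows),
    tibble(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
           ref = fix$REF, alt = fix$ALT),
    bind_rows(hap_meta),
    chrom_lengths = chrom_lengths
  )
  attr(panel, "skipped") <- n_skipped
  panel
}

vcf_contig_lengths <- function(vcf) {
  meta <- vcf@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  if (length(contig) == 0) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                          contig)))
  if (anyNA(lens)) return(NULL)
  setNames(lens, ids)
}

#' Write intervals as BED
#'
#' Columns beyond `chrom`, `start`, `end` are appended in order (e.g. origin
#' label, haplotype id). No header, tab-separated, 0-based half-open.
#'
#' @param intervals Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  core <- c("chrom", "start", "end")
  abort_if(!all(core %in% names(intervals)),
           "`intervals` needs chrom, start, end")
  d <- select(as_tibble(intervals), all_of(core),
              all_of(setdiff(names(intervals), core)))
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED path (tab-separated, no header).
#' @param extra_cols Names for columns after the third, e.g.
#'   `c("origin", "hap_id")`.
#' @return Interval tibble.
#' @export
read_bed <- function(path, extra_cols = character()) {
  abort_if(!file.exists(path), sprintf("BED not found: %s", path))
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  abort_if(ncol(d) < 3, sprintf("malformed BED (need >= 3 columns): %s", path))
  names(d)[1:3] <- c("chrom", "start", "end")
  if (length(extra_cols) > 0) {
    abort_if(ncol(d) < 3 + length(extra_cols),
             "fewer columns than `extra_cols` expects")
    names(d)[3 + seq_along(extra_cols)] <- extra_cols
  }
  abort_if(any(is.na(d$start)) || any(is.na(d$end)) ||
             any(d$start >= d$end),
           sprintf("malformed BED intervals in %s", path))
  d
}

#' Write / read a recombination map table
#'
#' Tab-separated with header `chrom`, `start`, `end`, `rate_cM_per_Mb`
#' (100 kb windows by convention). [read_recomb_map()] also accepts the
#' 3-column form (`chrom`, `start`, `rate_cM_per_Mb`), inferring window ends
#' from the next start.
#'
#' @param map Map tibble from [simulate_recombination_map()] or equivalent.
#' @param path File path.
#' @return `path` (write) or the map tibble with derived cumulative genetic
#'   position columns `cum_cM_start`, `cum_cM_end` (read).
#' @export
write_recomb_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(path) {
  abort_if(!file.exists(path), sprintf("map not found: %s", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  abort_if(!all(c("chrom", "start") %in% names(d)),
           "map needs chrom and start columns")
  rate_col <- grep("rate", names(d), value = TRUE)[1]
  abort_if(is.na(rate_col), "map needs a rate column (cM/Mb)")
  d <- rename(d, rate_cM_per_Mb = all_of(rate_col))
  if (!"end" %in% names(d)) {
    d <- d %>%
      group_by(.data$chrom) %>%
      arrange(.data$start, .by_group = TRUE) %>%
      mutate(end = lead(.data$start,
                        default = max(.data$start) +
                          median(diff(.data$start)))) %>%
      ungroup()
  }
  abort_if(any(is.na(d$rate_cM_per_Mb)) || any(d$rate_cM_per_Mb < 0),
           "map rates must be non-negative and complete")
  map_cumulative(select(d, "chrom", "start", "end", "rate_cM_per_Mb"))
}

#' Cumulative genetic position along a recombination map
#'
#' @param map Map tibble (`chrom`, `start`, `end`, `rate_cM_per_Mb`).
#' @return The map with `cum_cM_start` and `cum_cM_end` columns.
#' @export
map_cumulative <- function(map) {
  map %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(
      g = .data$rate_cM_per_Mb * (.data$end - .data$start) / 1e6,
      cum_cM_end = cumsum(.data$g),
      cum_cM_start = .data$cum_cM_end - .data$g
    ) %>%
    ungroup() %>%
    select(-"g")
}

#' Read exon intervals from a GFF3 annotation
#'
#' GFF3 1-based closed coordinates are converted to 0-based half-open and
#' overlapping exons are unioned.
#'
#' @param path GFF3 file.
#' @return Interval tibble `chrom`, `start`, `end` (union of exons).
#' @export
read_gff_exons <- function(path) {
  abort_if(!file.exists(path), sprintf("GFF not found: %s", path))
  lines <- readLines(path)
  data_lines <- which(!grepl("^#", lines) & nzchar(lines))
  bad <- data_lines[vapply(strsplit(lines[data_lines], "\t"),
                           length, integer(1)) < 9]
  abort_if(length(bad) > 0,
           sprintf("malformed GFF3 line %d in %s", bad[1], path))
  g <- ape::read.gff(path, GFF3 = TRUE)
  ex <- g[g$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  merge_intervals(
    tibble(chrom = as.character(ex$seqid), start = ex$start - 1,
           end = as.numeric(ex$end)),
    max_gap = 0
  ) %>% select("chrom", "start", "end")
}

#' Write exon intervals as GFF3
#'
#' @param exons Interval tibble (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_exons <- function(exons, path) {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\thsrscan\texon\t%d\t%d\t.\t+\t.\tID=exon%05d",
            exons$chrom, as.integer(exons$start + 1),
            as.integer(exons$end), seq_len(nrow(exons)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Generates the full synthetic dataset and writes: phased VCF, truth-block
#' BED (columns origin and haplotype id), recombination-map TSV, toy exon
#' GFF3 and a YAML manifest with realized summary parameters.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return The manifest (named list), invisibly readable back with
#'   [yaml::read_yaml()].
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  abort_if(!dir.exists(out_dir), sprintf("cannot create: %s", out_dir))
  ds <- simulate_hybrid_dataset(config)
  paths <- list(
    vcf = file.path(out_dir, "panel.vcf"),
    truth_bed = file.path(out_dir, "truth_blocks.bed"),
    map = file.path(out_dir, "recomb_map.tsv"),
    gff = file.path(out_dir, "exons.gff3"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_phased_vcf(ds$panel, paths$vcf)
  write_bed(select(ds$truth, "chrom", "start", "end", "origin", "hap_id"),
            paths$truth_bed)
  write_recomb_map(ds$map, paths$map)
  write_gff_exons(ds$exons, paths$gff)
  qhaps <- ds$panel$haplotypes$hap_id[ds$panel$haplotypes$group == "query"]
  fr <- truth_fractions(ds$truth, ds$panel$chrom_lengths, qhaps)
  div <- panel_divergence(ds$panel)
  manifest <- list(
    files = lapply(paths[c("vcf", "truth_bed", "map", "gff")], normalizePath),
    chromosomes = as.list(setNames(as.numeric(ds$panel$chrom_lengths),
                                   names(ds$panel$chrom_lengths))),
    # all bases are accessible in the synthetic data: pi / d_xy denominators
    # are full window widths, so invariant records need not be emitted
    accessible = "all",
    n_sites = ncol(ds$panel$geno),
    realized = c(div, list(
      admix_fraction = as.list(setNames(fr$fraction, fr$hap_id)),
      admix_fraction_mean = mean(fr$fraction)
    )),
    config = unclass(config)
  )
  yaml::write_yaml(manifest, paths$manifest)
  invisible(manifest)
}

# genome-wide sample-based divergence summaries used in the manifest
panel_divergence <- function(panel) {
  total <- sum(panel$chrom_lengths)
  ga <- panel_matrix(panel, "ref_A")
  gb <- panel_matrix(panel, "ref_B")
  ka <- colSums(ga); kb <- colSums(gb)
  na <- nrow(ga); nb <- nrow(gb)
  dxy <- sum(ka * (nb - kb) + kb * (na - ka)) / (na * nb) / total
  pi_g <- function(k, n) sum(k * (n - k)) / (n * (n - 1) / 2) / total
  list(dxy = dxy, pi_ref_A = pi_g(ka, na), pi_ref_B = pi_g(kb, nb))
}
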