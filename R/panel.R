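#' Phased haplotype panel
#'
#' Container for phased biallelic haplotypes: a 0/1 matrix (rows = haploid
#' genomes, columns = ordered sites) plus a site table and a haplotype table
#' carrying panel-group labels (`query`, `ref_A`, `ref_B`).
#'
#' @param geno Integer/numeric matrix of 0/1 alleles, one row per haplotype,
#'   one column per site. No missing values.
#' @param sites Tibble with columns `chrom`, `pos` (0-based bp), `ref`, `alt`.
#'   Positions must be strictly increasing within each chromosome.
#' @param haplotypes Tibble with columns `hap_id` (unique), `sample`,
#'   `phase` (1 or 2) and `group` (one of `"query"`, `"ref_A"`, `"ref_B"`).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'   Defaults to `max(pos) + 1` per chromosome when unknown.
#'
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(geno, sites, haplotypes, chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  abort_if(anyNA(geno), "haplotype matrix must not contain missing values")
  abort_if(!all(geno %in% c(0L, 1L)), "haplotype matrix values must be 0/1")
  sites <- as_tibble(sites)
  haplotypes <- as_tibble(haplotypes)
  abort_if(!all(c("chrom", "pos") %in% names(sites)),
           "`sites` needs columns chrom, pos")
  abort_if(!all(c("hap_id", "group") %in% names(haplotypes)),
           "`haplotypes` needs columns hap_id, group")
  abort_if(nrow(sites) != ncol(geno),
           "number of sites must match matrix columns")
  abort_if(nrow(haplotypes) != nrow(geno),
           "number of haplotypes must match matrix rows")
  abort_if(anyDuplicated(haplotypes$hap_id) > 0, "hap_id must be unique")
  bad_order <- sites %>%
    group_by(.data$chrom) %>%
    summarise(ok = all(diff(.data$pos) > 0) || n() < 2L) %>%
    pull(.data$ok)
  abort_if(!all(bad_order), "site positions must be strictly increasing")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- sites %>%
      group_by(.data$chrom) %>%
      summarise(len = max(.data$pos) + 1) %>%
      (function(d) setNames(d$len, d$chrom))
  }
  rownames(geno) <- haplotypes$hap_id
  structure(
    list(geno = geno, sites = sites, haplotypes = haplotypes,
         chrom_lengths = chrom_lengths),
    class = "phased_panel"
  )
}

#' @export
print.phased_panel <- function(x, ...) {
  grp <- table(x$haplotypes$group)
  cat(sprintf(
    "<phased_panel> %d haplotypes x %d sites on %d chromosome(s)\n",
    nrow(x$geno), ncol(x$geno), length(x$chrom_lengths)))
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset a panel by group label
#'
#' @param panel A [phased_panel()].
#' @param group One or more group labels to keep.
#' @return A `phased_panel` with only the selected haplotypes.
#' @export
panel_subset <- function(panel, group) {
  keep <- panel$haplotypes$group %in% group
  abort_if(!any(keep), sprintf("no haplotypes in group(s) %s",
                               paste(group, collapse = ", ")))
  phased_panel(panel$geno[keep, , drop = FALSE], panel$sites,
               panel$haplotypes[keep, ], panel$chrom_lengths)
}

#' Combine panels that share a site set
#'
#' @param ... `phased_panel` objects over the identical site table.
#' @return A single `phased_panel`.
#' @export
panel_bind <- function(...) {
  panels <- list(...)
  abort_if(length(panels) < 1L, "no panels supplied")
  ref <- panels[[1]]
  for (p in panels[-1]) {
    abort_if(!identical(ref$sites$chrom, p$sites$chrom) ||
               !identical(ref$sites$pos, p$sites$pos),
             "panels must share an identical site set")
  }
  phased_panel(
    do.call(rbind, lapply(panels, function(p) p$geno)),
    ref$sites,
    bind_rows(lapply(panels, function(p) p$haplotypes)),
    ref$chrom_lengths
  )
}

# group-specific genotype matrix
panel_matrix <- function(panel, group = NULL) {
  if (is.null(group)) return(panel$geno)
  panel$geno[panel$haplotypes$group %in% group, , drop = FALSE]
}
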