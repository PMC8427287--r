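venn_region_labels <- c("gcn_only", "cc_only", "wgcn_only", "gcn_cc",
                        "gcn_wgcn", "cc_wgcn", "all_three")

#' Seven-region Venn partition of the three candidate sets
#'
#' Partitions the union of the GCN, CC and WGCN sets into the seven
#' disjoint membership regions of a three-set Venn diagram.
#'
#' @param sets A [candidate_sets()] object.
#' @return Object of class `venn_partition`: `regions` (named list of
#'   seven sorted gene-id vectors) and `union_size`.
#' @export
venn_partition <- function(sets) {
  stopifnot(inherits(sets, "candidate_sets"))
  genes <- sort(unique(c(sets$gcn, sets$cc, sets$wgcn)))
  g <- genes %in% sets$gcn
  c_ <- genes %in% sets$cc
  w <- genes %in% sets$wgcn
  regions <- list(
    gcn_only = genes[g & !c_ & !w],
    cc_only = genes[!g & c_ & !w],
    wgcn_only = genes[!g & !c_ & w],
    gcn_cc = genes[g & c_ & !w],
    gcn_wgcn = genes[g & !c_ & w],
    cc_wgcn = genes[!g & c_ & w],
    all_three = genes[g & c_ & w])
  structure(list(regions = regions, union_size = length(genes)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition (union", x$union_size, "genes)\n")
  for (nm in names(x$regions))
    cat(sprintf("  %-10s %d\n", nm, length(x$regions[[nm]])))
  invisible(x)
}

#' Retain candidate genes carrying SNP evidence
#'
#' A gene survives if the SNP table holds at least one record for it; a
#' `region_classes` restriction keeps only records of the chosen classes
#' (e.g. `"promoter"`).  Applied per method and to the union.
#'
#' @param sets A [candidate_sets()] object.
#' @param snps A `snp_table` data frame (see [read_snp_table()]).
#' @param region_classes Optional character vector restricting which
#'   region classes count as evidence (default: any).
#' @return List with the surviving `gcn`, `cc`, `wgcn` sets, the
#'   `combined` union, and `region_breakdown`, a table of region classes
#'   among the combined genes' records.
#' @export
filter_by_snp <- function(sets, snps, region_classes = NULL) {
  stopifnot(inherits(sets, "candidate_sets"))
  snps <- as.data.frame(snps)
  if (!is.null(region_classes))
    snps <- snps[snps$region_class %in% region_classes, , drop = FALSE]
  evid <- unique(snps$gene_id)
  keep <- function(g) sort(intersect(g, evid))
  out <- list(gcn = keep(sets$gcn), cc = keep(sets$cc),
              wgcn = keep(sets$wgcn))
  out$combined <- sort(unique(c(out$gcn, out$cc, out$wgcn)))
  sub <- snps[snps$gene_id %in% out$combined, , drop = FALSE]
  out$region_breakdown <- table(sub$region_class)
  out
}

#' Retain genes located in a genomic interval
#'
#' Keeps genes whose annotated locus overlaps the query interval on the
#' same chromosome.  Coordinates are 0-based half-open, so overlap means
#' `gene.start < interval.end && interval.start < gene.end`; with
#' `mode = "within"` the locus must lie entirely inside the interval.
#' Genes missing from the annotation are dropped with a warning.
#'
#' @param genes Character vector of gene ids.
#' @param annotation A `gene_annotation` data frame.
#' @param interval A [genomic_interval()].
#' @param mode `"overlap"` (default) or `"within"`.
#' @return Sorted character vector of retained gene ids.
#' @export
filter_by_interval <- function(genes, annotation, interval,
                               mode = c("overlap", "within")) {
  mode <- match.arg(mode)
  stopifnot(inherits(interval, "genomic_interval"))
  ann <- as.data.frame(annotation)
  i <- match(genes, ann$gene_id)
  if (anyNA(i)) {
    snet_warn("%d gene(s) missing from the annotation were dropped",
              sum(is.na(i)))
    genes <- genes[!is.na(i)]
    i <- i[!is.na(i)]
  }
  same_chr <- ann$chromosome[i] == interval$chromosome
  hit <- if (mode == "overlap")
    ann$start[i] < interval$end & interval$start < ann$end[i]
  else
    ann$start[i] >= interval$start & ann$end[i] <= interval$end
  sort(genes[same_chr & hit])
}
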