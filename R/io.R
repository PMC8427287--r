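#' Read an expression matrix and its sample sheet
#'
#' The matrix file is TSV with a header row of sample ids and gene ids in
#' the first column.  The sample sheet is TSV with columns `sample_id`,
#' `state`, `stage`, `replicate`.  Row and column order are preserved.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample-sheet TSV.
#' @return An [expression_set()].
#' @export
read_expression_matrix <- function(matrix_path, sample_sheet_path) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    snet_stop("expression matrix needs a gene column plus >=1 sample",
              "saltnet_format_error")
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    snet_stop("duplicate gene id(s): %s", "saltnet_format_error",
              paste(unique(dup), collapse = ", "))
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(gene_ids, names(raw)[-1L]))
  bad <- which(is.na(num) & !is.na(as.matrix(raw[-1L])), arr.ind = TRUE)
  if (nrow(bad))
    snet_stop("non-numeric cell at gene '%s', sample '%s'",
              "saltnet_format_error",
              gene_ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]])
  sheet <- utils::read.delim(sample_sheet_path, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             colClasses = "character")
  if ("replicate" %in% names(sheet))
    sheet$replicate <- as.integer(sheet$replicate)
  expression_set(num, sheet)
}

#' Write an expression matrix and its sample sheet
#' @param x An [expression_set()].
#' @param matrix_path,sample_sheet_path Output TSV paths.
#' @return Invisibly, `x`.
#' @export
write_expression_matrix <- function(x, matrix_path, sample_sheet_path) {
  stopifnot(inherits(x, "expression_set"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, sample_sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(x)
}

known_region_classes <- c("promoter", "five_prime_utr", "exon", "intron",
                          "three_prime_utr")

#' Read a SNP evidence table
#'
#' Accepts either a TSV with columns `gene_id`, `position`, `ref`, `alt`,
#' `region_class`, or a minimal VCF dialect (`#` header lines; CHROM POS
#' ID REF ALT columns honored, gene id taken from a `GENE=` key and
#' region class from an optional `REGION=` key in the INFO column).
#' Records with identical ref and alt alleles are dropped with a warning;
#' unrecognized region classes map to `"unknown"`.
#'
#' @param path Input path; the VCF dialect is detected from `#` header
#'   lines or a `.vcf` extension.
#' @return A data frame of class `snp_table` with columns `gene_id`,
#'   `position`, `ref`, `alt`, `region_class`.  The number of rejected
#'   records is attached as attribute `n_rejected`.
#' @export
read_snp_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^#", first) || grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    get_info <- function(parts, key) {
      info <- if (length(parts) >= 8L) parts[[8L]] else ""
      m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1L]]
      if (length(m) == 2L) m[[2L]] else NA_character_
    }
    df <- data.frame(
      gene_id = vapply(fields, get_info, character(1L), key = "GENE"),
      position = vapply(fields, function(p) p[[2L]], character(1L)),
      ref = vapply(fields, function(p) p[[4L]], character(1L)),
      alt = vapply(fields, function(p) p[[5L]], character(1L)),
      region_class = vapply(fields, get_info, character(1L), key = "REGION"))
    df$region_class[is.na(df$region_class)] <- "unknown"
    if (anyNA(df$gene_id))
      snet_stop("VCF record without a GENE= tag in INFO",
                "saltnet_format_error")
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    need <- c("gene_id", "position", "ref", "alt", "region_class")
    miss <- setdiff(need, names(df))
    if (length(miss))
      snet_stop("SNP table lacks column(s): %s", "saltnet_format_error",
                paste(miss, collapse = ", "))
    df <- df[need]
  }
  pos <- suppressWarnings(as.integer(df$position))
  if (any(is.na(pos) | pos <= 0L))
    snet_stop("malformed SNP position '%s'", "saltnet_format_error",
              df$position[which(is.na(pos) | pos <= 0L)[1L]])
  df$position <- pos
  df$region_class[!(df$region_class %in% known_region_classes)] <- "unknown"
  same <- df$ref == df$alt
  if (any(same))
    snet_warn("dropped %d SNP record(s) with ref == alt", sum(same))
  out <- df[!same, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_rejected = sum(same),
            class = c("snp_table", "data.frame"))
}

#' Write a SNP table as TSV
#' @param snps A `snp_table` data frame.
#' @param path Output path.
#' @return Invisibly, `snps`.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(as.data.frame(snps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(snps)
}

#' Read a BED4 gene annotation
#'
#' BED convention: tab-separated `chromosome start end gene_id` with
#' 0-based half-open coordinates.  A gene id occurring on several lines
#' keeps the last line, with a warning.
#'
#' @param path Input BED4 path.
#' @return Data frame of class `gene_annotation` with columns `gene_id`,
#'   `chromosome`, `start`, `end` (one row per gene).
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 4L)
  if (length(short))
    snet_stop("line %d: expected 4 tab-separated BED fields",
              "saltnet_format_error", short[1L])
  df <- data.frame(
    chromosome = vapply(fields, `[[`, character(1L), 1L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 3L))),
    gene_id = vapply(fields, `[[`, character(1L), 4L))
  if (anyNA(df$start) || anyNA(df$end))
    snet_stop("line %d: non-integer coordinate", "saltnet_format_error",
              which(is.na(df$start) | is.na(df$end))[1L])
  bad <- which(df$start >= df$end)
  if (length(bad))
    snet_stop("line %d: start >= end (%d >= %d)", "saltnet_format_error",
              bad[1L], df$start[bad[1L]], df$end[bad[1L]])
  if (anyDuplicated(df$gene_id)) {
    snet_warn("%d duplicated gene id line(s); later lines override earlier",
              sum(duplicated(df$gene_id)))
    df <- df[!duplicated(df$gene_id, fromLast = TRUE), , drop = FALSE]
  }
  df <- df[c("gene_id", "chromosome", "start", "end")]
  rownames(df) <- NULL
  structure(df, class = c("gene_annotation", "data.frame"))
}

#' Write a BED4 gene annotation
#' @param annotation A `gene_annotation` data frame.
#' @param path Output path.
#' @return Invisibly, `annotation`.
#' @export
write_gene_annotation <- function(annotation, path) {
  df <- as.data.frame(annotation)[c("chromosome", "start", "end", "gene_id")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(annotation)
}

#' Genomic interval (0-based half-open)
#'
#' Describes a marker-delimited region, e.g. a QTL interval between two
#' SSR markers, in BED coordinates.
#'
#' @param chromosome Chromosome name.
#' @param start,end Integer bounds, `start < end`, 0-based half-open.
#' @param label Free-text label (e.g. the marker pair).
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chromosome, start, end, label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start >= end)
    snet_stop("interval requires integer start < end",
              "saltnet_format_error")
  structure(list(chromosome = as.character(chromosome), start = start,
                 end = end, label = as.character(label)),
            class = "genomic_interval")
}

#' Parse an interval string such as "chr1:1500-98000"
#' @param spec String `chrom:start-end`.
#' @param label Optional label.
#' @return A [genomic_interval()].
#' @export
parse_interval <- function(spec, label = "") {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1L]]
  if (length(m) != 4L)
    snet_stop("cannot parse interval '%s' (expected chrom:start-end)",
              "saltnet_format_error", spec)
  genomic_interval(m[[2L]], as.integer(m[[3L]]), as.integer(m[[4L]]), label)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("genomic_interval %s:%d-%d%s\n", x$chromosome, x$start, x$end,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Write the integrated candidate table
#'
#' One row per gene in the union of the three candidate sets, with
#' membership flags, the Venn region, and the per-state metric values.
#' Rows are ordered lexicographically by gene id so output is
#' platform-independent.
#'
#' @param sets A [candidate_sets()] object.
#' @param metrics A node-metrics table from [node_metrics()].
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_candidates <- function(sets, metrics, path) {
  stopifnot(inherits(sets, "candidate_sets"))
  vp <- venn_partition(sets)
  genes <- sort(unique(c(sets$gcn, sets$cc, sets$wgcn)))
  region_of <- character(0)
  for (nm in names(vp$regions))
    region_of[vp$regions[[nm]]] <- nm
  df <- data.frame(gene_id = genes,
                   in_gcn = genes %in% sets$gcn,
                   in_cc = genes %in% sets$cc,
                   in_wgcn = genes %in% sets$wgcn,
                   venn_region = unname(region_of[genes]))
  for (st in c("normal", "stress")) {
    sub <- metrics[metrics$state == st, , drop = FALSE]
    i <- match(genes, sub$gene_id)
    for (col in c("degree", "cc", "wdegree", "wcc"))
      df[[paste(col, st, sep = "_")]] <- sub[[col]][i]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read back a candidate table written by [write_candidates()]
#' @param path Input TSV path.
#' @return A [candidate_sets()] object reconstructed from the flags.
#' @export
read_candidates <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  candidate_sets(gcn = df$gene_id[df$in_gcn],
                 cc = df$gene_id[df$in_cc],
                 wgcn = df$gene_id[df$in_wgcn])
}
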