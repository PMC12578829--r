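# Readers/writers for the formats the cascade touches.  All interval
# coordinates are normalised at this boundary to 0-based half-open;
# GTF (1-based closed) is converted on the way in and out.

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open throughout the package: an interval
#' covers positions `start, ..., end - 1`.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param name Identifier.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `selnc_interval`.
#' @export
genomic_interval <- function(chrom, start, end, name = NA_character_,
                             strand = ".") {
  if (!nzchar(chrom)) stop("chrom must be non-empty")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("non-integer coordinates")
  if (start < 0L || start >= end) stop("invalid interval: need 0 <= start < end")
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of +, -, .")
  structure(list(chrom = chrom, start = start, end = end,
                 name = name, strand = strand),
            class = "selnc_interval")
}

#' Construct a gene model
#'
#' @param gene_id Identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end Gene span, 0-based half-open.
#' @param biotype Free-text biotype (e.g. `"lncRNA"`).
#' @param exons Optional list of `selnc_interval`; defaults to a single
#'   exon equal to the span.  Exons must lie within the span, be sorted
#'   by start and be non-overlapping.
#' @return An object of class `selnc_gene`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       biotype = "lncRNA", exons = NULL) {
  if (!strand %in% c("+", "-")) stop("gene strand must be + or -")
  span <- genomic_interval(chrom, start, end, name = gene_id, strand = strand)
  if (is.null(exons)) {
    exons <- list(genomic_interval(chrom, start, end,
                                   name = paste0(gene_id, ".e1"),
                                   strand = strand))
  }
  es <- vapply(exons, `[[`, integer(1), "start")
  ee <- vapply(exons, `[[`, integer(1), "end")
  if (any(es < span$start | ee > span$end))
    stop("exon outside gene span for gene ", gene_id)
  o <- order(es)
  exons <- exons[o]; es <- es[o]; ee <- ee[o]
  if (length(exons) > 1L && any(es[-1L] < ee[-length(ee)]))
    stop("overlapping exons for gene ", gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 span = span, biotype = biotype, exons = exons),
            class = "selnc_gene")
}

#' Read a BED file of intervals
#'
#' BED is natively 0-based half-open, so coordinates are kept verbatim.
#' `track`, `browser` and `#` comment lines are skipped.  When column 4
#' is absent, names `bed_<lineno>` are generated.  Names must be unique
#' in the loaded set.
#'
#' @param path Path to a BED file with at least 3 tab-separated columns.
#' @return List of [genomic_interval()] objects.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("empty BED file: ", path)
  out <- vector("list", sum(keep))
  k <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("fewer than 3 columns at line ", i)
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e)) stop("non-integer coordinates at line ", i)
    if (s >= e) stop("start >= end at line ", i)
    nm <- if (length(f) >= 4L && nzchar(f[4L])) f[4L] else paste0("bed_", i)
    strand <- if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "."
    k <- k + 1L
    out[[k]] <- genomic_interval(f[1L], s, e, nm, strand)
  }
  nms <- vapply(out, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate interval names in ", path)
  out
}

#' Write intervals to BED
#'
#' @param intervals List of [genomic_interval()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  lines <- vapply(intervals, function(iv)
    paste(iv$chrom, iv$start, iv$end, iv$name, 0L, iv$strand, sep = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

# Parse the attribute string of a GTF record into a named character vector.
.gtf_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  kv <- regmatches(parts, regexec('^(\\S+)\\s+"?([^"]*)"?$', parts))
  keys <- vapply(kv, function(x) if (length(x) == 3L) x[2L] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(x) if (length(x) == 3L) x[3L] else NA_character_,
                 character(1))
  setNames(vals, keys)
}

#' Read gene models from a GTF file
#'
#' GTF uses 1-based closed coordinates; they are converted here to the
#' package's 0-based half-open convention (start `s` becomes `s - 1`).
#' Genes without `exon` records receive a single exon equal to their
#' span.  Records are retained when their `gene_biotype` (or
#' `gene_type`) attribute matches `biotype_filter`; pass `"any"` to
#' disable filtering.
#'
#' @param path Path to a GTF file.
#' @param biotype_filter Biotype to keep, or `"any"`.
#' @return List of [gene_model()] objects.
#' @export
read_gtf <- function(path, biotype_filter = "any") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  genes <- list(); exons <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) stop("malformed GTF record at line ", i)
    feat <- f[3L]
    if (!feat %in% c("gene", "exon")) next
    at <- .gtf_attrs(f[9L])
    if (!"gene_id" %in% names(at) || is.na(at[["gene_id"]]))
      stop("missing gene_id attribute at line ", i)
    gid <- at[["gene_id"]]
    s <- as.integer(f[4L]) - 1L   # to 0-based half-open
    e <- as.integer(f[5L])
    bt <- if (!is.na(at["gene_biotype"])) at[["gene_biotype"]]
          else if (!is.na(at["gene_type"])) at[["gene_type"]]
          else NA_character_
    rec <- list(chrom = f[1L], start = s, end = e, strand = f[7L],
                biotype = bt)
    if (feat == "gene") genes[[gid]] <- rec
    else exons[[gid]] <- c(exons[[gid]], list(rec))
  }
  out <- list()
  for (gid in names(genes)) {
    g <- genes[[gid]]
    if (!identical(biotype_filter, "any") &&
        (is.na(g$biotype) || g$biotype != biotype_filter)) next
    ex <- exons[[gid]]
    exiv <- NULL
    if (!is.null(ex)) {
      if (any(vapply(ex, function(x) x$start < g$start || x$end > g$end,
                     logical(1))))
        stop("exon outside gene span for gene ", gid)
      exiv <- lapply(seq_along(ex), function(j)
        genomic_interval(g$chrom, ex[[j]]$start, ex[[j]]$end,
                         name = paste0(gid, ".e", j), strand = g$strand))
    }
    out[[gid]] <- gene_model(gid, g$chrom, g$strand, g$start, g$end,
                             biotype = if (is.na(g$biotype)) "NA" else g$biotype,
                             exons = exiv)
  }
  unname(out)
}

#' Write gene models to GTF
#'
#' Converts back from the internal 0-based half-open convention to
#' GTF's 1-based closed coordinates, emitting one `gene` and one `exon`
#' record per exon.
#'
#' @param genes List of [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    at <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
    lines <- c(lines, paste(g$chrom, "selnc", "gene", g$span$start + 1L,
                            g$span$end, ".", g$strand, ".", at, sep = "\t"))
    for (ex in g$exons)
      lines <- c(lines, paste(g$chrom, "selnc", "exon", ex$start + 1L,
                              ex$end, ".", g$strand, ".", at, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file of DNA/RNA sequences
#'
#' Sequences are normalised to uppercase DNA over `{A,C,G,T,N}`; `U` is
#' mapped to `T`.  Any other character is an error, as are duplicate
#' ids or empty sequences.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) < 1L)) stop("empty sequence in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("invalid characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct an expression matrix container
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param scale `"raw"` (all values must be non-negative) or `"log2"`.
#' @return An object of class `selnc_expr`.
#' @export
expression_matrix <- function(values, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature and sample names")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyNA(values)) stop("missing entries in expression matrix")
  if (scale == "raw" && any(values < 0))
    stop("negative values with scale=raw")
  structure(list(values = values, scale = scale), class = "selnc_expr")
}

#' Read an expression matrix from TSV
#'
#' Layout is fixed: features in rows, samples in columns, first column
#' the feature id, first row the header of sample ids.
#'
#' @param path Path to the TSV file.
#' @param scale Declared scale of the values (`"log2"` or `"raw"`).
#' @return An [expression_matrix()] object.
#' @export
read_matrix <- function(path, scale = "log2") {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", fill = FALSE)
  if (ncol(df) < 2L) stop("matrix TSV needs an id column and >=1 sample")
  ids <- df[[1L]]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1L]))
  if (anyNA(vals)) stop("non-numeric or missing entries in ", path)
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' @param expr An [expression_matrix()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(expr, path) {
  df <- data.frame(feature = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical survival table
#'
#' Expected header: `sample<TAB>time<TAB>event[<TAB>subtype][...covariates]`.
#' Times must be positive, events coded 0 (censored) / 1 (event), and
#' sample ids unique.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `sample`, `time`, `event` and any
#'   further columns present in the file, of class `selnc_clinical`.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("clinical table must have columns sample, time, event")
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in ", path)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (anyNA(df$time) || any(df$time <= 0)) stop("time must be > 0")
  if (anyNA(df$event) || !all(df$event %in% c(0L, 1L)))
    stop("event must be 0 or 1")
  class(df) <- c("selnc_clinical", "data.frame")
  df
}

#' Write a clinical survival table
#'
#' @param clin A clinical `data.frame` as returned by [read_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
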