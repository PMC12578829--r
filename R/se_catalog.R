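# SE-lncRNA catalogue: match super-enhancer intervals against lncRNA
# gene models and summarise the chromosomal distribution.

# Strip an optional "chr" prefix so dbSUPER-style and Ensembl-style
# chromosome names compare equal.
.norm_chrom <- function(x) sub("^chr", "", x)

#' Build an overlap-queryable interval index
#'
#' Thin wrapper over [IRanges::IRanges] nested containment lists, one
#' per chromosome.  Query semantics are strictly half-open: intervals
#' abutting the query (`end == query_start`) do not overlap.
#'
#' @param intervals List of [genomic_interval()].
#' @return An object of class `selnc_index`.
#' @export
build_interval_index <- function(intervals) {
  chroms <- .norm_chrom(vapply(intervals, `[[`, character(1), "chrom"))
  by_chrom <- split(seq_along(intervals), chroms)
  idx <- lapply(by_chrom, function(ii) {
    s <- vapply(intervals[ii], `[[`, integer(1), "start")
    e <- vapply(intervals[ii], `[[`, integer(1), "end")
    # store closed integer ranges [start, end-1] to emulate half-open
    list(ranges = IRanges::IRanges(start = s, end = e - 1L), which = ii)
  })
  structure(list(by_chrom = idx, intervals = intervals),
            class = "selnc_index")
}

#' Query an interval index
#'
#' @param index A `selnc_index` from [build_interval_index()].
#' @param chrom Chromosome name.
#' @param start,end Query interval, 0-based half-open.
#' @return Integer vector of indices (into the original list) of all
#'   stored intervals overlapping `[start, end)` by at least 1 bp.
#' @export
query_index <- function(index, chrom, start, end) {
  if (start >= end) stop("invalid query: start >= end")
  ch <- index$by_chrom[[.norm_chrom(chrom)]]
  if (is.null(ch)) return(integer(0))
  q <- IRanges::IRanges(start = as.integer(start), end = as.integer(end) - 1L)
  hits <- IRanges::findOverlaps(q, ch$ranges)
  sort(ch$which[S4Vectors::subjectHits(hits)])
}

#' Identify SE-lncRNAs by interval matching
#'
#' In `gene_overlap` mode a gene qualifies when its span overlaps at
#' least one super-enhancer by >= 1 bp (strand ignored).  In
#' `tss_window` mode it qualifies when its transcription start site
#' (span start on `+`, `span end - 1` on `-`) falls inside a
#' super-enhancer extended by `window_bp` on both sides; `overlap_bp`
#' then reports the overlap of the gene span with the unextended SE and
#' may be 0.
#'
#' @param se_intervals List of super-enhancer [genomic_interval()].
#' @param gene_models List of [gene_model()].
#' @param mode `"gene_overlap"` (default) or `"tss_window"`.
#' @param window_bp TSS window half-width in bp (tss_window mode only).
#' @return An object of class `selnc_catalog`: list with `entries`
#'   (data.frame `gene_id`, `se_name`, `overlap_bp`, `mode`) and
#'   `se_lncrna_ids` (character vector of distinct qualifying genes).
#' @export
identify_se_lncrnas <- function(se_intervals, gene_models,
                                mode = c("gene_overlap", "tss_window"),
                                window_bp = 2000L) {
  mode <- match.arg(mode)
  window_bp <- as.integer(window_bp)
  if (window_bp < 0L) stop("window_bp must be >= 0")
  se_chroms <- unique(.norm_chrom(vapply(se_intervals, `[[`, character(1), "chrom")))
  g_chroms <- unique(.norm_chrom(vapply(gene_models, `[[`, character(1), "chrom")))
  empty <- data.frame(gene_id = character(0), se_name = character(0),
                      overlap_bp = integer(0), mode = character(0),
                      stringsAsFactors = FALSE)
  if (length(se_intervals) == 0L || length(gene_models) == 0L ||
      !any(g_chroms %in% se_chroms)) {
    if (length(se_intervals) > 0L && length(gene_models) > 0L)
      warning("chromosome name sets disjoint between SEs and genes")
    return(structure(list(entries = empty, se_lncrna_ids = character(0)),
                     class = "selnc_catalog"))
  }
  index <- build_interval_index(se_intervals)
  rows <- vector("list", length(gene_models))
  for (gi in seq_along(gene_models)) {
    g <- gene_models[[gi]]
    sp <- g$span
    if (mode == "gene_overlap") {
      hits <- query_index(index, g$chrom, sp$start, sp$end)
    } else {
      tss <- if (g$strand == "+") sp$start else sp$end - 1L
      hits <- integer(0)
      ch <- index$by_chrom[[.norm_chrom(g$chrom)]]
      if (!is.null(ch)) {
        for (j in seq_along(ch$which)) {
          se <- se_intervals[[ch$which[j]]]
          if (tss >= se$start - window_bp && tss < se$end + window_bp)
            hits <- c(hits, ch$which[j])
        }
      }
    }
    if (length(hits) == 0L) next
    ov <- vapply(hits, function(h) {
      se <- se_intervals[[h]]
      max(0L, min(sp$end, se$end) - max(sp$start, se$start))
    }, integer(1))
    rows[[gi]] <- data.frame(
      gene_id = g$gene_id,
      se_name = vapply(se_intervals[hits], `[[`, character(1), "name"),
      overlap_bp = ov, mode = mode, stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                              list(empty)))
  structure(list(entries = entries,
                 se_lncrna_ids = unique(entries$gene_id)),
            class = "selnc_catalog")
}

#' Per-chromosome density of SEs and SE-lncRNAs
#'
#' Counts, for every chromosome present in either input, the number of
#' distinct super-enhancers overlapped by at least one catalogued gene
#' and the number of distinct SE-lncRNAs.  Chromosomes with no entries
#' are reported with count 0; rows are sorted in natural chromosome
#' order (1..22, X, Y, then others alphabetically).
#'
#' @param catalog A `selnc_catalog` from [identify_se_lncrnas()].
#' @param gene_models The gene models the catalogue was built from.
#' @param se_intervals The SE intervals the catalogue was built from.
#' @return data.frame with columns `chrom`, `n_se`, `n_se_lncrna`.
#' @export
chromosome_density <- function(catalog, gene_models, se_intervals) {
  g_chrom <- setNames(.norm_chrom(vapply(gene_models, `[[`, character(1), "chrom")),
                      vapply(gene_models, `[[`, character(1), "gene_id"))
  se_chrom <- setNames(.norm_chrom(vapply(se_intervals, `[[`, character(1), "chrom")),
                       vapply(se_intervals, `[[`, character(1), "name"))
  chroms <- unique(c(unname(g_chrom), unname(se_chrom)))
  num <- suppressWarnings(as.integer(chroms))
  grp <- ifelse(!is.na(num), 0L, ifelse(chroms %in% c("X", "Y"), 1L, 2L))
  o <- order(grp, ifelse(is.na(num), 0L, num),
             ifelse(chroms == "Y", 1L, 0L), chroms)
  chroms <- chroms[o]
  ent <- catalog$entries
  n_se <- vapply(chroms, function(ch)
    length(unique(ent$se_name[se_chrom[ent$se_name] == ch])), integer(1))
  n_g <- vapply(chroms, function(ch)
    length(unique(ent$gene_id[g_chrom[ent$gene_id] == ch])), integer(1))
  data.frame(chrom = chroms, n_se = n_se, n_se_lncrna = n_g,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an SE-lncRNA catalogue to TSV
#'
#' @param catalog A `selnc_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
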