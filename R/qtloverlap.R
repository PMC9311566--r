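#' Load a QTL interval table
#'
#' Reads BED (0-based half-open, shifted to 1-based inclusive) or an
#' already 1-based CSV with columns chrom, start, end, category.
#'
#' @param path file path.
#' @param dialect `"bed"` (tab-separated, no header) or `"csv"`
#'   (header chrom,start,end,category).
#' @return data.frame chrom, start, end, category (1-based inclusive).
#' @examples
#' qtl <- load_qtl_table(system.file("extdata",
#'                                   "qtl_intervals_synthetic.csv",
#'                                   package = "crossherd"), "csv")
#' head(qtl)
#' @export
load_qtl_table <- function(path, dialect = c("bed", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED QTL table needs chrom/start/end/category")
    df <- df[, 1:4]
    names(df) <- c("chrom", "start", "end", "category")
    df$start <- df$start + 1L  # 0-based half-open -> 1-based inclusive
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "category")
    if (!all(need %in% names(df))) {
      stop("CSV QTL table needs columns ", paste(need, collapse = ", "))
    }
    df <- df[, need]
  }
  bad <- which(df$start > df$end | !nzchar(df$category))
  if (length(bad)) {
    stop("malformed QTL rows (start > end or empty category): line(s) ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Count QTL containing significant variants, by trait category
#'
#' A QTL interval is counted once per component column when it contains at
#' least one significant variant for that component; percentages are
#' column-wise over the counted QTL.
#'
#' @param sig_variants data.frame with columns chrom, pos and one logical
#'   column per component (e.g. `sig_a_cw`, `sig_d_cw`, ...).
#' @param intervals QTL table from [load_qtl_table()].
#' @param components names of the logical columns to tabulate; an `All`
#'   column (any component) is always added.
#' @return list with `counts` and `percent` data.frames
#'   (rows = categories).
#' @export
overlap_counts <- function(sig_variants, intervals,
                           components = setdiff(names(sig_variants),
                                                c("chrom", "pos"))) {
  stopifnot(all(c("chrom", "pos") %in% names(sig_variants)))
  cats <- sort(unique(intervals$category))
  comp_all <- c(components, "All")
  counts <- matrix(0L, length(cats), length(comp_all),
                   dimnames = list(cats, comp_all))
  any_sig <- Reduce(`|`, lapply(components, function(cc) sig_variants[[cc]]))
  flags <- c(stats::setNames(
    lapply(components, function(cc) sig_variants[[cc]]), components),
    list(All = any_sig))
  for (i in seq_len(nrow(intervals))) {
    inside <- sig_variants$chrom == intervals$chrom[i] &
      sig_variants$pos >= intervals$start[i] &
      sig_variants$pos <= intervals$end[i]
    for (cc in comp_all) {
      if (any(inside & flags[[cc]])) {
        counts[intervals$category[i], cc] <-
          counts[intervals$category[i], cc] + 1L
      }
    }
  }
  tot <- colSums(counts)
  percent <- sweep(counts, 2, pmax(tot, 1L), `/`) * 100
  list(counts = as.data.frame(counts), percent = as.data.frame(percent))
}
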