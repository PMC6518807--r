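#' Read a panel definition from BED
#'
#' BED intervals are 0-based half-open. Lines are pre-validated (at least
#' 3 columns, numeric bounds, `end > start`) so malformed input is
#' rejected with the offending line number; import itself goes through
#' rtracklayer. Unsorted input is sorted; overlapping intervals are
#' merged with a warning (adjacent intervals merge silently).
#'
#' @param path BED file path.
#' @return A `tmb_panel`.
#' @export
read_panel <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("package 'rtracklayer' is required to read BED files")
  }
  lines <- readLines(path)
  data_lines <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  if (length(data_lines) == 0) abort("no intervals found in BED file")
  for (i in data_lines) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("malformed BED line %d: fewer than 3 columns", i))
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      abort(sprintf("malformed BED line %d: non-numeric interval bounds", i))
    }
    if (e <= s) {
      abort(sprintf("malformed BED line %d: end <= start", i))
    }
  }
  gr <- rtracklayer::import(path, format = "BED")
  panel_definition(tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # GRanges is 1-based closed
    end = GenomicRanges::end(gr)
  ))
}

#' Write a panel definition as BED
#'
#' @param panel a `tmb_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("package 'rtracklayer' is required to write BED files")
  }
  gr <- GenomicRanges::GRanges(
    panel$chrom,
    IRanges::IRanges(start = panel$start + 1, end = panel$end)
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
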