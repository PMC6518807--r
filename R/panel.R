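#' Construct a sequencing panel definition
#'
#' A panel is the set of genomic intervals targeted by the capture assay;
#' its summed length in megabases (Mb) is the TMB denominator. Intervals
#' use BED conventions: 0-based, half-open `[start, end)`. Overlapping or
#' adjacent intervals are merged (with a warning when a true overlap is
#' collapsed), and rows are sorted by contig then start.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A `tmb_panel`: a tibble of sorted, disjoint intervals with the
#'   derived coding territory stored in megabases (see
#'   [panel_territory_mb()]).
#' @seealso [generate_panel()], [read_panel()]
#' @export
panel_definition <- function(intervals) {
  check_cols(intervals, c("chrom", "start", "end"), "`intervals`")
  intervals <- as_tibble(intervals)
  if (nrow(intervals) == 0) abort("panel must contain at least one interval")
  if (!is.numeric(intervals$start) || !is.numeric(intervals$end)) {
    abort("`start` and `end` must be numeric")
  }
  bad <- which(intervals$end <= intervals$start | intervals$start < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid interval (end <= start or negative start) at row %d: %s:%s-%s",
      bad[1], intervals$chrom[bad[1]], intervals$start[bad[1]],
      intervals$end[bad[1]]
    ))
  }
  merged <- merge_intervals(intervals)
  if (attr(merged, "overlap_merged")) {
    warn("overlapping panel intervals were merged")
  }
  out <- merged$intervals
  structure(
    out,
    territory_mb = sum(out$end - out$start) / 1e6,
    class = c("tmb_panel", class(tibble()))
  )
}

# Merge sorted 0-based half-open intervals per contig; adjacency merges
# silently, true overlap is flagged for the caller's warning.
merge_intervals <- function(intervals) {
  intervals <- arrange(intervals, .data$chrom, .data$start, .data$end)
  pieces <- split(intervals, intervals$chrom)
  overlap <- FALSE
  merged <- lapply(pieces, function(df) {
    s <- df$start; e <- df$end
    keep_s <- s[1]; keep_e <- e[1]
    out_s <- numeric(0); out_e <- numeric(0)
    if (nrow(df) > 1) {
      for (i in 2:nrow(df)) {
        if (s[i] < keep_e) overlap <<- TRUE
        if (s[i] <= keep_e) {
          keep_e <- max(keep_e, e[i])
        } else {
          out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
          keep_s <- s[i]; keep_e <- e[i]
        }
      }
    }
    tibble(chrom = df$chrom[1], start = c(out_s, keep_s), end = c(out_e, keep_e))
  })
  res <- bind_rows(merged)
  res <- arrange(res, .data$chrom, .data$start)
  out <- list(intervals = res)
  attr(out, "overlap_merged") <- overlap
  out
}

#' Panel coding territory in megabases
#'
#' @param panel a `tmb_panel` from [panel_definition()].
#' @return territory in Mb (double).
#' @export
panel_territory_mb <- function(panel) {
  mb <- attr(panel, "territory_mb")
  if (is.null(mb)) {
    check_cols(panel, c("chrom", "start", "end"), "`panel`")
    mb <- sum(panel$end - panel$start) / 1e6
  }
  mb
}

#' Test whether 1-based positions fall inside the panel
#'
#' @param panel a `tmb_panel`.
#' @param chrom,pos vectors of contig names and 1-based positions.
#' @return logical vector.
#' @export
panel_contains <- function(panel, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  if (length(chrom) == 0) return(logical(0))
  # 0-based half-open [start, end) covers 1-based positions start+1 .. end
  res <- logical(length(chrom))
  idx <- split(seq_along(chrom), chrom)
  for (ctg in names(idx)) {
    iv <- panel[panel$chrom == ctg, , drop = FALSE]
    if (nrow(iv) == 0) next
    p <- pos[idx[[ctg]]]
    # intervals are sorted and disjoint: locate candidate interval by start
    j <- findInterval(p - 1, iv$start)
    hit <- j >= 1 & p <= iv$end[pmax(j, 1)]
    res[idx[[ctg]]] <- hit
  }
  res
}

#' Simulate a capture panel
#'
#' Draws `n_intervals` disjoint intervals on a genome-like contig layout
#' whose lengths sum to exactly `round(territory_mb * 1e6)` bases, emulating
#' the footprint of a large targeted cancer panel (on the order of a
#' thousand genes).
#'
#' @param n_intervals number of intervals (>= 1).
#' @param territory_mb total coding territory in megabases (> 0).
#' @param seed integer seed; identical seeds give identical panels.
#' @return A `tmb_panel`.
#' @examples
#' panel <- generate_panel(n_intervals = 100, territory_mb = 1.4, seed = 1)
#' panel_territory_mb(panel)
#' @export
generate_panel <- function(n_intervals, territory_mb, seed = 1L) {
  if (!is.numeric(territory_mb) || territory_mb <= 0) {
    abort("`territory_mb` must be a positive size in megabases")
  }
  if (!is.numeric(n_intervals) || n_intervals < 1) {
    abort("`n_intervals` must be >= 1")
  }
  n_intervals <- as.integer(n_intervals)
  total <- round(territory_mb * 1e6)
  if (total < n_intervals) abort("territory too small for requested interval count")
  withr::with_seed(as.integer(seed), {
    # split total bases into n positive parts (normalized gamma weights,
    # largest-remainder rounding keeps the sum exact)
    w <- stats::rgamma(n_intervals, shape = 5)
    raw <- w / sum(w) * (total - n_intervals)
    len <- 1 + floor(raw)
    short <- total - sum(len)
    if (short > 0) {
      bump <- order(raw - floor(raw), decreasing = TRUE)[seq_len(short)]
      len[bump] <- len[bump] + 1
    }
    # scatter intervals over up to 22 autosome-like contigs with random gaps
    n_chrom <- min(22L, n_intervals)
    chrom_of <- sort(sample.int(n_chrom, n_intervals, replace = TRUE))
    gaps <- floor(runif(n_intervals, 1e3, 5e4))
    start <- numeric(n_intervals)
    pos <- setNames(rep(0, n_chrom), seq_len(n_chrom))
    for (i in seq_len(n_intervals)) {
      ctg <- chrom_of[i]
      start[i] <- pos[ctg] + gaps[i]
      pos[ctg] <- start[i] + len[i]
    }
    panel_definition(tibble(
      chrom = paste0("chr", chrom_of),
      start = start,
      end = start + len
    ))
  })
}
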