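#' Construct a genome layout table
#'
#' A genome layout records chromosome names and lengths; every interval the
#' package handles must lie within `[0, chrom_length)` of a known chromosome.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in base pairs (>= 1).
#' @return A tibble with columns `chrom` and `length`.
#' @export
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
genome_layout <- function(chrom, length) {
  if (anyDuplicated(chrom) > 0) stop("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(length < 1)) stop("chromosome lengths must be >= 1")
  tibble::tibble(chrom = as.character(chrom), length = length)
}

#' Validate and sort a genomic interval table
#'
#' Intervals use the BED convention throughout: 0-based starts, exclusive
#' ends, so `length = end - start` and abutting intervals never overlap.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and optionally
#'   `signal` (nonnegative) and `name`.
#' @param genome Optional genome layout; intervals on unknown chromosomes or
#'   out of bounds are rejected.
#' @return A tibble sorted by (chrom, start, end).
#' @export
as_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing interval columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(is.na(x$start)) || any(is.na(x$end))) stop("non-numeric coordinates")
  if (any(x$start < 0)) stop("negative start coordinate")
  if (any(x$start >= x$end)) stop("start must be < end (0-based half-open)")
  if ("signal" %in% names(x) && any(x$signal < 0, na.rm = TRUE)) {
    stop("signal must be nonnegative")
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown)) {
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    }
    lens <- genome$length[match(x$chrom, genome$chrom)]
    if (any(x$end > lens)) stop("interval extends beyond chromosome end")
  }
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

# tibble (0-based half-open) -> GRanges (1-based closed). Internal only; all
# user-facing coordinates stay BED-convention.
iv_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

gr_to_iv <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}

#' Read a BED file
#'
#' Accepts BED3+ (tab-separated, 0-based half-open). An optional column is
#' interpreted as a per-interval signal (e.g. a SEACR peak score).
#'
#' @param path Path to a BED file.
#' @param signal_column 1-based column index holding the signal, or `NULL`.
#' @param genome Optional genome layout used to reject out-of-bounds records.
#' @return A sorted interval tibble (`chrom`, `start`, `end`, and `signal`
#'   when requested; column 4, if present, is kept as `name`).
#' @export
read_bed <- function(path, signal_column = NULL, genome = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  if (nrow(raw) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
    if (!is.null(signal_column)) out$signal <- numeric()
    return(out)
  }
  if (ncol(raw) < 3) stop("BED file must have at least 3 columns: ", path)
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end |
                 start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop(sprintf("malformed BED record at line %d of %s", bad[1], path))
  }
  out <- tibble::tibble(chrom = raw[[1]], start = start, end = end)
  if (ncol(raw) >= 4) out$name <- raw[[4]]
  if (!is.null(signal_column)) {
    if (signal_column > ncol(raw)) {
      stop("signal_column ", signal_column, " beyond last column of ", path)
    }
    sig <- suppressWarnings(as.numeric(raw[[signal_column]]))
    if (any(is.na(sig))) {
      stop(sprintf("non-numeric signal at line %d of %s", which(is.na(sig))[1], path))
    }
    out$signal <- sig
  }
  as_intervals(out, genome = genome)
}

#' Write intervals as BED
#'
#' Writes BED3 when the table carries neither name nor signal, otherwise
#' BED5-style columns (`chrom start end name score`) so that
#' `read_bed(write_bed(x), signal_column = 5)` round-trips.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  has_sig <- "signal" %in% names(x)
  if (has_sig) {
    nm <- if ("name" %in% names(x)) x$name else paste0("iv_", seq_len(nrow(x)))
    out <- tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                          name = nm, score = x$signal)
  } else if ("name" %in% names(x)) {
    out <- x[, c("chrom", "start", "end", "name")]
  } else {
    out <- x[, c("chrom", "start", "end")]
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Merge intervals closer than a gap
#'
#' Fuses intervals whose separation is at most `gap` base pairs; the signal
#' of a fused interval is the sum of its members' signals. With `gap = 0`
#' only overlapping intervals are fused (half-open abutment does not count
#' as overlap, but abutting intervals have gap 0 and are fused).
#'
#' @param x Interval tibble (may carry `signal`).
#' @param gap Maximum separation in bp to fuse across (>= 0).
#' @return Merged interval tibble with `n_members` and, when input had
#'   signal, summed `signal`.
#' @export
merge_intervals <- function(x, gap = 0) {
  if (gap < 0) stop("gap must be >= 0")
  x <- as_intervals(x)
  if (nrow(x) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          n_members = integer())
    if ("signal" %in% names(x)) out$signal <- numeric()
    return(out)
  }
  gr <- iv_to_gr(x)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1, with.revmap = TRUE)
  out <- gr_to_iv(red)
  revmap <- S4Vectors::mcols(red)$revmap
  out$n_members <- lengths(revmap)
  if ("signal" %in% names(x)) {
    out$signal <- vapply(revmap, function(i) sum(x$signal[i]), numeric(1))
  }
  as_intervals(out)
}

#' Enumerate overlapping interval pairs between two sets
#'
#' Returns every pair of intervals sharing at least `min_bp` bases. The
#' half-open convention means intervals that merely abut never pair.
#'
#' @param a,b Interval tibbles.
#' @param min_bp Minimum shared bases (>= 1).
#' @return A tibble with indices `idx_a`, `idx_b` into the sorted inputs,
#'   the pair coordinates, and `overlap_bp`.
#' @export
overlap_pairs <- function(a, b, min_bp = 1) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  a <- as_intervals(a)
  b <- as_intervals(b)
  empty <- tibble::tibble(idx_a = integer(), idx_b = integer(),
                          chrom = character(),
                          start_a = numeric(), end_a = numeric(),
                          start_b = numeric(), end_b = numeric(),
                          overlap_bp = numeric())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(iv_to_gr(a), iv_to_gr(b), minoverlap = min_bp)
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  if (length(ia) == 0) return(empty)
  tibble::tibble(
    idx_a = ia, idx_b = ib,
    chrom = a$chrom[ia],
    start_a = a$start[ia], end_a = a$end[ia],
    start_b = b$start[ib], end_b = b$end[ib],
    overlap_bp = pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  )
}

# Logical: which rows of a overlap >= 1 row of b (>= min_bp shared bases).
overlaps_any <- function(a, b, min_bp = 1) {
  a <- as_intervals(a)
  if (nrow(a) == 0) return(logical(0))
  b <- as_intervals(b)
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  hits <- GenomicRanges::findOverlaps(iv_to_gr(a), iv_to_gr(b), minoverlap = min_bp)
  seq_len(nrow(a)) %in% S4Vectors::queryHits(hits)
}

#' Read a BEDPE loop file
#'
#' Reads the first six columns (chrom1 start1 end1 chrom2 start2 end2) of a
#' tab-separated BEDPE file of chromatin loops.
#'
#' @param path Path to a BEDPE file.
#' @return A tibble with one row per loop and both anchors.
#' @export
read_bedpe <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  if (nrow(raw) == 0) {
    return(tibble::tibble(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                          chrom2 = character(), start2 = numeric(), end2 = numeric()))
  }
  if (ncol(raw) < 6) stop("BEDPE file must have at least 6 columns: ", path)
  num <- lapply(raw[c(2, 3, 5, 6)], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, is.na)) |
                 num[[1]] >= num[[2]] | num[[3]] >= num[[4]] |
                 num[[1]] < 0 | num[[3]] < 0)
  if (length(bad)) stop(sprintf("malformed BEDPE record at line %d of %s", bad[1], path))
  tibble::tibble(chrom1 = raw[[1]], start1 = num[[1]], end1 = num[[2]],
                 chrom2 = raw[[4]], start2 = num[[3]], end2 = num[[4]])
}

#' Read a bedGraph signal track
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value).
#' @return An interval tibble with a `value` column.
#' @export
read_bedgraph <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  if (nrow(raw) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          value = numeric()))
  }
  if (ncol(raw) < 4) stop("bedGraph must have 4 columns: ", path)
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  value <- suppressWarnings(as.numeric(raw[[4]]))
  bad <- which(is.na(start) | is.na(end) | is.na(value) | start < 0 | start >= end)
  if (length(bad)) stop(sprintf("malformed bedGraph record at line %d of %s", bad[1], path))
  dplyr::arrange(
    tibble::tibble(chrom = raw[[1]], start = start, end = end, value = value),
    .data$chrom, .data$start, .data$end
  )
}
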