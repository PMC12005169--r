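# Telomere window scan: count overlapping occurrences of a tandem-repeat
# query (default three units of the plant telomere repeat TTTAGGG, a 21-bp
# query) and its reverse complement in fixed-size windows, retain windows
# above a copy-number threshold, and classify contigs by whether their
# terminal windows carry telomeric signal. A perfect array of k repeat
# units contains k - 2 overlapping 21-mers.

#' Scan scaffolds for telomeric repeat windows
#'
#' Tiles each scaffold into non-overlapping windows and counts, at every
#' start position (overlapping matches included), occurrences of the query
#' `strrep(motif, repeats)` and of its reverse complement. Matches spanning
#' a window boundary are assigned to the window containing the match start;
#' the trailing partial window is counted as its own shorter window. `N`
#' bases never match.
#'
#' @param seqs Named character vector or `DNAStringSet` of scaffold
#'   sequences.
#' @param motif Telomere unit repeat (default `"TTTAGGG"`).
#' @param repeats Unit multiplicity of the query (default 3, giving the
#'   21-bp query).
#' @param window Window size in bases (default 1e6).
#' @param min_count Copy threshold for retaining a window (default 20).
#' @param joint If TRUE (default) the threshold applies to the sum of
#'   forward and reverse-complement counts; if FALSE, to each separately.
#' @return Data frame of class `telomere_windows`: `scaffold`,
#'   `window_index` (0-based), `start`, `end` (0-based half-open),
#'   `fwd_count`, `rev_count`, `retained`.
#' @export
scan_telomere_windows <- function(seqs, motif = "TTTAGGG", repeats = 3,
                                  window = 1e6, min_count = 20,
                                  joint = TRUE) {
  stopifnot(nchar(motif) > 0, repeats >= 1, min_count >= 1)
  if (grepl("[^ACGT]", motif)) stop("motif must be over A/C/G/T", call. = FALSE)
  query <- strrep(motif, repeats)
  if (window < nchar(query)) stop("window smaller than query", call. = FALSE)
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  qlen <- nchar(query)
  rquery <- .revcomp(query)
  out <- list()
  for (sc in names(seqs)) {
    s <- Biostrings::DNAString(seqs[[sc]])
    len <- length(s)
    if (len == 0) next
    starts <- seq(1L, len, by = as.integer(window))
    for (wi in seq_along(starts)) {
      wstart <- starts[wi]
      wend <- min(wstart + as.integer(window) - 1L, len)
      ext_end <- min(wend + qlen - 1L, len)
      sub <- Biostrings::subseq(s, wstart, ext_end)
      cnt <- function(q) {
        m <- Biostrings::matchPattern(q, sub)
        sum(Biostrings::start(m) <= (wend - wstart + 1L))
      }
      fwd <- cnt(query)
      rev <- cnt(rquery)
      retained <- if (joint) fwd + rev >= min_count else
        fwd >= min_count || rev >= min_count
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, window_index = wi - 1L,
        start = wstart - 1L, end = wend,
        fwd_count = fwd, rev_count = rev, retained = retained,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(0), window_index = integer(0),
               start = integer(0), end = integer(0),
               fwd_count = integer(0), rev_count = integer(0),
               retained = logical(0))
  class(res) <- c("telomere_windows", "data.frame")
  res
}

#' Classify contigs by terminal telomeric windows
#'
#' A contig is `both_ends` when both its first and last windows are
#' retained, `one_end` when exactly one is, and `none` otherwise (interior
#' telomeric windows do not count toward end status but are reported).
#'
#' @param windows Output of [scan_telomere_windows()].
#' @return Data frame: `scaffold`, `status` (`both_ends` / `one_end` /
#'   `none`), `end5`, `end3` (logical), `interior_windows` (count of
#'   retained non-terminal windows).
#' @export
classify_contig_telomeres <- function(windows) {
  out <- lapply(split(windows, windows$scaffold), function(w) {
    w <- w[order(w$window_index), ]
    e5 <- w$retained[1]
    e3 <- w$retained[nrow(w)]
    if (nrow(w) == 1) e3 <- e5  # single window is both ends
    interior <- if (nrow(w) > 2) sum(w$retained[2:(nrow(w) - 1)]) else 0L
    status <- if (e5 && e3) "both_ends" else if (e5 || e3) "one_end" else "none"
    data.frame(scaffold = w$scaffold[1], status = status,
               end5 = e5, end3 = e3, interior_windows = interior,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
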