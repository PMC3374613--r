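#' DUST-style low-complexity mask for one read
#'
#' Slides a window across the sequence and scores each window by the classic
#' triplet statistic `S = sum(c_t * (c_t - 1) / 2) / (L - 1)`, where `c_t`
#' counts each overlapping trinucleotide and `L` is the number of (N-free)
#' trinucleotides in the window. Windows scoring above `level` are masked in
#' full; overlapping masked spans are merged; N bases are always masked.
#'
#' @param sequence A single read sequence over `{A, C, G, T, N}`.
#' @param window Window length in bases (default 64; at least 8). Windows
#'   shorter than the read use the full read.
#' @param level Score threshold (default 2.0); higher is more permissive.
#' @return A list with `masked_intervals` (data.frame of 0-based half-open
#'   `start`, `end`) and `masked_fraction`.
#' @examples
#' dust_mask(strrep("A", 100))$masked_fraction  # 1: homopolymer
#' @export
dust_mask <- function(sequence, window = 64L, level = 2.0) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L) stop("dust_mask() takes a single sequence")
  if (window < 8L) stop("window must be at least 8")
  res <- cpp_dust_mask(sequence, as.integer(window), level)
  list(masked_intervals = data.frame(start = res$start, end = res$end),
       masked_fraction = res$masked_fraction)
}

#' Masked fraction of each read in a set
#'
#' Vectorized companion to [dust_mask()] returning only the masked fraction.
#'
#' @param reads Character vector of read sequences.
#' @inheritParams dust_mask
#' @return Numeric vector of masked fractions.
#' @export
dust_fractions <- function(reads, window = 64L, level = 2.0) {
  if (window < 8L) stop("window must be at least 8")
  cpp_dust_fractions(toupper(as.character(reads)), as.integer(window), level)
}

#' Screen reads for low complexity, orphaning broken pairs
#'
#' A read is removed when its masked fraction exceeds `max_masked_fraction`
#' (reads consisting entirely of N are always removed). When exactly one mate
#' of a pair is removed, the survivor is orphaned into the fragment set; when
#' both are removed the pair vanishes. Input order is preserved within each
#' output set, with orphans appended after the surviving original fragments.
#'
#' @param r1,r2 Named character vectors of mate sequences (equal length,
#'   positionally paired).
#' @param fragments Named character vector of single-end reads (may be empty).
#' @param max_masked_fraction Removal threshold in `(0, 1]` (default 0.5).
#' @inheritParams dust_mask
#' @return A list: `r1`, `r2` (kept pairs), `fragments` (kept fragments plus
#'   orphans) and `removed` (data.frame: `read_id`, `masked_fraction`).
#' @export
filter_reads <- function(r1, r2, fragments = character(0),
                         max_masked_fraction = 0.5, window = 64L,
                         level = 2.0) {
  if (!(max_masked_fraction > 0 && max_masked_fraction <= 1))
    stop("max_masked_fraction must be in (0, 1]")
  if (length(r1) != length(r2))
    stop("mate files have unequal length: ", length(r1), " vs ", length(r2))
  f1 <- dust_fractions(r1, window, level)
  f2 <- dust_fractions(r2, window, level)
  ff <- dust_fractions(fragments, window, level)
  drop1 <- f1 > max_masked_fraction | cpp_all_n(toupper(as.character(r1)))
  drop2 <- f2 > max_masked_fraction | cpp_all_n(toupper(as.character(r2)))
  dropf <- ff > max_masked_fraction | cpp_all_n(toupper(as.character(fragments)))

  keep_pair <- !drop1 & !drop2
  orphan1 <- !drop1 & drop2
  orphan2 <- drop1 & !drop2
  removed <- data.frame(
    read_id = c(names(r1)[drop1], names(r2)[drop2], names(fragments)[dropf]),
    masked_fraction = c(f1[drop1], f2[drop2], ff[dropf]),
    stringsAsFactors = FALSE)
  list(r1 = r1[keep_pair], r2 = r2[keep_pair],
       fragments = c(fragments[!dropf], r1[orphan1], r2[orphan2]),
       removed = removed)
}
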