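#' Build a seed index over a reference database
#'
#' Canonical (strand-minimum) k-mers of every reference sequence are stored
#' with their positions; seeds occurring more often than
#' `max_seed_occupancy` are dropped as repetitive. Construction is
#' deterministic.
#'
#' @param db A `ReferenceDB`.
#' @param k Seed length (default 16, at least 11).
#' @param max_seed_occupancy Maximum number of reference positions a seed may
#'   have before it is discarded (default 1024).
#' @return A `SeedIndex` object.
#' @export
build_index <- function(db, k = 16L, max_seed_occupancy = 1024L) {
  stopifnot(is(db, "ReferenceDB"))
  k <- as.integer(k)
  if (k < 11L) stop("seed length k must be at least 11")
  ptr <- cpp_build_index(db$seq_info$sequence_id,
                         toupper(as.character(db$sequences)),
                         k, as.integer(max_seed_occupancy))
  structure(list(ptr = ptr, k = k,
                 max_seed_occupancy = as.integer(max_seed_occupancy),
                 sequence_ids = db$seq_info$sequence_id,
                 db = db),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  s <- index_stats(x)
  cat(sprintf(
    "SeedIndex: k=%d over %d sequences; %s seeds, %s positions (%s repetitive seeds dropped)\n",
    s$k, s$n_sequences, format(s$n_seeds, big.mark = ","),
    format(s$n_positions, big.mark = ","), format(s$n_dropped, big.mark = ",")))
  invisible(x)
}

#' Seed index summary statistics
#'
#' @param index A `SeedIndex`.
#' @return A list: `k`, `max_seed_occupancy`, `n_seeds` (distinct retained
#'   seeds), `n_positions` (retained positions), `n_dropped` (repetitive
#'   seeds discarded), `n_sequences`.
#' @export
index_stats <- function(index) {
  stopifnot(is(index, "SeedIndex"))
  cpp_index_stats(index$ptr)
}

#' Reference positions of one seed
#'
#' @param index A `SeedIndex`.
#' @param kmer A k-length ACGT string.
#' @return data.frame: `sequence_id`, `pos` (0-based), `forward_match`
#'   (whether the reference forward strand carries `kmer` itself, as opposed
#'   to its reverse complement).
#' @export
seed_positions <- function(index, kmer) {
  stopifnot(is(index, "SeedIndex"))
  d <- cpp_index_lookup(index$ptr, toupper(kmer))
  data.frame(sequence_id = index$sequence_ids[d$seq], pos = d$pos,
             forward_match = as.logical(d$forward_match),
             stringsAsFactors = FALSE)
}

# default scoring; the pipeline's contract fixes only the filter thresholds
default_scoring <- function() {
  list(match = 1L, mismatch = 2L, gap_open = 3L, gap_ext = 1L)
}

new_hitsets <- function(reads_df, hits_df) {
  structure(list(reads = reads_df, hits = hits_df), class = "HitSets")
}

#' @export
print.HitSets <- function(x, ...) {
  n <- nrow(x$reads)
  mapped <- sum(x$reads$n_hits > 0)
  tied <- sum(x$reads$n_hits > 1)
  cat(sprintf("HitSets: %d reads; %d mapped (%.1f%%), %d with tied best hits\n",
              n, mapped, if (n) 100 * mapped / n else 0, tied))
  invisible(x)
}

#' Map reads against an indexed reference
#'
#' Seed-and-extend mapping under length/identity filters: alignments with identity
#' below `min_similarity` or aligned query fraction below
#' `min_length_fraction` are discarded; among survivors the maximal score
#' defines the per-read set of equally-best hits. Each candidate locus
#' contributes its best local alignment and the length filter measures that
#' alignment's soft-clipping, so `min_length_fraction = 1` admits only reads
#' whose optimal alignment is end-to-end. Scoring is
#' match +1, mismatch -2, gap of length L costs 3 + L; identity counts
#' matches over all alignment columns including gap columns.
#'
#' @param reads Named character vector of read sequences.
#' @param index A [build_index()] result.
#' @param min_length_fraction Minimum aligned fraction of the query
#'   (default 0.75).
#' @param min_similarity Minimum identity within the alignment
#'   (default 0.80).
#' @return A `HitSets` object: `$reads` (read_id, best_score, n_hits,
#'   suppressed_count) and `$hits` (read_id, sequence_id, ref_start, ref_end
#'   0-based half-open, strand, score, matches, columns, identity,
#'   query_aligned_fraction, cigar).
#' @export
map_reads <- function(reads, index, min_length_fraction = 0.75,
                      min_similarity = 0.80) {
  stopifnot(is(index, "SeedIndex"))
  if (!(min_length_fraction > 0 && min_length_fraction <= 1) ||
      !(min_similarity > 0 && min_similarity <= 1))
    stop("filters must be in (0, 1]")
  ids <- names(reads)
  if (length(reads) && is.null(ids)) stop("reads must be named")
  short <- nchar(reads) < index$k
  if (any(short))
    warning(sum(short), " read(s) shorter than the seed length are unmappable")
  sc <- default_scoring()
  res <- cpp_map(index$ptr, toupper(as.character(reads)),
                 min_length_fraction, min_similarity,
                 sc$match, sc$mismatch, sc$gap_open, sc$gap_ext)
  h <- res$hits
  rl <- nchar(reads)[h$read]
  hits <- data.frame(
    read_id = ids[h$read],
    sequence_id = index$sequence_ids[h$seq],
    ref_start = h$start, ref_end = h$end,
    strand = ifelse(h$strand == 1L, "-", "+"),
    score = h$score, matches = h$matches, columns = h$columns,
    identity = h$matches / h$columns,
    query_aligned_fraction = (h$qend - h$qstart) / rl,
    cigar = h$cigar, stringsAsFactors = FALSE)
  reads_df <- data.frame(read_id = if (is.null(ids)) character(0) else ids,
                         best_score = res$best_score,
                         n_hits = res$n_hits,
                         suppressed_count = res$suppressed,
                         stringsAsFactors = FALSE)
  new_hitsets(reads_df, hits)
}

#' Map a single read
#'
#' @param read A single (optionally named) read sequence.
#' @inheritParams map_reads
#' @return A `HitSets` with one read.
#' @export
map_read <- function(read, index, min_length_fraction = 0.75,
                     min_similarity = 0.80) {
  if (is.null(names(read))) names(read) <- "read1"
  map_reads(read, index, min_length_fraction, min_similarity)
}

#' Map paired-end and fragment reads together
#'
#' Mates are mapped independently; for pairs where both mates have hits, the
#' tied hits of each mate that participate in a proper pair (opposite
#' strands, forward/reverse orientation, fragment span within
#' `insert_range` on the same sequence) are promoted: when at least one
#' proper combination exists, non-participating tied hits are demoted from
#' that mate's hit set. Fragments are mapped as singletons in the same pass.
#'
#' @param r1,r2 Named character vectors of mates (`.../1`, `.../2` naming;
#'   pairing is positional).
#' @param fragments Named character vector of single-end reads.
#' @param index A [build_index()] result.
#' @inheritParams map_reads
#' @param insert_range Allowed fragment span `c(min, max)` in bases
#'   (default `c(180, 250)`).
#' @return A list: `hitsets` (combined `HitSets` over all reads) and
#'   `pairing` (data.frame per pair: `pair_id`, `proper`, `demoted`).
#' @export
map_pairs <- function(r1, r2, fragments = character(0), index,
                      min_length_fraction = 0.75, min_similarity = 0.80,
                      insert_range = c(180L, 250L)) {
  if (length(r1) != length(r2))
    stop("mate vectors have unequal length")
  hs1 <- map_reads(r1, index, min_length_fraction, min_similarity)
  hs2 <- map_reads(r2, index, min_length_fraction, min_similarity)
  hsf <- map_reads(fragments, index, min_length_fraction, min_similarity)

  pair_id <- if (length(r1)) sub("/[12]$", "", names(r1)) else character(0)
  pairing <- data.frame(pair_id = pair_id,
                        proper = logical(length(pair_id)),
                        demoted = integer(length(pair_id)),
                        stringsAsFactors = FALSE)
  if (length(r1)) {
    h1 <- hs1$hits; h1$pair <- sub("/[12]$", "", h1$read_id)
    h2 <- hs2$hits; h2$pair <- sub("/[12]$", "", h2$read_id)
    both <- intersect(unique(h1$pair), unique(h2$pair))
    if (length(both)) {
      m <- merge(h1[h1$pair %in% both, c("pair", "read_id", "sequence_id",
                                         "ref_start", "ref_end", "strand")],
                 h2[h2$pair %in% both, c("pair", "read_id", "sequence_id",
                                         "ref_start", "ref_end", "strand")],
                 by = c("pair", "sequence_id"), suffixes = c("_1", "_2"))
      if (nrow(m)) {
        fwd_first <- ifelse(m$strand_1 == "+", m$ref_start_1, m$ref_start_2)
        rev_start <- ifelse(m$strand_1 == "+", m$ref_start_2, m$ref_start_1)
        span <- pmax(m$ref_end_1, m$ref_end_2) - pmin(m$ref_start_1, m$ref_start_2)
        proper <- m$strand_1 != m$strand_2 & fwd_first <= rev_start &
          span >= insert_range[1] & span <= insert_range[2]
        pm <- m[proper, , drop = FALSE]
        if (nrow(pm)) {
          key1 <- paste(pm$read_id_1, pm$sequence_id, pm$ref_start_1, pm$strand_1)
          key2 <- paste(pm$read_id_2, pm$sequence_id, pm$ref_start_2, pm$strand_2)
          proper_keys <- unique(c(key1, key2))
          proper_reads <- unique(c(pm$read_id_1, pm$read_id_2))
          demote <- function(hs) {
            hk <- paste(hs$hits$read_id, hs$hits$sequence_id,
                        hs$hits$ref_start, hs$hits$strand)
            drop <- hs$hits$read_id %in% proper_reads & !(hk %in% proper_keys)
            dropped_pairs <- sub("/[12]$", "", hs$hits$read_id[drop])
            if (any(drop)) {
              hs$hits <- hs$hits[!drop, , drop = FALSE]
              nh <- table(hs$hits$read_id)
              hs$reads$n_hits <- as.integer(nh[hs$reads$read_id])
              hs$reads$n_hits[is.na(hs$reads$n_hits)] <- 0L
            }
            list(hs = hs, dropped_pairs = dropped_pairs)
          }
          d1 <- demote(hs1); d2 <- demote(hs2)
          hs1 <- d1$hs; hs2 <- d2$hs
          pairing$proper <- pairing$pair_id %in% unique(pm$pair)
          dem <- table(c(d1$dropped_pairs, d2$dropped_pairs))
          got <- match(pairing$pair_id, names(dem))
          pairing$demoted <- ifelse(is.na(got), 0L, as.integer(dem[got]))
        }
      }
    }
  }
  hitsets <- new_hitsets(rbind(hs1$reads, hs2$reads, hsf$reads),
                         rbind(hs1$hits, hs2$hits, hsf$hits))
  list(hitsets = hitsets, pairing = pairing)
}
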