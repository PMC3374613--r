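#' Resolve equally-best hits into final placements
#'
#' Converts per-read hit sets into placements under the standard
#' multi-mapping strategies:
#' \describe{
#'   \item{`top_random`}{one best hit per read; among equally-scoring best
#'     hits one is chosen uniformly at random by a generator keyed on
#'     `(seed, read_id)`, so resolution is reproducible and independent of
#'     input order.}
#'   \item{`unique_only`}{a read is placed only when it has a single best
#'     placement; tied reads are suppressed.}
#'   \item{`topN`}{all tied best hits are reported when their count is at
#'     most `n`; reads tied at more than `n` loci are suppressed.}
#'   \item{`all_hits`}{every tied best hit is reported.}
#' }
#'
#' @param hitsets A `HitSets` object (from [map_reads()] or [map_pairs()]).
#' @param strategy One of `"top_random"`, `"unique_only"`, `"topN"`,
#'   `"all_hits"`.
#' @param seed Integer seed; required for `top_random`.
#' @param n Maximum reported ties for `topN` (default 5).
#' @return A `Placements` data.frame (ordered by read id) with columns
#'   `read_id`, `sequence_id`, `ref_start`, `ref_end`, `strand`, `score`,
#'   `matches`, `columns`, `cigar`, `mapq`, `status`
#'   (`placed`/`unmapped`/`suppressed_multi`) and `tie_count`.
#' @export
resolve_hits <- function(hitsets,
                         strategy = c("top_random", "unique_only", "topN",
                                      "all_hits"),
                         seed = NULL, n = 5L) {
  strategy <- match.arg(strategy)
  stopifnot(is(hitsets, "HitSets"))
  if (strategy == "top_random" && is.null(seed))
    stop("top_random requires a seed (reproducibility contract)")
  if (strategy == "topN" && (!is.numeric(n) || n < 1))
    stop("topN requires n >= 1")

  rd <- hitsets$reads[order(hitsets$reads$read_id), , drop = FALSE]
  h <- hitsets$hits[order(hitsets$hits$read_id, hitsets$hits$sequence_id,
                          hitsets$hits$ref_start, hitsets$hits$strand), ,
                    drop = FALSE]

  empty_like <- function(ids, status, ties) {
    k <- length(ids)
    data.frame(read_id = ids, sequence_id = rep(NA_character_, k),
               ref_start = rep(NA_integer_, k), ref_end = rep(NA_integer_, k),
               strand = rep(NA_character_, k), score = rep(NA_integer_, k),
               matches = rep(NA_integer_, k), columns = rep(NA_integer_, k),
               cigar = rep(NA_character_, k), mapq = rep(NA_integer_, k),
               status = rep(status, k), tie_count = rep_len(as.integer(ties), k),
               stringsAsFactors = FALSE)
  }
  placed_from <- function(rows, ties) {
    data.frame(read_id = rows$read_id, sequence_id = rows$sequence_id,
               ref_start = rows$ref_start, ref_end = rows$ref_end,
               strand = rows$strand, score = rows$score,
               matches = rows$matches, columns = rows$columns,
               cigar = rows$cigar,
               mapq = ifelse(rep_len(ties, nrow(rows)) >= 2L, 0L, 60L),
               status = rep("placed", nrow(rows)),
               tie_count = rep_len(as.integer(ties), nrow(rows)),
               stringsAsFactors = FALSE)
  }

  unmapped <- empty_like(rd$read_id[rd$n_hits == 0L], "unmapped", 0L)
  mapped <- rd[rd$n_hits > 0L, , drop = FALSE]
  first_hit <- match(mapped$read_id, h$read_id)

  out <- switch(strategy,
    top_random = {
      pick <- cpp_tie_pick(mapped$read_id, as.integer(seed), mapped$n_hits)
      placed_from(h[first_hit + pick - 1L, , drop = FALSE], mapped$n_hits)
    },
    unique_only = {
      uni <- mapped$n_hits == 1L
      rbind(placed_from(h[first_hit[uni], , drop = FALSE], 1L),
            empty_like(mapped$read_id[!uni], "suppressed_multi",
                       mapped$n_hits[!uni]))
    },
    topN = {
      ok <- mapped$n_hits <= n
      keep <- h$read_id %in% mapped$read_id[ok]
      ties <- mapped$n_hits[match(h$read_id[keep], mapped$read_id)]
      rbind(placed_from(h[keep, , drop = FALSE], ties),
            empty_like(mapped$read_id[!ok], "suppressed_multi",
                       mapped$n_hits[!ok]))
    },
    all_hits = {
      ties <- mapped$n_hits[match(h$read_id, mapped$read_id)]
      placed_from(h, ties)
    })

  out <- rbind(out, unmapped)
  out <- out[order(out$read_id, out$sequence_id, out$ref_start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("Placements", "data.frame"),
            strategy = strategy, seed = seed)
}
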