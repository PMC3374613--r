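#' Per-strain breadth and depth of coverage
#'
#' Accumulates per-base coverage over the reference spans
#' `[ref_start, ref_end)` of all placed alignments and aggregates per strain
#' across all member sequences (chromosome plus plasmids). Breadth is the
#' percentage of strain bases covered at least once; depth is the sum of
#' per-base coverages divided by the strain's total length. Strains with no
#' placements get explicit zero rows. With multi-placement strategies
#' (`topN`, `all_hits`) every emitted placement contributes.
#'
#' @param placements A `Placements` data.frame (or any data.frame with
#'   `sequence_id`, `ref_start`, `ref_end`, `status` columns).
#' @param db The `ReferenceDB` mapped against.
#' @return A `CoverageStats` data.frame: `prefix`, `breadth` (percent),
#'   `depth` (x), `covered_bases`, `assigned_reads`, `detected` (NA until
#'   [apply_detection()] is applied).
#' @export
compute_coverage <- function(placements, db) {
  stopifnot(is(db, "ReferenceDB"))
  p <- as.data.frame(placements, stringsAsFactors = FALSE)
  p <- p[!is.na(p$sequence_id) & p$status == "placed", , drop = FALSE]
  unknown <- setdiff(unique(p$sequence_id), db$seq_info$sequence_id)
  if (length(unknown))
    stop("placement on unknown sequence: ", unknown[1])

  cov_bases <- stats::setNames(numeric(nrow(db$seq_info)),
                               db$seq_info$sequence_id)
  cov_sum <- cov_bases
  if (nrow(p)) {
    by_seq <- split(p[, c("ref_start", "ref_end")], p$sequence_id)
    for (sid in names(by_seq)) {
      d <- by_seq[[sid]]
      width <- db$seq_info$length[db$seq_info$sequence_id == sid]
      cov <- IRanges::coverage(IRanges::IRanges(start = d$ref_start + 1L,
                                                end = d$ref_end),
                               width = width)
      rl <- S4Vectors::runLength(cov)
      rv <- S4Vectors::runValue(cov)
      cov_bases[sid] <- sum(rl[rv > 0])
      cov_sum[sid] <- sum(as.numeric(rv) * rl)
    }
  }
  prefixes <- db$strains$prefix
  agg <- function(v) vapply(prefixes, function(pr)
    sum(v[db$seq_info$sequence_id[db$seq_info$prefix == pr]]), numeric(1))
  covered <- agg(cov_bases)
  total_cov <- agg(cov_sum)
  strain_len <- db$strains$total_length
  n_assigned <- table(db$seq_info$prefix[match(p$sequence_id,
                                               db$seq_info$sequence_id)])
  assigned <- as.integer(ifelse(prefixes %in% names(n_assigned),
                                n_assigned[prefixes], 0L))
  out <- data.frame(prefix = prefixes,
                    breadth = 100 * covered / strain_len,
                    depth = total_cov / strain_len,
                    covered_bases = as.numeric(covered),
                    assigned_reads = assigned,
                    detected = NA,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("CoverageStats", "data.frame")
  out
}

#' Apply the detection cutoff
#'
#' A strain is called detected when breadth and depth both reach their
#' thresholds (inclusive). The defaults — 1% breadth and 0.01x depth —
#' admit low-abundance organisms while suppressing spurious alignments.
#'
#' @param stats A `CoverageStats` data.frame.
#' @param min_breadth Minimum breadth in percent (default 1).
#' @param min_depth Minimum depth in x (default 0.01).
#' @return `stats` with the `detected` flag filled in.
#' @export
apply_detection <- function(stats, min_breadth = 1.0, min_depth = 0.01) {
  if (min_breadth < 0 || min_depth < 0) stop("thresholds must be >= 0")
  stats$detected <- stats$breadth >= min_breadth & stats$depth >= min_depth
  stats
}

#' Roll strain coverage up to species or genus abundance tables
#'
#' Taxon breadth and depth are the unweighted arithmetic means over the
#' member strains present in the database. A taxon is detected when any
#' member strain is detected; relative abundance is taxon depth divided by
#' the summed depth of detected taxa.
#'
#' @param stats A `CoverageStats` with `detected` flags (see
#'   [apply_detection()]).
#' @param db The `ReferenceDB`.
#' @param level `"strain"`, `"species"` or `"genus"`.
#' @return An `AbundanceTable` data.frame: `level`, `taxon`, `breadth`,
#'   `depth`, `covered_bases`, `assigned_reads`, `detected`,
#'   `relative_abundance`, `n_strains_in_db`.
#' @export
rollup <- function(stats, db, level = c("species", "genus", "strain")) {
  level <- match.arg(level)
  stopifnot(is(db, "ReferenceDB"))
  if (any(is.na(stats$detected)))
    stop("apply_detection() must be run before rollup()")
  taxon <- switch(level,
                  strain = db$strains$prefix[match(stats$prefix,
                                                   db$strains$prefix)],
                  species = db$strains$species[match(stats$prefix,
                                                     db$strains$prefix)],
                  genus = db$strains$genus[match(stats$prefix,
                                                 db$strains$prefix)])
  agg <- function(v, f) as.numeric(tapply(v, taxon, f))  # sorted-taxon order
  taxa <- sort(unique(taxon))
  out <- data.frame(
    level = level, taxon = taxa,
    breadth = agg(stats$breadth, mean),
    depth = agg(stats$depth, mean),
    covered_bases = agg(stats$covered_bases, sum),
    assigned_reads = agg(stats$assigned_reads, sum),
    detected = as.logical(agg(stats$detected, any)),
    n_strains_in_db = as.integer(table(taxon)[taxa]),
    stringsAsFactors = FALSE)
  if (!any(out$detected)) out <- out[0L, , drop = FALSE]
  denom <- sum(out$depth[out$detected])
  out$relative_abundance <- ifelse(out$detected & denom > 0,
                                   out$depth / denom, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("AbundanceTable", "data.frame")
  out
}
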