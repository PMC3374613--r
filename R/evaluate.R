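#' Classify read fates against the simulated truth
#'
#' Each read receives exactly one fate: `correct_strain` when placed on its
#' true source strain; `correct_at_level` when placed on another strain that
#' shares the source's species or genus (per `level`); `wrong_taxon` when
#' placed outside the source taxon at that level; `unmapped`; or
#' `suppressed_multi` (suppressed under unique-only/topN resolution). Reads
#' with multiple emitted placements (topN/all-hits strategies) are
#' classified by their best-resolvable fate and counted separately in
#' `ambiguous_multi`.
#'
#' @param placements A `Placements` data.frame.
#' @param truth Truth table data.frame (`read_id`, `prefix`, ...).
#' @param db The `ReferenceDB` mapped against.
#' @param level `"strain"`, `"species"` or `"genus"`.
#' @return A `FateCounts` list: `level`, `counts` (named integer vector over
#'   the five fates), `total`, `fractions`, `ambiguous_multi`.
#' @export
classify_fates <- function(placements, truth, db,
                           level = c("strain", "species", "genus")) {
  level <- match.arg(level)
  stopifnot(is(db, "ReferenceDB"))
  p <- as.data.frame(placements, stringsAsFactors = FALSE)
  missing_truth <- setdiff(p$read_id[p$status == "placed"], truth$read_id)
  if (length(missing_truth))
    stop("placed read missing from truth table: ", missing_truth[1])

  truth_prefix <- truth$prefix[match(p$read_id, truth$read_id)]
  placed_prefix <- db$seq_info$prefix[match(p$sequence_id,
                                            db$seq_info$sequence_id)]
  st <- db$strains
  lineage <- function(pr, what) st[[what]][match(pr, st$prefix)]

  fate <- character(nrow(p))
  fate[p$status == "unmapped"] <- "unmapped"
  fate[p$status == "suppressed_multi"] <- "suppressed_multi"
  placed <- p$status == "placed"
  same_strain <- placed & placed_prefix == truth_prefix
  fate[same_strain] <- "correct_strain"
  rest <- placed & !same_strain
  if (level == "strain") {
    fate[rest] <- "wrong_taxon"
  } else {
    same_tax <- lineage(placed_prefix, level) == lineage(truth_prefix, level)
    fate[rest & same_tax] <- "correct_at_level"
    fate[rest & !same_tax] <- "wrong_taxon"
  }

  # one fate per read: best fate among multiple emitted placements
  rank <- c(correct_strain = 1L, correct_at_level = 2L, wrong_taxon = 3L,
            suppressed_multi = 4L, unmapped = 5L)
  fr <- rank[fate]
  best <- tapply(fr, p$read_id, min)
  multi <- tapply(fr, p$read_id, length)
  fates <- names(rank)[best]
  counts <- stats::setNames(integer(5), names(rank))
  tab <- table(fates)
  counts[names(tab)] <- as.integer(tab)
  total <- length(best)
  structure(list(level = level, counts = counts, total = total,
                 fractions = counts / total,
                 ambiguous_multi = sum(multi > 1L)),
            class = "FateCounts")
}

#' @export
print.FateCounts <- function(x, ...) {
  cat(sprintf("FateCounts (%s level), %d reads:\n", x$level, x$total))
  for (nm in names(x$counts))
    cat(sprintf("  %-17s %9d (%5.1f%%)\n", nm, x$counts[[nm]],
                100 * x$fractions[[nm]]))
  if (x$ambiguous_multi)
    cat(sprintf("  (%d reads had multiple emitted placements)\n",
                x$ambiguous_multi))
  invisible(x)
}

#' Tie-corrected Spearman rank correlation
#'
#' Average-rank Spearman coefficient between two vectors (e.g. true mock
#' concentrations versus detected depths).
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation is undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Chi-square comparison of two depth-of-coverage profiles
#'
#' Scales profile `b` to the total of profile `a` (expected values
#' `e_i = b_i * sum(a) / sum(b)`), computes the goodness-of-fit statistic
#' `X2 = sum((a_i - e_i)^2 / e_i)`, and returns the upper-tail p-value on
#' `n - 1` degrees of freedom. p-values at or above 0.05 are read as the two
#' profiles being similar.
#'
#' @param depths_a,depths_b Per-strain depth vectors in the same strain
#'   order (length at least 2; all of `b` positive — drop undetected
#'   strains first).
#' @return An object of class `htest` with `statistic`, `parameter` (df) and
#'   `p.value`.
#' @export
chisq_depth_compare <- function(depths_a, depths_b) {
  if (length(depths_a) != length(depths_b))
    stop("depth vectors must have equal length")
  n <- length(depths_a)
  if (n < 2) stop("need at least 2 strains")
  e <- depths_b * sum(depths_a) / sum(depths_b)
  if (any(e <= 0))
    stop("zero expected depth; drop undetected strains before comparing")
  x2 <- sum((depths_a - e)^2 / e)
  p <- stats::pchisq(x2, df = n - 1, lower.tail = FALSE)
  structure(list(statistic = c("X-squared" = x2),
                 parameter = c(df = n - 1), p.value = p,
                 method = "Chi-square comparison of depth-of-coverage profiles",
                 data.name = "depths_a vs depths_b"),
            class = "htest")
}

#' Paired log-depth table for reference vs amended databases
#'
#' For each taxon, the log10 depth under the reference database and under
#' the amended database. Taxa with equal depths lie on the diagonal; taxa
#' whose strains were swapped for more divergent congeners fall below it.
#' Zero or absent depths are reported as missing, not -Inf.
#'
#' @param tab_ref,tab_amended `AbundanceTable`s computed at the same level
#'   from the same query reads.
#' @return data.frame: `taxon`, `log10_depth_ref`, `log10_depth_amended`.
#' @export
depth_log_ratio <- function(tab_ref, tab_amended) {
  if (nrow(tab_ref) && nrow(tab_amended) &&
      !identical(tab_ref$level[1], tab_amended$level[1]))
    stop("profiles must be computed at the same taxonomic level")
  m <- merge(tab_ref[, c("taxon", "depth")],
             tab_amended[, c("taxon", "depth")],
             by = "taxon", all = TRUE, suffixes = c("_ref", "_amended"))
  safe_log10 <- function(v) ifelse(!is.na(v) & v > 0, log10(v), NA_real_)
  data.frame(taxon = m$taxon,
             log10_depth_ref = safe_log10(m$depth_ref),
             log10_depth_amended = safe_log10(m$depth_amended),
             stringsAsFactors = FALSE)
}
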