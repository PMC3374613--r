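#' Write resolved placements as SAM
#'
#' Emits one record per placement row. Reads that were resolved from tied
#' best hits carry MAPQ 0; uniquely placed reads carry MAPQ 60. Unmapped and
#' suppressed reads are written with FLAG 4 (a `ZS:Z:` tag preserves the
#' suppression status and `ZT:i:` the tie count). Coordinates are converted
#' from the package's 0-based half-open convention to SAM's 1-based POS.
#'
#' @param placements A `Placements` data.frame from [resolve_hits()].
#' @param db The `ReferenceDB` the reads were mapped against.
#' @param path Output path.
#' @param reads Optional named character vector with the read sequences; when
#'   supplied, SEQ is emitted (reverse-complemented for minus-strand
#'   placements, per SAM convention), otherwise `*`.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(placements, db, path, reads = NULL) {
  stopifnot(is(db, "ReferenceDB"))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", db$seq_info$sequence_id,
                   db$seq_info$length),
           "@PG\tID:mockmap\tPN:mockmap")
  p <- as.data.frame(placements, stringsAsFactors = FALSE)
  placed <- !is.na(p$sequence_id) & p$status == "placed"

  seq_field <- rep("*", nrow(p))
  if (!is.null(reads)) {
    seq_field <- unname(reads[p$read_id])
    rev <- placed & p$strand == "-"
    seq_field[rev] <- rc_chr(seq_field[rev])
    seq_field[is.na(seq_field)] <- "*"
  }
  flag <- ifelse(placed, ifelse(p$strand == "-", 16L, 0L), 4L)
  rname <- ifelse(placed, p$sequence_id, "*")
  pos <- ifelse(placed, p$ref_start + 1L, 0L)
  mapq <- ifelse(placed, p$mapq, 0L)
  cig <- ifelse(placed, p$cigar, "*")
  tags <- ifelse(placed,
                 sprintf("AS:i:%d\tNM:i:%d\tZT:i:%d", p$score,
                         p$columns - p$matches, p$tie_count),
                 sprintf("ZS:Z:%s\tZT:i:%d", p$status, p$tie_count))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\t%s",
                 p$read_id, flag, rname, pos, mapq, cig, seq_field, tags)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# parse CIGAR strings into per-record op/length lists
parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  regmatches(cigar, m)
}

cigar_stats <- function(cigar) {
  toks <- parse_cigar(cigar)
  t(vapply(toks, function(tk) {
    len <- as.integer(sub("[MIDNSHP=X]$", "", tk))
    op <- sub("^\\d+", "", tk)
    gap_runs <- op %in% c("I", "D")
    c(M = sum(len[op %in% c("M", "=", "X")]),
      I = sum(len[op == "I"]), D = sum(len[op == "D"]),
      S = sum(len[op == "S"]),
      n_gap_runs = sum(gap_runs))
  }, numeric(5)))
}

#' Read a SAM file into hit sets
#'
#' Ingests external aligner output: records are grouped per read and the
#' top-scoring entries form each read's hit set. The alignment score is
#' taken from the `AS:i:` tag when present, otherwise recomputed from
#' CIGAR and `NM:i:` under the package scoring scheme (match +1,
#' mismatch -2, gap of length L costs 3 + L).
#'
#' @param path SAM path.
#' @param db The `ReferenceDB` named in the header.
#' @return A `HitSets` object.
#' @export
read_sam <- function(path, db) {
  stopifnot(is(db, "ReferenceDB"))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (!length(body)) return(new_hitsets(
    data.frame(read_id = character(0), best_score = integer(0),
               n_hits = integer(0), suppressed_count = integer(0),
               stringsAsFactors = FALSE),
    data.frame(read_id = character(0), sequence_id = character(0),
               ref_start = integer(0), ref_end = integer(0),
               strand = character(0), score = integer(0),
               matches = integer(0), columns = integer(0),
               identity = numeric(0), query_aligned_fraction = numeric(0),
               cigar = character(0), stringsAsFactors = FALSE)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM line (fewer than 11 fields) at line ",
         which(nf < 11)[1] + sum(startsWith(lines, "@")))
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  cig <- vapply(fields, `[[`, "", 6L)
  tag_of <- function(f, tag) {
    if (length(f) < 12) return(NA_character_)
    extra <- f[12:length(f)]
    hit <- extra[startsWith(extra, tag)]
    if (length(hit)) sub(tag, "", hit[1]) else NA_character_
  }
  as_tag <- vapply(fields, tag_of, "", "AS:i:")
  nm_tag <- vapply(fields, tag_of, "", "NM:i:")

  mapped <- !bitwAnd(flag, 4L)
  unknown <- mapped & !(rname %in% db$seq_info$sequence_id)
  if (any(unknown))
    stop("unknown reference name in SAM: ", rname[which(unknown)[1]])

  hits <- NULL
  if (any(mapped)) {
    cs <- cigar_stats(cig[mapped])
    rl <- cs[, "M"] + cs[, "I"] + cs[, "S"]
    columns <- cs[, "M"] + cs[, "I"] + cs[, "D"]
    gap_bases <- cs[, "I"] + cs[, "D"]
    nm <- suppressWarnings(as.integer(nm_tag[mapped]))
    nm[is.na(nm)] <- gap_bases[is.na(nm)]  # assume no mismatches if NM absent
    mismatches <- pmax(nm - gap_bases, 0)
    matches <- cs[, "M"] - mismatches
    sc <- default_scoring()
    score_rec <- matches * sc$match - mismatches * sc$mismatch -
      cs[, "n_gap_runs"] * sc$gap_open - gap_bases * sc$gap_ext
    as_num <- suppressWarnings(as.integer(as_tag[mapped]))
    score <- ifelse(is.na(as_num), as.integer(round(score_rec)), as_num)
    hits <- data.frame(
      read_id = qname[mapped], sequence_id = rname[mapped],
      ref_start = pos[mapped] - 1L,
      ref_end = pos[mapped] - 1L + as.integer(cs[, "M"] + cs[, "D"]),
      strand = ifelse(bitwAnd(flag[mapped], 16L) > 0L, "-", "+"),
      score = score, matches = as.integer(matches),
      columns = as.integer(columns),
      identity = matches / columns,
      query_aligned_fraction = (cs[, "M"] + cs[, "I"]) / rl,
      cigar = cig[mapped], stringsAsFactors = FALSE)
    # keep only each read's top-scoring entries
    best <- tapply(hits$score, hits$read_id, max)
    keep <- hits$score == best[hits$read_id]
    supp <- tapply(!keep, hits$read_id, sum)
    hits <- hits[keep, , drop = FALSE]
  } else {
    supp <- integer(0)
    best <- integer(0)
  }

  all_ids <- unique(qname)
  nh <- if (!is.null(hits)) table(hits$read_id) else integer(0)
  reads_df <- data.frame(
    read_id = all_ids,
    best_score = as.integer(unname(best[all_ids])),
    n_hits = as.integer(ifelse(all_ids %in% names(nh), nh[all_ids], 0L)),
    suppressed_count = as.integer(ifelse(all_ids %in% names(supp),
                                         supp[all_ids], 0L)),
    stringsAsFactors = FALSE)
  if (is.null(hits)) {
    hits <- data.frame(read_id = character(0), sequence_id = character(0),
                       ref_start = integer(0), ref_end = integer(0),
                       strand = character(0), score = integer(0),
                       matches = integer(0), columns = integer(0),
                       identity = numeric(0),
                       query_aligned_fraction = numeric(0),
                       cigar = character(0), stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  new_hitsets(reads_df, hits)
}
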