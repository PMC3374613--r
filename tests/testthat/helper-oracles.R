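# Independent brute-force oracles used to check the package's optimized
# implementations on small instances. These deliberately re-derive every
# quantity from first principles (string enumeration, per-base arrays,
# established library calls) rather than sharing any code with R/ or src/.

rc_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# distinct canonical k-mers of a sequence set, by explicit enumeration
oracle_kmer_set <- function(seqs, k) {
  out <- character(0)
  for (s in toupper(as.character(seqs))) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    if (!length(km)) next
    out <- c(out, pmin(km, rc_str(km)))
  }
  unique(out)
}

oracle_containment <- function(a, b, k) {
  la <- sum(nchar(as.character(a)))
  lb <- sum(nchar(as.character(b)))
  ka <- oracle_kmer_set(a, k)
  kb <- oracle_kmer_set(b, k)
  small <- if (la <= lb) ka else kb
  large <- if (la <= lb) kb else ka
  if (!length(small)) return(0)
  length(intersect(small, large)) / length(small)
}

# naive re-scan DUST: recomputes the triplet table of every window from
# scratch with table()
oracle_dust <- function(s, window = 64, level = 2.0) {
  s <- toupper(s)
  n <- nchar(s)
  spans <- matrix(integer(0), ncol = 2)
  wlen <- min(window, n)
  if (n >= 3) {
    for (start in 0:(n - wlen)) {
      w <- substr(s, start + 1, start + wlen)
      tri <- substring(w, 1:(wlen - 2), 3:wlen)
      tri <- tri[!grepl("N", tri, fixed = TRUE)]
      L <- length(tri)
      if (L < 2) next
      cnt <- table(tri)
      score <- sum(cnt * (cnt - 1) / 2) / (L - 1)
      if (score > level) spans <- rbind(spans, c(start, start + wlen))
    }
  }
  nmask <- gregexpr("[^ACGT]+", s)[[1]]
  if (nmask[1] != -1) {
    spans <- rbind(spans, cbind(nmask - 1,
                                nmask - 1 + attr(nmask, "match.length")))
  }
  if (nrow(spans) == 0)
    return(list(intervals = spans, fraction = 0))
  mask <- logical(n)
  for (i in seq_len(nrow(spans))) mask[(spans[i, 1] + 1):spans[i, 2]] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  list(intervals = cbind(starts[r$values], ends[r$values]),
       fraction = mean(mask))
}

# per-base coverage accumulation into an explicit integer array
oracle_coverage <- function(starts, ends, len) {
  cov <- integer(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i])
      cov[(starts[i] + 1):ends[i]] <- cov[(starts[i] + 1):ends[i]] + 1L
  }
  list(covered = sum(cov > 0), total = sum(cov),
       breadth = 100 * sum(cov > 0) / len, depth = sum(cov) / len)
}

# exhaustive local alignment score over the whole reference, both strands,
# via Biostrings (match +1, mismatch -2, gap of length L costs 3 + L)
oracle_sw_score <- function(read, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  s <- function(q) Biostrings::pairwiseAlignment(
    pattern = q, subject = ref, type = "local", substitutionMatrix = mat,
    gapOpening = 3, gapExtension = 1, scoreOnly = TRUE)
  max(s(read), s(rc_str(read)))
}

# definitional tie-corrected Spearman: average ranks then Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small fixture builders ------------------------------------------------------

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# de Bruijn order-3 sequence over ACGT (greedy prefer-smallest construction),
# doubled so any 64-base window holds 62 distinct triplets
balanced_sequence <- function(len) {
  bases <- c("A", "C", "G", "T")
  s <- "AAA"
  seen <- c("AAA")
  repeat {
    tail2 <- substr(s, nchar(s) - 1, nchar(s))
    added <- FALSE
    for (b in rev(bases)) {  # prefer-largest greedy
      tri <- paste0(tail2, b)
      if (!(tri %in% seen)) {
        s <- paste0(s, b)
        seen <- c(seen, tri)
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  substr(strrep(s, ceiling(len / nchar(s)) + 1), 1, len)
}

# direct HitSets constructor for resolution tests
make_hitsets <- function(reads_df, hits_df) {
  mockmap:::new_hitsets(reads_df, hits_df)
}
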