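#' Simulate a strain-indexed reference database of synthetic genomes
#'
#' Generates random (uniform-composition) genome sequences with a synthetic
#' taxonomy, one chromosome per strain. Random genomes of kb-Mb size are
#' effectively free of internal repeats, so every community member is unique
#' in the database unless near-duplicates are added deliberately (see
#' [mutate_genome()] and [amend_database()]).
#'
#' @param n_strains Number of strains.
#' @param genome_length Chromosome length in bases; recycled across strains.
#' @param seed Integer seed; the same seed reproduces the same database.
#' @param genera_sizes Integer vector giving how many strains fall in each
#'   genus (must sum to `n_strains`). Default: one genus per strain.
#' @param strains_per_species Strains per species within a genus (default 1,
#'   i.e. every strain is its own species).
#' @return A `ReferenceDB`.
#' @export
simulate_reference_db <- function(n_strains = 10L, genome_length = 1e5,
                                  seed = 1L, genera_sizes = NULL,
                                  strains_per_species = 1L) {
  n_strains <- as.integer(n_strains)
  lens <- as.integer(rep_len(genome_length, n_strains))
  if (is.null(genera_sizes)) genera_sizes <- rep(1L, n_strains)
  if (sum(genera_sizes) != n_strains)
    stop("genera_sizes must sum to n_strains")
  genus_of <- rep(seq_along(genera_sizes), genera_sizes)
  within_genus <- unlist(lapply(genera_sizes, seq_len))
  species_of <- paste0("G", sprintf("%02d", genus_of), "sp",
                       sprintf("%02d", ceiling(within_genus / strains_per_species)))
  with_seed(seed, {
    prefixes <- sprintf("S%02d", seq_len(n_strains))
    seqs <- vapply(lens, random_dna, character(1))
    names(seqs) <- paste0(prefixes, "_chr")
    idx <- data.frame(prefix = prefixes,
                      strain_name = sprintf("Genus%02d species strain %02d",
                                            genus_of, within_genus),
                      species = species_of,
                      genus = sprintf("Genus%02d", genus_of),
                      superkingdom = "Bacteria", protected = 0,
                      stringsAsFactors = FALSE)
    reference_db(seqs, idx)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run expr under a private RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Introduce point substitutions into a genome
#'
#' Used to build synthetic congeners of a given average nucleotide divergence:
#' each base is substituted independently with probability `divergence`, never
#' to itself.
#'
#' @param seq A single sequence (character or DNAString).
#' @param divergence Per-base substitution probability.
#' @param seed Integer seed.
#' @return A character sequence of the same length.
#' @export
mutate_genome <- function(seq, divergence, seed = 1L) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  with_seed(seed, {
    hit <- which(stats::runif(length(s)) < divergence)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      repl <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L),
                     character(1), USE.NAMES = FALSE)
      s[hit] <- repl
    }
    paste(s, collapse = "")
  })
}

#' Build a synthetic congener of a database strain
#'
#' Copies a strain's chromosome, applies [mutate_genome()] divergence, and
#' packages it as a new species in the same genus, ready for
#' [amend_database()].
#'
#' @param db A `ReferenceDB`.
#' @param prefix Prefix of the template strain.
#' @param divergence Per-base substitution probability of the congener.
#' @param new_prefix Prefix for the congener (default `"<prefix>c"`).
#' @param seed Integer seed.
#' @return A [strain_entry()].
#' @export
synthetic_congener <- function(db, prefix, divergence, new_prefix = NULL,
                               seed = 1L) {
  stopifnot(is(db, "ReferenceDB"))
  row <- db$strains[db$strains$prefix == prefix, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown strain prefix: ", prefix)
  if (is.null(new_prefix)) new_prefix <- paste0(prefix, "c")
  chr <- paste(strain_chromosome(db, prefix), collapse = "")
  mut <- mutate_genome(chr, divergence, seed = seed)
  seqs <- stats::setNames(mut, paste0(new_prefix, "_chr"))
  strain_entry(prefix = new_prefix,
               strain_name = paste(row$strain_name, "congener"),
               species = paste0(row$species, "_congener"),
               genus = row$genus, sequences = seqs,
               superkingdom = row$superkingdom)
}

#' Specify a mock community
#'
#' Describes a defined mixture of database strains at known relative
#' concentrations, the sequencing geometry (100 bp paired-end reads with a
#' uniform insert length, forward/reverse orientation), and the substitution
#' error rate.
#'
#' @param members data.frame with columns `prefix` and `concentration`
#'   (relative, non-negative, not all zero).
#' @param n_pairs Number of read pairs to simulate.
#' @param read_length Read length in bases (default 100).
#' @param n_fragments Number of additional single-end fragment reads
#'   (default 0).
#' @param insert_range Integer `c(min, max)` fragment length in bases
#'   (default `c(180, 250)`; overlapping mates are allowed).
#' @param substitution_rate Per-base substitution error probability; errors
#'   never reproduce the original base.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `CommunitySpec` list.
#' @export
community_spec <- function(members, n_pairs, read_length = 100L,
                           n_fragments = 0L, insert_range = c(180L, 250L),
                           substitution_rate = 0, seed = 1L) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  stopifnot(all(c("prefix", "concentration") %in% names(members)))
  if (any(members$concentration < 0) || all(members$concentration == 0))
    stop("concentrations must be non-negative and not all zero")
  if (insert_range[2] < insert_range[1])
    stop("insert_range must satisfy max >= min")
  structure(list(members = members, n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 n_fragments = as.integer(n_fragments),
                 insert_range = as.integer(insert_range),
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "CommunitySpec")
}

#' Simulate mock-community reads with per-read truth labels
#'
#' Fragments are placed uniformly over valid positions of a genome chosen
#' with probability proportional to concentration times genome length
#' (abundance by DNA mass, since shotgun sequencing samples base pairs, not
#' cells). Mates are generated in forward/reverse orientation from the two
#' fragment ends; fragment strands are random. Qualities are constant Phred
#' 40 ('I'); the downstream pipeline never consumes qualities.
#'
#' @param db A `ReferenceDB`.
#' @param spec A [community_spec()].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_1.fastq`, `<prefix>_2.fastq`, `<prefix>_frag.fastq` and
#'   `<prefix>_truth.tsv`.
#' @return A list with `r1`, `r2`, `fragments` (named character vectors of
#'   read sequences) and `truth` (data.frame: `read_id`, `prefix`,
#'   `sequence_id`, `start` (0-based leftmost reference base), `strand`).
#' @export
simulate_community <- function(db, spec, out_prefix = NULL) {
  stopifnot(is(db, "ReferenceDB"), is(spec, "CommunitySpec"))
  mem <- spec$members
  bad <- setdiff(mem$prefix, db$strains$prefix)
  if (length(bad)) stop("community member absent from database: ",
                        paste(bad, collapse = ", "))
  rl <- spec$read_length
  ins_min <- spec$insert_range[1]; ins_max <- spec$insert_range[2]

  # candidate sequences per member: long enough for the largest insert
  seq_tab <- db$seq_info[db$seq_info$prefix %in% mem$prefix &
                           db$seq_info$length >= max(ins_max, rl), , drop = FALSE]
  active <- mem[mem$concentration > 0, , drop = FALSE]
  for (p in active$prefix) {
    if (!any(seq_tab$prefix == p))
      stop("no sequence of member ", p, " is at least insert_max long")
  }
  strain_len <- vapply(active$prefix, function(p)
    sum(seq_tab$length[seq_tab$prefix == p]), numeric(1))
  weights <- active$concentration * strain_len
  seq_chars <- lapply(stats::setNames(seq_tab$sequence_id, seq_tab$sequence_id),
                      function(id) as.character(db$sequences[[id]]))

  with_seed(spec$seed, {
    n <- spec$n_pairs
    res <- list()
    if (n > 0L) {
      member_i <- sample.int(nrow(active), n, replace = TRUE, prob = weights)
      ins <- ins_min + floor(stats::runif(n) * (ins_max - ins_min + 1L))
      ins <- pmin(as.integer(ins), ins_max)
      seq_id <- character(n)
      for (i in seq_len(nrow(active))) {
        sel <- member_i == i
        if (!any(sel)) next
        cand <- seq_tab[seq_tab$prefix == active$prefix[i], , drop = FALSE]
        pick <- if (nrow(cand) == 1L) rep(1L, sum(sel)) else
          sample.int(nrow(cand), sum(sel), replace = TRUE, prob = cand$length)
        seq_id[sel] <- cand$sequence_id[pick]
      }
      seq_len_of <- seq_tab$length[match(seq_id, seq_tab$sequence_id)]
      start <- floor(stats::runif(n) * (seq_len_of - ins + 1L))
      start <- as.integer(pmin(start, seq_len_of - ins))
      flip <- stats::runif(n) < 0.5  # fragment sampled from the reverse strand

      frag <- substring_by_seq(seq_chars, seq_id, start + 1L, start + ins)
      left <- substring(frag, 1L, rl)
      right_rc <- substring(frag, ins - rl + 1L, ins)
      right <- rc_chr(right_rc)
      # fb geometry: R1 from the fragment 5' end, R2 from the 3' end
      r1 <- ifelse(flip, right, left)
      r2 <- ifelse(flip, left, right)
      r1_strand <- ifelse(flip, "-", "+")
      r2_strand <- ifelse(flip, "+", "-")
      r1_start <- ifelse(flip, start + ins - rl, start)
      r2_start <- ifelse(flip, start, start + ins - rl)

      base <- sprintf("p%07d", seq_len(n))
      r1 <- apply_substitutions(r1, spec$substitution_rate)
      r2 <- apply_substitutions(r2, spec$substitution_rate)
      names(r1) <- paste0(base, "/1")
      names(r2) <- paste0(base, "/2")
      truth_pairs <- data.frame(
        read_id = c(names(r1), names(r2)),
        prefix = rep(active$prefix[member_i], 2L),
        sequence_id = rep(seq_id, 2L),
        start = as.integer(c(r1_start, r2_start)),
        strand = c(r1_strand, r2_strand),
        stringsAsFactors = FALSE)
      res$r1 <- r1; res$r2 <- r2; res$truth <- truth_pairs
    } else {
      res$r1 <- res$r2 <- stats::setNames(character(0), character(0))
      res$truth <- data.frame(read_id = character(0), prefix = character(0),
                              sequence_id = character(0), start = integer(0),
                              strand = character(0), stringsAsFactors = FALSE)
    }

    nf <- spec$n_fragments
    if (nf > 0L) {
      member_i <- sample.int(nrow(active), nf, replace = TRUE, prob = weights)
      seq_id <- character(nf)
      for (i in seq_len(nrow(active))) {
        sel <- member_i == i
        if (!any(sel)) next
        cand <- seq_tab[seq_tab$prefix == active$prefix[i], , drop = FALSE]
        pick <- if (nrow(cand) == 1L) rep(1L, sum(sel)) else
          sample.int(nrow(cand), sum(sel), replace = TRUE, prob = cand$length)
        seq_id[sel] <- cand$sequence_id[pick]
      }
      seq_len_of <- seq_tab$length[match(seq_id, seq_tab$sequence_id)]
      start <- as.integer(floor(stats::runif(nf) * (seq_len_of - rl + 1L)))
      rev <- stats::runif(nf) < 0.5
      fr <- substring_by_seq(seq_chars, seq_id, start + 1L, start + rl)
      fr[rev] <- rc_chr(fr[rev])
      fr <- apply_substitutions(fr, spec$substitution_rate)
      names(fr) <- sprintf("f%07d", seq_len(nf))
      res$fragments <- fr
      res$truth <- rbind(res$truth, data.frame(
        read_id = names(fr), prefix = active$prefix[member_i],
        sequence_id = seq_id, start = start,
        strand = ifelse(rev, "-", "+"), stringsAsFactors = FALSE))
    } else {
      res$fragments <- stats::setNames(character(0), character(0))
    }
    res
  }) -> out

  if (!is.null(out_prefix)) {
    write_fastq(out$r1, paste0(out_prefix, "_1.fastq"))
    write_fastq(out$r2, paste0(out_prefix, "_2.fastq"))
    write_fastq(out$fragments, paste0(out_prefix, "_frag.fastq"))
    utils::write.table(out$truth, paste0(out_prefix, "_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# vectorized substring extraction grouped by source sequence (avoids
# materializing one genome copy per read)
substring_by_seq <- function(seq_chars, seq_id, first, last) {
  out <- character(length(seq_id))
  for (id in unique(seq_id)) {
    sel <- seq_id == id
    out[sel] <- substring(seq_chars[[id]], first[sel], last[sel])
  }
  out
}

# vectorized reverse complement on character vectors
rc_chr <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# i.i.d. per-base substitutions that never reproduce the original base
apply_substitutions <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  rl <- nchar(reads)
  nmut <- stats::rbinom(length(reads), rl, rate)
  idx <- which(nmut > 0L)
  bases <- c("A", "C", "G", "T")
  bmap <- stats::setNames(0:3, bases)
  for (i in idx) {
    s <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(s), nmut[i])
    cur <- bmap[s[pos]]
    off <- sample.int(3L, nmut[i], replace = TRUE)
    ok <- !is.na(cur)  # leave non-ACGT bases untouched
    s[pos[ok]] <- bases[((cur[ok] + off[ok]) %% 4L) + 1L]
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Replace a random subset of reads with low-complexity repeats
#'
#' Test fixture for low-complexity screening: a seeded random subset of size
#' `round(fraction * n)` has its sequence replaced by a homopolymer or
#' dinucleotide repeat of equal length.
#'
#' @param reads Named character vector of read sequences.
#' @param fraction Fraction of reads to replace, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The modified read vector (same names, same length).
#' @export
inject_low_complexity <- function(reads, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n_alter <- round(fraction * length(reads))
  if (n_alter == 0L) return(reads)
  with_seed(seed, {
    chosen <- sample.int(length(reads), n_alter)
    motifs <- c("A", "C", "G", "T", "AC", "AG", "AT", "CG", "CT", "GT")
    pick <- sample(motifs, n_alter, replace = TRUE)
    for (j in seq_along(chosen)) {
      len <- nchar(reads[chosen[j]])
      reads[chosen[j]] <- substr(strrep(pick[j], ceiling(len / nchar(pick[j]))),
                                 1L, len)
    }
    reads
  })
}

#' Write reads to FASTQ (Sanger/Phred+33, constant quality 'I')
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads)) {
    qual <- strrep("I", nchar(reads))
    lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                             "+", qual))
  } else lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}
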