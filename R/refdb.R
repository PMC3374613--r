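#' Strain-indexed reference genome databases
#'
#' A `ReferenceDB` bundles a multi-record reference FASTA with a strain index:
#' every sequence ID carries a prefix unique to its strain, so any alignment
#' can be related back to the parent genome, and per-genome abundance metrics
#' become possible. Sequences whose ID contains the token `"plasmid"` are
#' treated as plasmids; the remainder form the chromosome (one or many
#' contigs for draft genomes).
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference sequences. Names must be `"<prefix>_<id>"`.
#' @param index A data.frame with columns `prefix`, `strain_name`, `species`,
#'   `genus`, `superkingdom` and `protected` (0/1 or logical).
#' @return A `ReferenceDB` object: a list with elements `strains` (one row per
#'   strain: prefix, lineage, protected flag, chromosome/plasmid/total
#'   lengths), `seq_info` (one row per sequence), `sequences` (DNAStringSet)
#'   and `total_length`.
#' @examples
#' seqs <- c(AA_chr = "ACGTACGTACGTACGT", BB_chr = "TTTTACGTACGTAAAA")
#' idx <- data.frame(prefix = c("AA", "BB"),
#'                   strain_name = c("strain A", "strain B"),
#'                   species = c("spA", "spB"), genus = c("genA", "genB"),
#'                   superkingdom = "Bacteria", protected = 0)
#' db <- reference_db(seqs, idx)
#' db$total_length
#' @export
reference_db <- function(sequences, index) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  } else {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  need <- c("prefix", "strain_name", "species", "genus", "superkingdom", "protected")
  missing_cols <- setdiff(need, names(index))
  if (length(missing_cols))
    stop("strain index is missing columns: ", paste(missing_cols, collapse = ", "))
  index <- as.data.frame(index, stringsAsFactors = FALSE)
  index$prefix <- as.character(index$prefix)
  index$protected <- as.logical(as.integer(as.logical(index$protected)))
  if (anyDuplicated(index$prefix))
    stop("duplicate strain prefix in index: ",
         paste(unique(index$prefix[duplicated(index$prefix)]), collapse = ", "))

  ids <- names(sequences)
  if (length(sequences) && (is.null(ids) || anyDuplicated(ids)))
    stop("reference sequences must have unique names")

  seq_prefix <- character(length(ids))
  for (i in seq_along(ids)) {
    hit <- index$prefix[startsWith(ids[i], paste0(index$prefix, "_"))]
    if (length(hit) == 0L)
      stop("sequence ID not covered by any indexed prefix: ", ids[i])
    if (length(hit) > 1L)
      stop("sequence ID matches multiple indexed prefixes: ", ids[i])
    seq_prefix[i] <- hit
  }

  lens <- if (length(sequences)) Biostrings::width(sequences) else integer(0)
  is_plasmid <- grepl("plasmid", ids, ignore.case = TRUE)
  seq_info <- data.frame(sequence_id = as.character(ids), prefix = seq_prefix,
                         length = as.integer(lens), is_plasmid = is_plasmid,
                         stringsAsFactors = FALSE)

  chr_len <- vapply(index$prefix, function(p) {
    sum(seq_info$length[seq_info$prefix == p & !seq_info$is_plasmid])
  }, numeric(1))
  pls_len <- vapply(index$prefix, function(p) {
    sum(seq_info$length[seq_info$prefix == p & seq_info$is_plasmid])
  }, numeric(1))

  present <- index$prefix %in% seq_info$prefix
  if (any(present & chr_len == 0))
    stop("strain has no chromosome sequence (only plasmids): ",
         paste(index$prefix[present & chr_len == 0], collapse = ", "))

  strains <- data.frame(prefix = index$prefix,
                        strain_name = as.character(index$strain_name),
                        species = as.character(index$species),
                        genus = as.character(index$genus),
                        superkingdom = as.character(index$superkingdom),
                        protected = index$protected,
                        chromosome_length = chr_len,
                        plasmid_length = pls_len,
                        total_length = chr_len + pls_len,
                        stringsAsFactors = FALSE)
  strains <- strains[strains$prefix %in% seq_info$prefix | nrow(seq_info) == 0L, ,
                     drop = FALSE]
  if (nrow(seq_info) == 0L) strains <- strains[0L, , drop = FALSE]
  rownames(strains) <- NULL

  structure(list(strains = strains, seq_info = seq_info, sequences = sequences,
                 total_length = sum(as.numeric(lens))),
            class = "ReferenceDB")
}

#' @export
print.ReferenceDB <- function(x, ...) {
  cat(sprintf("ReferenceDB: %d strains, %d sequences, %s bp total\n",
              nrow(x$strains), nrow(x$seq_info),
              format(x$total_length, big.mark = ",")))
  if (nrow(x$strains)) {
    cat(sprintf("  genera: %d, species: %d, protected strains: %d\n",
                length(unique(x$strains$genus)), length(unique(x$strains$species)),
                sum(x$strains$protected)))
  }
  invisible(x)
}

#' Load a reference database from FASTA plus a strain index
#'
#' @param fasta_path Path to a multi-record FASTA whose record IDs are
#'   `"<prefix>_<id>"`.
#' @param index_path Path to a tab-separated strain index with columns
#'   `prefix`, `strain_name`, `species`, `genus`, `superkingdom`,
#'   `protected` (0/1).
#' @return A [reference_db()] object.
#' @export
load_database <- function(fasta_path, index_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(index_path)) stop("index file not found: ", index_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  # keep only the first whitespace-delimited token of each FASTA header
  if (length(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  idx <- utils::read.delim(index_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(idx)) idx$protected <- as.integer(idx$protected)
  reference_db(seqs, idx)
}

#' Write a reference database to FASTA plus a strain index
#'
#' @param db A `ReferenceDB`.
#' @param fasta_path,index_path Output paths.
#' @return Invisibly, `db`.
#' @export
write_database <- function(db, fasta_path, index_path) {
  stopifnot(is(db, "ReferenceDB"))
  Biostrings::writeXStringSet(db$sequences, fasta_path)
  idx <- db$strains[, c("prefix", "strain_name", "species", "genus",
                        "superkingdom", "protected")]
  idx$protected <- as.integer(idx$protected)
  utils::write.table(idx, index_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(db)
}

# chromosome (non-plasmid) sequences of one strain, as character
strain_chromosome <- function(db, prefix) {
  ids <- db$seq_info$sequence_id[db$seq_info$prefix == prefix &
                                   !db$seq_info$is_plasmid]
  as.character(db$sequences[ids])
}

# all sequences of one strain
strain_sequences <- function(db, prefix) {
  ids <- db$seq_info$sequence_id[db$seq_info$prefix == prefix]
  db$sequences[ids]
}

#' Genome-wide similarity by canonical k-mer containment
#'
#' Fraction of the smaller genome's distinct canonical k-mers that are shared
#' with the other genome. A genome that is a subset of another scores near 1,
#' so redundancy screening removes genomes contributing little unique
#' sequence. The measure is a deterministic, alignment-free stand-in for
#' genome-wide pairwise alignment similarity.
#'
#' @param strain_a,strain_b Sequence sets (character vectors or
#'   [Biostrings::DNAStringSet]) making up each genome.
#' @param k Odd k-mer size, at least 11 (default 21).
#' @return A similarity fraction in `[0, 1]`.
#' @export
genome_similarity <- function(strain_a, strain_b, k = 21L) {
  k <- as.integer(k)
  if (k < 11L) stop("k must be at least 11")
  if (k %% 2L == 0L) stop("k must be odd (avoids palindromic canonical k-mers)")
  a <- as.character(strain_a); b <- as.character(strain_b)
  if (length(a) == 0L || sum(nchar(a)) == 0L ||
      length(b) == 0L || sum(nchar(b)) == 0L)
    stop("both genomes must be non-empty")
  if (max(nchar(a)) < k || max(nchar(b)) < k) {
    warning("genome shorter than k; similarity defined as 0")
    return(0)
  }
  cpp_kmer_containment(a, b, k)$similarity
}

#' Remove near-redundant genomes within species
#'
#' Greedy dereplication per species group: genomes are sorted by chromosome
#' length (descending, prefix as tie-break) and admitted in turn; a candidate
#' is removed when its genome-wide similarity to any already-kept genome of
#' the same species exceeds `threshold`. Protected strains are never removed
#' and act as kept representatives. Plasmids are excluded from the similarity
#' computation and retained with their kept strains.
#'
#' The threshold is on the nucleotide-identity scale used for genome-wide
#' pairwise comparisons: the k-mer containment `c` from
#' [genome_similarity()] is converted to an average nucleotide identity
#' estimate `c^(1/k)` (two genomes differing by a per-base divergence `d`
#' share about `(1-d)^k` of their k-mers), so e.g. a strain 2% diverged from
#' a kept one scores about 0.98 and is removed at the default 0.90.
#'
#' @param db A `ReferenceDB`.
#' @param threshold Genome-wide identity above which a genome is redundant
#'   (default 0.90; a relaxed 0.83 mirrors screening of large strain groups).
#' @param k k-mer size passed to [genome_similarity()].
#' @return A list with `kept` (the dereplicated `ReferenceDB`) and `removed`
#'   (data.frame: `prefix`, `kept_by`, `reason`, `similarity` — the identity
#'   estimate that triggered removal).
#' @export
dereplicate <- function(db, threshold = 0.90, k = 21L) {
  stopifnot(is(db, "ReferenceDB"))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  st <- db$strains
  removed <- data.frame(prefix = character(0), kept_by = character(0),
                        reason = character(0), similarity = numeric(0),
                        stringsAsFactors = FALSE)
  kept_prefixes <- character(0)
  for (sp in unique(st$species)) {
    grp <- st[st$species == sp, , drop = FALSE]
    grp <- grp[order(-grp$chromosome_length, grp$prefix), , drop = FALSE]
    kept_in_sp <- character(0)
    for (i in seq_len(nrow(grp))) {
      p <- grp$prefix[i]
      if (grp$protected[i]) {
        kept_in_sp <- c(kept_in_sp, p)
        next
      }
      cand <- strain_chromosome(db, p)
      drop_by <- NA_character_
      drop_sim <- NA_real_
      for (q in kept_in_sp) {
        cont <- suppressWarnings(
          genome_similarity(cand, strain_chromosome(db, q), k = k))
        sim <- cont^(1 / k)  # containment -> nucleotide-identity estimate
        if (sim > threshold) { drop_by <- q; drop_sim <- sim; break }
      }
      if (is.na(drop_by)) {
        kept_in_sp <- c(kept_in_sp, p)
      } else {
        removed <- rbind(removed, data.frame(
          prefix = p, kept_by = drop_by, reason = "redundant",
          similarity = drop_sim, stringsAsFactors = FALSE))
      }
    }
    kept_prefixes <- c(kept_prefixes, kept_in_sp)
  }
  keep_ids <- db$seq_info$sequence_id[db$seq_info$prefix %in% kept_prefixes]
  idx <- st[st$prefix %in% kept_prefixes,
            c("prefix", "strain_name", "species", "genus", "superkingdom",
              "protected")]
  kept <- reference_db(db$sequences[keep_ids], idx)
  list(kept = kept, removed = removed)
}

#' Amend a database by swapping strains
#'
#' Removes named strains and adds replacement strains (typically congeners of
#' removed ones, emulating a community member whose exact genome is absent
#' from the reference). Strains not named in any swap are untouched.
#'
#' @param db A `ReferenceDB`.
#' @param swaps A list of swaps; each swap is a list with `remove` (character
#'   vector of prefixes, possibly empty) and optionally `add` (a strain entry
#'   as produced by [strain_entry()]).
#' @return The amended `ReferenceDB`.
#' @export
amend_database <- function(db, swaps) {
  stopifnot(is(db, "ReferenceDB"))
  if (length(swaps) == 0L) return(db)
  remove <- character(0)
  adds <- list()
  for (sw in swaps) {
    rm_p <- as.character(sw$remove %||% character(0))
    bad <- setdiff(rm_p, db$strains$prefix)
    if (length(bad)) stop("cannot remove nonexistent prefix: ",
                          paste(bad, collapse = ", "))
    remove <- c(remove, rm_p)
    if (!is.null(sw$add)) adds <- c(adds, list(sw$add))
  }
  keep <- !(db$seq_info$prefix %in% remove)
  seqs <- db$sequences[db$seq_info$sequence_id[keep]]
  idx <- db$strains[!(db$strains$prefix %in% remove),
                    c("prefix", "strain_name", "species", "genus",
                      "superkingdom", "protected")]
  for (a in adds) {
    need <- c("prefix", "strain_name", "species", "genus", "superkingdom")
    if (!all(need %in% names(a)) || is.null(a$sequences))
      stop("added strain must carry full lineage and sequences")
    idx <- rbind(idx, data.frame(prefix = a$prefix, strain_name = a$strain_name,
                                 species = a$species, genus = a$genus,
                                 superkingdom = a$superkingdom,
                                 protected = isTRUE(a$protected),
                                 stringsAsFactors = FALSE))
    add_seqs <- Biostrings::DNAStringSet(a$sequences)
    seqs <- c(seqs, add_seqs)
  }
  reference_db(seqs, idx)
}

#' Construct a strain entry for [amend_database()]
#'
#' @param prefix Unique strain prefix.
#' @param strain_name,species,genus Lineage fields.
#' @param sequences Named character vector or DNAStringSet; names must start
#'   with `"<prefix>_"`.
#' @param superkingdom Default `"Bacteria"`.
#' @param protected Default `FALSE`.
#' @return A list usable as the `add` element of a swap.
#' @export
strain_entry <- function(prefix, strain_name, species, genus, sequences,
                         superkingdom = "Bacteria", protected = FALSE) {
  list(prefix = prefix, strain_name = strain_name, species = species,
       genus = genus, superkingdom = superkingdom, protected = protected,
       sequences = sequences)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
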