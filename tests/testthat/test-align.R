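one_strain_db <- function(seq, prefix = "S01") {
  reference_db(stats::setNames(seq, paste0(prefix, "_chr")),
               data.frame(prefix = prefix, strain_name = "s", species = "sp",
                          genus = "gen", superkingdom = "Bacteria",
                          protected = 0))
}

test_that("the seed index stores every position and drops repetitive seeds", {
  set.seed(61)
  db <- one_strain_db(rand_dna(1000))
  idx <- build_index(db, k = 16)
  st <- index_stats(idx)
  expect_equal(st$n_positions, 1000 - 16 + 1)
  expect_equal(st$n_dropped, 0)
  # lookup returns the exact positions of a seed
  kmer <- substr(as.character(db$sequences[[1]]), 101, 116)
  hit <- seed_positions(idx, kmer)
  expect_true(100 %in% hit$pos)

  polyA <- one_strain_db(strrep("A", 5000))
  stA <- index_stats(build_index(polyA, k = 16))
  expect_equal(stA$n_dropped, 1)  # the poly-A seed exceeds default occupancy
  expect_equal(stA$n_positions, 0)

  empty <- reference_db(character(0),
                        data.frame(prefix = character(0),
                                   strain_name = character(0),
                                   species = character(0),
                                   genus = character(0),
                                   superkingdom = character(0),
                                   protected = integer(0)))
  expect_equal(index_stats(build_index(empty))$n_seeds, 0)
})

test_that("exact unique reads map perfectly on both strands", {
  set.seed(62)
  db <- one_strain_db(rand_dna(5000))
  idx <- build_index(db)
  g <- as.character(db$sequences[[1]])
  read <- substr(g, 2001, 2100)
  hs <- map_read(stats::setNames(read, "fwd"), idx)
  expect_equal(hs$reads$n_hits, 1)
  expect_equal(hs$hits$ref_start, 2000)
  expect_equal(hs$hits$ref_end, 2100)
  expect_equal(hs$hits$identity, 1.0)
  expect_equal(hs$hits$query_aligned_fraction, 1.0)
  expect_equal(hs$hits$score, 100)
  expect_equal(hs$hits$strand, "+")
  expect_equal(hs$hits$cigar, "100M")

  hr <- map_read(stats::setNames(rc_str(read), "rev"), idx)
  expect_equal(hr$hits$ref_start, 2000)
  expect_equal(hr$hits$strand, "-")
  expect_equal(hr$hits$score, 100)
})

test_that("a verbatim duplicated segment forces a two-way tie", {
  set.seed(63)
  seg <- rand_dna(100)
  g <- paste0(rand_dna(500), seg, rand_dna(1400), seg, rand_dna(500))
  db <- one_strain_db(g)
  hs <- map_read(stats::setNames(seg, "dup"), build_index(db))
  expect_equal(hs$reads$n_hits, 2)
  expect_equal(sort(hs$hits$ref_start), c(500, 2000))
  expect_equal(unique(hs$hits$score), 100)
})

test_that("the similarity filter rejects reads below the identity cutoff", {
  set.seed(64)
  db <- one_strain_db(rand_dna(5000))
  g <- as.character(db$sequences[[1]])
  read <- substr(g, 1001, 1100)
  # exactly 21 substitutions (full-length identity 0.79) placed so that any
  # window of >= 75 query bases holds at least 16 of them (identity < 0.80
  # at every span passing the length filter), while [42, 58] stays clean for
  # seeding
  s <- strsplit(read, "")[[1]]
  pos <- c(23, 24, 25, 27, 30, 33, 36, 39, 41,
           59, 62, 65, 68, 71, 73, 75, 76, 77, 78, 79, 80)
  for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  mutread <- paste(s, collapse = "")
  idx <- build_index(db)
  hs <- map_read(stats::setNames(mutread, "r"), idx,
                 min_length_fraction = 0.75, min_similarity = 0.80)
  expect_equal(hs$reads$n_hits, 0)
  # the same read is alignable under permissive filters
  hs2 <- map_read(stats::setNames(mutread, "r"), idx,
                  min_length_fraction = 0.1, min_similarity = 0.5)
  expect_gt(hs2$reads$n_hits, 0)
})

test_that("reads shorter than the seed are unmappable with a warning", {
  set.seed(65)
  db <- one_strain_db(rand_dna(2000))
  idx <- build_index(db, k = 16)
  expect_warning(hs <- map_reads(c(tiny = "ACGTACGT"), idx), "shorter")
  expect_equal(hs$reads$n_hits, 0)
})

test_that("mapper best scores equal the exhaustive Smith-Waterman oracle", {
  set.seed(66)
  ref <- rand_dna(20000)
  db <- one_strain_db(ref)
  idx <- build_index(db)
  for (i in 1:25) {
    start <- sample(19000, 1)
    read <- substr(ref, start, start + 99)
    nmut <- sample(0:5, 1)
    if (nmut > 0) read <- mutate_genome(read, 0, seed = i)  # placeholder
    s <- strsplit(read, "")[[1]]
    if (nmut > 0) {
      pos <- sample(100, nmut)
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    }
    if (i %% 3 == 0) s <- s[-sample(length(s), 1)]           # 1-base deletion
    if (i %% 4 == 0) s <- append(s, sample(c("A", "C", "G", "T"), 1),
                                 after = sample(length(s), 1))
    read <- paste(s, collapse = "")
    if (i %% 2 == 0) read <- rc_str(read)
    hs <- map_reads(stats::setNames(read, "r"), idx,
                    min_length_fraction = 0.3, min_similarity = 0.5)
    expect_equal(hs$reads$best_score, as.integer(oracle_sw_score(read, ref)),
                 info = paste("case", i))
  }
})

test_that("all reported hits satisfy both filters", {
  db <- simulate_reference_db(3, 2e4, seed = 67)
  spec <- community_spec(data.frame(prefix = db$strains$prefix,
                                    concentration = c(1, 1, 1)),
                         n_pairs = 500, substitution_rate = 0.05, seed = 8)
  sim <- simulate_community(db, spec)
  hs <- map_reads(sim$r1, build_index(db), 0.75, 0.80)
  expect_true(all(hs$hits$identity >= 0.80 - 1e-9))
  expect_true(all(hs$hits$query_aligned_fraction >= 0.75 - 1e-9))
  expect_true(all(hs$hits$ref_end > hs$hits$ref_start))
})

test_that("mapped read counts are monotone in both filters", {
  db <- simulate_reference_db(3, 3e4, seed = 68)
  spec <- community_spec(data.frame(prefix = db$strains$prefix,
                                    concentration = c(1, 1, 1)),
                         n_pairs = 1500, substitution_rate = 0.01, seed = 9)
  sim <- simulate_community(db, spec)
  idx <- build_index(db)
  mapped <- matrix(NA_integer_, 3, 2,
                   dimnames = list(c("0.5", "0.75", "1"), c("0.8", "0.9")))
  for (lf in rownames(mapped)) for (ms in colnames(mapped)) {
    hs <- map_reads(sim$r1, idx, as.numeric(lf), as.numeric(ms))
    mapped[lf, ms] <- sum(hs$reads$n_hits > 0)
  }
  expect_true(all(diff(mapped[, "0.8"]) <= 0))
  expect_true(all(diff(mapped[, "0.9"]) <= 0))
  expect_true(all(mapped[, "0.9"] <= mapped[, "0.8"]))
  expect_lt(mapped["1", "0.8"], mapped["0.75", "0.8"])
})

test_that("pairing promotes the tied hit that forms a proper pair", {
  set.seed(69)
  seg <- rand_dna(100)
  g <- paste0(rand_dna(200), seg, rand_dna(1100), seg, rand_dna(600))
  # copies of seg at 200 and 1400; unique mate downstream of the first copy
  db <- one_strain_db(g)
  idx <- build_index(db)
  r1 <- stats::setNames(seg, "p1/1")
  r2 <- stats::setNames(rc_str(substr(g, 351, 450)), "p1/2")  # 0-based 350..450
  solo <- map_reads(r1, idx)
  expect_equal(solo$reads$n_hits, 2)
  mp <- map_pairs(r1, r2, index = idx, insert_range = c(180, 250))
  h1 <- mp$hitsets$hits[mp$hitsets$hits$read_id == "p1/1", ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$ref_start, 200)
  expect_true(mp$pairing$proper)
  expect_equal(mp$pairing$demoted, 1L)
})

test_that("fragment-only input behaves exactly like per-read mapping", {
  db <- simulate_reference_db(2, 2e4, seed = 70)
  spec <- community_spec(data.frame(prefix = db$strains$prefix,
                                    concentration = c(1, 1)),
                         n_pairs = 0, n_fragments = 300,
                         substitution_rate = 0.01, seed = 10)
  sim <- simulate_community(db, spec)
  idx <- build_index(db)
  mp <- map_pairs(character(0), character(0), fragments = sim$fragments,
                  index = idx)
  direct <- map_reads(sim$fragments, idx)
  expect_equal(mp$hitsets$hits, direct$hits)
  expect_equal(mp$hitsets$reads, direct$reads)
})

test_that("SAM round-trips preserve placements, ties and unmapped reads", {
  db <- simulate_reference_db(2, 2e4, seed = 71)
  spec <- community_spec(data.frame(prefix = db$strains$prefix,
                                    concentration = c(1, 1)),
                         n_pairs = 50, substitution_rate = 0.01, seed = 11)
  sim <- simulate_community(db, spec)
  reads <- c(sim$r1, sim$r2, unmappable = strrep("ACGGT", 20))
  hs <- map_reads(reads, build_index(db))
  pl <- resolve_hits(hs, "top_random", seed = 3)
  sam <- tempfile(fileext = ".sam")
  write_sam(pl, db, sam, reads = reads)

  back <- read_sam(sam, db)
  placed <- pl[pl$status == "placed", ]
  expect_equal(nrow(back$hits), nrow(placed))
  m <- match(back$hits$read_id, placed$read_id)
  expect_equal(back$hits$sequence_id, placed$sequence_id[m])
  expect_equal(back$hits$ref_start, placed$ref_start[m])
  expect_equal(back$hits$strand, placed$strand[m])
  expect_equal(back$hits$score, placed$score[m])
  expect_equal(back$hits$cigar, placed$cigar[m])

  lines <- readLines(sam)
  rec <- strsplit(grep("^@", lines, value = TRUE, invert = TRUE), "\t")
  flags <- vapply(rec, function(f) as.integer(f[2]), 1L)
  expect_true(any(flags == 4L))  # the unmappable read
  un <- back$reads[back$reads$read_id == "unmappable", ]
  expect_equal(un$n_hits, 0)
})

test_that("tie-resolved reads carry MAPQ 0 in SAM output", {
  set.seed(72)
  seg <- rand_dna(100)
  g <- paste0(rand_dna(300), seg, rand_dna(1200), seg, rand_dna(300))
  db <- one_strain_db(g)
  hs <- map_read(stats::setNames(seg, "tied"), build_index(db))
  pl <- resolve_hits(hs, "top_random", seed = 4)
  sam <- tempfile(fileext = ".sam")
  write_sam(pl, db, sam)
  rec <- strsplit(grep("^@", readLines(sam), value = TRUE, invert = TRUE),
                  "\t")[[1]]
  expect_equal(as.integer(rec[5]), 0L)  # MAPQ
})

test_that("score recomputation from CIGAR + NM matches the AS tag", {
  db <- simulate_reference_db(1, 2e4, seed = 73)
  spec <- community_spec(data.frame(prefix = "S01", concentration = 1),
                         n_pairs = 40, substitution_rate = 0.03, seed = 12)
  sim <- simulate_community(db, spec)
  hs <- map_reads(sim$r1, build_index(db))
  pl <- resolve_hits(hs, "top_random", seed = 5)
  sam <- tempfile(fileext = ".sam")
  write_sam(pl, db, sam, reads = sim$r1)
  # strip the AS tag so read_sam must rebuild scores from CIGAR + NM
  lines <- readLines(sam)
  stripped <- gsub("AS:i:-?[0-9]+\t", "", lines)
  sam2 <- tempfile(fileext = ".sam")
  writeLines(stripped, sam2)
  with_as <- read_sam(sam, db)
  without_as <- read_sam(sam2, db)
  m <- match(without_as$hits$read_id, with_as$hits$read_id)
  expect_equal(without_as$hits$score, with_as$hits$score[m])
})
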