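test_that("databases load from FASTA + index with validated prefixes", {
  set.seed(11)
  seqs <- c(AA_chr = rand_dna(400), AA_plasmid1 = rand_dna(80),
            BB_chr = rand_dna(300))
  idx <- data.frame(prefix = c("AA", "BB"),
                    strain_name = c("strain A", "strain B"),
                    species = c("spA", "spB"), genus = c("genA", "genB"),
                    superkingdom = "Bacteria", protected = c(0, 1))
  db <- reference_db(seqs, idx)
  expect_equal(nrow(db$strains), 2)
  expect_equal(db$total_length, 780)
  expect_equal(db$strains$chromosome_length, c(400, 300))
  expect_equal(db$strains$plasmid_length, c(80, 0))
  expect_true(db$strains$protected[2])

  # round-trips through FASTA + TSV unchanged
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_database(db, fa, tsv)
  db2 <- load_database(fa, tsv)
  expect_equal(db2$strains, db$strains)
  expect_equal(as.character(db2$sequences), as.character(db$sequences))

  # unindexed sequence ID is a hard error naming the ID
  expect_error(reference_db(c(seqs, CC_chr1 = "ACGTACGT"), idx), "CC_chr1")
  # duplicate prefix is a hard error
  expect_error(reference_db(seqs, rbind(idx, idx[1, ])), "duplicate")
})

test_that("an empty database is representable", {
  idx0 <- data.frame(prefix = character(0), strain_name = character(0),
                     species = character(0), genus = character(0),
                     superkingdom = character(0), protected = integer(0))
  db <- reference_db(character(0), idx0)
  expect_equal(nrow(db$strains), 0)
  expect_equal(db$total_length, 0)
})

test_that("k-mer containment matches identity, disjointness and the oracle", {
  set.seed(12)
  g <- rand_dna(2000)
  expect_equal(genome_similarity(g, g, k = 15), 1.0)
  expect_equal(genome_similarity(strrep("A", 1000), strrep("C", 1000), k = 15),
               0.0)
  # half genome against full genome: exact agreement with set enumeration
  a <- rand_dna(10000)
  b <- substr(a, 1, 5000)
  expect_equal(genome_similarity(a, b, k = 15), oracle_containment(a, b, 15))
  # and on a diverged pair
  d <- mutate_genome(a, 0.05, seed = 3)
  expect_equal(genome_similarity(a, d, k = 15), oracle_containment(a, d, 15))
  expect_warning(sim <- genome_similarity("ACGTACGTACGT", g, k = 15),
                 "shorter")
  expect_equal(sim, 0)
  expect_error(genome_similarity(g, g, k = 9), "at least 11")
  expect_error(genome_similarity(g, g, k = 16), "odd")
})

make_family_db <- function(protect_short = FALSE) {
  set.seed(21)
  a_long <- rand_dna(60000)
  a_short <- mutate_genome(substr(a_long, 1, 50000), 0.02, seed = 5)
  b <- rand_dna(40000)
  seqs <- c(AL_chr = a_long, AS_chr = a_short, BB_chr = b)
  idx <- data.frame(prefix = c("AL", "AS", "BB"),
                    strain_name = c("A long", "A short", "B"),
                    species = c("spA", "spA", "spB"),
                    genus = c("genA", "genA", "genB"),
                    superkingdom = "Bacteria",
                    protected = c(0, as.integer(protect_short), 0))
  reference_db(seqs, idx)
}

test_that("dereplication removes the shorter near-duplicate and keeps the rest", {
  db <- make_family_db()
  res <- dereplicate(db, threshold = 0.90)
  expect_setequal(res$kept$strains$prefix, c("AL", "BB"))
  expect_equal(res$removed$prefix, "AS")
  expect_equal(res$removed$kept_by, "AL")
  expect_gt(res$removed$similarity, 0.90)

  # idempotent: a second pass removes nothing
  res2 <- dereplicate(res$kept, threshold = 0.90)
  expect_equal(nrow(res2$removed), 0)
  expect_setequal(res2$kept$strains$prefix, c("AL", "BB"))
})

test_that("protected strains survive dereplication at any threshold", {
  db <- make_family_db(protect_short = TRUE)
  for (thr in c(0.83, 0.90, 0.99)) {
    res <- dereplicate(db, threshold = thr)
    expect_setequal(res$kept$strains$prefix, c("AL", "AS", "BB"))
    expect_equal(nrow(res$removed), 0)
  }
})

test_that("mutually dissimilar genomes are all kept and the longest always survives", {
  set.seed(23)
  seqs <- c(S1_chr = rand_dna(30000), S2_chr = rand_dna(20000),
            S3_chr = rand_dna(10000))
  idx <- data.frame(prefix = c("S1", "S2", "S3"), strain_name = c("a", "b", "c"),
                    species = "spX", genus = "genX", superkingdom = "Bacteria",
                    protected = 0)
  db <- reference_db(seqs, idx)
  res <- dereplicate(db, threshold = 0.90)
  expect_equal(nrow(res$removed), 0)
  # longest member of a species group is kept for every threshold
  db2 <- make_family_db()
  for (thr in c(0.5, 0.83, 0.90)) {
    kept <- dereplicate(db2, threshold = thr)$kept$strains
    expect_true("AL" %in% kept$prefix[kept$species == "spA"])
  }
})

test_that("plasmids of kept strains are restored after dereplication", {
  set.seed(24)
  a <- rand_dna(30000)
  seqs <- c(AA_chr = a, AA_plasmid = rand_dna(5000),
            AB_chr = substr(a, 1, 25000), AB_plasmid = rand_dna(4000))
  idx <- data.frame(prefix = c("AA", "AB"), strain_name = c("a", "b"),
                    species = "spA", genus = "genA", superkingdom = "Bacteria",
                    protected = 0)
  res <- dereplicate(reference_db(seqs, idx), threshold = 0.90)
  expect_setequal(res$kept$seq_info$sequence_id, c("AA_chr", "AA_plasmid"))
  expect_equal(res$kept$strains$plasmid_length, 5000)
})

test_that("amend_database swaps strains and leaves the rest untouched", {
  db <- simulate_reference_db(3, c(5000, 4000, 3000), seed = 31,
                              genera_sizes = c(3L))
  y_len <- 4500
  set.seed(32)
  y <- strain_entry("YY", "congener Y", "G01spY", "Genus01",
                    c(YY_chr = rand_dna(y_len)))
  out <- amend_database(db, list(list(remove = "S01", add = y)))
  expect_false("S01" %in% out$strains$prefix)
  expect_true("YY" %in% out$strains$prefix)
  expect_equal(out$total_length, db$total_length + y_len - 5000)
  expect_equal(out$strains[out$strains$prefix %in% c("S02", "S03"), ],
               db$strains[db$strains$prefix %in% c("S02", "S03"), ],
               ignore_attr = TRUE)

  # removing 2 of 3 strains of a genus with no replacement leaves 1 strain
  pruned <- amend_database(db, list(list(remove = c("S01", "S02"))))
  expect_equal(sum(pruned$strains$genus == "Genus01"), 1)
  expect_equal(pruned$strains$prefix, "S03")

  # empty swap list is the identity
  expect_equal(amend_database(db, list()), db)
  expect_error(amend_database(db, list(list(remove = "ZZ"))), "nonexistent")
})
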