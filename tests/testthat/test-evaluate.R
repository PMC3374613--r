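# two genera; Genus01 holds two congeneric species (S01, S02)
eval_db <- function() simulate_reference_db(3, 4000, seed = 91,
                                            genera_sizes = c(2L, 1L))

place_rows <- function(read_id, sequence_id, status = "placed") {
  k <- length(read_id)
  data.frame(read_id = read_id,
             sequence_id = ifelse(status == "placed", sequence_id, NA),
             ref_start = ifelse(status == "placed", 0L, NA),
             ref_end = ifelse(status == "placed", 100L, NA),
             strand = "+", score = 100L, matches = 100L, columns = 100L,
             cigar = "100M", mapq = 60L, status = rep(status, k),
             tie_count = ifelse(status == "suppressed_multi", 2L, 1L),
             stringsAsFactors = FALSE)
}

truth_rows <- function(read_id, prefix) {
  data.frame(read_id = read_id, prefix = prefix,
             sequence_id = paste0(prefix, "_chr"), start = 0L, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("fates distinguish strain, level and wrong-taxon placements", {
  db <- eval_db()
  pl <- rbind(place_rows("a", "S01_chr"),              # correct strain
              place_rows("b", "S02_chr"),              # congener of S01
              place_rows("c", "S03_chr"),              # wrong genus for S01
              place_rows("d", NA, status = "unmapped"),
              place_rows("e", NA, status = "suppressed_multi"))
  tr <- truth_rows(c("a", "b", "c", "d", "e"), rep("S01", 5))

  genus <- classify_fates(pl, tr, db, "genus")
  expect_equal(unname(genus$counts[c("correct_strain", "correct_at_level",
                                     "wrong_taxon", "suppressed_multi",
                                     "unmapped")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(genus$counts), genus$total)

  species <- classify_fates(pl, tr, db, "species")
  # the congener placement is a different species: wrong taxon at this level
  expect_equal(unname(species$counts["correct_at_level"]), 0L)
  expect_equal(unname(species$counts["wrong_taxon"]), 2L)

  strain <- classify_fates(pl, tr, db, "strain")
  expect_equal(unname(strain$counts["correct_at_level"]), 0L)
  expect_equal(unname(strain$counts["wrong_taxon"]), 2L)

  # coarser levels only absorb errors
  expect_lte(genus$counts[["wrong_taxon"]], species$counts[["wrong_taxon"]])
  expect_lte(species$counts[["wrong_taxon"]], strain$counts[["wrong_taxon"]])

  expect_error(classify_fates(place_rows("zz", "S01_chr"), tr, db, "genus"),
               "missing from truth")
})

test_that("multi-placement reads take their best fate and are flagged", {
  db <- eval_db()
  pl <- rbind(place_rows(c("a", "a"), c("S01_chr", "S03_chr")))
  tr <- truth_rows("a", "S01")
  f <- classify_fates(pl, tr, db, "genus")
  expect_equal(unname(f$counts["correct_strain"]), 1L)
  expect_equal(f$total, 1L)
  expect_equal(f$ambiguous_multi, 1L)
})

test_that("Spearman correlation matches the definitional oracle", {
  expect_equal(spearman_rank(c(1, 2, 3), c(10, 20, 30)), 1.0)
  expect_equal(spearman_rank(c(1, 2, 3), c(3, 2, 1)), -1.0)
  x <- c(1, 2, 2, 4); y <- c(5, 6, 7, 8)
  expect_equal(spearman_rank(x, y), oracle_spearman(x, y))
  set.seed(92)
  for (i in 1:5) {
    a <- sample(1:10, 8, replace = TRUE)
    b <- rnorm(8)
    expect_equal(spearman_rank(a, b), oracle_spearman(a, b))
  }
  expect_error(spearman_rank(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
})

test_that("chi-square depth comparison is scale-invariant and matches stats::chisq.test", {
  same <- chisq_depth_compare(c(10, 10), c(10, 10))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1.0)
  scaled <- chisq_depth_compare(c(10, 10), c(20, 20))
  expect_equal(scaled$p.value, 1.0)

  got <- chisq_depth_compare(c(5, 15), c(10, 10))
  want <- suppressWarnings(stats::chisq.test(c(5, 15), p = c(0.5, 0.5)))
  expect_equal(unname(got$statistic), unname(want$statistic))
  expect_equal(got$p.value, want$p.value)

  set.seed(93)
  a <- runif(6, 1, 40); b <- runif(6, 1, 40)
  want2 <- suppressWarnings(stats::chisq.test(a, p = b / sum(b)))
  got2 <- chisq_depth_compare(a, b)
  expect_equal(unname(got2$statistic), unname(want2$statistic))
  expect_equal(got2$p.value, want2$p.value)

  expect_error(chisq_depth_compare(c(1, 2), c(0, 5)), "undetected")
  expect_error(chisq_depth_compare(1, 1), "at least 2")
})

test_that("log-depth tables flag amended taxa and report zeros as missing", {
  tab <- function(taxon, depth, detected = TRUE) {
    data.frame(level = "genus", taxon = taxon, breadth = 50, depth = depth,
               covered_bases = 1, assigned_reads = 1, detected = detected,
               n_strains_in_db = 1L, relative_abundance = NA,
               stringsAsFactors = FALSE)
  }
  ref <- tab(c("GenA", "GenB", "GenC"), c(2.0, 1.0, 0.5))
  amd <- tab(c("GenA", "GenB"), c(2.0, 0.1))
  out <- depth_log_ratio(ref, amd)
  a <- out[out$taxon == "GenA", ]
  expect_equal(a$log10_depth_ref, a$log10_depth_amended)  # on-diagonal
  b <- out[out$taxon == "GenB", ]
  expect_lt(b$log10_depth_amended, b$log10_depth_ref)     # off-diagonal below
  expect_true(is.na(out$log10_depth_amended[out$taxon == "GenC"]))

  zero <- depth_log_ratio(ref, tab("GenA", 0))
  expect_true(is.na(zero$log10_depth_amended[zero$taxon == "GenA"]))
})
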