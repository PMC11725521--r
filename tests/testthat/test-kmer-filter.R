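test_that("canonical k-mer enumeration collapses strands and skips Ns", {
  # revcomp(CGT) = ACG < CGT; GTA < TAC
  expect_equal(canonical_kmers("ACGTA", 3), c("ACG", "ACG", "GTA"))
  expect_equal(canonical_kmers("AAAA", 4), "AAAA")
  # every length-3 window of ACNGT contains the N
  expect_equal(canonical_kmers("ACNGT", 3), character(0))
  expect_equal(canonical_kmers("AC", 3), character(0))
})

test_that("count table equals a brute-force tally and window arithmetic holds", {
  r31 <- random_seq(31)
  two <- tibble::tibble(id = c("a", "b"), seq = c(r31, r31))
  tab <- kmer_count_table(two, k = 31)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$count, 2L)

  one <- tibble::tibble(id = "a", seq = random_seq(40))
  expect_equal(sum(kmer_count_table(one, k = 31)$count), 10L) # L - k + 1

  set.seed(71)
  reads <- tibble::tibble(
    id = sprintf("r%02d", 1:20),
    seq = vapply(1:20, function(i) random_seq(500), character(1))
  )
  tab <- kmer_count_table(reads, k = 31)
  oracle <- naive_kmer_tally(reads$seq, 31)
  expect_equal(tab$kmer, oracle$kmer)
  expect_equal(tab$count, oracle$count)

  expect_error(kmer_count_table(reads[0, ]), "no reads")
})

test_that("read medians use mean-of-middles for even window counts", {
  # one read whose windows have known counts: build via repeated k-mers
  profiles <- tibble::tibble(
    read_id = c("a", "b"),
    n_kmers = c(3L, 2L),
    rmkc = c(stats::median(c(5, 7, 9)), stats::median(c(4, 8))),
    window_counts = list(c(5, 7, 9), c(4, 8))
  )
  expect_equal(profiles$rmkc, c(7, 6))

  th <- kmer_thresholds(tibble::tibble(rmkc = c(100, 100, 100)))
  expect_equal(th$mkc, 100)
  expect_equal(th$lkc, 30)
  expect_equal(th$hkc, 500)
  expect_equal(th$max_outlier_frac, 1 / 5)

  expect_equal(kmer_thresholds(tibble::tibble(rmkc = 10))$hkc, 50)
  expect_equal(kmer_thresholds(tibble::tibble(rmkc = c(10, 1000)))$mkc, 505)
  expect_error(kmer_thresholds(tibble::tibble(rmkc = NA_real_)), "usable")
})

test_that("filter removes reads only above the strict one-fifth outlier bound", {
  th <- structure(list(mkc = 50, lkc = 15, hkc = 250, max_outlier_frac = 1 / 5),
                  class = "kmer_thresholds")
  reads <- tibble::tibble(id = c("low3", "edge2", "short"),
                          seq = c("x", "y", "z")) # seqs unused with profiles
  profiles <- tibble::tibble(
    read_id = reads$id,
    n_kmers = c(10L, 10L, 0L),
    rmkc = c(50, 50, NA),
    window_counts = list(
      c(1, 1, 1, rep(50, 7)),      # 3/10 below lkc -> removed
      c(1, 1, rep(50, 8)),         # exactly 2/10 -> kept (0.2 is not > 1/5)
      numeric(0)                   # no k-mers -> too_short
    )
  )
  out <- kmer_filter_reads(reads, thresholds = th, profiles = profiles)
  expect_equal(out$kept, c(FALSE, TRUE, FALSE))
  expect_equal(out$reason, c("low_kmer", NA, "too_short"))
  expect_equal(out$frac_low[1], 0.3)
  expect_equal(out$frac_high[1], 0)
  # kept plus removed partitions the input in order
  expect_equal(out$id, reads$id)
})

test_that("filtering is permutation invariant and monotone in the thresholds", {
  set.seed(72)
  genome <- random_seq(5000)
  reads <- simulate_reads(
    tibble::tibble(name = "g", seq = genome, circular = TRUE, copy = 30,
                   label = "plastid"),
    coverage = 1, mean_len = 500, len_sd = 100, error_rate = 0, seed = 9
  )
  prof <- kmer_profiles(reads)
  th <- kmer_thresholds(prof)
  out <- kmer_filter_reads(reads, thresholds = th, profiles = prof)

  perm <- sample(nrow(reads))
  prof_p <- kmer_profiles(reads[perm, ])
  th_p <- kmer_thresholds(prof_p)
  expect_equal(th_p$mkc, th$mkc)
  out_p <- kmer_filter_reads(reads[perm, ], thresholds = th_p, profiles = prof_p)
  expect_setequal(out_p$id[out_p$kept], out$id[out$kept])

  looser <- structure(list(mkc = th$mkc, lkc = th$lkc / 2, hkc = th$hkc * 2,
                           max_outlier_frac = th$max_outlier_frac),
                      class = "kmer_thresholds")
  out_l <- kmer_filter_reads(reads, thresholds = looser, profiles = prof)
  expect_true(all(out$id[out$kept] %in% out_l$id[out_l$kept]))
})

test_that("coverage filter separates organelle, nuclear and chimeric reads", {
  # organelle at 50x vs nuclear at 1x; chimeric reads carry >= 40% nuclear flank
  set.seed(73)
  organelle <- random_seq(20000)
  nuclear <- random_seq(60000)
  genomes <- tibble::tibble(
    name = c("org", "nuc"),
    seq = c(organelle, nuclear),
    circular = c(TRUE, FALSE),
    copy = c(50, 1),
    label = c("plastid", "nuclear")
  )
  reads <- simulate_reads(genomes, coverage = 1, mean_len = 1500,
                          len_sd = 300, error_rate = 0, seed = 10)
  chimeras <- tibble::tibble(
    id = sprintf("chimera%02d", 1:20),
    seq = vapply(1:20, function(i) {
      paste0(substr(organelle, 1 + 50 * i, 50 * i + 900),
             substr(nuclear, 1 + 40 * i, 40 * i + 700))
    }, character(1)),
    qual = NA_character_, label = "plastid", source = "chimera",
    start = NA_integer_, length = NA_integer_
  )
  pool <- dplyr::bind_rows(reads[reads$label == "plastid", ], chimeras,
                           reads[reads$label == "nuclear", ][1:30, ])
  out <- kmer_filter_reads(pool)
  by_src <- split(out$kept, out$source)
  expect_true(mean(by_src$org) >= 0.99)       # pure organelle retained
  expect_equal(mean(by_src$nuc), 0)           # pure nuclear removed
  expect_true(mean(!by_src$chimera) >= 0.9)   # chimeric NUPT-like removed
})
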