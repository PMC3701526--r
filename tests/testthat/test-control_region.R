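bph_unit <- "GGAAAAAATGTCACGTTTTTC"
sbph_unit <- "CACGATTTTTGGAAAAAATGT"

test_that("planted arrays are recovered with exact period and copy number", {
  set.seed(81)
  for (p in c(10, 15, 21, 27, 30)) {
    for (K in c(5, 20, 60)) {
      unit <- random_dna(p, prob = c(0.35, 0.15, 0.15, 0.35))
      s <- paste0(random_dna(300), strrep(unit, K), random_dna(300))
      arr <- find_tandem_repeats(s)
      expect_gt(nrow(arr), 0)
      main <- arr[which.max(arr$end - arr$start), ]
      expect_equal(main$period, as.integer(p))
      expect_equal(main$copy_number, as.integer(K))
      expect_equal(main$end - main$start + 1L, as.integer(p * K))
      expect_true(all(main$copies[[1]]$complete))
    }
  }
})

test_that("degenerate and truncated copies are reported as incomplete", {
  for (sd in c(1, 6)) {
    sim <- make_mitogenome(bph_genome_spec(seed = sd))
    crs <- extract_feature_seq(sim$genome,
                               sim$features[sim$features$gene == "CR", ])
    arr <- find_tandem_repeats(crs)
    main <- arr[which.max(arr$end - arr$start), ]
    expect_equal(main$period, 21L)
    expect_equal(main$copy_number, 55L)
    expect_equal(which(!main$copies[[1]]$complete), 2L)
    expect_equal(compare_units(bph_unit, main$unit_consensus)$distance, 0L)

    sims <- make_mitogenome(sbph_genome_spec(seed = sd), id = "sbph")
    crs <- extract_feature_seq(sims$genome,
                               sims$features[sims$features$gene == "CR", ])
    arr <- find_tandem_repeats(crs)
    main <- arr[which.max(arr$end - arr$start), ]
    expect_equal(main$period, 21L)
    expect_equal(main$copy_number, 35L)
    expect_equal(which(!main$copies[[1]]$complete), c(3L, 14L, 35L))
    expect_equal(compare_units(sbph_unit, main$unit_consensus)$distance, 0L)
  }
})

test_that("random sequence yields no confident arrays", {
  for (sd in 1:20) {
    set.seed(sd)
    s <- random_dna(5000)
    arr <- find_tandem_repeats(s)
    if (nrow(arr)) {
      complete <- vapply(arr$copies, function(cp) sum(cp$complete), integer(1))
      expect_true(all(complete < 3))
    } else {
      succeed()
    }
  }
})

test_that("detected periods are primitive", {
  set.seed(82)
  unit <- random_dna(12, prob = c(0.35, 0.15, 0.15, 0.35))
  s <- paste0(random_dna(200), strrep(unit, 24), random_dna(200))
  arr <- find_tandem_repeats(s)
  main <- arr[which.max(arr$end - arr$start), ]
  expect_equal(main$period, 12L)
  # short exact arrays match the brute-force smallest-period oracle
  for (p in c(4, 6, 9)) {
    u <- random_dna(p)
    s <- strrep(u, 6)
    arr <- find_tandem_repeats(s, min_period = 2, min_copies = 2)
    if (!nrow(arr)) next
    expect_equal(arr$period[1], oracle_smallest_period(substr(s, 1, 2 * p)))
  }
})

test_that("poly runs are maximal and complete", {
  expect_equal(nrow(find_poly_runs("TTTT", "T", min_len = 5)), 0L)
  r <- find_poly_runs("AATTTTTGGTTTTTTTTA", "T", min_len = 5)
  expect_equal(r$start, c(3L, 10L))
  expect_equal(r$run_length, c(5L, 8L))
  # regex oracle on random strings
  set.seed(83)
  for (i in 1:20) {
    s <- random_dna(500, prob = c(0.4, 0.1, 0.1, 0.4))
    r <- find_poly_runs(s, "A", min_len = 4)
    m <- gregexpr("A{4,}", s)[[1]]
    if (m[1] == -1) {
      expect_equal(nrow(r), 0L)
    } else {
      expect_equal(r$start, as.integer(m))
      expect_equal(r$run_length, attr(m, "match.length"))
    }
  }
  # the generated control region carries its 23-bp poly-T run
  sim <- make_mitogenome(genome_spec(seed = 19))
  crs <- extract_feature_seq(sim$genome, sim$features[sim$features$gene == "CR", ])
  runs <- find_poly_runs(crs, "T", min_len = 15)
  expect_equal(runs$run_length, 23L)
})

test_that("repeat units compare up to rotation and strand", {
  u <- "GGAAAAAATGTC"
  expect_equal(compare_units(u, u)$distance, 0L)
  expect_equal(compare_units(u, u)$offset, 0L)
  rot <- paste0(substr(u, 5, 12), substr(u, 1, 4))
  expect_equal(compare_units(u, rot)$distance, 0L)
  rc <- mitohopper:::revcomp(u)
  cmp <- compare_units(u, rc)
  expect_equal(cmp$distance, 0L)
  expect_equal(cmp$strand, "revcomp")
  # symmetry of the distance
  set.seed(84)
  for (i in 1:10) {
    u1 <- random_dna(15); u2 <- random_dna(15)
    expect_equal(compare_units(u1, u2)$distance, compare_units(u2, u1)$distance)
  }
  # the two planthopper units are rotations two substitutions apart
  expect_lte(compare_units(bph_unit, sbph_unit)$distance, 2L)
})

test_that("VNTR genotyping recovers planted copy numbers per individual", {
  set.seed(85)
  planted <- c(30L, 35L, 40L)
  seqs <- tibble::tibble(
    id = paste0("ind", seq_along(planted)),
    seq = vapply(planted, function(K) {
      paste0(random_dna(250), strrep(bph_unit, K), random_dna(250))
    }, character(1))
  )
  gt <- vntr_genotype(seqs)
  expect_equal(gt$copy_number, planted)
  expect_equal(gt$period, rep(21L, 3))
  expect_equal(gt$array_length, planted * 21L)
  # single sequence agrees with find_tandem_repeats directly
  arr <- find_tandem_repeats(seqs$seq[1])
  main <- arr[which.max(arr$end - arr$start), ]
  expect_equal(gt$copy_number[1], main$copy_number)
})
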