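ords <- reference_gene_orders()

test_that("gene orders are built from feature tables with duplicates collapsed", {
  sim <- make_mitogenome(bph_genome_spec(seed = 15))
  ord <- order_from_table(sim$features)
  expect_s3_class(ord, "gene_order")
  expect_equal(attr(ord, "duplicated"), "trnC")
  expect_equal(sum(mitohopper:::strip_sign(unclass(ord)) == "trnC"), 1L)
  expect_equal(breakpoint_distance(ord, ords$planthopper), 0L)
  # single gene -> singleton order
  g <- circular_genome("g", random_dna(50))
  ft <- feature_table(data.frame(gene = "cox1", type = "PCG", start = 1L,
                                 end = 30L, strand = "J"), 50L)
  expect_length(order_from_table(ft), 1L)
})

test_that("rotation is exact and anchored", {
  o <- gene_order(c("cox1", "-trnQ", "nad2", "trnW"))
  expect_equal(as.character(canonical_rotation(o, "cox1")), as.character(o))
  r <- canonical_rotation(o, "nad2")
  expect_equal(as.character(r), c("nad2", "trnW", "cox1", "-trnQ"))
  expect_equal(as.character(canonical_rotation(r, "cox1")), as.character(o))
  expect_error(canonical_rotation(o, "nad5"), "not present")
  # order derived from a rotated table equals the rotation of the original
  sim <- make_mitogenome(genome_spec(seed = 16))
  ord <- order_from_table(sim$features)
  expect_equal(
    as.character(canonical_rotation(ord, "cox1")),
    as.character(canonical_rotation(ords$planthopper, "cox1"))
  )
})

test_that("breakpoint distance equals the exhaustive adjacency oracle", {
  set.seed(61)
  for (n in 3:6) {
    labels <- paste0("g", seq_len(n))
    for (rep in 1:12) {
      a <- random_signed_order(labels)
      b <- random_signed_order(labels)
      expect_equal(breakpoint_distance(a, b), oracle_breakpoints(a, b))
      # symmetry and rotation invariance
      expect_equal(breakpoint_distance(a, b), breakpoint_distance(b, a))
      rot <- canonical_rotation(a, sample(labels, 1))
      expect_equal(breakpoint_distance(rot, b), breakpoint_distance(a, b))
    }
  }
  expect_equal(breakpoint_distance(ords$planthopper, ords$planthopper), 0L)
  expect_error(breakpoint_distance(ords$planthopper,
                                   gene_order(c("cox1", "cox2"))),
               "different label sets")
})

test_that("planthopper rearrangements are confined to the two known regions", {
  a <- ords$ancestral_insect
  b <- ords$planthopper
  keys_a <- mitohopper:::adjacency_keys(a)
  keys_b <- mitohopper:::adjacency_keys(b)
  labels <- unclass(a)
  n <- length(labels)
  broken <- which(!(keys_a %in% keys_b))
  region <- c("nad2", "trnC", "trnW", "trnY",
              "nad4L", "trnT", "trnP", "nad6", "cob")
  for (i in broken) {
    pair <- mitohopper:::strip_sign(c(labels[i], labels[if (i == n) 1 else i + 1]))
    expect_true(all(pair %in% region),
                info = paste("breakpoint outside rearranged regions:",
                             paste(pair, collapse = "-")))
  }
  expect_gt(length(broken), 0)
})

test_that("the two SBPH annotations differ by a single displaced trnH", {
  rep <- diff_blocks(ords$planthopper, ords$sbph_prior)
  expect_equal(rep$displaced_genes, "trnH")
  expect_equal(glance(rep)$n_displaced, 1L)
  # identical orders: one block, no displacement
  rep0 <- diff_blocks(ords$planthopper, ords$planthopper)
  expect_equal(rep0$breakpoint_count, 0L)
  expect_equal(nrow(rep0$conserved_blocks), 1L)
  expect_length(rep0$displaced_genes, 0L)
})

test_that("displaced genes are always adjacent to breakpoints", {
  set.seed(62)
  for (rep in 1:10) {
    labels <- paste0("g", 1:7)
    a <- random_signed_order(labels)
    b <- random_signed_order(labels)
    r <- diff_blocks(a, b)
    keys_a <- mitohopper:::adjacency_keys(a)
    in_b <- keys_a %in% mitohopper:::adjacency_keys(b)
    la <- unclass(a); n <- length(la)
    bp_adjacent <- unique(mitohopper:::strip_sign(
      c(la[!in_b], la[c(seq_len(n)[-1], 1)][!in_b])))
    expect_true(all(r$displaced_genes %in% bp_adjacent))
    expect_equal(r$breakpoint_count, breakpoint_distance(a, b))
  }
})

test_that("shared derived adjacencies separate planthoppers from the ancestor", {
  sha <- shared_derived_adjacencies(list(ords$planthopper, ords$sbph_prior),
                                    ords$ancestral_insect)
  genes <- mitohopper:::strip_sign(c(sha$from, sha$to))
  expect_true("trnW" %in% genes)
  expect_true(any(c("nad6", "trnP", "trnT") %in% genes))
  # all orders equal to the reference -> nothing derived
  none <- shared_derived_adjacencies(list(ords$planthopper, ords$planthopper),
                                     ords$planthopper)
  expect_equal(nrow(none), 0L)
  # matches a plain intersection computed by the oracle on random instances
  set.seed(63)
  labels <- paste0("g", 1:6)
  for (rep in 1:8) {
    o1 <- random_signed_order(labels)
    o2 <- random_signed_order(labels)
    ref <- random_signed_order(labels)
    got <- shared_derived_adjacencies(list(o1, o2), ref)
    n <- length(labels)
    expected <- 0L
    l1 <- unclass(o1)
    for (i in seq_len(n)) {
      x <- l1[i]; y <- l1[if (i == n) 1 else i + 1]
      if (oracle_adj_present(x, y, unclass(o2)) &&
          !oracle_adj_present(x, y, unclass(ref))) expected <- expected + 1L
    }
    expect_equal(nrow(got), expected)
  }
})

test_that("gene-order spec files parse and reject malformed lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "x: cox1,-trnQ,nad2", "", "y: nad2,cox1,-trnQ"), path)
  o <- read_gene_orders(path)
  expect_named(o, c("x", "y"))
  # y is a rotation of x, so no adjacency is broken
  expect_equal(breakpoint_distance(o$x, o$y), 0L)
  writeLines("nonsense without colon", path)
  expect_error(read_gene_orders(path), "unparseable")
})
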