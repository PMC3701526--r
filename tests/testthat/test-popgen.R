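pop_spec <- population_spec(seed = 7)
pop <- make_population(pop_spec)

test_that("aligned sets are validated", {
  expect_error(aligned_set(tibble::tibble(id = c("a", "a"), seq = c("AC", "AC"))),
               "unique")
  expect_error(aligned_set(tibble::tibble(id = c("a", "b"), seq = c("AC", "ACG"))),
               "same length")
})

test_that("variable sites match a column-scan oracle", {
  aln <- tibble::tibble(id = c("a", "b"), seq = c("ACGT", "ACGT"))
  expect_equal(nrow(call_variable_sites(aln)), 0L)
  # planted sites are exactly recovered
  vs <- call_variable_sites(pop)
  planted <- sort(unique(unlist(pop_spec$haplotypes$positions)))
  expect_equal(vs$position, planted)
  expect_equal(nrow(vs), 16L)
  # oracle equality on random alignments (with ambiguity codes)
  set.seed(91)
  for (rep in 1:5) {
    ref <- random_dna(80)
    seqs <- vapply(1:8, function(i) {
      ch <- strsplit(ref, "")[[1]]
      at <- sample(80, 4)
      ch[at] <- sample(c("A", "C", "G", "T", "N"), 4, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
    aln <- tibble::tibble(id = paste0("s", 1:8), seq = seqs)
    got <- call_variable_sites(aln)$position
    m <- do.call(rbind, strsplit(seqs, ""))
    want <- which(apply(m, 2, function(col) {
      length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
    }))
    expect_equal(got, want)
  }
})

test_that("haplotype collapsing recovers planted frequencies", {
  ht <- collapse_haplotypes(pop)
  expect_equal(nrow(ht$haplotypes), 16L)
  expect_equal(sum(ht$haplotypes$count), 309L)
  expect_equal(ht$haplotypes$count[1:3], c(178L, 93L, 18L))
  expect_equal(sort(ht$haplotypes$count[4:16], decreasing = TRUE),
               c(rep(2L, 7), rep(1L, 6)))
  # membership is consistent with the generator's own assignment
  truth <- attr(pop, "assignments")
  hap1 <- ht$haplotypes$members[[1]]
  expect_setequal(hap1, truth$id[truth$haplotype == "H1"])
  # degenerate case: all identical
  aln <- tibble::tibble(id = c("a", "b", "c"), seq = rep("ACGT", 3))
  ht1 <- collapse_haplotypes(aln)
  expect_equal(ht1$haplotypes$count, 3L)
})

test_that("mutations map to codons and effects correctly", {
  ref <- pop_spec$reference
  map <- pop_spec$map
  m <- classify_mutation(277, ref, "T", map)
  expect_equal(m$codon_number, 93L)
  expect_equal(m$codon_position, 1L)
  expect_equal(m$aa_change, "M93L")
  m <- classify_mutation(391, ref, "A", map)
  expect_equal(m$codon_number, 131L)
  expect_equal(m$aa_change, "D131N")
  # frame consistency: positions p and p+3 land on adjacent codons
  m1 <- classify_mutation(100, ref, "A", map)
  m2 <- classify_mutation(103, ref, "A", map)
  expect_equal(m2$codon_number, m1$codon_number + 1L)
  expect_equal(m1$codon_position, m2$codon_position)
  # third-position change in a 4-fold family is synonymous
  m <- classify_mutation(60, ref, "G", map)  # GGA -> GGG
  expect_equal(m$effect, "synonymous")
  # non-coding segments
  m <- classify_mutation(545, ref, "T", map)
  expect_equal(m$effect, "noncoding")
  expect_equal(m$segment, "intergenic")
  m <- classify_mutation(500, ref, "T", map)
  expect_equal(m$segment, "trnH")
  expect_error(classify_mutation(900, ref, "T", map), "outside")
})

test_that("the haplotype network is a minimum spanning network", {
  ht <- collapse_haplotypes(pop)
  net <- build_network(ht)
  expect_equal(nrow(net$nodes), 16L)
  # edge labels agree with signature Hamming distances
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    s1 <- ht$haplotypes$signature[ht$haplotypes$haplotype == e$from]
    s2 <- ht$haplotypes$signature[ht$haplotypes$haplotype == e$to]
    expect_equal(e$weight, mitohopper:::hamming(s1, s2))
    expect_equal(length(strsplit(e$positions, ",")[[1]]), e$weight)
  }
  # connectivity
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
  # MST weight equals an independent algorithm's (ape) on a small subset
  small <- collapse_haplotypes(pop[1:40, ])
  snet <- build_network(small)
  k <- nrow(small$haplotypes)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    d[i, j] <- mitohopper:::hamming(small$haplotypes$signature[i],
                                    small$haplotypes$signature[j])
  }
  m <- ape::mst(as.dist(d))
  expect_equal(snet$mst_weight, sum(d[m == 1]) / 2)
  # single haplotype: one node, no edges
  one <- collapse_haplotypes(tibble::tibble(id = c("a", "b"), seq = c("AA", "AA")))
  n1 <- build_network(one)
  expect_equal(nrow(n1$edges), 0L)
})

test_that("a star-configured population yields a star network", {
  set.seed(92)
  centre <- random_dna(60)
  spokes <- vapply(1:5, function(i) {
    ch <- strsplit(centre, "")[[1]]
    ch[i * 10] <- setdiff(c("A", "C", "G", "T"), ch[i * 10])[1]
    paste(ch, collapse = "")
  }, character(1))
  aln <- tibble::tibble(
    id = paste0("s", 1:15),
    seq = c(rep(centre, 10), spokes)
  )
  net <- build_network(collapse_haplotypes(aln))
  expect_equal(nrow(net$edges), 5L)
  expect_true(all(net$edges$from == "Hap1" | net$edges$to == "Hap1"))
  expect_true(all(net$edges$weight == 1L))
})

test_that("nucleotide diversity equals the quadratic pairwise oracle", {
  aln <- tibble::tibble(id = c("a", "b"), seq = c(strrep("A", 100),
                                                  paste0(strrep("A", 99), "C")))
  expect_equal(nucleotide_diversity(aln), 0.01)
  expect_equal(nucleotide_diversity(tibble::tibble(id = c("a", "b"),
                                                   seq = c("ACGT", "ACGT"))), 0)
  set.seed(93)
  seqs <- vapply(1:8, function(i) random_dna(60), character(1))
  seqs[3] <- paste0(substr(seqs[3], 1, 55), "NNNNN")
  aln <- tibble::tibble(id = paste0("s", 1:8), seq = seqs)
  expect_equal(nucleotide_diversity(aln), oracle_pi(seqs), tolerance = 1e-12)
  # the emulated survey shows low diversity
  expect_lt(nucleotide_diversity(pop), 0.01)
})

test_that("per-gene divergence recovers planted substitution counts", {
  g <- make_mitogenome(genome_spec(seed = 24))
  expect_equal(tidy(pairwise_gene_divergence(g, g))$rate,
               rep(0, nrow(tidy(pairwise_gene_divergence(g, g)))))
  planted <- c(rrnS = 6L, rrnL = 2L, cox1 = 4L, cob = 3L)
  mut <- mutate_genome(g, per_gene_substitutions = planted, seed = 25)
  div <- pairwise_gene_divergence(g, mut)
  got <- tidy(div)
  for (gene in names(planted)) {
    expect_equal(got$substitutions[got$gene == gene], unname(planted[gene]))
    expect_equal(got$rate[got$gene == gene],
                 unname(planted[gene]) / got$length[got$gene == gene])
  }
  expect_equal(sum(got$substitutions), sum(planted))
  # a 747-bp gene with 6 substitutions diverges at ~0.8%
  expect_equal(round(100 * got$rate[got$gene == "rrnS"], 1), 0.8)
})

test_that("length-variant genes are excluded from divergence with a reason", {
  g <- make_mitogenome(genome_spec(seed = 26))
  nad5 <- g$features[g$features$gene == "nad5", ]
  mut <- mutate_genome(
    g, indel_spec = tibble::tibble(pos = nad5$start + 100L,
                                   length = 57L, type = "deletion"),
    seed = 27)
  div <- pairwise_gene_divergence(g, mut)
  expect_true("nad5" %in% div$excluded$gene)
  expect_match(div$excluded$reason[div$excluded$gene == "nad5"], "length differs")
  expect_false("nad5" %in% tidy(div)$gene)
})

test_that("indel events are reported with exact lengths and positions", {
  expect_equal(nrow(indel_report("ACGT", "ACGT")), 0L)
  expect_error(indel_report("AC-", "ACGT"), "equal length")
  r <- indel_report("AC--GT", "ACGTG-")
  expect_equal(r$type, c("insertion", "deletion"))
  expect_equal(r$length, c(2L, 1L))
  # planted indel set recovered exactly; lengths sum to total gap count
  g <- make_mitogenome(genome_spec(seed = 28))
  spec <- tibble::tibble(
    pos = c(2000L, 4000L, 6000L, 8000L, 10000L, 12000L),
    length = c(57L, 21L, 84L, 55L, 21L, 60L),
    type = c("deletion", "deletion", "insertion", "deletion", "deletion",
             "deletion")
  )
  mut <- mutate_genome(g, indel_spec = spec, seed = 29)
  r <- indel_report(mut$alignment$a, mut$alignment$b)
  expect_equal(nrow(r), 6L)
  expect_equal(r$length, spec$length)
  expect_equal(r$type, spec$type)
  gaps <- sum(strsplit(mut$alignment$a, "")[[1]] == "-") +
    sum(strsplit(mut$alignment$b, "")[[1]] == "-")
  expect_equal(sum(r$length), gaps)
  expect_error(
    mutate_genome(g, indel_spec = tibble::tibble(
      pos = c(100L, 110L), length = c(50L, 10L),
      type = c("deletion", "deletion")), seed = 1),
    "overlap")
})
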