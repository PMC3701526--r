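test_that("circular genome validates its sequence", {
  g <- circular_genome("g1", "acgtn")
  expect_equal(g$sequence, "ACGTN")
  expect_equal(g$length, 5L)
  expect_error(circular_genome("g1", ""), "non-empty")
  expect_error(circular_genome("g1", "ACGX"), "A, C, G, T, N")
})

test_that("feature spans wrap the origin with end < start", {
  expect_equal(feature_span_length(1L, 3L, 100L), 3L)
  expect_equal(feature_span_length(16400L, 12L, 16431L), 16431L - 16400L + 1L + 12L)
})

test_that("extract_feature_seq honours strand and origin wrap", {
  g <- circular_genome("g", "ATGCCCGGGTTT")
  expect_equal(extract_feature_seq(g, list(start = 1L, end = 3L, strand = "J")), "ATG")
  expect_equal(extract_feature_seq(g, list(start = 1L, end = 3L, strand = "N")), "CAT")
  # wrap equals tail + head concatenation for random fixtures
  set.seed(41)
  for (i in 1:20) {
    s <- random_dna(60)
    g <- circular_genome("g", s)
    st <- sample(40:60, 1); en <- sample(1:10, 1)
    expect_equal(
      extract_feature_seq(g, list(start = st, end = en, strand = "J")),
      paste0(substr(s, st, 60), substr(s, 1, en))
    )
    expect_equal(
      extract_feature_seq(g, list(start = st, end = en, strand = "N")),
      mitohopper:::revcomp(paste0(substr(s, st, 60), substr(s, 1, en)))
    )
  }
})

test_that("GenBank round trip preserves genome and annotations", {
  sim <- make_mitogenome(bph_genome_spec(seed = 11), id = "roundtrip")
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, sim$features, path)
  back <- read_genbank(path)
  expect_equal(back$genome$sequence, sim$genome$sequence)
  expect_equal(back$genome$id, sim$genome$id)
  cols <- c("gene", "type", "start", "end", "strand", "anticodon", "copy_index")
  expect_equal(as.data.frame(back$features[cols]),
               as.data.frame(sim$features[cols]))
})

test_that("sequence-only records give an empty feature table", {
  g <- circular_genome("bare", random_dna(100))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, feature_table(data.frame(gene = character(), type = character(),
                                            start = integer(), end = integer(),
                                            strand = character()), 100L), path)
  back <- read_genbank(path)
  expect_equal(back$genome$length, 100L)
  expect_equal(nrow(back$features), 0L)
})

test_that("origin-wrapping features survive a GenBank round trip", {
  g <- circular_genome("wrap", random_dna(200))
  ft <- feature_table(data.frame(
    gene = c("cox1", "trnM"), type = c("PCG", "tRNA"),
    start = c(150L, 30L), end = c(20L, 95L),
    strand = c("J", "N"), anticodon = c(NA, "CAT")
  ), 200L)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, ft, path)
  back <- read_genbank(path)
  wrapped <- back$features[back$features$gene == "cox1", ]
  expect_equal(wrapped$start, 150L)
  expect_equal(wrapped$end, 20L)
  expect_equal(feature_span_length(wrapped$start, wrapped$end, 200L), 71L)
})

test_that("malformed GenBank input is rejected with a clear error", {
  path <- withr::local_tempfile(fileext = ".gb")
  g <- circular_genome("a", random_dna(50))
  empty <- feature_table(data.frame(gene = character(), type = character(),
                                    start = integer(), end = integer(),
                                    strand = character()), 50L)
  write_genbank(g, empty, path)
  txt <- readLines(path)
  writeLines(c(txt, txt), path)  # two concatenated records
  expect_error(read_genbank(path), "single-record")
  expect_error(
    feature_table(data.frame(gene = "cox1", type = "PCG", start = 10L,
                             end = 99L, strand = "J"), 50L),
    "cox1"
  )
})

test_that("feature table TSV round trips", {
  sim <- make_mitogenome(genome_spec(seed = 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(sim$features, path)
  back <- read_feature_tsv(path, sim$genome$length)
  expect_equal(as.data.frame(back), as.data.frame(sim$features))
})

test_that("gene name aliases are canonicalized", {
  expect_equal(canonical_gene_name("COI"), "cox1")
  expect_equal(canonical_gene_name("ND4L"), "nad4L")
  expect_equal(canonical_gene_name("16S"), "rrnL")
  expect_equal(canonical_gene_name("D-loop"), "CR")
  expect_equal(canonical_gene_name("tRNA-Lys"), "trnK")
  expect_equal(canonical_gene_name("tRNA-Leu", anticodon = "TAG"), "trnL1")
  expect_equal(canonical_gene_name("tRNA-Ser", anticodon = "TGA"), "trnS2")
  expect_equal(canonical_gene_name("tRNA-Ser", anticodon = "TCT"), "trnS1")
})

test_that("intergenic report conserves the circle and flags overlaps", {
  # abutting features -> spacer 0
  g <- circular_genome("g", random_dna(100))
  ft <- feature_table(data.frame(
    gene = c("cox1", "cox2"), type = "PCG",
    start = c(1L, 11L), end = c(10L, 40L), strand = "J"), 100L)
  ir <- intergenic_report(g, ft)
  expect_equal(ir$spacer[ir$upstream == "cox1"], 0L)
  # closing pair spans the rest of the circle
  expect_equal(ir$spacer[ir$upstream == "cox2"], 60L)
  expect_error(intergenic_report(g, ft[0, ]), "empty")

  # conservation: feature lengths plus signed spacers tile the genome
  sim <- make_mitogenome(bph_genome_spec(seed = 13))
  ir <- intergenic_report(sim$genome, sim$features)
  lens <- feature_span_length(sim$features$start, sim$features$end,
                              sim$genome$length)
  expect_equal(sum(lens) + sum(ir$spacer), sim$genome$length)

  # the atp8/atp6 junction overlaps by 1 bp (7 bp in the sbph flavour)
  expect_equal(ir$spacer[ir$upstream == "atp8"], -1L)
  sims <- make_mitogenome(sbph_genome_spec(seed = 13))
  irs <- intergenic_report(sims$genome, sims$features)
  expect_equal(irs$spacer[irs$upstream == "atp8"], -7L)
})
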