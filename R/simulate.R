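# Seeded generators of synthetic mitogenomes and population samples ----------
#
# The generators produce every input the analysis modules consume, with the
# statistical structure those analyses assume: a circular, A+T-biased genome
# realizing a chosen signed gene order; protein-coding genes with valid
# starts, in-frame bodies and complete or planted-incomplete stops; tRNA
# genes built to fold to a requested arm configuration; a control region
# carrying a tandem-repeat array (with optional degenerate and truncated
# copies) and a poly-T run; and population samples with planted haplotype
# structure. All outputs are deterministic functions of the spec seed.

#' Specification for a synthetic planthopper-like mitogenome
#'
#' Defaults describe the Delphacidae-like study conditions: the 37-gene
#' planthopper order with the control region between rrnS and trnI, A+T
#' content 0.77 with positive AT-skew and negative GC-skew, a 21-bp
#' control-region repeat unit in 55 copies with one degenerate copy, a 23-bp
#' poly-T run, a loop-only DHU arm in trnS1, incomplete stop codons in cox1,
#' cox3, atp6 and nad5, and a 1-bp atp8/atp6 overlap.
#'
#' @param order Signed gene labels (circular) including a `CR` entry.
#' @param gene_lengths Named lengths (bp) for PCGs, rRNAs and the control
#'   region; tRNA lengths are determined by [make_trna_seq()].
#' @param base_comp Named fractions `a`, `t`, `g`, `c` summing to 1.
#' @param control_region List: `unit`, `copies`, `degenerate` (copy indices
#'   rendered at reduced identity), `truncated_last` (bp kept of the final
#'   copy, which becomes a partial copy; 0 for none), `poly_t` (run length).
#' @param trna_arms Named list mapping tRNA genes to an arm configuration
#'   (`"canonical"`, `"dhu_loop_only"`, `"t_loop_only"`).
#' @param starts Named start-codon overrides for PCGs (default ATG).
#' @param stops Named stop-codon overrides (default TAA).
#' @param incomplete_stops PCGs ending in a 1-2 nt incomplete stop.
#' @param overlaps Named vector: `overlaps["atp8"] = 1` makes atp8 overlap
#'   the following gene by 1 bp (supported overlaps: 1 and 7 bp, J-strand
#'   PCG junctions).
#' @param duplications Named vector of tandem gene copy numbers (e.g.
#'   `c(trnC = 3)`).
#' @param spacer Default intergenic spacer (bp).
#' @param seed Integer seed driving all randomness.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(order = NULL,
                        gene_lengths = NULL,
                        base_comp = c(a = 0.42, t = 0.35, g = 0.094, c = 0.136),
                        control_region = list(
                          unit = "GGAAAAAATGTCACGTTTTTC",
                          copies = 55L, degenerate = 2L,
                          truncated_last = 0L, poly_t = 23L),
                        trna_arms = list(trnS1 = "dhu_loop_only"),
                        starts = c(nad3 = "ATA", atp6 = "ATA"),
                        stops = character(),
                        incomplete_stops = c("cox1", "cox3", "atp6", "nad5"),
                        overlaps = c(atp8 = 1L),
                        duplications = integer(),
                        spacer = 2L,
                        seed = 1L) {
  if (is.null(order)) {
    ords <- reference_gene_orders()
    order <- c(unclass(ords$planthopper), "CR")
  }
  defaults <- c(
    atp6 = 679L, atp8 = 99L, cox1 = 1537L, cox2 = 684L, cox3 = 790L,
    cob = 1137L, nad1 = 936L, nad2 = 978L, nad3 = 351L, nad4 = 1341L,
    nad4L = 291L, nad5 = 1720L, nad6 = 498L,
    rrnS = 748L, rrnL = 1219L, CR = 2429L
  )
  if (!is.null(gene_lengths))
    defaults[names(gene_lengths)] <- as.integer(gene_lengths)
  if (abs(sum(base_comp) - 1) > 1e-8) abort("base_comp fractions must sum to 1")
  if (any(defaults <= 0)) abort("gene lengths must be positive")
  cr_defaults <- list(unit = "GGAAAAAATGTCACGTTTTTC", copies = 55L,
                      degenerate = 2L, truncated_last = 0L, poly_t = 23L)
  control_region <- modifyList(cr_defaults, control_region)
  if (control_region$copies < 0) abort("repeat copy number must be >= 0")
  structure(
    list(order = order, gene_lengths = defaults, base_comp = base_comp,
         control_region = control_region, trna_arms = trna_arms,
         starts = starts, stops = stops, incomplete_stops = incomplete_stops,
         overlaps = overlaps, duplications = duplications,
         spacer = as.integer(spacer), seed = as.integer(seed)),
    class = "genome_spec"
  )
}

#' SBPH-flavoured genome spec
#'
#' Like [genome_spec()] but with the small-brown-planthopper style control
#' region: the rotated 21-bp unit in 35 copies with degenerate copies 3 and
#' 14 and a truncated final copy, a shorter control region, trnS2 (not
#' trnS1) with the loop-only DHU arm, and a 7-bp atp8/atp6 overlap.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [genome_spec()].
#' @return A `genome_spec`.
#' @export
sbph_genome_spec <- function(seed = 1L, ...) {
  genome_spec(
    control_region = list(unit = "CACGATTTTTGGAAAAAATGT", copies = 35L,
                          degenerate = c(3L, 14L), truncated_last = 12L,
                          poly_t = 23L),
    gene_lengths = c(CR = 2042L, rrnS = 747L),
    trna_arms = list(trnS2 = "dhu_loop_only"),
    overlaps = c(atp8 = 7L),
    stops = c(cox2 = "TAG"),
    seed = seed,
    ...
  )
}

#' BPH-flavoured genome spec
#'
#' [genome_spec()] defaults plus the triplicated trnC gene.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [genome_spec()].
#' @return A `genome_spec`.
#' @export
bph_genome_spec <- function(seed = 1L, ...) {
  genome_spec(duplications = c(trnC = 3L), seed = seed, ...)
}

sample_bases <- function(k, comp) {
  if (k <= 0) return(character(0))
  sample(c("A", "T", "G", "C"), k, replace = TRUE, prob = comp[c("a", "t", "g", "c")])
}

codon_pool <- function(comp, code) {
  codons <- sense_codons(code)
  w <- vapply(codons, function(cd) {
    prod(comp[c(A = "a", T = "t", G = "g", C = "c")[seq_chars(cd)]])
  }, numeric(1))
  list(codons = codons, weights = unname(w))
}

sample_codons <- function(k, pool) {
  if (k <= 0) return(character(0))
  sample(pool$codons, k, replace = TRUE, prob = pool$weights)
}

# junction constructions for overlapping J-strand PCG pairs: the upstream
# gene's last `o` bases must equal the downstream gene's first `o` bases
# while keeping a stop upstream and a start downstream in frame
overlap_junction <- function(o) {
  if (o == 1L) {
    list(up_tail = "TAA", down_head = "ATA")      # shared A
  } else if (o == 7L) {
    list(up_tail = "GCATATTAA", down_head = "ATATTAATT")
  } else {
    abort("overlap junctions are implemented for 1 and 7 bp only")
  }
}

build_pcg <- function(gene, len, spec, pool, forced_head = NULL,
                      forced_tail = NULL) {
  rem <- len %% 3L
  incomplete <- gene %in% spec$incomplete_stops
  if (incomplete && rem == 0L)
    abort(sprintf("gene %s: an incomplete stop needs length not divisible by 3", gene))
  if (!incomplete && rem != 0L)
    abort(sprintf("gene %s: length must be divisible by 3", gene))
  stop_seq <- if (incomplete) substr("TA", 1, rem) else
    unname(spec$stops[gene] %||% NA_character_)
  if (is.na(stop_seq)) stop_seq <- "TAA"
  start_codon <- forced_head %||% unname(spec$starts[gene] %||% NA_character_)
  if (is.na(start_codon)) start_codon <- "ATG"
  head_len <- nchar(start_codon)
  tail_len <- nchar(forced_tail %||% stop_seq)
  body_n <- (len - head_len - tail_len) %/% 3L
  if (body_n < 1 || (len - head_len - tail_len) %% 3L != 0L)
    abort(sprintf("gene %s: infeasible length %d for its start/stop layout",
                  gene, len))
  paste0(start_codon,
         paste(sample_codons(body_n, pool), collapse = ""),
         forced_tail %||% stop_seq)
}

build_control_region <- function(spec) {
  cr <- spec$control_region
  comp <- spec$base_comp
  unit <- toupper(cr$unit)
  p <- nchar(unit)
  copies <- character(0)
  if (cr$copies > 0) {
    copies <- rep(unit, cr$copies)
    n_mut <- max(5L, ceiling(0.25 * p))  # identity ~0.7: kept but incomplete
    for (ci in cr$degenerate) {
      if (ci < 1 || ci > cr$copies) next
      chs <- seq_chars(unit)
      at <- sample(seq_len(p), n_mut)
      for (i in at) chs[i] <- sample(setdiff(c("A", "C", "G", "T"), chs[i]), 1)
      copies[ci] <- paste(chs, collapse = "")
    }
    # a truncated final copy replaces the last full copy
    if (cr$truncated_last > 0)
      copies[cr$copies] <- substr(unit, 1, cr$truncated_last)
  }
  array_seq <- paste(copies, collapse = "")
  poly_t <- paste0("A", strrep("T", cr$poly_t), "A")  # guards keep the run maximal
  # the poly-T run is kept well clear of the repeat array so the T-rich tail
  # of the unit cannot phase-lock onto it
  mid_len <- max(25L, p + 4L)
  mid <- paste(sample_bases(mid_len, comp), collapse = "")
  core_len <- nchar(array_seq) + nchar(poly_t) + mid_len
  total <- spec$gene_lengths[["CR"]]
  pad <- total - core_len
  if (pad < 20)
    abort("control region too short for its repeat array and poly-T run")
  left <- pad %/% 2L
  right <- pad - left
  flank_l <- paste(sample_bases(left, comp), collapse = "")
  flank_r <- paste(sample_bases(right, comp), collapse = "")
  # free positions (available to composition repair): flanks and mid spacer
  seqs <- c(flank_l, poly_t, mid, array_seq, flank_r)
  free_local <- c(seq_len(left),
                  left + nchar(poly_t) + seq_len(mid_len),
                  (left + nchar(poly_t) + mid_len + nchar(array_seq)) +
                    seq_len(right))
  list(seq = paste(seqs, collapse = ""), free_local = free_local)
}

repair_composition <- function(ch, free_pos, comp, tol = 0.005) {
  # rewrite the free (non-coding, non-structured) positions with exactly the
  # base multiset that brings the whole genome to its target composition
  L <- length(ch)
  bases <- c("A", "T", "G", "C")
  target <- round(comp[c("a", "t", "g", "c")] * L)
  names(target) <- bases
  fixed <- setdiff(seq_len(L), free_pos)
  fixed_counts <- vapply(bases, function(b) sum(ch[fixed] == b), numeric(1))
  needed <- target - fixed_counts
  # a base over-supplied by the fixed regions borrows from its A/T or G/C
  # partner, so A+T and G+C contents stay on target even when one skew is
  # not fully realizable
  for (pair in list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))) {
    b1 <- pair[1]; b2 <- pair[2]
    if (needed[b1] < 0) {
      needed[b2] <- needed[b2] + needed[b1]
      needed[b1] <- 0
    }
  }
  needed <- pmax(needed, 0)
  nf <- length(free_pos)
  if (sum(needed) == 0) return(ch)
  # scale to the number of free positions (largest-remainder rounding)
  scaled <- needed / sum(needed) * nf
  fill <- floor(scaled)
  rem <- nf - sum(fill)
  if (rem > 0) {
    extra <- order(scaled - fill, decreasing = TRUE)[seq_len(rem)]
    fill[extra] <- fill[extra] + 1
  }
  ch[free_pos] <- sample(rep(bases, times = fill))
  counts <- vapply(bases, function(b) sum(ch == b), numeric(1))
  at_dev <- abs((counts["A"] + counts["T"]) / L - (comp["a"] + comp["t"]))
  if (at_dev > 2 * tol && L >= 10000)
    abort("composition target infeasible for this spec")
  ch
}

#' Generate a synthetic annotated mitogenome
#'
#' Realizes the spec's gene order exactly on a circular sequence, with PCGs
#' starting at a valid start codon and ending with a complete or planted
#' incomplete stop, tRNAs built by [make_trna_seq()] to their configured arm
#' status, rRNAs and spacers sampled at the target composition, and the
#' control region carrying the specified repeat array and poly-T run.
#' Residual compositional drift is repaired at non-coding positions only, so
#' codons, tRNA structure and the repeat array are never touched. Output is
#' deterministic for a given spec (including its seed).
#'
#' @param spec A [genome_spec()].
#' @param id Genome identifier.
#' @return List with `genome` ([circular_genome()]) and `features` (feature
#'   table).
#' @export
make_mitogenome <- function(spec, id = "synthetic_mitogenome") {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  comp <- spec$base_comp
  code <- mito_genetic_code("5")
  pool <- codon_pool(comp, code)
  anticodons <- trna_anticodons()

  parts <- character(0)
  free_ranges <- list()     # positions open to composition repair
  rows <- list()
  cur <- 1L                 # next write position
  pending_overlap <- 0L     # bp shared with the previous gene
  n_items <- length(spec$order)

  for (i in seq_len(n_items)) {
    label <- spec$order[i]
    gene <- strip_sign(label)
    strand <- if (startsWith(label, "-")) "N" else "J"
    n_copies <- if (gene %in% names(spec$duplications))
      spec$duplications[[gene]] else 1L

    for (copy in seq_len(n_copies)) {
      o_next <- if (gene %in% names(spec$overlaps) && copy == n_copies)
        as.integer(spec$overlaps[[gene]]) else 0L
      forced_tail <- NULL; forced_head <- NULL
      if (o_next > 0L) {
        if (strand != "J") abort("overlaps are supported on J-strand genes only")
        forced_tail <- overlap_junction(o_next)$up_tail
      }
      if (pending_overlap > 0L) {
        forced_head <- overlap_junction(pending_overlap)$down_head
      }

      if (gene == "CR") {
        crb <- build_control_region(spec)
        gseq <- crb$seq
        type <- "control_region"
        free_local <- crb$free_local
        anticodon <- NA_character_
      } else if (gene %in% trna_genes()) {
        cfg <- spec$trna_arms[[gene]] %||% "canonical"
        gseq <- make_trna_seq(gene, arm_config = cfg,
                              anticodon = unname(anticodons[gene]))
        type <- "tRNA"
        free_local <- integer(0)
        anticodon <- unname(anticodons[gene])
      } else if (gene %in% rrna_genes()) {
        len <- spec$gene_lengths[[gene]]
        gseq <- paste(sample_bases(len, comp), collapse = "")
        type <- "rRNA"
        free_local <- seq_len(len)
        anticodon <- NA_character_
      } else if (gene %in% pcg_genes()) {
        len <- spec$gene_lengths[[gene]]
        gseq <- build_pcg(gene, len, spec, pool,
                          forced_head = forced_head,
                          forced_tail = forced_tail)
        type <- "PCG"
        free_local <- integer(0)
        anticodon <- NA_character_
      } else {
        abort(sprintf("unknown gene label in order: %s", gene))
      }

      insert <- if (strand == "N") revcomp(gseq) else gseq
      len <- nchar(insert)
      start_pos <- cur - pending_overlap
      if (pending_overlap > 0L) {
        insert <- substring(insert, pending_overlap + 1L)
      }
      parts[[length(parts) + 1L]] <- insert
      end_pos <- start_pos + len - 1L
      rows[[length(rows) + 1L]] <- tibble(
        gene = gene, type = type, start = start_pos, end = end_pos,
        strand = strand, anticodon = anticodon)
      if (length(free_local))
        free_ranges[[length(free_ranges) + 1L]] <- start_pos - 1L + free_local
      cur <- end_pos + 1L
      pending_overlap <- o_next

      # intergenic spacer (free positions), skipped before an overlap
      is_last <- (i == n_items && copy == n_copies)
      if (pending_overlap == 0L && !is_last && spec$spacer > 0L) {
        sp <- paste(sample_bases(spec$spacer, comp), collapse = "")
        parts[[length(parts) + 1L]] <- sp
        free_ranges[[length(free_ranges) + 1L]] <- cur - 1L + seq_len(spec$spacer)
        cur <- cur + spec$spacer
      }
    }
  }

  seq <- paste(parts, collapse = "")
  ch <- seq_chars(seq)
  free_pos <- unlist(free_ranges, use.names = FALSE)
  free_pos <- sample(free_pos)   # spread repairs across free regions
  ch <- repair_composition(ch, free_pos, comp)
  genome <- circular_genome(id, paste(ch, collapse = ""))
  features <- feature_table(dplyr::bind_rows(rows), genome$length)
  list(genome = genome, features = features)
}

#' Generate a tRNA gene sequence with a requested arm configuration
#'
#' Builds a sequence that folds (with default [fold_params()]) into a
#' cloverleaf whose arms have exactly the requested statuses and whose
#' anticodon decodes the requested amino acid; loop-only arms are rendered as
#' unpairable poly-A regions. Draws are retried (deterministically under the
#' current RNG state) until the folder confirms the configuration.
#'
#' @param amino_acid One-letter amino acid, or a gene label like `"trnK"`,
#'   `"trnS1"`.
#' @param arm_config `"canonical"`, `"dhu_loop_only"` or `"t_loop_only"`.
#' @param seed Optional integer seed (when `NULL`, the current RNG state is
#'   used, e.g. inside [make_mitogenome()]).
#' @param anticodon Optional anticodon override (DNA alphabet).
#' @param params Folding parameters used for verification.
#' @return A tRNA gene sequence (DNA string, 56-71 nt).
#' @export
make_trna_seq <- function(amino_acid,
                          arm_config = c("canonical", "dhu_loop_only",
                                         "t_loop_only"),
                          seed = NULL, anticodon = NULL,
                          params = fold_params()) {
  arm_config <- match.arg(arm_config)
  if (!is.null(seed)) set.seed(seed)
  gene <- if (startsWith(amino_acid, "trn")) amino_acid else {
    hits <- trna_genes()[substr(sub("^trn", "", trna_genes()), 1, 1) == amino_acid]
    if (!length(hits)) abort(sprintf("unknown amino acid '%s'", amino_acid))
    hits[length(hits)]  # L -> trnL2, S -> trnS2 by default
  }
  if (is.null(anticodon)) anticodon <- unname(trna_anticodons()[gene])
  if (is.na(anticodon)) abort(sprintf("no anticodon known for %s", gene))

  comp <- c(a = 0.36, t = 0.34, g = 0.14, c = 0.16)
  pair_of <- c(A = "T", T = "A", G = "C", C = "G")
  rand <- function(k) paste(sample_bases(k, comp), collapse = "")
  stem_pair <- function(k) {
    s5 <- sample_bases(k, comp)
    list(left = paste(s5, collapse = ""),
         right = paste(rev(unname(pair_of[s5])), collapse = ""))
  }

  for (attempt in seq_len(40)) {
    acc <- stem_pair(7L)
    acarm <- stem_pair(5L)
    d_part <- if (arm_config == "dhu_loop_only") strrep("A", 9L) else {
      d <- stem_pair(3L)
      paste0(rand(2L), d$left, rand(7L), d$right, rand(1L))
    }
    # a loop-only T arm is rendered as poly-A with a C-only variable region,
    # so no accidental stem can form against it
    t_part <- if (arm_config == "t_loop_only") strrep("A", 11L) else {
      t <- stem_pair(4L)
      paste0(t$left, rand(7L), t$right)
    }
    v_part <- if (arm_config == "t_loop_only") strrep("C", 4L) else rand(4L)
    seqs <- paste0(
      acc$left, d_part,
      acarm$left, rand(2L), anticodon, rand(2L), acarm$right,
      v_part, t_part, acc$right, rand(1L)
    )
    fold <- fold_cloverleaf(seqs, params = params)
    if (inherits(fold, "cloverleaf_failure")) next
    if (!identical(fold$anticodon, anticodon)) next
    cls <- classify_structure(fold)
    want <- switch(arm_config, canonical = "canonical",
                   dhu_loop_only = "dhu_loop_only",
                   t_loop_only = "t_loop_only")
    if (identical(cls, want)) return(seqs)
  }
  abort(sprintf("could not realize arm configuration '%s' for %s",
                arm_config, gene))
}

#' Specification for a synthetic population sample
#'
#' Defaults emulate a 642-bp mitochondrial fragment survey: a fragment made
#' of a 482-bp nad5 portion (coding, frame from position 1), the complete
#' 62-bp trnH gene, 2 intergenic nucleotides and a 96-bp nad4 portion; 16
#' haplotypes over 16 variable sites (15 in nad5, 1 intergenic) with counts
#' 178, 93 and 18 for the three major haplotypes and the remaining 20
#' individuals spread over 7 doubletons and 6 singletons; and the two major
#' nonsynonymous mutations at fragment positions 277 (M93L) and 391 (D131N).
#'
#' @param seed Integer seed.
#' @param n_samples Total sample size.
#' @return A list of class `population_spec` with elements `reference`
#'   (fragment string), `map` ([fragment_map()]), `haplotypes` (tibble
#'   `haplotype`, `positions` list, `alts` list, `count`), `seed`.
#' @export
population_spec <- function(seed = 1L, n_samples = 309L) {
  set.seed(seed)
  comp <- c(a = 0.42, t = 0.35, g = 0.094, c = 0.136)
  code <- mito_genetic_code("5")
  pool <- codon_pool(comp, code)

  nad5_codons <- sample_codons(160L, pool)
  nad5_codons[93] <- "ATA"   # Met: position 277 A>T gives M93L
  nad5_codons[131] <- "GAT"  # Asp: position 391 G>A gives D131N
  # anchor codons for the planted minor-haplotype mutations
  syn_codon_idx <- c(20L, 45L, 70L, 101L, 120L, 140L, 150L, 155L)
  for (ci in syn_codon_idx) nad5_codons[ci] <- "GGA"  # 4-fold Gly family
  nonsyn_codon_idx <- c(30L, 55L, 85L, 110L)
  for (ci in nonsyn_codon_idx) nad5_codons[ci] <- "CTA"  # Leu; pos-2 changes are nonsyn
  nad5 <- paste0(paste(nad5_codons, collapse = ""),
                 paste(sample_bases(2L, comp), collapse = ""))
  trnh <- paste(sample_bases(62L, comp), collapse = "")
  inter <- "AT"
  nad4 <- paste(sample_codons(32L, pool), collapse = "")
  reference <- paste0(nad5, trnh, inter, nad4)

  map <- fragment_map(tibble(
    name = c("nad5", "trnH", "intergenic", "nad4"),
    start = c(1L, 483L, 545L, 547L),
    end = c(482L, 544L, 546L, 642L),
    coding = c(TRUE, FALSE, FALSE, TRUE),
    frame_offset = c(0L, 0L, 0L, 0L)
  ))

  syn_pos <- syn_codon_idx * 3L              # third positions of GGA codons
  nonsyn_pos <- (nonsyn_codon_idx - 1L) * 3L + 2L  # second positions of CTA
  minor <- list(
    list(pos = nonsyn_pos[1], alt = "A"),                    # CTA->CAA L>Q
    list(pos = syn_pos[1], alt = "G"),                       # GGA->GGG syn
    list(pos = syn_pos[2], alt = "T"),
    list(pos = syn_pos[3], alt = "C"),
    list(pos = syn_pos[4], alt = "G"),
    list(pos = 545L, alt = "T"),                             # intergenic
    list(pos = syn_pos[5], alt = "G"),
    list(pos = c(syn_pos[6], syn_pos[7]), alt = c("T", "G")),# two-step hap
    list(pos = nonsyn_pos[2], alt = "G"),                    # L>R
    list(pos = nonsyn_pos[3], alt = "A"),                    # L>Q
    list(pos = nonsyn_pos[4], alt = "G"),                    # L>R
    list(pos = syn_pos[8], alt = "C"),
    list(pos = 6L, alt = sub_base(reference, 6L))
  )
  minor_counts <- c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L)
  haplotypes <- tibble(
    haplotype = paste0("H", seq_len(16L)),
    positions = c(list(integer(0)), list(277L), list(c(277L, 391L)),
                  lapply(minor, function(m) as.integer(m$pos))),
    alts = c(list(character(0)), list("T"), list(c("T", "A")),
             lapply(minor, function(m) m$alt)),
    count = c(178L, 93L, 18L, minor_counts)
  )
  if (sum(haplotypes$count) != n_samples)
    abort("haplotype counts must sum to the sample size")
  structure(
    list(reference = reference, map = map, haplotypes = haplotypes,
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "population_spec"
  )
}

sub_base <- function(seq, pos) {
  b <- substr(seq, pos, pos)
  setdiff(c("A", "C", "G", "T"), b)[1]
}

#' Generate an aligned population sample from a spec
#'
#' Applies each haplotype's planted mutations to the reference fragment and
#' replicates it to the planted count; individuals are shuffled
#' deterministically under the spec seed. The true assignment is attached as
#' the `assignments` attribute.
#'
#' @param spec A [population_spec()].
#' @return Aligned tibble (`id`, `seq`) of `spec$n_samples` sequences.
#' @export
make_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed + 1L)
  h <- spec$haplotypes
  seqs <- vapply(seq_len(nrow(h)), function(i) {
    pos <- h$positions[[i]]; alt <- h$alts[[i]]
    if (length(pos) != length(alt))
      abort("haplotype mutation positions and alleles differ in length")
    if (anyDuplicated(pos))
      abort("conflicting alleles at one position within a haplotype")
    ch <- seq_chars(spec$reference)
    if (length(pos)) {
      if (any(pos < 1 | pos > length(ch)))
        abort("planted mutation outside the fragment")
      ch[pos] <- alt
    }
    paste(ch, collapse = "")
  }, character(1))
  idx <- rep(seq_len(nrow(h)), h$count)
  idx <- sample(idx)
  out <- tibble(
    id = sprintf("S%03d", seq_along(idx)),
    seq = seqs[idx]
  )
  attr(out, "assignments") <- tibble(id = out$id, haplotype = h$haplotype[idx])
  out
}

#' Derive a diverged copy of a genome with planted differences
#'
#' Plants an exact number of substitutions per gene (positions uniform
#' without replacement) and the requested insertion/deletion events, and
#' returns the mutated genome, its re-mapped feature table and the implied
#' pairwise alignment (gap character `-`), so detection tools can be checked
#' against the planted truth.
#'
#' @param g List with `genome` and `features` (e.g. from
#'   [make_mitogenome()]).
#' @param per_gene_substitutions Named integer vector of substitution counts.
#' @param indel_spec Optional tibble with columns `pos` (1-based position in
#'   the original genome; insertions are placed before it), `length`, `type`
#'   (`"insertion"`/`"deletion"`). Spans must not overlap.
#' @param seed Integer seed.
#' @return List: `genome`, `features` (both for the mutated copy),
#'   `alignment` (list `a`, `b`), `substitutions` (tibble `gene`, `position`,
#'   `ref`, `alt`).
#' @export
mutate_genome <- function(g, per_gene_substitutions = integer(),
                          indel_spec = NULL, seed = 1L) {
  set.seed(seed)
  L <- g$genome$length
  ch_a <- seq_chars(g$genome$sequence)
  ch_b <- ch_a
  subs <- list()
  for (gene in names(per_gene_substitutions)) {
    k <- per_gene_substitutions[[gene]]
    f <- g$features[g$features$gene == gene & g$features$copy_index == 1L, ]
    if (!nrow(f)) abort(sprintf("gene %s not found in the feature table", gene))
    flen <- feature_span_length(f$start, f$end, L)
    if (k > flen) abort(sprintf("gene %s: more substitutions than bases", gene))
    offs <- sample(seq_len(flen), k)
    pos <- ((f$start - 1L + offs - 1L) %% L) + 1L
    for (p in pos) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), ch_b[p]), 1)
      subs[[length(subs) + 1L]] <- tibble(gene = gene, position = p,
                                          ref = ch_a[p], alt = alt)
      ch_b[p] <- alt
    }
  }
  subs <- if (length(subs)) dplyr::bind_rows(subs) else
    tibble(gene = character(), position = integer(),
           ref = character(), alt = character())

  if (is.null(indel_spec) || !nrow(indel_spec)) {
    indel_spec <- tibble(pos = integer(), length = integer(), type = character())
  }
  indel_spec <- dplyr::arrange(as_tibble(indel_spec), .data$pos)
  if (nrow(indel_spec) > 1) {
    spans <- cbind(indel_spec$pos,
                   ifelse(indel_spec$type == "deletion",
                          indel_spec$pos + indel_spec$length - 1L,
                          indel_spec$pos))
    for (i in seq_len(nrow(spans) - 1L)) {
      if (spans[i + 1L, 1] <= spans[i, 2])
        abort("indel spans overlap")
    }
  }

  a_parts <- character(0); b_parts <- character(0)
  cur <- 1L
  comp <- c(a = 0.42, t = 0.35, g = 0.094, c = 0.136)
  for (i in seq_len(nrow(indel_spec))) {
    e <- indel_spec[i, ]
    if (e$pos < cur || e$pos > L + 1L) abort("indel position out of range")
    seg <- if (e$pos > cur) paste(ch_a[cur:(e$pos - 1L)], collapse = "") else ""
    segb <- if (e$pos > cur) paste(ch_b[cur:(e$pos - 1L)], collapse = "") else ""
    a_parts <- c(a_parts, seg); b_parts <- c(b_parts, segb)
    if (e$type == "insertion") {
      ins <- paste(sample_bases(e$length, comp), collapse = "")
      a_parts <- c(a_parts, strrep("-", e$length))
      b_parts <- c(b_parts, ins)
      cur <- e$pos
    } else if (e$type == "deletion") {
      del_end <- e$pos + e$length - 1L
      if (del_end > L) abort("deletion runs past the genome end")
      a_parts <- c(a_parts, paste(ch_a[e$pos:del_end], collapse = ""))
      b_parts <- c(b_parts, strrep("-", e$length))
      cur <- del_end + 1L
    } else {
      abort("indel type must be 'insertion' or 'deletion'")
    }
  }
  if (cur <= L) {
    a_parts <- c(a_parts, paste(ch_a[cur:L], collapse = ""))
    b_parts <- c(b_parts, paste(ch_b[cur:L], collapse = ""))
  }
  a_aln <- paste(a_parts, collapse = "")
  b_aln <- paste(b_parts, collapse = "")

  # map original coordinates onto the mutated genome
  a_cols <- seq_chars(a_aln) != "-"
  b_cols <- seq_chars(b_aln) != "-"
  b_index <- cumsum(b_cols)
  map_left <- b_index[a_cols]                    # last B position at-or-before
  b_seq <- gsub("-", "", b_aln, fixed = TRUE)
  newL <- nchar(b_seq)

  f <- g$features
  a_col_of <- which(a_cols)           # alignment column of each A position
  survived <- b_cols[a_col_of]        # TRUE if the base is still present in B
  new_start <- ifelse(survived[f$start], map_left[f$start],
                      pmin(map_left[f$start] + 1L, newL))
  new_end <- map_left[f$end]
  keep <- new_end >= new_start
  nf <- f[keep, ]
  nf$start <- as.integer(new_start[keep])
  nf$end <- as.integer(new_end[keep])

  genome_b <- circular_genome(paste0(g$genome$id, "_mut"), b_seq)
  list(
    genome = genome_b,
    features = feature_table(nf[, c("gene", "type", "start", "end",
                                    "strand", "anticodon")], newL),
    alignment = list(a = a_aln, b = b_aln),
    substitutions = subs
  )
}
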