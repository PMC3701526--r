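# Intraspecific variation: haplotypes, networks, diversity, divergence -------

#' Validate an aligned set of sequences
#'
#' @param aln Tibble with columns `id` and `seq`, or a named character
#'   vector. All sequences must have equal length and unique ids.
#' @return A validated tibble with columns `id` and `seq`.
#' @export
aligned_set <- function(aln) {
  if (is.character(aln)) aln <- tibble(id = names(aln), seq = unname(aln))
  aln <- as_tibble(aln)
  stopifnot(all(c("id", "seq") %in% names(aln)))
  if (anyDuplicated(aln$id)) abort("sequence ids must be unique")
  lens <- nchar(aln$seq)
  if (length(unique(lens)) > 1)
    abort("aligned sequences must all have the same length")
  aln$seq <- toupper(aln$seq)
  aln[, c("id", "seq")]
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Variable sites of an alignment
#'
#' Positions at which at least two distinct unambiguous alleles (A/C/G/T) are
#' observed.
#'
#' @param aln An aligned set (see [aligned_set()]) with >= 2 sequences.
#' @return Tibble: `position`, `n_alleles`, `alleles` (comma-joined, ordered
#'   by descending count then base).
#' @export
call_variable_sites <- function(aln) {
  aln <- aligned_set(aln)
  if (nrow(aln) < 2) abort("need at least 2 sequences")
  m <- aln_matrix(aln)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) < 2) return(NULL)
    tibble(position = j, n_alleles = length(tb),
           alleles = paste(names(tb), collapse = ","))
  })
  out <- purrr::list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    out <- tibble(position = integer(), n_alleles = integer(),
                  alleles = character())
  out
}

#' Collapse an alignment into haplotypes
#'
#' Groups sequences with identical signatures over the variable sites.
#' Haplotypes are numbered `Hap1`, `Hap2`, ... by descending count, ties by
#' first occurrence in the input.
#'
#' @param aln An aligned set with >= 2 sequences.
#' @return Object of class `haplotype_table`: list with `haplotypes` (tibble
#'   `haplotype`, `signature`, `count`, `members` list-column),
#'   `variable_sites` (tibble from [call_variable_sites()]), `n_sequences`.
#' @export
collapse_haplotypes <- function(aln) {
  aln <- aligned_set(aln)
  sites <- call_variable_sites(aln)
  m <- aln_matrix(aln)
  sig <- if (nrow(sites)) {
    apply(m[, sites$position, drop = FALSE], 1, paste, collapse = "")
  } else {
    rep("", nrow(aln))
  }
  first_seen <- match(unique(sig), sig)
  groups <- split(aln$id, factor(sig, levels = unique(sig)))
  counts <- lengths(groups)
  ord <- order(-counts, first_seen)
  haps <- tibble(
    haplotype = paste0("Hap", seq_along(ord)),
    signature = names(groups)[ord],
    count = as.integer(counts[ord]),
    members = unname(groups[ord])
  )
  structure(
    list(haplotypes = haps, variable_sites = sites, n_sequences = nrow(aln)),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d haplotypes over %d sequences, %d variable sites\n",
              nrow(x$haplotypes), x$n_sequences, nrow(x$variable_sites)))
  print(x$haplotypes[, c("haplotype", "signature", "count")])
  invisible(x)
}

#' @method tidy haplotype_table
#' @export
tidy.haplotype_table <- function(x, ...) {
  x$haplotypes[, c("haplotype", "signature", "count")]
}

#' @method glance haplotype_table
#' @export
glance.haplotype_table <- function(x, ...) {
  tibble(n_haplotypes = nrow(x$haplotypes), n_sequences = x$n_sequences,
         n_variable_sites = nrow(x$variable_sites))
}

#' Fragment map of a sequenced region
#'
#' Describes how a sequenced fragment partitions into named segments (gene
#' portions, RNA genes, intergenic nucleotides). Coding segments carry a
#' frame offset: the offset of the first in-frame codon position relative to
#' the segment start (0 means the segment starts on codon position 1).
#'
#' @param segments Data frame with columns `name`, `start`, `end`, `coding`
#'   (logical), `frame_offset` (integer, used only for coding segments).
#' @return Validated tibble; segments must be contiguous, non-overlapping and
#'   cover positions 1..max(end).
#' @export
fragment_map <- function(segments) {
  fm <- as_tibble(segments)
  stopifnot(all(c("name", "start", "end", "coding", "frame_offset") %in% names(fm)))
  fm <- dplyr::arrange(fm, .data$start)
  if (fm$start[1] != 1L) abort("fragment map must start at position 1")
  if (nrow(fm) > 1 && any(fm$start[-1] != fm$end[-nrow(fm)] + 1L))
    abort("fragment map segments must be contiguous and non-overlapping")
  fm
}

#' Classify a point mutation within a mapped fragment
#'
#' For a site in a coding segment, computes the codon number (1-based from
#' the segment's frame start), the position within the codon, and whether the
#' substitution is synonymous under the chosen genetic code; amino-acid
#' changes are reported in `M93L` style. Sites in non-coding segments are
#' labelled by segment.
#'
#' @param site 1-based position within the fragment.
#' @param ref_seq Reference fragment sequence.
#' @param alt Alternate allele (single base).
#' @param map A [fragment_map()].
#' @param code Genetic code id (default invertebrate mitochondrial).
#' @return One-row tibble: `site`, `segment`, `coding`, `codon_number`,
#'   `codon_position`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect` (`synonymous`, `nonsynonymous` or `noncoding`), `aa_change`.
#' @export
classify_mutation <- function(site, ref_seq, alt, map, code = "5") {
  ref_seq <- toupper(ref_seq)
  alt <- toupper(alt)
  hit <- which(map$start <= site & site <= map$end)
  if (!length(hit)) abort(sprintf("site %d outside the mapped fragment", site))
  seg <- map[hit[1], ]
  if (!seg$coding) {
    return(tibble(site = site, segment = seg$name, coding = FALSE,
                  codon_number = NA_integer_, codon_position = NA_integer_,
                  ref_codon = NA_character_, alt_codon = NA_character_,
                  ref_aa = NA_character_, alt_aa = NA_character_,
                  effect = "noncoding", aa_change = NA_character_))
  }
  gc <- mito_genetic_code(code)
  coding_start <- seg$start + seg$frame_offset
  offset <- site - coding_start
  if (offset < 0) abort(sprintf("site %d precedes the coding frame of %s",
                                site, seg$name))
  codon_number <- offset %/% 3L + 1L
  codon_position <- offset %% 3L + 1L
  codon_start <- coding_start + (codon_number - 1L) * 3L
  ref_codon <- substr(ref_seq, codon_start, codon_start + 2L)
  alt_chars <- seq_chars(ref_codon)
  alt_chars[codon_position] <- alt
  alt_codon <- paste(alt_chars, collapse = "")
  ref_aa <- translate_codon(ref_codon, gc)
  alt_aa <- translate_codon(alt_codon, gc)
  syn <- identical(ref_aa, alt_aa)
  tibble(
    site = site, segment = seg$name, coding = TRUE,
    codon_number = codon_number, codon_position = codon_position,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa,
    effect = if (syn) "synonymous" else "nonsynonymous",
    aa_change = if (syn) NA_character_ else
      sprintf("%s%d%s", ref_aa, codon_number, alt_aa)
  )
}

hamming <- function(s1, s2) {
  a <- seq_chars(s1); b <- seq_chars(s2)
  sum(a != b)
}

#' Minimum spanning network of a haplotype table
#'
#' Builds the minimum spanning network on Hamming distances between
#' haplotype signatures: all edges belonging to any minimum spanning tree are
#' retained (Kruskal with ties kept), so reticulations among equally
#' parsimonious connections are preserved. Edges are labelled with the
#' variable-site positions at which their endpoints differ.
#'
#' @param t A `haplotype_table` from [collapse_haplotypes()].
#' @return Object of class `haplotype_network`: list with `nodes` (tibble
#'   `haplotype`, `count`, `signature`), `edges` (tibble `from`, `to`,
#'   `weight`, `positions` comma-joined), and `mst_weight` (total weight of
#'   one minimum spanning tree).
#' @export
build_network <- function(t) {
  stopifnot(inherits(t, "haplotype_table"))
  h <- t$haplotypes
  k <- nrow(h)
  nodes <- h[, c("haplotype", "count", "signature")]
  if (k == 1) {
    return(structure(list(
      nodes = nodes,
      edges = tibble(from = character(), to = character(),
                     weight = integer(), positions = character()),
      mst_weight = 0L
    ), class = "haplotype_network"))
  }
  pos <- t$variable_sites$position
  cand <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- seq_chars(h$signature[i]); b <- seq_chars(h$signature[j])
    diffs <- which(a != b)
    cand[[length(cand) + 1L]] <- tibble(
      from = h$haplotype[i], to = h$haplotype[j],
      weight = length(diffs),
      positions = paste(pos[diffs], collapse = ","))
  }
  cand <- dplyr::bind_rows(cand)

  # Kruskal over weight classes; within a class, every edge joining two
  # different components (as they stood before the class) is retained.
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  idx <- setNames(seq_len(k), h$haplotype)
  keep <- logical(nrow(cand))
  mst_weight <- 0L
  for (w in sort(unique(cand$weight))) {
    rows <- which(cand$weight == w)
    comp_before <- vapply(seq_len(k), find, integer(1))
    joins <- rows[comp_before[idx[cand$from[rows]]] !=
                    comp_before[idx[cand$to[rows]]]]
    keep[joins] <- TRUE
    for (r in joins) {
      ra <- find(idx[cand$from[r]]); rb <- find(idx[cand$to[r]])
      if (ra != rb) {
        parent[ra] <- rb
        mst_weight <- mst_weight + w
      }
    }
  }
  structure(
    list(nodes = nodes, edges = cand[keep, ], mst_weight = mst_weight),
    class = "haplotype_network"
  )
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d nodes, %d edges (MST weight %d)\n",
              nrow(x$nodes), nrow(x$edges), x$mst_weight))
  invisible(x)
}

#' @method tidy haplotype_network
#' @export
tidy.haplotype_network <- function(x, ...) x$edges

#' @method glance haplotype_network
#' @export
glance.haplotype_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         mst_weight = x$mst_weight)
}

#' Convert a haplotype network to an igraph object
#'
#' @param x A `haplotype_network`.
#' @return An [igraph::graph_from_data_frame()] graph with node `count` and
#'   edge `weight` attributes.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "haplotype_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(x$edges[, c("from", "to", "weight")]),
    directed = FALSE,
    vertices = as.data.frame(x$nodes[, c("haplotype", "count")])
  )
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise p-distance over all unordered pairs of sequences; positions
#' where either sequence carries an ambiguous base (not A/C/G/T) are excluded
#' from that pair's comparison.
#'
#' @param aln An aligned set with >= 2 sequences.
#' @return Numeric pi in `[0,1]`.
#' @export
nucleotide_diversity <- function(aln) {
  aln <- aligned_set(aln)
  if (nrow(aln) < 2) abort("need at least 2 sequences")
  m <- aln_matrix(aln)
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  n <- nrow(m)
  total <- 0
  npairs <- 0L
  for (i in seq_len(n - 1)) {
    rows <- (i + 1):n
    both_ok <- ok[rows, , drop = FALSE] &
      matrix(ok[i, ], nrow = length(rows), ncol = ncol(m), byrow = TRUE)
    diffs <- (m[rows, , drop = FALSE] !=
                matrix(m[i, ], nrow = length(rows), ncol = ncol(m), byrow = TRUE)) &
      both_ok
    valid <- rowSums(both_ok)
    d <- rowSums(diffs)
    pd <- ifelse(valid > 0, d / valid, NA_real_)
    total <- total + sum(pd, na.rm = TRUE)
    npairs <- npairs + sum(!is.na(pd))
  }
  total / npairs
}

#' Per-gene divergence between two annotated genomes
#'
#' Compares, gene by gene, the coding-strand sequences of genes shared by two
#' genomes. Equal-length gene pairs are compared position-wise (no
#' alignment); genes whose lengths differ between the genomes are excluded
#' with a reason, mirroring the practice of excluding length-variant genes
#' from substitution-rate comparisons.
#'
#' @param a,b Lists with elements `genome` ([circular_genome()]) and
#'   `features` (feature table).
#' @return Object of class `divergence_report`: list with `per_gene` (tibble
#'   `gene`, `length`, `substitutions`, `rate`) and `excluded` (tibble
#'   `gene`, `reason`).
#' @export
pairwise_gene_divergence <- function(a, b) {
  fa <- dplyr::filter(a$features, .data$type %in% c("PCG", "tRNA", "rRNA"),
                      .data$copy_index == 1L)
  fb <- dplyr::filter(b$features, .data$type %in% c("PCG", "tRNA", "rRNA"),
                      .data$copy_index == 1L)
  shared <- intersect(fa$gene, fb$gene)
  if (!length(shared)) abort("no shared genes between the two genomes")
  per_gene <- list(); excluded <- list()
  for (g in shared) {
    sa <- extract_feature_seq(a$genome, fa[match(g, fa$gene), ])
    sb <- extract_feature_seq(b$genome, fb[match(g, fb$gene), ])
    if (nchar(sa) != nchar(sb)) {
      excluded[[length(excluded) + 1L]] <- tibble(
        gene = g,
        reason = sprintf("length differs (%d vs %d bp)", nchar(sa), nchar(sb)))
      next
    }
    subs <- hamming(sa, sb)
    per_gene[[length(per_gene) + 1L]] <- tibble(
      gene = g, length = nchar(sa), substitutions = subs,
      rate = subs / nchar(sa))
  }
  structure(
    list(
      per_gene = if (length(per_gene)) dplyr::bind_rows(per_gene) else
        tibble(gene = character(), length = integer(),
               substitutions = integer(), rate = numeric()),
      excluded = if (length(excluded)) dplyr::bind_rows(excluded) else
        tibble(gene = character(), reason = character())
    ),
    class = "divergence_report"
  )
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("<divergence_report> %d genes compared, %d excluded\n",
              nrow(x$per_gene), nrow(x$excluded)))
  print(dplyr::arrange(x$per_gene, dplyr::desc(.data$rate)))
  invisible(x)
}

#' @method tidy divergence_report
#' @export
tidy.divergence_report <- function(x, ...) x$per_gene

#' @method glance divergence_report
#' @export
glance.divergence_report <- function(x, ...) {
  tibble(n_compared = nrow(x$per_gene), n_excluded = nrow(x$excluded),
         mean_rate = mean(x$per_gene$rate),
         max_rate = if (nrow(x$per_gene)) max(x$per_gene$rate) else NA_real_)
}

#' Indel events between two aligned sequences
#'
#' Reports each maximal run of gap characters as one event. With `a` taken as
#' the reference, a gap run in `a` is an insertion (in `b`) and a gap run in
#' `b` is a deletion (from `b`).
#'
#' @param aligned_a,aligned_b Equal-length aligned strings using `-` for
#'   gaps.
#' @return Tibble: `type` (`insertion`/`deletion`), `start`, `end` (alignment
#'   coordinates), `length`.
#' @export
indel_report <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b))
    abort("aligned sequences must have equal length")
  gap_events <- function(s, type) {
    r <- rle(seq_chars(s) == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- r$values
    tibble(type = type, start = starts[hit], end = ends[hit],
           length = r$lengths[hit])
  }
  out <- dplyr::bind_rows(
    gap_events(toupper(aligned_a), "insertion"),
    gap_events(toupper(aligned_b), "deletion")
  )
  dplyr::arrange(out, .data$start)
}
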