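# Base composition, AT/GC skew, codon usage and RSCU -------------------------

#' Tally bases in a nucleotide string
#'
#' Exact per-base tally; `N` and any other ambiguity characters are counted
#' in `n_other` and excluded from downstream skew and content denominators.
#'
#' @param seq Nucleotide string (may be empty).
#' @return One-row tibble with columns `a`, `t`, `g`, `c`, `n_other`.
#' @export
count_bases <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- seq_chars(toupper(seq))
  a <- sum(ch == "A"); t <- sum(ch == "T")
  g <- sum(ch == "G"); c <- sum(ch == "C")
  base_counts(a, t, g, c, length(ch) - a - t - g - c)
}

#' Construct a base-count record directly
#'
#' Useful for working from published per-strand counts rather than a
#' sequence.
#'
#' @param a,t,g,c,n_other Non-negative integers.
#' @return One-row tibble of class used by [skew_report()].
#' @export
base_counts <- function(a, t, g, c, n_other = 0L) {
  stopifnot(all(c(a, t, g, c, n_other) >= 0))
  tibble(a = as.integer(a), t = as.integer(t), g = as.integer(g),
         c = as.integer(c), n_other = as.integer(n_other))
}

#' AT content and strand skews from base counts
#'
#' Computes `at_content = (A+T)/(A+T+G+C)`, `AT-skew = (A-T)/(A+T)` and
#' `GC-skew = (G-C)/(G+C)`. A zero denominator yields `NA` for the affected
#' skew rather than an error.
#'
#' @param counts A base-count tibble from [count_bases()] or [base_counts()].
#' @return One-row tibble with `at_content`, `gc_content`, `at_skew`,
#'   `gc_skew`.
#' @export
skew_report <- function(counts) {
  a <- counts$a; t <- counts$t; g <- counts$g; c <- counts$c
  tot <- a + t + g + c
  tibble(
    at_content = if (tot > 0) (a + t) / tot else NA_real_,
    gc_content = if (tot > 0) (g + c) / tot else NA_real_,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c > 0) (g - c) / (g + c) else NA_real_
  )
}

#' Per-base fractions of a count record
#'
#' @param counts A base-count tibble.
#' @return Tibble with columns `base`, `count`, `fraction` (fraction of the
#'   unambiguous total).
#' @export
base_fractions <- function(counts) {
  tot <- counts$a + counts$t + counts$g + counts$c
  tibble(
    base = c("A", "T", "G", "C"),
    count = c(counts$a, counts$t, counts$g, counts$c),
    fraction = if (tot > 0) c(counts$a, counts$t, counts$g, counts$c) / tot
               else rep(NA_real_, 4)
  )
}

# Codon usage ----------------------------------------------------------------

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0) return(character())
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Codon usage and RSCU over a set of coding sequences
#'
#' Reads codons in frame from position 1 of each CDS. A trailing partial
#' codon (an incomplete stop completed by polyadenylation) is excluded; full
#' stop codons are excluded from the sense-codon counts and totals but
#' tallied separately. Relative synonymous codon usage is
#' `RSCU_c = count_c * k / sum(family counts)` for a synonymous family of
#' size `k` under the chosen genetic code; codons of a family never observed
#' get RSCU 0.
#'
#' @param cds_list Character vector (or list) of coding-strand CDS strings,
#'   each at least 3 nt.
#' @param code Genetic code id (default `"5"`, invertebrate mitochondrial).
#' @return Object of class `codon_usage`: a list with `codons` (tibble
#'   `codon`, `aa`, `count`, `rscu`), `aa_freq` (tibble `aa`, `count`,
#'   `freq`), `stops` (tibble `codon`, `count`), and `total_codons`.
#' @export
codon_usage <- function(cds_list, code = "5") {
  cds_list <- unlist(cds_list, use.names = FALSE)
  stopifnot(all(nchar(cds_list) >= 3))
  gc <- mito_genetic_code(code)
  stops <- stop_codons(gc)
  sense <- sense_codons(gc)

  codons <- unlist(lapply(toupper(cds_list), split_codons), use.names = FALSE)
  clean <- grepl("^[ACGT]{3}$", codons)
  n_skipped <- sum(!clean)
  if (n_skipped > 0)
    message(sprintf("codon_usage: skipped %d codon(s) with ambiguous bases",
                    n_skipped))
  codons <- codons[clean]

  tab <- table(factor(codons, levels = names(gc)))
  stop_tab <- tab[stops]
  counts <- as.integer(tab[sense])
  aa <- unname(gc[sense])

  fam_tot <- tapply(counts, aa, sum)
  fam_k <- tapply(counts, aa, length)
  rscu <- ifelse(fam_tot[aa] > 0, counts * fam_k[aa] / fam_tot[aa], 0)

  total <- sum(counts)
  aa_freq <- tibble(
    aa = names(fam_tot),
    count = as.integer(fam_tot),
    freq = if (total > 0) as.integer(fam_tot) / total else rep(0, length(fam_tot))
  )
  structure(
    list(
      codons = tibble(codon = sense, aa = aa, count = counts,
                      rscu = unname(as.numeric(rscu))),
      aa_freq = aa_freq,
      stops = tibble(codon = stops, count = as.integer(stop_tab)),
      total_codons = total,
      code = code
    ),
    class = "codon_usage"
  )
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %d sense codons over %d codon types (code %s)\n",
              x$total_codons, nrow(x$codons), x$code))
  print(head(dplyr::arrange(x$codons, dplyr::desc(.data$count)), 5))
  invisible(x)
}

#' @method tidy codon_usage
#' @export
tidy.codon_usage <- function(x, ...) x$codons

#' @method glance codon_usage
#' @export
glance.codon_usage <- function(x, ...) {
  tibble(
    total_codons = x$total_codons,
    n_sense_codon_types = nrow(x$codons),
    n_absent_codons = sum(x$codons$count == 0),
    n_stop_codons = sum(x$stops$count)
  )
}

#' Start and stop codon of a coding sequence
#'
#' The start codon is the first triplet. The stop is the trailing `TAA`/`TAG`
#' triplet when the length is a multiple of 3; otherwise the trailing `TA` or
#' `T` is reported as an incomplete stop (completed to `TAA` by
#' polyadenylation in mitochondrial transcripts). A trailing full triplet
#' other than `TAA`/`TAG` is reported with `stop_complete = FALSE`.
#'
#' @param cds Coding-strand CDS string, length >= 4.
#' @param gene Optional gene label carried into the output.
#' @return One-row tibble `gene`, `start_codon`, `stop_codon`,
#'   `stop_complete`.
#' @export
start_stop_report <- function(cds, gene = NA_character_) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 4) abort("CDS must be at least 4 nt long")
  start <- substr(cds, 1, 3)
  rem <- n %% 3L
  if (rem == 0L) {
    stop_c <- substr(cds, n - 2, n)
    complete <- stop_c %in% c("TAA", "TAG")
  } else if (rem == 2L) {
    stop_c <- substr(cds, n - 1, n)
    complete <- FALSE
  } else {
    stop_c <- substr(cds, n, n)
    complete <- FALSE
  }
  tibble(gene = gene, start_codon = start, stop_codon = stop_c,
         stop_complete = complete)
}

#' Start/stop codon table for all protein-coding genes of a genome
#'
#' @param genome A [circular_genome()].
#' @param features Feature table; only rows with `type == "PCG"` are used.
#' @return Tibble with one row per PCG.
#' @export
start_stop_table <- function(genome, features) {
  pcg <- dplyr::filter(features, .data$type == "PCG")
  purrr::list_rbind(lapply(seq_len(nrow(pcg)), function(i) {
    start_stop_report(extract_feature_seq(genome, pcg[i, ]), gene = pcg$gene[i])
  }))
}

#' Squared Pearson correlation of paired A+T fractions
#'
#' Used to ask how well per-gene A+T content tracks whole-genome A+T content
#' across taxa.
#'
#' @param x Either a data frame whose first two numeric columns are the
#'   paired fractions, or a numeric vector.
#' @param y Numeric vector when `x` is a vector.
#' @return Squared correlation coefficient, or `NA` if either margin has
#'   zero variance.
#' @export
at_correlation <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    num <- x[vapply(x, is.numeric, logical(1))]
    stopifnot(ncol(num) >= 2)
    y <- num[[2]]; x <- num[[1]]
  }
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Composition and skew summary for an annotated genome
#'
#' Whole-genome J-strand skews plus per-gene A+T content on each gene's
#' coding strand.
#'
#' @param genome A [circular_genome()].
#' @param features Feature table (may be empty for genome-level stats only).
#' @return List with `genome_stats` (one-row tibble) and `gene_stats`
#'   (per-feature tibble).
#' @export
composition_report <- function(genome, features = NULL) {
  gstats <- dplyr::bind_cols(
    tibble(id = genome$id, length = genome$length),
    skew_report(count_bases(genome$sequence))
  )
  gene_stats <- NULL
  if (!is.null(features) && nrow(features)) {
    gene_stats <- purrr::list_rbind(lapply(seq_len(nrow(features)), function(i) {
      s <- extract_feature_seq(genome, features[i, ])
      dplyr::bind_cols(
        tibble(gene = features$gene[i], type = features$type[i],
               length = nchar(s)),
        skew_report(count_bases(s))
      )
    }))
  }
  list(genome_stats = gstats, gene_stats = gene_stats)
}
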