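# Circular genome container and annotation I/O ------------------------------

#' Create a circular genome object
#'
#' A minimal container for a circular DNA molecule: an identifier, an
#' upper-case nucleotide string over `{A,C,G,T,N}` and its length. All
#' coordinates used elsewhere in the package are 1-based inclusive positions
#' on this sequence (the J-strand); features may wrap the origin.
#'
#' @param id Genome identifier.
#' @param sequence Nucleotide string; lower case is accepted and upper-cased.
#' @return An object of class `circular_genome` with fields `id`, `sequence`
#'   and `length`.
#' @export
circular_genome <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) abort("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    abort("genome sequence may only contain A, C, G, T, N")
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp (circular)\n", x$id, x$length))
  invisible(x)
}

#' Length of a circular feature span
#'
#' Computes feature length on a circle of size `genome_length`; a span with
#' `end < start` wraps the origin and has length `L - start + 1 + end`.
#'
#' @param start,end 1-based inclusive positions.
#' @param genome_length Circle size in bp.
#' @return Integer vector of lengths.
#' @export
feature_span_length <- function(start, end, genome_length) {
  ifelse(end >= start, end - start + 1L, genome_length - start + 1L + end)
}

#' Build a validated feature table
#'
#' Normalises and validates a table of gene annotations for a circular
#' genome. Rows are sorted by `start` on the J-strand; duplicated gene names
#' are disambiguated by `copy_index` in positional order.
#'
#' @param features Data frame with columns `gene`, `type` (one of `PCG`,
#'   `tRNA`, `rRNA`, `control_region`, `repeat_region`, `other`), `start`,
#'   `end`, `strand` (`J` or `N`), and optionally `anticodon` and
#'   `copy_index`.
#' @param genome_length Genome length in bp used for bounds checks.
#' @return A tibble sorted by `start` with all seven columns.
#' @export
feature_table <- function(features, genome_length) {
  ft <- as_tibble(features)
  required <- c("gene", "type", "start", "end", "strand")
  missing <- setdiff(required, names(ft))
  if (length(missing))
    abort(paste("feature table missing columns:", paste(missing, collapse = ", ")))
  if (!"anticodon" %in% names(ft)) ft$anticodon <- NA_character_
  ft$start <- as.integer(ft$start)
  ft$end <- as.integer(ft$end)
  ok_types <- c("PCG", "tRNA", "rRNA", "control_region", "repeat_region", "other")
  bad <- setdiff(unique(ft$type), ok_types)
  if (length(bad)) abort(paste("unknown feature type:", paste(bad, collapse = ", ")))
  if (!all(ft$strand %in% c("J", "N")))
    abort("strand must be 'J' or 'N'")
  oob <- ft$start < 1L | ft$start > genome_length |
    ft$end < 1L | ft$end > genome_length
  if (any(oob))
    abort(paste0("feature outside sequence bounds: ",
                 paste(ft$gene[oob], collapse = ", ")))
  ft <- dplyr::arrange(ft, .data$start, .data$end)
  ft <- dplyr::group_by(ft, .data$gene)
  ft <- dplyr::mutate(ft, copy_index = dplyr::row_number())
  ft <- dplyr::ungroup(ft)
  ft[, c("gene", "type", "start", "end", "strand", "anticodon", "copy_index")]
}

# GenBank flat files ---------------------------------------------------------

format_gb_location <- function(start, end, strand, genome_length) {
  loc <- if (end >= start) {
    sprintf("%d..%d", start, end)
  } else {
    sprintf("join(%d..%d,1..%d)", start, genome_length, end)
  }
  if (strand == "N") loc <- sprintf("complement(%s)", loc)
  loc
}

gb_feature_key <- function(type) {
  switch(type,
         PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
         control_region = "D-loop", repeat_region = "repeat_region",
         "misc_feature")
}

#' Write a genome and its features as a GenBank flat file
#'
#' Emits a single-record GenBank file with circular topology, one feature
#' entry per table row (CDS/tRNA/rRNA/D-loop/repeat_region/misc_feature) and
#' the sequence in standard 60-column ORIGIN blocks. Origin-wrapping features
#' are encoded as `join(s..L,1..e)`.
#'
#' @param genome A [circular_genome()].
#' @param features A feature table (see [feature_table()]); may have 0 rows.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, features, path) {
  lines <- c(sprintf("LOCUS       %-16s %d bp    DNA     circular INV",
                     genome$id, genome$length),
             sprintf("DEFINITION  %s mitochondrial genome.", genome$id),
             sprintf("ACCESSION   %s", genome$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", genome$length))
  if (nrow(features)) {
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      loc <- format_gb_location(f$start, f$end, f$strand, genome$length)
      lines <- c(lines,
                 sprintf("     %-15s %s", gb_feature_key(f$type), loc),
                 sprintf("                     /gene=\"%s\"", f$gene))
      if (!is.na(f$anticodon))
        lines <- c(lines, sprintf("                     /anticodon=\"%s\"", f$anticodon))
      if (f$copy_index > 1L)
        lines <- c(lines, sprintf("                     /note=\"copy %d\"", f$copy_index))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, genome$length, by = 60L)
  for (st in starts) {
    block <- substr(s, st, min(st + 59L, genome$length))
    chunks <- substring(block, seq(1, nchar(block), 10),
                        pmin(seq(10, nchar(block) + 9, 10), nchar(block)))
    lines <- c(lines, sprintf("%9d %s", st, paste(chunks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

parse_gb_location <- function(loc) {
  strand <- if (grepl("^complement", loc)) "N" else "J"
  inner <- gsub("^complement\\(|\\)$", "", loc)
  inner <- gsub("^join\\(|\\)$", "", inner)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  rng <- do.call(rbind, lapply(parts, function(p) {
    m <- regmatches(p, regexec("(<?)(\\d+)\\.\\.(>?)(\\d+)", p))[[1]]
    if (length(m) < 5) abort(paste("unparseable location:", loc))
    c(as.integer(m[3]), as.integer(m[5]))
  }))
  list(start = rng[1, 1], end = rng[nrow(rng), 2], strand = strand)
}

#' Read a single-record GenBank flat file
#'
#' Parses the sequence and the CDS/tRNA/rRNA/D-loop/repeat_region/
#' misc_feature entries of a GenBank record into a [circular_genome()] and a
#' feature table. Gene names are canonicalized via [canonical_gene_name()];
#' `complement(...)` locations become strand `N`; `join(s..L,1..e)` locations
#' become origin-wrapping spans with `end < start`.
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @return A list with elements `genome` and `features`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^LOCUS", lines)) != 1L)
    abort("expected a single-record GenBank file")
  locus <- lines[grepl("^LOCUS", lines)][1]
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]

  origin_at <- which(grepl("^ORIGIN", lines))[1]
  if (is.na(origin_at)) abort("no ORIGIN section found")
  seq_lines <- lines[(origin_at + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome <- circular_genome(id, sequence)

  feat_at <- which(grepl("^FEATURES", lines))
  rows <- list()
  if (length(feat_at)) {
    block <- lines[(feat_at[1] + 1):(origin_at - 1)]
    # feature headers start at column 6; qualifiers are indented further
    is_hdr <- grepl("^ {5}\\S", block)
    idx <- which(is_hdr)
    for (k in seq_along(idx)) {
      hdr <- block[idx[k]]
      key <- sub("^\\s*(\\S+).*$", "\\1", hdr)
      if (key %in% c("source", "gene")) next
      loc_txt <- trimws(sub("^\\s*\\S+\\s*", "", hdr))
      to <- if (k < length(idx)) idx[k + 1] - 1 else length(block)
      quals <- block[seq(idx[k] + 1, length.out = max(0, to - idx[k]))]
      # continuation lines of a long location start before any qualifier
      while (length(quals) && !grepl("^\\s+/", quals[1])) {
        loc_txt <- paste0(loc_txt, trimws(quals[1]))
        quals <- quals[-1]
      }
      getq <- function(name) {
        hit <- grep(sprintf("^\\s+/%s=", name), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("^[^=]*=\"?|\"$", "", hit[1])
      }
      loc <- parse_gb_location(loc_txt)
      if (loc$start > genome$length || loc$end > genome$length)
        abort(sprintf("feature '%s' outside sequence bounds",
                      getq("gene") %||% key))
      gene_raw <- getq("gene")
      if (is.na(gene_raw)) gene_raw <- getq("product")
      anticodon <- getq("anticodon")
      if (!is.na(anticodon)) {
        # accept both bare triplets and full (pos:..,aa:..,seq:xxx) form
        m <- regmatches(anticodon, regexec("seq:([A-Za-z]{3})", anticodon))[[1]]
        anticodon <- toupper(chartr("Uu", "Tt", if (length(m) == 2) m[2] else anticodon))
      }
      type <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     `D-loop` = "control_region",
                     repeat_region = "repeat_region", "other")
      gene <- canonical_gene_name(gene_raw, anticodon)
      rows[[length(rows) + 1]] <- tibble(
        gene = gene, type = type, start = loc$start, end = loc$end,
        strand = loc$strand, anticodon = anticodon
      )
    }
  }
  features <- if (length(rows)) {
    feature_table(dplyr::bind_rows(rows), genome$length)
  } else {
    feature_table(tibble(gene = character(), type = character(),
                         start = integer(), end = integer(),
                         strand = character()), genome$length)
  }
  list(genome = genome, features = features)
}

# FASTA and feature-table TSV ------------------------------------------------

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id` and `seq`, or a named character
#'   vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- tibble(id = names(seqs), seq = unname(seqs))
  x <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read or write a feature table as tab-separated text
#'
#' The TSV dialect has a header line and columns `gene`, `type`, `start`,
#' `end`, `strand`, `anticodon`, `copy_index`; coordinates are 1-based
#' J-strand positions with strand recorded separately.
#'
#' @param path File path.
#' @param genome_length Genome length for validation on read.
#' @return `read_feature_tsv()` returns a feature tibble;
#'   `write_feature_tsv()` returns `path` invisibly.
#' @export
read_feature_tsv <- function(path, genome_length) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  feature_table(df, genome_length)
}

#' @rdname read_feature_tsv
#' @param features Feature tibble to write.
#' @export
write_feature_tsv <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Feature sequence extraction ------------------------------------------------

#' Extract the coding-strand sequence of a feature
#'
#' Returns the J-strand slice (wrapping the origin when `end < start`) for
#' strand-`J` features, and its reverse complement for strand-`N` features,
#' so the result always reads 5' to 3' on the feature's own coding strand.
#'
#' @param genome A [circular_genome()].
#' @param feature A single-row feature tibble or a list with `start`, `end`,
#'   `strand`.
#' @return Nucleotide string.
#' @export
extract_feature_seq <- function(genome, feature) {
  start <- feature$start
  end <- feature$end
  if (start < 1 || start > genome$length || end < 1 || end > genome$length)
    abort("feature outside sequence bounds")
  s <- if (end >= start) {
    substr(genome$sequence, start, end)
  } else {
    paste0(substr(genome$sequence, start, genome$length),
           substr(genome$sequence, 1, end))
  }
  if (identical(feature$strand, "N")) revcomp(s) else s
}

#' Intergenic spacers and overlaps around the circle
#'
#' Reports, for each pair of adjacent features in J-strand order, the number
#' of nucleotides between them; negative values indicate overlap. The pair
#' closing the circle (last feature back to the first) is included, so the
#' signed spacers and the feature lengths sum to the genome length.
#'
#' @param genome A [circular_genome()].
#' @param features A non-empty feature table.
#' @return Tibble with columns `upstream`, `downstream` and `spacer`.
#' @export
intergenic_report <- function(genome, features) {
  if (nrow(features) == 0) abort("feature table is empty")
  ft <- dplyr::arrange(features, .data$start)
  L <- genome$length
  len <- feature_span_length(ft$start, ft$end, L)
  end_lin <- ft$start + len - 1L  # may exceed L for the wrapping feature
  n <- nrow(ft)
  nxt <- c(seq_len(n)[-1], 1L)
  next_start <- ft$start[nxt] + ifelse(nxt == 1L, L, 0L)
  tibble(
    upstream = ft$gene,
    downstream = ft$gene[nxt],
    spacer = as.integer(next_start - end_lin - 1L)
  )
}
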