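# Signed circular gene orders and rearrangement detection --------------------

#' Create a signed circular gene order
#'
#' A gene order is an ordered, circular list of signed gene labels; a leading
#' `-` marks a gene encoded on the N-strand. Each label may appear at most
#' once.
#'
#' @param labels Character vector of signed labels, e.g.
#'   `c("cox1", "-trnQ", ...)`.
#' @param source_id Identifier of the genome the order came from.
#' @return Object of class `gene_order` (a character vector with attributes
#'   `source_id` and optionally `duplicated`).
#' @export
gene_order <- function(labels, source_id = NA_character_) {
  stopifnot(is.character(labels), length(labels) >= 1)
  stripped <- strip_sign(labels)
  if (anyDuplicated(stripped))
    abort(paste("duplicated labels in gene order:",
                paste(unique(stripped[duplicated(stripped)]), collapse = ", ")))
  structure(labels, source_id = source_id, class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s: %d genes\n",
              attr(x, "source_id") %||% "?", length(x)))
  cat(" ", paste(unclass(x), collapse = ","), "\n")
  dup <- attr(x, "duplicated")
  if (length(dup)) cat("  duplicated (collapsed):", paste(dup, collapse = ", "), "\n")
  invisible(x)
}

strip_sign <- function(labels) sub("^-", "", labels)

negate_label <- function(labels) {
  ifelse(startsWith(labels, "-"), substring(labels, 2), paste0("-", labels))
}

#' Derive a gene order from a feature table
#'
#' Labels are taken in J-strand positional order with sign from strand.
#' Duplicated genes (e.g. tandem tRNA copies) are collapsed to a single
#' entry at their first position when `collapse_duplicates = TRUE`, and the
#' collapsed names recorded in the `duplicated` attribute. The control
#' region is not a gene and is excluded unless requested.
#'
#' @param features Feature table sorted by start.
#' @param collapse_duplicates Collapse repeated gene names to one entry.
#' @param include_control_region Keep the `CR` feature in the order.
#' @param source_id Identifier for the resulting order.
#' @return A [gene_order()].
#' @export
order_from_table <- function(features, collapse_duplicates = TRUE,
                             include_control_region = FALSE,
                             source_id = NA_character_) {
  ft <- dplyr::arrange(features, .data$start)
  if (!include_control_region)
    ft <- dplyr::filter(ft, .data$type != "control_region", .data$gene != "CR")
  labels <- ifelse(ft$strand == "N", paste0("-", ft$gene), ft$gene)
  stripped <- strip_sign(labels)
  dup <- unique(stripped[duplicated(stripped)])
  if (collapse_duplicates && length(dup)) {
    keep <- !duplicated(stripped)
    labels <- labels[keep]
  } else if (length(dup)) {
    abort("feature table contains duplicated genes; use collapse_duplicates = TRUE")
  }
  out <- gene_order(labels, source_id = source_id)
  attr(out, "duplicated") <- dup
  out
}

#' Rotate a circular order to start at an anchor gene
#'
#' @param order A [gene_order()].
#' @param anchor Unsigned gene label to place first (default `cox1`).
#' @return The rotated [gene_order()].
#' @export
canonical_rotation <- function(order, anchor = "cox1") {
  labels <- unclass(order)
  i <- match(anchor, strip_sign(labels))
  if (is.na(i)) abort(sprintf("anchor gene '%s' not present in order", anchor))
  rotated <- labels[((seq_along(labels) - 1 + i - 1) %% length(labels)) + 1]
  out <- gene_order(rotated, source_id = attr(order, "source_id"))
  attr(out, "duplicated") <- attr(order, "duplicated")
  out
}

# A signed circular adjacency x -> y is orientation-free: it equals -y -> -x.
# Each adjacency is keyed by the lexicographically smaller of the two forms.
adjacency_keys <- function(order) {
  labels <- unclass(order)
  n <- length(labels)
  from <- labels
  to <- labels[c(seq_len(n)[-1], 1L)]
  fwd <- paste(from, to, sep = ">")
  rev <- paste(negate_label(to), negate_label(from), sep = ">")
  pmin(fwd, rev)
}

check_same_label_set <- function(a, b) {
  sa <- sort(strip_sign(unclass(a)))
  sb <- sort(strip_sign(unclass(b)))
  if (!identical(sa, sb)) {
    only_a <- setdiff(sa, sb); only_b <- setdiff(sb, sa)
    abort(paste0(
      "gene orders have different label sets",
      if (length(only_a)) paste0("; only in first: ", paste(only_a, collapse = ", ")) else "",
      if (length(only_b)) paste0("; only in second: ", paste(only_b, collapse = ", ")) else ""
    ))
  }
  invisible(TRUE)
}

#' Breakpoint distance between two signed circular gene orders
#'
#' The number of signed adjacencies of `a` (circular, orientation-aware: the
#' adjacency `x -> y` is identified with `-y -> -x`) that are absent from
#' `b`. Zero iff the orders are identical up to rotation and simultaneous
#' reflection with sign flip.
#'
#' @param a,b [gene_order()] objects over the same label set.
#' @return Non-negative integer.
#' @export
breakpoint_distance <- function(a, b) {
  check_same_label_set(a, b)
  sum(!(adjacency_keys(a) %in% adjacency_keys(b)))
}

#' Conserved blocks and displaced genes between two orders
#'
#' Decomposes order `a` into maximal runs whose internal adjacencies are all
#' shared with `b` (leftmost-longest; the decomposition starts after the
#' first breakpoint so blocks never straddle one), and reports genes whose
#' both flanking adjacencies in `a` are absent from `b` ("displaced": a
#' single-gene translocation shows up as one displaced gene with unchanged
#' flanks elsewhere).
#'
#' @param a,b [gene_order()] objects over the same label set.
#' @return Object of class `rearrangement_report`: list with
#'   `breakpoint_count`, `conserved_blocks` (tibble `block`, `genes`,
#'   `length`), `displaced_genes` (character).
#' @export
diff_blocks <- function(a, b) {
  check_same_label_set(a, b)
  labels <- unclass(a)
  n <- length(labels)
  keys <- adjacency_keys(a)         # keys[i] joins labels[i] -> labels[i+1]
  in_b <- keys %in% adjacency_keys(b)
  bp <- sum(!in_b)

  displaced <- character()
  for (i in seq_len(n)) {
    prev_adj <- in_b[if (i == 1) n else i - 1]
    next_adj <- in_b[i]
    if (!prev_adj && !next_adj) displaced <- c(displaced, strip_sign(labels[i]))
  }

  blocks <- list()
  if (bp == 0) {
    blocks[[1]] <- labels
  } else {
    first_break <- which(!in_b)[1]
    ord <- ((seq_len(n) + first_break - 1L) %% n) + 1L  # start after the break
    cur <- character()
    for (i in ord) {
      cur <- c(cur, labels[i])
      if (!in_b[i]) { blocks[[length(blocks) + 1]] <- cur; cur <- character() }
    }
    if (length(cur)) blocks[[length(blocks) + 1]] <- cur
  }
  structure(
    list(
      breakpoint_count = bp,
      conserved_blocks = tibble(
        block = seq_along(blocks),
        genes = purrr::map_chr(blocks, paste, collapse = ","),
        length = purrr::map_int(blocks, length)
      ),
      displaced_genes = displaced
    ),
    class = "rearrangement_report"
  )
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("<rearrangement_report> %d breakpoint(s), %d conserved block(s)\n",
              x$breakpoint_count, nrow(x$conserved_blocks)))
  if (length(x$displaced_genes))
    cat("  displaced genes:", paste(x$displaced_genes, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy rearrangement_report
#' @export
tidy.rearrangement_report <- function(x, ...) x$conserved_blocks

#' @method glance rearrangement_report
#' @export
glance.rearrangement_report <- function(x, ...) {
  tibble(breakpoint_count = x$breakpoint_count,
         n_blocks = nrow(x$conserved_blocks),
         n_displaced = length(x$displaced_genes))
}

#' Adjacencies shared by all query orders but absent from a reference
#'
#' Identifies derived adjacencies common to a set of genomes relative to an
#' ancestral (reference) order -- shared rearrangement signatures.
#'
#' @param orders List of [gene_order()] objects (at least 2).
#' @param reference Reference [gene_order()].
#' @return Tibble with columns `from`, `to` (signed labels, in the canonical
#'   orientation of the adjacency key).
#' @export
shared_derived_adjacencies <- function(orders, reference) {
  stopifnot(length(orders) >= 2)
  for (o in orders) check_same_label_set(o, reference)
  shared <- Reduce(intersect, lapply(orders, adjacency_keys))
  derived <- setdiff(shared, adjacency_keys(reference))
  parts <- strsplit(derived, ">", fixed = TRUE)
  tibble(from = purrr::map_chr(parts, 1), to = purrr::map_chr(parts, 2))
}

#' Read gene orders from a spec file
#'
#' One genome per line: `name: l1,l2,-l3,...` with a minus marking N-strand
#' genes. Blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Named list of [gene_order()] objects.
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort(paste("unparseable gene-order line:", ln))
    name <- trimws(parts[1])
    labels <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    out[[name]] <- gene_order(labels, source_id = name)
  }
  out
}

#' Packaged reference gene orders
#'
#' Returns the gene orders shipped with the package: the putative ancestral
#' insect order, the shared planthopper (Delphacidae) order with its two
#' rearranged regions (trnC-trnW and nad6-trnP-trnT), and a prior
#' small-brown-planthopper annotation in which trnH sits between nad4L and
#' nad6 instead of between nad5 and nad4.
#'
#' @return Named list of [gene_order()] objects with entries
#'   `ancestral_insect`, `planthopper`, `sbph_prior`.
#' @export
reference_gene_orders <- function() {
  read_gene_orders(system.file("extdata", "gene_orders.txt",
                               package = "mitohopper", mustWork = TRUE))
}
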