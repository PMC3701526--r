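# Tandem repeats (VNTRs) and homopolymer runs in control regions -------------

rolling_sum <- function(x, width) {
  cs <- cumsum(c(0L, x))
  cs[(width + 1L):length(cs)] - cs[1:(length(cs) - width)]
}

majority_consensus <- function(tiles_mat) {
  # tiles_mat: copies x period character matrix; ties broken by A<C<G<T order
  apply(tiles_mat, 2, function(col) {
    tb <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    names(tb)[which.max(tb)]
  })
}

key_better <- function(k1, k2) {
  d <- k1 - k2
  nz <- which(d != 0)
  if (!length(nz)) FALSE else d[nz[1]] > 0
}

prefix_identity <- function(copy_chars, consensus) {
  k <- min(length(copy_chars), length(consensus))
  if (k == 0) return(0)
  sum(copy_chars[seq_len(k)] == consensus[seq_len(k)]) / k
}

#' Detect tandem-repeat arrays in a sequence
#'
#' Self-comparison at each candidate period finds windows in which the
#' sequence matches itself `period` positions away at identity at least
#' `min_identity`; overlapping windows are merged into candidate arrays
#' (bridging at most one divergent copy), tiled into copies from the array
#' start, and summarised against a per-column majority consensus. A copy is
#' complete iff its identity to the consensus is at least `min_identity` and
#' its length at least 0.8 x period; a trailing partial copy is kept (flagged
#' incomplete) when it still matches the consensus prefix. Overlapping calls
#' at different periods are resolved longest-array-first, ties to the
#' smaller (primitive) period. Deterministic.
#'
#' @param seq Nucleotide string.
#' @param min_period,max_period Candidate period bounds (bp).
#' @param min_copies Minimum number of copies for a reported array.
#' @param min_identity Per-copy identity threshold in `[0,1]`.
#' @return Tibble with one row per array: `start`, `end`, `period`,
#'   `copy_number`, `unit_consensus`, `mean_identity`, and a list-column
#'   `copies` of per-copy tibbles (`copy`, `start`, `end`, `length`,
#'   `identity`, `complete`).
#' @export
find_tandem_repeats <- function(seq, min_period = 10L, max_period = 50L,
                                min_copies = 3L, min_identity = 0.8) {
  stopifnot(min_period >= 2L, min_copies >= 2L)
  seq <- toupper(seq)
  ch <- seq_chars(seq)
  n <- length(ch)
  cands <- list()
  for (p in seq(min_period, min(max_period, max(min_period, n %/% 2)))) {
    if (n < 2L * p) next
    mism <- as.integer(ch[seq_len(n - p)] != ch[(p + 1L):n])
    if (length(mism) < p) next
    w <- rolling_sum(mism, p)             # w[i] = mismatches in i..i+p-1
    tol <- floor((1 - min_identity) * p)
    good <- which(w <= tol)
    good <- good[good <= n - 2L * p + 1L]
    if (!length(good)) next
    # split into runs, bridging up to one strongly divergent copy (whose
    # self-match windows can fail on both of its flanks)
    splits <- which(diff(good) > 3L * p)
    run_start <- c(1L, splits + 1L)
    run_end <- c(splits, length(good))
    for (k in seq_along(run_start)) {
      i0 <- good[run_start[k]]
      i1 <- good[run_end[k]]
      arr <- summarise_array(ch, i0, i1 + 2L * p - 1L, p, min_identity)
      if (!is.null(arr))
        arr <- reduce_primitive(arr, ch, min_identity, min_period)
      if (!is.null(arr) && arr$copy_number >= min_copies)
        cands[[length(cands) + 1L]] <- arr
    }
  }
  if (!length(cands)) {
    return(tibble(start = integer(), end = integer(), period = integer(),
                  copy_number = integer(), unit_consensus = character(),
                  mean_identity = numeric(), copies = list()))
  }
  res <- dplyr::bind_rows(cands)
  res <- dplyr::arrange(res, dplyr::desc(.data$end - .data$start),
                        .data$period, .data$start)
  keep <- rep(FALSE, nrow(res))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(res))) {
    s <- res$start[i]; e <- res$end[i]
    overlaps <- nrow(occupied) > 0 &&
      any(pmax(occupied[, 1], s) <= pmin(occupied[, 2], e))
    if (!overlaps) {
      keep[i] <- TRUE
      occupied <- rbind(occupied, c(s, e))
    }
  }
  dplyr::arrange(res[keep, ], .data$start)
}

# prefer the primitive unit: an array called at period p whose consensus is
# itself made of near-identical q-tiles (q | p) is re-called at q
reduce_primitive <- function(arr, ch, min_identity, min_period) {
  p <- arr$period
  divs <- seq_len(p %/% 2)
  divs <- divs[p %% divs == 0 & divs >= min_period]
  cons <- seq_chars(arr$unit_consensus)
  for (q in divs) {
    tiles <- matrix(cons, ncol = q, byrow = TRUE)
    # all q-tiles of the consensus must agree pairwise (a majority consensus
    # over two tiles would split their differences and overstate identity)
    k <- nrow(tiles)
    agree <- TRUE
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (mean(tiles[i, ] == tiles[j, ]) < min_identity) agree <- FALSE
    }
    if (agree) {
      red <- summarise_array(ch, arr$start, arr$end, q, min_identity)
      if (!is.null(red)) return(red)
    }
  }
  arr
}

summarise_array <- function(ch, start, end, p, min_identity) {
  end <- min(end, length(ch))
  len <- end - start + 1L
  n_full <- len %/% p
  if (n_full < 2L) return(NULL)
  tile_chars <- matrix(ch[start:(start + n_full * p - 1L)],
                       nrow = n_full, ncol = p, byrow = TRUE)
  consensus <- majority_consensus(tile_chars)
  ids <- apply(tile_chars, 1, function(row) mean(row == consensus))
  # trim boundary copies that are clearly flank noise
  first <- 1L; last <- n_full
  while (first <= last && ids[first] < min_identity) first <- first + 1L
  while (last >= first && ids[last] < min_identity) last <- last - 1L
  if (last - first + 1L < 2L) return(NULL)
  if (first > 1L || last < n_full) {
    tile_chars <- tile_chars[first:last, , drop = FALSE]
    consensus <- majority_consensus(tile_chars)
    ids <- apply(tile_chars, 1, function(row) mean(row == consensus))
  }
  a_start <- start + (first - 1L) * p
  n_kept <- last - first + 1L
  # phase refinement: the window chain can begin a few bases into the flank,
  # rotating every tile; choose the tiling phase that maximizes the number of
  # high-identity copies (ties: mean identity, then leftmost start)
  region_end <- min(a_start + n_kept * p - 1L + (p - 1L), length(ch))
  best <- NULL
  for (r in seq(0L, p - 1L)) {
    for (s in unique(pmax(1L, c(a_start + r - p, a_start + r)))) {
      nt <- (region_end - s + 1L) %/% p
      if (nt < 2L) next
      tc <- matrix(ch[s:(s + nt * p - 1L)], nrow = nt, ncol = p, byrow = TRUE)
      cs <- majority_consensus(tc)
      idv <- apply(tc, 1, function(row) mean(row == cs))
      # flank-noise tiles at the borders don't count toward the phase score
      f1 <- 1L; l1 <- nt
      while (f1 <= l1 && idv[f1] < min_identity) f1 <- f1 + 1L
      while (l1 >= f1 && idv[l1] < min_identity) l1 <- l1 - 1L
      if (l1 - f1 + 1L < 2L) next
      # perfect copies first: a mis-phased tiling smears a divergent copy
      # over two tiles, which lowers the perfect-copy count below that of
      # the true phase even when mean identity is unchanged. Ties prefer the
      # later start: an earlier rotation can only tie by borrowing a
      # coincidentally matching flank base
      sc <- c(sum(idv[f1:l1] == 1), sum(idv[f1:l1] >= min_identity),
              mean(idv[f1:l1]), s)
      if (is.null(best) || key_better(sc, best$sc)) {
        best <- list(sc = sc, s = s + (f1 - 1L) * p, n = l1 - f1 + 1L)
      }
    }
  }
  if (is.null(best)) return(NULL)
  a_start <- best$s
  n_kept <- best$n
  tile_chars <- matrix(ch[a_start:(a_start + n_kept * p - 1L)],
                       nrow = n_kept, ncol = p, byrow = TRUE)
  consensus <- majority_consensus(tile_chars)
  # extend outward copy-by-copy. A copy at >= min_identity is accreted
  # outright; a divergent copy (>= 0.6) is bridged only when the copy beyond
  # it also matches, so flank sequence is never absorbed
  copy_id <- function(from) {
    if (from < 1L || from + p - 1L > length(ch)) return(-1)
    prefix_identity(ch[from:(from + p - 1L)], consensus)
  }
  hi <- min(1, min_identity + 0.1)
  repeat {
    id1 <- copy_id(a_start - p)
    if (id1 >= hi || (id1 >= 0.6 && copy_id(a_start - 2L * p) >= hi)) {
      a_start <- a_start - p
      n_kept <- n_kept + 1L
    } else break
  }
  a_end_full <- a_start + n_kept * p - 1L
  repeat {
    id1 <- copy_id(a_end_full + 1L)
    if (id1 >= hi || (id1 >= 0.6 && copy_id(a_end_full + p + 1L) >= hi)) {
      a_end_full <- a_end_full + p
      n_kept <- n_kept + 1L
    } else break
  }
  end <- max(end, a_end_full)
  tile_chars <- matrix(ch[a_start:(a_start + n_kept * p - 1L)],
                       nrow = n_kept, ncol = p, byrow = TRUE)
  consensus <- majority_consensus(tile_chars)
  ids <- apply(tile_chars, 1, function(row) mean(row == consensus))
  copies <- tibble(
    copy = seq_len(n_kept),
    start = a_start + (seq_len(n_kept) - 1L) * p,
    end = a_start + seq_len(n_kept) * p - 1L,
    length = p,
    identity = as.numeric(ids)
  )
  # candidate trailing partial (truncated) copy: longest consensus prefix of
  # at least 0.4 periods matching at >= 0.9, so random flank sequence is
  # essentially never promoted to a copy
  tail_start <- a_start + n_kept * p
  max_tail_end <- min(length(ch), tail_start + p - 2L)
  min_tail <- max(5L, ceiling(0.4 * p))
  if (tail_start <= max_tail_end &&
      max_tail_end - tail_start + 1L >= min_tail) {
    tail_chars <- ch[tail_start:max_tail_end]
    for (k in seq(length(tail_chars), min_tail)) {
      tid <- prefix_identity(tail_chars[seq_len(k)], consensus)
      if (tid >= 0.9) {
        copies <- dplyr::bind_rows(copies, tibble(
          copy = n_kept + 1L, start = tail_start,
          end = tail_start + k - 1L, length = k, identity = tid))
        end <- tail_start + k - 1L
        break
      }
    }
  }
  copies$complete <- copies$identity >= min_identity & copies$length >= 0.8 * p
  tibble(
    start = copies$start[1], end = copies$end[nrow(copies)],
    period = as.integer(p), copy_number = nrow(copies),
    unit_consensus = paste(consensus, collapse = ""),
    mean_identity = mean(copies$identity),
    copies = list(copies)
  )
}

#' Maximal homopolymer runs of a base
#'
#' @param seq Nucleotide string.
#' @param base One of `A`, `C`, `G`, `T`.
#' @param min_len Minimum run length to report (>= 2).
#' @return Tibble with columns `base`, `start`, `run_length`, one row per
#'   maximal run.
#' @export
find_poly_runs <- function(seq, base, min_len = 5L) {
  stopifnot(min_len >= 2L, base %in% c("A", "C", "G", "T"))
  ch <- seq_chars(toupper(seq))
  r <- rle(ch == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= min_len
  tibble(base = base, start = starts[hit], run_length = r$lengths[hit])
}

rotations <- function(u) {
  k <- nchar(u)
  vapply(seq_len(k) - 1L, function(off) {
    paste0(substr(u, off + 1L, k), substr(u, 1L, off))
  }, character(1))
}

#' Compare two tandem-repeat units up to rotation and strand
#'
#' Tandem-repeat units are circular and strandless: the same array can be
#' reported starting at any phase and on either strand. This computes the
#' minimum edit distance between `u1` and all cyclic rotations of `u2` and of
#' its reverse complement.
#'
#' @param u1,u2 Non-empty repeat-unit strings.
#' @return One-row tibble: `offset` (rotation of `u2` achieving the minimum),
#'   `strand` (`"forward"` or `"revcomp"`), `distance` (Levenshtein).
#' @export
compare_units <- function(u1, u2) {
  stopifnot(nzchar(u1), nzchar(u2))
  u1 <- toupper(u1); u2 <- toupper(u2)
  fwd <- utils::adist(u1, rotations(u2))[1, ]
  rev <- utils::adist(u1, rotations(revcomp(u2)))[1, ]
  if (min(fwd) <= min(rev)) {
    off <- which.min(fwd) - 1L
    tibble(offset = off, strand = "forward", distance = as.integer(min(fwd)))
  } else {
    off <- which.min(rev) - 1L
    tibble(offset = off, strand = "revcomp", distance = as.integer(min(rev)))
  }
}

#' Per-individual VNTR genotypes
#'
#' Runs [find_tandem_repeats()] on each control-region sequence and reports
#' the dominant (longest) array per individual, supporting copy-number
#' (length-polymorphism) comparisons across individuals.
#'
#' @param seqs Tibble with columns `id` and `seq`, or a named character
#'   vector.
#' @param ... Passed to [find_tandem_repeats()].
#' @return Tibble: `id`, `period`, `copy_number`, `array_length` (`NA`s when
#'   no array was found).
#' @export
vntr_genotype <- function(seqs, ...) {
  if (is.character(seqs)) seqs <- tibble(id = names(seqs), seq = unname(seqs))
  stopifnot(nrow(seqs) >= 1)
  purrr::list_rbind(lapply(seq_len(nrow(seqs)), function(i) {
    arrays <- find_tandem_repeats(seqs$seq[i], ...)
    if (!nrow(arrays)) {
      return(tibble(id = seqs$id[i], period = NA_integer_,
                    copy_number = NA_integer_, array_length = NA_integer_))
    }
    top <- arrays[which.max(arrays$end - arrays$start), ]
    tibble(id = seqs$id[i], period = top$period,
           copy_number = top$copy_number,
           array_length = as.integer(top$end - top$start + 1L))
  }))
}
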