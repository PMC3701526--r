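# Cloverleaf tRNA folding and arm classification -----------------------------
#
# Mitochondrial tRNA genes are identified by their ability to fold into the
# canonical cloverleaf: acceptor stem, D(HU) arm, anticodon arm with a 7-nt
# loop, variable region and T(PsiC) arm. This module implements a
# deterministic, layout-constrained stem search (not free-energy folding):
# the anticodon arm is anchored first, then stem lengths in the remaining
# arms are maximized subject to the positional layout. Arms whose stem cannot
# reach the minimum length are reported as loop-only, the configuration seen
# in insect trnS1 (AGN) and relatives.

#' Folding parameters for the cloverleaf search
#'
#' Target and minimum stem lengths (bp) per arm, whether G:U wobble pairs are
#' allowed, and the layout bounds of the search.
#'
#' @param acceptor_target,d_target,anticodon_target,t_target Target stem
#'   lengths (7, 3, 5, 4).
#' @param acceptor_min,d_min,anticodon_min,t_min Minimum stem lengths
#'   (5, 2, 4, 2); an arm that cannot pair at its minimum is loop-only.
#' @param allow_gu Allow G:U wobble pairs in stems.
#' @param d_loop_range,t_loop_range,spacer1_range,spacer2_range,variable_range,
#'   discriminator_range Inclusive bounds for the D loop, T loop, the two
#'   spacers flanking the D stem, the variable region, and the unpaired 3'
#'   discriminator.
#' @return A list of class `fold_params`.
#' @export
fold_params <- function(acceptor_target = 7L, d_target = 3L,
                        anticodon_target = 5L, t_target = 4L,
                        acceptor_min = 5L, d_min = 2L,
                        anticodon_min = 4L, t_min = 2L,
                        allow_gu = TRUE,
                        d_loop_range = c(3L, 14L),
                        t_loop_range = c(3L, 12L),
                        spacer1_range = c(1L, 3L),
                        spacer2_range = c(0L, 2L),
                        variable_range = c(0L, 30L),
                        discriminator_range = c(0L, 1L)) {
  stopifnot(acceptor_min <= acceptor_target, d_min <= d_target,
            anticodon_min <= anticodon_target, t_min <= t_target)
  structure(as.list(environment()), class = "fold_params")
}

can_pair_matrix <- function(ch, allow_gu) {
  pairs <- list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
  if (allow_gu) pairs <- c(pairs, list(c("G", "T"), c("T", "G")))
  n <- length(ch)
  m <- matrix(FALSE, n, n)
  for (p in pairs) {
    i <- which(ch == p[1]); j <- which(ch == p[2])
    if (length(i) && length(j)) m[i, j] <- TRUE
  }
  m
}

stem_valid <- function(pm, left_start, right_end, k) {
  # stem of k pairs: left_start..left_start+k-1 against right_end..right_end-k+1
  if (k <= 0) return(TRUE)
  i <- left_start + seq_len(k) - 1L
  j <- right_end - seq_len(k) + 1L
  all(pm[cbind(i, j)])
}

# Deterministic preference among candidate layouts: higher total pairs, then
# longer acceptor stem, then smaller variable region, then leftmost anchor,
# then longer anticodon/D/T stems, then smaller discriminator/spacers/loops.
layout_key <- function(cand) {
  c(cand$score, cand$a, -cand$v, -cand$p, cand$c, cand$d, cand$t,
    -cand$disc, -(cand$s1 %||% 0), -(cand$dl %||% 0), -(cand$tl %||% 0))
}

key_greater <- function(k1, k2) {
  d <- k1 - k2
  nz <- which(d != 0)
  if (!length(nz)) FALSE else d[nz[1]] > 0
}

best_d_layout <- function(pm, a, r, params) {
  # region of size r between acceptor 5' stem and the anticodon arm:
  # s1 + d + dl + d + s2 = r. Returns the best (d, s1, dl, s2) or d = 0.
  s1r <- params$spacer1_range; s2r <- params$spacer2_range
  dlr <- params$d_loop_range
  for (d in seq(params$d_target, params$d_min)) {
    for (s1 in seq(s1r[1], s1r[2])) {
      for (s2 in seq(s2r[2], s2r[1])) {   # descending s2 => ascending dl
        dl <- r - s1 - 2L * d - s2
        if (dl < dlr[1] || dl > dlr[2]) next
        left <- a + s1 + 1L
        right <- a + s1 + 2L * d + dl
        if (stem_valid(pm, left, right, d))
          return(list(d = d, s1 = s1, dl = dl, s2 = s2))
      }
    }
  }
  list(d = 0L, s1 = NA_integer_, dl = r, s2 = NA_integer_)
}

best_t_layout <- function(pm, arm_end, m, params) {
  # region of size m between the anticodon arm and the 3' acceptor stem:
  # v + t + tl + t = m. Returns the best (t, v, tl) or t = 0.
  vr <- params$variable_range; tlr <- params$t_loop_range
  for (t in seq(params$t_target, params$t_min)) {
    for (v in seq(vr[1], min(vr[2], m))) {
      tl <- m - v - 2L * t
      if (tl < tlr[1] || tl > tlr[2]) next
      left <- arm_end + v + 1L
      right <- arm_end + v + 2L * t + tl
      if (stem_valid(pm, left, right, t))
        return(list(t = t, v = v, tl = tl))
    }
  }
  list(t = 0L, v = 0L, tl = m)
}

#' Fold a candidate tRNA sequence into a cloverleaf
#'
#' Anchors the anticodon arm (at the supplied anticodon, or the best-scoring
#' candidate) and then maximizes the number of paired bases in the acceptor,
#' D and T stems subject to the cloverleaf layout. All stem pairs must be
#' Watson-Crick (A:T, G:C) or, when allowed, G:U wobble. Arms that cannot
#' pair at their minimum stem length are reported `loop_only`. The search is
#' exhaustive over the layout bounds in `params` and deterministic: ties are
#' broken by longer acceptor stem, then smaller variable region, then
#' leftmost anchor.
#'
#' @param seq Candidate tRNA gene sequence, 50-100 nt, DNA alphabet.
#' @param expected_anticodon Optional anticodon triplet (DNA or RNA); when
#'   given, only anchors presenting this anticodon at the loop centre are
#'   considered.
#' @param params A [fold_params()] object.
#' @return An object of class `cloverleaf`, or of class `cloverleaf_failure`
#'   (with a `reason` field) when no anticodon-arm anchor exists.
#' @export
fold_cloverleaf <- function(seq, expected_anticodon = NULL,
                            params = fold_params()) {
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  if (n < 50 || n > 100)
    abort("candidate tRNA sequence must be 50-100 nt long")
  ch <- seq_chars(seq)
  pm <- can_pair_matrix(ch, params$allow_gu)
  if (!is.null(expected_anticodon))
    expected_anticodon <- toupper(chartr("U", "T", expected_anticodon))

  accr <- seq(params$acceptor_target, params$acceptor_min)
  discr <- seq(params$discriminator_range[1], params$discriminator_range[2])
  best <- NULL; best_key <- NULL

  for (c_len in seq(params$anticodon_target, params$anticodon_min)) {
    arm_len <- 2L * c_len + 7L
    for (p in seq_len(n - arm_len + 1L)) {
      arm_end <- p + arm_len - 1L
      anticodon <- paste(ch[(p + c_len + 2L):(p + c_len + 4L)], collapse = "")
      if (!is.null(expected_anticodon) && anticodon != expected_anticodon) next
      if (!stem_valid(pm, p, arm_end, c_len)) next
      acc_cands <- list()
      for (disc in discr) for (a in accr) {
        if (stem_valid(pm, 1L, n - disc, a))
          acc_cands[[length(acc_cands) + 1L]] <- c(a, disc)
      }
      acc_cands[[length(acc_cands) + 1L]] <- c(0L, 0L)  # loop-only fallback
      for (ad in acc_cands) {
        a <- ad[1]; disc <- ad[2]
        r <- p - 1L - a
        m <- (n - disc - a) - arm_end
        if (r < 0L || m < 0L) next
        dfit <- best_d_layout(pm, a, r, params)
        tfit <- best_t_layout(pm, arm_end, m, params)
        cand <- list(p = p, c = c_len, a = a, disc = disc,
                     d = dfit$d, s1 = dfit$s1, dl = dfit$dl, s2 = dfit$s2,
                     t = tfit$t, v = tfit$v, tl = tfit$tl,
                     anticodon = anticodon,
                     score = a + dfit$d + c_len + tfit$t)
        k <- layout_key(cand)
        if (is.null(best) || key_greater(k, best_key)) {
          best <- cand; best_key <- k
        }
      }
    }
  }

  if (is.null(best)) {
    reason <- if (!is.null(expected_anticodon)) {
      sprintf("no anticodon-arm candidate presenting anticodon %s",
              expected_anticodon)
    } else {
      "no anticodon-arm candidate with a pairable stem"
    }
    return(structure(list(reason = reason, seq = seq), class = "cloverleaf_failure"))
  }
  build_cloverleaf(seq, ch, n, best, params)
}

build_cloverleaf <- function(seq, ch, n, lay, params) {
  pairs <- list()
  add_stem <- function(arm, left, right, k) {
    if (k > 0)
      pairs[[length(pairs) + 1L]] <<- tibble(
        arm = arm, pos5 = left + seq_len(k) - 1L, pos3 = right - seq_len(k) + 1L)
  }
  add_stem("acceptor", 1L, n - lay$disc, lay$a)
  if (lay$d > 0) add_stem("d", lay$a + lay$s1 + 1L,
                          lay$a + lay$s1 + 2L * lay$d + lay$dl, lay$d)
  add_stem("anticodon", lay$p, lay$p + 2L * lay$c + 6L, lay$c)
  arm_end <- lay$p + 2L * lay$c + 6L
  if (lay$t > 0) add_stem("t", arm_end + lay$v + 1L,
                          arm_end + lay$v + 2L * lay$t + lay$tl, lay$t)
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble(arm = character(), pos5 = integer(), pos3 = integer())

  db <- rep(".", n)
  db[pairs$pos5] <- "("
  db[pairs$pos3] <- ")"

  status <- function(len, minlen) if (len >= minlen) "full" else "loop_only"
  statuses <- c(
    acceptor = status(lay$a, params$acceptor_min),
    d = status(lay$d, params$d_min),
    anticodon = "full",
    t = status(lay$t, params$t_min)
  )
  d_region <- if (lay$p - 1L >= lay$a + 1L) c(lay$a + 1L, lay$p - 1L) else c(NA, NA)
  t_region <- if (n - lay$disc - lay$a >= arm_end + 1L)
    c(arm_end + 1L, n - lay$disc - lay$a) else c(NA, NA)
  structure(
    list(
      seq = seq, length = n, layout = lay, pairs = pairs,
      statuses = statuses, anticodon = lay$anticodon,
      anticodon_loop = c(lay$p + lay$c, lay$p + lay$c + 6L),
      d_region = d_region, t_region = t_region,
      variable_region = if (lay$t > 0 && lay$v > 0)
        c(arm_end + 1L, arm_end + lay$v) else c(NA, NA),
      score = lay$score,
      dot_bracket = paste(db, collapse = "")
    ),
    class = "cloverleaf"
  )
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat(sprintf("<cloverleaf> %d nt, anticodon %s, %d paired bases\n",
              x$length, x$anticodon, x$score))
  cat("  arms:", paste(names(x$statuses), x$statuses, sep = "=", collapse = " "), "\n")
  cat(" ", x$seq, "\n ", x$dot_bracket, "\n")
  invisible(x)
}

#' @export
print.cloverleaf_failure <- function(x, ...) {
  cat("<cloverleaf_failure>", x$reason, "\n")
  invisible(x)
}

#' @method tidy cloverleaf
#' @export
tidy.cloverleaf <- function(x, ...) {
  lay <- x$layout
  tibble(
    arm = c("acceptor", "d", "anticodon", "t"),
    stem_length = c(lay$a, lay$d, lay$c, lay$t),
    status = unname(x$statuses[c("acceptor", "d", "anticodon", "t")])
  )
}

#' @method glance cloverleaf
#' @export
glance.cloverleaf <- function(x, ...) {
  tibble(length = x$length, anticodon = x$anticodon, paired_bases = x$score,
         classification = classify_structure(x))
}

#' Classify a cloverleaf by arm completeness
#'
#' `canonical` when all four arms are full; `dhu_loop_only` when only the
#' D arm lacks a stem; `t_loop_only` when only the T arm lacks one;
#' `degenerate` otherwise.
#'
#' @param s A `cloverleaf` object from [fold_cloverleaf()].
#' @return One of `"canonical"`, `"dhu_loop_only"`, `"t_loop_only"`,
#'   `"degenerate"`.
#' @export
classify_structure <- function(s) {
  if (inherits(s, "cloverleaf_failure"))
    abort("cannot classify a failed fold; inspect its $reason")
  stopifnot(inherits(s, "cloverleaf"))
  st <- s$statuses
  if (all(st == "full")) return("canonical")
  if (st[["d"]] == "loop_only" && st[["acceptor"]] == "full" &&
      st[["t"]] == "full") return("dhu_loop_only")
  if (st[["t"]] == "loop_only" && st[["acceptor"]] == "full" &&
      st[["d"]] == "full") return("t_loop_only")
  "degenerate"
}

aa_from_anticodon <- function(anticodon, code = "5") {
  gc <- mito_genetic_code(code)
  translate_codon(revcomp(toupper(chartr("U", "T", anticodon))), gc)
}

#' Validate a tRNA annotation against its fold
#'
#' Extracts the annotated feature, folds it, classifies the structure and
#' checks that the anticodon found decodes the amino acid implied by the gene
#' name.
#'
#' @param genome A [circular_genome()].
#' @param feature A single-row feature tibble with `type == "tRNA"`.
#' @param params A [fold_params()].
#' @return One-row tibble: `gene`, `length`, `anticodon`,
#'   `expected_anticodon`, `anticodon_match`, `structure`, `paired_bases`.
#' @export
validate_trna_annotation <- function(genome, feature, params = fold_params()) {
  if (!identical(feature$type, "tRNA"))
    abort("feature is not annotated as a tRNA")
  s <- extract_feature_seq(genome, feature)
  expected <- feature$anticodon
  if (is.na(expected %||% NA_character_))
    expected <- unname(trna_anticodons()[feature$gene])
  fold <- fold_cloverleaf(s, expected_anticodon = NULL, params = params)
  if (inherits(fold, "cloverleaf_failure")) {
    return(tibble(gene = feature$gene, length = nchar(s),
                  anticodon = NA_character_, expected_anticodon = expected,
                  anticodon_match = FALSE, structure = "fold_failure",
                  paired_bases = 0L))
  }
  gene_aa <- substr(sub("^trn", "", feature$gene), 1, 1)
  found_aa <- aa_from_anticodon(fold$anticodon)
  tibble(
    gene = feature$gene, length = nchar(s), anticodon = fold$anticodon,
    expected_anticodon = expected,
    anticodon_match = identical(found_aa, gene_aa),
    structure = classify_structure(fold),
    paired_bases = fold$score
  )
}

#' Fold and classify every annotated tRNA of a genome
#'
#' @param genome A [circular_genome()].
#' @param features Feature table; rows with `type == "tRNA"` are processed.
#' @param params A [fold_params()].
#' @return Tibble with one row per tRNA feature.
#' @export
trna_report <- function(genome, features, params = fold_params()) {
  tr <- dplyr::filter(features, .data$type == "tRNA")
  purrr::list_rbind(lapply(seq_len(nrow(tr)), function(i) {
    validate_trna_annotation(genome, tr[i, ], params)
  }))
}
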