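# Independent oracles used across the suite. Each reimplements the quantity
# under test by direct enumeration, kept deliberately naive and separate from
# the package's own code paths.

# -- signed circular adjacency oracle ----------------------------------------

oracle_negate <- function(l) {
  if (startsWith(l, "-")) substring(l, 2) else paste0("-", l)
}

# is the signed adjacency x -> y present in order b (either orientation)?
oracle_adj_present <- function(x, y, b) {
  n <- length(b)
  for (j in seq_len(n)) {
    nxt <- b[if (j == n) 1L else j + 1L]
    if (identical(b[j], x) && identical(nxt, y)) return(TRUE)
    if (identical(oracle_negate(nxt), x) && identical(oracle_negate(b[j]), y))
      return(TRUE)
  }
  FALSE
}

oracle_breakpoints <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  n <- length(a)
  miss <- 0L
  for (i in seq_len(n)) {
    nxt <- a[if (i == n) 1L else i + 1L]
    if (!oracle_adj_present(a[i], nxt, b)) miss <- miss + 1L
  }
  miss
}

random_signed_order <- function(labels) {
  signs <- sample(c("", "-"), length(labels), replace = TRUE)
  gene_order(paste0(signs, sample(labels)))
}

# -- codon tally / RSCU oracle ------------------------------------------------

oracle_codon_tally <- function(cds_list, code) {
  counts <- setNames(rep(0L, 64L), names(code))
  stops <- setNames(rep(0L, sum(code == "*")), names(code)[code == "*"])
  for (cds in toupper(cds_list)) {
    k <- nchar(cds) %/% 3L
    for (i in seq_len(k)) {
      cd <- substr(cds, 3 * i - 2, 3 * i)
      if (!grepl("^[ACGT]{3}$", cd)) next
      if (code[[cd]] == "*") stops[cd] <- stops[cd] + 1L
      else counts[cd] <- counts[cd] + 1L
    }
  }
  sense <- names(code)[code != "*"]
  rscu <- setNames(numeric(length(sense)), sense)
  for (aa in unique(code[sense])) {
    fam <- sense[code[sense] == aa]
    tot <- sum(counts[fam])
    rscu[fam] <- if (tot > 0) counts[fam] * length(fam) / tot else 0
  }
  list(counts = counts[sense], rscu = rscu, stops = stops)
}

# -- exhaustive cloverleaf layout search --------------------------------------

# Enumerates every layout tuple allowed by the fold parameters and returns
# the one maximizing (score, acceptor, -variable, -anchor, anticodon stem,
# d stem, t stem, -discriminator, -spacer1, -dloop, -tloop).
oracle_fold <- function(seq, params = fold_params()) {
  seq <- toupper(chartr("U", "T", seq))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pairs <- list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
  if (params$allow_gu) pairs <- c(pairs, list(c("G", "T"), c("T", "G")))
  ok <- matrix(FALSE, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  for (pp in pairs) ok[pp[1], pp[2]] <- TRUE
  stem_ok <- function(l, r, k) {
    if (k == 0) return(TRUE)
    for (m in seq_len(k)) {
      if (!ok[ch[l + m - 1L], ch[r - m + 1L]]) return(FALSE)
    }
    TRUE
  }
  key_of <- function(x) {
    c(x$score, x$a, -x$v, -x$p, x$c, x$d, x$t, -x$disc,
      -(if (is.na(x$s1)) 0L else x$s1),
      -(if (is.na(x$dl)) 0L else x$dl),
      -(if (is.na(x$tl)) 0L else x$tl))
  }
  better <- function(k1, k2) {
    d <- k1 - k2; nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] > 0
  }
  best <- NULL; bk <- NULL
  consider <- function(cand) {
    k <- key_of(cand)
    if (is.null(best) || better(k, bk)) { best <<- cand; bk <<- k }
  }
  s1r <- params$spacer1_range; s2r <- params$spacer2_range
  dlr <- params$d_loop_range; tlr <- params$t_loop_range
  vr <- params$variable_range
  for (c_len in seq(params$anticodon_target, params$anticodon_min)) {
    arm <- 2L * c_len + 7L
    for (p in seq_len(max(0, n - arm + 1L))) {
      if (!stem_ok(p, p + arm - 1L, c_len)) next
      arm_end <- p + arm - 1L
      for (disc in seq(params$discriminator_range[1],
                       params$discriminator_range[2])) {
        for (a in c(seq(params$acceptor_target, params$acceptor_min), 0L)) {
          if (a == 0L && disc != 0L) next
          if (a > 0L && !stem_ok(1L, n - disc, a)) next
          r <- p - 1L - a
          m <- (n - disc - a) - arm_end
          if (r < 0L || m < 0L) next
          d_layouts <- list(list(d = 0L, s1 = NA_integer_, dl = r,
                                 s2 = NA_integer_))
          for (d in seq(params$d_target, params$d_min)) {
            for (s1 in seq(s1r[1], s1r[2])) for (s2 in seq(s2r[1], s2r[2])) {
              dl <- r - s1 - 2L * d - s2
              if (dl < dlr[1] || dl > dlr[2]) next
              if (!stem_ok(a + s1 + 1L, a + s1 + 2L * d + dl, d)) next
              d_layouts[[length(d_layouts) + 1L]] <-
                list(d = d, s1 = s1, dl = dl, s2 = s2)
            }
          }
          t_layouts <- list(list(t = 0L, v = 0L, tl = m))
          for (t in seq(params$t_target, params$t_min)) {
            for (v in seq(vr[1], min(vr[2], m))) {
              tl <- m - v - 2L * t
              if (tl < tlr[1] || tl > tlr[2]) next
              if (!stem_ok(arm_end + v + 1L, arm_end + v + 2L * t + tl, t)) next
              t_layouts[[length(t_layouts) + 1L]] <- list(t = t, v = v, tl = tl)
            }
          }
          for (dd in d_layouts) for (tt in t_layouts) {
            consider(list(p = p, c = c_len, a = a, disc = disc,
                          d = dd$d, s1 = dd$s1, dl = dd$dl,
                          t = tt$t, v = tt$v, tl = tt$tl,
                          score = a + dd$d + c_len + tt$t))
          }
        }
      }
    }
  }
  best
}

layout_tuple <- function(lay) {
  c(p = lay$p, c = lay$c, a = lay$a, disc = lay$disc, d = lay$d,
    t = lay$t, v = lay$v, score = lay$score)
}

# -- misc ---------------------------------------------------------------------

oracle_pearson_r2 <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxy <- sum(x * y); sxx <- sum(x^2); syy <- sum(y^2)
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  r^2
}

oracle_pi <- function(seqs) {
  n <- length(seqs)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    okp <- a %in% c("A","C","G","T") & b %in% c("A","C","G","T")
    if (sum(okp) == 0) next
    tot <- tot + sum(a[okp] != b[okp]) / sum(okp)
    np <- np + 1
  }
  tot / np
}

# smallest exact period of a string (brute force)
oracle_smallest_period <- function(s) {
  ch <- strsplit(s, "")[[1]]; n <- length(ch)
  for (p in seq_len(n)) {
    if (all(ch[seq_len(n - p)] == ch[(p + 1):n])) return(p)
  }
  n
}

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
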