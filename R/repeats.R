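#' @name repeat_scan
#' @title Repeat detection in plastome sequences
#'
#' @description
#' Finders for the three repeat classes used in comparative plastome work:
#' dispersed (direct) repeats, palindromic (inverted) repeats and tandem
#' arrays. All three enforce the same joint similarity constraint: at most
#' `max_mm` mismatches (Hamming model, no internal indels) *and* identity
#' `>= min_ident`, on maximal hits (not extendable in either direction
#' without violating a constraint). Search is seed-and-extend with exact
#' k-mer seeds sized by a pigeonhole bound over both constraints (see
#' `seed_k`), so no hit passing the thresholds can be missed.
#'
#' Hits are returned as data frames with columns `type`, `start1`, `end1`,
#' `start2`, `end2` (0-based half-open; for tandem arrays `start1..end1` is
#' the full array span and `start2/end2` are `NA`), `length`, `unit_len`,
#' `copies`, `mismatches`, `identity`.
NULL

encode_dna <- function(s) match(seq_chars(s), c("A", "C", "G", "T"))

empty_hits <- function() {
  data.frame(type = character(0), start1 = integer(0), end1 = integer(0),
             start2 = integer(0), end2 = integer(0), length = integer(0),
             unit_len = integer(0), copies = integer(0),
             mismatches = integer(0), identity = numeric(0))
}

# all exact k-mer self-match pairs (i < j, 0-based) of sequence string s,
# optionally restricted to j - i <= max_sep
forward_seed_pairs <- function(s, k, max_sep = Inf, cap = 200L) {
  n <- nchar(s)
  if (n < k + 1) return(data.frame(i = integer(0), j = integer(0)))
  pos <- 0:(n - k)
  km <- substring(s, pos + 1L, pos + k)
  ok <- !grepl("N", km, fixed = TRUE)
  groups <- split(pos[ok], km[ok])
  groups <- groups[lengths(groups) >= 2]
  out_i <- vector("list", length(groups)); out_j <- out_i
  for (g in seq_along(groups)) {
    p <- groups[[g]]
    if (length(p) > cap) p <- p[seq_len(cap)]
    m <- length(p)
    a <- rep(seq_len(m - 1L), times = (m - 1L):1L)
    b <- unlist(lapply(seq_len(m - 1L), function(t) (t + 1L):m))
    keep <- p[b] - p[a] <= max_sep
    out_i[[g]] <- p[a][keep]; out_j[[g]] <- p[b][keep]
  }
  data.frame(i = unlist(out_i) %||% integer(0),
             j = unlist(out_j) %||% integer(0))
}

# exact k-mer match pairs between s and its reverse complement r, with the
# coordinate-sum window that bounds the eventual gap between copies
revcomp_seed_pairs <- function(s, r, k, sum_lo, sum_hi) {
  n <- nchar(s)
  if (n < k) return(data.frame(i = integer(0), j = integer(0)))
  pos <- 0:(n - k)
  ks <- substring(s, pos + 1L, pos + k)
  kr <- substring(r, pos + 1L, pos + k)
  oks <- !grepl("N", ks, fixed = TRUE)
  gs <- split(pos[oks], ks[oks])
  okr <- !grepl("N", kr, fixed = TRUE)
  gr <- split(pos[okr], kr[okr])
  shared <- intersect(names(gs), names(gr))
  out_i <- vector("list", length(shared)); out_j <- out_i
  for (t in seq_along(shared)) {
    px <- gs[[shared[t]]]
    py <- sort(gr[[shared[t]]])
    lo_idx <- findInterval(sum_lo - px - 1L, py) + 1L
    hi_idx <- findInterval(sum_hi - px, py)
    cnt <- pmax(0L, hi_idx - lo_idx + 1L)
    if (sum(cnt) == 0) next
    xi <- rep(px, cnt)
    yi <- py[unlist(mapply(function(a, b) if (b >= a) a:b else integer(0),
                           lo_idx, hi_idx, SIMPLIFY = FALSE))]
    out_i[[t]] <- xi; out_j[[t]] <- yi
  }
  data.frame(i = unlist(out_i) %||% integer(0),
             j = unlist(out_j) %||% integer(0))
}

# Largest exact seed size that cannot miss any window of length >=
# min_len satisfying both the Hamming and the identity constraint: a
# window of length L with q mismatches contains an exact run of at least
# ceiling((L - q) / (q + 1)) bases, and the identity constraint forces
# L >= q / (1 - min_ident) for q mismatches to be admissible at all.
seed_k <- function(min_len, max_mm, min_ident) {
  ks <- vapply(0:max_mm, function(q) {
    L <- max(min_len, min_len_for_mm(q, min_ident))
    as.integer(ceiling((L - q) / (q + 1)))
  }, integer(1))
  max(2L, min(ks))
}

# smallest window length at which q mismatches still satisfy the
# identity constraint (epsilon guards floating-point division)
min_len_for_mm <- function(q, min_ident) {
  if (q == 0) return(0L)
  as.integer(ceiling(q / (1 - min_ident) - 1e-9))
}

# Vectorised seed triage: keep only seed pairs around which some fixed
# window (wlen, allowing wmm mismatches, containing the full seed) fits.
# Every valid hit window of length L with q mismatches contains such a
# sub-window for one of the supplied tests, so discarding the rest cannot
# lose hits; it removes the vast majority of random seed matches before
# the per-cluster maximal-window machinery runs.
prefilter_seeds <- function(x, y, si, sj, k, tests) {
  if (length(si) == 0) return(logical(0))
  wmax <- max(vapply(tests, `[[`, numeric(1), 1))
  ts <- (-(wmax - k)):(wmax - 1L)
  nS <- length(si)
  mm <- matrix(TRUE, nS, length(ts))
  nx <- length(x); ny <- length(y)
  for (c in seq_along(ts)) {
    xi <- si + ts[c]; yj <- sj + ts[c]
    ok <- xi >= 0L & xi < nx & yj >= 0L & yj < ny
    v <- rep(TRUE, nS)
    neq <- x[xi[ok] + 1L] != y[yj[ok] + 1L]
    neq[is.na(neq)] <- TRUE
    v[ok] <- neq
    mm[, c] <- v
  }
  # cumulative mismatch counts along the diagonal offsets
  cs <- matrix(0L, nS, length(ts) + 1L)
  for (c in seq_along(ts)) cs[, c + 1L] <- cs[, c] + mm[, c]
  pass <- rep(FALSE, nS)
  zero <- which(ts == 0L)   # column index of the seed start
  for (tst in tests) {
    wlen <- tst[1]; wmm <- tst[2]
    # window starts at offset o in [-(wlen-k), 0]
    for (o in (-(wlen - k)):0) {
      c0 <- zero + o
      pass <- pass | (cs[, c0 + wlen] - cs[, c0]) <= wmm
    }
  }
  pass
}

# the (wlen, wmm) prefilter tests implied by a joint length/identity
# constraint: a valid window with q mismatches contains a clean
# sub-window of the minimum length admitting q mismatches
prefilter_tests <- function(min_len, max_mm, min_ident) {
  lapply(0:max_mm, function(q) {
    c(max(min_len, min_len_for_mm(q, min_ident)), q)
  })
}

# Maximal similarity windows around seed matches.
#
# x, y: integer-encoded sequences (NA = ambiguous, never matches);
# si, sj: 0-based seed start positions (exact k matches). A window is a
# diagonal segment with mm <= max_mm and identity >= min_ident; returned
# windows are flush against mismatches, sequence ends, or a per-diagonal
# lower position bound (t_lo_of, used to stop palindromic copies from
# growing into each other), on both sides. Containment pruning is left
# to the callers, after their own validity constraints. Every valid
# window contains an exact run of >= seed_k() bases, hence a seed.
mm_windows <- function(x, y, si, sj, k, max_mm, min_len, min_ident = 0,
                       t_lo_of = NULL) {
  if (length(si) == 0) {
    return(data.frame(i = integer(0), j = integer(0), len = integer(0),
                      mm = integer(0)))
  }
  nx <- length(x); ny <- length(y)
  d <- si - sj
  o <- order(d, si)
  d <- d[o]; si <- si[o]
  new_cluster <- c(TRUE, d[-1] != d[-length(d)] |
                     si[-1] - si[-length(si)] > (min_len + k))
  cl <- cumsum(new_cluster)
  res_i <- list(); res_len <- list(); res_mm <- list(); res_d <- list()
  for (g in unique(cl)) {
    idx <- which(cl == g)
    dd <- d[idx[1]]
    seeds <- si[idx]
    rng_lo <- max(0L, dd); rng_hi <- min(nx, ny + dd)
    if (!is.null(t_lo_of)) rng_lo <- max(rng_lo, t_lo_of(dd))
    seeds <- seeds[seeds >= rng_lo]
    if (length(seeds) == 0) next
    t_min <- min(seeds); t_max <- max(seeds) + k
    L0 <- min_len + 8L * (max_mm + 1L)
    repeat {
      lo <- max(rng_lo, t_min - L0); hi <- min(rng_hi, t_max + L0)
      neq <- x[(lo + 1L):hi] != y[(lo - dd + 1L):(hi - dd)]
      neq[is.na(neq)] <- TRUE
      sent <- c(lo - 1L, lo + which(neq) - 1L, hi)
      ns <- length(sent)
      # all flush windows with q = 0..max_mm internal mismatches
      cand <- lapply(0:min(max_mm, ns - 2L), function(q) {
        a <- seq_len(ns - q - 1L)
        cbind(ws = sent[a] + 1L, we = sent[a + q + 1L], mm = q)
      })
      cand <- do.call(rbind, cand)
      ws <- cand[, "ws"]; we <- cand[, "we"]; mm <- cand[, "mm"]
      len <- we - ws
      keep <- len >= min_len & (len - mm) / pmax(len, 1L) >= min_ident &
        !duplicated(paste(ws, we))
      # windows must contain a full seed of this cluster
      if (any(keep)) {
        keep[keep] <- vapply(which(keep), function(t) {
          any(seeds >= ws[t] & seeds + k <= we[t])
        }, logical(1))
      }
      soft <- (ws == lo & lo > rng_lo) | (we == hi & hi < rng_hi)
      if (any(keep & soft)) { L0 <- 2L * L0; next }
      ws <- ws[keep]; we <- we[keep]; mm <- mm[keep]
      break
    }
    if (length(ws) > 0) {
      res_i[[length(res_i) + 1L]] <- ws
      res_len[[length(res_len) + 1L]] <- we - ws
      res_mm[[length(res_mm) + 1L]] <- mm
      res_d[[length(res_d) + 1L]] <- rep(dd, length(ws))
    }
  }
  if (length(res_i) == 0) {
    return(data.frame(i = integer(0), j = integer(0), len = integer(0),
                      mm = integer(0)))
  }
  out <- data.frame(i = unlist(res_i), d = unlist(res_d),
                    len = unlist(res_len), mm = unlist(res_mm))
  out <- out[!duplicated(out[c("i", "d", "len")]), ]
  data.frame(i = out$i, j = out$i - out$d, len = out$len, mm = out$mm)
}

# drop hits whose copies are both contained in a longer hit of the same
# type (deterministic redundancy filtering)
drop_contained <- function(h) {
  if (nrow(h) < 2) return(h)
  keep <- rep(TRUE, nrow(h))
  for (a in seq_len(nrow(h))) {
    inside <- h$start1 >= h$start1[a] & h$end1 <= h$end1[a] &
      ((is.na(h$start2) & is.na(h$start2[a])) |
         (!is.na(h$start2) & !is.na(h$start2[a]) &
            h$start2 >= h$start2[a] & h$end2 <= h$end2[a])) &
      h$length < h$length[a]
    inside[is.na(inside)] <- FALSE
    keep[inside] <- FALSE
  }
  h[keep, , drop = FALSE]
}

#' @rdname repeat_scan
#' @param seq DNA string.
#' @param min_len minimum hit length (30 bp for dispersed, 20 bp for
#'   palindromic).
#' @param max_mm maximum Hamming distance between the two copies.
#' @param min_ident minimum identity (matches / length).
#' @export
find_dispersed <- function(seq, min_len = 30, max_mm = 3, min_ident = 0.90) {
  seq <- toupper(seq)
  if (nchar(seq) < min_len) stop("sequence shorter than min_len")
  k <- seed_k(min_len, max_mm, min_ident)
  seeds <- forward_seed_pairs(seq, k)
  x <- encode_dna(seq)
  ok <- prefilter_seeds(x, x, seeds$i, seeds$j, k,
                        prefilter_tests(min_len, max_mm, min_ident))
  w <- mm_windows(x, x, seeds$i[ok], seeds$j[ok], k, max_mm, min_len,
                  min_ident)
  w <- w[w$j - w$i >= w$len, , drop = FALSE]       # copies must not overlap
  w <- w[(w$len - w$mm) / w$len >= min_ident, , drop = FALSE]
  if (nrow(w) == 0) return(empty_hits())
  h <- data.frame(type = "dispersed", start1 = w$i, end1 = w$i + w$len,
                  start2 = w$j, end2 = w$j + w$len, length = w$len,
                  unit_len = NA_integer_, copies = 2L, mismatches = w$mm,
                  identity = (w$len - w$mm) / w$len)
  h <- drop_contained(h)
  h[order(h$start1, h$start2), , drop = FALSE]
}

#' @rdname repeat_scan
#' @param max_gap maximum gap between the two copies of a palindromic
#'   repeat (3 kb).
#' @param max_copy_len longest palindromic copy the seed filter guarantees
#'   to find; hits longer than this and within `max_gap` would be plastome
#'   IR-scale structures, handled by [detect_inverted_repeats()].
#' @export
find_palindromic <- function(seq, min_len = 20, max_mm = 3, min_ident = 0.90,
                             max_gap = 3000, max_copy_len = 2000) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < min_len) stop("sequence shorter than min_len")
  k <- seed_k(min_len, max_mm, min_ident)
  r <- revcomp(seq)
  seeds <- revcomp_seed_pairs(seq, r, k, sum_lo = n,
                              sum_hi = n + max_gap + 2L * (max_copy_len - k))
  x <- encode_dna(seq); y <- encode_dna(r)
  ok <- prefilter_seeds(x, y, seeds$i, seeds$j, k,
                        prefilter_tests(min_len, max_mm, min_ident))
  # windows whose copies would overlap are clipped at the gap-0 point:
  # on diagonal d the gap between the copies is 2 t - d - n
  w <- mm_windows(x, y, seeds$i[ok], seeds$j[ok], k, max_mm, min_len,
                  min_ident,
                  t_lo_of = function(d) as.integer(ceiling((n + d) / 2)))
  if (nrow(w) == 0) return(empty_hits())
  copy_a <- n - w$j - w$len
  copy_b <- w$i
  gap <- copy_b - (copy_a + w$len)
  keep <- gap >= 0 & gap <= max_gap & (w$len - w$mm) / w$len >= min_ident
  w <- w[keep, , drop = FALSE]; copy_a <- copy_a[keep]; copy_b <- copy_b[keep]
  if (nrow(w) == 0) return(empty_hits())
  h <- data.frame(type = "palindromic", start1 = copy_a,
                  end1 = copy_a + w$len, start2 = copy_b,
                  end2 = copy_b + w$len, length = w$len,
                  unit_len = NA_integer_, copies = 2L, mismatches = w$mm,
                  identity = (w$len - w$mm) / w$len)
  h <- h[!duplicated(h[c("start1", "start2", "length")]), , drop = FALSE]
  h <- drop_contained(h)
  h[order(h$start1, h$start2), , drop = FALSE]
}

#' @rdname repeat_scan
#' @param min_total minimum tandem array span (unit length times copy
#'   number; 15 bp).
#' @param max_unit largest repeat unit considered for tandem arrays.
#' @export
find_tandem <- function(seq, min_total = 15, max_mm = 3, min_ident = 0.90,
                        max_unit = 500) {
  seq <- toupper(seq)
  if (nchar(seq) < min_total) stop("sequence shorter than min_total")
  core_min <- as.integer(ceiling(min_total / 2))
  k <- seed_k(core_min, max_mm, min_ident)
  seeds <- forward_seed_pairs(seq, k, max_sep = max_unit)
  x <- encode_dna(seq)
  ok <- prefilter_seeds(x, x, seeds$i, seeds$j, k,
                        prefilter_tests(core_min, max_mm, min_ident))
  w <- mm_windows(x, x, seeds$i[ok], seeds$j[ok], k, max_mm, core_min,
                  min_ident)
  if (nrow(w) == 0) return(empty_hits())
  p <- w$j - w$i
  keep <- w$len >= p &                     # at least two full units
    w$len + p >= min_total &
    (w$len - w$mm) / w$len >= min_ident
  w <- w[keep, , drop = FALSE]; p <- p[keep]
  if (nrow(w) == 0) return(empty_hits())
  h <- data.frame(type = "tandem", start1 = w$i, end1 = w$i + w$len + p,
                  start2 = NA_integer_, end2 = NA_integer_,
                  length = w$len + p, unit_len = p,
                  copies = as.integer(floor((w$len + p) / p)),
                  mismatches = w$mm, identity = (w$len - w$mm) / w$len)
  # identical spans found at several periods: keep the smallest unit
  h <- h[order(h$start1, h$end1, h$unit_len), , drop = FALSE]
  h <- h[!duplicated(h[c("start1", "end1")]), , drop = FALSE]
  h <- drop_contained(h)
  h[order(h$start1), , drop = FALSE]
}

#' Merge overlapping repeats and resolve type precedence
#'
#' Overlapping hits of the same type are merged into one motif (coordinate
#' union); a region claimed by both a tandem array and a dispersed repeat
#' is emitted as tandem only, so that each genomic region carries at most
#' one repeat type (precedence tandem > dispersed > palindromic). Output is
#' sorted by position. The operation is idempotent.
#'
#' @param hits a repeat-hit data frame (or list of them, e.g. one per
#'   type), as returned by the finders.
#' @param seq optional DNA string used to recompute mismatch counts of
#'   merged two-copy hits; left `NA` otherwise.
#' @return merged, classified hit data frame.
#' @export
merge_and_classify <- function(hits, seq = NULL) {
  if (is.list(hits) && !is.data.frame(hits)) hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) return(empty_hits())
  merged <- do.call(rbind, lapply(split(hits, hits$type), merge_same_type,
                                  seq = seq))
  span_olap <- function(a, b) {
    sa <- c(merged$start1[a], merged$start2[a]); ea <- c(merged$end1[a], merged$end2[a])
    sb <- c(merged$start1[b], merged$start2[b]); eb <- c(merged$end1[b], merged$end2[b])
    sa <- sa[!is.na(sa)]; ea <- ea[!is.na(ea)]
    sb <- sb[!is.na(sb)]; eb <- eb[!is.na(eb)]
    any(outer(sa, eb, `<`) & outer(ea, sb, `>`))
  }
  prec <- c(tandem = 1, dispersed = 2, palindromic = 3)
  keep <- rep(TRUE, nrow(merged))
  if (nrow(merged) > 1) {
    for (a in seq_len(nrow(merged) - 1)) {
      for (b in (a + 1):nrow(merged)) {
        if (merged$type[a] == merged$type[b]) next
        if (span_olap(a, b)) {
          if (prec[[merged$type[a]]] <= prec[[merged$type[b]]]) {
            keep[b] <- FALSE
          } else keep[a] <- FALSE
        }
      }
    }
  }
  out <- merged[keep, , drop = FALSE]
  out <- out[order(out$start1, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

merge_same_type <- function(h, seq = NULL) {
  if (nrow(h) < 2) return(h)
  repeat {
    done <- TRUE
    i <- 1L
    while (i < nrow(h)) {
      j <- i + 1L
      while (j <= nrow(h)) {
        o1 <- h$start1[j] < h$end1[i] & h$start1[i] < h$end1[j]
        o2 <- if (is.na(h$start2[i]) || is.na(h$start2[j])) {
          is.na(h$start2[i]) && is.na(h$start2[j])
        } else h$start2[j] < h$end2[i] & h$start2[i] < h$end2[j]
        if (o1 && o2) {
          h$start1[i] <- min(h$start1[i], h$start1[j])
          h$end1[i] <- max(h$end1[i], h$end1[j])
          if (!is.na(h$start2[i])) {
            h$start2[i] <- min(h$start2[i], h$start2[j])
            h$end2[i] <- max(h$end2[i], h$end2[j])
          }
          h$length[i] <- h$end1[i] - h$start1[i]
          if (!is.na(h$unit_len[i]) && !is.na(h$unit_len[j])) {
            h$unit_len[i] <- min(h$unit_len[i], h$unit_len[j])
            h$copies[i] <- as.integer(floor(h$length[i] / h$unit_len[i]))
          }
          h$mismatches[i] <- NA_integer_; h$identity[i] <- NA_real_
          if (!is.null(seq) && !is.na(h$start2[i]) &&
              h$end1[i] - h$start1[i] == h$end2[i] - h$start2[i]) {
            c1 <- encode_dna(substr(seq, h$start1[i] + 1, h$end1[i]))
            c2 <- encode_dna(substr(seq, h$start2[i] + 1, h$end2[i]))
            if (h$type[i] == "palindromic") c2 <- rev(5L - c2)
            mm <- sum(c1 != c2 | is.na(c1 != c2))
            h$mismatches[i] <- as.integer(mm)
            h$identity[i] <- (h$length[i] - mm) / h$length[i]
          }
          h <- h[-j, , drop = FALSE]
          done <- FALSE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (done) break
  }
  h
}

#' Annotate repeats with their genomic context
#'
#' A hit is `coding(gene)` when the midpoint of its first copy lies inside
#' any gene-type feature (half-open containment), else `noncoding`.
#'
#' @param hits repeat-hit data frame.
#' @param record annotated [plastome_record()].
#' @return `hits` with a `context` column.
#' @export
locate_repeats <- function(hits, record) {
  if (nrow(hits) == 0) { hits$context <- character(0); return(hits) }
  n <- record$length
  genes <- Filter(function(f) f$kind %in% c("gene", "CDS", "tRNA", "rRNA"),
                  record$features)
  mid <- circ_pos(floor((hits$start1 + hits$end1) / 2), n)
  hits$context <- vapply(mid, function(p) {
    for (f in genes) {
      for (t in seq_len(nrow(f$intervals))) {
        if (circ_pos(p - f$intervals$start[t], n) <
            f$intervals$end[t] - f$intervals$start[t]) {
          return(paste0("coding(", f$name, ")"))
        }
      }
    }
    "noncoding"
  }, character(1))
  hits
}

#' Scan a whole (circular) plastome record for repeats
#'
#' Runs the three finders on the record, handling circularity by scanning
#' the doubled sequence and deduplicating modulo the genome length, merges
#' and classifies the hits, annotates context, and removes hits that merely
#' restate the IRa/IRb duplication (hits longer than `ir_exclude`, and —
#' when `part` is supplied — hits whose two copies are images of each other
#' under the IR mirror map).
#'
#' @param record a [plastome_record()].
#' @param part optional `ir_partition` of the record.
#' @param min_tandem,min_dispersed,min_palindromic type-specific minimum
#'   lengths.
#' @param max_mm,min_ident,max_gap shared thresholds, see the finders.
#' @param ir_exclude hits at least this long are treated as the IR
#'   duplication itself and dropped.
#' @return classified, context-annotated hit data frame (coordinates
#'   0-based half-open on the original circle; `end` beyond the genome
#'   length wraps the origin).
#' @export
scan_repeats <- function(record, part = NULL, min_tandem = 15,
                         min_dispersed = 30, min_palindromic = 20,
                         max_mm = 3, min_ident = 0.90, max_gap = 3000,
                         ir_exclude = 10000) {
  s <- record$sequence
  n <- record$length
  s2 <- if (record$circular) paste0(s, s) else s
  hits <- rbind(find_tandem(s2, min_total = min_tandem, max_mm = max_mm,
                            min_ident = min_ident),
                find_dispersed(s2, min_len = min_dispersed, max_mm = max_mm,
                               min_ident = min_ident),
                find_palindromic(s2, min_len = min_palindromic,
                                 max_mm = max_mm, min_ident = min_ident,
                                 max_gap = max_gap))
  if (record$circular && nrow(hits) > 0) {
    hits <- hits[hits$start1 < n & hits$length <= n, , drop = FALSE]
    # a segment paired with its own image on the doubled sequence is not
    # a repeat
    self <- !is.na(hits$start2) &
      circ_pos(hits$start1, n) == circ_pos(hits$start2, n)
    hits <- hits[!self, , drop = FALSE]
    a <- circ_pos(hits$start1, n)
    b <- ifelse(is.na(hits$start2), -1L, circ_pos(hits$start2, n))
    key <- paste(hits$type, pmin(a, b), pmax(a, b), hits$length)
    hits <- hits[!duplicated(key), , drop = FALSE]
  }
  hits <- hits[hits$length < ir_exclude, , drop = FALSE]
  if (!is.null(part) && nrow(hits) > 0) {
    # drop copies that map onto each other under the IR mirror
    mirror <- function(p) circ_pos(part$ira[["start"]] +
                                     (part$irb[["end"]] - p), n)
    art <- !is.na(hits$start2) & hits$type == "palindromic" &
      abs(mirror(circ_pos(hits$start1, n)) - circ_pos(hits$end2, n)) <= 5
    hits <- hits[!art, , drop = FALSE]
  }
  hits <- merge_and_classify(hits, seq = if (record$circular) s2 else s)
  locate_repeats(hits, record)
}

#' Summarise repeats across genomes
#'
#' @param hitlists named list (one entry per genome) of located hit data
#'   frames.
#' @param length_breaks lower bounds of the length classes (each class is
#'   15 bp wide by default, mirroring 15-30, 31-45, ... binning).
#' @return list with `total`, `by_type`, `by_length` (counts and
#'   percentages), `by_location`, and a per-genome type count table.
#' @export
repeat_summary <- function(hitlists,
                           length_breaks = c(15, 31, 46, 61, 76)) {
  if (is.data.frame(hitlists)) hitlists <- list(genome = hitlists)
  if (length(hitlists) == 0) stop("at least one genome is required")
  all_hits <- do.call(rbind, hitlists)
  total <- nrow(all_hits)
  types <- c("tandem", "dispersed", "palindromic")
  by_type <- vapply(types, function(t) sum(all_hits$type == t), integer(1))
  labs <- c(paste0(length_breaks[-length(length_breaks)], "-",
                   length_breaks[-1] - 1),
            paste0(">=", length_breaks[length(length_breaks)]))
  cls <- findInterval(all_hits$length, length_breaks)
  cls[cls == 0] <- 1L
  by_length <- vapply(seq_along(labs), function(t) sum(cls == t), integer(1))
  names(by_length) <- labs
  loc <- ifelse(all_hits$context == "noncoding", "noncoding", "coding")
  by_location <- c(coding = sum(loc == "coding"),
                   noncoding = sum(loc == "noncoding"))
  per_genome <- t(vapply(hitlists, function(h) {
    vapply(types, function(t) sum(h$type == t), integer(1))
  }, integer(length(types))))
  pct <- function(x) if (total == 0) x * 0 else round(100 * x / total, 1)
  list(total = total,
       by_type = data.frame(type = types, n = as.integer(by_type),
                            pct = pct(by_type), row.names = NULL),
       by_length = data.frame(class = labs, n = as.integer(by_length),
                              pct = pct(by_length), row.names = NULL),
       by_location = data.frame(location = names(by_location),
                                n = as.integer(by_location),
                                pct = pct(by_location), row.names = NULL),
       per_genome = per_genome)
}
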