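#' Uncorrected pairwise distances from an alignment
#'
#' p-distance: mismatching sites over compared sites per taxon pair. Under
#' `complete` deletion, every column containing a gap or N in any taxon is
#' excluded for all pairs; under `pairwise` deletion, columns are dropped
#' per pair.
#'
#' @param x a [msa()] with >= 2 taxa.
#' @param deletion `"complete"` or `"pairwise"`.
#' @return symmetric matrix of p-distances in `[0, 1]` with zero diagonal
#'   and attribute `deletion`.
#' @export
p_distance <- function(x, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(x, "plasto_msa"), length(x$taxa) >= 2)
  m <- msa_matrix(x)
  ok <- m != "-" & m != "N"
  if (deletion == "complete") {
    keep <- apply(ok, 2, all)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  nt <- nrow(m)
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      comp <- ok[i, ] & ok[j, ]
      ncomp <- sum(comp)
      if (ncomp == 0) {
        stop("no compared sites between ", rownames(m)[i], " and ",
             rownames(m)[j])
      }
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / ncomp
    }
  }
  attr(d, "deletion") <- deletion
  d
}

#' Within- and between-group mean divergence
#'
#' @param dm symmetric distance matrix (e.g. from [p_distance()]).
#' @param groups named character vector mapping taxa to group labels.
#' @return list with `within` (named vector of within-group means; `NA`
#'   for singleton groups), `between` (matrix of between-group means) and
#'   `overall` (mean over all pairs). Report at 3 decimals; full precision
#'   is retained here.
#' @export
group_divergence <- function(dm, groups) {
  taxa <- rownames(dm)
  stopifnot(all(taxa %in% names(groups)))
  g <- groups[taxa]
  labs <- unique(g)
  pick <- function(ta, tb) {
    v <- dm[ta, tb, drop = FALSE]
    if (identical(ta, tb)) v <- v[upper.tri(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  within <- vapply(labs, function(l) pick(taxa[g == l], taxa[g == l]),
                   numeric(1))
  between <- matrix(NA_real_, length(labs), length(labs),
                    dimnames = list(labs, labs))
  for (a in seq_along(labs)) {
    for (b in seq_along(labs)) {
      if (a != b) between[a, b] <- pick(taxa[g == labs[a]],
                                        taxa[g == labs[b]])
    }
  }
  list(within = within, between = between,
       overall = mean(dm[upper.tri(dm)]))
}

#' Variable and parsimony-informative site counts
#'
#' Columns containing a gap or N are excluded entirely (complete
#' deletion). A retained column is variable when at least two distinct
#' bases occur; parsimony-informative when at least two distinct bases
#' each occur in at least two taxa. Percentages are relative to the full
#' aligned length.
#'
#' @param x a [msa()] with >= 2 taxa.
#' @return list `n_variable`, `pct_variable`, `n_pis`, `pct_pis`,
#'   `aligned_length`.
#' @export
site_stats <- function(x) {
  stopifnot(inherits(x, "plasto_msa"), length(x$taxa) >= 2)
  m <- msa_matrix(x)
  L <- ncol(m)
  keep <- apply(m != "-" & m != "N", 2, all)
  m <- m[, keep, drop = FALSE]
  nv <- 0L; np <- 0L
  if (ncol(m) > 0) {
    counts <- do.call(rbind, lapply(c("A", "C", "G", "T"),
                                    function(b) colSums(m == b)))
    states <- colSums(counts > 0)
    nv <- sum(states >= 2)
    np <- sum(colSums(counts >= 2) >= 2)
  }
  list(n_variable = as.integer(nv),
       pct_variable = if (L > 0) 100 * nv / L else 0,
       n_pis = as.integer(np),
       pct_pis = if (L > 0) 100 * np / L else 0,
       aligned_length = L)
}

#' Proportion of mutation events of an aligned region
#'
#' `(NS / L) * 100`, with NS the number of variable sites (substitution
#' events countable from the alignment) and L the aligned length.
#'
#' @param x a [msa()].
#' @return percent.
#' @export
mutation_event_proportion <- function(x) {
  s <- site_stats(x)
  if (s$aligned_length == 0) stop("empty alignment")
  s$pct_variable
}

#' Per-region marker statistics
#'
#' @param msas named list of [msa()] objects (one per candidate region).
#' @return data frame `region`, `aligned_length`, `n_variable`,
#'   `pct_variable`, `n_pis`, `pct_pis`, suitable for [rank_markers()].
#' @export
marker_report <- function(msas) {
  rows <- lapply(msas, function(m) {
    s <- site_stats(m)
    data.frame(region = m$region, aligned_length = s$aligned_length,
               n_variable = s$n_variable,
               pct_variable = s$pct_variable,
               n_pis = s$n_pis, pct_pis = s$pct_pis)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank candidate markers by variability
#'
#' Retains regions whose percentage of variable sites exceeds the
#' threshold and sorts them by decreasing variability (ties broken
#' alphabetically by region name).
#'
#' @param reports data frame from [marker_report()].
#' @param threshold_pct retain regions with `pct_variable > threshold_pct`.
#' @return the filtered, ordered data frame with a `rank` column.
#' @export
rank_markers <- function(reports, threshold_pct = 5.0) {
  out <- reports[reports$pct_variable > threshold_pct, , drop = FALSE]
  out <- out[order(-out$pct_variable, out$region), , drop = FALSE]
  if (nrow(out) > 0) out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Regression of informative-site on variable-site percentages
#'
#' Ordinary least squares of `pct_pis` on `pct_variable` across regions,
#' with the two-sided slope test.
#'
#' @param reports data frame from [marker_report()] (>= 3 regions).
#' @return list `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
pis_variability_regression <- function(reports) {
  if (nrow(reports) < 3) stop("at least three regions are required")
  if (stats::var(reports$pct_variable) == 0) {
    stop("zero variance in pct_variable")
  }
  fit <- stats::lm(pct_pis ~ pct_variable, data = reports)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["pct_variable", "Pr(>|t|)"],
       slope = sm$coefficients["pct_variable", "Estimate"],
       intercept = sm$coefficients["(Intercept)", "Estimate"],
       n = nrow(reports))
}
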