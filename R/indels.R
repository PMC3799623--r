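#' Extract indel events from an alignment
#'
#' Simple indel coding: every distinct maximal gap run with identical
#' start and end columns across the taxa sharing it is one event;
#' overlapping or nested runs with different coordinates are distinct
#' events. Runs touching either alignment end are ignored (missing data
#' rather than indels). Events shared by all taxa or by none are not
#' returned.
#'
#' @param x a [msa()] (typically an aligned exon region).
#' @return data frame `region`, `start_col`, `end_col` (0-based
#'   half-open alignment columns), `length`, `n_with_gap`, plus one
#'   logical presence column per taxon (prefixed `gap.`).
#' @export
extract_indel_events <- function(x) {
  stopifnot(inherits(x, "plasto_msa"))
  L <- ncol_msa(x)
  runs <- lapply(x$taxa, function(tx) {
    ch <- seq_chars(x$seqs[[tx]])
    r <- rle(ch == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    if (length(gi) == 0) return(NULL)
    out <- data.frame(start_col = starts[gi] - 1L, end_col = ends[gi])
    out[out$start_col > 0 & out$end_col < L, , drop = FALSE]  # no terminal runs
  })
  names(runs) <- x$taxa
  all_runs <- do.call(rbind, runs)
  if (is.null(all_runs) || nrow(all_runs) == 0) {
    return(data.frame(region = character(0), start_col = integer(0),
                      end_col = integer(0), length = integer(0),
                      n_with_gap = integer(0)))
  }
  sig <- unique(all_runs[order(all_runs$start_col, all_runs$end_col), ,
                         drop = FALSE])
  pres <- vapply(x$taxa, function(tx) {
    r <- runs[[tx]]
    if (is.null(r) || nrow(r) == 0) return(rep(FALSE, nrow(sig)))
    paste(sig$start_col, sig$end_col) %in% paste(r$start_col, r$end_col)
  }, logical(nrow(sig)))
  if (nrow(sig) == 1) pres <- matrix(pres, nrow = 1,
                                     dimnames = list(NULL, x$taxa))
  nw <- rowSums(pres)
  keep <- nw >= 1 & nw < length(x$taxa)
  out <- data.frame(region = x$region, start_col = sig$start_col,
                    end_col = sig$end_col,
                    length = sig$end_col - sig$start_col,
                    n_with_gap = as.integer(nw))
  colnames(pres) <- paste0("gap.", x$taxa)
  out <- cbind(out, as.data.frame(pres))[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Code indel events as a binary character matrix
#'
#' @param events data frame from [extract_indel_events()] (possibly
#'   rbind-ed across regions).
#' @param taxa taxon set (defaults to the taxa covered by `events`).
#' @param informative_only keep only parsimony-informative events (>= 2
#'   taxa in each state).
#' @return character matrix (taxa x events) of `"1"` (gap present) /
#'   `"0"`, columns ordered by (region, start), named
#'   `region:start-end`.
#' @export
code_binary <- function(events, taxa = NULL, informative_only = FALSE) {
  gcols <- grep("^gap\\.", colnames(events), value = TRUE)
  if (is.null(taxa)) taxa <- sub("^gap\\.", "", gcols)
  if (nrow(events) == 0) {
    return(matrix(character(0), nrow = length(taxa), ncol = 0,
                  dimnames = list(taxa, NULL)))
  }
  events <- events[order(events$region, events$start_col, events$end_col), ,
                   drop = FALSE]
  m <- t(as.matrix(events[, paste0("gap.", taxa), drop = FALSE]))
  rownames(m) <- taxa
  colnames(m) <- paste0(events$region, ":", events$start_col, "-",
                        events$end_col)
  if (informative_only) {
    ones <- colSums(m)
    keep <- ones >= 2 & (nrow(m) - ones) >= 2
    m <- m[, keep, drop = FALSE]
  }
  ifelse(m, "1", "0")
}
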