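#' Read a GenBank flat file into a plastome record
#'
#' Parses LOCUS, ORGANISM, the FEATURES table (gene, CDS, tRNA, rRNA, exon
#' and intron keys; `join`/`complement` locations, including joins that wrap
#' the origin of a circular record) and the ORIGIN sequence. GenBank
#' 1-based-inclusive coordinates are converted to the package's 0-based
#' half-open convention at this boundary.
#'
#' @param path path to a GenBank flat file containing one record.
#' @return a [plastome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty GenBank file: ", path)

  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) stop("not a GenBank flat file (no LOCUS line): ", path)
  if (length(locus_i) > 1) lines <- lines[locus_i[1]:(locus_i[2] - 1L)]

  locus <- strsplit(trimws(lines[grep("^LOCUS", lines)[1]]), "\\s+")[[1]]
  id <- locus[2]
  circular <- any(tolower(locus) == "circular")

  taxon <- id
  org_i <- grep("^  ORGANISM", lines)
  if (length(org_i) > 0) taxon <- trimws(sub("^  ORGANISM", "", lines[org_i[1]]))

  # sequence
  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0) stop("GenBank record has no ORIGIN sequence: ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i) > 0) end_i[1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record has an empty ORIGIN sequence: ", path)
  n <- nchar(sequence)

  # features
  feats <- list()
  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i) > 0) {
    block <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    starts <- grep("^ {5}\\S", block)
    keep_kinds <- c(gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                    exon = "exon", intron = "intron")
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- trimws(substr(chunk[1], 1, 20))
      if (!key %in% names(keep_kinds)) next

      # location may continue over lines until the first qualifier
      body <- trimws(substring(chunk, 22))
      qual_start <- grep("^/", body)
      loc_end <- if (length(qual_start) > 0) qual_start[1] - 1L else length(body)
      loc <- paste(body[seq_len(loc_end)], collapse = "")
      quals <- if (length(qual_start) > 0) body[qual_start[1]:length(body)] else character(0)

      ints <- tryCatch(parse_gb_location(loc, n, circular),
                       error = function(e) NULL)
      if (is.null(ints)) {
        warning("skipping ", key, " feature with unparseable location: ", loc,
                call. = FALSE)
        next
      }
      name <- gb_qualifier(quals, "gene") %||%
        gb_qualifier(quals, "locus_tag") %||%
        gb_qualifier(quals, "product") %||% key
      pseudo <- any(grepl("^/pseudo\\b", quals))
      feats[[length(feats) + 1L]] <- feature(name, keep_kinds[[key]], ints, pseudo)
    }
  }
  plastome_record(id, sequence, taxon = taxon, circular = circular,
                  features = feats)
}

gb_qualifier <- function(quals, what) {
  hit <- grep(paste0("^/", what, "="), quals, value = TRUE)
  if (length(hit) == 0) return(NULL)
  gsub('^"|"$', "", sub(paste0("^/", what, "="), "", hit[1]))
}

# recursive-descent parser for GenBank location strings; returns a data
# frame (start, end, strand) in 0-based half-open coordinates, with joins
# adjacent at the origin of a circular record merged into one wrapped
# interval
parse_gb_location <- function(loc, n, circular) {
  loc <- gsub("[<> ]", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- parse_gb_location(sub("\\)$", "", sub("^complement\\(", "", loc)),
                               n, circular)
    inner$strand <- ifelse(inner$strand == "+", "-", "+")
    inner <- inner[rev(seq_len(nrow(inner))), , drop = FALSE]
    rownames(inner) <- NULL
    return(inner)
  }
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("\\)$", "", sub("^(join|order)\\(", "", loc))
    parts <- split_top_level(inner)
    ints <- do.call(rbind, lapply(parts, parse_gb_location, n = n,
                                  circular = circular))
    # merge segments adjacent at the origin into one wrapped interval
    if (circular && nrow(ints) > 1) {
      i <- 1L
      while (i < nrow(ints)) {
        if (ints$end[i] == n && ints$start[i + 1L] == 0 &&
            ints$strand[i] == ints$strand[i + 1L]) {
          ints$end[i] <- n + ints$end[i + 1L]
          ints <- ints[-(i + 1L), , drop = FALSE]
        } else i <- i + 1L
      }
    }
    rownames(ints) <- NULL
    return(ints)
  }
  if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
    se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
    return(data.frame(start = se[1] - 1L, end = se[2], strand = "+"))
  }
  if (grepl("^[0-9]+$", loc)) {
    p <- as.integer(loc)
    return(data.frame(start = p - 1L, end = p, strand = "+"))
  }
  stop("unparseable location: ", loc)
}

# split "a,b(c,d),e" on commas at parenthesis depth zero
split_top_level <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cuts <- which(chars == "," & depth == 0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends)
}

#' Write a plastome record as a GenBank flat file
#'
#' @param record a [plastome_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  n <- record$length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %s bp    DNA     %s PLN 01-JAN-2000",
                     record$id, n,
                     if (record$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s chloroplast genome.", record$taxon), con)
  writeLines("SOURCE      .", con)
  writeLines(sprintf("  ORGANISM  %s", record$taxon), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  writeLines(sprintf('                     /organism="%s"', record$taxon), con)
  for (f in record$features) {
    loc <- gb_location_string(f$intervals, n)
    writeLines(sprintf("     %-15s %s", f$kind, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name), con)
    if (f$pseudo) writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1, n, by = 60)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

gb_location_string <- function(ints, n) {
  seg <- function(s, e) {
    if (e <= n) sprintf("%d..%d", s + 1L, e)
    else sprintf("%d..%d,%d..%d", s + 1L, n, 1L, e - n)
  }
  if (all(ints$strand == "-")) {
    # complement(join(...)) of the reading-order-reversed intervals
    parts <- vapply(rev(seq_len(nrow(ints))),
                    function(i) seg(ints$start[i], ints$end[i]), character(1))
    inner <- paste(parts, collapse = ",")
    if (nrow(ints) > 1 || grepl(",", inner)) inner <- sprintf("join(%s)", inner)
    sprintf("complement(%s)", inner)
  } else {
    parts <- vapply(seq_len(nrow(ints)), function(i) {
      s <- seg(ints$start[i], ints$end[i])
      if (ints$strand[i] == "-") {
        if (grepl(",", s)) s <- sprintf("join(%s)", s)
        sprintf("complement(%s)", s)
      } else s
    }, character(1))
    out <- paste(parts, collapse = ",")
    if (nrow(ints) > 1 || grepl(",", out)) sprintf("join(%s)", out) else out
  }
}
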