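#' Read genomic intervals from GFF3, BED or RepeatMasker .out
#'
#' Parses one of the three interval dialects the pipeline consumes and
#' returns a [GenomicRanges::GRanges] in the package-wide convention
#' (1-based, closed intervals, as native to the Bioconductor stack).
#' BED's 0-based half-open starts are shifted accordingly; RepeatMasker's
#' "C" orientation becomes strand \code{"-"}.  Feature attributes (GFF3
#' attribute string, BED name/score, RepeatMasker family columns) are kept
#' as metadata columns so that [write_intervals()] can reproduce the input
#' byte-for-byte in the fields that carry information.
#'
#' @param path Path to the file.
#' @param format One of \code{"gff3"}, \code{"bed"}, \code{"repeatmasker"}.
#' @return A \code{GRanges}; metadata columns depend on the dialect.
#' @export
read_intervals <- function(path, format = c("gff3", "bed", "repeatmasker")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  switch(format,
    gff3 = parse_gff3(lines),
    bed = parse_bed(lines),
    repeatmasker = parse_rmout(lines)
  )
}

parse_gff3 <- function(lines) {
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GFF3 line ", idx[which(nf != 9L)[1L]],
         ": expected 9 tab-separated columns, got ", nf[nf != 9L][1L])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end) | start < 1L | end < start)
  if (length(bad)) stop("malformed GFF3 line ", idx[bad[1L]],
                        ": bad coordinates")
  strand <- m[, 7L]
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1L],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = m[, 2L], type = m[, 3L], score = m[, 6L], phase = m[, 8L],
    attributes = m[, 9L],
    ID = gff3_attr(m[, 9L], "ID"),
    Name = gff3_attr(m[, 9L], "Name"),
    Parent = gff3_attr(m[, 9L], "Parent")
  )
  gr
}

gff3_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1L))
}

parse_bed <- function(lines) {
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) stop("malformed BED line ", idx[which(nf < 3L)[1L]],
                         ": fewer than 3 columns")
  get <- function(i) vapply(fields, function(x)
    if (length(x) >= i) x[i] else NA_character_, character(1L))
  start0 <- suppressWarnings(as.integer(get(2L)))
  end0 <- suppressWarnings(as.integer(get(3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0L | end0 <= start0)
  if (length(bad)) stop("malformed BED line ", idx[bad[1L]],
                        ": bad coordinates")
  strand <- get(6L)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = get(1L),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = get(4L),
    score = suppressWarnings(as.numeric(get(5L)))
  )
  gr
}

# RepeatMasker .out: two header lines + blank line, then whitespace-split
# rows (score div del ins query qbegin qend qleft C/+ repeat class ...).
parse_rmout <- function(lines) {
  body <- grepl("^\\s*[0-9]", lines)
  idx <- which(body)
  if (length(idx) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed RepeatMasker line ", idx[which(nf < 11L)[1L]],
         ": expected >= 11 whitespace-separated columns")
  }
  m <- t(vapply(fields, function(x) x[1:11], character(11L)))
  start <- suppressWarnings(as.integer(m[, 6L]))
  end <- suppressWarnings(as.integer(m[, 7L]))
  bad <- which(is.na(start) | is.na(end) | start < 1L | end < start)
  if (length(bad)) stop("malformed RepeatMasker line ", idx[bad[1L]],
                        ": bad coordinates")
  orient <- m[, 9L]
  if (!all(orient %in% c("+", "C"))) {
    stop("malformed RepeatMasker line ",
         idx[which(!orient %in% c("+", "C"))[1L]],
         ": orientation must be '+' or 'C'")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 5L],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = ifelse(orient == "C", "-", "+")
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    score = as.numeric(m[, 1L]),
    divergence = as.numeric(m[, 2L]),
    family = m[, 10L],
    repeat_class = m[, 11L]
  )
  gr
}

#' Write intervals back to GFF3 or BED
#'
#' Inverse of [read_intervals()] for the writable dialects; together they
#' satisfy the round-trip property `read(write(x)) == x` on the fields each
#' dialect carries (coordinate conversion is an involution).
#'
#' @param gr A `GRanges`, typically from [read_intervals()].
#' @param path Output path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  mc <- S4Vectors::mcols(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (format == "gff3") {
    col <- function(nm, default) {
      if (nm %in% names(mc)) {
        v <- as.character(mc[[nm]]); v[is.na(v)] <- default; v
      } else rep(default, length(gr))
    }
    out <- paste(chrom, col("source", "."), col("type", "region"),
                 GenomicRanges::start(gr), GenomicRanges::end(gr),
                 col("score", "."), ifelse(strand == "*", ".", strand),
                 col("phase", "."), col("attributes", "."), sep = "\t")
    writeLines(c("##gff-version 3", out), path)
  } else {
    name <- if ("name" %in% names(mc)) as.character(mc$name) else
      rep(".", length(gr))
    name[is.na(name)] <- "."
    score <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
    score[is.na(score)] <- 0
    out <- paste(chrom, GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr), name, score,
                 ifelse(strand == "*", ".", strand), sep = "\t")
    writeLines(out, path)
  }
  invisible(path)
}

#' Read a sequence-similarity hit table (BLAST outfmt 6 or PSL)
#'
#' Normalizes both dialects to one data frame of hit records.  BLAST
#' subject coordinates given in descending order denote minus-strand hits;
#' PSL block structure is collapsed to the outer target span, with identity
#' taken as matched bases over that span (PSL carries no E-value, so
#' `evalue` is `NA` and downstream E-value filters fall back to
#' identity/coverage proxies).
#'
#' @param path Path to the table.
#' @param format `"blast6"` or `"psl"`.
#' @param query_lengths Optional named vector of query lengths (bp) used to
#'   compute `coverage` for BLAST-6 input (PSL carries its own qSize).
#' @return data.frame with columns `query, qstart, qend, chrom, start,
#'   end, strand, identity, length, evalue, score, coverage`.
#'   Coordinates are 1-based closed.
#' @export
read_hit_table <- function(path, format = c("blast6", "psl"),
                           query_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (format == "psl") {
    # drop psLayout header block if present
    if (length(lines) && grepl("^psLayout", lines[1L])) {
      first <- grep("^[0-9]", lines)[1L]
      lines <- if (is.na(first)) character(0) else lines[first:length(lines)]
    }
  }
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "blast6") {
    nf <- lengths(fields)
    if (any(nf < 12L)) stop("malformed BLAST-6 line ",
                            which(nf < 12L)[1L], ": expected 12 columns")
    m <- do.call(rbind, lapply(fields, `[`, 1:12))
    sstart <- as.numeric(m[, 9L]); send <- as.numeric(m[, 10L])
    qstart <- as.integer(m[, 7L]); qend <- as.integer(m[, 8L])
    alen <- as.integer(m[, 4L])
    cov <- rep(NA_real_, nrow(m))
    if (!is.null(query_lengths)) {
      ql <- query_lengths[m[, 1L]]
      cov <- (abs(qend - qstart) + 1) / as.numeric(ql)
    }
    data.frame(
      query = m[, 1L], qstart = qstart, qend = qend,
      chrom = m[, 2L],
      start = as.integer(pmin(sstart, send)),
      end = as.integer(pmax(sstart, send)),
      strand = ifelse(send >= sstart, "+", "-"),
      identity = as.numeric(m[, 3L]),
      length = alen,
      evalue = as.numeric(m[, 11L]),
      score = as.numeric(m[, 12L]),
      coverage = cov,
      stringsAsFactors = FALSE
    )
  } else {
    nf <- lengths(fields)
    if (any(nf < 17L)) stop("malformed PSL line ", which(nf < 17L)[1L],
                            ": expected >= 17 columns")
    m <- do.call(rbind, lapply(fields, `[`, 1:17))
    matches <- as.numeric(m[, 1L]) + as.numeric(m[, 3L])
    tstart <- as.integer(m[, 16L]); tend <- as.integer(m[, 17L])
    span <- tend - tstart
    qsize <- as.numeric(m[, 11L])
    qstart0 <- as.integer(m[, 12L]); qend0 <- as.integer(m[, 13L])
    data.frame(
      query = m[, 10L], qstart = qstart0 + 1L, qend = qend0,
      chrom = m[, 14L],
      start = tstart + 1L, end = tend,
      strand = ifelse(substr(m[, 9L], 1L, 1L) == "-", "-", "+"),
      identity = 100 * matches / span,
      length = span,
      evalue = NA_real_,
      score = matches,
      coverage = (qend0 - qstart0) / qsize,
      stringsAsFactors = FALSE
    )
  }
}

empty_hits <- function() {
  data.frame(query = character(), qstart = integer(), qend = integer(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), identity = numeric(),
             length = integer(), evalue = numeric(), score = numeric(),
             coverage = numeric(), stringsAsFactors = FALSE)
}

#' Read a per-cytosine methylation report
#'
#' Bismark-style cytosine report: tab-separated chrom, 1-based position,
#' strand, methylated read count, unmethylated read count, context
#' (CG/CHG/CHH); a 7th trinucleotide column is tolerated and ignored.
#'
#' @param path Path to the report.
#' @return data.frame with columns `chrom, pos, strand, context, meth,
#'   total` (one row per cytosine; `total = meth + unmeth`).
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      meth = integer(), total = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) stop("malformed cytosine report line ",
                         which(nf < 6L)[1L], ": expected 6 columns")
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  meth <- suppressWarnings(as.integer(m[, 4L]))
  unmeth <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(meth) | is.na(unmeth) | meth < 0L | unmeth < 0L)
  if (length(bad)) stop("malformed cytosine report line ", bad[1L],
                        ": counts must be non-negative integers")
  ctx <- m[, 6L]
  if (!all(ctx %in% c("CG", "CHG", "CHH"))) {
    stop("malformed cytosine report line ",
         which(!ctx %in% c("CG", "CHG", "CHH"))[1L],
         ": context must be CG, CHG or CHH")
  }
  strand <- m[, 3L]
  if (!all(strand %in% c("+", "-"))) {
    stop("malformed cytosine report line ",
         which(!strand %in% c("+", "-"))[1L], ": strand must be + or -")
  }
  data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]), strand = strand,
             context = ctx, meth = meth, total = meth + unmeth,
             stringsAsFactors = FALSE)
}

#' @rdname read_cytosine_report
#' @param calls data.frame as returned by [read_cytosine_report()].
#' @export
write_cytosine_report <- function(calls, path) {
  stopifnot(all(calls$total >= calls$meth), all(calls$meth >= 0))
  out <- paste(calls$chrom, calls$pos, calls$strand, calls$meth,
               calls$total - calls$meth, calls$context, sep = "\t")
  writeLines(out, path)
  invisible(path)
}
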