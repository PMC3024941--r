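# Alignment container and file I/O.
#
# An alignment is a named set of equal-length gapped DNA sequences; all
# downstream stages (region delimitation, pairwise distances, encoding)
# operate on this object.  User-facing coordinates are 1-based inclusive
# columns; internal substring arithmetic converts at the boundary.

#' Construct an alignment object
#'
#' Bundles named, equal-length gapped sequences into the container used
#' throughout the package.  Sequences are uppercased; `?` is normalized
#' to `N` (missing data) and `.` to `-` (gap), so that a single missing
#' symbol and a single gap symbol reach the distance code.
#'
#' @param seqs character vector of gapped sequences (IUPAC DNA plus `-`).
#' @param names character vector of unique OTU names; defaults to
#'   `names(seqs)`.
#' @return An object of class `"aln"`: a list with elements `names`,
#'   `seqs` (uppercase strings) and `ncol` (alignment length).
#' @examples
#' aln <- alignment(c(a = "ACGT-A", b = "ACGTTA"))
#' aln$ncol
#' @export
alignment <- function(seqs, names = base::names(seqs)) {
  if (is.null(names)) stop("alignment rows must be named")
  names <- as.character(names)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("?", "N", seqs, fixed = TRUE)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(seqs) != length(names)) stop("names/seqs length mismatch")
  if (anyDuplicated(names)) {
    stop("duplicate OTU names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (any(!nzchar(names))) stop("empty OTU name")
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    bad <- names[w != w[1L]][1L]
    stop("ragged alignment: row '", bad, "' has length ", nchar(seqs[names == bad]),
         ", expected ", w[1L])
  }
  structure(list(names = unname(names), seqs = unname(seqs), ncol = w[1L]),
            class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat("Alignment:", length(x$names), "sequences x", x$ncol, "columns\n")
  show <- head(seq_along(x$names), 6L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", x$names[i], s))
  }
  if (length(x$names) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
as.matrix.aln <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$names
  m
}

aln_nrow <- function(aln) length(aln$names)

#' Read a multiple sequence alignment
#'
#' Supports FASTA, relaxed PHYLIP (sequential; names are whitespace
#' delimited, not limited to 10 characters) and NEXUS `DATA`/`CHARACTERS`
#' blocks.  Characters are uppercased and `?`/`.` normalized as in
#' [alignment()].
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`; `"auto"` guesses
#'   from the first non-blank line.
#' @return An [alignment()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- ""
    con <- file(path, "r"); on.exit(close(con))
    while (!nzchar(trimws(first))) {
      first <- readLines(con, n = 1L)
      if (length(first) == 0L) stop("empty alignment file: ", path)
    }
    close(con); on.exit()
    format <- if (startsWith(trimws(first), ">")) "fasta"
      else if (grepl("^#nexus", trimws(first), ignore.case = TRUE)) "nexus"
      else "phylip"
  }
  switch(format,
    fasta = {
      x <- ape::read.FASTA(path)
      alignment(vapply(as.character(x), paste, "", collapse = ""),
                names = names(x))
    },
    nexus = {
      x <- ape::read.nexus.data(path)
      alignment(vapply(x, paste, "", collapse = ""), names = names(x))
    },
    phylip = read_relaxed_phylip(path)
  )
}

# relaxed sequential PHYLIP: "ntax nchar" header, then one record per line
# ("name sequence", sequence possibly split by spaces); continuation lines
# without enough records are appended in order.
read_relaxed_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("malformed PHYLIP header: ", lines[1L])
  ntax <- as.integer(hdr[1L]); nchar_exp <- as.integer(hdr[2L])
  body <- lines[-1L]
  nms <- character(0); seqs <- character(0)
  for (ln in body) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(nms) < ntax) {
      nms <- c(nms, toks[1L])
      seqs <- c(seqs, paste(toks[-1L], collapse = ""))
    } else {
      # interleaved continuation, cycle through taxa in order
      i <- 1L + (length(seqs) %% ntax)
      seqs[i] <- paste0(seqs[i], paste(toks, collapse = ""))
    }
  }
  if (length(nms) != ntax) stop("PHYLIP: expected ", ntax, " taxa, found ", length(nms))
  aln <- alignment(seqs, names = nms)
  if (aln$ncol != nchar_exp)
    stop("PHYLIP: header promises ", nchar_exp, " columns, rows have ", aln$ncol)
  aln
}

#' Write an alignment
#'
#' @param aln an [alignment()] object.
#' @param path output file.
#' @param format `"fasta"`, `"phylip"` (relaxed sequential) or `"nexus"`.
#' @param strict_names if `TRUE`, PHYLIP names are truncated/padded to the
#'   strict 10-character convention.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip", "nexus"),
                            strict_names = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "aln"))
  out <- switch(format,
    fasta = as.vector(rbind(paste0(">", aln$names), aln$seqs)),
    phylip = {
      nms <- phylip_names(aln$names, strict_names)
      c(paste(length(aln$names), aln$ncol),
        paste(nms, aln$seqs))
    },
    nexus = c(
      "#NEXUS", "BEGIN DATA;",
      paste0("  DIMENSIONS NTAX=", length(aln$names), " NCHAR=", aln$ncol, ";"),
      "  FORMAT DATATYPE=DNA MISSING=N GAP=-;",
      "  MATRIX",
      paste("   ", aln$names, aln$seqs),
      "  ;", "END;")
  )
  writeLines(out, path)
  invisible(path)
}

phylip_names <- function(nms, strict) {
  if (strict) {
    sprintf("%-10s", substr(nms, 1L, 10L))
  } else {
    sprintf(paste0("%-", max(nchar(nms)) + 2L, "s"), nms)
  }
}

#' Define an ambiguous-region interval
#'
#' @param start,end 1-based inclusive alignment columns.
#' @param label free-text region label.
#' @return An object of class `"region_spec"`.
#' @export
region_spec <- function(start, end, label = sprintf("r%d_%d", start, end)) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("invalid region: start=", start, " end=", end)
  structure(list(start = start, end = end, label = as.character(label)),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("Region %s: columns %d-%d (%d cols)\n",
              x$label, x$start, x$end, x$end - x$start + 1L))
  invisible(x)
}

#' Read ambiguous-region coordinates from a text file
#'
#' One region per line, `label start end` (whitespace or comma separated),
#' coordinates 1-based inclusive.  Regions are returned sorted by start;
#' overlapping regions are an error.
#'
#' @param path file path.
#' @param ncol optional alignment length for range validation.
#' @return list of [region_spec()] objects.
#' @export
read_regions <- function(path, ncol = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  specs <- lapply(lines, function(ln) {
    toks <- strsplit(ln, "[,[:space:]]+")[[1L]]
    if (length(toks) < 3L) stop("cannot parse region line: ", ln)
    region_spec(as.integer(toks[2L]), as.integer(toks[3L]), label = toks[1L])
  })
  validate_regions(specs, ncol)
}

validate_regions <- function(specs, ncol = NULL) {
  if (length(specs) == 0L) return(specs)
  specs <- specs[order(vapply(specs, `[[`, 1L, "start"))]
  if (!is.null(ncol)) {
    for (r in specs) {
      if (r$end > ncol)
        stop("region ", r$label, " (", r$start, "-", r$end,
             ") exceeds alignment length ", ncol)
    }
  }
  if (length(specs) > 1L) {
    for (i in 2:length(specs)) {
      if (specs[[i]]$start <= specs[[i - 1L]]$end)
        stop("overlapping regions: ", specs[[i - 1L]]$label, " and ",
             specs[[i]]$label)
    }
  }
  specs
}

# extract region columns of each OTU and strip gaps; non-ACGTN IUPAC
# codes are passed through uppercased (distance engines treat them as N)
region_sequences <- function(aln, region) {
  stopifnot(inherits(aln, "aln"), inherits(region, "region_spec"))
  if (region$end > aln$ncol)
    stop("region ", region$label, " exceeds alignment length")
  sub <- substr(aln$seqs, region$start, region$end)
  setNames(gsub("-", "", sub, fixed = TRUE), aln$names)
}
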