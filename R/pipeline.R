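# End-to-end pipeline: delimit (or accept) ambiguous regions, encode
# each as ordered integer characters, and merge with the untouched DNA
# partition into a mixed matrix ready for RAxML / PAUP / MrBayes.

#' Recode ambiguous alignment regions as ordered integer characters
#'
#' The main entry point.  Non-ambiguous columns pass through unchanged
#' as the DNA partition; each ambiguous region is replaced by the
#' integer codes of its positive principal-coordinate axes.  Regions may
#' be supplied explicitly or delimited automatically from conserved
#' 5-base flanks.
#'
#' @param aln an [alignment()], or a path passed to [read_alignment()].
#' @param regions list of [region_spec()] objects, a region file path
#'   (see [read_regions()]), or `NULL` to delimit automatically with
#'   [delimit_regions()].
#' @param engine distance engine: `"zeta"` (default), `"identity"` or
#'   `"cost"`.
#' @param model optional [cost_model()] overriding the engine default.
#' @param k number of code states (default 10).
#' @param window,threshold,min_len_var delimitation parameters, used
#'   only when `regions` is `NULL`.
#' @param tol eigenvalue tolerance for [pcoa()].
#' @return object of class `"pics_ord"`, with components `alignment`,
#'   `regions`, `codes` (list of `"code_matrix"`, one per retained
#'   region), `dna` (DNA block rows), `partition_table`, `params`.
#'   Regions with no positive axes are dropped with a warning.
#' @examples
#' aln <- alignment(c(s1 = "AAACGTACGT---ACGTTTT",
#'                    s2 = "AAACGTA------ACGTTTT",
#'                    s3 = "AAACGTACGTCGTACGTTTT",
#'                    s4 = "AAACGT-------ACGTTTT"))
#' fit <- pics_ord(aln, regions = list(region_spec(7, 13, "r1")),
#'                 engine = "identity")
#' fit
#' @export
pics_ord <- function(aln, regions = NULL,
                     engine = c("zeta", "identity", "cost"),
                     model = NULL, k = 10L, window = 5L, threshold = 2.0,
                     min_len_var = 3L, tol = 1e-8) {
  engine <- match.arg(engine)
  if (is.character(aln)) aln <- read_alignment(aln)
  stopifnot(inherits(aln, "aln"))
  if (aln_nrow(aln) < 2L) stop("need at least two sequences")
  delimited <- is.null(regions)
  if (delimited) {
    regions <- delimit_regions(aln, w = window, threshold = threshold,
                               min_len_var = min_len_var)
  } else if (is.character(regions)) {
    regions <- read_regions(regions, ncol = aln$ncol)
  } else {
    if (inherits(regions, "region_spec")) regions <- list(regions)
    regions <- validate_regions(regions, ncol = aln$ncol)
  }
  if (is.null(model)) {
    model <- switch(engine,
      zeta = zeta_costs(),
      cost = cost_model(match_cost = 0, ts_cost = 1, tv_cost = 1,
                        gap_a = 1, gap_b = 1, gap_c = 0),
      identity = NULL)
  }

  codes <- list()
  kept_regions <- list()
  for (r in regions) {
    cm <- encode_region(aln, r, engine = engine, model = model, k = k,
                        tol = tol)
    if (ncol(cm$codes) == 0L) {
      warning("region ", r$label,
              ": no variable positive axes; region dropped")
      next
    }
    codes[[length(codes) + 1L]] <- cm
    kept_regions[[length(kept_regions) + 1L]] <- r
  }

  dna <- dna_block(aln, regions)
  structure(list(alignment = aln, regions = kept_regions,
                 all_regions = regions, codes = codes, dna = dna,
                 partition_table = partition_table(dna, codes),
                 params = list(engine = engine, k = as.integer(k),
                               window = as.integer(window),
                               threshold = threshold,
                               min_len_var = as.integer(min_len_var),
                               tol = tol, delimited = delimited,
                               model = unclass(model)),
                 call = match.call()),
            class = "pics_ord")
}

# DNA partition: the input alignment with all region columns removed
dna_block <- function(aln, regions) {
  keep <- rep(TRUE, aln$ncol)
  for (r in regions) keep[r$start:r$end] <- FALSE
  rows <- vapply(strsplit(aln$seqs, ""),
                 function(ch) paste(ch[keep], collapse = ""), "")
  setNames(rows, aln$names)
}

partition_table <- function(dna, codes) {
  widths <- c(nchar(dna[[1L]]),
              vapply(codes, function(cm) ncol(cm$codes), 0L))
  labels <- c("dna", vapply(codes, function(cm) cm$region_label, ""))
  types <- c("DNA", rep("MULTI", length(codes)))
  ends <- cumsum(widths)
  df <- data.frame(name = labels, type = types,
                   start = ends - widths + 1L, end = ends,
                   width = widths)
  df[df$width > 0L, , drop = FALSE]
}

#' @export
print.pics_ord <- function(x, ...) {
  cat("PICS-Ord recoding (", x$params$engine, " engine, ",
      x$params$k, " states)\n", sep = "")
  cat("  alignment: ", aln_nrow(x$alignment), " OTUs x ",
      x$alignment$ncol, " columns\n", sep = "")
  cat("  DNA partition: ", nchar(x$dna[[1L]]), " columns\n", sep = "")
  for (i in seq_along(x$codes)) {
    r <- x$regions[[i]]; cm <- x$codes[[i]]
    cat(sprintf("  region %s (cols %d-%d): %d code characters\n",
                r$label, r$start, r$end, ncol(cm$codes)))
  }
  dropped <- length(x$all_regions) - length(x$regions)
  if (dropped > 0L) cat("  (", dropped, " region(s) dropped as invariant)\n",
                        sep = "")
  invisible(x)
}

#' @export
summary.pics_ord <- function(object, ...) {
  regs <- lapply(seq_along(object$codes), function(i) {
    r <- object$regions[[i]]; cm <- object$codes[[i]]
    data.frame(region = r$label, start = r$start, end = r$end,
               dna_cols = r$end - r$start + 1L,
               code_cols = ncol(cm$codes),
               top_axis_weight = if (length(cm$axis_weights))
                 max(cm$axis_weights) else NA_real_)
  })
  out <- list(regions = if (length(regs)) do.call(rbind, regs) else
                data.frame(),
              partition_table = object$partition_table,
              params = object$params)
  class(out) <- "summary.pics_ord"
  out
}

#' @export
print.summary.pics_ord <- function(x, ...) {
  cat("Encoded regions:\n")
  print(x$regions, row.names = FALSE)
  cat("\nPartition table:\n")
  print(x$partition_table, row.names = FALSE)
  invisible(x)
}

#' Plot the ordination of one encoded region
#'
#' Scatter of the first two principal-coordinate axes (recomputed from
#' the stored alignment), labelled with OTU names.
#'
#' @param x a [pics_ord()] object.
#' @param region region index or label (default first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.pics_ord <- function(x, region = 1L, ...) {
  if (length(x$regions) == 0L) stop("no encoded regions to plot")
  if (is.character(region))
    region <- match(region, vapply(x$regions, `[[`, "", "label"))
  r <- x$regions[[region]]
  dm <- region_matrix(x$alignment, r, engine = x$params$engine,
                      model = if (x$params$engine == "identity") NULL else
                        do.call(cost_model, x$params$model[
                          intersect(names(x$params$model),
                                    names(formals(cost_model)))]))
  ord <- pcoa(dm, tol = x$params$tol)
  ev <- explained_variance(ord)
  if (ncol(ord$coords) < 1L) stop("region has no positive axes")
  xs <- ord$coords[, 1L]
  ys <- if (ncol(ord$coords) >= 2L) ord$coords[, 2L] else rep(0, length(xs))
  graphics::plot(xs, ys,
                 xlab = sprintf("PCo 1 (%.1f%%)", 100 * ev[1L]),
                 ylab = if (length(ev) >= 2L)
                   sprintf("PCo 2 (%.1f%%)", 100 * ev[2L]) else "PCo 2",
                 main = paste("Region", r$label), ...)
  graphics::text(xs, ys, labels = ord$names, pos = 3, cex = 0.7)
  invisible(x)
}

#' Write the mixed DNA + code matrix and its companions
#'
#' Writes, under a common prefix: a relaxed PHYLIP file with the DNA
#' block followed by the code blocks (codes rendered 0-9 then A-V, the
#' RAxML multi-state convention), a RAxML partition file (`DNA, dna =
#' 1-738` / `MULTI, r1 = 739-758` style), a NEXUS file with a
#' PAUP-compatible ordered-character `TYPESET` (and optional `WTSET`
#' from the axis variance fractions), and a JSON run manifest recording
#' every parameter and per-region axis summary.
#'
#' @param x a [pics_ord()] object.
#' @param out_prefix output path prefix.
#' @param formats subset of `"phylip"`, `"partitions"`, `"nexus"`,
#'   `"manifest"`; default all.
#' @param strict_names strict 10-character PHYLIP names.
#' @param weights include a NEXUS `WTSET` from axis weights.
#' @return named character vector of the written paths, invisibly.
#' @export
write_mixed <- function(x, out_prefix,
                        formats = c("phylip", "partitions", "nexus",
                                    "manifest"),
                        strict_names = FALSE, weights = FALSE) {
  stopifnot(inherits(x, "pics_ord"))
  formats <- match.arg(formats, several.ok = TRUE)
  k <- x$params$k
  if (k > 32L && any(c("phylip", "partitions") %in% formats))
    stop("the RAxML writer supports at most 32 states; for k in 33..64 ",
         "request the NEXUS-only path: formats = c(\"nexus\", \"manifest\")")
  paths <- c(phylip = paste0(out_prefix, ".phy"),
             partitions = paste0(out_prefix, ".partitions"),
             nexus = paste0(out_prefix, ".nex"),
             manifest = paste0(out_prefix, ".json"))
  paths <- paths[formats]

  coderows <- function(cm) apply(cm$codes, 1L, function(z)
    paste(render_codes(z, cm$k), collapse = ""))
  blocks <- c(list(x$dna), lapply(x$codes, coderows))
  rows <- do.call(paste0, blocks)
  nms <- x$alignment$names
  total <- nchar(rows[1L])

  if ("phylip" %in% formats)
    writeLines(c(paste(length(nms), total),
                 paste(phylip_names(nms, strict_names), rows)),
               paths[["phylip"]])

  pt <- x$partition_table
  if ("partitions" %in% formats)
    writeLines(sprintf("%s, %s = %d-%d", pt$type, pt$name, pt$start, pt$end),
               paths[["partitions"]])

  if ("nexus" %in% formats)
    writeLines(mixed_nexus(x, rows, weights), paths[["nexus"]])

  if (!"manifest" %in% formats) return(invisible(paths))
  manifest <- list(
    package = "picsord",
    version = as.character(utils::packageVersion("picsord")),
    params = x$params,
    n_otu = length(nms),
    alignment_columns = x$alignment$ncol,
    dna_columns = nchar(x$dna[[1L]]),
    regions = lapply(seq_along(x$codes), function(i) {
      r <- x$regions[[i]]; cm <- x$codes[[i]]
      list(label = r$label, start = r$start, end = r$end,
           code_columns = ncol(cm$codes),
           axis_weights = cm$axis_weights)
    }))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

mixed_nexus <- function(x, rows, weights) {
  pt <- x$partition_table
  nms <- x$alignment$names
  total <- nchar(rows[1L])
  k <- x$params$k
  dna_end <- pt$end[pt$type == "DNA"]
  multi <- pt[pt$type == "MULTI", , drop = FALSE]
  symbols <- paste(code_symbols[seq_len(min(k, 64L))], collapse = "")
  fmt <- if (nrow(multi)) {
    sprintf("  FORMAT DATATYPE=MIXED(DNA:1-%d,STANDARD:%d-%d) SYMBOLS=\"%s\" MISSING=? GAP=-;",
            dna_end, min(multi$start), total, symbols)
  } else {
    "  FORMAT DATATYPE=DNA MISSING=? GAP=-;"
  }
  out <- c("#NEXUS", "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(nms), total),
           fmt, "  MATRIX",
           paste("   ", nms, rows), "  ;", "END;",
           "BEGIN ASSUMPTIONS;")
  if (nrow(multi)) {
    out <- c(out, sprintf("  TYPESET * picsord = ord: %s;",
                          paste(sprintf("%d-%d", multi$start, multi$end),
                                collapse = " ")))
    if (weights) {
      w <- unlist(lapply(x$codes, `[[`, "axis_weights"))
      out <- c(out, sprintf(
        "  WTSET * picsordwt = %s;",
        paste(sprintf("%.4f: %d", w, multi$start[1L] +
                        seq_along(w) - 1L), collapse = ", ")))
    }
  }
  c(out, "END;")
}
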