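# Readcount-table, annotation and result-table I/O.
#
# Internal coordinate convention: 1-based, closed on both ends (the convention
# of the readcount position column). BED input (0-based half-open) is converted
# on parse; GFF3 is already 1-based closed.

#' @importFrom stats median p.adjust phyper rbeta rbinom rnbinom runif sd setNames t.test var
#' @importFrom utils modifyList read.delim write.table
NULL

NUC_BASES <- c("A", "C", "G", "T")

#' Per-replicate count column names in the readcount dialect
#'
#' The readcount table carries one row per site (`chrom`, `pos`, `ref`) and,
#' for every pool replicate `R`, the five columns `R_A, R_C, R_G, R_T, R_indel`.
#' Columns are discovered by header name, not position.
#'
#' @param replicate Character vector of replicate names.
#' @return Character vector of column names.
#' @export
count_columns <- function(replicate) {
  as.vector(t(outer(replicate, c(NUC_BASES, "indel"), paste, sep = "_")))
}

#' Validate a two-group pool layout
#'
#' @param pools Named list of exactly two groups (e.g. `female`, `male`), each a
#'   character vector of replicate names. Replicate names must be unique across
#'   groups.
#' @return The validated `pools`, invisibly.
#' @export
validate_pools <- function(pools) {
  if (!is.list(pools) || length(pools) != 2L ||
      is.null(names(pools)) || any(!nzchar(names(pools)))) {
    stop("configuration error: 'pools' must be a named list of two groups", call. = FALSE)
  }
  reps <- unlist(pools, use.names = FALSE)
  if (length(reps) < 2L || !is.character(reps)) {
    stop("configuration error: each group needs at least one replicate name", call. = FALSE)
  }
  if (anyDuplicated(reps)) {
    stop("configuration error: duplicate replicate name '",
         reps[duplicated(reps)][1L], "'", call. = FALSE)
  }
  invisible(pools)
}

count_leading_comments <- function(path) {
  head <- readLines(path, n = 500L, warn = FALSE)
  n <- 0L
  for (ln in head) {
    if (startsWith(ln, "#")) n <- n + 1L else break
  }
  n
}

#' Parse a per-site nucleotide readcount table
#'
#' Reads the tab-separated readcount dialect: a header line naming `chrom`,
#' `pos`, `ref` and one count column per base per pool replicate (see
#' [count_columns()]), one row per genomic site. Leading `#` comment lines are
#' skipped. Positions are 1-based; reference bases outside `A,C,G,T,N` are
#' mapped to `N`.
#'
#' @param path Path to the TSV file.
#' @param pools Pool layout, see [validate_pools()]. Every replicate named here
#'   must have its five count columns in the header.
#' @return A data.frame with columns `chrom`, `pos`, `ref` and all count
#'   columns, rows in file order; the pool layout is attached as
#'   `attr(, "pools")`.
#' @export
parse_readcounts <- function(path, pools) {
  validate_pools(pools)
  n_comment <- count_leading_comments(path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = n_comment,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "ref")) {
    if (!col %in% names(df)) {
      stop("configuration error: missing required column '", col, "'", call. = FALSE)
    }
  }
  reps <- unlist(pools, use.names = FALSE)
  need <- count_columns(reps)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("configuration error: missing required column '", missing[1L], "'", call. = FALSE)
  }
  # line number of data row i in the file (comments + header precede it)
  line_of <- function(i) n_comment + 1L + i
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos) | pos < 1 | pos != floor(pos))
  if (length(bad)) {
    stop("parse error at line ", line_of(bad[1L]), ": invalid position '",
         df$pos[bad[1L]], "'", call. = FALSE)
  }
  df$pos <- as.integer(pos)
  df$ref <- toupper(as.character(df$ref))
  df$ref[!df$ref %in% c(NUC_BASES, "N")] <- "N"
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      stop("parse error at line ", line_of(bad[1L]), ": negative or non-numeric count '",
           df[[col]][bad[1L]], "' in column '", col, "'", call. = FALSE)
    }
    df[[col]] <- v
  }
  out <- df[, c("chrom", "pos", "ref", need), drop = FALSE]
  out$chrom <- as.character(out$chrom)
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  out
}

#' Write a readcount table
#'
#' Inverse of [parse_readcounts()]: writes the comment header (tool version and
#' parameters) followed by the tab-separated table.
#'
#' @param counts Readcount data.frame (columns `chrom`, `pos`, `ref`, counts).
#' @param path Output path.
#' @param params Named list recorded in the comment header.
#' @return `path`, invisibly.
#' @export
write_readcounts <- function(counts, path, params = list()) {
  write_tsv_with_header(counts, path, params, signif_digits = NULL)
}

pkg_version_string <- function() {
  tryCatch(as.character(utils::packageVersion("sexfst")), error = function(e) "dev")
}

comment_header <- function(params) {
  lines <- paste0("# sexfst ", pkg_version_string())
  if (length(params)) {
    kv <- vapply(seq_along(params), function(i) {
      paste0(names(params)[i], "=", paste(format(params[[i]]), collapse = ","))
    }, character(1))
    lines <- c(lines, paste0("# ", kv))
  }
  lines
}

write_tsv_with_header <- function(df, path, params, signif_digits = 6L) {
  out <- df
  if (!is.null(signif_digits)) {
    for (col in names(out)) {
      if (is.double(out[[col]])) {
        na <- is.na(out[[col]])
        v <- trimws(formatC(signif(out[[col]], signif_digits),
                            digits = signif_digits, format = "g"))
        v[na] <- "NA"
        out[[col]] <- v
      }
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(comment_header(params), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write site-level and gene-level statistic tables
#'
#' Tab-separated, deterministic row order (chromosome then position / gene
#' start), floating point values at 6 significant digits, and a comment header
#' recording the tool version and the parameter set.
#'
#' @param stats A `SiteStats` (from [site_stats()]) or `GeneStats` (from
#'   [gene_stats()]) data.frame.
#' @param path Output path.
#' @param params Named list recorded in the comment header.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(stats, path, params = list()) {
  ord <- order(stats$chrom, stats$pos)
  write_tsv_with_header(stats[ord, , drop = FALSE], path, params)
}

#' @rdname write_site_table
#' @export
write_gene_table <- function(stats, path, params = list()) {
  ord <- order(stats$chrom, stats$start)
  write_tsv_with_header(stats[ord, , drop = FALSE], path, params)
}

#' Read back a result table written by this package
#'
#' @param path Path to a TSV written by [write_site_table()],
#'   [write_gene_table()] or any of the report writers.
#' @return A data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Parse gene intervals from BED or GFF3
#'
#' Both dialects are normalized to the internal 1-based closed convention.
#' BED (0-based half-open) needs at least 4 columns, the 4th being the gene id.
#' For GFF3, only `gene`, `mRNA` and `transcript` features are kept (a message
#' reports the number of skipped features); the gene id is the `ID` attribute
#' (falling back to `Name`). The annotated span is used as-is, i.e. including
#' UTRs and introns for transcript features.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`; `"auto"` guesses from the file extension.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one of `+`, `-`, `.`), 1-based closed coordinates.
#' @export
parse_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    keep_types <- c("gene", "mRNA", "transcript")
    type <- as.character(gr$type)
    skipped <- sum(!type %in% keep_types)
    if (skipped > 0) {
      message("parse_gene_intervals: skipped ", skipped,
              " non-gene/transcript GFF3 feature(s)")
    }
    gr <- gr[type %in% keep_types]
    ids <- as.character(gr$ID)
    if (!is.null(gr$Name)) {
      ids[is.na(ids)] <- as.character(gr$Name)[is.na(ids)]
    }
  } else {
    ids <- as.character(gr$name)
  }
  if (length(gr) && (anyNA(ids) || any(!nzchar(ids)))) {
    stop("format error: interval without a gene id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("format error: duplicate gene_id '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  }
  out <- data.frame(
    gene_id = ids,
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr),
    end     = GenomicRanges::end(gr),
    strand  = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
  bad <- which(out$end <= out$start)
  if (length(bad)) {
    stop("format error: interval with end <= start for gene_id '",
         out$gene_id[bad[1L]], "'", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write gene intervals as BED4
#'
#' Converts the internal 1-based closed intervals back to 0-based half-open BED.
#'
#' @param genes Gene interval data.frame (see [parse_gene_intervals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
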