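#' Strand-resolved binned count table
#'
#' The primary observation table: one record per (cell, chromosome, bin,
#' haplotype tag) holding Watson and Crick read counts. Haplotype tags are
#' `"H1"`, `"H2"` (and `"H3"` for trisomic baselines) for reads whose
#' haplotype is known from phasing-informative positions, or `"untagged"`.
#'
#' @param df a data.frame with columns `cell`, `chrom`, `start`, `end`,
#'   `hap`, `w`, `c`; coordinates must lie on the bin grid.
#' @param grid an [build_bin_grid()] grid.
#' @return A `data.table` of class `sk_counts`, keyed by
#'   (cell, chrom, bin, hap), with an added `bin` column.
#' @export
strand_bin_counts <- function(df, grid) {
  need <- c("cell", "chrom", "start", "end", "hap", "w", "c")
  miss <- setdiff(need, names(df))
  if (length(miss))
    sk_format_error(paste0("counts table missing columns: ", paste(miss, collapse = ", ")))
  dt <- data.table::as.data.table(df)[, need, with = FALSE]
  genome <- grid_genome(grid)
  bad_chr <- setdiff(unique(dt$chrom), genome$chrom)
  if (length(bad_chr))
    sk_model_error(paste0("unknown chromosome(s): ", paste(bad_chr, collapse = ", ")))
  if (nrow(dt)) {
    neg <- which(dt$w < 0 | dt$c < 0)
    if (length(neg))
      sk_validation_error(paste0("negative counts at row(s) ", paste(head(neg, 5L), collapse = ", ")))
    key <- grid[, .(chrom, start, end, bin)]
    dt <- key[dt, on = c("chrom", "start", "end")]
    off <- which(is.na(dt$bin))
    if (length(off))
      sk_validation_error(paste0(
        "coordinates not on the bin grid at row(s) ",
        paste(head(off, 5L), collapse = ", ")))
    bad_hap <- setdiff(unique(dt$hap), c(paste0("H", 1:3), "untagged"))
    if (length(bad_hap))
      sk_validation_error(paste0("invalid haplotype tag(s): ", paste(bad_hap, collapse = ", ")))
    if (anyDuplicated(dt, by = c("cell", "chrom", "bin", "hap")))
      sk_validation_error("duplicate (cell, chrom, bin, hap) records")
  } else {
    dt[, bin := integer()]
  }
  dt[, `:=`(w = as.integer(w), c = as.integer(c), bin = as.integer(bin))]
  data.table::setcolorder(dt, c("cell", "chrom", "bin", "start", "end", "hap", "w", "c"))
  data.table::setkeyv(dt, c("cell", "chrom", "bin", "hap"))
  data.table::setattr(dt, "class", c("sk_counts", class(dt)))
  dt[]
}

#' Read a strand-resolved counts TSV
#'
#' The file must be tab-separated with header
#' `cell chrom start end hap w c` and coordinates aligned to `grid`;
#' misaligned coordinates are an error, never silently rebinned. Gzipped
#' files are read transparently.
#'
#' @param path path to the TSV (optionally `.gz`).
#' @param grid an [build_bin_grid()] grid.
#' @return An `sk_counts` table.
#' @export
read_counts_table <- function(path, grid) {
  if (!file.exists(path)) sk_io_error(paste0("no such file: ", path))
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = "cell"))
  if (nrow(dt) == 0L && ncol(dt) == 0L)
    dt <- data.table::data.table(cell = character(), chrom = character(),
                                 start = numeric(), end = numeric(),
                                 hap = character(), w = integer(), c = integer())
  strand_bin_counts(dt, grid)
}

#' Write a strand-resolved counts TSV
#'
#' Rows are written in deterministic (cell, chrom, bin, hap) order so that
#' the same table always produces byte-identical files, and a written table
#' re-reads record-identically.
#'
#' @param counts an `sk_counts` table.
#' @param path output path.
#' @export
write_counts_table <- function(counts, path) {
  stopifnot(inherits(counts, "sk_counts"))
  out <- data.table::as.data.table(counts)[, .(cell, chrom, start, end, hap, w, c)]
  data.table::setorderv(out, c("cell", "chrom", "start", "hap"))
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) sk_io_error(paste0("cannot write: ", path))
  invisible(path)
}

#' Per-cell fragment totals and QC status
#'
#' Cells whose total mapped fragment count falls below
#' `config$qc_min_fragments` are flagged as QC failures.
#'
#' @param counts an `sk_counts` table.
#' @param config an [sk_config()].
#' @return A `data.table` with columns `cell`, `total`, `qc_pass`.
#' @export
cell_qc <- function(counts, config = sk_config()) {
  config <- as_sk_config(config)
  tot <- data.table::as.data.table(counts)[, .(total = sum(w) + sum(c)), by = cell]
  tot[, qc_pass := total >= config$qc_min_fragments]
  tot[]
}
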