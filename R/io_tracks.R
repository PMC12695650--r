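# TSV round-trip for segment tracks, consensus tables and pair tables, so
# the pipeline stages can be chained from the command line.

#' Write / read a segment track TSV
#'
#' @param track an `sk_track`.
#' @param path file path.
#' @export
write_track_tsv <- function(track, path) {
  out <- data.table::as.data.table(track)
  data.table::setorderv(out, c("cell", "chrom", "start_bin"))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path) {
  if (!file.exists(path)) sk_io_error(paste0("no such file: ", path))
  dt <- data.table::fread(path, sep = "\t")
  H <- sum(grepl("^cn_h[0-9]+$", names(dt)))
  data.table::setattr(dt, "n_hap", H)
  data.table::setattr(dt, "class", c("sk_track", class(dt)))
  dt[]
}

#' Write / read a consensus TSV
#'
#' The blacklist mask is carried as a `blacklist` column.
#'
#' @param consensus an `sk_consensus`.
#' @param path file path.
#' @export
write_consensus_tsv <- function(consensus, path) {
  out <- data.table::as.data.table(consensus)
  out[, blacklist := attr(consensus, "blacklist", exact = TRUE)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_consensus_tsv
#' @export
read_consensus_tsv <- function(path) {
  if (!file.exists(path)) sk_io_error(paste0("no such file: ", path))
  dt <- data.table::fread(path, sep = "\t")
  mask <- dt$blacklist
  dt[, blacklist := NULL]
  data.table::setattr(dt, "blacklist", mask)
  data.table::setattr(dt, "n_hap", sum(grepl("^cn_h[0-9]+$", names(dt))))
  data.table::setattr(dt, "class", c("sk_consensus", class(dt)))
  dt[]
}
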