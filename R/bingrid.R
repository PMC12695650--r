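#' Build a genome-wide bin grid
#'
#' Tiles every chromosome with fixed-size, 0-based half-open bins. The last
#' bin of a chromosome may be short. The grid is a pure function of the
#' genome and the bin size.
#'
#' @param genome an [genome_model()].
#' @param bin_size bin width in bp (default 200 kb, the detection-limit scale
#'   of intermediate-coverage strand-resolved single-cell sequencing).
#' @return A `data.table` of class `sk_grid` with columns `chrom`, `bin`
#'   (1-based index within chromosome), `gbin` (1-based genome-wide index),
#'   `start`, `end`, `width`. The genome and bin size are kept as attributes.
#' @examples
#' grid <- build_bin_grid(synthetic_genome())
#' nrow(grid)
#' @export
build_bin_grid <- function(genome, bin_size = 200000L) {
  stopifnot(inherits(genome, "sk_genome"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    sk_parameter_error("bin_size must be a single positive number")
  bin_size <- as.numeric(bin_size)
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    end <- pmin(start + bin_size, len)
    data.table::data.table(
      chrom = genome$chrom[i], bin = seq_len(n), start = start, end = end
    )
  })
  grid <- data.table::rbindlist(pieces)
  grid[, `:=`(gbin = seq_len(nrow(grid)), width = end - start)]
  data.table::setattr(grid, "genome", genome)
  data.table::setattr(grid, "bin_size", bin_size)
  data.table::setattr(grid, "class", c("sk_grid", class(grid)))
  grid[]
}

grid_genome <- function(grid) attr(grid, "genome", exact = TRUE)
grid_bin_size <- function(grid) attr(grid, "bin_size", exact = TRUE)

# number of bins per chromosome, named
grid_nbins <- function(grid) {
  tab <- grid[, .N, by = chrom]
  setNames(tab$N, tab$chrom)
}

# map (chrom, pos) to the 1-based within-chromosome bin index containing pos
pos_to_bin <- function(grid, chrom_, pos) {
  pmin(floor(pos / grid_bin_size(grid)) + 1L,
       grid_nbins(grid)[chrom_])
}
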