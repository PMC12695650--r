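#' Genome model
#'
#' A genome model holds chromosome names, lengths, centromere positions (the
#' p/q arm boundary) and the baseline homologue count per chromosome (2 for a
#' disomic chromosome; 3 for a modelled trisomy). All coordinates are 0-based,
#' half-open base pairs.
#'
#' @param chrom character vector of chromosome names.
#' @param length integer-ish vector of chromosome lengths in bp.
#' @param centromere centromere position per chromosome, strictly inside
#'   `(0, length)`.
#' @param homologues baseline homologue count per chromosome (>= 1).
#' @return A `data.frame` of class `sk_genome`.
#' @examples
#' g <- genome_model(c("A", "B"), c(50e6, 30e6), c(20e6, 12e6))
#' @export
genome_model <- function(chrom, length, centromere,
                         homologues = rep(2L, base::length(chrom))) {
  n <- base::length(chrom)
  if (n == 0L) sk_model_error("genome model needs at least one chromosome")
  if (anyDuplicated(chrom)) sk_model_error("duplicated chromosome names")
  if (base::length(length) != n || base::length(centromere) != n ||
      base::length(homologues) != n)
    sk_model_error("chrom, length, centromere and homologues must have equal length")
  if (any(length <= 0)) sk_model_error("chromosome lengths must be positive")
  if (any(centromere <= 0 | centromere >= length))
    sk_model_error("every centromere must lie strictly between 0 and the chromosome length")
  if (any(homologues < 1)) sk_model_error("homologue count must be >= 1 for every chromosome")
  g <- data.frame(
    chrom = as.character(chrom),
    length = as.numeric(length),
    centromere = as.numeric(centromere),
    homologues = as.integer(homologues),
    stringsAsFactors = FALSE
  )
  class(g) <- c("sk_genome", "data.frame")
  g
}

#' Default reduced synthetic genome
#'
#' Five chromosomes of 50-150 Mb. Small enough that a full simulated
#' population segments in seconds, large enough to carry realistic event
#' sizes (1 Mb to whole-arm). `trisomy` marks chromosomes whose baseline
#' homologue count is 3 instead of 2.
#'
#' @param trisomy character vector of chromosome names to model at baseline
#'   copy number 3.
#' @return An `sk_genome`.
#' @export
synthetic_genome <- function(trisomy = character()) {
  chrom <- c("chr1", "chr2", "chr3", "chr4", "chr5")
  len <- c(150e6, 120e6, 100e6, 80e6, 50e6)
  cen <- c(62e6, 48e6, 45e6, 34e6, 21e6)
  hom <- ifelse(chrom %in% trisomy, 3L, 2L)
  if (!all(trisomy %in% chrom))
    sk_model_error("trisomy names not in the synthetic genome")
  genome_model(chrom, len, cen, hom)
}

#' hg38-like chromosome size table
#'
#' Approximate GRCh38 chromosome lengths and centromere midpoints (autosomes
#' plus X), for users who want a full-scale genome model. Nothing downstream
#' depends on real coordinates.
#'
#' @return An `sk_genome` with 23 chromosomes.
#' @export
hg38_like_genome <- function() {
  chrom <- c(paste0("chr", 1:22), "chrX")
  len <- c(248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
           159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
           114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
           58617616, 64444167, 46709983, 50818468, 156040895)
  cen <- c(123400000, 93900000, 90900000, 50000000, 48800000, 59800000,
           60100000, 45200000, 43000000, 39800000, 53400000, 35500000,
           17700000, 17200000, 19000000, 36800000, 25100000, 18500000,
           26200000, 28100000, 12000000, 15000000, 61000000)
  genome_model(chrom, len, cen)
}

#' Read / write a genome model TSV
#'
#' Columns: `chrom`, `length`, `centromere`, `homologues`.
#'
#' @param path file path.
#' @return `read_genome_tsv` returns an `sk_genome`.
#' @export
read_genome_tsv <- function(path) {
  if (!file.exists(path)) sk_io_error(paste0("no such file: ", path))
  dt <- data.table::fread(path, sep = "\t")
  need <- c("chrom", "length", "centromere", "homologues")
  miss <- setdiff(need, names(dt))
  if (base::length(miss))
    sk_format_error(paste0("genome TSV missing columns: ", paste(miss, collapse = ", ")))
  genome_model(dt$chrom, dt$length, dt$centromere, dt$homologues)
}

#' @param genome an `sk_genome`.
#' @rdname read_genome_tsv
#' @export
write_genome_tsv <- function(genome, path) {
  stopifnot(inherits(genome, "sk_genome"))
  data.table::fwrite(as.data.frame(genome), path, sep = "\t")
  invisible(path)
}

# "p" or "q" arm for a position (midpoint rule for intervals spanning the
# centromere is applied by callers).
arm_of <- function(genome, chrom, pos) {
  cen <- genome$centromere[match(chrom, genome$chrom)]
  ifelse(pos < cen, "p", "q")
}
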