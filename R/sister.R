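# Sister-cell pair identification from reciprocal template-strand
# inheritance and mirrored SCE breakpoints. Two daughters of one division
# inherit complementary template strands on every homologue, and every
# parental SCE appears at the same breakpoint in both with mirrored
# orientation - a uniquely identifying record of sisterhood. Under the null
# (independent cells) per-homologue template agreement is Bernoulli(0.5),
# so genome-wide reciprocity near 1 essentially never arises by chance.

#' Infer per-homologue template-strand states from a segment track
#'
#' The template strand of a homologue is read off segments carrying exactly
#' one copy of that haplotype; a strand switch between adjacent single-copy
#' segments (no copy-number change) is reported as an SCE with its
#' orientation. Segments where the haplotype's copy number differs from one
#' are uninformative; chromosomes entirely at copy number zero are skipped
#' with a warning.
#'
#' @param track an `sk_track` for one cell.
#' @param grid the bin grid.
#' @return An object of class `sk_strand_state`: list with `cell`, `strand`
#'   (bins x haplotypes matrix, 1 = Watson template, -1 = Crick, 0 =
#'   uninformative) and `sces` (chrom, hap, boundary_bin, orientation).
#' @export
infer_strand_states <- function(track, grid) {
  genome <- grid_genome(grid)
  H <- attr(track, "n_hap", exact = TRUE)
  if (is.null(H)) H <- max(genome$homologues)
  B <- nrow(grid)
  S <- matrix(0L, B, H)
  sch <- character(); shp <- integer(); sbd <- integer(); sor <- character()
  cell_id <- unique(track$cell)
  for (ch in unique(track$chrom)) {
    idx <- grid[chrom == ch, gbin]
    tr <- track[chrom == ch]
    data.table::setorder(tr, start_bin)
    if (all(tr$cn_total == 0L)) {
      warning("chromosome ", ch, " has copy number 0 in cell ", cell_id,
              "; skipped", call. = FALSE)
      next
    }
    for (h in seq_len(H)) {
      cnh <- tr[[paste0("cn_h", h)]]
      wh <- tr[[paste0("w_h", h)]]
      prev_strand <- NA_integer_; prev_seg <- NA_integer_
      for (k in seq_len(nrow(tr))) {
        if (cnh[k] == 1L) {
          s <- if (wh[k] == 1L) 1L else -1L
          S[idx[tr$start_bin[k]:tr$end_bin[k]], h] <- s
          if (!is.na(prev_strand) && prev_seg == k - 1L && s != prev_strand) {
            sch <- c(sch, ch); shp <- c(shp, h)
            sbd <- c(sbd, tr$end_bin[k - 1L])
            sor <- c(sor, if (prev_strand == 1L) "WtoC" else "CtoW")
          }
          prev_strand <- s; prev_seg <- k
        }
      }
    }
  }
  structure(list(cell = cell_id, strand = S,
                 sces = data.table::data.table(chrom = sch, hap = shp,
                                               boundary_bin = sbd,
                                               orientation = sor)),
            class = "sk_strand_state")
}

#' Infer strand states for every cell of a population track
#'
#' @param tracks an `sk_track` with several cells.
#' @param grid the bin grid.
#' @return A named list of `sk_strand_state` objects.
#' @export
strand_state_population <- function(tracks, grid) {
  cells <- unique(tracks$cell)
  out <- lapply(cells, function(cl) {
    tr <- tracks[cell == cl]
    data.table::setattr(tr, "n_hap", attr(tracks, "n_hap", exact = TRUE))
    infer_strand_states(tr, grid)
  })
  setNames(out, cells)
}

# number of homologue-bin positions that can in principle be informative
informative_capacity <- function(grid) {
  genome <- grid_genome(grid)
  nb <- grid_nbins(grid)
  sum(nb[genome$chrom] * genome$homologues)
}

#' Score a cell pair for sisterhood
#'
#' Reciprocity is the fraction of homologue-bins, informative in both
#' cells, with opposite template strand. An SCE is mirrored when both cells
#' switch within `config$sce_tol_bins` bins of the same position in
#' opposite orientations. The verdict is `sisters` when reciprocity >=
#' `config$reciprocity_min` and either at least one SCE is mirrored or
#' reciprocity is exactly 1 over at least `config$min_informative_frac` of
#' the genome; cells identical to each other score reciprocity 0 (identical
#' is not reciprocal).
#'
#' @param a,b `sk_strand_state` objects on the same grid.
#' @param grid the bin grid.
#' @param config an [sk_config()].
#' @return A one-row `data.table`: cell_a, cell_b, reciprocity,
#'   informative_bins, coverage, mirrored_sces, verdict.
#' @export
score_pair <- function(a, b, grid, config = sk_config()) {
  config <- as_sk_config(config)
  if (!identical(dim(a$strand), dim(b$strand)))
    sk_model_error("strand-state tracks do not share a grid")
  both <- a$strand != 0L & b$strand != 0L
  inf <- sum(both)
  opp <- sum(a$strand[both] != b$strand[both])
  recip <- if (inf > 0) opp / inf else 0
  cap <- informative_capacity(grid)
  coverage <- inf / cap
  mirrored <- 0L
  if (nrow(a$sces) && nrow(b$sces)) {
    used <- rep(FALSE, nrow(b$sces))
    for (i in seq_len(nrow(a$sces))) {
      j <- which(!used & b$sces$chrom == a$sces$chrom[i] &
                   b$sces$hap == a$sces$hap[i] &
                   abs(b$sces$boundary_bin - a$sces$boundary_bin[i]) <=
                   config$sce_tol_bins &
                   b$sces$orientation != a$sces$orientation[i])
      if (length(j)) { used[j[1]] <- TRUE; mirrored <- mirrored + 1L }
    }
  }
  verdict <- if (coverage < 0.2) "ambiguous"
  else if (recip >= config$reciprocity_min &&
           (mirrored >= 1L ||
              (recip == 1 && coverage >= config$min_informative_frac))) "sisters"
  else "unrelated"
  data.table::data.table(cell_a = a$cell, cell_b = b$cell,
                         reciprocity = recip, informative_bins = inf,
                         coverage = coverage, mirrored_sces = mirrored,
                         verdict = verdict)
}

#' Find sister-cell pairs in a population
#'
#' All-pairs reciprocity screening (vectorized through a strand-state
#' matrix cross-product), full scoring of candidate pairs, then greedy
#' matching by descending reciprocity with each cell in at most one pair;
#' ties break by cell id.
#'
#' @param states a list of `sk_strand_state` objects (see
#'   [strand_state_population()]).
#' @param grid the bin grid.
#' @param config an [sk_config()].
#' @return A `data.table` of pairs with verdict `sisters` (possibly empty).
#' @export
find_sister_pairs <- function(states, grid, config = sk_config()) {
  config <- as_sk_config(config)
  empty <- data.table::data.table(cell_a = character(), cell_b = character(),
                                  reciprocity = numeric(),
                                  informative_bins = integer(),
                                  coverage = numeric(),
                                  mirrored_sces = integer(),
                                  verdict = character())
  if (length(states) < 2L) return(empty)
  S <- vapply(states, function(s) as.numeric(s$strand), numeric(length(states[[1]]$strand)))
  A <- crossprod(S)                      # agreements - disagreements
  N <- crossprod(abs(S))                 # informative positions
  opp <- (N - A) / 2
  recip <- ifelse(N > 0, opp / N, 0)
  cand <- which(upper.tri(recip) & recip >= config$reciprocity_min, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  scored <- data.table::rbindlist(lapply(seq_len(nrow(cand)), function(k) {
    score_pair(states[[cand[k, 1]]], states[[cand[k, 2]]], grid, config)
  }))
  scored <- scored[verdict == "sisters"]
  if (!nrow(scored)) return(empty)
  data.table::setorder(scored, -reciprocity, cell_a, cell_b)
  taken <- character()
  keep <- logical(nrow(scored))
  for (k in seq_len(nrow(scored))) {
    if (!(scored$cell_a[k] %in% taken) && !(scored$cell_b[k] %in% taken)) {
      keep[k] <- TRUE
      taken <- c(taken, scored$cell_a[k], scored$cell_b[k])
    }
  }
  scored[keep]
}

#' Check reciprocal CA segregation within a sister pair
#'
#' For each chromosome affected in either cell, CA calls on the same
#' haplotype and overlapping interval are compared: copy-number deltas
#' summing to zero are `reciprocal` (one division's gain/loss split),
#' equal deltas are `shared` (pre-existing in the parent), anything else is
#' `independent`.
#'
#' @param calls_a,calls_b `sk_calls` tables of the two sister cells.
#' @return A `data.table` with columns `chrom`, `hap`, `status`.
#' @export
reciprocal_ca_check <- function(calls_a, calls_b) {
  chroms <- union(calls_a$chrom, calls_b$chrom)
  out <- list()
  for (ch in chroms) {
    ca <- calls_a[chrom == ch]; cb <- calls_b[chrom == ch]
    haps <- union(ca$hap, cb$hap)
    for (h in haps) {
      xa <- ca[hap == h]; xb <- cb[hap == h]
      status <- "independent"
      if (nrow(xa) && nrow(xb)) {
        for (i in seq_len(nrow(xa))) {
          ov <- pmin(xb$end, xa$end[i]) - pmax(xb$start, xa$start[i])
          span <- pmin(xb$end - xb$start, xa$end[i] - xa$start[i])
          j <- which(ov >= 0.5 * span)
          if (length(j)) {
            j <- j[1]
            status <- if (xa$delta[i] + xb$delta[j] == 0) "reciprocal"
            else if (xa$delta[i] == xb$delta[j]) "shared"
            else "independent"
            break
          }
        }
      }
      out[[length(out) + 1L]] <- data.table::data.table(chrom = ch, hap = h,
                                                        status = status)
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), hap = character(),
                                  status = character()))
  data.table::rbindlist(out)
}
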