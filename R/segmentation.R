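# Haplotype-aware joint segmentation of total copy number and Watson/Crick
# composition against a population consensus.
#
# Per cell, four per-bin signals are stacked: normalized total copy number,
# overall Watson fraction, and the per-haplotype Watson fractions of tagged
# reads. Change-points come from a penalized least-squares multiple
# change-point search (PELT, compiled); each segment is then assigned the
# maximum-likelihood integer state from an enumerated space of per-haplotype
# copy numbers and strand assignments, with ties broken toward the
# consensus. A single-bin refinement scan recovers bin-sized events that sit
# below the two-change-point penalty of the global search.

# -- per-cell arrays --------------------------------------------------------

# dense per-bin arrays for one cell's counts
cell_arrays <- function(cnts, grid, H) {
  B <- nrow(grid)
  g <- grid[, .(chrom, bin, gbin)]
  x <- g[cnts, on = c("chrom", "bin")]
  tot <- numeric(B); wsum <- numeric(B)
  tw <- matrix(0, B, H); tc <- matrix(0, B, H)
  agg <- x[, .(w = sum(w), c = sum(c)), by = gbin]
  tot[agg$gbin] <- agg$w + agg$c
  wsum[agg$gbin] <- agg$w
  tg <- x[hap != "untagged", .(w = sum(w), c = sum(c)), by = .(gbin, hap)]
  if (nrow(tg)) {
    hidx <- as.integer(sub("H", "", tg$hap))
    tw[cbind(tg$gbin, hidx)] <- tg$w
    tc[cbind(tg$gbin, hidx)] <- tg$c
  }
  list(tot = tot, wsum = wsum, tw = tw, tc = tc)
}

# population blacklist: bins whose population median coverage rate is below
# blacklist_frac of the genome-wide median rate (proxy for unmappable bins)
blacklist_bins <- function(counts, grid, config = sk_config()) {
  config <- as_sk_config(config)
  B <- nrow(grid)
  g <- grid[, .(chrom, bin, gbin, width)]
  x <- g[data.table::as.data.table(counts), on = c("chrom", "bin")]
  per <- x[, .(tot = sum(w) + sum(c)), by = .(cell, gbin)]
  allbins <- data.table::CJ(cell = unique(per$cell), gbin = seq_len(B))
  per <- per[allbins, on = c("cell", "gbin")]
  per[is.na(tot), tot := 0]
  per[, rate := tot / grid$width[gbin] * grid_bin_size(grid)]
  med <- per[, .(m = median(rate)), by = gbin]
  gm <- median(med$m)
  mask <- rep(FALSE, B)
  mask[med$gbin[med$m < config$blacklist_frac * gm]] <- TRUE
  mask
}

#' Normalize strand-resolved counts
#'
#' Scales each cell's per-bin coverage so that the consensus baseline maps
#' to its integer copy number (copy number 2 for a disomic baseline), and
#' computes the pseudocounted Watson fraction per bin.
#'
#' @param counts an `sk_counts` table (QC-passing cells).
#' @param grid the bin grid.
#' @param consensus optional [build_consensus()] result; without it a
#'   diploid baseline is assumed for scaling.
#' @param config an [sk_config()].
#' @return A `data.table` with columns `cell`, `chrom`, `bin`, `total`,
#'   `y` (normalized copy number), `wfrac`.
#' @export
normalize_counts <- function(counts, grid, consensus = NULL,
                             config = sk_config()) {
  config <- as_sk_config(config)
  H <- max(grid_genome(grid)$homologues)
  base_cn <- consensus_baseline_vec(consensus, grid)
  cells <- unique(counts$cell)
  out <- lapply(cells, function(cl) {
    a <- cell_arrays(counts[cell == cl], grid, H)
    if (sum(a$tot) == 0) sk_stop("sk_qc_error", paste0("zero-coverage cell: ", cl))
    rate <- a$tot / grid$width * grid_bin_size(grid)
    rho <- median(rate / pmax(base_cn, 1))
    if (rho <= 0) sk_stop("sk_qc_error", paste0("degenerate coverage in cell: ", cl))
    data.table::data.table(
      cell = cl, chrom = grid$chrom, bin = grid$bin, total = a$tot,
      y = rate / rho, wfrac = (a$wsum + 1) / (a$tot + 2)
    )
  })
  data.table::rbindlist(out)
}

# per-bin baseline total copy number implied by a consensus (or 2)
consensus_baseline_vec <- function(consensus, grid) {
  if (is.null(consensus)) return(rep(2, nrow(grid)))
  consensus$cn_total
}

# -- consensus --------------------------------------------------------------

#' Build the population consensus karyotype
#'
#' Per-bin modal integer copy number, total and per haplotype, across all
#' cells. The consensus is the baseline against which per-cell de novo
#' deviations are called; a chromosome present at three homologues in most
#' cells gets consensus copy number 3.
#'
#' @param counts an `sk_counts` table for the population.
#' @param grid the bin grid.
#' @param config an [sk_config()].
#' @return A `data.table` of class `sk_consensus` with columns `chrom`,
#'   `bin`, `gbin`, `cn_h<h>` per haplotype and `cn_total`, plus a
#'   `blacklist` attribute (logical per bin).
#' @export
build_consensus <- function(counts, grid, config = sk_config()) {
  config <- as_sk_config(config)
  cells <- unique(counts$cell)
  if (length(cells) < config$consensus_min_cells)
    sk_stop("sk_consensus_error",
            paste0("need at least ", config$consensus_min_cells, " cells"))
  genome <- grid_genome(grid)
  H <- max(genome$homologues)
  B <- nrow(grid)
  mask <- blacklist_bins(counts, grid, config)
  est_tot <- matrix(0L, length(cells), B)
  est_hap <- array(0L, c(length(cells), B, H))
  for (i in seq_along(cells)) {
    a <- cell_arrays(counts[cell == cells[i]], grid, H)
    rate <- a$tot / grid$width * grid_bin_size(grid)
    rho <- median(rate[!mask]) / 2
    if (rho <= 0) next
    y <- rate / rho
    est_tot[i, ] <- as.integer(round(pmin(y, 12)))
    ntag <- a$tw + a$tc
    share <- (ntag + 1 / H) / (rowSums(ntag) + 1)
    for (h in seq_len(H))
      est_hap[i, , h] <- as.integer(round(pmin(y * share[, h], 12)))
  }
  colmode <- function(m) {
    # modal value per column over the small range 0..12
    cnt <- vapply(0:12, function(v) colSums(m == v), numeric(ncol(m)))
    as.integer(max.col(cnt, ties.method = "first") - 1L)
  }
  cons <- data.table::data.table(chrom = grid$chrom, bin = grid$bin,
                                 gbin = grid$gbin)
  for (h in seq_len(H))
    cons[, paste0("cn_h", h) := colmode(est_hap[, , h, drop = TRUE])]
  # smooth per-hap consensus within chromosome to its modal value: the
  # baseline is a whole-chromosome property of the population
  for (h in seq_len(H)) {
    col <- paste0("cn_h", h)
    cons[, (col) := as.integer(names(sort(-table(.SD[[1]])))[1]),
         by = chrom, .SDcols = col]
  }
  cons[, cn_total := Reduce(`+`, .SD),
       .SDcols = paste0("cn_h", seq_len(H))]
  data.table::setattr(cons, "blacklist", mask)
  data.table::setattr(cons, "n_hap", H)
  data.table::setattr(cons, "class", c("sk_consensus", class(cons)))
  cons[]
}

#' Consensus implied by a genome model's baseline
#'
#' Builds the consensus table directly from the genome's baseline homologue
#' counts (one copy per homologue, no blacklisted bins) - the reference for
#' segmenting single cells when no population is available.
#'
#' @param genome an [genome_model()].
#' @param grid the matching bin grid.
#' @return An `sk_consensus`.
#' @export
consensus_from_genome <- function(genome, grid) {
  H <- max(genome$homologues)
  cons <- data.table::data.table(chrom = grid$chrom, bin = grid$bin,
                                 gbin = grid$gbin)
  hom <- genome$homologues[match(grid$chrom, genome$chrom)]
  for (h in seq_len(H)) cons[, paste0("cn_h", h) := as.integer(hom >= h)]
  cons[, cn_total := as.integer(hom)]
  data.table::setattr(cons, "blacklist", rep(FALSE, nrow(grid)))
  data.table::setattr(cons, "n_hap", H)
  data.table::setattr(cons, "class", c("sk_consensus", class(cons)))
  cons[]
}

# -- state space ------------------------------------------------------------

.state_env <- new.env(parent = emptyenv())

# enumerate integer states: per haplotype a copy number cn_h (0..cap_total)
# and a count w_h (0..cn_h) of copies emitting Watson; total <= cap
state_space <- function(H, cap) {
  key <- paste0("S", H, "_", cap)
  if (!is.null(.state_env[[key]])) return(.state_env[[key]])
  per_hap <- do.call(rbind, lapply(0:cap, function(cn)
    cbind(cn = cn, w = 0:cn)))
  idx <- rep(list(seq_len(nrow(per_hap))), H)
  gridx <- as.matrix(do.call(expand.grid, idx))
  cn <- matrix(per_hap[gridx, "cn"], ncol = H)
  w <- matrix(per_hap[gridx, "w"], ncol = H)
  keep <- rowSums(cn) <= cap
  st <- list(cn = cn[keep, , drop = FALSE], w = w[keep, , drop = FALSE])
  st$cn_tot <- rowSums(st$cn)
  st$w_tot <- rowSums(st$w)
  .state_env[[key]] <- st
  st
}

# log-likelihood of every state for one segment summary
state_loglik <- function(st, T_all, W_all, ntag, wtag, rho, nb_eff, eps) {
  H <- ncol(st$cn)
  mu <- pmax(rho * st$cn_tot * nb_eff, 0.02 * rho * nb_eff)
  ll <- dnbinom(T_all, size = mu, mu = mu, log = TRUE)
  pw <- ifelse(st$cn_tot > 0, st$w_tot / st$cn_tot, 0.5)
  pw <- pw * (1 - 2 * eps) + eps
  ll <- ll + dbinom(W_all, T_all, pw, log = TRUE)
  cn_tot_f <- pmax(st$cn_tot, 1e-9)
  for (h in seq_len(H)) {
    ph <- (st$cn[, h] + 0.05) / (cn_tot_f + 0.05 * H)
    ll <- ll + ntag[h] * log(ph)
    pwh <- ifelse(st$cn[, h] > 0, st$w[, h] / pmax(st$cn[, h], 1), 0.5)
    pwh <- pwh * (1 - 2 * eps) + eps
    ll <- ll + dbinom(wtag[h], ntag[h], pwh, log = TRUE)
  }
  ll
}

# -- segmentation -----------------------------------------------------------

# robust per-dimension noise scale from successive differences within
# chromosomes
diff_scale <- function(v, chrom_f) {
  d <- unlist(lapply(split(v, chrom_f), diff), use.names = FALSE)
  s <- median(abs(d)) * 1.4826 / sqrt(2)
  max(s, 1e-3)
}

#' Segment one cell into copy-number / strand-state segments
#'
#' @param counts an `sk_counts` table containing the cell (other cells are
#'   ignored when `cell_id` is given).
#' @param grid the bin grid.
#' @param consensus a [build_consensus()] result, or NULL for a diploid
#'   baseline without blacklisting.
#' @param cell_id which cell to segment (defaults to the only cell present).
#' @param config an [sk_config()]; `config$penalty` (> 0) scales the
#'   per-change-point penalty `penalty * d * log(n)`.
#' @return A `data.table` of class `sk_track`: one row per segment with the
#'   assigned per-haplotype copy numbers (`cn_h<h>`), Watson/Crick copy
#'   split (`w_h<h>`, `c_h<h>`), total copy number, strand label and an
#'   `at_cap` flag.
#' @export
segment_cell <- function(counts, grid, consensus = NULL, cell_id = NULL,
                         config = sk_config()) {
  config <- as_sk_config(config)
  if (config$penalty <= 0) sk_parameter_error("segmentation penalty must be > 0")
  if (is.null(cell_id)) {
    cell_id <- unique(counts$cell)
    if (length(cell_id) != 1L)
      sk_parameter_error("cell_id required when counts hold several cells")
  }
  genome <- grid_genome(grid)
  H <- max(genome$homologues)
  a <- cell_arrays(counts[cell == cell_id], grid, H)
  if (sum(a$tot) == 0) sk_stop("sk_qc_error", paste0("zero-coverage cell: ", cell_id))
  mask <- if (is.null(consensus)) rep(FALSE, nrow(grid))
  else attr(consensus, "blacklist", exact = TRUE)
  base_cn <- consensus_baseline_vec(consensus, grid)
  cons_cn <- consensus_hap_matrix(consensus, grid, H)

  rate <- a$tot / grid$width * grid_bin_size(grid)
  rho2 <- median((rate / pmax(base_cn, 1))[!mask])
  if (rho2 <= 0) sk_stop("sk_qc_error", paste0("degenerate coverage: ", cell_id))
  y <- rate / rho2
  # change-points are searched on the two high-count signals: normalized
  # total copy number and overall Watson fraction, both variance-stabilized
  # (square root for the overdispersed counts, arcsine-square-root for the
  # fraction) so one pooled noise scale holds across WW, WC and CC
  # chromosomes. The sparse per-haplotype tag counts are too heteroscedastic
  # for a pooled-scale cost and enter only in the per-segment state
  # likelihood.
  sig <- cbind(sqrt(pmax(y, 0)), asin(sqrt((a$wsum + 1) / (a$tot + 2))))
  chrom_f <- factor(grid$chrom, levels = unique(grid$chrom))
  scl <- apply(sig, 2, diff_scale, chrom_f = chrom_f)
  sigz <- sweep(sig, 2, scl, "/")
  d <- ncol(sigz)
  st <- state_space(H, config$cn_cap)
  eps <- config$bg_flip
  B <- nrow(grid)
  thr_single <- qchisq(1 - config$single_bin_alpha / B, df = 2)

  out <- list()
  for (ch in unique(grid$chrom)) {
    idx <- grid[chrom == ch, gbin]
    keep <- idx[!mask[idx]]
    n <- length(keep)
    if (n == 0L) next
    pen <- config$penalty * d * log(max(n, 2))
    cps <- .pelt_cpp(sigz[keep, , drop = FALSE], pen)
    bounds <- c(0L, cps, n)
    segs <- data.table::data.table(
      from = keep[bounds[-length(bounds)] + 1L],
      to = keep[bounds[-1L]]
    )
    # assign ML state per segment
    assign_state <- function(bins) {
      T_all <- sum(a$tot[bins]); W_all <- sum(a$wsum[bins])
      ntag <- colSums(a$tw[bins, , drop = FALSE] + a$tc[bins, , drop = FALSE])
      wtag <- colSums(a$tw[bins, , drop = FALSE])
      nb_eff <- sum(grid$width[bins]) / grid_bin_size(grid)
      ll <- state_loglik(st, T_all, W_all, ntag, wtag, rho2, nb_eff, eps)
      cc <- round(colMeans(cons_cn[bins, , drop = FALSE]))
      dist <- rowSums(abs(sweep(st$cn, 2, cc)))
      which.max(ll - 1e-6 * dist)
    }
    seg_state <- integer(nrow(segs))
    for (k in seq_len(nrow(segs))) {
      bins <- setdiff(seq(segs$from[k], segs$to[k]), idx[mask[idx]])
      seg_state[k] <- assign_state(bins)
    }
    # single-bin refinement: isolate bins whose own counts strongly prefer
    # a different *total* copy number than the host segment. The acceptance
    # statistic uses only the total-count and overall-strand components
    # (large counts, well approximated by the chi-square reference); the
    # haplotype placement of the accepted state is then chosen by the full
    # likelihood. Alternatives that merely move copies between haplotypes
    # are never accepted: a bin-sized event must change total copy number.
    refined_from <- integer(); refined_state <- integer()
    if (n >= 3L) {
      for (k in seq_len(nrow(segs))) {
        bins <- setdiff(seq(segs$from[k], segs$to[k]), idx[mask[idx]])
        if (length(bins) < 2L) next
        s0 <- seg_state[k]
        alts <- neighbor_states(st, s0, config$cn_cap)
        if (!length(alts)) next
        same_tot <- alts[st$cn_tot[alts] == st$cn_tot[s0]]
        diff_tot <- alts[st$cn_tot[alts] != st$cn_tot[s0]]
        if (!length(diff_tot)) next
        cand <- c(s0, same_tot, diff_tot)
        is_diff <- c(FALSE, rep(FALSE, length(same_tot)),
                     rep(TRUE, length(diff_tot)))
        stc <- lapply_states(st, cand)
        S <- length(cand); nb <- length(bins)
        Tb <- a$tot[bins]; Wb <- a$wsum[bins]
        nbe <- grid$width[bins] / grid_bin_size(grid)
        mu <- pmax(outer(nbe, stc$cn_tot) * rho2, 0.02 * rho2 * nbe)
        ll0 <- matrix(dnbinom(rep(Tb, S), size = mu, mu = mu, log = TRUE), nb, S)
        pw <- ifelse(stc$cn_tot > 0, stc$w_tot / pmax(stc$cn_tot, 1L), 0.5)
        pw <- pw * (1 - 2 * eps) + eps
        ll0 <- ll0 + matrix(dbinom(rep(Wb, S), rep(Tb, S),
                                   rep(pw, each = nb), log = TRUE), nb, S)
        # full likelihood (adds haplotype terms) for placement only
        llf <- ll0
        cn_tot_f <- pmax(stc$cn_tot, 1e-9)
        for (h in seq_len(H)) {
          nth <- a$tw[bins, h] + a$tc[bins, h]
          wth <- a$tw[bins, h]
          ph <- (stc$cn[, h] + 0.05) / (cn_tot_f + 0.05 * H)
          llf <- llf + outer(nth, log(ph))
          pwh <- ifelse(stc$cn[, h] > 0, stc$w[, h] / pmax(stc$cn[, h], 1L), 0.5)
          pwh <- pwh * (1 - 2 * eps) + eps
          llf <- llf + matrix(dbinom(rep(wth, S), rep(nth, S),
                                     rep(pwh, each = nb), log = TRUE), nb, S)
        }
        # a copy-number-changing alternative must beat both the host state
        # and every same-total strand rearrangement (a stray bin at a
        # mislocalized SCE boundary is explained by the latter, not by a CA)
        best_null <- apply(ll0[, !is_diff, drop = FALSE], 1L, max)
        ll_diff <- ll0[, is_diff, drop = FALSE]
        best_d <- max.col(ll_diff, ties.method = "first")
        dev <- 2 * (ll_diff[cbind(seq_len(nb), best_d)] - best_null)
        hit <- which(dev > thr_single)
        if (length(hit)) {
          diff_cols <- which(is_diff)
          pick <- vapply(hit, function(i) {
            tgt <- stc$cn_tot[diff_cols[best_d[i]]]
            cols <- which(stc$cn_tot == tgt)
            cols[which.max(llf[i, cols])]
          }, integer(1))
          refined_from <- c(refined_from, bins[hit])
          refined_state <- c(refined_state, cand[pick])
        }
      }
    }
    # rebuild the segment list with refined single bins spliced in
    pieces <- data.table::data.table(from = segs$from, to = segs$to,
                                     state = seg_state)
    for (j in seq_along(refined_from)) {
      b <- refined_from[j]
      hit <- which(pieces$from <= b & pieces$to >= b)[1]
      row <- pieces[hit]
      add <- list()
      if (row$from < b) add <- c(add, list(data.table::data.table(
        from = row$from, to = b - 1L, state = row$state)))
      add <- c(add, list(data.table::data.table(
        from = b, to = b, state = refined_state[j])))
      if (row$to > b) add <- c(add, list(data.table::data.table(
        from = b + 1L, to = row$to, state = row$state)))
      pieces <- rbind(pieces[-hit], data.table::rbindlist(add))
      data.table::setorder(pieces, from)
    }
    # merge adjacent segments with identical assigned state
    m <- nrow(pieces)
    keep_row <- c(TRUE, pieces$state[-1L] != pieces$state[-m])
    grp <- cumsum(keep_row)
    merged <- pieces[, .(from = min(from), to = max(to)),
                     by = .(grp = grp, state = state)]
    # re-assign merged segments (state may sharpen with pooled reads)
    for (k in seq_len(nrow(merged))) {
      bins <- setdiff(seq(merged$from[k], merged$to[k]), idx[mask[idx]])
      merged$state[k] <- assign_state(bins)
    }
    m <- nrow(merged)
    keep_row <- c(TRUE, merged$state[-1L] != merged$state[-m])
    grp2 <- cumsum(keep_row)
    merged <- merged[, .(from = min(from), to = max(to)),
                     by = .(grp = grp2, state = state)]
    for (k in seq_len(nrow(merged))) {
      s <- merged$state[k]
      bins <- seq(merged$from[k], merged$to[k])
      ymean <- mean(y[setdiff(bins, idx[mask[idx]])])
      row <- data.table::data.table(
        cell = cell_id, chrom = ch,
        start_bin = grid$bin[merged$from[k]], end_bin = grid$bin[merged$to[k]],
        start = grid$start[merged$from[k]], end = grid$end[merged$to[k]],
        n_bins = merged$to[k] - merged$from[k] + 1L,
        cn_total = st$cn_tot[s],
        strand_label = state_label(st, s),
        at_cap = st$cn_tot[s] >= config$cn_cap & ymean > config$cn_cap + 0.5
      )
      for (h in seq_len(H)) {
        row[, paste0("cn_h", h) := st$cn[s, h]]
        row[, paste0("w_h", h) := st$w[s, h]]
        row[, paste0("c_h", h) := st$cn[s, h] - st$w[s, h]]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  track <- data.table::rbindlist(out)
  data.table::setattr(track, "n_hap", H)
  data.table::setattr(track, "class", c("sk_track", class(track)))
  track[]
}

# subset a state space to chosen row indices (keeps the same structure)
lapply_states <- function(st, rows) {
  list(cn = st$cn[rows, , drop = FALSE], w = st$w[rows, , drop = FALSE],
       cn_tot = st$cn_tot[rows], w_tot = st$w_tot[rows])
}

# indices of states reachable from s0 by +-1 copy on one haplotype (any
# strand placement) or a balanced +2; used by the single-bin scan
neighbor_states <- function(st, s0, cap) {
  H <- ncol(st$cn)
  cn0 <- st$cn[s0, ]; w0 <- st$w[s0, ]
  cand <- list()
  for (h in seq_len(H)) {
    for (dcn in c(-1L, 1L, 2L)) {
      ncn <- cn0; ncn[h] <- ncn[h] + dcn
      if (ncn[h] < 0L || sum(ncn) > cap) next
      wopts <- if (dcn > 0) 0:dcn else unique(pmax(w0[h] + dcn, 0L):min(w0[h], ncn[h]))
      for (dw in wopts) {
        nw <- w0
        nw[h] <- if (dcn > 0) w0[h] + dw else dw
        if (nw[h] > ncn[h] || nw[h] < 0L) next
        hit <- which(rowSums(st$cn == matrix(ncn, nrow(st$cn), H, byrow = TRUE)) == H &
                       rowSums(st$w == matrix(nw, nrow(st$w), H, byrow = TRUE)) == H)
        if (length(hit)) cand[[length(cand) + 1L]] <- hit[1L]
      }
    }
  }
  setdiff(unique(unlist(cand)), s0)
}

state_label <- function(st, s) {
  wn <- st$w_tot[s]; cn <- st$cn_tot[s] - wn
  if (wn + cn == 0) return("none")
  paste0(strrep("W", wn), strrep("C", cn))
}

# per-bin consensus haplotype copy-number matrix (defaults to 1 copy per
# haplotype up to the chromosome's homologue count)
consensus_hap_matrix <- function(consensus, grid, H) {
  B <- nrow(grid)
  if (is.null(consensus)) {
    genome <- grid_genome(grid)
    hom <- genome$homologues[match(grid$chrom, genome$chrom)]
    m <- matrix(0L, B, H)
    for (h in seq_len(H)) m[, h] <- as.integer(hom >= h)
    return(m)
  }
  as.matrix(consensus[, paste0("cn_h", seq_len(H)), with = FALSE])
}

#' Segment every cell of a population
#'
#' @inheritParams segment_cell
#' @param cells optional subset of cell ids.
#' @return An `sk_track` with all cells' segments.
#' @export
segment_population <- function(counts, grid, consensus = NULL, cells = NULL,
                               config = sk_config()) {
  if (is.null(cells)) cells <- unique(counts$cell)
  tracks <- lapply(cells, function(cl)
    segment_cell(counts[cell == cl], grid, consensus, cl, config))
  track <- data.table::rbindlist(tracks)
  data.table::setattr(track, "n_hap", attr(tracks[[1]], "n_hap", exact = TRUE))
  data.table::setattr(track, "class", c("sk_track", class(track)))
  track[]
}
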