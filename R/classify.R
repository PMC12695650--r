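# CA taxonomy classifier: maps per-cell segment tracks to abnormality
# classes by comparing per-haplotype copy number against the population
# consensus, then annotates strand-informative subtypes.
#
# Decision tree per (chromosome, haplotype):
#   1. one deviating run covering the whole chromosome -> chromosome gain/loss
#   2. >= K oscillating switches between exactly two copy-number states
#      -> chromothripsis
#   3. >= 2 deviating runs forming one contiguous telomere-anchored block on
#      a single arm -> terminal multi-step (includes localized oscillations
#      alongside terminal events)
#   4. > 2 breakpoints not resolved above -> complex
#   5. single telomere-anchored run -> terminal gain/loss; single interior
#      run -> interstitial gain/loss

CALL_CLASSES <- c("chromosome_gain", "chromosome_loss", "terminal_gain",
                  "terminal_loss", "interstitial_gain", "interstitial_loss",
                  "terminal_multistep", "complex", "chromothripsis")

empty_calls <- function(H = 2L) {
  dt <- data.table::data.table(
    cell = character(), chrom = character(), start = numeric(),
    end = numeric(), hap = character(), delta = integer(),
    strand_config = character(), class = character(),
    annotations = character(), n_breakpoints = integer()
  )
  data.table::setattr(dt, "class", c("sk_calls", class(dt)))
  dt
}

add_annotation <- function(ann, new) {
  ifelse(ann == "", new, paste(ann, new, sep = ","))
}

has_annotation <- function(calls, name) {
  vapply(strsplit(calls$annotations, ","), function(x) name %in% x, logical(1))
}

# expand an sk_track to per-bin haplotype copy matrices for one chromosome
track_bins <- function(track_ch, nb, H) {
  cn <- matrix(NA_integer_, nb, H)
  wm <- matrix(NA_integer_, nb, H)
  for (k in seq_len(nrow(track_ch))) {
    rng <- track_ch$start_bin[k]:track_ch$end_bin[k]
    for (h in seq_len(H)) {
      cn[rng, h] <- track_ch[[paste0("cn_h", h)]][k]
      wm[rng, h] <- track_ch[[paste0("w_h", h)]][k]
    }
  }
  list(cn = cn, w = wm)
}

# host-homologue template strand in [lo, hi] bins: taken from the nearest
# segment of the same haplotype carrying exactly one copy
host_template <- function(track_ch, h, lo, hi) {
  cnh <- track_ch[[paste0("cn_h", h)]]
  one <- which(cnh == 1L)
  if (!length(one)) return(NA_character_)
  mid <- (lo + hi) / 2
  centers <- (track_ch$start_bin[one] + track_ch$end_bin[one]) / 2
  k <- one[which.min(abs(centers - mid))]
  if (track_ch[[paste0("w_h", h)]][k] == 1L) "W" else "C"
}

# strand configuration of the copies gained relative to the consensus
strand_config_of <- function(track_ch, h, lo, hi, cons_h) {
  seg <- track_ch[start_bin <= hi & end_bin >= lo]
  cnh <- seg[[paste0("cn_h", h)]]
  wh <- seg[[paste0("w_h", h)]]
  if (length(unique(paste(cnh, wh))) != 1L) return("mixed")
  extra <- cnh[1] - cons_h
  if (extra <= 0) return(NA_character_)
  tpl <- host_template(track_ch, h, lo, hi)
  if (is.na(tpl)) return("mixed")
  extra_w <- wh[1] - as.integer(tpl == "W")
  extra_c <- (cnh[1] - wh[1]) - as.integer(tpl == "C")
  if (extra_w < 0 || extra_c < 0) return("mixed")
  if (extra_c == 0) { if (tpl == "W") "same" else "opposite" }
  else if (extra_w == 0) { if (tpl == "C") "same" else "opposite" }
  else if (extra_w == extra_c) "balanced"
  else "mixed"
}

#' Classify one cell's segment track into CA calls
#'
#' Deviating runs of per-haplotype copy number versus the consensus are
#' merged and mapped onto the CA taxonomy (see the package vignette for the
#' full decision tree). Whole-arm (> 90 percent of an arm) and
#' amplification (delta >= +2) annotations are attached, as is the inverted
#' duplication annotation for opposite-strand terminal gains and, when a
#' locus is supplied, an on-breakpoint annotation for calls with a
#' breakpoint within one bin of it.
#'
#' @param track an `sk_track` for one cell.
#' @param consensus a [build_consensus()] result (or NULL for the genome
#'   baseline).
#' @param grid the bin grid.
#' @param config an [sk_config()].
#' @param locus optional `"chrom:pos"` string for on-breakpoint annotation.
#' @return An `sk_calls` data.table.
#' @export
classify_cell <- function(track, consensus, grid, config = sk_config(),
                          locus = NULL) {
  config <- as_sk_config(config)
  genome <- grid_genome(grid)
  H <- attr(track, "n_hap", exact = TRUE)
  if (is.null(H)) H <- max(genome$homologues)
  if (!is.null(consensus) && !identical(nrow(consensus), nrow(grid)))
    sk_model_error("consensus and grid do not share a bin grid")
  cons_m <- consensus_hap_matrix(consensus, grid, H)
  cell_id <- unique(track$cell)
  if (length(cell_id) != 1L) sk_parameter_error("classify_cell takes one cell's track")
  bs <- grid_bin_size(grid)
  loc <- parse_locus(locus)
  out <- list()

  for (ch in unique(track$chrom)) {
    idx <- grid[chrom == ch, gbin]
    nb <- length(idx)
    track_ch <- track[chrom == ch]
    tb <- track_bins(track_ch, nb, H)
    gi <- match(ch, genome$chrom)
    cen <- genome$centromere[gi]
    len <- genome$length[gi]
    starts <- grid$start[idx]; ends <- grid$end[idx]

    for (h in seq_len(H)) {
      cons_h <- cons_m[idx, h]
      cnh <- tb$cn[, h]
      if (anyNA(cnh)) next
      delta_b <- cnh - cons_h
      r <- rle(delta_b)
      rends <- cumsum(r$lengths)
      rstarts <- c(1L, head(rends, -1L) + 1L)
      runs <- data.table::data.table(from = rstarts, to = rends,
                                     delta = r$values)
      dev <- runs[delta != 0L]
      if (!nrow(dev)) next
      # adjacent deviating runs of the same sign collapse into one event
      # (an isolated gain whose interior carries an extra amplified step is
      # still one isolated gain; the dominant delta labels it)
      if (nrow(dev) > 1L) {
        adj <- c(FALSE, dev$from[-1L] == dev$to[-nrow(dev)] + 1L &
                   sign(dev$delta[-1L]) == sign(dev$delta[-nrow(dev)]))
        grp <- cumsum(!adj)
        dev <- dev[, {
          wts <- to - from + 1L
          dsum <- tapply(wts, delta, sum)
          .(from = min(from), to = max(to),
            delta = as.integer(names(dsum)[which.max(dsum)]))
        }, by = grp][, grp := NULL]
      }

      mk_call <- function(lo, hi, cls, delta, n_bp) {
        sc <- if (delta > 0) strand_config_of(track_ch, h, lo, hi,
                                              round(mean(cons_h[lo:hi])))
        else NA_character_
        data.table::data.table(
          cell = cell_id, chrom = ch, start = starts[lo], end = ends[hi],
          hap = paste0("H", h), delta = as.integer(delta),
          strand_config = sc, class = cls, annotations = "",
          n_breakpoints = as.integer(n_bp)
        )
      }

      span_lo <- min(dev$from); span_hi <- max(dev$to)
      # (1) whole-chromosome uniform deviation
      if (nrow(dev) == 1L && dev$from == 1L && dev$to == nb) {
        cls <- if (dev$delta > 0) "chromosome_gain" else "chromosome_loss"
        out[[length(out) + 1L]] <- mk_call(1L, nb, cls, dev$delta, 0L)
        next
      }
      # (2) chromothripsis: oscillation between two copy-number states
      span_runs <- runs[to >= span_lo & from <= span_hi]
      vals <- span_runs[, .(bins = sum(to - from + 1L)), by = .(cn = delta + cons_h[from])]
      data.table::setorder(vals, -bins)
      n_trans <- nrow(span_runs) - 1L
      if (nrow(vals) >= 2L) {
        top2 <- sum(vals$bins[1:2]) / sum(vals$bins)
        if (n_trans >= config$chromothripsis_k &&
            (nrow(vals) == 2L || top2 >= 0.95)) {
          dmin <- dev$delta[which.max(abs(dev$delta))]
          cl <- mk_call(span_lo, span_hi, "chromothripsis", dmin,
                        n_bp = n_trans)
          out[[length(out) + 1L]] <- cl
          next
        }
      }
      # breakpoints: deviating-run edges not at a chromosome end
      edges <- unique(c(dev$from - 1L, dev$to))
      n_bp <- sum(edges > 0L & edges < nb)
      # (3) terminal multi-step: >= 2 deviating runs forming one contiguous
      # telomere-anchored block on a single arm
      contiguous <- nrow(dev) >= 2L &&
        all(dev$from[-1L] == dev$to[-nrow(dev)] + 1L)
      touches_tel <- span_lo == 1L || span_hi == nb
      one_arm <- (ends[span_hi] <= cen) || (starts[span_lo] >= cen)
      if (contiguous && touches_tel && one_arm) {
        tdelta <- if (span_lo == 1L) dev$delta[1L] else dev$delta[nrow(dev)]
        out[[length(out) + 1L]] <- mk_call(span_lo, span_hi,
                                           "terminal_multistep", tdelta, n_bp)
        next
      }
      # (4) complex: > 2 breakpoints not resolvable as terminal multi-step
      if (n_bp > 2L) {
        out[[length(out) + 1L]] <- mk_call(span_lo, span_hi, "complex",
                                           0L, n_bp)
        next
      }
      # (5)/(6) isolated simple runs
      for (k in seq_len(nrow(dev))) {
        lo <- dev$from[k]; hi <- dev$to[k]
        terminal <- lo == 1L || hi == nb
        cls <- if (terminal) {
          if (dev$delta[k] > 0) "terminal_gain" else "terminal_loss"
        } else {
          if (dev$delta[k] > 0) "interstitial_gain" else "interstitial_loss"
        }
        out[[length(out) + 1L]] <- mk_call(lo, hi, cls, dev$delta[k],
                                           if (terminal) 1L else 2L)
      }
    }
  }
  calls <- if (length(out)) data.table::rbindlist(out) else empty_calls(H)
  data.table::setattr(calls, "class", c("sk_calls", class(calls)))
  calls <- annotate_simple(calls, genome, config)
  calls <- annotate_inverted_duplication(calls, track)
  if (!is.null(loc)) calls <- annotate_on_breakpoint(calls, loc, bs)
  calls[]
}

parse_locus <- function(locus) {
  if (is.null(locus)) return(NULL)
  parts <- strsplit(locus, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) sk_parameter_error("locus must be 'chrom:pos'")
  list(chrom = parts[1], pos = as.numeric(parts[2]))
}

# whole-arm and amplification annotations
annotate_simple <- function(calls, genome, config) {
  if (!nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    cls <- calls$class[i]
    gi <- match(calls$chrom[i], genome$chrom)
    cen <- genome$centromere[gi]; len <- genome$length[gi]
    if (cls %in% c("terminal_gain", "terminal_loss", "interstitial_gain",
                   "interstitial_loss")) {
      p_ov <- max(0, min(calls$end[i], cen) - max(calls$start[i], 0)) / cen
      q_ov <- max(0, min(calls$end[i], len) - max(calls$start[i], cen)) /
        (len - cen)
      if (max(p_ov, q_ov) > config$whole_arm_frac)
        calls$annotations[i] <- add_annotation(calls$annotations[i], "whole_arm")
    }
    if (!is.na(calls$delta[i]) && calls$delta[i] >= 2L &&
        cls %in% c("terminal_gain", "interstitial_gain", "chromosome_gain"))
      calls$annotations[i] <- add_annotation(calls$annotations[i], "amplification")
  }
  calls
}

#' Annotate opposite-strand terminal gains as inverted duplications
#'
#' A terminal gain is an inverted duplication when the gained copy emits
#' reads on the strand opposite to the host homologue's template in that
#' interval, the footprint of breakage-fusion-bridge intermediates.
#'
#' @param calls an `sk_calls` table.
#' @param track the `sk_track` the calls were derived from (unused beyond
#'   the strand configuration already recorded on the calls, kept for
#'   interface symmetry).
#' @return The calls with `inverted_duplication` added where it applies.
#' @export
annotate_inverted_duplication <- function(calls, track = NULL) {
  if (!nrow(calls)) return(calls)
  hit <- calls$class == "terminal_gain" & !is.na(calls$strand_config) &
    calls$strand_config == "opposite"
  calls$annotations[hit] <- add_annotation(calls$annotations[hit],
                                           "inverted_duplication")
  calls
}

annotate_on_breakpoint <- function(calls, loc, bs) {
  if (!nrow(calls)) return(calls)
  near <- function(x) abs(x - loc$pos) <= bs
  hit <- calls$chrom == loc$chrom & (near(calls$start) | near(calls$end))
  calls$annotations[hit] <- add_annotation(calls$annotations[hit],
                                           "on_breakpoint")
  calls
}

#' Detect the isoacentric (balanced Watson/Crick) gain signature
#'
#' Isoacentric derivatives - two inverted copies of an acentric fragment
#' fused at the break site - segregate and amplify in multiples of two and
#' add Watson and Crick template copies in equal number. A gain with even
#' delta whose Watson and Crick copy increments are equal (and, when raw
#' counts are supplied, whose read-level Watson fraction is compatible with
#' the balanced state by a two-sided binomial test at `config$iso_alpha`)
#' receives the `isoacentric_signature` annotation.
#'
#' @param calls an `sk_calls` table.
#' @param track the corresponding `sk_track` (strand configurations).
#' @param counts optional `sk_counts` for the read-level tolerance test.
#' @param grid the bin grid (required with `counts`).
#' @param config an [sk_config()].
#' @return list with `calls` (annotated), `n_balanced`, `n_total` - the
#'   cohort tally for the exact binomial test.
#' @export
detect_isoacentric_signature <- function(calls, track = NULL, counts = NULL,
                                         grid = NULL, config = sk_config()) {
  config <- as_sk_config(config)
  if (!nrow(calls))
    return(list(calls = calls, n_balanced = 0L, n_total = 0L))
  eligible <- which(!is.na(calls$delta) & calls$delta >= 2L &
                      calls$delta %% 2L == 0L &
                      calls$class %in% c("terminal_gain", "interstitial_gain",
                                         "chromosome_gain"))
  n_bal <- 0L
  for (i in eligible) {
    bal <- !is.na(calls$strand_config[i]) && calls$strand_config[i] == "balanced"
    if (bal && !is.null(counts) && !is.null(grid) && !is.null(track)) {
      sub <- counts[cell == calls$cell[i] & chrom == calls$chrom[i] &
                      start >= calls$start[i] & end <= calls$end[i]]
      W <- sum(sub$w); Tt <- W + sum(sub$c)
      seg <- track[cell == calls$cell[i] & chrom == calls$chrom[i] &
                     start < calls$end[i] & end > calls$start[i]]
      if (Tt > 0 && nrow(seg)) {
        # expected Watson fraction under the assigned balanced state: the
        # W/C-symmetric increments sit on top of the (possibly one-sided)
        # baseline copies
        H <- sum(grepl("^cn_h[0-9]+$", names(seg)))
        wcols <- paste0("w_h", seq_len(H)); ccols <- paste0("c_h", seq_len(H))
        wl <- sum(vapply(wcols, function(cl) sum(seg[[cl]] * seg$n_bins), 0))
        cl_ <- sum(vapply(ccols, function(cl) sum(seg[[cl]] * seg$n_bins), 0))
        p <- wl / (wl + cl_)
        p <- p * (1 - 2 * config$bg_flip) + config$bg_flip
        # quasi-binomial: per-copy totals are negative-binomial, so the
        # W/C split is overdispersed by about the count dispersion factor
        phi <- max(config$dispersion, 1)
        bal <- binom_exact_two_sided(round(W / phi), round(Tt / phi), p) >=
          config$iso_alpha
      }
    }
    if (bal) {
      n_bal <- n_bal + 1L
      calls$annotations[i] <- add_annotation(calls$annotations[i],
                                             "isoacentric_signature")
    }
  }
  list(calls = calls, n_balanced = n_bal, n_total = length(eligible))
}

#' Per-class breakdown of CA calls
#'
#' @param calls an `sk_calls` table.
#' @return list of class `sk_breakdown` with `classes` (class, n, pct),
#'   `annotations` (annotation, n, pct of all calls), `chromosomes`
#'   (chrom, n) and `total`. Percentages are reported to one decimal.
#' @export
class_breakdown <- function(calls) {
  total <- nrow(calls)
  if (!total) {
    return(structure(list(
      classes = data.table::data.table(class = character(), n = integer(),
                                       pct = numeric()),
      annotations = data.table::data.table(annotation = character(),
                                           n = integer(), pct = numeric()),
      chromosomes = data.table::data.table(chrom = character(), n = integer()),
      total = 0L), class = "sk_breakdown"))
  }
  cl <- data.table::as.data.table(calls)[, .(n = .N), by = class]
  cl[, pct := round(100 * n / total, 1)]
  ann <- data.table::rbindlist(lapply(strsplit(calls$annotations, ","),
                                      function(x) data.table::data.table(annotation = x)))
  ann <- ann[annotation != ""][, .(n = .N), by = annotation]
  ann[, pct := round(100 * n / total, 1)]
  chr <- data.table::as.data.table(calls)[, .(n = .N), by = chrom]
  structure(list(classes = cl[], annotations = ann[], chromosomes = chr[],
                 total = total), class = "sk_breakdown")
}

#' Filter calls below the detection minimum size
#'
#' Intermediate-coverage strand-resolved sequencing cannot resolve events
#' below about one bin; calls narrower than `min_size` are removed
#' (chromothripsis events are judged by their total affected span).
#'
#' @param calls an `sk_calls` table.
#' @param min_size minimum interval size in bp (default 200 kb).
#' @return The filtered calls.
#' @export
filter_min_size <- function(calls, min_size = 200000) {
  if (!nrow(calls)) return(calls)
  keep <- (calls$end - calls$start) >= min_size
  out <- calls[keep]
  data.table::setattr(out, "class", unique(c("sk_calls", class(out))))
  out
}

#' Classify every cell of a population
#'
#' Runs [classify_cell()] per cell, applies the isoacentric signature
#' detector and the minimum-size filter.
#'
#' @param tracks an `sk_track` for the population.
#' @param consensus a [build_consensus()] result.
#' @param grid the bin grid.
#' @param counts optional `sk_counts` for the isoacentric read-level test.
#' @param config an [sk_config()].
#' @param locus optional `"chrom:pos"` for on-breakpoint annotation.
#' @return An `sk_calls` table for all cells.
#' @export
classify_population <- function(tracks, consensus, grid, counts = NULL,
                                config = sk_config(), locus = NULL) {
  config <- as_sk_config(config)
  cells <- unique(tracks$cell)
  calls <- data.table::rbindlist(lapply(cells, function(cl) {
    tr <- tracks[cell == cl]
    data.table::setattr(tr, "n_hap", attr(tracks, "n_hap", exact = TRUE))
    classify_cell(tr, consensus, grid, config, locus)
  }))
  if (!nrow(calls)) return(empty_calls())
  data.table::setattr(calls, "class", c("sk_calls", class(calls)))
  iso <- detect_isoacentric_signature(calls, tracks, counts, grid, config)
  filter_min_size(iso$calls, config$min_size)
}

#' Write / read a CA call table TSV
#'
#' @param calls an `sk_calls` table.
#' @param path file path.
#' @export
write_calls_table <- function(calls, path) {
  out <- data.table::as.data.table(calls)
  data.table::setorderv(out, c("cell", "chrom", "start"))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_calls_table
#' @export
read_calls_table <- function(path) {
  if (!file.exists(path)) sk_io_error(paste0("no such file: ", path))
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("annotations",
                                                          "strand_config")))
  dt[is.na(annotations), annotations := ""]
  data.table::setattr(dt, "class", c("sk_calls", class(dt)))
  dt[]
}

#' Match classifier calls against a generator truth table
#'
#' For every injected event, looks for a call of the expected class (and
#' required annotation) on the same cell, chromosome and haplotype whose
#' interval overlaps at least half of the truth interval.
#'
#' @param calls an `sk_calls` table.
#' @param truth the `events` truth table from [simulate_population()].
#' @return The truth table with columns `matched` (any overlapping call)
#'   and `recovered` (class and annotation as expected).
#' @export
match_calls_to_truth <- function(calls, truth) {
  exp_map <- function(cls, delta) {
    switch(cls,
      chromosome_gain = list(cl = "chromosome_gain", ann = NA),
      chromosome_loss = list(cl = "chromosome_loss", ann = NA),
      terminal_gain = list(cl = "terminal_gain", ann = NA),
      terminal_loss = list(cl = "terminal_loss", ann = NA),
      interstitial_gain = list(cl = "interstitial_gain", ann = NA),
      interstitial_loss = list(cl = "interstitial_loss", ann = NA),
      terminal_inverted_duplication =
        list(cl = "terminal_gain", ann = "inverted_duplication"),
      terminal_multistep = list(cl = "terminal_multistep", ann = NA),
      chromothripsis = list(cl = "chromothripsis", ann = NA),
      whole_arm = list(cl = if (delta > 0) "terminal_gain" else "terminal_loss",
                       ann = "whole_arm"),
      amplification = list(cl = c("interstitial_gain", "terminal_gain"),
                           ann = "amplification"),
      isoacentric_gain = list(cl = c("terminal_gain", "interstitial_gain"),
                              ann = "isoacentric_signature")
    )
  }
  truth <- data.table::copy(truth)
  truth[, `:=`(matched = FALSE, recovered = FALSE)]
  if (!nrow(truth)) return(truth[])
  for (i in seq_len(nrow(truth))) {
    ex <- exp_map(truth$class[i], truth$delta[i])
    cand <- calls[cell == truth$cell[i] & chrom == truth$chrom[i] &
                    hap == paste0("H", truth$hap[i])]
    if (!nrow(cand)) next
    ov <- pmin(cand$end, truth$end[i]) - pmax(cand$start, truth$start[i])
    cand <- cand[ov >= 0.5 * (truth$end[i] - truth$start[i])]
    if (!nrow(cand)) next
    data.table::set(truth, i, "matched", TRUE)
    ok <- cand$class %in% ex$cl
    if (!is.na(ex$ann[1])) ok <- ok & has_annotation(cand, ex$ann)
    data.table::set(truth, i, "recovered", any(ok))
  }
  truth[]
}
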