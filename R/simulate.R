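# Synthetic Strand-seq-like population generator.
#
# A cell's genomic state is held at bin resolution as two matrices of
# expected copy counts, one per emitted strand: w_cn[b, h] and c_cn[b, h]
# give the number of copies of haplotype h whose reads map to Watson /
# Crick in bin b. The baseline homologue contributes one copy on its
# template strand (switching at SCEs); CA events add or remove copies with
# a strand rule (same as template, opposite, or balanced W/C).

CA_CLASSES <- c(
  "chromosome_gain", "chromosome_loss", "interstitial_gain",
  "interstitial_loss", "terminal_gain", "terminal_loss",
  "terminal_inverted_duplication", "terminal_multistep", "chromothripsis",
  "whole_arm", "amplification", "isoacentric_gain"
)

#' CA event specification
#'
#' Describes one abnormality to inject into a synthetic cell. Coordinates
#' are 0-based half-open bp and must align to bin boundaries; events operate
#' at bin resolution throughout.
#'
#' @param class one of `r paste0('\x60', CA_CLASSES, '\x60', collapse = ", ")`.
#' @param chrom,start,end the affected interval (whole chromosome for
#'   `chromosome_gain`/`chromosome_loss`).
#' @param hap 1-based haplotype index of the host homologue.
#' @param delta copy-number change (defaults: +1 gains, -1 losses, +2
#'   amplification and isoacentric).
#' @param strand_rule strand of the added copies relative to the host
#'   homologue's template: `"same"` (tandem), `"opposite"` (inverted),
#'   `"balanced"` (half Watson half Crick, the isoacentric signature).
#' @param breakpoints for `chromothripsis`: strictly increasing interior
#'   breakpoints (bp) partitioning `[start, end)` into alternating
#'   retained/lost fragments on the host haplotype.
#' @param steps for `terminal_multistep`: data.frame of contiguous,
#'   telomere-anchored sub-intervals with columns `start`, `end`, `delta`
#'   (alternating sign).
#' @return An object of class `sk_event`.
#' @export
ca_event_spec <- function(class, chrom, start, end, hap = 1L, delta = NULL,
                          strand_rule = NULL, breakpoints = NULL, steps = NULL) {
  if (!class %in% CA_CLASSES)
    sk_parameter_error(paste0("unknown CA class: ", class))
  if (end <= start) sk_parameter_error("event end must exceed start")
  is_gainish <- class %in% c("chromosome_gain", "interstitial_gain", "terminal_gain",
                             "terminal_inverted_duplication", "amplification",
                             "isoacentric_gain")
  if (is.null(delta)) {
    delta <- if (class %in% c("amplification", "isoacentric_gain")) 2L
    else if (is_gainish) 1L
    else if (class %in% c("chromosome_loss", "interstitial_loss",
                          "terminal_loss")) -1L
    else if (class == "whole_arm") -1L
    else 0L
  }
  if (is.null(strand_rule)) {
    strand_rule <- if (class == "terminal_inverted_duplication") "opposite"
    else if (class == "isoacentric_gain") "balanced"
    else "same"
  }
  if (class == "isoacentric_gain") {
    if (delta %% 2L != 0L || delta <= 0L)
      sk_validation_error("isoacentric_gain requires a positive even delta")
    if (strand_rule != "balanced")
      sk_validation_error("isoacentric_gain requires the balanced strand rule")
  }
  if (class == "chromothripsis") {
    if (is.null(breakpoints) || length(breakpoints) < 3L)
      sk_validation_error("chromothripsis needs at least 3 interior breakpoints")
    if (any(diff(breakpoints) <= 0) || any(breakpoints <= start | breakpoints >= end))
      sk_validation_error("chromothripsis breakpoints must be strictly increasing inside the interval")
  }
  if (class == "terminal_multistep") {
    if (is.null(steps) || nrow(steps) < 2L)
      sk_validation_error("terminal_multistep needs at least 2 steps")
  }
  structure(list(
    class = class, chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), hap = as.integer(hap), delta = as.integer(delta),
    strand_rule = strand_rule, breakpoints = breakpoints, steps = steps
  ), class = "sk_event")
}

# -- cell state -------------------------------------------------------------

# template: B x H integer matrix, 0 = haplotype absent, 1 = Watson template,
# 2 = Crick template.
new_cell_state <- function(cell, grid, template, sces) {
  genome <- grid_genome(grid)
  B <- nrow(grid)
  H <- ncol(template)
  w_cn <- matrix(0, B, H)
  c_cn <- matrix(0, B, H)
  w_cn[template == 1L] <- 1
  c_cn[template == 2L] <- 1
  list(cell = cell, grid = grid, genome = genome, template = template,
       w_cn = w_cn, c_cn = c_cn, sces = sces, events = list())
}

empty_sce_table <- function() {
  data.table::data.table(chrom = character(), hap = integer(),
                         boundary_bin = integer(), orientation = character(),
                         pos = numeric())
}

# Random per-homologue template tracks for one cell: start strand uniform,
# SCE count Poisson(sce_mean) genome-wide, SCE positions snapped to interior
# bin boundaries (chromosome chosen proportional to length, homologue
# uniform). Uses the current RNG stream. Several SCEs can hit the same
# homologue; the final orientations are read off the assembled template.
random_templates <- function(grid, sce_mean) {
  genome <- grid_genome(grid)
  B <- nrow(grid)
  H <- max(genome$homologues)
  template <- matrix(0L, B, H)
  nb <- grid_nbins(grid)
  for (i in seq_len(nrow(genome))) {
    idx <- grid[chrom == genome$chrom[i], gbin]
    for (h in seq_len(genome$homologues[i]))
      template[idx, h] <- sample(1:2, 1L)
  }
  n_sce <- rpois(1L, sce_mean)
  sce_chrom <- if (n_sce > 0L)
    sample(genome$chrom, n_sce, replace = TRUE, prob = genome$length) else character()
  sch <- character(0); shp <- integer(0); sbd <- integer(0)
  for (ch in sce_chrom) {
    i <- match(ch, genome$chrom)
    n <- nb[[ch]]
    if (n < 2L) next
    h <- sample.int(genome$homologues[i], 1L)
    b <- sample.int(n - 1L, 1L)  # switch between bin b and b+1
    idx <- grid[chrom == ch, gbin]
    seg <- idx[(b + 1L):n]
    template[seg, h] <- 3L - template[seg, h]
    sch <- c(sch, ch); shp <- c(shp, h); sbd <- c(sbd, b)
  }
  sces <- data.table::data.table(chrom = sch, hap = shp, boundary_bin = sbd,
                                 orientation = NA_character_)
  if (nrow(sces)) {
    sces[, pos := boundary_bin * grid_bin_size(grid)]
    for (r in seq_len(nrow(sces))) {
      idx <- grid[chrom == sces$chrom[r], gbin]
      b <- sces$boundary_bin[r]
      before <- template[idx[b], sces$hap[r]]
      after <- template[idx[b + 1L], sces$hap[r]]
      data.table::set(sces, r, "orientation",
                      if (before == after) "none"
                      else if (before == 1L) "WtoC" else "CtoW")
    }
    sces <- sces[orientation != "none"]
  } else {
    sces <- empty_sce_table()
  }
  list(template = template, sces = sces)
}

# complement of a template matrix (1 <-> 2, 0 stays 0)
complement_template <- function(template) {
  out <- template
  out[template == 1L] <- 2L
  out[template == 2L] <- 1L
  out
}

# SCE table of the complementary daughter: same positions, mirrored
# orientation.
mirror_sces <- function(sces) {
  if (!nrow(sces)) return(data.table::copy(sces))
  out <- data.table::copy(sces)
  out[, orientation := ifelse(orientation == "WtoC", "CtoW", "WtoC")]
  out
}

#' Inject a CA event into a synthetic cell state
#'
#' Modifies the expected strand-resolved copy profile of a cell according to
#' the event class: losses remove the template-strand copy, tandem gains add
#' copies on the template strand, inverted duplications add them on the
#' opposite strand, isoacentric gains split the added copies 1:1 between
#' Watson and Crick, chromothripsis removes alternating fragments of one
#' haplotype, and terminal multi-step applies a telomere-anchored run of
#' alternating gains and losses.
#'
#' @param state a cell state from the population generator.
#' @param spec a [ca_event_spec()].
#' @param seed optional seed (the population generator drives the RNG
#'   itself).
#' @return The modified state, with the event appended to `state$events`.
#' @export
inject_event <- function(state, spec, seed = NULL) {
  with_rng_seed(seed, {
    grid <- state$grid
    genome <- state$genome
    ci <- match(spec$chrom, genome$chrom)
    if (is.na(ci)) sk_model_error(paste0("unknown chromosome: ", spec$chrom))
    len <- genome$length[ci]
    if (spec$start < 0 || spec$end > len)
      sk_stop("sk_bounds_error", "event interval off-chromosome")
    if (spec$hap > genome$homologues[ci])
      sk_stop("sk_bounds_error", "haplotype index exceeds homologue count")
    bs <- grid_bin_size(grid)
    aligned <- function(x) x %% bs == 0 || x == len
    if (!aligned(spec$start) || !aligned(spec$end))
      sk_validation_error("event coordinates must align to bin boundaries")

    apply_delta <- function(st, s, e, h, delta, rule) {
      idx <- grid[chrom == spec$chrom & start >= s & end <= e, gbin]
      tpl <- st$template[idx, h]
      if (delta < 0) {
        for (k in seq_len(-delta)) {
          # remove one copy per bin, preferring the template strand
          fromw <- tpl == 1L & st$w_cn[idx, h] > 0
          fromc <- tpl != 1L & st$c_cn[idx, h] > 0
          # fall back to whichever strand still has copies
          fallbackw <- !fromw & !fromc & st$w_cn[idx, h] > 0
          fallbackc <- !fromw & !fromc & !fallbackw & st$c_cn[idx, h] > 0
          st$w_cn[idx[fromw | fallbackw], h] <- st$w_cn[idx[fromw | fallbackw], h] - 1
          st$c_cn[idx[fromc | fallbackc], h] <- st$c_cn[idx[fromc | fallbackc], h] - 1
        }
      } else if (delta > 0) {
        if (rule == "balanced") {
          st$w_cn[idx, h] <- st$w_cn[idx, h] + delta / 2
          st$c_cn[idx, h] <- st$c_cn[idx, h] + delta / 2
        } else {
          on_w <- if (rule == "same") tpl == 1L else tpl != 1L
          st$w_cn[idx[on_w], h] <- st$w_cn[idx[on_w], h] + delta
          st$c_cn[idx[!on_w], h] <- st$c_cn[idx[!on_w], h] + delta
        }
      }
      st
    }

    cls <- spec$class
    if (cls %in% c("chromosome_gain", "chromosome_loss")) {
      d <- if (cls == "chromosome_gain") abs(spec$delta) else -abs(spec$delta)
      state <- apply_delta(state, 0, len, spec$hap, d, spec$strand_rule)
    } else if (cls == "terminal_multistep") {
      for (r in seq_len(nrow(spec$steps))) {
        state <- apply_delta(state, spec$steps$start[r], spec$steps$end[r],
                             spec$hap, spec$steps$delta[r], spec$strand_rule)
      }
    } else if (cls == "chromothripsis") {
      edges <- c(spec$start, spec$breakpoints, spec$end)
      for (k in seq_len(length(edges) - 1L)) {
        if (k %% 2L == 0L) {  # even fragments are lost
          state <- apply_delta(state, edges[k], edges[k + 1L], spec$hap, -1L, "same")
        }
      }
    } else {
      state <- apply_delta(state, spec$start, spec$end, spec$hap, spec$delta,
                           spec$strand_rule)
    }
    if (any(state$w_cn < 0) || any(state$c_cn < 0))
      sk_validation_error("event would produce negative copy number")
    state$events <- c(state$events, list(spec))
    state
  })
}

#' Expected strand-resolved copy profile of a synthetic cell
#'
#' @param state a cell state.
#' @return A `data.table` with columns `chrom`, `bin`, `hap`, `w_cn`,
#'   `c_cn`, `cn` (expected copies emitting Watson / Crick and their sum),
#'   one row per (bin, haplotype).
#' @export
expected_profile <- function(state) {
  grid <- state$grid
  H <- ncol(state$w_cn)
  out <- data.table::rbindlist(lapply(seq_len(H), function(h) {
    data.table::data.table(chrom = grid$chrom, bin = grid$bin, hap = h,
                           w_cn = state$w_cn[, h], c_cn = state$c_cn[, h])
  }))
  out[, cn := w_cn + c_cn]
  out[]
}

# -- fragment sampling ------------------------------------------------------

# Draw a counts table for one cell from its state. Expected totals always
# sum to `depth` (sequencing depth is a library property, independent of the
# genome's copy content), fragments are apportioned proportional to local
# copy number x bin width, with negative-binomial noise
# (variance = dispersion x mean), a strand flip probability bg_flip, and a
# haplotype tag retained with probability tag_frac.
simulate_counts_from_state <- function(state, depth, config, noise = "nb") {
  grid <- state$grid
  B <- nrow(grid)
  H <- ncol(state$w_cn)
  wrel <- grid$width / grid_bin_size(grid)
  cn <- state$w_cn + state$c_cn
  wt <- cn * wrel
  W_tot <- sum(wt)
  if (W_tot <= 0) sk_validation_error("cell has no genomic material")
  rows <- vector("list", H + 1L)
  uw <- numeric(B); uc <- numeric(B)
  eps <- config$bg_flip
  for (h in seq_len(H)) {
    mu <- depth * wt[, h] / W_tot
    pos <- which(mu > 0)
    if (!length(pos)) next
    pw <- state$w_cn[pos, h] / cn[pos, h]
    pw <- pw * (1 - eps) + (1 - pw) * eps
    if (noise == "none") {
      n <- mu[pos]
      wreads <- n * pw
      creads <- n - wreads
      tw <- round(wreads * config$tag_frac); tc <- round(creads * config$tag_frac)
      wreads <- round(wreads); creads <- round(creads)
      tw <- pmin(tw, wreads); tc <- pmin(tc, creads)
    } else {
      m <- mu[pos]
      n <- if (config$dispersion <= 1) rpois(length(m), m)
      else rnbinom(length(m), size = m / (config$dispersion - 1), mu = m)
      wreads <- rbinom(length(n), n, pw)
      creads <- n - wreads
      tw <- rbinom(length(n), wreads, config$tag_frac)
      tc <- rbinom(length(n), creads, config$tag_frac)
    }
    keep <- (tw + tc) > 0
    if (any(keep)) {
      rows[[h]] <- data.table::data.table(
        cell = state$cell, chrom = grid$chrom[pos][keep],
        bin = grid$bin[pos][keep], start = grid$start[pos][keep],
        end = grid$end[pos][keep], hap = paste0("H", h),
        w = as.integer(tw[keep]), c = as.integer(tc[keep])
      )
    }
    uw[pos] <- uw[pos] + (wreads - tw)
    uc[pos] <- uc[pos] + (creads - tc)
  }
  keepu <- (uw + uc) > 0
  rows[[H + 1L]] <- data.table::data.table(
    cell = state$cell, chrom = grid$chrom[keepu], bin = grid$bin[keepu],
    start = grid$start[keepu], end = grid$end[keepu], hap = "untagged",
    w = as.integer(uw[keepu]), c = as.integer(uc[keepu])
  )
  data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
}

# -- event geometry sampling ------------------------------------------------

# log-uniform size draw in [lo, hi], snapped to whole bins (>= 2 bins)
runif_log_size <- function(lo, hi, bs) {
  lo <- max(lo, 2 * bs)
  if (hi <= lo) return(ceiling(lo / bs) * bs)
  s <- exp(runif(1L, log(lo), log(hi)))
  max(2 * bs, round(s / bs) * bs)
}

# Draw a concrete event spec of a given class, uniform over allowed
# positions. Sizes are log-uniform between 1 Mb and the arm length.
sample_event_spec <- function(genome, grid, class) {
  bs <- grid_bin_size(grid)
  i <- sample.int(nrow(genome), 1L)
  ch <- genome$chrom[i]; len <- genome$length[i]; cen <- genome$centromere[i]
  hap <- sample.int(genome$homologues[i], 1L)
  cen_b <- round(cen / bs) * bs  # centromere snapped to a bin boundary
  arm <- sample(c("p", "q"), 1L)
  a_lo <- if (arm == "p") 0 else cen_b
  a_hi <- if (arm == "p") cen_b else len
  arm_len <- a_hi - a_lo

  term_interval <- function(size) {
    if (arm == "p") c(0, size) else c(floor((len - size) / bs) * bs, len)
  }
  if (class %in% c("chromosome_gain", "chromosome_loss")) {
    return(ca_event_spec(class, ch, 0, len, hap))
  }
  if (class %in% c("terminal_gain", "terminal_loss",
                   "terminal_inverted_duplication", "isoacentric_gain")) {
    s <- runif_log_size(1e6, arm_len * 0.85, bs)
    iv <- term_interval(s)
    return(ca_event_spec(class, ch, iv[1], iv[2], hap))
  }
  if (class == "whole_arm") {
    frac <- runif(1L, 0.92, 1.0)
    s <- max(2 * bs, floor(arm_len * frac / bs) * bs)
    iv <- term_interval(s)
    return(ca_event_spec(class, ch, iv[1], iv[2], hap,
                         delta = sample(c(-1L, 1L), 1L)))
  }
  if (class %in% c("interstitial_gain", "interstitial_loss", "amplification")) {
    s <- runif_log_size(1e6, max(2e6, arm_len - 4 * bs), bs)
    lo <- a_lo + bs; hi <- a_hi - bs - s
    if (hi < lo) { s <- 2 * bs; hi <- max(lo, a_hi - bs - s) }
    st <- lo + floor(runif(1L) * max(1, (hi - lo) / bs + 1)) * bs
    st <- min(st, hi)
    delta <- if (class == "amplification") sample(2:3, 1L) else NULL
    return(ca_event_spec(class, ch, st, st + s, hap, delta = delta))
  }
  if (class == "terminal_multistep") {
    k <- sample(2:4, 1L)
    total <- runif_log_size(max(4e6, k * 2 * bs * 2), arm_len * 0.8, bs)
    nb <- max(k * 2, round(total / bs))
    cuts <- sort(sample.int(nb - 1L, k - 1L))
    sizes <- diff(c(0L, cuts, nb)) * bs
    sizes <- pmax(sizes, 2 * bs)
    deltas <- rep_len(c(1L, -1L), k) * sample(c(1L, -1L), 1L)
    if (arm == "q") {
      ends <- len - c(0, cumsum(sizes))[-(k + 1L)]
      starts <- pmax(len - cumsum(sizes), a_lo)
    } else {
      starts <- c(0, cumsum(sizes))[-(k + 1L)]
      ends <- pmin(cumsum(sizes), a_hi)
    }
    steps <- data.table::data.table(start = pmin(starts, ends - 2 * bs),
                                    end = ends, delta = deltas)
    steps <- steps[end > start]
    return(ca_event_spec("terminal_multistep", ch, min(steps$start),
                         max(steps$end), hap, steps = steps))
  }
  if (class == "chromothripsis") {
    span <- max(24 * bs, floor(arm_len * runif(1L, 0.6, 1.0) / bs) * bs)
    span <- min(span, arm_len)
    st <- if (arm == "p") 0 else floor((len - span) / bs) * bs
    en <- st + span
    nb <- round(span / bs)
    k <- min(sample(10:16, 1L), floor(nb / 2) - 1L)
    bks <- sort(sample(seq(2L, nb - 2L, by = 2L), k)) * bs + st
    bks <- unique(bks)
    return(ca_event_spec("chromothripsis", ch, st, en, hap, breakpoints = bks))
  }
  sk_parameter_error(paste0("cannot sample class: ", class))
}

default_class_weights <- function() {
  c(chromosome_gain = 0.016, chromosome_loss = 0.153,
    terminal_gain = 0.031, terminal_inverted_duplication = 0.187,
    terminal_loss = 0.174, interstitial_gain = 0.020,
    interstitial_loss = 0.020, terminal_multistep = 0.234,
    chromothripsis = 0.065, whole_arm = 0.050, amplification = 0.030,
    isoacentric_gain = 0.020)
}

event_to_truth_row <- function(cell, spec) {
  data.table::data.table(
    cell = cell, class = spec$class, chrom = spec$chrom, start = spec$start,
    end = spec$end, hap = spec$hap, delta = spec$delta,
    strand_rule = spec$strand_rule,
    n_breakpoints = if (is.null(spec$breakpoints)) NA_integer_
    else length(spec$breakpoints)
  )
}

#' Simulate a daughter pair from one parent cell
#'
#' Sister cells inherit complementary template strands on every homologue;
#' each parental SCE appears at the same breakpoint in both daughters with
#' mirrored orientation. A dicentric-bridge breakage (`"bfb_bridge"`)
#' deposits a terminal inverted duplication in daughter A and the reciprocal
#' terminal loss in daughter B on the same haplotype and breakpoint; a
#' `"reciprocal_fragment"` outcome assigns a segmental gain to one daughter
#' and the matching loss to the other.
#'
#' @param parent a parent description as returned internally by
#'   [simulate_population()], or NULL to draw one: a list with `grid` and
#'   optionally `template`/`sces`.
#' @param outcome `"none"`, `"bfb_bridge"` or `"reciprocal_fragment"`.
#' @param seed optional RNG seed.
#' @param cells length-2 character vector of daughter cell ids.
#' @param config an [sk_config()].
#' @return list with `state_a`, `state_b` and `truth` (events data.table).
#' @export
simulate_sister_pair <- function(parent, outcome = "none", seed = NULL,
                                 cells = c("sisterA", "sisterB"),
                                 config = sk_config()) {
  config <- as_sk_config(config)
  with_rng_seed(seed, {
    grid <- parent$grid
    if (is.null(parent$template)) {
      tpl <- random_templates(grid, config$sce_mean)
    } else {
      tpl <- list(template = parent$template, sces = parent$sces)
    }
    a <- new_cell_state(cells[1], grid, tpl$template, tpl$sces)
    b <- new_cell_state(cells[2], grid, complement_template(tpl$template),
                        mirror_sces(tpl$sces))
    truth <- list()
    genome <- grid_genome(grid)
    if (outcome %in% c("bfb_bridge", "reciprocal_fragment")) {
      spec_a <- sample_event_spec(genome, grid,
                                  if (outcome == "bfb_bridge")
                                    "terminal_inverted_duplication" else "terminal_gain")
      spec_b <- ca_event_spec("terminal_loss", spec_a$chrom, spec_a$start,
                              spec_a$end, spec_a$hap)
      a <- inject_event(a, spec_a)
      b <- inject_event(b, spec_b)
      truth <- list(event_to_truth_row(cells[1], spec_a),
                    event_to_truth_row(cells[2], spec_b))
    }
    list(state_a = a, state_b = b,
         truth = if (length(truth)) data.table::rbindlist(truth)
         else empty_event_table())
  })
}

empty_event_table <- function() {
  data.table::data.table(cell = character(), class = character(),
                         chrom = character(), start = numeric(),
                         end = numeric(), hap = integer(), delta = integer(),
                         strand_rule = character(), n_breakpoints = integer())
}

#' Simulate a Strand-seq-like cell population with known truth
#'
#' Generates `n_cells` single-cell count tables over `grid`. Each cell gets
#' per-homologue template strands with Poisson-distributed SCEs; a fraction
#' of cells form sister pairs with complementary templates and mirrored
#' SCEs; CA events are injected per singleton cell and recorded in a truth
#' table (sister pairs carry only the planted `pair_outcome`, so that pair
#' truth stays interpretable).
#' Fragments are apportioned across bins proportional to local haplotype
#' copy number with negative-binomial noise; Watson/Crick assignment follows
#' the source copy's strand with a background flip rate; a fraction of reads
#' carries the true haplotype tag.
#'
#' @param genome an [genome_model()].
#' @param grid the matching [build_bin_grid()].
#' @param n_cells number of cells (>= 1).
#' @param depth mean mapped fragments per cell.
#' @param event_rate expected CA events per cell.
#' @param sister_fraction fraction of cells that are members of sister
#'   pairs, in `[0, 1]`.
#' @param class_weights named numeric vector of event-class sampling
#'   weights; defaults to the observed spontaneous-micronucleation class
#'   mix.
#' @param events_per_cell `"poisson"` (Poisson around `event_rate`) or
#'   `"fixed"` (every cell gets exactly `round(event_rate)` events).
#' @param pair_outcome CA outcome planted in sister pairs: `"none"`,
#'   `"bfb_bridge"` or `"reciprocal_fragment"`.
#' @param noise `"nb"` or `"none"` (expected counts, for oracle tests).
#' @param config an [sk_config()].
#' @param seed RNG seed; fixed seed gives identical counts and truth.
#' @return list with `counts` (an `sk_counts` table) and `truth`, a list of
#'   `events`, `siblings` (cell_a, cell_b) and `sces` tables.
#' @export
simulate_population <- function(genome, grid, n_cells, depth = 285000,
                                event_rate = 0, sister_fraction = 0,
                                class_weights = NULL,
                                events_per_cell = c("poisson", "fixed"),
                                pair_outcome = "none", noise = "nb",
                                config = sk_config(), seed = 1L) {
  config <- as_sk_config(config)
  events_per_cell <- match.arg(events_per_cell)
  if (n_cells < 1L) sk_parameter_error("n_cells must be >= 1")
  if (depth <= 0) sk_parameter_error("depth must be positive")
  if (sister_fraction < 0 || sister_fraction > 1)
    sk_parameter_error("sister_fraction must be in [0, 1]")
  if (is.null(class_weights)) class_weights <- default_class_weights()
  if (is.null(names(class_weights)) || !all(names(class_weights) %in% CA_CLASSES))
    sk_parameter_error("class_weights must be named by CA class")

  with_rng_seed(seed, {
    ids <- sprintf("cell%03d", seq_len(n_cells))
    n_pairs <- floor(n_cells * sister_fraction / 2)
    pair_members <- if (n_pairs > 0) seq_len(2L * n_pairs) else integer()
    counts <- vector("list", n_cells)
    ev_rows <- list()
    sce_rows <- list()
    sib <- data.table::data.table(cell_a = character(), cell_b = character())

    draw_events <- function(state) {
      k <- if (events_per_cell == "fixed") round(event_rate)
      else rpois(1L, event_rate)
      for (j in seq_len(k)) {
        cls <- sample(names(class_weights), 1L, prob = class_weights)
        spec <- sample_event_spec(genome, grid, cls)
        state <- inject_event(state, spec)
      }
      state
    }

    finish_cell <- function(state) {
      state <- draw_events(state)
      counts[[match(state$cell, ids)]] <<- simulate_counts_from_state(
        state, depth, config, noise)
      for (sp in state$events)
        ev_rows[[length(ev_rows) + 1L]] <<- event_to_truth_row(state$cell, sp)
      if (nrow(state$sces)) {
        s <- data.table::copy(state$sces)
        s[, cell := state$cell]
        sce_rows[[length(sce_rows) + 1L]] <<- s
      }
      invisible(NULL)
    }

    if (n_pairs > 0) {
      for (p in seq_len(n_pairs)) {
        ia <- 2L * p - 1L; ib <- 2L * p
        pr <- simulate_sister_pair(list(grid = grid), outcome = pair_outcome,
                                   cells = c(ids[ia], ids[ib]), config = config)
        for (r in seq_len(nrow(pr$truth)))
          ev_rows[[length(ev_rows) + 1L]] <- pr$truth[r]
        # planted pair events are part of the pair truth, not re-drawn below
        st_a <- pr$state_a; st_b <- pr$state_b
        counts[[ia]] <- simulate_counts_from_state(st_a, depth, config, noise)
        counts[[ib]] <- simulate_counts_from_state(st_b, depth, config, noise)
        for (st in list(st_a, st_b)) {
          if (nrow(st$sces)) {
            s <- data.table::copy(st$sces); s[, cell := st$cell]
            sce_rows[[length(sce_rows) + 1L]] <- s
          }
        }
        sib <- rbind(sib, data.table::data.table(cell_a = ids[ia], cell_b = ids[ib]))
      }
    }
    for (i in setdiff(seq_len(n_cells), pair_members)) {
      tpl <- random_templates(grid, config$sce_mean)
      st <- new_cell_state(ids[i], grid, tpl$template, tpl$sces)
      finish_cell(st)
    }

    counts_dt <- data.table::rbindlist(counts)
    counts <- strand_bin_counts(
      counts_dt[, .(cell, chrom, start, end, hap, w, c)], grid)
    events <- if (length(ev_rows)) data.table::rbindlist(ev_rows) else
      empty_event_table()
    sces <- if (length(sce_rows)) data.table::rbindlist(sce_rows) else
      cbind(empty_sce_table(), data.table::data.table(cell = character()))
    list(counts = counts, truth = list(events = events, siblings = sib, sces = sces))
  })
}
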