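# Shared fixtures: a small three-chromosome genome keeps unit tests fast
# while preserving the per-bin depth of the full-scale setting (the
# acceptance tests use the five-chromosome default genome at 285k
# fragments per cell).

tiny_genome <- function(trisomy = character()) {
  hom <- ifelse(c("chrA", "chrB", "chrC") %in% trisomy, 3L, 2L)
  genome_model(c("chrA", "chrB", "chrC"), c(40e6, 30e6, 20e6),
               c(16e6, 12e6, 9e6), hom)
}

tiny_grid <- function(genome = tiny_genome()) build_bin_grid(genome)

# depth scaled so per-bin coverage matches the full-genome default
tiny_depth <- 60000

quick_sim <- function(n_cells, event_rate = 0, seed = 1, ...) {
  g <- tiny_genome()
  grid <- tiny_grid(g)
  sim <- simulate_population(g, grid, n_cells, depth = tiny_depth,
                             event_rate = event_rate, seed = seed, ...)
  list(genome = g, grid = grid, sim = sim)
}

# build a call-table fixture row by row
make_calls <- function(class, n = 1, cell = "c1", chrom = "chrA",
                       start = 0, end = 4e5, hap = "H1", delta = 1L,
                       strand_config = NA_character_, annotations = "") {
  dt <- data.table::data.table(
    cell = rep(cell, n), chrom = rep(chrom, n), start = rep(start, n),
    end = rep(end, n), hap = rep(hap, n), delta = rep(as.integer(delta), n),
    strand_config = rep(strand_config, n), class = rep(class, n),
    annotations = rep(annotations, n), n_breakpoints = rep(1L, n)
  )
  data.table::setattr(dt, "class", c("sk_calls", class(dt)))
  dt
}

bind_calls <- function(...) {
  dt <- data.table::rbindlist(list(...))
  data.table::setattr(dt, "class", c("sk_calls", class(dt)))
  dt
}

# a one-cell synthetic state with chosen injected events, returning counts
one_cell_counts <- function(specs = list(), seed = 1, noise = "nb",
                            genome = tiny_genome(), depth = tiny_depth,
                            sce_mean = 0, config = sk_config()) {
  grid <- build_bin_grid(genome)
  withr_seed <- seed
  set.seed(withr_seed)
  tpl <- strandkaryo:::random_templates(grid, sce_mean)
  st <- strandkaryo:::new_cell_state("c1", grid, tpl$template, tpl$sces)
  for (sp in specs) st <- inject_event(st, sp)
  cnt <- strandkaryo:::simulate_counts_from_state(st, depth, config, noise)
  counts <- strand_bin_counts(cnt[, .(cell, chrom, start, end, hap, w, c)], grid)
  list(grid = grid, state = st, counts = counts)
}

# build an sk_track fixture from per-chromosome segment specs:
# segs = data.frame(chrom, from, to, cn1, w1, cn2, w2) in within-chromosome
# bin indices; untouched chromosomes get a single disomic WC segment
make_track <- function(segs, cell = "c1", grid = tiny_grid()) {
  genome <- strandkaryo:::grid_genome(grid)
  nb <- table(grid$chrom)
  rows <- list()
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(s))) {
      i0 <- which(grid$chrom == ch & grid$bin == s$from[k])
      i1 <- which(grid$chrom == ch & grid$bin == s$to[k])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        cell = cell, chrom = ch, start_bin = s$from[k], end_bin = s$to[k],
        start = grid$start[i0], end = grid$end[i1],
        n_bins = s$to[k] - s$from[k] + 1L,
        cn_total = s$cn1[k] + s$cn2[k],
        strand_label = paste0(strrep("W", s$w1[k] + s$w2[k]),
                              strrep("C", s$cn1[k] - s$w1[k] + s$cn2[k] - s$w2[k])),
        at_cap = FALSE,
        cn_h1 = s$cn1[k], w_h1 = s$w1[k], c_h1 = s$cn1[k] - s$w1[k],
        cn_h2 = s$cn2[k], w_h2 = s$w2[k], c_h2 = s$cn2[k] - s$w2[k]
      )
    }
  }
  track <- data.table::rbindlist(rows)
  data.table::setattr(track, "n_hap", 2L)
  data.table::setattr(track, "class", c("sk_track", class(track)))
  track
}

# one flat WC segment for a whole chromosome
flat_seg <- function(chrom, nb) {
  data.frame(chrom = chrom, from = 1L, to = nb, cn1 = 1L, w1 = 1L,
             cn2 = 1L, w2 = 0L)
}
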