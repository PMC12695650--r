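# Strand-state inference, pair scoring and sister-pair recovery.

grid_s <- tiny_grid()
cons_s <- consensus_from_genome(tiny_genome(), grid_s)

test_that("a switch-free WC chromosome yields two runs and zero SCEs", {
  track <- make_track(flat_seg("chrA", 200))
  st <- infer_strand_states(track, grid_s)
  idx <- which(grid_s$chrom == "chrA")
  expect_true(all(st$strand[idx, 1] == 1L))
  expect_true(all(st$strand[idx, 2] == -1L))
  expect_equal(nrow(st$sces), 0L)
})

test_that("an injected SCE is recovered within one bin with its orientation", {
  g <- tiny_genome(); grid <- build_bin_grid(g)
  set.seed(40)
  tpl <- strandkaryo:::random_templates(grid, 0)
  idxA <- which(grid$chrom == "chrA")
  tpl$template[idxA, 1] <- c(rep(1L, 120), rep(2L, 80))  # W -> C at bin 120
  st0 <- strandkaryo:::new_cell_state("c1", grid, tpl$template, tpl$sces)
  cnt <- strandkaryo:::simulate_counts_from_state(st0, tiny_depth, sk_config(), "nb")
  counts <- strand_bin_counts(cnt[, .(cell, chrom, start, end, hap, w, c)], grid)
  track <- segment_cell(counts, grid, cons_s)
  st <- infer_strand_states(track, grid)
  sce <- st$sces[chrom == "chrA"]
  expect_equal(nrow(sce), 1L)
  expect_lte(abs(sce$boundary_bin - 120L), 1L)
  expect_equal(sce$orientation, "WtoC")
})

test_that("copy-number changes without strand switch emit no SCE", {
  track <- make_track(rbind(
    data.frame(chrom = "chrA", from = 1, to = 100, cn1 = 1L, w1 = 1L,
               cn2 = 1L, w2 = 0L),
    data.frame(chrom = "chrA", from = 101, to = 200, cn1 = 2L, w1 = 2L,
               cn2 = 1L, w2 = 0L)))
  st <- infer_strand_states(track, grid_s)
  expect_equal(nrow(st$sces), 0L)
})

test_that("a cell scored against itself is unrelated (identical, not reciprocal)", {
  track <- make_track(flat_seg("chrA", 200))
  st <- infer_strand_states(track, grid_s)
  sc <- score_pair(st, st, grid_s)
  expect_equal(sc$reciprocity, 0)
  expect_equal(sc$verdict, "unrelated")
})

test_that("pair scoring is symmetric", {
  qs <- quick_sim(4, sister_fraction = 0.5, seed = 41)
  cons <- consensus_from_genome(qs$genome, qs$grid)
  tr <- segment_population(qs$sim$counts, qs$grid, cons)
  states <- strand_state_population(tr, qs$grid)
  ab <- score_pair(states[[1]], states[[2]], qs$grid)
  ba <- score_pair(states[[2]], states[[1]], qs$grid)
  expect_equal(ab$reciprocity, ba$reciprocity)
  expect_equal(ab$mirrored_sces, ba$mirrored_sces)
  expect_equal(ab$verdict, ba$verdict)
})

test_that("generated sister pairs score high reciprocity with mirrored SCEs", {
  qs <- quick_sim(6, sister_fraction = 1, seed = 42)
  cons <- consensus_from_genome(qs$genome, qs$grid)
  tr <- segment_population(qs$sim$counts, qs$grid, cons)
  states <- strand_state_population(tr, qs$grid)
  for (p in seq_len(nrow(qs$sim$truth$siblings))) {
    a <- states[[qs$sim$truth$siblings$cell_a[p]]]
    b <- states[[qs$sim$truth$siblings$cell_b[p]]]
    sc <- score_pair(a, b, qs$grid)
    expect_gte(sc$reciprocity, 0.98)
    expect_equal(sc$verdict, "sisters")
  }
})

test_that("unrelated cells have reciprocity near one half and never verdict sisters", {
  # direct template-level null: independent cells, Bernoulli(0.5) agreement
  g <- tiny_genome(); grid <- build_bin_grid(g)
  set.seed(43)
  states <- lapply(1:40, function(i) {
    tpl <- strandkaryo:::random_templates(grid, 6)
    S <- matrix(0L, nrow(grid), 2L)
    S[tpl$template == 1L] <- 1L
    S[tpl$template == 2L] <- -1L
    structure(list(cell = paste0("n", i), strand = S, sces = tpl$sces),
              class = "sk_strand_state")
  })
  rec <- vapply(1:200, function(k) {
    i <- sample.int(40, 2)
    score_pair(states[[i[1]]], states[[i[2]]], grid)$reciprocity
  }, numeric(1))
  expect_lt(abs(mean(rec) - 0.5), 0.05)
  expect_equal(nrow(find_sister_pairs(states, grid)), 0L)
})

test_that("planted pairs are matched exactly in small populations", {
  qs <- quick_sim(2, sister_fraction = 1, seed = 44)
  cons <- consensus_from_genome(qs$genome, qs$grid)
  tr <- segment_population(qs$sim$counts, qs$grid, cons)
  states <- strand_state_population(tr, qs$grid)
  pairs <- find_sister_pairs(states, qs$grid)
  expect_equal(nrow(pairs), 1L)
  expect_setequal(c(pairs$cell_a, pairs$cell_b), c("cell001", "cell002"))
  # a population of singletons gives an empty list
  qs2 <- quick_sim(4, sister_fraction = 0, seed = 45)
  tr2 <- segment_population(qs2$sim$counts, qs2$grid, cons)
  pairs2 <- find_sister_pairs(strand_state_population(tr2, qs2$grid), qs2$grid)
  expect_equal(nrow(pairs2), 0L)
})

test_that("reciprocal CA segregation within a pair is recognized", {
  a <- make_calls("terminal_gain", cell = "a", chrom = "chrA",
                  start = 30e6, end = 40e6, hap = "H1", delta = 1L)
  b <- make_calls("terminal_loss", cell = "b", chrom = "chrA",
                  start = 30e6, end = 40e6, hap = "H1", delta = -1L)
  expect_equal(reciprocal_ca_check(a, b)$status, "reciprocal")

  b2 <- make_calls("terminal_gain", cell = "b", chrom = "chrA",
                   start = 30e6, end = 40e6, hap = "H1", delta = 1L)
  expect_equal(reciprocal_ca_check(a, b2)$status, "shared")

  b3 <- make_calls("terminal_loss", cell = "b", chrom = "chrB",
                   start = 10e6, end = 30e6, hap = "H2", delta = -1L)
  out <- reciprocal_ca_check(a, b3)
  expect_true(all(out$status == "independent"))
})

test_that("a planted dicentric-bridge pair shows reciprocal segregation end to end", {
  g <- tiny_genome(); grid <- build_bin_grid(g)
  sim <- simulate_population(g, grid, 2, depth = tiny_depth,
                             sister_fraction = 1, pair_outcome = "bfb_bridge",
                             seed = 46)
  cons <- consensus_from_genome(g, grid)
  tr <- segment_population(sim$counts, grid, cons)
  calls <- classify_population(tr, cons, grid, counts = sim$counts)
  chk <- reciprocal_ca_check(calls[cell == "cell001"], calls[cell == "cell002"])
  expect_true("reciprocal" %in% chk$status)
  # the gain side is the inverted duplication
  ev <- sim$truth$events
  gain_cell <- ev[class == "terminal_inverted_duplication"]$cell
  m <- match_calls_to_truth(calls, ev)
  expect_true(all(m$recovered))
})
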