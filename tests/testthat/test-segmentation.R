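# Normalization, consensus and change-point segmentation.

test_that("normalized totals of a disomic cell concentrate near 2", {
  oc <- one_cell_counts(list(), seed = 3)
  norm <- normalize_counts(oc$counts, oc$grid)
  expect_lt(abs(median(norm$y) - 2), 0.05)
  expect_gt(mean(abs(norm$y - 2) < 0.8), 0.99)
})

test_that("a haplotype terminal loss pulls normalized totals toward 1", {
  spec <- ca_event_spec("terminal_loss", "chrA", 20e6, 40e6, hap = 1)
  oc <- one_cell_counts(list(spec), seed = 4)
  norm <- normalize_counts(oc$counts, oc$grid)
  lost <- norm[chrom == "chrA" & bin > 100]
  expect_lt(abs(median(lost$y) - 1), 0.1)
})

test_that("a WW-state chromosome has Watson fraction near 1 minus background", {
  set.seed(10)
  grid <- tiny_grid()
  tpl <- strandkaryo:::random_templates(grid, 0)
  tpl$template[grid$chrom == "chrB", ] <- 1L  # force WW
  st <- strandkaryo:::new_cell_state("c1", grid, tpl$template, tpl$sces)
  cnt <- strandkaryo:::simulate_counts_from_state(st, tiny_depth, sk_config(), "nb")
  counts <- strand_bin_counts(cnt[, .(cell, chrom, start, end, hap, w, c)], grid)
  norm <- normalize_counts(counts, grid)
  expect_gt(median(norm[chrom == "chrB"]$wfrac), 0.93)
})

test_that("zero-coverage cells raise a QC error", {
  grid <- tiny_grid()
  df <- data.frame(cell = "c1", chrom = "chrA", start = 0, end = 2e5,
                   hap = "untagged", w = 0L, c = 0L)
  counts <- strand_bin_counts(df, grid)
  expect_error(normalize_counts(counts, grid), class = "sk_qc_error")
})

test_that("consensus recovers the population baseline, including trisomy", {
  g <- tiny_genome(trisomy = "chrB")
  grid <- build_bin_grid(g)
  sim <- simulate_population(g, grid, 12, depth = tiny_depth, seed = 6)
  cons <- build_consensus(sim$counts, grid)
  expect_true(all(cons[chrom == "chrB"]$cn_total == 3))
  expect_true(all(cons[chrom != "chrB"]$cn_total == 2))

  # with no events the consensus equals the generator baseline everywhere
  qs <- quick_sim(10, seed = 7)
  cons2 <- build_consensus(qs$sim$counts, qs$grid)
  expect_true(all(cons2$cn_total == 2))
  expect_true(all(cons2$cn_h1 == 1) && all(cons2$cn_h2 == 1))
})

test_that("the consensus mode is robust to a recurrent minority event", {
  # 1 of 12 cells (~8%) carries the same loss; the modal consensus ignores it
  g <- tiny_genome(); grid <- build_bin_grid(g)
  set.seed(20)
  rows <- list()
  spec <- ca_event_spec("terminal_loss", "chrA", 20e6, 40e6, hap = 1)
  for (i in 1:12) {
    tpl <- strandkaryo:::random_templates(grid, 3)
    st <- strandkaryo:::new_cell_state(sprintf("c%02d", i), grid, tpl$template, tpl$sces)
    if (i == 1) st <- inject_event(st, spec)
    rows[[i]] <- strandkaryo:::simulate_counts_from_state(st, tiny_depth, sk_config(), "nb")
  }
  counts <- strand_bin_counts(
    data.table::rbindlist(rows)[, .(cell, chrom, start, end, hap, w, c)], grid)
  cons <- build_consensus(counts, grid)
  expect_true(all(cons$cn_total == 2))
  expect_error(build_consensus(counts[cell %in% c("c01", "c02")], grid),
               class = "sk_consensus_error")
})

test_that("a flat disomic chromosome yields exactly one segment", {
  oc <- one_cell_counts(list(), seed = 11)
  cons <- consensus_from_genome(tiny_genome(), oc$grid)
  track <- segment_cell(oc$counts, oc$grid, cons)
  expect_true(all(track[, .N, by = chrom]$N == 1L))
  expect_true(all(track$cn_total == 2))
  expect_error(segment_cell(oc$counts, oc$grid, cons,
                            config = sk_config(penalty = 0)),
               class = "sk_parameter_error")
})

test_that("an injected change-point is recovered within one bin", {
  g <- tiny_genome(); grid <- build_bin_grid(g)
  cons <- consensus_from_genome(g, grid)
  hits <- 0L; reps <- 12L
  for (r in seq_len(reps)) {
    spec <- ca_event_spec("terminal_loss", "chrA", 24e6, 40e6, hap = 1 + r %% 2)
    oc <- one_cell_counts(list(spec), seed = 100 + r)
    track <- segment_cell(oc$counts, oc$grid, cons)
    bks <- track[chrom == "chrA", start]
    if (any(abs(bks - 24e6) <= 2e5)) hits <- hits + 1L
  }
  expect_gte(hits, reps - 1L)
})

test_that("noise-free segmentation recovers injected states exactly", {
  specs <- list(
    ca_event_spec("terminal_loss", "chrA", 24e6, 40e6, hap = 1),
    ca_event_spec("interstitial_gain", "chrB", 4e6, 10e6, hap = 2),
    ca_event_spec("isoacentric_gain", "chrC", 12e6, 20e6, hap = 1)
  )
  oc <- one_cell_counts(specs, seed = 12, noise = "none")
  cons <- consensus_from_genome(tiny_genome(), oc$grid)
  track <- segment_cell(oc$counts, oc$grid, cons)
  prof <- expected_profile(oc$state)
  for (k in seq_len(nrow(track))) {
    seg <- track[k]
    for (h in 1:2) {
      truth_cn <- prof[chrom == seg$chrom & hap == h &
                         bin >= seg$start_bin & bin <= seg$end_bin]$cn
      expect_true(all(truth_cn == seg[[paste0("cn_h", h)]]))
    }
  }
})

test_that("breakpoint count is non-increasing in the penalty", {
  spec <- ca_event_spec("terminal_multistep", "chrA", 24e6, 40e6, hap = 1,
                        steps = data.frame(start = c(32e6, 24e6),
                                           end = c(40e6, 32e6),
                                           delta = c(1L, -1L)))
  oc <- one_cell_counts(list(spec), seed = 13)
  cons <- consensus_from_genome(tiny_genome(), oc$grid)
  nseg <- vapply(c(0.5, 1.5, 4, 12, 40), function(pen) {
    nrow(segment_cell(oc$counts, oc$grid, cons, config = sk_config(penalty = pen)))
  }, numeric(1))
  expect_true(all(diff(nseg) <= 0))
})

test_that("segmentation treats cells independently of ordering", {
  qs <- quick_sim(3, event_rate = 1, seed = 14, events_per_cell = "fixed")
  cons <- consensus_from_genome(qs$genome, qs$grid)
  t12 <- segment_population(qs$sim$counts, qs$grid, cons,
                            cells = c("cell001", "cell002"))
  t21 <- segment_population(qs$sim$counts, qs$grid, cons,
                            cells = c("cell002", "cell001"))
  expect_equal(as.data.frame(t12[cell == "cell001"]),
               as.data.frame(t21[cell == "cell001"]))
})

test_that("population-low-coverage bins are blacklisted", {
  qs <- quick_sim(5, seed = 15)
  counts <- data.table::as.data.table(qs$sim$counts)
  # empty out one bin across every cell (unmappable-region proxy)
  counts <- counts[!(chrom == "chrA" & bin == 50)]
  counts <- strand_bin_counts(counts[, .(cell, chrom, start, end, hap, w, c)],
                              qs$grid)
  mask <- strandkaryo:::blacklist_bins(counts, qs$grid, sk_config())
  expect_true(mask[50])
  expect_equal(sum(mask), 1L)
})
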