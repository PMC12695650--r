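# Synthetic Strand-seq population generator: template states, event
# injection, fragment sampling, sister pairs.

test_that("an event-free population has canonical template compositions", {
  g <- tiny_genome(); grid <- tiny_grid(g)
  sim <- simulate_population(g, grid, 6, depth = tiny_depth, event_rate = 0,
                             config = sk_config(sce_mean = 0), seed = 2)
  expect_equal(nrow(sim$truth$events), 0L)
  comp <- sim$counts[, .(wf = sum(w) / (sum(w) + sum(c))), by = .(cell, chrom)]
  # without SCEs each chromosome is WW, WC or CC up to the 2% strand flips
  ok <- abs(comp$wf - 0.5) < 0.05 | comp$wf < 0.05 | comp$wf > 0.95
  expect_true(all(ok))
})

test_that("median per-cell fragment count tracks the depth parameter", {
  g <- synthetic_genome(); grid <- build_bin_grid(g)
  sim <- simulate_population(g, grid, 200, depth = 285000, event_rate = 0,
                             seed = 4)
  qc <- cell_qc(sim$counts)
  expect_equal(nrow(qc), 200L)
  expect_lt(abs(median(qc$total) - 285000) / 285000, 0.02)
})

test_that("the generator is deterministic under a fixed seed", {
  a <- quick_sim(4, event_rate = 1, seed = 77, events_per_cell = "fixed",
                 sister_fraction = 0.5)
  b <- quick_sim(4, event_rate = 1, seed = 77, events_per_cell = "fixed",
                 sister_fraction = 0.5)
  expect_identical(as.data.frame(a$sim$counts), as.data.frame(b$sim$counts))
  expect_identical(as.data.frame(a$sim$truth$events),
                   as.data.frame(b$sim$truth$events))
  c <- quick_sim(4, event_rate = 1, seed = 78, events_per_cell = "fixed")
  expect_false(identical(as.data.frame(a$sim$counts), as.data.frame(c$sim$counts)))
})

test_that("expected fragment totals are conserved regardless of events", {
  # depth is a property of the library, not of the genome's copy content
  # noise-free counts are per-bin rounded expectations; the systematic part
  # of the rounding stays within 2% of the depth
  spec <- ca_event_spec("terminal_loss", "chrA", 20e6, 40e6, hap = 1)
  oc <- one_cell_counts(list(spec), noise = "none")
  expect_lt(abs(sum(oc$counts$w + oc$counts$c) - tiny_depth), 0.02 * tiny_depth)
  oc2 <- one_cell_counts(list(), noise = "none")
  expect_lt(abs(sum(oc2$counts$w + oc2$counts$c) - tiny_depth), 0.02 * tiny_depth)
  # with sampling noise the mean behaves likewise
  qsA <- quick_sim(6, event_rate = 1, seed = 30, events_per_cell = "fixed")
  tot <- cell_qc(qsA$sim$counts)$total
  expect_lt(abs(mean(tot) - tiny_depth) / tiny_depth, 0.02)
})

test_that("noise-free counts recover the injected copy-number profile", {
  spec <- ca_event_spec("interstitial_gain", "chrB", 4e6, 10e6, hap = 2)
  oc <- one_cell_counts(list(spec), noise = "none")
  prof <- expected_profile(oc$state)[, .(cn = sum(cn)), by = .(chrom, bin)]
  obs <- oc$counts[, .(tot = sum(w) + sum(c)), by = .(chrom, bin)]
  obs <- obs[prof, on = c("chrom", "bin")]
  obs[is.na(tot), tot := 0]
  wrel <- oc$grid$width / 2e5
  per_copy <- sum(obs$tot) / sum(prof$cn * wrel)
  cn_rec <- obs$tot / (per_copy * wrel)
  expect_lt(max(abs(cn_rec - prof$cn)), 0.05)
  # gained interval sits at 3 copies, elsewhere 2
  gained <- prof[chrom == "chrB" & bin > 20 & bin <= 50]
  expect_true(all(gained$cn == 3))
})

test_that("event injection shapes the expected strand-resolved profile", {
  # terminal loss drops one haplotype to zero in the affected bins
  loss <- ca_event_spec("terminal_loss", "chrA", 20e6, 40e6, hap = 1)
  oc <- one_cell_counts(list(loss))
  prof <- expected_profile(oc$state)
  lost <- prof[chrom == "chrA" & hap == 1 & bin > 100]
  expect_true(all(lost$cn == 0))
  expect_true(all(prof[chrom == "chrA" & hap == 2]$cn == 1))

  # isoacentric gain adds equal Watson and Crick increments
  iso <- ca_event_spec("isoacentric_gain", "chrB", 20e6, 30e6, hap = 1)
  oc2 <- one_cell_counts(list(iso))
  p2 <- expected_profile(oc2$state)[chrom == "chrB" & hap == 1 & bin > 100]
  base <- expected_profile(one_cell_counts(list(), seed = 1)$state)
  b2 <- base[chrom == "chrB" & hap == 1 & bin > 100]
  expect_true(all(p2$w_cn - b2$w_cn == 1))
  expect_true(all(p2$c_cn - b2$c_cn == 1))

  # inverted duplication emits the extra copy on the opposite strand
  inv <- ca_event_spec("terminal_inverted_duplication", "chrC", 10e6, 20e6)
  oc3 <- one_cell_counts(list(inv))
  p3 <- expected_profile(oc3$state)[chrom == "chrC" & hap == 1 & bin > 50]
  b3 <- base[chrom == "chrC" & hap == 1 & bin > 50]
  expect_true(all(p3$w_cn - b3$w_cn + (p3$c_cn - b3$c_cn) == 1))
  # the added copy is always on the strand with zero baseline copies
  expect_true(all((p3$w_cn - b3$w_cn) * b3$w_cn + (p3$c_cn - b3$c_cn) * b3$c_cn == 0))
})

test_that("chromothripsis injection oscillates between exactly two states", {
  bks <- seq(2e6, 14e6, by = 2e6)
  spec <- ca_event_spec("chromothripsis", "chrC", 0, 16e6, hap = 2,
                        breakpoints = bks)
  oc <- one_cell_counts(list(spec))
  prof <- expected_profile(oc$state)[chrom == "chrC" & hap == 2 & bin <= 80]
  expect_setequal(unique(prof$cn), c(0, 1))
  # direct tally: alternating 10-bin fragments, even fragments lost
  frag <- ceiling(prof$bin / 10)
  expect_true(all(prof$cn[frag %% 2 == 0] == 0))
  expect_true(all(prof$cn[frag %% 2 == 1] == 1))
  # untouched haplotype intact
  other <- expected_profile(oc$state)[chrom == "chrC" & hap == 1]
  expect_true(all(other$cn == 1))
})

test_that("event specs are validated", {
  expect_error(ca_event_spec("isoacentric_gain", "chrA", 0, 1e6, delta = 3),
               class = "sk_validation_error")
  expect_error(ca_event_spec("nonsense", "chrA", 0, 1e6),
               class = "sk_parameter_error")
  expect_error(ca_event_spec("terminal_loss", "chrA", 2e6, 1e6),
               class = "sk_parameter_error")
  oc <- one_cell_counts(list())
  off <- ca_event_spec("terminal_loss", "chrA", 20e6, 60e6)
  expect_error(inject_event(oc$state, off), class = "sk_bounds_error")
  misaligned <- ca_event_spec("interstitial_loss", "chrA", 1e5 + 1, 5e6)
  expect_error(inject_event(oc$state, misaligned), class = "sk_validation_error")
  expect_error(quick_sim(2, sister_fraction = 2), class = "sk_parameter_error")
})

test_that("sister daughters inherit complementary templates and mirrored SCEs", {
  g <- tiny_genome(); grid <- tiny_grid(g)
  set.seed(31)
  pr <- simulate_sister_pair(list(grid = grid), outcome = "none",
                             config = sk_config(sce_mean = 3))
  ta <- pr$state_a$template; tb <- pr$state_b$template
  live <- ta != 0L
  expect_true(all(ta[live] + tb[live] == 3L))  # exact complements everywhere
  expect_equal(nrow(pr$state_a$sces), nrow(pr$state_b$sces))
  if (nrow(pr$state_a$sces)) {
    expect_equal(pr$state_a$sces$boundary_bin, pr$state_b$sces$boundary_bin)
    expect_true(all(pr$state_a$sces$orientation != pr$state_b$sces$orientation))
  }
})

test_that("a dicentric-bridge pair carries reciprocal inverted dup / loss", {
  g <- tiny_genome(); grid <- tiny_grid(g)
  set.seed(8)
  pr <- simulate_sister_pair(list(grid = grid), outcome = "bfb_bridge",
                             cells = c("a", "b"))
  tr <- pr$truth
  expect_equal(nrow(tr), 2L)
  expect_setequal(tr$class, c("terminal_inverted_duplication", "terminal_loss"))
  expect_equal(length(unique(tr$chrom)), 1L)
  expect_equal(length(unique(tr$hap)), 1L)
  expect_equal(length(unique(tr$start)), 1L)
  expect_equal(sum(tr$delta), 0L)
})
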