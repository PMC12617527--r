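test_that("read-end classification is a partition into the four categories", {
  ref <- trna_reference("Ser-AGA-1", mature_len = 82, leader_len = 10, trailer_len = 8)
  mature3 <- 10 + 82 + 3
  expect_equal(classify_read_end(mature3, "GGTCCA", ref), "charged_mature")
  expect_equal(classify_read_end(mature3 - 1, "GGTCC", ref), "uncharged_mature")
  expect_equal(classify_read_end(mature3 + 4, "GGTAAC", ref), "pre")
  expect_equal(classify_read_end(mature3, "GGTCC", ref, read_start = 2), "pre")
  expect_equal(classify_read_end(mature3 - 5, "GGTGG", ref), "ambiguous")
  expect_equal(classify_read_end(mature3, "GGTGG", ref), "ambiguous")
  expect_error(classify_read_end(200, "CCA", ref), "outside reference bounds")

  # every (end, terminal) combination maps to exactly one category
  cats <- c("charged_mature", "uncharged_mature", "pre", "ambiguous")
  for (end in c(mature3 - 2, mature3 - 1, mature3, mature3 + 1)) {
    for (term in c("CCA", "TCC", "GGA")) {
      out <- classify_read_end(end, term, ref)
      expect_length(out, 1)
      expect_true(out %in% cats)
    }
  }
  expect_error(trna_reference("X-YYY-1", mature_len = 20), "50-150")
})

test_that("charging fraction is the CCA share of mature reads", {
  expect_equal(charging_fraction(50, 50), 50)
  expect_true(is.na(charging_fraction(0, 0)))
  expect_equal(charging_fraction(70, 30), 70)
  expect_error(charging_fraction(-1, 5), "non-negative")
})

test_that("charging estimator recovers simulated truth (binomial draws)", {
  # truth 70% charging at depth 1000; small replicate set (the acceptance
  # suite runs the full 200-replicate version)
  truth <- data.frame(isodecoder_id = "Ser-AGA-1", condition = "x",
                      level = 1, charging = 0.7, pre_frac = 0,
                      stringsAsFactors = FALSE)
  est <- vapply(1:40, function(i) {
    cfg <- sim_config(seed = 5000 + i, trna_truth = truth, trna_depth = 1000L)
    counts <- simulate_trna_seq(cfg)$counts
    charging_fraction(counts$n_cca, counts$n_cc)
  }, numeric(1))
  expect_lt(abs(mean(est) - 70), 1)
  # normal-approximation CI coverage
  ci_covers <- vapply(1:40, function(i) {
    cfg <- sim_config(seed = 5000 + i, trna_truth = truth, trna_depth = 1000L)
    counts <- simulate_trna_seq(cfg)$counts
    n <- counts$n_cca + counts$n_cc
    phat <- counts$n_cca / n
    se <- sqrt(phat * (1 - phat) / n)
    (0.7 >= phat - 1.96 * se) && (0.7 <= phat + 1.96 * se)
  }, logical(1))
  expect_gte(mean(ci_covers), 0.9)
})

test_that("isoacceptor aggregation sums isodecoders and conserves totals", {
  counts <- data.frame(
    isodecoder_id = c("Ser-AGA-1", "Ser-AGA-2", "Ser-GCU-1", "Arg-ACG-1"),
    condition = "rich",
    n_cca = c(10, 5, 7, 3),
    n_cc = c(2, 1, 4, 6),
    n_pre = c(1, 0, 2, 1),
    stringsAsFactors = FALSE
  )
  iso <- sum_isoacceptors(counts)
  aga <- iso[iso$isoacceptor_id == "Ser-AGA", ]
  expect_equal(aga$n_cca, 15)
  expect_equal(aga$n_mature, 18)
  expect_equal(sum(iso$n_cca), sum(counts$n_cca))
  expect_equal(sum(iso$n_pre), sum(counts$n_pre))

  empty <- sum_isoacceptors(counts[0, ])
  expect_equal(nrow(empty), 0)

  # brute-force group-by oracle on a random mixed table
  set.seed(8)
  big <- data.frame(
    isodecoder_id = paste0(sample(c("Ser-AGA", "Ser-GCU", "Leu-CAA", "Arg-ACG"),
                                  40, replace = TRUE),
                           "-", sample(1:3, 40, replace = TRUE)),
    condition = sample(c("rich", "deprived"), 40, replace = TRUE),
    n_cca = sample(0:50, 40, replace = TRUE),
    n_cc = sample(0:50, 40, replace = TRUE),
    n_pre = sample(0:10, 40, replace = TRUE),
    stringsAsFactors = FALSE
  )
  iso <- sum_isoacceptors(big)
  for (r in seq_len(nrow(iso))) {
    pick <- startsWith(big$isodecoder_id,
                       paste0(iso$isoacceptor_id[r], "-")) &
      big$condition == iso$condition[r]
    expect_equal(iso$n_cca[r], sum(big$n_cca[pick]))
    expect_equal(iso$n_cc[r], sum(big$n_cc[pick]))
    expect_equal(iso$n_pre[r], sum(big$n_pre[pick]))
  }
  expect_error(sum_isoacceptors(data.frame(isodecoder_id = "bad", condition = "c",
                                           n_cca = 1, n_cc = 1, n_pre = 0)),
               "unparseable")
})

test_that("charged level multiplies charging percentage into the mature pool", {
  expect_equal(charged_level(50, 100), 50)
  expect_equal(charged_level(0, 123), 0)
  expect_equal(charged_level(100, 77), 77)
  expect_true(is.na(charged_level(NA_real_, 10)))
})

test_that("cpm normalization", {
  expect_equal(cpm_normalize(10, 1e6), 10)
  expect_equal(cpm_normalize(0, 1234), 0)
  expect_equal(cpm_normalize(5, 5e6), 1)
  expect_error(cpm_normalize(5, 0), "library_size")
})

test_that("isoacceptor ratios normalize within the pool and report the pairwise shift", {
  eq <- stats::setNames(rep(10, 4), c("Ser-AGA", "Ser-CGA", "Ser-UGA", "Ser-GCU"))
  res <- isoacceptor_ratio_table(eq, pair = c("Ser-AGA", "Ser-GCU"))
  expect_equal(res$table$ratio_in_pool, rep(0.25, 4))
  expect_equal(res$pairwise, 1)
  expect_equal(sum(res$table$ratio_in_pool), 1, tolerance = 1e-9)

  # knockout-like shift: GCU / 3, AGA / 2 from an equal baseline
  ko <- eq
  ko[["Ser-GCU"]] <- ko[["Ser-GCU"]] / 3
  ko[["Ser-AGA"]] <- ko[["Ser-AGA"]] / 2
  shifted <- isoacceptor_ratio_table(ko, pair = c("Ser-AGA", "Ser-GCU"))
  expect_equal(shifted$pairwise, 1.5)

  one_zero <- c("Ser-AGA" = 0, "Ser-GCU" = 5)
  expect_equal(isoacceptor_ratio_table(one_zero)$table$ratio_in_pool, c(0, 1))

  zeros <- c("Ser-AGA" = 0, "Ser-GCU" = 0)
  res0 <- isoacceptor_ratio_table(zeros, pair = c("Ser-AGA", "Ser-GCU"))
  expect_true(all(is.na(res0$table$ratio_in_pool)))
  expect_true(is.na(res0$pairwise))
  expect_equal(attr(res0, "flag"), "all_zero_pool")
})

test_that("charging_table pools sum to 1 per amino acid and recover simulated levels", {
  cfg <- sim_config(seed = 3, trna_depth = 2000L)
  sim <- simulate_trna_seq(cfg)
  ct <- charging_table(sim$counts)
  for (grp in split(ct, list(ct$amino_acid, ct$condition), drop = TRUE)) {
    ok <- !is.na(grp$ratio_in_pool)
    if (any(ok)) expect_equal(sum(grp$ratio_in_pool[ok]), 1, tolerance = 1e-9)
  }
  # conservation: isoacceptor totals equal isodecoder totals per condition
  for (cond in unique(ct$condition)) {
    expect_equal(sum(ct$n_mature[ct$condition == cond]),
                 sum(sim$counts$n_cca[sim$counts$condition == cond]) +
                   sum(sim$counts$n_cc[sim$counts$condition == cond]))
  }
})

test_that("charging and level estimates recover the generator truth within 5% relative error", {
  # depth chosen so counting noise sits inside the 5% band (pre-tRNA reads
  # are the scarcest class); recovery rate pooled over replicates
  within5 <- c()
  for (i in 1:20) {
    cfg <- sim_config(seed = 6000 + i, trna_depth = 50000L)
    sim <- simulate_trna_seq(cfg)
    ct <- charging_table(sim$counts)
    truth <- sim$truth
    truth$isoacceptor <- sub("-[0-9]+$", "", truth$isodecoder_id)
    for (cond in unique(ct$condition)) {
      sub <- ct[ct$condition == cond, ]
      tr <- truth[truth$condition == cond, ]
      true_charging <- 100 * tr$charging[1]
      lvl_true <- tapply(tr$level, tr$isoacceptor, sum)
      rel_true <- lvl_true[sub$isoacceptor_id] / sum(lvl_true)
      rel_mature <- sub$n_mature / sum(sub$n_mature)
      rel_pre <- sub$n_pre / sum(sub$n_pre)
      within5 <- c(
        within5,
        abs(sub$pct_charged - true_charging) / true_charging < 0.05,
        abs(rel_mature - rel_true) / rel_true < 0.05,
        abs(rel_pre - rel_true) / rel_true < 0.05
      )
    }
  }
  expect_gte(mean(within5), 0.95)
})
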