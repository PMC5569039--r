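# qPCR ddCt, Dunnett testing, FPKM, and the call rules.

make_ct <- function(target_dct, control_dct, ref_ct = 20, base = 25) {
  # build an exact Ct table realizing the requested per-replicate dCt values
  rows <- list()
  add <- function(gene, cond, rep, ct) {
    rows[[length(rows) + 1]] <<- data.frame(
      gene_id = gene, condition = cond, replicate = rep, ct = ct,
      stringsAsFactors = FALSE)
  }
  for (r in seq_along(control_dct)) {
    add("actin", "ctrl", r, ref_ct)
    add("gX", "ctrl", r, ref_ct + control_dct[r])
  }
  for (r in seq_along(target_dct)) {
    add("actin", "treat", r, ref_ct)
    add("gX", "treat", r, ref_ct + target_dct[r])
  }
  do.call(rbind, rows)
}

test_that("ddct closed forms hold", {
  # treatment dCt equal to the control mean: rq = 1
  ct <- make_ct(target_dct = c(2, 2, 2), control_dct = c(1.5, 2, 2.5))
  rq <- ddct(ct, "actin", "ctrl")
  expect_equal(rq$rq[rq$condition == "treat"], 1)
  # ddCt = -1 exactly: rq = 2
  ct2 <- make_ct(target_dct = c(1, 1, 1), control_dct = c(2, 2, 2))
  rq2 <- ddct(ct2, "actin", "ctrl")
  expect_equal(rq2$rq[rq2$condition == "treat"], 2)
  expect_equal(rq2$rq[rq2$condition == "ctrl"], 1)
})

test_that("ddct cancels any per-replicate constant shift", {
  set.seed(51)
  sim <- gen_ct_table("gA", conditions = c("c0", "c1"), fold_changes = 3,
                      sigma = 0.2, seed = 52)
  base <- ddct(sim$ct, "actin", "c0")
  shifted <- sim$ct
  key <- paste(shifted$condition, shifted$replicate)
  bump <- setNames(runif(length(unique(key)), -5, 5), unique(key))
  shifted$ct <- shifted$ct + bump[key]
  again <- ddct(shifted, "actin", "c0")
  expect_equal(base$rq, again$rq, tolerance = 1e-12)
})

test_that("geometric aggregation pins the control rq at exactly 1", {
  sim <- gen_ct_table("gA", conditions = c("c0", "c1"), fold_changes = 2,
                      sigma = 0.3, seed = 53)
  g <- ddct(sim$ct, "actin", "c0", method = "geometric")
  expect_equal(g$rq[g$condition == "c0"], 1, tolerance = 1e-12)
})

test_that("ddct drops replicates with missing reference and validates input", {
  ct <- make_ct(c(1, 1, 1), c(2, 2, 2))
  ct <- ct[!(ct$gene_id == "actin" & ct$condition == "treat" &
               ct$replicate == 3), ]
  rq <- suppressMessages(ddct(ct, "actin", "ctrl"))
  expect_equal(rq$n_reps[rq$condition == "treat"], 2)
  expect_error(ddct(ct, "nope", "ctrl"), "reference gene")
  expect_error(ddct(ct, "actin", "nope"), "control condition")
})

test_that("ddct recovers a true 4-fold induction within stated tolerance", {
  rqs <- vapply(1:100, function(s) {
    sim <- gen_ct_table("gA", conditions = c("c0", "c1"), fold_changes = 4,
                        sigma = 0.1, seed = 1000 + s)
    r <- ddct(sim$ct, "actin", "c0")
    r$rq[r$condition == "c1"]
  }, numeric(1))
  expect_gte(mean(rqs), 3.4)
  expect_lte(mean(rqs), 4.7)
})

test_that("dunnett with one group matches the pooled t-test oracle", {
  set.seed(54)
  for (rep in 1:5) {
    ctrl <- rnorm(sample(3:5, 1)); trt <- rnorm(sample(3:5, 1), mean = 1)
    d <- dunnett_test(ctrl, list(g = trt), n_draws = 200000, seed = rep)
    tt <- stats::t.test(trt, ctrl, var.equal = TRUE)
    expect_lt(abs(d$p - tt$p.value), 0.005)
  }
})

test_that("dunnett handles degenerate zero-variance input", {
  same <- dunnett_test(c(1, 1, 1), list(a = c(1, 1, 1)), seed = 1)
  expect_equal(same$p, 1)
  diff <- suppressMessages(
    dunnett_test(c(1, 1, 1), list(a = c(2, 2, 2)), seed = 1))
  expect_equal(diff$p, 0)
  expect_error(dunnett_test(c(1), list(a = c(1, 2))), "at least 2")
})

test_that("dunnett p-values decrease with |mean difference|", {
  set.seed(55)
  ctrl <- rnorm(4)
  noise <- rnorm(4)
  ps <- vapply(c(0.5, 1, 2, 4), function(shift) {
    dunnett_test(ctrl, list(a = noise + shift), n_draws = 50000,
                 seed = 7)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("qPCR calls apply the exact threshold mix", {
  grid <- data.frame(gene_id = "g", condition = "c",
                     rq = c(1.6, 0.60, 1.6, 1.5, 0.66, 0.67),
                     p = c(0.01, 0.01, 0.20, 0.01, 0.01, 0.01))
  out <- call_de_qpcr(grid)
  expect_equal(out$call,
               c("up", "down", "unchanged", "unchanged", "down", "unchanged"))
  # up and down sets are disjoint by construction over a random grid
  set.seed(56)
  g2 <- data.frame(gene_id = "g", condition = "c",
                   rq = exp(rnorm(200)), p = runif(200))
  o2 <- call_de_qpcr(g2)
  expect_equal(sum(o2$call == "up" & o2$call == "down"), 0)
  expect_true(all(o2$rq[o2$call == "up"] > 1.5 & o2$p[o2$call == "up"] < 0.05))
  expect_true(all(o2$rq[o2$call == "down"] <= 0.66 &
                    o2$p[o2$call == "down"] < 0.05))
})

test_that("fpkm matches hand computation and is scale invariant", {
  counts <- data.frame(
    gene_id = rep(c("a", "b", "c"), 2),
    sample = rep(c("s1", "s2"), each = 3),
    count = c(100, 200, 700, 50, 100, 350),
    length = rep(c(1000, 2000, 500), 2))
  f <- fpkm(counts)
  expect_equal(f$fpkm[1], 100 * 1e9 / (1000 * 1000))
  expect_equal(f$fpkm[2], 200 * 1e9 / (2000 * 1000))
  # single-sample toy from the contract: count 100, length 1000, total 100
  one <- fpkm(data.frame(gene_id = "a", sample = "s", count = 100,
                         length = 1000))
  expect_equal(one$fpkm, 1e6)
  doubled <- counts; doubled$count <- doubled$count * 2
  expect_equal(fpkm(doubled)$fpkm, f$fpkm)
  bad <- counts; bad$count[bad$sample == "s2"] <- 0
  expect_error(fpkm(bad), "zero total")
  expect_error(fpkm(transform(counts, length = 0)), "positive")
})

test_that("call_de_fpkm applies validity, thresholds and bootstrap", {
  ctrl <- rbind(g_up = c(100, 110, 90), g_low = c(5, 5, 5),
                g_flat = c(50, 55, 45), g_zero = c(0, 0, 0))
  trt <- rbind(g_up = c(210, 190, 200), g_low = c(5, 6, 4),
               g_flat = c(50, 55, 45), g_zero = c(20, 22, 18))
  out <- call_de_fpkm(ctrl, trt, seed = 3)
  expect_equal(out$call[out$gene_id == "g_up"], "up")
  expect_gte(out$deviation_probability[out$gene_id == "g_up"], 0.99)
  expect_false(out$valid[out$gene_id == "g_low"])
  expect_true(is.na(out$call[out$gene_id == "g_low"]))
  expect_equal(out$call[out$gene_id == "g_flat"], "unchanged")
  expect_equal(out$fold_change[out$gene_id == "g_flat"], 1)
  expect_equal(out$fold_change[out$gene_id == "g_zero"], Inf)
  expect_equal(out$call[out$gene_id == "g_zero"], "up")
  expect_error(call_de_fpkm(ctrl[, 1, drop = FALSE], trt), "2 replicates")
})
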