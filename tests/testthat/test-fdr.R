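hand_records <- function() {
  # 8 hand records: 4 with positive mutant log-likelihood, of which 3 are
  # predicted stabilising (2 TP, 1 FP); the other 4 contribute 2 more
  # predicted-stabilising records (1 TP, 1 FP)
  data.frame(
    protein_id = "P1",
    mutation = sprintf("AA%dV", 1:8),
    ddg_pred = c(-1, -1, -1, 1, -1, -1, 1, 1),
    ddg_exp = c(-2, -1, 1, -1, -1, 2, 1, 1),
    loglik_mut = c(1, 1, 1, 1, -1, -1, -1, -1),
    delta_loglik = c(0.5, -0.5, 0.5, 0.5, 0.5, 0.5, -0.5, -0.5),
    stringsAsFactors = FALSE)
}

test_that("classification counts and FDR match hand arithmetic", {
  r <- canonicalise_records(hand_records())
  full <- classify_and_fdr(r, "none")
  expect_equal(full$tp, 3)
  expect_equal(full$fp, 2)
  expect_equal(full$tn, 2)
  expect_equal(full$fn, 1)
  expect_equal(full$fdr, 2 / 5)
  expect_equal(full$n_kept, 8)

  filt <- classify_and_fdr(r, "ll_pos")
  expect_equal(filt$n_kept, 4)
  expect_equal(filt$fdr, 1 / 3)

  strict <- classify_and_fdr(r, "ll_and_delta")
  expect_equal(strict$n_kept, 3)  # records 1, 3 and 4
  expect_equal(c(strict$tp, strict$fp, strict$fn), c(1, 1, 1))
  expect_equal(strict$fdr, 1 / 2)
})

test_that("boundary ddG of zero counts as non-stabilising", {
  r <- canonicalise_records(data.frame(
    protein_id = "P", mutation = c("AA1V", "AA2V"),
    ddg_pred = c(0, -1), ddg_exp = c(-1, 0),
    loglik_mut = 1, delta_loglik = 1))
  res <- classify_and_fdr(r, "none")
  expect_equal(res$fn, 1)  # pred 0 >= 0 with exp < 0
  expect_equal(res$fp, 1)  # pred < 0 with exp 0 >= 0
  expect_equal(res$fdr, 1)
})

test_that("an empty predicted-stabilising set yields FDR zero", {
  r <- canonicalise_records(data.frame(
    protein_id = "P", mutation = c("AA1V", "AA2V"),
    ddg_pred = c(1, 2), ddg_exp = c(-1, 1),
    loglik_mut = 1, delta_loglik = 1))
  expect_equal(classify_and_fdr(r, "none")$fdr, 0)
})

test_that("sign conventions flip inputs into the canonical form", {
  raw <- hand_records()
  flipped <- raw
  flipped$ddg_exp <- -flipped$ddg_exp
  r1 <- canonicalise_records(raw)
  r2 <- canonicalise_records(flipped, exp_sign_convention = "pos_stabilising")
  expect_equal(r1$ddg_exp, r2$ddg_exp)
  expect_equal(classify_and_fdr(r2, "none")$fdr,
               classify_and_fdr(r1, "none")$fdr)
  bad <- raw; bad$ddg_pred[1] <- NA
  expect_error(canonicalise_records(bad), "non-finite")
})

test_that("the near-zero control filter needs and uses its threshold", {
  r <- canonicalise_records(data.frame(
    protein_id = "P", mutation = sprintf("AA%dV", 1:5),
    ddg_pred = c(-2, -1, -0.4, 0.3, 1.8), ddg_exp = c(-1, 1, -1, 1, 1),
    loglik_mut = 1, delta_loglik = 1))
  res <- classify_and_fdr(r, "abs_pred_ge", epsilon = 1)
  expect_error(classify_and_fdr(r, "abs_pred_ge"), "epsilon")
  expect_equal(res$n_kept, 3)  # |pred| in {2, 1, 1.8}
  expect_equal(res$fdr, 1 / 2)  # of the kept, pred < 0 for records 1 and 2
})

test_that("filtered FDR agrees with an independent row-scan oracle", {
  r <- make_ddg_benchmark(300, seed = 7)
  for (f in c("none", "ll_pos", "ll_and_delta")) {
    keep <- switch(f, none = rep(TRUE, nrow(r)),
                   ll_pos = r$loglik_mut > 0,
                   ll_and_delta = r$loglik_mut > 0 & r$delta_loglik > 0)
    oracle <- brute_force_fdr(r, keep)
    res <- classify_and_fdr(r, f)
    expect_equal(res$fdr, oracle$fdr)
    expect_equal(res$n_kept, oracle$n_kept)
    expect_equal(c(res$tp, res$fp, res$tn, res$fn),
                 c(oracle$tp, oracle$fp, oracle$tn, oracle$fn))
  }
})

test_that("the phylogenetic filters order the FDR as designed", {
  r <- make_ddg_benchmark(4000, seed = 11)
  tab <- fdr_benchmark(r, n_resample = 0)
  fdr <- stats::setNames(tab$fdr, tab$filter)
  expect_equal(unname(fdr["none"]), 0.30, tolerance = 0.04)
  expect_equal(unname(fdr["ll_and_delta"]), 0.15, tolerance = 0.04)
  expect_lt(fdr["ll_and_delta"], fdr["ll_pos"])
  expect_lt(fdr["ll_pos"], fdr["none"])
})

test_that("the resampling p-value matches exhaustive enumeration", {
  # 4 predicted-stabilising records out of 8; filter keeps 4 records.
  # With C(8,4) = 70 subsets the add-one estimate converges to the exact
  # subset fraction as the number of resamples grows.
  r <- canonicalise_records(hand_records())
  obs <- classify_and_fdr(r, "ll_pos")
  idx <- utils::combn(8, 4, simplify = FALSE)
  pred <- r$ddg_pred < 0; expv <- r$ddg_exp < 0
  frac <- mean(vapply(idx, function(i) {
    fp <- sum(pred[i] & !expv[i]); tp <- sum(pred[i] & expv[i])
    fdr <- if (fp + tp == 0) 0 else fp / (fp + tp)
    fdr <= obs$fdr
  }, logical(1)))
  res <- resampling_pvalue(r, "ll_pos", n_resample = 40000L, seed = 5)
  expect_equal(res$pvalue, frac, tolerance = 0.02)
  # valid p-value: never exactly zero thanks to the add-one correction
  expect_gt(res$pvalue, 0)
  expect_lte(res$pvalue, 1)
})

test_that("resampling is deterministic per seed and restores the RNG", {
  r <- make_ddg_benchmark(200, seed = 3)
  set.seed(99)
  before <- .Random.seed
  p1 <- resampling_pvalue(r, "ll_and_delta", n_resample = 500L, seed = 2)
  expect_identical(.Random.seed, before)
  p2 <- resampling_pvalue(r, "ll_and_delta", n_resample = 500L, seed = 2)
  expect_equal(p1$pvalue, p2$pvalue)
  p3 <- resampling_pvalue(r, "ll_and_delta", n_resample = 500L, seed = 3)
  # different seed gives an estimate of the same quantity, not the same draw
  expect_lt(abs(p3$pvalue - p1$pvalue), 0.1)
})

test_that("under a sign-independent filter the p-value is not significant", {
  # delta log-likelihood independent of the ddG signs: filtering is then a
  # uniform random subset and the observed FDR is typical, not depressed
  set.seed(42)
  n <- 400
  r <- canonicalise_records(data.frame(
    protein_id = "P", mutation = sprintf("AA%dV", 1:n),
    ddg_pred = sample(c(-1, 1), n, replace = TRUE),
    ddg_exp = sample(c(-1, 1), n, replace = TRUE),
    loglik_mut = rnorm(n), delta_loglik = rnorm(n)))
  p <- resampling_pvalue(r, "ll_pos", n_resample = 2000L, seed = 8)$pvalue
  expect_gt(p, 0.01)
})

test_that("benchmark CSV round-trips and validates columns", {
  r <- make_ddg_benchmark(50, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_benchmark_csv(r, f)
  r2 <- read_benchmark_csv(f)
  expect_equal(r2$ddg_pred, r$ddg_pred, tolerance = 1e-9)
  expect_equal(r2$ddg_exp, r$ddg_exp, tolerance = 1e-9)
  expect_equal(classify_and_fdr(r2, "none")$fdr,
               classify_and_fdr(r, "none")$fdr)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("protein_id,mutation,ddg_exp", bad)
  expect_error(read_benchmark_csv(bad), "missing column")
})
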