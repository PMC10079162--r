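# False-discovery-rate benchmark for stability predictions under
# phylogenetic filters, with explicit resampling significance.
#
# Sign convention: negative ddG = stabilising, for both experiment and
# prediction. A record is a False Positive when it is predicted stabilising
# (pred < 0) but experimentally destabilising (exp >= 0); boundary values
# (ddG = 0) count as non-stabilising.

#' Canonicalise benchmark records to the negative-stabilising convention
#'
#' @param records data frame with columns `protein_id`, `mutation`,
#'   `ddg_exp`, `ddg_pred`, `loglik_mut`, `delta_loglik`
#' @param exp_sign_convention `"neg_stabilising"` (default) or
#'   `"pos_stabilising"`; in the latter case experimental signs are flipped
#' @param pred_sign_convention same for predictions
#' @return records in canonical convention, with a `sign_flipped` attribute
#' @export
canonicalise_records <- function(records,
                                 exp_sign_convention = c("neg_stabilising",
                                                         "pos_stabilising"),
                                 pred_sign_convention = c("neg_stabilising",
                                                          "pos_stabilising")) {
  exp_sign_convention <- match.arg(exp_sign_convention)
  pred_sign_convention <- match.arg(pred_sign_convention)
  if (any(!is.finite(records$ddg_exp)) || any(!is.finite(records$ddg_pred)))
    stop("non-finite ddG values in benchmark records")
  flipped <- c(exp = FALSE, pred = FALSE)
  if (exp_sign_convention == "pos_stabilising") {
    records$ddg_exp <- -records$ddg_exp; flipped["exp"] <- TRUE
  }
  if (pred_sign_convention == "pos_stabilising") {
    records$ddg_pred <- -records$ddg_pred; flipped["pred"] <- TRUE
  }
  attr(records, "sign_flipped") <- flipped
  records
}

# filter specification -> logical keep vector
apply_benchmark_filter <- function(records, filter, epsilon = NULL) {
  switch(filter,
         none = rep(TRUE, nrow(records)),
         ll_pos = records$loglik_mut > 0,
         ll_and_delta = records$loglik_mut > 0 & records$delta_loglik > 0,
         abs_pred_ge = {
           if (is.null(epsilon)) stop("abs_pred_ge filter needs epsilon")
           abs(records$ddg_pred) >= epsilon
         },
         stop("unknown filter: ", filter))
}

#' Classify predictions and compute the false discovery rate
#'
#' Keeps the records passing the phylogenetic filter and classifies each by
#' the signs of predicted and experimental ddG: TP (both < 0), FP (pred < 0,
#' exp >= 0), TN (both >= 0), FN (pred >= 0, exp < 0). The FDR is
#' `FP / (FP + TP)` (0 when nothing is predicted stabilising).
#'
#' @param records canonicalised benchmark records
#' @param filter one of `"none"`, `"ll_pos"` (log-likelihood > 0),
#'   `"ll_and_delta"` (log-likelihood > 0 and delta log-likelihood > 0),
#'   `"abs_pred_ge"` (|predicted ddG| >= `epsilon`, the near-zero control)
#' @param epsilon threshold for the `abs_pred_ge` filter (kcal/mol)
#' @return object of class `fdr_result`: counts `tp`, `fp`, `tn`, `fn`,
#'   `fdr`, `filter`, `n_kept`
#' @export
classify_and_fdr <- function(records,
                             filter = c("none", "ll_pos", "ll_and_delta",
                                        "abs_pred_ge"),
                             epsilon = NULL) {
  filter <- match.arg(filter)
  keep <- apply_benchmark_filter(records, filter, epsilon)
  kept <- records[keep, , drop = FALSE]
  if (nrow(kept) == 0) stop("no records pass filter '", filter, "'")
  pred_stab <- kept$ddg_pred < 0
  exp_stab <- kept$ddg_exp < 0
  tp <- sum(pred_stab & exp_stab)
  fp <- sum(pred_stab & !exp_stab)
  tn <- sum(!pred_stab & !exp_stab)
  fn <- sum(!pred_stab & exp_stab)
  fdr <- if (fp + tp == 0) 0 else fp / (fp + tp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, fdr = fdr,
                 filter = filter, epsilon = epsilon, n_kept = nrow(kept),
                 pvalue = NA_real_),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf(
    "FDR %.4f under filter '%s' (n=%d: TP=%d FP=%d TN=%d FN=%d)%s\n",
    x$fdr, x$filter, x$n_kept, x$tp, x$fp, x$tn, x$fn,
    if (is.na(x$pvalue)) "" else sprintf(", p=%.4g", x$pvalue)))
  invisible(x)
}

#' Resampling significance of a filtered FDR
#'
#' Tests whether the FDR obtained under the filter is lower than expected
#' for a random subset of the same size: `n_resample` uniform subsets
#' (without replacement) of the full record set are drawn, and
#' `p = (1 + #{resampled FDR <= observed}) / (n_resample + 1)`. This
#' separates the effect of the specific filter from a generic reduction of
#' the dataset size. Deterministic given the seed.
#'
#' @param records canonicalised benchmark records
#' @param filter as in [classify_and_fdr()]
#' @param epsilon threshold for `abs_pred_ge`
#' @param n_resample number of random subsets
#' @param seed integer seed
#' @return an `fdr_result` with the `pvalue` field set
#' @export
resampling_pvalue <- function(records, filter, epsilon = NULL,
                              n_resample = 10000L, seed = 1L) {
  obs <- classify_and_fdr(records, filter, epsilon)
  if (obs$fp + obs$tp == 0)
    stop("filtered subset has no predicted-stabilising records")
  k <- obs$n_kept
  n <- nrow(records)
  if (k > n) stop("subset size exceeds record count")
  pred_stab <- records$ddg_pred < 0
  exp_stab <- records$ddg_exp < 0
  fp_all <- pred_stab & !exp_stab
  tp_all <- pred_stab & exp_stab
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_resample)) {
    idx <- sample.int(n, k)
    fp <- sum(fp_all[idx]); tp <- sum(tp_all[idx])
    fdr <- if (fp + tp == 0) 0 else fp / (fp + tp)
    if (fdr <= obs$fdr) hits <- hits + 1L
  }
  obs$pvalue <- (1 + hits) / (n_resample + 1)
  obs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read a benchmark CSV
#'
#' Expected columns: `protein_id,mutation,ddg_exp,ddg_pred,loglik_mut,
#' delta_loglik`.
#' @param path CSV path
#' @inheritParams canonicalise_records
#' @return canonicalised record data frame
#' @export
read_benchmark_csv <- function(path,
                               exp_sign_convention = "neg_stabilising",
                               pred_sign_convention = "neg_stabilising") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "mutation", "ddg_exp", "ddg_pred",
            "loglik_mut", "delta_loglik")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("benchmark CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  canonicalise_records(df, exp_sign_convention, pred_sign_convention)
}

#' Run the FDR benchmark over a set of filters
#'
#' @param records canonicalised records
#' @param filters character vector of filters (see [classify_and_fdr()])
#' @param epsilon threshold used when `"abs_pred_ge"` is included
#' @param n_resample resamples for significance (0 disables p-values)
#' @param seed integer seed
#' @return data frame, one row per filter
#' @export
fdr_benchmark <- function(records,
                          filters = c("none", "ll_pos", "ll_and_delta"),
                          epsilon = 0.5, n_resample = 10000L, seed = 1L) {
  rows <- lapply(filters, function(f) {
    res <- if (n_resample > 0 && f != "none")
      resampling_pvalue(records, f, epsilon, n_resample, seed)
    else classify_and_fdr(records, f, epsilon)
    data.frame(filter = f, n_kept = res$n_kept, tp = res$tp, fp = res$fp,
               tn = res$tn, fn = res$fn, fdr = res$fdr,
               pvalue = res$pvalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
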