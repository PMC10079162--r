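# Pluggable stability-change (ddG) prediction. Negative values are
# stabilising. Ships a deterministic physicochemical surrogate and a CSV
# table adapter for values computed by an external energy function;
# replicate aggregation and chain-multiplicity propagation are shared.

#' Construct a ddG estimate
#' @param mean_kcal_mol predicted mean ddG (kcal/mol, negative = stabilising)
#' @param sd_kcal_mol standard deviation over runs
#' @param n_runs number of replicate runs
#' @param multiplicity chain multiplicity already applied to `propagated`
#' @return object of class `ddg_estimate`
#' @export
ddg_estimate <- function(mean_kcal_mol, sd_kcal_mol = 0, n_runs = 1L,
                         multiplicity = 1L) {
  stopifnot(sd_kcal_mol >= 0, n_runs >= 1)
  structure(list(mean = mean_kcal_mol, sd = sd_kcal_mol,
                 n_runs = as.integer(n_runs),
                 multiplicity = as.integer(multiplicity),
                 propagated = mean_kcal_mol * multiplicity),
            class = "ddg_estimate")
}

#' @export
print.ddg_estimate <- function(x, ...) {
  cat(sprintf("ddG %.3f +/- %.3f kcal/mol (n=%d, x%d -> %.3f)\n",
              x$mean, x$sd, x$n_runs, x$multiplicity, x$propagated))
  invisible(x)
}

#' Multiply a single-chain ddG by the identity-group size
#'
#' The ddG is calculated on one chain for efficiency; for identical chains
#' the mutation is present once per chain, so the propagated value is the
#' mean times the group size. Mean and sd are left unchanged.
#'
#' @param estimate a `ddg_estimate`
#' @param group_size number of chains in the identity group (>= 1)
#' @return updated `ddg_estimate`
#' @export
propagate_multiplicity <- function(estimate, group_size) {
  if (group_size < 1) stop("group_size must be >= 1")
  estimate$multiplicity <- as.integer(group_size)
  estimate$propagated <- estimate$mean * group_size
  estimate
}

#' Deterministic surrogate ddG predictor
#'
#' A transparent additive model over burial-weighted physicochemical terms:
#' with burial `b = 1 - exposure` at the site,
#' `ddG = c_h * b * (h_wt - h_mut) + c_v * b * max(0, V_mut - V_wt)/100 +`
#' (h the z-scored hydropathy, V residue volume in cubic Angstrom)
#' `+
#'  c_P * [mut is Pro] + c_G * [wt is Gly] + sum of pair terms with
#' context mutations whose sites contact this site`. Hydrophobic-to-polar
#' substitutions in the core and over-packing are penalised; prolines and
#' mutations of glycines carry fixed penalties. Context dependence enters
#' only through explicit `pair_terms`, so the predictor is exactly additive
#' when none are given.
#'
#' @param structure a `protein_structure`
#' @param exposure named exposure vector
#' @param mutation list or one-row data frame with `chain`, `resno`, `icode`,
#'   `wt`, `mut` (and optionally `key`)
#' @param context data frame of already-applied mutations (same columns), or
#'   NULL
#' @param pair_terms optional named numeric vector: `"key1|key2"` (sorted
#'   keys) -> kcal/mol added when both sites are mutated and in contact
#' @param cmap `contact_map`, required when `pair_terms` are given
#' @param coef named list of coefficients `c_h`, `c_v`, `c_P`, `c_G`
#' @return a `ddg_estimate` (n_runs = 1, sd = 0)
#' @export
surrogate_ddg <- function(structure, exposure, mutation, context = NULL,
                          pair_terms = NULL, cmap = NULL,
                          coef = list(c_h = 0.8, c_v = 1.0,
                                      c_P = 1.0, c_G = 0.5)) {
  m <- as.list(mutation)
  if (is.null(m$icode)) m$icode <- ""
  key <- if (!is.null(m$key)) m$key else res_key(m$chain, m$resno, m$icode)
  ch <- structure$chains[[m$chain]]
  if (is.null(ch)) stop("unknown chain id: ", m$chain)
  res <- ch$residues
  ri <- which(res$key == key)
  if (length(ri) != 1) stop("mutation site not found: ", key)
  if (res$aa[ri] != m$wt)
    stop("wild-type mismatch at ", key, ": structure has ", res$aa[ri],
         ", mutation says ", m$wt)
  if (!m$mut %in% AA_ALPHABET) stop("unknown residue type: ", m$mut)
  if (!m$wt %in% AA_ALPHABET) stop("unknown residue type: ", m$wt)
  if (m$mut == m$wt) return(ddg_estimate(0, 0, 3L))
  b <- 1 - exposure[[key]]
  val <- coef$c_h * b * (AA_HYDROPATHY_Z[[m$wt]] - AA_HYDROPATHY_Z[[m$mut]]) +
    coef$c_v * b * max(0, AA_VOLUME[[m$mut]] - AA_VOLUME[[m$wt]]) / 100 +
    coef$c_P * (m$mut == "P") + coef$c_G * (m$wt == "G")
  if (!is.null(pair_terms) && !is.null(context) && NROW(context) > 0) {
    if (is.null(cmap)) stop("pair_terms require a contact map")
    for (i in seq_len(NROW(context))) {
      cx <- as.list(context[i, , drop = FALSE])
      ckey <- if (!is.null(cx$key)) cx$key else
        res_key(cx$chain, cx$resno, if (is.null(cx$icode)) "" else cx$icode)
      if (ckey == key) next
      if (in_contact(cmap, key, ckey))
        val <- val + pair_term_value(pair_terms, key, ckey)
    }
  }
  # deterministic model: three nominal runs, identical by construction
  ddg_estimate(unname(val), 0, 3L)
}

pair_term_key <- function(key1, key2) {
  paste(sort(c(key1, key2)), collapse = "|")
}

pair_term_value <- function(pair_terms, key1, key2) {
  k <- pair_term_key(key1, key2)
  if (k %in% names(pair_terms)) unname(pair_terms[[k]]) else 0
}

#' ddG predictor backed by a CSV table
#'
#' Reads a table with columns `mutation_name`, `ddg` and optionally `run`,
#' as produced by an external energy function, and returns a predictor
#' function `f(mutation_name) -> ddg_estimate` aggregating replicates
#' (mean, sd, n). The predictor is context-independent.
#'
#' @param csv_path path to the ddG table
#' @return function of one argument (mutation name)
#' @export
table_ddg_adapter <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (!all(c("mutation_name", "ddg") %in% names(df)))
    stop("ddG table must have columns mutation_name, ddg")
  function(mutation_name) {
    vals <- df$ddg[df$mutation_name == mutation_name]
    if (length(vals) == 0)
      stop("no ddG value in table for mutation: ", mutation_name)
    # SD over the runs themselves (population form), as replicate spread
    sdv <- sqrt(mean((vals - mean(vals))^2))
    ddg_estimate(mean(vals), sdv, length(vals))
  }
}

#' Export ddG estimates to the CSV dialect read by [table_ddg_adapter()]
#' @param names character vector of mutation names
#' @param estimates list of `ddg_estimate` (parallel to `names`); replicate
#'   rows are expanded as mean only when sd = 0
#' @param path output path
#' @export
write_ddg_csv <- function(names, estimates, path) {
  rows <- mapply(function(nm, e) {
    data.frame(mutation_name = nm, ddg = rep(e$mean, e$n_runs),
               run = seq_len(e$n_runs))
  }, names, estimates, SIMPLIFY = FALSE)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
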