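# Transparent sequence-based solubility model: per-residue intrinsic profile
# from physicochemical scales, window smoothing, a single global score, and
# the structure-corrected profile combining exposure and 3-D neighbourhoods.
# Higher values mean more soluble; negative profile regions are
# aggregation-prone.

# raw per-residue solubility propensity before window averaging
raw_residue_score <- function(aa, w_hydro = 1.0, w_charge = 0.5, w_beta = 0.5) {
  r <- numeric(length(aa))
  std <- aa %in% AA_ALPHABET
  a <- aa[std]
  r[std] <- w_hydro * (-AA_HYDROPATHY_Z[a]) +
    w_charge * abs(AA_CHARGE[a]) +
    w_beta * (-AA_BETA_Z[a])
  r  # non-standard ('X') residues score 0
}

#' Intrinsic solubility profile of a sequence
#'
#' Each residue gets a raw score combining z-scored hydropathy (more
#' hydrophobic = less soluble), absolute net charge at pH 7 (charged = more
#' soluble) and z-scored beta-sheet propensity (beta-prone = less soluble);
#' the profile is the mean of raw scores over a sliding window (default 7
#' residues) truncated at the termini.
#'
#' @param sequence amino-acid string (20 standard letters plus `X`)
#' @param window odd window length for local averaging
#' @param weights named list with `hydro`, `charge`, `beta` weights
#' @return numeric vector, one value per residue
#' @export
intrinsic_profile <- function(sequence, window = 7,
                              weights = list(hydro = 1.0, charge = 0.5,
                                             beta = 0.5)) {
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) == 0) stop("empty sequence")
  r <- raw_residue_score(aa, weights$hydro, weights$charge, weights$beta)
  n <- length(r)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(r[lo:hi])
  }, 0)
}

#' Global solubility score of one or more chains
#'
#' Over the concatenated intrinsic profiles of all chains,
#' `G = mean(p) - (1/L) * sum(max(0, -1 - p))`: the mean profile value minus a
#' penalty for residues in poorly soluble regions (profile below -1).
#' One number per sequence set; a complex scores its chains jointly.
#'
#' @param sequences character vector of amino-acid strings
#' @param window,weights passed to [intrinsic_profile()]
#' @return single numeric score (higher = more soluble)
#' @export
global_score <- function(sequences, window = 7,
                         weights = list(hydro = 1.0, charge = 0.5,
                                        beta = 0.5)) {
  if (any(!nzchar(sequences))) stop("empty sequence")
  p <- unlist(lapply(sequences, intrinsic_profile,
                     window = window, weights = weights))
  mean(p) - sum(pmax(0, -1 - p)) / length(p)
}

#' Structure-corrected solubility profile
#'
#' Reweights the intrinsic profile by solvent exposure and the 3-D
#' neighbourhood: `ptilde_i = e_i * mean(p over {i} + contacts(i))`. Buried
#' residues (exposure near zero) score near zero; low-scoring exposed patches
#' are aggregation hotspots. Only residues with coordinates get a value.
#'
#' @param structure a `protein_structure`
#' @param exposure named exposure vector from [relative_exposure()]
#' @param cmap a `contact_map` on the same structure
#' @param intrinsic named list: per chain id, the chain's intrinsic profile in
#'   comparison-sequence space (from [intrinsic_profile()])
#' @return named numeric vector keyed by residue key
#' @export
structural_profile <- function(structure, exposure, cmap, intrinsic) {
  # intrinsic value per residue key (residues with coordinates only)
  pkey <- c()
  for (ch in names(structure$chains)) {
    pos <- seqres_positions(structure, ch)
    keys <- structure$chains[[ch]]$residues$key
    vals <- intrinsic[[ch]][pos]
    vals[is.na(vals)] <- 0
    pkey[keys] <- vals
  }
  out <- vapply(names(pkey), function(k) {
    nb <- contacts_of(cmap, k)
    nb <- nb[nb %in% names(pkey)]
    if (!k %in% names(exposure)) return(NA_real_)
    e <- exposure[[k]]
    e * sum(pkey[c(k, nb)]) / (1 + length(nb))
  }, 0)
  out[!is.na(out)]
}

#' Change in global solubility score upon mutation
#'
#' Applies each mutation to every chain of its identity group (identical
#' chains are encoded by one gene, so a logical mutation hits all copies),
#' recomputes the global score of the full sequence set and subtracts the
#' wild-type score.
#'
#' @param wt_chains named character vector: chain id -> comparison sequence
#' @param mutations data frame with columns `chain`, `seq_pos`, `wt`, `mut`
#'   (one row per logical mutation; `chain` is the representative chain)
#' @param groups identity groups (list of chain-id vectors)
#' @param window,weights passed through to [global_score()]
#' @return numeric: mutant minus wild-type global score
#' @export
delta_solubility <- function(wt_chains, mutations, groups,
                             window = 7,
                             weights = list(hydro = 1.0, charge = 0.5,
                                            beta = 0.5)) {
  mut_chains <- apply_mutations(wt_chains, mutations, groups)
  if (identical(mut_chains, wt_chains)) return(0)
  global_score(unname(mut_chains), window = window, weights = weights) -
    global_score(unname(wt_chains), window = window, weights = weights)
}

#' Apply logical mutations to a set of chain sequences
#'
#' Each mutation is mirrored to all chains of the identity group containing
#' its chain. Errors if the wild-type letter does not match the sequence.
#'
#' @inheritParams delta_solubility
#' @return named character vector of mutant sequences
#' @export
apply_mutations <- function(wt_chains, mutations, groups) {
  out <- wt_chains
  if (is.null(mutations) || nrow(mutations) == 0) return(out)
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    grp <- Filter(function(g) m$chain %in% g, groups)
    targets <- if (length(grp)) grp[[1]] else m$chain
    for (ch in targets) {
      if (!ch %in% names(out)) next
      s <- out[[ch]]
      have <- substr(s, m$seq_pos, m$seq_pos)
      wt_orig <- substr(wt_chains[[ch]], m$seq_pos, m$seq_pos)
      if (wt_orig != m$wt)
        stop("wild-type mismatch for mutation ", m$wt, ch, m$seq_pos, m$mut,
             ": sequence has ", wt_orig)
      substr(s, m$seq_pos, m$seq_pos) <- m$mut
      out[[ch]] <- s
    }
  }
  out
}

#' Export solubility profiles as CSV
#' @param structure a `protein_structure`
#' @param intrinsic named list of per-chain intrinsic profiles
#' @param corrected named vector from [structural_profile()]
#' @param path output path
#' @export
write_profiles_csv <- function(structure, intrinsic, corrected, path) {
  rows <- list()
  for (ch in names(structure$chains)) {
    seq <- chain_sequence(structure, ch)
    pos <- seqres_positions(structure, ch)
    res <- structure$chains[[ch]]$residues
    keymap <- stats::setNames(res$key, pos)
    n <- nchar(seq)
    key <- keymap[as.character(seq_len(n))]
    corr <- ifelse(is.na(key), NA_real_, unname(corrected[key]))
    rows[[ch]] <- data.frame(chain = ch, seq_pos = seq_len(n),
                             aa = strsplit(seq, "")[[1]],
                             residue_key = ifelse(is.na(key), "", key),
                             intrinsic = intrinsic[[ch]],
                             corrected = corr)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
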