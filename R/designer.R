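# Core design pipeline: candidate-site selection, single mutational scan,
# Mutation Score, combination into multi-mutation designs, group selection,
# final shortlist, interaction check and antigen-contact flagging.

#' Format a mutation name
#'
#' Concatenates WT amino acid, chain id, author residue number, insertion
#' code (if any) and mutant amino acid, e.g. `LA24D` for Leu 24 of chain A
#' mutated to Asp.
#'
#' @param wt,mut one-letter amino-acid codes
#' @param chain single-character chain id
#' @param resno integer residue number
#' @param icode insertion code or `""`
#' @return character name
#' @export
mutation_name <- function(wt, chain, resno, icode = "", mut) {
  icode[is.na(icode)] <- ""
  paste0(wt, chain, resno, icode, mut)
}

#' Parse a mutation name
#'
#' Inverse of [mutation_name()].
#' @param name mutation name string
#' @return list with `wt`, `chain`, `resno`, `icode`, `mut`
#' @export
parse_mutation_name <- function(name) {
  m <- regmatches(name, regexec(
    "^([A-Z])(.)(-?[0-9]+)([A-Za-z]?)([A-Z])$", name))[[1]]
  if (length(m) == 0) stop("unparsable mutation name: ", name)
  list(wt = m[2], chain = m[3], resno = as.integer(m[4]),
       icode = m[5], mut = m[6])
}

#' Combined Mutation Score
#'
#' `MS = w_s * delta_solubility - w_g * ddg_propagated + w_p *
#' delta_loglik_norm`: strictly increasing in the solubility gain and the
#' normalised phylogenetic support, strictly decreasing in the (propagated)
#' stability change.
#'
#' @param delta_solubility change in global solubility score
#' @param ddg_propagated propagated ddG (kcal/mol, negative = stabilising)
#' @param delta_loglik_norm normalised delta log-likelihood
#' @param weights named vector/list with `w_s`, `w_g`, `w_p` (all positive)
#' @return numeric score
#' @export
mutation_score <- function(delta_solubility, ddg_propagated,
                           delta_loglik_norm,
                           weights = c(w_s = 1, w_g = 1, w_p = 1)) {
  weights[["w_s"]] * delta_solubility - weights[["w_g"]] * ddg_propagated +
    weights[["w_p"]] * delta_loglik_norm
}

#' Default configuration for the design pipeline
#'
#' @param pssm_mode substitution filter: `"ll_and_delta"` (default) or
#'   `"ll_pos"`
#' @param min_exposure relative solvent exposure from which a site counts as
#'   exposed
#' @param theta_seq intrinsic-profile threshold below which a residue is a
#'   sequence-solubility liability
#' @param theta_str corrected-profile threshold below which a residue belongs
#'   to a surface aggregation hotspot
#' @param ci_min minimum conservation index for conservation sites
#' @param ci_consensus conservation index above which a consensus wild type
#'   blocks exposed-solubility sites
#' @param max_sites cap on the number of candidate sites
#' @param excluded_targets substitution targets never proposed
#' @param excluded_chains chains never mutated
#' @param excluded_positions residue keys (`"A:33"`) never mutated
#' @param antigen_chains chains treated as antigen (never designed; used for
#'   contact flagging)
#' @param antigen_cutoff heavy-atom distance (Angstrom) for antigen contacts
#' @param max_mutations maximum simultaneous mutations in a design
#' @param contact_cutoff heavy-atom distance (Angstrom) for the contact map
#' @param window solubility window length
#' @param sol_weights weights of the intrinsic solubility model
#' @param score_weights Mutation Score weights
#' @param pseudocount PSSM pseudocount
#' @param probe,sphere_points SASA parameters
#' @param seed integer seed recorded with every run
#' @return list of class `design_config`
#' @export
design_config <- function(pssm_mode = "ll_and_delta",
                          min_exposure = 0.10,
                          theta_seq = -1.0,
                          theta_str = -0.5,
                          ci_min = 0.25,
                          ci_consensus = 0.7,
                          max_sites = 100L,
                          excluded_targets = c("C", "M"),
                          excluded_chains = character(0),
                          excluded_positions = character(0),
                          antigen_chains = character(0),
                          antigen_cutoff = 4.5,
                          max_mutations = 5L,
                          contact_cutoff = 8.0,
                          window = 7L,
                          sol_weights = list(hydro = 1.0, charge = 0.5,
                                             beta = 0.5),
                          score_weights = c(w_s = 1, w_g = 1, w_p = 1),
                          pseudocount = 1.0,
                          probe = 1.4,
                          sphere_points = 256L,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(pssm_mode %in% c("ll_and_delta", "ll_pos"))
  class(cfg) <- "design_config"
  cfg
}

# chains that may carry mutations, one representative per identity group
designable_representatives <- function(structure, config) {
  banned <- union(config$excluded_chains, config$antigen_chains)
  reps <- character(0)
  for (g in structure$identity_groups) {
    ok <- setdiff(g, banned)
    if (length(ok)) reps <- c(reps, ok[1])
  }
  reps
}

group_of_chain <- function(structure, chain) {
  for (g in structure$identity_groups) if (chain %in% g) return(g)
  chain
}

#' Select candidate mutation sites
#'
#' Builds the site list from four categories: poorly soluble exposed residues
#' of the sequence profile (`sequence_solubility`), members of surface
#' aggregation hotspots in the corrected profile (`structure_solubility`),
#' conserved positions where the wild type is weakly supported
#' (`conservation`), and exposed positions with a solubilising permitted
#' substitution (`exposed_solubility`) unless highly conserved with a
#' consensus wild type. User-supplied `custom_sites` are appended. If the
#' first three categories already reach the site cap, the fourth is discarded
#' entirely; otherwise its sites are added by descending best achievable
#' solubility gain until the cap is reached.
#'
#' @param structure a `protein_structure` (identity groups resolved)
#' @param pssms named list: representative chain id -> `pssm`
#' @param exposure named exposure vector
#' @param profiles list with `intrinsic` (per-chain profiles) and `corrected`
#'   (named vector by residue key)
#' @param config a `design_config`
#' @param custom_sites character vector of residue keys
#' @return data frame of candidate sites with an `identified_from` column
#' @export
select_sites <- function(structure, pssms, exposure, profiles, config,
                         custom_sites = character(0)) {
  reps <- designable_representatives(structure, config)
  rows <- list()
  for (ch in reps) {
    pssm <- pssms[[ch]]
    if (is.null(pssm)) stop("no PSSM for designable chain ", ch)
    seq <- chain_sequence(structure, ch)
    n <- nchar(seq)
    if (nrow(pssm$matrix) != n)
      stop("PSSM for chain ", ch, " has ", nrow(pssm$matrix),
           " positions but sequence has ", n)
    pos2key <- rep(NA_character_, n)
    sp <- seqres_positions(structure, ch)
    res <- structure$chains[[ch]]$residues
    pos2key[sp[!is.na(sp)]] <- res$key[!is.na(sp)]
    grp <- group_of_chain(structure, ch)
    wts <- strsplit(seq, "")[[1]]
    for (i in seq_len(n)) {
      wt <- wts[i]
      if (wt == "X") next
      key <- pos2key[i]
      if (!is.na(key) && key %in% config$excluded_positions) next
      expo <- if (!is.na(key) && key %in% names(exposure))
        unname(exposure[[key]]) else NA_real_
      intr <- profiles$intrinsic[[ch]][i]
      corr <- if (!is.na(key) && key %in% names(profiles$corrected))
        unname(profiles$corrected[[key]]) else NA_real_
      ci <- pssm$conservation[i]
      exposed <- !is.na(expo) && expo >= config$min_exposure
      cats <- character(0)
      if (exposed && intr < config$theta_seq)
        cats <- c(cats, "sequence_solubility")
      if (!is.na(corr) && corr < config$theta_str)
        cats <- c(cats, "structure_solubility")
      if (ci > config$ci_min && wt_is_low(pssm, i, wt))
        cats <- c(cats, "conservation")
      best_dsol <- NA_real_
      if (exposed && !(ci > config$ci_consensus && wt == pssm$consensus[i])) {
        subs <- allowed_substitutions(pssm, i, wt, config$pssm_mode)
        if (length(subs)) {
          wt_chains <- all_chain_sequences(structure)
          dsols <- vapply(subs, function(a) {
            delta_solubility(wt_chains,
                             data.frame(chain = ch, seq_pos = i,
                                        wt = wt, mut = a),
                             structure$identity_groups,
                             window = config$window,
                             weights = config$sol_weights)
          }, 0)
          if (any(dsols > 0)) {
            cats <- c(cats, "exposed_solubility")
            best_dsol <- max(dsols)
          }
        }
      }
      if (length(cats) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, seq_pos = i,
        resno = if (!is.na(key)) res$resno[match(key, res$key)] else NA_integer_,
        icode = if (!is.na(key)) res$icode[match(key, res$key)] else "",
        key = ifelse(is.na(key), "", key), wt = wt,
        exposure = expo, conservation = ci,
        intrinsic = intr, corrected = corr,
        identified_from = paste(cats, collapse = ";"),
        best_dsol = best_dsol,
        group_size = length(grp),
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    utils::head(data.frame(chain = character(), seq_pos = integer(),
                           resno = integer(), icode = character(),
                           key = character(), wt = character(),
                           exposure = numeric(), conservation = numeric(),
                           intrinsic = numeric(), corrected = numeric(),
                           identified_from = character(),
                           best_dsol = numeric(), group_size = integer()), 0)

  has_core <- grepl("sequence_solubility|structure_solubility|conservation",
                    sites$identified_from)
  cat4_only <- !has_core
  if (sum(has_core) >= config$max_sites) {
    # the first three classes already fill the cap: class 4 is discarded
    sites$identified_from <- gsub(";?exposed_solubility", "",
                                  sites$identified_from)
    sites$identified_from <- sub("^;", "", sites$identified_from)
    sites <- sites[!cat4_only, , drop = FALSE]
  } else if (any(cat4_only)) {
    room <- config$max_sites - sum(has_core)
    extra <- which(cat4_only)
    extra <- extra[order(-sites$best_dsol[extra])]
    drop4 <- extra[-seq_len(min(room, length(extra)))]
    if (length(drop4)) sites <- sites[-drop4, , drop = FALSE]
  }

  # user-requested custom sites, appended regardless of the categories
  for (key in custom_sites) {
    at <- structure$atoms[structure$atoms$key == key, , drop = FALSE]
    if (nrow(at) == 0) stop("custom site not found in structure: ", key)
    ch <- at$chain[1]
    if (!ch %in% designable_representatives(structure, config))
      stop("custom site ", key, " is not on a designable chain")
    if (key %in% sites$key) {
      i <- match(key, sites$key)
      sites$identified_from[i] <- paste(sites$identified_from[i], "custom",
                                        sep = ";")
      next
    }
    sp <- seqres_positions(structure, ch)
    res <- structure$chains[[ch]]$residues
    i <- match(key, res$key)
    pos <- sp[i]
    sites <- rbind(sites, data.frame(
      chain = ch, seq_pos = pos, resno = res$resno[i], icode = res$icode[i],
      key = key, wt = res$aa[i],
      exposure = if (key %in% names(exposure)) unname(exposure[[key]]) else NA,
      conservation = pssms[[ch]]$conservation[pos],
      intrinsic = profiles$intrinsic[[ch]][pos],
      corrected = if (key %in% names(profiles$corrected))
        unname(profiles$corrected[[key]]) else NA,
      identified_from = "custom", best_dsol = NA,
      group_size = length(group_of_chain(structure, ch)),
      stringsAsFactors = FALSE))
  }
  rownames(sites) <- NULL
  sites$best_dsol <- NULL
  sites
}

#' @keywords internal
all_chain_sequences <- function(structure) {
  vapply(names(structure$chains),
         function(ch) chain_sequence(structure, ch), "")
}

#' Wrap the bundled surrogate as a stability predictor
#'
#' Returns a function `f(mutation, context)` evaluating [surrogate_ddg()]
#' with fixed structure, exposure and (optional) pair terms.
#'
#' @inheritParams surrogate_ddg
#' @return predictor closure
#' @export
make_surrogate_predictor <- function(structure, exposure, pair_terms = NULL,
                                     cmap = NULL,
                                     coef = list(c_h = 0.8, c_v = 1.0,
                                                 c_P = 1.0, c_G = 0.5)) {
  function(mutation, context = NULL) {
    surrogate_ddg(structure, exposure, mutation, context = context,
                  pair_terms = pair_terms, cmap = cmap, coef = coef)
  }
}

#' Wrap a ddG CSV table as a stability predictor
#'
#' The returned predictor looks mutations up by name and ignores context.
#' @param csv_path path to the ddG table (see [table_ddg_adapter()])
#' @return predictor closure `f(mutation, context)`
#' @export
make_table_predictor <- function(csv_path) {
  adapter <- table_ddg_adapter(csv_path)
  function(mutation, context = NULL) adapter(as.list(mutation)$name)
}

#' Single mutational scan
#'
#' At every candidate site, each substitution permitted by the PSSM (minus
#' the excluded targets, cysteine and methionine by default) is evaluated:
#' change in global solubility (mutation mirrored across the identity group),
#' ddG on one chain propagated by group size, and delta log-likelihood.
#' Substitutions predicted to decrease solubility are discarded unless the
#' site is a non-exposed conservation site; substitutions with propagated
#' ddG >= 0 are discarded. All attempts are reported with their drop reason.
#'
#' @param sites data frame from [select_sites()]
#' @param structure a `protein_structure`
#' @param pssms named list of `pssm` by representative chain
#' @param stability predictor closure `f(mutation, context)`
#' @param exposure named exposure vector
#' @param config a `design_config`
#' @return list with `attempts` (all substitutions, `kept` flag and
#'   `drop_reason`) and `shortlist` (survivors with `delta_loglik_norm` and
#'   `mutation_score` filled in)
#' @export
single_scan <- function(sites, structure, pssms, stability, exposure,
                        config) {
  wt_chains <- all_chain_sequences(structure)
  rows <- list()
  for (s in seq_len(nrow(sites))) {
    site <- sites[s, ]
    pssm <- pssms[[site$chain]]
    subs <- allowed_substitutions(pssm, site$seq_pos, site$wt,
                                  config$pssm_mode)
    subs <- setdiff(subs, config$excluded_targets)
    if (length(subs) == 0) next
    cats <- strsplit(site$identified_from, ";")[[1]]
    buried_cons <- "conservation" %in% cats &&
      (is.na(site$exposure) || site$exposure < config$min_exposure)
    has_coords <- nzchar(site$key)
    for (a in subs) {
      mut <- data.frame(chain = site$chain, resno = site$resno,
                        icode = site$icode, seq_pos = site$seq_pos,
                        wt = site$wt, mut = a,
                        key = site$key, stringsAsFactors = FALSE)
      mut$name <- mutation_name(site$wt, site$chain, site$resno,
                                site$icode, a)
      dsol <- delta_solubility(wt_chains, mut, structure$identity_groups,
                               window = config$window,
                               weights = config$sol_weights)
      drop <- ""
      if (dsol < 0 && !buried_cons) drop <- "solubility"
      ddg_mean <- NA_real_; ddg_sd <- NA_real_; ddg_prop <- NA_real_
      if (drop == "" && has_coords) {
        est <- stability(mut, NULL)
        est <- propagate_multiplicity(est, site$group_size)
        ddg_mean <- est$mean; ddg_sd <- est$sd; ddg_prop <- est$propagated
        if (ddg_prop >= 0) drop <- "ddg"
      } else if (drop == "" && !has_coords) {
        drop <- "no_coordinates"
      }
      dll <- pssm_value(pssm, site$seq_pos, a) -
        pssm_value(pssm, site$seq_pos, site$wt)
      rows[[length(rows) + 1L]] <- data.frame(
        mut, site_key = site$key, identified_from = site$identified_from,
        exposure = site$exposure, group_size = site$group_size,
        delta_solubility = dsol, ddg_mean = ddg_mean, ddg_sd = ddg_sd,
        ddg_propagated = ddg_prop, delta_loglik = dll,
        kept = drop == "", drop_reason = drop,
        stringsAsFactors = FALSE)
    }
  }
  attempts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), icode = character(),
               seq_pos = integer(), wt = character(), mut = character(),
               key = character(), name = character(), site_key = character(),
               identified_from = character(), exposure = numeric(),
               group_size = integer(), delta_solubility = numeric(),
               ddg_mean = numeric(), ddg_sd = numeric(),
               ddg_propagated = numeric(), delta_loglik = numeric(),
               kept = logical(), drop_reason = character())
  shortlist <- attempts[attempts$kept, , drop = FALSE]
  if (nrow(shortlist)) {
    shortlist <- normalize_delta_loglik(shortlist, pssms)
    shortlist$mutation_score <- mutation_score(
      shortlist$delta_solubility, shortlist$ddg_propagated,
      shortlist$delta_loglik_norm, config$score_weights)
    shortlist <- shortlist[order_records(shortlist), , drop = FALSE]
    rownames(shortlist) <- NULL
  } else {
    shortlist$delta_loglik_norm <- numeric(0)
    shortlist$mutation_score <- numeric(0)
  }
  rownames(attempts) <- NULL
  list(attempts = attempts, shortlist = shortlist)
}

# deterministic ranking: score desc, then ddG asc, dsol desc, name
order_records <- function(df, score = df$mutation_score) {
  order(-score, df$ddg_propagated, -df$delta_solubility, df$name,
        method = "radix")
}

#' Normalise delta log-likelihoods across chains
#'
#' Divides each record's delta log-likelihood by the standard deviation of
#' all entries of its chain's PSSM matrix, making values comparable between
#' chains; a degenerate constant matrix yields 0.
#'
#' @param records data frame with `chain` and `delta_loglik`
#' @param pssms named list of `pssm`
#' @return records with a `delta_loglik_norm` column
#' @export
normalize_delta_loglik <- function(records, pssms) {
  sds <- vapply(pssms, function(p) stats::sd(as.numeric(p$matrix)), 0)
  s <- sds[records$chain]
  records$delta_loglik_norm <- ifelse(is.na(s) | s == 0, 0,
                                      records$delta_loglik / s)
  records
}

#' Combine shortlisted point mutations into multi-mutation designs
#'
#' Single mutants with a negative Mutation Score are discarded first. Designs
#' are built for sizes 2..`max_mutations` with at most one mutation per
#' logical site; ddGs and normalised delta log-likelihoods are summed while
#' the solubility change is recomputed on the fully mutated sequences. From
#' triples onward only the top-ranking substitution per site is considered.
#' A design is flagged `potentially_interacting` when at least two of its
#' sites are in structural contact. Each group (designs of equal size) is
#' ranked by Mutation Score.
#'
#' @param shortlist survivors of [single_scan()] (with scores)
#' @param max_mutations largest design size to build
#' @param cmap a `contact_map`
#' @param structure a `protein_structure`
#' @param config a `design_config`
#' @return named list: design size -> ranked data frame of designs
#' @export
combine_mutations <- function(shortlist, max_mutations, cmap, structure,
                              config) {
  if (max_mutations < 1) stop("max_mutations must be >= 1")
  recs <- shortlist[shortlist$mutation_score >= 0, , drop = FALSE]
  groups_out <- list()
  if (nrow(recs) == 0) return(groups_out)
  recs <- recs[order_records(recs), , drop = FALSE]
  wt_chains <- all_chain_sequences(structure)
  singles <- data.frame(
    n = 1L, mutations = recs$name, ddg_sum = recs$ddg_propagated,
    delta_loglik_norm_sum = recs$delta_loglik_norm,
    delta_solubility = recs$delta_solubility,
    mutation_score = recs$mutation_score,
    potentially_interacting = FALSE, checked = FALSE,
    stringsAsFactors = FALSE)
  groups_out[["1"]] <- rank_group(singles)

  make_design <- function(idx) {
    sel <- recs[idx, , drop = FALSE]
    dsol <- delta_solubility(wt_chains, sel, structure$identity_groups,
                             window = config$window,
                             weights = config$sol_weights)
    ddg <- sum(sel$ddg_propagated)
    dll <- sum(sel$delta_loglik_norm)
    data.frame(
      n = length(idx),
      mutations = paste(sel$name, collapse = ";"),
      ddg_sum = ddg, delta_loglik_norm_sum = dll,
      delta_solubility = dsol,
      mutation_score = mutation_score(dsol, ddg, dll, config$score_weights),
      potentially_interacting = sites_interact(sel, cmap, structure),
      checked = FALSE, stringsAsFactors = FALSE)
  }

  # pairs: every combination of surviving substitutions at distinct sites
  if (max_mutations >= 2 && nrow(recs) >= 2) {
    pair_idx <- utils::combn(nrow(recs), 2, simplify = FALSE)
    pair_idx <- Filter(function(ij)
      recs$site_key[ij[1]] != recs$site_key[ij[2]] ||
        recs$seq_pos[ij[1]] != recs$seq_pos[ij[2]] ||
        recs$chain[ij[1]] != recs$chain[ij[2]], pair_idx)
    if (length(pair_idx)) {
      pairs <- do.call(rbind, lapply(pair_idx, make_design))
      groups_out[["2"]] <- rank_group(pairs)
    }
  }

  # triples onward: only the top substitution per logical site
  site_id <- paste(recs$chain, recs$seq_pos)
  top_idx <- which(!duplicated(site_id))  # recs already ranked
  n_sites <- length(top_idx)
  n <- 3L
  while (n <= max_mutations && n <= n_sites) {
    combos <- utils::combn(top_idx, n, simplify = FALSE)
    designs <- do.call(rbind, lapply(combos, make_design))
    groups_out[[as.character(n)]] <- rank_group(designs)
    n <- n + 1L
  }
  groups_out
}

# at least two mutation sites (mirrored across identity groups) in contact
sites_interact <- function(sel, cmap, structure) {
  keysets <- lapply(seq_len(nrow(sel)), function(i)
    mutation_keys(sel[i, ], structure))
  nm <- length(keysets)
  if (nm < 2) return(FALSE)
  for (i in seq_len(nm - 1)) for (j in (i + 1):nm) {
    for (ki in keysets[[i]]) for (kj in keysets[[j]])
      if (ki != kj && in_contact(cmap, ki, kj)) return(TRUE)
  }
  FALSE
}

# residue keys occupied by a logical mutation on every chain of its group
mutation_keys <- function(m, structure) {
  grp <- group_of_chain(structure, m$chain)
  keys <- res_key(grp, m$resno, m$icode)
  keys[keys %in% structure$atoms$key]
}

rank_group <- function(df) {
  df <- df[order_records_design(df), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

order_records_design <- function(df) {
  order(-df$mutation_score, df$ddg_sum, -df$delta_solubility, df$mutations,
        method = "radix")
}

#' Select the best design-size groups
#'
#' Looks for the point where the growth of the top Mutation Score per group
#' slows down: with `M(n)` the top score of the size-`n` group and
#' `g(n) = M(n) - M(n-1)`, a size `n` (with `2 <= n < N`) is selected when
#' the next gain `g(n+1)` falls below the mean of the gains so far. If no
#' size qualifies the largest group is the best; otherwise the largest group
#' is additionally included when the score is still growing into it at no
#' less than the average rate.
#'
#' @param groups named list of ranked design data frames (or a numeric vector
#'   of top scores per size)
#' @return integer vector of selected design sizes
#' @export
select_best_groups <- function(groups) {
  M <- if (is.numeric(groups)) groups else
    vapply(groups, function(g) g$mutation_score[1], 0)
  ns <- if (is.null(names(M))) seq_along(M) else as.integer(names(M))
  o <- order(ns); ns <- ns[o]; M <- M[o]
  N <- length(M)
  if (N <= 1) return(ns)
  g <- diff(M)  # g[k] = gain going from group ns[k] to ns[k+1]
  sel <- integer(0)
  for (k in seq_len(N - 2)) {
    # candidate knee after the (k+1)-th group
    if (g[k + 1] < mean(g[seq_len(k)])) sel <- c(sel, ns[k + 1])
  }
  if (length(sel) == 0) return(ns[N])
  if (g[N - 1] > 0 && g[N - 1] >= mean(g[seq_len(N - 2)]))
    sel <- c(sel, ns[N])
  sel
}

#' Final shortlist of designs
#'
#' Three top-ranking designs for each best group and the single top design of
#' every other group, ordered by design size then rank.
#'
#' @param groups named list of ranked design data frames
#' @param best_set integer vector from [select_best_groups()]
#' @return data frame of shortlisted designs with `best_group` flag
#' @export
final_shortlist <- function(groups, best_set) {
  out <- list()
  ns <- sort(as.integer(names(groups)))
  for (n in ns) {
    g <- groups[[as.character(n)]]
    take <- if (n %in% best_set) min(3L, nrow(g)) else min(1L, nrow(g))
    if (take == 0) next
    sel <- g[seq_len(take), , drop = FALSE]
    sel$best_group <- n %in% best_set
    out[[as.character(n)]] <- sel
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sequentially re-evaluate a potentially interacting design
#'
#' Mutations are applied one by one (descending single Mutation Score); the
#' ddG of each is recomputed in the context of those already applied. If a
#' mutation turns destabilising in context (ddG >= 0), up to three
#' alternative substitutions shortlisted for the same site are tried; if
#' none is stabilising the site is dropped. ddG sum, solubility change and
#' Mutation Score are recomputed from the in-context values and the design
#' is marked `checked`.
#'
#' @param design one-row design data frame (from [combine_mutations()] /
#'   [final_shortlist()]) with at least 2 mutations
#' @param stability predictor closure `f(mutation, context)`
#' @param scan_table the scan shortlist (ranked alternatives per site)
#' @param cmap a `contact_map`
#' @param structure a `protein_structure`
#' @param config a `design_config`
#' @return updated one-row design data frame
#' @export
interaction_check <- function(design, stability, scan_table, cmap,
                              structure, config) {
  names_in <- strsplit(design$mutations, ";")[[1]]
  if (length(names_in) < 2) stop("interaction check needs >= 2 mutations")
  recs <- scan_table[match(names_in, scan_table$name), , drop = FALSE]
  if (anyNA(recs$name)) stop("design mutation missing from scan table")
  recs <- recs[order_records(recs), , drop = FALSE]
  context <- recs[0, , drop = FALSE]
  kept <- list(); ddg_ctx <- numeric(0)
  for (i in seq_len(nrow(recs))) {
    cand <- recs[i, , drop = FALSE]
    est <- propagate_multiplicity(stability(cand, context), cand$group_size)
    if (est$propagated >= 0) {
      # try up to three ranked alternatives shortlisted for this site
      alts <- scan_table[scan_table$chain == cand$chain &
                           scan_table$seq_pos == cand$seq_pos &
                           scan_table$name != cand$name, , drop = FALSE]
      alts <- alts[order_records(alts), , drop = FALSE]
      alts <- utils::head(alts, 3L)
      cand <- NULL
      for (j in seq_len(nrow(alts))) {
        alt <- alts[j, , drop = FALSE]
        est_a <- propagate_multiplicity(stability(alt, context),
                                        alt$group_size)
        if (est_a$propagated < 0) {
          cand <- alt; est <- est_a
          break
        }
      }
      if (is.null(cand)) next  # disruptive site removed from the design
    }
    kept[[length(kept) + 1L]] <- cand
    ddg_ctx <- c(ddg_ctx, est$propagated)
    context <- rbind(context, cand)
  }
  sel <- do.call(rbind, kept)
  out <- design
  if (is.null(sel) || nrow(sel) == 0) {
    out$n <- 0L; out$mutations <- ""
    out$ddg_sum <- 0; out$delta_loglik_norm_sum <- 0
    out$delta_solubility <- 0; out$mutation_score <- 0
    out$potentially_interacting <- FALSE; out$checked <- TRUE
    return(out)
  }
  wt_chains <- all_chain_sequences(structure)
  dsol <- delta_solubility(wt_chains, sel, structure$identity_groups,
                           window = config$window,
                           weights = config$sol_weights)
  out$n <- nrow(sel)
  out$mutations <- paste(sel$name, collapse = ";")
  out$ddg_sum <- sum(ddg_ctx)
  out$delta_loglik_norm_sum <- sum(sel$delta_loglik_norm)
  out$delta_solubility <- dsol
  out$mutation_score <- mutation_score(dsol, out$ddg_sum,
                                       out$delta_loglik_norm_sum,
                                       config$score_weights)
  out$potentially_interacting <- sites_interact(sel, cmap, structure)
  out$checked <- TRUE
  out
}

#' Resolve the best design of a group via the interaction check
#'
#' Runs [interaction_check()] on the group's top design when it is flagged;
#' if the checked score drops below another group member, the group is
#' re-ranked and the check repeated on the new top design, at most three
#' times. Returns the group with checked designs substituted and re-ranked.
#'
#' @param group ranked data frame of designs of one size
#' @inheritParams interaction_check
#' @return re-ranked group data frame
#' @export
resolve_group <- function(group, stability, scan_table, cmap, structure,
                          config) {
  for (round in 1:3) {
    top <- group[1, , drop = FALSE]
    if (!isTRUE(top$potentially_interacting) || isTRUE(top$checked)) break
    checked <- interaction_check(top, stability, scan_table, cmap,
                                 structure, config)
    group[1, ] <- checked[, names(group), drop = FALSE]
    group <- rank_group(group)
    if (isTRUE(group$checked[1])) break
  }
  group
}

#' Flag mutations close to an antigen
#'
#' A mutation is flagged when any heavy atom of its wild-type residue (on any
#' chain of its identity group) lies within `cutoff` of any heavy atom of an
#' antigen chain. Flags are advisory and never alter scores.
#'
#' @param records data frame with `chain`, `resno`, `icode` columns
#' @param structure a `protein_structure`
#' @param antigen_chains chain ids of the antigen
#' @param cutoff heavy-atom distance cutoff in Angstrom
#' @return logical vector, one flag per record
#' @export
flag_antigen_contacts <- function(records, structure, antigen_chains,
                                  cutoff = 4.5) {
  unknown <- setdiff(antigen_chains, names(structure$chains))
  if (length(unknown))
    stop("unknown antigen chain id(s): ", paste(unknown, collapse = ", "))
  ag <- structure$atoms[structure$atoms$chain %in% antigen_chains, ,
                        drop = FALSE]
  agxyz <- as.matrix(ag[, c("x", "y", "z")])
  cut2 <- cutoff^2
  vapply(seq_len(NROW(records)), function(i) {
    m <- records[i, , drop = FALSE]
    keys <- mutation_keys(m, structure)
    at <- structure$atoms[structure$atoms$key %in% keys, , drop = FALSE]
    if (nrow(at) == 0 || nrow(ag) == 0) return(FALSE)
    for (k in seq_len(nrow(at))) {
      d2 <- (agxyz[, 1] - at$x[k])^2 + (agxyz[, 2] - at$y[k])^2 +
        (agxyz[, 3] - at$z[k])^2
      if (any(d2 <= cut2)) return(TRUE)
    }
    FALSE
  }, logical(1))
}
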