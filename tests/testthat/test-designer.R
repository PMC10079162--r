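test_that("mutation names round-trip, including insertion codes", {
  expect_equal(mutation_name("L", "A", 24, "", "D"), "LA24D")
  expect_equal(mutation_name("S", "H", 100, "a", "K"), "SH100aK")
  p <- parse_mutation_name("LA24D")
  expect_equal(p, list(wt = "L", chain = "A", resno = 24L, icode = "",
                       mut = "D"))
  p2 <- parse_mutation_name("SH100aK")
  expect_equal(p2$icode, "a")
  expect_equal(p2$resno, 100L)
  expect_error(parse_mutation_name("not a name"), "unparsable")
})

test_that("the Mutation Score combines the three terms with signed weights", {
  expect_equal(mutation_score(0.2, -1.5, 0.3), 0.2 + 1.5 + 0.3)
  w <- c(w_s = 2, w_g = 0.5, w_p = 1)
  expect_equal(mutation_score(0.2, -1.5, 0.3, w), 0.4 + 0.75 + 0.3)
  # increasing in solubility and support, decreasing in ddG
  expect_gt(mutation_score(0.3, -1, 0.1), mutation_score(0.2, -1, 0.1))
  expect_gt(mutation_score(0.2, -2, 0.1), mutation_score(0.2, -1, 0.1))
})

test_that("the configuration validates its mode and records defaults", {
  cfg <- design_config()
  expect_equal(cfg$pssm_mode, "ll_and_delta")
  expect_equal(cfg$min_exposure, 0.10)
  expect_equal(cfg$excluded_targets, c("C", "M"))
  expect_equal(cfg$max_mutations, 5L)
  expect_error(design_config(pssm_mode = "frequency"))
})

test_that("site selection finds the buried conserved liabilities of the demo", {
  fx <- demo_fixture()
  res <- demo_pipeline()
  sites <- res$sites
  expect_gt(nrow(sites), 0)
  # no sites on excluded or antigen chains
  expect_true(all(sites$chain == "A"))
  cons <- sites[grepl("conservation", sites$identified_from), ]
  expect_true(all(c(9, 16, 20) %in% cons$seq_pos))
  # conservation sites have CI above the floor and a weakly supported WT
  expect_true(all(cons$conservation > fx$config$ci_min))
  # the hydrophobic patch appears as sequence-solubility liabilities
  seqsol <- sites[grepl("sequence_solubility", sites$identified_from), ]
  expect_true(all(seqsol$intrinsic < fx$config$theta_seq))
  expect_true(all(seqsol$exposure >= fx$config$min_exposure))
})

test_that("the site cap discards the exposed-solubility class when full", {
  res <- demo_pipeline()
  fx <- demo_fixture()
  sites <- res$sites
  core <- grepl("sequence_solubility|structure_solubility|conservation",
                sites$identified_from)
  n_core <- sum(core)
  expect_gt(n_core, 0)
  cfg <- fx$config
  cfg$max_sites <- n_core
  pssms <- res$pssms
  capped <- select_sites(res$structure, pssms, res$exposure, res$profiles,
                         cfg)
  expect_equal(nrow(capped), n_core)
  expect_false(any(grepl("exposed_solubility", capped$identified_from)))
  # with one free slot exactly one class-4 site is admitted
  n4 <- sum(!core)
  if (n4 >= 2) {
    cfg$max_sites <- n_core + 1L
    one <- select_sites(res$structure, pssms, res$exposure, res$profiles,
                        cfg)
    expect_equal(nrow(one), n_core + 1L)
  }
})

test_that("custom sites are appended and validated", {
  res <- demo_pipeline()
  fx <- demo_fixture()
  sites <- select_sites(res$structure, res$pssms, res$exposure,
                        res$profiles, fx$config, custom_sites = "A:2")
  expect_true("custom" %in% sites$identified_from[sites$key == "A:2"] ||
                grepl("custom", sites$identified_from[sites$key == "A:2"]))
  expect_error(
    select_sites(res$structure, res$pssms, res$exposure, res$profiles,
                 fx$config, custom_sites = "A:999"),
    "not found")
  expect_error(
    select_sites(res$structure, res$pssms, res$exposure, res$profiles,
                 fx$config, custom_sites = "C:3"),
    "not on a designable chain")
})

test_that("the single scan drops and keeps substitutions for stated reasons", {
  res <- demo_pipeline()
  att <- res$scan$attempts
  sl <- res$scan$shortlist
  expect_gt(nrow(att), 0)
  expect_gt(nrow(sl), 0)
  expect_true(all(att$drop_reason %in%
                    c("", "solubility", "ddg", "no_coordinates")))
  expect_equal(att$kept, att$drop_reason == "")
  # excluded targets never proposed
  expect_false(any(att$mut %in% c("C", "M")))
  # every survivor is predicted stabilising after propagation
  expect_true(all(sl$ddg_propagated < 0))
  # survivors with negative solubility change sit at buried conservation sites
  neg <- sl[sl$delta_solubility < 0, ]
  if (nrow(neg)) {
    expect_true(all(grepl("conservation", neg$identified_from)))
    expect_true(all(neg$exposure < 0.10))
  }
  # homodimer: ddG propagated at twice the single-chain mean
  expect_true(all(sl$group_size == 2))
  expect_equal(sl$ddg_propagated, 2 * sl$ddg_mean, tolerance = 1e-12)
  # shortlist sorted by decreasing Mutation Score
  expect_true(all(diff(sl$mutation_score) <= 1e-12))
})

test_that("mutation scores on the shortlist follow the recorded components", {
  res <- demo_pipeline()
  sl <- res$scan$shortlist
  expect_equal(sl$mutation_score,
               sl$delta_solubility - sl$ddg_propagated + sl$delta_loglik_norm,
               tolerance = 1e-12)
})

test_that("delta log-likelihood normalisation divides by the matrix spread", {
  recs <- data.frame(chain = c("A", "B"), delta_loglik = c(1.0, 1.0))
  mat <- matrix(rnorm(40, sd = 2), nrow = 2)
  colnames(mat) <- AA_ALPHABET
  pA <- pssm_stub(mat)
  pB <- pssm_stub(matrix(1, nrow = 2, ncol = 20))  # degenerate, sd = 0
  out <- normalize_delta_loglik(recs, list(A = pA, B = pB))
  expect_equal(out$delta_loglik_norm[1], 1 / sd(as.numeric(mat)),
               tolerance = 1e-12)
  expect_equal(out$delta_loglik_norm[2], 0)
})

test_that("combinations pair distinct sites and recompute solubility jointly", {
  res <- demo_pipeline()
  groups <- res$groups
  expect_true("1" %in% names(groups))
  expect_true("2" %in% names(groups))
  sl <- res$scan$shortlist
  g2 <- groups[["2"]]
  for (i in seq_len(nrow(g2))) {
    nm <- strsplit(g2$mutations[i], ";")[[1]]
    expect_length(nm, 2)
    pr <- lapply(nm, parse_mutation_name)
    # never two substitutions at the same logical site
    expect_false(pr[[1]]$chain == pr[[2]]$chain &&
                   pr[[1]]$resno == pr[[2]]$resno)
  }
  # sums carried from the singles; solubility recomputed on the full mutant
  un2 <- g2[!g2$checked, , drop = FALSE]
  i <- 1
  nm <- strsplit(un2$mutations[i], ";")[[1]]
  recs <- sl[match(nm, sl$name), ]
  expect_equal(un2$ddg_sum[i], sum(recs$ddg_propagated), tolerance = 1e-12)
  expect_equal(un2$delta_loglik_norm_sum[i], sum(recs$delta_loglik_norm),
               tolerance = 1e-12)
  dsol <- delta_solubility(all_chain_sequences(res$structure), recs,
                           res$structure$identity_groups)
  expect_equal(un2$delta_solubility[i], dsol, tolerance = 1e-12)
  # each group ranked by decreasing score with dense ranks
  for (g in groups) {
    expect_true(all(diff(g$mutation_score) <= 1e-12))
    expect_equal(g$rank, seq_len(nrow(g)))
  }
})

test_that("from triples onward only the top substitution per site is used", {
  res <- demo_pipeline()
  expect_true("3" %in% names(res$groups))
  sl <- res$scan$shortlist
  g3 <- res$groups[["3"]]
  site_id <- paste(sl$chain, sl$seq_pos)
  top_per_site <- sl$name[!duplicated(site_id)]
  for (i in seq_len(nrow(g3))) {
    if (g3$checked[i]) next
    nm <- strsplit(g3$mutations[i], ";")[[1]]
    expect_true(all(nm %in% top_per_site))
  }
})

test_that("interaction flags reflect structural contacts between sites", {
  res <- demo_pipeline()
  cm <- res$contact_map
  sl <- res$scan$shortlist
  g2 <- res$groups[["2"]]
  un <- g2[!g2$checked, , drop = FALSE]
  for (i in seq_len(nrow(un))) {
    nm <- strsplit(un$mutations[i], ";")[[1]]
    keys <- sl$site_key[match(nm, sl$name)]
    expect_equal(un$potentially_interacting[i],
                 in_contact(cm, keys[1], keys[2]) ||
                   in_contact(cm, sub("^A", "B", keys[1]),
                              sub("^A", "B", keys[2])))
  }
  # sanity: the helix geometry separates distant sites
  expect_true(in_contact(cm, "A:16", "A:20"))
  expect_false(in_contact(cm, "A:9", "A:20"))
})

test_that("the knee rule picks the group where gains flatten", {
  # validated hand case: scores 1, 2, 3, 3.1 -> group 3 only
  expect_equal(select_best_groups(c(`1` = 1, `2` = 2, `3` = 3, `4` = 3.1)), 3L)
  # strictly linear growth has no knee: the largest group wins
  expect_equal(select_best_groups(c(`1` = 1, `2` = 2, `3` = 3, `4` = 4)), 4L)
  # early flattening keeps every flat group
  expect_equal(select_best_groups(c(`1` = 1, `2` = 3, `3` = 3.5, `4` = 3.6)),
               c(2L, 3L))
  # a late re-acceleration adds the largest group back
  expect_equal(select_best_groups(c(`1` = 1, `2` = 2, `3` = 2.1, `4` = 4)),
               c(2L, 4L))
  expect_equal(select_best_groups(c(`1` = 0.5)), 1L)
})

test_that("the final shortlist takes three of the best group, one elsewhere", {
  mk <- function(n, scores) {
    rank_group(data.frame(
      n = n, mutations = sprintf("d%d_%d", n, seq_along(scores)),
      ddg_sum = -1, delta_loglik_norm_sum = 0, delta_solubility = 0,
      mutation_score = scores, potentially_interacting = FALSE,
      checked = FALSE, stringsAsFactors = FALSE))
  }
  groups <- list(`1` = mk(1, c(1, 0.9, 0.8, 0.7)),
                 `2` = mk(2, c(2, 1.9, 1.8, 1.7)),
                 `3` = mk(3, c(3, 2.9, 2.8, 2.7)),
                 `4` = mk(4, c(3.1, 3.05)))
  fs <- final_shortlist(groups, select_best_groups(groups))
  expect_equal(sum(fs$n == 3), 3)
  expect_equal(sum(fs$n == 1), 1)
  expect_equal(sum(fs$n == 2), 1)
  expect_equal(sum(fs$n == 4), 1)
  expect_equal(nrow(fs), 6)
  expect_true(all(fs$best_group[fs$n == 3]))
  expect_false(any(fs$best_group[fs$n != 3]))
})

test_that("the interaction check is a no-op for an additive predictor", {
  res <- demo_pipeline()
  fx <- demo_fixture()
  sl <- res$scan$shortlist
  g2 <- combine_mutations(sl, 2, res$contact_map, res$structure,
                          fx$config)[["2"]]
  flagged <- g2[g2$potentially_interacting, , drop = FALSE]
  expect_gt(nrow(flagged), 0)
  pred <- make_surrogate_predictor(res$structure, res$exposure,
                                   cmap = res$contact_map)
  chk <- interaction_check(flagged[1, ], pred, sl, res$contact_map,
                           res$structure, fx$config)
  expect_true(chk$checked)
  expect_equal(chk$n, 2L)
  expect_equal(chk$ddg_sum, flagged$ddg_sum[1], tolerance = 1e-12)
  expect_equal(chk$mutation_score, flagged$mutation_score[1],
               tolerance = 1e-12)
  expect_error(interaction_check(res$groups[["1"]][1, ], pred, sl,
                                 res$contact_map, res$structure, fx$config),
               ">= 2 mutations")
})

test_that("a repulsive pair term forces an alternative or drops the site", {
  res <- demo_pipeline()
  fx <- demo_fixture()
  sl <- res$scan$shortlist
  g2 <- combine_mutations(sl, 2, res$contact_map, res$structure,
                          fx$config)[["2"]]
  flagged <- g2[g2$potentially_interacting, , drop = FALSE]
  nm <- strsplit(flagged$mutations[1], ";")[[1]]
  keys <- sl$site_key[match(nm, sl$name)]
  pt <- stats::setNames(100, pair_term_key(keys[1], keys[2]))
  pred <- make_surrogate_predictor(res$structure, res$exposure,
                                   pair_terms = pt, cmap = res$contact_map)
  chk <- interaction_check(flagged[1, ], pred, sl, res$contact_map,
                           res$structure, fx$config)
  expect_true(chk$checked)
  # all substitutions at the clashing site share the key, so no alternative
  # can rescue it: the design collapses to the first-applied mutation
  expect_equal(chk$n, 1L)
  expect_false(grepl(";", chk$mutations))
  expect_lt(chk$ddg_sum, 0)
})

test_that("resolve_group leaves groups with unflagged leaders untouched", {
  res <- demo_pipeline()
  fx <- demo_fixture()
  g2 <- res$groups[["2"]]
  g2$potentially_interacting <- FALSE
  g2$checked <- FALSE
  pred <- make_surrogate_predictor(res$structure, res$exposure,
                                   cmap = res$contact_map)
  out <- resolve_group(g2, pred, res$scan$shortlist, res$contact_map,
                       res$structure, fx$config)
  expect_equal(out, g2)
})

test_that("antigen contacts are flagged by proximity to the antigen chain", {
  res <- demo_pipeline()
  sl <- res$scan$shortlist
  flags <- flag_antigen_contacts(sl, res$structure, "G", 4.5)
  expect_length(flags, nrow(sl))
  # the antigen sits on the -x face of chain A; direct check by distance
  ag <- res$structure$atoms[res$structure$atoms$chain == "G", ]
  for (i in seq_len(nrow(sl))) {
    near <- FALSE
    for (k in c(sl$site_key[i], sub("^A", "B", sl$site_key[i]))) {
      at <- res$structure$atoms[res$structure$atoms$key == k, ]
      if (nrow(at) == 0) next
      for (j in seq_len(nrow(at))) {
        d <- sqrt((ag$x - at$x[j])^2 + (ag$y - at$y[j])^2 +
                    (ag$z - at$z[j])^2)
        if (any(d <= 4.5)) near <- TRUE
      }
    }
    expect_equal(flags[i], near)
  }
  expect_error(flag_antigen_contacts(sl, res$structure, "Q"),
               "unknown antigen chain")
})
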