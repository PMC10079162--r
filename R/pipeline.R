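# End-to-end orchestration: input processing, site selection, single scan,
# combination, shortlist, interaction check, antigen flagging, and emission
# of the CSV tables, FASTA and markdown report.

#' Run the full design pipeline
#'
#' Executes the pipeline stages in order: input processing (structure,
#' identity groups, PSSMs), candidate-site selection, single mutational
#' scanning, combination into multi-mutation designs, best-group selection
#' and final shortlist, and the interaction check on flagged top designs.
#' Writes `sites.csv`, `scan_attempts.csv`, `scan_shortlist.csv`,
#' `combinations.csv`, `final_designs.csv`, `designs.fasta`, `report.md`,
#' the resolved configuration and a log with per-stage counts into
#' `output_dir`.
#'
#' @param structure_path path to the input PDB file
#' @param msa_paths named character vector: representative chain id -> MSA
#'   path; a single unnamed path is used for every designable chain
#' @param output_dir output directory (created if missing)
#' @param config a [design_config()]
#' @param manual_groups optional manual identity groups (list of chain-id
#'   vectors)
#' @param custom_sites character vector of residue keys to add as custom
#'   candidate sites
#' @param msa_format `"fasta"` or `"a3m"`
#' @param stability optional stability predictor closure; defaults to the
#'   bundled surrogate
#' @return (invisibly) a list with all intermediate objects and the output
#'   directory
#' @export
run_design <- function(structure_path, msa_paths, output_dir,
                       config = design_config(), manual_groups = NULL,
                       custom_sites = character(0), msa_format = "fasta",
                       stability = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # (i) input processing
  ps <- stage("read_structure", read_structure(structure_path))
  if (!is.null(manual_groups))
    ps$identity_groups <- identity_groups(ps, manual_groups)
  say("structure: %d chain(s), %d identity group(s)",
      length(ps$chains), length(ps$identity_groups))
  reps <- designable_representatives(ps, config)
  if (length(reps) == 0) stop("no designable chains left after exclusions")
  if (is.null(names(msa_paths)) && length(msa_paths) == 1)
    msa_paths <- stats::setNames(rep(msa_paths, length(reps)), reps)
  pssms <- list()
  for (ch in reps) {
    if (!ch %in% names(msa_paths))
      stop("no MSA supplied for designable chain ", ch)
    msa <- stage("read_msa", read_msa(msa_paths[[ch]], msa_format))
    pssms[[ch]] <- stage("build_pssm",
                         build_pssm(msa, pseudocount = config$pseudocount))
    say("chain %s: %d aligned sequences -> %s matrix",
        ch, msa$n_sequences, pssms[[ch]]$kind)
  }

  expo <- stage("relative_exposure",
                relative_exposure(ps, probe = config$probe,
                                  sphere_points = config$sphere_points))
  cmap <- stage("contact_map", contact_map(ps, config$contact_cutoff))
  intr <- lapply(names(ps$chains), function(ch)
    intrinsic_profile(chain_sequence(ps, ch), window = config$window,
                      weights = config$sol_weights))
  names(intr) <- names(ps$chains)
  corr <- stage("structural_profile",
                structural_profile(ps, expo, cmap, intr))
  profiles <- list(intrinsic = intr, corrected = corr)

  # (ii) candidate mutation sites
  sites <- stage("select_sites",
                 select_sites(ps, pssms, expo, profiles, config,
                              custom_sites))
  say("candidate sites: %d", nrow(sites))

  # (iii) single mutational scanning
  if (is.null(stability))
    stability <- make_surrogate_predictor(ps, expo, cmap = cmap)
  scan <- stage("single_scan",
                single_scan(sites, ps, pssms, stability, expo, config))
  say("scan: %d attempted substitutions, %d shortlisted",
      nrow(scan$attempts), nrow(scan$shortlist))

  # (iv) combination and shortlist
  groups <- stage("combine",
                  combine_mutations(scan$shortlist, config$max_mutations,
                                    cmap, ps, config))
  say("combination groups: %s",
      paste(vapply(names(groups),
                   function(n) sprintf("n=%s:%d", n, nrow(groups[[n]])), ""),
            collapse = " "))
  finals <- NULL
  best <- integer(0)
  if (length(groups)) {
    best <- select_best_groups(groups)
    say("best group size(s): %s", paste(best, collapse = ", "))
    # (v) interaction check on flagged designs within each group shortlist
    for (n in names(groups)) {
      if (as.integer(n) < 2) next
      groups[[n]] <- resolve_group(groups[[n]], stability, scan$shortlist,
                                   cmap, ps, config)
    }
    groups <- reassign_checked(groups)
    finals <- final_shortlist(groups, best)
    say("final shortlist: %d design(s)", nrow(finals))
  } else {
    say("no surviving mutations; empty design set")
  }

  # antigen-contact flags (advisory)
  if (length(config$antigen_chains) && !is.null(finals) && nrow(finals)) {
    finals$antigen_contacts <- vapply(finals$mutations, function(ms) {
      recs <- scan$shortlist[match(strsplit(ms, ";")[[1]],
                                   scan$shortlist$name), , drop = FALSE]
      fl <- flag_antigen_contacts(recs, ps, config$antigen_chains,
                                  config$antigen_cutoff)
      paste(recs$name[fl], collapse = ";")
    }, "")
  }

  write_outputs(output_dir, ps, pssms, sites, scan, groups, best, finals,
                config, log_lines)
  invisible(list(structure = ps, pssms = pssms, exposure = expo,
                 contact_map = cmap, profiles = profiles, sites = sites,
                 scan = scan, groups = groups, best_groups = best,
                 finals = finals, output_dir = output_dir))
}

# a checked design whose site count shrank competes in its new group
reassign_checked <- function(groups) {
  for (n in names(groups)) {
    g <- groups[[n]]
    moved <- which(g$checked & g$n != as.integer(n) & g$n > 0)
    for (i in moved) {
      tgt <- as.character(g$n[i])
      row <- g[i, , drop = FALSE]
      if (tgt %in% names(groups))
        groups[[tgt]] <- rank_group(rbind(groups[[tgt]],
                                          row[, names(groups[[tgt]])]))
      else
        groups[[tgt]] <- rank_group(row)
    }
    if (length(moved)) groups[[n]] <- rank_group(g[-moved, , drop = FALSE])
  }
  groups[order(as.integer(names(groups)))]
}

write_outputs <- function(output_dir, ps, pssms, sites, scan, groups, best,
                          finals, config, log_lines) {
  p <- function(f) file.path(output_dir, f)
  utils::write.csv(sites, p("sites.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(scan$attempts, p("scan_attempts.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(scan$shortlist, p("scan_shortlist.csv"),
                   row.names = FALSE, quote = FALSE)
  combos <- if (length(groups)) do.call(rbind, unname(groups)) else
    data.frame()
  utils::write.csv(combos, p("combinations.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(finals))
    utils::write.csv(finals, p("final_designs.csv"), row.names = FALSE,
                     quote = FALSE)
  else
    utils::write.csv(data.frame(), p("final_designs.csv"),
                     row.names = FALSE)
  write_design_fasta(ps, scan$shortlist, finals, p("designs.fasta"))
  for (ch in names(pssms))
    write_pssm_csv(pssms[[ch]], p(sprintf("pssm_%s.csv", ch)))
  cfg <- unclass(config)
  yaml::write_yaml(cfg, p("config.yaml"))
  writeLines(log_lines, p("run.log"))
  write_report(p("report.md"), ps, pssms, sites, scan, groups, best, finals,
               config)
  invisible(output_dir)
}

write_design_fasta <- function(ps, shortlist, finals, path) {
  lines <- character(0)
  wt_chains <- all_chain_sequences(ps)
  if (!is.null(finals) && nrow(finals)) {
    for (i in seq_len(nrow(finals))) {
      if (!nzchar(finals$mutations[i])) next
      nm <- strsplit(finals$mutations[i], ";")[[1]]
      recs <- shortlist[match(nm, shortlist$name), , drop = FALSE]
      mut_chains <- apply_mutations(wt_chains, recs, ps$identity_groups)
      tag <- gsub(";", "_", finals$mutations[i])
      for (ch in names(mut_chains))
        lines <- c(lines,
                   sprintf(">design_n%d_rank%d_%s|chain_%s",
                           finals$n[i], finals$rank[i], tag, ch),
                   mut_chains[[ch]])
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_report <- function(path, ps, pssms, sites, scan, groups, best,
                         finals, config) {
  L <- c("# Design report", "",
         sprintf("Input structure: `%s`", ps$path),
         sprintf("Chains: %s", paste(names(ps$chains), collapse = ", ")),
         sprintf("Identity groups: %s",
                 paste(vapply(ps$identity_groups, paste, "",
                              collapse = ","), collapse = " | ")),
         "", "## PSSM summary", "")
  for (ch in names(pssms))
    L <- c(L, sprintf("- chain %s: %s matrix from %d sequences, %d positions",
                      ch, pssms[[ch]]$kind, pssms[[ch]]$n_sequences,
                      nrow(pssms[[ch]]$matrix)))
  L <- c(L, "", "## Candidate mutation sites", "",
         sprintf("%d site(s) selected (cap %d).", nrow(sites),
                 config$max_sites))
  if (nrow(sites)) {
    tab <- table(unlist(strsplit(sites$identified_from, ";")))
    L <- c(L, "", "Identified from:",
           sprintf("- %s: %d", names(tab), as.integer(tab)))
  }
  L <- c(L, "", "## Single mutational scanning", "",
         sprintf("%d substitutions attempted, %d shortlisted (mode `%s`).",
                 nrow(scan$attempts), nrow(scan$shortlist),
                 config$pssm_mode))
  if (nrow(scan$attempts)) {
    dr <- table(scan$attempts$drop_reason[scan$attempts$drop_reason != ""])
    if (length(dr))
      L <- c(L, "", "Dropped:",
             sprintf("- %s: %d", names(dr), as.integer(dr)))
  }
  L <- c(L, "", "## Combinations", "")
  if (length(groups)) {
    for (n in names(groups))
      L <- c(L, sprintf("- n=%s: %d design(s), top Mutation Score %.3f",
                        n, nrow(groups[[n]]),
                        groups[[n]]$mutation_score[1]))
    L <- c(L, "",
           sprintf("Best group size(s): %s.", paste(best, collapse = ", ")))
  } else L <- c(L, "No combinations (no surviving single mutations).")
  L <- c(L, "", "## Final designs", "")
  if (!is.null(finals) && nrow(finals)) {
    L <- c(L, "| n | rank | mutations | dCamSol-like | ddG sum | score |",
           "|---|------|-----------|--------------|---------|-------|")
    for (i in seq_len(nrow(finals)))
      L <- c(L, sprintf("| %d | %d | %s | %.3f | %.3f | %.3f |",
                        finals$n[i], finals$rank[i], finals$mutations[i],
                        finals$delta_solubility[i], finals$ddg_sum[i],
                        finals$mutation_score[i]))
  } else L <- c(L, "None.")
  writeLines(L, path)
  invisible(path)
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [design_config()]; missing keys keep their
#' defaults.
#' @param path YAML config path
#' @return a `design_config`
#' @export
read_design_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(design_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(design_config, vals)
}
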