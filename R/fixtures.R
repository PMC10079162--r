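# Deterministic synthetic inputs: ideal alpha-helix PDB files (backbone +
# C-beta), column-controlled multiple sequence alignments, and stratified
# synthetic ddG benchmark tables. Every generator is a pure function of its
# arguments (plus an explicit seed), so identical specs give byte-identical
# outputs.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) v / sqrt(sum(v^2))

# Natural extension of reference frame: place atom D bonded to C with bond
# length r, angle B-C-D theta, dihedral A-B-C-D phi (degrees).
place_atom <- function(a, b, c, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# ideal backbone + CB coordinates for one chain; returns data frame
helix_coords <- function(sequence, phi = -57, psi = -47, omega = 180) {
  aa <- strsplit(sequence, "")[[1]]
  n_res <- length(aa)
  # bond lengths / angles (standard peptide geometry)
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  b_ca_cb <- 1.521
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7
  a_ca_c_o <- 120.8; a_n_ca_cb <- 110.4
  rows <- list()
  # seed frame for residue 1
  N <- c(0, 0, 0)
  CA <- c(b_n_ca, 0, 0)
  ang <- a_n_ca_c * pi / 180
  C <- CA + c(-b_ca_c * cos(ang), b_ca_c * sin(ang), 0)
  prevN <- NULL; prevCA <- NULL; prevC <- NULL
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N <- place_atom(prevN, prevCA, prevC, b_c_n, a_ca_c_n, psi)
      CA <- place_atom(prevCA, prevC, N, b_n_ca, a_c_n_ca, omega)
      C <- place_atom(prevC, N, CA, b_ca_c, a_n_ca_c, phi)
    }
    O <- place_atom(N, CA, C, b_c_o, a_ca_c_o,
                    if (i < n_res) psi + 180 else psi)
    res <- list(N = N, CA = CA, C = C, O = O)
    if (aa[i] != "G")
      res$CB <- place_atom(C, N, CA, b_ca_cb, a_n_ca_cb, 122.6)
    for (nm in names(res))
      rows[[length(rows) + 1L]] <- data.frame(
        resno = i, aa = aa[i], elety = nm,
        elesy = substr(nm, 1, 1),
        x = res[[nm]][1], y = res[[nm]][2], z = res[[nm]][3])
    prevN <- N; prevCA <- CA; prevC <- C
  }
  do.call(rbind, rows)
}

format_pdb_atom <- function(serial, name, resid3, chain, resno, x, y, z,
                            element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resid3, chain, resno, x, y, z, 1.00, 0.00, element)
}

#' Write an ideal alpha-helix PDB fixture
#'
#' Builds ideal alpha-helical chains (phi = -57, psi = -47, standard bond
#' geometry) with backbone and C-beta atoms, rigidly translating each chain
#' by its offset so inter-chain distances are controllable, and emits
#' standards-conformant PDB text including SEQRES records.
#'
#' @param sequences named character vector: chain id -> amino-acid sequence
#' @param offsets optional list of numeric xyz translation per chain;
#'   defaults to spacing chains 30 Angstrom apart along z
#' @param path optional output file; when NULL the PDB text is returned
#' @param seqres write SEQRES records (default TRUE)
#' @param waters number of decorative water (HOH) HETATM records to append
#' @return path (invisibly) when `path` given, else character vector of lines
#' @export
make_helix_pdb <- function(sequences, offsets = NULL, path = NULL,
                           seqres = TRUE, waters = 0L) {
  if (any(!nzchar(sequences))) stop("empty sequence")
  ids <- names(sequences)
  if (is.null(ids)) ids <- LETTERS[seq_along(sequences)]
  if (is.null(offsets))
    offsets <- lapply(seq_along(ids) - 1, function(i) c(0, 0, 30 * i))
  lines <- character(0)
  if (seqres) {
    for (ci in seq_along(ids)) {
      aa3 <- AA_THREE[strsplit(sequences[[ci]], "")[[1]]]
      nres <- length(aa3)
      chunks <- split(aa3, (seq_along(aa3) - 1) %/% 13)
      for (k in seq_along(chunks))
        lines <- c(lines, sprintf("SEQRES %3d %s %4d  %s", k, ids[ci], nres,
                                  paste(chunks[[k]], collapse = " ")))
    }
  }
  serial <- 0L
  for (ci in seq_along(ids)) {
    co <- helix_coords(sequences[[ci]])
    co$x <- co$x + offsets[[ci]][1]
    co$y <- co$y + offsets[[ci]][2]
    co$z <- co$z + offsets[[ci]][3]
    for (r in seq_len(nrow(co))) {
      serial <- serial + 1L
      lines <- c(lines, format_pdb_atom(
        serial, co$elety[r], AA_THREE[co$aa[r]], ids[ci], co$resno[r],
        co$x[r], co$y[r], co$z[r], co$elesy[r]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %s%4d",
                              serial, AA_THREE[co$aa[nrow(co)]], ids[ci],
                              co$resno[nrow(co)]))
  }
  if (waters > 0) {
    for (w in seq_len(waters)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
        serial, w, 50 + w * 3, 50, 50, 1.00, 0.00))
    }
  }
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a column-controlled multiple sequence alignment
#'
#' Per column, each row carries the master letter with probability
#' `consensus` and otherwise a letter drawn uniformly from the remaining
#' `alphabet`. Column-specific consensus fractions may be given as a vector.
#' Deterministic given the seed.
#'
#' @param master master amino-acid sequence (no gaps)
#' @param n_sequences number of rows to generate
#' @param consensus consensus fraction in `[0, 1]`, scalar or per-column
#' @param alphabet letters the non-consensus draws come from: a character
#'   vector shared by all columns, or a list with one vector per column
#' @param seed integer seed
#' @return an `msa` object
#' @export
make_msa <- function(master, n_sequences, consensus = 0.8,
                     alphabet = AA_ALPHABET, seed = 1L) {
  stopifnot(n_sequences >= 1)
  if (any(consensus < 0 | consensus > 1)) stop("invalid consensus fraction")
  cols <- strsplit(master, "")[[1]]
  L <- length(cols)
  consensus <- rep_len(consensus, L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mat <- matrix("", nrow = n_sequences, ncol = L)
  for (j in seq_len(L)) {
    keep <- stats::runif(n_sequences) < consensus[j]
    mat[, j] <- cols[j]
    alt <- setdiff(if (is.list(alphabet)) alphabet[[j]] else alphabet,
                   cols[j])
    if (any(!keep) && length(alt))
      mat[!keep, j] <- sample(alt, sum(!keep), replace = TRUE)
  }
  rows <- apply(mat, 1, paste, collapse = "")
  structure(list(master_sequence = master, rows = rows,
                 n_sequences = n_sequences),
            class = "msa")
}

#' Write an alignment as aligned FASTA
#' @param msa an `msa`
#' @param path output path
#' @export
write_msa_fasta <- function(msa, path) {
  lines <- as.vector(rbind(paste0(">seq", seq_len(msa$n_sequences)),
                           msa$rows))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a stratified synthetic ddG benchmark table
#'
#' Emulates a curated stability benchmark in which phylogenetically
#' supported mutations (delta log-likelihood > 0) have a lower false
#' discovery rate than the rest. Each record falls in the positive stratum
#' with probability `frac_pos`; records predicted stabilising (probability
#' `pred_stab_prob`) are false positives with their stratum's FDR.
#' The overall FDR is `frac_pos * fdr_pos + (1 - frac_pos) * fdr_nonpos`.
#'
#' @param n number of records
#' @param fdr_pos FDR within the delta-log-likelihood > 0 stratum
#' @param fdr_nonpos FDR within the complement stratum
#' @param frac_pos fraction of records in the positive stratum
#' @param pred_stab_prob probability a record is predicted stabilising
#' @param seed integer seed
#' @return canonicalised benchmark record data frame
#' @export
make_ddg_benchmark <- function(n, fdr_pos = 0.15, fdr_nonpos = 0.45,
                               frac_pos = 0.5, pred_stab_prob = 0.6,
                               seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  probs <- c(fdr_pos, fdr_nonpos, frac_pos, pred_stab_prob)
  if (any(probs < 0 | probs > 1)) stop("invalid probability in spec")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pos <- stats::runif(n) < frac_pos
  loglik_mut <- ifelse(pos, stats::runif(n, 0.2, 2),
                       stats::runif(n, -2, 2))
  delta_loglik <- ifelse(pos, stats::runif(n, 0.1, 1.5),
                         stats::runif(n, -1.5, -0.1))
  pred_stab <- stats::runif(n) < pred_stab_prob
  stratum_fdr <- ifelse(pos, fdr_pos, fdr_nonpos)
  is_fp <- pred_stab & (stats::runif(n) < stratum_fdr)
  exp_stab <- ifelse(pred_stab, !is_fp, stats::runif(n) < 0.5)
  mag_pred <- abs(stats::rnorm(n, 1.2, 0.6)) + 0.05
  mag_exp <- abs(stats::rnorm(n, 1.2, 0.6)) + 0.05
  ddg_pred <- ifelse(pred_stab, -mag_pred, mag_pred)
  ddg_exp <- ifelse(exp_stab, -mag_exp, mag_exp)
  wt <- sample(AA_ALPHABET, n, replace = TRUE)
  mut <- sample(AA_ALPHABET, n, replace = TRUE)
  records <- data.frame(
    protein_id = sprintf("P%02d", sample.int(20, n, replace = TRUE)),
    mutation = mutation_name(wt, "A", sample.int(200, n, replace = TRUE),
                             "", mut),
    ddg_exp = ddg_exp, ddg_pred = ddg_pred,
    loglik_mut = loglik_mut, delta_loglik = delta_loglik,
    stringsAsFactors = FALSE)
  canonicalise_records(records)
}

#' Build the bundled demonstration complex
#'
#' A deterministic worked example exercising every pipeline stage: an A/B
#' homodimer of 27-residue helices, three poly-Gly/Ser occluder helices
#' (chains C, D, E) packed against one face of chain A so that several of
#' its residues are buried, and an "antigen" helix (chain G) approaching
#' chain A from the opposite side. The companion alignment favours
#' hydrophobic residues at three buried polar positions of chain A
#' (conserved stability liabilities), charged residues at exposed
#' hydrophobic positions, and is essentially unconserved at two positions.
#'
#' @param dir directory the PDB and MSA files are written into
#' @param n_sequences alignment depth
#' @param seed integer seed for the alignment sampling
#' @return list with `pdb` and `msa` paths, the chain `sequence`, and a
#'   ready `config` (occluders excluded, chain G as antigen)
#' @export
make_demo_complex <- function(dir = tempdir(), n_sequences = 120L,
                              seed = 1L) {
  seqA <- "MKVLLIVFSTKDETSSWLNTGKVVISK"
  occ <- "GSGSGSGSGSGSGSGSGSGSGSGSGSG"
  offsets <- list(c(0, 0, 0), c(0, 40, 0),
                  c(8.5 * cos(0.7), 8.5 * sin(0.7), 0),
                  c(8.5, 0, 0),
                  c(8.5 * cos(-0.7), 8.5 * sin(-0.7), 0),
                  c(-9, 0, 0))
  pdb <- file.path(dir, "demo_complex.pdb")
  make_helix_pdb(c(A = seqA, B = seqA, C = occ, D = occ, E = occ, G = occ),
                 offsets = offsets, path = pdb)
  # column model: consensus letter and fraction per position
  master <- strsplit(seqA, "")[[1]]
  consensus <- rep(0.6, nchar(seqA))
  alphabet <- rep(list(AA_ALPHABET), nchar(seqA))
  # buried polar positions where the family prefers hydrophobics
  master[9] <- "I";  consensus[9] <- 0.55; alphabet[[9]] <- c("I", "V", "L")
  master[16] <- "A"; consensus[16] <- 0.55; alphabet[[16]] <- c("A", "I", "V")
  master[20] <- "V"; consensus[20] <- 0.55; alphabet[[20]] <- c("V", "I", "L")
  # exposed hydrophobic positions where the family prefers charged residues
  master[3] <- "K"; consensus[3] <- 0.8
  master[7] <- "E"; consensus[7] <- 0.8
  # essentially unconserved positions
  consensus[21] <- 0.08; consensus[22] <- 0.08
  msa <- make_msa(paste(master, collapse = ""), n_sequences,
                  consensus = consensus, alphabet = alphabet, seed = seed)
  msa_path <- file.path(dir, "demo_msa_A.fasta")
  write_msa_fasta(msa, msa_path)
  list(pdb = pdb, msa = msa_path, sequence = seqA,
       config = design_config(excluded_chains = c("C", "D", "E"),
                              antigen_chains = "G", seed = seed))
}

#' Write benchmark records as CSV
#' @param records benchmark record data frame
#' @param path output path
#' @export
write_benchmark_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
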