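# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.cache[[name]])) .cache[[name]] <- builder()
  .cache[[name]]
}

# the bundled demonstration complex plus its parsed structure and pipeline run
demo_fixture <- function() memo("demo", function() {
  dir <- file.path(tempdir(), "solstab-demo")
  dir.create(dir, showWarnings = FALSE)
  fx <- make_demo_complex(dir, seed = 1)
  fx$structure <- read_structure(fx$pdb)
  fx$exposure <- relative_exposure(fx$structure)
  fx$cmap <- contact_map(fx$structure)
  fx
})

demo_pipeline <- function() memo("demo_run", function() {
  fx <- demo_fixture()
  out <- file.path(tempdir(), "solstab-demo-run")
  res <- suppressMessages(
    run_design(fx$pdb, fx$msa, out, config = fx$config))
  res
})

# small helix homodimer without occluders
dimer_fixture <- function() memo("dimer", function() {
  seq <- "MKVTLSATSDELVKQWLNSGKVVISTA"
  pdb <- file.path(tempdir(), "solstab-dimer.pdb")
  make_helix_pdb(c(A = seq, B = seq), path = pdb)
  ps <- read_structure(pdb)
  list(pdb = pdb, sequence = seq, structure = ps,
       exposure = relative_exposure(ps))
})

# build an msa object directly from aligned rows
msa_from_rows <- function(rows) {
  structure(list(master_sequence = gsub("-", "", rows[1]), rows = rows,
                 n_sequences = length(rows)), class = "msa")
}

# hand-built pssm for rule-level tests
pssm_stub <- function(mat, kind = "loglik", raw = NULL,
                      background = rep(1 / 20, 20)) {
  colnames(mat) <- AA_ALPHABET
  names(background) <- AA_ALPHABET
  if (is.null(raw)) raw <- mat
  structure(list(kind = kind, matrix = mat, raw_freq = raw,
                 background = background,
                 conservation = rep(0.5, nrow(mat)),
                 consensus = AA_ALPHABET[apply(mat, 1, which.max)],
                 n_sequences = if (kind == "pwm") 10L else 100L,
                 master_sequence = strrep("A", nrow(mat))),
            class = "pssm")
}

# brute-force residue contact oracle: all residue pairs, all atom pairs
brute_force_contacts <- function(structure, cutoff) {
  atoms <- structure$atoms
  keys <- unique(atoms$key)
  n <- length(keys)
  mat <- matrix(FALSE, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ai <- atoms[atoms$key == keys[i], ]
    aj <- atoms[atoms$key == keys[j], ]
    dmin <- Inf
    for (p in seq_len(nrow(ai))) {
      d <- sqrt((aj$x - ai$x[p])^2 + (aj$y - ai$y[p])^2 +
                  (aj$z - ai$z[p])^2)
      dmin <- min(dmin, min(d))
    }
    mat[i, j] <- mat[j, i] <- dmin <= cutoff
  }
  mat
}

# independent row-scan FDR oracle
brute_force_fdr <- function(records, keep) {
  kept <- records[keep, , drop = FALSE]
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(kept))) {
    p <- kept$ddg_pred[i] < 0
    e <- kept$ddg_exp[i] < 0
    if (p && e) tp <- tp + 1L
    else if (p && !e) fp <- fp + 1L
    else if (!p && !e) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       fdr = if (tp + fp == 0) 0 else fp / (fp + tp),
       n_kept = nrow(kept))
}
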