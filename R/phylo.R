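# MSA ingestion and PSSM machinery: log-likelihood matrices versus a
# background, raw-frequency PWMs for small alignments, per-position
# conservation, and allowed-substitution queries.

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA (all rows equal length) and A3M, where lowercase
#' letters mark insert states relative to the master (first) sequence and are
#' removed so every row matches the master length.
#'
#' @param path path to the alignment file
#' @param format `"fasta"` or `"a3m"`
#' @return object of class `msa`: `master_sequence`, `rows` (character
#'   vector of aligned sequences, gaps as `-`), `n_sequences`
#' @export
read_msa <- function(path, format = c("fasta", "a3m")) {
  format <- match.arg(format)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) stop("empty alignment: ", path)
  rows <- as.character(aa)
  if (format == "a3m") {
    # lowercase = insertion relative to the alignment columns; drop them
    rows <- vapply(rows, function(s) gsub("[a-z]", "", s), "",
                   USE.NAMES = FALSE)
    rows <- gsub("\\.", "-", rows)
  } else {
    rows <- unname(rows)
  }
  rows <- toupper(rows)
  lens <- nchar(rows)
  if (length(unique(lens)) > 1)
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X\\-]"), rows)
  if (any(bad))
    stop("illegal characters in alignment row(s) ",
         paste(which(bad), collapse = ", "))
  master <- gsub("-", "", rows[1])
  structure(list(master_sequence = master, rows = rows,
                 n_sequences = length(rows)),
            class = "msa")
}

#' Build a position-specific scoring matrix from an alignment
#'
#' Per column, gap-excluded counts are smoothed with a background-proportional
#' pseudocount (total added weight = `pseudocount`) and normalised to
#' frequencies. With at least 50 sequences the stored matrix holds natural-log
#' likelihood ratios `ln(f/background)` (`kind = "loglik"`); below 50
#' sequences raw smoothed frequencies are stored instead (`kind = "pwm"`).
#' The per-position conservation index is computed from the raw (unsmoothed)
#' column frequencies as one minus the normalised Shannon entropy.
#'
#' @param msa an `msa` object
#' @param pseudocount total pseudocount weight per column (>= 0)
#' @param background named vector of 20 strictly positive frequencies
#' @return object of class `pssm`: `kind`, `matrix` (positions x 20),
#'   `raw_freq`, `background`, `conservation`, `consensus`, `n_sequences`,
#'   `master_sequence`
#' @export
build_pssm <- function(msa, pseudocount = 1.0, background = AA_BACKGROUND) {
  stopifnot(inherits(msa, "msa"), pseudocount >= 0)
  background <- background[AA_ALPHABET]
  if (anyNA(background) || any(background <= 0))
    stop("background must assign a positive frequency to all 20 amino acids")
  background <- background / sum(background)
  rows <- do.call(rbind, strsplit(msa$rows, ""))
  npos <- ncol(rows)
  counts <- vapply(seq_len(npos), function(j) {
    col <- rows[, j]
    tab <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    as.numeric(tab)
  }, numeric(20))
  counts <- t(counts)  # positions x 20
  colnames(counts) <- AA_ALPHABET
  tot <- rowSums(counts)
  raw_freq <- counts / ifelse(tot > 0, tot, 1)
  empty <- tot == 0
  if (any(empty)) {
    warning(sum(empty), " column(s) with zero non-gap observations; ",
            "frequencies set to background")
    raw_freq[empty, ] <- rep(background, each = sum(empty))
  }
  gap_frac <- 1 - tot / nrow(rows)
  if (any(gap_frac >= 0.5 & !empty))
    warning(sum(gap_frac >= 0.5 & !empty),
            " column(s) with >=50% gaps; low-confidence estimates")
  smoothed <- sweep(counts, 2, pseudocount * background, "+") /
    (tot + pseudocount)
  smoothed[empty, ] <- rep(background, each = sum(empty))
  kind <- if (msa$n_sequences < 50) "pwm" else "loglik"
  mat <- if (kind == "loglik")
    log(sweep(smoothed, 2, background, "/")) else smoothed
  H <- apply(raw_freq, 1, function(f) {
    f <- f[f > 0]
    -sum(f * log(f))
  })
  conservation <- pmin(pmax(1 - H / log(20), 0), 1)
  consensus <- AA_ALPHABET[apply(raw_freq, 1, which.max)]
  structure(list(kind = kind, matrix = mat, raw_freq = raw_freq,
                 background = background, conservation = conservation,
                 consensus = consensus, n_sequences = msa$n_sequences,
                 master_sequence = msa$master_sequence),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm (%s): %d positions, %d sequences\n",
              x$kind, nrow(x$matrix), x$n_sequences))
  invisible(x)
}

#' Per-position conservation index
#'
#' `CI_j = 1 - H_j / ln(20)` with `H_j` the Shannon entropy of the gap-excluded
#' column frequencies: 1 for an invariant column, 0 for a uniform one.
#'
#' @param pssm a `pssm`
#' @return numeric vector in `[0, 1]`, one value per position
#' @export
conservation_index <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  pssm$conservation
}

#' Substitutions permitted by the PSSM at a position
#'
#' For a log-likelihood matrix, mode `"ll_pos"` returns the amino acids (other
#' than the wild type) with log-likelihood > 0; `"ll_and_delta"` additionally
#' requires a positive delta log-likelihood versus the wild type. For a PWM
#' the corresponding thresholds are frequency >= 0.05 and frequency greater
#' than the wild type's.
#'
#' @param pssm a `pssm`
#' @param position 1-based position in the master sequence
#' @param wt wild-type amino acid at that position
#' @param mode `"ll_and_delta"` (default) or `"ll_pos"`
#' @return character vector of permitted substitution targets
#' @export
allowed_substitutions <- function(pssm, position, wt,
                                  mode = c("ll_and_delta", "ll_pos")) {
  mode <- match.arg(mode)
  stopifnot(position >= 1, position <= nrow(pssm$matrix))
  if (!wt %in% AA_ALPHABET) return(character(0))
  row <- pssm$matrix[position, ]
  if (pssm$kind == "loglik") {
    ok <- row > 0
    if (mode == "ll_and_delta") ok <- ok & (row - row[wt] > 0)
  } else {
    ok <- row >= 0.05
    if (mode == "ll_and_delta") ok <- ok & (row > row[wt])
  }
  ok[wt] <- FALSE
  AA_ALPHABET[ok[AA_ALPHABET]]
}

#' Whether the wild-type residue is weakly supported at a position
#'
#' True when the wild type's log-likelihood is <= 0 (log-likelihood matrix)
#' or its frequency is below 0.05 (PWM).
#'
#' @inheritParams allowed_substitutions
#' @return logical
#' @export
wt_is_low <- function(pssm, position, wt) {
  if (!wt %in% AA_ALPHABET) return(FALSE)
  v <- pssm$matrix[position, wt]
  if (pssm$kind == "loglik") v <= 0 else v < 0.05
}

#' Score of an amino acid at a position
#' @inheritParams allowed_substitutions
#' @param aa amino acid
#' @return log-likelihood (or PWM frequency) value
#' @export
pssm_value <- function(pssm, position, aa) {
  if (!aa %in% AA_ALPHABET) return(NA_real_)
  unname(pssm$matrix[position, aa])
}

#' Export a PSSM as CSV
#'
#' Columns: position, wt (master sequence), the 20 amino acids, conservation.
#' @param pssm a `pssm`
#' @param path output CSV path
#' @export
write_pssm_csv <- function(pssm, path) {
  wt <- strsplit(pssm$master_sequence, "")[[1]]
  if (length(wt) != nrow(pssm$matrix)) wt <- rep(NA_character_, nrow(pssm$matrix))
  df <- data.frame(position = seq_len(nrow(pssm$matrix)), wt = wt,
                   pssm$matrix, conservation = pssm$conservation,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
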