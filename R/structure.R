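# Structure model: PDB ingestion, chain sequences, identity groups,
# residue keys and the heavy-atom contact map.

#' Residue key
#'
#' Canonical string key for a residue: `chain:number[insertion_code]`.
#'
#' @param chain single-character chain id
#' @param resno author residue number (integer)
#' @param icode insertion code, `""` when absent
#' @return character vector of keys
#' @export
res_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste0(chain, ":", resno, icode)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (waters and non-polymer HETATM are excluded) and the
#' SEQRES header. Per chain, `seqres_sequence` is taken from SEQRES when
#' present, otherwise set equal to the ATOM-derived sequence; the ATOM-derived
#' sequence is always retained separately together with the author residue
#' numbering and insertion codes.
#'
#' @param path path to a PDB file
#' @return an object of class `protein_structure` with elements
#'   `atoms` (data frame of heavy atoms: chain, resno, icode, aa, elety,
#'   elesy, x, y, z, key), `chains` (named list with `id`, `seqres_sequence`,
#'   `atom_sequence`, `residues` data frame) and `identity_groups`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  # polymer residues: ATOM records plus HETATM for modified amino acids
  keep <- at$type == "ATOM" |
    (at$type == "HETATM" & at$resid %in% names(AA_NONSTANDARD))
  at <- at[keep & at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0) stop("no polymer chains with standard amino acids in ", path)
  # heavy atoms only
  elesy <- at$elesy
  miss <- is.na(elesy) | elesy == ""
  if (any(miss)) elesy[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1, 1)
  at <- at[toupper(elesy) != "H", , drop = FALSE]
  icode <- at$insert
  icode[is.na(icode)] <- ""
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, icode = icode,
    aa = aa_from_three(at$resid), elety = at$elety,
    elesy = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                           substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy)),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)

  seqres <- pdb$seqres
  chain_ids <- unique(atoms$chain)
  chains <- lapply(chain_ids, function(ch) {
    ca <- atoms[atoms$chain == ch, , drop = FALSE]
    resdf <- unique(ca[, c("resno", "icode", "aa", "key")])
    if (anyDuplicated(resdf$key))
      stop("duplicated residue key in chain ", ch)
    atom_seq <- paste(resdf$aa, collapse = "")
    if (nchar(atom_seq) == 0) stop("chain ", ch, " has zero standard residues")
    sr <- ""
    if (!is.null(seqres) && any(names(seqres) == ch))
      sr <- paste(aa_from_three(unname(seqres[names(seqres) == ch])), collapse = "")
    if (sr == "") sr <- atom_seq
    list(id = ch, seqres_sequence = sr, atom_sequence = atom_seq,
         residues = resdf)
  })
  names(chains) <- chain_ids
  ps <- structure(list(atoms = atoms, chains = chains,
                       identity_groups = NULL, path = path),
                  class = "protein_structure")
  ps$identity_groups <- identity_groups(ps)
  ps
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", length(x$chains), "chain(s),",
      nrow(x$atoms), "heavy atoms\n")
  for (ch in x$chains)
    cat(sprintf("  chain %s: %d residues with coordinates, seqres length %d\n",
                ch$id, nrow(ch$residues), nchar(ch$seqres_sequence)))
  cat("  identity groups:",
      paste(vapply(x$identity_groups, paste, "", collapse = ","),
            collapse = " | "), "\n")
  invisible(x)
}

#' Sequence used for chain comparison and design
#'
#' SEQRES-derived sequence when available, else the ATOM-derived sequence.
#' @param structure a `protein_structure`
#' @param chain chain id
#' @return amino-acid string
#' @export
chain_sequence <- function(structure, chain) {
  ch <- structure$chains[[chain]]
  if (is.null(ch)) stop("unknown chain id: ", chain)
  if (nzchar(ch$seqres_sequence)) ch$seqres_sequence else ch$atom_sequence
}

#' Group chains by sequence identity
#'
#' Chains encoded by the same gene (identical sequence) form one identity
#' group; mutations are later mirrored across all chains of a group. Without
#' a manual specification, grouping is by exact equality of the comparison
#' sequence. A manual specification overrides the automatic grouping;
#' unmentioned chains become singletons.
#'
#' @param structure a `protein_structure`
#' @param manual optional list of character vectors of chain ids
#' @return list of character vectors partitioning the chain ids
#' @export
identity_groups <- function(structure, manual = NULL) {
  ids <- names(structure$chains)
  if (!is.null(manual)) {
    named <- unlist(manual)
    if (anyDuplicated(named))
      stop("manual identity groups mention a chain more than once")
    unknown <- setdiff(named, ids)
    if (length(unknown))
      stop("manual identity group names unknown chain id(s): ",
           paste(unknown, collapse = ", "))
    for (g in manual) {
      lens <- vapply(g, function(ch) nchar(chain_sequence(structure, ch)), 0L)
      if (length(unique(lens)) > 1)
        warning("manual identity group {", paste(g, collapse = ","),
                "} mixes chains of unequal sequence length")
    }
    singles <- lapply(setdiff(ids, named), identity)
    groups <- c(manual, singles)
  } else {
    seqs <- vapply(ids, function(ch) chain_sequence(structure, ch), "")
    groups <- unname(split(ids, factor(seqs, levels = unique(seqs))))
  }
  # preserve chain order within and across groups
  groups <- lapply(groups, function(g) g[order(match(g, ids))])
  groups[order(vapply(groups, function(g) match(g[1], ids), 0L))]
}

#' Heavy-atom residue contact map
#'
#' Two residues are in contact iff the minimum distance between their heavy
#' atoms is at most `cutoff`. The relation is symmetric and irreflexive.
#'
#' @param structure a `protein_structure`
#' @param cutoff contact distance cutoff in Angstrom
#' @return object of class `contact_map`: logical matrix `mat` with residue
#'   keys as dimnames, plus the `cutoff`
#' @export
contact_map <- function(structure, cutoff = 8.0) {
  atoms <- structure$atoms
  keys <- unique(atoms$key)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ridx <- match(atoms$key, keys)
  n <- length(keys)
  mat <- matrix(FALSE, n, n, dimnames = list(keys, keys))
  # squared distances between all atoms, then reduce per residue pair
  d2 <- as.matrix(stats::dist(xyz))^2
  cut2 <- cutoff^2
  hit <- which(d2 <= cut2, arr.ind = TRUE)
  ri <- ridx[hit[, 1]]; rj <- ridx[hit[, 2]]
  off <- ri != rj
  mat[cbind(ri[off], rj[off])] <- TRUE
  structure(list(mat = mat, cutoff = cutoff), class = "contact_map")
}

#' Query a contact map
#' @param cm a `contact_map`
#' @param key residue key
#' @return character vector of residue keys in contact with `key`
#' @export
contacts_of <- function(cm, key) {
  if (!key %in% rownames(cm$mat)) return(character(0))
  names(which(cm$mat[key, ]))
}

#' Test whether two residues are in contact
#' @param cm a `contact_map`
#' @param key1,key2 residue keys
#' @return logical
#' @export
in_contact <- function(cm, key1, key2) {
  if (!key1 %in% rownames(cm$mat) || !key2 %in% colnames(cm$mat)) return(FALSE)
  unname(cm$mat[key1, key2])
}

#' Map residues with coordinates to positions in the comparison sequence
#'
#' When SEQRES and ATOM sequences coincide the mapping is the identity; when
#' the ATOM sequence is an exact substring of SEQRES (missing termini) it is
#' an offset; otherwise a global alignment (Biostrings) recovers it.
#'
#' @param structure a `protein_structure`
#' @param chain chain id
#' @return integer vector, one entry per residue with coordinates, giving the
#'   1-based position in `chain_sequence()`; NA where unalignable
#' @export
seqres_positions <- function(structure, chain) {
  ch <- structure$chains[[chain]]
  if (is.null(ch)) stop("unknown chain id: ", chain)
  sr <- chain_sequence(structure, chain)
  as <- ch$atom_sequence
  n <- nchar(as)
  if (identical(sr, as)) return(seq_len(n))
  hit <- regexpr(as, sr, fixed = TRUE)
  if (hit > 0) return(seq.int(hit, length.out = n))
  aln <- Biostrings::pairwiseAlignment(as, sr, type = "global",
                                       gapOpening = 10, gapExtension = 0.5)
  pos <- rep(NA_integer_, n)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; is_ <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ia <- ia + 1L
    if (sub[k] != "-") is_ <- is_ + 1L
    if (pat[k] != "-" && sub[k] != "-") pos[ia] <- is_
  }
  pos
}
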