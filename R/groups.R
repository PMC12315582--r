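AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
NUCLEOTIDES <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O5'")
RIBOSE_ATOMS <- c("C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")

#' Classify an atom into a chemical group
#'
#' Amino-acid atoms split into backbone (`N`, `CA`, `C`, `O`, `OXT`) and
#' side chain; nucleotide atoms into phosphate (`P`, `OP1-3`, `O5'`),
#' ribose (`C1'`-`C5'`, `O2'`-`O4'`; `O2'` simply absent in DNA) and base
#' (everything else); waters map to `"water"`; any other component (ligand,
#' saccharide) maps to its own component name, scored as one unit. Unknown
#' polymer-like names fall back to `"other"` with a warning.
#'
#' @param res_name Residue / component name(s), e.g. `"ALA"`, `"G"`, `"NAG"`.
#' @param atom_name Atom name(s), e.g. `"CB"`, `"OP1"`.
#' @return Character vector of group labels.
#' @export
classify_atom <- function(res_name, atom_name) {
  res_name <- trimws(res_name)
  atom_name <- trimws(atom_name)
  n <- max(length(res_name), length(atom_name))
  res_name <- rep_len(res_name, n)
  atom_name <- rep_len(atom_name, n)
  out <- character(n)
  aa <- res_name %in% AMINO_ACIDS
  out[aa] <- ifelse(atom_name[aa] %in% BACKBONE_ATOMS, "backbone", "sidechain")
  nt <- res_name %in% NUCLEOTIDES
  out[nt] <- ifelse(atom_name[nt] %in% PHOSPHATE_ATOMS, "phosphate",
             ifelse(atom_name[nt] %in% RIBOSE_ATOMS, "ribose", "base"))
  wat <- res_name %in% c("HOH", "WAT", "DOD")
  out[wat] <- "water"
  rest <- !aa & !nt & !wat
  out[rest] <- res_name[rest]
  out
}

#' Aggregate per-atom Q-scores over chemical groups
#'
#' Averages per-atom Q-scores within each (chain, residue, group) cell.
#' `level` controls the grouping: `"residue"` gives backbone/side-chain
#' means per amino acid, `"nucleotide"` gives phosphate/ribose/base means
#' per nucleotide, `"component"` gives one mean per non-polymer component
#' instance (ligands, saccharides). `"auto"` applies each rule to the
#' residue types it covers. Groups with no scored atom are omitted and
#' listed in attribute `omitted`.
#'
#' @param q A `qscore_result` from [qscore].
#' @param model The `atomic_model` the scores were computed on.
#' @param level `"auto"`, `"residue"`, `"nucleotide"` or `"component"`.
#' @return A `group_scores` data frame with columns `chain`, `res_seq`,
#'   `res_name`, `group`, `mean_q`, `n_atoms`.
#' @export
aggregate_q <- function(q, model, level = c("auto", "residue", "nucleotide",
                                            "component")) {
  level <- match.arg(level)
  stopifnot(inherits(q, "qscore_result"))
  at <- q$atoms
  if (!all(at$serial %in% model$serial))
    stop("qscore_result does not match model (serial mismatch)")
  at$group <- classify_atom(at$res_name, at$name)
  keep <- switch(level,
    auto = rep(TRUE, nrow(at)),
    residue = at$res_name %in% AMINO_ACIDS,
    nucleotide = at$res_name %in% NUCLEOTIDES,
    component = !(at$res_name %in% c(AMINO_ACIDS, NUCLEOTIDES,
                                     "HOH", "WAT", "DOD")))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms match level '", level, "'")
  if (any(!(at$res_name %in% c(AMINO_ACIDS, NUCLEOTIDES, "HOH", "WAT", "DOD")) &
          at$group == "other"))
    warning("atoms of unknown residue type assigned to group 'other'")
  key <- interaction(at$chain, at$res_seq, at$res_name, at$group, drop = TRUE)
  idx <- split(seq_len(nrow(at)), key)
  rows <- lapply(idx, function(i) {
    qi <- at$q[i]
    scored <- !is.na(qi)
    data.frame(chain = at$chain[i[1]], res_seq = at$res_seq[i[1]],
               res_name = at$res_name[i[1]], group = at$group[i[1]],
               mean_q = if (any(scored)) mean(qi[scored]) else NA_real_,
               n_atoms = sum(scored), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  omitted <- out[out$n_atoms == 0L, c("chain", "res_seq", "group")]
  out <- out[out$n_atoms > 0L, , drop = FALSE]
  out <- out[order(out$chain, out$res_seq, out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  class(out) <- c("group_scores", "data.frame")
  out
}

#' Flag groups against the archive bounds at a given resolution
#'
#' Compares each group mean to the `Q_low_95%` / `Q_high_95%` curves of a
#' fitted archive model at resolution `d`: below the low bound flags a
#' possibly misfitted or unresolved group, above the high bound an
#' unusually sharp one.
#'
#' @param groups A `group_scores` data frame from [aggregate_q].
#' @param fit A `qstat` model from [qstat_fit].
#' @param d Reported resolution of the map (A).
#' @return `groups` with an added `flag` column, one of `"below_low"`,
#'   `"typical"`, `"above_high"`.
#' @export
flag_groups <- function(groups, fit, d) {
  b <- predict(fit, d)
  if (b$extrapolated[1])
    warning("resolution ", d, " A is outside the fitted domain; ",
            "bounds are extrapolated")
  groups$flag <- ifelse(groups$mean_q < b$q_low, "below_low",
                 ifelse(groups$mean_q > b$q_high, "above_high", "typical"))
  groups
}
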