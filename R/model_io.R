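#' Read an atomic coordinate model (PDB or mmCIF)
#'
#' Parses coordinates through bio3d and normalizes them to a flat
#' `atomic_model` data frame. Hydrogens and waters are retained but
#' flagged (`is_h`, `is_water`); all scoring functions skip hydrogens.
#' Alternate locations are resolved per `altloc_policy`: the default keeps,
#' within each (chain, residue, atom name), the altloc with the highest
#' occupancy (ties: first in file); `"all"` keeps every altloc.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @param altloc_policy `"highest_occupancy"` (default) or `"all"`.
#' @param entry_id Optional identifier stored on the model; defaults to the
#'   file base name.
#' @return An `atomic_model`: a data frame with columns `serial`, `name`,
#'   `element`, `chain`, `res_name`, `res_seq`, `x`, `y`, `z`, `occupancy`,
#'   `altloc`, `b_iso`, `is_h`, `is_water`, and attribute `entry_id`.
#' @export
read_model <- function(path, altloc_policy = c("highest_occupancy", "all"),
                       entry_id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("model file not found: ", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
         else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms parsed from ", path)
  m <- atomic_model(
    serial = at$eleno, name = at$elety, element = at$elesy,
    chain = at$chain, res_name = at$resid, res_seq = at$resno,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o, altloc = at$alt, b_iso = at$b,
    entry_id = if (is.null(entry_id))
      sub("\\.(pdb|ent|cif)$", "", basename(path), ignore.case = TRUE)
      else entry_id)
  if (altloc_policy == "highest_occupancy") m <- resolve_altlocs(m)
  m
}

#' Construct an atomic model from vectors
#'
#' Lower-level constructor used by [read_model] and the toy-model
#' generator. All vectors are recycled to a common length.
#'
#' @param serial,name,element,chain,res_name,res_seq,x,y,z,occupancy,altloc,b_iso
#'   Per-atom fields; see [read_model] for meaning.
#' @param entry_id Identifier string stored as an attribute.
#' @return An `atomic_model` data frame.
#' @export
atomic_model <- function(serial, name, element, chain, res_name, res_seq,
                         x, y, z, occupancy = 1, altloc = "", b_iso = 0,
                         entry_id = "model") {
  element <- toupper(trimws(ifelse(is.na(element) | element == "",
                                   substr(trimws(name), 1L, 1L), element)))
  if (any(element == "")) stop("atom with empty element symbol")
  if (!all(is.finite(x) & is.finite(y) & is.finite(z)))
    stop("non-finite atom coordinates")
  occupancy <- ifelse(is.na(occupancy), 1, occupancy)
  if (any(occupancy < 0 | occupancy > 1))
    stop("occupancy outside [0, 1]")
  altloc <- ifelse(is.na(altloc), "", altloc)
  m <- data.frame(
    serial = as.integer(serial), name = trimws(name), element = element,
    chain = ifelse(is.na(chain), "A", chain),
    res_name = trimws(res_name), res_seq = as.integer(res_seq),
    x = x, y = y, z = z, occupancy = occupancy, altloc = altloc,
    b_iso = ifelse(is.na(b_iso), 0, b_iso),
    stringsAsFactors = FALSE)
  m$is_h <- m$element %in% c("H", "D")
  m$is_water <- m$res_name %in% c("HOH", "WAT", "DOD")
  if (!any(!m$is_h)) stop("model has no non-hydrogen atoms")
  attr(m, "entry_id") <- entry_id
  class(m) <- c("atomic_model", "data.frame")
  m
}

resolve_altlocs <- function(m) {
  key <- paste(m$chain, m$res_seq, m$name, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(m)), key), function(i) {
    if (length(i) == 1L) return(i)
    i[which.max(m$occupancy[i])]   # ties: first in file
  }), use.names = FALSE)
  out <- m[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "entry_id") <- attr(m, "entry_id")
  class(out) <- class(m)
  out
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model '%s': %d atoms (%d non-H, %d water) in %d chain(s)\n",
              attr(x, "entry_id"), nrow(x), sum(!x$is_h), sum(x$is_water),
              length(unique(x$chain))))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param model An `atomic_model`.
#' @return n x 3 matrix of Angstrom coordinates.
#' @export
model_xyz <- function(model) {
  cbind(x = model$x, y = model$y, z = model$z)
}

#' Read an archive table of (entry, resolution, Q)
#'
#' Accepts delimited text with columns mappable to an entry identifier, a
#' reported resolution in Angstrom and a mean Q-score (column names are
#' matched case-insensitively against common variants, e.g. `emdb_id`,
#' `resolution`, `average_qscore_value`). Rows with missing or non-finite
#' resolution or Q are dropped and counted in attribute `n_dropped`.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field separator; `","` by default.
#' @return An `archive_table`: data frame with columns `entry_id`, `d`, `q`.
#' @export
read_archive <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", fill = TRUE)
  if (nrow(raw) == 0L) stop("no parsable rows in ", path)
  pick <- function(cands) {
    hit <- which(tolower(names(raw)) %in% cands)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  ci <- pick(c("entry_id", "emdb_id", "entry", "id"))
  cd <- pick(c("d", "resolution", "res", "reported_resolution"))
  cq <- pick(c("q", "qscore", "q_score", "mean_q", "average_qscore_value",
               "q_mean", "model_q"))
  if (is.na(cd) || is.na(cq))
    stop("cannot map columns of ", path, " to (resolution, Q)")
  d <- suppressWarnings(as.numeric(raw[[cd]]))
  q <- suppressWarnings(as.numeric(raw[[cq]]))
  id <- if (is.na(ci)) sprintf("row%d", seq_len(nrow(raw)))
        else as.character(raw[[ci]])
  ok <- is.finite(d) & is.finite(q) & d > 0
  if (!any(ok)) stop("no rows with finite resolution and Q in ", path)
  archive_table(id[ok], d[ok], q[ok], n_dropped = sum(!ok))
}

#' Construct an archive table
#' @param entry_id Character vector of entry identifiers.
#' @param d Reported resolutions (Angstrom, > 0).
#' @param q Mean model Q-scores.
#' @param n_dropped Rows discarded during parsing (attribute).
#' @return An `archive_table` data frame.
#' @export
archive_table <- function(entry_id, d, q, n_dropped = 0L) {
  stopifnot(length(d) == length(q), length(entry_id) == length(d))
  if (length(d) == 0L) stop("archive table must be non-empty")
  if (any(!is.finite(d)) || any(d <= 0)) stop("resolutions must be finite and > 0")
  if (any(!is.finite(q))) stop("Q values must be finite")
  t <- data.frame(entry_id = as.character(entry_id), d = as.numeric(d),
                  q = as.numeric(q), stringsAsFactors = FALSE)
  attr(t, "n_dropped") <- as.integer(n_dropped)
  class(t) <- c("archive_table", "data.frame")
  t
}

#' Write and re-read per-atom or per-group score tables
#'
#' Plain CSV with a stable column order; `read_scores` round-trips the
#' numeric values exactly (full precision write).
#'
#' @param scores Non-empty data frame of scores.
#' @param path Output path.
#' @return `path` invisibly (`write_scores`); a data frame (`read_scores`).
#' @export
write_scores <- function(scores, path) {
  if (is.null(scores) || nrow(scores) == 0L) stop("no scores to write")
  utils::write.csv(scores, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a model with Q-derived B factors into a PDB file
#'
#' Replaces the isotropic B-factor column with the supplied values.
#' Atoms without a score (e.g. hydrogens or zero-occupancy atoms) receive a
#' sentinel `b_iso = 0.00`; their serial numbers are written to a sidecar
#' text file `<path>.unscored` so the output stays standards-valid while
#' the sentinel remains identifiable.
#'
#' @param model An `atomic_model`.
#' @param b_factors Numeric vector: either one value per atom of `model`,
#'   or one value per scorable atom (non-H, occupancy > 0), matched in
#'   model order.
#' @param path Output `.pdb` path.
#' @return `path`, invisibly.
#' @export
write_annotated_model <- function(model, b_factors, path) {
  scorable <- !model$is_h & model$occupancy > 0
  b <- rep(NA_real_, nrow(model))
  if (length(b_factors) == nrow(model)) {
    b <- as.numeric(b_factors)
  } else if (length(b_factors) == sum(scorable)) {
    b[scorable] <- as.numeric(b_factors)
  } else {
    stop("length(b_factors) must equal the number of atoms (", nrow(model),
         ") or of scorable atoms (", sum(scorable), ")")
  }
  unscored <- which(is.na(b))
  b[unscored] <- 0
  xyz <- as.numeric(t(model_xyz(model)))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = "ATOM",
    resno = model$res_seq, resid = model$res_name, chain = model$chain,
    eleno = model$serial, elety = model$name, elesy = model$element,
    o = model$occupancy, b = b)
  if (length(unscored) > 0L)
    writeLines(as.character(model$serial[unscored]),
               paste0(path, ".unscored"))
  invisible(path)
}

#' Write a per-residue attribute file for visualization tools
#'
#' Emits the UCSF Chimera `defattr` text format, keyed by
#' `/:residue.chain`, so group scores can color ribbons.
#'
#' @param groups A data frame with columns `chain`, `res_seq` and a value
#'   column.
#' @param path Output path.
#' @param attribute Attribute name; also the value column looked up in
#'   `groups` (default `"mean_q"` written as attribute `qscore`).
#' @param value_col Column of `groups` holding the value.
#' @return `path`, invisibly.
#' @export
write_attribute_file <- function(groups, path, attribute = "qscore",
                                 value_col = "mean_q") {
  stopifnot(all(c("chain", "res_seq", value_col) %in% names(groups)))
  lines <- c(sprintf("attribute: %s", attribute),
             "match mode: 1-to-1", "recipient: residues",
             sprintf("\t/%s:%d\t%.6g",
                     groups$chain, groups$res_seq, groups[[value_col]]))
  writeLines(lines, path)
  invisible(path)
}
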