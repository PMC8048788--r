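#' Structure models
#'
#' A `structure_model` is a light container for one coordinate file: an atom
#' table in bio3d column layout (`record`, `eleno`, `elety`, `alt`, `resid`,
#' `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`) plus an
#' identifier and the source format.  Polymer atoms are the `ATOM` records;
#' everything routed through `HETATM` (metals, ions, waters, ligands) is kept
#' and queried through the interaction detectors.  Coordinates are Angstrom
#' throughout; author residue numbering is the canonical residue key.
#'
#' @name structure_model
NULL

.atom_cols <- c("record", "eleno", "elety", "alt", "resid", "chain", "resno",
                "insert", "x", "y", "z", "o", "b", "elesy")

new_structure_model <- function(atom, id = "structure", source_format = "pdb") {
  atom <- as.data.frame(atom, stringsAsFactors = FALSE)
  for (col in c("alt", "insert", "chain"))
    atom[[col]][is.na(atom[[col]])] <- ""
  atom$resno <- as.integer(atom$resno)
  atom$eleno <- as.integer(atom$eleno)
  atom$o[is.na(atom$o)] <- 1
  atom$b[is.na(atom$b)] <- 0
  if (!all(.atom_cols %in% names(atom)))
    stop("atom table is missing columns: ",
         paste(setdiff(.atom_cols, names(atom)), collapse = ", "))
  bad <- !is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)
  if (any(bad)) stop("non-finite coordinates in ", sum(bad), " atom(s)")
  if (any(atom$o < 0 | atom$o > 1))
    stop("occupancies outside [0, 1]")
  structure(list(id = id, atom = atom[, .atom_cols],
                 source_format = source_format),
            class = "structure_model")
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parsing is delegated to bio3d (`read.pdb`/`read.cif`); the result is
#' normalised into a [structure_model] with all ATOM and HETATM records,
#' waters and metals included, and chain order preserved.  When the element
#' column is absent it is inferred from the atom name.
#'
#' @param path path to a coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param id identifier stored on the model (defaults to the file stem).
#' @return A `structure_model`.
#' @seealso [write_structure()], [resolve_altlocs()], [extract_calpha_trace()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("cannot parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  atom <- parsed$atom
  if (is.null(atom) || nrow(atom) == 0L)
    stop("empty coordinate set in ", path)
  names(atom)[names(atom) == "type"] <- "record"
  if (is.null(atom$elesy) || all(is.na(atom$elesy) | atom$elesy == ""))
    atom$elesy <- guess_element(atom$elety)
  atom$elesy <- toupper(trimws(atom$elesy))
  if (is.null(id)) id <- sub("\\.(pdb|ent|cif|mmcif)$", "",
                             basename(path), ignore.case = TRUE)
  new_structure_model(atom, id = id, source_format =
                        if (format == "mmcif") "mmcif" else "pdb")
}

# element from an atom name, PDB conventions (fallback only)
guess_element <- function(elety) {
  nm <- toupper(trimws(elety))
  two <- c("ZN", "CL", "CA", "MG", "NA", "MN", "FE", "CU", "NI", "CO", "BR", "SE")
  ifelse(nm %in% two & nchar(nm) == 2L, nm, substr(nm, 1L, 1L))
}

#' Write a structure to a PDB file
#'
#' Emits ATOM/HETATM records through `bio3d::write.pdb`; coordinates
#' round-trip to the PDB fixed-format precision of 0.001 Angstrom.
#'
#' @param s a [structure_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure_model"))
  a <- s$atom
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  bio3d::write.pdb(pdb = NULL, file = path,
                   type = a$record,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   alt = ifelse(a$alt == "", NA, a$alt),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atom
  pol <- a[a$record == "ATOM", ]
  chains <- unique(pol$chain)
  nres <- nrow(unique(pol[, c("chain", "resno", "insert")]))
  het <- a[a$record == "HETATM", ]
  cat(sprintf("structure_model '%s' (%s): %d atoms, %d polymer residues in %d chain(s) [%s]\n",
              x$id, x$source_format, nrow(a), nres, length(chains),
              paste(chains, collapse = ",")))
  if (nrow(het))
    cat("  hetero:", paste(sprintf("%s x%d", names(tb <- table(het$resid)), tb),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Chains of a structure
#' @param s a [structure_model].
#' @param polymer restrict to chains with polymer (ATOM) records.
#' @return Character vector of chain identifiers, in file order.
#' @export
structure_chains <- function(s, polymer = TRUE) {
  a <- if (polymer) s$atom[s$atom$record == "ATOM", ] else s$atom
  unique(a$chain)
}

#' Resolve alternate atom locations
#'
#' Crystal structures may model one atom in several positions (altlocs).
#' `"highest_occupancy"` keeps, per atom, the conformer with the largest
#' occupancy (ties broken by the lexicographically first altloc id) and is
#' idempotent; `"keep_all"` leaves every labelled conformer in place for
#' distance queries.
#'
#' @param s a [structure_model].
#' @param policy `"highest_occupancy"` or `"keep_all"`.
#' @return A `structure_model`.
#' @export
resolve_altlocs <- function(s, policy = c("highest_occupancy", "keep_all")) {
  policy <- match.arg(policy)
  if (policy == "keep_all") return(s)
  a <- s$atom
  key <- paste(a$record, a$chain, a$resno, a$insert, a$resid, a$elety, sep = "\r")
  ord <- order(key, -a$o, a$alt)
  keep <- ord[!duplicated(key[ord])]
  s$atom <- a[sort(keep), , drop = FALSE]
  rownames(s$atom) <- NULL
  s
}

#' Extract the C-alpha trace of a chain
#'
#' One entry per polymer residue possessing a CA atom, in chain order;
#' residues lacking a CA are skipped (their count is attached as the
#' `n_skipped` attribute).  Altlocs are resolved to highest occupancy first.
#'
#' @param s a [structure_model].
#' @param chain_id chain identifier.
#' @return Data frame with columns `resno`, `insert`, `resid`, `x`, `y`, `z`.
#' @export
extract_calpha_trace <- function(s, chain_id) {
  if (!chain_id %in% structure_chains(s, polymer = TRUE))
    stop("no polymer chain '", chain_id, "' in structure '", s$id, "'")
  a <- resolve_altlocs(s, "highest_occupancy")$atom
  a <- a[a$record == "ATOM" & a$chain == chain_id, , drop = FALSE]
  res <- unique(a[, c("resno", "insert")])
  ca <- a[a$elety == "CA", c("resno", "insert", "resid", "x", "y", "z")]
  ca <- ca[!duplicated(ca[, c("resno", "insert")]), , drop = FALSE]
  rownames(ca) <- NULL
  attr(ca, "n_skipped") <- nrow(res) - nrow(ca)
  ca
}

#' Select residues by chain and residue-number specification
#'
#' Selection strings follow `"chain"` or `"chain:ranges"` with ranges like
#' `"A:11-97,272-417"`; a bare chain selects the whole chain (polymer and
#' hetero records alike).
#'
#' @param s a [structure_model].
#' @param spec selection string.
#' @return The matching rows of the atom table.
#' @export
select_residues <- function(s, spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  chain <- parts[1]
  a <- s$atom[s$atom$chain == chain, , drop = FALSE]
  if (length(parts) > 1L && nzchar(parts[2])) {
    resnos <- parse_ranges(parts[2])
    a <- a[a$resno %in% resnos, , drop = FALSE]
  }
  a
}

# "11-97,272-417,507" -> integer vector
parse_ranges <- function(txt) {
  pieces <- strsplit(txt, ",", fixed = TRUE)[[1]]
  unlist(lapply(pieces, function(p) {
    ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
    if (length(ab) == 1L) ab else seq.int(ab[1], ab[2])
  }))
}

#' Locate single-atom hetero (metal/ion) records
#'
#' @param s a [structure_model].
#' @param selector residue name or element symbol (e.g. `"ZN"`).
#' @param chain optional chain to disambiguate multiple matches.
#' @return Atom-table rows for the matching hetero atoms.
#' @export
hetero_atoms <- function(s, selector, chain = NULL) {
  a <- s$atom[s$atom$record == "HETATM", , drop = FALSE]
  sel <- toupper(selector)
  a <- a[toupper(a$resid) == sel | toupper(a$elesy) == sel, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  a
}

#' Fetch a deposited structure by accession
#'
#' Downloads `<accession>.pdb` (or `.cif`) from the RCSB into a local cache
#' directory and returns the cached path.  Purely a convenience for
#' reproducing published comparisons; nothing in the package or its tests
#' requires network access.
#'
#' @param accession 4-character PDB accession.
#' @param dir cache directory.
#' @param format `"pdb"` or `"cif"`.
#' @return Path to the cached file.
#' @export
fetch_structure <- function(accession, dir = file.path(tempdir(), "pdb_cache"),
                            format = c("pdb", "cif")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dest <- file.path(dir, paste0(tolower(accession), ".", format))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.%s",
                   toupper(accession), format)
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}
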