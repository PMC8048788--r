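#' Pipeline report commands
#'
#' Thin orchestration layer over the analysis functions: each `cmd_*`
#' function reads its inputs, runs one analysis and writes TSV and JSON
#' reports into an output directory.  Every number in a report is
#' recomputable by calling the underlying function; one structured message
#' per stage logs the residue/pair bookkeeping.  These functions back the
#' `inst/cli/clamshell.R` command-line script.
#'
#' @name pipeline
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

ensure_outdir <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outdir
}

load_input <- function(x) {
  if (inherits(x, "structure_model")) x else read_structure(x)
}

#' Compare two conformations and write the full motion report
#'
#' Runs [domain_motion()] and writes `profile.tsv`, `regions.tsv`,
#' `hinges.tsv` and `compare.json` (superposition summaries, screw axis,
#' hetero displacements) into `outdir`.
#'
#' @param mobile,reference paths or [structure_model]s.
#' @param outdir output directory (created if needed).
#' @param scheme a [subdomain_scheme].
#' @param ... passed on to [domain_motion()].
#' @return The `domain_motion` fit, invisibly.
#' @export
cmd_compare <- function(mobile, reference, outdir, scheme = nace_scheme(),
                        ...) {
  ensure_outdir(outdir)
  mobile <- load_input(mobile); reference <- load_input(reference)
  fit <- domain_motion(mobile, reference, scheme, ...)
  message(sprintf("compare: %d corresponded pairs; anchored RMSD %.3f A (n=%d), global %.3f A (n=%d)",
                  nrow(fit$map), fit$anchored$rmsd_selection,
                  fit$anchored$n_selection, fit$global$rmsd_selection,
                  fit$global$n_selection))
  write_tsv(as.data.frame(fit$profile), file.path(outdir, "profile.tsv"))
  write_tsv(fit$regions, file.path(outdir, "regions.tsv"))
  write_tsv(fit$hinges, file.path(outdir, "hinges.tsv"))
  js <- list(
    mobile = fit$mobile_id, reference = fit$reference_id,
    scheme = fit$scheme$name, n_pairs = nrow(fit$map),
    anchored = list(rmsd_selection = fit$anchored$rmsd_selection,
                    n_selection = fit$anchored$n_selection,
                    rmsd_global = fit$anchored$rmsd_global,
                    n_global = fit$anchored$n_global),
    global = list(rmsd = fit$global$rmsd_selection,
                  n = fit$global$n_selection),
    screw = list(angle_deg = fit$screw$angle_deg,
                 axis_defined = fit$screw$axis_defined,
                 axis_direction = fit$screw$axis_direction,
                 axis_point = fit$screw$axis_point,
                 translation_along_axis = fit$screw$translation_along_axis,
                 residual_rmsd = fit$screw$residual_rmsd,
                 hinge_axis_distances = fit$screw$hinge_axis_distances),
    hetero_displacement = as.list(fit$hetero))
  write_json_report(js, file.path(outdir, "compare.json"))
  invisible(fit)
}

#' Pairwise RMSD matrix report
#'
#' Writes `matrix.tsv` (RMSD with the pair count in brackets, the layout
#' of published open/closed comparison tables) and `matrix.json`.
#'
#' @param inputs list/vector of paths or [structure_model]s (>= 2).
#' @param outdir output directory.
#' @param chains chain id(s), recycled.
#' @param mode correspondence mode.
#' @return The `rmsd_matrix`, invisibly.
#' @export
cmd_matrix <- function(inputs, outdir, chains = "A",
                       mode = c("number", "align")) {
  mode <- match.arg(mode)
  ensure_outdir(outdir)
  structures <- lapply(inputs, load_input)
  m <- pairwise_rmsd_matrix(structures, chains, mode)
  message(sprintf("matrix: %d structures, %d pairwise fits",
                  length(structures), choose(length(structures), 2)))
  k <- nrow(m$rmsd)
  txt <- matrix("-", k, k, dimnames = dimnames(m$rmsd))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    txt[i, j] <- sprintf("%.3f (%d)", m$rmsd[i, j], m$n[i, j])
  write_tsv(data.frame(structure = rownames(txt), txt,
                       check.names = FALSE), file.path(outdir, "matrix.tsv"))
  write_json_report(list(ids = rownames(m$rmsd), rmsd = m$rmsd, n_pairs = m$n),
                    file.path(outdir, "matrix.json"))
  invisible(m)
}

#' Interface-contact report
#'
#' Writes the per-residue interface fingerprint (`fingerprint.tsv`),
#' metal coordination spheres (`metal.tsv`) and water bridges between the
#' two chains, plus a merged `contacts.json`.
#'
#' @param input path or [structure_model].
#' @param peptide_chain,receptor_chain chain identifiers.
#' @param outdir output directory.
#' @param metal hetero selector for coordination analysis; skipped with a
#'   message when absent.
#' @param ... cutoffs passed to [interface_fingerprint()].
#' @return The `interface_fingerprint`, invisibly.
#' @export
cmd_contacts <- function(input, peptide_chain, receptor_chain, outdir,
                         metal = "ZN", ...) {
  ensure_outdir(outdir)
  s <- load_input(input)
  fp <- interface_fingerprint(s, peptide_chain, receptor_chain, ...)
  message(sprintf("contacts: %d records across %d peptide residues (%d silent)",
                  nrow(fp$records), nrow(fp$by_residue), length(fp$silent)))
  write_tsv(as.data.frame(fp$records), file.path(outdir, "fingerprint.tsv"))
  coord <- tryCatch(find_metal_coordination(s, metal),
                    error = function(e) {
                      message("metal coordination skipped: ",
                              conditionMessage(e))
                      empty_records()
                    })
  write_tsv(as.data.frame(coord), file.path(outdir, "metal.tsv"))
  write_json_report(list(peptide_chain = peptide_chain,
                         receptor_chain = receptor_chain,
                         records = as.data.frame(fp$records),
                         silent_residues = fp$silent,
                         metal_coordination = as.data.frame(coord)),
                    file.path(outdir, "contacts.json"))
  invisible(fp)
}

#' Simulate a clam-shell pair to disk
#'
#' Writes `closed.pdb`, `open.pdb` and `truth.json` for a
#' [clamshell_spec()]; byte-identical output for identical spec and seed.
#'
#' @param spec a [clamshell_spec].
#' @param outdir output directory.
#' @return The [generate_clamshell()] result, invisibly.
#' @export
cmd_simulate <- function(spec, outdir) {
  ensure_outdir(outdir)
  pair <- generate_clamshell(spec)
  write_structure(pair$closed, file.path(outdir, "closed.pdb"))
  write_structure(pair$open, file.path(outdir, "open.pdb"))
  write_scheme_json(pair$scheme, file.path(outdir, "scheme.json"))
  tr <- pair$truth
  write_json_report(list(theta = tr$theta,
                         axis_direction = tr$axis_direction,
                         axis_point = tr$axis_point,
                         hinge_range = range(tr$hinge_range),
                         metal_displacement = tr$metal_displacement,
                         noise_sigma = tr$noise_sigma,
                         displacement = tr$displacement),
                    file.path(outdir, "truth.json"))
  message(sprintf("simulate: %d residues, theta %.1f deg, sigma %.2f A",
                  nrow(tr$displacement), tr$theta, tr$noise_sigma))
  invisible(pair)
}
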