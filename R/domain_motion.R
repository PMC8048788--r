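#' Superpose two chains on a residue selection
#'
#' Least-squares fit of the mobile chain onto the reference computed only
#' from corresponded C-alpha pairs whose (reference-numbering) residue
#' number lies in `selection`; the same transform is then scored over all
#' corresponded pairs.  Anchoring the fit on subdomain 2 and reading off
#' the global RMSD is how the relative movement of subdomain 1 between
#' open and closed conformations is visualised and quantified.
#'
#' @param mobile,reference [structure_model] objects.
#' @param selection integer vector of residue numbers (reference numbering),
#'   e.g. `nace_scheme()$subdomain2`; `NULL` selects all corresponded pairs
#'   (a global, Table-2-style fit).
#' @param map a [build_correspondence()] result; built on the fly if `NULL`.
#' @param chain_mobile,chain_reference chain identifiers.
#' @param mode correspondence mode when `map` is `NULL`.
#' @return An object of class `superposition`: `transform` (mobile onto
#'   reference), `rmsd_selection`/`n_selection`, `rmsd_global`/`n_global`.
#' @export
superpose_on_selection <- function(mobile, reference, selection = NULL,
                                   map = NULL, chain_mobile = "A",
                                   chain_reference = "A",
                                   mode = c("number", "align")) {
  mode <- match.arg(mode)
  if (is.null(map))
    map <- build_correspondence(mobile, reference, chain_mobile,
                                chain_reference, mode)
  tm <- extract_calpha_trace(mobile, attr(map, "chain_a"))
  tr_ <- extract_calpha_trace(reference, attr(map, "chain_b"))
  pc <- paired_coords(map, tm, tr_)
  in_sel <- if (is.null(selection)) rep(TRUE, length(pc$resno))
            else pc$resno %in% selection
  if (sum(in_sel) < 3L)
    stop("fewer than 3 corresponded C-alpha pairs in the selection (",
         sum(in_sel), ")")
  fit <- kabsch_fit(pc$a[in_sel, , drop = FALSE], pc$b[in_sel, , drop = FALSE])
  moved <- apply_transform(fit$transform, pc$a)
  structure(list(transform = fit$transform,
                 rmsd_selection = fit$rmsd, n_selection = fit$n,
                 rmsd_global = rmsd_coords(moved, pc$b),
                 n_global = nrow(pc$a),
                 mobile_id = mobile$id, reference_id = reference$id),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition %s -> %s: selection RMSD %.3f A (%d CA), global RMSD %.3f A (%d CA)\n",
              x$mobile_id, x$reference_id, x$rmsd_selection, x$n_selection,
              x$rmsd_global, x$n_global))
  invisible(x)
}

#' Per-residue C-alpha displacement profile
#'
#' After anchoring the mobile structure on the reference's subdomain 2,
#' the Euclidean distance between each corresponded mobile and reference
#' C-alpha.  The profile is the raw material for region summaries and hinge
#' detection: mobile regions stand out as displacement peaks and hinges as
#' near-zero troughs between them.
#'
#' @inheritParams superpose_on_selection
#' @param scheme a [subdomain_scheme]; its `subdomain2` is the anchor.
#' @return Class `displacement_profile`: data frame `resno`, `insert`,
#'   `displacement` (A), with the anchoring `superposition` in the
#'   `superposition` attribute.
#' @export
displacement_profile <- function(mobile, reference, scheme, map = NULL,
                                 chain_mobile = "A", chain_reference = "A",
                                 mode = c("number", "align")) {
  mode <- match.arg(mode)
  if (is.null(map))
    map <- build_correspondence(mobile, reference, chain_mobile,
                                chain_reference, mode)
  sup <- superpose_on_selection(mobile, reference, scheme$subdomain2, map)
  tm <- extract_calpha_trace(mobile, attr(map, "chain_a"))
  tr_ <- extract_calpha_trace(reference, attr(map, "chain_b"))
  pc <- paired_coords(map, tm, tr_)
  moved <- apply_transform(sup$transform, pc$a)
  out <- data.frame(resno = pc$resno, insert = pc$insert,
                    displacement = sqrt(rowSums((moved - pc$b)^2)))
  out <- out[order(out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("displacement_profile", "data.frame"),
            superposition = sup, anchored_on = paste0(scheme$name, ":subdomain2"),
            mobile_id = mobile$id, reference_id = reference$id)
}

#' @export
print.displacement_profile <- function(x, ...) {
  cat(sprintf("displacement_profile %s vs %s (anchored on %s): %d residues, max %.2f A at %d\n",
              attr(x, "mobile_id"), attr(x, "reference_id"),
              attr(x, "anchored_on"), nrow(x), max(x$displacement),
              x$resno[which.max(x$displacement)]))
  invisible(x)
}

#' Summarise displacement by named region
#'
#' One row per scheme region (the lid included): maximum displacement and
#' the residue attaining it, mean displacement, residues covered and
#' residues of the region missing from the correspondence.
#'
#' @param profile a [displacement_profile()].
#' @param scheme a [subdomain_scheme].
#' @return Data frame with columns `region`, `max_displacement`,
#'   `argmax_resno`, `mean_displacement`, `n_residues`, `n_missing`.
#' @export
summarize_regions <- function(profile, scheme) {
  regs <- scheme_regions_all(scheme)
  out <- do.call(rbind, lapply(names(regs), function(rn) {
    rows <- profile[profile$resno %in% regs[[rn]], , drop = FALSE]
    if (nrow(rows) == 0L)
      return(data.frame(region = rn, max_displacement = NA_real_,
                        argmax_resno = NA_integer_,
                        mean_displacement = NA_real_, n_residues = 0L,
                        n_missing = length(regs[[rn]])))
    data.frame(region = rn,
               max_displacement = max(rows$displacement),
               argmax_resno = rows$resno[which.max(rows$displacement)],
               mean_displacement = mean(rows$displacement),
               n_residues = nrow(rows),
               n_missing = length(regs[[rn]]) - nrow(rows))
  }))
  rownames(out) <- NULL
  if (any(out$n_residues == 0L))
    warning("region(s) with no corresponded residues: ",
            paste(out$region[out$n_residues == 0L], collapse = ", "))
  out
}

#' Detect hinge regions in a displacement profile
#'
#' A hinge is a short residue stretch that stays put while the regions it
#' connects swing: formally, after smoothing the profile with a centred
#' moving mean of width `window`, a maximal run of residues with smoothed
#' displacement below `t_low` that (i) lies in subdomain 1 or within
#' `window` residues of the subdomain boundary (when a scheme is supplied)
#' and (ii) has a residue exceeding `t_high` within `window` positions of
#' the run.  The score is the maximum flanking displacement divided by the
#' mean raw displacement inside the run (floored at 0.2 A).
#'
#' @param profile a [displacement_profile()] (or any data frame with
#'   `resno` and `displacement`).
#' @param scheme optional [subdomain_scheme] restricting where hinges may
#'   lie; `NULL` considers the whole profile.
#' @param window smoothing window and adjacency distance, residues.
#' @param t_low smoothed-displacement ceiling for hinge residues, Angstrom.
#' @param t_high displacement a flanking mobile region must exceed, Angstrom.
#' @return Data frame of hinge calls: `start_resno`, `end_resno`, `n`,
#'   `mean_displacement`, `flank_max`, `score`; zero rows when the profile
#'   is flat.
#' @export
detect_hinges <- function(profile, scheme = NULL, window = 5,
                          t_low = 1.5, t_high = 3.0) {
  stopifnot(nrow(profile) >= window)
  ord <- order(profile$resno)
  resno <- profile$resno[ord]
  disp <- profile$displacement[ord]
  n <- length(disp)
  half <- floor(window / 2)
  sm <- vapply(seq_len(n), function(i)
    mean(disp[max(1, i - half):min(n, i + half)]), numeric(1))
  low <- sm < t_low
  eligible <- rep(TRUE, n)
  if (!is.null(scheme)) {
    near_sub1 <- vapply(resno, function(r)
      any(abs(scheme$subdomain1 - r) <= window), logical(1))
    eligible <- near_sub1
  }
  runs <- rle(low & eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  calls <- list()
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    flank_idx <- c(seq(max(1, i0 - window), i0 - 1L),
                   seq(i1 + 1L, min(n, i1 + window)))
    flank_idx <- flank_idx[flank_idx >= 1 & flank_idx <= n]
    if (length(flank_idx) == 0L) next
    flank_max <- max(disp[flank_idx])
    if (flank_max <= t_high) next
    mean_in <- mean(disp[i0:i1])
    calls[[length(calls) + 1L]] <- data.frame(
      start_resno = resno[i0], end_resno = resno[i1], n = i1 - i0 + 1L,
      mean_displacement = mean_in, flank_max = flank_max,
      score = flank_max / max(mean_in, 0.2))
  }
  if (length(calls) == 0L)
    return(data.frame(start_resno = integer(0), end_resno = integer(0),
                      n = integer(0), mean_displacement = numeric(0),
                      flank_max = numeric(0), score = numeric(0)))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Screw-axis decomposition of the subdomain opening
#'
#' After anchoring the mobile structure on subdomain 2, the residual rigid
#' transform carrying the reference's subdomain-1 C-alphas onto the
#' (anchored) mobile subdomain 1 is fitted and decomposed into a screw
#' axis: the opening angle, its axis in the reference frame and the
#' translation along it.  Scheme hinges are ranked by their minimum
#' C-alpha distance to the axis — a true hinge sits on it.
#'
#' @inheritParams displacement_profile
#' @return Class `opening_screw`: the `screw_axis` fields plus
#'   `residual_rmsd` (subdomain-1 fit), `anchor` (the subdomain-2
#'   `superposition`) and `hinge_axis_distances` (data frame, one row per
#'   scheme hinge, sorted by distance; `NULL` when the axis is undefined).
#' @export
opening_transform <- function(mobile, reference, scheme, map = NULL,
                              chain_mobile = "A", chain_reference = "A",
                              mode = c("number", "align")) {
  mode <- match.arg(mode)
  if (is.null(map))
    map <- build_correspondence(mobile, reference, chain_mobile,
                                chain_reference, mode)
  sup <- superpose_on_selection(mobile, reference, scheme$subdomain2, map)
  tm <- extract_calpha_trace(mobile, attr(map, "chain_a"))
  tr_ <- extract_calpha_trace(reference, attr(map, "chain_b"))
  pc <- paired_coords(map, tm, tr_)
  in1 <- pc$resno %in% scheme$subdomain1
  if (sum(in1) < 3L)
    stop("fewer than 3 corresponded subdomain-1 C-alpha pairs")
  anchored <- apply_transform(sup$transform, pc$a)
  # reference subdomain 1 -> anchored mobile subdomain 1 (how the lobe moves)
  fit <- kabsch_fit(pc$b[in1, , drop = FALSE], anchored[in1, , drop = FALSE])
  screw <- screw_decompose(fit$transform)
  hd <- NULL
  if (isTRUE(screw$axis_defined) && length(scheme$hinges)) {
    ref_ca <- pc$b
    hd <- do.call(rbind, lapply(names(scheme$hinges), function(hn) {
      rows <- which(pc$resno %in% scheme$hinges[[hn]])
      if (length(rows) == 0L)
        return(data.frame(hinge = hn, min_axis_distance = NA_real_))
      d <- sweep(ref_ca[rows, , drop = FALSE], 2, screw$axis_point)
      along <- d %*% screw$axis_direction
      data.frame(hinge = hn,
                 min_axis_distance = sqrt(min(pmax(0, rowSums(d^2) - along^2))))
    }))
    hd <- hd[order(hd$min_axis_distance), , drop = FALSE]
    rownames(hd) <- NULL
  }
  structure(c(unclass(screw),
              list(residual_rmsd = fit$rmsd, n_subdomain1 = fit$n,
                   anchor = sup, hinge_axis_distances = hd)),
            class = c("opening_screw", "screw_axis"))
}

#' Displacement of a hetero atom (e.g. the catalytic zinc) on opening
#'
#' Distance between the mobile structure's metal (after a given or
#' subdomain-2-anchored transform) and the reference's metal.
#'
#' @inheritParams displacement_profile
#' @param selector hetero residue name or element symbol (e.g. `"ZN"`).
#' @param transform a `rigid_transform` from a prior anchored superposition;
#'   computed from `scheme`'s subdomain 2 when `NULL`.
#' @param scheme needed only when `transform` is `NULL`.
#' @param chain optional chain to disambiguate multiple hetero matches.
#' @return Displacement in Angstrom.
#' @export
hetero_displacement <- function(mobile, reference, selector = "ZN",
                                transform = NULL, scheme = NULL, map = NULL,
                                chain = NULL, chain_mobile = "A",
                                chain_reference = "A") {
  hm <- hetero_atoms(mobile, selector, chain)
  hr <- hetero_atoms(reference, selector, chain)
  if (nrow(hm) != 1L || nrow(hr) != 1L)
    stop("hetero selector '", selector, "' matches ", nrow(hm), " atom(s) in ",
         mobile$id, " and ", nrow(hr), " in ", reference$id,
         "; disambiguate with chain =")
  if (is.null(transform)) {
    if (is.null(scheme)) stop("supply either a transform or a scheme")
    transform <- superpose_on_selection(mobile, reference, scheme$subdomain2,
                                        map, chain_mobile,
                                        chain_reference)$transform
  }
  moved <- apply_transform(transform, c(hm$x, hm$y, hm$z))
  sqrt(sum((moved - c(hr$x, hr$y, hr$z))^2))
}

#' Pairwise RMSD matrix over a set of conformers
#'
#' For every structure pair, a global least-squares fit over all
#' corresponded C-alphas and its RMSD — the layout of published
#' open/closed comparison tables (RMSD with the pair count in brackets).
#'
#' @param structures list of [structure_model]s (length >= 2), ideally named.
#' @param chains chain identifier(s), recycled across structures.
#' @param mode correspondence mode.
#' @return Class `rmsd_matrix`: list of symmetric `rmsd` and `n` matrices.
#' @export
pairwise_rmsd_matrix <- function(structures, chains = "A",
                                 mode = c("number", "align")) {
  mode <- match.arg(mode)
  stopifnot(length(structures) >= 2L)
  k <- length(structures)
  chains <- rep_len(chains, k)
  ids <- names(structures)
  if (is.null(ids)) ids <- vapply(structures, function(s) s$id, "")
  rmsd <- matrix(0, k, k, dimnames = list(ids, ids))
  npair <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    ti <- extract_calpha_trace(structures[[i]], chains[i])
    npair[i, i] <- nrow(ti)
    for (j in seq_len(k)) {
      if (j <= i) next
      cell <- tryCatch({
        map <- build_correspondence(structures[[i]], structures[[j]],
                                    chains[i], chains[j], mode)
        tj <- extract_calpha_trace(structures[[j]], chains[j])
        pc <- paired_coords(map, ti, tj)
        fit <- kabsch_fit(pc$a, pc$b)
        c(fit$rmsd, fit$n)
      }, error = function(e) c(NA_real_, 0))
      rmsd[i, j] <- rmsd[j, i] <- cell[1]
      npair[i, j] <- npair[j, i] <- as.integer(cell[2])
    }
  }
  structure(list(rmsd = rmsd, n = npair), class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, digits = 3, ...) {
  k <- nrow(x$rmsd)
  txt <- matrix("", k, k, dimnames = dimnames(x$rmsd))
  for (i in seq_len(k)) for (j in seq_len(k))
    txt[i, j] <- if (i == j) "-" else if (is.na(x$rmsd[i, j])) "NA"
      else sprintf("%.*f (%d)", digits, x$rmsd[i, j], x$n[i, j])
  print(txt, quote = FALSE)
  invisible(x)
}
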