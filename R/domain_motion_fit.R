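#' Fit the domain motion between two conformations
#'
#' The package's central analysis: given a mobile and a reference
#' conformation of a two-lobe structure and a subdomain partition, it
#' (1) builds the residue correspondence, (2) superposes the mobile chain
#' on the reference's anchor subdomain (subdomain 2) and, for comparison,
#' globally over all corresponded C-alphas, (3) profiles per-residue
#' C-alpha displacements, (4) summarises the named mobile regions,
#' (5) detects hinges, (6) fits the residual subdomain-1 transform and
#' decomposes it into an opening screw axis, and (7) measures the
#' displacement of selected hetero atoms (e.g. the active-site zinc).
#'
#' @param mobile,reference [structure_model] objects (e.g. open and closed
#'   conformations; the screw describes how subdomain 1 moves from the
#'   reference to the mobile conformation).
#' @param scheme a [subdomain_scheme]; defaults to [nace_scheme()].
#' @param chain_mobile,chain_reference chain identifiers (default `"A"`,
#'   the first copy of multi-copy crystal forms).
#' @param mode correspondence mode, `"number"` or `"align"`.
#' @param hetero character vector of hetero selectors to track (a selector
#'   is skipped with a message when absent or ambiguous).
#' @param window,t_low,t_high hinge-detection parameters, see
#'   [detect_hinges()].
#' @return An object of class `domain_motion` with components `map`,
#'   `anchored` (subdomain-2 [superpose_on_selection()] result), `global`
#'   (all-C-alpha fit), `profile`, `regions`, `hinges`, `screw`
#'   ([opening_transform()] result) and `hetero` (named displacement
#'   vector).  Methods: `print`, `summary`, `coef` (opening angle, axis,
#'   axial translation), `residuals` (the displacement profile) and `plot`.
#' @examples
#' pair <- generate_clamshell(clamshell_spec(theta = 25, noise_sigma = 0.2))
#' fit <- domain_motion(pair$open, pair$closed, pair$scheme)
#' coef(fit)["angle_deg"]
#' @export
domain_motion <- function(mobile, reference, scheme = nace_scheme(),
                          chain_mobile = "A", chain_reference = "A",
                          mode = c("number", "align"), hetero = "ZN",
                          window = 5, t_low = 1.5, t_high = 3.0) {
  mode <- match.arg(mode)
  stopifnot(inherits(mobile, "structure_model"),
            inherits(reference, "structure_model"),
            inherits(scheme, "subdomain_scheme"))
  map <- build_correspondence(mobile, reference, chain_mobile,
                              chain_reference, mode)
  anchored <- superpose_on_selection(mobile, reference, scheme$subdomain2, map)
  global <- superpose_on_selection(mobile, reference, NULL, map)
  profile <- displacement_profile(mobile, reference, scheme, map)
  regions <- summarize_regions(profile, scheme)
  hinges <- detect_hinges(profile, scheme, window, t_low, t_high)
  screw <- opening_transform(mobile, reference, scheme, map)
  het <- numeric(0)
  for (sel in hetero) {
    d <- tryCatch(hetero_displacement(mobile, reference, sel,
                                      transform = anchored$transform),
                  error = function(e) {
                    message("hetero '", sel, "' skipped: ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(d)) het[sel] <- d
  }
  structure(list(call = match.call(), scheme = scheme, map = map,
                 anchored = anchored, global = global, profile = profile,
                 regions = regions, hinges = hinges, screw = screw,
                 hetero = het, mobile_id = mobile$id,
                 reference_id = reference$id),
            class = "domain_motion")
}

#' @export
print.domain_motion <- function(x, ...) {
  cat(sprintf("domain_motion: %s (mobile) vs %s (reference), scheme '%s'\n",
              x$mobile_id, x$reference_id, x$scheme$name))
  cat(sprintf("  %d corresponded C-alpha pairs\n", nrow(x$map)))
  cat(sprintf("  anchored fit (subdomain 2): RMSD %.3f A (%d CA); global over all pairs: %.3f A\n",
              x$anchored$rmsd_selection, x$anchored$n_selection,
              x$anchored$rmsd_global))
  cat(sprintf("  global least-squares fit: RMSD %.3f A (%d CA)\n",
              x$global$rmsd_selection, x$global$n_selection))
  if (isTRUE(x$screw$axis_defined))
    cat(sprintf("  opening: %.2f deg about axis [%s], axial shift %.2f A\n",
                x$screw$angle_deg,
                paste(sprintf("%.3f", x$screw$axis_direction), collapse = ", "),
                x$screw$translation_along_axis))
  else
    cat(sprintf("  opening: %.2f deg (axis undefined)\n", x$screw$angle_deg))
  if (length(x$hetero))
    cat("  hetero displacement:",
        paste(sprintf("%s %.2f A", names(x$hetero), x$hetero),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.domain_motion <- function(object, ...) {
  structure(list(fit = object), class = "summary.domain_motion")
}

#' @export
print.summary.domain_motion <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nRegion motion summary:\n")
  print(f$regions, row.names = FALSE, digits = 3)
  cat("\nHinge calls:\n")
  if (nrow(f$hinges)) print(f$hinges, row.names = FALSE, digits = 3)
  else cat("  (none)\n")
  if (!is.null(f$screw$hinge_axis_distances)) {
    cat("\nScheme hinges ranked by distance to the opening axis (A):\n")
    print(f$screw$hinge_axis_distances, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.domain_motion <- function(object, ...) {
  s <- object$screw
  c(angle_deg = s$angle_deg,
    axis_x = s$axis_direction[1], axis_y = s$axis_direction[2],
    axis_z = s$axis_direction[3],
    translation_along_axis = s$translation_along_axis)
}

#' @export
residuals.domain_motion <- function(object, ...) {
  stats::setNames(object$profile$displacement, object$profile$resno)
}

#' Plot a domain-motion displacement profile
#'
#' Per-residue C-alpha displacement against residue number, with scheme
#' regions shaded, hinge calls marked at the baseline and the hinge
#' thresholds drawn as reference lines.
#'
#' @param x a [domain_motion()] fit.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.domain_motion <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$resno, p$displacement, type = "h", lwd = 1,
                 col = "grey40", xlab = "residue",
                 ylab = expression("C" * alpha * " displacement (" * ring(A) * ")"),
                 main = sprintf("%s vs %s", x$mobile_id, x$reference_id), ...)
  regs <- scheme_regions_all(x$scheme)
  if (length(regs)) {
    cols <- grDevices::hcl.colors(max(3L, length(regs)), "Set 2", alpha = 0.25)
    for (i in seq_along(regs)) {
      r <- range(regs[[i]])
      graphics::rect(r[1], 0, r[2], max(p$displacement) * 1.02,
                     col = cols[i], border = NA)
      graphics::mtext(names(regs)[i], side = 3, at = mean(r), cex = 0.7,
                      line = 0.1)
    }
  }
  graphics::abline(h = c(1.5, 3.0), lty = 3, col = "grey60")
  if (nrow(x$hinges))
    graphics::segments(x$hinges$start_resno, 0, x$hinges$end_resno, 0,
                       lwd = 4, col = "red3")
  invisible(x)
}
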