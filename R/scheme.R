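#' Subdomain partition schemes
#'
#' A `subdomain_scheme` names the residue partition driving the domain-motion
#' analysis: the anchor subdomain (subdomain 2) on which structures are
#' superposed, the mobile subdomain (subdomain 1), the named mobile regions
#' inside subdomain 1, the annotated hinge stretches and the lid-like
#' region.  All residue sets are expressed in author numbering.
#'
#' @param name scheme name.
#' @param subdomain1,subdomain2 integer vectors of residue numbers (disjoint).
#' @param regions named list of integer residue-number vectors, each inside
#'   `subdomain1`.
#' @param hinges named list of integer residue-number vectors.
#' @param lid integer vector for the lid-like region (may straddle the
#'   subdomain boundary).
#' @return An object of class `subdomain_scheme`.
#' @seealso [nace_scheme()] for the built-in ACE N-domain partition.
#' @export
subdomain_scheme <- function(name, subdomain1, subdomain2,
                             regions = list(), hinges = list(),
                             lid = integer(0)) {
  subdomain1 <- as.integer(subdomain1); subdomain2 <- as.integer(subdomain2)
  if (length(intersect(subdomain1, subdomain2)))
    stop("subdomain residue sets overlap")
  for (rn in names(regions)) {
    out <- setdiff(as.integer(regions[[rn]]), subdomain1)
    if (length(out))
      stop("region '", rn, "' has residues outside subdomain 1: ",
           paste(utils::head(out), collapse = ", "))
  }
  structure(list(name = name,
                 subdomain1 = subdomain1, subdomain2 = subdomain2,
                 regions = lapply(regions, as.integer),
                 hinges = lapply(hinges, as.integer),
                 lid = as.integer(lid)),
            class = "subdomain_scheme")
}

#' @export
print.subdomain_scheme <- function(x, ...) {
  cat(sprintf("subdomain_scheme '%s': |subdomain1| = %d, |subdomain2| = %d, %d region(s), %d hinge(s)\n",
              x$name, length(x$subdomain1), length(x$subdomain2),
              length(x$regions), length(x$hinges)))
  invisible(x)
}

#' ACE N-domain subdomain scheme
#'
#' The built-in partition of the ACE N-domain (nACE, author numbering):
#' subdomain 1 comprises residues 11-97, 272-417 and 507-566 and subdomain 2
#' residues 98-271, 418-506 and 567-601.  The mobile portion of subdomain 1
#' splits into the lid-like region (residues 14-100, helices H2/H3) and four
#' regions — 272-378, 384-417, 507-547 and 552-566 — each pivoting about two
#' of the eight annotated hinges: residue 14 (h0), 78-100 (h1), 272 (h2),
#' 378-384 (h3), 417 (h4), 507 (h5), 548-551 (h6) and 567 (h7).  The same
#' scheme is applied to C-domain and ACE2 comparisons through the residue
#' correspondence map (nACE numbering).
#'
#' @return A [subdomain_scheme].
#' @export
nace_scheme <- function() {
  subdomain_scheme(
    name = "nACE",
    subdomain1 = c(11:97, 272:417, 507:566),
    subdomain2 = c(98:271, 418:506, 567:601),
    regions = list(region1 = 272:378, region2 = 384:417,
                   region3 = 507:547, region4 = 552:566),
    hinges = list(h0 = 14L, h1 = 78:100, h2 = 272L, h3 = 378:384,
                  h4 = 417L, h5 = 507L, h6 = 548:551, h7 = 567L),
    lid = 14:100
  )
}

#' Read or write a subdomain scheme as JSON
#'
#' Residue sets are stored as lists of `[from, to]` ranges, so custom
#' partitions can be passed to the command-line tools.
#'
#' @param path JSON file path.
#' @return `read_scheme_json()` returns a [subdomain_scheme];
#'   `write_scheme_json()` returns `path` invisibly.
#' @export
read_scheme_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expand <- function(x) {
    if (is.null(x) || length(x) == 0L) return(integer(0))
    m <- if (is.matrix(x)) x else matrix(unlist(x), ncol = 2, byrow = TRUE)
    unlist(lapply(seq_len(nrow(m)), function(i) seq.int(m[i, 1], m[i, 2])))
  }
  subdomain_scheme(name = js$name,
                   subdomain1 = expand(js$subdomain1),
                   subdomain2 = expand(js$subdomain2),
                   regions = lapply(js$regions, expand),
                   hinges = lapply(js$hinges, expand),
                   lid = expand(js$lid))
}

#' @rdname read_scheme_json
#' @param scheme a [subdomain_scheme].
#' @export
write_scheme_json <- function(scheme, path) {
  compress <- function(v) {
    if (!length(v)) return(list())
    v <- sort(unique(v))
    brk <- c(0, which(diff(v) != 1), length(v))
    lapply(seq_len(length(brk) - 1), function(i)
      c(v[brk[i] + 1], v[brk[i + 1]]))
  }
  js <- list(name = scheme$name,
             subdomain1 = compress(scheme$subdomain1),
             subdomain2 = compress(scheme$subdomain2),
             regions = lapply(scheme$regions, compress),
             hinges = lapply(scheme$hinges, compress),
             lid = compress(scheme$lid))
  jsonlite::write_json(js, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# regions plus the lid as an extra summarisable region
scheme_regions_all <- function(scheme) {
  out <- scheme$regions
  if (length(scheme$lid)) out <- c(list(lid = scheme$lid), out)
  out
}
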