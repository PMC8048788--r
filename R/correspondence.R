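#' Residue correspondence between two chains
#'
#' Builds the one-to-one pairing of residues that have a C-alpha observed in
#' both structures — the atom set over which every RMSD and displacement in
#' the package is computed.
#'
#' `mode = "number"` pairs residues with equal author residue number and
#' insertion code, appropriate when both structures use the same numbering
#' convention (e.g. two conformations of the same protein).
#' `mode = "align"` pairs residues through a global sequence alignment of the
#' one-letter sequences (BLOSUM62, affine gaps: open 10, extend 0.5, via
#' Biostrings), keeping only aligned non-gap positions; use it for homologue
#' comparisons such as ACE versus ACE2.
#'
#' @param a,b [structure_model] objects.
#' @param chain_a,chain_b chain identifiers (default `"A"`).
#' @param mode `"number"` or `"align"`.
#' @return An object of class `correspondence_map`: a data frame with
#'   columns `resno_a`, `insert_a`, `resid_a`, `resno_b`, `insert_b`,
#'   `resid_b`, with attributes `method`, `chain_a`, `chain_b` and (align
#'   mode) `alignment_score`.
#' @export
build_correspondence <- function(a, b, chain_a = "A", chain_b = "A",
                                 mode = c("number", "align")) {
  mode <- match.arg(mode)
  ta <- extract_calpha_trace(a, chain_a)
  tb <- extract_calpha_trace(b, chain_b)
  if (nrow(ta) == 0L || nrow(tb) == 0L)
    stop("empty C-alpha trace (", a$id, " chain ", chain_a, ": ", nrow(ta),
         "; ", b$id, " chain ", chain_b, ": ", nrow(tb), ")")
  score <- NA_real_
  if (mode == "number") {
    m <- merge(ta[, c("resno", "insert", "resid")],
               tb[, c("resno", "insert", "resid")],
               by = c("resno", "insert"), suffixes = c("_a", "_b"))
    pairs <- data.frame(resno_a = m$resno, insert_a = m$insert,
                        resid_a = m$resid_a,
                        resno_b = m$resno, insert_b = m$insert,
                        resid_b = m$resid_b, stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$resno_a, pairs$insert_a), , drop = FALSE]
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("mode = 'align' requires the Biostrings package")
    sa <- bio3d::aa321(ta$resid); sb <- bio3d::aa321(tb$resid)
    sa[is.na(sa) | sa == ""] <- "X"; sb[is.na(sb) | sb == ""] <- "X"
    blosum <- get_blosum62()
    aln <- Biostrings::pairwiseAlignment(paste(sa, collapse = ""),
                                         paste(sb, collapse = ""),
                                         substitutionMatrix = blosum,
                                         gapOpening = 10, gapExtension = 0.5,
                                         type = "global")
    score <- Biostrings::score(aln)
    ca <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    cb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ia <- ib <- 0L
    idx <- matrix(NA_integer_, 0, 2)
    take <- ca != "-" & cb != "-"
    ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
    idx <- cbind(ia[take], ib[take])
    pairs <- data.frame(resno_a = ta$resno[idx[, 1]],
                        insert_a = ta$insert[idx[, 1]],
                        resid_a = ta$resid[idx[, 1]],
                        resno_b = tb$resno[idx[, 2]],
                        insert_b = tb$insert[idx[, 2]],
                        resid_b = tb$resid[idx[, 2]],
                        stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0L)
    stop("empty correspondence between ", a$id, ":", chain_a,
         " and ", b$id, ":", chain_b)
  rownames(pairs) <- NULL
  structure(pairs, class = c("correspondence_map", "data.frame"),
            method = mode, chain_a = chain_a, chain_b = chain_b,
            alignment_score = score)
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat(sprintf("correspondence_map: %d residue pairs (%s mode, chains %s/%s)\n",
              nrow(x), attr(x, "method"), attr(x, "chain_a"),
              attr(x, "chain_b")))
  invisible(x)
}

# paired CA coordinate matrices for (mobile = a-side, reference = b-side)
paired_coords <- function(map, trace_a, trace_b) {
  ka <- match(paste(map$resno_a, map$insert_a),
              paste(trace_a$resno, trace_a$insert))
  kb <- match(paste(map$resno_b, map$insert_b),
              paste(trace_b$resno, trace_b$insert))
  ok <- !is.na(ka) & !is.na(kb)
  list(a = as.matrix(trace_a[ka[ok], c("x", "y", "z")]),
       b = as.matrix(trace_b[kb[ok], c("x", "y", "z")]),
       resno = map$resno_b[ok], insert = map$insert_b[ok])
}
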