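## Readers/writers for timed trees, alignments and strain metadata, plus the
## shared validation used throughout the package.

GAP <- "-"

#' Construct a TimedTree
#'
#' @param tree rooted \code{ape::phylo} with branch lengths in years.
#' @param tipDates named numeric vector of decimal calendar years covering all
#'   tips.
#' @return a validated \code{TimedTree}.
#' @export
timedTree <- function(tree, tipDates) {
  new("TimedTree", tree = tree, tipDates = tipDates[tree$tip.label])
}

#' Construct an MsaAlignment
#'
#' @param seqs named character vector of aligned sequences (equal length) or a
#'   character matrix of single residues with rownames.
#' @param alphabet one of \code{"dna"}, \code{"codon"}, \code{"protein"}.
#' @param validate run codon/residue validation (default TRUE).
#' @return a validated \code{MsaAlignment}.
#' @export
msaAlignment <- function(seqs, alphabet = c("dna", "codon", "protein"),
                         validate = TRUE) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) stop("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  m[] <- toupper(m)
  obj <- new("MsaAlignment", seqs = m, alphabet = alphabet)
  if (validate) validateAlignment(obj)
  obj
}

validateAlignment <- function(x) {
  m <- alignmentMatrix(x)
  ok <- switch(alphabetOf(x),
    dna = , codon = c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                      "B", "D", "H", "V", "N", GAP, "?"),
    protein = c(names(AA_CLASS_DEFAULT), "X", "B", "Z", "J", "*", GAP, "?"))
  bad <- setdiff(unique(as.vector(m)), ok)
  if (length(bad))
    stop("unknown symbols for alphabet '", alphabetOf(x), "': ",
         paste(bad, collapse = " "))
  if (alphabetOf(x) == "codon") {
    cm <- codonMatrix(x)
    stops <- c("TAA", "TAG", "TGA")
    cm_res <- gsub("U", "T", cm)
    hit <- which(matrix(cm_res %in% stops, nrow(cm)), arr.ind = TRUE)
    if (nrow(hit) > 0L)
      stop("in-frame stop codon in sequence '", rownames(cm)[hit[1, 1]],
           "' at codon position ", hit[1, 2])
  }
  invisible(TRUE)
}

#' Normalize a strain identifier
#'
#' Trims surrounding whitespace, collapses internal whitespace runs to a
#' single underscore and strips quotes. Idempotent.
#'
#' @param x character vector of ids.
#' @export
normalizeStrainId <- function(x) {
  x <- gsub("^['\" ]+|['\" ]+$", "", x)
  gsub("[[:space:]]+", "_", x)
}

parseDateSuffix <- function(labels) {
  m <- regmatches(labels, regexpr("_[0-9]+(\\.[0-9]+)?$", labels))
  out <- rep(NA_real_, length(labels))
  has <- grepl("_[0-9]+(\\.[0-9]+)?$", labels)
  out[has] <- as.numeric(sub("^_", "", m))
  names(out) <- labels
  out
}

#' Read a time-calibrated tree
#'
#' Parses a Newick file into a \code{TimedTree}. Tip dates come either from a
#' \code{name_YYYY[.fraction]} suffix after the last underscore of each tip
#' label, or from a sidecar table (data.frame or TSV path with columns
#' \code{strain_id}, \code{year}); the table overrides label suffixes.
#'
#' @param path Newick file path (or a \code{phylo} object).
#' @param dateSource \code{"label-suffix"} or \code{"table"}.
#' @param dates sidecar table (data.frame or TSV path) when
#'   \code{dateSource = "table"}.
#' @param calibrated additionally assert that tip heights match tip dates
#'   (strict chronogram), within \code{tol} years.
#' @param tol calibration tolerance in years.
#' @param stripDateSuffix drop the parsed \code{_year} suffix from tip labels
#'   (only with \code{dateSource = "label-suffix"}).
#' @return a \code{TimedTree}.
#' @export
readTimedTree <- function(path, dateSource = c("label-suffix", "table"),
                          dates = NULL, calibrated = FALSE, tol = 1e-6,
                          stripDateSuffix = FALSE) {
  dateSource <- match.arg(dateSource)
  tr <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in tree")
  tr$tip.label <- normalizeStrainId(tr$tip.label)
  if (dateSource == "label-suffix") {
    d <- parseDateSuffix(tr$tip.label)
    if (anyNA(d)) {
      missing_tips <- tr$tip.label[is.na(d)]
      stop("no date suffix on tip(s): ", paste(missing_tips, collapse = ", "))
    }
    if (stripDateSuffix) {
      tr$tip.label <- sub("_[0-9]+(\\.[0-9]+)?$", "", tr$tip.label)
      names(d) <- tr$tip.label
      if (anyDuplicated(tr$tip.label))
        stop("stripping date suffixes creates duplicate tip labels")
    }
  } else {
    tab <- if (is.character(dates)) read.delim(dates, stringsAsFactors = FALSE) else dates
    if (is.null(tab)) stop("dateSource = 'table' requires 'dates'")
    ids <- normalizeStrainId(tab$strain_id)
    d <- setNames(as.numeric(tab$year), ids)
    missing_tips <- setdiff(tr$tip.label, ids)
    if (length(missing_tips))
      stop("no date for tip(s): ", paste(missing_tips, collapse = ", "))
    d <- d[tr$tip.label]
  }
  tt <- timedTree(tr, d)
  if (calibrated && !isChronogram(tt, tol))
    stop("tree is not a chronogram consistent with the tip dates (tol ", tol, ")")
  tt
}

#' Write a timed tree
#'
#' Writes Newick with \code{_year} suffixes appended to tip labels (so the
#' file round-trips through \code{readTimedTree}) unless labels already carry
#' a parseable suffix matching the stored dates.
#'
#' @param x a \code{TimedTree}.
#' @param path output file.
#' @param digits significant digits for branch lengths.
#' @export
writeTimedTree <- function(x, path, digits = 15) {
  tr <- treeOf(x)
  d <- tipDates(x)
  suff <- parseDateSuffix(tr$tip.label)
  need <- is.na(suff) | abs(suff - d) > 1e-9
  tr$tip.label[need] <- paste0(tr$tip.label[need],
                               sub("0+$", "", sprintf("_%.6f", d[need])))
  tr$tip.label[need] <- sub("\\.$", ".0", tr$tip.label[need])
  ape::write.tree(tr, file = path, digits = digits)
  invisible(path)
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param path FASTA file.
#' @param alphabet \code{"dna"}, \code{"codon"} or \code{"protein"}; codon
#'   mode additionally checks frame and in-frame stop codons.
#' @return an \code{MsaAlignment}.
#' @export
readAlignment <- function(path, alphabet = c("dna", "codon", "protein")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  v <- setNames(as.character(ss), normalizeStrainId(names(ss)))
  msaAlignment(v, alphabet)
}

#' Write an alignment to FASTA
#'
#' @param x an \code{MsaAlignment}.
#' @param path output file.
#' @export
writeAlignment <- function(x, path) {
  m <- alignmentMatrix(x)
  v <- apply(m, 1, paste0, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(setNames(v, rownames(m))),
                              filepath = path)
  invisible(path)
}

#' Read strain metadata
#'
#' TSV with columns \code{strain_id}, \code{species}, \code{host},
#' \code{country}, \code{year}.
#'
#' @param path TSV file (or a data.frame passed through).
#' @param ids optional vector of tree/alignment ids that must all be covered.
#' @return data.frame with normalized \code{strain_id}.
#' @export
readStrainMetadata <- function(path, ids = NULL) {
  tab <- if (is.character(path)) read.delim(path, stringsAsFactors = FALSE) else path
  req <- c("strain_id", "species", "host", "country", "year")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  tab$strain_id <- normalizeStrainId(tab$strain_id)
  if (anyDuplicated(tab$strain_id)) stop("duplicate strain_id in metadata")
  if (!is.null(ids)) {
    missing_ids <- setdiff(normalizeStrainId(ids), tab$strain_id)
    if (length(missing_ids))
      stop("metadata missing strain(s): ", paste(missing_ids, collapse = ", "))
  }
  tab
}

## 61 sense codons under the standard genetic code, in fixed lexicographic
## order; the state space of the codon models.
senseCodons <- local({
  nt <- c("T", "C", "A", "G")
  all_codons <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  all_codons <- sort(all_codons)
  stops <- c("TAA", "TAG", "TGA")
  function() setdiff(all_codons, stops)
})

#' Amino acid encoded by each sense codon
#'
#' @return named character vector over the 61 sense codons.
#' @export
codonAminoAcids <- function() {
  cods <- senseCodons()
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc[cods]), cods)
}

#' Results envelope
#'
#' Standard list wrapper for stage outputs: \code{stage}, \code{params},
#' \code{results}, \code{seed}, \code{version}, plus optional warnings.
#'
#' @param stage short stage name.
#' @param params named list of parameters used.
#' @param results the payload.
#' @param seed RNG seed used (or NA).
#' @param warnings character vector of warnings raised.
#' @export
resultsEnvelope <- function(stage, params, results, seed = NA_integer_,
                            warnings = character()) {
  list(stage = stage, params = params, results = results, seed = seed,
       version = as.character(utils::packageVersion("parevol")),
       warnings = warnings)
}
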