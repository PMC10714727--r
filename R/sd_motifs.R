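## Shine-Dalgarno-like motif characterization: region extraction from
## annotated segments, degenerate-core scanning upstream of start codons,
## positional entropy / stability profiling, logo matrices and metadata
## reconciliation.

SD_CANONICAL <- "AGGAGGT"
SD_CORE_G_POSITIONS <- c(2L, 3L, 5L, 6L)   # xGGxGGx

#' Annotated genome segment
#'
#' @param sequence DNA string, 5'->3' coding strand.
#' @param orfs data.frame with columns \code{orf_name}, \code{start},
#'   \code{end} (1-based inclusive). Every ORF must begin with ATG and end
#'   with a stop codon, and ORFs must not overlap.
#' @return list of class data: \code{sequence}, \code{orfs} (sorted).
#' @export
annotatedSegment <- function(sequence, orfs) {
  sequence <- toupper(gsub("U", "T", sequence))
  if (grepl("[^ACGTRYSWKMBDHVN-]", sequence))
    stop("non-DNA characters in sequence")
  stopifnot(all(c("start", "end") %in% names(orfs)))
  if (is.null(orfs$orf_name)) orfs$orf_name <- paste0("ORF", seq_len(nrow(orfs)))
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  n <- nchar(sequence)
  if (any(orfs$start < 1 | orfs$end > n | orfs$start >= orfs$end))
    stop("ORF coordinates out of range")
  if (nrow(orfs) > 1 && any(orfs$start[-1] <= orfs$end[-nrow(orfs)]))
    stop("overlapping ORFs")
  for (i in seq_len(nrow(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    if ((e - s + 1L) %% 3L != 0L)
      stop("ORF ", orfs$orf_name[i], " length not a multiple of 3")
    if (substr(sequence, s, s + 2L) != "ATG")
      stop("ORF ", orfs$orf_name[i], " does not start with ATG")
    if (!substr(sequence, e - 2L, e) %in% c("TAA", "TAG", "TGA"))
      stop("ORF ", orfs$orf_name[i], " does not end with a stop codon")
  }
  list(sequence = sequence, orfs = orfs)
}

#' Extract untranslated regions from an annotated segment
#'
#' @param record an \code{annotatedSegment}.
#' @return data.frame: \code{region} ("5UTR", "intergenic_<k>", "3UTR"),
#'   \code{start}, \code{end} (1-based inclusive; start > end means empty),
#'   \code{sequence}, \code{upstreamOf} (ORF name whose start codon follows
#'   the region, NA for the 3'UTR).
#' @export
extractRegions <- function(record) {
  orfs <- record$orfs
  seqlen <- nchar(record$sequence)
  rows <- list()
  sub0 <- function(s, e) if (s > e) "" else substr(record$sequence, s, e)
  rows[[1]] <- data.frame(region = "5UTR", start = 1L,
                          end = orfs$start[1] - 1L,
                          sequence = sub0(1L, orfs$start[1] - 1L),
                          upstreamOf = orfs$orf_name[1])
  if (nrow(orfs) > 1) {
    for (k in 2:nrow(orfs)) {
      rows[[length(rows) + 1]] <- data.frame(
        region = paste0("intergenic_", k - 1L),
        start = orfs$end[k - 1] + 1L, end = orfs$start[k] - 1L,
        sequence = sub0(orfs$end[k - 1] + 1L, orfs$start[k] - 1L),
        upstreamOf = orfs$orf_name[k])
    }
  }
  rows[[length(rows) + 1]] <- data.frame(
    region = "3UTR", start = orfs$end[nrow(orfs)] + 1L, end = seqlen,
    sequence = sub0(orfs$end[nrow(orfs)] + 1L, seqlen),
    upstreamOf = NA_character_)
  do.call(rbind, rows)
}

#' Scan for a Shine-Dalgarno-like motif upstream of a start codon
#'
#' The search window places the 7-mer so that its 3' end lies
#' \code{spacerCenter - spacerTol} to \code{spacerCenter + spacerTol}
#' nucleotides upstream of the ATG. A window matching the canonical 7-mer
#' (U = T) is "canonical"; one matching the degenerate core xGGxGGx
#' (G required at positions 2, 3, 5, 6; positions 1, 4, 7 free, up to
#' \code{maxCoreMismatch} of the required Gs excused) is "variant". When
#' several windows match, canonical matches win over variants; among equals
#' the spacer closest to \code{spacerCenter} is reported, ties toward the
#' shorter spacer. "absent" means no window matches; NA means the region is
#' shorter than the minimal scan window (7 + shortest spacer).
#'
#' @param utr upstream region (coding strand); the ATG is assumed to start
#'   immediately after its 3' end.
#' @param canonical canonical 7-mer (default AGGAGGT).
#' @param spacerCenter,spacerTol spacer model (default 5 +/- 2 nt).
#' @param maxCoreMismatch mismatches tolerated among the four core Gs
#'   (default 0).
#' @return one-row data.frame: \code{category}, \code{motif}, \code{spacer},
#'   \code{position} (1-based start of the motif in the region).
#' @export
scanSD <- function(utr, canonical = SD_CANONICAL, spacerCenter = 5L,
                   spacerTol = 2L, maxCoreMismatch = 0L) {
  utr <- toupper(gsub("U", "T", utr))
  if (nchar(utr) && grepl("[^ACGTRYSWKMBDHVN-]", utr))
    stop("non-DNA characters in UTR")
  canonical <- toupper(gsub("U", "T", canonical))
  spacers <- (spacerCenter - spacerTol):(spacerCenter + spacerTol)
  spacers <- spacers[spacers >= 0]
  L <- nchar(utr)
  if (L < 7L + min(spacers))
    return(data.frame(category = "NA", motif = NA_character_,
                      spacer = NA_integer_, position = NA_integer_))
  hits <- data.frame(spacer = integer(), motif = character(),
                     canonical = logical(), position = integer())
  for (s in spacers) {
    en <- L - s
    st <- en - 6L
    if (st < 1L) next
    w <- substr(utr, st, en)
    gs <- strsplit(w, "")[[1]][SD_CORE_G_POSITIONS]
    if (sum(gs != "G") <= maxCoreMismatch) {
      hits <- rbind(hits, data.frame(spacer = s, motif = w,
                                     canonical = (w == canonical),
                                     position = st))
    }
  }
  if (nrow(hits) == 0L)
    return(data.frame(category = "absent", motif = NA_character_,
                      spacer = NA_integer_, position = NA_integer_))
  pick <- function(h) {
    d <- abs(h$spacer - spacerCenter)
    h <- h[order(d, h$spacer), , drop = FALSE]
    h[1, ]
  }
  best <- if (any(hits$canonical)) pick(hits[hits$canonical, , drop = FALSE])
          else pick(hits)
  data.frame(category = if (best$canonical) "canonical" else "variant",
             motif = best$motif, spacer = best$spacer, position = best$position)
}

#' Scan every upstream region of a set of annotated segments
#'
#' @param segments named list of \code{annotatedSegment}s (names = strain ids).
#' @param ... passed to \code{scanSD}.
#' @return data.frame: \code{strain_id}, \code{region}, \code{category},
#'   \code{motif}, \code{spacer}.
#' @export
scanSegments <- function(segments, ...) {
  out <- lapply(names(segments), function(id) {
    regs <- extractRegions(segments[[id]])
    regs <- regs[!is.na(regs$upstreamOf), , drop = FALSE]
    hits <- do.call(rbind, lapply(seq_len(nrow(regs)), function(r)
      scanSD(regs$sequence[r], ...)))
    cbind(strain_id = id, region = regs$region, hits)
  })
  do.call(rbind, out)
}

#' Per-position Shannon entropy of aligned motifs
#'
#' H = -sum_b p_b log2 p_b over the observed bases at each of the 7 motif
#' positions (no pseudocounts); a motif group is called stable when the mean
#' positional entropy does not exceed \code{threshold} bits.
#'
#' @param motifs character vector of equal-length motifs (U = T).
#' @param threshold stability threshold in bits (default 0.5).
#' @return list: \code{entropy} per position (bits), \code{stable} logical,
#'   \code{meanEntropy}, \code{threshold}, \code{n}.
#' @export
positionEntropy <- function(motifs, threshold = 0.5) {
  motifs <- toupper(gsub("U", "T", motifs))
  motifs <- motifs[!is.na(motifs)]
  if (!length(motifs)) stop("no motifs")
  if (length(unique(nchar(motifs))) != 1L) stop("motifs differ in length")
  m <- do.call(rbind, strsplit(motifs, ""))
  H <- apply(m, 2, function(col) {
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
  list(entropy = unname(H), meanEntropy = mean(H),
       stable = mean(H) <= threshold, threshold = threshold,
       n = length(motifs))
}

#' Position probability matrix of aligned motifs
#'
#' @param motifs character vector of equal-length motifs.
#' @return column-stochastic 4 x width matrix over A, C, G, T.
#' @export
logoMatrix <- function(motifs) {
  motifs <- toupper(gsub("U", "T", motifs))
  motifs <- motifs[!is.na(motifs)]
  if (!length(motifs)) stop("no motifs")
  if (length(unique(nchar(motifs))) != 1L) stop("motifs differ in length")
  m <- do.call(rbind, strsplit(motifs, ""))
  out <- apply(m, 2, function(col)
    as.numeric(table(factor(col, levels = NT))) / length(col))
  rownames(out) <- NT
  out
}

#' Reconcile motif hits with strain metadata
#'
#' @param hits data.frame from \code{scanSegments} (or any table with
#'   \code{strain_id} and \code{category}).
#' @param metadata data.frame from \code{readStrainMetadata}.
#' @param epochs optional named vector strain_id -> epoch label, appended as
#'   a grouping variable.
#' @param groupBy metadata columns to cross-tabulate by.
#' @return list: \code{overall} (category proportions), \code{byGroup}
#'   (long data.frame: variable, group, category, n, proportion),
#'   \code{excluded} count of hits without metadata.
#' @export
summarizeByMetadata <- function(hits, metadata,
                                epochs = NULL,
                                groupBy = c("species", "host", "country")) {
  hits$strain_id <- normalizeStrainId(hits$strain_id)
  idx <- match(hits$strain_id, metadata$strain_id)
  excluded <- sum(is.na(idx))
  if (excluded > 0)
    warning(excluded, " hit(s) without matching metadata excluded")
  ok <- !is.na(idx)
  h <- cbind(hits[ok, , drop = FALSE],
             metadata[idx[ok], setdiff(names(metadata), "strain_id"),
                      drop = FALSE])
  if (!is.null(epochs)) {
    h$epoch <- epochs[h$strain_id]
    groupBy <- c(groupBy, "epoch")
  }
  lev <- c("canonical", "variant", "absent", "NA")
  prop <- function(x) {
    tb <- table(factor(x, levels = lev))
    as.numeric(tb) / max(sum(tb), 1L)
  }
  overall <- setNames(prop(h$category), lev)
  long <- list()
  for (v in intersect(groupBy, names(h))) {
    for (g in unique(h[[v]])) {
      sub <- h$category[h[[v]] == g]
      tb <- table(factor(sub, levels = lev))
      long[[length(long) + 1]] <- data.frame(
        variable = v, group = as.character(g), category = lev,
        n = as.numeric(tb), proportion = as.numeric(tb) / sum(tb))
    }
  }
  list(overall = overall,
       byGroup = if (length(long)) do.call(rbind, long) else NULL,
       excluded = excluded)
}
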