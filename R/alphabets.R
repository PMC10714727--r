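## Physicochemical reduction schemes for amino-acid alphabets.

#' Default 5-class physicochemical reduction
#'
#' Maps each of the 20 standard residues to one of five classes:
#' nonpolar, polar (uncharged), positive, negative, aromatic.
#' @export
AA_CLASS_DEFAULT <- c(
  G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
  I = "nonpolar", P = "nonpolar", M = "nonpolar", C = "nonpolar",
  S = "polar", T = "polar", N = "polar", Q = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative",
  F = "aromatic", Y = "aromatic", W = "aromatic")

#' Identity scheme: every residue its own class
#' @export
AA_CLASS_IDENTITY <- setNames(names(AA_CLASS_DEFAULT), names(AA_CLASS_DEFAULT))

#' Two-class charge scheme (charged vs uncharged)
#' @export
AA_CLASS_CHARGE <- setNames(
  ifelse(AA_CLASS_DEFAULT %in% c("positive", "negative"), "charged", "uncharged"),
  names(AA_CLASS_DEFAULT))

AA_LETTERS <- names(AA_CLASS_DEFAULT)
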