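## Translation, codon-aware back-translation, substitution classification.

## Vectorized codon -> amino acid lookup under the standard genetic code.
## Codons containing N (or any non-ACGT character) translate to "X".
translateCodons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a coding sequence under the standard genetic code
#'
#' The input must be in frame (length divisible by 3, starting at codon
#' position 1). Codons containing \code{N} translate to \code{X}. A
#' terminal stop codon is removed and flagged in the \code{terminalStop}
#' attribute; internal stops are kept as \code{*}, flagged in the
#' \code{internalStops} attribute (1-based codon indices), and raise a
#' warning.
#'
#' @param nt Coding sequence (character, \code{DNAString} or length-1
#'   \code{DNAStringSet}).
#' @return Protein string (character scalar) with attributes
#'   \code{terminalStop} (logical) and \code{internalStops} (integer).
#' @examples
#' translateCds("ATGGAA")  # "ME"
#' @export
translateCds <- function(nt) {
  s <- seqToChar(nt, "CDS")
  n <- nchar(s)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") not divisible by 3", call. = FALSE)
  }
  cods <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- translateCodons(cods)
  terminal <- FALSE
  if (length(aa) && aa[length(aa)] == "*") {
    terminal <- TRUE
    aa <- aa[-length(aa)]
  }
  internal <- which(aa == "*")
  if (length(internal)) {
    warning("internal stop codon(s) at codon position(s) ",
            paste(internal, collapse = ", "), call. = FALSE)
  }
  structure(paste(aa, collapse = ""),
            terminalStop = terminal,
            internalStops = as.integer(internal))
}

#' Thread coding sequences through a protein alignment
#'
#' Converts an amino-acid alignment to a codon-aware nucleotide alignment
#' (back-translation): each residue expands to its source codon and each
#' protein gap to \code{---}. Every ungapped protein row must equal the
#' translation of its CDS (ignoring a terminal stop, which is dropped from
#' the nucleotide row as well).
#'
#' @param proteinAln Named character vector of gap-padded protein rows of
#'   equal length.
#' @param cds Coding sequences with matching names (named character vector,
#'   list, or \code{DNAStringSet}).
#' @return A \linkS4class{CodonAlignment}.
#' @examples
#' codonRows(codonAlign(c(x = "M-E", y = "MKE"),
#'                      c(x = "ATGGAA", y = "ATGAAAGAA")))
#' @export
codonAlign <- function(proteinAln, cds) {
  if (is.null(names(proteinAln)) || anyDuplicated(names(proteinAln))) {
    stop("protein rows must have unique names", call. = FALSE)
  }
  cds <- panelToChars(cds)
  missing <- setdiff(names(proteinAln), names(cds))
  if (length(missing)) {
    stop("no CDS supplied for row(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(nchar(proteinAln))) > 1L) {
    stop("protein rows differ in length", call. = FALSE)
  }
  rows <- vapply(names(proteinAln), function(id) {
    prot <- chars(toupper(proteinAln[[id]]))
    s <- cds[[id]]
    n <- nchar(s)
    if (n %% 3L != 0L) {
      stop("CDS for ", id, " not divisible by 3", call. = FALSE)
    }
    cods <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- translateCodons(cods)
    if (length(aa) && aa[length(aa)] == "*") {
      aa <- aa[-length(aa)]
      cods <- cods[-length(cods)]
    }
    res <- prot[prot != "-"]
    if (length(res) != length(aa) || any(res != aa)) {
      bad <- if (length(res) != length(aa)) {
        min(length(res), length(aa)) + 1L
      } else {
        which(res != aa)[1L]
      }
      stop("protein/CDS mismatch for ", id, " at residue ", bad,
           call. = FALSE)
    }
    out <- character(length(prot))
    out[prot == "-"] <- "---"
    out[prot != "-"] <- cods
    paste(out, collapse = "")
  }, "")
  methods::new("CodonAlignment", aln = rows)
}

#' Classify a codon substitution
#'
#' Compares a reference and alternative codon: \code{none} when identical,
#' \code{synonymous}/\code{nonsynonymous} (by amino-acid comparison) when
#' exactly one position differs, \code{multi_hit} when two or more differ.
#' Pairs in which either codon is a stop are flagged as \code{stop} rather
#' than silently classified.
#'
#' @param refCodon,altCodon Character vectors of sense codons (recycled to
#'   a common length).
#' @return Character vector over
#'   \code{none, synonymous, nonsynonymous, multi_hit, stop}.
#' @examples
#' classifyCodonChange("GAA", "GAG")  # synonymous (both Glu)
#' classifyCodonChange("GAA", "GTA")  # nonsynonymous (Glu -> Val)
#' @export
classifyCodonChange <- function(refCodon, altCodon) {
  refCodon <- toupper(refCodon)
  altCodon <- toupper(altCodon)
  n <- max(length(refCodon), length(altCodon))
  refCodon <- rep_len(refCodon, n)
  altCodon <- rep_len(altCodon, n)
  if (any(nchar(refCodon) != 3L) || any(nchar(altCodon) != 3L)) {
    stop("codons must be 3 characters long", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", c(refCodon, altCodon)))) {
    stop("codons must be over {A,C,G,T}", call. = FALSE)
  }
  nd <- integer(n)
  for (k in 1:3) {
    nd <- nd + (substr(refCodon, k, k) != substr(altCodon, k, k))
  }
  aaRef <- translateCodons(refCodon)
  aaAlt <- translateCodons(altCodon)
  out <- character(n)
  out[nd == 0L] <- "none"
  isStop <- aaRef == "*" | aaAlt == "*"
  out[nd > 0L & isStop] <- "stop"
  one <- nd == 1L & !isStop
  out[one & aaRef == aaAlt] <- "synonymous"
  out[one & aaRef != aaAlt] <- "nonsynonymous"
  out[nd >= 2L & !isStop] <- "multi_hit"
  out
}

## Net amino-acid effect of a (possibly multi-hit) codon substitution:
## "nonsynonymous" if the encoded residue changes, else "synonymous".
## Stop-involving pairs count as nonsynonymous (truncation/readthrough
## changes the protein) and are tallied by the caller.
netCodonEffect <- function(refCodon, altCodon) {
  aaRef <- translateCodons(refCodon)
  aaAlt <- translateCodons(altCodon)
  ifelse(aaRef == aaAlt, "synonymous", "nonsynonymous")
}
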