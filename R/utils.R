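## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")
SENSE_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
        1L, paste, collapse = ""),
  STOP_CODONS)

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number stream seeded at
#' \code{seed}, then restores the previous stream so callers' randomness is
#' unaffected. All simulators route their randomness through this helper so
#' that every generated dataset is a pure function of its seed.
#'
#' @param seed Integer seed, or \code{NULL} to run without re-seeding.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

## Coerce a sequence input (character scalar, DNAString, length-1
## DNAStringSet) to an uppercase character scalar, validating the alphabet.
seqToChar <- function(x, what = "sequence") {
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1L) {
      stop("expected a single ", what, ", got ", length(x), call. = FALSE)
    }
    x <- x[[1L]]
  }
  if (methods::is(x, "DNAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L) {
    stop(what, " must be a single character string or DNAString",
         call. = FALSE)
  }
  x <- toupper(x)
  if (nchar(x) == 0L) stop(what, " is empty", call. = FALSE)
  if (grepl("[^ACGTN]", x)) {
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  x
}

## Split a sequence/alignment row into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

## Named list of panel sequences as character vectors, from a DNAStringSet,
## named character vector or named list.
panelToChars <- function(panel) {
  if (methods::is(panel, "DNAStringSet")) {
    out <- as.character(panel)
  } else if (is.list(panel)) {
    out <- vapply(panel, function(s) seqToChar(s, "panel sequence"), "")
  } else if (is.character(panel)) {
    out <- toupper(panel)
  } else {
    stop("panel must be a DNAStringSet, character vector or list",
         call. = FALSE)
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("panel sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(out))) {
    stop("duplicate ids in panel", call. = FALSE)
  }
  out
}

pkgVersionString <- function() {
  as.character(utils::packageVersion("tractScan"))
}
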