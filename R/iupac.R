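#' @keywords internal
"_PACKAGE"

# IUPAC degeneracy map.  Codes expand to concrete bases only: an N in a
# *sequence window* belongs to no expansion and therefore never matches any
# consensus position (masked bases cannot support a site call).
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

is_iupac <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  all(chars %in% names(IUPAC_CODES))
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements every IUPAC degeneracy code (R to Y, S to S, W to W, K to M,
#' N to N, ...) and reverses the string, so the operation is an involution.
#'
#' @param seq A single character string over the IUPAC alphabet
#'   (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).  Case-insensitive; the result is
#'   uppercase.  The empty string maps to itself.
#' @return The reverse complement as a character string.
#' @examples
#' reverse_complement("GATGAG")   # "CTCATC"
#' reverse_complement("RYSWKM")   # involutive degenerate codes
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% names(IUPAC_COMPLEMENT))
  if (any(bad)) {
    stop("non-IUPAC character(s) in sequence: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Test whether a sequence window matches an IUPAC consensus
#'
#' A window position matches when its base is in the expansion of the
#' consensus code at that position; N in the window matches nothing.  The
#' window matches overall when the number of mismatching positions is at
#' most `max_mismatches`.
#'
#' @param window DNA string (A,C,G,T,N), same length as `consensus`.
#' @param consensus IUPAC consensus string.
#' @param max_mismatches Maximum number of tolerated mismatching positions.
#' @return `TRUE` or `FALSE`.
#' @examples
#' iupac_matches("GATGAG", "GATRAG", 0)  # TRUE, R allows G
#' iupac_matches("GATAAG", "GATGAG", 1)  # TRUE with one mismatch allowed
#' @export
iupac_matches <- function(window, consensus, max_mismatches = 0L) {
  window <- toupper(window)
  consensus <- toupper(consensus)
  if (nchar(window) != nchar(consensus)) {
    stop("window and consensus have different lengths (",
         nchar(window), " vs ", nchar(consensus), ")")
  }
  wc <- strsplit(window, "", fixed = TRUE)[[1]]
  cc <- strsplit(consensus, "", fixed = TRUE)[[1]]
  if (!all(cc %in% names(IUPAC_CODES))) {
    stop("invalid IUPAC character in consensus: ",
         paste(unique(cc[!(cc %in% names(IUPAC_CODES))]), collapse = ", "))
  }
  mm <- sum(vapply(seq_along(cc),
                   function(j) !(wc[j] %in% IUPAC_CODES[[cc[j]]]),
                   logical(1)))
  mm <= max_mismatches
}

# Restore the RNG state on exit so seeded helpers do not perturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
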