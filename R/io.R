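# Coordinate convention used throughout: upstream regions are stored 5'->3'
# on the gene's strand, index 0 is the most upstream base and index
# length-1 abuts the translation start.  Feature coordinates are 0-based,
# end-exclusive; dist_to_atg = region_length - end (bases between the
# feature's 3' edge and the ATG).

OCC_COLUMNS <- c("gene_id", "motif", "start", "end", "strand",
                 "mismatches", "dist_to_atg")

#' Read upstream-region sequences from a FASTA file
#'
#' One record per gene, sequence written 5'->3' in the gene's reading
#' direction with the last base adjacent to the translation start.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @param expected_length Optional expected region length in bp.  Shorter
#'   records are kept with their actual length; a warning lists them.
#' @return A named [Biostrings::DNAStringSet] (names are gene ids,
#'   sequences uppercase).
#' @export
read_upstream_fasta <- function(path, expected_length = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  # keep only the first whitespace-delimited token of the header
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup) > 0L) {
    stop("duplicate gene id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ",
         paste(names(x)[bad], collapse = ", "))
  }
  x <- Biostrings::DNAStringSet(seqs)
  if (!is.null(expected_length)) {
    short <- Biostrings::width(x) != expected_length
    if (any(short)) {
      warning(sum(short), " record(s) differ from expected length ",
              expected_length, " (e.g. ", names(x)[short][1], "=",
              Biostrings::width(x)[short][1], " bp); actual lengths kept")
    }
  }
  x
}

#' Write upstream regions to FASTA
#'
#' @param regions Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_upstream_fasta <- function(regions, path) {
  regions <- as_dna_set(regions)
  Biostrings::writeXStringSet(regions, path)
  invisible(path)
}

as_dna_set <- function(regions) {
  if (methods::is(regions, "DNAStringSet")) return(regions)
  stopifnot(is.character(regions), !is.null(names(regions)))
  Biostrings::DNAStringSet(toupper(regions))
}

# named uppercase character vector view of a region set
region_chars <- function(regions) {
  if (methods::is(regions, "DNAStringSet")) {
    stats::setNames(as.character(regions), names(regions))
  } else {
    stopifnot(is.character(regions), !is.null(names(regions)))
    toupper(regions)
  }
}

region_lengths <- function(regions) {
  x <- region_chars(regions)
  stats::setNames(nchar(x), names(x))
}

#' Construct a set of motif models
#'
#' A motif model is a named IUPAC consensus plus an allowed number of
#' mismatches.  Arguments are either bare consensus strings (0 mismatches)
#' or lists `list(consensus =, max_mismatches =)`.
#'
#' @param ... Named motif definitions.
#' @return A `motif_set` data frame with columns `name`, `consensus`,
#'   `width`, `max_mismatches`.
#' @examples
#' motif_set(PAC = "GATGAG", R9 = list(consensus = "AAAAWTTTT",
#'                                     max_mismatches = 1))
#' @export
motif_set <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && is.null(names(defs)) && is.list(defs[[1]]) &&
      !is.null(names(defs[[1]]))) {
    defs <- defs[[1]]                      # a single named list was passed
  }
  if (length(defs) == 0L) stop("no motif definitions given")
  nm <- names(defs)
  if (is.null(nm) || any(nm == "")) stop("all motifs must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate motif name(s): ", paste(unique(nm[duplicated(nm)]),
                                            collapse = ", "))
  }
  rows <- lapply(seq_along(defs), function(i) {
    d <- defs[[i]]
    if (is.character(d)) d <- list(consensus = d, max_mismatches = 0L)
    cons <- toupper(d$consensus)
    mm <- as.integer(d$max_mismatches %||% 0L)
    if (!is_iupac(cons) || nchar(cons) == 0L) {
      stop("invalid IUPAC consensus for motif ", nm[i], ": ", cons)
    }
    if (mm < 0L || mm >= nchar(cons)) {
      stop("max_mismatches for motif ", nm[i],
           " must be in [0, width): got ", mm)
    }
    data.frame(name = nm[i], consensus = cons, width = nchar(cons),
               max_mismatches = mm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("motif_set", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Motif definitions shipped by default
#'
#' PAC (polymerase A/C box, consensus GATGAG) and its single-nucleotide
#' variant PAC2 (GATAAG), both with 0 allowed mismatches.  RRPE is A/T-rich
#' and has no universally agreed consensus, so it is only included when one
#' is supplied.
#'
#' @param rrpe Optional IUPAC consensus for RRPE.
#' @param rrpe_max_mismatches Allowed mismatches for the RRPE consensus.
#' @return A `motif_set`.
#' @export
default_motifs <- function(rrpe = NULL, rrpe_max_mismatches = 0L) {
  defs <- list(PAC = "GATGAG", PAC2 = "GATAAG")
  if (!is.null(rrpe)) {
    defs$RRPE <- list(consensus = rrpe, max_mismatches = rrpe_max_mismatches)
  }
  motif_set(defs)
}

#' Load motif definitions from a file or an inline mapping
#'
#' Accepts a TSV file with columns `name`, `consensus` and optional
#' `max_mismatches`; a JSON file mapping names to consensus strings or to
#' objects with `consensus`/`max_mismatches`; or an in-memory named
#' list/vector.
#'
#' @param x File path or named list/character vector.
#' @return A `motif_set`.
#' @export
load_motif_definitions <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (grepl("\\.json$", x, ignore.case = TRUE)) {
      defs <- jsonlite::read_json(x, simplifyVector = FALSE)
      return(motif_set(defs))
    }
    tab <- utils::read.delim(x, stringsAsFactors = FALSE)
    if (!all(c("name", "consensus") %in% names(tab))) {
      stop("motif TSV must have columns: name, consensus")
    }
    if (is.null(tab$max_mismatches)) tab$max_mismatches <- 0L
    defs <- lapply(seq_len(nrow(tab)), function(i) {
      list(consensus = tab$consensus[i], max_mismatches = tab$max_mismatches[i])
    })
    names(defs) <- tab$name
    return(motif_set(defs))
  }
  motif_set(as.list(x))
}

motif_row <- function(motifs, name) {
  i <- match(name, motifs$name)
  if (is.na(i)) stop("unknown motif: ", name)
  motifs[i, , drop = FALSE]
}

empty_occurrences <- function() {
  data.frame(gene_id = character(), motif = character(),
             start = integer(), end = integer(), strand = character(),
             mismatches = integer(), dist_to_atg = integer(),
             stringsAsFactors = FALSE)
}

validate_occurrences <- function(occ) {
  miss <- setdiff(setdiff(OCC_COLUMNS, "dist_to_atg"), names(occ))
  if (length(miss) > 0L) {
    stop("occurrence table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(occ$strand %in% c("+", "-")))
  if (length(bad) > 0L) {
    stop("invalid strand value in row ", bad[1], ": '", occ$strand[bad[1]],
         "' (must be + or -)")
  }
  if (any(occ$start < 0L) || any(occ$end <= occ$start)) {
    stop("occurrence coordinates must satisfy 0 <= start < end")
  }
  occ
}

#' Write a motif occurrence table to TSV
#'
#' Columns: gene_id, motif, start, end, strand, mismatches, dist_to_atg.
#' Coordinates are 0-based, end-exclusive, on the upstream string; strand is
#' relative to the gene.
#'
#' @param occ Occurrence data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  if (nrow(occ) > 0L) validate_occurrences(occ)
  cols <- intersect(OCC_COLUMNS, names(occ))
  utils::write.table(occ[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif occurrence table from TSV
#'
#' @param path Path to a TSV written by [write_occurrences()] (or following
#'   the same schema).
#' @return Occurrence data frame; malformed rows raise an error naming the
#'   first offending line.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  occ <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(occ) == 0L) return(empty_occurrences())
  for (col in c("start", "end", "mismatches", "dist_to_atg")) {
    if (is.null(occ[[col]])) next
    v <- suppressWarnings(as.integer(occ[[col]]))
    bad <- which(is.na(v) & !is.na(occ[[col]]))
    if (length(bad) > 0L) {
      stop("malformed ", col, " at line ", bad[1] + 1L, " of ", path)
    }
    occ[[col]] <- v
  }
  tryCatch(validate_occurrences(occ),
           error = function(e) stop("in ", path, ": ", conditionMessage(e)))
  occ
}

#' Read a gene-to-annotation-term table
#'
#' @param path TSV with columns `gene_id` and `term` (one row per
#'   gene-term assignment).
#' @return Data frame with columns `gene_id`, `term`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term") %in% names(ann))) {
    stop("annotation TSV must have columns: gene_id, term")
  }
  if (any(!nzchar(ann$term))) stop("empty annotation term(s) in ", path)
  ann[, c("gene_id", "term")]
}

#' Write a module instance table to TSV
#' @param modules Module data frame from [pair_occurrences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  utils::write.table(modules, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a module instance table from TSV
#' @param path Path to a TSV written by [write_modules()].
#' @return Module data frame.
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) stop("module file not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(m) > 0L) m$same_strand <- as.logical(m$same_strand)
  m
}
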