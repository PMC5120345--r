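#' Sequence panels
#'
#' A sequence panel is a data.frame (class `seq_panel`) with one row per
#' aligned marker sequence: columns `id`, `species` (`"UNKNOWN"` for query
#' specimens), `marker` (`"COI"` or `"NADH2"`) and `residues` (uppercase
#' string over `A C G T N -`). Sequences of a panel share a marker; ids are
#' unique within a panel.
#'
#' @param id character vector of unique, non-empty sequence ids.
#' @param residues character vector of aligned sequences (case-insensitive
#'   on input; stored uppercase).
#' @param species species labels, or `"UNKNOWN"`; recycled if length 1.
#' @param marker `"COI"` or `"NADH2"`.
#' @return A `seq_panel` data.frame.
#' @export
seq_panel <- function(id, residues, species = "UNKNOWN",
                      marker = c("COI", "NADH2")) {
  marker <- match.arg(marker)
  id <- as.character(id)
  if (length(id) == 0) stop("empty panel")
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1])
  residues <- toupper(as.character(residues))
  if (length(residues) != length(id)) stop("id / residues length mismatch")
  if (any(!nzchar(residues))) stop("empty sequence for id ",
                                   id[!nzchar(residues)][1])
  bad <- regexpr("[^ACGTN-]", residues)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("illegal character '", substr(residues[i], bad[i], bad[i]),
         "' at position ", bad[i], " in record ", id[i])
  }
  species <- rep_len(as.character(species), length(id))
  structure(
    data.frame(id = id, species = species, marker = marker,
               residues = residues, stringsAsFactors = FALSE),
    class = c("seq_panel", "data.frame")
  )
}

#' Read aligned marker sequences from a FASTA file
#'
#' Standard multi-line FASTA. The header dialect is
#' `>id [species=Genus_species]`: the first whitespace-delimited token is
#' the sequence id and an optional `species=` token supplies the species
#' label (absent token = `"UNKNOWN"`, i.e. a query specimen). Only DNA
#' residues `A C G T N -` are accepted (case-insensitive; `U` is rejected).
#'
#' @param path path to a FASTA file.
#' @param marker `"COI"` or `"NADH2"`.
#' @return A [seq_panel()].
#' @export
read_fasta <- function(path, marker = c("COI", "NADH2")) {
  marker <- match.arg(marker)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  species <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("species=\\S+", h))
    if (length(m)) sub("^species=", "", m) else "UNKNOWN"
  }, character(1), USE.NAMES = FALSE)
  seq_panel(id, as.character(x), species, marker)
}

#' Write a sequence panel to FASTA
#'
#' @param panel a [seq_panel()].
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(panel, path, width = 70) {
  stopifnot(inherits(panel, "seq_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(panel))) {
    hdr <- paste0(">", panel$id[i])
    if (panel$species[i] != "UNKNOWN")
      hdr <- paste0(hdr, " species=", panel$species[i])
    writeLines(hdr, con)
    s <- panel$residues[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# integer coding of an aligned panel: L x n matrix, 0=A 1=C 2=G 3=T 4=N/gap
.seq_codes <- local({
  lut <- rep(4L, 127)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  function(residues) {
    L <- unique(nchar(residues))
    if (length(L) != 1)
      stop("sequences are not aligned (unequal lengths: ",
           paste(sort(L), collapse = ", "), ")")
    vapply(residues, function(s) lut[utf8ToInt(s)], integer(L),
           USE.NAMES = FALSE)
  }
})

.decode_seq <- function(codes) {
  chartr("01234", "ACGTN", paste(codes, collapse = ""))
}
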