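#' Read a multiple sequence alignment
#'
#' Reads a gapped alignment from FASTA (via \pkg{seqinr}) or relaxed
#' sequential PHYLIP (name and sequence separated by whitespace, names of any
#' length). Sequence order is preserved from the file; residues are
#' upper-cased and \code{"."} gaps normalised to \code{"-"}.
#'
#' @param path file path.
#' @param format \code{"fasta"} or \code{"phylip"}; by default guessed from
#'   the file extension (\code{.phy}/\code{.phylip} select PHYLIP).
#' @param label source label for the alignment; defaults to the file name
#'   without extension.
#' @return an \code{msa} object.
#' @export
read_alignment <- function(path, format = c("guess", "fasta", "phylip"),
                           label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "guess") {
    format <- if (grepl("\\.(phy|phylip)$", path, ignore.case = TRUE))
      "phylip" else "fasta"
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  rows <- switch(format,
    fasta = {
      seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                                 set.attributes = FALSE)
      if (length(seqs) == 0) stop("no sequences in ", path)
      stats::setNames(unlist(seqs), names(seqs))
    },
    phylip = read_relaxed_phylip(path))
  msa(rows, label = label)
}

# relaxed sequential PHYLIP: header "ntaxa ncols", then one record per taxon;
# a record may span lines, its name is the first whitespace token
read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("empty or truncated PHYLIP file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stop("malformed PHYLIP header in ", path)
  ntax <- hdr[1]; ncols <- hdr[2]
  body <- lines[-1]
  ids <- character(ntax); rows <- character(ntax)
  i <- 0L
  for (ln in body) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (i == 0L || nchar(rows[i]) >= ncols) {
      i <- i + 1L
      if (i > ntax) stop("more records than the PHYLIP header declares in ", path)
      ids[i] <- toks[1]
      rows[i] <- paste(toks[-1], collapse = "")
    } else {
      rows[i] <- paste0(rows[i], paste(toks, collapse = ""))
    }
  }
  if (i < ntax) stop("fewer records (", i, ") than the PHYLIP header declares (",
                     ntax, ") in ", path)
  bad <- which(nchar(rows) != ncols)
  if (length(bad))
    stop("row '", ids[bad[1]], "' has ", nchar(rows[bad[1]]),
         " characters, PHYLIP header declares ", ncols)
  stats::setNames(rows, ids)
}

#' Write a multiple sequence alignment
#'
#' @param x an \code{msa} object.
#' @param path output file path.
#' @param format \code{"fasta"} or \code{"phylip"} (relaxed sequential).
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(x, path, format = c("fasta", "phylip")) {
  stopifnot(inherits(x, "msa"))
  format <- match.arg(format)
  rows <- msa_strings(x)
  if (format == "fasta") {
    seqinr::write.fasta(as.list(unname(rows)), names = names(rows),
                        file.out = path, nbchar = 80)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(length(rows), x$length), con)
    writeLines(paste(names(rows), rows), con)
  }
  invisible(path)
}
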